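# Readers and writers for the standard formats: FASTA (Biostrings), TSV
# tables (tab-delimited, UTF-8, header row), newick trees (ape), JSON run
# logs and ground truth (jsonlite).

#' Read phased allele FASTA plus a sample-to-group mapping
#'
#' FASTA record ids carry sample and allele labels as
#' `sampleID<delim>alleleIndex`; the groups TSV has columns `sample_id` and
#' `group`. Sequences are uppercased and U is normalized to T. Records whose
#' sample lacks a group row are an error.
#'
#' @param fasta_path Path to a nucleotide FASTA, one record per phased
#'   allele.
#' @param groups_path Path to the mapping TSV.
#' @param delim Delimiter between sample id and allele index in record names
#'   (default `"."`, the last occurrence splits).
#' @return Data frame: `seq_id`, `sample_id`, `allele_index`, `group`,
#'   `sequence`.
#' @export
read_grouped_fasta <- function(fasta_path, groups_path, delim = ".") {
  if (!file.exists(fasta_path)) abort2(paste("no such file:", fasta_path),
                                       "missing_file")
  # BStringSet: accept lower case and RNA 'u' for normalization below
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) abort2("empty FASTA", "empty_file")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort2(paste("duplicate record ids:",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
           "duplicate_ids")
  }
  parts <- strsplit(ids, delim, fixed = TRUE)
  sample_id <- vapply(parts, function(p)
    if (length(p) > 1L) paste(p[-length(p)], collapse = delim) else p, "")
  allele_index <- vapply(parts, function(p)
    if (length(p) > 1L) p[length(p)] else "1", "")
  groups <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(groups))) {
    abort2("groups TSV needs columns sample_id, group", "bad_input")
  }
  miss <- setdiff(sample_id, groups$sample_id)
  if (length(miss)) {
    abort2(paste("no group mapping for sample(s):",
                 paste(unique(miss), collapse = ", ")), "missing_mapping")
  }
  data.frame(
    seq_id = ids, sample_id = sample_id, allele_index = allele_index,
    group = groups$group[match(sample_id, groups$sample_id)],
    sequence = chartr("U", "T", toupper(as.character(seqs))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Read a grouped allele spectrum TSV
#'
#' Expects columns `group`, `allele`, `count` (positive integer counts);
#' extra columns are carried through as attributes. Each row expands into
#' `count` per-sequence labels.
#'
#' @param tsv_path Path to the spectrum TSV.
#' @return A [grouped_spectrum()]; attribute `counts` holds the raw table
#'   and attribute `group_totals` the per-group sequence totals.
#' @export
read_spectrum_table <- function(tsv_path) {
  if (!file.exists(tsv_path)) abort2(paste("no such file:", tsv_path),
                                     "missing_file")
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) abort2("empty spectrum table", "empty_file")
  spec <- spectrum_from_counts(tab)
  attr(spec, "counts") <- tab
  attr(spec, "group_totals") <- vapply(spec$groups, length, integer(1))
  spec
}

#' Write a named character vector of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Published Pan PRDM9 allele spectrum
#'
#' The grouped allele-occurrence table for 81 Pan PRDM9 sequences (eastern,
#' central and western chimpanzees plus bonobos; 10/7/52/12 sequences per
#' group). Allele labels encode identity: the one nucleotide allele shared
#' between the central and eastern samples carries the same label in both
#' groups, and the `aa_allele` column records the amino-acid-level collapses
#' (two synonymous-only pairs).
#'
#' @param level `"nt"` (default) or `"aa"`: which label column to use.
#' @return A [grouped_spectrum()] (attribute `counts` holds the raw table).
#' @export
pan_prdm9_spectrum <- function(level = c("nt", "aa")) {
  level <- match.arg(level)
  path <- system.file("extdata", "pan_prdm9_spectrum.tsv",
                      package = "prdm9znf", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (level == "aa") {
    agg <- stats::aggregate(count ~ group + aa_allele, tab, sum)
    names(agg)[names(agg) == "aa_allele"] <- "allele"
    # keep the published group order
    agg$group <- factor(agg$group, levels = unique(tab$group))
    agg <- agg[order(agg$group), ]
    agg$group <- as.character(agg$group)
    tab <- agg
  }
  spec <- spectrum_from_counts(tab[, c("group", "allele", "count")])
  attr(spec, "counts") <- tab
  spec
}
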