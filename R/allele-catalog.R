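# Collapsing phased array sequences into unique nucleotide / amino-acid
# alleles, repeat-letter encodings, polymorphic-site and sharing reports.
#
# Allele identity is exact full-length string equality (length variants are
# distinct alleles); there is no alignment-based clustering.

#' Collapse labelled sequences into unique nucleotide alleles
#'
#' @param sequences Data frame with columns `sequence`, `sample_id`, `group`
#'   (one row per phased allele sequence). Sequences must be ambiguity-free;
#'   rows carrying IUPAC ambiguity codes raise an error (validate and filter
#'   first, see [validate_array()]).
#' @param prefix Label prefix for allele ids (default `"p"`, giving
#'   `p1..pk` by descending count then lexicographic sequence).
#' @param labels Optional named character vector mapping canonical sequence
#'   to a user label (e.g. published allele names), overriding the automatic
#'   ids.
#' @return Data frame of class `nt_allele_table`: `nt_allele_id`, `sequence`,
#'   `count`, `groups` (comma-separated, sorted), `samples`.
#' @export
collapse_to_nt_alleles <- function(sequences, prefix = "p", labels = NULL) {
  if (nrow(sequences) == 0L) {
    out <- data.frame(nt_allele_id = character(), sequence = character(),
                      count = integer(), groups = character(),
                      samples = character(), stringsAsFactors = FALSE)
    class(out) <- c("nt_allele_table", class(out))
    return(out)
  }
  if (any(has_ambiguity(sequences$sequence))) {
    abort2("input contains IUPAC ambiguity codes; reject those alleles first",
           "ambiguous_sequence")
  }
  sp <- split(sequences, sequences$sequence)
  out <- data.frame(
    sequence = names(sp),
    count = vapply(sp, nrow, integer(1)),
    groups = vapply(sp, function(d)
      paste(sort(unique(d$group)), collapse = ","), character(1)),
    samples = vapply(sp, function(d)
      paste(sort(d$sample_id), collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  out$nt_allele_id <- paste0(prefix, seq_len(nrow(out)))
  if (!is.null(labels)) {
    hit <- match(out$sequence, names(labels))
    out$nt_allele_id[!is.na(hit)] <- unname(labels[hit[!is.na(hit)]])
  }
  out <- out[, c("nt_allele_id", "sequence", "count", "groups", "samples")]
  rownames(out) <- NULL
  class(out) <- c("nt_allele_table", class(out))
  out
}

#' Collapse a nucleotide allele table to amino-acid alleles
#'
#' Nucleotide alleles whose full-length translations are identical (i.e.
#' differing only by synonymous substitutions) merge into one amino-acid
#' allele; counts are summed and group sets unioned.
#'
#' @param nt_table An `nt_allele_table` from [collapse_to_nt_alleles()].
#' @param prefix Label prefix (default `"P"`).
#' @param truncated_leading Do the sequences start with a truncated leading
#'   repeat? Passed to the translation frame logic ([translate_repeats()]);
#'   the default `FALSE` translates from the first base.
#' @return Data frame of class `aa_allele_table`: `aa_allele_id`, `aa_seq`,
#'   `count`, `nt_allele_ids` (comma-separated), `groups`.
#' @export
collapse_to_aa_alleles <- function(nt_table, prefix = "P",
                                   truncated_leading = FALSE) {
  if (nrow(nt_table) == 0L) {
    out <- data.frame(aa_allele_id = character(), aa_seq = character(),
                      count = integer(), nt_allele_ids = character(),
                      groups = character(), stringsAsFactors = FALSE)
    class(out) <- c("aa_allele_table", class(out))
    return(out)
  }
  aa <- vapply(nt_table$sequence, function(s) {
    if (truncated_leading) {
      off <- nchar(s) %% 3L
      if (off > 0L) s <- substr(s, off + 1L, nchar(s))
    }
    translate_nt(s)
  }, character(1), USE.NAMES = FALSE)
  sp <- split(seq_len(nrow(nt_table)), aa)
  out <- data.frame(
    aa_seq = names(sp),
    count = vapply(sp, function(i) sum(nt_table$count[i]), integer(1)),
    nt_allele_ids = vapply(sp, function(i)
      paste(nt_table$nt_allele_id[i], collapse = ","), character(1)),
    groups = vapply(sp, function(i)
      paste(sort(unique(unlist(strsplit(nt_table$groups[i], ",")))),
            collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$count, out$aa_seq), , drop = FALSE]
  out$aa_allele_id <- paste0(prefix, seq_len(nrow(out)))
  out <- out[, c("aa_allele_id", "aa_seq", "count", "nt_allele_ids", "groups")]
  rownames(out) <- NULL
  class(out) <- c("aa_allele_table", class(out))
  out
}

#' Encode alleles as repeat-letter strings
#'
#' Assigns one letter per distinct amino-acid repeat sequence, in
#' first-encounter order over the alleles as given (callers wanting a
#' canonical order should sort first). Distinct nucleotide variants of the
#' same letter (synonymous variants) are suffixed with asterisks: the first
#' encountered nucleotide sequence is the plain letter, later ones `A*`,
#' `A**`, ... The truncated leading repeat, when present, is excluded.
#'
#' @param alleles List of translated [znf_allele()] objects.
#' @return List of class `repeat_letter_encoding` with elements `encodings`
#'   (named list, one character vector of symbols per allele) and `legend`
#'   (data frame `symbol`, `letter`, `aa_seq`, `nt_seq`).
#' @export
assign_repeat_letters <- function(alleles) {
  letters_pool <- c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))
  aa2letter <- character()   # aa_seq -> letter
  nt2symbol <- character()   # nt_seq -> full symbol
  legend <- list()
  encodings <- lapply(alleles, function(al) {
    vapply(full_repeats(al), function(r) {
      if (is.na(r$aa_seq)) abort2("repeats must be translated first",
                                  "bad_input")
      if (!r$nt_seq %in% names(nt2symbol)) {
        if (!r$aa_seq %in% names(aa2letter)) {
          aa2letter[r$aa_seq] <<- letters_pool[length(aa2letter) + 1L]
        }
        letter <- aa2letter[[r$aa_seq]]
        n_var <- if (length(legend))
          sum(vapply(legend, function(x) x$letter == letter, logical(1)))
        else 0L
        symbol <- paste0(letter, strrep("*", n_var))
        nt2symbol[r$nt_seq] <<- symbol
        legend[[length(legend) + 1L]] <<- data.frame(
          symbol = symbol, letter = letter, aa_seq = r$aa_seq,
          nt_seq = r$nt_seq, stringsAsFactors = FALSE)
      }
      nt2symbol[[r$nt_seq]]
    }, character(1))
  })
  names(encodings) <- vapply(alleles, `[[`, character(1), "allele_id")
  structure(list(encodings = encodings,
                 legend = do.call(rbind, legend)),
            class = "repeat_letter_encoding")
}

#' @export
print.repeat_letter_encoding <- function(x, ...) {
  for (id in names(x$encodings)) {
    cat(sprintf("%s: %s\n", id, paste(x$encodings[[id]], collapse = "-")))
  }
  invisible(x)
}

#' Polymorphic sites in an alignment of full repeats
#'
#' @param repeats_aa Character vector of equal-length amino-acid repeat
#'   sequences (truncated leading repeats must be excluded by the caller).
#' @param contact_offsets Absolute 0-based columns counted as DNA-contact
#'   positions (default: positions -1, 3 and 6 located on the first repeat
#'   via [contact_columns()]; position 2 is excluded because it is fixed).
#' @return List of class `polymorphic_site_report`: `columns` (0-based
#'   polymorphic columns), `n_polymorphic`, `n_at_contact`,
#'   `fraction_at_contact`.
#' @export
find_polymorphic_sites <- function(repeats_aa, contact_offsets = NULL) {
  if (length(repeats_aa) == 0L) abort2("no repeats", "bad_input")
  L <- unique(nchar(repeats_aa))
  if (length(L) != 1L) {
    abort2("ragged alignment: repeats differ in length", "ragged_alignment")
  }
  if (is.null(contact_offsets)) {
    co <- default_contact_offsets()
    contact_offsets <- contact_columns(repeats_aa[1L],
                                       co[c("pos_minus1", "pos3", "pos6")])
  }
  m <- do.call(rbind, strsplit(repeats_aa, ""))
  poly <- which(apply(m, 2L, function(col) length(unique(col)) > 1L)) - 1L
  n_contact <- sum(poly %in% contact_offsets)
  structure(
    list(columns = poly, n_polymorphic = length(poly),
         n_at_contact = n_contact,
         fraction_at_contact = if (length(poly)) n_contact / length(poly)
                               else NA_real_,
         contact_offsets = contact_offsets),
    class = "polymorphic_site_report"
  )
}

#' Alleles shared across groups
#'
#' @param nt_table,aa_table Allele tables from [collapse_to_nt_alleles()] and
#'   [collapse_to_aa_alleles()] (either may be `NULL`).
#' @return Data frame `level` (`"nt"`/`"aa"`), `allele_id`, `groups`; one row
#'   per allele present in more than one group.
#' @export
cross_group_sharing <- function(nt_table = NULL, aa_table = NULL) {
  pick <- function(tab, idcol, level) {
    if (is.null(tab) || nrow(tab) == 0L) return(NULL)
    multi <- vapply(strsplit(tab$groups, ","), length, integer(1)) > 1L
    if (!any(multi)) return(NULL)
    data.frame(level = level, allele_id = tab[[idcol]][multi],
               groups = tab$groups[multi], stringsAsFactors = FALSE)
  }
  out <- rbind(pick(nt_table, "nt_allele_id", "nt"),
               pick(aa_table, "aa_allele_id", "aa"))
  if (is.null(out)) {
    out <- data.frame(level = character(), allele_id = character(),
                      groups = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
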