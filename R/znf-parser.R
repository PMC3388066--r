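# Decomposition of PRDM9 zinc-finger (ZnF) array sequences into repeat units,
# C2H2 scaffold validation and DNA-contact residue extraction.
#
# Conventions: one full repeat is 84 nt / 28 aa. The first repeat of a real
# array is truncated (it lacks the first zinc-coordinating cysteine) and is
# flagged and excluded from "full repeat" counts. All offsets are 0-based.

#' Construct a single ZnF repeat record
#'
#' @param index_in_array 0-based ordinal of the repeat within its array.
#' @param nt_seq Nucleotide sequence (84 nt for a full repeat).
#' @param aa_seq Amino-acid translation, or `NA` if not yet translated.
#' @param is_truncated `TRUE` for the shortened leading repeat.
#' @return An object of class `znf_repeat`.
#' @export
znf_repeat <- function(index_in_array, nt_seq, aa_seq = NA_character_,
                       is_truncated = FALSE) {
  structure(
    list(index_in_array = as.integer(index_in_array), nt_seq = nt_seq,
         aa_seq = aa_seq, is_truncated = isTRUE(is_truncated)),
    class = "znf_repeat"
  )
}

#' @export
print.znf_repeat <- function(x, ...) {
  cat(sprintf("<znf_repeat #%d%s> %s / %s\n", x$index_in_array,
              if (x$is_truncated) " (truncated)" else "",
              x$nt_seq, ifelse(is.na(x$aa_seq), "<untranslated>", x$aa_seq)))
  invisible(x)
}

#' Construct a ZnF array allele
#'
#' @param allele_id,sample_id,group Labels for the allele, the source sample
#'   and its (sub)species group.
#' @param repeats List of [znf_repeat()] objects in array order.
#' @return An object of class `znf_allele`.
#' @export
znf_allele <- function(allele_id, sample_id = NA_character_,
                       group = NA_character_, repeats = list()) {
  structure(
    list(allele_id = allele_id, sample_id = sample_id, group = group,
         repeats = repeats,
         leading_truncated_present = length(repeats) > 0L &&
           repeats[[1L]]$is_truncated),
    class = "znf_allele"
  )
}

#' @export
print.znf_allele <- function(x, ...) {
  cat(sprintf("<znf_allele %s> sample=%s group=%s, %d full repeat(s)%s\n",
              x$allele_id, x$sample_id, x$group, n_full_repeats(x),
              if (x$leading_truncated_present) " + truncated leading repeat"
              else ""))
  invisible(x)
}

#' Number of full (non-truncated) repeats in an allele
#' @param allele A `znf_allele`.
#' @export
n_full_repeats <- function(allele) {
  sum(!vapply(allele$repeats, `[[`, logical(1), "is_truncated"))
}

full_repeats <- function(allele) {
  Filter(function(r) !r$is_truncated, allele$repeats)
}

#' Split a ZnF array sequence into repeat units
#'
#' Cuts an array nucleotide sequence into consecutive `repeat_length`-nt
#' units. If `leading_truncated` is `TRUE`, a shortened leading segment (by
#' default the remainder `nchar(array_nt) %% repeat_length`) is peeled off
#' first and flagged; it does not count as a full repeat.
#'
#' @param array_nt Uppercase nucleotide string for one phased allele.
#' @param repeat_length Repeat unit size in nt (default 84).
#' @param leading_truncated Declare a truncated leading repeat.
#' @param truncated_length Length of the truncated segment; required when the
#'   total length is an exact multiple of `repeat_length`.
#' @return List of [znf_repeat()], in array order; concatenating their
#'   `nt_seq` reproduces `array_nt`.
#' @export
split_into_repeats <- function(array_nt, repeat_length = 84L,
                               leading_truncated = FALSE,
                               truncated_length = NULL) {
  stopifnot_string(array_nt, "array_nt")
  n <- nchar(array_nt)
  lead <- 0L
  if (leading_truncated) {
    lead <- if (is.null(truncated_length)) n %% repeat_length
            else as.integer(truncated_length)
    if (lead <= 0L) {
      abort2(paste("leading_truncated = TRUE but the sequence length is an",
                   "exact repeat multiple; give truncated_length explicitly"),
             "malformed_array", remainder = 0L)
    }
    if (lead >= repeat_length) {
      abort2("truncated leading segment must be shorter than repeat_length",
             "malformed_array", remainder = lead)
    }
  }
  rem <- (n - lead) %% repeat_length
  if (n - lead <= 0L || rem != 0L) {
    abort2(sprintf(
      "array length %d is not a positive multiple of %d after leading-segment handling (remainder %d)",
      n - lead, repeat_length, rem), "malformed_array", remainder = rem)
  }
  k <- (n - lead) %/% repeat_length
  out <- vector("list", k + (lead > 0L))
  j <- 1L
  if (lead > 0L) {
    out[[1L]] <- znf_repeat(0L, substr(array_nt, 1L, lead),
                            is_truncated = TRUE)
    j <- 2L
  }
  starts <- lead + seq(1L, by = repeat_length, length.out = k)
  for (i in seq_len(k)) {
    out[[j + i - 1L]] <- znf_repeat(j + i - 2L,
                                    substr(array_nt, starts[i],
                                           starts[i] + repeat_length - 1L))
  }
  out
}

#' Translate repeats in place
#'
#' Fills the `aa_seq` field of each repeat by standard-genetic-code
#' translation. The truncated leading repeat is translated in the array
#' reading frame: if its length is not a multiple of 3 the out-of-frame
#' leading bases are skipped so that the translated part is in frame with
#' the downstream full repeats.
#'
#' @param repeats List of [znf_repeat()].
#' @return The same list with `aa_seq` filled.
#' @export
translate_repeats <- function(repeats) {
  lapply(repeats, function(r) {
    nt <- r$nt_seq
    if (r$is_truncated) {
      off <- nchar(nt) %% 3L
      if (off > 0L) nt <- substr(nt, off + 1L, nchar(nt))
    }
    aa <- tryCatch(translate_nt(nt), invalid_repeat = function(e) {
      abort2(sprintf("repeat %d: %s", r$index_in_array, conditionMessage(e)),
             "invalid_repeat", repeat_index = r$index_in_array)
    })
    r$aa_seq <- aa
    r
  })
}

#' Locate the C2H2 scaffold of one repeat
#'
#' Matches a configurable C2H2 pattern against the amino-acid sequence of a
#' repeat and returns the 0-based offsets of the two zinc-coordinating
#' cysteines and histidines. Truncated leading repeats lack the first
#' cysteine; for those `cys1` is reported as `NA`.
#'
#' @param repeat_aa Amino-acid string of one repeat.
#' @param truncated Is this the truncated leading repeat?
#' @param pattern,pattern_truncated Regular expressions with capture groups on
#'   the C/H residues (2 cysteines + 2 histidines, or 1 + 2 when truncated).
#' @return List with 0-based offsets `cys1`, `cys2`, `his1`, `his2`
#'   (class `scaffold_positions`).
#' @export
locate_scaffold <- function(repeat_aa, truncated = FALSE,
                            pattern = "(C).{2,4}(C).{12}(H).{3,5}(H)",
                            pattern_truncated = "(C).{12}(H).{3,5}(H)") {
  stopifnot_string(repeat_aa, "repeat_aa")
  pat <- if (truncated) pattern_truncated else pattern
  m <- regexec(pat, repeat_aa)[[1L]]
  if (m[1L] == -1L) {
    abort2(sprintf("C2H2 scaffold not found in repeat '%s'", repeat_aa),
           "scaffold_not_found", repeat_aa = repeat_aa)
  }
  pos <- as.integer(m[-1L]) - 1L  # capture-group starts, 0-based
  out <- if (truncated) {
    list(cys1 = NA_integer_, cys2 = pos[1L], his1 = pos[2L], his2 = pos[3L])
  } else {
    list(cys1 = pos[1L], cys2 = pos[2L], his1 = pos[3L], his2 = pos[4L])
  }
  structure(out, class = "scaffold_positions")
}

#' Default contact-residue offsets relative to the first histidine
#'
#' With the alpha helix ending at the first zinc-coordinating histidine
#' (helix position +7 convention), helix positions -1, 2, 3 and 6 sit at
#' h-7, h-5, h-4 and h-1 respectively.
#' @export
default_contact_offsets <- function() {
  c(pos_minus1 = -7L, pos2 = -5L, pos3 = -4L, pos6 = -1L)
}

#' Extract the DNA-contact residues of one repeat
#'
#' Returns the residues at helix positions -1, 2, 3 and 6, the sites that
#' determine the DNA-binding specificity of a C2H2 finger. Offsets are
#' computed from the first zinc-coordinating histidine and are configurable.
#'
#' @param repeat_aa Amino-acid string of one repeat.
#' @param scaffold A `scaffold_positions` object from [locate_scaffold()].
#' @param offsets Named integer offsets relative to `his1`
#'   (default [default_contact_offsets()]).
#' @return List with `pos_minus1`, `pos2`, `pos3`, `pos6` and `triplet`
#'   (the (-1, 3, 6) combination used for colour coding), class
#'   `contact_residues`.
#' @export
extract_contact_residues <- function(repeat_aa, scaffold,
                                     offsets = default_contact_offsets()) {
  h <- scaffold$his1
  idx <- h + offsets  # 0-based
  if (any(idx < 0L) || any(idx >= nchar(repeat_aa))) {
    abort2("contact-residue offset outside the repeat", "out_of_range",
           offsets = idx)
  }
  res <- substring(repeat_aa, idx + 1L, idx + 1L)
  names(res) <- names(offsets)
  structure(
    list(pos_minus1 = res[["pos_minus1"]], pos2 = res[["pos2"]],
         pos3 = res[["pos3"]], pos6 = res[["pos6"]],
         triplet = paste0(res[["pos_minus1"]], res[["pos3"]], res[["pos6"]])),
    class = "contact_residues"
  )
}

#' Absolute 0-based contact-residue columns within a full repeat
#'
#' Convenience wrapper used by the polymorphism report and the simulators.
#' @param repeat_aa A representative full-repeat amino-acid sequence.
#' @param offsets See [extract_contact_residues()].
#' @export
contact_columns <- function(repeat_aa, offsets = default_contact_offsets()) {
  sc <- locate_scaffold(repeat_aa)
  sort(unname(sc$his1 + offsets))
}

#' Parse one array sequence into a ZnF allele
#'
#' Splits, translates and wraps an array sequence. `leading_truncated =
#' "auto"` flags a truncated leading repeat whenever the length is not an
#' exact repeat multiple.
#'
#' @inheritParams split_into_repeats
#' @param allele_id,sample_id,group Labels attached to the allele.
#' @param leading_truncated `TRUE`, `FALSE` or `"auto"`.
#' @return A [znf_allele()].
#' @export
parse_znf_allele <- function(array_nt, allele_id, sample_id = NA_character_,
                             group = NA_character_, repeat_length = 84L,
                             leading_truncated = "auto",
                             truncated_length = NULL) {
  if (identical(leading_truncated, "auto")) {
    leading_truncated <- nchar(array_nt) %% repeat_length != 0L
  }
  reps <- split_into_repeats(array_nt, repeat_length, leading_truncated,
                             truncated_length)
  reps <- translate_repeats(reps)
  znf_allele(allele_id, sample_id, group, reps)
}

#' Validate a ZnF array allele
#'
#' Report-based validation: IUPAC ambiguity characters, length anomalies,
#' in-frame stop codons and broken C2H2 scaffolds are listed per repeat;
#' nothing is dropped silently. Alleles with ambiguity codes should be
#' rejected for downstream cataloguing (heterozygous base calls cannot be
#' phased into alleles).
#'
#' @param allele A [znf_allele()].
#' @param repeat_length Expected full-repeat length in nt.
#' @return A data frame with columns `repeat_index`, `type`, `detail`; zero
#'   rows for a clean allele. Attribute `ok` is `TRUE` when empty.
#' @export
validate_array <- function(allele, repeat_length = 84L) {
  issues <- list()
  add <- function(idx, type, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      repeat_index = idx, type = type, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (r in allele$repeats) {
    if (has_ambiguity(r$nt_seq)) {
      add(r$index_in_array, "ambiguity",
          paste0("non-ACGT base(s): ",
                 paste(unique(chars(gsub("[ACGT]", "", r$nt_seq))),
                       collapse = ",")))
      next  # translation/scaffold checks meaningless with ambiguous bases
    }
    if (!r$is_truncated && nchar(r$nt_seq) != repeat_length) {
      add(r$index_in_array, "bad_length",
          sprintf("full repeat of %d nt (expected %d)", nchar(r$nt_seq),
                  repeat_length))
      next
    }
    aa <- r$aa_seq
    if (is.na(aa)) {
      aa <- tryCatch(translate_repeats(list(r))[[1L]]$aa_seq,
                     invalid_repeat = function(e) NA_character_)
    }
    if (is.na(aa)) {
      add(r$index_in_array, "stop_codon", "in-frame stop codon")
      next
    }
    ok <- tryCatch({
      locate_scaffold(aa, truncated = r$is_truncated)
      TRUE
    }, scaffold_not_found = function(e) FALSE)
    if (!ok) add(r$index_in_array, "scaffold", "C2H2 pattern not matched")
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(repeat_index = integer(), type = character(),
               detail = character(), stringsAsFactors = FALSE)
  attr(out, "ok") <- nrow(out) == 0L
  out
}

#' Concatenated nucleotide sequence of an allele
#' @param allele A [znf_allele()].
#' @export
allele_nt <- function(allele) {
  paste(vapply(allele$repeats, `[[`, character(1), "nt_seq"), collapse = "")
}

#' Per-allele repeat table
#'
#' Flat table of repeats with contact residues, the canonical per-allele
#' output of the parsing stage.
#'
#' @param alleles List of [znf_allele()] objects.
#' @param offsets Contact-residue offsets, see [extract_contact_residues()].
#' @return Data frame: `allele_id`, `repeat_index`, `is_truncated`, `nt_seq`,
#'   `aa_seq`, `pos_minus1`, `pos2`, `pos3`, `pos6`, `triplet`.
#' @export
repeat_table <- function(alleles, offsets = default_contact_offsets()) {
  rows <- lapply(alleles, function(al) {
    do.call(rbind, lapply(al$repeats, function(r) {
      cr <- if (r$is_truncated) NULL else tryCatch({
        sc <- locate_scaffold(r$aa_seq)
        extract_contact_residues(r$aa_seq, sc, offsets)
      }, prdm9znf_error = function(e) NULL)
      data.frame(
        allele_id = al$allele_id, repeat_index = r$index_in_array,
        is_truncated = r$is_truncated, nt_seq = r$nt_seq, aa_seq = r$aa_seq,
        pos_minus1 = if (is.null(cr)) NA_character_ else cr$pos_minus1,
        pos2 = if (is.null(cr)) NA_character_ else cr$pos2,
        pos3 = if (is.null(cr)) NA_character_ else cr$pos3,
        pos6 = if (is.null(cr)) NA_character_ else cr$pos6,
        triplet = if (is.null(cr)) NA_character_ else cr$triplet,
        stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
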