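# Standard genetic code and codon-level helpers.
#
# The standard code is hard-coded (alternative codes are out of scope); the
# test suite cross-checks every codon against Biostrings' table.

GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

STOP_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == "*"]

# The 61 sense codons in fixed (alphabetical) order; this order indexes every
# rate matrix, frequency vector and simulated state in the selection module.
SENSE_CODONS <- sort(names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"])

split_codons <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    abort2(sprintf("sequence length %d is not a multiple of 3", n),
           "frame_error")
  }
  substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a nucleotide sequence under the standard genetic code
#'
#' @param nt A single in-frame nucleotide string (length a multiple of 3,
#'   uppercase `ACGT`).
#' @param allow_stop If `FALSE` (default) an in-frame stop codon raises an
#'   `invalid_repeat` error naming the offending codon index.
#' @return A single amino-acid string (`*` marks stops when `allow_stop`).
#' @examples
#' translate_nt("GCTGCA")  # "AA"
#' @export
translate_nt <- function(nt, allow_stop = FALSE) {
  stopifnot_string(nt, "nt")
  cods <- split_codons(nt)
  aa <- unname(GENETIC_CODE_STD[cods])
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1L]
    abort2(sprintf("unknown codon '%s' at codon %d", cods[bad], bad),
           "invalid_codon", codon_index = which(is.na(aa)))
  }
  if (!allow_stop && any(aa == "*")) {
    idx <- which(aa == "*")
    abort2(sprintf("in-frame stop codon at codon position %s",
                   paste(idx, collapse = ", ")),
           "invalid_repeat", codon_index = idx)
  }
  paste(aa, collapse = "")
}

# One representative codon per amino acid, used by the simulators when
# reverse-translating planted residues.
PREFERRED_CODON <- vapply(
  split(names(GENETIC_CODE_STD), GENETIC_CODE_STD),
  function(x) sort(x)[1L], character(1)
)

has_ambiguity <- function(nt) {
  grepl("[^ACGT]", nt)
}
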