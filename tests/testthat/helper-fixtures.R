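# Shared fixture builders. Everything is generated in code; no binary data.

# A 28-aa repeat with the C2H2 scaffold at known offsets, all other
# positions filled with `fill`.
make_scaffold_aa <- function(c1 = 2, c2 = 5, h1 = 18, h2 = 22, fill = "G",
                             len = 28) {
  x <- rep(fill, len)
  if (!is.na(c1)) x[c1 + 1] <- "C"
  x[c2 + 1] <- "C"
  x[h1 + 1] <- "H"
  x[h2 + 1] <- "H"
  paste(x, collapse = "")
}

base_nt <- function() prdm9znf:::BASE_REPEAT_NT
base_aa <- function() prdm9znf:::BASE_REPEAT_AA
trunc_nt <- function() prdm9znf:::TRUNCATED_LEAD_NT

# Random stop-free in-frame nucleotide sequence of n_codons codons.
random_codon_nt <- function(n_codons, seed = 1) {
  sense <- prdm9znf:::SENSE_CODONS
  prdm9znf:::with_seed(seed, paste(sample(sense, n_codons, TRUE),
                                   collapse = ""))
}

# Build a znf_allele directly from repeat nt sequences.
allele_from_repeats <- function(nts, id = "a1", truncated_lead = FALSE) {
  nt <- paste(c(if (truncated_lead) trunc_nt(), nts), collapse = "")
  parse_znf_allele(nt, id, leading_truncated = truncated_lead)
}

# Mutate the aa at 0-based offset col of an 84-nt repeat.
mutate_repeat <- function(nt, col, res) prdm9znf:::mutate_residue(nt, col, res)

# Tiny sequence table for catalogue tests.
seq_table <- function(sequences, groups, samples = NULL) {
  data.frame(
    sequence = sequences, group = groups,
    sample_id = if (is.null(samples)) sprintf("s%d", seq_along(sequences))
                else samples,
    stringsAsFactors = FALSE)
}

# Dense matrix-exponential likelihood oracle for small trees (independent of
# the pruning/eigendecomposition code path): likelihood of one site under one
# omega class, via Matrix::expm on the scaled generator.
dense_site_likelihood <- function(tree, states_row_by_tip, Qscaled, pi) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  P <- lapply(seq_len(nrow(tr$edge)), function(k)
    as.matrix(Matrix::expm(Qscaled * tr$edge.length[k])))
  part <- vector("list", ntip + tr$Nnode)
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    v <- if (ch <= ntip) P[[k]][, states_row_by_tip[[tr$tip.label[ch]]]]
         else P[[k]] %*% part[[ch]]
    part[[par]] <- if (is.null(part[[par]])) v else part[[par]] * v
  }
  sum(pi * part[[ntip + 1]])
}
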