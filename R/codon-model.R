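# GY94-style codon substitution machinery: codon frequency models, rate
# matrix construction (three frequency-incorporation styles), and transition
# probabilities via symmetric eigendecomposition (all models are reversible).

NUC <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

codon_nt_matrix <- function() {
  do.call(rbind, strsplit(SENSE_CODONS, ""))
}

# Precompute, for all 61x61 sense-codon pairs differing at exactly one
# position: indices, changed position, transition flag, synonymous flag.
build_codon_pairs <- function() {
  nts <- codon_nt_matrix()
  aa <- GENETIC_CODE_STD[SENSE_CODONS]
  n <- length(SENSE_CODONS)
  res <- list(i = integer(), j = integer(), pos = integer(),
              is_ts = logical(), is_syn = logical())
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    diffs <- which(nts[i, ] != nts[j, ])
    if (length(diffs) != 1L) next
    p <- diffs
    ts <- (nts[i, p] %in% PURINES) == (nts[j, p] %in% PURINES)
    res$i <- c(res$i, i); res$j <- c(res$j, j); res$pos <- c(res$pos, p)
    res$is_ts <- c(res$is_ts, ts)
    res$is_syn <- c(res$is_syn, aa[i] == aa[j])
  }
  res
}

# Cached at load time; ~263 single-change unordered pairs.
.codon_env <- new.env(parent = emptyenv())
codon_pairs <- function() {
  if (is.null(.codon_env$pairs)) .codon_env$pairs <- build_codon_pairs()
  .codon_env$pairs
}

#' Codon frequency models F1x4, F3x4 and F61
#'
#' Computes equilibrium sense-codon frequencies from an alignment: `F1x4`
#' (nucleotide frequencies pooled over codon positions), `F3x4`
#' (position-specific nucleotide frequencies) or `F61` (empirical sense-codon
#' frequencies with a 0.5 pseudocount per codon so that unobserved codons
#' keep nonzero frequency). `F60` is accepted as an alias of `F61`. Stop
#' codons always carry zero frequency; the returned vector sums to 1 over the
#' 61 sense codons and carries the position-specific nucleotide frequencies
#' as attribute `nt_freqs` (used by the Muse-Gaut rate parameterization).
#'
#' @param aln A [codon_alignment()].
#' @param model `"F3x4"`, `"F1x4"`, `"F61"` (or `"F60"`).
#' @return Named numeric vector over [SENSE_CODONS].
#' @export
codon_frequencies <- function(aln, model = c("F3x4", "F1x4", "F61", "F60")) {
  model <- match.arg(model)
  cods <- as.vector(aln$codons)
  nts <- do.call(rbind, strsplit(cods, ""))
  # 0.5 pseudocount per nucleotide: keeps every sense codon at positive
  # frequency (the reversible eigen machinery needs pi > 0), negligible for
  # realistic alignment sizes.
  pos_freq <- sapply(1:3, function(p) {
    tab <- table(factor(nts[, p], levels = NUC)) + 0.5
    as.numeric(tab) / sum(tab)
  })  # 4 x 3, rows = NUC
  rownames(pos_freq) <- NUC
  cm <- codon_nt_matrix()
  pi <- switch(model,
    F3x4 = pos_freq[cm[, 1L], 1L] * pos_freq[cm[, 2L], 2L] *
           pos_freq[cm[, 3L], 3L],
    F1x4 = {
      f <- rowMeans(pos_freq)
      fm <- matrix(rep(f, 3), ncol = 3, dimnames = list(NUC, NULL))
      pos_freq <- fm
      f[cm[, 1L]] * f[cm[, 2L]] * f[cm[, 3L]]
    },
    F61 = ,
    F60 = {
      tab <- table(factor(cods, levels = SENSE_CODONS))
      (as.numeric(tab) + 0.5) / (sum(tab) + 0.5 * length(SENSE_CODONS))
    })
  pi <- pi / sum(pi)
  names(pi) <- SENSE_CODONS
  attr(pi, "nt_freqs") <- pos_freq
  pi
}

#' GY94-style codon rate matrix
#'
#' Builds the 61x61 generator with rate kappa^[transition] * omega^[nonsyn]
#' times a frequency term chosen by `freq_incorporation`:
#' \describe{
#'   \item{GY}{target codon frequency `pi_j` (Goldman-Yang 1994).}
#'   \item{MuseGaut}{frequency of the target nucleotide at the changed codon
#'     position (Muse-Gaut 1994 style).}
#'   \item{GoldmanWhelan}{`sqrt(pi_j / pi_i)` (Goldman-Whelan style).}
#' }
#' All three are reversible; the stationary distribution is `pi` (for
#' MuseGaut, the product-measure `pi` implied by the nucleotide frequencies;
#' pass F3x4/F1x4 frequencies for consistency). The matrix is returned
#' unscaled; scaling to one expected substitution per unit time is applied at
#' the mixture level so that relative rates between site classes are
#' preserved.
#'
#' @param kappa Transition/transversion rate ratio.
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @param pi Codon frequencies from [codon_frequencies()].
#' @param freq_incorporation One of `"GY"`, `"MuseGaut"`, `"GoldmanWhelan"`.
#' @return List: `Q` (unscaled generator), `rate` (expected rate under `pi`).
#' @keywords internal
codon_rate_matrix <- function(kappa, omega, pi,
                              freq_incorporation = c("GY", "MuseGaut",
                                                     "GoldmanWhelan")) {
  freq_incorporation <- match.arg(freq_incorporation)
  cp <- codon_pairs()
  n <- length(SENSE_CODONS)
  Q <- matrix(0, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  base <- ifelse(cp$is_ts, kappa, 1) * ifelse(cp$is_syn, 1, omega)
  cm <- codon_nt_matrix()
  fwd <- bwd <- base
  if (freq_incorporation == "GY") {
    fwd <- base * pi[cp$j]
    bwd <- base * pi[cp$i]
  } else if (freq_incorporation == "MuseGaut") {
    nf <- attr(pi, "nt_freqs")
    if (is.null(nf)) abort2("pi lacks nt_freqs attribute needed for MuseGaut",
                            "bad_input")
    tgt_j <- cm[cbind(cp$j, cp$pos)]
    tgt_i <- cm[cbind(cp$i, cp$pos)]
    fwd <- base * nf[cbind(match(tgt_j, NUC), cp$pos)]
    bwd <- base * nf[cbind(match(tgt_i, NUC), cp$pos)]
  } else {  # GoldmanWhelan
    fwd <- base * sqrt(pi[cp$j] / pi[cp$i])
    bwd <- base * sqrt(pi[cp$i] / pi[cp$j])
  }
  Q[cbind(cp$i, cp$j)] <- fwd
  Q[cbind(cp$j, cp$i)] <- bwd
  diag(Q) <- -rowSums(Q)
  list(Q = Q, rate = -sum(pi * diag(Q)))
}

# Eigendecomposition of a reversible generator via symmetrization:
# S = D^{1/2} Q D^{-1/2} is symmetric for reversible Q with stationary pi.
codon_eigen <- function(Q, pi) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2  # symmetrize away rounding noise
  e <- eigen(S, symmetric = TRUE)
  list(vals = e$values, U = e$vectors, d = d)
}

# P(t) from a cached eigendecomposition; clamps small negatives.
codon_pmat <- function(eig, t) {
  if (t <= 0) return(diag(length(eig$vals)))
  M <- eig$U %*% (exp(eig$vals * t) * t(eig$U))
  P <- (1 / eig$d) * M * rep(eig$d, each = length(eig$d))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Stationary distribution actually implied by a parameterization: MuseGaut
# rates are reversible w.r.t. the product measure of the position-specific
# nucleotide frequencies, not w.r.t. an arbitrary pi (e.g. F61).
stationary_pi <- function(pi, freq_incorporation) {
  if (freq_incorporation != "MuseGaut") return(pi)
  nf <- attr(pi, "nt_freqs")
  cm <- codon_nt_matrix()
  p <- nf[cm[, 1L], 1L] * nf[cm[, 2L], 2L] * nf[cm[, 3L], 3L]
  p <- p / sum(p)
  names(p) <- SENSE_CODONS
  attr(p, "nt_freqs") <- nf
  p
}
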