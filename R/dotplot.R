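# Self-comparison dot plots with windowed mismatch tolerance and a
# quantitative two-block-structure score.

#' Self-comparison dot plot of a nucleotide sequence
#'
#' Compares every window of the sequence against every other window of the
#' same sequence (same strand only; no reverse complement). Cell (i, j) is
#' `TRUE` iff the windows starting at positions i and j differ at no more
#' than `mismatch_limit` positions.
#'
#' @param seq Nucleotide string, at least `window` long.
#' @param window Window size in nt (default 83).
#' @param mismatch_limit Maximum tolerated mismatches per window pair
#'   (default 5); must satisfy `0 <= mismatch_limit < window`.
#' @param placement `"start"` (cells indexed by window start; default) or
#'   `"centered"` (cells indexed by window centre). The matrix is identical;
#'   only the recorded axis coordinates differ.
#' @return Object of class `dotplot_matrix`: logical matrix over the
#'   `nchar(seq) - window + 1` valid window positions, with attributes
#'   `window`, `mismatch_limit`, `placement` and `coords` (1-based axis
#'   coordinates).
#' @export
self_dotplot <- function(seq, window = 83L, mismatch_limit = 5L,
                         placement = c("start", "centered")) {
  placement <- match.arg(placement)
  stopifnot_string(seq, "seq")
  n <- nchar(seq)
  window <- as.integer(window)
  if (n < window) abort2(sprintf("sequence (%d nt) shorter than window (%d)",
                                 n, window), "sequence_too_short")
  if (mismatch_limit < 0L || mismatch_limit >= window) {
    abort2("need 0 <= mismatch_limit < window", "bad_input")
  }
  x <- chars(seq)
  npos <- n - window + 1L
  m <- matrix(FALSE, npos, npos)
  # Fill by diagonal lag: windowed mismatch counts from a cumulative sum.
  for (d in 0:(npos - 1L)) {
    k <- n - d
    mism <- x[seq_len(k)] != x[seq_len(k) + d]
    cs <- c(0L, cumsum(mism))
    nw <- k - window + 1L
    if (nw < 1L) break
    wsum <- cs[(window + 1L):(window + nw)] - cs[seq_len(nw)]
    hit <- wsum <= mismatch_limit
    idx <- seq_len(nw)
    m[cbind(idx, idx + d)] <- hit
    m[cbind(idx + d, idx)] <- hit
  }
  coords <- seq_len(npos) + if (placement == "centered") window %/% 2L else 0L
  structure(m, window = window, mismatch_limit = as.integer(mismatch_limit),
            placement = placement, coords = coords,
            class = c("dotplot_matrix", "matrix", "array"))
}

#' Render a dot plot matrix (optional thin layer over base graphics)
#'
#' @param x A `dotplot_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.dotplot_matrix <- function(x, ...) {
  co <- attr(x, "coords")
  graphics::image(co, co, unclass(x)[, rev(seq_len(ncol(x)))],
                  col = c("white", "black"), xlab = "position",
                  ylab = "position", useRaster = TRUE, ...)
  invisible(x)
}

aa_identity <- function(a, b) {
  mean(chars(a) == chars(b))
}

mean_pairwise_identity <- function(seqs_a, seqs_b = NULL) {
  if (is.null(seqs_b)) {  # within-set mean over unordered pairs
    k <- length(seqs_a)
    if (k < 2L) return(NA_real_)
    tot <- 0
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      tot <- tot + aa_identity(seqs_a[i], seqs_a[j])
    }
    tot / choose(k, 2)
  } else {
    mean(outer(seq_along(seqs_a), seq_along(seqs_b),
               Vectorize(function(i, j) aa_identity(seqs_a[i], seqs_b[j]))))
  }
}

#' Two-block structure score of a ZnF array
#'
#' Quantifies whether the repeats of each half of an array resemble each
#' other more than they resemble repeats of the other half (the pattern seen
#' in the human PRDM9 A allele). Uses amino-acid repeat identity; the array
#' is split at the midpoint, an odd middle repeat going to the first half.
#'
#' score = (mean identity within first half + within second half) / 2
#'         - mean identity between halves
#'
#' Positive scores indicate two-block structure; homogeneous arrays score 0.
#'
#' @param allele A translated [znf_allele()] with at least 4 full repeats.
#' @return Numeric score.
#' @export
two_block_score <- function(allele) {
  reps <- vapply(full_repeats(allele), `[[`, character(1), "aa_seq")
  k <- length(reps)
  if (k < 4L) abort2("two_block_score needs >= 4 full repeats", "bad_input")
  if (anyNA(reps)) abort2("repeats must be translated", "bad_input")
  h <- ceiling(k / 2)
  first <- reps[1:h]
  second <- reps[(h + 1L):k]
  (mean_pairwise_identity(first) + mean_pairwise_identity(second)) / 2 -
    mean_pairwise_identity(first, second)
}
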