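# Permutation tests of allelic richness between and among groups.
#
# Two statistics are implemented:
#   * two_group  - the number of unique alleles in the smaller group;
#   * multi_group - the sum of squared deviations from the mean of
#     (unique alleles / total sequences) per group.
# P-values are the proportion of permutations with a statistic at least as
# large as the observed one (the observed value is NOT added to numerator or
# denominator, so p = 0 is attainable).

#' Construct a grouped allele spectrum
#'
#' @param labels_by_group Named list; each element is a character vector of
#'   allele labels, one label per observed sequence in that group. Labels
#'   shared across groups mean the underlying allele is shared.
#' @return Object of class `grouped_spectrum`.
#' @export
grouped_spectrum <- function(labels_by_group) {
  if (is.null(names(labels_by_group)) ||
      any(!nzchar(names(labels_by_group)))) {
    abort2("groups must be named", "bad_input")
  }
  sizes <- lengths(labels_by_group)
  if (any(sizes < 1L)) abort2("every group needs at least one sequence",
                              "empty_group")
  structure(list(groups = lapply(labels_by_group, as.character)),
            class = "grouped_spectrum")
}

#' Build a spectrum from (group, allele, count) rows
#'
#' @param counts Data frame with columns `group`, `allele`, `count`
#'   (positive integers). Each row is expanded into `count` per-sequence
#'   labels.
#' @return A [grouped_spectrum()].
#' @export
spectrum_from_counts <- function(counts) {
  need <- c("group", "allele", "count")
  if (!all(need %in% names(counts))) {
    abort2("counts needs columns group, allele, count", "bad_input")
  }
  if (nrow(counts) == 0L) abort2("empty counts table", "bad_input")
  if (any(counts$count != as.integer(counts$count)) ||
      any(counts$count < 1L)) {
    abort2("counts must be positive integers", "bad_count")
  }
  if (anyDuplicated(counts[, c("group", "allele")])) {
    abort2("duplicate (group, allele) rows", "bad_input")
  }
  grouped_spectrum(lapply(
    split(counts, factor(counts$group, levels = unique(counts$group))),
    function(d) rep(d$allele, d$count)))
}

#' @export
print.grouped_spectrum <- function(x, ...) {
  for (g in names(x$groups)) {
    cat(sprintf("%s: n=%d, unique=%d\n", g, length(x$groups[[g]]),
                length(unique(x$groups[[g]]))))
  }
  invisible(x)
}

#' Pool groups of a spectrum
#'
#' @param spectrum A [grouped_spectrum()].
#' @param groups Character vector of group names to pool.
#' @param name Name of the pooled group.
#' @return A [grouped_spectrum()] in which `groups` are replaced by one
#'   pooled group (placed first), other groups unchanged.
#' @export
pool_groups <- function(spectrum, groups, name = "pooled") {
  miss <- setdiff(groups, names(spectrum$groups))
  if (length(miss)) abort2(paste("unknown group(s):",
                                 paste(miss, collapse = ", ")), "bad_input")
  pooled <- unlist(spectrum$groups[groups], use.names = FALSE)
  rest <- spectrum$groups[setdiff(names(spectrum$groups), groups)]
  grouped_spectrum(c(stats::setNames(list(pooled), name), rest))
}

#' Number of distinct alleles in (a subset of) a spectrum
#' @param spectrum A [grouped_spectrum()].
#' @param groups Groups to pool before counting (default: all).
#' @export
n_unique_alleles <- function(spectrum, groups = names(spectrum$groups)) {
  length(unique(unlist(spectrum$groups[groups], use.names = FALSE)))
}

#' Two-group richness statistic
#'
#' The number of unique alleles in the smaller group ("smaller" = fewer
#' sequences; ties broken in favour of the first-listed group).
#'
#' @param spectrum A [grouped_spectrum()] with exactly two groups.
#' @return Integer statistic.
#' @export
unique_count_statistic_two_group <- function(spectrum) {
  if (length(spectrum$groups) != 2L) {
    abort2("two_group statistic requires exactly 2 groups", "bad_input")
  }
  sizes <- lengths(spectrum$groups)
  smaller <- which(sizes == min(sizes))[1L]
  length(unique(spectrum$groups[[smaller]]))
}

#' Multi-group dispersion statistic
#'
#' For each group compute u_g / n_g (distinct alleles over sequences) and
#' return the sum of squared deviations from the mean of those ratios.
#'
#' @param spectrum A [grouped_spectrum()] with at least two groups.
#' @return Non-negative numeric statistic; 0 iff all ratios are equal.
#' @export
dispersion_statistic_multi_group <- function(spectrum) {
  if (length(spectrum$groups) < 2L) {
    abort2("multi_group statistic requires >= 2 groups", "bad_input")
  }
  r <- vapply(spectrum$groups,
              function(g) length(unique(g)) / length(g), numeric(1))
  sum((r - mean(r))^2)
}

spectrum_statistic <- function(kind) {
  switch(kind,
         two_group = unique_count_statistic_two_group,
         multi_group = dispersion_statistic_multi_group,
         abort2(sprintf("unknown statistic kind '%s'", kind), "bad_input"))
}

#' Permutation test of allelic richness
#'
#' Shuffles the per-sequence allele labels across groups (preserving group
#' sizes), recomputes the statistic for each permutation and reports the
#' one-tailed p-value: the proportion of permutations whose statistic is at
#' least as large as the observed one.
#'
#' @param spectrum A [grouped_spectrum()].
#' @param statistic_kind `"two_group"` or `"multi_group"`.
#' @param n_permutations Number of random label reassignments (default
#'   10000).
#' @param seed Integer seed; the result is bit-identical given the seed.
#' @return List of class `permutation_result`: `observed_statistic`,
#'   `p_value`, `n_permutations`, `seed`, `statistic_kind`,
#'   `permuted_statistics`.
#' @export
permutation_test <- function(spectrum, statistic_kind = c("two_group",
                                                          "multi_group"),
                             n_permutations = 10000L, seed = 1L) {
  statistic_kind <- match.arg(statistic_kind)
  if (n_permutations < 1L) abort2("n_permutations must be >= 1", "bad_input")
  stat <- spectrum_statistic(statistic_kind)
  obs <- stat(spectrum)
  pool <- unlist(spectrum$groups, use.names = FALSE)
  sizes <- lengths(spectrum$groups)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  gnames <- names(spectrum$groups)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      perm <- sample(pool)
      gl <- lapply(seq_along(sizes),
                   function(i) perm[starts[i]:ends[i]])
      names(gl) <- gnames
      stat(structure(list(groups = gl), class = "grouped_spectrum"))
    }, numeric(1))
  })
  structure(
    list(observed_statistic = obs,
         p_value = mean(perm_stats >= obs - 1e-12),
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed),
         statistic_kind = statistic_kind,
         permuted_statistics = perm_stats),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed = %.4g, p = %.4g (%d permutations, seed %d)\n",
              x$statistic_kind, x$observed_statistic, x$p_value,
              x$n_permutations, x$seed))
  invisible(x)
}

#' Exact permutation p-value by complete enumeration
#'
#' Enumerates every distinct assignment of the sequence labels to groups of
#' the observed sizes (uniformly over label permutations) and returns the
#' exact tail probability. Intended as an oracle for small spectra.
#'
#' @param spectrum A [grouped_spectrum()].
#' @param statistic_kind `"two_group"` or `"multi_group"`.
#' @param max_arrangements Error out above this bound (default `1e6`).
#' @return Exact p-value in `[0, 1]`.
#' @export
exhaustive_permutation_oracle <- function(spectrum,
                                          statistic_kind = c("two_group",
                                                             "multi_group"),
                                          max_arrangements = 1e6) {
  statistic_kind <- match.arg(statistic_kind)
  stat <- spectrum_statistic(statistic_kind)
  obs <- stat(spectrum)
  pool <- unlist(spectrum$groups, use.names = FALSE)
  sizes <- lengths(spectrum$groups)
  gnames <- names(spectrum$groups)
  n <- length(pool)
  total <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (total > max_arrangements) {
    abort2(sprintf(
      "%.3g arrangements exceed the bound %g; use permutation_test()",
      total, max_arrangements), "too_many_arrangements")
  }
  # Recursively choose which token positions form each group.
  tail_count <- 0
  n_arr <- 0
  recurse <- function(avail, assigned) {
    g <- length(assigned) + 1L
    if (g > length(sizes)) {
      gl <- lapply(assigned, function(ix) pool[ix])
      names(gl) <- gnames
      s <- stat(structure(list(groups = gl), class = "grouped_spectrum"))
      n_arr <<- n_arr + 1
      if (s >= obs - 1e-12) tail_count <<- tail_count + 1
      return(invisible())
    }
    if (g == length(sizes)) {  # last group takes the remainder
      recurse(integer(), c(assigned, list(avail)))
      return(invisible())
    }
    sel <- utils::combn(avail, sizes[g], simplify = FALSE)
    for (ix in sel) recurse(setdiff(avail, ix), c(assigned, list(ix)))
    invisible()
  }
  recurse(seq_len(n), list())
  tail_count / n_arr
}
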