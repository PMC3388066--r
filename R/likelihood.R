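# Codon alignments and Felsenstein-pruning likelihood for site-class mixture
# models. Patterns are compressed; partial likelihoods are rescaled per
# internal node to avoid underflow on large trees.

#' Construct a codon alignment
#'
#' @param sequences Named character vector of in-frame nucleotide sequences
#'   (equal lengths, multiples of 3, no stop codons, no ambiguity codes).
#' @param n_excluded_truncated Number of truncated leading repeats that were
#'   dropped on the way in (bookkeeping only).
#' @return Object of class `codon_alignment`: `taxa`, `codons` (taxa x sites
#'   character matrix), `states` (integer indices into [SENSE_CODONS]),
#'   `n_sites`, `n_excluded_truncated`.
#' @export
codon_alignment <- function(sequences, n_excluded_truncated = 0L) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    abort2("sequences must be named", "bad_input")
  }
  if (anyDuplicated(names(sequences))) {
    abort2("duplicate taxon names", "bad_input")
  }
  L <- unique(nchar(sequences))
  if (length(L) != 1L) abort2("ragged alignment", "ragged_alignment")
  if (any(has_ambiguity(sequences))) {
    abort2("alignment contains ambiguity codes", "ambiguous_sequence")
  }
  cod <- t(vapply(sequences, split_codons,
                  character(nchar(sequences[[1L]]) %/% 3L)))
  if (any(cod %in% STOP_CODONS)) {
    abort2("alignment contains stop codons", "stop_codon")
  }
  states <- matrix(match(cod, SENSE_CODONS), nrow = nrow(cod),
                   dimnames = dimnames(cod))
  structure(
    list(taxa = names(sequences), codons = cod, states = states,
         n_sites = ncol(cod),
         n_excluded_truncated = as.integer(n_excluded_truncated)),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa x %d codon sites%s\n",
              length(x$taxa), x$n_sites,
              if (x$n_excluded_truncated > 0)
                sprintf(" (%d truncated leading repeats excluded)",
                        x$n_excluded_truncated) else ""))
  invisible(x)
}

#' Build a codon alignment from parsed ZnF repeats
#'
#' Collects the full (non-truncated) repeats of a set of alleles into an
#' in-frame codon matrix; truncated leading repeats are excluded. By default
#' rows are deduplicated to distinct repeat sequences (set `dedupe = FALSE`
#' to keep every repeat token).
#'
#' @param alleles List of translated [znf_allele()] objects, or a character
#'   vector of repeat nucleotide sequences.
#' @param dedupe Deduplicate identical repeat sequences (default `TRUE`).
#' @return A [codon_alignment()], taxa named `r1..rk` in first-encounter
#'   order.
#' @export
build_codon_alignment <- function(alleles, dedupe = TRUE) {
  nts <- if (is.character(alleles)) alleles else {
    unlist(lapply(alleles, function(al)
      vapply(full_repeats(al), `[[`, character(1), "nt_seq")))
  }
  n_trunc <- if (is.character(alleles)) 0L else {
    sum(vapply(alleles, function(al)
      length(al$repeats) - n_full_repeats(al), integer(1)))
  }
  if (dedupe) nts <- unique(nts)
  names(nts) <- paste0("r", seq_along(nts))
  codon_alignment(nts, n_excluded_truncated = n_trunc)
}

# --- tree plumbing -----------------------------------------------------------

# Normalize an ape phylo for pruning: postorder edge list, children known
# before parents. Works for rooted and unrooted (root trifurcation) trees.
tree_plan <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) abort2("tree must be an ape phylo object",
                                       "bad_input")
  if (!setequal(tree$tip.label, taxa)) {
    abort2("tree tips do not match alignment taxa", "bad_input")
  }
  if (is.null(tree$edge.length)) abort2("tree needs branch lengths",
                                        "bad_input")
  if (any(tree$edge.length < 0)) abort2("negative branch lengths",
                                        "bad_input")
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  list(edge = tr$edge, lengths = tr$edge.length, ntip = ntip,
       root = ntip + 1L,  # ape numbers the root ntip+1
       tip_index = match(taxa, tr$tip.label), tree = tr)
}

# --- pruning -----------------------------------------------------------------

# Per-pattern log-likelihood for a single omega class, with progressive
# rescaling of partials to dodge underflow.
# plan: tree_plan(); states: ntaxa x npat integer matrix (alignment order);
# eig: codon_eigen(); pi: stationary frequencies; scale: branch multiplier.
class_pattern_loglik <- function(plan, states, eig, pi, scale) {
  npat <- ncol(states)
  nnode <- plan$ntip + plan$tree$Nnode
  partial <- vector("list", nnode)
  logscaler <- vector("list", nnode)
  edge <- plan$edge
  lens <- plan$lengths * scale
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1L]; child <- edge[k, 2L]
    P <- codon_pmat(eig, lens[k])
    if (child <= plan$ntip) {
      # leaf: P %*% indicator == column gather
      row <- which(plan$tip_index == child)  # alignment row for this tip
      contrib <- P[, states[row, ], drop = FALSE]
      ls <- NULL
    } else {
      contrib <- P %*% partial[[child]]
      ls <- logscaler[[child]]
    }
    if (is.null(partial[[par]])) {
      partial[[par]] <- contrib
      logscaler[[par]] <- if (is.null(ls)) numeric(npat) else ls
    } else {
      partial[[par]] <- partial[[par]] * contrib
      if (!is.null(ls)) logscaler[[par]] <- logscaler[[par]] + ls
    }
    mx <- colSums(partial[[par]])
    if (any(mx < 1e-120)) {
      sc <- pmax(mx, 1e-300)
      partial[[par]] <- sweep(partial[[par]], 2L, sc, `/`)
      logscaler[[par]] <- logscaler[[par]] + log(sc)
    }
  }
  lik <- as.vector(pi %*% partial[[plan$root]])
  log(lik) + logscaler[[plan$root]]
}

pattern_compress <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  list(states = states[, u, drop = FALSE],
       weights = as.vector(table(factor(key, levels = key[u]))),
       map = match(key, key[u]))
}

#' Mixture log-likelihood of a codon alignment under a site-class model
#'
#' Felsenstein-pruning likelihood with a GY94-style rate matrix per omega
#' class, site classes integrated per site. Exposed mainly for testing; model
#' fitting goes through [fit_site_model()].
#'
#' @param aln A [codon_alignment()].
#' @param tree An `ape::phylo` with branch lengths (expected substitutions
#'   per codon).
#' @param kappa Transition/transversion ratio.
#' @param props,omegas Site-class proportions (summing to 1) and their omega
#'   values.
#' @param pi Codon frequencies ([codon_frequencies()]).
#' @param freq_incorporation See [codon_rate_matrix()].
#' @param scale Multiplier applied to all branch lengths.
#' @param per_site Return per-site log-likelihood contributions and
#'   per-class per-site log-likelihoods too.
#' @return Log-likelihood (scalar), or a list when `per_site = TRUE`.
#' @export
codon_mixture_loglik <- function(aln, tree, kappa, props, omegas, pi,
                                 freq_incorporation = "GY", scale = 1,
                                 per_site = FALSE) {
  if (length(props) != length(omegas)) abort2("props/omegas mismatch",
                                              "bad_input")
  ctx <- make_loglik_ctx(aln, tree, pi, freq_incorporation)
  ctx_loglik(ctx, kappa, omegas, props, scale, per_site = per_site)
}
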