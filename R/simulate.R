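# Synthetic-data generators with recorded ground truth: ZnF repeat libraries,
# diploid array populations, grouped allele spectra, two-block arrays and
# codon alignments evolved under the site models the fitter implements.
#
# Every generator is deterministic under the seed in its config.

# Base full repeat: a realistic C2H2 unit, 84 nt / 28 aa, with the scaffold
# cysteines at aa offsets 2 and 5, histidines at 18 and 22 (so the contact
# residues sit at offsets 11 (-1), 13 (2, fixed serine), 14 (3) and 17 (6)),
# and a TGEKP-style linker at the tail.
BASE_REPEAT_AA <- "YVCRECGRGFSRKSALVQHQRTHTGEKP"
BASE_REPEAT_NT <- paste0(
  "TAT", "GTG", "TGT", "CGT", "GAA", "TGC", "GGA", "CGC", "GGT", "TTT",
  "AGT", "AGA", "AAA", "TCA", "GCA", "CTG", "GTT", "CAA", "CAT", "CAG",
  "CGA", "ACA", "CAC", "ACT", "GGC", "GAG", "AAG", "CCA")

# aa offsets that must never vary: zinc-coordinating C2H2 residues and the
# fixed serine at helix position 2.
REPEAT_FIXED_OFFSETS <- c(2L, 5L, 13L, 18L, 22L)
REPEAT_CONTACT_OFFSETS <- c(11L, 14L, 17L)  # helix -1, 3, 6 (0-based)

# Truncated leading repeat: the tail of the base repeat, missing the first
# cysteine (drop the first 4 codons -> 72 nt).
TRUNCATED_LEAD_NT <- substr(BASE_REPEAT_NT, 13L, 84L)

ALT_RESIDUES <- c("A", "D", "E", "G", "I", "K", "L", "N", "Q", "R", "S",
                  "T", "V", "W", "Y")

#' Simulation configuration
#'
#' Bundles and validates the knobs shared by the synthetic-data generators.
#' Defaults emulate observed Pan PRDM9 structure: 84-nt repeats, arrays of
#' 7-17 repeats, a truncated leading repeat, allele-frequency spectra shaped
#' as one common allele plus a tail of rare ones, and roughly half of the
#' repeat-library variation at the DNA-contact offsets.
#'
#' @param seed Integer seed (all generators derive their streams from it).
#' @param repeat_length Repeat unit length in nt (default 84).
#' @param array_length_range Inclusive range of full repeats per array
#'   (default `c(7, 17)`).
#' @param n_repeat_types Distinct amino-acid repeat types in the library.
#' @param n_variable_columns Number of variable aa columns planted in the
#'   library (default 6).
#' @param contact_fraction Fraction of variable columns planted at contact
#'   offsets (default 0.5). Ignored when `contact_multiplier` is given.
#' @param contact_multiplier Optional weight multiplier for sampling variable
#'   columns at contact offsets (0 keeps contact residues invariant).
#' @param n_synonymous_variants Extra synonymous nucleotide variants added to
#'   library repeats (default 1).
#' @param groups Named integer vector: individuals per group.
#' @param n_alleles_per_group Distinct alleles segregating per group.
#' @param common_allele_freq Frequency of each group's common allele
#'   (remaining mass spread evenly; default 0.5).
#' @param n_shared_alleles Alleles shared between the first two groups.
#' @param heterozygote_dropout Probability that an individual's second
#'   allele record is not recovered (default 0).
#' @param leading_truncated Emit the truncated leading repeat (default TRUE).
#' @param two_block_gap Planted aa-identity gap for [make_two_block_array()].
#' @param two_block_length Repeats in the two-block array (default 10).
#' @param model,kappa,props,omegas,beta_p,beta_q Site-model parameters for
#'   [simulate_codon_alignment()].
#' @param n_sites Codon sites to simulate (default 300).
#' @param n_taxa Taxa for the simulated tree (default 16).
#' @param branch_length_range Uniform range for simulated branch lengths
#'   (expected substitutions per codon; default `c(0.02, 0.12)`).
#' @param codon_freqs Root/stationary codon frequencies for simulation
#'   (default uniform over the 61 sense codons).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       repeat_length = 84L,
                       array_length_range = c(7L, 17L),
                       n_repeat_types = 8L,
                       n_variable_columns = 6L,
                       contact_fraction = 0.5,
                       contact_multiplier = NULL,
                       n_synonymous_variants = 1L,
                       groups = c(g1 = 5L, g2 = 5L),
                       n_alleles_per_group = 4L,
                       common_allele_freq = 0.5,
                       n_shared_alleles = 0L,
                       heterozygote_dropout = 0,
                       leading_truncated = TRUE,
                       two_block_gap = 0.3,
                       two_block_length = 10L,
                       model = "M0", kappa = 2,
                       props = 1, omegas = 0.3,
                       beta_p = NULL, beta_q = NULL,
                       n_sites = 300L, n_taxa = 16L,
                       branch_length_range = c(0.02, 0.12),
                       codon_freqs = NULL) {
  cfg <- as.list(environment())
  # accept JSON-style lists for vector fields
  for (f in c("groups", "props", "omegas", "array_length_range",
              "branch_length_range", "codon_freqs")) {
    if (is.list(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  }
  if (cfg$n_variable_columns > 28L - length(REPEAT_FIXED_OFFSETS)) {
    abort2("requested variable columns exceed available repeat columns",
           "bad_config")
  }
  if (any(cfg$groups < 1L)) abort2("group sizes must be >= 1", "bad_config")
  probs <- c(cfg$contact_fraction, cfg$heterozygote_dropout,
             cfg$common_allele_freq)
  if (any(probs < 0 | probs > 1)) abort2("probabilities must be in [0,1]",
                                         "bad_config")
  if (cfg$array_length_range[1L] < 1L ||
      diff(cfg$array_length_range) < 0L) {
    abort2("bad array_length_range", "bad_config")
  }
  if (abs(sum(cfg$props) - 1) > 1e-8) abort2("props must sum to 1",
                                             "bad_config")
  if (length(cfg$props) != length(cfg$omegas)) {
    abort2("props/omegas length mismatch", "bad_config")
  }
  structure(cfg, class = "sim_config")
}

# Replace the aa at 0-based offset `col` of (nt, aa) with `res`.
mutate_residue <- function(nt, col, res) {
  codon <- PREFERRED_CODON[[res]]
  substr(nt, 3L * col + 1L, 3L * col + 3L) <- codon
  nt
}

# Synonymous toggle of the codon at 0-based aa offset `col`.
synonymous_variant <- function(nt, col) {
  codon <- substr(nt, 3L * col + 1L, 3L * col + 3L)
  aa <- GENETIC_CODE_STD[[codon]]
  alts <- setdiff(names(GENETIC_CODE_STD)[GENETIC_CODE_STD == aa], codon)
  if (!length(alts)) return(NULL)
  substr(nt, 3L * col + 1L, 3L * col + 3L) <- sort(alts)[1L]
  nt
}

#' Simulate a ZnF repeat library
#'
#' Mutates the base repeat at a planted set of variable aa columns, a
#' controlled fraction of which fall on the DNA-contact offsets (helix
#' positions -1, 3, 6); the serine at helix position 2 and the C2H2 scaffold
#' residues never vary. Optionally adds synonymous nucleotide variants.
#'
#' @param config A [sim_config()].
#' @return List of class `repeat_library`: `nt` (character vector of repeat
#'   nucleotide sequences; synonymous variants included), `aa`,
#'   `ground_truth` (list with `variable_columns`, `contact_columns`,
#'   `base_nt`).
#' @export
simulate_repeat_library <- function(config) {
  k <- config$n_variable_columns
  candidates <- setdiff(0:27, REPEAT_FIXED_OFFSETS)
  contact <- intersect(candidates, REPEAT_CONTACT_OFFSETS)
  noncontact <- setdiff(candidates, contact)
  with_seed(derive_seed(config$seed, 11L), {
    cols <- if (!is.null(config$contact_multiplier)) {
      w <- ifelse(candidates %in% contact, config$contact_multiplier, 1)
      if (all(w == 0)) abort2("all column weights zero", "bad_config")
      sample(candidates, k, prob = w)
    } else {
      kc <- min(round(k * config$contact_fraction), length(contact))
      c(sample(contact, kc), sample(noncontact, k - kc))
    }
    cols <- sort(cols)
    base_chars <- chars(BASE_REPEAT_AA)
    nts <- BASE_REPEAT_NT
    for (t in seq_len(config$n_repeat_types - 1L)) {
      nt <- BASE_REPEAT_NT
      n_mut <- sample(seq_along(cols), 1L)
      for (col in sample(cols, n_mut)) {
        res <- sample(setdiff(ALT_RESIDUES, base_chars[col + 1L]), 1L)
        nt <- mutate_residue(nt, col, res)
      }
      nts <- c(nts, nt)
    }
    nts <- unique(nts)
    # guarantee every planted column actually varies across the library
    aa_mat <- do.call(rbind, strsplit(vapply(nts, translate_nt, character(1),
                                             USE.NAMES = FALSE), ""))
    for (col in cols) {
      if (length(unique(aa_mat[, col + 1L])) < 2L) {
        res <- sample(setdiff(ALT_RESIDUES, base_chars[col + 1L]), 1L)
        nts <- c(nts, mutate_residue(BASE_REPEAT_NT, col, res))
      }
    }
    nts <- unique(nts)
    if (config$n_synonymous_variants > 0L) {
      syn_cols <- sample(setdiff(0:27, c(cols, REPEAT_FIXED_OFFSETS)),
                         config$n_synonymous_variants)
      for (col in syn_cols) {
        v <- synonymous_variant(nts[1L], col)
        if (!is.null(v)) nts <- c(nts, v)
      }
      nts <- unique(nts)
    }
    structure(
      list(nt = nts,
           aa = vapply(nts, translate_nt, character(1), USE.NAMES = FALSE),
           ground_truth = list(variable_columns = cols,
                               contact_columns = intersect(cols, contact),
                               base_nt = BASE_REPEAT_NT)),
      class = "repeat_library")
  })
}

# Assemble one array allele nt sequence from library repeats.
assemble_array <- function(library_nt, n_repeats, leading_truncated) {
  reps <- sample(library_nt, n_repeats, replace = TRUE)
  paste0(if (leading_truncated) TRUNCATED_LEAD_NT else "",
         paste(reps, collapse = ""))
}

#' Simulate a diploid ZnF-array population
#'
#' Per group, a small set of distinct array alleles is built from the repeat
#' library and assigned frequencies shaped as "one common allele plus an even
#' tail". Each individual draws two alleles; with probability
#' `heterozygote_dropout` the second record is not recovered (emulating
#' incomplete allele recovery). Optionally the first `n_shared_alleles`
#' alleles are shared between the first two groups.
#'
#' Exact spectra: pass `exact_spectra` (named list: group -> integer counts
#' per allele, summing to `2 * individuals` of the group) to realize given
#' per-sequence allele counts instead of random draws (requires dropout 0).
#'
#' @param config A [sim_config()].
#' @param exact_spectra Optional list of per-group allele count vectors.
#' @return List of class `znf_population`: `fasta` (named character vector of
#'   phased allele sequences, names `sample.index`), `groups` (data frame
#'   `sample_id`, `group`), `ground_truth` (allele sequences per group, the
#'   per-sequence allele assignments, genotypes, and the repeat-library
#'   ground truth).
#' @export
simulate_znf_population <- function(config, exact_spectra = NULL) {
  lib <- simulate_repeat_library(config)
  with_seed(derive_seed(config$seed, 23L), {
    rng <- config$array_length_range
    gnames <- names(config$groups)
    alleles_by_group <- list()
    for (g in gnames) {
      n_all <- if (!is.null(exact_spectra[[g]]))
        length(exact_spectra[[g]]) else config$n_alleles_per_group
      seqs <- character(0)
      guard <- 0L
      while (length(seqs) < n_all && guard < 200L) {
        s <- assemble_array(lib$nt, sample(rng[1L]:rng[2L], 1L),
                            config$leading_truncated)
        if (!s %in% seqs) seqs <- c(seqs, s)
        guard <- guard + 1L
      }
      alleles_by_group[[g]] <- seqs
    }
    if (config$n_shared_alleles > 0L && length(gnames) >= 2L) {
      idx <- seq_len(config$n_shared_alleles)
      alleles_by_group[[gnames[2L]]][idx] <- alleles_by_group[[gnames[1L]]][idx]
    }
    fasta <- character(0)
    grows <- list()
    assignments <- list()
    genotypes <- list()
    for (g in gnames) {
      n_ind <- config$groups[[g]]
      seqs <- alleles_by_group[[g]]
      n_all <- length(seqs)
      if (!is.null(exact_spectra[[g]])) {
        cnt <- exact_spectra[[g]]
        if (sum(cnt) != 2L * n_ind) {
          abort2("exact spectrum must sum to 2 * individuals", "bad_config")
        }
        slots <- sample(rep(seq_len(n_all), cnt))
      } else {
        freq <- c(config$common_allele_freq,
                  rep((1 - config$common_allele_freq) / max(n_all - 1L, 1L),
                      n_all - 1L))
        slots <- sample(seq_len(n_all), 2L * n_ind, replace = TRUE,
                        prob = freq)
      }
      for (i in seq_len(n_ind)) {
        sid <- sprintf("%s_ind%02d", g, i)
        a1 <- slots[2L * i - 1L]; a2 <- slots[2L * i]
        keep2 <- stats::runif(1) >= config$heterozygote_dropout
        fasta[[paste0(sid, ".1")]] <- seqs[a1]
        assignments[[paste0(sid, ".1")]] <- c(group = g, allele = a1)
        if (keep2) {
          fasta[[paste0(sid, ".2")]] <- seqs[a2]
          assignments[[paste0(sid, ".2")]] <- c(group = g, allele = a2)
        }
        genotypes[[sid]] <- c(a1, a2)
        grows[[sid]] <- data.frame(sample_id = sid, group = g,
                                   stringsAsFactors = FALSE)
      }
    }
    structure(
      list(fasta = fasta, groups = do.call(rbind, grows),
           ground_truth = list(
             alleles_by_group = alleles_by_group,
             assignments = assignments, genotypes = genotypes,
             library = lib$ground_truth,
             library_nt = lib$nt)),
      class = "znf_population")
  })
}

#' Simulate (or transcribe) a grouped allele spectrum
#'
#' With `counts` given (data frame `group`, `allele`, `count`), transcribes
#' it literally into a [grouped_spectrum()] — used to replicate published
#' tables exactly. Otherwise samples, per group, `n` sequences from a
#' "one common allele + even tail" frequency distribution.
#'
#' @param config A [sim_config()]; `groups` is interpreted as sequences per
#'   group here.
#' @param counts Optional literal counts table.
#' @return List of class `spectrum_sim`: `spectrum`, `ground_truth` (counts
#'   per group/allele).
#' @export
simulate_grouped_spectrum <- function(config, counts = NULL) {
  if (!is.null(counts)) {
    spec <- spectrum_from_counts(counts)
    return(structure(list(spectrum = spec, ground_truth = counts),
                     class = "spectrum_sim"))
  }
  with_seed(derive_seed(config$seed, 37L), {
    labs <- list()
    for (g in names(config$groups)) {
      n <- config$groups[[g]]
      n_all <- config$n_alleles_per_group
      freq <- c(config$common_allele_freq,
                rep((1 - config$common_allele_freq) / max(n_all - 1L, 1L),
                    n_all - 1L))
      labs[[g]] <- paste0(g, "_a",
                          sample(seq_len(n_all), n, TRUE, prob = freq))
    }
    spec <- grouped_spectrum(labs)
    gt <- do.call(rbind, lapply(names(labs), function(g) {
      tab <- table(labs[[g]])
      data.frame(group = g, allele = names(tab),
                 count = as.integer(tab), stringsAsFactors = FALSE)
    }))
    structure(list(spectrum = spec, ground_truth = gt),
              class = "spectrum_sim")
  })
}

#' Build an array with planted two-block structure
#'
#' Concatenates two internally identical repeat families that differ at
#' `round(two_block_gap * 28)` amino-acid columns, the first family filling
#' the first half of the array. The realized identity gap (the expected
#' [two_block_score()]) is recorded in the ground truth.
#'
#' @param config A [sim_config()] (`two_block_gap`, `two_block_length`).
#' @return List of class `two_block_sim`: `allele` (a [znf_allele()]),
#'   `ground_truth` (`gap`, `split`, family sequences).
#' @export
make_two_block_array <- function(config) {
  L <- config$two_block_length
  if (L < 4L) abort2("two-block array needs length >= 4", "bad_config")
  with_seed(derive_seed(config$seed, 53L), {
    n_diff <- round(config$two_block_gap * 28L)
    candidates <- setdiff(0:27, REPEAT_FIXED_OFFSETS)
    cols <- sample(candidates, min(n_diff, length(candidates)))
    fam_a <- BASE_REPEAT_NT
    fam_b <- BASE_REPEAT_NT
    base_chars <- chars(BASE_REPEAT_AA)
    for (col in cols) {
      res <- sample(setdiff(ALT_RESIDUES, base_chars[col + 1L]), 1L)
      fam_b <- mutate_residue(fam_b, col, res)
    }
    h <- ceiling(L / 2)
    nt <- paste(c(rep(fam_a, h), rep(fam_b, L - h)), collapse = "")
    allele <- parse_znf_allele(nt, "twoblock", leading_truncated = FALSE)
    structure(
      list(allele = allele,
           ground_truth = list(gap = length(cols) / 28,
                               split = h, family_a = fam_a,
                               family_b = fam_b)),
      class = "two_block_sim")
  })
}

#' Simulate a codon alignment under a site-class model
#'
#' Draws a class per site from the mixture, then evolves codons along the
#' tree under the same GY94-style process the fitter uses (root states from
#' the stationary distribution; the mixture-average rate is normalized to 1
#' so branch lengths are expected substitutions per codon).
#'
#' @param config A [sim_config()] (`model`, `kappa`, `props`, `omegas`,
#'   `n_sites`, `n_taxa`, `branch_length_range`, `codon_freqs`, `seed`).
#' @param tree Optional `ape::phylo`; by default a random topology with
#'   uniform branch lengths in `branch_length_range` is generated.
#' @param freq_incorporation See [codon_rate_matrix()].
#' @return List of class `codon_sim`: `aln` (a [codon_alignment()]), `tree`,
#'   `ground_truth` (`site_classes`, `selected_sites`, the parameters).
#' @export
simulate_codon_alignment <- function(config, tree = NULL,
                                     freq_incorporation = "GY") {
  with_seed(derive_seed(config$seed, 71L), {
    if (is.null(tree)) {
      tree <- ape::rtree(config$n_taxa, rooted = TRUE,
                         br = function(n) stats::runif(
                           n, config$branch_length_range[1L],
                           config$branch_length_range[2L]))
    }
    pi <- config$codon_freqs
    if (is.null(pi)) {
      pi <- rep(1 / length(SENSE_CODONS), length(SENSE_CODONS))
      names(pi) <- SENSE_CODONS
    }
    attr(pi, "nt_freqs") <- {
      # product-measure nucleotide frequencies implied by pi (for MuseGaut)
      cm <- codon_nt_matrix()
      sapply(1:3, function(p)
        vapply(NUC, function(nc) sum(pi[cm[, p] == nc]), numeric(1)))
    }
    props <- config$props
    omegas <- config$omegas
    classes <- sample(seq_along(props), config$n_sites, TRUE, prob = props)
    qs <- lapply(omegas, function(w)
      codon_rate_matrix(config$kappa, w, pi, freq_incorporation))
    mean_rate <- sum(props * vapply(qs, `[[`, numeric(1), "rate"))
    eigs <- lapply(qs, function(q)
      codon_eigen(q$Q, stationary_pi(pi, freq_incorporation)))
    tr <- stats::reorder(tree, "postorder")
    ntip <- length(tr$tip.label)
    nnode <- ntip + tr$Nnode
    states <- matrix(NA_integer_, nnode, config$n_sites)
    root <- ntip + 1L
    states[root, ] <- sample(seq_along(pi), config$n_sites, TRUE, prob = pi)
    edge_order <- rev(seq_len(nrow(tr$edge)))  # parents before children
    pmats <- vector("list", length(omegas))
    for (k in edge_order) {
      par <- tr$edge[k, 1L]; child <- tr$edge[k, 2L]
      t_eff <- tr$edge.length[k] / mean_rate
      for (c in seq_along(omegas)) {
        pmats[[c]] <- codon_pmat(eigs[[c]], t_eff)
      }
      states[child, ] <- vapply(seq_len(config$n_sites), function(s) {
        sample.int(length(pi), 1L, prob = pmats[[classes[s]]][
          states[par, s], ])
      }, integer(1))
    }
    seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L, function(st)
      paste(SENSE_CODONS[st], collapse = ""))
    names(seqs) <- tr$tip.label
    aln <- codon_alignment(seqs)
    structure(
      list(aln = aln, tree = tree,
           ground_truth = list(
             site_classes = classes,
             selected_sites = which(omegas[classes] > 1),
             model = config$model, kappa = config$kappa,
             props = props, omegas = omegas)),
      class = "codon_sim")
  })
}
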