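# Codon site-model machinery. The heavier simulation-recovery checks live in
# test-acceptance.R; these tests pin the building blocks against independent
# oracles on small instances.

test_that("codon frequency models are proper distributions", {
  sim <- simulate_codon_alignment(sim_config(seed = 2, n_taxa = 5,
                                             n_sites = 60))
  for (m in c("F3x4", "F1x4", "F61")) {
    pi <- codon_frequencies(sim$aln, m)
    expect_equal(sum(pi), 1)
    expect_true(all(pi > 0))
    expect_length(pi, 61L)
    expect_false(any(names(pi) %in% prdm9znf:::STOP_CODONS))
  }
  # F60 is an alias
  expect_equal(codon_frequencies(sim$aln, "F60"),
               codon_frequencies(sim$aln, "F61"))
})

test_that("rate matrices are proper reversible generators", {
  sim <- simulate_codon_alignment(sim_config(seed = 3, n_taxa = 4,
                                             n_sites = 50))
  pi <- codon_frequencies(sim$aln, "F3x4")
  for (fi in c("GY", "MuseGaut", "GoldmanWhelan")) {
    q <- prdm9znf:::codon_rate_matrix(2, 0.5, pi, fi)
    expect_equal(unname(rowSums(q$Q)), rep(0, 61), tolerance = 1e-12)
    pst <- prdm9znf:::stationary_pi(pi, fi)
    # detailed balance
    db <- pst * q$Q
    expect_equal(db, t(db), tolerance = 1e-12, ignore_attr = TRUE)
    # stationarity
    expect_equal(as.vector(pst %*% q$Q), rep(0, 61), tolerance = 1e-12)
  }
})

test_that("pruning equals the dense matrix-exponential oracle (<= 2 taxa, <= 3 sites)", {
  tree <- ape::read.tree(text = "(A:0.07,B:0.31);")
  cfg <- sim_config(seed = 5, n_taxa = 2, n_sites = 3, kappa = 3,
                    props = 1, omegas = 0.5)
  sim <- simulate_codon_alignment(cfg, tree)
  pi <- codon_frequencies(sim$aln, "F3x4")
  for (fi in c("GY", "MuseGaut", "GoldmanWhelan")) {
    ll <- codon_mixture_loglik(sim$aln, tree, kappa = 3, props = 1,
                               omegas = 0.5, pi = pi,
                               freq_incorporation = fi)
    q <- prdm9znf:::codon_rate_matrix(3, 0.5, pi, fi)
    pst <- prdm9znf:::stationary_pi(pi, fi)
    Qs <- q$Q / q$rate
    ll_dense <- sum(vapply(seq_len(sim$aln$n_sites), function(s) {
      log(dense_site_likelihood(
        tree, list(A = sim$aln$states["A", s], B = sim$aln$states["B", s]),
        Qs, pst))
    }, numeric(1)))
    expect_equal(ll, ll_dense, tolerance = 1e-8)
  }
})

test_that("mixture likelihood equals the dense oracle on a 3-taxon mixture", {
  tree <- ape::read.tree(text = "(A:0.1,(B:0.2,C:0.15):0.05);")
  cfg <- sim_config(seed = 8, n_taxa = 3, n_sites = 3,
                    props = c(0.6, 0.4), omegas = c(0.2, 4), kappa = 2)
  sim <- simulate_codon_alignment(cfg, tree)
  pi <- codon_frequencies(sim$aln, "F1x4")
  props <- c(0.7, 0.3); omegas <- c(0.3, 5)
  ll <- codon_mixture_loglik(sim$aln, tree, kappa = 2, props = props,
                             omegas = omegas, pi = pi)
  qs <- lapply(omegas, function(w) prdm9znf:::codon_rate_matrix(2, w, pi))
  mean_rate <- sum(props * vapply(qs, `[[`, numeric(1), "rate"))
  ll_dense <- sum(vapply(seq_len(sim$aln$n_sites), function(s) {
    states <- as.list(sim$aln$states[, s])
    lik_c <- vapply(qs, function(q) dense_site_likelihood(
      tree, states, q$Q / mean_rate, pi), numeric(1))
    log(sum(props * lik_c))
  }, numeric(1)))
  expect_equal(ll, ll_dense, tolerance = 1e-8)
})

test_that("build_codon_alignment dedupes repeats and drops the truncated lead", {
  r <- vapply(1:5, function(i) random_codon_nt(28, seed = 200 + i),
              character(1))
  aln <- build_codon_alignment(r)
  expect_equal(dim(aln$codons), c(5L, 28L))

  al1 <- allele_from_repeats(c(r[1], r[2], r[1]), id = "a",
                             truncated_lead = TRUE)
  al2 <- allele_from_repeats(c(r[2], r[3]), id = "b")
  aln2 <- build_codon_alignment(list(al1, al2))
  expect_equal(length(aln2$taxa), 3L)  # set-size oracle: unique of {1,2,1,2,3}
  expect_equal(aln2$n_excluded_truncated, 1L)
  expect_equal(length(unique(c(r[1], r[2], r[1], r[2], r[3]))), 3L)

  aln3 <- build_codon_alignment(list(al1, al2), dedupe = FALSE)
  expect_equal(length(aln3$taxa), 5L)

  expect_error(codon_alignment(c(a = "TAA")), class = "stop_codon")
  expect_error(codon_alignment(c(a = "ACGTT", b = "ACG")),
               class = "ragged_alignment")
})

test_that("likelihood_ratio_test handles the recognized pairs and edge cases", {
  f <- function(model, lnL) structure(list(model = model, lnL = lnL),
                                      class = "site_model_fit")
  lr <- likelihood_ratio_test(f("M1a", -100), f("M2a", -93.25))
  expect_equal(lr$two_delta_l, 13.5)
  expect_equal(lr$df, 2L)
  expect_equal(lr$p_value, exp(-13.5 / 2), tolerance = 1e-12)

  eq <- likelihood_ratio_test(f("M7", -50), f("M8", -50))
  expect_equal(eq$two_delta_l, 0)
  expect_equal(eq$p_value, 1)
  # small negative differences are clipped at zero
  expect_equal(likelihood_ratio_test(f("M0", -50),
                                     f("M3", -50.0001))$two_delta_l, 0)
  expect_error(likelihood_ratio_test(f("M0", -50), f("M8", -49)),
               class = "bad_model_pair")
})

test_that("M0 recovers simulated omega within 3 SE and refits agree", {
  cfg <- sim_config(seed = 13, n_taxa = 8, n_sites = 500, kappa = 2,
                    props = 1, omegas = 0.3)
  sim <- simulate_codon_alignment(cfg)
  fit <- fit_site_model(sim$aln, sim$tree, "M0", n_restarts = 1, seed = 1)
  se <- fit_parameter_se(fit)
  expect_true(fit$converged)
  expect_lt(abs(log(fit$omega) - log(0.3)), 3 * se[["lw"]])
  expect_lt(abs(log(fit$kappa) - log(2)), 3 * se[["log_kappa"]])
  # run twice (jittered restart) -> same lnL within 1e-3
  fit2 <- fit_site_model(sim$aln, sim$tree, "M0", n_restarts = 2, seed = 99)
  expect_lt(abs(fit$lnL - fit2$lnL), 1e-3)
})

test_that("NEB posteriors equal Bayes' rule computed from dense per-class likelihoods", {
  tree <- ape::read.tree(text = "(A:0.1,(B:0.2,C:0.15):0.05);")
  cfg <- sim_config(seed = 17, n_taxa = 3, n_sites = 4,
                    props = c(0.5, 0.3, 0.2), omegas = c(0.2, 1, 6))
  sim <- simulate_codon_alignment(cfg, tree)
  pi <- codon_frequencies(sim$aln, "F3x4")
  props <- c(0.55, 0.3, 0.15); omegas <- c(0.25, 1, 5)
  fake_fit <- structure(list(
    model = "M2a", omegas = omegas, proportions = props, kappa = 2.2,
    branch_scale = 1, aln = sim$aln, tree = tree, pi = pi,
    freq_incorporation = "GY"), class = "site_model_fit")
  neb <- empirical_bayes_site_classes(fake_fit, "NEB")

  qs <- lapply(omegas, function(w) prdm9znf:::codon_rate_matrix(2.2, w, pi))
  mean_rate <- sum(props * vapply(qs, `[[`, numeric(1), "rate"))
  for (s in seq_len(sim$aln$n_sites)) {
    lik_c <- vapply(qs, function(q) dense_site_likelihood(
      tree, as.list(sim$aln$states[, s]), q$Q / mean_rate, pi), numeric(1))
    post <- props * lik_c / sum(props * lik_c)
    expect_equal(neb$P[s], post[3], tolerance = 1e-8)
    expect_equal(neb$post_mean_omega[s], sum(post * omegas),
                 tolerance = 1e-8)
  }
  expect_true(all(neb$P >= 0 & neb$P <= 1))
  expect_error(empirical_bayes_site_classes(
    structure(list(model = "M1a"), class = "site_model_fit")),
    class = "no_selection_class")
})

test_that("posteriors equal prior proportions when the alignment is uninformative", {
  # identical rows: every class explains the data equally well
  tree <- ape::read.tree(text = "(A:0.1,(B:0.2,C:0.15):0.05);")
  nt <- random_codon_nt(10, seed = 31)
  aln <- codon_alignment(c(A = nt, B = nt, C = nt))
  # zero-length tree: likelihood independent of omega
  tree0 <- tree; tree0$edge.length[] <- 0
  pi <- codon_frequencies(aln, "F3x4")
  fake <- structure(list(
    model = "M2a", omegas = c(0.2, 1, 7), proportions = c(0.5, 0.4, 0.1),
    kappa = 2, branch_scale = 1, aln = aln, tree = tree0, pi = pi,
    freq_incorporation = "GY"), class = "site_model_fit")
  neb <- empirical_bayes_site_classes(fake, "NEB")
  expect_equal(neb$P, rep(0.1, 10), tolerance = 1e-10)
})

test_that("BEB on strong simulated selection ranks planted sites on top", {
  cfg <- sim_config(seed = 19, n_taxa = 10, n_sites = 80, kappa = 2,
                    props = c(0.6, 0.3, 0.1), omegas = c(0.2, 1, 8),
                    branch_length_range = c(0.05, 0.2))
  sim <- simulate_codon_alignment(cfg)
  fit <- fit_site_model(sim$aln, sim$tree, "M2a", n_restarts = 1, seed = 3)
  beb <- empirical_bayes_site_classes(fit, "BEB")
  neb <- empirical_bayes_site_classes(fit, "NEB")
  sel <- sim$ground_truth$selected_sites
  expect_true(length(sel) >= 3)
  expect_gt(mean(beb$P[sel]), mean(beb$P[-sel]))
  # NEB and BEB broadly agree on ranking here
  expect_gt(stats::cor(beb$P, neb$P, method = "spearman"), 0.8)
})

test_that("sitewise test flags invariant sites and finds a planted selected site", {
  cfg <- sim_config(seed = 23, n_taxa = 10, n_sites = 150, kappa = 2,
                    props = c(0.95, 0.05), omegas = c(0.15, 12),
                    branch_length_range = c(0.05, 0.2))
  sim <- simulate_codon_alignment(cfg)
  sw <- sitewise_selection_test(sim$aln, sim$tree)
  expect_equal(nrow(sw), 150L)
  expect_true(all(sw$lrt >= 0))
  expect_true(all(sw$p[sw$invariant] == 1))
  expect_true(all(is.na(sw$omega_hat[sw$invariant])))
  sel <- sim$ground_truth$selected_sites
  expect_true(length(sel) >= 2)
  expect_true(which.min(sw$p) %in% sel)
})

test_that("neighbor_joining_tree recovers additive topologies deterministically", {
  aln3 <- build_codon_alignment(vapply(1:3, function(i)
    random_codon_nt(30, seed = 300 + i), character(1)))
  tr3 <- neighbor_joining_tree(aln3)
  expect_s3_class(tr3, "phylo")
  expect_equal(length(tr3$tip.label), 3L)

  # 4-taxon: simulate on a known topology with distinct branch lengths and
  # check NJ recovers the split
  tree4 <- ape::read.tree(text = "((A:0.05,B:0.05):0.1,(C:0.05,D:0.05):0.1);")
  sim <- simulate_codon_alignment(sim_config(seed = 29, n_sites = 400,
                                             props = 1, omegas = 0.5),
                                  tree4)
  nj <- neighbor_joining_tree(sim$aln)
  expect_true(all(nj$edge.length >= 0))
  # A+B form a clade in the unrooted tree
  d <- ape::cophenetic.phylo(nj)
  expect_lt(d["A", "B"], d["A", "C"])
  expect_lt(d["C", "D"], d["B", "C"])

  # identical sequences -> all pairwise distances zero
  nt <- random_codon_nt(20, seed = 41)
  aln_same <- codon_alignment(c(a = nt, b = nt, c = nt))
  tr_same <- neighbor_joining_tree(aln_same)
  expect_equal(sum(tr_same$edge.length), 0)
  expect_error(neighbor_joining_tree(codon_alignment(c(a = nt, b = nt))),
               class = "bad_input")
})

test_that("simulated alignments behave at the degenerate limits", {
  # zero-length branches -> identical rows
  tree <- ape::rtree(5, br = function(n) rep(0, n))
  sim <- simulate_codon_alignment(sim_config(seed = 37, n_sites = 30,
                                             props = 1, omegas = 1), tree)
  seqs <- apply(sim$aln$codons, 1, paste, collapse = "")
  expect_equal(length(unique(seqs)), 1L)

  # determinism
  cfg <- sim_config(seed = 43, n_taxa = 6, n_sites = 40)
  s1 <- simulate_codon_alignment(cfg)
  s2 <- simulate_codon_alignment(cfg)
  expect_identical(s1$aln$codons, s2$aln$codons)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("M1a-vs-M2a LRT is calibrated (conservative) under the M1a null", {
  # data simulated under M1a: rejection rate at the chi2_2 5% cutoff should
  # not exceed 0.05 + MC error (the boundary null makes chi2 conservative)
  n_rep <- 8L
  rejected <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(seed = 600L + i, n_taxa = 6L, n_sites = 120L,
                      kappa = 2, props = c(0.7, 0.3), omegas = c(0.2, 1))
    sim <- simulate_codon_alignment(cfg)
    f1 <- fit_site_model(sim$aln, sim$tree, "M1a", n_restarts = 1L, seed = i)
    f2 <- fit_site_model(sim$aln, sim$tree, "M2a", n_restarts = 1L, seed = i)
    rejected[i] <- likelihood_ratio_test(f1, f2)$p_value <= 0.05
  }
  expect_lte(mean(rejected), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("neutral simulation yields omega-hat near 1 (neutral limit)", {
  cfg <- sim_config(seed = 47, n_taxa = 8, n_sites = 300, kappa = 2,
                    props = 1, omegas = 1)
  sim <- simulate_codon_alignment(cfg)
  fit <- fit_site_model(sim$aln, sim$tree, "M0", n_restarts = 1, seed = 2)
  se <- fit_parameter_se(fit)
  expect_lt(abs(log(fit$omega)), 3 * se[["lw"]])
})
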