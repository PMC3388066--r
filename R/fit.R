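# Site-model fitting (M0/M1a/M2a/M3/M7/M8), likelihood-ratio tests,
# empirical-Bayes site classification and the sitewise per-site omega test.
#
# Parameters are optimized on an unconstrained/box-transformed scale with
# nlminb: log(kappa), log branch scale, logistic-transformed omegas in (0,1),
# 1+exp(u) for selection omegas, softmax for class proportions, log beta
# shapes. Bounds follow common practice: omega in [1e-4, 50], kappa in
# [0.1, 50], beta shapes in [0.005, 99].

SITE_MODELS <- c("M0", "M1a", "M2a", "M3", "M7", "M8")

softmax <- function(z) {
  e <- exp(c(z, 0) - max(z, 0))
  e / sum(e)
}

model_pars <- function(model, ncat_beta = 10L) {
  K <- ncat_beta
  switch(model,
    M0 = list(
      names = "lw",
      lower = log(1e-4), upper = log(50),
      init = log(0.5),
      decode = function(v) list(omegas = exp(v[1L]), props = 1,
                                omega = exp(v[1L]))),
    M1a = list(
      names = c("zp0", "zw0"),
      lower = c(-15, -12), upper = c(15, 12),
      init = c(0.5, stats::qlogis(0.2)),
      decode = function(v) {
        p0 <- stats::plogis(v[1L]); w0 <- stats::plogis(v[2L])
        list(props = c(p0, 1 - p0), omegas = c(w0, 1), p0 = p0, omega0 = w0)
      }),
    M2a = list(
      names = c("z1", "z2", "zw0", "uw2"),
      lower = c(-15, -15, -12, -12), upper = c(15, 15, 12, log(49)),
      init = c(1.2, 0.9, stats::qlogis(0.2), log(2)),
      decode = function(v) {
        p <- softmax(v[1:2]); w0 <- stats::plogis(v[3L])
        w2 <- 1 + exp(v[4L])
        list(props = p, omegas = c(w0, 1, w2), p0 = p[1L], p1 = p[2L],
             p2 = p[3L], omega0 = w0, omega2 = w2)
      }),
    M3 = list(
      names = c("z1", "z2", "lw1", "lw2", "lw3"),
      lower = c(-15, -15, rep(log(1e-4), 3)),
      upper = c(15, 15, rep(log(50), 3)),
      init = c(0.7, 0.7, log(0.1), log(0.8), log(3)),
      decode = function(v) {
        p <- softmax(v[1:2]); w <- exp(v[3:5])
        o <- order(w)
        list(props = p[o], omegas = w[o])
      }),
    M7 = list(
      names = c("lp", "lq"),
      lower = rep(log(0.005), 2), upper = rep(log(99), 2),
      init = c(log(0.5), log(1.5)),
      decode = function(v) {
        p <- exp(v[1L]); q <- exp(v[2L])
        w <- pmax(stats::qbeta((seq_len(K) - 0.5) / K, p, q), 1e-6)
        list(props = rep(1 / K, K), omegas = w, beta_p = p, beta_q = q)
      }),
    M8 = list(
      names = c("zp0", "lp", "lq", "uws"),
      lower = c(-15, rep(log(0.005), 2), -12),
      upper = c(15, rep(log(99), 2), log(49)),
      init = c(2, log(0.5), log(1.5), log(2)),
      decode = function(v) {
        p0 <- stats::plogis(v[1L]); p <- exp(v[2L]); q <- exp(v[3L])
        ws <- 1 + exp(v[4L])
        w <- pmax(stats::qbeta((seq_len(K) - 0.5) / K, p, q), 1e-6)
        list(props = c(rep(p0 / K, K), 1 - p0), omegas = c(w, ws),
             p0 = p0, beta_p = p, beta_q = q, omega_s = ws)
      }),
    abort2(sprintf("unknown model '%s'", model), "bad_input"))
}

# Shared likelihood context so optimization does not re-plan the tree or
# re-compress patterns on every evaluation.
make_loglik_ctx <- function(aln, tree, pi, freq_incorporation) {
  list(plan = tree_plan(tree, aln$taxa),
       pc = pattern_compress(aln$states),
       pi = pi, pi_st = stationary_pi(pi, freq_incorporation),
       freq_incorporation = freq_incorporation)
}

ctx_class_loglik <- function(ctx, kappa, omegas, props, scale) {
  qs <- lapply(omegas, function(w)
    codon_rate_matrix(kappa, w, ctx$pi, ctx$freq_incorporation))
  mean_rate <- sum(props * vapply(qs, `[[`, numeric(1), "rate"))
  vapply(qs, function(q) {
    eig <- codon_eigen(q$Q, ctx$pi_st)
    class_pattern_loglik(ctx$plan, ctx$pc$states, eig, ctx$pi_st,
                         scale / mean_rate)
  }, numeric(ncol(ctx$pc$states)))
}

ctx_loglik <- function(ctx, kappa, omegas, props, scale,
                       per_site = FALSE) {
  cls <- ctx_class_loglik(ctx, kappa, omegas, props, scale)
  cls <- matrix(cls, ncol = length(omegas))
  site_log <- logsumexp_rows(cls, log(props))
  ll <- sum(site_log * ctx$pc$weights)
  if (!per_site) return(ll)
  list(loglik = ll, site_loglik = site_log[ctx$pc$map],
       class_site_loglik = cls[ctx$pc$map, , drop = FALSE])
}

#' Fit a codon site model by maximum likelihood
#'
#' Maximizes the pruning-algorithm likelihood of a GY94-style codon mixture
#' model. Site classes: M0 one ratio; M1a nearly-neutral (omega0 < 1, omega1
#' = 1); M2a adds a selection class (omega2 >= 1); M3 three free discrete
#' classes; M7 beta-distributed omega in (0, 1) (10 equal-probability
#' categories); M8 beta plus a selection class.
#'
#' Branch lengths are taken from `tree` and, under the default `branch_mode =
#' "scale"`, jointly rescaled by one free factor estimated with the model
#' parameters (branch lengths in expected substitutions per codon, averaged
#' over site classes); `"fixed"` keeps them untouched.
#'
#' @param aln A [codon_alignment()].
#' @param tree `ape::phylo` with branch lengths; see
#'   [neighbor_joining_tree()] for a fallback builder.
#' @param model One of `"M0"`, `"M1a"`, `"M2a"`, `"M3"`, `"M7"`, `"M8"`.
#' @param codon_freq_model `"F3x4"` (default), `"F1x4"`, `"F61"`/`"F60"`.
#' @param freq_incorporation See [codon_rate_matrix()].
#' @param n_restarts Optimizer restarts from jittered starts (default 3).
#' @param branch_mode `"scale"` (default) or `"fixed"`.
#' @param ncat_beta Discretization categories for M7/M8 (default 10).
#' @param seed Seed driving the restart jitter.
#' @param init Optional named list of natural starting values
#'   (`kappa`, `omega`, `omega0`, `omega2`, `p0`, ...).
#' @return Object of class `site_model_fit`: `model`, `lnL`, `kappa`,
#'   `branch_scale`, `proportions`, `omegas`, `beta_p`/`beta_q` (M7/M8),
#'   `codon_freq_model`, `freq_incorporation`, `converged`, `n_restarts`,
#'   plus the data (`aln`, `tree`, `pi`) needed downstream.
#' @export
fit_site_model <- function(aln, tree, model = SITE_MODELS,
                           codon_freq_model = "F3x4",
                           freq_incorporation = "GY",
                           n_restarts = 3L,
                           branch_mode = c("scale", "fixed"),
                           ncat_beta = 10L, seed = 1L, init = NULL) {
  model <- match.arg(model)
  branch_mode <- match.arg(branch_mode)
  if (length(aln$taxa) < 3L) abort2("need >= 3 taxa for tree-based fits",
                                    "bad_input")
  pi <- codon_frequencies(aln, codon_freq_model)
  ctx <- make_loglik_ctx(aln, tree, pi, freq_incorporation)
  mp <- model_pars(model, ncat_beta)
  use_scale <- branch_mode == "scale"
  lower <- c(log(0.1), if (use_scale) log(1e-3), mp$lower)
  upper <- c(log(50), if (use_scale) log(1e3), mp$upper)
  start0 <- c(log(2), if (use_scale) 0, mp$init)
  if (!is.null(init)) start0 <- encode_init(model, mp, init, use_scale, start0)

  negll <- function(theta) {
    kappa <- exp(theta[1L])
    scale <- if (use_scale) exp(theta[2L]) else 1
    dec <- mp$decode(theta[(2L + use_scale):length(theta)])
    val <- tryCatch(
      -ctx_loglik(ctx, kappa, dec$omegas, dec$props, scale),
      error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }

  best <- NULL
  convs <- logical(0)
  for (r in seq_len(max(1L, n_restarts))) {
    start <- if (r == 1L) start0 else with_seed(derive_seed(seed, r), {
      pmin(pmax(start0 + stats::rnorm(length(start0), 0, 0.6), lower), upper)
    })
    opt <- tryCatch(
      stats::nlminb(start, negll, lower = lower, upper = upper,
                    control = list(rel.tol = 1e-10, iter.max = 500L,
                                   eval.max = 2000L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    convs <- c(convs, opt$convergence == 0L)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) abort2("all optimizer restarts failed", "fit_failed")
  theta <- best$par
  kappa <- exp(theta[1L])
  scale <- if (use_scale) exp(theta[2L]) else 1
  dec <- mp$decode(theta[(2L + use_scale):length(theta)])
  structure(
    list(model = model, lnL = -best$objective, kappa = kappa,
         branch_scale = scale, proportions = dec$props,
         omegas = dec$omegas,
         omega = dec$omega, p0 = dec$p0, p1 = dec$p1, p2 = dec$p2,
         omega0 = dec$omega0, omega2 = dec$omega2, omega_s = dec$omega_s,
         beta_p = dec$beta_p, beta_q = dec$beta_q,
         codon_freq_model = codon_freq_model,
         freq_incorporation = freq_incorporation,
         branch_mode = branch_mode, ncat_beta = as.integer(ncat_beta),
         converged = any(convs), n_restarts = as.integer(max(1L, n_restarts)),
         theta = theta, lower = lower, upper = upper,
         aln = aln, tree = tree, pi = pi, use_scale = use_scale,
         negll = negll, mp = mp),
    class = "site_model_fit"
  )
}

encode_init <- function(model, mp, init, use_scale, start0) {
  v <- start0
  if (!is.null(init$kappa)) v[1L] <- log(init$kappa)
  if (use_scale && !is.null(init$scale)) v[2L] <- log(init$scale)
  off <- 1L + use_scale
  set <- function(i, val) v[off + i] <<- val
  if (model == "M0" && !is.null(init$omega)) set(1L, log(init$omega))
  if (model %in% c("M1a", "M2a") && !is.null(init$omega0)) {
    set(if (model == "M1a") 2L else 3L, stats::qlogis(init$omega0))
  }
  if (model == "M1a" && !is.null(init$p0)) set(1L, stats::qlogis(init$p0))
  if (model == "M2a") {
    if (!is.null(init$p0) && !is.null(init$p1)) {
      p2 <- max(1 - init$p0 - init$p1, 1e-4)
      set(1L, log(init$p0 / p2)); set(2L, log(init$p1 / p2))
    }
    if (!is.null(init$omega2)) set(4L, log(max(init$omega2 - 1, 1e-4)))
  }
  if (model == "M8") {
    if (!is.null(init$p0)) set(1L, stats::qlogis(init$p0))
    if (!is.null(init$omega_s)) set(4L, log(max(init$omega_s - 1, 1e-4)))
  }
  v
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("<site_model_fit %s> lnL = %.4f, kappa = %.3f, scale = %.3f\n",
              x$model, x$lnL, x$kappa, x$branch_scale))
  cat("  classes:\n")
  for (i in seq_along(x$proportions)) {
    cat(sprintf("    p%d = %.4f, omega = %.4f\n", i - 1L,
                x$proportions[i], x$omegas[i]))
  }
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' Standard errors for a fitted site model
#'
#' Numerical (central-difference) observed-information standard errors on
#' the optimizer's transformed scale, delta-method mapped to the requested
#' natural parameters.
#'
#' @param fit A [fit_site_model()] result.
#' @return Named numeric vector of standard errors for `kappa`, the branch
#'   scale and the model's omega/proportion parameters (on their natural
#'   scale); `log_omega*` entries give log-scale SEs for omegas.
#' @export
fit_parameter_se <- function(fit) {
  f <- fit$negll
  th <- fit$theta
  d <- length(th)
  h <- pmax(abs(th), 1) * 1e-4
  H <- matrix(NA_real_, d, d)
  f0 <- f(th)
  for (i in seq_len(d)) for (j in i:d) {
    ei <- ej <- numeric(d); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (f(th + ei) - 2 * f0 + f(th - ei)) / h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (f(th + ei + ej) - f(th + ei - ej) - f(th - ei + ej) +
           f(th - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  V <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, d, d)
  })
  se_theta <- sqrt(pmax(diag(V), 0))
  names(se_theta) <- c("log_kappa", if (fit$use_scale) "log_scale",
                       fit$mp$names)
  se_theta
}

LRT_PAIRS <- list(
  c("M0", "M3", df = 4L),
  c("M1a", "M2a", df = 2L),
  c("M7", "M8", df = 2L)
)

#' Likelihood-ratio test for a nested site-model pair
#'
#' Recognized pairs: M0 vs M3 (df 4), M1a vs M2a (df 2), M7 vs M8 (df 2).
#' The statistic 2(lnL_alt - lnL_null) is clipped at zero; the p-value is the
#' chi-square upper tail at the pair's degrees of freedom.
#'
#' @param null_fit,alt_fit [fit_site_model()] results, or (for desk checks of
#'   published statistics) use [chisq_lrt_pvalue()] directly.
#' @return List of class `lrt_result`: `null_model`, `alt_model`,
#'   `two_delta_l`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit) {
  pair <- vapply(LRT_PAIRS, function(p)
    p[[1L]] == null_fit$model && p[[2L]] == alt_fit$model, logical(1))
  if (!any(pair)) {
    abort2(sprintf("unrecognized nested pair %s vs %s", null_fit$model,
                   alt_fit$model), "bad_model_pair")
  }
  df <- as.integer(LRT_PAIRS[[which(pair)]][[3L]])
  stat <- max(0, 2 * (alt_fit$lnL - null_fit$lnL))
  structure(
    list(null_model = null_fit$model, alt_model = alt_fit$model,
         two_delta_l = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
    class = "lrt_result"
  )
}

#' Chi-square upper-tail p-value for a likelihood-ratio statistic
#'
#' @param two_delta_l The statistic 2(lnL_alt - lnL_null).
#' @param df Degrees of freedom.
#' @export
chisq_lrt_pvalue <- function(two_delta_l, df) {
  stats::pchisq(max(0, two_delta_l), df, lower.tail = FALSE)
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2dl = %.3f, df = %d, p = %.3g\n",
              x$null_model, x$alt_model, x$two_delta_l, x$df, x$p_value))
  invisible(x)
}

selection_class_index <- function(fit) {
  if (!fit$model %in% c("M2a", "M8")) {
    abort2(sprintf("model %s has no positive-selection class", fit$model),
           "no_selection_class")
  }
  length(fit$omegas)  # the omega > 1 class is last by construction
}

#' Empirical-Bayes classification of sites into omega classes
#'
#' Computes, for every codon site, the posterior probability of membership
#' in the positive-selection class of an M2a or M8 fit, and the posterior
#' mean (and sd) of omega. `method = "NEB"` (default) plugs in the ML
#' parameter estimates; `method = "BEB"` (M2a only) integrates over the
#' mixture parameters on a uniform grid (10-point grids over the (p0, p1)
#' simplex, omega0 in (0,1) and omega2 in (1,11)), which accounts for their
#' sampling error.
#'
#' @param fit A [fit_site_model()] result for M2a or M8.
#' @param method `"NEB"` or `"BEB"`.
#' @return Data frame of class `site_posterior`: `site`, `P` (posterior of
#'   the selection class), `post_mean_omega`, `post_sd_omega`, `method`.
#' @export
empirical_bayes_site_classes <- function(fit, method = c("NEB", "BEB")) {
  method <- match.arg(method)
  sel <- selection_class_index(fit)
  if (method == "BEB" && fit$model != "M8") {
    return(beb_m2a(fit))
  }
  if (method == "BEB" && fit$model == "M8") {
    # BEB grids for M8 are not implemented; fall back to NEB with a note.
    out <- empirical_bayes_site_classes(fit, "NEB")
    out$method <- "NEB"
    attr(out, "note") <- "BEB unavailable for M8; NEB reported"
    return(out)
  }
  ctx <- make_loglik_ctx(fit$aln, fit$tree, fit$pi, fit$freq_incorporation)
  ps <- ctx_loglik(ctx, fit$kappa, fit$omegas, fit$proportions,
                   fit$branch_scale, per_site = TRUE)
  lp <- sweep(ps$class_site_loglik, 2L, log(fit$proportions), `+`)
  post <- exp(lp - apply(lp, 1L, logsumexp))
  mean_w <- as.vector(post %*% fit$omegas)
  var_w <- as.vector(post %*% fit$omegas^2) - mean_w^2
  out <- data.frame(site = seq_len(fit$aln$n_sites), P = post[, sel],
                    post_mean_omega = mean_w,
                    post_sd_omega = sqrt(pmax(var_w, 0)),
                    method = "NEB", stringsAsFactors = FALSE)
  class(out) <- c("site_posterior", class(out))
  out
}

# Bayes empirical Bayes for M2a: uniform prior over a grid of the mixture
# parameters (p0, p1 on the simplex; omega0 in (0,1); omega2 in (1,11)),
# other parameters (kappa, branch lengths, frequencies) fixed at their MLEs.
beb_m2a <- function(fit, ngrid = 10L) {
  ctx <- make_loglik_ctx(fit$aln, fit$tree, fit$pi, fit$freq_incorporation)
  mids <- (seq_len(ngrid) - 0.5) / ngrid
  w0g <- mids                 # omega0 grid in (0, 1)
  w2g <- 1 + 10 * mids        # omega2 grid in (1, 11)
  # Class-site log-likelihoods for each grid omega (proportions do not enter
  # the per-class likelihoods; rate normalization uses the MLE mixture so
  # branch lengths keep their fitted meaning).
  qs_fit <- lapply(fit$omegas, function(w)
    codon_rate_matrix(fit$kappa, w, ctx$pi, ctx$freq_incorporation))
  mean_rate <- sum(fit$proportions * vapply(qs_fit, `[[`, numeric(1), "rate"))
  cls_for <- function(w) {
    q <- codon_rate_matrix(fit$kappa, w, ctx$pi, ctx$freq_incorporation)
    eig <- codon_eigen(q$Q, ctx$pi_st)
    class_pattern_loglik(ctx$plan, ctx$pc$states, eig, ctx$pi_st,
                         fit$branch_scale / mean_rate)[ctx$pc$map]
  }
  L0 <- vapply(w0g, cls_for, numeric(fit$aln$n_sites))  # sites x 10
  L1 <- cls_for(1)
  L2 <- vapply(w2g, cls_for, numeric(fit$aln$n_sites))
  # p-grid over the (p0, p1) triangle.
  pg <- expand.grid(p0 = mids, p1 = mids)
  pg <- pg[pg$p0 + pg$p1 <= 1, , drop = FALSE]
  pg$p2 <- pmax(1 - pg$p0 - pg$p1, 0)  # guard rounding at the simplex edge
  nsite <- fit$aln$n_sites
  n_combo <- nrow(pg) * ngrid * ngrid
  log_post <- numeric(n_combo)
  P_acc <- numeric(nsite); m1 <- numeric(nsite); m2 <- numeric(nsite)
  store <- vector("list", n_combo)
  k <- 0L
  for (a in seq_len(ngrid)) for (b in seq_len(ngrid)) {
    for (r in seq_len(nrow(pg))) {
      k <- k + 1L
      lp <- cbind(log(pg$p0[r]) + L0[, a], log(pg$p1[r]) + L1,
                  log(pg$p2[r]) + L2[, b])
      m <- apply(lp, 1L, max)
      den <- m + log(rowSums(exp(lp - m)))
      log_post[k] <- sum(den)
      store[[k]] <- list(post2 = exp(lp[, 3L] - den),
                         mw = exp(lp[, 1L] - den) * w0g[a] +
                              exp(lp[, 2L] - den) +
                              exp(lp[, 3L] - den) * w2g[b],
                         mw2 = exp(lp[, 1L] - den) * w0g[a]^2 +
                               exp(lp[, 2L] - den) +
                               exp(lp[, 3L] - den) * w2g[b]^2)
    }
  }
  wgrid <- exp(log_post - logsumexp(log_post))
  for (k in seq_len(n_combo)) {
    P_acc <- P_acc + wgrid[k] * store[[k]]$post2
    m1 <- m1 + wgrid[k] * store[[k]]$mw
    m2 <- m2 + wgrid[k] * store[[k]]$mw2
  }
  out <- data.frame(site = seq_len(nsite), P = P_acc, post_mean_omega = m1,
                    post_sd_omega = sqrt(pmax(m2 - m1^2, 0)),
                    method = "BEB", stringsAsFactors = FALSE)
  class(out) <- c("site_posterior", class(out))
  out
}

#' Sitewise likelihood-ratio test for positive selection
#'
#' A direct per-site test of neutrality in the spirit of sitewise
#' likelihood-ratio (SLR) testing: global parameters (kappa and the branch
#' scale) are estimated once under a single-ratio (M0) reference, then each
#' site's omega is maximized on a dense log-spaced grid and compared against
#' omega = 1 by a one-tailed likelihood-ratio test restricted to positive
#' selection (p = 0.5 * chi2_1 upper tail when the site's omega-hat exceeds
#' 1, else 1). Grid maximization makes the test slightly conservative.
#'
#' @param aln A [codon_alignment()].
#' @param tree `ape::phylo` with branch lengths.
#' @param codon_freq_model See [codon_frequencies()].
#' @param freq_incorporation `"MuseGaut"` (default) or `"GoldmanWhelan"`
#'   (`"GY"` also accepted).
#' @param n_grid Number of omega grid points between 1e-3 and 50 (default
#'   40; omega = 1 is always included).
#' @param correction Multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"holm"`).
#' @param alpha Significance levels for the adjusted flags.
#' @param seed Seed for the reference-model restarts.
#' @return Data frame of class `sitewise_result`: `site`, `omega_hat`,
#'   `lrt`, `p`, `p_adj`, `sig_adj_05`, `sig_adj_01`, `invariant`; attributes
#'   `kappa`, `branch_scale`, `freq_incorporation`.
#' @export
sitewise_selection_test <- function(aln, tree, codon_freq_model = "F3x4",
                                    freq_incorporation = c("MuseGaut",
                                                           "GoldmanWhelan",
                                                           "GY"),
                                    n_grid = 40L, correction = "holm",
                                    alpha = c(0.05, 0.01), seed = 1L) {
  freq_incorporation <- match.arg(freq_incorporation)
  ref <- fit_site_model(aln, tree, "M0", codon_freq_model,
                        freq_incorporation, n_restarts = 1L, seed = seed)
  ctx <- make_loglik_ctx(aln, tree, ref$pi, freq_incorporation)
  grid <- sort(unique(c(exp(seq(log(1e-3), log(50), length.out = n_grid)),
                        1)))
  # Rate normalization fixed at the reference omega so the branch scale keeps
  # its meaning across candidate omegas (global parameters are shared).
  q_ref <- codon_rate_matrix(ref$kappa, ref$omega, ctx$pi,
                             freq_incorporation)
  eff_scale <- ref$branch_scale / q_ref$rate
  site_ll <- vapply(grid, function(w) {
    q <- codon_rate_matrix(ref$kappa, w, ctx$pi, freq_incorporation)
    eig <- codon_eigen(q$Q, ctx$pi_st)
    class_pattern_loglik(ctx$plan, ctx$pc$states, eig, ctx$pi_st,
                         eff_scale)[ctx$pc$map]
  }, numeric(aln$n_sites))
  site_ll <- matrix(site_ll, nrow = aln$n_sites)
  i1 <- which(grid == 1)
  invariant <- apply(aln$states, 2L, function(col) length(unique(col)) == 1L)
  imax <- max.col(site_ll, ties.method = "first")
  omega_hat <- grid[imax]
  lrt <- pmax(0, 2 * (site_ll[cbind(seq_len(aln$n_sites), imax)] -
                        site_ll[, i1]))
  p <- ifelse(omega_hat > 1 & lrt > 0,
              0.5 * stats::pchisq(lrt, 1L, lower.tail = FALSE), 1)
  omega_hat[invariant] <- NA_real_
  lrt[invariant] <- 0
  p[invariant] <- 1
  p_adj <- stats::p.adjust(p, method = correction)
  out <- data.frame(site = seq_len(aln$n_sites), omega_hat = omega_hat,
                    lrt = lrt, p = p, p_adj = p_adj,
                    sig_adj_05 = p_adj <= alpha[1L],
                    sig_adj_01 = p_adj <= alpha[2L],
                    invariant = invariant, stringsAsFactors = FALSE)
  attr(out, "kappa") <- ref$kappa
  attr(out, "branch_scale") <- ref$branch_scale
  attr(out, "freq_incorporation") <- freq_incorporation
  attr(out, "correction") <- correction
  class(out) <- c("sitewise_result", class(out))
  out
}

#' Neighbor-joining tree from a codon alignment
#'
#' Fallback tree builder: NJ on nucleotide p-distances, negative branch
#' lengths clamped to zero. Tie-breaking follows taxon order (ape's
#' deterministic implementation).
#'
#' @param aln A [codon_alignment()].
#' @return An unrooted `ape::phylo`.
#' @export
neighbor_joining_tree <- function(aln) {
  n <- length(aln$taxa)
  if (n < 3L) abort2("NJ needs >= 3 taxa", "bad_input")
  seqs <- apply(aln$codons, 1L, paste, collapse = "")
  ch <- do.call(rbind, strsplit(seqs, ""))
  D <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- mean(ch[i, ] != ch[j, ])
  }
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
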