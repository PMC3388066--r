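# End-to-end pipeline: parse -> catalog -> diversity tests -> dot plots ->
# selection, with a machine-readable run log sufficient to reproduce a run.

#' Assemble a pipeline run configuration
#'
#' @param fasta,groups Paths to the input FASTA and group-mapping TSV
#'   (omit both to run from a simulated population).
#' @param spectrum Optional spectrum TSV (used by the diversity stage when no
#'   sequences are given).
#' @param outdir Output directory (created if needed).
#' @param seed Global seed; per-stage streams are derived from it.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("parse", "catalog", "divtest", "dotplot", "selection")`.
#' @param repeat_length,n_permutations,window,mismatch_limit,models,codon_freq_model,n_restarts
#'   Stage parameters (see the stage functions).
#' @param simulate Optional [sim_config()] used when no FASTA is given.
#' @return List of class `run_config`.
#' @export
run_config <- function(fasta = NULL, groups = NULL, spectrum = NULL,
                       outdir = "prdm9znf_out", seed = 1L,
                       stages = c("parse", "catalog", "divtest", "dotplot",
                                  "selection"),
                       repeat_length = 84L, n_permutations = 10000L,
                       window = 83L, mismatch_limit = 5L,
                       models = c("M0", "M1a", "M2a"),
                       codon_freq_model = "F3x4", n_restarts = 2L,
                       simulate = NULL) {
  bad <- setdiff(stages, c("parse", "catalog", "divtest", "dotplot",
                           "selection"))
  if (length(bad)) abort2(paste("unknown stage(s):",
                                paste(bad, collapse = ", ")), "bad_config")
  if (!is.null(fasta) && !file.exists(fasta)) {
    abort2(paste("no such file:", fasta), "missing_file")
  }
  if (!is.null(groups) && !file.exists(groups)) {
    abort2(paste("no such file:", groups), "missing_file")
  }
  structure(as.list(environment())[names(formals(run_config))],
            class = "run_config")
}

#' Read a JSON run configuration file
#'
#' @param path JSON file whose fields mirror the arguments of
#'   [run_config()]; `simulate` may be a list of [sim_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$simulate)) raw$simulate <- do.call(sim_config, raw$simulate)
  keep <- intersect(names(raw), names(formals(run_config)))
  do.call(run_config, raw[keep])
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order and writes all outputs plus a run log
#' (`run_log.json`: seed, parameters, package version, per-stage status) to
#' `config$outdir`. Any stage error aborts with a stage-tagged message; the
#' log then marks the run incomplete.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("prdm9znf")),
              stages = config$stages,
              parameters = config[setdiff(names(config),
                                          c("simulate", "stages"))],
              status = "incomplete")
  write_log <- function() {
    jsonlite::write_json(log, file.path(config$outdir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
  }
  write_log()
  res <- list()
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(invisible(NULL))
    tryCatch(expr, error = function(e) {
      log$status <<- sprintf("failed at stage '%s': %s", name,
                             conditionMessage(e))
      write_log()
      abort2(sprintf("[%s] %s", name, conditionMessage(e)), "stage_error")
    })
  }

  # -- input ------------------------------------------------------------
  if (!is.null(config$fasta)) {
    seqs <- read_grouped_fasta(config$fasta, config$groups)
  } else if (!is.null(config$simulate)) {
    pop <- simulate_znf_population(config$simulate)
    write_fasta(pop$fasta, file.path(config$outdir, "simulated.fasta"))
    write_tsv(pop$groups, file.path(config$outdir, "simulated_groups.tsv"))
    jsonlite::write_json(pop$ground_truth,
                         file.path(config$outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    seqs <- data.frame(
      seq_id = names(pop$fasta),
      sample_id = sub("\\.[0-9]+$", "", names(pop$fasta)),
      allele_index = sub("^.*\\.", "", names(pop$fasta)),
      group = pop$groups$group[match(sub("\\.[0-9]+$", "", names(pop$fasta)),
                                     pop$groups$sample_id)],
      sequence = unname(pop$fasta), stringsAsFactors = FALSE)
    res$population <- pop
  } else {
    seqs <- NULL
  }

  alleles <- NULL
  stage("parse", {
    if (is.null(seqs)) abort2("parse stage needs sequences", "bad_config")
    alleles <- mapply(function(s, id, sid, g)
      parse_znf_allele(s, id, sid, g, config$repeat_length),
      seqs$sequence, seqs$seq_id, seqs$sample_id, seqs$group,
      SIMPLIFY = FALSE)
    reports <- lapply(alleles, validate_array, config$repeat_length)
    ok <- vapply(reports, function(r) isTRUE(attr(r, "ok")), logical(1))
    issues <- do.call(rbind, reports[!ok])
    write_tsv(repeat_table(alleles[ok]),
              file.path(config$outdir, "repeats.tsv"))
    if (!all(ok)) {
      write_tsv(issues, file.path(config$outdir, "validation_issues.tsv"))
    }
    alleles <- alleles[ok]
    seqs <- seqs[ok, , drop = FALSE]
    res$alleles <- alleles
  })

  nt_tab <- aa_tab <- NULL
  stage("catalog", {
    if (is.null(seqs)) abort2("catalog stage needs sequences", "bad_config")
    nt_tab <- collapse_to_nt_alleles(seqs)
    aa_tab <- collapse_to_aa_alleles(
      nt_tab, truncated_leading = any(nchar(seqs$sequence) %% 3L != 0L))
    write_tsv(nt_tab, file.path(config$outdir, "nt_alleles.tsv"))
    write_tsv(aa_tab, file.path(config$outdir, "aa_alleles.tsv"))
    write_tsv(cross_group_sharing(nt_tab, aa_tab),
              file.path(config$outdir, "sharing.tsv"))
    write_fasta(stats::setNames(nt_tab$sequence, nt_tab$nt_allele_id),
                file.path(config$outdir, "alleles.fasta"))
    if (!is.null(alleles)) {
      enc <- assign_repeat_letters(alleles)
      write_tsv(enc$legend, file.path(config$outdir, "letter_legend.tsv"))
      write_tsv(data.frame(
        allele_id = names(enc$encodings),
        encoding = vapply(enc$encodings, paste, character(1),
                          collapse = "-"), stringsAsFactors = FALSE),
        file.path(config$outdir, "letter_encodings.tsv"))
    }
    res$nt_alleles <- nt_tab
    res$aa_alleles <- aa_tab
  })

  stage("divtest", {
    spec <- if (!is.null(config$spectrum)) {
      read_spectrum_table(config$spectrum)
    } else if (!is.null(seqs)) {
      lab <- stats::setNames(nt_tab$nt_allele_id, nt_tab$sequence)
      grouped_spectrum(split(unname(lab[seqs$sequence]), seqs$group))
    } else {
      abort2("divtest stage needs a spectrum or sequences", "bad_config")
    }
    rows <- list()
    if (length(spec$groups) >= 2L) {
      pr <- permutation_test(spec, "multi_group", config$n_permutations,
                             derive_seed(config$seed, 1L))
      rows[["multi"]] <- data.frame(
        statistic_kind = "multi_group", observed = pr$observed_statistic,
        p_value = pr$p_value, n_permutations = pr$n_permutations,
        seed = pr$seed, stringsAsFactors = FALSE)
    }
    if (length(spec$groups) == 2L) {
      pr2 <- permutation_test(spec, "two_group", config$n_permutations,
                              derive_seed(config$seed, 2L))
      rows[["two"]] <- data.frame(
        statistic_kind = "two_group", observed = pr2$observed_statistic,
        p_value = pr2$p_value, n_permutations = pr2$n_permutations,
        seed = pr2$seed, stringsAsFactors = FALSE)
    }
    res$divtest <- do.call(rbind, rows)
    write_tsv(res$divtest, file.path(config$outdir, "divtest.tsv"))
  })

  stage("dotplot", {
    if (is.null(nt_tab) || nrow(nt_tab) == 0L) {
      abort2("dotplot stage needs catalogued alleles", "bad_config")
    }
    top <- nt_tab$sequence[1L]
    dp <- self_dotplot(top, config$window, config$mismatch_limit)
    utils::write.table(unclass(dp) * 1L,
                       file.path(config$outdir, "dotplot_top_allele.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    scores <- vapply(res$alleles, function(al) {
      if (n_full_repeats(al) >= 4L) two_block_score(al) else NA_real_
    }, numeric(1))
    write_tsv(data.frame(
      allele_id = vapply(res$alleles, `[[`, character(1), "allele_id"),
      two_block_score = scores, stringsAsFactors = FALSE),
      file.path(config$outdir, "two_block_scores.tsv"))
    res$dotplot <- dp
  })

  stage("selection", {
    if (is.null(res$alleles)) abort2("selection stage needs parsed alleles",
                                     "bad_config")
    aln <- build_codon_alignment(res$alleles)
    if (length(aln$taxa) < 3L) {
      abort2("selection stage needs >= 3 distinct repeats", "bad_config")
    }
    tree <- neighbor_joining_tree(aln)
    fits <- lapply(config$models, function(m)
      fit_site_model(aln, tree, m, config$codon_freq_model,
                     n_restarts = config$n_restarts,
                     seed = derive_seed(config$seed, 3L)))
    names(fits) <- config$models
    fit_rows <- do.call(rbind, lapply(fits, function(f) data.frame(
      model = f$model, lnL = f$lnL, kappa = f$kappa,
      branch_scale = f$branch_scale,
      proportions = paste(signif(f$proportions, 6), collapse = ","),
      omegas = paste(signif(f$omegas, 6), collapse = ","),
      converged = f$converged, stringsAsFactors = FALSE)))
    write_tsv(fit_rows, file.path(config$outdir, "selection_fits.tsv"))
    lrt_rows <- list()
    for (pair in LRT_PAIRS) {
      if (pair[[1L]] %in% names(fits) && pair[[2L]] %in% names(fits)) {
        lr <- likelihood_ratio_test(fits[[pair[[1L]]]], fits[[pair[[2L]]]])
        lrt_rows[[length(lrt_rows) + 1L]] <- data.frame(
          null_model = lr$null_model, alt_model = lr$alt_model,
          two_delta_l = lr$two_delta_l, df = lr$df, p_value = lr$p_value,
          stringsAsFactors = FALSE)
      }
    }
    if (length(lrt_rows)) {
      write_tsv(do.call(rbind, lrt_rows),
                file.path(config$outdir, "selection_lrt.tsv"))
    }
    if ("M2a" %in% names(fits)) {
      write_tsv(empirical_bayes_site_classes(fits[["M2a"]]),
                file.path(config$outdir, "site_posteriors.tsv"))
    }
    res$selection_fits <- fits
  })

  log$status <- "complete"
  write_log()
  invisible(res)
}
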