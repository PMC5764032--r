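#' Simulate a cohort and write it to disk
#'
#' Runs [generate_cohort()] and writes one recording TSV per child plus the
#' marker, cohort-metadata, ground-truth and trial-metadata tables, printing
#' a short manifest.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the list of files written.
#' @export
cmd_simulate <- function(config, out_dir) {
  sim <- generate_cohort(config)
  rec_dir <- file.path(out_dir, "recordings")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (rec in sim$recordings) {
    p <- file.path(rec_dir, paste0(rec$child_id, ".tsv"))
    write_recording(rec, p)
    files <- c(files, p)
  }
  markers <- do.call(rbind, lapply(sim$recordings, function(r)
    cbind(child_id = r$child_id, r$markers)))
  tabs <- list(markers = file.path(out_dir, "markers.tsv"),
               cohort = file.path(out_dir, "cohort.tsv"),
               truth = file.path(out_dir, "truth.tsv"),
               trials = file.path(out_dir, "trials.tsv"))
  write_markers(markers, tabs$markers)
  write_cohort_table(sim$cohort, tabs$cohort, "cohort")
  write_cohort_table(sim$truth, tabs$truth, "truth")
  write_cohort_table(sim$trials, tabs$trials, "trials")
  files <- c(files, unlist(tabs))
  cat(sprintf("simulated %d recordings (%d pairs) -> %s\n",
              length(sim$recordings), config$n_pairs, out_dir))
  invisible(files)
}

#' Process a directory of recordings into per-child laterality results
#'
#' Reads every recording, runs [process_recording()], attaches handedness
#' and dominance coding from the cohort metadata, and writes a
#' laterality-results table plus a per-trial processing log. A malformed
#' recording is reported and skipped; the run continues and the number of
#' failures is returned.
#'
#' @param recordings_dir directory of recording TSVs.
#' @param markers_path path to the marker sidecar table.
#' @param cohort_path path to the cohort metadata table (optional; needed
#'   for dominance coding).
#' @param out_dir output directory (optional; tables written when given).
#' @param params pipeline parameters from [ftcd_params()].
#' @return List with `results` (data frame, one row per child), `cohort`
#'   (analysis table: metadata joined with results, usable children only),
#'   `log` (per-child accounting) and `n_failed`.
#' @export
cmd_process <- function(recordings_dir, markers_path, cohort_path = NULL,
                        out_dir = NULL, params = ftcd_params()) {
  paths <- list.files(recordings_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(paths)) stop("no recordings in ", recordings_dir)
  markers <- read_markers(markers_path)
  rows <- list(); logs <- list(); n_failed <- 0L
  for (p in paths) {
    res <- tryCatch({
      at <- parse_header(p, "recording")
      m <- markers[markers$child_id == at$child, ]
      rec <- read_recording(p, m)
      process_recording(rec, params)
    }, error = function(e) {
      message("failed: ", p, " (", conditionMessage(e), ")")
      NULL
    })
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      child_id = res$child_id, li = res$li, peak_time = res$peak_time,
      se = res$se,
      ci_lo = if (is.null(res$ci95)) NA_real_ else res$ci95[1],
      ci_hi = if (is.null(res$ci95)) NA_real_ else res$ci95[2],
      category = res$category, n_valid = res$n_valid,
      usable = res$usable,
      unusable_reason = if (is.na(res$reason)) "" else res$reason,
      pct_left = res$pct_left, pct_right = res$pct_right,
      li_odd = res$li_odd, li_even = res$li_even,
      mean_words = res$mean_words, n_imputed = res$n_imputed)
    logs[[length(logs) + 1L]] <- data.frame(
      child_id = res$child_id, n_markers = res$n_markers,
      n_accepted = res$n_valid, n_rejected = res$n_rejected,
      rejected_behaviour = sum(res$reject_reasons[
        names(res$reject_reasons) == "behaviour"]),
      rejected_range = sum(res$reject_reasons[
        names(res$reject_reasons) == "range"]),
      rejected_dropout = sum(res$reject_reasons[
        names(res$reject_reasons) == "flat/dropout"]),
      n_imputed = res$n_imputed)
  }
  results <- do.call(rbind, rows)
  log <- do.call(rbind, logs)
  cohort <- NULL
  if (!is.null(cohort_path)) {
    meta <- read_cohort_table(cohort_path, "cohort")
    cohort <- merge(meta, results, by = "child_id")
    cohort <- cohort[cohort$usable, ]
    dom <- mapply(function(cat, er, qr) code_dominance(cat, er, qr)$consistent,
                  cohort$category, cohort$ehi_right, cohort$qhp_right)
    cohort$consistent <- as.logical(dom)
    cohort$right_both <- cohort$ehi_right & cohort$qhp_right
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_table(results, file.path(out_dir, "laterality_results.tsv"),
                       "results")
    write_cohort_table(log, file.path(out_dir, "processing_log.tsv"), "log")
    if (!is.null(cohort))
      write_cohort_table(cohort, file.path(out_dir, "analysis_cohort.tsv"),
                         "cohort")
  }
  list(results = results, cohort = cohort, log = log, n_failed = n_failed)
}

run_or_skip <- function(name, out, expr) {
  out[[name]] <- tryCatch(expr, error = function(e) {
    message("analysis skipped: ", name, " (", conditionMessage(e), ")")
    list(skipped = TRUE, reason = conditionMessage(e))
  })
  out
}

#' Run the full group-comparison analysis on a processed cohort
#'
#' Fits every model of the analysis plan against the usable-children table:
#' group LMMs on LI, per-MCA percent change and words per trial; sex+age
#' and zygosity LMMs on LI; the Bayesian multinomial model on laterality
#' category; zero-one-inflated beta regressions on both handedness measures
#' in the two twin subsamples; the QHP position model; multilevel logistic
#' models for consistent left-hemisphere dominance and consistent
#' right-handedness; split-half reliability; the replicated Spearman screen
#' on signed and absolute LI; the descriptive table; and Cohen's d values
#' from the fitted marginal means.
#'
#' @param cohort analysis table from [cmd_process()] (usable children).
#' @param seed seed for the MCMC sampler.
#' @param mcmc_settings named list overriding `n_iter`, `burn_in`, `thin`.
#' @param out_json optional path; results summary written as JSON.
#' @return Named list of results; each model summarised with estimate, CI,
#'   p and seed where applicable.
#' @export
cmd_analyse <- function(cohort, seed = 1L, mcmc_settings = list(),
                        out_json = NULL) {
  res <- list()
  res <- run_or_skip("li_lmm", res, fit_lmm(cohort, "li"))
  res <- run_or_skip("pct_left_lmm", res, fit_lmm(cohort, "pct_left"))
  res <- run_or_skip("pct_right_lmm", res, fit_lmm(cohort, "pct_right"))
  res <- run_or_skip("words_lmm", res, fit_lmm(cohort, "mean_words"))
  res <- run_or_skip("iq_lmm", res, fit_lmm(cohort, "performance_iq"))
  res <- run_or_skip("sex_age_lmm", res,
                     fit_lmm(cohort, "li", fixed = c("sex", "age")))
  res <- run_or_skip("zygosity_lmm", res,
                     fit_lmm(cohort, "li", fixed = "zygosity"))
  ms <- utils::modifyList(list(n_iter = 6000, burn_in = 1500, thin = 2),
                          mcmc_settings)
  res <- run_or_skip("multinomial_mcmc", res,
                     fit_multinomial_mcmc(cohort, seed = seed,
                                          n_iter = ms$n_iter,
                                          burn_in = ms$burn_in,
                                          thin = ms$thin))
  res <- run_or_skip("zoib_ehi", res, {
    cohort$ehi01 <- rescale_ehi(cohort$ehi_li)
    fit_zoib_replicated(cohort, "ehi01")
  })
  res <- run_or_skip("zoib_qhp", res, {
    cohort$qhp01 <- rescale_qhp(cohort$qhp_score)
    fit_zoib_replicated(cohort, "qhp01")
  })
  res <- run_or_skip("qhp_position", res, qhp_position_model(cohort))
  res <- run_or_skip("dominance_logistic", res,
                     fit_multilevel_logistic(cohort, "consistent"))
  res <- run_or_skip("righthand_logistic", res,
                     fit_multilevel_logistic(cohort, "right_both"))
  res <- run_or_skip("split_half_r", res, {
    ok <- !is.na(cohort$li_odd) & !is.na(cohort$li_even)
    stats::cor(cohort$li_odd[ok], cohort$li_even[ok])
  })
  res <- run_or_skip("spearman_li", res, spearman_replication(cohort, "li"))
  res <- run_or_skip("spearman_abs_li", res,
                     spearman_replication(cohort, abs(cohort$li)))
  res <- run_or_skip("descriptives", res, summarize_cohort(cohort))
  res <- run_or_skip("cohens_d_iq", res, {
    s <- tapply(cohort$performance_iq, cohort$group, stats::sd, na.rm = TRUE)
    em <- res$iq_lmm$emmeans
    cohens_d(em$emmean[em$group == "TD"], s[["TD"]],
             em$emmean[em$group == "DLD"], s[["DLD"]])
  })
  res$seed <- seed
  if (!is.null(out_json)) {
    jsonlite::write_json(summarise_analyses(res), out_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

# flat JSON-ready summary: one object per analysis with estimate/ci/p keys
summarise_analyses <- function(res) {
  out <- list(seed = res$seed)
  for (nm in setdiff(names(res), "seed")) {
    x <- res[[nm]]
    out[[nm]] <- if (is.list(x) && isTRUE(x$skipped)) {
      list(skipped = TRUE)
    } else if (inherits(x, "ftcd_model") && x$kind == "lmm") {
      k <- min(2, nrow(x$coef))
      list(estimate = x$coef$estimate[k], p = x$coef$p[k],
           df = x$coef$df[k])
    } else if (inherits(x, "ftcd_model")) {
      list(or = x$or, ci = x$or_ci95, p = x$coef$p[2])
    } else if (inherits(x, "ftcd_mcmc")) {
      list(or_bilateral = unname(x$or["bilateral"]),
           or_right = unname(x$or["right"]),
           pmcmc_bilateral = unname(x$pmcmc["bilateral"]),
           pmcmc_right = unname(x$pmcmc["right"]), seed = x$seed)
    } else if (is.list(x) && !is.null(x$sample1)) {
      list(p1 = if (!is.null(x$sample1$coef)) x$sample1$coef$p[2] else NA,
           p2 = if (!is.null(x$sample2$coef)) x$sample2$coef$p[2] else NA,
           significant = x$significant)
    } else if (is.data.frame(x)) {
      list(rows = nrow(x),
           replicated = if ("replicated" %in% names(x)) sum(x$replicated)
                        else NULL)
    } else if (is.numeric(x) && length(x) == 1) {
      list(value = x)
    } else list(summary = "see full result object")
  }
  out
}
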