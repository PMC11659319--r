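# End-to-end pipeline runner: simulate or read a cohort, score it, run the
# association suite, the ROC sweeps with chance band, and cross-validation;
# write result CSVs, a run manifest and a human-readable report.

#' Default pipeline configuration
#'
#' @param outdir output directory.
#' @param seed master seed; stage seeds derive from it.
#' @param cohort_path optional path to an existing canonical cohort CSV;
#'   when `NULL` a synthetic cohort is generated from `cohort_params`.
#' @param cohort_params generator parameters for the synthetic cohort.
#' @param stages character subset of
#'   `c("score", "associate", "sweep", "crossval")`.
#' @param sweep_predictors named orientation vector for the sweep stage.
#' @param chance_replicates replicates for the chance band.
#' @param k folds for cross-validation (2, 5 or 10 unless `allow_any_k`).
#' @param allow_any_k permit other fold counts.
#' @param percentiles percentile grid.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "results", seed = 1L,
                            cohort_path = NULL,
                            cohort_params = abrcog::cohort_params(seed = seed),
                            stages = c("score", "associate", "sweep", "crossval"),
                            sweep_predictors = c(wave_v_latency = "lower_better",
                                                 wave_v_amplitude = "higher_better"),
                            chance_replicates = 1000L, k = 2L,
                            allow_any_k = FALSE, percentiles = 1:99) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 cohort_path = cohort_path, cohort_params = cohort_params,
                 stages = stages, sweep_predictors = sweep_predictors,
                 chance_replicates = as.integer(chance_replicates),
                 k = as.integer(k), allow_any_k = allow_any_k,
                 percentiles = percentiles),
            class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop_param("config must be a 'pipeline_config'")
  bad <- setdiff(cfg$stages, c("score", "associate", "sweep", "crossval"))
  if (length(bad)) stop_param("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!cfg$allow_any_k && !cfg$k %in% c(2L, 5L, 10L))
    stop_param("k must be one of 2, 5, 10 (set allow_any_k to override)")
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on a synthetic or supplied cohort,
#' writing per-stage CSVs, a machine-readable manifest (seed, stage timings,
#' row counts, content digests of every output file) and a plain-text report
#' with the association, sweep and cross-validation summary tables. Stage
#' failures abort with the failing stage named; files already written are
#' retained alongside a `FAILED` marker.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `scored`, `associations`, `sweeps`,
#'   `chance`, `crossval`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(name) file.path(config$outdir, name)
  manifest <- list(seed = config$seed, stages = list(), files = list(),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  outputs <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      writeLines(paste0("failed in stage: ", name, "\n", conditionMessage(e)),
                 outfile("FAILED"))
      stop("pipeline failed in stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  cohort <- stage("input", {
    if (!is.null(config$cohort_path)) {
      read_cohort(config$cohort_path)
    } else {
      g <- generate_cohort(config$cohort_params, seed = config$seed)
      write_cohort(g$cohort, outfile("cohort.csv"))
      g$cohort
    }
  })
  manifest$stages$input$n_rows <- nrow(cohort)

  scored <- NULL
  if (any(c("score", "associate", "sweep", "crossval") %in% config$stages)) {
    scored <- stage("score", {
      s <- score_cohort(cohort)
      write_cohort(s, outfile("scored_cohort.csv"))
      s
    })
  }

  assoc <- NULL
  if ("associate" %in% config$stages) {
    assoc <- stage("associate", {
      a <- run_association_suite(scored)
      write.csv(a, outfile("associations.csv"), row.names = FALSE)
      a
    })
    grp <- stage("group_compare", {
      g <- compare_age_groups(scored, "composite")
      write.csv(g$pairwise, outfile("age_group_pairwise.csv"), row.names = FALSE)
      g
    })
    outputs$group_comparison <- grp
  }

  sweeps <- list(); chance <- NULL
  if ("sweep" %in% config$stages) {
    res <- stage("sweep", {
      out <- list()
      for (pred in names(config$sweep_predictors)) {
        for (adj in c(FALSE, TRUE)) {
          sw <- run_sweep(scored, pred,
                          orientation = config$sweep_predictors[[pred]],
                          adjust_age = adj, percentiles = config$percentiles)
          tag <- paste0(pred, if (adj) "_age_adjusted" else "_raw")
          write.csv(sw$table, outfile(paste0("sweep_", tag, ".csv")),
                    row.names = FALSE)
          out[[tag]] <- sw
        }
      }
      cb <- chance_band(scored, replicates = config$chance_replicates,
                        seed = config$seed, percentiles = config$percentiles)
      write.csv(data.frame(replicate = seq_along(cb$replicate_mean_auc),
                           mean_auc = cb$replicate_mean_auc),
                outfile("chance_band.csv"), row.names = FALSE)
      list(sweeps = out, chance = cb)
    })
    sweeps <- res$sweeps; chance <- res$chance
  }

  cvs <- list()
  if ("crossval" %in% config$stages) {
    cvs <- stage("crossval", {
      out <- list()
      for (pred in names(config$sweep_predictors)) {
        for (adj in c(FALSE, TRUE)) {
          cv <- cv_sweep(scored, pred,
                         orientation = config$sweep_predictors[[pred]],
                         k = config$k, seed = config$seed, adjust_age = adj,
                         percentiles = config$percentiles,
                         allow_any_k = config$allow_any_k)
          tag <- paste0(pred, if (adj) "_age_adjusted" else "_raw")
          write.csv(cv$table, outfile(paste0("crossval_", tag, ".csv")),
                    row.names = FALSE)
          out[[tag]] <- cv
        }
      }
      out
    })
  }

  stage("report", {
    lines <- character(0)
    w <- function(...) lines <<- c(lines, sprintf(...))
    w("ABR-cognition pipeline report (seed %d, n = %d)", config$seed, nrow(cohort))
    if (!is.null(assoc)) {
      w("\n== Key associations (full sample, composite) ==")
      key <- assoc[assoc$subgroup == "all" & assoc$outcome == "composite", ]
      for (i in seq_len(nrow(key))) {
        w("  %-24s %-12s B = %8.4f  CI [%8.4f, %8.4f]  p = %.4g",
          key$predictor[i], if (key$adjusted[i]) "age-adj" else "univariate",
          key$B[i], key$ci_low[i], key$ci_high[i], key$p[i])
      }
    }
    if (length(sweeps)) {
      w("\n== Percentile ROC sweeps ==")
      for (tag in names(sweeps)) {
        s <- sweeps[[tag]]$summary
        w("  %-36s mean AUC %.3f (sd %.3f, range %.3f-%.3f), peak @ %d%%",
          tag, s$mean_auc, s$sd_auc, s$min_auc, s$max_auc, s$argmax_percentile)
      }
      if (!is.null(chance))
        w("  chance band: mean %.4f, sd across replicates %.4f, across percentiles %.4f",
          chance$mean, chance$sd_across_replicates, chance$sd_across_percentiles)
    }
    if (length(cvs)) {
      w("\n== %d-fold cross-validated sweeps ==", config$k)
      for (tag in names(cvs)) {
        s <- cvs[[tag]]$summary
        w("  %-36s mean AUC %.3f (sd %.3f), %d missing percentile(s)",
          tag, s$mean_auc, s$sd_auc, s$missing_percentiles)
      }
    }
    writeLines(lines, outfile("report.txt"))
    NULL
  })

  files <- list.files(config$outdir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest$files <- lapply(setNames(files, basename(files)), function(f) {
    list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))
  })
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(scored = scored, associations = assoc, sweeps = sweeps,
                 chance = chance, crossval = cvs, manifest = manifest,
                 outputs = outputs))
}
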