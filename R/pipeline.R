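#' Pipeline configuration
#'
#' Bundles every stage's settings: the synthetic cohort, the task, the QC
#' policy, which measures get developmental curve fits, and the centile
#' (LMS) settings. Can also be loaded from a YAML or JSON document with the
#' same block names via [read_pipeline_config()].
#'
#' @param cohort A [cohort_config()].
#' @param task `"pushball"` or `"launchball"`.
#' @param qc A [qc_policy()].
#' @param fit_measures Measure columns to fit against age at the
#'   end-of-learning epoch (inverse model for angles, exponential for the
#'   compensation angle).
#' @param centiles List: `enabled`, `measure`, `epoch`, `candidates`, `df`,
#'   `levels`, plus an optional `exclude` character vector of participant
#'   ids dropped before centile fitting (the explicit outlier list).
#' @param visual_delay_frac Passed to the simulator.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), task = "pushball",
                            qc = qc_policy(),
                            fit_measures = c(
                              "initial_angle_deg", "final_angle_deg",
                              "compensation_angle_deg"
                            ),
                            centiles = list(
                              enabled = TRUE,
                              measure = "initial_angle_deg",
                              epoch = "end_learning",
                              candidates = c("NO", "BCCG"),
                              df = c(mu = 3, sigma = 3, lambda = 1),
                              levels = c(1, 5, 10, 25, 50, 75, 90, 95, 99),
                              exclude = character()
                            ),
                            visual_delay_frac = 0.25) {
  task <- check_task(task)
  structure(
    list(
      cohort = cohort, task = task, qc = qc, fit_measures = fit_measures,
      centiles = utils::modifyList(
        list(
          enabled = TRUE, measure = "initial_angle_deg",
          epoch = "end_learning", candidates = c("NO", "BCCG"),
          df = c(mu = 3, sigma = 3, lambda = 1),
          levels = c(1, 5, 10, 25, 50, 75, 90, 95, 99), exclude = character()
        ),
        centiles
      ),
      visual_delay_frac = visual_delay_frac
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path A YAML or JSON config file with blocks `cohort`, `task`,
#'   `qc`, `fit_measures`, `centiles`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pipeline_config(
    cohort = do.call(cohort_config, raw$cohort %||% list()),
    task = raw$task %||% "pushball",
    qc = do.call(qc_policy, raw$qc %||% list()),
    fit_measures = raw$fit_measures %||% c(
      "initial_angle_deg", "final_angle_deg", "compensation_angle_deg"
    ),
    centiles = raw$centiles %||% list(),
    visual_delay_frac = raw$visual_delay_frac %||% 0.25
  )
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  writeLines(line, con)
  invisible(line)
}

adult_age_mo <- function() 216

#' Run the full analysis pipeline
#'
#' Executes simulate -> qc -> extract -> epochs -> fits -> centiles under a
#' single seed (the cohort seed), writing every artifact into `out_dir`:
#' `sessions.jsonl`, `qc_report.csv`, `measures.csv`, `epochs.csv`,
#' `fits.json`, `centiles.csv` and `log.txt`. Rerunning with the same config
#' reproduces all outputs byte-identically except the timestamps in the log.
#' Adults (age >= 216 months) are excluded from curve and centile fits but
#' retained in summaries. Any stage failure halts with the stage named;
#' artifacts written before the failure are retained.
#'
#' @param config A [pipeline_config()] or a path to a YAML/JSON config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts: `sessions`,
#'   `qc_report`, `measures`, `epochs`, `fits`, `centile_fit`, `centiles`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config or a config file path.",
      class = "reachdev_bad_config"
    )
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "log.txt"), "w")
  on.exit(close(log_con))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pipeline_log(log_con, name, paste("FAILED:", conditionMessage(e)))
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        parent = e
      )
    })
  }

  sessions <- stage("simulate", {
    s <- simulate_cohort(config$cohort, config$task, config$visual_delay_frac)
    write_sessions(s, file.path(out_dir, "sessions.jsonl"))
    pipeline_log(log_con, "simulate", sprintf(
      "%d participants, %d trials", length(unique(s$participant_id)), nrow(s)
    ))
    s
  })

  qc <- stage("qc", {
    q <- apply_qc(sessions, config$qc)
    readr::write_csv(q$report, file.path(out_dir, "qc_report.csv"))
    pipeline_log(log_con, "qc", sprintf(
      "%d of %d participants kept (%d exclusions)",
      length(unique(q$sessions$participant_id)),
      length(unique(sessions$participant_id)), nrow(q$report)
    ))
    q
  })

  measures <- stage("extract", {
    m <- extract_measures(qc$sessions)
    readr::write_csv(m, file.path(out_dir, "measures.csv"))
    pipeline_log(log_con, "extract", sprintf(
      "%d trials measured, %d invalid", nrow(m), sum(!m$valid)
    ))
    m
  })

  epochs <- stage("epochs", {
    e <- extract_epochs(measures)
    readr::write_csv(e, file.path(out_dir, "epochs.csv"))
    pipeline_log(log_con, "epochs", sprintf("%d epoch summaries", nrow(e)))
    e
  })

  fits <- stage("fit-curves", {
    children <- epochs |>
      filter(.data$epoch == "end_learning", .data$age_mo < adult_age_mo())
    fl <- purrr::map(config$fit_measures, function(mm) {
      d <- children |> filter(.data$measure == mm)
      f <- if (mm == "compensation_angle_deg") {
        fit_exponential(d, mean)
      } else {
        fit_inverse(d, mean)
      }
      list(
        measure = mm, model = f$model, a = f$a, b = f$b,
        ci_a = f$ci_a, ci_b = f$ci_b, adj_r2 = f$adj_r2, n = f$n
      )
    })
    jsonlite::write_json(fl, file.path(out_dir, "fits.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    pipeline_log(log_con, "fit-curves", sprintf("%d measures fitted", length(fl)))
    fl
  })

  centile_fit <- NULL
  centiles <- NULL
  if (isTRUE(config$centiles$enabled)) {
    cent <- stage("centiles", {
      cc <- config$centiles
      d <- epochs |>
        filter(
          .data$epoch == cc$epoch, .data$measure == cc$measure,
          .data$age_mo < adult_age_mo(),
          !.data$participant_id %in% cc$exclude
        ) |>
        select("age_mo", y = "mean")
      fit <- select_family(d, y,
        candidates = cc$candidates,
        df = unlist(cc$df)
      )
      pt <- percentile_curve(fit, levels = cc$levels)
      readr::write_csv(as_tibble(pt), file.path(out_dir, "centiles.csv"))
      pipeline_log(log_con, "centiles", sprintf(
        "family %s over %d ages x %d levels", fit$family,
        length(unique(pt$age_mo)), length(unique(pt$level))
      ))
      list(fit = fit, table = pt)
    })
    centile_fit <- cent$fit
    centiles <- cent$table
  } else {
    pipeline_log(log_con, "centiles", "disabled by config")
  }

  invisible(list(
    sessions = sessions, qc_report = qc$report, measures = measures,
    epochs = epochs, fits = fits, centile_fit = centile_fit,
    centiles = centiles
  ))
}
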