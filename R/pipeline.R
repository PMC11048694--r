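#' Configure a full pipeline run
#'
#' Collects inputs (file paths or in-memory data frames), the task list,
#' MCMC profile, stage toggles and the root seed for one reproducible run of
#' score -> factor analysis -> learning curves -> associations -> gaze ->
#' report.
#'
#' @param scores trial-score table (data frame or CSV path); required unless
#'   `events` is given.
#' @param events optional raw key-press log (data frame or CSV path); when
#'   present it is scored with `sequences`.
#' @param battery test-battery table (data frame or CSV path).
#' @param gaze gaze-count table (data frame or CSV path).
#' @param musicality musicality covariates (data frame or CSV path) with
#'   `gold_msi_total` and `piano_hours`.
#' @param sequences named list of [sequence_spec()] per task, or a YAML file
#'   `task: [k1, k2, k3, k4]`.
#' @param tasks tasks to analyse (default all in the score table).
#' @param predictors which predictors get a trial-wise association model:
#'   any of the factor names and `"gold_msi_total"`, `"piano_hours"`.
#' @param mcmc an [mcmc_config()]; [reduced_config()] is the desk-scale
#'   default, `mcmc_config()` the full headline profile.
#' @param stages character vector of enabled stages, a subset of
#'   `c("scoring", "errors", "cfa", "curves", "compare", "associations",
#'   "gaze", "musicality")`.
#' @param constrain_wm passed to [battery_model()].
#' @param seed root seed; every stochastic stage derives its own seed from
#'   it.
#' @param out_dir optional output directory for the report files.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(scores = NULL, events = NULL, battery = NULL,
                       gaze = NULL, musicality = NULL,
                       sequences = default_sequences(),
                       tasks = NULL,
                       predictors = c("WM", "PS", "PM", "DX",
                                      "gold_msi_total", "piano_hours"),
                       mcmc = reduced_config(),
                       stages = c("scoring", "errors", "cfa", "curves",
                                  "compare", "associations", "gaze",
                                  "musicality"),
                       constrain_wm = FALSE,
                       seed = 1L, out_dir = NULL) {
  read_maybe <- function(x) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("input file does not exist: ", x)
      utils::read.csv(x, stringsAsFactors = FALSE)
    } else x
  }
  if (is.character(sequences)) sequences <- read_sequences_yaml(sequences)
  cfg <- list(scores = read_maybe(scores), events = read_maybe(events),
              battery = read_maybe(battery), gaze = read_maybe(gaze),
              musicality = read_maybe(musicality), sequences = sequences,
              tasks = tasks, predictors = predictors, mcmc = mcmc,
              stages = stages, constrain_wm = constrain_wm,
              seed = as.integer(seed), out_dir = out_dir)
  if (is.null(cfg$scores) && is.null(cfg$events))
    stop("either 'scores' or 'events' must be provided")
  class(cfg) <- "run_config"
  cfg
}

read_sequences_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  lapply(y, function(el) {
    if (is.list(el) && !is.null(el$keys)) sequence_spec(el$keys, el$hands)
    else sequence_spec(unlist(el))
  })
}

stage_seed <- function(root, k) (root + 104729L * k) %% 2147483629L

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on one dataset: scoring
#' (if a raw key log is given), error summaries, confirmatory factor
#' analysis with factor scores, hierarchical exponential learning curves
#' per task (optionally compared with polynomial families by PSIS-LOO
#' elpd), trial-wise performance-ability associations controlling for
#' individual learning rates, the gaze change-point model, and
#' musicality-association checks. Writes `report.json` and `report.md` when
#' an output directory is configured. A stage failure halts the run with
#' the stage name; completed stage outputs are preserved in the error
#' condition's `partial` field.
#'
#' @param cfg a [run_config()].
#' @return list of class `"skillcurve_report"` with one element per stage
#'   plus `meta` (seed, versions, wall-clock per stage).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  report <- list()
  timings <- list()
  run_stage <- function(name, expr) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      cond <- simpleError(paste0("pipeline stage '", name, "' failed: ",
                                 conditionMessage(e)))
      cond$partial <- report
      stop(cond)
    })
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    report[[name]] <<- res
    res
  }

  scores <- cfg$scores
  if (!is.null(cfg$events) && "scoring" %in% cfg$stages) {
    scores <- run_stage("scoring", score_dataset(cfg$events, cfg$sequences))
  }
  if (is.null(scores)) stop("no trial scores available")
  tasks <- cfg$tasks
  if (is.null(tasks)) tasks <- unique(as.character(scores$task))

  run_stage("errors", {
    lapply(stats::setNames(tasks, tasks), function(tk) {
      s <- scores[scores$task == tk, ]
      first <- s[s$trial == min(s$trial), ]
      last <- s[s$trial == max(s$trial), ]
      list(trial1 = list(errors_mean = mean(first$wrong_key + first$wrong_order),
                         errors_sd = stats::sd(first$wrong_key + first$wrong_order),
                         error_rate_pct = 100 * mean(first$error_rate, na.rm = TRUE)),
           last = list(errors_mean = mean(last$wrong_key + last$wrong_order),
                       errors_sd = stats::sd(last$wrong_key + last$wrong_order),
                       error_rate_pct = 100 * mean(last$error_rate, na.rm = TRUE)))
    })
  })

  cfa <- NULL; fscores <- NULL
  if (!is.null(cfg$battery)) {
    cfa <- run_stage("cfa", fit_cfa(cfg$battery,
                                    battery_model(cfg$constrain_wm)))
    if (!is.null(cfa)) fscores <- factor_scores(cfa)
  }

  curve_fits <- list(); ind_est <- list()
  if ("curves" %in% cfg$stages) {
    run_stage("curves", {
      out <- list()
      for (k in seq_along(tasks)) {
        tk <- tasks[k]
        fit <- fit_learning_curves(scores, task = tk, config = cfg$mcmc,
                                   seed = stage_seed(cfg$seed, k))
        curve_fits[[tk]] <- fit
        ind_est[[tk]] <- individual_estimates(fit)
        s <- summary(fit)
        out[[tk]] <- list(population = s,
                          max_rhat = max(pop_rhat(fit), na.rm = TRUE),
                          divergences = fit$run$divergences)
      }
      if (length(tasks) == 2) {
        e1 <- ind_est[[tasks[1]]]; e2 <- ind_est[[tasks[2]]]
        m <- match(e1$participant, e2$participant)
        out$cross_task <- lapply(stats::setNames(c("alpha", "beta", "gamma"),
                                                 c("alpha", "beta", "gamma")),
                                 function(p) {
          ct <- stats::cor.test(e1[[p]], e2[[p]][m])
          list(r = unname(ct$estimate), p = ct$p.value)
        })
      }
      out
    })
  }

  if ("compare" %in% cfg$stages) {
    run_stage("compare", {
      lapply(stats::setNames(tasks, tasks), function(tk) {
        cmp <- compare_models(scores, task = tk, config = cfg$mcmc,
                              seed = stage_seed(cfg$seed, 10L))
        list(table = cmp$table, diff = cmp$diff, diff_se = cmp$diff_se,
             unreliable = cmp$unreliable)
      })
    })
  }

  if ("associations" %in% cfg$stages && length(curve_fits)) {
    run_stage("associations", {
      preds <- list()
      if (!is.null(fscores))
        for (f in intersect(cfg$predictors, names(fscores)))
          preds[[f]] <- fscores[c("participant", f)]
      if (!is.null(cfg$musicality))
        for (mvar in intersect(cfg$predictors, names(cfg$musicality)))
          preds[[mvar]] <- cfg$musicality[c("participant", mvar)]
      out <- list()
      for (tk in names(curve_fits)) {
        fe <- fitted(curve_fits[[tk]])
        zt <- standardize_by_trial(fe)
        out[[tk]] <- list()
        for (pn in names(preds)) {
          ac <- trialwise_association(zt, preds[[pn]], ind_est[[tk]],
                                      config = cfg$mcmc,
                                      seed = stage_seed(cfg$seed, 20L))
          out[[tk]][[pn]] <- list(table = ac$table,
                                  profile = association_profile(ac))
        }
      }
      out
    })
    if (!is.null(fscores) && length(ind_est)) {
      run_stage("rate_correlations", {
        lapply(stats::setNames(names(ind_est), names(ind_est)), function(tk)
          rate_ability_correlations(ind_est[[tk]], fscores, column = "gamma"))
      })
    }
  }

  if (!is.null(cfg$gaze) && "gaze" %in% cfg$stages) {
    run_stage("gaze", {
      lapply(stats::setNames(tasks, tasks), function(tk) {
        fit <- fit_gaze_changepoint(cfg$gaze, task = tk, config = cfg$mcmc,
                                    seed = stage_seed(cfg$seed, 30L))
        list(population = fit$population,
             individual = fit$individual,
             max_rhat = max(fit$rhat, na.rm = TRUE))
      })
    })
  }

  if (!is.null(cfg$musicality) && "musicality" %in% cfg$stages &&
      length(ind_est)) {
    run_stage("musicality", {
      lapply(stats::setNames(names(ind_est), names(ind_est)), function(tk)
        rate_ability_correlations(ind_est[[tk]],
                                  cfg$musicality, column = "gamma"))
    })
  }

  report$meta <- list(seed = cfg$seed,
                      mcmc = unclass(cfg$mcmc),
                      tasks = tasks,
                      timings_sec = timings,
                      r_version = as.character(getRversion()),
                      package_version = as.character(utils::packageVersion("skillcurve")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  class(report) <- "skillcurve_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

strip_fits <- function(x) {
  if (inherits(x, "data.frame")) return(x)
  if (is.list(x)) return(lapply(x, strip_fits))
  x
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (machine-readable) and `report.md` (human-readable
#' summary) into a directory.
#'
#' @param report a `"skillcurve_report"`.
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- report
  if (!is.null(json$cfa)) {
    cf <- json$cfa
    json$cfa <- list(fit_indices = unclass(cf$fit),
                     loadings = as.data.frame(as.table(cf$lambda)),
                     factor_correlations = as.data.frame(as.table(cf$phi)),
                     converged = cf$converged, n = cf$n)
  }
  json <- strip_fits(json)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  md <- c("# skillcurve pipeline report", "",
          paste0("Seed ", report$meta$seed, "; tasks: ",
                 paste(report$meta$tasks, collapse = ", "), "; ",
                 report$meta$mcmc$chains, " chains x ",
                 report$meta$mcmc$iter, " iterations (",
                 report$meta$mcmc$warmup, " warmup)."), "")
  if (!is.null(report$cfa))
    md <- c(md, "## Latent factor analysis",
            utils::capture.output(print(report$cfa$fit)), "")
  if (!is.null(report$errors)) {
    md <- c(md, "## Errors")
    for (tk in names(report$errors)) {
      e <- report$errors[[tk]]
      md <- c(md, sprintf("- %s: error rate %.2f%% (trial 1) -> %.2f%% (last trial)",
                          tk, e$trial1$error_rate_pct, e$last$error_rate_pct))
    }
    md <- c(md, "")
  }
  if (!is.null(report$gaze)) {
    md <- c(md, "## Gaze change points")
    for (tk in names(report$gaze)) {
      g <- report$gaze[[tk]]$population
      md <- c(md, sprintf("- %s: visual control negligible around trial %.2f [%.2f, %.2f]",
                          tk, g$mean, g$lower, g$upper))
    }
    md <- c(md, "")
  }
  if (!is.null(report$curves)) {
    md <- c(md, "## Learning curves")
    for (tk in setdiff(names(report$curves), "cross_task")) {
      s <- report$curves[[tk]]$population
      gam <- s[s$parameter == "mu_gamma", ]
      md <- c(md, sprintf("- %s: population gamma %.2f [%.2f, %.2f], max Rhat %.3f",
                          tk, gam$mean, gam$lower, gam$upper,
                          report$curves[[tk]]$max_rhat))
    }
    md <- c(md, "")
  }
  if (!is.null(report$associations)) {
    md <- c(md, "## Trial-wise performance-ability associations")
    for (tk in names(report$associations))
      for (pn in names(report$associations[[tk]])) {
        pr <- report$associations[[tk]][[pn]]$profile
        md <- c(md, sprintf("- %s ~ %s: trial 1 %.2f, min %.2f (trial %d), plateau %.2f%s",
                            tk, pn, pr$initial, pr$minimum, pr$argmin_trial,
                            pr$plateau,
                            if (isTRUE(pr$dip_rebound)) ", dip-rebound" else ""))
      }
    md <- c(md, "")
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' @export
print.skillcurve_report <- function(x, ...) {
  cat("skillcurve pipeline report; stages:",
      paste(setdiff(names(x), "meta"), collapse = ", "), "\n")
  cat("  seed", x$meta$seed, "|",
      paste0(names(x$meta$timings_sec), ": ",
             round(unlist(x$meta$timings_sec), 1), "s", collapse = ", "), "\n")
  invisible(x)
}

#' Ingest an external data deposit into the pipeline schemas
#'
#' Converts a directory of deposited CSV files with arbitrary column names
#' into the pipeline's standard input tables, using an explicit user-supplied
#' mapping (the deposit layout is not assumed). The mapping is a named list
#' with one entry per table (`events`, `scores`, `battery`, `gaze`,
#' `musicality`), each `list(file = "name.csv", columns = c(target =
#' source, ...))`; battery indicator columns with matching names are carried
#' over automatically.
#'
#' @param path directory containing the deposited files.
#' @param mapping the table/column mapping described above.
#' @param out_dir optional directory to write the standardized CSVs into.
#' @return named list of standardized data frames (invisibly writes CSVs
#'   when `out_dir` is given).
#' @export
ingest_osf <- function(path, mapping, out_dir = NULL) {
  required <- list(
    events = c("participant", "task", "trial", "press_index", "key"),
    scores = c("participant", "task", "trial", "correct", "wrong_key",
               "wrong_order", "total"),
    battery = c("participant"),
    gaze = c("participant", "task", "trial", "gaze_changes"),
    musicality = c("participant", "gold_msi_total", "piano_hours"))
  out <- list()
  for (tbl in names(mapping)) {
    spec <- mapping[[tbl]]
    f <- file.path(path, spec$file)
    if (!file.exists(f)) stop("mapped file not found: ", f)
    raw <- utils::read.csv(f, stringsAsFactors = FALSE)
    cols <- spec$columns
    df <- raw
    if (!is.null(cols)) {
      src <- unlist(cols)
      missing_src <- setdiff(src, names(raw))
      if (length(missing_src))
        stop("mapping for '", tbl, "' names source column(s) absent from ",
             spec$file, ": ", paste(missing_src, collapse = ", "),
             "; available: ", paste(names(raw), collapse = ", "))
      names(df)[match(src, names(df))] <- names(cols)
    }
    need <- required[[tbl]]
    if (!is.null(need)) {
      miss <- setdiff(need, names(df))
      if (length(miss))
        stop("table '", tbl, "' lacks required column(s) after mapping: ",
             paste(miss, collapse = ", "),
             "; candidates in ", spec$file, ": ",
             paste(names(raw), collapse = ", "))
    }
    out[[tbl]] <- df
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fname <- c(events = "events.csv", scores = "trial_scores.csv",
               battery = "battery.csv", gaze = "gaze.csv",
               musicality = "musicality.csv")
    for (tbl in names(out))
      utils::write.csv(out[[tbl]], file.path(out_dir, fname[[tbl]]),
                       row.names = FALSE, na = "")
  }
  out
}
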