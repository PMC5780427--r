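# Trial-table interchange format and the end-to-end pipeline driver.

trial_table_version <- "# vforage trial-table v1"
trial_required_cols <- c("participant", "session", "forest", "day",
                         "weather", "energy", "choice", "outcome",
                         "energy_after", "valid", "p_bad", "g_bad",
                         "p_good", "g_good", "start_energy")

#' Read and write trial tables
#'
#' Trial tables are plain CSV with a versioned header comment line.
#' Validation names the offending rows: weather must be coded 1/2, days
#' 1--5, and no row may record a choice at energy 0 (starvation marker
#' rows have \code{valid = FALSE} and a missing choice). The \code{rt}
#' column is optional (choice-only analyses).
#'
#' @param path file path.
#' @return \code{read_trial_table}: the validated data frame.
#' @export
read_trial_table <- function(path) {
  x <- utils::read.csv(path, comment.char = "#",
                       stringsAsFactors = FALSE)
  validate_trial_table(x)
  x
}

#' @rdname read_trial_table
#' @param trials a trial table data frame.
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(trial_table_version, con)
  utils::write.csv(trials, con, row.names = FALSE)
  invisible(path)
}

validate_trial_table <- function(x) {
  miss <- setdiff(trial_required_cols, names(x))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!x$weather %in% 1:2)
  if (length(bad))
    stop("malformed weather code at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(x$day < 1 | x$day > 5)
  if (length(bad))
    stop("day out of 1..5 at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(x$energy == 0 & !is.na(x$choice))
  if (length(bad))
    stop("choice recorded at energy 0 at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: seeds, scale, model-space
#' stages and output directory. The configuration round-trips through
#' JSON unchanged.
#'
#' @param seed master seed; stage seeds are derived deterministically.
#' @param n_participants,n_sessions scale (defaults give a small demo).
#' @param stages model-space stages to fit.
#' @param out_dir output directory (\code{NULL}: no files written).
#' @param bms_samples Monte-Carlo samples for the exceedance
#'   probabilities.
#' @param rt_re random-effects structure for the RT model.
#' @param ... overrides for \code{\link{generative_params}} fields.
#' @return a list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1, n_participants = 5, n_sessions = 2,
                            stages = c("single", "second_given_p"),
                            out_dir = NULL, bms_samples = 1e5,
                            rt_re = "diagonal", ...) {
  params <- generative_params(n_participants = n_participants,
                              n_sessions = n_sessions, ...)
  structure(list(seed = seed, params = params, stages = stages,
                 out_dir = out_dir, bms_samples = bms_samples,
                 rt_re = rt_re),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes synthetic-data generation, heuristic computation, choice
#' fits over the configured model spaces, group-level model comparison,
#' policy metrics, and the RT model, writing every artifact (plus a
#' manifest with seeds and checksums) when an output directory is
#' configured. Identical configurations reproduce identical evidence
#' matrices.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return a list with the dataset, evidence objects, comparison
#'   results, opposing-trial metrics and the RT fit.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- generate_dataset(config$params, seed = config$seed)
  trials <- ds$trials
  evidence <- list()
  comparison <- list()
  for (st in config$stages) {
    ev <- fit_choice_models(trials, choice_model_space(st),
                            keep_fits = st == config$stages[1])
    evidence[[st]] <- ev
    comparison[[st]] <- list(
      lgbf = lgbf(ev),
      bms = bms(ev, n_samples = config$bms_samples,
                seed = config$seed + 1000))
  }
  opp <- opposing_trials(trials)
  rt_fit <- fit_rt(trials, re_structure = config$rt_re, lrt = FALSE)
  result <- list(dataset = ds, evidence = evidence,
                 comparison = comparison, opposing = opp,
                 rt_fit = rt_fit, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    f <- file.path(config$out_dir, "trials.csv")
    write_trial_table(trials, f)
    files <- c(files, f)
    for (st in names(evidence)) {
      f <- file.path(config$out_dir, sprintf("evidence_%s.csv", st))
      utils::write.csv(evidence[[st]]$bic, f)
      files <- c(files, f)
      f <- file.path(config$out_dir, sprintf("bms_%s.json", st))
      b <- comparison[[st]]$bms
      jsonlite::write_json(
        list(alpha = b$alpha, exp_r = b$exp_r, ep = b$ep, bor = b$bor,
             pep = b$pep, lgbf = comparison[[st]]$lgbf),
        f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    }
    f <- file.path(config$out_dir, "rt_coefficients.csv")
    utils::write.csv(data.frame(term = names(rt_fit$coefficients),
                                estimate = rt_fit$coefficients), f,
                     row.names = FALSE)
    files <- c(files, f)
    manifest <- list(
      seed = config$seed, stages = config$stages,
      n_participants = config$params$n_participants,
      package_version = as.character(utils::packageVersion("vforage")),
      files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files))))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}
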