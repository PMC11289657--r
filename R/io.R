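# 17 significant digits guarantees numeric round-trip through text
fmt17 <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

write_csv17 <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col)
    if (is.double(col)) fmt17(col) else col), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read a cohort from the three standard CSV tables
#'
#' @param longitudinal_path CSV with columns `patient_id`, `time`, then one
#'   column per biomarker (empty cell = missing).
#' @param baseline_path CSV with `patient_id` plus covariate columns, or
#'   `NULL`.
#' @param survival_path CSV with `patient_id`, `time`, `event`.
#' @param dt Grid step, in the units of the `time` columns.
#' @param ... Passed to [grid_cohort()].
#' @return An `lsdsm_cohort`.
#' @export
read_cohort_csv <- function(longitudinal_path, baseline_path, survival_path,
                            dt, ...) {
  long <- utils::read.csv(longitudinal_path, stringsAsFactors = FALSE)
  base <- if (is.null(baseline_path)) NULL else
    utils::read.csv(baseline_path, stringsAsFactors = FALSE)
  surv <- utils::read.csv(survival_path, stringsAsFactors = FALSE)
  grid_cohort(long, base, surv, dt, ...)
}

#' Write a cohort to the three standard CSV tables
#'
#' Longitudinal rows are emitted at grid times `(j-1)*dt` for every grid
#' interval, with empty cells for missing measurements; floats carry 17
#' significant digits so write-then-read round-trips exactly.
#'
#' @param cohort An `lsdsm_cohort`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"cohort"`).
#' @return Invisibly, the three file paths.
#' @export
write_cohort_csv <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dt <- attr(cohort, "dt")
  biomarkers <- attr(cohort, "biomarkers")
  covariates <- attr(cohort, "covariates")
  long <- do.call(rbind, lapply(cohort, function(p) {
    df <- data.frame(patient_id = p$patient_id,
                     time = (seq_len(p$m) - 1) * dt)
    y <- as.data.frame(p$y)
    names(y) <- biomarkers
    cbind(df, y)
  }))
  # drop fully missing rows: an empty bin carries no file content
  keep <- rowSums(!is.na(long[biomarkers])) > 0
  long <- long[keep, , drop = FALSE]
  base <- do.call(rbind, lapply(cohort, function(p) {
    df <- data.frame(patient_id = p$patient_id)
    if (length(p$omega)) {
      om <- as.data.frame(as.list(p$omega))
      names(om) <- covariates
      df <- cbind(df, om)
    }
    df
  }))
  surv <- do.call(rbind, lapply(cohort, function(p)
    data.frame(patient_id = p$patient_id, time = p$T, event = p$delta)))
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("longitudinal", "baseline", "survival"),
                                 ".csv"))
  write_csv17(long, paths[1L])
  write_csv17(base, paths[2L])
  write_csv17(surv, paths[3L])
  invisible(paths)
}

#' Serialize fitted parameters to flat JSON
#'
#' @param params An [lsdsm_params()] object.
#' @param path Output file.
#' @param provenance Optional named list recorded alongside (e.g. tol,
#'   iterations, converged).
#' @return Invisibly, `path`.
#' @export
write_params_json <- function(params, path, provenance = list()) {
  st <- params$structure
  doc <- list(structure = list(m_y = st$m_y, M = st$M, H = as.numeric(st$H),
                               H_dim = dim(st$H)),
              A_bar = as.numeric(params$A_bar),
              W_breve = as.numeric(params$W_breve),
              V = as.numeric(params$V),
              x1_bar = params$x1_bar,
              W1_bar = as.numeric(params$W1_bar),
              gamma = params$gamma,
              alpha = params$alpha,
              provenance = provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read parameters back from JSON
#'
#' @param path File written by [write_params_json()].
#' @return An [lsdsm_params()] object.
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- matrix(doc$structure$H, doc$structure$H_dim[1L], doc$structure$H_dim[2L])
  st <- canonical_structure(doc$structure$m_y, doc$structure$M, H)
  lsdsm_params(st,
               A_bar = matrix(doc$A_bar, st$m_y, st$m_x),
               W_breve = matrix(doc$W_breve, st$m_y, st$m_y),
               V = matrix(doc$V, st$m_y, st$m_y),
               x1_bar = doc$x1_bar,
               W1_bar = matrix(doc$W1_bar, st$m_x, st$m_x),
               gamma = doc$gamma, alpha = doc$alpha)
}

read_config <- function(config_path) {
  if (is.null(config_path)) return(list())
  jsonlite::read_json(config_path, simplifyVector = TRUE)
}

manifest_write <- function(dir, config_path, extra = list()) {
  man <- c(list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                package_version = as.character(utils::packageVersion("lsdsm")),
                config_hash = if (!is.null(config_path))
                  unname(tools::md5sum(config_path)) else NA_character_),
           extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate a cohort to disk
#'
#' Reads a JSON configuration (its `simulation` block feeds [sim_config()]),
#' simulates a cohort, and writes the three standard CSVs plus a truth
#' bundle (latent states and true survival curves) and a manifest with the
#' seed and config hash.
#'
#' @param config_path JSON configuration file, or `NULL` for all defaults.
#' @param out_dir Output directory.
#' @return Invisibly, the simulated `lsdsm_cohort`.
#' @export
cmd_simulate <- function(config_path = NULL, out_dir) {
  cfg <- read_config(config_path)
  sc <- do.call(sim_config, as.list(cfg$simulation))
  cohort <- simulate_cohort(true_model(), sc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(cohort, out_dir)
  latent <- attr(cohort, "latent")
  truth <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    data.frame(patient_id = p$patient_id, step = seq_len(p$m),
               x1 = latent[[i]][, 1L],
               true_survival = attr(cohort, "true_survival")[[i]])
  }))
  write_csv17(truth, file.path(out_dir, "cohort_truth.csv"))
  manifest_write(out_dir, config_path,
                 list(seed = sc$seed, n = sc$n,
                      missing_pct = sc$missing_pct))
  invisible(cohort)
}

#' Fit the model from CSV inputs
#'
#' Grids the three tables and runs the EM fit; writes the estimated
#' parameters as JSON with fit provenance.
#'
#' @param longitudinal_path,baseline_path,survival_path Input CSVs.
#' @param config_path JSON configuration (blocks `structure`: `m_y`, `M`;
#'   `grid`: `dt`; `fit`: `tol`, `max_iter`), or `NULL` for defaults
#'   (AR(2), `dt = 1`, `tol = 5e-4`, `max_iter = 600`).
#' @param out_params Output parameter JSON path.
#' @return Invisibly, the `lsdsm_fit`.
#' @export
cmd_fit <- function(longitudinal_path, baseline_path, survival_path,
                    config_path = NULL, out_params) {
  cfg <- read_config(config_path)
  dt <- if (!is.null(cfg$grid$dt)) cfg$grid$dt else 1
  M <- if (!is.null(cfg$structure$M)) cfg$structure$M else 2L
  cohort <- read_cohort_csv(longitudinal_path, baseline_path, survival_path,
                            dt)
  st <- canonical_structure(attr(cohort, "m_y"), M)
  ctl <- fit_control(
    tol = if (!is.null(cfg$fit$tol)) cfg$fit$tol else 5e-4,
    max_iter = if (!is.null(cfg$fit$max_iter)) cfg$fit$max_iter else 600L)
  fit <- lsdsm_fit(cohort, st, ctl)
  write_params_json(fit$params, out_params,
                    provenance = list(tol = ctl$tol, max_iter = ctl$max_iter,
                                      n_iter = fit$n_iter,
                                      converged = fit$converged))
  invisible(fit)
}

#' Predict survival curves from CSV inputs and a parameter file
#'
#' Truncates each requested patient's record at the landmark and runs the
#' dynamic prediction recursion out to the horizon.
#'
#' @inheritParams cmd_fit
#' @param params_path Parameter JSON written by [cmd_fit()] or
#'   [write_params_json()].
#' @param landmark,horizon Landmark time and horizon span (model time units).
#' @param out_csv Output CSV with columns `patient_id`, `landmark`,
#'   `horizon_time`, `survival_probability`.
#' @param dt Grid step (default 1).
#' @return Invisibly, the prediction data frame.
#' @export
cmd_predict <- function(longitudinal_path, baseline_path, survival_path,
                        params_path, landmark, horizon, out_csv, dt = 1) {
  params <- read_params_json(params_path)
  cohort <- read_cohort_csv(longitudinal_path, baseline_path, survival_path,
                            dt)
  eligible <- Filter(function(p)
    p$T > landmark + 1e-9 || (p$delta == 0 && p$T >= landmark - 1e-9), cohort)
  if (!length(eligible)) {
    stop("no patient has follow-up reaching the landmark", call. = FALSE)
  }
  out <- do.call(rbind, lapply(eligible, function(p) {
    cv <- predict_survival(p, params, landmark, horizon)
    data.frame(patient_id = p$patient_id, landmark = cv$landmark,
               horizon_time = cv$horizon_time,
               survival_probability = cv$survival)
  }))
  write_csv17(out, out_csv)
  invisible(out)
}

#' Evaluate predictions against observed outcomes
#'
#' @param prediction_csv CSV written by [cmd_predict()].
#' @param survival_csv Survival outcome CSV.
#' @param landmarks,horizons Landmark times and horizon spans to report.
#' @param out_csv Output report CSV.
#' @return Invisibly, the report data frame (`landmark`, `horizon`,
#'   `n_at_risk`, `auc`, `brier`).
#' @export
cmd_evaluate <- function(prediction_csv, survival_csv, landmarks, horizons,
                         out_csv) {
  pred <- utils::read.csv(prediction_csv, stringsAsFactors = FALSE)
  surv <- utils::read.csv(survival_csv, stringsAsFactors = FALSE)
  rep <- evaluate_predictions(pred, surv, landmarks, horizons)
  write_csv17(rep, out_csv)
  invisible(rep)
}
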