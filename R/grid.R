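#' Discretize one patient's irregular observations onto the model grid
#'
#' The state-space model runs on a regular grid with step `dt`.  Interval `j`
#' (1-based) covers `[(j-1)*dt, j*dt)`; an observation at time `t` is assigned
#' to interval `floor(t/dt) + 1`, multiple observations falling in one
#' interval are aggregated, and empty intervals are recorded as missing.  The
#' patient contributes `m = ceiling(T/dt)` intervals; per-interval exposure is
#' `tau_j = dt` for `j < m` and `tau_m = T - (m-1)*dt` for the (possibly
#' partial) last interval, so that `sum(tau) == T`.  If the event occurred
#' (`delta = 1`) it is attributed to interval `m`, the interval containing
#' `T`.
#'
#' @param patient_id Identifier carried through to outputs.
#' @param times Observation times, all in `[0, T]`.
#' @param values Biomarker values: a numeric vector (one biomarker) or a
#'   matrix with one row per observation time and one column per biomarker.
#'   `NA` entries are allowed and treated as missing.
#' @param omega Baseline covariate vector.
#' @param T_i Event or censoring time (> 0), in the same units as `dt`.
#' @param delta Event indicator: 1 event, 0 censored.
#' @param dt Grid step (> 0).
#' @param aggregate How to combine multiple observations landing in the same
#'   interval: `"mean"` (default) or `"first"`.
#'
#' @return An object of class `lsdsm_patient`: a list with the measurement
#'   grid `y` (`m` x `m_y`, `NA` where missing), `observed_mask`, exposure
#'   vector `tau`, interval event indicators `delta_bar`, and the scalars
#'   `patient_id`, `omega`, `T`, `delta`, `m`, `dt`.
#' @export
grid_patient <- function(patient_id, times, values, omega, T_i, delta, dt,
                         aggregate = c("mean", "first")) {
  aggregate <- match.arg(aggregate)
  if (length(T_i) != 1L || !is.finite(T_i) || T_i <= 0) {
    stop("event/censoring time 'T_i' must be a single positive number",
         call. = FALSE)
  }
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a single positive number", call. = FALSE)
  }
  if (!delta %in% c(0, 1)) stop("'delta' must be 0 or 1", call. = FALSE)
  values <- if (is.null(dim(values))) matrix(values, ncol = 1L) else
    as.matrix(values)
  if (length(times) != nrow(values)) {
    stop("'times' and 'values' must have matching lengths", call. = FALSE)
  }
  if (length(times) && (min(times) < 0 || max(times) > T_i)) {
    stop("all observation times must lie in [0, T_i]", call. = FALSE)
  }
  m_y <- ncol(values)
  m <- as.integer(ceiling(T_i / dt))
  # T exactly on a grid point: ceiling of an integer, no zero-length interval
  tau <- rep(dt, m)
  tau[m] <- T_i - (m - 1L) * dt
  delta_bar <- rep(0L, m)
  if (delta == 1) delta_bar[m] <- 1L

  y <- matrix(NA_real_, m, m_y)
  if (length(times)) {
    bin <- pmin(as.integer(floor(times / dt)) + 1L, m)  # t == T_i -> interval m
    for (j in unique(bin)) {
      rows <- values[bin == j, , drop = FALSE]
      y[j, ] <- if (aggregate == "mean") {
        colMeans(rows, na.rm = TRUE)
      } else {
        rows[1L, ]
      }
    }
    y[is.nan(y)] <- NA_real_
  }
  structure(list(patient_id = patient_id, omega = as.numeric(omega),
                 dt = dt, y = y, observed_mask = !is.na(y),
                 T = T_i, delta = as.integer(delta), m = m,
                 tau = tau, delta_bar = delta_bar),
            class = "lsdsm_patient")
}

#' @export
print.lsdsm_patient <- function(x, ...) {
  cat(sprintf("Gridded patient '%s': %d interval(s) of dt = %g, T = %g, %s\n",
              as.character(x$patient_id), x$m, x$dt, x$T,
              if (x$delta == 1) "event" else "censored"))
  cat(sprintf("  %d/%d measurement cells observed\n",
              sum(x$observed_mask), length(x$observed_mask)))
  invisible(x)
}

#' Grid a whole cohort from long-format tables
#'
#' Joins the three standard tables (longitudinal, baseline, survival) by
#' patient id and grids every patient with [grid_patient()].  Every patient in
#' the longitudinal or baseline table must have a survival record.
#'
#' @param longitudinal Data frame with columns `patient_id`, `time`, then one
#'   column per biomarker (empty/`NA` cell = missing).
#' @param baseline Data frame with `patient_id` plus one numeric column per
#'   baseline covariate, or `NULL` for none.
#' @param survival Data frame with columns `patient_id`, `time`, `event`.
#' @param dt Grid step.
#' @param aggregate Passed to [grid_patient()].
#'
#' @return An object of class `lsdsm_cohort`: a list of `lsdsm_patient`
#'   objects with attributes `dt`, `m_y`, `m_omega` and the biomarker /
#'   covariate column names.
#' @export
grid_cohort <- function(longitudinal, baseline, survival, dt,
                        aggregate = c("mean", "first")) {
  aggregate <- match.arg(aggregate)
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  req(longitudinal, c("patient_id", "time"), "longitudinal")
  req(survival, c("patient_id", "time", "event"), "survival")
  ids <- unique(c(longitudinal$patient_id,
                  if (!is.null(baseline)) baseline$patient_id))
  ids <- union(ids, survival$patient_id)
  missing_surv <- setdiff(ids, survival$patient_id)
  if (length(missing_surv)) {
    stop(sprintf("no survival record for patient(s): %s",
                 paste(missing_surv, collapse = ", ")), call. = FALSE)
  }
  biomarkers <- setdiff(names(longitudinal), c("patient_id", "time"))
  if (!length(biomarkers)) {
    stop("longitudinal table has no biomarker columns", call. = FALSE)
  }
  covariates <- if (is.null(baseline)) character(0) else
    setdiff(names(baseline), "patient_id")
  ids <- survival$patient_id
  patients <- lapply(seq_along(ids), function(k) {
    id <- ids[k]
    li <- longitudinal[longitudinal$patient_id == id, , drop = FALSE]
    om <- if (length(covariates)) {
      bi <- baseline[baseline$patient_id == id, covariates, drop = FALSE]
      if (nrow(bi) != 1L) {
        stop(sprintf("patient '%s' has %d baseline rows (expected 1)",
                     as.character(id), nrow(bi)), call. = FALSE)
      }
      as.numeric(bi[1L, ])
    } else numeric(0)
    grid_patient(id, li$time, as.matrix(li[, biomarkers, drop = FALSE]),
                 om, survival$time[k], survival$event[k], dt,
                 aggregate = aggregate)
  })
  structure(patients, class = "lsdsm_cohort", dt = dt,
            m_y = length(biomarkers), m_omega = length(covariates),
            biomarkers = biomarkers, covariates = covariates)
}

#' @export
print.lsdsm_cohort <- function(x, ...) {
  n <- length(x)
  ev <- sum(vapply(x, function(p) p$delta, integer(1)))
  obs <- vapply(x, function(p) mean(p$observed_mask), numeric(1))
  cat(sprintf("Gridded cohort: %d patients, dt = %g, %d biomarker(s), %d covariate(s)\n",
              n, attr(x, "dt"), attr(x, "m_y"), attr(x, "m_omega")))
  cat(sprintf("  events: %d (%.1f%%); mean observed fraction of grid cells: %.1f%%\n",
              ev, 100 * ev / n, 100 * mean(obs)))
  invisible(x)
}

#' Truncate and rescale a raw biomarker
#'
#' Caps values at `cap` and divides by `scale`, e.g. walking distances capped
#' at 1000 m and divided by 1000 so that a value of 0.5 reads as 500 m.
#' Missing values pass through unchanged; negative inputs are rejected.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param cap Upper truncation point (> 0).
#' @param scale Divisor (> 0).
#' @return Numeric vector `pmin(values, cap) / scale`.
#' @export
#' @examples
#' normalize_biomarker(c(1020, 500, 0), cap = 1000, scale = 1000)
normalize_biomarker <- function(values, cap, scale = cap) {
  stopifnot(cap > 0, scale > 0)
  if (any(values < 0, na.rm = TRUE)) {
    stop("negative biomarker values are not allowed", call. = FALSE)
  }
  pmin(values, cap) / scale
}
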