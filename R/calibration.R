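# IVIVE scaling, bounded least-squares calibration against time courses or
# reported excretion windows, and normalized local sensitivity analysis.

#' Get or set a model parameter by dotted path
#'
#' Paths address leaves of the parameter object, e.g.
#' `"metabolism.k_gut_composite"` or
#' `"chemical.partition_coefficients.fat"`.
#'
#' @param p A `bpa_parameters` object.
#' @param path Dotted path string.
#' @return `get_param()` the value; `set_param()` a modified copy of `p`.
#' @export
get_param <- function(p, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- p
  for (k in keys) {
    x <- x[[k]]
    if (is.null(x)) stop("unknown parameter path: ", path, call. = FALSE)
  }
  x
}

#' @rdname get_param
#' @param value New value for the leaf.
#' @export
set_param <- function(p, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, keys) {
    if (is.null(x[[keys[1]]])) stop("unknown parameter path: ", path, call. = FALSE)
    if (length(keys) == 1L) x[[keys[1]]] <- value
    else x[[keys[1]]] <- rec(x[[keys[1]]], keys[-1])
    x
  }
  rec(p, keys)
}

# numeric leaf paths of selected blocks, for default sensitivity scans
numeric_leaf_paths <- function(p, blocks = c("metabolism", "absorption",
                                             "ehr", "conjugate")) {
  paths <- character(0)
  for (b in blocks) {
    if (is.null(p[[b]])) next
    u <- rapply(p[[b]], function(v) v, classes = c("numeric", "integer"),
                how = "unlist")
    paths <- c(paths, paste0(b, ".", names(u)))
  }
  paths
}

# multiplicative perturbation that keeps the parameter set self-consistent:
# cardiac output carries all tissue flows with it (flow conservation)
perturb_param <- function(p, path, factor) {
  if (identical(path, "physiology.cardiac_output")) {
    p$physiology$cardiac_output <- p$physiology$cardiac_output * factor
    p$physiology$tissue_flows <- scale_leaves(p$physiology$tissue_flows, factor)
    p
  } else {
    set_param(p, path, get_param(p, path) * factor)
  }
}

#' In vitro to in vivo extrapolation of a maximal metabolic velocity
#'
#' Whole-liver Vmax as the product of the microsomal in vitro velocity, the
#' microsomal protein yield per gram of liver, and the liver mass.
#'
#' @param vmax_in_vitro nmol/h per mg microsomal protein.
#' @param mppgl mg microsomal protein per g liver.
#' @param liver_mass g liver.
#' @return Whole-organ Vmax (nmol/h); linear in each factor.
#' @export
ivive_vmax <- function(vmax_in_vitro, mppgl, liver_mass) {
  if (any(c(vmax_in_vitro, mppgl, liver_mass) <= 0)) {
    stop("all IVIVE factors must be positive", call. = FALSE)
  }
  vmax_in_vitro * mppgl * liver_mass
}

#' Normalized local sensitivity coefficients
#'
#' Central-difference coefficients (dM/M)/(dp/p) of a scalar model metric
#' with respect to each parameter, at the packaged values. Parameters whose
#' packaged value is zero have no defined relative perturbation and are
#' reported with coefficient 0.
#'
#' @param p A `bpa_parameters` object.
#' @param metric Function of a `bpa_parameters` object returning a scalar
#'   (see [metric_parent_auc()]).
#' @param parameters Character vector of dotted parameter paths; defaults to
#'   all numeric constants of the metabolism, absorption, EHR and conjugate
#'   blocks plus cardiac output and the fat partition coefficient.
#' @param perturbation Relative perturbation, in (0, 0.1]; default 1%.
#' @return A `bpa_sensitivity` data.frame (parameter, value, coefficient),
#'   sorted by decreasing |coefficient|.
#' @export
normalized_sensitivity <- function(p, metric, parameters = NULL,
                                   perturbation = 0.01) {
  if (perturbation <= 0 || perturbation > 0.1) {
    stop("perturbation must lie in (0, 0.1]", call. = FALSE)
  }
  parameters <- parameters %||% c(numeric_leaf_paths(p),
                                  "physiology.cardiac_output",
                                  "chemical.partition_coefficients.fat")
  m0 <- metric(p)
  if (!is_scalar_number(m0) || m0 == 0) {
    stop("metric must return a finite non-zero scalar at the base point", call. = FALSE)
  }
  coefs <- vapply(parameters, function(path) {
    v <- get_param(p, path)
    if (!is.numeric(v) || length(v) != 1L || v == 0) return(0)
    m_hi <- metric(perturb_param(p, path, 1 + perturbation))
    m_lo <- metric(perturb_param(p, path, 1 - perturbation))
    (m_hi - m_lo) / (2 * perturbation * m0)
  }, 0)
  out <- data.frame(parameter = parameters,
                    value = vapply(parameters, function(pp) {
                      v <- get_param(p, pp); if (is.numeric(v)) v else NA_real_
                    }, 0),
                    coefficient = coefs, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$coefficient)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("bpa_sensitivity", "data.frame"))
}

#' Scalar dose-metric functions for sensitivity and calibration
#'
#' Returns a function of a parameter set that simulates the given scenario
#' and evaluates one summary quantity, for use with
#' [normalized_sensitivity()] or window calibration targets.
#'
#' @param route,dose_per_kg Scenario definition.
#' @param window AUC window (h).
#' @param analyte `"parent"` or `"conjugate"`.
#' @param what `"auc"`, `"cmax"` or `"cavg"`.
#' @param dt_out,rtol Simulation resolution (looser than the default for
#'   speed; finite differences at 1% remain well resolved).
#' @return A function `p -> value`.
#' @export
metric_parent_auc <- function(route = "oral", dose_per_kg = 100,
                              window = c(0, 24), analyte = "parent",
                              what = "auc", dt_out = 0.05, rtol = 1e-8) {
  force(route); force(dose_per_kg); force(window)
  function(p) {
    r <- simulate_pk(p, dose_schedule(route, dose_per_kg),
                     t_end = window[2], dt_out = dt_out, rtol = rtol)
    dose_metrics(r, window = window, analyte = analyte)[[what]]
  }
}

## ---- calibration ----------------------------------------------------------

#' Time-course calibration target
#'
#' @param series A `bpa_series` of observations (see [generate_series()] or
#'   [read_series()]).
#' @param schedule The `bpa_schedule` that produced the observations.
#' @param weight Residual weight.
#' @return A calibration target for [calibrate_model()].
#' @export
target_series <- function(series, schedule, weight = 1) {
  stopifnot(inherits(series, "bpa_series"), inherits(schedule, "bpa_schedule"))
  structure(list(type = "series", series = series, schedule = schedule,
                 weight = weight), class = "bpa_target")
}

#' Window (range) calibration target
#'
#' Contributes a hinge residual: zero anywhere inside `[lower, upper]`,
#' growing linearly (relative to the nearest bound) outside. Reported ranges
#' are therefore perfect fits anywhere inside the range.
#'
#' @param fn Function of a parameter set returning the scalar observable.
#' @param lower,upper Window bounds.
#' @param weight Residual weight.
#' @param name Label used in reports.
#' @return A calibration target for [calibrate_model()].
#' @export
target_window <- function(fn, lower, upper, weight = 1, name = "window") {
  stopifnot(is.function(fn), lower <= upper)
  structure(list(type = "window", fn = fn, lower = lower, upper = upper,
                 weight = weight, name = name), class = "bpa_target")
}

target_residuals <- function(tg, p) {
  if (tg$type == "window") {
    v <- tg$fn(p)
    scale <- max(abs(tg$lower), abs(tg$upper), 1e-12)
    return(tg$weight * max(0, (tg$lower - v) / scale, (v - tg$upper) / scale))
  }
  s <- tg$series
  sched <- tg$schedule
  t_end <- max(max(s$time), max(sched$dose_times) + 1e-3)
  r <- simulate_pk(p, sched, t_end = t_end, dt_out = min(0.1, max(s$time) / 50))
  pred <- predict_series_values(r, attr(s, "matrix"), attr(s, "analyte"), s$time)
  keep <- !s$below_lod & s$value > 0
  tg$weight * log(pmax(pred[keep], 1e-12) / s$value[keep])
}

#' Bounded least-squares calibration of selected model constants
#'
#' Free parameters are optimized in log10 space within bounds
#' (Levenberg-Marquardt via minpack.lm). Time-course targets contribute
#' log-scale residuals at the observation times (censored observations are
#' excluded); window targets contribute hinge losses that vanish anywhere
#' inside the reported range. The procedure is deterministic given the
#' starting point; `seed` is recorded for provenance of any
#' synthetically generated targets.
#'
#' @param problem List with elements `base` (a `bpa_parameters`), `free`
#'   (data.frame with columns `path`, `lower`, `upper`, `start`; all
#'   positive), and `targets` (list of [target_series()]/[target_window()]).
#' @param seed Integer recorded in the result.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return A `bpa_calibration` list: `params` (fitted set), `estimates`
#'   (named vector), `converged`, `message`, `rss_trace`, `seed`.
#' @export
calibrate_model <- function(problem, seed = 1L, maxiter = 50L) {
  base <- problem$base
  free <- problem$free
  targets <- problem$targets
  stopifnot(inherits(base, "bpa_parameters"))
  if (length(targets) < 1L) stop("calibration needs at least one target", call. = FALSE)
  if (is.null(free) || nrow(free) == 0L) {
    return(structure(list(params = base, estimates = numeric(0),
                          converged = TRUE, message = "no free parameters",
                          rss_trace = sum(unlist(lapply(targets, target_residuals, p = base))^2),
                          seed = seed),
                     class = "bpa_calibration"))
  }
  stopifnot(all(c("path", "lower", "upper", "start") %in% names(free)))
  if (any(free$lower <= 0) || any(free$start < free$lower) ||
      any(free$start > free$upper)) {
    stop("free-parameter bounds must be positive with lower <= start <= upper",
         call. = FALSE)
  }
  for (pp in free$path) get_param(base, pp)   # fail early on bad paths

  apply_theta <- function(theta) {
    p <- base
    vals <- 10^theta
    for (i in seq_along(vals)) p <- set_param(p, free$path[i], vals[i])
    p
  }
  resid_fn <- function(theta) {
    p <- apply_theta(theta)
    unlist(lapply(targets, target_residuals, p = p), use.names = FALSE)
  }
  fit <- minpack.lm::nls.lm(par = log10(free$start), lower = log10(free$lower),
                            upper = log10(free$upper), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = 1e-10, ptol = 1e-10))
  est <- stats::setNames(10^fit$par, free$path)
  structure(list(params = apply_theta(fit$par), estimates = est,
                 converged = fit$info %in% 1:4, message = fit$message,
                 rss_trace = fit$rsstrace, seed = seed),
            class = "bpa_calibration")
}

#' @export
print.bpa_calibration <- function(x, ...) {
  cat("<bpa_calibration> ", if (x$converged) "converged" else "NOT converged",
      " (", x$message, ")\n", sep = "")
  if (length(x$estimates)) {
    for (i in seq_along(x$estimates)) {
      cat(sprintf("  %s = %.6g\n", names(x$estimates)[i], x$estimates[i]))
    }
  }
  invisible(x)
}
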