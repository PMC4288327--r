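# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate a packaged data file
#' @noRd
bpk_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "bpapbpk")
  if (identical(path, "")) {
    stop("packaged file not found: inst/extdata/", file.path(...), call. = FALSE)
  }
  path
}

#' Trapezoidal integral of y over x
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Linear interpolation that errors outside the range
#' @noRd
interp_strict <- function(x, y, xout, what = "value") {
  if (any(xout < min(x) - 1e-9) || any(xout > max(x) + 1e-9)) {
    stop(what, ": requested times outside the simulated range [",
         format(min(x)), ", ", format(max(x)), "] h", call. = FALSE)
  }
  stats::approx(x, y, xout = pmin(pmax(xout, min(x)), max(x)), ties = "ordered")$y
}

# micrograms -> nmol for a given molecular weight (g/mol)
ug_to_nmol <- function(ug, mw) ug / mw * 1000
# nmol/L -> ug/L
nM_to_ugL <- function(nmolL, mw) nmolL * mw / 1000

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
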