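#' Fit a polynomial height profile to the sliding phase of a trace
#'
#' The probe height recorded during sliding traces the sample surface: a
#' mounting tilt plus, on cured-polymer samples, a meniscus-shaped bowl. The
#' measured height is approximated by a least-squares polynomial in the stage
#' position `x` (degree 5 by default), whose analytic derivative gives the
#' local surface slope used for the misalignment correction.
#'
#' @param trace A [as_tribo_trace()] object.
#' @param degree Polynomial degree (>= 1); default 5.
#' @return An object of class `height_model`: coefficients in ascending
#'   powers, the fit domain, and the residual RMS in mm.
#' @examples
#' tr <- generate_trace(trace_scenario(seed = 1))
#' hm <- fit_height_profile(tr)
#' hm$rms
#' @export
fit_height_profile <- function(trace, degree = 5) {
  stopifnot(inherits(trace, "tribo_trace"))
  if (!is.numeric(degree) || length(degree) != 1 || degree < 1) {
    abort("`degree` must be a single integer >= 1.")
  }
  degree <- as.integer(degree)
  sel <- trace$x_mm > trace$x_mm[1]
  x <- trace$x_mm[sel]
  h <- trace$h_mm[sel]
  if (diff(range(trace$x_mm)) == 0) {
    abort("`x_mm` is constant: no sliding phase to fit a height profile to.")
  }
  if (length(x) < degree + 2) {
    abort(sprintf(
      "Need at least degree + 2 = %d sliding-phase samples, got %d.",
      degree + 2, length(x)))
  }
  fit <- lm(h ~ stats::poly(x, degree, raw = TRUE))
  coefs <- unname(coef(fit))
  coefs[is.na(coefs)] <- 0
  structure(
    list(
      coefficients = coefs,
      degree = degree,
      domain = range(x),
      rms = sqrt(mean(stats::residuals(fit)^2))
    ),
    class = "height_model"
  )
}

check_domain <- function(model, x) {
  tol <- 1e-8 * max(1, diff(model$domain))
  if (any(x < model$domain[1] - tol | x > model$domain[2] + tol)) {
    abort("Height model evaluated outside its fit domain.")
  }
}

#' Evaluate a fitted height profile
#'
#' @param object A `height_model`.
#' @param x Positions in mm (must lie inside the fit domain).
#' @param ... Unused.
#' @return Fitted heights in mm.
#' @export
predict.height_model <- function(object, x, ...) {
  check_domain(object, x)
  powers <- outer(x, 0:object$degree, `^`)
  as.numeric(powers %*% object$coefficients)
}

#' Analytic slope of a fitted height profile
#'
#' @param model A `height_model`.
#' @param x Positions in mm inside the fit domain.
#' @return The derivative dh/dx (mm/mm) at `x`.
#' @export
height_slope <- function(model, x) {
  stopifnot(inherits(model, "height_model"))
  check_domain(model, x)
  d <- model$degree
  dcoef <- model$coefficients[-1] * seq_len(d)
  powers <- outer(x, 0:(d - 1), `^`)
  as.numeric(powers %*% dcoef)
}

#' @export
print.height_model <- function(x, ...) {
  cat(sprintf(
    "<height_model> degree %d on [%.3g, %.3g] mm, residual RMS %.3g mm\n",
    x$degree, x$domain[1], x$domain[2], x$rms))
  invisible(x)
}
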