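#' Fit Amonton's law through the origin
#'
#' Fits the proportionality `F_F = mu * F_N` by least squares constrained
#' through the origin: `mu = sum(F_N * F_F) / sum(F_N^2)`. This is the
#' friction-coefficient estimator used to summarise per-slide friction forces
#' across normal loads.
#'
#' @param data A data frame of per-slide points.
#' @param f_n,f_f Columns (tidy-eval) holding the normal load and friction
#'   force in mN; default `F_N_mN` / `F_F_mN`.
#' @return An object of class `amonton_fit` with elements `mu`, `n`,
#'   `points` (a tibble with per-point residuals) and `rmse`. Supports
#'   [tidy()], [glance()] and `predict()`.
#' @examples
#' pts <- tibble::tibble(F_N_mN = c(10, 20, 40, 80), F_F_mN = 0.5 * F_N_mN)
#' fit_amontons(pts)$mu
#' @export
fit_amontons <- function(data, f_n = F_N_mN, f_f = F_F_mN) {
  fn <- dplyr::pull(data, {{ f_n }})
  ff <- dplyr::pull(data, {{ f_f }})
  if (length(fn) == 0) abort("No points supplied to the Amonton fit.")
  if (length(fn) < 2) abort("Amonton fit needs at least 2 points.")
  if (any(!is.finite(fn)) || any(!is.finite(ff))) {
    abort("Amonton fit points must all be finite.")
  }
  if (any(fn <= 0)) abort("All normal loads must be > 0.")
  mu <- sum(fn * ff) / sum(fn^2)
  resid <- ff - mu * fn
  se <- sqrt(sum(resid^2) / (length(fn) - 1) / sum(fn^2))
  structure(
    list(
      mu = mu,
      n = length(fn),
      std_error = se,
      points = tibble::tibble(F_N_mN = fn, F_F_mN = ff, residual_mN = resid),
      rmse = sqrt(mean(resid^2))
    ),
    class = "amonton_fit"
  )
}

#' @export
print.amonton_fit <- function(x, ...) {
  cat(sprintf("<amonton_fit> F_F = mu * F_N, mu = %.4g (se %.2g, n = %d)\n",
              x$mu, x$std_error, x$n))
  invisible(x)
}

#' @export
predict.amonton_fit <- function(object, F_N_mN, ...) object$mu * F_N_mN

#' Tidy an Amonton fit
#' @param x An `amonton_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate`, `std.error`.
#' @method tidy amonton_fit
#' @export
tidy.amonton_fit <- function(x, ...) {
  tibble::tibble(term = "mu", estimate = x$mu, std.error = x$std_error)
}

#' One-row summary of an Amonton fit
#' @param x An `amonton_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `mu`, `n`, `rmse`.
#' @method glance amonton_fit
#' @export
glance.amonton_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, n = x$n, rmse = x$rmse)
}
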