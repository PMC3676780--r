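#' Fit a Hill function to a dose-response curve
#'
#' Least-squares fit of the four-parameter Hill function
#' \deqn{A(L) = A_{low} + \frac{A_{high} - A_{low}}{1 + (L/K)^{n_H}}}
#' for decreasing curves (the exponent is mirrored for increasing curves).
#' The Hill coefficient `n_H` is a descriptive summary of cooperativity; no
#' mechanistic interpretation is attached.  Fitting is done in log-L space
#' with `K` and `n_H` parameterised on the log scale, using
#' Levenberg--Marquardt with a deterministic multi-start: the initial `K`
#' is the grid point nearest the half-range response, the initial `n_H`
#' comes from the steepest log-L slope (for a Hill curve the peak slope is
#' `n_H * range / 4`), and the exponent start is additionally halved and
#' doubled, keeping the best of the three fits.  Plateaus are free, so the
#' curve need not span [0, 1].
#'
#' @param curve a [dose_response()] data.frame, or any data.frame whose
#'   first two columns are ligand level and response.  At least 8 points;
#'   20+ spanning most of the dynamic range recommended.
#' @return Object of class `hill_fit`: a list with `n_H`, `K_half`,
#'   `A_high`, `A_low`, `residual` (root-mean-square error) and
#'   `direction` ("decreasing"/"increasing").
#' @examples
#' L <- 10^seq(-2, 2, length.out = 50)
#' y <- 0.1 + 0.8 / (1 + (L / 1)^2)
#' fit_hill(data.frame(L, y))
#' @export
fit_hill <- function(curve) {
  stopifnot(is.data.frame(curve), ncol(curve) >= 2)
  L <- curve[[1]]; y <- curve[[2]]
  ok <- is.finite(L) & is.finite(y) & L > 0
  L <- L[ok]; y <- y[ok]
  if (length(L) < 8) stop_invalid("need at least 8 points with L > 0")
  rng <- max(y) - min(y)
  if (rng < 1e-6) stop_invalid("no transition: response range < 1e-6")

  lx <- log(L)
  decreasing <- stats::cor(lx, y) < 0
  sgn <- if (decreasing) 1 else -1

  # deterministic starts
  y_half <- (max(y) + min(y)) / 2
  K0 <- L[which.min(abs(y - y_half))]
  slope <- abs(diff(y) / diff(lx))
  n0 <- max(0.2, min(50, 4 * max(slope, na.rm = TRUE) / rng))

  model <- function(p, lx) {
    # p = (A_high, A_low, logK, logn)
    p[2] + (p[1] - p[2]) / (1 + exp(sgn * exp(p[4]) * (lx - p[3])))
  }
  best <- NULL
  for (mult in c(1, 0.5, 2)) {
    start <- c(max(y), min(y), log(K0), log(n0 * mult))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        fn = function(p) y - model(p, lx),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(fit$fvec^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) stop_invalid("Hill fit failed to converge")
  p <- best$fit$par
  a_high <- max(p[1], p[2]); a_low <- min(p[1], p[2])
  structure(list(
    n_H = exp(p[4]),
    K_half = exp(p[3]),
    A_high = a_high,
    A_low = a_low,
    residual = sqrt(best$sse / length(y)),
    direction = if (decreasing) "decreasing" else "increasing"
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit (%s): n_H = %.4g, K_half = %.4g, plateaus [%.4g, %.4g], rms = %.3g\n",
    x$direction, x$n_H, x$K_half, x$A_low, x$A_high, x$residual))
  invisible(x)
}

#' Classify cooperativity from a Hill fit
#'
#' Maps the fitted Hill coefficient onto the conventional three-tier
#' cooperativity scale for chemoreceptor signalling: a single effective
#' site gives n_H ~ 1 (low), a trimer of dimers gives n_H ~ 2--3
#' (moderate), and strongly coupled clusters of trimers give n_H well above
#' 3 (high).  The class boundaries partition those regimes and are
#' adjustable.
#'
#' @param fit a [fit_hill()] result, or a bare Hill coefficient.
#' @param low_cut boundary between "low" and "moderate" (default 1.5).
#' @param high_cut boundary between "moderate" and "high" (default 3).
#' @return One of `"low"`, `"moderate"`, `"high"`.
#' @export
cooperativity_class <- function(fit, low_cut = 1.5, high_cut = 3) {
  n_H <- if (inherits(fit, "hill_fit")) fit$n_H else as.numeric(fit)
  check_positive(n_H, "n_H")
  if (n_H < low_cut) "low" else if (n_H <= high_cut) "moderate" else "high"
}
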