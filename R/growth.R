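#' Cells per unit OD600
#'
#' Calibration constant: an optical density of 1 at 600 nm corresponds to
#' 1e8 cells.
#' @export
CELLS_PER_OD <- 1e8

#' Specific growth rate from a growth curve
#'
#' Computes \eqn{\mu(t) = (1/N)\,dN/dt = d\ln N/dt} by differentiating the
#' growth curve.  For more than 5 points a smoothing spline is fitted to
#' `ln(OD)` and differentiated analytically; with 5 or fewer points central
#' finite differences on `ln(OD)` are used.  Because `ln(cN)` and `ln(N)`
#' differ by a constant, the estimate is exactly invariant to the OD-to-cell
#' calibration.
#'
#' @param curve Data frame with columns `time_h` (strictly increasing) and
#'   `od600` (must be positive at all points used).
#' @param spar Optional smoothing parameter forwarded to
#'   [stats::smooth.spline()]; by default the spline interpolates closely
#'   (generalized cross-validation).
#' @return Data frame with `time_h` and `mu` (1/h) at the input times.
#' @examples
#' tt <- 0:10
#' specific_growth_rate(data.frame(time_h = tt, od600 = 0.02 * exp(0.3 * tt)))
#' @export
specific_growth_rate <- function(curve, spar = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("time_h", "od600") %in% names(curve)))
  tt <- as.numeric(curve$time_h)
  od <- as.numeric(curve$od600)
  if (length(tt) < 4L) stop("need at least 4 points", call. = FALSE)
  if (any(diff(tt) <= 0)) {
    stop("'time_h' must be strictly increasing", call. = FALSE)
  }
  if (any(od <= 0)) {
    stop("od600 must be positive at all evaluation points (zero cell count ",
         "gives an undefined rate)", call. = FALSE)
  }
  # centring ln(OD) and canonicalizing to 12 significant digits makes the
  # estimate exactly invariant to rescaling the curve (OD vs cell count):
  # the spline sees bit-identical data either way
  ln <- log(od) - mean(log(od))
  ln <- signif(ln, 12)
  if (length(tt) > 5L) {
    fit <- if (is.null(spar)) {
      stats::smooth.spline(tt, ln)
    } else {
      stats::smooth.spline(tt, ln, spar = spar)
    }
    mu <- stats::predict(fit, tt, deriv = 1)$y
  } else {
    mu <- numeric(length(tt))
    i <- 2:(length(tt) - 1L)
    mu[i] <- (ln[i + 1L] - ln[i - 1L]) / (tt[i + 1L] - tt[i - 1L])
    mu[1] <- (ln[2] - ln[1]) / (tt[2] - tt[1])
    n <- length(tt)
    mu[n] <- (ln[n] - ln[n - 1L]) / (tt[n] - tt[n - 1L])
  }
  data.frame(time_h = tt, mu = mu)
}

#' Monod specific growth rate
#'
#' \eqn{\mu = \mu_{max}\, s / (k + s)}: monotone increasing in the nutrient
#' concentration `s`, half-maximal at `s = k`, saturating at `mu_max`.
#'
#' @param s Nutrient concentration (arbitrary units), nonnegative;
#'   vectorised.
#' @param k Half-saturation constant (same units as `s`), positive.
#' @param mu_max Maximal specific growth rate (1/h), positive.
#' @return Specific growth rate (1/h).
#' @export
monod_mu <- function(s, k, mu_max) {
  stopifnot(is.numeric(s), is.numeric(k), is.numeric(mu_max),
            k > 0, mu_max > 0)
  if (any(s < 0)) stop("nutrient concentration 's' must be >= 0",
                       call. = FALSE)
  mu_max * s / (k + s)
}

#' Growth-retardation law
#'
#' The metabolic burden of synthesising a protein at concentration `x`
#' reduces the specific growth rate as
#' \deqn{\mu(x) = \frac{\phi}{1 + \theta x},}
#' strictly decreasing in `x` for `theta > 0` and equal to `phi` when the
#' burden vanishes (`x = 0` or `theta = 0`).
#'
#' @param x Protein level (concentration or reporter-intensity proxy),
#'   nonnegative; vectorised.
#' @param phi Unburdened growth rate (1/h), positive.  May also be a
#'   `retardation_fit` object, in which case `theta` is taken from it.
#' @param theta Burden coefficient (per protein unit), nonnegative.
#' @return Specific growth rate (1/h).
#' @examples
#' retarded_mu(1, 0.94, 0.317)
#' @export
retarded_mu <- function(x, phi, theta = NULL) {
  if (inherits(phi, "retardation_fit")) {
    theta <- phi$theta
    phi <- phi$phi
  }
  stopifnot(is.numeric(phi), phi > 0, is.numeric(theta), theta >= 0)
  if (any(x < 0)) stop("protein level 'x' must be >= 0", call. = FALSE)
  phi / (1 + theta * x)
}

#' Retardation parameters from Monod quantities
#'
#' First-order reduction of Monod growth with a protein-proportional
#' nutrient burden `epsilon = lambda * x`: expanding
#' \eqn{\mu = \mu_{max} / (1 + (k/s)(1 - \epsilon)^{-1})} to first order in
#' `epsilon` yields the retardation law with
#' \deqn{\phi = \mu_{max}\frac{s}{s+k},\qquad \theta = \frac{k\lambda}{s+k}.}
#'
#' @param mu_max Maximal specific growth rate (1/h).
#' @param s Nutrient concentration.
#' @param k Half-saturation constant.
#' @param lambda Burden per protein unit (so that `epsilon = lambda * x`),
#'   nonnegative.
#' @return A `retardation_fit` object with fields `phi` and `theta`.
#' @export
phi_theta_from_monod <- function(mu_max, s, k, lambda) {
  stopifnot(mu_max > 0, s >= 0, k > 0, lambda >= 0)
  if (s + k <= 0) stop("s + k must be positive", call. = FALSE)
  structure(list(phi = mu_max * s / (s + k),
                 theta = k * lambda / (s + k),
                 fitted = FALSE),
            class = "retardation_fit")
}

#' Fit the growth-retardation law to (protein level, growth rate) pairs
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `mu ~ phi / (1 + theta * x)` on unweighted pairs, e.g. specific growth
#' rate against GFP reporter intensity, in which case the fitted `phi` is
#' the apparent maximal growth rate and `theta` the burden per intensity
#' unit.
#'
#' @param x Protein levels (nonnegative), at least 3.
#' @param mu Specific growth rates (positive), same length.
#' @param start Named start values `c(phi = , theta = )`; default
#'   `phi = max(mu)`, `theta = 0.1`.
#' @return A `retardation_fit` with `phi`, `theta`, `fitted = TRUE`,
#'   `residuals`, `rss`, and the underlying [minpack.lm::nls.lm()] object
#'   in `$fit`.
#' @examples
#' x <- seq(0, 3, length.out = 20)
#' fit_growth_retardation(x, 0.94 / (1 + 0.317 * x))
#' @export
fit_growth_retardation <- function(x, mu,
                                   start = c(phi = max(mu), theta = 0.1)) {
  x <- as.numeric(x)
  mu <- as.numeric(mu)
  if (length(x) < 3L || length(mu) != length(x)) {
    stop("need at least 3 (x, mu) pairs of equal length", call. = FALSE)
  }
  if (any(x < 0)) stop("'x' must be >= 0", call. = FALSE)
  if (any(mu <= 0)) stop("'mu' must be > 0", call. = FALSE)
  fit <- minpack.lm::nls.lm(
    par = list(phi = unname(start[["phi"]]), theta = unname(start[["theta"]])),
    lower = c(0, 0),
    fn = function(p) mu - p$phi / (1 + p$theta * x),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  if (fit$info == 0 || fit$info == 5) {
    stop("growth-retardation fit did not converge (", fit$message,
         "); last iterate phi = ", fit$par$phi, ", theta = ", fit$par$theta,
         call. = FALSE)
  }
  structure(list(phi = fit$par$phi, theta = fit$par$theta,
                 fitted = TRUE,
                 residuals = -fit$fvec,
                 rss = fit$deviance,
                 fit = fit),
            class = "retardation_fit")
}

#' @export
print.retardation_fit <- function(x, ...) {
  cat(sprintf("Growth-retardation law mu = phi / (1 + theta x): phi = %.6g 1/h, theta = %.6g\n",
              x$phi, x$theta))
  if (isTRUE(x$fitted)) cat(sprintf("  residual sum of squares: %.4g\n", x$rss))
  invisible(x)
}
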