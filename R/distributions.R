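#' Low-expression (L) Gaussian component
#'
#' The L subpopulation's fluorescence distribution is modelled as a Gaussian
#' written in peak-width form,
#' \deqn{P_1(x) = \frac{\exp(-2((x - x_{01})/w_{01})^2)}{w_{01}\sqrt{\pi/2}},}
#' with centre `x01` and width `w01` (both in fluorescence a.u.).  This
#' parameterisation is equivalent to a normal density with standard deviation
#' `w01 / 2`; a plain-sigma reading (`sd = w01`) is available through the
#' `convention` argument of [gaussian_pdf()] and [sample_component()].
#'
#' @param center Peak position `x01` (fluorescence a.u.).
#' @param width Width parameter `w01` (fluorescence a.u.), must be positive.
#' @return An object of class `gaussian_component`.
#' @seealso [lognormal_component()], [mixture_model()]
#' @examples
#' comp <- gaussian_component(97.3366, 103.0731)
#' gaussian_pdf(97.3366, comp)
#' @export
gaussian_component <- function(center, width) {
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(width), length(width) == 1L, is.finite(width))
  if (width <= 0) {
    stop("'width' (w01) must be positive, got ", width, call. = FALSE)
  }
  structure(list(center = center, width = width),
            class = c("gaussian_component", "mix_component"))
}

#' High-expression (H) lognormal component
#'
#' The H subpopulation's fluorescence distribution is modelled as lognormal
#' with log-mean `x02` and log-standard-deviation `w02` (both dimensionless,
#' on the natural-log scale of intensity).  The median intensity is
#' `exp(x02)` and the mode `exp(x02 - w02^2)`.
#'
#' @param log_mean Log-scale location `x02`.
#' @param log_sd Log-scale spread `w02`, must be positive.
#' @return An object of class `lognormal_component`.
#' @examples
#' comp <- lognormal_component(5.95526, 0.17618)
#' exp(comp$log_mean)  # median intensity
#' @export
lognormal_component <- function(log_mean, log_sd) {
  stopifnot(is.numeric(log_mean), length(log_mean) == 1L, is.finite(log_mean),
            is.numeric(log_sd), length(log_sd) == 1L, is.finite(log_sd))
  if (log_sd <= 0) {
    stop("'log_sd' (w02) must be positive, got ", log_sd, call. = FALSE)
  }
  structure(list(log_mean = log_mean, log_sd = log_sd),
            class = c("lognormal_component", "mix_component"))
}

#' Gamma component for high-expression fits
#'
#' Alternative positive-support family for the H subpopulation, used when
#' comparing lognormal against gamma fits of single-cell protein levels.
#'
#' @param shape Gamma shape (dimensionless), positive.
#' @param scale Gamma scale (fluorescence a.u.), positive.
#' @return An object of class `gamma_component`.
#' @export
gamma_component <- function(shape, scale) {
  stopifnot(is.numeric(shape), length(shape) == 1L, is.finite(shape),
            is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (shape <= 0 || scale <= 0) {
    stop("gamma 'shape' and 'scale' must be positive", call. = FALSE)
  }
  structure(list(shape = shape, scale = scale),
            class = c("gamma_component", "mix_component"))
}

#' Two-component mixture of invariant L and H distributions
#'
#' The population distribution of reporter fluorescence at time `t` is the
#' linear combination
#' \deqn{P(x, t) = C_1(t) P_1(x) + C_2(t) P_2(x),}
#' where the Gaussian \eqn{P_1} and lognormal \eqn{P_2} are shared by all time
#' points ("invariant") and only the weights depend on time.
#'
#' @param gaussian A [gaussian_component()].
#' @param lognormal A [lognormal_component()].
#' @param weights A data frame with columns `time` (labels, coerced to
#'   character), `C1` and `C2` (nonnegative).  In density mode
#'   (`C1 + C2 = 1` at each time) the mixture integrates to 1; count-scaled
#'   weights are allowed for histogram overlays (see [mixture_counts()]).
#' @return An object of class `mixture_model`.
#' @examples
#' m <- mixture_model(
#'   gaussian_component(97.3366, 103.0731),
#'   lognormal_component(5.95526, 0.17618),
#'   data.frame(time = c("18h", "27h"), C1 = c(0.9, 0.2), C2 = c(0.1, 0.8))
#' )
#' mixture_pdf(150, m, "18h")
#' @export
mixture_model <- function(gaussian, lognormal, weights) {
  stopifnot(inherits(gaussian, "gaussian_component"),
            inherits(lognormal, "lognormal_component"),
            is.data.frame(weights),
            all(c("time", "C1", "C2") %in% names(weights)))
  weights$time <- as.character(weights$time)
  if (anyDuplicated(weights$time)) {
    stop("duplicate time labels in mixture weights", call. = FALSE)
  }
  if (any(weights$C1 < 0) || any(weights$C2 < 0)) {
    stop("mixture weights must be nonnegative", call. = FALSE)
  }
  structure(list(gaussian = gaussian, lognormal = lognormal,
                 weights = weights),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("Two-component mixture (invariant Gaussian + lognormal)\n")
  cat(sprintf("  L / Gaussian : x01 = %.6g, w01 = %.6g\n",
              x$gaussian$center, x$gaussian$width))
  cat(sprintf("  H / lognormal: x02 = %.6g, w02 = %.6g\n",
              x$lognormal$log_mean, x$lognormal$log_sd))
  cat(sprintf("  %d time point(s): %s\n", nrow(x$weights),
              paste(x$weights$time, collapse = ", ")))
  invisible(x)
}

# sd implied by the peak-width convention
.gaussian_sd <- function(comp, convention = c("half-width", "sd")) {
  convention <- match.arg(convention)
  if (convention == "half-width") comp$width / 2 else comp$width
}

#' Gaussian component density
#'
#' @param x Intensities (a.u.); vectorised.
#' @param comp A [gaussian_component()].
#' @param convention `"half-width"` (default; `sd = w01/2`, matching the
#'   peak-width form of the density) or `"sd"` (`sd = w01`).
#' @return Density values (1/a.u.).
#' @export
gaussian_pdf <- function(x, comp, convention = c("half-width", "sd")) {
  stopifnot(inherits(comp, "gaussian_component"))
  stats::dnorm(x, mean = comp$center, sd = .gaussian_sd(comp, convention))
}

#' Lognormal component density
#'
#' Zero for `x <= 0`; mode at `exp(x02 - w02^2)`, median `exp(x02)`.
#'
#' @param x Intensities (a.u.); vectorised.
#' @param comp A [lognormal_component()].
#' @return Density values (1/a.u.).
#' @export
lognormal_pdf <- function(x, comp) {
  stopifnot(inherits(comp, "lognormal_component"))
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- stats::dlnorm(x[pos], meanlog = comp$log_mean,
                            sdlog = comp$log_sd)
  out
}

#' Gamma component density
#'
#' @param x Intensities (a.u.); vectorised.
#' @param comp A [gamma_component()].
#' @return Density values (1/a.u.).
#' @export
gamma_pdf <- function(x, comp) {
  stopifnot(inherits(comp, "gamma_component"))
  stats::dgamma(x, shape = comp$shape, scale = comp$scale)
}

.weights_at <- function(model, t) {
  t <- as.character(t)
  i <- match(t, model$weights$time)
  if (is.na(i)) {
    stop("time label '", t, "' not present in mixture weights (have: ",
         paste(model$weights$time, collapse = ", "), ")", call. = FALSE)
  }
  c(C1 = model$weights$C1[i], C2 = model$weights$C2[i])
}

#' Mixture density at a given time point
#'
#' Evaluates `C1(t) * P1(x) + C2(t) * P2(x)`.
#'
#' @param x Intensities (a.u.); vectorised.
#' @param model A [mixture_model()].
#' @param t Time label (must be present in `model$weights`).
#' @return Density values if the weights at `t` sum to 1; otherwise the
#'   same linear combination on the stored (possibly count) scale.
#' @export
mixture_pdf <- function(x, model, t) {
  stopifnot(inherits(model, "mixture_model"))
  w <- .weights_at(model, t)
  w[["C1"]] * gaussian_pdf(x, model$gaussian) +
    w[["C2"]] * lognormal_pdf(x, model$lognormal)
}

#' Count-scaled mixture curve for histogram overlays
#'
#' Scales the density-mode mixture by the event count `n`, giving expected
#' counts per unit intensity, for overlay on an event histogram.
#'
#' @inheritParams mixture_pdf
#' @param n Number of events at time `t`.
#' @return Expected counts per unit intensity.
#' @export
mixture_counts <- function(x, model, t, n) {
  stopifnot(is.numeric(n), n > 0)
  n * mixture_pdf(x, model, t)
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Draw i.i.d. samples from a mixture component
#'
#' Reproducible for a fixed seed.  Gaussian draws may be clipped at zero
#' (`clip_at_zero = TRUE`) to mimic the nonnegative support of measured
#' intensities; off by default so the sample follows the component law
#' exactly.
#'
#' @param comp A component object.
#' @param n Number of draws, positive.
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @param ... Passed to methods.
#' @return Numeric vector of `n` intensities.
#' @export
sample_component <- function(comp, n, seed = NULL, ...) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("'n' must be a positive count", call. = FALSE)
  }
  UseMethod("sample_component")
}

#' @rdname sample_component
#' @param clip_at_zero Clip Gaussian draws at 0 (default `FALSE`).
#' @param convention See [gaussian_pdf()].
#' @export
sample_component.gaussian_component <- function(comp, n, seed = NULL,
                                                clip_at_zero = FALSE,
                                                convention = c("half-width", "sd"),
                                                ...) {
  x <- .with_seed(seed, stats::rnorm(n, mean = comp$center,
                                     sd = .gaussian_sd(comp, convention)))
  if (clip_at_zero) x <- pmax(x, 0)
  x
}

#' @rdname sample_component
#' @export
sample_component.lognormal_component <- function(comp, n, seed = NULL, ...) {
  .with_seed(seed, stats::rlnorm(n, meanlog = comp$log_mean,
                                 sdlog = comp$log_sd))
}

#' @rdname sample_component
#' @export
sample_component.gamma_component <- function(comp, n, seed = NULL, ...) {
  .with_seed(seed, stats::rgamma(n, shape = comp$shape, scale = comp$scale))
}
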