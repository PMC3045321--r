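#' Reference mixture parameter sets
#'
#' Component parameters of the invariant Gaussian + lognormal decomposition
#' for the three reporter fusions: `"mprA"` (x01 = 97.3366,
#' w01 = 103.0731, x02 = 5.95526, w02 = 0.17618), `"sigE"`
#' (145.86181, 154.67381, 6.1171, 0.2509).  No printed set exists for
#' `"rel"`; requesting it is an error.
#'
#' @param promoter `"mprA"` or `"sigE"`.
#' @return List with `gaussian` and `lognormal` components.
#' @examples
#' reference_components("mprA")$lognormal
#' @export
reference_components <- function(promoter = c("mprA", "sigE")) {
  promoter <- match.arg(promoter)
  if (promoter == "mprA") {
    list(gaussian = gaussian_component(97.3366, 103.0731),
         lognormal = lognormal_component(5.95526, 0.17618))
  } else {
    list(gaussian = gaussian_component(145.86181, 154.67381),
         lognormal = lognormal_component(6.1171, 0.2509))
  }
}

#' Default logistic schedule of the H-subpopulation fraction
#'
#' A gradual L-to-H transition: `omega2(t) = 1 / (1 + exp(-(t - midpoint)
#' / scale))`, sigmoidal in time like the observed rise of the
#' high-expression fraction during nutrient depletion.
#'
#' @param times_h Numeric hours.
#' @param midpoint Hour of half-transition (default 20).
#' @param scale Transition time scale in hours (default 2).
#' @return Numeric `omega2` values in (0, 1).
#' @export
logistic_weight_schedule <- function(times_h, midpoint = 20, scale = 2) {
  stopifnot(scale > 0)
  1 / (1 + exp(-(times_h - midpoint) / scale))
}

#' Default per-acquisition event count
#'
#' Number of fluorescence events recorded per acquisition: 20,000.
#' @export
DEFAULT_EVENTS_PER_TIMEPOINT <- 20000L

#' Define a synthetic flow-cytometry scenario
#'
#' Bundles the ground truth for a simulated reporter time course: the
#' invariant two-component mixture, the schedule of true H fractions
#' `omega2(t)`, the per-acquisition event count and the seed.  Optionally
#' the Gaussian (L) component's width is inflated by `l_noise_factor`
#' inside `l_noise_window` to emulate a transient burst of expression
#' noise in the low state around the switching period (a constructed
#' stress-test scenario for the CV analysis, not a fitted one).
#'
#' @param promoter Reference parameter set to use (see
#'   [reference_components()]).
#' @param times_h Acquisition times (hours).
#' @param omega2 True H fractions, one per time point; default: the
#'   logistic schedule of [logistic_weight_schedule()].
#' @param n_events Events per acquisition (default 20,000).
#' @param seed Integer seed.
#' @param l_noise_factor Width multiplier for the L component inside the
#'   noise window (default 1 = off).
#' @param l_noise_window Length-2 hour range where the inflation applies.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(promoter = "mprA",
                               times_h = c(15, 18, 21, 24, 27),
                               omega2 = logistic_weight_schedule(times_h),
                               n_events = DEFAULT_EVENTS_PER_TIMEPOINT,
                               seed = 1L,
                               l_noise_factor = 1,
                               l_noise_window = c(-Inf, Inf)) {
  comps <- reference_components(promoter)
  if (length(omega2) != length(times_h)) {
    stop("'omega2' must match 'times_h' in length", call. = FALSE)
  }
  if (any(omega2 < 0 | omega2 > 1)) {
    stop("'omega2' values must lie in [0, 1]", call. = FALSE)
  }
  if (n_events <= 0) stop("'n_events' must be positive", call. = FALSE)
  if (l_noise_factor <= 0) stop("'l_noise_factor' must be > 0", call. = FALSE)
  structure(list(gaussian = comps$gaussian, lognormal = comps$lognormal,
                 times_h = as.numeric(times_h), omega2 = as.numeric(omega2),
                 n_events = as.integer(n_events), seed = as.integer(seed),
                 l_noise_factor = l_noise_factor,
                 l_noise_window = l_noise_window),
            class = "synthetic_scenario")
}

#' Generate a synthetic flow-cytometry time course
#'
#' For each acquisition, each of the `n_events` events independently comes
#' from the H (lognormal) component with probability `omega2(t)` and from
#' the L (Gaussian) component otherwise, reproducing the
#' invariant-components / time-varying-weights structure of the bistable
#' induction data.  Output is bit-reproducible for a fixed scenario.
#'
#' @param scenario A [synthetic_scenario()].
#' @return Data frame with columns `time` (labels like `"18h"`) and
#'   `intensity`; the generating truth (components, schedule, per-time
#'   realized H counts) is attached as attribute `"truth"`.
#' @examples
#' d <- generate_flow_timecourse(synthetic_scenario(n_events = 200))
#' table(d$time)
#' @export
generate_flow_timecourse <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  out <- .with_seed(sc$seed, {
    per_time <- lapply(seq_along(sc$times_h), function(k) {
      n <- sc$n_events
      from_h <- stats::runif(n) < sc$omega2[k]
      x <- numeric(n)
      nh <- sum(from_h)
      if (nh > 0) {
        x[from_h] <- stats::rlnorm(nh, sc$lognormal$log_mean,
                                   sc$lognormal$log_sd)
      }
      if (nh < n) {
        w <- sc$gaussian$width
        th <- sc$times_h[k]
        if (th >= sc$l_noise_window[1] && th <= sc$l_noise_window[2]) {
          w <- w * sc$l_noise_factor
        }
        x[!from_h] <- stats::rnorm(n - nh, sc$gaussian$center, w / 2)
      }
      list(x = x, n_high = nh)
    })
    per_time
  })
  labels <- paste0(format(scenario$times_h, trim = TRUE), "h")
  df <- data.frame(
    time = rep(labels, each = scenario$n_events),
    intensity = unlist(lapply(out, `[[`, "x"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  attr(df, "truth") <- list(
    gaussian = scenario$gaussian,
    lognormal = scenario$lognormal,
    times_h = scenario$times_h,
    omega2 = scenario$omega2,
    n_events = scenario$n_events,
    n_high = vapply(out, `[[`, 0L, "n_high"),
    seed = scenario$seed
  )
  df
}

#' Generate a logistic growth curve
#'
#' Optical-density trajectory under nutrient depletion:
#' `od(t) = capacity / (1 + (capacity/od0 - 1) exp(-mu0 t))`, exponential
#' with rate `mu0` at early times and saturating at `capacity`.  Optional
#' multiplicative lognormal measurement noise.
#'
#' @param mu0 Early-phase specific growth rate (1/h), positive.
#' @param capacity Carrying-capacity OD600 (default 2).
#' @param od0 Inoculum OD600 (default 0.01).
#' @param times_h Sampling times (hours).
#' @param noise_sd Standard deviation of log-scale multiplicative noise
#'   (default 0 = noiseless).
#' @param seed Optional seed.
#' @return Data frame `time_h`, `od600`; the noiseless closed form is
#'   attached as attribute `"truth_mu"` (a function of `t`).
#' @export
generate_growth_curve <- function(mu0, capacity = 2, od0 = 0.01,
                                  times_h = seq(0, 40, by = 1),
                                  noise_sd = 0, seed = NULL) {
  stopifnot(mu0 > 0, capacity > od0, od0 > 0, noise_sd >= 0)
  a <- capacity / od0 - 1
  od <- capacity / (1 + a * exp(-mu0 * times_h))
  if (noise_sd > 0) {
    od <- od * exp(.with_seed(seed, stats::rnorm(length(od), 0, noise_sd)))
  }
  df <- data.frame(time_h = times_h, od600 = od)
  # per-capita rate of the noiseless logistic: mu0 * (1 - od/capacity)
  attr(df, "truth_mu") <- function(t) {
    odt <- capacity / (1 + a * exp(-mu0 * t))
    mu0 * (1 - odt / capacity)
  }
  df
}

#' Generate (protein level, growth rate) pairs from the retardation law
#'
#' Evaluates `mu = phi / (1 + theta x)` on a grid of protein levels with
#' optional additive Gaussian noise, e.g. to emulate the specific growth
#' rate versus reporter-intensity relationship.
#'
#' @param phi Unburdened growth rate (1/h), positive.
#' @param theta Burden coefficient, nonnegative.
#' @param x_grid Protein levels (nonnegative).
#' @param noise_sd Additive noise SD on `mu` (default 0).
#' @param seed Optional seed.
#' @return Data frame `x`, `mu`.
#' @examples
#' generate_mu_x_pairs(0.94, 0.317, x_grid = seq(0, 3, length.out = 5))
#' @export
generate_mu_x_pairs <- function(phi, theta, x_grid, noise_sd = 0,
                                seed = NULL) {
  stopifnot(phi > 0, theta >= 0, all(x_grid >= 0), noise_sd >= 0)
  mu <- phi / (1 + theta * x_grid)
  if (noise_sd > 0) {
    mu <- mu + .with_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  }
  data.frame(x = as.numeric(x_grid), mu = mu)
}
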