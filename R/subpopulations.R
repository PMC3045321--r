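#' Membership ratios of an event between the L and H components
#'
#' For an event with intensity `x`, the probability of belonging to the
#' low-expression (L, Gaussian) subpopulation is
#' \deqn{g_1(x) = \frac{P_1(x)}{P_1(x) + P_2(x)},\qquad g_2(x) = 1 - g_1(x),}
#' computed from the *unweighted* component densities by default.  Setting
#' `weighted = TRUE` instead uses the posterior under the per-time mixture
#' weights, `C1(t) P1 / (C1(t) P1 + C2(t) P2)`; this requires `t`.
#'
#' @param x Intensities (a.u.); vectorised.
#' @param model A [mixture_model()].
#' @param weighted Use weight-scaled posteriors (default `FALSE`).
#' @param t Time label, required when `weighted = TRUE`.
#' @return Data frame with columns `g1`, `g2` (each in \[0, 1\],
#'   `g1 + g2 = 1`).
#' @examples
#' m <- mixture_model(gaussian_component(97.3366, 103.0731),
#'                    lognormal_component(5.95526, 0.17618),
#'                    data.frame(time = "18h", C1 = 0.5, C2 = 0.5))
#' membership_ratios(150, m)
#' @export
membership_ratios <- function(x, model, weighted = FALSE, t = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  p1 <- gaussian_pdf(x, model$gaussian)
  p2 <- lognormal_pdf(x, model$lognormal)
  if (weighted) {
    if (is.null(t)) stop("'t' is required when weighted = TRUE", call. = FALSE)
    w <- .weights_at(model, t)
    p1 <- w[["C1"]] * p1
    p2 <- w[["C2"]] * p2
  }
  den <- p1 + p2
  if (any(den <= 0)) {
    bad <- which(den <= 0)[1]
    stop("membership undefined at x = ", x[bad],
         ": both component densities are zero", call. = FALSE)
  }
  data.frame(g1 = p1 / den, g2 = p2 / den)
}

#' Stochastic binning of events into L and H subpopulations
#'
#' Implements the random-assignment partition: for each event `j` a uniform
#' draw `r` is generated and the event is assigned to L when
#' `0 <= r < g1(x_j)`, to H otherwise.  Because the components overlap, the
#' same intensity can land in either subpopulation; repeated runs with the
#' same seed reproduce the labelling exactly.
#'
#' @param events Numeric vector of intensities (one acquisition).
#' @param model A [mixture_model()].
#' @param seed Optional integer seed (global RNG state restored afterwards).
#' @param weighted,t Passed to [membership_ratios()].
#' @return Factor of labels `"L"`/`"H"`, one per event, in input order,
#'   with the seed stored in attribute `"seed"`.
#' @export
stochastic_binning <- function(events, model, seed = NULL,
                               weighted = FALSE, t = NULL) {
  events <- as.numeric(events)
  if (length(events) == 0L) stop("'events' is empty", call. = FALSE)
  g <- membership_ratios(events, model, weighted = weighted, t = t)
  r <- .with_seed(seed, stats::runif(length(events)))
  lab <- factor(ifelse(r < g$g1, "L", "H"), levels = c("L", "H"))
  attr(lab, "seed") <- seed
  lab
}

#' Subpopulation statistics for one acquisition
#'
#' Given events and their L/H labels, computes per subpopulation `i` the
#' count \eqn{N_i}, fraction \eqn{\omega_i = N_i/N}, mean intensity
#' \eqn{\mu_i}, sample variance \eqn{\sigma_i^2} (with `N_i - 1`
#' denominator), and coefficient of variation
#' \eqn{CV_i = \sigma_i/\mu_i}.  Variance (and CV) are `NA` for a
#' subpopulation with fewer than 2 events.
#'
#' @param events Numeric intensities.
#' @param labels Factor/character of `"L"`/`"H"` labels, same length.
#' @return Data frame with one row per subpopulation: `subpopulation`,
#'   `N`, `omega`, `mean`, `var`, `cv`.
#' @examples
#' subpopulation_summary(c(1, 2, 3, 700), c("L", "L", "L", "H"))
#' @export
subpopulation_summary <- function(events, labels) {
  events <- as.numeric(events)
  labels <- factor(as.character(labels), levels = c("L", "H"))
  if (length(labels) != length(events) || anyNA(labels)) {
    stop("'labels' must assign every event to L or H", call. = FALSE)
  }
  n <- length(events)
  rows <- lapply(c("L", "H"), function(s) {
    xi <- events[labels == s]
    ni <- length(xi)
    mu <- if (ni > 0) mean(xi) else NA_real_
    v <- if (ni >= 2) sum((xi - mu)^2) / (ni - 1) else NA_real_
    data.frame(subpopulation = s, N = ni, omega = ni / n,
               mean = mu, var = v,
               cv = if (!is.na(v) && mu != 0) sqrt(v) / mu else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' L-to-H transition-rate time series
#'
#' Estimates the per-capita switching rate from the L to the H subpopulation
#' over each interval \eqn{[t_a, t_b]} as
#' \deqn{k_{LH} = \frac{\omega_2(t_b) - \omega_2(t_a)}{(t_b - t_a)\,\omega_1(t_a)},}
#' the one-way flux estimator consistent with a gradual L-to-H transition.
#' Rates are reported at interval midpoints; an interval with
#' \eqn{\omega_1(t_a) = 0} yields `NA`.
#'
#' @param report A data frame with columns `time_h` (numeric hours, strictly
#'   increasing) and `omega2` (H fraction); `omega1` optional (defaults to
#'   `1 - omega2`).
#' @return Data frame with `time_h` (midpoints) and `rate` (1/h).
#' @examples
#' transition_rate_series(data.frame(time_h = c(0, 2), omega2 = c(0.2, 0.4)))
#' @export
transition_rate_series <- function(report) {
  stopifnot(is.data.frame(report),
            all(c("time_h", "omega2") %in% names(report)))
  tt <- as.numeric(report$time_h)
  if (length(tt) < 2L) {
    stop("need at least 2 time points for transition rates", call. = FALSE)
  }
  if (any(diff(tt) <= 0)) {
    stop("'time_h' must be strictly increasing", call. = FALSE)
  }
  w2 <- as.numeric(report$omega2)
  w1 <- if ("omega1" %in% names(report)) as.numeric(report$omega1) else 1 - w2
  a <- seq_len(length(tt) - 1L)
  dt <- tt[a + 1L] - tt[a]
  rate <- ifelse(w1[a] > 0, (w2[a + 1L] - w2[a]) / (dt * w1[a]), NA_real_)
  data.frame(time_h = (tt[a] + tt[a + 1L]) / 2, rate = rate)
}

#' Full time-course subpopulation analysis
#'
#' Bins every acquisition of a time course into L and H subpopulations using
#' one seeded random stream, then assembles the per-time statistics table,
#' the L-to-H transition-rate series, and the L-subpopulation CV series —
#' the three standard views of a bistable induction time course.
#'
#' @param dataset A data frame with columns `time` and `intensity`, or a
#'   named list of intensity vectors.  Time labels may be of the form
#'   `"18h"`; numeric hours are parsed with [parse_hours()].
#' @param model A [mixture_model()].
#' @param seed Optional integer seed; per-time-point sub-seeds are derived
#'   deterministically from it.
#' @param weighted Use weighted posteriors in the binning (default `FALSE`).
#' @return A list of class `timecourse_report` with `stats` (one row per
#'   time point x subpopulation: `time`, `time_h`, `subpopulation`, `N`,
#'   `omega`, `mean`, `var`, `cv`), `rates` (transition-rate series, `NULL`
#'   for a single time point), and `cv_L` (`time_h`, `cv`).
#' @export
analyze_timecourse <- function(dataset, model, seed = NULL,
                               weighted = FALSE) {
  events_by_time <- .as_events_by_time(dataset)
  labs <- names(events_by_time)
  empty <- vapply(events_by_time, length, 0L) == 0L
  if (any(empty)) {
    stop("time point '", labs[which(empty)[1]], "' has no events",
         call. = FALSE)
  }
  th <- parse_hours(labs)
  stats_list <- vector("list", length(labs))
  for (k in seq_along(labs)) {
    sk <- if (is.null(seed)) NULL else as.integer(seed) + k - 1L
    lab <- stochastic_binning(events_by_time[[k]], model, seed = sk,
                              weighted = weighted, t = labs[k])
    s <- subpopulation_summary(events_by_time[[k]], lab)
    s <- cbind(time = labs[k], time_h = th[k], s)
    stats_list[[k]] <- s
  }
  stats <- do.call(rbind, stats_list)
  rownames(stats) <- NULL
  per_time <- data.frame(
    time_h = th,
    omega1 = stats$omega[stats$subpopulation == "L"],
    omega2 = stats$omega[stats$subpopulation == "H"]
  )
  per_time <- per_time[order(per_time$time_h), ]
  rates <- if (nrow(per_time) >= 2L) transition_rate_series(per_time) else NULL
  cv_L <- data.frame(time_h = stats$time_h[stats$subpopulation == "L"],
                     cv = stats$cv[stats$subpopulation == "L"])
  cv_L <- cv_L[order(cv_L$time_h), ]
  structure(list(stats = stats, rates = rates, cv_L = cv_L),
            class = "timecourse_report")
}

#' @export
print.timecourse_report <- function(x, ...) {
  cat("Subpopulation time-course report\n")
  print(x$stats, row.names = FALSE)
  if (!is.null(x$rates)) {
    cat("\nL -> H transition rates (1/h):\n")
    print(x$rates, row.names = FALSE)
  }
  invisible(x)
}

#' Parse hour labels such as "18h" into numeric hours
#'
#' Accepts plain numbers, or numbers suffixed by `h`/`hr`/`hrs`/`hours`
#' (with optional space).  Unparseable labels fall back to their rank
#' order, so purely categorical labels still yield a usable time axis.
#'
#' @param labels Character vector of time labels.
#' @return Numeric hours.
#' @examples
#' parse_hours(c("18h", "21 h", "24"))
#' @export
parse_hours <- function(labels) {
  labels <- as.character(labels)
  num <- suppressWarnings(
    as.numeric(sub("^\\s*([-+0-9.eE]+)\\s*(h|hr|hrs|hours)?\\s*$", "\\1",
                   labels))
  )
  if (anyNA(num)) num[is.na(num)] <- rank(labels)[is.na(num)]
  num
}
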