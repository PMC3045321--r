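#' Parameters of the MprAB-SigE-Rel pathway model
#'
#' Deterministic model of the stringent-response circuit: the `mprAB`
#' operon (encoding the response regulator MprA and sensor kinase MprB) is
#' transcribed at a basal rate plus a MprA-P-activated term; MprB
#' autophosphorylates (poly-P availability is lumped into the
#' autophosphorylation rate `k_auto`, the swept bifurcation parameter) and
#' transfers its phosphate to MprA; unphosphorylated MprB also acts as a
#' MprA-P phosphatase; MprA-P activates `sigE` transcription and SigE drives
#' `rel` and the GFP reporter.  Every species is lost at the effective rate
#' \deqn{\gamma_{eff}(x_{tot}) = \gamma + \frac{\phi}{1 + \theta x_{tot}},}
#' the sum of intrinsic degradation and growth dilution retarded by the
#' total stress-protein burden \eqn{x_{tot}}.  The retarded dilution closes
#' a second, noncooperative positive feedback loop which widens the
#' bistable region far beyond what transcriptional autoregulation alone
#' gives.
#'
#' @param basal_mprAB Basal transcription rate of the operon (conc/h).
#' @param act_mprAB Maximal activated transcription rate (conc/h).
#' @param K_mprAB Activation constant of MprA-P at the mprAB promoter
#'   (conc).
#' @param hill_n Hill coefficient of promoter activation (default 1,
#'   noncooperative).
#' @param k_auto MprB autophosphorylation rate (1/h); the bifurcation
#'   parameter.
#' @param k_transfer Phosphotransfer rate MprB-P + MprA -> MprB + MprA-P
#'   (1/(conc h)).
#' @param k_phosphatase MprB-mediated dephosphorylation rate of MprA-P
#'   (1/(conc h)).
#' @param act_sigE,K_sigE Maximal rate (conc/h) and activation constant
#'   (conc) of MprA-P-driven sigE expression.
#' @param act_rel,K_rel SigE-driven rel expression parameters.
#' @param act_gfp,K_gfp SigE-driven reporter expression parameters.
#' @param gamma Intrinsic protein decay rate (1/h).
#' @param phi,theta Growth-retardation dilution parameters: unburdened
#'   dilution `phi` (1/h) and burden coefficient `theta` (per conc);
#'   `theta = 0` makes the decay linear.
#' @param burden `"total"` (default): \eqn{x_{tot}} is the summed
#'   concentration of all seven species; `"per-species"`: each species'
#'   dilution is retarded by its own concentration only.
#' @return A list of class `pathway_params`.
#' @export
pathway_params <- function(basal_mprAB = 0.1,
                           act_mprAB = 1,
                           K_mprAB = 4,
                           hill_n = 1,
                           k_auto = 0.7,
                           k_transfer = 4,
                           k_phosphatase = 4,
                           act_sigE = 0.6, K_sigE = 0.5,
                           act_rel = 0.6, K_rel = 0.5,
                           act_gfp = 0.6, K_gfp = 0.5,
                           gamma = 0.05,
                           phi = 0.94, theta = 1,
                           burden = c("total", "per-species")) {
  p <- list(basal_mprAB = basal_mprAB, act_mprAB = act_mprAB,
            K_mprAB = K_mprAB, hill_n = hill_n, k_auto = k_auto,
            k_transfer = k_transfer, k_phosphatase = k_phosphatase,
            act_sigE = act_sigE, K_sigE = K_sigE,
            act_rel = act_rel, K_rel = K_rel,
            act_gfp = act_gfp, K_gfp = K_gfp,
            gamma = gamma, phi = phi, theta = theta,
            burden = match.arg(burden))
  num <- p[setdiff(names(p), "burden")]
  if (any(unlist(num) < 0)) {
    stop("all pathway rates and constants must be >= 0", call. = FALSE)
  }
  if (p$hill_n < 1) stop("'hill_n' must be >= 1", call. = FALSE)
  structure(p, class = "pathway_params")
}

#' Species names of the pathway state vector
#' @export
PATHWAY_SPECIES <- c("MprA", "MprB", "MprAP", "MprBP", "SigE", "Rel", "GFP")

#' Construct a pathway state vector
#'
#' @param MprA,MprB,MprAP,MprBP,SigE,Rel,GFP Nonnegative concentrations
#'   (arbitrary units).  `MprAP`/`MprBP` are the phosphorylated forms.
#' @return Named numeric vector in canonical species order.
#' @export
pathway_state <- function(MprA = 0, MprB = 0, MprAP = 0, MprBP = 0,
                          SigE = 0, Rel = 0, GFP = 0) {
  s <- c(MprA = MprA, MprB = MprB, MprAP = MprAP, MprBP = MprBP,
         SigE = SigE, Rel = Rel, GFP = GFP)
  if (any(s < 0)) stop("concentrations must be >= 0", call. = FALSE)
  s
}

#' Right-hand side of the pathway ODE system
#'
#' Mass-action phospho-reactions, Hill-form transcription (noncooperative
#' by default) and shared nonlinear dilution; see [pathway_params()] for
#' the reaction scheme.
#'
#' @param state Named nonnegative state vector (see [pathway_state()]).
#' @param params A [pathway_params()] object.
#' @return Named vector of time derivatives (conc/h).
#' @export
pathway_rhs <- function(state, params) {
  stopifnot(inherits(params, "pathway_params"))
  s <- state[PATHWAY_SPECIES]
  if (anyNA(s)) stop("state must name all species", call. = FALSE)
  if (any(s < -1e-9)) stop("negative concentrations in state", call. = FALSE)
  s <- pmax(s, 0)
  p <- params
  xt <- if (p$burden == "total") sum(s) else s
  geff <- p$gamma + p$phi / (1 + p$theta * xt)
  apn <- s[["MprAP"]]^p$hill_n
  transcription <- p$basal_mprAB +
    p$act_mprAB * apn / (p$K_mprAB^p$hill_n + apn)
  v_auto <- p$k_auto * s[["MprB"]]
  v_pt <- p$k_transfer * s[["MprBP"]] * s[["MprA"]]
  v_ph <- p$k_phosphatase * s[["MprB"]] * s[["MprAP"]]
  prod <- c(
    MprA = transcription + v_ph - v_pt,
    MprB = transcription + v_pt - v_auto,
    MprAP = v_pt - v_ph,
    MprBP = v_auto - v_pt,
    SigE = p$act_sigE * s[["MprAP"]] / (p$K_sigE + s[["MprAP"]]),
    Rel = p$act_rel * s[["SigE"]] / (p$K_rel + s[["SigE"]]),
    GFP = p$act_gfp * s[["SigE"]] / (p$K_gfp + s[["SigE"]])
  )
  # geff is scalar for burden = "total", per-species vector otherwise
  prod - geff * s
}

.rhs_desolve <- function(t, y, parms) {
  list(pathway_rhs(y, parms))
}

#' Integrate the pathway model
#'
#' Stiff-capable integration (lsoda) of the circuit from an initial state.
#'
#' @param params A [pathway_params()].
#' @param init Initial state ([pathway_state()] or named vector).
#' @param t_grid Increasing time grid (hours).
#' @param ... Passed to [deSolve::ode()].
#' @return Data frame: `time` plus one column per species; attribute
#'   `"params"` carries the parameter set.
#' @examples
#' p <- pathway_params(k_auto = 0.6)
#' tr <- simulate_pathway(p, pathway_state(), seq(0, 50, by = 1))
#' tail(tr$GFP, 1)
#' @export
simulate_pathway <- function(params, init = pathway_state(),
                             t_grid = seq(0, 200, by = 1), ...) {
  stopifnot(inherits(params, "pathway_params"))
  if (any(diff(t_grid) <= 0)) {
    stop("'t_grid' must be strictly increasing", call. = FALSE)
  }
  y0 <- pathway_state()
  y0[names(init)] <- init
  out <- deSolve::ode(y = y0, times = t_grid, func = .rhs_desolve,
                      parms = params, method = "lsoda",
                      rtol = 1e-9, atol = 1e-10, ...)
  if (attr(out, "istate")[1] < 0) {
    stop("integrator failed: istate = ", attr(out, "istate")[1],
         call. = FALSE)
  }
  df <- as.data.frame(out)
  df[PATHWAY_SPECIES] <- lapply(df[PATHWAY_SPECIES], function(v) pmax(v, 0))
  attr(df, "params") <- params
  df
}

# damped Newton polish of a candidate steady state
.polish_root <- function(y, params, max_iter = 60L, tol = 1e-11) {
  f <- function(v) pathway_rhs(stats::setNames(pmax(v, 0), PATHWAY_SPECIES),
                               params)
  y <- pmax(as.numeric(y), 0)
  for (i in seq_len(max_iter)) {
    fy <- f(y)
    if (max(abs(fy)) < tol) break
    J <- pracma::jacobian(f, y)
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      y_new <- y + lam * step
      if (all(y_new > -1e-8) &&
          all(is.finite(f(pmax(y_new, 0)))) &&
          max(abs(f(pmax(y_new, 0)))) < max(abs(fy)) * (1 - 1e-4 * lam) + tol) {
        break
      }
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    y <- pmax(y + lam * step, 0)
  }
  fy <- f(y)
  if (max(abs(fy)) < 1e-8) stats::setNames(y, PATHWAY_SPECIES) else NULL
}

.classify_stability <- function(y, params) {
  f <- function(v) pathway_rhs(stats::setNames(v, PATHWAY_SPECIES), params)
  J <- pracma::jacobian(f, as.numeric(y))
  ev <- eigen(J, only.values = TRUE)$values
  max(Re(ev)) < 0
}

#' Locate and classify steady states of the pathway model
#'
#' Runs the integrator from several initial states (near-zero, fully
#' induced, and randomized log-uniform states), polishes each endpoint to a
#' root of [pathway_rhs()] by damped Newton iteration, de-duplicates the
#' roots, and classifies each by the eigenvalues of the local Jacobian.
#'
#' @param params A [pathway_params()].
#' @param n_starts Number of randomized starts in addition to the two
#'   deterministic ones (default 8).
#' @param seed Optional seed for the randomized starts.
#' @param t_settle Integration horizon used to approach each attractor
#'   (hours, default 600).
#' @return A list of class `steady_states`: `states` (matrix, one row per
#'   steady state), `stable` (logical), `params`.  Zero rows if no root
#'   converged.
#' @export
find_steady_states <- function(params, n_starts = 8L, seed = NULL,
                               t_settle = 600) {
  stopifnot(inherits(params, "pathway_params"), n_starts >= 1L)
  hi <- (params$basal_mprAB + params$act_mprAB) / params$gamma
  starts <- list(pathway_state(),
                 pathway_state(MprA = hi, MprB = hi, MprAP = hi,
                               MprBP = hi, SigE = hi, Rel = hi, GFP = hi))
  rnd <- .with_seed(seed, matrix(stats::runif(7L * n_starts, 0, 1),
                                 ncol = 7L))
  for (i in seq_len(n_starts)) {
    starts[[length(starts) + 1L]] <-
      stats::setNames(hi * rnd[i, ]^2, PATHWAY_SPECIES)
  }
  roots <- list()
  # roots found by forward integration are candidate *stable* states; an
  # unstable intermediate (if any) is bracketed afterwards
  for (y0 in starts) {
    tr <- try(simulate_pathway(params, y0, c(0, t_settle / 2, t_settle)),
              silent = TRUE)
    if (inherits(tr, "try-error")) next
    yend <- unlist(tr[nrow(tr), PATHWAY_SPECIES])
    r <- .polish_root(yend, params)
    if (!is.null(r)) roots[[length(roots) + 1L]] <- r
  }
  roots <- .dedup_states(roots)
  # between two distinct stable states, seed Newton from midpoints to
  # capture the separating unstable state
  if (length(roots) >= 2L) {
    extra <- list()
    for (i in seq_len(length(roots) - 1L)) {
      for (j in (i + 1L):length(roots)) {
        for (w in c(0.3, 0.5, 0.7)) {
          r <- .polish_root(w * roots[[i]] + (1 - w) * roots[[j]], params)
          if (!is.null(r)) extra[[length(extra) + 1L]] <- r
        }
      }
    }
    roots <- .dedup_states(c(roots, extra))
  }
  if (length(roots) == 0L) {
    return(structure(list(states = matrix(numeric(0), ncol = 7L,
                                          dimnames = list(NULL, PATHWAY_SPECIES)),
                          stable = logical(0), params = params),
                     class = "steady_states"))
  }
  m <- do.call(rbind, roots)
  colnames(m) <- PATHWAY_SPECIES
  ord <- order(m[, "GFP"])
  m <- m[ord, , drop = FALSE]
  stable <- apply(m, 1L, .classify_stability, params = params)
  structure(list(states = m, stable = stable, params = params),
            class = "steady_states")
}

.dedup_states <- function(roots, tol = 1e-4) {
  out <- list()
  for (r in roots) {
    dup <- FALSE
    for (o in out) {
      if (max(abs(r - o)) <= tol * (1 + max(abs(o)))) { dup <- TRUE; break }
    }
    if (!dup) out[[length(out) + 1L]] <- r
  }
  out
}

#' @export
print.steady_states <- function(x, ...) {
  cat(sprintf("%d steady state(s) (%d stable)\n",
              nrow(x$states), sum(x$stable)))
  if (nrow(x$states)) {
    df <- as.data.frame(round(x$states, 5))
    df$stable <- x$stable
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Quasi-static hysteresis sweep over the autophosphorylation rate
#'
#' Continuation in `k_auto`: the sweep starts from the branch endpoint
#' appropriate to its direction (uninduced state for an up-sweep, fully
#' induced for a down-sweep) and at each subsequent value integrates from
#' the previous steady state before polishing, so the followed branch is
#' retained until it loses stability (a fold), where the trajectory jumps
#' to the remaining attractor — the numerical analogue of ramping the
#' inducer up or down and reading the stationary reporter level.
#'
#' @param params A [pathway_params()]; its `k_auto` is overridden.
#' @param k_values Sweep values of the autophosphorylation rate.  Must be
#'   sorted increasing for `direction = "up"`, decreasing for `"down"`
#'   (an increasing grid is reversed automatically for a down-sweep).
#' @param direction `"up"` or `"down"`.
#' @param t_settle Relaxation horizon per step (hours, default 400).
#' @return Data frame of class `branch`: `k_auto`, `direction`, one column
#'   per species, ordered by `k_auto`.
#' @export
hysteresis_scan <- function(params, k_values, direction = c("up", "down"),
                            t_settle = 400) {
  stopifnot(inherits(params, "pathway_params"))
  direction <- match.arg(direction)
  k_values <- as.numeric(k_values)
  if (direction == "up" && any(diff(k_values) < 0)) {
    stop("up-sweep needs increasing k_values", call. = FALSE)
  }
  if (direction == "down") {
    if (all(diff(k_values) >= 0)) k_values <- rev(k_values)
    if (any(diff(k_values) > 0)) {
      stop("down-sweep needs decreasing k_values", call. = FALSE)
    }
  }
  hi <- (params$basal_mprAB + params$act_mprAB) / params$gamma
  y <- if (direction == "up") {
    pathway_state()
  } else {
    pathway_state(MprA = hi, MprB = hi, MprAP = hi, MprBP = hi,
                  SigE = hi, Rel = hi, GFP = hi)
  }
  rows <- vector("list", length(k_values))
  for (i in seq_along(k_values)) {
    p <- params
    p$k_auto <- k_values[i]
    tr <- simulate_pathway(p, y, c(0, t_settle / 2, t_settle))
    y <- unlist(tr[nrow(tr), PATHWAY_SPECIES])
    r <- .polish_root(y, p)
    if (!is.null(r)) y <- r
    rows[[i]] <- c(k_auto = k_values[i], y)
  }
  df <- as.data.frame(do.call(rbind, rows))
  df$direction <- direction
  df <- df[order(df$k_auto), c("k_auto", "direction", PATHWAY_SPECIES)]
  rownames(df) <- NULL
  class(df) <- c("branch", "data.frame")
  df
}

#' Bistable window of the autophosphorylation rate
#'
#' Runs an up- and a down-sweep over `k_values` and reports the interval
#' where the two branches of the tracked species differ beyond tolerance —
#' the coexistence (hysteresis) region.  Outside the window the branches
#' coincide.
#'
#' @param params A [pathway_params()].
#' @param k_values Increasing sweep grid spanning both monostable regimes.
#' @param species Tracked species (default `"GFP"`).
#' @param rel_tol Relative branch-separation threshold (default 0.05).
#' @param t_settle Passed to [hysteresis_scan()].
#' @return A list of class `bistable_window`: `k_lo`, `k_hi` (NA when the
#'   window is empty), `width` (0 when empty), `empty`, `up`, `down`
#'   (the two branches), `separated` (logical per grid point).
#' @export
bistable_window <- function(params, k_values, species = "GFP",
                            rel_tol = 0.05, t_settle = 400) {
  up <- hysteresis_scan(params, sort(k_values), "up", t_settle = t_settle)
  down <- hysteresis_scan(params, sort(k_values), "down", t_settle = t_settle)
  vu <- up[[species]]
  vd <- down[[species]]
  scale <- pmax(abs(vu), abs(vd), 1e-6)
  sep <- abs(vd - vu) > rel_tol * scale
  if (any(sep)) {
    k_lo <- min(up$k_auto[sep])
    k_hi <- max(up$k_auto[sep])
  } else {
    k_lo <- NA_real_
    k_hi <- NA_real_
  }
  structure(list(k_lo = k_lo, k_hi = k_hi,
                 width = if (any(sep)) k_hi - k_lo else 0,
                 empty = !any(sep),
                 up = up, down = down, separated = sep,
                 species = species),
            class = "bistable_window")
}

#' @export
print.bistable_window <- function(x, ...) {
  if (x$empty) {
    cat("No bistable window on the tested grid (branches coincide)\n")
  } else {
    cat(sprintf("Bistable window in k_auto: [%.4g, %.4g] (width %.4g), tracked species %s\n",
                x$k_lo, x$k_hi, x$width, x$species))
  }
  invisible(x)
}
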