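# shared fixtures and small independent oracles

mprA_gaussian <- function() gaussian_component(97.3366, 103.0731)
mprA_lognormal <- function() lognormal_component(5.95526, 0.17618)
sigE_lognormal <- function() lognormal_component(6.1171, 0.2509)

mprA_mixture <- function(times = "18h", C2 = 0.5) {
  mixture_model(mprA_gaussian(), mprA_lognormal(),
                data.frame(time = times, C1 = 1 - C2, C2 = C2))
}

# reference circuit parameters (package defaults) with theta overridable
ref_params <- function(...) pathway_params(...)

# quadrature oracle independent of the closed forms under test
integrate_density <- function(f, lower, upper, ...) {
  stats::integrate(f, lower, upper, rel.tol = 1e-10,
                   subdivisions = 500L, ...)$value
}

# induction-shape summary used by the pathway tests: amplitude, lag to 10%
# of the rise, and inflection count of GFP(t) over the dominant rise
# (5%-95% of the total amplitude, so sub-percent transients near the
# uninduced level are not counted as extra inflections)
induction_shape <- function(params, t_max = 300, by = 0.25) {
  tr <- simulate_pathway(params, pathway_state(), seq(0, t_max, by = by))
  g <- tr$GFP
  tt <- tr$time
  rise <- g - g[1]
  total <- rise[length(rise)]
  lag10 <- tt[min(which(rise >= 0.10 * total))]
  win <- which(rise >= 0.05 * total & rise <= 0.95 * total)
  d2 <- diff(diff(g[win]))
  keep <- abs(d2) > 0.02 * max(abs(d2))
  sgn <- sign(d2[keep])
  inflections <- sum(diff(sgn) != 0)
  list(amplitude = total, lag10 = lag10, inflections = inflections,
       t = tt, gfp = g)
}

# minimal FCS 3.0 writer (list mode, 32-bit float, little-endian) used to
# build binary fixtures in tempdir at test time
write_minimal_fcs <- function(path, channels) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  n_tot <- length(channels[[1]])
  n_par <- length(channels)
  kw <- c("$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
          "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot))
  for (i in seq_len(n_par)) {
    kw[paste0("$P", i, "B")] <- "32"
    kw[paste0("$P", i, "N")] <- names(channels)[i]
    kw[paste0("$P", i, "R")] <- "262144"
  }
  text <- paste0("/", paste(rbind(names(kw), unname(kw)), collapse = "/"),
                 "/")
  text_start <- 58L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n_par * n_tot - 1L
  pad8 <- function(x) formatC(x, width = 8L, flag = " ")
  header <- paste0("FCS3.0    ", pad8(text_start), pad8(text_end),
                   pad8(data_start), pad8(data_end), pad8(0), pad8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  m <- do.call(cbind, channels)
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}
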