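#' Ionic solution pair for permeability analysis
#'
#' Extracellular/intracellular Na+ and Cl- concentrations (mM) and the
#' recording temperature. Impermeant constituents (sucrose, HEPES) are not
#' modelled; only Na+ and Cl- enter the Goldman-Hodgkin-Katz relation.
#'
#' @param na_out,na_in,cl_out,cl_in Concentrations in mM (> 0).
#' @param temperature Temperature in K (default 298.15 K, i.e. RT/F =
#'   25.693 mV).
#' @return Object of class `solution_pair`.
#' @examples
#' # the asymmetric selectivity solutions: 150 mM vs 30 mM NaCl
#' sol <- solution_pair(150, 30, 150, 30)
#' @export
solution_pair <- function(na_out, na_in, cl_out = na_out, cl_in = na_in,
                          temperature = 298.15) {
  v <- c(na_out, na_in, cl_out, cl_in, temperature)
  if (any(!is.finite(v)) || any(v <= 0))
    stop_usage("concentrations and temperature must be positive")
  structure(list(na_out = na_out, na_in = na_in,
                 cl_out = cl_out, cl_in = cl_in,
                 temperature = temperature),
            class = "solution_pair")
}

#' GHK reversal potential from a permeability ratio
#'
#' Bi-ionic Goldman-Hodgkin-Katz relation with P_Na = 1 and
#' P_Cl = `ratio_cl_na`:
#' `Erev = (RT/F) ln[(P_Na [Na]o + P_Cl [Cl]i) / (P_Na [Na]i + P_Cl [Cl]o)]`.
#'
#' @param sol A [solution_pair].
#' @param ratio_cl_na P_Cl / P_Na (> 0).
#' @return Reversal potential in mV.
#' @examples
#' ghk_erev(solution_pair(150, 30), 9.8)  # about -31.3 mV
#' @export
ghk_erev <- function(sol, ratio_cl_na) {
  stopifnot(inherits(sol, "solution_pair"))
  if (!is.finite(ratio_cl_na) || ratio_cl_na <= 0)
    stop_usage("permeability ratio must be positive")
  rtf_mV(sol$temperature) *
    log((sol$na_out + ratio_cl_na * sol$cl_in) /
        (sol$na_in  + ratio_cl_na * sol$cl_out))
}

#' Permeability ratio from a measured reversal potential
#'
#' Inverts the GHK relation:
#' `ratio = ([Na]o - e^x [Na]i) / (e^x [Cl]o - [Cl]i)` with
#' `x = Erev F / (RT)`. `erev` must lie strictly between the Na+ Nernst
#' potential (ratio -> 0) and the Cl- Nernst potential (ratio -> Inf);
#' symmetric solutions leave the ratio unidentifiable and raise an error.
#'
#' @param sol A [solution_pair].
#' @param erev Reversal potential, mV.
#' @return P_Cl / P_Na, dimensionless. Round-trips [ghk_erev()] to 1e-9
#'   relative.
#' @export
ghk_ratio_from_erev <- function(sol, erev) {
  stopifnot(inherits(sol, "solution_pair"))
  if (!is.finite(erev)) stop_usage("erev must be finite")
  rtf <- rtf_mV(sol$temperature)
  e_na <- rtf * log(sol$na_out / sol$na_in)
  e_cl <- rtf * log(sol$cl_in / sol$cl_out)
  lo <- min(e_na, e_cl); hi <- max(e_na, e_cl)
  if (hi - lo < 1e-12)
    stop("degenerate solutions: reversal potential does not identify the ",
         "permeability ratio", call. = FALSE)
  if (erev <= lo || erev >= hi)
    stop(sprintf(paste0("erev = %.3f mV is outside the feasible open ",
                        "interval (%.3f, %.3f) mV"), erev, lo, hi),
         call. = FALSE)
  ex <- exp(erev / rtf)
  (sol$na_out - ex * sol$na_in) / (ex * sol$cl_out - sol$cl_in)
}

#' Reversal potential by linear interpolation of I-V data
#'
#' Finds the first adjacent voltage pair (sorted by voltage) whose currents
#' bracket zero and interpolates linearly. A point with exactly zero
#' current is returned directly.
#'
#' @param iv_points data.frame with columns `v` (mV) and `i` (pA), or a
#'   two-column matrix.
#' @return Interpolated Erev in mV.
#' @export
interpolate_erev <- function(iv_points) {
  iv <- as.data.frame(iv_points)
  names(iv)[1:2] <- c("v", "i")
  iv <- iv[order(iv$v), ]
  z <- which(iv$i == 0)
  if (length(z)) return(iv$v[z[1]])
  sgn <- sign(iv$i)
  k <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(k))
    stop("current-voltage points do not bracket zero current", call. = FALSE)
  k <- k[1]
  v1 <- iv$v[k]; v2 <- iv$v[k + 1]; i1 <- iv$i[k]; i2 <- iv$i[k + 1]
  v1 - i1 * (v2 - v1) / (i2 - i1)
}

#' Patch-clamp sweep trace
#'
#' Uniformly sampled current trace with its stimulus series.
#'
#' @param time Time, s (uniform).
#' @param current Current, pA.
#' @param pressure Optional pressure stimulus, mmHg.
#' @param voltage Optional holding potential series, mV (scalar recycled).
#' @param sampling_rate Hz; default inferred from `time`.
#' @return data.frame of class `sweep_trace`.
#' @export
sweep_trace <- function(time, current, pressure = NA_real_,
                        voltage = NA_real_, sampling_rate = NULL) {
  if (length(time) != length(current))
    stop_usage("time and current must have equal length")
  if (length(time) > 2 &&
      max(abs(diff(diff(time)))) > 1e-9 * max(abs(diff(time))))
    stop_usage("time must be uniformly sampled")
  x <- data.frame(time_s = time, current_pA = current,
                  pressure_mmHg = rep_len(pressure, length(time)),
                  voltage_mV = rep_len(voltage, length(time)))
  attr(x, "sampling_rate") <- sampling_rate %||%
    (if (length(time) > 1) 1 / diff(time)[1] else NA_real_)
  class(x) <- c("sweep_trace", "data.frame")
  x
}

#' Off-line leak subtraction
#'
#' Subtracts the leak current estimated in a pre-stimulus baseline window
#' from the whole sweep: either the window mean (`mode = "constant"`) or a
#' least-squares line fitted in the window and extrapolated over the sweep
#' (`mode = "linear"`, for drifting baselines). Idempotent.
#'
#' @param sweep A [sweep_trace].
#' @param baseline_window `c(t0, t1)` in s, before stimulus onset.
#' @param mode `"constant"` or `"linear"`.
#' @return The leak-subtracted [sweep_trace].
#' @export
leak_subtract <- function(sweep, baseline_window,
                          mode = c("constant", "linear")) {
  mode <- match.arg(mode)
  w <- sweep$time_s >= baseline_window[1] & sweep$time_s <= baseline_window[2]
  if (!any(w)) stop_usage("baseline window contains no samples")
  if (mode == "constant") {
    sweep$current_pA <- sweep$current_pA - mean(sweep$current_pA[w])
  } else {
    fit <- lm(current_pA ~ time_s, data = sweep[w, , drop = FALSE])
    sweep$current_pA <- sweep$current_pA -
      predict(fit, newdata = data.frame(time_s = sweep$time_s))
  }
  sweep
}

#' Gaussian amplitude-histogram fit of a single-channel trace
#'
#' Bins the current trace (bins aligned so multiples of `bin_width` are bin
#' centers) and fits a sum of `n_components` Gaussians to the counts by
#' nonlinear least squares, initialized at the highest histogram peaks. The
#' single-channel amplitude is the difference between the means of the two
#' heaviest adjacent components (closed and open levels). Traces with fewer
#' resolvable peaks than components (or an ill-conditioned least-squares
#' problem, e.g. a noiseless two-spike histogram) fall back to assigning
#' bins to the nearest peak and using count-weighted moments; such fits are
#' flagged `degenerate`.
#'
#' @param sweep A [sweep_trace] or numeric current vector, pA.
#' @param n_components Number of Gaussian components (>= 2).
#' @param bin_width Histogram bin width, pA.
#' @param rng_seed Seed for jittered initialization of surplus components.
#' @return Object of class `amplitude_fit`: `means`, `sds`, `weights`
#'   (normalized), `single_channel_amplitude` (pA), `degenerate` flag.
#' @export
fit_amplitude_histogram <- function(sweep, n_components = 2,
                                    bin_width = 0.2, rng_seed = 1) {
  cur <- if (inherits(sweep, "sweep_trace")) sweep$current_pA
         else as.numeric(sweep)
  if (n_components < 2) stop_usage("n_components must be at least 2")
  # bin centers at multiples of bin_width
  k0 <- floor(min(cur) / bin_width) - 1
  k1 <- ceiling(max(cur) / bin_width) + 1
  breaks <- (seq(k0, k1 + 1) - 0.5) * bin_width
  h <- hist(cur, breaks = breaks, plot = FALSE)
  mids <- h$mids; counts <- h$counts
  # local maxima of the (lightly smoothed) histogram, heaviest first
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  sm <- as.numeric(sm)
  is_peak <- sm >= c(-Inf, head(sm, -1)) & sm >= c(tail(sm, -1), -Inf) &
    counts > 0
  # collapse plateaus and require separation of at least 2 bins
  peaks <- which(is_peak)
  if (length(peaks) > 1) {
    keep <- order(sm[peaks], decreasing = TRUE)
    chosen <- integer(0)
    for (p in peaks[keep])
      if (!any(abs(p - chosen) <= 2)) chosen <- c(chosen, p)
    peaks <- sort(chosen)
  }
  degenerate <- length(peaks) < n_components
  if (degenerate)
    warning("fewer histogram peaks than components; fit flagged degenerate")
  init_mu <- mids[peaks[order(sm[peaks], decreasing = TRUE)]]
  init_mu <- head(init_mu, n_components)
  if (length(init_mu) < n_components) {
    extra <- with_seed(rng_seed,
      init_mu[1] + rnorm(n_components - length(init_mu), sd = 2 * bin_width))
    init_mu <- c(init_mu, extra)
  }
  init_sd <- rep(max(bin_width, sd(cur) / (2 * n_components)), n_components)
  init_a <- vapply(init_mu, function(m) {
    max(counts[which.min(abs(mids - m))], 1)
  }, numeric(1))

  model <- function(p) {
    mu <- p[1:n_components]
    sg <- abs(p[(n_components + 1):(2 * n_components)])
    aa <- abs(p[(2 * n_components + 1):(3 * n_components)])
    rowSums(vapply(seq_len(n_components), function(k)
      aa[k] * exp(-0.5 * ((mids - mu[k]) / sg[k])^2),
      numeric(length(mids))))
  }
  fit_ok <- FALSE
  # discrete-level (noiseless) traces: the histogram is a few isolated
  # spikes; weighted moments are exact and a Gaussian LS fit is
  # ill-conditioned
  discrete <- sum(counts > 0) <= 2 * n_components
  p0 <- c(init_mu, init_sd, init_a)
  fit <- if (discrete) NULL else tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = p0,
                         fn = function(p) counts - model(p),
                         control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$info %in% 1:4 && !degenerate) {
    p <- fit$par
    mu <- p[1:n_components]
    sg <- abs(p[(n_components + 1):(2 * n_components)])
    aa <- abs(p[(2 * n_components + 1):(3 * n_components)])
    fit_ok <- all(is.finite(c(mu, sg, aa))) && all(sg > 1e-6) &&
      all(sg < diff(range(mids)) + bin_width)
  }
  if (fit_ok) {
    wts <- aa * sg            # component mass proportional to area
  } else {
    # moment fallback on nearest-peak assignment
    mu_ref <- init_mu
    assign_k <- apply(outer(mids, mu_ref, function(a, b) abs(a - b)),
                      1, which.min)
    mu <- sg <- wts <- numeric(n_components)
    for (k in seq_len(n_components)) {
      w <- counts * (assign_k == k)
      if (sum(w) == 0) { mu[k] <- mu_ref[k]; sg[k] <- bin_width; next }
      mu[k] <- sum(w * mids) / sum(w)
      v <- sum(w * (mids - mu[k])^2) / sum(w)
      sg[k] <- max(sqrt(v), bin_width / sqrt(12))
      wts[k] <- sum(w)
    }
    degenerate <- degenerate || !discrete
  }
  o <- order(mu)
  mu <- mu[o]; sg <- sg[o]; wts <- wts[o]
  wts <- wts / sum(wts)
  # heaviest adjacent pair = closed/open levels
  pair_mass <- wts[-length(wts)] + wts[-1]
  k <- which.max(pair_mass)
  amp <- abs(mu[k + 1] - mu[k])
  structure(list(means = mu, sds = sg, weights = wts,
                 single_channel_amplitude = amp,
                 degenerate = isTRUE(degenerate)),
            class = "amplitude_fit")
}

#' @export
print.amplitude_fit <- function(x, ...) {
  cat(sprintf("<amplitude_fit> %d components%s\n", length(x$means),
              if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  means: %s pA; weights: %s\n",
              paste(sprintf("%.2f", x$means), collapse = ", "),
              paste(sprintf("%.2f", x$weights), collapse = ", ")))
  cat(sprintf("  single-channel amplitude: %.3f pA\n",
              x$single_channel_amplitude))
  invisible(x)
}

#' Slope conductance from a single-channel I-V relation
#'
#' Ordinary least squares of single-channel current (pA) on holding
#' potential (mV); the slope in pA/mV is reported in pS (x 1000) and the
#' zero-current intercept as the reversal potential.
#'
#' @param iv_points data.frame with columns `v` (mV) and `i` (pA); at least
#'   3 distinct voltages.
#' @return Object of class `iv_fit`: `slope_pS`, `erev_intercept_mV`,
#'   `r_squared`, and the underlying `lm` fit.
#' @examples
#' v <- seq(-80, 80, 20)
#' slope_conductance(data.frame(v = v, i = 0.27 * v))  # 270 pS
#' @export
slope_conductance <- function(iv_points) {
  iv <- as.data.frame(iv_points)
  names(iv)[1:2] <- c("v", "i")
  if (length(unique(iv$v)) < 3)
    stop_usage("need at least 3 distinct voltages")
  fit <- lm(i ~ v, data = iv)
  b <- coef(fit)
  tss <- sum((iv$i - mean(iv$i))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 1
  structure(list(slope_pS = unname(b[2]) * 1000,
                 erev_intercept_mV = unname(-b[1] / b[2]),
                 r_squared = r2, fit = fit),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf("<iv_fit> slope %.1f pS, Erev %.2f mV, R^2 = %.4f\n",
              x$slope_pS, x$erev_intercept_mV, x$r_squared))
  invisible(x)
}

#' Deactivation time constant after stimulus end
#'
#' Fits `I(t) = A exp(-(t - stim_end)/tau) + baseline` to the post-stimulus
#' current by nonlinear least squares. The initial tau comes from the 1/e
#' crossing of the decay; non-decaying segments raise a convergence error.
#' Set `components = 2` for a bi-exponential fit (the reported `tau_s` is
#' then the amplitude-weighted mean of the two time constants, and both are
#' returned in `taus`).
#'
#' @param sweep A [sweep_trace].
#' @param stim_end Stimulus end time, s.
#' @param fit_window Length of the fit window after `stim_end`, s.
#' @param components 1 (default) or 2 exponentials.
#' @return Object of class `decay_fit`: `tau_s`, `amplitude_pA`,
#'   `baseline_pA`, `window_s`, and the `nls` fit.
#' @export
deactivation_tau <- function(sweep, stim_end, fit_window, components = 1) {
  w <- sweep$time_s >= stim_end & sweep$time_s <= stim_end + fit_window
  if (sum(w) < 5) stop_usage("fit window contains too few samples")
  t <- sweep$time_s[w] - stim_end
  y <- sweep$current_pA[w]
  n <- length(y)
  base0 <- mean(tail(y, max(3, n %/% 10)))
  A0 <- mean(head(y, max(3, n %/% 50))) - base0
  if (!is.finite(A0) || abs(A0) < 10 * .Machine$double.eps)
    stop("segment does not decay: no amplitude above baseline",
         call. = FALSE)
  cross <- which(abs(y - base0) <= abs(A0) / exp(1))
  tau0 <- if (length(cross)) max(t[cross[1]], t[2]) else max(t) / 3
  df <- data.frame(t = t, y = y)
  if (components == 1) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-t / tau) + b, data = df,
                        start = list(A = A0, tau = tau0, b = base0),
                        lower = c(-Inf, 1e-9, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("deactivation fit did not converge: ",
                               conditionMessage(e), call. = FALSE))
    p <- coef(fit)
    if (p[["tau"]] <= 0 || p[["tau"]] > 100 * max(t))
      stop("deactivation fit did not converge to a positive finite tau",
           call. = FALSE)
    resid_sd <- sd(residuals(fit))
    if (resid_sd > 0 && abs(p[["A"]]) < 2 * resid_sd)
      stop("segment does not decay: fitted amplitude is below the noise",
           call. = FALSE)
    taus <- p[["tau"]]; amps <- p[["A"]]; base <- p[["b"]]
    tau_rep <- taus
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2) + b,
                        data = df,
                        start = list(A1 = A0 * 0.6, tau1 = tau0 / 2,
                                     A2 = A0 * 0.4, tau2 = tau0 * 2,
                                     b = base0),
                        lower = c(-Inf, 1e-9, -Inf, 1e-9, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) stop("deactivation fit did not converge: ",
                               conditionMessage(e), call. = FALSE))
    p <- coef(fit)
    taus <- c(p[["tau1"]], p[["tau2"]]); amps <- c(p[["A1"]], p[["A2"]])
    base <- p[["b"]]
    tau_rep <- sum(abs(amps) * taus) / sum(abs(amps))
  }
  structure(list(tau_s = tau_rep, taus = taus, amplitude_pA = sum(amps),
                 baseline_pA = base, window_s = c(stim_end,
                                                  stim_end + fit_window),
                 fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> tau = %.4g s, amplitude %.3g pA, baseline %.3g pA\n",
              x$tau_s, x$amplitude_pA, x$baseline_pA))
  invisible(x)
}

#' Fold change of two quantities
#'
#' `a / b`, the convention used to compare mutant and wild-type channel
#' conductances or deactivation time constants.
#'
#' @param a,b Numeric; `b` must be non-zero.
#' @return `a / b`.
#' @examples
#' fold_change(270, 54)    # 5
#' fold_change(270, 22.6)  # 11.95
#' @export
fold_change <- function(a, b) {
  if (any(b == 0)) stop_usage("denominator must be non-zero")
  a / b
}
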