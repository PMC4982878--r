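# Differential scanning calorimetry: melting-peak integration, molar
# enthalpies, complexed fraction, complexation ratio alpha and yield.
#
# The two-run protocol: the first heating run melts the guest and lets
# complexation proceed; in the second run only guest molecules NOT locked
# in a host cavity melt, so the deficit of the second-run molar melting
# heat relative to the pure-guest fusion enthalpy measures the complexed
# fraction.

#' A DSC thermogram
#'
#' @param temperature strictly increasing temperatures (degrees C).
#' @param heat_flow heat flow (W per gram of sample); endotherm-up by
#'   default, set `endotherm_up = FALSE` for exotherm-up instruments.
#' @param heating_rate heating rate (degrees C per minute).
#' @param sample_mass optional sample mass (mg), metadata only.
#' @param endotherm_up sign convention of `heat_flow`.
#' @return object of class `thermogram`.
#' @export
thermogram <- function(temperature, heat_flow, heating_rate = 5,
                       sample_mass = NA_real_, endotherm_up = TRUE) {
  stopifnot(length(temperature) == length(heat_flow))
  if (length(temperature) < 20L) stop("thermogram needs at least 20 points")
  if (!all(is.finite(temperature)) || !all(is.finite(heat_flow))) {
    stop("thermogram values must be finite")
  }
  if (any(diff(temperature) <= 0)) {
    stop("temperatures must be strictly increasing")
  }
  if (!(heating_rate > 0)) stop("heating rate must be positive")
  if (!endotherm_up) heat_flow <- -heat_flow
  structure(list(temperature = as.numeric(temperature),
                 heat_flow = as.numeric(heat_flow),
                 heating_rate = heating_rate, sample_mass = sample_mass),
            class = "thermogram")
}

#' Read a thermogram CSV
#'
#' Columns `T_C, heat_flow_W_per_g`.
#'
#' @param path CSV path.
#' @param ... passed to [thermogram()] (heating_rate, sign convention...).
#' @return a [thermogram()].
#' @export
read_thermogram_csv <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("T_C", "heat_flow_W_per_g") %in% names(df))) {
    stop("thermogram CSV must have columns T_C, heat_flow_W_per_g")
  }
  thermogram(df$T_C, df$heat_flow_W_per_g, ...)
}

#' Write a thermogram CSV
#' @param tg a [thermogram()].
#' @param path output path.
#' @export
write_thermogram_csv <- function(tg, path) {
  utils::write.csv(data.frame(T_C = tg$temperature,
                              heat_flow_W_per_g = tg$heat_flow),
                   path, row.names = FALSE)
  invisible(path)
}

#' Guest / host mixture specification
#'
#' @param w_guest,w_host mass fractions (must sum to 1).
#' @param M_guest,M_host molar masses (g/mol).
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(w_guest = 0.5, w_host = 1 - w_guest,
                         M_guest, M_host = 1135) {
  if (abs(w_guest + w_host - 1) > 1e-9) {
    stop("mass fractions must sum to 1")
  }
  if (!(M_guest > 0) || !(M_host > 0)) stop("molar masses must be positive")
  structure(list(w_guest = w_guest, w_host = w_host,
                 M_guest = M_guest, M_host = M_host),
            class = "mixture_spec")
}

# guest:host molar ratio of the mixture — the ceiling for alpha
molar_ratio <- function(mix) {
  (mix$w_guest / mix$M_guest) / (mix$w_host / mix$M_host)
}

#' Integrate a melting endotherm
#'
#' Net area above the baseline inside the window, trapezoidal, converted
#' from (W/g)*degC to J/g via the heating rate:
#' enthalpy = 60 * integral((q - baseline) dT) / heating_rate.
#'
#' @param tg a [thermogram()].
#' @param window numeric `c(T_lo, T_hi)` (degrees C) inside the data range.
#' @param baseline "linear" interpolates the signal between the window
#'   endpoints; "flat" subtracts the smaller endpoint value.
#' @param baseline_margin width (degrees C) of the flat pre-/post-peak
#'   segments just inside the window edges over which the baseline anchor
#'   levels are averaged. 0 anchors on the two raw endpoint values; a
#'   positive margin makes the baseline robust to point noise and is the
#'   standard practice when the window comfortably brackets the peak.
#' @return list: `enthalpy` (J per g of sample), `T_onset` (baseline /
#'   steepest-ascent-tangent intersection, degrees C), `T_peak` (degrees C).
#' @export
integrate_peak <- function(tg, window, baseline = c("linear", "flat"),
                           baseline_margin = 0) {
  baseline <- match.arg(baseline)
  stopifnot(length(window) == 2L, window[1] < window[2])
  Tr <- range(tg$temperature)
  if (window[1] < Tr[1] - 1e-9 || window[2] > Tr[2] + 1e-9) {
    stop("window [", window[1], ", ", window[2],
         "] outside thermogram range [", Tr[1], ", ", Tr[2], "]")
  }
  # resample window boundary points so the window edges are grid points
  Tv <- tg$temperature
  q <- tg$heat_flow
  keep <- Tv > window[1] & Tv < window[2]
  Tw <- c(window[1], Tv[keep], window[2])
  qw <- c(stats::approx(Tv, q, xout = window[1])$y, q[keep],
          stats::approx(Tv, q, xout = window[2])$y)
  if (baseline_margin > 0) {
    if (2 * baseline_margin >= diff(window)) {
      stop("baseline_margin must be less than half the window width")
    }
    lo_seg <- Tw <= window[1] + baseline_margin
    hi_seg <- Tw >= window[2] - baseline_margin
    x1 <- mean(Tw[lo_seg]); y1 <- mean(qw[lo_seg])
    x2 <- mean(Tw[hi_seg]); y2 <- mean(qw[hi_seg])
  } else {
    x1 <- Tw[1]; y1 <- qw[1]
    x2 <- Tw[length(Tw)]; y2 <- qw[length(qw)]
  }
  base <- switch(baseline,
    linear = y1 + (y2 - y1) * (Tw - x1) / (x2 - x1),
    flat = rep(min(y1, y2), length(Tw))
  )
  net <- qw - base
  area <- pracma::trapz(Tw, net)                # (W/g) * degC
  enthalpy <- 60 * area / tg$heating_rate       # J/g
  if (area < 0) {
    warning("net peak area is negative; returning signed enthalpy")
  }
  ipk <- which.max(net)
  T_peak <- Tw[ipk]
  # onset: tangent at the steepest ascent of the leading edge, intersected
  # with the (local) baseline level
  T_onset <- NA_real_
  if (ipk > 2L) {
    slopes <- diff(net[1:ipk]) / diff(Tw[1:ipk])
    j <- which.max(slopes)
    slope <- slopes[j]
    Tj <- (Tw[j] + Tw[j + 1]) / 2
    yj <- (net[j] + net[j + 1]) / 2
    if (is.finite(slope) && slope > 0) T_onset <- Tj - yj / slope
  }
  list(enthalpy = enthalpy, T_onset = T_onset, T_peak = T_peak)
}

#' Specific to molar enthalpy
#'
#' @param dh_specific enthalpy in J per g.
#' @param M molar mass (g/mol).
#' @return enthalpy in kcal per mol (1 kcal = 4184 J).
#' @export
molar_enthalpy <- function(dh_specific, M) {
  if (!(M > 0)) stop("molar mass must be positive")
  dh_specific * M / 4184
}

#' Complexed fraction from the two-run melting heats
#'
#' Guests locked in a cavity do not melt in the second run, so
#' f = (dH_pure - q_mix) / dH_pure, where both heats are per mole of total
#' guest. Clipped to [0, 1]; clipping by more than 1% raises a warning.
#'
#' @param q_mix second-run melting heat (kcal per mol of total guest).
#' @param dH_pure pure-guest fusion enthalpy (kcal/mol).
#' @return fraction in [0, 1].
#' @export
complexed_fraction <- function(q_mix, dH_pure) {
  if (!(dH_pure > 0)) stop("dH_pure must be positive")
  f <- (dH_pure - q_mix) / dH_pure
  if (f < -0.01 || f > 1.01) {
    warning(sprintf("complexed fraction %.3f clipped to [0, 1]", f))
  }
  min(1, max(0, f))
}

#' Complexation ratio alpha from the complexed fraction
#'
#' alpha = f * (guest moles / host moles in the mixture); for the 50% w/w
#' samples this is f * M_host / M_guest. alpha is the number of guest
#' moles complexed per mole of host.
#'
#' @param f complexed fraction in [0, 1].
#' @param mix a [mixture_spec()].
#' @return alpha (guests per host).
#' @export
complexation_ratio <- function(f, mix) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  alpha <- f * molar_ratio(mix)
  stopifnot(alpha <= molar_ratio(mix) + 1e-12)
  alpha
}

#' Reaction yield from alpha and an assumed stoichiometry
#'
#' For N:1 complexes the yield is 100 * alpha / N percent of the host
#' converted to the full complex.
#'
#' @param alpha complexation ratio (guests per host), >= 0.
#' @param N assumed guests per complex (integer >= 1).
#' @return list: `percent` (exact), `percent_1dp` (one decimal),
#'   `percent_int` (nearest integer, half away from zero).
#' @export
yield_from_alpha <- function(alpha, N) {
  if (alpha < 0) stop("alpha must be non-negative")
  if (N < 1 || N != round(N)) stop("N must be a positive integer")
  pct <- 100 * alpha / N
  if (pct > 100) {
    warning("alpha/N exceeds 1: assumed stoichiometry underestimates capacity")
  }
  list(percent = pct,
       percent_1dp = round(pct, 1),
       percent_int = floor(pct + 0.5))
}

#' Full DSC complexation analysis for a pure / mixture thermogram pair
#'
#' Integrates both melting peaks, converts to molar heats per mole of
#' (total) guest, and derives the complexed fraction, alpha and yield.
#' When the mixture melting peak has shifted by more than `t_shift_warn`
#' degrees the result is flagged: a large shift (salicylic-acid-like, host
#' dissolving in the guest melt) biases the proportionality.
#'
#' @param pure pure-guest [thermogram()] (per gram of guest).
#' @param mix second-run mixture [thermogram()] (per gram of sample).
#' @param window_pure,window_mix integration windows `c(T_lo, T_hi)`.
#' @param mixspec a [mixture_spec()].
#' @param N assumed guests per complex for the yield (default 2).
#' @param t_shift_warn peak-shift flag threshold (degrees C, default 5).
#' @param baseline_margin baseline anchor averaging width passed to
#'   [integrate_peak()] (degrees C; default 3, suitable for windows that
#'   bracket the peak by several widths).
#' @return object of class `complexation_result`: dH_pure and q_mix
#'   (kcal per mol guest), f_complexed, alpha, yield percentages, onset and
#'   peak temperatures, `peak_shift_flag`.
#' @export
dsc_complexation <- function(pure, mix, window_pure, window_mix = window_pure,
                             mixspec, N = 2, t_shift_warn = 5,
                             baseline_margin = 3) {
  pk_pure <- integrate_peak(pure, window_pure,
                            baseline_margin = baseline_margin)
  pk_mix <- integrate_peak(mix, window_mix,
                           baseline_margin = baseline_margin)
  dH_pure <- molar_enthalpy(pk_pure$enthalpy, mixspec$M_guest)
  # mixture heat is per g sample; scale to per g (then per mol) of guest
  q_mix <- molar_enthalpy(pk_mix$enthalpy / mixspec$w_guest, mixspec$M_guest)
  f <- complexed_fraction(q_mix, dH_pure)
  alpha <- complexation_ratio(f, mixspec)
  yld <- yield_from_alpha(alpha, N)
  shift <- abs(pk_mix$T_peak - pk_pure$T_peak)
  structure(list(dH_pure = dH_pure, q_mix = q_mix, f_complexed = f,
                 alpha = alpha, N = N, yield_percent = yld$percent,
                 yield_percent_int = yld$percent_int,
                 T_onset_pure = pk_pure$T_onset, T_peak_pure = pk_pure$T_peak,
                 T_onset_mix = pk_mix$T_onset, T_peak_mix = pk_mix$T_peak,
                 peak_shift = shift,
                 peak_shift_flag = shift > t_shift_warn),
            class = "complexation_result")
}

#' @export
print.complexation_result <- function(x, ...) {
  cat(sprintf(
    paste0("<complexation_result> dH_pure = %.3f kcal/mol, q_mix = %.3f ",
           "kcal/mol\n  f_complexed = %.3f, alpha = %.3f guests/host, ",
           "yield(%d:1) = %.1f%%%s\n"),
    x$dH_pure, x$q_mix, x$f_complexed, x$alpha, x$N, x$yield_percent,
    if (x$peak_shift_flag)
      sprintf("  [peak shifted %.1f C - proportionality suspect]",
              x$peak_shift) else ""))
  invisible(x)
}
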