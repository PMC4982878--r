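# IR band attenuation as a complexation-yield proxy, and interaction-energy
# bookkeeping for N:1 host-guest complexes.

#' An IR spectrum
#'
#' @param wavenumber increasing wavenumbers (cm^-1).
#' @param absorbance absorbance (a.u.).
#' @return object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavenumber, absorbance) {
  stopifnot(length(wavenumber) == length(absorbance))
  if (length(wavenumber) < 2L) stop("spectrum needs at least 2 points")
  if (!all(is.finite(wavenumber)) || !all(is.finite(absorbance))) {
    stop("spectrum values must be finite")
  }
  if (any(diff(wavenumber) <= 0)) stop("wavenumbers must be increasing")
  structure(list(wavenumber = as.numeric(wavenumber),
                 absorbance = as.numeric(absorbance)),
            class = "spectrum")
}

#' Read a spectrum CSV (columns `wavenumber_cm1, absorbance`)
#' @param path CSV path.
#' @return a [spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavenumber_cm1", "absorbance") %in% names(df))) {
    stop("spectrum CSV must have columns wavenumber_cm1, absorbance")
  }
  ir_spectrum(df$wavenumber_cm1, df$absorbance)
}

.band_area <- function(sp, band) {
  lo <- band[1]; hi <- band[2]
  wn <- sp$wavenumber; ab <- sp$absorbance
  if (lo < wn[1] - 1e-9 || hi > wn[length(wn)] + 1e-9) {
    stop("band [", lo, ", ", hi, "] cm^-1 outside spectrum coverage [",
         wn[1], ", ", wn[length(wn)], "]")
  }
  keep <- wn > lo & wn < hi
  x <- c(lo, wn[keep], hi)
  y <- c(stats::approx(wn, ab, xout = lo)$y, ab[keep],
         stats::approx(wn, ab, xout = hi)$y)
  pracma::trapz(x, y)
}

#' IR band attenuation ratio
#'
#' Fraction by which the integrated band absorbance of the mixture falls
#' below the pure compound: 1 - area_mix / area_pure over the band. The
#' default 2500-3200 cm^-1 window covers aromatic C-H stretching
#' vibrations, which complexation attenuates; an attenuation near 1
#' (total band disappearance) indicates near-complete inclusion. Both
#' spectra must be on the same guest-mass basis (caller's contract).
#'
#' @param pure,mix [spectrum()] objects covering the band.
#' @param band numeric `c(lo, hi)` in cm^-1.
#' @return attenuation ratio in [0, 1]; values outside are clipped with a
#'   warning.
#' @export
band_attenuation <- function(pure, mix, band = c(2500, 3200)) {
  a_pure <- .band_area(pure, band)
  if (abs(a_pure) < 1e-12) {
    stop("pure spectrum has zero band area: attenuation undefined")
  }
  r <- 1 - .band_area(mix, band) / a_pure
  if (r < -1e-9 || r > 1 + 1e-9) {
    warning(sprintf("attenuation %.4f clipped to [0, 1]", r))
  }
  min(1, max(0, r))
}

#' Host-guest interaction energy
#'
#' dE_int = E_complex - E_host - E_guest_aggregate, all on a common
#' reference (kcal/mol). For an N:1 complex the guest aggregate energy is
#' the energy of the N guest molecules taken together.
#'
#' @param E_complex,E_host,E_guest_aggregate energies (kcal/mol).
#' @return dE_int (kcal/mol); negative means the complex is bound.
#' @export
interaction_energy <- function(E_complex, E_host, E_guest_aggregate) {
  E_complex - E_host - E_guest_aggregate
}

#' Read a component-energy CSV and tabulate interaction energies
#'
#' Columns `guest, N, E_complex, E_host, E_guest_aggregate` (kcal/mol).
#'
#' @param path CSV path.
#' @return data frame with an added `dE_int` column.
#' @export
read_energy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("guest", "N", "E_complex", "E_host", "E_guest_aggregate")
  if (!all(need %in% names(df))) {
    stop("energy CSV must have columns ", paste(need, collapse = ","))
  }
  if (!all(df$N %in% c(1, 2, 4))) stop("N must be one of 1, 2, 4")
  df$dE_int <- interaction_energy(df$E_complex, df$E_host,
                                  df$E_guest_aggregate)
  df
}

#' Per-guest incremental stabilization along an N series
#'
#' For interaction energies dE(N) of N:1 complexes sorted by N starting at
#' N = 1, the per-step gain is dE(N_i) - dE(N_{i-1}); the first entry's
#' gain is dE(1) itself. A shrinking |gain| with N means each additional
#' included guest stabilizes less (cavity crowding).
#'
#' @param N integer vector, sorted increasing, starting at 1, no
#'   duplicates.
#' @param dE_int interaction energies (kcal/mol) matching `N`.
#' @return data frame: N, dE_int, gain.
#' @export
incremental_stabilization <- function(N, dE_int) {
  stopifnot(length(N) == length(dE_int), length(N) >= 1L)
  if (anyDuplicated(N)) stop("duplicate N in stabilization series")
  if (is.unsorted(N)) stop("series must be sorted by N")
  if (N[1] != 1) stop("series must start at N = 1")
  data.frame(N = N, dE_int = dE_int, gain = c(dE_int[1], diff(dE_int)))
}
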