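#' Analytic tungsten-anode tube spectrum
#'
#' Kramers-law bremsstrahlung shape with fixed inherent filtration
#' (water-equivalent, in g/cm^2), tabulated on a 1 keV grid and clipped below
#' 20 keV (the lowest detector threshold) and above the tube voltage. The
#' relative photon fluence weights are normalized to sum to 1. Characteristic
#' lines are omitted; any smooth bremsstrahlung-shaped spectrum preserves the
#' K-edge effects under study.
#'
#' @param tube_kvp Tube voltage in kVp (default 140).
#' @param filtration_g_cm2 Inherent filtration as a water-equivalent areal
#'   density (default 2.5 g/cm^2).
#' @param e_min Lower clip energy in keV (default 20, the lowest threshold).
#' @return Object of class `spectrum_model`: list with `tube_kvp`, `energies`
#'   (keV) and `fluence_weights` (sum 1; zero above `tube_kvp`).
#' @export
tube_spectrum <- function(tube_kvp = 140, filtration_g_cm2 = 2.5,
                          e_min = 20) {
  stopifnot(tube_kvp > e_min)
  energies <- seq(10, 150, by = 1)
  water <- load_attenuation("water")
  w <- pmax(tube_kvp / energies - 1, 0)
  w <- w * exp(-mass_attenuation_at(water, energies) * filtration_g_cm2)
  w[energies < e_min | energies > tube_kvp] <- 0
  w <- w / sum(w)
  structure(list(tube_kvp = tube_kvp, energies = energies,
                 fluence_weights = w),
            class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("<spectrum_model: %g kVp, mean energy %.1f keV>\n",
              x$tube_kvp, sum(x$energies * x$fluence_weights)))
  invisible(x)
}

#' Energy-bin configuration of a photon-counting detector
#'
#' Four ascending thresholds define four half-open bins
#' `[t1,t2), [t2,t3), [t3,t4), [t4, tube_kvp]`. The clinical configuration
#' under study uses thresholds 20/55/72/90 keV at 140 kVp.
#'
#' @param thresholds Ascending threshold energies in keV.
#' @param upper_limit Upper bin edge (tube voltage), keV.
#' @return Object of class `energy_bins` with `thresholds`, `upper_limit`,
#'   and `n_bins`.
#' @export
energy_bins <- function(thresholds = c(20, 55, 72, 90), upper_limit = 140) {
  stopifnot(length(thresholds) >= 2, all(diff(thresholds) > 0),
            thresholds[1] < upper_limit,
            max(thresholds) < upper_limit)
  structure(list(thresholds = thresholds, upper_limit = upper_limit,
                 n_bins = length(thresholds)),
            class = "energy_bins")
}

#' Bin index of each energy (0 = below the lowest threshold / above kVp)
#' @noRd
bin_index <- function(bins, energies) {
  edges <- c(bins$thresholds, bins$upper_limit)
  idx <- findInterval(energies, edges, rightmost.closed = TRUE)
  idx[energies > bins$upper_limit] <- 0L
  idx
}

#' Expected photon counts per energy bin
#'
#' Polychromatic Beer-Lambert forward model for an ideal counting detector:
#' `N_b = n0 * sum_{E in bin b} w(E) * exp(-sum_m (mu/rho)_m(E) * L_m)`,
#' where `L_m` are per-material path integrals in g/cm^2. Every photon is
#' assigned to exactly one bin.
#'
#' @param path_integrals Either a named numeric vector (one ray) or a matrix
#'   with one row per material and one column per ray; names/rownames among
#'   `"water"`, `"iodine"`, `"gadolinium"`, units g/cm^2.
#' @param spectrum A [tube_spectrum()].
#' @param bins An [energy_bins()].
#' @param n0 Incident photons per ray.
#' @param tables Pre-loaded attenuation tables (see [attenuation_tables()]).
#' @return A matrix `n_bins x n_rays` of expected counts (a plain vector of
#'   length `n_bins` if the input was a single ray).
#' @export
expected_bin_counts <- function(path_integrals, spectrum, bins, n0,
                                tables = attenuation_tables()) {
  stopifnot(n0 > 0)
  single <- is.null(dim(path_integrals))
  L <- if (single) matrix(path_integrals, ncol = 1,
                          dimnames = list(names(path_integrals))) else path_integrals
  if (is.null(rownames(L)) || !all(rownames(L) %in% KEDGE_MATERIALS))
    stop("path_integrals must be named by material")
  if (any(L < 0)) stop("path integrals must be non-negative")
  keep <- spectrum$fluence_weights > 0
  E <- spectrum$energies[keep]
  w <- spectrum$fluence_weights[keep]
  A <- vapply(rownames(L),
              function(m) mass_attenuation_at(tables[[m]], E),
              numeric(length(E)))                     # nE x n_mat
  Tm <- exp(-A %*% L)                                 # nE x n_rays
  b <- bin_index(bins, E)
  W <- matrix(0, bins$n_bins, length(E))
  for (k in seq_len(bins$n_bins)) W[k, b == k] <- w[b == k]
  counts <- n0 * (W %*% Tm)
  if (single) drop(counts) else counts
}
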