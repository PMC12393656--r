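#' @useDynLib kedgesim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @importFrom stats approx sd quantile median setNames
#' @importFrom utils head tail
NULL

KEDGE_MATERIALS <- c("water", "iodine", "gadolinium")

#' Load a packaged mass-attenuation table
#'
#' Reads the 1 keV-step mass-attenuation table (10--150 keV, cm^2/g) shipped
#' with the package for one of the three basis materials. The iodine and
#' gadolinium tables carry a duplicated grid point at the K-edge (33.2 and
#' 50.2 keV respectively) holding the below-edge and above-edge values, so the
#' attenuation discontinuity is representable on the grid. Water has no K-edge
#' in this range.
#'
#' @param material One of `"water"`, `"iodine"`, `"gadolinium"`.
#' @return An object of class `attenuation_table`: a list with `material`,
#'   `energies` (keV, ascending, duplicated at the K-edge), `mu_rho`
#'   (cm^2/g) and `kedge_energy` (keV, `NA` for water).
#' @examples
#' load_attenuation("gadolinium")$kedge_energy
#' @export
load_attenuation <- function(material) {
  material <- match.arg(material, KEDGE_MATERIALS)
  path <- system.file("extdata", paste0("attenuation_", material, ".csv"),
                      package = "kedgesim", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#",
                         col.names = c("energy", "mu_rho"))
  hdr <- readLines(path, n = 1L)
  ek_str <- sub(".*kedge_keV=", "", hdr)
  ek <- if (identical(ek_str, "NA")) NA_real_ else as.numeric(ek_str)
  out <- structure(
    list(material = material, energies = tab$energy, mu_rho = tab$mu_rho,
         kedge_energy = ek),
    class = "attenuation_table"
  )
  validate_attenuation_table(out)
  out
}

validate_attenuation_table <- function(x) {
  stopifnot(all(diff(x$energies) >= 0), all(x$mu_rho > 0))
  dup <- which(diff(x$energies) == 0)
  if (is.na(x$kedge_energy)) {
    if (length(dup) != 0L)
      stop("water table must not contain a K-edge discontinuity")
  } else {
    if (length(dup) != 1L || x$energies[dup] != x$kedge_energy)
      stop("expected exactly one duplicated grid point at the K-edge")
    if (x$mu_rho[dup + 1L] <= x$mu_rho[dup])
      stop("K-edge discontinuity must be an upward jump")
  }
  invisible(x)
}

#' @export
print.attenuation_table <- function(x, ...) {
  cat(sprintf("<attenuation_table: %s, %d..%d keV, K-edge %s>\n",
              x$material, min(x$energies), max(x$energies),
              ifelse(is.na(x$kedge_energy), "none",
                     paste0(x$kedge_energy, " keV"))))
  invisible(x)
}

#' Mass attenuation at arbitrary energies
#'
#' Piecewise-linear interpolation of a mass-attenuation table, except that no
#' interpolation is performed across a K-edge: energies strictly below the
#' edge use the below-edge branch and energies at or above it use the
#' above-edge branch (right-continuous at the edge).
#'
#' @param table An [`attenuation_table`][load_attenuation].
#' @param energy Numeric vector of energies in keV, inside the table range.
#' @return Mass attenuation in cm^2/g, same length as `energy`.
#' @export
mass_attenuation_at <- function(table, energy) {
  stopifnot(inherits(table, "attenuation_table"))
  rng <- range(table$energies)
  if (any(energy < rng[1] | energy > rng[2]))
    stop(sprintf("energy outside table range [%g, %g] keV", rng[1], rng[2]))
  ek <- table$kedge_energy
  if (is.na(ek)) {
    return(approx(table$energies, table$mu_rho, xout = energy,
                  ties = "ordered")$y)
  }
  dup <- which(diff(table$energies) == 0)
  lo <- seq_len(dup)              # below-edge branch (includes edge-below row)
  hi <- seq(dup + 1L, length(table$energies))
  out <- numeric(length(energy))
  below <- energy < ek
  if (any(below))
    out[below] <- approx(table$energies[lo], table$mu_rho[lo],
                         xout = energy[below])$y
  if (any(!below))
    out[!below] <- approx(table$energies[hi], table$mu_rho[hi],
                          xout = energy[!below])$y
  out
}

#' Linear attenuation of a water/iodine/gadolinium mixture
#'
#' Additive basis-material model: `mu(E) = sum_m (mu/rho)_m(E) * rho_m`, with
#' water given as a mass density in g/mL and contrast agents as mg/mL
#' (converted internally to g/cm^3).
#'
#' @param concentrations Named numeric vector or list; names among
#'   `"water"` (g/mL), `"iodine"`, `"gadolinium"` (mg/mL). Missing materials
#'   count as zero.
#' @param energy Energies in keV (vectorized).
#' @param tables Optional pre-loaded list of attenuation tables keyed by
#'   material (avoids repeated fixture reads in tight loops).
#' @return Linear attenuation in 1/cm, one value per energy.
#' @export
mixture_attenuation <- function(concentrations, energy,
                                tables = attenuation_tables()) {
  concentrations <- unlist(concentrations)
  bad <- setdiff(names(concentrations), KEDGE_MATERIALS)
  if (length(bad))
    stop("unknown material(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(KEDGE_MATERIALS, collapse = ", "))
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  out <- numeric(length(energy))
  for (m in names(concentrations)) {
    dens <- concentrations[[m]] * if (m == "water") 1 else 1e-3  # -> g/cm^3
    out <- out + mass_attenuation_at(tables[[m]], energy) * dens
  }
  out
}

#' All three attenuation tables at once
#' @return Named list of [`attenuation_table`][load_attenuation] objects.
#' @export
attenuation_tables <- function() {
  setNames(lapply(KEDGE_MATERIALS, load_attenuation), KEDGE_MATERIALS)
}

#' Locate the K-edge in an attenuation table
#'
#' Scans a table for its discontinuity: the duplicated grid point whose
#' above-edge value exceeds the below-edge value. Returns its energy, or `NA`
#' when the table is continuous (water).
#'
#' @param table An [`attenuation_table`][load_attenuation].
#' @return K-edge energy in keV, or `NA`.
#' @export
detect_kedge <- function(table) {
  stopifnot(inherits(table, "attenuation_table"))
  dup <- which(diff(table$energies) == 0 & diff(table$mu_rho) > 0)
  if (!length(dup)) return(NA_real_)
  table$energies[dup[which.max(table$mu_rho[dup + 1L] / table$mu_rho[dup])]]
}
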