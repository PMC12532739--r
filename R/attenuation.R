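# Mass-attenuation physics: packaged NIST tables, log-log interpolation,
# theoretical Hounsfield units and theoretical DEI.

#' Construct a mass-attenuation table
#'
#' A table of total mass attenuation coefficients (mu/rho, cm^2/g) versus
#' photon energy (keV). Energies must be strictly increasing; K-edge
#' discontinuities are represented by paired nodes 1 eV apart.
#'
#' @param energies Numeric vector of photon energies in keV, strictly
#'   increasing, length >= 2.
#' @param mu_over_rho Numeric vector of mass attenuation coefficients in
#'   cm^2/g, positive and finite, same length as `energies`.
#' @return An object of class `attenuation_table`.
#' @export
attenuation_table <- function(energies, mu_over_rho) {
  if (length(energies) < 2L || length(energies) != length(mu_over_rho)) {
    stop("attenuation table needs >= 2 (energy, mu/rho) pairs of equal length",
         call. = FALSE)
  }
  if (!all(is.finite(energies)) || !all(is.finite(mu_over_rho))) {
    stop("attenuation table values must be finite", call. = FALSE)
  }
  if (any(diff(energies) <= 0)) {
    stop("energies must be strictly increasing", call. = FALSE)
  }
  if (any(mu_over_rho <= 0)) {
    stop("mu/rho values must be positive", call. = FALSE)
  }
  structure(list(energies = as.numeric(energies),
                 mu_over_rho = as.numeric(mu_over_rho)),
            class = "attenuation_table")
}

#' Construct a material specification
#'
#' Bundles a material's identity, density and attenuation table. Pellet
#' materials are the five commercial shot metals (Fe, Cu, W, Pb, Bi);
#' ballistic gelatine is modelled by the water entry at 1.0 g/cm^3.
#'
#' @param name Material name (e.g. "iron").
#' @param symbol Chemical symbol or "water".
#' @param atomic_number Integer Z, or `NA` for compounds.
#' @param density Mass density in g/cm^3, positive.
#' @param table An [attenuation_table()].
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, symbol, atomic_number, density, table) {
  stopifnot_scalar_number(density, "density")
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  if (!inherits(table, "attenuation_table")) {
    stop("'table' must be an attenuation_table", call. = FALSE)
  }
  structure(list(name = as.character(name), symbol = as.character(symbol),
                 atomic_number = if (is.na(atomic_number)) NA_integer_
                                 else as.integer(atomic_number),
                 density = density, table = table),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s (%s), Z = %s, density = %.2f g/cm^3, %d nodes over %.1f-%.1f keV\n",
              x$name, x$symbol,
              ifelse(is.na(x$atomic_number), "-", x$atomic_number),
              x$density, length(x$table$energies),
              min(x$table$energies), max(x$table$energies)))
  invisible(x)
}

.materials_cache <- new.env(parent = emptyenv())

#' Load the packaged pellet materials
#'
#' Reads the shipped NIST mass-attenuation tables (30-150 keV) for the five
#' pellet metals plus the water/gelatine reference and returns them as named
#' [material_spec()] objects. Results are cached per path.
#'
#' @param path Directory containing `manifest.tsv` and per-material tables;
#'   defaults to the fixtures shipped with the package.
#' @return Named list of `material_spec` objects
#'   (`Fe`, `Cu`, `W`, `Pb`, `Bi`, `water`).
#' @examples
#' mats <- dect_materials()
#' mass_attenuation(mats$water, 100)
#' @export
dect_materials <- function(path = system.file("extdata", "attenuation",
                                              package = "dectpellet")) {
  key <- normalizePath(path, mustWork = TRUE)
  if (!is.null(.materials_cache[[key]])) return(.materials_cache[[key]])
  manifest <- utils::read.delim(file.path(path, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  mats <- lapply(seq_len(nrow(manifest)), function(i) {
    tab <- utils::read.delim(file.path(path, manifest$file[i]))
    material_spec(name = manifest$name[i], symbol = manifest$symbol[i],
                  atomic_number = manifest$atomic_number[i],
                  density = manifest$density_g_cm3[i],
                  table = attenuation_table(tab$energy_kev,
                                            tab$mu_over_rho_cm2_g))
  })
  names(mats) <- manifest$symbol
  .materials_cache[[key]] <- mats
  mats
}

#' Interpolate a mass attenuation coefficient
#'
#' Log-log linear interpolation of mu/rho between bracketing table nodes
#' (attenuation is near power-law in energy between absorption edges, so
#' interpolation is performed in (log E, log mu/rho) space). Values at table
#' nodes are returned exactly.
#'
#' @param material A [material_spec()].
#' @param energy Photon energy (keV); vectorized. Must lie within the
#'   tabulated range.
#' @return Mass attenuation coefficient(s) in cm^2/g.
#' @export
mass_attenuation <- function(material, energy) {
  if (!inherits(material, "material_spec")) {
    stop("'material' must be a material_spec", call. = FALSE)
  }
  if (!is.numeric(energy) || !all(is.finite(energy))) {
    stop("'energy' must be finite numeric", call. = FALSE)
  }
  tab <- material$table
  rng <- range(tab$energies)
  if (any(energy < rng[1] | energy > rng[2])) {
    stop(sprintf("energy outside tabulated range [%g, %g] keV for %s",
                 rng[1], rng[2], material$symbol), call. = FALSE)
  }
  exp(stats::approx(log(tab$energies), log(tab$mu_over_rho),
                    xout = log(energy), ties = "ordered")$y)
}

#' Theoretical Hounsfield value of a material at a monoenergetic energy
#'
#' Standard HU definition: 1000 * (mu_material / mu_water - 1), with linear
#' attenuation mu = (mu/rho) * density evaluated at the same energy. Dense
#' metals far exceed the conventional 3071 HU ceiling; values are on the
#' extended scale.
#'
#' @inheritParams mass_attenuation
#' @param reference Water/gelatine reference `material_spec`; defaults to the
#'   packaged water entry.
#' @return Theoretical HU (extended scale); vectorized over `energy`.
#' @export
hu_theoretical <- function(material, energy,
                           reference = dect_materials()[["water"]]) {
  mu_m <- mass_attenuation(material, energy) * material$density
  mu_w <- mass_attenuation(reference, energy) * reference$density
  1000 * (mu_m / mu_w - 1)
}

#' Theoretical dual-energy index from attenuation physics
#'
#' With r_i = mu_material(E_i) / mu_water(E_i), the theoretical DEI of a
#' monoenergetic low/high pair is (r_low - r_high) / (r_low + r_high),
#' algebraically identical to the DEI formula applied to the two theoretical
#' HU values (HU + 1000 = 1000 * r). It is zero for water at any energy pair
#' and grows with the energy dependence of the attenuation ratio.
#'
#' @inheritParams hu_theoretical
#' @param e_low,e_high Low and high photon energies in keV, `e_low < e_high`,
#'   both within the tabulated range.
#' @return Dimensionless theoretical DEI.
#' @export
theoretical_dei <- function(material, e_low, e_high,
                            reference = dect_materials()[["water"]]) {
  if (!all(e_low < e_high)) stop("e_low must be < e_high", call. = FALSE)
  r_low <- mass_attenuation(material, e_low) * material$density /
    (mass_attenuation(reference, e_low) * reference$density)
  r_high <- mass_attenuation(material, e_high) * material$density /
    (mass_attenuation(reference, e_high) * reference$density)
  stopifnot(all(r_low + r_high > 0))
  (r_low - r_high) / (r_low + r_high)
}
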