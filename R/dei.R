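# dei_core: the dual-energy volume container and the DEI formula.

#' Construct a dual-energy volume pair
#'
#' Holds co-registered low-kVp and high-kVp voxel grids in extended
#' Hounsfield units, with voxel spacing and acquisition metadata. The two
#' grids must be voxel-for-voxel aligned (dual-source acquisition or
#' generator output); no resampling or registration is performed.
#'
#' @param low_kv,high_kv 3D numeric arrays of extended-scale HU values with
#'   identical dimensions; values may exceed 3071 and fall below -1024 but
#'   must be finite.
#' @param spacing Voxel spacing `(x, y, z)` in mm, all > 0.
#' @param kvp_pair Integer tube-voltage pair `(low, high)`, e.g. `c(100, 140)`;
#'   `NA` allowed when unknown.
#' @param meta Free-form list of acquisition annotations.
#' @return An object of class `dual_energy_volume`.
#' @export
dual_energy_volume <- function(low_kv, high_kv, spacing,
                               kvp_pair = c(NA_integer_, NA_integer_),
                               meta = list()) {
  check_3d_numeric(low_kv, "low_kv")
  check_3d_numeric(high_kv, "high_kv")
  if (!identical(dim(low_kv), dim(high_kv))) {
    stop("low_kv and high_kv must have identical dimensions", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive numbers (mm)", call. = FALSE)
  }
  structure(list(low_kv = low_kv, high_kv = high_kv, spacing = spacing,
                 kvp_pair = as.integer(kvp_pair), meta = meta),
            class = "dual_energy_volume")
}

#' @export
print.dual_energy_volume <- function(x, ...) {
  cat(sprintf("<dual_energy_volume> %s voxels, spacing %.3f x %.3f x %.3f mm, kVp %s/%s\n",
              paste(dim(x$low_kv), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3],
              ifelse(is.na(x$kvp_pair[1]), "?", x$kvp_pair[1]),
              ifelse(is.na(x$kvp_pair[2]), "?", x$kvp_pair[2])))
  invisible(x)
}

#' Dual-energy index of a low/high HU pair
#'
#' The scalar DEI formula, `(i_low - i_high) / (i_low + i_high + 2000)`,
#' vectorized. Zero for water (both inputs 0), positive when the low-energy
#' acquisition attenuates more strongly. No denominator guard is applied
#' here; see [compute_dei_volume()] for the guarded voxelwise version.
#'
#' @param i_low,i_high HU values at the low and high tube voltage.
#' @return Dimensionless DEI value(s).
#' @export
dei_index <- function(i_low, i_high) {
  (i_low - i_high) / (i_low + i_high + 2000)
}

#' Compute a DEI volume from a dual-energy pair
#'
#' Applies the DEI formula voxelwise. Voxels whose denominator
#' `|I_low + I_high + 2000|` falls below `guard_epsilon` are marked invalid
#' in the returned mask and set to 0 in the DEI grid, so downstream
#' statistics never see non-finite values (the degenerate case cannot occur
#' for metal or gelatine voxels but is guarded for arbitrary input).
#'
#' @param vol A [dual_energy_volume()].
#' @param guard_epsilon Denominator guard in HU, >= 0; default 1.
#' @return An object of class `dei_volume`: list with `dei` (3D double
#'   array), `valid_mask` (3D logical) and `spacing` (mm).
#' @examples
#' v <- dual_energy_volume(array(3000, c(2, 2, 1)), array(2000, c(2, 2, 1)),
#'                         spacing = c(0.504, 0.504, 1))
#' compute_dei_volume(v)$dei[1, 1, 1]  # 1000 / 7000
#' @export
compute_dei_volume <- function(vol, guard_epsilon = 1) {
  if (!inherits(vol, "dual_energy_volume")) {
    stop("'vol' must be a dual_energy_volume", call. = FALSE)
  }
  stopifnot_scalar_number(guard_epsilon, "guard_epsilon")
  if (guard_epsilon < 0) stop("guard_epsilon must be >= 0", call. = FALSE)
  denom <- vol$low_kv + vol$high_kv + 2000
  valid <- abs(denom) >= guard_epsilon
  dei <- array(0, dim(vol$low_kv))
  dei[valid] <- (vol$low_kv[valid] - vol$high_kv[valid]) / denom[valid]
  structure(list(dei = dei, valid_mask = valid, spacing = vol$spacing),
            class = "dei_volume")
}

#' @export
print.dei_volume <- function(x, ...) {
  cat(sprintf("<dei_volume> %s voxels, %d invalid, DEI range [%.4f, %.4f]\n",
              paste(dim(x$dei), collapse = " x "), sum(!x$valid_mask),
              min(x$dei[x$valid_mask]), max(x$dei[x$valid_mask])))
  invisible(x)
}
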