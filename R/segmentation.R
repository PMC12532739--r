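# pellet_segmentation: fixed-threshold mask, slicewise disk erosion,
# 3D connected-component labelling, per-pellet DEI summaries.

#' Segmentation configuration
#'
#' Parameters of the automated pellet segmentation: a fixed HU threshold on
#' the high-kVp volume (strict `>`, so a voxel exactly at the threshold is
#' background), in-plane morphological erosion by a disk structuring element,
#' and 3D connected-component labelling. The optional `min_voxel_count` /
#' `max_voxel_count` hooks allow size-based filtering of components (e.g. to
#' exclude dental work or implants in clinical volumes); both default to off.
#'
#' @param threshold HU threshold on the high-kVp volume (default 2000).
#' @param erosion_diameter Disk diameter in pixels for in-plane erosion
#'   (default 4); 0 or 1 disables erosion.
#' @param connectivity 3D neighborhood order for labelling: 6, 18 or 26
#'   (default 26, the most permissive, so an eroded core spanning adjacent
#'   slices is never split into two pellets).
#' @param min_core_voxels Minimum surviving voxels for a component to be
#'   reported (default 1).
#' @param min_voxel_count,max_voxel_count Optional size-filter bounds on
#'   component voxel count; `NULL` disables.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold = 2000, erosion_diameter = 4,
                                connectivity = 26, min_core_voxels = 1,
                                min_voxel_count = NULL,
                                max_voxel_count = NULL) {
  stopifnot_scalar_number(threshold, "threshold")
  stopifnot_scalar_number(erosion_diameter, "erosion_diameter")
  if (erosion_diameter < 0) stop("erosion_diameter must be >= 0", call. = FALSE)
  if (!connectivity %in% c(6, 18, 26)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  if (min_core_voxels < 1) stop("min_core_voxels must be >= 1", call. = FALSE)
  structure(list(threshold = threshold,
                 erosion_diameter = erosion_diameter,
                 connectivity = as.integer(connectivity),
                 min_core_voxels = as.integer(min_core_voxels),
                 min_voxel_count = min_voxel_count,
                 max_voxel_count = max_voxel_count),
            class = "segmentation_config")
}

#' Disk structuring element
#'
#' The in-plane erosion footprint: pixels whose Euclidean distance from the
#' element center (itself on a pixel) is at most `diameter / 2`. For the
#' default diameter 4 this keeps 13 of the 5 x 5 bounding-box pixels (the
#' diamond-with-center at Euclidean distance <= 2.0); the same footprint is
#' shipped as a plain-text fixture under `extdata/footprints/` as the
#' frozen convention.
#'
#' @param diameter Disk diameter in pixels, >= 0.
#' @return Logical matrix footprint with odd side length.
#' @export
disk_footprint <- function(diameter = 4) {
  stopifnot_scalar_number(diameter, "diameter")
  if (diameter < 0) stop("diameter must be >= 0", call. = FALSE)
  r <- diameter / 2
  n <- floor(r)
  off <- -n:n
  fp <- outer(off^2, off^2, "+") <= r^2
  storage.mode(fp) <- "logical"
  fp
}

#' Threshold the high-kVp volume
#'
#' Voxels strictly above the configured HU threshold are pellet candidates;
#' anything at or below it is background. Strongly attenuating pellet metals
#' exceed 2000 HU on the extended scale even after partial-volume blending
#' well into the boundary shell, while gelatine/tissue stays far below.
#'
#' @param high_kv 3D numeric array of high-kVp HU values (or a 2D slice).
#' @param cfg A [segmentation_config()].
#' @return Logical array of the same shape.
#' @export
threshold_mask <- function(high_kv, cfg = segmentation_config()) {
  if (!all(is.finite(high_kv))) {
    stop("'high_kv' contains non-finite voxels", call. = FALSE)
  }
  high_kv > cfg$threshold
}

#' Erode a mask in-plane
#'
#' Binary erosion of each axial (x-y) slice by the disk footprint of the
#' configured diameter; pixels outside the image are treated as background,
#' so the output is always a subset of the input. Erosion is deliberately 2D
#' slicewise: in-plane pixels (0.504 mm) and slice thickness (1.0 mm) are
#' strongly anisotropic, so a 3D ball of a pixel-specified diameter would be
#' ambiguous. Stripping the partial-volume boundary shell before averaging
#' is what makes per-pellet DEI size-invariant.
#'
#' @param mask Logical 3D array (or 2D matrix, treated as one slice).
#' @param cfg A [segmentation_config()].
#' @return Eroded logical mask of the same shape as the input.
#' @export
erode_mask <- function(mask, cfg = segmentation_config()) {
  was_2d <- is.matrix(mask)
  m <- as_slice_stack(mask)
  if (!is.logical(m)) stop("'mask' must be logical", call. = FALSE)
  fp <- disk_footprint(cfg$erosion_diameter)
  out <- erode_with_footprint(m, fp)
  if (was_2d) out <- out[, , 1] else out
}

# Erosion by shift-and-AND over the footprint offsets, applied to every
# slice of the stack at once. Border policy: out-of-image = background.
erode_with_footprint <- function(mask, footprint) {
  d <- dim(mask)
  idx <- which(footprint, arr.ind = TRUE)
  ci <- (nrow(footprint) + 1L) %/% 2L
  cj <- (ncol(footprint) + 1L) %/% 2L
  di <- idx[, 1] - ci
  dj <- idx[, 2] - cj
  out <- mask
  n1 <- d[1]; n2 <- d[2]
  for (k in seq_along(di)) {
    if (di[k] == 0L && dj[k] == 0L) next
    sh <- array(FALSE, d)
    ti <- max(1L, 1L - di[k]):min(n1, n1 - di[k])
    tj <- max(1L, 1L - dj[k]):min(n2, n2 - dj[k])
    if (length(ti) > 0L && length(tj) > 0L) {
      sh[ti, tj, ] <- mask[ti + di[k], tj + dj[k], , drop = FALSE]
    }
    out <- out & sh
    if (!any(out)) break
  }
  out
}

# Neighbor offsets for a 3D connectivity order.
connectivity_offsets <- function(connectivity) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  ord <- abs(g$di) + abs(g$dj) + abs(g$dk)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)))
  as.matrix(g[keep, ])
}

#' Label connected components
#'
#' Assigns a distinct positive integer label to each maximal connected
#' component of the mask under the configured 3D connectivity (breadth-first
#' flood fill). Components smaller than `min_core_voxels`, or outside the
#' optional `min_voxel_count`/`max_voxel_count` size filter, are dropped
#' (their voxels are relabelled 0). Surviving labels are renumbered 1..n in
#' order of first raster-scan appearance.
#'
#' @param mask Logical 3D array (or 2D matrix, treated as one slice).
#' @param cfg A [segmentation_config()].
#' @return List with `labels` (integer array, 0 = background) and `census`
#'   (data.frame with `label`, `voxel_count`).
#' @export
label_pellets <- function(mask, cfg = segmentation_config()) {
  was_2d <- is.matrix(mask)
  m <- as_slice_stack(mask)
  if (!is.logical(m)) stop("'mask' must be logical", call. = FALSE)
  d <- dim(m)
  labels <- array(0L, d)
  offs <- connectivity_offsets(cfg$connectivity)
  n_off <- nrow(offs)
  seeds <- which(m)
  next_label <- 0L
  counts <- integer(0)
  n1 <- d[1]; n12 <- d[1] * d[2]
  for (s in seeds) {
    if (labels[s] != 0L) next
    next_label <- next_label + 1L
    stack <- s
    labels[s] <- next_label
    n_comp <- 1L
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      v0 <- v - 1L
      k <- v0 %/% n12
      r <- v0 %% n12
      j <- r %/% n1
      i <- r %% n1
      for (o in seq_len(n_off)) {
        ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; kk <- k + offs[o, 3]
        if (ii < 0L || ii >= d[1] || jj < 0L || jj >= d[2] ||
            kk < 0L || kk >= d[3]) next
        w <- 1L + ii + jj * n1 + kk * n12
        if (m[w] && labels[w] == 0L) {
          labels[w] <- next_label
          stack <- c(stack, w)
          n_comp <- n_comp + 1L
        }
      }
    }
    counts[next_label] <- n_comp
  }
  keep <- counts >= cfg$min_core_voxels
  if (!is.null(cfg$min_voxel_count)) keep <- keep & counts >= cfg$min_voxel_count
  if (!is.null(cfg$max_voxel_count)) keep <- keep & counts <= cfg$max_voxel_count
  remap <- integer(length(counts))
  remap[keep] <- seq_len(sum(keep))
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  census <- data.frame(label = seq_len(sum(keep)),
                       voxel_count = counts[keep])
  if (was_2d) labels <- labels[, , 1]
  list(labels = labels, census = census)
}

#' Per-pellet DEI summaries
#'
#' For each labelled component, computes the mean and standard deviation of
#' DEI over its voxels (invalid DEI voxels excluded), the centroid in mm
#' (voxel centers at `(index - 0.5) * spacing`), and optionally the mean
#' high-kVp HU. A component whose voxels are all DEI-invalid is excluded
#' with a warning.
#'
#' @param labels Integer label array from [label_pellets()].
#' @param dei A `dei_volume` from [compute_dei_volume()], or a bare 3D
#'   numeric array of DEI values (all voxels then taken as valid).
#' @param high_kv Optional high-kVp HU array for `mean_hu_high`.
#' @param spacing Voxel spacing (mm); defaults to the `dei_volume` spacing.
#' @return Data frame with one row per pellet: `label`, `voxel_count`,
#'   `centroid_x_mm`, `centroid_y_mm`, `centroid_z_mm`, `mean_dei`,
#'   `sd_dei`, `mean_hu_high`.
#' @export
pellet_dei_stats <- function(labels, dei, high_kv = NULL, spacing = NULL) {
  if (inherits(dei, "dei_volume")) {
    if (is.null(spacing)) spacing <- dei$spacing
    valid <- dei$valid_mask
    dei <- dei$dei
  } else {
    valid <- array(TRUE, dim(dei))
  }
  labels <- as_slice_stack(labels)
  dei <- as_slice_stack(dei)
  valid <- as_slice_stack(valid)
  if (!identical(dim(labels), dim(dei))) {
    stop("labels and dei must have identical dimensions", call. = FALSE)
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  spacing <- as.numeric(spacing)
  labs <- sort(unique(labels[labels > 0L]))
  rows <- lapply(labs, function(L) {
    sel <- which(labels == L)
    ok <- sel[valid[sel]]
    if (length(ok) == 0L) {
      warning(sprintf("pellet label %d has no valid DEI voxels; excluded", L),
              call. = FALSE)
      return(NULL)
    }
    ai <- arrayInd(sel, dim(labels))
    data.frame(label = L,
               voxel_count = length(sel),
               centroid_x_mm = mean((ai[, 1] - 0.5) * spacing[1]),
               centroid_y_mm = mean((ai[, 2] - 0.5) * spacing[2]),
               centroid_z_mm = mean((ai[, 3] - 0.5) * spacing[3]),
               mean_dei = mean(dei[ok]),
               sd_dei = if (length(ok) > 1L) stats::sd(dei[ok]) else 0,
               mean_hu_high = if (is.null(high_kv)) NA_real_
                              else mean(as_slice_stack(high_kv)[sel]))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(label = integer(0), voxel_count = integer(0),
                      centroid_x_mm = numeric(0), centroid_y_mm = numeric(0),
                      centroid_z_mm = numeric(0), mean_dei = numeric(0),
                      sd_dei = numeric(0), mean_hu_high = numeric(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the segmentation pipeline on one dual-energy volume
#'
#' Convenience wrapper chaining [compute_dei_volume()], [threshold_mask()],
#' [erode_mask()], [label_pellets()] and [pellet_dei_stats()] -- the fully
#' automated per-volume analysis.
#'
#' @param vol A [dual_energy_volume()].
#' @param cfg A [segmentation_config()].
#' @param guard_epsilon Denominator guard passed to [compute_dei_volume()].
#' @return List with `dei` (dei_volume), `mask` (thresholded), `eroded`,
#'   `labels`, `census` and `records` (the per-pellet data frame).
#' @export
analyze_volume <- function(vol, cfg = segmentation_config(),
                           guard_epsilon = 1) {
  dei <- compute_dei_volume(vol, guard_epsilon)
  mask <- threshold_mask(vol$high_kv, cfg)
  eroded <- erode_mask(mask, cfg)
  lab <- label_pellets(eroded, cfg)
  records <- pellet_dei_stats(lab$labels, dei, high_kv = vol$high_kv)
  list(dei = dei, mask = mask, eroded = eroded,
       labels = lab$labels, census = lab$census, records = records)
}
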