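# io_cli: NIfTI readers/writers, sidecars, run configuration and the
# end-to-end file-based pipeline.

# Wrap an array as a NIfTI image with the voxel spacing in the header.
as_nifti_spaced <- function(arr, spacing) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  img
}

#' Write a dual-energy volume pair to NIfTI
#'
#' Writes `<prefix>_low.nii.gz`, `<prefix>_high.nii.gz` (voxel spacing in
#' the header) and `<prefix>_sidecar.json` carrying the kVp pair, spacing
#' and metadata.
#'
#' @param vol A [dual_energy_volume()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, default `"block"`.
#' @return Invisibly, the named character vector of paths written.
#' @export
write_dual_energy <- function(vol, dir, prefix = "block") {
  if (!inherits(vol, "dual_energy_volume")) {
    stop("'vol' must be a dual_energy_volume", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(low = file.path(dir, paste0(prefix, "_low.nii.gz")),
             high = file.path(dir, paste0(prefix, "_high.nii.gz")),
             sidecar = file.path(dir, paste0(prefix, "_sidecar.json")))
  RNifti::writeNifti(as_nifti_spaced(vol$low_kv, vol$spacing),
                     paths[["low"]], datatype = "double")
  RNifti::writeNifti(as_nifti_spaced(vol$high_kv, vol$spacing),
                     paths[["high"]], datatype = "double")
  jsonlite::write_json(list(kvp_pair = vol$kvp_pair, spacing = vol$spacing,
                            meta = vol$meta),
                       paths[["sidecar"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a dual-energy volume pair from NIfTI
#'
#' Loads two co-registered volumes; voxel spacing comes from the NIfTI
#' header unless the JSON sidecar carries a `spacing` override, which wins
#' with a warning. A missing sidecar (or missing `kvp_pair` in it) leaves
#' the kVp pair recorded as unknown, with a warning.
#'
#' @param low_path,high_path Paths to the low- and high-kVp NIfTI files.
#' @param sidecar Optional path to the JSON sidecar.
#' @param spacing_tol Header-agreement tolerance in mm (default 1e-4);
#'   shape mismatch or spacing disagreement beyond it is an error.
#' @return A [dual_energy_volume()].
#' @export
read_dual_energy <- function(low_path, high_path, sidecar = NULL,
                             spacing_tol = 1e-4) {
  low <- RNifti::readNifti(low_path)
  high <- RNifti::readNifti(high_path)
  if (!identical(dim(low), dim(high))) {
    stop("low and high volumes have mismatched shapes", call. = FALSE)
  }
  sp_low <- RNifti::pixdim(low)[1:3]
  sp_high <- RNifti::pixdim(high)[1:3]
  if (any(abs(sp_low - sp_high) > spacing_tol)) {
    stop("low and high volumes disagree on voxel spacing", call. = FALSE)
  }
  spacing <- sp_low
  kvp <- c(NA_integer_, NA_integer_)
  meta <- list()
  if (!is.null(sidecar) && file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$spacing)) {
      if (any(abs(as.numeric(side$spacing) - spacing) > spacing_tol)) {
        warning("sidecar spacing overrides NIfTI header spacing",
                call. = FALSE)
      }
      spacing <- as.numeric(side$spacing)
    }
    if (!is.null(side$kvp_pair)) {
      kvp <- as.integer(side$kvp_pair)
    } else {
      warning("sidecar has no kvp_pair; recording kVp as unknown",
              call. = FALSE)
    }
    if (!is.null(side$meta)) meta <- side$meta
  } else {
    warning("no sidecar provided; recording kVp as unknown", call. = FALSE)
  }
  dual_energy_volume(array(as.numeric(low), dim(low)),
                     array(as.numeric(high), dim(high)),
                     spacing = spacing, kvp_pair = kvp, meta = meta)
}

#' Write a DEI volume (and its validity mask) to NIfTI
#'
#' @param dei A `dei_volume` from [compute_dei_volume()].
#' @param dir Output directory.
#' @param prefix File-name prefix, default `"block"`.
#' @return Invisibly, the paths written.
#' @export
write_dei_volume <- function(dei, dir, prefix = "block") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dei = file.path(dir, paste0(prefix, "_dei.nii.gz")),
             mask = file.path(dir, paste0(prefix, "_dei_valid.nii.gz")))
  RNifti::writeNifti(as_nifti_spaced(dei$dei, dei$spacing),
                     paths[["dei"]], datatype = "double")
  RNifti::writeNifti(as_nifti_spaced(array(as.integer(dei$valid_mask),
                                           dim(dei$valid_mask)),
                                     dei$spacing),
                     paths[["mask"]])
  invisible(paths)
}

#' Write per-pellet records as CSV
#'
#' Comma-separated, "." decimal, header row, UTF-8; DEI columns printed at
#' 6 decimals so identical runs produce byte-identical files.
#'
#' @param records Per-pellet data frame from [pellet_dei_stats()] or
#'   [run_phantom_study()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_pellet_records <- function(records, path) {
  out <- records
  for (col in intersect(c("mean_dei", "sd_dei"), names(out))) {
    out[[col]] <- sprintf("%.6f", out[[col]])
  }
  for (col in intersect(c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm",
                          "mean_hu_high"), names(out))) {
    out[[col]] <- sprintf("%.3f", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a Wilcoxon p-value matrix as CSV
#'
#' Square layout with material names on both axes and a unit diagonal.
#'
#' @param wm A `wilcoxon_matrix` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_wilcoxon_csv <- function(wm, path) {
  m <- format(round(wm$p, 4), nsmall = 4, trim = TRUE)
  df <- data.frame(material = rownames(wm$p), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Box plot of per-material DEI distributions
#'
#' Per-material box plots of per-pellet mean DEI with the group mean marked
#' by a cross, written as a PNG.
#'
#' @param records Data frame with `material` and `mean_dei` columns.
#' @param path Output PNG path.
#' @param width,height,res Device geometry passed to [grDevices::png()].
#' @return Invisibly, `path`.
#' @export
plot_group_boxplot <- function(records, path, width = 900, height = 700,
                               res = 120) {
  f <- factor(records$material, levels = unique(records$material))
  grDevices::png(path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  graphics::boxplot(records$mean_dei ~ f, xlab = "Pellet material",
                    ylab = "Mean DEI per pellet",
                    main = "Dual-energy index by pellet material")
  means <- tapply(records$mean_dei, f, mean)
  graphics::points(seq_along(means), means, pch = 4, cex = 1.4)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Either a phantom profile to simulate (`profile`) or a pair of input
#' volume paths (`low_path`/`high_path` plus optional `sidecar`), together
#' with segmentation settings, classification boundaries, output directory
#' and seed. The seed and a hash of the configuration are recorded in every
#' run log so a run is reproducible from its log alone.
#'
#' @param out_dir Output directory for all artifacts.
#' @param profile Phantom profile name to simulate, or `NULL` to read files.
#' @param low_path,high_path Input NIfTI paths (when `profile` is `NULL`).
#' @param sidecar Optional JSON sidecar path for the inputs.
#' @param seg A [segmentation_config()].
#' @param boundaries A [classification_boundaries()].
#' @param seed Integer seed (simulation and any other randomness).
#' @param block_size Simulated block size (mm), forwarded to
#'   [default_phantom()].
#' @param noise_sd Simulated noise SD (HU).
#' @param write_volumes Whether to write the (possibly large) NIfTI volumes
#'   for simulated blocks (default TRUE).
#' @param verbose Print stage progress messages.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, profile = NULL, low_path = NULL,
                       high_path = NULL, sidecar = NULL,
                       seg = segmentation_config(),
                       boundaries = classification_boundaries(),
                       seed = 1, block_size = c(70, 70, 150), noise_sd = 15,
                       write_volumes = TRUE, verbose = FALSE) {
  if (is.null(profile) && (is.null(low_path) || is.null(high_path))) {
    stop("provide either a phantom 'profile' or both input volume paths",
         call. = FALSE)
  }
  structure(list(out_dir = out_dir, profile = profile, low_path = low_path,
                 high_path = high_path, sidecar = sidecar, seg = seg,
                 boundaries = boundaries, seed = as.integer(seed),
                 block_size = block_size, noise_sd = noise_sd,
                 write_volumes = isTRUE(write_volumes),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end pipeline with file outputs
#'
#' Executes the full workflow described by a [run_config()]: simulate (or
#' read) the dual-energy volumes, compute DEI, segment, summarize each
#' pellet, and -- when material labels are available (simulated data) --
#' run group summaries, the Wilcoxon matrix, classification and the box
#' plot. All artifacts are written under `cfg$out_dir`: per-block NIfTI
#' volumes, DEI and label volumes, `pellets.csv`, `summary.csv`,
#' `pvalues.csv`, `boxplot.png` and a machine-readable `run_log.json`
#' (config echo, seed, config hash, package version). An empty segmentation
#' yields an empty CSV plus a warning, not an error.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the result bundle (same shape as
#'   [run_phantom_study()] plus `paths`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop("'cfg' must be a run_config",
                                         call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (cfg$verbose) message(sprintf(...))
  paths <- list()
  if (!is.null(cfg$profile)) {
    say("simulating phantom profile '%s' (seed %d)", cfg$profile, cfg$seed)
    st <- run_phantom_study(cfg$profile, seed = cfg$seed,
                            block_size = cfg$block_size,
                            noise_sd = cfg$noise_sd, cfg = cfg$seg)
    if (cfg$write_volumes) {
      for (bn in names(st$phantom$blocks)) {
        gen <- generate_block(st$phantom$blocks[[bn]],
                              st$phantom$calibration,
                              kvp_pair = st$phantom$kvp_pair)
        paths[[paste0("vol_", bn)]] <-
          write_dual_energy(gen$volume, cfg$out_dir, prefix = bn)
        dei <- compute_dei_volume(gen$volume)
        paths[[paste0("dei_", bn)]] <-
          write_dei_volume(dei, cfg$out_dir, prefix = bn)
      }
    }
    truth_path <- file.path(cfg$out_dir, "truth.csv")
    utils::write.csv(st$truth, truth_path, row.names = FALSE, quote = FALSE)
    paths$truth <- truth_path
  } else {
    say("reading volumes %s / %s", cfg$low_path, cfg$high_path)
    vol <- read_dual_energy(cfg$low_path, cfg$high_path, cfg$sidecar)
    res <- analyze_volume(vol, cfg$seg)
    st <- list(records = res$records, truth = NULL, summary = NULL,
               wilcoxon = NULL, classification = NULL, phantom = NULL)
    paths$dei <- write_dei_volume(res$dei, cfg$out_dir, prefix = "input")
    lab_img <- as_nifti_spaced(res$labels, vol$spacing)
    lab_path <- file.path(cfg$out_dir, "input_labels.nii.gz")
    RNifti::writeNifti(lab_img, lab_path)
    paths$labels <- lab_path
    if (nrow(res$records) > 0) {
      st$summary <- NULL  # no material labels on real volumes
    }
  }
  if (nrow(st$records) == 0) {
    warning("segmentation found no pellets; writing empty records",
            call. = FALSE)
  }
  pellets_path <- file.path(cfg$out_dir, "pellets.csv")
  write_pellet_records(st$records, pellets_path)
  paths$pellets <- pellets_path
  if (!is.null(st$summary)) {
    summary_path <- file.path(cfg$out_dir, "summary.csv")
    utils::write.csv(st$summary, summary_path, row.names = FALSE,
                     quote = FALSE)
    paths$summary <- summary_path
  }
  if (!is.null(st$wilcoxon)) {
    paths$pvalues <- write_wilcoxon_csv(st$wilcoxon,
                                        file.path(cfg$out_dir, "pvalues.csv"))
    paths$boxplot <- plot_group_boxplot(st$records,
                                        file.path(cfg$out_dir, "boxplot.png"))
  }
  if (!is.null(st$classification)) {
    cls_path <- file.path(cfg$out_dir, "classification.csv")
    utils::write.csv(st$classification, cls_path, row.names = FALSE,
                     quote = FALSE)
    paths$classification <- cls_path
  }
  log <- list(package = "dectpellet",
              version = as.character(utils::packageVersion("dectpellet")),
              seed = cfg$seed, config = unclass(cfg),
              config_md5 = config_hash(cfg),
              n_pellets = nrow(st$records),
              outputs = lapply(paths, as.character))
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
  st$paths <- paths
  invisible(st)
}
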