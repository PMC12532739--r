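# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately share no code with the package internals.

# Erosion by the definition: a pixel survives iff every footprint pixel,
# translated to it, lies inside the image and on the mask.
erode_oracle_2d <- function(mask, footprint) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  off <- which(footprint, arr.ind = TRUE)
  ci <- (nrow(footprint) + 1) %/% 2
  cj <- (ncol(footprint) + 1) %/% 2
  out <- matrix(FALSE, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      ok <- TRUE
      for (k in seq_len(nrow(off))) {
        ii <- i + off[k, 1] - ci
        jj <- j + off[k, 2] - cj
        if (ii < 1 || ii > n1 || jj < 1 || jj > n2 || !mask[ii, jj]) {
          ok <- FALSE
          break
        }
      }
      out[i, j] <- ok
    }
  }
  out
}

# Connected components by set-based region growing (vectorized frontier
# expansion), structurally different from the package's stack-based BFS.
# Returns component count and sorted sizes.
components_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(offs)) == 1,
                 "18" = rowSums(abs(offs)) <= 2,
                 "26" = rep(TRUE, nrow(offs)))
  offs <- offs[keep, , drop = FALSE]
  remaining <- which(mask)
  sizes <- integer(0)
  while (length(remaining) > 0) {
    comp <- remaining[1]
    frontier <- comp
    repeat {
      ai <- arrayInd(frontier, d)
      nb <- integer(0)
      for (o in seq_len(nrow(offs))) {
        co <- sweep(ai, 2, offs[o, ], "+")
        ok <- co[, 1] >= 1 & co[, 1] <= d[1] &
              co[, 2] >= 1 & co[, 2] <= d[2] &
              co[, 3] >= 1 & co[, 3] <= d[3]
        co <- co[ok, , drop = FALSE]
        nb <- c(nb, co[, 1] + (co[, 2] - 1) * d[1] +
                     (co[, 3] - 1) * d[1] * d[2])
      }
      frontier <- setdiff(intersect(unique(nb), remaining), comp)
      if (length(frontier) == 0) break
      comp <- c(comp, frontier)
    }
    sizes <- c(sizes, length(comp))
    remaining <- setdiff(remaining, comp)
  }
  list(n = length(sizes), sizes = sort(sizes))
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# C(nx+ny, nx) assignments of the pooled ranks to group x.
wilcox_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  cmb <- utils::combn(nx + ny, nx)
  u_all <- apply(cmb, 2, function(id) sum(r[id]) - nx * (nx + 1) / 2)
  p <- if (u_obs > nx * ny / 2) 2 * mean(u_all >= u_obs)
       else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# Compact single-material phantom block for fast end-to-end tests.
small_block <- function(seed, n_pellets = 3, material = "Fe", diameter = 3,
                        noise_sd = 15, block_size = c(40, 40, 50)) {
  calib <- build_calibration(material_dei_reference("paper-100-140"))
  lay <- pellet_layout(n_pellets, material, diameter = diameter,
                       block_size = block_size,
                       depth_range = c(5, block_size[3] - 5), seed = seed)
  spec <- phantom_spec(lay, block_size = block_size, noise_sd = noise_sd,
                       seed = seed)
  c(generate_block(spec, calib), list(spec = spec, calibration = calib))
}
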