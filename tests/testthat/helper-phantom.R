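# Shared small-grid phantom objects, built once per test run. The grid is
# deliberately modest (48 x 48 x 24 voxels at 2 mm; AP extent 96 mm) so the
# full pipeline stays fast while the 68 mm pathway still fits.
tg <- voxel_grid(c(48L, 48L, 24L), voxel_size = 2)
tt <- make_geometry(tg, decussation_fraction = 0.53, seed = 7L)
tlm <- phantom_landmarks(tt)
tsl <- simulate_streamlines(tt, n_per_side = 300, jitter_sd = 1.2, seed = 3L)
tdens <- density_map(tsl, tg)
tvol_control <- simulate_volumes(tt, group = "control", seed = 5L)
tfrac <- compartment_fractions(tvol_control$intensities)

# Independent breadth-first-search oracle for 26-connectivity (no igraph):
# returns TRUE iff some component touches both ROIs.
bfs_connected <- function(mask, seed_idx, way_idx) {
  dims <- dim(mask)
  key <- function(m) m[, 1] + dims[1] * (m[, 2] + dims[2] * m[, 3])
  vox <- which(mask) - 1L
  if (length(vox) == 0L) return(FALSE)
  inmask <- logical(prod(dims)); inmask[vox + 1L] <- TRUE
  seen <- logical(prod(dims))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  starts <- intersect(key(seed_idx), vox)
  frontier <- starts
  seen[frontier + 1L] <- TRUE
  while (length(frontier)) {
    i <- frontier %% dims[1]
    rest <- frontier %/% dims[1]
    j <- rest %% dims[2]; k <- rest %/% dims[2]
    nxt <- integer(0)
    for (r in seq_len(nrow(offs))) {
      ni <- i + offs[r, 1]; nj <- j + offs[r, 2]; nk <- k + offs[r, 3]
      ok <- ni >= 0 & ni < dims[1] & nj >= 0 & nj < dims[2] &
        nk >= 0 & nk < dims[3]
      nkey <- (ni + dims[1] * (nj + dims[2] * nk))[ok]
      nkey <- nkey[inmask[nkey + 1L] & !seen[nkey + 1L]]
      seen[nkey + 1L] <- TRUE
      nxt <- c(nxt, nkey)
    }
    frontier <- unique(nxt)
  }
  any(seen[key(way_idx) + 1L])
}

# Brute-force Hochberg step-up: test every k directly.
hochberg_brute <- function(p, alpha = 0.05) {
  m <- length(p)
  if (m == 0L) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  k_best <- 0L
  for (k in seq_len(m)) if (ps[k] <= alpha / (m - k + 1)) k_best <- k
  flags <- logical(m)
  if (k_best > 0) flags[ord[seq_len(k_best)]] <- TRUE
  flags
}

# TRUE on AP slices from..to (0-based, inclusive), FALSE elsewhere.
slice_range_mask <- function(grid, from, to) {
  m <- array(FALSE, dim = grid$dims)
  sl <- rep(rep(seq_len(grid$dims[2]) - 1L, each = grid$dims[1]),
            times = grid$dims[3])
  m[] <- sl >= from & sl <= to
  m
}

# Straight AP-axis tube mask with landmarks, for continuity fixtures.
make_tube <- function(dims = c(9L, 20L, 9L), from = 2L, to = 17L,
                      center = c(4L, 4L), radius = 1L) {
  g <- voxel_grid(dims, voxel_size = 2)
  m <- array(FALSE, dim = dims)
  for (j in from:to)
    m[center[1] + 1L + (-radius:radius), j + 1L,
      center[2] + 1L + (-radius:radius)] <- TRUE
  attr(m, "grid") <- g
  seed <- as.matrix(expand.grid(center[1] + (-radius:radius), to,
                                center[2] + (-radius:radius)))
  way <- as.matrix(expand.grid(center[1] + (-radius:radius), from,
                               center[2] + (-radius:radius)))
  lm <- landmarks(seed, way, as.integer(round(mean(c(from, to)))), g)
  list(mask = m, grid = g, landmarks = lm)
}
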