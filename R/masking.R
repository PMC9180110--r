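#' Streamline visitation density map
#'
#' Projects a streamline set into voxel space: each streamline is resampled
#' at arclength steps of at most half a voxel, mapped to 0-based voxel
#' indices (half-open cells), and increments each voxel it visits at most
#' once (binary per-streamline visitation, track-density style). Points
#' outside the grid are clipped with a single warning.
#'
#' @param streamlines a [streamline_set].
#' @param grid a [voxel_grid].
#' @return a `density_map`: integer 3-D array of visitation counts with the
#'   grid attached.
#' @export
density_map <- function(streamlines, grid) {
  stopifnot(inherits(streamlines, "streamline_set"), inherits(grid, "voxel_grid"))
  counts <- array(0L, dim = grid$dims)
  step <- grid$voxel_size / 2
  clipped <- FALSE
  for (p in streamlines$points) {
    q <- resample_polyline(p, step)
    idx <- world_to_voxel(grid, q)
    keep <- in_grid(grid, idx)
    if (!all(keep)) clipped <- TRUE
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) == 0L) next
    key <- unique(encode_voxels(grid, idx))
    pos <- key + 1L
    counts[pos] <- counts[pos] + 1L
  }
  if (clipped) warning("some streamline points fell outside the grid and were clipped")
  attr(counts, "grid") <- grid
  class(counts) <- c("density_map", class(counts))
  counts
}

# Resample a polyline at fixed arclength spacing, keeping both endpoints.
resample_polyline <- function(p, step) {
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  L <- sum(seg)
  if (L == 0) return(p[1, , drop = FALSE])
  s <- c(0, cumsum(seg))
  t <- unique(c(seq(0, L, by = step), L))
  i <- findInterval(t, s, rightmost.closed = TRUE)
  i <- pmin(i, length(seg))
  w <- (t - s[i]) / seg[i]
  w[!is.finite(w)] <- 0
  p[i, , drop = FALSE] * (1 - w) + p[i + 1L, , drop = FALSE] * w
}

#' Landmark ROIs for tract continuity and binning
#'
#' @param seed_voxels integer matrix (n x 3) of 0-based voxel indices of
#'   the LGN seed ROI.
#' @param waypoint_voxels integer matrix of the postorbital waypoint ROI.
#' @param chiasm_slice 0-based AP slice index of the chiasm plane, strictly
#'   between seed and waypoint along the AP axis.
#' @param grid a [voxel_grid].
#' @param lgn_mm,chiasm_mm,orbit_mm optional landmark AP positions in mm
#'   (used by segment binning; derived from the voxel ROIs when omitted).
#' @return an object of class `landmarks`.
#' @export
landmarks <- function(seed_voxels, waypoint_voxels, chiasm_slice, grid,
                      lgn_mm = NULL, chiasm_mm = NULL, orbit_mm = NULL) {
  seed_voxels <- as_index_matrix(seed_voxels)
  waypoint_voxels <- as_index_matrix(waypoint_voxels)
  ks <- encode_voxels(grid, seed_voxels)
  kw <- encode_voxels(grid, waypoint_voxels)
  if (length(intersect(ks, kw)) > 0) stop("seed and waypoint ROIs must be disjoint")
  ap <- grid$ap_axis
  centers <- ap_slice_centers(grid)
  if (is.null(lgn_mm)) lgn_mm <- mean(centers[seed_voxels[, ap] + 1L])
  if (is.null(orbit_mm)) orbit_mm <- mean(centers[waypoint_voxels[, ap] + 1L])
  if (is.null(chiasm_mm)) chiasm_mm <- centers[chiasm_slice + 1L]
  if (!(lgn_mm > chiasm_mm && chiasm_mm > orbit_mm))
    stop("chiasm slice must lie strictly between seed (LGN) and waypoint (orbit)")
  structure(list(seed_voxels = seed_voxels, waypoint_voxels = waypoint_voxels,
                 chiasm_slice = as.integer(chiasm_slice),
                 seed_count = nrow(seed_voxels), grid = grid,
                 lgn_mm = lgn_mm, chiasm_mm = chiasm_mm, orbit_mm = orbit_mm),
            class = "landmarks")
}

as_index_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  storage.mode(x) <- "integer"
  x
}

#' Landmark ROIs of the synthetic phantom
#'
#' Seed = in-tube voxels of the LGN plane, waypoint = in-tube voxels of the
#' orbital plane (both tubes of the requested kind), derived from the truth
#' centerlines.
#'
#' @param truth a `phantom_truth`.
#' @param grid a [voxel_grid] (defaults to the truth's grid).
#' @param radius ROI radius in mm around the centerline intersections.
#' @return a [landmarks] object.
#' @export
phantom_landmarks <- function(truth, grid = truth$grid,
                              radius = truth$params$tube_radius) {
  lm <- truth$landmarks
  seed <- plane_roi(truth, grid, lm$lgn_mm, radius)
  way <- plane_roi(truth, grid, lm$orbit_mm, radius)
  chiasm_slice <- world_to_voxel(grid, centerline_points(truth, "left",
                                                         "noncrossing",
                                                         lm$chiasm_mm))[lm$ap_axis]
  landmarks(seed, way, chiasm_slice, grid,
            lgn_mm = lm$lgn_mm, chiasm_mm = lm$chiasm_mm, orbit_mm = lm$orbit_mm)
}

# All in-grid voxels of the AP plane at y within `radius` of any centerline.
plane_roi <- function(truth, grid, y, radius) {
  lm <- truth$landmarks
  dims <- grid$dims; vs <- grid$voxel_size
  lat_c <- grid$origin[lm$lat_axis] + (seq_len(dims[lm$lat_axis]) - 1L) * vs
  vrt_c <- grid$origin[lm$vert_axis] + (seq_len(dims[lm$vert_axis]) - 1L) * vs
  plane <- as.matrix(expand.grid(lat = lat_c, vrt = vrt_c))
  inside <- rep(FALSE, nrow(plane))
  for (nm in names(truth$centerlines)) {
    parts <- strsplit(nm, "_")[[1]]
    cp <- centerline_points(truth, parts[1], parts[2], y)
    inside <- inside | (plane[, 1] - cp[lm$lat_axis])^2 +
      (plane[, 2] - cp[lm$vert_axis])^2 <= radius^2
  }
  j <- round((y - grid$origin[lm$ap_axis]) / vs)
  idx <- matrix(0L, nrow = sum(inside), ncol = 3)
  idx[, lm$ap_axis] <- j
  idx[, lm$lat_axis] <- as.integer(round((plane[inside, 1] -
                                            grid$origin[lm$lat_axis]) / vs))
  idx[, lm$vert_axis] <- as.integer(round((plane[inside, 2] -
                                             grid$origin[lm$vert_axis]) / vs))
  idx
}

#' Slicewise relative-density threshold
#'
#' For each AP slice containing at least one fibre, voxels with fewer than
#' `fraction` of the slice's maximum count are excluded; exact ties at the
#' threshold are kept (strictly-less-than exclusion). Slices without fibres
#' contribute nothing.
#'
#' @param density a [density_map].
#' @param ap_axis AP axis (defaults to the grid's).
#' @param fraction relative threshold in (0, 1], default 0.4.
#' @return a `tract_mask`: logical 3-D array with the grid attached.
#' @export
slicewise_threshold <- function(density, ap_axis = NULL, fraction = 0.4) {
  grid <- grid_of(density)
  if (is.null(ap_axis)) ap_axis <- grid$ap_axis
  if (!(fraction > 0 && fraction <= 1)) stop("`fraction` must be in (0, 1]")
  mx <- apply(density, ap_axis, max)
  thr <- fraction * mx
  # broadcast slice thresholds back over the volume
  perm_thr <- array(thr[slice_of_index(dim(density), ap_axis)],
                    dim = dim(density))
  mask <- density > 0 & density >= perm_thr
  attr(mask, "grid") <- grid
  class(mask) <- c("tract_mask", class(mask))
  mask
}

# AP slice number (1-based) of every element of an array (internal).
slice_of_index <- function(dims, ap_axis) {
  idx <- arrayInd(seq_len(prod(dims)), dims)[, ap_axis]
  idx
}

#' Background exclusion mask
#'
#' TRUE (excluded) where the normalized background fraction reaches the
#' threshold. Lowering the threshold never shrinks the excluded set.
#'
#' @param fractions output of [normalize_fractions()] (x, y, z, 4).
#' @param threshold nBG cutoff in `[0, 1]`.
#' @return logical 3-D array, TRUE = excluded.
#' @export
exclusion_mask <- function(fractions, threshold) {
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  nbg <- fractions[, , , 4]
  out <- nbg >= threshold
  attr(out, "grid") <- attr(fractions, "grid", exact = TRUE)
  out
}

#' Tract continuity check (26-connectivity)
#'
#' TRUE iff a single 26-connected component of the mask intersects both the
#' seed (LGN) ROI and the postorbital waypoint ROI.
#'
#' @param mask logical 3-D array (a `tract_mask`).
#' @param landmarks a [landmarks] object on the same grid.
#' @return logical scalar.
#' @export
continuity_check <- function(mask, landmarks) {
  grid <- grid_of(mask)
  keys <- which(mask) - 1L
  if (length(keys) == 0L) return(FALSE)
  comp <- connected_components(grid, keys)
  seed_k <- encode_voxels(grid, landmarks$seed_voxels)
  way_k <- encode_voxels(grid, landmarks$waypoint_voxels)
  cs <- comp[match(intersect(seed_k, keys), keys)]
  cw <- comp[match(intersect(way_k, keys), keys)]
  length(intersect(cs, cw)) > 0
}

# 26-connected component label per voxel key, via the igraph components of
# the neighbourhood graph (internal; the test-suite oracle is an
# independent breadth-first search).
connected_components <- function(grid, keys) {
  n <- length(keys)
  idx <- decode_voxels(grid, keys)
  lookup <- match(keys, keys)  # identity; membership via match below
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[r, ], "+")
    ok <- in_grid(grid, nb)
    nb_key <- rep(NA_integer_, n)
    nb_key[ok] <- encode_voxels(grid, nb[ok, , drop = FALSE])
    hit <- match(nb_key, keys)
    src <- which(!is.na(hit))
    if (length(src))
      edges <- c(edges, rbind(src, hit[src]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - ifelse(length(edges), max(edges), 0L)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Refine the tract mask until it is continuous
#'
#' Applies the slicewise relative threshold, then removes voxels excluded
#' by the background rule at threshold `t`, starting from `t0` and stepping
#' by `step` in the configured direction until the mask connects the seed
#' to the waypoint. If the threshold leaves (0, 1] without success the
#' opposite direction is tried once from `t0` before failing.
#'
#' @param density a [density_map].
#' @param fractions compartment fractions (x, y, z, 4).
#' @param landmarks a [landmarks] object.
#' @param t0 initial nBG threshold (default 0.15).
#' @param step threshold increment per iteration (default 0.01).
#' @param direction `"decreasing"` (default, following the published
#'   procedure) or `"increasing"`.
#' @param fraction slicewise relative threshold (default 0.4).
#' @param label subject/side label used in the failure message.
#' @return a `tract_mask` with attributes `threshold` (final nBG cutoff)
#'   and `landmarks`.
#' @export
refine_until_continuous <- function(density, fractions, landmarks,
                                    t0 = 0.15, step = 0.01,
                                    direction = c("decreasing", "increasing"),
                                    fraction = 0.4, label = "tract") {
  direction <- match.arg(direction)
  if (!(t0 > 0 && t0 <= 1)) stop("`t0` must be in (0, 1]")
  if (step <= 0) stop("`step` must be > 0")
  base <- slicewise_threshold(density, fraction = fraction)
  sgn <- if (direction == "decreasing") -1 else 1
  for (dir_sign in c(sgn, -sgn)) {
    t <- t0
    while (t > 0 && t <= 1) {
      mask <- base & !exclusion_mask(fractions, t)
      attr(mask, "grid") <- grid_of(base)
      class(mask) <- c("tract_mask", class(mask))
      if (continuity_check(mask, landmarks)) {
        attr(mask, "threshold") <- t
        attr(mask, "landmarks") <- landmarks
        return(mask)
      }
      t <- t + dir_sign * step
    }
  }
  stop(sprintf("tract not continuous for %s at any nBG threshold in (0, 1]",
               label))
}

#' Union of pre- and postchiasmatic tract masks
#'
#' When whole-pathway tracking fails, tracking is run separately on the
#' pre- and postchiasmatic bundles and the voxelwise union defines the
#' tract. Landmark metadata are merged: the seed (LGN) from the
#' postchiasmatic piece, the waypoint (orbit) from the prechiasmatic piece.
#'
#' @param pre_mask prechiasmatic `tract_mask` (orbit side).
#' @param post_mask postchiasmatic `tract_mask` (LGN side).
#' @return a `tract_mask` on the shared grid.
#' @export
piecewise_union <- function(pre_mask, post_mask) {
  ga <- grid_of(pre_mask); gb <- grid_of(post_mask)
  if (!same_grid(ga, gb)) stop("pre and post masks are on different grids")
  out <- pre_mask | post_mask
  attr(out, "grid") <- ga
  lm_pre <- attr(pre_mask, "landmarks", exact = TRUE)
  lm_post <- attr(post_mask, "landmarks", exact = TRUE)
  if (!is.null(lm_pre) && !is.null(lm_post)) {
    attr(out, "landmarks") <- landmarks(
      seed_voxels = lm_post$seed_voxels,
      waypoint_voxels = lm_pre$waypoint_voxels,
      chiasm_slice = lm_post$chiasm_slice, grid = ga,
      lgn_mm = lm_post$lgn_mm, chiasm_mm = lm_post$chiasm_mm,
      orbit_mm = lm_pre$orbit_mm)
  }
  class(out) <- c("tract_mask", class(out))
  out
}
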