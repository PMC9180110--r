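#' Synthetic anterior-optic-pathway phantom
#'
#' The phantom emulates the anatomy and statistical structure the along-tract
#' analysis assumes: two optic nerves converging at a chiasm where a fraction
#' of fibres decussates, four streamline bundles (left/right LGN origin x
#' crossing/noncrossing), compartment and tensor-derived scalar volumes whose
#' segment means follow published group summaries, and clinical covariates
#' with a plantable correlation against optic-nerve white-matter fraction.
#'
#' @name phantom
NULL

#' Default phantom grid: 96 x 96 x 60 voxels at 2 mm isotropic
#' @return a [voxel_grid] with AP axis 2.
#' @export
default_phantom_grid <- function() voxel_grid(c(96L, 96L, 60L), voxel_size = 2)

#' Published per-ROI group summary profiles
#'
#' Means and standard deviations of FA, MD (x1000 mm^2 s^-1), nCSF, nGM and
#' nWM for patient and control groups in five macroscopic ROIs (optic tract
#' left/right, chiasm, optic nerve left/right). These drive the volume
#' generator's segment targets.
#'
#' @return a data.frame with columns variable, roi, side, m_patient,
#'   sd_patient, m_control, sd_control.
#' @export
group_profiles <- function() {
  path <- system.file("extdata", "group_summaries.tsv", package = "opticpath",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

# Lateral offset magnitude of a noncrossing centerline at AP position y
# (mm from midline); C1 everywhere, minimum delta at the chiasm.
nc_offset <- function(y, lm, p) {
  h <- sqrt((y - lm$chiasm_mm)^2 + p$eps^2) - p$eps
  h_post <- sqrt((lm$lgn_mm - lm$chiasm_mm)^2 + p$eps^2) - p$eps
  h_pre <- sqrt((lm$chiasm_mm - lm$orbit_mm)^2 + p$eps^2) - p$eps
  a <- ifelse(y >= lm$chiasm_mm,
              (p$lgn_offset - p$delta) / h_post,
              (p$orbit_offset - p$delta) / h_pre)
  p$delta + a * h
}

# World coordinates of a centerline sampled at AP positions y (descending
# LGN -> orbit). lgn_side/kind select the bundle; crossing bundles blend
# smoothly to the mirrored nerve across the chiasm.
centerline_points <- function(truth, lgn_side, kind, y) {
  lm <- truth$landmarks
  p <- truth$params
  s <- if (lgn_side == "left") -1 else 1
  off_same <- s * nc_offset(y, lm, p)
  if (kind == "noncrossing") {
    lat <- lm$midline_mm + off_same
  } else {
    w <- smoothstep((y - (lm$chiasm_mm - p$blend_hw)) / (2 * p$blend_hw))
    lat <- lm$midline_mm + w * off_same + (1 - w) * (-off_same)
  }
  out <- matrix(0, nrow = length(y), ncol = 3)
  out[, lm$ap_axis] <- y
  out[, lm$lat_axis] <- lat
  out[, lm$vert_axis] <- lm$vert_mm
  out
}

#' Build the phantom's ground-truth geometry
#'
#' Places the LGN, chiasm and postorbital landmark planes on the grid's AP
#' axis (snapped to slice centres, 40 mm tract + 28 mm nerve when the grid
#' allows, scaled down proportionally otherwise), and constructs four smooth
#' (C1) centerlines: left/right LGN origin x crossing/noncrossing. The
#' noncrossing centerlines of the two sides approach within one voxel of
#' each other only at the chiasm plane; crossing centerlines pass through
#' the midline there.
#'
#' @param grid a [voxel_grid]; AP extent must be at least 60 mm so that 17
#'   segments of roughly 4 mm fit.
#' @param decussation_fraction probability that a fibre crosses at the
#'   chiasm; default 0.53, distinguishable from the idealized 0.5.
#' @param seed integer seed stored with the truth (used by the simulators).
#' @return an object of class `phantom_truth` with fields `grid`,
#'   `centerlines` (four polylines sampled at 1 mm, mm coordinates),
#'   `decussation_fraction`, `landmarks`, `group_profiles`, `params`,
#'   `seed`.
#' @export
make_geometry <- function(grid = default_phantom_grid(),
                          decussation_fraction = 0.53, seed = 1L) {
  if (decussation_fraction < 0 || decussation_fraction > 1)
    stop("`decussation_fraction` must be in [0, 1]")
  ext <- grid_extent(grid)
  if (ext < 60)
    stop(sprintf("grid AP extent %.1f mm < 60 mm: cannot fit 17 segments", ext))
  vs <- grid$voxel_size
  ap <- grid$ap_axis
  others <- setdiff(1:3, ap)
  lat_axis <- others[1]; vert_axis <- others[2]
  o_ap <- grid$origin[ap]
  mid_ap <- o_ap + (grid$dims[ap] - 1) * vs / 2
  len <- min(68, ext - 12)                    # LGN -> orbit distance, mm
  snap <- function(y) o_ap + round((y - o_ap) / vs) * vs
  orbit <- snap(mid_ap - len / 2)
  lgn <- snap(mid_ap + len / 2)
  chiasm <- snap(orbit + len * 28 / 68)
  if (!(lgn > chiasm && chiasm > orbit))
    stop("degenerate landmark placement: grid AP extent too small")
  landmarks_mm <- list(
    lgn_mm = lgn, chiasm_mm = chiasm, orbit_mm = orbit,
    ap_axis = ap, lat_axis = lat_axis, vert_axis = vert_axis,
    midline_mm = grid$origin[lat_axis] + (grid$dims[lat_axis] - 1) * vs / 2,
    vert_mm = grid$origin[vert_axis] + (grid$dims[vert_axis] - 1) * vs / 2)
  params <- list(lgn_offset = 14, orbit_offset = 16, delta = 0.9, eps = 1,
                 blend_hw = 3, tube_radius = 3)
  truth <- structure(
    list(grid = grid, decussation_fraction = decussation_fraction,
         landmarks = landmarks_mm, params = params,
         group_profiles = group_profiles(), seed = as.integer(seed)),
    class = "phantom_truth")
  ys <- seq(lgn, orbit, by = -1)
  if (ys[length(ys)] != orbit) ys <- c(ys, orbit)
  cl <- list()
  for (side in c("left", "right"))
    for (kind in c("noncrossing", "crossing"))
      cl[[paste(side, kind, sep = "_")]] <-
        centerline_points(truth, side, kind, ys)
  truth$centerlines <- cl
  truth
}

#' @export
print.phantom_truth <- function(x, ...) {
  lm <- x$landmarks
  cat(sprintf(paste0("phantom_truth: LGN %.0f / chiasm %.0f / orbit %.0f mm",
                     " (AP axis %d), decussation %.2f\n"),
              lm$lgn_mm, lm$chiasm_mm, lm$orbit_mm, lm$ap_axis,
              x$decussation_fraction))
  invisible(x)
}

#' Simulate streamlines around the phantom centerlines
#'
#' Each streamline is its bundle centerline plus smooth Gaussian lateral
#' jitter applied in the plane perpendicular to the local tangent (so the
#' arclength parametrization and the AP endpoints stay stable). Per LGN
#' side, the number of crossing streamlines is a binomial draw with the
#' truth's decussation fraction.
#'
#' @param truth a `phantom_truth`.
#' @param n_per_side streamlines per LGN side (>= 1).
#' @param jitter_sd pointwise lateral jitter standard deviation in mm
#'   (default 1.2; 0 reproduces the centerlines exactly).
#' @param seed integer seed; identical seeds give identical output.
#' @return a [streamline_set] (streamlines run LGN to orbit).
#' @export
simulate_streamlines <- function(truth, n_per_side = 1000, jitter_sd = 1.2,
                                 seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (n_per_side < 1) stop("`n_per_side` must be >= 1")
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  set.seed(as.integer(seed))
  frames <- lapply(truth$centerlines, centerline_frame)
  pts <- list(); sides <- character(0); kinds <- character(0)
  for (side in c("left", "right")) {
    n_cross <- stats::rbinom(1L, n_per_side, truth$decussation_fraction)
    kind_vec <- c(rep("crossing", n_cross),
                  rep("noncrossing", n_per_side - n_cross))
    for (kind in kind_vec) {
      fr <- frames[[paste(side, kind, sep = "_")]]
      m <- nrow(fr$pts)
      s <- seq(0, 1, length.out = m)
      cs <- jitter_sd / sqrt(2)
      u <- smooth_jitter(s, cs, jitter_sd)
      v <- smooth_jitter(s, cs, jitter_sd)
      pts[[length(pts) + 1L]] <- fr$pts + u * fr$n1 + v * fr$n2
      sides <- c(sides, side); kinds <- c(kinds, kind)
    }
  }
  streamline_set(pts, sides, kinds)
}

# Low-order random smooth displacement along [0, 1]; clamped at 2 sd so
# endpoints never stray beyond a voxel off their landmark plane.
smooth_jitter <- function(s, coef_sd, sd_clamp) {
  cf <- stats::rnorm(3L, 0, coef_sd)
  val <- cf[1] + cf[2] * cos(pi * s) + cf[3] * sin(pi * s)
  pmin(2 * sd_clamp, pmax(-2 * sd_clamp, val))
}

# Tangent + perpendicular frame along a polyline (internal).
centerline_frame <- function(p) {
  m <- nrow(p)
  tg <- rbind(p[2, ] - p[1, ],
              (p[3:m, , drop = FALSE] - p[1:(m - 2), , drop = FALSE]) / 2,
              p[m, ] - p[m - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  ref <- c(0, 0, 1)
  if (abs(tg[1, 3]) > 0.9) ref <- c(1, 0, 0)
  n1 <- cbind(tg[, 2] * ref[3] - tg[, 3] * ref[2],
              tg[, 3] * ref[1] - tg[, 1] * ref[3],
              tg[, 1] * ref[2] - tg[, 2] * ref[1])
  n1 <- n1 / sqrt(rowSums(n1^2))
  n2 <- cbind(tg[, 2] * n1[, 3] - tg[, 3] * n1[, 2],
              tg[, 3] * n1[, 1] - tg[, 1] * n1[, 3],
              tg[, 1] * n1[, 2] - tg[, 2] * n1[, 1])
  list(pts = p, tg = tg, n1 = n1, n2 = n2)
}

#' Segment id for AP positions, given the phantom landmarks
#'
#' Seventeen anatomy-scaled segments: ids 1-10 tile the chiasm-to-LGN
#' interval evenly (1 adjacent to the LGN, 10 adjacent to the chiasm) and
#' ids 11-17 tile the orbit-to-chiasm interval (11 adjacent to the chiasm,
#' 17 adjacent to the orbit).
#'
#' @param y numeric vector of AP positions (mm).
#' @param lgn_mm,chiasm_mm,orbit_mm landmark AP positions, ordered
#'   `lgn_mm > chiasm_mm > orbit_mm`.
#' @param n_post,n_pre number of postchiasmatic / prechiasmatic segments.
#' @param tol positions within `tol` mm beyond the terminal landmarks are
#'   still assigned to the terminal segments (default 0).
#' @return integer vector of segment ids; NA outside the pathway.
#' @export
ap_segment_id <- function(y, lgn_mm, chiasm_mm, orbit_mm,
                          n_post = 10L, n_pre = 7L, tol = 0) {
  if (!(lgn_mm > chiasm_mm && chiasm_mm > orbit_mm))
    stop("landmarks must satisfy lgn > chiasm > orbit")
  len_post <- (lgn_mm - chiasm_mm) / n_post
  len_pre <- (chiasm_mm - orbit_mm) / n_pre
  id <- rep(NA_integer_, length(y))
  post <- y >= chiasm_mm & y <= lgn_mm + tol
  id[post] <- pmin(n_post, pmax(1L, ceiling((lgn_mm - y[post]) / len_post)))
  pre <- y < chiasm_mm & y >= orbit_mm - tol
  id[pre] <- n_post + 1L + pmin(n_pre - 1L, floor((chiasm_mm - y[pre]) / len_pre))
  id
}

# Macroscopic ROI key for a segment id and lateral sign (internal):
# tract_left/right (segments 1-9), chiasm (10-11), nerve_left/right (12-17).
segment_roi_key <- function(segment, is_left) {
  ifelse(segment <= 9L, ifelse(is_left, "optic_tract.left", "optic_tract.right"),
         ifelse(segment <= 11L, "chiasm.both",
                ifelse(is_left, "optic_nerve.left", "optic_nerve.right")))
}

# Draw per-segment parameter targets for one synthetic subject: a subject-
# level ROI effect from the published N(m, sd), plus independent
# within-subject wiggle (0.25 * sd) per segment.
draw_segment_targets <- function(truth, group, wiggle = 0.25) {
  gp <- truth$group_profiles
  mcol <- paste0("m_", group); scol <- paste0("sd_", group)
  if (!mcol %in% names(gp)) stop("unknown group label: ", group)
  vars <- unique(gp$variable)
  keys <- paste(gp$roi, gp$side, sep = ".")
  u <- stats::rnorm(nrow(gp), gp[[mcol]], gp[[scol]])
  segs <- expand.grid(segment = 1:17, lat = c("left", "right"),
                      stringsAsFactors = FALSE)
  segs <- segs[!(segs$segment %in% c(10L, 11L) & segs$lat == "right"), ]
  segs$roi_key <- segment_roi_key(segs$segment, segs$lat == "left")
  segs$roi_key[segs$segment %in% c(10L, 11L)] <- "chiasm.both"
  out <- list()
  for (v in vars) {
    rows <- gp$variable == v
    ku <- stats::setNames(u[rows], keys[rows])
    ks <- stats::setNames(gp[[scol]][rows], keys[rows])
    val <- ku[segs$roi_key] + stats::rnorm(nrow(segs), 0, wiggle * ks[segs$roi_key])
    out[[v]] <- val
  }
  tg <- data.frame(segment = segs$segment, lat = segs$lat,
                   roi_key = segs$roi_key, stringsAsFactors = FALSE)
  tg$FA <- pmin(0.95, pmax(0.02, out$FA))
  tg$MD <- pmax(0.2, out$MD)                      # x1000 mm^2/s units
  tg$nCSF <- pmin(0.97, pmax(0.01, out$nCSF))
  tg$nGM <- pmin(0.97, pmax(0.01, out$nGM))
  tg$nWM <- pmin(0.97, pmax(0.01, out$nWM))
  tg
}

#' Simulate phantom volumes for one synthetic subject
#'
#' Voxels within `tube_radius` of any bundle centerline receive raw
#' compartment intensities and axially symmetric diffusion tensors whose
#' derived FA, MD and tissue fractions match per-segment targets drawn from
#' the requested group's published profile; voxels outside the tubes get a
#' low total compartment intensity (below the 0.075 background threshold)
#' and a zero tensor. DWI volumes follow the monoexponential tensor model
#' with optional Rician noise.
#'
#' @param truth a `phantom_truth`.
#' @param grid target [voxel_grid] (defaults to the truth's grid).
#' @param group `"control"` or `"patient"`.
#' @param noise_sd Rician noise sd in signal units (0 for exact tests).
#' @param seed integer seed.
#' @param scheme a [dwi_scheme] for the DWI simulation.
#' @param tube_radius tube radius in mm (default from the truth's params).
#' @return a list with `intensities` (x,y,z,3 raw WM/GM/CSF),
#'   `tensor` (a `tensor_field`), `dwi` (x,y,z,volumes), `scheme`,
#'   `targets` (per-segment parameter targets), `membership` (logical
#'   in-tract array), `segment` (integer segment-id array, NA outside),
#'   `s0`, `group`.
#' @export
simulate_volumes <- function(truth, grid = truth$grid,
                             group = c("control", "patient"),
                             noise_sd = 0, seed = 1L,
                             scheme = default_dwi_scheme(),
                             tube_radius = truth$params$tube_radius) {
  group <- match.arg(group)
  set.seed(as.integer(seed))
  lm <- truth$landmarks
  targets <- draw_segment_targets(truth, group)

  dims <- grid$dims; vs <- grid$voxel_size
  ap <- lm$ap_axis; lat <- lm$lat_axis; vrt <- lm$vert_axis
  ap_centers <- grid$origin[ap] + (seq_len(dims[ap]) - 1L) * vs
  lat_centers <- grid$origin[lat] + (seq_len(dims[lat]) - 1L) * vs
  vrt_centers <- grid$origin[vrt] + (seq_len(dims[vrt]) - 1L) * vs
  seg_of_slice <- ap_segment_id(ap_centers, lm$lgn_mm, lm$chiasm_mm,
                                lm$orbit_mm, tol = vs / 2)

  membership <- array(FALSE, dim = dims)
  segment <- array(NA_integer_, dim = dims)
  is_left <- array(NA, dim = dims)
  # slicewise tube test: in-plane distance to each centerline at this AP slice
  cl_names <- names(truth$centerlines)
  plane <- as.matrix(expand.grid(lat = lat_centers, vrt = vrt_centers))
  for (j in seq_len(dims[ap])) {
    sid <- seg_of_slice[j]
    if (is.na(sid)) next
    y <- ap_centers[j]
    inside <- rep(FALSE, nrow(plane))
    for (nm in cl_names) {
      parts <- strsplit(nm, "_")[[1]]
      cp <- centerline_points(truth, parts[1], parts[2], y)
      d2 <- (plane[, 1] - cp[lat])^2 + (plane[, 2] - cp[vrt])^2
      inside <- inside | d2 <= tube_radius^2
    }
    idx <- slice_index(dims, ap, lat, vrt, j)
    membership[idx] <- inside
    segment[idx][inside] <- sid
    is_left[idx][inside] <- plane[inside, 1] < lm$midline_mm
  }

  # per-voxel targets via (segment, laterality) lookup
  key <- paste(segment[membership],
               ifelse(segment[membership] %in% c(10L, 11L), "left",
                      ifelse(is_left[membership], "left", "right")))
  tkey <- paste(targets$segment, targets$lat)
  row <- match(key, tkey)

  low <- 0.015                                  # background exercised outside
  raw <- array(low, dim = c(dims, 3L))
  wm <- array(low, dim = dims); gm <- array(low, dim = dims)
  cs <- array(low, dim = dims)
  wm[membership] <- targets$nWM[row]
  gm[membership] <- targets$nGM[row]
  cs[membership] <- targets$nCSF[row]
  raw[, , , 1] <- wm; raw[, , , 2] <- gm; raw[, , , 3] <- cs
  attr(raw, "grid") <- grid

  # axially symmetric tensor with the target FA and MD, long axis along AP
  fa <- targets$FA[row]
  md <- targets$MD[row] * 1e-3                  # printed units -> mm^2/s
  f <- fa / sqrt(3 - 2 * fa^2)
  lam1 <- md * (1 + 2 * f); lamp <- md * (1 - f)
  tensor <- array(0, dim = c(dims, 6L))
  diag_idx <- c(1L, 2L, 3L)
  for (k in 1:3) {
    comp <- array(0, dim = dims)
    comp[membership] <- if (k == ap) lam1 else lamp
    tensor[, , , diag_idx[k]] <- comp
  }
  attr(tensor, "grid") <- grid
  class(tensor) <- c("tensor_field", class(tensor))

  s0 <- array(0.05, dim = dims)
  s0[membership] <- 1
  dwi <- dwi_signal(tensor, s0, scheme)
  if (noise_sd > 0) {
    n <- length(dwi)
    dwi <- sqrt((dwi + stats::rnorm(n, 0, noise_sd))^2 +
                  stats::rnorm(n, 0, noise_sd)^2)
    dim(dwi) <- c(dims, scheme$n)
  }
  attr(dwi, "grid") <- grid
  list(intensities = raw, tensor = tensor, dwi = dwi, scheme = scheme,
       targets = targets, membership = membership, segment = segment,
       s0 = s0, group = group)
}

# Logical index selecting one AP slice of a 3-D array (internal).
slice_index <- function(dims, ap, lat, vrt, j) {
  idx <- array(FALSE, dim = dims)
  if (ap == 1) idx[j, , ] <- TRUE
  else if (ap == 2) idx[, j, ] <- TRUE
  else idx[, , j] <- TRUE
  idx
}

#' Simulate clinical covariates with a planted correlation
#'
#' Per subject and eye, draws an optic-nerve nWM value from the patient
#' profile and visual acuity / RNFL so that the population correlation
#' between nWM and VA (logMAR) is `r_target` and between nWM and average
#' RNFL is `-r_target`. Disease duration and quadrant RNFL values follow
#' the published cohort summaries; the order in which eyes were affected is
#' randomized per subject.
#'
#' @param truth a `phantom_truth`.
#' @param n_subjects number of synthetic patients (0 gives an empty table).
#' @param r_target target correlation, `|r_target| <= 1`.
#' @param seed integer seed.
#' @return a data.frame with one row per subject-eye: columns subject, eye,
#'   va_logmar, rnfl_um, rnfl_temporal_um, rnfl_nasal_um, duration_days,
#'   affected_order, and the latent nwm_nerve used for the planting.
#' @export
simulate_clinical <- function(truth, n_subjects, r_target = 0.57, seed = 1L) {
  if (abs(r_target) > 1) stop("|r_target| must be <= 1")
  cols <- c("subject", "eye", "va_logmar", "rnfl_um", "rnfl_temporal_um",
            "rnfl_nasal_um", "duration_days", "affected_order", "nwm_nerve")
  if (n_subjects == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$subject <- character(0); out$eye <- character(0)
    out$affected_order <- character(0)
    return(out)
  }
  set.seed(as.integer(seed))
  gp <- truth$group_profiles
  nerve <- gp[gp$variable == "nWM" & gp$roi == "optic_nerve", ]
  res <- vector("list", n_subjects)
  va_m <- 1.69; va_sd <- c(right = 0.34, left = 0.36)
  rnfl_m <- c(right = 76.2, left = 74.9); rnfl_sd <- c(right = 22.0, left = 22.2)
  dur_m <- c(right = 332, left = 315); dur_sd <- c(right = 315, left = 126)
  resid <- sqrt(1 - r_target^2)
  for (i in seq_len(n_subjects)) {
    first <- sample(c("left", "right"), 1L)
    eyes <- c("left", "right")
    zw <- stats::rnorm(2L)
    nm <- nerve$m_patient[match(eyes, nerve$side)]
    ns <- nerve$sd_patient[match(eyes, nerve$side)]
    nwm <- nm + ns * zw
    z_va <- r_target * zw + resid * stats::rnorm(2L)
    z_rn <- -r_target * zw + resid * stats::rnorm(2L)
    rnfl <- pmax(5, rnfl_m[eyes] + rnfl_sd[eyes] * z_rn)
    res[[i]] <- data.frame(
      subject = sprintf("P%03d", i), eye = eyes,
      va_logmar = va_m + va_sd[eyes] * z_va,
      rnfl_um = rnfl,
      rnfl_temporal_um = pmax(5, rnfl + stats::rnorm(2L, 0, 8)),
      rnfl_nasal_um = pmax(5, rnfl + stats::rnorm(2L, 0, 8)),
      duration_days = round(pmax(14, dur_m[eyes] + dur_sd[eyes] * stats::rnorm(2L))),
      affected_order = ifelse(eyes == first, "first", "second"),
      nwm_nerve = nwm,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, res)
}

#' Write a complete phantom dataset to disk
#'
#' Volumes as NIfTI-1 (.nii.gz), streamlines as TCK, clinical covariates as
#' TSV, and the ground truth (landmarks, decussation fraction, seed) as a
#' JSON sidecar.
#'
#' @param dir output directory (created if missing).
#' @param truth a `phantom_truth`.
#' @param streamlines optional [streamline_set].
#' @param volumes optional output of [simulate_volumes()].
#' @param clinical optional output of [simulate_clinical()].
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(dir, truth, streamlines = NULL, volumes = NULL,
                          clinical = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sidecar <- list(decussation_fraction = truth$decussation_fraction,
                  landmarks = truth$landmarks[c("lgn_mm", "chiasm_mm", "orbit_mm",
                                                "ap_axis")],
                  seed = truth$seed,
                  grid = list(dims = truth$grid$dims,
                              voxel_size = truth$grid$voxel_size,
                              origin = truth$grid$origin,
                              ap_axis = truth$grid$ap_axis))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(streamlines))
    write_tck(streamlines, file.path(dir, "streamlines.tck"))
  if (!is.null(volumes)) {
    write_nifti(volumes$intensities, file.path(dir, "compartments_raw.nii.gz"))
    write_nifti(unclass(volumes$tensor), file.path(dir, "tensor.nii.gz"))
    write_nifti(volumes$dwi, file.path(dir, "dwi.nii.gz"))
    writeLines(paste(volumes$scheme$bvals, collapse = " "),
               file.path(dir, "dwi.bval"))
    writeLines(apply(t(volumes$scheme$bvecs), 1, paste, collapse = " "),
               file.path(dir, "dwi.bvec"))
  }
  if (!is.null(clinical))
    utils::write.table(clinical, file.path(dir, "clinical.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
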