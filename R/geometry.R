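#' Anatomy-scaled segment binning
#'
#' Bins AP slices into 17 segments: the chiasm-to-LGN interval is divided
#' into `n_post` equal-length segments (id 1 adjacent to the LGN, id 10
#' adjacent to the chiasm) and the orbit-to-chiasm interval into `n_pre`
#' segments (id 11 adjacent to the chiasm, id 17 adjacent to the orbit).
#' Interval lengths are per subject ("adjusted to the cranial dimensions"):
#' segment boundaries come from the subject's own landmark positions.
#' Slices are assigned by their centre coordinate.
#'
#' @param mask a `tract_mask` (used to verify the pathway is populated).
#' @param landmarks a [landmarks] object carrying `lgn_mm`, `chiasm_mm`,
#'   `orbit_mm`.
#' @param n_post,n_pre segment counts for the postchiasmatic (default 10)
#'   and prechiasmatic (default 7) portions.
#' @return a `segment_assignment`: list with `slice_segment` (integer
#'   vector over AP slices, NA outside the pathway), `slice_ap_mm`,
#'   `boundaries_mm`, `mean_length_mm`, `n_post`, `n_pre`, `landmarks`.
#' @export
bin_segments <- function(mask, landmarks, n_post = 10L, n_pre = 7L) {
  grid <- grid_of(mask)
  lm <- landmarks
  centers <- ap_slice_centers(grid)
  # streamline endpoints may legitimately sit within one voxel of the
  # terminal landmark planes, so terminal segments absorb one voxel of slack
  seg <- ap_segment_id(centers, lm$lgn_mm, lm$chiasm_mm, lm$orbit_mm,
                       n_post = n_post, n_pre = n_pre,
                       tol = grid$voxel_size)
  n_slices_post <- sum(!is.na(seg) & seg <= n_post)
  n_slices_pre <- sum(!is.na(seg) & seg > n_post)
  if (n_slices_post < n_post)
    stop(sprintf("postchiasmatic portion has %d slices for %d segments",
                 n_slices_post, n_post))
  if (n_slices_pre < n_pre)
    stop(sprintf("prechiasmatic portion has %d slices for %d segments",
                 n_slices_pre, n_pre))
  ap_counts <- apply(mask, grid$ap_axis, sum)
  if (sum(ap_counts[!is.na(seg)]) == 0)
    stop("mask is empty between the landmarks")
  len_post <- (lm$lgn_mm - lm$chiasm_mm) / n_post
  len_pre <- (lm$chiasm_mm - lm$orbit_mm) / n_pre
  boundaries <- c(seq(lm$lgn_mm, lm$chiasm_mm, by = -len_post),
                  seq(lm$chiasm_mm - len_pre, lm$orbit_mm, by = -len_pre))
  structure(list(slice_segment = seg, slice_ap_mm = centers,
                 boundaries_mm = boundaries,
                 mean_length_mm = (n_post * len_post + n_pre * len_pre) /
                   (n_post + n_pre),
                 n_post = as.integer(n_post), n_pre = as.integer(n_pre),
                 landmarks = lm, grid = grid),
            class = "segment_assignment")
}

#' @export
print.segment_assignment <- function(x, ...) {
  cat(sprintf("segment_assignment: %d segments (%d post + %d pre), mean length %.2f mm\n",
              x$n_post + x$n_pre, x$n_post, x$n_pre, x$mean_length_mm))
  invisible(x)
}

#' Map segments to macroscopic ROIs
#'
#' Optic tract = segments 1-9; chiasm = the two juxtachiasmatic segments
#' (10 and 11), pooled across sides into a single bilateral ROI; optic
#' nerve = segments 12-17. Every segment belongs to exactly one ROI.
#'
#' @param segments a `segment_assignment`.
#' @return an `roi_partition`: data.frame with columns `segment`, `roi`.
#' @export
partition_rois <- function(segments) {
  n <- segments$n_post + segments$n_pre
  seg <- seq_len(n)
  roi <- ifelse(seg <= segments$n_post - 1L, "optic_tract",
                ifelse(seg <= segments$n_post + 1L, "chiasm", "optic_nerve"))
  structure(data.frame(segment = seg, roi = roi, stringsAsFactors = FALSE),
            class = c("roi_partition", "data.frame"))
}

#' Nondecussating (or crossing) fibre fraction by weighted fibre volume
#'
#' The weighted fibre volume of a bundle is the voxelwise sum of its
#' streamline visitation counts. The returned value is the noncrossing
#' bundle's share of the two volumes.
#'
#' @param cross_density [density_map] of the crossing bundle (one LGN side).
#' @param noncross_density [density_map] of the noncrossing bundle of the
#'   same side.
#' @return noncrossing fraction in `[0, 1]`; `NA` (with a warning) when
#'   both maps are empty.
#' @export
noncrossing_fraction <- function(cross_density, noncross_density) {
  if (!same_grid(grid_of(cross_density), grid_of(noncross_density)))
    stop("density maps are on different grids")
  a <- sum(as.numeric(noncross_density))
  b <- sum(as.numeric(cross_density))
  if (a + b == 0) {
    warning("both density maps are empty: fraction undefined")
    return(NA_real_)
  }
  a / (a + b)
}

#' Dice overlap coefficient of two tract masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Undefined (error) when both masks are
#' empty.
#'
#' @param mask_a,mask_b logical arrays on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!same_grid(grid_of(mask_a), grid_of(mask_b)))
    stop("masks are on different grids")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) stop("both masks are empty: Dice undefined")
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Tractography success verdict
#'
#' Tractography counts as successful when (i) every requested tract is
#' continuous from seed to waypoint, (ii) crossing and noncrossing paths
#' overlap substantially (Dice at or above `dice_min`), and (iii) each
#' side's noncrossing fraction is close to the anatomically attested value
#' of about one half (within `delta`).
#'
#' @param masks named list of `tract_mask` objects, each carrying a
#'   `landmarks` attribute (or use `continuous` to pass precomputed flags).
#' @param fractions named numeric vector of per-side noncrossing fractions.
#' @param dice_values named numeric vector of per-side crossing-vs-
#'   noncrossing Dice coefficients.
#' @param dice_min minimum acceptable Dice (default 0.5).
#' @param delta allowed deviation of the noncrossing fraction from 0.5
#'   (default 0.15).
#' @param continuous optional named logical vector overriding the
#'   continuity evaluation of `masks`.
#' @return a list with `success` (logical) and `reasons` (character vector
#'   naming every failed criterion; empty on success).
#' @export
success_report <- function(masks = list(), fractions = numeric(0),
                           dice_values = numeric(0), dice_min = 0.5,
                           delta = 0.15, continuous = NULL) {
  reasons <- character(0)
  if (is.null(continuous)) {
    continuous <- vapply(masks, function(m) {
      lm <- attr(m, "landmarks", exact = TRUE)
      if (is.null(lm)) stop("mask lacks a landmarks attribute")
      continuity_check(m, lm)
    }, logical(1))
  }
  bad <- names(continuous)[!continuous]
  if (length(bad))
    reasons <- c(reasons, sprintf("tract not continuous: %s",
                                  paste(bad, collapse = ", ")))
  low <- names(dice_values)[dice_values < dice_min]
  if (length(low))
    reasons <- c(reasons, sprintf("crossing/noncrossing overlap below %.2f: %s",
                                  dice_min, paste(low, collapse = ", ")))
  off <- names(fractions)[abs(fractions - 0.5) > delta]
  if (length(off))
    reasons <- c(reasons, sprintf(
      "noncrossing fraction outside [%.2f, %.2f]: %s",
      0.5 - delta, 0.5 + delta, paste(off, collapse = ", ")))
  list(success = length(reasons) == 0L, reasons = reasons)
}

#' Write a segment assignment as TSV (and optionally a label volume)
#'
#' @param segments a `segment_assignment`.
#' @param path output TSV path (columns slice_index, ap_mm, segment_id,
#'   roi_label).
#' @param label_volume_path optional NIfTI path for a segment-id volume
#'   (0 outside the pathway).
#' @param mask optional `tract_mask` restricting the label volume.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, label_volume_path = NULL,
                           mask = NULL) {
  rois <- partition_rois(segments)
  seg <- segments$slice_segment
  df <- data.frame(slice_index = seq_along(seg) - 1L,
                   ap_mm = segments$slice_ap_mm,
                   segment_id = seg,
                   roi_label = rois$roi[match(seg, rois$segment)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(label_volume_path)) {
    grid <- segments$grid
    lab <- array(0L, dim = grid$dims)
    sl <- slice_of_index(grid$dims, grid$ap_axis)
    val <- seg[sl]
    val[is.na(val)] <- 0L
    lab[] <- val
    if (!is.null(mask)) lab[!mask] <- 0L
    attr(lab, "grid") <- grid
    write_nifti(lab, label_volume_path)
  }
  invisible(path)
}
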