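#' Per-slice along-tract profile
#'
#' For each AP slice, the mean within the tract mask of FA, MD and the
#' three tissue fractions, plus the number of voxels containing at least
#' one fibre and the maximum fibre count normalized by the seed voxel
#' count. Voxels failing the scalar validity bounds (FA outside (0,1), MD
#' outside (0, 0.005)) are excluded from the FA/MD means but retained for
#' the fraction means. Slices with no in-mask voxels yield NA, not zero.
#'
#' @param scalars a `scalar_maps` object ([fa_md()] output).
#' @param fractions compartment fractions (x, y, z, 4).
#' @param density a [density_map].
#' @param mask a `tract_mask`.
#' @param landmarks a [landmarks] object (provides the seed voxel count).
#' @return a `slice_profile` data.frame: slice_index (0-based), ap_mm, fa,
#'   md, ncsf, ngm, nwm, n_vox (in-mask voxels), n_valid (in-mask voxels
#'   passing validity), n_fibre_vox, max_fibre_norm.
#' @export
slice_profile <- function(scalars, fractions, density, mask, landmarks) {
  grid <- grid_of(mask)
  if (sum(mask) == 0) stop("tract mask is empty")
  ap <- grid$ap_axis
  sl <- slice_of_index(grid$dims, ap)
  nsl <- grid$dims[ap]
  valid <- scalars$valid
  m <- as.logical(mask)
  mv <- m & valid

  slice_mean <- function(x, keep) {
    x[!keep] <- 0                       # NaN outside the kept set must not
    s <- tapply_sum(x, sl, nsl)         # poison the slice sums
    n <- tapply_sum(keep, sl, nsl)
    ifelse(n > 0, s / n, NA_real_)
  }
  n_vox <- tapply_sum(m, sl, nsl)
  out <- data.frame(
    slice_index = seq_len(nsl) - 1L,
    ap_mm = ap_slice_centers(grid),
    fa = slice_mean(as.numeric(scalars$fa), mv),
    md = slice_mean(as.numeric(scalars$md), mv),
    ncsf = slice_mean(as.numeric(fractions[, , , 3]), m),
    ngm = slice_mean(as.numeric(fractions[, , , 2]), m),
    nwm = slice_mean(as.numeric(fractions[, , , 1]), m),
    n_vox = n_vox,
    n_valid = tapply_sum(mv, sl, nsl),
    n_fibre_vox = tapply_sum(m & density > 0, sl, nsl),
    max_fibre_norm = tapply_max(as.numeric(density) * m, sl, nsl) /
      landmarks$seed_count)
  class(out) <- c("slice_profile", "data.frame")
  out
}

tapply_sum <- function(x, group, ngroup) {
  as.numeric(rowsum(as.numeric(x), group, reorder = TRUE)[
    match(seq_len(ngroup), sort(unique(group))), 1])
}

tapply_max <- function(x, group, ngroup) {
  out <- rep(0, ngroup)
  agg <- tapply(x, group, max)
  out[as.integer(names(agg))] <- agg
  out
}

#' Segment and ROI means from a slice profile
#'
#' Segment values are means of slice means weighted by each slice's in-mask
#' voxel count; ROI values are computed the same way over all the ROI's
#' slices. Segments whose slices are all missing stay missing.
#'
#' @param profile a `slice_profile`.
#' @param segments a `segment_assignment`.
#' @param rois an `roi_partition` (default: [partition_rois()] of
#'   `segments`).
#' @param subject,group,tract optional labels attached to the output.
#' @return a `segment_stats` data.frame: subject, group, tract, level
#'   (`"segment"` or `"roi"`), unit (segment id or ROI name), one column
#'   per variable (fa, md, ncsf, ngm, nwm), and n_vox.
#' @export
segment_means <- function(profile, segments, rois = partition_rois(segments),
                          subject = "S1", group = NA_character_,
                          tract = NA_character_) {
  seg <- segments$slice_segment
  vars <- c("fa", "md", "ncsf", "ngm", "nwm")
  wmean <- function(rows) {
    w <- profile$n_vox[rows]
    vapply(vars, function(v) {
      x <- profile[[v]][rows]
      ok <- !is.na(x) & w > 0
      if (!any(ok)) return(NA_real_)
      sum(x[ok] * w[ok]) / sum(w[ok])
    }, numeric(1))
  }
  seg_rows <- lapply(seq_len(segments$n_post + segments$n_pre),
                     function(s) which(!is.na(seg) & seg == s))
  seg_tab <- t(vapply(seg_rows, wmean, numeric(length(vars))))
  roi_names <- unique(rois$roi)
  roi_rows <- lapply(roi_names, function(r)
    which(!is.na(seg) & seg %in% rois$segment[rois$roi == r]))
  roi_tab <- t(vapply(roi_rows, wmean, numeric(length(vars))))
  out <- data.frame(
    subject = subject, group = group, tract = tract,
    level = c(rep("segment", nrow(seg_tab)), rep("roi", nrow(roi_tab))),
    unit = c(as.character(seq_len(nrow(seg_tab))), roi_names),
    rbind(seg_tab, roi_tab),
    n_vox = c(vapply(seg_rows, function(r) sum(profile$n_vox[r]), numeric(1)),
              vapply(roi_rows, function(r) sum(profile$n_vox[r]), numeric(1))),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("segment_stats", "data.frame")
  out
}

#' Welch's t-test from group summaries
#'
#' `t = (m1 - m2) / sqrt(sd1^2/n1 + sd2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @param m1,sd1,n1 mean, standard deviation and size of group 1.
#' @param m2,sd2,n2 mean, standard deviation and size of group 2.
#' @return a list with `t`, `df`, `p`. Vectorized over rows.
#' @export
welch_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (any(n1 < 2) || any(n2 < 2)) stop("Welch's t-test needs n >= 2 per group")
  if (any(sd1 < 0) || any(sd2 < 0)) stop("standard deviations must be >= 0")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  if (any(v1 + v2 == 0)) stop("both group variances are zero: t undefined")
  se <- sqrt(v1 + v2)
  t <- (m1 - m2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Hochberg step-up familywise error control
#'
#' Sorts the m p-values ascending and finds the largest k with
#' `p(k) <= alpha / (m - k + 1)`; the hypotheses with the k smallest
#' p-values are rejected. Ties are broken by stable original order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha familywise error rate (default 0.05).
#' @return logical rejection flags in the original order (empty input gives
#'   an empty vector).
#' @export
hochberg <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) return(logical(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  m <- length(pvalues)
  ord <- order(pvalues)                     # stable for ties
  ps <- pvalues[ord]
  ok <- ps <= alpha / (m - seq_len(m) + 1L)
  k <- if (any(ok)) max(which(ok)) else 0L
  flags <- logical(m)
  if (k > 0) flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Group comparison over a declared test family
#'
#' One Welch test per (variable, segment-or-ROI) in the family, with
#' Hochberg correction applied within the family; the family size is
#' recorded in the output. Subjects with missing values are dropped
#' pairwise per test and per-test group sizes are reported.
#'
#' @param stats a `segment_stats` data.frame (rows from several subjects;
#'   `group` must hold exactly two labels).
#' @param level which rows form the family: `"roi"` (default; with the
#'   five Table-style ROIs x five variables this is a 25-test family) or
#'   `"segment"`.
#' @param variables variables tested (default fa, md, ncsf, ngm, nwm).
#' @param alpha familywise error rate (default 0.05).
#' @param groups optional length-2 character giving the group order
#'   (group 1 minus group 2); defaults to sorted unique labels.
#' @return a `group_table` data.frame: variable, unit, m1, sd1, n1, m2,
#'   sd2, n2, t, df, p, fwe_reject, family_size, alpha.
#' @export
group_compare <- function(stats, level = c("roi", "segment"),
                          variables = c("fa", "md", "ncsf", "ngm", "nwm"),
                          alpha = 0.05, groups = NULL) {
  level <- match.arg(level)
  df <- stats[stats$level == level, , drop = FALSE]
  if (is.null(groups)) groups <- sort(unique(df$group))
  if (length(groups) != 2L) stop("exactly two groups are required")
  # a tract may contribute several rows per subject/unit (e.g. chiasm from
  # both tracts); average within subject first
  units <- unique(df$unit)
  rows <- list()
  for (v in variables) for (u in units) {
    sub <- df[df$unit == u, c("subject", "group", v)]
    names(sub)[3] <- "value"
    agg <- stats::aggregate(value ~ subject + group, data = sub, FUN = mean,
                            na.rm = TRUE, na.action = stats::na.pass)
    agg <- agg[is.finite(agg$value), , drop = FALSE]
    x1 <- agg$value[agg$group == groups[1]]
    x2 <- agg$value[agg$group == groups[2]]
    if (length(x1) < 2 || length(x2) < 2)
      stop(sprintf("group with fewer than 2 subjects for %s / %s", v, u))
    w <- welch_from_summary(mean(x1), stats::sd(x1), length(x1),
                            mean(x2), stats::sd(x2), length(x2))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, unit = u,
      m1 = mean(x1), sd1 = stats::sd(x1), n1 = length(x1),
      m2 = mean(x2), sd2 = stats::sd(x2), n2 = length(x2),
      t = w$t, df = w$df, p = w$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$fwe_reject <- hochberg(out$p, alpha)
  out$family_size <- nrow(out)
  out$alpha <- alpha
  attr(out, "groups") <- groups
  class(out) <- c("group_table", "data.frame")
  out
}

#' Write a group comparison table as TSV
#' @param x a `group_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
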