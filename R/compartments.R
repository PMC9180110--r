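#' Add the background compartment to three-tissue intensities
#'
#' Multi-shell multi-tissue spherical deconvolution yields three raw
#' compartment intensities per voxel (WM-like, GM-like, CSF-like). Voxels
#' whose total intensity falls short of a small threshold contain tissue
#' that generates no MR signal (bone, air) or no tissue at all; the
#' shortfall is assigned to a fourth "background" compartment so that
#' normalization is well defined everywhere.
#'
#' @param intensities a 4-D array (x, y, z, 3) of raw WM, GM, CSF
#'   intensities in that order (signal units, non-negative), or a list with
#'   elements `wm`, `gm`, `csf` of identical 3-D arrays.
#' @param threshold total-intensity floor in signal units (default 0.075,
#'   on the scale of the deconvolution output).
#' @return a 4-D array (x, y, z, 4) of raw components WM, GM, CSF, BG, with
#'   any `voxel_grid` attribute carried over.
#' @export
add_background <- function(intensities, threshold = 0.075) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("`threshold` must be a positive scalar")
  grid <- attr(intensities, "grid", exact = TRUE)
  if (is.list(intensities) && !is.null(intensities$wm)) {
    if (is.null(grid)) grid <- attr(intensities$wm, "grid", exact = TRUE)
    d <- dim(intensities$wm)
    intensities <- array(c(intensities$wm, intensities$gm, intensities$csf),
                         dim = c(d, 3L))
  }
  d <- dim(intensities)
  if (length(d) != 4L || d[4] != 3L)
    stop("`intensities` must be an (x, y, z, 3) array or wm/gm/csf list")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("raw compartment intensities must be finite and non-negative")
  total <- intensities[, , , 1] + intensities[, , , 2] + intensities[, , , 3]
  bg <- pmax(0, threshold - total)
  out <- array(c(intensities, bg), dim = c(d[1:3], 4L))
  attr(out, "grid") <- grid
  attr(out, "threshold") <- threshold
  out
}

#' Normalize four raw components to unit-sum compartment fractions
#'
#' Each component is divided by `max(total_tissue, threshold)` where
#' `total_tissue` is the WM+GM+CSF sum: at or above the threshold this is
#' ordinary division by the total, below it the background component fills
#' the voxel to exactly the threshold, making the fractions continuous in
#' the input. The four fractions (nWM, nGM, nCSF, nBG) sum to one at every
#' voxel.
#'
#' @param raw a 4-D array (x, y, z, 4) of WM, GM, CSF, BG raw components,
#'   as produced by [add_background()].
#' @param threshold the same floor used by [add_background()]; defaults to
#'   the value recorded on `raw`.
#' @return a 4-D array (x, y, z, 4) of fractions in order nWM, nGM, nCSF,
#'   nBG, class `compartment_fractions`.
#' @export
normalize_fractions <- function(raw, threshold = attr(raw, "threshold", exact = TRUE)) {
  if (is.null(threshold)) threshold <- 0.075
  d <- dim(raw)
  if (length(d) != 4L || d[4] != 4L)
    stop("`raw` must be an (x, y, z, 4) array (run add_background first)")
  total <- raw[, , , 1] + raw[, , , 2] + raw[, , , 3]
  denom <- pmax(total, threshold)
  out <- array(0, dim = d)
  for (c in 1:4) out[, , , c] <- raw[, , , c] / denom
  attr(out, "grid") <- attr(raw, "grid", exact = TRUE)
  class(out) <- c("compartment_fractions", class(out))
  out
}

#' One-step compartment-fraction normalization
#'
#' Convenience wrapper: [add_background()] then [normalize_fractions()].
#'
#' @inheritParams add_background
#' @return see [normalize_fractions()].
#' @export
compartment_fractions <- function(intensities, threshold = 0.075) {
  normalize_fractions(add_background(intensities, threshold), threshold)
}

#' Extract one named fraction volume
#' @param fractions output of [normalize_fractions()].
#' @param which one of `"nWM"`, `"nGM"`, `"nCSF"`, `"nBG"`.
#' @return a 3-D array with the grid attribute carried over.
#' @export
fraction_volume <- function(fractions, which = c("nWM", "nGM", "nCSF", "nBG")) {
  which <- match.arg(which)
  i <- match(which, c("nWM", "nGM", "nCSF", "nBG"))
  out <- fractions[, , , i]
  attr(out, "grid") <- attr(fractions, "grid", exact = TRUE)
  out
}
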