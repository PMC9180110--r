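#' Diffusion-weighting scheme
#'
#' Holds the b-value (s mm^-2) and unit gradient direction of each DWI
#' volume. At least one b=0 volume and at least six non-collinear b>0
#' directions (a full-rank tensor design) are required.
#'
#' @param bvals numeric vector of b-values, one per volume.
#' @param bvecs numeric n x 3 matrix of gradient directions; rows with
#'   b > 0 are normalized to unit length.
#' @return an object of class `dwi_scheme`.
#' @export
dwi_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  if (is.null(dim(bvecs))) bvecs <- matrix(bvecs, ncol = 3)
  if (nrow(bvecs) != length(bvals)) stop("bvals and bvecs disagree in length")
  if (any(!is.finite(bvals)) || any(bvals < 0)) stop("b-values must be finite and >= 0")
  if (!any(bvals == 0)) stop("scheme needs at least one b = 0 volume")
  dwi <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(dwi & (nrm == 0 | !is.finite(nrm))))
    stop("b > 0 volumes need nonzero finite gradient directions")
  bvecs[dwi, ] <- bvecs[dwi, , drop = FALSE] / nrm[dwi]
  X <- tensor_design(bvals[dwi], bvecs[dwi, , drop = FALSE])
  if (qr(X)$rank < 6L)
    stop("gradient directions are collinear: tensor design is rank deficient")
  structure(list(bvals = bvals, bvecs = bvecs, n = length(bvals)),
            class = "dwi_scheme")
}

#' @export
print.dwi_scheme <- function(x, ...) {
  tb <- table(x$bvals)
  cat("dwi_scheme:", paste(sprintf("b=%s (n=%s)", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

# Rows: -b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz); multiplying the
# stacked tensor (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) gives log(S/S0).
tensor_design <- function(bvals, bvecs) {
  g <- bvecs
  -bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

#' Read an FSL-dialect gradient table
#'
#' `bvals` is one whitespace-separated row of b-values; `bvecs` is three
#' rows (x, y, z components), one column per volume.
#'
#' @param bval_path,bvec_path text file paths.
#' @return a [dwi_scheme].
#' @export
read_scheme_fsl <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  v <- scan(bvec_path, quiet = TRUE)
  if (length(v) != 3L * length(bvals)) stop("bvec file does not match bval count")
  dwi_scheme(bvals, t(matrix(v, nrow = 3, byrow = TRUE)))
}

#' The acquisition scheme the pipeline was designed around
#'
#' Four shells: b = 0 (n=8), 300 (n=8), 1000 (n=30), 2000 (n=64) s mm^-2,
#' with deterministic golden-spiral directions per shell.
#'
#' @return a [dwi_scheme] with 110 volumes.
#' @export
default_dwi_scheme <- function() {
  shells <- c(0, 300, 1000, 2000)
  counts <- c(8L, 8L, 30L, 64L)
  bvals <- rep(shells, counts)
  dirs <- do.call(rbind, lapply(counts, golden_spiral_directions))
  dirs[bvals == 0, ] <- 0
  dwi_scheme(bvals, dirs)
}

golden_spiral_directions <- function(n) {
  i <- seq_len(n) - 1L
  z <- (2 * i + 1) / n - 1
  theta <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Fit diffusion tensors by log-linear least squares
#'
#' The b = 0 volumes are averaged into a per-voxel S0; log(S/S0) of the
#' diffusion-weighted volumes is regressed on the six tensor design
#' coefficients by ordinary least squares. Signals at or below zero are
#' clamped to a small positive epsilon before the log, and negative fitted
#' eigenvalues are deliberately not clipped -- downstream validity masking
#' excludes the affected voxels instead.
#'
#' @param dwi 4-D array (x, y, z, volumes).
#' @param scheme a [dwi_scheme] matching the 4th dimension.
#' @param eps clamp value for non-positive signals (default 1e-10).
#' @return a `tensor_field`: 4-D array (x, y, z, 6) of per-voxel symmetric
#'   tensor components in order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz (mm^2 s^-1).
#' @export
fit_tensor <- function(dwi, scheme, eps = 1e-10) {
  d <- dim(dwi)
  if (length(d) != 4L || d[4] != scheme$n)
    stop("DWI volume count does not match the scheme")
  nvox <- prod(d[1:3])
  S <- matrix(dwi, nrow = nvox)
  b0 <- scheme$bvals == 0
  s0 <- rowMeans(S[, b0, drop = FALSE])
  Sw <- S[, !b0, drop = FALSE]
  Y <- log(pmax(Sw, eps) / pmax(s0, eps))    # nvox x ndwi
  X <- tensor_design(scheme$bvals[!b0], scheme$bvecs[!b0, , drop = FALSE])
  beta <- Y %*% X %*% solve(crossprod(X))    # nvox x 6
  out <- array(beta, dim = c(d[1:3], 6L))
  attr(out, "grid") <- attr(dwi, "grid", exact = TRUE)
  class(out) <- c("tensor_field", class(out))
  out
}

#' Eigenvalues of a tensor field
#'
#' Closed-form eigenvalues of each symmetric 3x3 tensor (trigonometric
#' method), vectorized over voxels.
#'
#' @param tensor a `tensor_field` (x, y, z, 6) array.
#' @return a matrix (voxels x 3) of eigenvalues in non-increasing order;
#'   voxels in column-major array order.
#' @export
tensor_eigenvalues <- function(tensor) {
  d <- dim(tensor)
  m <- matrix(tensor, ncol = 6L)
  xx <- m[, 1]; yy <- m[, 2]; zz <- m[, 3]
  xy <- m[, 4]; xz <- m[, 5]; yz <- m[, 6]
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  safe_p <- ifelse(p > 0, p, 1)
  bxx <- (xx - q) / safe_p; byy <- (yy - q) / safe_p; bzz <- (zz - q) / safe_p
  bxy <- xy / safe_p; bxz <- xz / safe_p; byz <- yz / safe_p
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  out <- cbind(e1, e2, e3, deparse.level = 0)
  iso <- p == 0                             # already diagonal-equal case
  out[iso, ] <- q[iso]
  out
}

#' FA and MD scalar maps from a tensor field
#'
#' MD is trace(D)/3; FA is `sqrt(3/2) * ||lambda - mean|| / ||lambda||` over
#' the eigenvalue vector. The zero tensor has undefined FA (NaN), which the
#' validity mask excludes.
#'
#' @param tensor a `tensor_field`.
#' @return a `scalar_maps` object: list with 3-D arrays `fa`, `md` and the
#'   logical array `valid` (see [validity_mask()]).
#' @export
fa_md <- function(tensor) {
  d <- dim(tensor)[1:3]
  ev <- tensor_eigenvalues(tensor)
  md <- rowMeans(ev)
  dev2 <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  nrm2 <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- sqrt(1.5) * sqrt(dev2 / nrm2)       # NaN where ||lambda|| = 0
  fa <- array(fa, dim = d)
  md <- array(md, dim = d)
  grid <- attr(tensor, "grid", exact = TRUE)
  attr(fa, "grid") <- grid; attr(md, "grid") <- grid
  out <- structure(list(fa = fa, md = md), class = "scalar_maps")
  out$valid <- validity_mask(out)
  out
}

#' Voxel validity mask for scalar maps
#'
#' Tensor estimation sometimes fails at the voxel level; values outside a
#' fixed physical range are treated as inaccurate and excluded from mean
#' calculations: FA outside the open interval (0, 1), MD outside the open
#' interval (0, 0.005) mm^2 s^-1.
#'
#' @param scalars a `scalar_maps` object (or list with `fa`, `md` arrays).
#' @param md_max upper MD bound in mm^2 s^-1 (default 0.005).
#' @return logical array, TRUE where both scalars are in range.
#' @export
validity_mask <- function(scalars, md_max = 0.005) {
  fa <- scalars$fa; md <- scalars$md
  v <- is.finite(fa) & is.finite(md) & fa > 0 & fa < 1 & md > 0 & md < md_max
  v[is.na(v)] <- FALSE
  attr(v, "grid") <- attr(fa, "grid", exact = TRUE)
  v
}

#' Noise-free DWI signal from a tensor field
#'
#' Monoexponential forward model `S = S0 * exp(-b g' D g)` per volume.
#'
#' @param tensor a `tensor_field` (x, y, z, 6).
#' @param s0 scalar or 3-D array of non-diffusion-weighted signal.
#' @param scheme a [dwi_scheme].
#' @return 4-D array (x, y, z, volumes).
#' @export
dwi_signal <- function(tensor, s0, scheme) {
  d <- dim(tensor)[1:3]
  nvox <- prod(d)
  D <- matrix(tensor, nrow = nvox)
  X <- tensor_design(scheme$bvals, scheme$bvecs)  # n x 6, gives log(S/S0)
  logatt <- D %*% t(X)                            # nvox x n
  S <- as.numeric(s0) * exp(logatt)
  out <- array(S, dim = c(d, scheme$n))
  attr(out, "grid") <- attr(tensor, "grid", exact = TRUE)
  out
}
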