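test_that("density map counts binary visitation per streamline", {
  g <- voxel_grid(c(10, 10, 5), voxel_size = 2)
  # straight streamline along a voxel row of length 5
  line <- cbind(seq(0, 8, by = 0.5), 4, 4)
  s <- streamline_set(list(line))
  d <- density_map(s, g)
  expect_equal(sum(d > 0), 5)
  expect_true(all(d[d > 0] == 1))
  # two identical streamlines: counts double
  d2 <- density_map(streamline_set(list(line, line)), g)
  expect_true(all(d2[d2 > 0] == 2))
  expect_equal(which(d2 > 0), which(d > 0))
})

test_that("a streamline re-entering a voxel counts once (brute-force check)", {
  g <- voxel_grid(c(10, 10, 5), voxel_size = 2)
  # out and back: leaves voxel row then re-enters the first voxels
  path <- cbind(c(0, 6, 6, 0), c(4, 4, 7, 7), 4)
  d <- density_map(streamline_set(list(path)), g)
  expect_true(all(d[d > 0] == 1))
  # brute-force: enumerate visited voxels by dense point sampling
  dense <- resampled <- apply(path, 2, function(col)
    approx(seq_len(4), col, xout = seq(1, 4, by = 0.001))$y)
  keys <- unique(world_to_voxel(g, dense) %*% c(1, 10, 100))
  expect_equal(sum(d > 0), length(keys))
  # u-turn inside one voxel row
  uturn <- cbind(c(0, 5, 0), c(4, 4.4, 4.8), 4)
  du <- density_map(streamline_set(list(uturn)), g)
  expect_true(all(du[du > 0] == 1))
})

test_that("slicewise 40% rule keeps ties and ignores empty slices", {
  g <- voxel_grid(c(5, 3, 1), voxel_size = 2)
  d <- array(0L, dim = c(5, 3, 1))
  d[1:3, 2, 1] <- c(10L, 4L, 3L)               # one populated slice
  attr(d, "grid") <- g
  m <- slicewise_threshold(d)
  expect_equal(which(m), which(array(c(rep(FALSE, 5),
                                       c(TRUE, TRUE, FALSE, FALSE, FALSE),
                                       rep(FALSE, 5)), dim = c(5, 3, 1))))
  # single nonzero voxel survives; empty slices contribute nothing
  expect_equal(sum(m[, 1, ]), 0)
  d2 <- array(0L, dim = c(5, 3, 1)); d2[3, 3, 1] <- 1L
  attr(d2, "grid") <- g
  expect_equal(which(slicewise_threshold(d2)), which(d2 > 0))
})

test_that("slicewise threshold agrees with brute force on random grids", {
  set.seed(5)
  for (i in 1:10) {
    dims <- c(sample(3:20, 1), sample(3:20, 1), sample(3:20, 1))
    g <- voxel_grid(dims, voxel_size = 2)
    d <- array(rpois(prod(dims), 0.7), dim = dims)
    attr(d, "grid") <- g
    m <- slicewise_threshold(d)
    brute <- array(FALSE, dim = dims)
    for (j in seq_len(dims[2])) {
      sl <- d[, j, ]
      mx <- max(sl)
      if (mx > 0) brute[, j, ] <- d[, j, ] > 0 & !(d[, j, ] < 0.4 * mx)
    }
    expect_equal(as.logical(m), as.logical(brute))
    # invariance under positive integer scaling of counts
    d3 <- d * 3L; attr(d3, "grid") <- g
    expect_equal(as.logical(slicewise_threshold(d3)), as.logical(m))
  }
})

test_that("exclusion mask thresholds nBG and is monotone in the threshold", {
  f <- tfrac
  e15 <- exclusion_mask(f, 0.15)
  expect_equal(as.logical(e15), as.logical(f[, , , 4] >= 0.15))
  e10 <- exclusion_mask(f, 0.10)
  expect_true(all(e15[e15] %in% e10[e15]))     # lower threshold excludes more
  expect_true(all(which(e15) %in% which(e10)))
  expect_true(all(exclusion_mask(f, 0)))
  expect_error(exclusion_mask(f, 1.2), "0, 1")
})

test_that("continuity_check matches spec cases and the BFS oracle", {
  tube <- make_tube()
  expect_true(continuity_check(tube$mask, tube$landmarks))
  severed <- tube$mask
  severed[, 10, ] <- FALSE                     # remove one slice entirely
  attr(severed, "grid") <- tube$grid
  expect_false(continuity_check(severed, tube$landmarks))
  # corner-touching diagonal voxels are connected under 26-connectivity
  g <- voxel_grid(c(3, 3, 3), 2)
  m <- array(FALSE, dim = c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  attr(m, "grid") <- g
  lm <- landmarks(matrix(c(0L, 0L, 0L), 1), matrix(c(1L, 1L, 1L), 1), 0L, g,
                  lgn_mm = 2, chiasm_mm = 1, orbit_mm = 0)
  expect_true(continuity_check(m, lm))
})

test_that("continuity agrees with exhaustive BFS on random small grids", {
  set.seed(9)
  for (i in 1:15) {
    dims <- c(sample(4:12, 1), sample(6:20, 1), sample(4:12, 1))
    g <- voxel_grid(dims, voxel_size = 2)
    m <- array(runif(prod(dims)) < 0.25, dim = dims)
    seed_idx <- matrix(c(sample(dims[1], 1) - 1L, dims[2] - 1L,
                         sample(dims[3], 1) - 1L), 1)
    way_idx <- matrix(c(sample(dims[1], 1) - 1L, 0L,
                        sample(dims[3], 1) - 1L), 1)
    m[seed_idx + 1L] <- TRUE; m[way_idx + 1L] <- TRUE
    attr(m, "grid") <- g
    lm <- landmarks(seed_idx, way_idx, as.integer(dims[2] %/% 2), g,
                    lgn_mm = (dims[2] - 1) * 2, chiasm_mm = dims[2],
                    orbit_mm = 0)
    expect_equal(continuity_check(m, lm), bfs_connected(m, seed_idx, way_idx),
                 info = sprintf("grid %s", paste(dims, collapse = "x")))
  }
})

test_that("refinement loop stops at t0 when nothing blocks the tract", {
  mask <- refine_until_continuous(tdens, tfrac, tlm)
  expect_equal(attr(mask, "threshold"), 0.15)
  expect_true(continuity_check(mask, tlm))
  # refine output never exceeds the slicewise-threshold mask
  base <- slicewise_threshold(tdens)
  expect_true(all(which(mask) %in% which(base)))
  expect_true(all(which(base) %in% which(tdens > 0)))
})

test_that("refinement walks to the designed bridge threshold", {
  # a straight tube whose middle slice has nBG = 0.498: it is excluded
  # whenever t <= 0.498, so the decreasing direction can never reconnect it
  # and the fallback (increasing) stops at the first t above 0.498, t = 0.50
  tube <- make_tube()
  g <- tube$grid
  d <- array(0L, dim = g$dims)
  d[tube$mask] <- 5L
  attr(d, "grid") <- g
  raw <- array(0, dim = c(g$dims, 3))
  raw[, , , 1] <- 0.5                          # tissue everywhere: nBG = 0
  bridge <- 11L                                # 0-based slice 10 (chiasm)
  raw[, bridge, , 1] <- 0.075 * (1 - 0.498)    # total -> nBG exactly 0.498
  attr(raw, "grid") <- g
  f <- compartment_fractions(raw)
  expect_equal(unique(as.numeric(f[, bridge, , 4])), 0.498, tolerance = 1e-12)
  m <- refine_until_continuous(d, f, tube$landmarks, t0 = 0.15, step = 0.01)
  expect_equal(attr(m, "threshold"), 0.50, tolerance = 1e-6)
  expect_true(continuity_check(m, tube$landmarks))
  # disconnected at every threshold: explicit failure naming the label
  d2 <- d; d2[, bridge, ] <- 0L; attr(d2, "grid") <- g
  expect_error(refine_until_continuous(d2, f, tube$landmarks, label = "P1 left"),
               "not continuous.*P1 left")
})

test_that("piecewise union restores continuity and keeps merged landmarks", {
  tube <- make_tube()
  g <- tube$grid
  lm <- tube$landmarks
  chiasm <- lm$chiasm_slice
  pre <- tube$mask & slice_range_mask(g, 0L, chiasm)
  post <- tube$mask & slice_range_mask(g, chiasm, g$dims[2] - 1L)
  attr(pre, "grid") <- g; attr(post, "grid") <- g
  attr(pre, "landmarks") <- lm; attr(post, "landmarks") <- lm
  expect_false(continuity_check(pre, lm))      # neither piece alone spans
  expect_false(continuity_check(post, lm))
  uni <- piecewise_union(pre, post)
  expect_true(continuity_check(uni, lm))
  expect_equal(as.logical(uni), as.logical(tube$mask))
  # idempotence and identity
  expect_equal(as.logical(piecewise_union(uni, uni)), as.logical(uni))
  empty <- array(FALSE, dim = g$dims); attr(empty, "grid") <- g
  expect_equal(as.logical(piecewise_union(uni, empty)), as.logical(uni))
  # grid mismatch rejected
  other <- array(FALSE, dim = c(4, 4, 4))
  attr(other, "grid") <- voxel_grid(c(4, 4, 4))
  expect_error(piecewise_union(uni, other), "different grids")
})
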