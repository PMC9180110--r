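test_that("welch_from_summary matches published group comparisons", {
  # null identity
  w <- welch_from_summary(0.4, 0.1, 8, 0.4, 0.2, 13)
  expect_equal(w$t, 0); expect_equal(w$p, 1)
  # recomputation from printed cohort summaries (n = 8 vs 13); the +-0.15
  # slack absorbs the 2-3-decimal rounding of the printed inputs
  gp <- group_profiles()
  printed_t <- c(-7.49, -5.25, -4.67, -3.57, -5.33,   # FA rows
                 1.49, 0.84, 0.07, -0.32, 1.77,       # MD rows
                 1.26, 0.22, -0.36, -1.01, 1.23,      # nCSF rows
                 -5.69, -4.37, -4.28, -2.72, -2.65,   # nGM rows
                 5.56, 3.83, 4.50, 4.89, 5.43)        # nWM rows
  w <- welch_from_summary(gp$m_patient, gp$sd_patient, 8,
                          gp$m_control, gp$sd_control, 13)
  expect_true(all(abs(w$t - printed_t) < 0.15))
  # frozen spot checks of the two quoted rows
  expect_equal(w$t[1], -7.49, tolerance = 0.15 / 7.49)
  expect_equal(w$t[16], -5.69, tolerance = 0.15 / 5.69)
})

test_that("welch statistics are antisymmetric and validated", {
  set.seed(4)
  for (i in 1:20) {
    m <- rnorm(2); s <- runif(2, 0.01, 2); n <- sample(2:30, 2, replace = TRUE)
    a <- welch_from_summary(m[1], s[1], n[1], m[2], s[2], n[2])
    b <- welch_from_summary(m[2], s[2], n[2], m[1], s[1], n[1])
    expect_equal(a$t, -b$t)
    expect_equal(a$df, b$df)
    expect_equal(a$p, b$p)
  }
  expect_error(welch_from_summary(1, 0.1, 1, 2, 0.1, 5), "n >= 2")
  expect_error(welch_from_summary(1, 0, 5, 2, 0, 5), "variances")
})

test_that("hochberg reproduces hand-traced cases", {
  expect_equal(hochberg(rep(1, 5)), rep(FALSE, 5))
  # 0.04 <= 0.05/1 at k = 4: everything rejected
  expect_equal(hochberg(c(0.001, 0.02, 0.03, 0.04)), rep(TRUE, 4))
  # step-up can reject nothing: 0.04 > 0.05/2 and 0.9 > 0.05
  expect_equal(hochberg(c(0.04, 0.9)), c(FALSE, FALSE))
  expect_equal(hochberg(numeric(0)), logical(0))
  expect_error(hochberg(c(0.2, 1.1)), "0, 1")
  expect_error(hochberg(c(0.2), alpha = 0), "alpha")
})

test_that("hochberg agrees with brute force and dominates Bonferroni", {
  set.seed(17)
  grid01 <- seq(0, 1, by = 0.01)
  for (i in 1:2000) {
    m <- sample(1:8, 1)
    p <- sample(grid01, m, replace = TRUE)
    got <- hochberg(p)
    expect_identical(got, hochberg_brute(p))
    bonf <- p <= 0.05 / m
    expect_true(all(got[bonf]))                # Hochberg rejects a superset
  }
})

test_that("slice profiles mean over in-mask voxels with validity filtering", {
  g <- voxel_grid(c(3, 4, 1), 2)
  mask <- array(TRUE, dim = c(3, 4, 1)); attr(mask, "grid") <- g
  fa <- array(0.4, dim = c(3, 4, 1)); md <- array(1.5e-3, dim = c(3, 4, 1))
  fa[2, 2, 1] <- 1.0                            # invalid: open interval
  scal <- list(fa = fa, md = md)
  scal$valid <- validity_mask(scal)
  fr <- array(0, dim = c(3, 4, 1, 4))
  fr[, , , 1] <- array(rep(c(0.2, 0.4, 0.6), 4), dim = c(3, 4, 1))
  dens <- array(1L, dim = c(3, 4, 1)); attr(dens, "grid") <- g
  lm <- landmarks(matrix(c(1L, 3L, 0L), 1), matrix(c(1L, 0L, 0L), 1), 1L, g,
                  lgn_mm = 6, chiasm_mm = 3, orbit_mm = 0)
  prof <- slice_profile(scal, fr, dens, mask, lm)
  expect_equal(prof$fa, rep(0.4, 4))            # invalid voxel excluded
  expect_equal(prof$n_valid, c(3, 2, 3, 3))
  expect_equal(prof$nwm, rep(0.4, 4))           # arithmetic mean 0.2/0.4/0.6
  expect_equal(prof$n_fibre_vox, rep(3, 4))
  expect_equal(prof$max_fibre_norm, rep(1, 4))  # max 1 over 1 seed voxel
  # empty slices give NA, empty masks error
  mask2 <- mask; mask2[, 3, ] <- FALSE; attr(mask2, "grid") <- g
  prof2 <- slice_profile(scal, fr, dens, mask2, lm)
  expect_true(is.na(prof2$fa[3])); expect_true(is.na(prof2$nwm[3]))
  empty <- array(FALSE, dim = c(3, 4, 1)); attr(empty, "grid") <- g
  expect_error(slice_profile(scal, fr, dens, empty, lm), "empty")
})

test_that("segment means weight slices by voxel count", {
  prof <- data.frame(slice_index = 0:3, ap_mm = c(7, 5, 3, 1),
                     fa = c(0.3, 0.5, NA, 0.2), md = 1e-3,
                     ncsf = 0.2, ngm = 0.3, nwm = c(0.1, 0.2, 0.3, 0.4),
                     n_vox = c(30, 10, 0, 8), n_valid = c(30, 10, 0, 8),
                     n_fibre_vox = 1, max_fibre_norm = 1)
  segs <- list(slice_segment = c(1L, 1L, 2L, 2L), slice_ap_mm = prof$ap_mm,
               n_post = 1L, n_pre = 1L)
  class(segs) <- "segment_assignment"
  rois <- data.frame(segment = 1:2, roi = c("optic_tract", "optic_nerve"))
  sm <- segment_means(prof, segs, rois, subject = "S", group = "g", tract = "LR")
  seg_rows <- sm[sm$level == "segment", ]
  expect_equal(seg_rows$fa[1], (0.3 * 30 + 0.5 * 10) / 40)   # weighted mean
  expect_equal(seg_rows$fa[2], 0.2)             # NA slice dropped, not zeroed
  expect_equal(seg_rows$nwm[1], (0.1 * 30 + 0.2 * 10) / 40)
  # splitting a slice into two pseudo-slices with the same voxels is a no-op
  prof2 <- rbind(prof[1, ], prof[1, ], prof[-1, ])
  prof2$n_vox[1:2] <- c(18, 12); prof2$n_valid[1:2] <- c(18, 12)
  segs2 <- segs; segs2$slice_segment <- c(1L, segs$slice_segment)
  segs2$slice_ap_mm <- c(7, segs$slice_ap_mm)
  sm2 <- segment_means(prof2, segs2, rois)
  expect_equal(sm2$fa[sm2$level == "segment"], seg_rows$fa)
  # all-missing segment propagates NA
  prof3 <- prof; prof3$fa <- NA_real_
  sm3 <- segment_means(prof3, segs, rois)
  expect_true(all(is.na(sm3$fa)))
})

test_that("group_compare builds a corrected family and handles degeneracy", {
  mk_stats <- function(subject, group, values) {
    data.frame(subject = subject, group = group, tract = "LR", level = "roi",
               unit = names(values), fa = as.numeric(values),
               md = rnorm(length(values), 1.5, 0.1),
               ncsf = 0.2, ngm = 0.3, nwm = 0.4, n_vox = 10)
  }
  units <- c("optic_tract", "chiasm", "optic_nerve")
  set.seed(2)
  rows <- list()
  for (i in 1:5) rows[[i]] <- mk_stats(paste0("C", i), "control",
                                       setNames(rnorm(3, 0.4, 0.05), units))
  for (i in 1:5) rows[[5 + i]] <- mk_stats(paste0("P", i), "patient",
                                           setNames(rnorm(3, 0.2, 0.05), units))
  tab <- group_compare(do.call(rbind, rows), variables = c("fa", "md"))
  expect_equal(nrow(tab), 6)                    # 2 variables x 3 ROIs
  expect_equal(unique(tab$family_size), 6)
  expect_equal(tab$fwe_reject, hochberg(tab$p))
  expect_true(all(tab$fwe_reject[tab$variable == "fa"]))
  # identical within-group data in both groups: t = 0, nothing rejected
  same <- c(lapply(1:3, function(i) mk_stats(paste0("A", i), "g1",
                                             setNames(c(0.1, 0.2, 0.3) + i / 10, units))),
            lapply(1:3, function(i) mk_stats(paste0("B", i), "g2",
                                             setNames(c(0.1, 0.2, 0.3) + i / 10, units))))
  tab0 <- group_compare(do.call(rbind, same), variables = "fa")
  expect_true(all(tab0$t == 0))
  expect_false(any(tab0$fwe_reject))
  # fewer than two subjects per group is an error
  expect_error(group_compare(do.call(rbind, rows[c(1, 6)]), variables = "fa"),
               "fewer than 2")
})

test_that("simulated null families control the familywise error rate", {
  # two groups drawn from one distribution; FWE across simulated families
  set.seed(123)
  n_rep <- 400; m_tests <- 10
  fwe_hits <- 0L
  for (r in seq_len(n_rep)) {
    p <- vapply(seq_len(m_tests), function(i) {
      x <- rnorm(8); y <- rnorm(13)
      welch_from_summary(mean(x), sd(x), 8, mean(y), sd(y), 13)$p
    }, numeric(1))
    if (any(hochberg(p))) fwe_hits <- fwe_hits + 1L
  }
  rate <- fwe_hits / n_rep
  # binomial 99% upper bound around the nominal 0.05
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_rep))
})
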