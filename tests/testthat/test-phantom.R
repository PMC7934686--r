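test_that("gradient schemes have leading b0s and well-spread directions", {
  s30 <- makeScheme(30, 1, 1000)
  expect_equal(nVolumes(s30), 31)
  expect_equal(bValues(s30)[1], 0)
  expect_true(all(bValues(s30)[-1] == 1000))

  s48 <- makeScheme(48, 6, 1000)
  expect_equal(nVolumes(s48), 54)
  expect_equal(sum(bValues(s48) == 0), 6)

  # exhaustive pairwise angular separation of the 48 directions
  g <- bVectors(s48)[bValues(s48) > 0, ]
  dots <- tcrossprod(g)
  diag(dots) <- -1
  min_angle <- acos(max(pmin(dots[upper.tri(dots)], 1))) * 180 / pi
  expect_gt(min_angle, 10)

  expect_error(makeScheme(6, 1, 1000), "at least 7")
})

test_that("tensors reconstruct exactly from spectrum and direction", {
  iso <- tensorFromEigen(c(1e-3, 1e-3, 1e-3), c(0.3, 0.5, -0.2))
  expect_equal(iso, c(1e-3, 1e-3, 1e-3, 0, 0, 0), tolerance = 1e-15)

  ax <- tensorFromEigen(c(1.7e-3, 2e-4, 2e-4), c(1, 0, 0))
  expect_equal(ax, c(1.7e-3, 2e-4, 2e-4, 0, 0, 0), tolerance = 1e-15)

  set.seed(3)
  for (i in 1:10) {
    ev <- sort(runif(3, 1e-4, 2e-3), decreasing = TRUE)
    d <- rnorm(3)
    t6 <- tensorFromEigen(ev, d)
    D <- matrix(c(t6[1], t6[4], t6[5],
                  t6[4], t6[2], t6[6],
                  t6[5], t6[6], t6[3]), 3, 3)
    expect_equal(sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
                      decreasing = TRUE), ev, tolerance = 1e-12)
  }
  expect_error(tensorFromEigen(c(1, 1, 1) * 1e-3, c(0, 0, 0)), "nonzero")
})

test_that("the forward signal model matches hand evaluation", {
  sch <- gradientScheme(c(0, rep(1000, 7)),
                        rbind(c(0, 0, 0), diag(3),
                              cbind(sqrt(0.5), sqrt(0.5), 0),
                              cbind(sqrt(0.5), 0, sqrt(0.5)),
                              cbind(0, sqrt(0.5), sqrt(0.5)),
                              c(1, 0, 0)))
  D <- c(1.7e-3, 2e-4, 2e-4, 0, 0, 0)
  s <- predictSignal(D, sch, s0 = 1)
  expect_equal(s[1], 1)                           # b = 0 returns s0
  expect_equal(s[2], exp(-1.7), tolerance = 1e-12)

  iso <- c(7e-4, 7e-4, 7e-4, 0, 0, 0)
  si <- predictSignal(iso, sch, s0 = 2)
  expect_equal(sd(si[-1]), 0, tolerance = 1e-15)  # rotational symmetry
})

test_that("Rician noise has the Rayleigh floor and is reproducible", {
  x <- matrix(runif(20, 100, 200), 4)
  expect_identical(addRicianNoise(x, 0), x)
  expect_equal(addRicianNoise(x, 5, seed = 7), addRicianNoise(x, 5, seed = 7))

  z <- addRicianNoise(rep(0, 1e6), 1, seed = 42)
  expect_equal(mean(z), sqrt(pi / 2), tolerance = 0.01)
})

test_that("outlier injection corrupts only selected DWI volume-slice blocks", {
  fix <- single_tensor_volume(dims = c(4, 4, 3), snr = Inf)
  out0 <- injectOutliers(fix$volume, 0)
  expect_identical(signalArray(out0$volume), signalArray(fix$volume))
  expect_false(any(out0$mask))

  out <- injectOutliers(fix$volume, 0.15, dropout_factor = 0.3, seed = 2)
  expect_true(any(out$mask))
  b0 <- which(bValues(fix$volume) == 0)
  expect_false(any(out$mask[b0, ]))
  orig <- signalArray(fix$volume)
  corr <- signalArray(out$volume)
  expect_true(all(corr <= orig + 1e-12))
  for (v in seq_len(nrow(out$mask))) for (z in seq_len(ncol(out$mask))) {
    blk_o <- orig[, , z, v]; blk_c <- corr[, , z, v]
    if (out$mask[v, z]) expect_equal(blk_c, 0.3 * blk_o, tolerance = 1e-12)
    else expect_equal(blk_c, blk_o)
  }
})

test_that("cohort generation is reproducible and matches the group design", {
  spec <- small_phantom_spec()
  cx <- generateCohort(spec)
  expect_length(cx$volumes, 15)
  expect_equal(as.vector(table(cx$cohort$group)), c(6, 5, 4))
  expect_equal(sort(unname(regionNames(cx$atlas))), c("fornix", "wm_shell"))

  cx2 <- generateCohort(spec)
  expect_identical(signalArray(cx2$volumes[[3]]), signalArray(cx$volumes[[3]]))
  expect_identical(cx2$cohort, cx$cohort)
})

test_that("overlapping ROIs are rejected", {
  spec <- small_phantom_spec()
  spec@rois <- list(
    roiBox("a", c(2, 2, 2), c(6, 6, 6), evals = c(1e-3, 5e-4, 5e-4)),
    roiBox("b", c(5, 5, 5), c(9, 9, 7), evals = c(1e-3, 5e-4, 5e-4)))
  expect_error(generateCohort(spec), "overlapping ROIs")
})

test_that("group effects move true ROI FA to the calibrated targets", {
  # At the default AD anisotropy factor the design points are
  # HC ~ 0.714 and AD ~ 0.609 mean true fornix FA (between-subject jitter
  # slightly shrinks the noiseless values 0.726 / 0.62).
  spec <- small_phantom_spec(nPerGroup = c(HC = 40, MCI = 3, AD = 40), seed = 21)
  cx <- generateCohort(spec)
  roi <- atlasLabels(cx$atlas) == 1L
  fa_mean <- vapply(cx$truth$trueFA, function(m) mean(m[roi]), numeric(1))
  hc <- fa_mean[cx$cohort$group == "HC"]
  ad <- fa_mean[cx$cohort$group == "AD"]
  se <- sqrt(var(hc) / length(hc))
  expect_lt(abs(mean(hc) - 0.714), 3 * se + 0.01)
  expect_lt(abs(mean(ad) - 0.609), 3 * sqrt(var(ad) / length(ad)) + 0.01)
  expect_gt(mean(hc) - mean(ad), 0.05)

  # null configuration: no systematic group separation
  spec0 <- small_phantom_spec(nPerGroup = c(HC = 40, MCI = 3, AD = 40), seed = 22)
  spec0@groupEffects <- data.frame(roi = character(), group = character(),
                                   factor = numeric(), stringsAsFactors = FALSE)
  cx0 <- generateCohort(spec0)
  fa0 <- vapply(cx0$truth$trueFA, function(m) mean(m[roi]), numeric(1))
  d0 <- mean(fa0[cx0$cohort$group == "HC"]) - mean(fa0[cx0$cohort$group == "AD"])
  expect_lt(abs(d0), 3 * sd(fa0) * sqrt(2 / 40))
})

test_that("cognitive scores couple monotonically to true ROI FA", {
  spec <- small_phantom_spec(nPerGroup = c(HC = 30, MCI = 3, AD = 30), seed = 31)
  cx <- generateCohort(spec)
  roi <- atlasLabels(cx$atlas) == 1L
  fa_mean <- vapply(cx$truth$trueFA, function(m) mean(m[roi]), numeric(1))
  expect_gt(cor(fa_mean, cx$cohort$MMSE, method = "spearman"), 0.3)
  expect_lt(cor(fa_mean, cx$cohort$ADAS, method = "spearman"), -0.3)
  # group means near the emulated clinical targets
  expect_equal(mean(cx$cohort$MMSE[cx$cohort$group == "HC"]), 29.3,
               tolerance = 0.05 * 29.3)
  expect_equal(mean(cx$cohort$MMSE[cx$cohort$group == "AD"]), 23.7,
               tolerance = 0.1 * 23.7)
})
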