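test_that("design matrix rows match the b-matrix expansion", {
  sch <- gradientScheme(c(0, rep(1000, 7)),
                        rbind(c(0, 0, 0), diag(3),
                              c(sqrt(0.5), sqrt(0.5), 0),
                              c(sqrt(0.5), 0, sqrt(0.5)),
                              c(0, sqrt(0.5), sqrt(0.5)),
                              c(0, 0, 1)))
  X <- buildDesign(sch)
  expect_equal(unname(X[1, ]), c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(X[2, ]), c(1, -1000, 0, 0, 0, 0, 0))
  expect_equal(unname(X[5, ]), c(1, -500, -500, 0, -1000, 0, 0),
               tolerance = 1e-12)
})

test_that("coplanar direction sets are rejected as degenerate", {
  ang <- seq(0, pi, length.out = 9)[-9]
  g <- cbind(cos(ang), sin(ang), 0)      # all in the x-y plane
  sch <- gradientScheme(c(0, rep(1000, 8)), rbind(c(0, 0, 0), g))
  expect_error(buildDesign(sch), "degenerate scheme")
})

test_that("all fit families recover noiseless tensors exactly", {
  fix <- single_tensor_volume(dims = c(3, 3, 2), snr = Inf)
  truth <- fix$tensor
  for (m in c("lls", "wlls", "nlls", "nlls-pos", "restore")) {
    f <- fitTensor(fix$volume, method = m, sigma = 1e-6)
    est <- f@tensors[2, 2, 1, ]
    expect_lt(max(abs(est - truth)) / max(abs(truth)), 1e-8)
    expect_equal(f@lnS0[2, 2, 1], log(fix$s0), tolerance = 1e-8)
  }
  # WLLS weights cannot move an already exact fit
  flls <- fitTensor(fix$volume, method = "lls")
  fwlls <- fitTensor(fix$volume, method = "wlls")
  expect_equal(fwlls@tensors, flls@tensors, tolerance = 1e-10)
})

test_that("NLLS improves (never worsens) the signal-domain objective", {
  fix <- single_tensor_volume(dims = c(8, 8, 1), snr = 10, seed = 3)
  X <- buildDesign(fix$scheme)
  sse <- function(field, i, j) {
    beta <- c(field@lnS0[i, j, 1], field@tensors[i, j, 1, ])
    s <- signalArray(fix$volume)[i, j, 1, ]
    sum((s - exp(X %*% beta))^2)
  }
  flls <- fitTensor(fix$volume, method = "lls")
  fnlls <- fitTensor(fix$volume, method = "nlls")
  for (i in 1:8) for (j in 1:8)
    expect_lte(sse(fnlls, i, j), sse(flls, i, j) * (1 + 1e-12))
})

test_that("constrained and unconstrained NLLS agree on PSD truth", {
  fix <- single_tensor_volume(dims = c(3, 3, 3), snr = Inf)
  a <- fitTensor(fix$volume, method = "nlls")
  b <- fitTensor(fix$volume, method = "nlls-pos")
  expect_equal(a@tensors, b@tensors, tolerance = 1e-6)
})

test_that("RESTORE equals plain NLLS when no residual exceeds 3 sigma", {
  fix <- single_tensor_volume(dims = c(6, 6, 1), snr = 30, seed = 8)
  nl <- fitTensor(fix$volume, method = "nlls")
  # generous sigma guarantees the early-accept path at every voxel
  rs <- fitTensor(fix$volume, method = "restore", sigma = 1e6)
  expect_identical(rs@tensors, nl@tensors)
  expect_true(all(outlierCount(rs) == 0))
})

test_that("noise SD is estimated from b0 repeats and by residual fallback", {
  fix <- single_tensor_volume(dims = c(16, 16, 4), snr = Inf)
  noiseless <- fix$volume
  expect_lt(estimateSigma(noiseless), 1e-9)

  noisy <- noiseless
  noisy@signal <- addRicianNoise(noisy@signal, 5, seed = 12)
  est <- estimateSigma(noisy)
  expect_equal(est, 5, tolerance = 0.1)

  sch1 <- makeScheme(48, 1, 1000)
  fix1 <- single_tensor_volume(dims = c(10, 10, 2), scheme = sch1, snr = 25,
                               seed = 13)
  est1 <- estimateSigma(fix1$volume)
  expect_true(is.finite(est1) && est1 > 0)
})

test_that("FA is invariant to joint rotation and to global signal scaling", {
  set.seed(17)
  m <- matrix(rnorm(9), 3, 3)
  R <- qr.Q(qr(m)); if (det(R) < 0) R[, 1] <- -R[, 1]
  sch <- makeScheme(30, 2, 1000)
  ev <- c(1.5e-3, 5e-4, 3e-4)
  v1 <- c(1, 2, 0.5)
  t6 <- tensorFromEigen(ev, v1)
  D <- matrix(c(t6[1], t6[4], t6[5], t6[4], t6[2], t6[6], t6[5], t6[6], t6[3]), 3)
  Dr <- R %*% D %*% t(R)
  t6r <- c(Dr[1, 1], Dr[2, 2], Dr[3, 3], Dr[1, 2], Dr[1, 3], Dr[2, 3])
  schr <- gradientScheme(bValues(sch), bVectors(sch) %*% t(R))

  mk <- function(t6v, sc) {
    sig <- predictSignal(t6v, sc, 100)
    new("DWIVolume", signal = array(rep(sig, each = 4), c(2, 2, 1, length(sig))),
        voxelSize = c(2, 2, 2), scheme = sc, subjectID = "r", refHeader = NULL)
  }
  fa1 <- computeFA(fitTensor(mk(t6, sch), method = "nlls"))@values[1, 1, 1]
  fa2 <- computeFA(fitTensor(mk(t6r, schr), method = "nlls"))@values[1, 1, 1]
  expect_equal(fa1, fa2, tolerance = 1e-6)

  vol10 <- mk(t6, sch); vol10@signal <- vol10@signal * 10
  fa3 <- computeFA(fitTensor(vol10, method = "lls"))@values[1, 1, 1]
  fa0 <- computeFA(fitTensor(mk(t6, sch), method = "lls"))@values[1, 1, 1]
  expect_equal(fa3, fa0, tolerance = 1e-10)
})

test_that("LLS FA of an isotropic tensor is positively biased under noise", {
  fix <- single_tensor_volume(dims = c(25, 20, 1), evals = rep(7e-4, 3),
                              scheme = makeScheme(30, 2, 1000),
                              snr = 20, seed = 19)
  fa <- computeFA(fitTensor(fix$volume, method = "lls"))@values
  expect_gt(mean(fa), 3 * sd(fa) / sqrt(length(fa)))  # true FA is 0
})

test_that("degenerate voxels are flagged rather than raising errors", {
  fix <- single_tensor_volume(dims = c(2, 2, 1), snr = Inf)
  sig <- signalArray(fix$volume)
  sig[1, 1, 1, ] <- 0                      # empty voxel
  sig[2, 1, 1, 10] <- 0                    # one non-positive measurement
  vol <- fix$volume; vol@signal <- sig
  f <- fitTensor(vol, mask = array(TRUE, dim(sig)[1:3]), method = "lls")
  expect_equal(fitFlags(f)[1, 1, 1], 1L)
  expect_equal(f@tensors[1, 1, 1, ], rep(0, 6))
  expect_equal(bitwAnd(fitFlags(f)[2, 1, 1], 2L), 2L)
  expect_equal(computeFA(f)@values[1, 1, 1], 0)
})
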