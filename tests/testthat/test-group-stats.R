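make_cohort_df <- function(n_per = c(HC = 8, MCI = 7, AD = 6), seed = 1) {
  set.seed(seed)
  n <- sum(n_per)
  validateCohort(data.frame(
    id = sprintf("s%02d", 1:n),
    group = rep(names(n_per), n_per),
    age = round(runif(n, 60, 85), 1),
    gender = rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE))
}

test_that("Gaussian smoothing preserves constants and matches the kernel", {
  arr <- array(runif(10 * 10 * 6), c(10, 10, 6))
  expect_identical(smoothMap(arr, 0, c(2, 2, 2)), arr)

  mask <- array(FALSE, c(10, 10, 6)); mask[3:8, 3:8, 2:5] <- TRUE
  const <- array(0, c(10, 10, 6)); const[mask] <- 0.7
  sm <- smoothMap(const, 3, c(2, 2, 2), mask = mask)
  expect_equal(sm[mask], rep(0.7, sum(mask)), tolerance = 1e-12)
  expect_true(all(sm[!mask] == 0))

  # unmasked impulse: center value is the kernel's central weight
  imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 1
  sm2 <- smoothMap(imp, 2, c(1, 1, 1))
  r <- ceiling(4 * 2)
  k <- exp(-0.5 * ((-r):r / 2)^2); k <- k / sum(k)
  expect_equal(sm2[11, 11, 11], k[r + 1]^3, tolerance = 1e-12)
})

test_that("WM mask thresholds mean FA strictly", {
  zero <- lapply(1:3, function(i) array(0, c(4, 4, 2)))
  expect_false(any(wmMask(zero, 0.2)))
  half <- lapply(1:3, function(i) array(0.5, c(4, 4, 2)))
  expect_true(all(wmMask(half, 0.2)))
  expect_false(any(wmMask(half, 1.0)))
  expect_false(any(wmMask(half, 0.5)))   # strict inequality
  expect_error(wmMask(list(), 0.2), "empty")
})

test_that("Bartlett gate behaves as a calibrated variance test", {
  x <- rnorm(30)
  res <- bartlettGate(list(x, x))        # duplicated samples: no difference
  expect_equal(res$statistic, 0, tolerance = 1e-12)

  set.seed(4)
  rej <- mean(replicate(1000, {
    bartlettGate(list(rnorm(50), rnorm(50)))$p.value < 0.05
  }))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)

  pow <- mean(replicate(200, {
    bartlettGate(list(rnorm(50, sd = 1), rnorm(50, sd = 3)))$p.value < 0.01
  }))
  expect_gte(pow, 0.95)

  expect_error(bartlettGate(list(rep(1, 5), rnorm(5))), "zero variance")
})

test_that("partial eta-squared matches a brute-force model comparison", {
  co <- make_cohort_df(c(HC = 4, MCI = 4, AD = 4), seed = 2)
  set.seed(2)
  nv <- 100
  Y <- matrix(rnorm(12 * nv), 12)
  st <- array(t(Y), c(nv, 1, 1, 12))
  em <- ancovaEta2p(st, co)
  for (v in seq_len(nv))
    expect_equal(em@values[v, 1, 1], oracle_eta2p(Y[, v], co),
                 tolerance = 1e-10)
})

test_that("eta2p hits its analytic limits and ignores age rescaling", {
  co <- make_cohort_df(c(HC = 5, MCI = 5, AD = 5), seed = 3)
  same <- array(0.5 + co$age * 0, c(1, 1, 1, 15))
  expect_equal(ancovaEta2p(same, co)@values[1, 1, 1], 0)

  shifted <- array(ifelse(co$group == "AD", 10, 0), c(1, 1, 1, 15))
  expect_gte(ancovaEta2p(shifted, co)@values[1, 1, 1], 0.999)

  set.seed(5)
  Y <- array(rnorm(15 * 8), c(8, 1, 1, 15))
  a <- ancovaEta2p(Y, co)@values
  co2 <- co; co2$age <- (co$age - 70) / 10
  b <- ancovaEta2p(Y, co2)@values
  expect_equal(a, b, tolerance = 1e-10)

  co3 <- co; co3$gender <- 1
  expect_warning(ancovaEta2p(Y, co3), "constant covariate")
})

test_that("Hedges' g applies the small-sample correction and recovers truth", {
  co <- make_cohort_df(c(HC = 10, MCI = 3, AD = 10), seed = 6)
  zero <- array(0.4, c(1, 1, 1, 23))
  expect_equal(hedgesG(zero, co, c("AD", "HC"))@values[1, 1, 1], 0)

  # raw two-sample form against a hand evaluation (J = 1 - 3/71 at n = 10+10)
  set.seed(20)
  y <- numeric(23)
  y[co$group == "AD"] <- rnorm(10, 1)
  y[co$group == "HC"] <- rnorm(10, 0)
  a <- y[co$group == "AD"]; b <- y[co$group == "HC"]
  pooled <- sqrt((9 * var(a) + 9 * var(b)) / 18)
  expected <- (1 - 3 / 71) * (mean(a) - mean(b)) / pooled
  g1 <- hedgesG(array(y, c(1, 1, 1, 23)), co, c("AD", "HC"),
                adjusted = FALSE)@values[1, 1, 1]
  expect_equal(g1, expected, tolerance = 1e-12)

  # simulation: true standardized difference 1.0, unbalanced 41 vs 12
  set.seed(7)
  n1 <- 41; n2 <- 12; reps <- 1000
  coh <- validateCohort(data.frame(
    id = sprintf("s%02d", 1:(n1 + n2)),
    group = rep(c("HC", "AD"), c(n1, n2)),
    age = round(runif(n1 + n2, 60, 85), 1),
    gender = rbinom(n1 + n2, 1, 0.5), stringsAsFactors = FALSE))
  mu <- ifelse(coh$group == "HC", 1, 0)
  Y <- matrix(rnorm((n1 + n2) * reps, mean = mu), n1 + n2)
  gm <- hedgesG(array(t(Y), c(reps, 1, 1, n1 + n2)), coh,
                c("HC", "AD"))@values[, 1, 1]
  se <- sd(gm) / sqrt(reps)
  expect_lt(abs(mean(gm) - 1), 3 * se + 0.02)
  # sign convention: first-listed group minus second
  gneg <- hedgesG(array(t(Y), c(reps, 1, 1, n1 + n2)), coh,
                  c("AD", "HC"))@values[, 1, 1]
  expect_equal(gneg, -gm, tolerance = 1e-12)
})

test_that("partial Spearman removes covariate confounding", {
  n <- 40
  co <- validateCohort(data.frame(
    id = sprintf("s%02d", 1:n), group = rep(c("HC", "AD"), each = n / 2),
    age = seq(60, 85, length.out = n), gender = rep(0:1, n / 2),
    stringsAsFactors = FALSE))
  set.seed(8)
  # strong monotone association
  fa <- runif(n)
  score <- 10 + 5 * fa + rnorm(n, 0, 1e-6)
  r <- partialSpearman(array(fa, c(1, 1, 1, n)), score, co)@values[1, 1, 1]
  expect_gt(r, 0.95)
  rneg <- partialSpearman(array(fa, c(1, 1, 1, n)), -score, co)@values[1, 1, 1]
  expect_equal(rneg, -r, tolerance = 1e-12)

  # both FA and score driven by age only: partial |rho| < plain |rho|
  reps <- 500
  FA <- matrix(co$age + rnorm(n * reps, 0, 3), n)
  score2 <- co$age + rnorm(n, 0, 3)
  part <- partialSpearman(array(t(FA), c(reps, 1, 1, n)), score2,
                          co)@values[, 1, 1]
  plain <- apply(FA, 2, function(y) cor(rank(y), rank(score2)))
  expect_gte(mean(abs(part) < abs(plain)), 0.95)

  cst <- partialSpearman(array(fa, c(1, 1, 1, n)), rep(5, n), co)
  expect_equal(cst@values[1, 1, 1], 0)
  expect_true(attr(cst, "degenerate"))

  missing_sc <- score; missing_sc[1:3] <- NA
  rm <- partialSpearman(array(fa, c(1, 1, 1, n)), missing_sc, co)@values[1, 1, 1]
  expect_gt(rm, 0.9)   # pairwise deletion keeps the remaining subjects
})

test_that("cluster extraction honors connectivity and strict thresholds", {
  arr <- array(0, c(12, 12, 6))
  arr[2:6, 2:6, 2:7 - 1] <- 1            # 5 x 5 x 6 = 150 voxels
  cl <- extractClusters(arr, 0.5, min_size = 100, two_sided = FALSE,
                        connectivity = 26)
  expect_length(cl, 1)
  expect_equal(clusterSize(cl[[1]]), 150)

  # two cubes touching only at one corner
  corner <- array(0, c(8, 8, 8))
  corner[2:4, 2:4, 2:4] <- 1
  corner[5:7, 5:7, 5:7] <- 1
  expect_length(extractClusters(corner, 0.5, 0, FALSE, 26), 1)
  expect_length(extractClusters(corner, 0.5, 0, FALSE, 6), 2)

  # strict "> min_size": a 100-voxel component is excluded, 101 is kept
  flat <- array(0, c(30, 30, 2))
  flat[1:10, 1:10, 1] <- 1               # exactly 100
  expect_length(extractClusters(flat, 0.5, 100, FALSE, 26), 0)
  flat[11, 1, 1] <- 1                    # 101
  expect_length(extractClusters(flat, 0.5, 100, FALSE, 26), 1)

  # two-sided maps keep signs separate and partition the supra set
  set.seed(9)
  noisy <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  cls <- extractClusters(noisy, 1.2, 0, TRUE, 6)
  supra <- sum(abs(noisy) > 1.2)
  expect_equal(sum(vapply(cls, clusterSize, numeric(1))), supra)
})

test_that("cluster labeling reports coverage percentages both ways", {
  lab <- array(0L, c(20, 20, 5))
  lab[1:10, 1:20, 1] <- 1L               # 200-voxel region
  atl <- labelAtlas(lab, c("1" = "fornix"))

  stat <- array(0, c(20, 20, 5))
  stat[1:10, 1:10, 1] <- 1               # 100-voxel cluster inside region
  cl <- extractClusters(stat, 0.5, 0, FALSE, 26)
  cl <- labelClusters(cl, atl, c(20, 20, 5))
  ov <- clusterOverlaps(cl[[1]])
  expect_equal(ov$pctRegionCovered, 50)
  expect_equal(ov$pctClusterInRegion, 100)

  stat2 <- array(0, c(20, 20, 5)); stat2[15:18, 15:18, 3] <- 1
  cl2 <- labelClusters(extractClusters(stat2, 0.5, 0, FALSE, 26), atl)
  expect_equal(nrow(clusterOverlaps(cl2[[1]])), 0)

  expect_error(labelClusters(cl, atl, c(10, 10, 5)), "does not match")
})

test_that("map averaging is elementwise, order-invariant and type-checked", {
  mk <- function(v) statMap(array(v, c(3, 3, 2)), "g", c(2, 2, 2), "AD vs HC")
  a <- mk(1); b <- mk(-1); c3 <- mk(0.5)
  expect_equal(mapValues(averageMaps(list(a, a))), mapValues(a))
  expect_equal(max(abs(mapValues(averageMaps(list(a, b))))), 0)
  expect_equal(mapValues(averageMaps(list(a, b, c3))),
               mapValues(averageMaps(list(c3, a, b))))
  bad <- statMap(array(0.2, c(3, 3, 2)), "eta2p", c(2, 2, 2))
  expect_error(averageMaps(list(a, bad)), "mixed kinds")
})
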