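# Fixture builders shared across the suite. Everything is generated in code;
# heavyweight cohort runs are memoized so several tests can share one
# computation.

.fixture_cache <- new.env(parent = emptyenv())

# A small single-tensor DWIVolume: every voxel carries the same tensor, with
# optional Rician noise, so voxels double as Monte-Carlo replicates.
single_tensor_volume <- function(dims = c(5, 5, 2), evals = c(1.7e-3, 4e-4, 4e-4),
                                 dir = c(1, 0, 0), scheme = makeScheme(48, 6, 1000),
                                 s0 = 1000, snr = Inf, seed = 1) {
  D6 <- tensorFromEigen(evals, dir)
  sig <- predictSignal(D6, scheme, s0)
  nvox <- prod(dims)
  arr <- matrix(rep(sig, each = nvox), nvox)
  if (is.finite(snr)) arr <- addRicianNoise(arr, s0 / snr, seed = seed)
  vol <- new("DWIVolume", signal = array(arr, c(dims, length(sig))),
             voxelSize = c(2, 2, 2), scheme = scheme, subjectID = "fix",
             refHeader = NULL)
  list(volume = vol, tensor = D6, scheme = scheme, s0 = s0)
}

# Downscaled phantom spec for fast functional tests.
small_phantom_spec <- function(nPerGroup = c(HC = 6, MCI = 5, AD = 4),
                               seed = 11, ...) {
  phantomSpec(
    dims = c(12, 12, 8), voxelSize = c(2, 2, 2),
    rois = list(
      roiEllipsoid("fornix", center = c(6, 6, 4), radii = c(3, 2.5, 2),
                   evals = c(1.7e-3, 0.4e-3, 0.4e-3), dir = c(1, 0, 0)),
      roiShell("wm_shell", lo = c(1, 1, 1), hi = c(12, 12, 8),
               cav_lo = c(3, 3, 2), cav_hi = c(10, 10, 7),
               evals = c(1.2e-3, 0.58e-3, 0.58e-3), dir = c(0, 0, 1))
    ),
    nPerGroup = nPerGroup, seed = seed, ...)
}

# One full default-conditions experiment (73 subjects, 5 fit variants),
# shared by the consistency-band and detection acceptance tests.
cohort_experiment <- function() {
  if (is.null(.fixture_cache$run)) {
    cfg <- runConfig(phantom = phantomSpec(),
                     outputDir = file.path(tempdir(), "dtivba_acc_run"),
                     seed = 101)
    .fixture_cache$run <- runExperiment(cfg, verbose = FALSE)
  }
  .fixture_cache$run
}

# Brute-force partial eta-squared via two explicit lm() fits.
oracle_eta2p <- function(y, cohort) {
  g <- droplevels(cohort$group)
  contrasts(g) <- stats::contr.sum(nlevels(g))
  full <- lm(y ~ g + age + gender, data = cbind(cohort, y = y))
  red <- lm(y ~ age + gender, data = cbind(cohort, y = y))
  sse_f <- sum(residuals(full)^2)
  sse_r <- sum(residuals(red)^2)
  (sse_r - sse_f) / sse_r
}

# Brute-force ICC(3,1) through aov() mean squares.
oracle_icc31 <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse)
}
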