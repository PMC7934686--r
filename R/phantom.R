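## Synthetic multi-group DWI cohorts with known tensor ground truth.
##
## The phantom places piecewise-constant tensors in simple geometric ROIs on
## a common grid (no registration stage is simulated), predicts single-shell
## signals through the Stejskal-Tanner model, corrupts selected
## volume x slice blocks to mimic dropout artifacts, and adds Rician
## magnitude noise. Group effects act multiplicatively on the anisotropic
## eigenvalue component (lambda1 - lambda2), which moves FA monotonically
## while preserving eigenvalue ordering.

#' Specification of a synthetic DWI cohort
#'
#' Defaults emulate a three-group (HC/MCI/AD) single-shell study: a GE-like
#' 48-direction b = 1000 s/mm^2 scheme with six leading b = 0 volumes, group
#' sizes 41/20/12, a high-FA "fornix-like" ellipsoid carrying an AD deficit
#' whose true standardized effect is approximately g = -1.5, a surrounding
#' white-matter shell above the 0.20 FA mask threshold, a nearly isotropic
#' background, SNR 25, and sporadic signal-dropout outliers.
#'
#' @slot dims grid dimensions (voxels).
#' @slot voxelSize voxel size in mm.
#' @slot rois list of ROI definitions from \code{\link{roiEllipsoid}} /
#'   \code{\link{roiBox}} / \code{\link{roiShell}}.
#' @slot background list(evals, dir) for non-ROI voxels.
#' @slot groupEffects data.frame(roi, group, factor); factor multiplies
#'   (lambda1 - lambda2) for members of that group.
#' @slot nPerGroup named integer vector (HC, MCI, AD).
#' @slot betweenSubjectSD SD of the per-subject, per-ROI anisotropy jitter
#'   factor (drawn around 1).
#' @slot snr reference signal-to-noise ratio S0 / sigma.
#' @slot s0 reference signal level (arbitrary scanner units).
#' @slot outlierRate probability that a given DWI volume x axial slice block
#'   is corrupted.
#' @slot dropoutFactor multiplicative signal loss of corrupted blocks.
#' @slot scheme list(nDirections, nB0, bval).
#' @slot ageModel data.frame(group, mean, sd) for age.
#' @slot femaleProp named numeric, proportion female per group.
#' @slot scoreModels list per score of list(hc, ad, sd): target HC and AD
#'   group means and residual SD; the linear coupling on true ROI FA is
#'   solved from these.
#' @slot scoreCouplingROI name of the ROI whose true FA drives the scores.
#' @slot seed integer master seed.
#' @export
setClass("PhantomSpec",
  representation(dims = "numeric", voxelSize = "numeric", rois = "list",
                 background = "list", groupEffects = "data.frame",
                 nPerGroup = "numeric", betweenSubjectSD = "numeric",
                 snr = "numeric", s0 = "numeric", outlierRate = "numeric",
                 dropoutFactor = "numeric", scheme = "list",
                 ageModel = "data.frame", femaleProp = "numeric",
                 scoreModels = "list", scoreCouplingROI = "character",
                 seed = "numeric"),
  validity = function(object) {
    msg <- character()
    for (roi in object@rois) {
      ev <- roi$evals
      if (!(ev[1] >= ev[2] && ev[2] >= ev[3] && ev[3] > 0))
        msg <- c(msg, sprintf("ROI '%s': eigenvalues must satisfy l1 >= l2 >= l3 > 0",
                              roi$name))
    }
    if (nrow(object@groupEffects) && any(object@groupEffects$factor <= 0))
      msg <- c(msg, "group effect factors must be > 0")
    if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
    if (object@outlierRate < 0 || object@outlierRate >= 0.5)
      msg <- c(msg, "outlierRate must lie in [0, 0.5)")
    if (object@dropoutFactor < 0 || object@dropoutFactor >= 1)
      msg <- c(msg, "dropoutFactor must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  }
)

#' Define an ellipsoidal ROI
#' @param name region name.
#' @param center voxel-coordinate center (1-based, length 3).
#' @param radii semi-axes in voxels (length 3).
#' @param evals baseline eigenvalues (mm^2/s), descending.
#' @param dir principal eigenvector (need not be normalized).
#' @return ROI definition list for \code{\link{phantomSpec}}.
#' @export
roiEllipsoid <- function(name, center, radii, evals, dir = c(1, 0, 0)) {
  list(name = name, shape = "ellipsoid", center = center, radii = radii,
       evals = evals, dir = dir / sqrt(sum(dir^2)))
}

#' Define a box ROI
#' @param lo,hi inclusive 1-based voxel index bounds (length 3).
#' @inheritParams roiEllipsoid
#' @return ROI definition list.
#' @export
roiBox <- function(name, lo, hi, evals, dir = c(1, 0, 0)) {
  list(name = name, shape = "box", lo = lo, hi = hi, evals = evals,
       dir = dir / sqrt(sum(dir^2)))
}

#' Define a box-shell ROI (outer box minus an inner cavity)
#' @param lo,hi inclusive bounds of the outer box.
#' @param cav_lo,cav_hi inclusive bounds of the excluded cavity.
#' @inheritParams roiEllipsoid
#' @return ROI definition list.
#' @export
roiShell <- function(name, lo, hi, cav_lo, cav_hi, evals, dir = c(0, 0, 1)) {
  list(name = name, shape = "shell", lo = lo, hi = hi, cav_lo = cav_lo,
       cav_hi = cav_hi, evals = evals, dir = dir / sqrt(sum(dir^2)))
}

roi_mask <- function(roi, dims) {
  m <- array(FALSE, dims)
  idx <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  inside <- switch(roi$shape,
    ellipsoid = ((idx$x - roi$center[1]) / roi$radii[1])^2 +
                ((idx$y - roi$center[2]) / roi$radii[2])^2 +
                ((idx$z - roi$center[3]) / roi$radii[3])^2 <= 1,
    box = idx$x >= roi$lo[1] & idx$x <= roi$hi[1] &
          idx$y >= roi$lo[2] & idx$y <= roi$hi[2] &
          idx$z >= roi$lo[3] & idx$z <= roi$hi[3],
    shell = {
      outer <- idx$x >= roi$lo[1] & idx$x <= roi$hi[1] &
               idx$y >= roi$lo[2] & idx$y <= roi$hi[2] &
               idx$z >= roi$lo[3] & idx$z <= roi$hi[3]
      inner <- idx$x >= roi$cav_lo[1] & idx$x <= roi$cav_hi[1] &
               idx$y >= roi$cav_lo[2] & idx$y <= roi$cav_hi[2] &
               idx$z >= roi$cav_lo[3] & idx$z <= roi$cav_hi[3]
      outer & !inner
    },
    stop("unknown ROI shape: ", roi$shape))
  m[as.matrix(idx[inside, c("x", "y", "z")])] <- TRUE
  m
}

#' Construct a PhantomSpec
#'
#' All arguments default to the emulated study conditions described in
#' \linkS4class{PhantomSpec}; pass replacements to explore other regimes.
#'
#' @param dims,voxelSize grid geometry.
#' @param rois,background,groupEffects tissue layout and group effects.
#' @param nPerGroup named group sizes.
#' @param betweenSubjectSD,snr,s0,outlierRate,dropoutFactor noise model.
#' @param scheme list(nDirections, nB0, bval).
#' @param ageModel,femaleProp,scoreModels,scoreCouplingROI covariate model.
#' @param seed master seed.
#' @return A validated \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(
    dims = c(20, 20, 12), voxelSize = c(2, 2, 2),
    rois = list(
      roiEllipsoid("fornix", center = c(10, 10, 6), radii = c(5, 4, 2.5),
                   evals = c(1.7e-3, 0.4e-3, 0.4e-3), dir = c(1, 0, 0)),
      roiShell("wm_shell", lo = c(2, 2, 2), hi = c(18, 18, 10),
               cav_lo = c(4, 5, 3), cav_hi = c(16, 15, 9),
               evals = c(1.2e-3, 0.58e-3, 0.58e-3), dir = c(0, 0, 1))
    ),
    background = list(evals = c(0.85e-3, 0.76e-3, 0.76e-3), dir = c(1, 0, 0)),
    groupEffects = data.frame(roi = "fornix", group = "AD", factor = 0.655,
                              stringsAsFactors = FALSE),
    nPerGroup = c(HC = 41, MCI = 20, AD = 12),
    betweenSubjectSD = 0.25, snr = 25, s0 = 1000,
    outlierRate = 0.02, dropoutFactor = 0.3,
    scheme = list(nDirections = 48, nB0 = 6, bval = 1000),
    ageModel = data.frame(group = c("HC", "MCI", "AD"),
                          mean = c(70.8, 72.7, 75.6),
                          sd = c(5.8, 9.3, 5.4), stringsAsFactors = FALSE),
    femaleProp = c(HC = 27 / 41, MCI = 9 / 20, AD = 2 / 12),
    scoreModels = list(
      MMSE = list(hc = 29.3, ad = 23.7, sd = 1.5),
      MoCA = list(hc = 25.4, ad = 16.1, sd = 3.0),
      ADAS = list(hc = 8.5, ad = 22.2, sd = 3.0)
    ),
    scoreCouplingROI = "fornix", seed = 42) {
  new("PhantomSpec", dims = dims, voxelSize = voxelSize, rois = rois,
      background = background, groupEffects = groupEffects,
      nPerGroup = nPerGroup, betweenSubjectSD = betweenSubjectSD, snr = snr,
      s0 = s0, outlierRate = outlierRate, dropoutFactor = dropoutFactor,
      scheme = scheme, ageModel = ageModel, femaleProp = femaleProp,
      scoreModels = scoreModels, scoreCouplingROI = scoreCouplingROI,
      seed = seed)
}

#' Build a single-shell gradient scheme
#'
#' b = 0 volumes are placed first, followed by diffusion directions spread
#' quasi-uniformly over the hemisphere by a deterministic spherical-Fibonacci
#' construction. A nonzero \code{seed} applies a seeded random rotation to
#' the whole direction set; the construction itself is not randomized.
#'
#' @param n_directions number of diffusion-weighted directions (>= 7).
#' @param n_b0 number of leading b = 0 volumes (>= 1).
#' @param bval diffusion weighting (s/mm^2).
#' @param seed 0 (default) for the canonical orientation, otherwise the seed
#'   of the random rotation.
#' @return A \linkS4class{GradientScheme} with \code{n_b0 + n_directions}
#'   volumes.
#' @export
makeScheme <- function(n_directions, n_b0 = 1, bval = 1000, seed = 0) {
  if (n_directions < 7)
    stop("at least 7 diffusion directions are required for a tensor fit")
  if (n_b0 < 1) stop("at least one b = 0 volume is required")
  i <- seq_len(n_directions) - 0.5
  z <- i / n_directions                      # upper hemisphere
  phi <- 2 * pi * (1 - 1 / ((1 + sqrt(5)) / 2)) * (seq_len(n_directions) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (seed != 0) {
    set.seed(seed)
    rot <- random_rotation()
    dirs <- dirs %*% t(rot)
  }
  bvals <- c(rep(0, n_b0), rep(bval, n_directions))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  gradientScheme(bvals, bvecs)
}

random_rotation <- function() {
  repeat {
    m <- matrix(rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    if (abs(det(q) - 1) < 1e-8) return(q)
  }
}

#' Build a symmetric tensor from its spectrum and principal direction
#'
#' The second and third eigenvectors are completed deterministically in the
#' orthogonal complement of \code{principal_dir}.
#'
#' @param eigenvalues descending positive eigenvalues (mm^2/s).
#' @param principal_dir direction of the leading eigenvector.
#' @return Numeric length-6 tensor (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @export
tensorFromEigen <- function(eigenvalues, principal_dir) {
  nrm <- sqrt(sum(principal_dir^2))
  if (nrm == 0) stop("principal direction must be nonzero")
  if (is.unsorted(rev(eigenvalues)) || any(eigenvalues < 0))
    stop("eigenvalues must be non-negative and in descending order")
  v1 <- principal_dir / nrm
  u <- diag(3)[, which.min(abs(v1))]
  v2 <- u - sum(u * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  D <- eigenvalues[1] * tcrossprod(v1) + eigenvalues[2] * tcrossprod(v2) +
       eigenvalues[3] * tcrossprod(v3)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Predict single-shell signals from a tensor
#'
#' Evaluates the Stejskal-Tanner forward model S_i = s0 exp(-b_i g_i' D g_i)
#' per volume; b = 0 volumes return \code{s0}.
#'
#' @param tensor length-6 tensor (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), mm^2/s.
#' @param scheme a \linkS4class{GradientScheme}.
#' @param s0 reference signal.
#' @return Numeric vector of per-volume signals.
#' @export
predictSignal <- function(tensor, scheme, s0 = 1) {
  g <- scheme@bvecs
  quad <- tensor[1] * g[, 1]^2 + tensor[2] * g[, 2]^2 + tensor[3] * g[, 3]^2 +
    2 * tensor[4] * g[, 1] * g[, 2] + 2 * tensor[5] * g[, 1] * g[, 3] +
    2 * tensor[6] * g[, 2] * g[, 3]
  s0 * exp(-scheme@bvals * quad)
}

#' Add Rician magnitude noise
#'
#' Each value S is replaced by sqrt((S + n1)^2 + n2^2) with n1, n2
#' independent zero-mean Gaussians of SD \code{sigma}; this is the standard
#' noise model for magnitude MR images. \code{sigma = 0} is the identity.
#'
#' @param signals numeric array of noiseless signals.
#' @param sigma noise standard deviation (signal units).
#' @param seed optional integer seed for reproducibility.
#' @return Array of the same shape.
#' @export
addRicianNoise <- function(signals, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signals)
  if (!is.null(seed)) set.seed(seed)
  n <- length(signals)
  out <- sqrt((signals + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signals))) dim(out) <- dim(signals)
  out
}

#' Corrupt volume x slice blocks with signal dropout
#'
#' Each (diffusion-weighted volume, axial slice) pair is independently
#' selected with probability \code{rate}; selected blocks are multiplied by
#' \code{dropout_factor}. b = 0 volumes are never corrupted. The returned
#' mask records corrupted positions as a volumes x slices logical matrix.
#'
#' @param volume a \linkS4class{DWIVolume}.
#' @param rate block corruption probability in [0, 0.5).
#' @param dropout_factor remaining signal fraction in [0, 1).
#' @param seed optional integer seed.
#' @return list(volume = corrupted \linkS4class{DWIVolume},
#'   mask = nvol x nz logical matrix).
#' @export
injectOutliers <- function(volume, rate, dropout_factor = 0.3, seed = NULL) {
  if (rate < 0 || rate >= 0.5) stop("rate must lie in [0, 0.5)")
  if (dropout_factor < 0 || dropout_factor >= 1)
    stop("dropout_factor must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  d <- dim(volume@signal)
  nvol <- d[4]; nz <- d[3]
  mask <- matrix(FALSE, nvol, nz)
  dwi <- which(volume@scheme@bvals > 0)
  if (rate > 0 && length(dwi)) {
    sel <- matrix(runif(length(dwi) * nz) < rate, length(dwi), nz)
    mask[dwi, ] <- sel
    if (any(sel)) {
      sig <- volume@signal
      for (k in seq_along(dwi)) {
        zs <- which(sel[k, ])
        if (length(zs))
          sig[, , zs, dwi[k]] <- sig[, , zs, dwi[k]] * dropout_factor
      }
      volume@signal <- sig
    }
  }
  list(volume = volume, mask = mask)
}

analytic_roi_fa <- function(evals, factor = 1) {
  l <- c(evals[2] + factor * (evals[1] - evals[2]), evals[2], evals[3])
  m <- mean(l)
  sqrt(1.5) * sqrt(sum((l - m)^2) / sum(l^2))
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 100000) * 20011 + 7919 * k) %% 2147483647L
}

#' Generate a synthetic multi-group DWI cohort
#'
#' Per subject: ROI tensors receive a multiplicative anisotropy jitter and
#' any group effect, covariates are drawn from the spec's models, cognitive
#' scores follow a monotone linear coupling on the subject's true FA in the
#' coupling ROI (solved so the HC and AD group means hit the spec targets),
#' signals are predicted through the tensor model, dropout outliers are
#' injected and Rician noise is added. Fully reproducible from
#' \code{spec@seed}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{volumes} (list of
#'   \linkS4class{DWIVolume}), \code{cohort} (validated covariate table),
#'   \code{truth} (list: per-subject \code{tensors} 4D arrays, \code{trueFA}
#'   3D arrays, \code{outlierMask} nvol x nz logical matrices), \code{atlas}
#'   (\linkS4class{LabelAtlas} of the ROI masks), and \code{scheme}.
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  dims <- spec@dims
  masks <- lapply(spec@rois, roi_mask, dims = dims)
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(overlap > 1)) stop("overlapping ROIs: ground truth would be ambiguous")

  labels <- array(0L, dims)
  for (i in seq_along(masks)) labels[masks[[i]]] <- i
  atlas <- labelAtlas(labels, setNames(
    vapply(spec@rois, `[[`, character(1), "name"),
    as.character(seq_along(spec@rois))))

  scheme <- makeScheme(spec@scheme$nDirections, spec@scheme$nB0,
                       spec@scheme$bval, seed = 0)
  nvol <- length(scheme@bvals)
  sigma <- spec@s0 / spec@snr

  groups <- rep(names(spec@nPerGroup), spec@nPerGroup)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))

  # linear score coupling solved from analytic HC/AD true-FA means
  cp <- which(vapply(spec@rois, `[[`, character(1), "name") == spec@scoreCouplingROI)
  couple <- NULL
  if (length(cp) == 1) {
    ev <- spec@rois[[cp]]$evals
    fa_hc <- analytic_roi_fa(ev, 1)
    ge <- spec@groupEffects
    fac_ad <- if (nrow(ge)) {
      hit <- ge$roi == spec@scoreCouplingROI & ge$group == "AD"
      if (any(hit)) ge$factor[which(hit)[1]] else 1
    } else 1
    fa_ad <- analytic_roi_fa(ev, fac_ad)
    couple <- lapply(spec@scoreModels, function(sm) {
      slope <- if (abs(fa_hc - fa_ad) > 1e-12) (sm$hc - sm$ad) / (fa_hc - fa_ad) else 0
      list(slope = slope, intercept = sm$hc - slope * fa_hc, sd = sm$sd)
    })
  }

  set.seed(derive_seed(spec@seed, 1))
  age <- numeric(n); gender <- integer(n)
  for (g in unique(groups)) {
    sel <- groups == g
    am <- spec@ageModel[spec@ageModel$group == g, ]
    age[sel] <- round(pmax(55, rnorm(sum(sel), am$mean, am$sd)), 1)
    gender[sel] <- as.integer(runif(sum(sel)) < spec@femaleProp[[g]])
  }
  # per-subject, per-ROI (plus background) anisotropy jitter factors
  nroi <- length(spec@rois)
  jitter <- matrix(pmax(0.05, rnorm(n * (nroi + 1), 1, spec@betweenSubjectSD)),
                   n, nroi + 1)

  effect_factor <- function(roi_name, group) {
    ge <- spec@groupEffects
    if (!nrow(ge)) return(1)
    hit <- ge$roi == roi_name & ge$group == group
    if (any(hit)) prod(ge$factor[hit]) else 1
  }

  nvox <- prod(dims)
  bg_idx <- which(labels == 0L)
  roi_idx <- lapply(masks, which)

  volumes <- vector("list", n)
  tensors_list <- vector("list", n)
  fa_list <- vector("list", n)
  outmask_list <- vector("list", n)
  score_fa <- numeric(n)

  for (s in seq_len(n)) {
    tens <- matrix(0, nvox, 6)
    fa_true <- numeric(nvox)
    sig <- matrix(0, nvox, nvol)
    regions <- c(spec@rois, list(c(spec@background, list(name = ".bg"))))
    for (k in seq_along(regions)) {
      roi <- regions[[k]]
      idx <- if (k <= nroi) roi_idx[[k]] else bg_idx
      if (!length(idx)) next
      fac <- jitter[s, k]
      if (k <= nroi) fac <- fac * effect_factor(roi$name, groups[s])
      ev <- roi$evals
      ev_adj <- c(ev[2] + fac * (ev[1] - ev[2]), ev[2], ev[3])
      D6 <- tensorFromEigen(ev_adj, roi$dir)
      tens[idx, ] <- matrix(D6, length(idx), 6, byrow = TRUE)
      m <- mean(ev_adj)
      fa_true[idx] <- sqrt(1.5) * sqrt(sum((ev_adj - m)^2) / sum(ev_adj^2))
      sig[idx, ] <- matrix(predictSignal(D6, scheme, spec@s0),
                           length(idx), nvol, byrow = TRUE)
      if (k == cp && !is.null(couple)) score_fa[s] <- fa_true[idx[1]]
    }
    vol <- new("DWIVolume", signal = array(sig, c(dims, nvol)),
               voxelSize = spec@voxelSize, scheme = scheme,
               subjectID = ids[s], refHeader = NULL)
    inj <- injectOutliers(vol, spec@outlierRate, spec@dropoutFactor,
                          seed = derive_seed(spec@seed, 1000 + s))
    noisy <- addRicianNoise(inj$volume@signal, sigma,
                            seed = derive_seed(spec@seed, 2000 + s))
    inj$volume@signal <- noisy
    volumes[[s]] <- inj$volume
    tensors_list[[s]] <- array(tens, c(dims, 6))
    fa_list[[s]] <- array(fa_true, dims)
    outmask_list[[s]] <- inj$mask
  }

  set.seed(derive_seed(spec@seed, 3))
  cohort <- data.frame(id = ids, group = groups, age = age, gender = gender,
                       stringsAsFactors = FALSE)
  for (sc in names(spec@scoreModels)) {
    if (!is.null(couple)) {
      cc <- couple[[sc]]
      cohort[[sc]] <- round(cc$intercept + cc$slope * score_fa +
                            rnorm(n, 0, cc$sd))
    } else cohort[[sc]] <- NA_real_
  }
  cohort <- validateCohort(cohort)

  list(volumes = volumes, cohort = cohort,
       truth = list(tensors = tensors_list, trueFA = fa_list,
                    outlierMask = outmask_list),
       atlas = atlas, scheme = scheme, spec = spec)
}
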