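## Tensor estimation: design matrix construction, the four regression
## families (LLS, WLLS, NLLS with optional positivity constraint, RESTORE),
## FA derivation and noise-level estimation.
##
## Regression parameter order is beta = (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz,
## Dyz); design rows are [1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy,
## -2b gx gz, -2b gy gz], so that X beta = ln S under the tensor model.

#' Build the tensor-model design matrix for a gradient scheme
#'
#' @param scheme a \linkS4class{GradientScheme}.
#' @return nvol x 7 matrix; an error is raised when the scheme cannot
#'   identify all 7 parameters (rank < 7, e.g. coplanar directions).
#' @export
buildDesign <- function(scheme) {
  b <- scheme@bvals
  g <- scheme@bvecs
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  colnames(X) <- c("lnS0", "Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  if (qr(X)$rank < 7)
    stop("degenerate scheme: design matrix has rank < 7")
  X
}

default_fit_mask <- function(volume) {
  d <- dim(volume@signal)
  apply(volume@signal, 1:3, max) > 0
}

#' Fit the diffusion tensor per voxel
#'
#' Four estimation families are available:
#' \describe{
#'   \item{lls}{ordinary least squares of log-signals on the design matrix.}
#'   \item{wlls}{two-pass weighted least squares; pass-2 weights are the
#'     squared signals predicted from the pass-1 LLS fit, which compensates
#'     the noise-variance distortion of the log transform without using the
#'     noise-correlated observed signals as weights.}
#'   \item{nlls / nlls-pos}{damped Gauss-Newton (Levenberg-Marquardt
#'     schedule) on raw signals, initialized at the LLS solution;
#'     convergence at relative parameter change < \code{tol} or
#'     \code{maxIter} iterations, with fallback to the LLS estimate (and a
#'     diagnostic flag) on non-convergence. \code{nlls-pos} parameterizes
#'     the tensor through its Cholesky factor so the estimate is positive
#'     semidefinite.}
#'   \item{restore}{robust fit: initial NLLS; early accept when all absolute
#'     residuals are within 3 sigma; otherwise iteratively reweighted NLLS
#'     with Geman-McClure weights 1 / (r^2 + C^2), C = 1.4826 median|r|
#'     recomputed each iteration; measurements with |r| > 3 sigma are then
#'     excluded and the remainder refit unweighted. If fewer than
#'     max(7, half the DWI volumes) diffusion-weighted measurements survive,
#'     the WLLS estimate is returned with a flag.}
#' }
#' Non-positive signals are clamped to machine-epsilon times the voxel
#' maximum before logs are taken (flagged in diagnostics). All-zero voxels
#' yield a zero tensor and a flag, not an error.
#'
#' @param volume a \linkS4class{DWIVolume}.
#' @param mask 3D logical array of voxels to fit (default: voxels with any
#'   positive signal).
#' @param method "lls", "wlls", "nlls", "nlls-pos" or "restore".
#' @param sigma noise SD for RESTORE's residual cutoff, or "auto" to
#'   estimate it with \code{\link{estimateSigma}}.
#' @param maxIter,tol non-linear optimizer controls.
#' @param details when TRUE, return list(field, outliers, maskIdx) where
#'   outliers is RESTORE's nvol x nvoxel exclusion mask over masked voxels.
#' @return A \linkS4class{TensorField} (or the detail list).
#' @export
fitTensor <- function(volume, mask = NULL,
                      method = c("lls", "wlls", "nlls", "nlls-pos", "restore"),
                      sigma = "auto", maxIter = 100, tol = 1e-8,
                      details = FALSE) {
  method <- match.arg(method)
  if (is.null(mask)) mask <- default_fit_mask(volume)
  d <- dim(volume@signal)
  stopifnot(identical(dim(mask), d[1:3]))
  X <- buildDesign(volume@scheme)

  sig_val <- 0
  if (method == "restore") {
    sig_val <- if (identical(sigma, "auto")) estimateSigma(volume, mask)
               else as.numeric(sigma)
    if (!is.finite(sig_val) || sig_val <= 0)
      stop("sigma must be positive for RESTORE")
  }

  idx <- which(mask)
  smat <- matrix(volume@signal, prod(d[1:3]), d[4])
  S <- t(smat[idx, , drop = FALSE])
  fit <- cpp_fit_dti(S, X, method, sig_val, as.integer(maxIter), tol)

  nvox <- prod(d[1:3])
  tens <- matrix(0, nvox, 6)
  tens[idx, ] <- t(fit$beta[2:7, , drop = FALSE])
  lnS0 <- array(0, d[1:3]); lnS0[idx] <- fit$beta[1, ]
  flags <- array(0L, d[1:3]); flags[idx] <- fit$flags
  nout <- array(0L, d[1:3]); nout[idx] <- fit$n_outliers

  field <- new("TensorField", tensors = array(tens, c(d[1:3], 6)),
               lnS0 = lnS0, mask = mask, method = method, flags = flags,
               outlierCount = nout, voxelSize = volume@voxelSize)
  if (details) {
    list(field = field,
         outliers = if (!is.null(fit$outliers)) fit$outliers else NULL,
         maskIdx = idx, sigma = sig_val)
  } else field
}

#' @rdname fitTensor
#' @param ... passed to \code{fitTensor}.
#' @export
fitLLS <- function(volume, mask = NULL, ...)
  fitTensor(volume, mask, method = "lls", ...)

#' @rdname fitTensor
#' @export
fitWLLS <- function(volume, mask = NULL, ...)
  fitTensor(volume, mask, method = "wlls", ...)

#' @rdname fitTensor
#' @param constrained fit the positive-semidefinite (Cholesky) variant.
#' @export
fitNLLS <- function(volume, mask = NULL, constrained = FALSE, ...)
  fitTensor(volume, mask, method = if (constrained) "nlls-pos" else "nlls", ...)

#' @rdname fitTensor
#' @export
fitRESTORE <- function(volume, mask = NULL, sigma = "auto", ...)
  fitTensor(volume, mask, method = "restore", sigma = sigma, ...)

#' Compute a fractional anisotropy map from fitted tensors
#'
#' Per voxel the symmetric tensor is eigendecomposed; eigenvalues below zero
#' are clamped to zero before FA = sqrt(3/2) sqrt(sum((l - lbar)^2)) /
#' sqrt(sum(l^2)) is evaluated (FA = 0 when the spectrum is all zero), and
#' the result is clipped to [0, 1]. The unclamped spectrum is kept in the
#' \code{eigenvalues} slot as a diagnostic.
#'
#' @param field a \linkS4class{TensorField}.
#' @return A \linkS4class{FAMap}.
#' @export
computeFA <- function(field) {
  d <- dim(field@tensors)
  nvox <- prod(d[1:3])
  idx <- which(field@mask)
  tm <- matrix(field@tensors, nvox, 6)
  res <- cpp_fa(t(tm[idx, , drop = FALSE]))
  fa <- array(0, d[1:3]); fa[idx] <- res$fa
  ev <- matrix(0, nvox, 3); ev[idx, ] <- t(res$evals)
  new("FAMap", values = fa, kind = "fa", contrast = field@method,
      voxelSize = field@voxelSize, thresholds = list(),
      eigenvalues = array(ev, c(d[1:3], 3)), mask = field@mask)
}

#' Estimate the noise standard deviation of an acquisition
#'
#' With two or more b = 0 volumes, sigma is estimated from successive b = 0
#' differences (SD of differences / sqrt(2)) pooled over a high-signal mask.
#' With a single b = 0 volume the estimate falls back to 1.4826 times the
#' median absolute LLS residual in the signal domain.
#'
#' @param volume a \linkS4class{DWIVolume}.
#' @param mask optional 3D logical analysis mask.
#' @return Estimated noise SD (signal units).
#' @export
estimateSigma <- function(volume, mask = NULL) {
  if (is.null(mask)) mask <- default_fit_mask(volume)
  b0 <- which(volume@scheme@bvals == 0)
  d <- dim(volume@signal)
  smat <- matrix(volume@signal, prod(d[1:3]), d[4])
  idx <- which(mask)
  if (length(b0) >= 2) {
    b0m <- smat[idx, b0, drop = FALSE]
    mb0 <- rowMeans(b0m)
    hi <- mb0 > 0.5 * median(mb0[mb0 > 0])
    if (!any(hi)) hi <- mb0 > 0
    diffs <- b0m[hi, -1, drop = FALSE] - b0m[hi, -length(b0), drop = FALSE]
    return(sd(as.numeric(diffs)) / sqrt(2))
  }
  X <- buildDesign(volume@scheme)
  S <- t(smat[idx, , drop = FALSE])
  fit <- cpp_fit_dti(S, X, "lls", 0, 1L, 1e-8)
  pred <- exp(X %*% fit$beta)
  r <- S - pred
  1.4826 * median(abs(r))
}
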