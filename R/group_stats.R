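## Voxel-based group analysis on FA maps: Gaussian smoothing, white-matter
## masking, ANCOVA effect sizes (partial eta-squared via Type-III model
## comparison), covariate-adjusted Hedges' g, partial Spearman correlation,
## cluster extraction/labeling and cross-fit map averaging.
##
## All voxelwise regressions share one design per analysis, so fits are
## vectorized: a single QR of the subject-level design is applied to the
## subjects x voxels response matrix.

shift_array3 <- function(a, off, axis) {
  d <- dim(a)
  out <- array(0, d)
  if (abs(off) >= d[axis]) return(out)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  if (off >= 0) {
    dst[[axis]] <- (1 + off):d[axis]
    src[[axis]] <- 1:(d[axis] - off)
  } else {
    dst[[axis]] <- 1:(d[axis] + off)
    src[[axis]] <- (1 - off):d[axis]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

gauss_kernel_1d <- function(sd_vox, truncate = 4) {
  if (sd_vox <= 0) return(1)
  r <- max(1L, ceiling(truncate * sd_vox))
  k <- exp(-0.5 * ((-r):r / sd_vox)^2)
  k / sum(k)
}

conv_separable <- function(a, kernels) {
  for (axis in 1:3) {
    k <- kernels[[axis]]
    if (length(k) == 1) next
    r <- (length(k) - 1) / 2
    acc <- array(0, dim(a))
    for (j in seq_along(k))
      acc <- acc + k[j] * shift_array3(a, j - r - 1, axis)
    a <- acc
  }
  a
}

#' Smooth a 3D map with an isotropic Gaussian kernel
#'
#' The kernel SD is \code{sigma_mm} converted to voxels per axis and
#' truncated at 4 SD. With a mask, smoothing is mask-normalized —
#' smooth(map * mask) / smooth(mask) inside the mask and zero outside — so
#' constant regions are preserved and values never bleed across the mask
#' edge. Without a mask a plain zero-padded convolution is applied.
#'
#' @param map 3D array or \linkS4class{StatMap}.
#' @param sigma_mm kernel sigma in mm (0 = identity).
#' @param voxel_size length-3 voxel size in mm (taken from the map when it is
#'   a \linkS4class{StatMap}).
#' @param mask optional 3D logical array.
#' @return Object of the same type as \code{map}.
#' @export
smoothMap <- function(map, sigma_mm, voxel_size = NULL, mask = NULL) {
  is_map <- is(map, "StatMap")
  arr <- if (is_map) map@values else map
  if (is.null(voxel_size)) {
    if (!is_map) stop("voxel_size required for a bare array")
    voxel_size <- map@voxelSize
  }
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  if (sigma_mm == 0) return(map)
  kernels <- lapply(1:3, function(ax) gauss_kernel_1d(sigma_mm / voxel_size[ax]))
  if (is.null(mask)) {
    sm <- conv_separable(arr, kernels)
  } else {
    stopifnot(identical(dim(mask), dim(arr)))
    m <- array(as.numeric(mask), dim(arr))
    num <- conv_separable(arr * m, kernels)
    den <- conv_separable(m, kernels)
    sm <- array(0, dim(arr))
    inside <- mask & den > 0
    sm[inside] <- num[inside] / den[inside]
  }
  if (is_map) { map@values <- sm; map } else sm
}

stack_fa <- function(fa_maps) {
  if (is.array(fa_maps) && length(dim(fa_maps)) == 4) return(fa_maps)
  stopifnot(is.list(fa_maps), length(fa_maps) >= 1)
  arrs <- lapply(fa_maps, function(m) if (is(m, "StatMap")) m@values else m)
  array(unlist(arrs), c(dim(arrs[[1]]), length(arrs)))
}

#' White-matter analysis mask from cohort FA maps
#'
#' A voxel enters the mask when the mean FA across subjects strictly exceeds
#' the threshold.
#'
#' @param fa_maps list of per-subject \linkS4class{FAMap}/3D arrays, or a 4D
#'   array (grid x subjects).
#' @param threshold mean-FA cutoff (default 0.20).
#' @return 3D logical array.
#' @export
wmMask <- function(fa_maps, threshold = 0.20) {
  if (is.list(fa_maps) && length(fa_maps) == 0) stop("empty FA map list")
  st <- stack_fa(fa_maps)
  mean_fa <- apply(st, 1:3, mean)
  mean_fa > threshold
}

#' Bartlett's test of equal variance across groups
#'
#' Intended as an advisory ANCOVA assumption gate on a scalar per-subject
#' summary (typically mean white-matter FA): the result is returned for
#' logging and does not stop an analysis.
#'
#' @param values_by_group list of numeric vectors, one per group (each of
#'   length >= 2).
#' @return list(statistic, p.value, df).
#' @export
bartlettGate <- function(values_by_group) {
  if (length(values_by_group) < 2) stop("need at least two groups")
  if (any(vapply(values_by_group, length, integer(1)) < 2))
    stop("each group needs at least two observations")
  if (any(vapply(values_by_group, function(v) var(v) == 0, logical(1))))
    stop("degenerate group with zero variance")
  bt <- bartlett.test(values_by_group)
  list(statistic = unname(bt$statistic), p.value = bt$p.value,
       df = unname(bt$parameter))
}

## Shared machinery: vectorized least squares of a subjects x voxels matrix
## on a fixed design, returning residual sums of squares (and coefficients).
rss_fit <- function(X, Y) {
  qx <- qr(X)
  res <- qr.resid(qx, Y)
  colSums(res^2)
}

group_design <- function(cohort, covariates = TRUE) {
  # effect coding (sum contrasts) for the 3-level group factor
  g <- cohort$group
  lev <- levels(droplevels(g))
  C <- stats::contr.sum(length(lev))
  G <- C[as.integer(droplevels(g)), , drop = FALSE]
  X <- cbind(1, G)
  dropped <- character()
  if (covariates) {
    if (length(unique(cohort$age)) > 1) X <- cbind(X, age = cohort$age)
    else dropped <- c(dropped, "age")
    if (length(unique(cohort$gender)) > 1) X <- cbind(X, gender = cohort$gender)
    else dropped <- c(dropped, "gender")
  }
  list(X = X, n_group_cols = ncol(G), dropped = dropped)
}

#' Voxelwise ANCOVA effect size (partial eta-squared) for the group factor
#'
#' Fits FA ~ group + age + gender per voxel with the three-level group
#' factor effect-coded and computes the Type-III partial eta-squared of the
#' group factor by model comparison: eta2p = (SSE_reduced - SSE_full) /
#' SSE_reduced, where the reduced model drops the group columns. A constant
#' covariate (e.g. a single-gender cohort) is dropped with a warning.
#'
#' @param fa_stack 4D array (grid x subjects) or list of per-subject maps.
#' @param cohort validated cohort table (see \code{\link{readCohort}}).
#' @param mask 3D logical analysis mask (default: all voxels).
#' @param voxel_size length-3 mm (default 1 mm isotropic for bare arrays).
#' @return A \linkS4class{StatMap} of kind "eta2p" (NA outside the mask).
#' @export
ancovaEta2p <- function(fa_stack, cohort, mask = NULL, voxel_size = c(1, 1, 1)) {
  st <- stack_fa(fa_stack)
  d <- dim(st)
  n <- d[4]
  stopifnot(n == nrow(cohort))
  if (any(table(droplevels(cohort$group)) < 3))
    stop("need at least 3 subjects per group")
  if (any(!is.finite(cohort$age)) || any(!is.finite(cohort$gender)))
    stop("missing age or gender")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  idx <- which(mask)
  Y <- t(matrix(st, prod(d[1:3]), n)[idx, , drop = FALSE])

  des <- group_design(cohort)
  if (length(des$dropped))
    warning("dropping constant covariate(s): ", paste(des$dropped, collapse = ", "))
  X_full <- des$X
  X_red <- X_full[, -(2:(1 + des$n_group_cols)), drop = FALSE]
  sse_f <- rss_fit(X_full, Y)
  sse_r <- rss_fit(X_red, Y)
  eta <- ifelse(sse_r <= .Machine$double.eps * n,
                0, (sse_r - sse_f) / sse_r)
  eta <- pmin(pmax(eta, 0), 1)
  vals <- array(NA_real_, d[1:3])
  vals[idx] <- eta
  statMap(vals, "eta2p", voxel_size, contrast = "AD vs MCI vs HC",
          thresholds = list())
}

#' Voxelwise covariate-adjusted Hedges' g between two groups
#'
#' Fits FA ~ group + age + gender on the two requested groups; g is the
#' small-sample-corrected standardized adjusted mean difference
#' J * (mean_A - mean_B) / sqrt(residual mean square), with
#' J = 1 - 3 / (4 (n1 + n2) - 9). The sign convention is first-listed group
#' minus second, so \code{groups = c("AD", "HC")} is negative where AD is
#' lower. Set \code{adjusted = FALSE} for the raw two-sample form.
#'
#' @param fa_stack 4D array (grid x subjects for the full cohort) or list.
#' @param cohort cohort table matching the stack's subject order.
#' @param groups length-2 character, contrast as (first - second).
#' @param mask 3D logical analysis mask.
#' @param adjusted include age and gender covariates (default TRUE).
#' @param voxel_size length-3 mm.
#' @return A \linkS4class{StatMap} of kind "g".
#' @export
hedgesG <- function(fa_stack, cohort, groups = c("AD", "HC"), mask = NULL,
                    adjusted = TRUE, voxel_size = c(1, 1, 1)) {
  st <- stack_fa(fa_stack)
  d <- dim(st)
  stopifnot(d[4] == nrow(cohort), length(groups) == 2)
  sel <- cohort$group %in% groups
  n1 <- sum(cohort$group == groups[1]); n2 <- sum(cohort$group == groups[2])
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  idx <- which(mask)
  Y <- t(matrix(st, prod(d[1:3]), d[4])[idx, sel, drop = FALSE])
  sub <- cohort[sel, ]
  ind <- as.numeric(sub$group == groups[1])
  X <- cbind(1, ind)
  if (adjusted) {
    if (length(unique(sub$age)) > 1) X <- cbind(X, sub$age)
    if (length(unique(sub$gender)) > 1) X <- cbind(X, sub$gender)
  }
  qx <- qr(X)
  cf <- qr.coef(qx, Y)[2, ]
  sse <- colSums(qr.resid(qx, Y)^2)
  dfree <- nrow(X) - ncol(X)
  s <- sqrt(sse / dfree)
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  # voxels with (numerically) zero residual variance: g is 0 when the
  # adjusted difference is also zero, undefined otherwise
  thr <- 1e-10 * (max(abs(Y)) + 1)
  gval <- ifelse(s > thr, J * cf / s, ifelse(abs(cf) <= thr, 0, NA_real_))
  vals <- array(NA_real_, d[1:3])
  vals[idx] <- gval
  statMap(vals, "g", voxel_size,
          contrast = paste(groups[1], "vs", groups[2]))
}

#' Voxelwise partial Spearman correlation between FA and a cognitive score
#'
#' FA values and scores are rank-transformed (average ranks on ties), each
#' rank vector is residualized on age and gender, and rho is the Pearson
#' correlation of the residuals. Subjects with a missing score are excluded
#' pairwise. A constant score yields a zero map with attribute
#' \code{degenerate = TRUE}.
#'
#' @param fa_stack 4D array or list (full cohort).
#' @param scores numeric vector of the cognitive score, NA allowed.
#' @param cohort cohort table matching the stack.
#' @param mask 3D logical analysis mask.
#' @param voxel_size length-3 mm.
#' @return A \linkS4class{StatMap} of kind "rho".
#' @export
partialSpearman <- function(fa_stack, scores, cohort, mask = NULL,
                            voxel_size = c(1, 1, 1)) {
  st <- stack_fa(fa_stack)
  d <- dim(st)
  stopifnot(d[4] == nrow(cohort), length(scores) == d[4])
  keep <- which(!is.na(scores))
  if (length(keep) < 4) stop("need at least 4 subjects with non-missing scores")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  idx <- which(mask)
  Y <- t(matrix(st, prod(d[1:3]), d[4])[idx, keep, drop = FALSE])
  sc <- scores[keep]
  degenerate <- length(unique(sc)) == 1
  vals <- array(NA_real_, d[1:3])
  if (degenerate) {
    vals[idx] <- 0
  } else {
    Z <- cbind(1, cohort$age[keep], cohort$gender[keep])
    qz <- qr(Z)
    Yr <- apply(Y, 2, rank)
    sr <- rank(sc)
    ry <- qr.resid(qz, Yr)
    rs <- qr.resid(qz, sr)
    denom <- sqrt(colSums(ry^2) * sum(rs^2))
    rho <- ifelse(denom > 0, colSums(ry * rs) / denom, 0)
    vals[idx] <- pmin(pmax(rho, -1), 1)
  }
  out <- statMap(vals, "rho", voxel_size, contrast = "FA ~ score")
  attr(out, "degenerate") <- degenerate
  out
}

make_cluster <- function(vox, values, sgn) {
  v <- values[vox]
  pk <- v[which.max(abs(v))]
  new("Cluster", voxels = vox, size = nrow(vox), peak = pk,
      centroid = colMeans(vox), sign = sgn)
}

#' Extract supra-threshold clusters from a statistic map
#'
#' Connected components of strictly supra-threshold voxels (|value| >
#' threshold two-sided; value > threshold one-sided), with positive and
#' negative components kept separate. Components whose size does not
#' strictly exceed \code{min_size} are discarded, following the "size > N
#' voxels" reporting convention. Clusters are sorted by size, descending.
#'
#' @param map a \linkS4class{StatMap} or 3D array.
#' @param threshold statistic cutoff (strict).
#' @param min_size cluster-size cutoff (strict; use 0 to keep all).
#' @param two_sided also extract negative components (default TRUE for g and
#'   rho maps, FALSE for eta2p when \code{map} is a StatMap).
#' @param connectivity 6, 18 or 26.
#' @return list of \linkS4class{Cluster}, possibly empty.
#' @export
extractClusters <- function(map, threshold, min_size = 100,
                            two_sided = NULL, connectivity = 26) {
  arr <- if (is(map, "StatMap")) map@values else map
  if (is.null(two_sided))
    two_sided <- if (is(map, "StatMap")) map@kind %in% c("g", "rho") else TRUE
  stopifnot(threshold > 0)
  d <- dim(arr)
  vals <- arr
  vals[!is.finite(vals)] <- 0
  out <- list()
  sides <- if (two_sided) c(1, -1) else 1
  for (sgn in sides) {
    supra <- (sgn * vals) > threshold
    if (!any(supra)) next
    lab <- cpp_label_components(as.logical(supra), as.integer(d),
                                as.integer(connectivity))
    for (l in seq_len(max(lab))) {
      vox <- which(lab == l, arr.ind = TRUE)
      if (nrow(vox) > min_size)
        out[[length(out) + 1]] <- make_cluster(vox, vals, sgn)
    }
  }
  if (length(out) > 1)
    out <- out[order(vapply(out, function(cl) cl@size, numeric(1)),
                     decreasing = TRUE)]
  out
}

#' Attach atlas-region overlaps to clusters
#'
#' For every region a cluster intersects, records the percentage of the
#' region covered by the cluster and the percentage of the cluster lying in
#' the region, sorted by region coverage (descending).
#'
#' @param clusters list of \linkS4class{Cluster}.
#' @param atlas a \linkS4class{LabelAtlas} on the same grid.
#' @param grid_dim grid dimensions the clusters were extracted on (used for
#'   the mismatch check).
#' @return The cluster list with \code{overlaps} filled.
#' @export
labelClusters <- function(clusters, atlas, grid_dim = NULL) {
  if (!is.null(grid_dim) && !identical(as.integer(grid_dim),
                                       as.integer(dim(atlas@labels))))
    stop("atlas grid does not match the statistic map grid")
  region_sizes <- table(atlas@labels[atlas@labels != 0])
  lapply(clusters, function(cl) {
    labs <- atlas@labels[cl@voxels]
    hit <- table(labs[labs != 0])
    if (length(hit)) {
      ov <- data.frame(
        region = unname(atlas@regionNames[names(hit)]),
        pctRegionCovered = 100 * as.numeric(hit) /
          as.numeric(region_sizes[names(hit)]),
        pctClusterInRegion = 100 * as.numeric(hit) / cl@size,
        stringsAsFactors = FALSE)
      ov <- ov[order(ov$pctRegionCovered, decreasing = TRUE), ]
      rownames(ov) <- NULL
      cl@overlaps <- ov
    }
    cl
  })
}

#' Average statistic maps voxelwise
#'
#' All maps must share grid, kind and contrast; the result is their
#' arithmetic mean (used to pool results across fits and acquisitions before
#' thresholding).
#'
#' @param maps list of \linkS4class{StatMap}.
#' @return A \linkS4class{StatMap}.
#' @export
averageMaps <- function(maps) {
  stopifnot(length(maps) >= 1)
  kinds <- vapply(maps, function(m) m@kind, character(1))
  if (length(unique(kinds)) != 1) stop("cannot average maps of mixed kinds")
  contrasts <- vapply(maps, function(m) m@contrast, character(1))
  if (length(unique(contrasts)) != 1)
    stop("cannot average maps of different contrasts")
  dims <- lapply(maps, function(m) dim(m@values))
  if (length(unique(dims)) != 1) stop("grid mismatch across maps")
  avg <- Reduce(`+`, lapply(maps, function(m) m@values)) / length(maps)
  statMap(avg, kinds[1], maps[[1]]@voxelSize, contrast = contrasts[1])
}

#' Tabulate clusters for reporting
#' @param clusters list of \linkS4class{Cluster} (after
#'   \code{\link{labelClusters}} if region columns are wanted).
#' @return data.frame with one row per cluster (id, size, peak, centroid,
#'   top region and its coverage).
#' @export
clusterTable <- function(clusters) {
  if (!length(clusters))
    return(data.frame(id = integer(), size = numeric(), peak = numeric(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      region = character(), pctRegionCovered = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    top <- if (nrow(cl@overlaps)) cl@overlaps[1, ] else
      data.frame(region = NA_character_, pctRegionCovered = NA_real_)
    data.frame(id = i, size = cl@size, peak = cl@peak,
               cx = cl@centroid[1], cy = cl@centroid[2], cz = cl@centroid[3],
               region = top$region, pctRegionCovered = top$pctRegionCovered,
               stringsAsFactors = FALSE)
  }))
}
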