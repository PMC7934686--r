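## Agreement across fit variants: ICC(3,1) (two-way mixed, consistency,
## single measure: variants fixed, subjects random), voxelwise ICC maps with
## leave-one-out diagnostics, and cross-fit correlation matrices of regional
## cluster volumes and effect sizes.

#' ICC(3,1): two-way mixed, consistency, single measure
#'
#' Computed from the two-way ANOVA decomposition of a subjects x raters
#' matrix without interaction replication:
#' ICC = (MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error).
#' Being the consistency form, it is invariant to adding a constant to any
#' rater column.
#'
#' @param ratings numeric matrix, subjects in rows, raters (fit variants) in
#'   columns; no missing cells.
#' @return ICC value in [-1, 1].
#' @export
icc31 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (anyNA(ratings)) stop("missing cells are not allowed")
  grand <- mean(ratings)
  sst <- sum((ratings - grand)^2)
  if (sst <= .Machine$double.eps * n * k * max(1, grand^2))
    stop("degenerate ratings: zero total variance")
  ssr <- k * sum((rowMeans(ratings) - grand)^2)
  ssc <- n * sum((colMeans(ratings) - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse
  if (denom <= 0) stop("degenerate ratings: zero total variance")
  (msr - mse) / denom
}

icc31_vectorized <- function(Y) {
  # Y: array (n subjects, k raters, V voxels); returns V ICC values (NA when
  # degenerate).
  d <- dim(Y)
  n <- d[1]; k <- d[2]; V <- d[3]
  Ym <- matrix(Y, n * k, V)
  grand <- colMeans(Ym)
  sst <- colSums(Ym^2) - n * k * grand^2
  rowm <- apply(Y, c(1, 3), mean)   # n x V
  colm <- apply(Y, c(2, 3), mean)   # k x V
  ssr <- k * (colSums(rowm^2) - n * grand^2)
  ssc <- n * (colSums(colm^2) - k * grand^2)
  sse <- pmax(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse
  icc <- (msr - mse) / denom
  scale_ref <- pmax(abs(grand)^2, 1)
  icc[sst <= .Machine$double.eps * n * k * scale_ref | denom <= 0] <- NA_real_
  pmin(pmax(icc, -1), 1)
}

#' Voxelwise ICC(3,1) across fit variants
#'
#' Per masked voxel the subjects x variants FA matrix is scored with
#' \code{\link{icc31}}; degenerate voxels (zero variance) are set to missing
#' and excluded from the reported mask mean (the "r-ICC").
#'
#' @param stack a \linkS4class{FitStack}.
#' @param mask 3D logical analysis mask.
#' @return list(iccMap = \linkS4class{StatMap} of kind "icc",
#'   meanICC = mean over the mask).
#' @export
voxelwiseICC <- function(stack, mask) {
  d <- dim(stack@data[[1]])
  stopifnot(identical(dim(mask), d[1:3]))
  idx <- which(mask)
  k <- length(stack@variants)
  n <- d[4]
  Y <- array(0, c(n, k, length(idx)))
  for (j in seq_len(k)) {
    m <- matrix(stack@data[[j]], prod(d[1:3]), n)
    Y[, j, ] <- t(m[idx, , drop = FALSE])
  }
  icc <- icc31_vectorized(Y)
  vals <- array(NA_real_, d[1:3])
  vals[idx] <- icc
  list(iccMap = statMap(vals, "icc", stack@voxelSize,
                        contrast = paste(stack@variants, collapse = "+")),
       meanICC = mean(icc, na.rm = TRUE))
}

#' Leave-one-out consistency across fit variants
#'
#' For each variant, the voxelwise ICC is recomputed on the stack without
#' it; the report gives the change in mean mask ICC (reduced minus full —
#' positive when removing the variant increases agreement) and the Pearson
#' correlation across masked voxels between the full and reduced ICC maps.
#'
#' @param stack a \linkS4class{FitStack} with at least 3 variants.
#' @param mask 3D logical analysis mask.
#' @return data.frame(variant, deltaMeanICC, mapCorrelation), one row per
#'   variant, plus attribute \code{fullMeanICC}.
#' @export
leaveOneOut <- function(stack, mask) {
  if (length(stack@variants) < 3) stop("need at least 3 variants")
  full <- voxelwiseICC(stack, mask)
  rows <- lapply(stack@variants, function(v) {
    keep <- setdiff(stack@variants, v)
    red_stack <- new("FitStack", variants = keep, data = stack@data[keep],
                     voxelSize = stack@voxelSize)
    red <- voxelwiseICC(red_stack, mask)
    a <- full$iccMap@values[mask]
    b <- red$iccMap@values[mask]
    ok <- is.finite(a) & is.finite(b)
    mc <- if (sum(ok) > 2 && sd(a[ok]) > 0 && sd(b[ok]) > 0)
      cor(a[ok], b[ok]) else NA_real_
    data.frame(variant = v,
               deltaMeanICC = red$meanICC - full$meanICC,
               mapCorrelation = mc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fullMeanICC") <- full$meanICC
  out
}

#' Cross-fit squared-correlation matrices of regional results
#'
#' For every variant pair, the Pearson correlation across regions of
#' significant-cluster volumes (and, separately, effect sizes) is squared.
#' Regions absent from a variant's results count as volume 0 / effect 0.
#'
#' @param per_fit_results named list (one element per variant) of data
#'   frames with columns \code{region}, \code{volume}, \code{effect}.
#' @return list(volume, effect): symmetric r^2 matrices with unit diagonal;
#'   cells are NA when fewer than 2 regions are available.
#' @export
crossfitMatrices <- function(per_fit_results) {
  stopifnot(length(per_fit_results) >= 2)
  variants <- names(per_fit_results)
  regions <- sort(unique(unlist(lapply(per_fit_results, `[[`, "region"))))
  get_vec <- function(df, col) {
    v <- setNames(rep(0, length(regions)), regions)
    if (nrow(df)) v[df$region] <- df[[col]]
    v
  }
  mats <- lapply(c("volume", "effect"), function(col) {
    vecs <- lapply(per_fit_results, get_vec, col = col)
    k <- length(variants)
    m <- matrix(NA_real_, k, k, dimnames = list(variants, variants))
    diag(m) <- 1
    if (length(regions) >= 2) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        if (sd(vecs[[i]]) > 0 && sd(vecs[[j]]) > 0)
          m[i, j] <- m[j, i] <- cor(vecs[[i]], vecs[[j]])^2
      }
    }
    m
  })
  names(mats) <- c("volume", "effect")
  mats
}
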