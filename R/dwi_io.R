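## File input/output: NIfTI volumes via RNifti, FSL-dialect bval/bvec text,
## cohort CSV and label-atlas TSV. Grids are never resampled here: maps must
## already share the reference grid (registration is out of scope and is
## enforced, not computed).

read_gradient_table <- function(path, nrow_expected = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("\r", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
  })
  if (any(vapply(rows, function(r) any(is.na(r)), logical(1))))
    stop("non-numeric entries in gradient table ", path)
  rows
}

#' Read a diffusion acquisition from NIfTI + FSL bval/bvec files
#'
#' The bval file holds one whitespace-delimited row of b-values; the bvec
#' file holds three rows (x, y, z components). Both space- and tab-delimited
#' files and Windows line endings are accepted. Diffusion-weighted b-vectors
#' are re-normalized to unit length when their norm deviates from 1 by less
#' than 1e-3. Vectors are interpreted in the image frame exactly as stored
#' (gradient-frame rotation is preprocessing and out of scope).
#'
#' @param image_path path to a 4D NIfTI file.
#' @param bval_path path to the b-value text file.
#' @param bvec_path path to the b-vector text file.
#' @param subject_id subject identifier stored on the object (defaults to the
#'   image file name).
#' @return A \linkS4class{DWIVolume}; voxel sizes come from the NIfTI header.
#' @export
readDWI <- function(image_path, bval_path, bvec_path,
                    subject_id = sub("\\.nii(\\.gz)?$", "", basename(image_path))) {
  img <- RNifti::readNifti(image_path)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4)
    stop("expected a 4D (3D + volumes) NIfTI file: ", image_path)
  nvol <- dim(arr)[4]

  bval_rows <- read_gradient_table(bval_path)
  bvals <- unlist(bval_rows)
  if (length(bvals) != nvol)
    stop(sprintf("volume count mismatch %d vs %d between image and bval table",
                 nvol, length(bvals)))
  if (any(bvals < 0)) stop("negative b-value in ", bval_path)

  bvec_rows <- read_gradient_table(bvec_path)
  if (length(bvec_rows) != 3)
    stop("bvec file must have 3 rows (x, y, z): ", bvec_path)
  if (any(lengths(bvec_rows) != nvol))
    stop(sprintf("volume count mismatch %d vs %d between image and bvec table",
                 nvol, length(bvec_rows[[1]])))
  bvecs <- t(do.call(rbind, bvec_rows))

  scheme <- gradientScheme(bvals, bvecs)
  vs <- RNifti::pixdim(img)[1:3]
  new("DWIVolume", signal = arr, voxelSize = as.numeric(vs), scheme = scheme,
      subjectID = subject_id, refHeader = RNifti::niftiHeader(img))
}

#' Write a 3D map as NIfTI next to a reference acquisition
#'
#' The file inherits the reference's voxel size and affine and is stored as
#' 32-bit float; values round-trip through \code{RNifti::readNifti} to within
#' the float32 cast.
#'
#' @param map a \linkS4class{StatMap} or a 3D array on the reference grid.
#' @param reference a \linkS4class{DWIVolume} (or a \linkS4class{StatMap})
#'   defining the grid and header.
#' @param out_path output file path (.nii or .nii.gz).
#' @return \code{out_path}, invisibly.
#' @export
writeMap <- function(map, reference, out_path) {
  arr <- if (is(map, "StatMap")) map@values else map
  if (length(dim(arr)) != 3) stop("map must be 3D")
  ref_dim <- if (is(reference, "DWIVolume")) dim(reference@signal)[1:3]
             else dim(reference@values)
  if (!identical(dim(arr), ref_dim))
    stop(sprintf("grid mismatch: map %s vs reference %s",
                 paste(dim(arr), collapse = "x"),
                 paste(ref_dim, collapse = "x")))
  vs <- if (is(reference, "DWIVolume")) reference@voxelSize else reference@voxelSize
  hdr <- if (is(reference, "DWIVolume")) reference@refHeader else NULL
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  if (!is.null(hdr)) {
    xf <- RNifti::xform(hdr)
    img <- RNifti::asNifti(arr, reference = NULL)
    RNifti::qform(img) <- structure(xf, code = 2L)
  }
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, out_path, datatype = "float")
  invisible(out_path)
}

#' Read and validate a subject covariate table
#'
#' Requires columns id, group, age and gender; MoCA, MMSE and ADAS are kept
#' when present and created as all-missing otherwise. Gender is encoded as a
#' 0/1 indicator (female = 1); character encodings "F"/"female" and
#' "M"/"male" are mapped, and the mapping used is recorded in the
#' \code{genderCoding} attribute.
#'
#' @param csv_path path to a CSV file with a header row.
#' @return A validated data.frame with columns id, group (factor with levels
#'   HC, MCI, AD), age, gender, MoCA, MMSE, ADAS.
#' @export
readCohort <- function(csv_path) {
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  validateCohort(df)
}

#' Validate an in-memory cohort table
#' @param df data.frame with at least id, group, age, gender.
#' @return The validated, normalized data.frame (see \code{\link{readCohort}}).
#' @export
validateCohort <- function(df) {
  need <- c("id", "group", "age", "gender")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("cohort table lacks required columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!df$group %in% c("HC", "MCI", "AD"))
  if (length(bad))
    stop("unknown group label in rows ", paste(bad, collapse = ", "),
         ": ", paste(unique(df$group[bad]), collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate subject ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("age must be positive and non-missing for all subjects")
  coding <- "numeric 0/1 as given"
  if (is.character(df$gender) || is.factor(df$gender)) {
    gl <- tolower(as.character(df$gender))
    mapped <- ifelse(gl %in% c("f", "female", "1"), 1,
                     ifelse(gl %in% c("m", "male", "0"), 0, NA))
    if (any(is.na(mapped)))
      stop("unrecognized gender values: ",
           paste(unique(df$gender[is.na(mapped)]), collapse = ", "))
    df$gender <- mapped
    coding <- "female = 1, male = 0"
  }
  if (!all(df$gender %in% c(0, 1)))
    stop("gender must be a 0/1 indicator")
  for (sc in c("MoCA", "MMSE", "ADAS"))
    if (!sc %in% names(df)) df[[sc]] <- NA_real_
  df$group <- factor(df$group, levels = c("HC", "MCI", "AD"))
  attr(df, "genderCoding") <- coding
  df
}

#' Read a label atlas from a NIfTI label volume and a TSV lookup
#'
#' @param nifti_path path to an integer-valued 3D NIfTI label volume.
#' @param tsv_path path to a two-column tab-separated file (label, name),
#'   without a header.
#' @return A \linkS4class{LabelAtlas}.
#' @export
readLabelAtlas <- function(nifti_path, tsv_path) {
  img <- RNifti::readNifti(nifti_path)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) != 3) stop("label volume must be 3D")
  lut <- read.delim(tsv_path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(lut) < 2) stop("label lookup must have two tab-separated columns")
  nm <- setNames(as.character(lut[[2]]), as.character(as.integer(lut[[1]])))
  labelAtlas(round(arr), nm)
}

#' Write a DWIVolume as NIfTI + bval/bvec
#' @param volume a \linkS4class{DWIVolume}.
#' @param prefix output path prefix; writes prefix.nii.gz, prefix.bval,
#'   prefix.bvec.
#' @return Named character vector of the three paths, invisibly.
#' @export
writeDWI <- function(volume, prefix) {
  img <- RNifti::asNifti(volume@signal)
  RNifti::pixdim(img) <- c(volume@voxelSize, 1)
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  bval <- paste0(prefix, ".bval")
  writeLines(paste(format(volume@scheme@bvals, trim = TRUE), collapse = " "), bval)
  bvec <- paste0(prefix, ".bvec")
  writeLines(apply(t(volume@scheme@bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec)
  invisible(c(image = nii, bval = bval, bvec = bvec))
}
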