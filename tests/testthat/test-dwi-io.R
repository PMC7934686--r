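test_that("DWI volumes round-trip through NIfTI + bval/bvec files", {
  sch <- makeScheme(12, 2, 1000)
  set.seed(5)
  arr <- array(runif(4 * 4 * 3 * nVolumes(sch), 10, 1000),
               c(4, 4, 3, nVolumes(sch)))
  vol <- new("DWIVolume", signal = arr, voxelSize = c(2, 2, 2.4),
             scheme = sch, subjectID = "rt", refHeader = NULL)
  prefix <- file.path(tempdir(), "rt_subj")
  paths <- writeDWI(vol, prefix)
  back <- readDWI(paths["image"], paths["bval"], paths["bvec"])
  expect_equal(signalArray(back), arr, tolerance = 1e-6)
  expect_equal(voxelSize(back), c(2, 2, 2.4), tolerance = 1e-6)
  expect_equal(bValues(back), bValues(vol))
  expect_equal(bVectors(back), bVectors(vol), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("gradient tables accept tabs and Windows line endings", {
  sch <- makeScheme(10, 1, 1000)
  arr <- array(100, c(2, 2, 2, nVolumes(sch)))
  vol <- new("DWIVolume", signal = arr, voxelSize = c(1, 1, 1),
             scheme = sch, subjectID = "d", refHeader = NULL)
  prefix <- file.path(tempdir(), "dialect")
  paths <- writeDWI(vol, prefix)
  # rewrite with tab separators and CRLF endings
  bv <- readLines(paths["bval"])
  writeLines(gsub(" ", "\t", bv), paths["bval"], sep = "\r\n")
  gv <- readLines(paths["bvec"])
  writeLines(gsub(" ", "\t", gv), paths["bvec"], sep = "\r\n")
  back <- readDWI(paths["image"], paths["bval"], paths["bvec"])
  expect_equal(bValues(back), bValues(vol))
  expect_equal(bVectors(back), bVectors(vol), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("mismatched or invalid gradient tables are rejected with counts", {
  sch <- makeScheme(10, 1, 1000)
  arr <- array(100, c(2, 2, 2, nVolumes(sch)))
  vol <- new("DWIVolume", signal = arr, voxelSize = c(1, 1, 1),
             scheme = sch, subjectID = "e", refHeader = NULL)
  prefix <- file.path(tempdir(), "mis")
  paths <- writeDWI(vol, prefix)
  writeLines(paste(rep("1000", 10), collapse = " "), paths["bval"])
  expect_error(readDWI(paths["image"], paths["bval"], paths["bvec"]),
               "volume count mismatch 11 vs 10")
  writeLines(paste(c(rep("1000", 10), "-5"), collapse = " "), paths["bval"])
  expect_error(readDWI(paths["image"], paths["bval"], paths["bvec"]),
               "negative b-value")
})

test_that("maps round-trip as float32 and grids are enforced", {
  sch <- makeScheme(12, 1, 1000)
  arr <- array(500, c(20, 20, 10, nVolumes(sch)))
  ref <- new("DWIVolume", signal = arr, voxelSize = c(2, 2, 2),
             scheme = sch, subjectID = "ref", refHeader = NULL)
  set.seed(9)
  fa <- array(runif(20 * 20 * 10), c(20, 20, 10))
  p <- file.path(tempdir(), "famap.nii.gz")
  writeMap(fa, ref, p)
  back <- as.array(RNifti::readNifti(p))
  expect_equal(back, fa, tolerance = 1e-6, ignore_attr = TRUE)

  zero <- array(0, c(20, 20, 10))
  pz <- file.path(tempdir(), "zero.nii.gz")
  writeMap(zero, ref, pz)
  expect_equal(sum(as.array(RNifti::readNifti(pz))), 0)

  bad <- array(0, c(20, 20, 12))
  expect_error(writeMap(bad, ref, p), "grid mismatch")
})

test_that("cohort tables are validated and normalized", {
  csv <- file.path(tempdir(), "cohort_ok.csv")
  writeLines(c("id,group,age,gender,MMSE",
               "s1,HC,70,F,29", "s2,MCI,72,M,27", "s3,AD,76,F,24"), csv)
  tab <- readCohort(csv)
  expect_equal(nrow(tab), 3)
  expect_equal(levels(tab$group), c("HC", "MCI", "AD"))
  expect_equal(tab$gender, c(1, 0, 1))
  expect_true(all(is.na(tab$MoCA)))   # absent score column kept as missing
  expect_false(anyNA(tab$MMSE))

  bad <- file.path(tempdir(), "cohort_bad.csv")
  writeLines(c("id,group,age,gender", "s1,HC,70,1", "s2,CTL,72,0"), bad)
  expect_error(readCohort(bad), "unknown group label in rows 2")

  dup <- file.path(tempdir(), "cohort_dup.csv")
  writeLines(c("id,group,age,gender", "s1,HC,70,1", "s1,AD,72,0"), dup)
  expect_error(readCohort(dup), "duplicate")
})

test_that("label atlases read from NIfTI + TSV and validate names", {
  lab <- array(0L, c(6, 6, 4))
  lab[2:4, 2:4, 2:3] <- 1L
  lab[5, 5, 1] <- 2L
  img <- RNifti::asNifti(lab + 0)
  pn <- file.path(tempdir(), "atlas.nii.gz")
  RNifti::writeNifti(img, pn)
  pt <- file.path(tempdir(), "atlas.tsv")
  writeLines(c("1\tfornix", "2\tsplenium"), pt)
  atl <- readLabelAtlas(pn, pt)
  expect_equal(unname(regionNames(atl)[["1"]]), "fornix")
  expect_equal(sum(atlasLabels(atl) == 1L), 18)
  expect_error(labelAtlas(lab, c("1" = "fornix")), "labels without names")
})
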