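test_that("NIfTI round trip preserves voxels exactly and spacing to float precision", {
  set.seed(101)
  v <- ct_volume(array(rnorm(4 * 4 * 4, 0, 200), c(4, 4, 4)),
                 c(2.5, 0.871, 0.871), origin = c(1, 2, 3))
  for (ext in c(".nii", ".nii.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_volume(v, path)
    v2 <- read_volume(path)
    expect_identical(v2$voxels, v$voxels)
    expect_lt(max(abs(v2$spacing - v$spacing)), 1e-6)
    expect_lt(max(abs(v2$origin - v$origin)), 1e-6)
  }
})

test_that("label maps round trip and unknown labels are rejected by name", {
  set.seed(102)
  arr <- array(sample(0:18, 5 * 6 * 7, replace = TRUE), c(5, 6, 7))
  lab <- label_map(arr, c(2.5, 0.871, 0.871))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_labels(lab, path)
  expect_identical(read_labels(path)$labels, lab$labels)

  arr[1, 1, 1] <- 99L
  expect_error(label_map(arr, c(1, 1, 1)), "99")
  # on-disk file with an out-of-taxonomy label is also rejected at read
  bad <- withr::local_tempfile(fileext = ".nii")
  kyphofat:::write_nifti(arr, c(1, 1, 1), path = bad, datatype = 4L)
  expect_error(read_labels(bad), "99")
})

test_that("phantom pair survives an I/O round trip with fat% unchanged", {
  ph <- generate_phantom(small_phantom_spec(seed = 7L))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  vol <- read_volume(file.path(dir, "volume.nii.gz"))
  lab <- read_labels(file.path(dir, "labels.nii.gz"))
  q1 <- quantify_all(vol, lab)
  q2 <- quantify_all(ph$volume, ph$labels)
  # voxel data are exact, so counts and fat% are identical; volume_mL only
  # to float32 precision (NIfTI stores spacing as float32)
  expect_identical(q1[c("group", "n_voxels", "n_fat_voxels", "fat_percent")],
                   q2[c("group", "n_voxels", "n_fat_voxels", "fat_percent")])
  expect_equal(q1$volume_mL, q2$volume_mL, tolerance = 1e-6)
})

test_that("resampling: identity, constants, and label conservation", {
  set.seed(103)
  v <- ct_volume(array(rnorm(8 * 12 * 12), c(8, 12, 12)), c(2.5, 1, 1))
  id <- resample(v, preprocess_spec(target_spacing = c(2.5, 1, 1)))
  expect_equal(id$voxels, v$voxels, tolerance = 1e-12)

  const <- ct_volume(array(42, c(6, 10, 10)), c(2, 1, 1))
  r <- resample(const, preprocess_spec(target_spacing = c(1.3, 0.7, 0.9)))
  expect_equal(range(r$voxels), c(42, 42))
  expect_identical(r$spacing, c(1.3, 0.7, 0.9))

  lab <- label_map(array(sample(c(0L, 3L, 7L), 6 * 10 * 10, TRUE),
                         c(6, 10, 10)), c(2, 1, 1))
  rl <- resample(lab, preprocess_spec(target_spacing = c(1, 0.5, 0.5)))
  expect_true(all(unique(as.vector(rl$labels)) %in% c(0L, 3L, 7L)))
  expect_identical(resample(lab, preprocess_spec(target_spacing = c(2, 1, 1)))$labels,
                   lab$labels)
})

test_that("down-up resampling of a labeled sphere keeps Dice >= 0.9", {
  n <- 32
  ax <- seq_len(n) - n / 2 - 0.5
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  sphere <- array(ifelse(d2 <= 10^2, 1L, 0L), c(n, n, n))
  lab <- label_map(sphere, c(1, 1, 1),
                   taxonomy = data.frame(label = 1L, group = "psoas",
                                         side = "left"))
  down <- resample(lab, preprocess_spec(target_spacing = c(2, 2, 2)))
  up <- resample(down, preprocess_spec(target_spacing = c(1, 1, 1)))
  m <- pmin(dim(up$labels), dim(lab$labels))
  d <- dice(up$labels[1:m[1], 1:m[2], 1:m[3]] == 1L,
            lab$labels[1:m[1], 1:m[2], 1:m[3]] == 1L)
  expect_gte(as.numeric(d), 0.9)
})

test_that("preprocess_for_model clips, z-scores, and rejects zero variance", {
  two <- ct_volume(array(c(-200, 200), c(2, 1, 1)), c(1, 1, 1))
  z <- preprocess_for_model(two)
  # clipped to {-95, 116}: mean 10.5, population SD 105.5 -> {-1, +1}
  expect_equal(as.vector(z$voxels), c(-1, 1), tolerance = 1e-12)

  set.seed(104)
  v <- ct_volume(array(rnorm(10 * 10 * 10, 20, 60), c(10, 10, 10)), c(1, 1, 1))
  out <- preprocess_for_model(v)$voxels
  expect_lt(abs(mean(out)), 1e-6)
  expect_lt(abs(sqrt(mean((out - mean(out))^2)) - 1), 1e-6)

  flat <- ct_volume(array(0, c(3, 3, 3)), c(1, 1, 1))
  expect_error(preprocess_for_model(flat), "variance")
})

test_that("fat% is computed on raw HU, invariant to preprocessing a copy", {
  ph <- generate_phantom(small_phantom_spec(seed = 9L))
  before <- quantify_all(ph$volume, ph$labels)
  invisible(preprocess_for_model(ph$volume))   # separate copy, must not leak
  after <- quantify_all(ph$volume, ph$labels)
  expect_identical(before, after)
})
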