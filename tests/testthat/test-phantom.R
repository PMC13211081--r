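test_that("zero planted fat gives measured fat% of exactly 0 everywhere", {
  sp <- small_phantom_spec(per_group_fat_fraction = 0, seed = 1L)
  ph <- generate_phantom(sp)
  q <- quantify_all(ph$volume, ph$labels)
  expect_true(all(q$present))
  expect_equal(q$fat_percent, rep(0, 9))
})

test_that("planted fat fractions are recovered within binomial tolerance", {
  # >= 10,000-voxel compartment at fraction 0.30: recovery within 1 pp
  fr <- c(psoas = 0.1, quadratus_lumborum = 0.1, paraspinal = 0.30,
          latissimus_dorsi = 0.1, iliacus = 0.1, rectus_femoris = 0.1,
          rhomboid = 0.1, trapezius = 0.1, vastus = 0.1)
  sp <- phantom_spec(grid_shape = c(120, 128, 128),
                     per_group_fat_fraction = fr, seed = 42L)
  ph <- generate_phantom(sp)
  q <- quantify_all(ph$volume, ph$labels)
  para <- q[q$group == "paraspinal", ]
  expect_gte(para$n_voxels, 10000)
  expect_lt(abs(para$fat_percent - 30), 1)

  # every group within 3 binomial SD of its planted fraction
  gt <- ph$ground_truth
  tol <- 3 * 100 * sqrt(fr[gt$group] * (1 - fr[gt$group]) / gt$n_voxels)
  expect_true(all(abs(q$fat_percent - 100 * gt$planted_fraction) < tol))
})

test_that("measured fat% matches the generator's realized fat voxel count exactly", {
  # HU tails are >= 4 SD from the threshold, so the -20 HU rule recovers the
  # planted fat voxel set itself (not just its expectation)
  ph <- generate_phantom(small_phantom_spec(seed = 3L))
  q <- quantify_all(ph$volume, ph$labels)
  expect_identical(q$n_fat_voxels, as.numeric(ph$ground_truth$n_fat_voxels))
  expect_equal(q$volume_mL, ph$ground_truth$volume_mL)
})

test_that("straight spine yields parallel endplates and zero Cobb", {
  ph <- generate_phantom(small_phantom_spec(planted_cobb = 0, seed = 1L))
  expect_equal(cobb_angle(ph$endplates)$angle_deg, 0)
})

test_that("generators are bit-reproducible under a fixed seed", {
  sp <- small_phantom_spec(seed = 11L)
  ph1 <- generate_phantom(sp)
  ph2 <- generate_phantom(sp)
  expect_identical(ph1$volume$voxels, ph2$volume$voxels)
  expect_identical(ph1$ground_truth, ph2$ground_truth)

  cs <- cohort_spec(n_cases = 50, seed = 5L)
  expect_identical(generate_cohort(cs), generate_cohort(cs))

  ns <- rater_noise_spec(seed = 8L)
  tr <- c(30, 40, 50)
  expect_identical(simulate_raters(tr, ns), simulate_raters(tr, ns))
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(per_group_fat_fraction = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(hu_fat_mean = -40), "threshold")
  expect_error(phantom_spec(hu_muscle_mean = 0), "threshold")
  expect_error(phantom_spec(planted_cobb = 95), "planted_cobb")
  expect_error(phantom_spec(spacing = c(1, -1, 1)), "positive")
  # a grid without room for the nine craniocaudal stations
  expect_error(generate_phantom(phantom_spec(grid_shape = c(30, 64, 64))),
               "grid too small")
  expect_error(cohort_spec(n_cases = 5, n_surgery = 4, n_atrophy = 3),
               "exceed")
  expect_error(cohort_spec(per_muscle_loading = stats::setNames(
    rep(1.5, 9), muscle_groups())), "\\[-1, 1\\]")
  expect_error(rater_noise_spec(k_raters = 1), "at least 2")
})

test_that("perfectly loaded cohort gives r near 1; null loadings give null r", {
  g1 <- stats::setNames(c(1, rep(0, 8)), muscle_groups())
  cs <- cohort_spec(n_cases = 10000, per_muscle_loading = g1,
                    per_muscle_fat_mean = stats::setNames(rep(50, 9), muscle_groups()),
                    per_muscle_fat_sd = stats::setNames(rep(5, 9), muscle_groups()),
                    n_surgery = 0, n_atrophy = 0, n_fracture = 0,
                    n_transitional = 0, seed = 21L)
  co <- generate_cohort(cs)
  expect_gt(correlate(co, "psoas")$r, 0.99)

  # lambda = 0 for all muscles: |r| < 0.1 in >= 95% of seeds at n = 1000
  g0 <- stats::setNames(rep(0, 9), muscle_groups())
  ok <- vapply(1:40, function(s) {
    co <- generate_cohort(cohort_spec(
      n_cases = 1000, per_muscle_loading = g0,
      per_muscle_fat_mean = stats::setNames(rep(50, 9), muscle_groups()),
      per_muscle_fat_sd = stats::setNames(rep(5, 9), muscle_groups()),
      n_surgery = 0, n_atrophy = 0, n_fracture = 0, n_transitional = 0,
      seed = s))
    all(abs(vapply(muscle_groups(),
                   function(m) correlate(co, m)$r, numeric(1))) < 0.1)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("cohort bookkeeping, flags and latent ground truth are coherent", {
  cs <- cohort_spec(n_cases = 200, n_surgery = 7, n_atrophy = 5,
                    n_fracture = 20, n_transitional = 9, seed = 13L)
  co <- generate_cohort(cs)
  expect_equal(nrow(co), 200)
  expect_equal(sum(co$surgery), 7)
  expect_equal(sum(co$atrophy), 5)
  expect_equal(sum(co$fracture), 20)
  expect_equal(sum(co$transitional), 9)
  expect_false(any(co$surgery & co$atrophy))
  # atrophy flag consistent with the paraspinal >50% rule for every case
  expect_identical(co$atrophy, co$fat_paraspinal > 50)
  expect_true(all(co$fat_paraspinal[co$atrophy] > 50 &
                  co$fat_paraspinal[co$atrophy] <= 90))
  expect_true(all(vapply(muscle_groups(), function(g)
    all(co[[paste0("fat_", g)]] >= 0), logical(1))))
})

test_that("simulate_raters is noiseless when told to be, and calibrated when not", {
  tr <- c(20, 35.5, 50)
  m <- simulate_raters(tr, rater_noise_spec(per_rating_error_sd = 0, seed = 1L))
  expect_equal(unname(m), matrix(tr, 3, 4))

  bias <- c(1, -1, 0.5, -0.5)
  mb <- simulate_raters(tr, rater_noise_spec(per_rating_error_sd = 0,
                                             per_rater_bias = bias, seed = 1L))
  expect_equal(unname(mb), outer(tr, bias, `+`))

  # n = 533, error SD 3.69, k = 4: mean per-case sample SD ~ 3.4
  # (E[S] = sigma * c4(4) ~ 0.9213 * 3.69)
  sds <- vapply(1:10, function(s) {
    tr <- with(list(), { set.seed(1000 + s); stats::rnorm(533, 38.6, 13.5) })
    per_case_sd(simulate_raters(tr, rater_noise_spec(seed = s)))$mean_sd
  }, numeric(1))
  expect_lt(abs(mean(sds) - 3.4), 0.1)
})
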