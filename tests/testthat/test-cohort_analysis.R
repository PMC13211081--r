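# Minimal cohort table with controllable flags.
toy_cohort <- function(n, ids = seq_len(n), surgery = integer(),
                       atrophy = integer(), fat_paraspinal = rep(10, n)) {
  co <- data.frame(case_id = ids, cobb_mean = seq(20, 60, length.out = n))
  for (g in muscle_groups()) co[[paste0("fat_", g)]] <- rep(5, n)
  co$fat_paraspinal <- fat_paraspinal
  co$fat_paraspinal[match(atrophy, ids)] <- 70
  co$surgery <- co$case_id %in% surgery
  co$atrophy <- co$fat_paraspinal > 50
  co$fracture <- FALSE
  co$transitional <- FALSE
  co$sex <- rep(c("M", "F"), length.out = n)
  co
}

test_that("apply_exclusions removes the surgery/atrophy union and logs per case", {
  co <- toy_cohort(10, surgery = c(2, 5), atrophy = c(5, 7))
  res <- apply_exclusions(co)
  expect_equal(nrow(res$cohort), 7)
  expect_equal(nrow(res$log), 3)
  expect_setequal(res$log$case_id, c(2, 5, 7))
  expect_equal(res$log$rules[res$log$case_id == 5], "surgery+atrophy")
  expect_equal(res$log$rules[res$log$case_id == 2], "surgery")

  # no flags: unchanged cohort, empty log
  clean <- toy_cohort(10)
  res0 <- apply_exclusions(clean)
  expect_identical(res0$cohort, clean)
  expect_equal(nrow(res0$log), 0)

  # idempotence
  res2 <- apply_exclusions(res$cohort)
  expect_identical(res2$cohort, res$cohort)
  expect_equal(nrow(res2$log), 0)
})

test_that("atrophy rule is evaluated on paraspinal fat% only", {
  co <- toy_cohort(6)
  co$fat_vastus <- c(95, rep(5, 5))   # extreme non-paraspinal value
  co$atrophy <- NULL                  # force derivation from fat_paraspinal
  res <- apply_exclusions(co)
  expect_equal(nrow(res$cohort), 6)
})

test_that("correlate matches hand values and the cor.test oracle", {
  co <- data.frame(case_id = 1:4, cobb_mean = c(2, 1, 4, 3),
                   fat_psoas = c(1, 2, 3, 4))
  res <- correlate(co, "psoas")
  expect_equal(res$r, 0.6, tolerance = 1e-12)
  ct <- stats::cor.test(co$fat_psoas, co$cobb_mean)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_equal(res$n, 4)

  # y = x: r = 1, p -> 0
  co2 <- data.frame(case_id = 1:20, cobb_mean = 1:20, fat_psoas = 1:20)
  res2 <- correlate(co2, "psoas")
  expect_equal(res2$r, 1)
  expect_lt(res2$p, 1e-12)

  set.seed(81)
  co3 <- data.frame(case_id = 1:30, cobb_mean = stats::rnorm(30),
                    fat_psoas = stats::rnorm(30))
  r3 <- correlate(co3, "psoas")
  ct3 <- stats::cor.test(co3$fat_psoas, co3$cobb_mean)
  expect_equal(r3$r, unname(ct3$estimate), tolerance = 1e-12)
  expect_equal(r3$p, ct3$p.value, tolerance = 1e-12)
})

test_that("r is invariant to affine rescaling of either variable", {
  set.seed(82)
  co <- data.frame(case_id = 1:50, cobb_mean = stats::rnorm(50, 40, 10),
                   fat_psoas = stats::rnorm(50, 10, 3))
  r0 <- correlate(co, "psoas")$r
  co$cobb_mean <- co$cobb_mean * pi / 180       # degrees -> radians
  co$fat_psoas <- co$fat_psoas / 100            # percent -> fraction
  expect_equal(correlate(co, "psoas")$r, r0, tolerance = 1e-12)
})

test_that("correlate contract: small n undefined, zero variance errors", {
  co <- toy_cohort(2)
  expect_true(is.na(correlate(co, "psoas")$r))
  co5 <- toy_cohort(5)   # fat columns constant at 5
  expect_error(correlate(co5, "vastus"), "zero variance")
})

test_that("run_table bookkeeping ties raw and adjusted cohorts together", {
  cs <- cohort_spec(n_cases = 120, n_surgery = 5, n_atrophy = 3,
                    n_fracture = 10, n_transitional = 5, seed = 17L)
  co <- generate_cohort(cs)
  tab <- run_table(co)
  log <- attr(tab, "exclusion_log")
  expect_equal(nrow(log), 8)
  raw_n <- unique(tab$n_used[tab$cohort_label == "raw"])
  adj_n <- unique(tab$n_used[tab$cohort_label == "adjusted"])
  expect_equal(raw_n, 120)
  expect_equal(adj_n, 120 - nrow(log))

  # no confounders planted -> identical raw and adjusted tables
  cs0 <- cohort_spec(n_cases = 80, n_surgery = 0, n_atrophy = 0,
                     n_fracture = 0, n_transitional = 0, seed = 18L)
  co0 <- generate_cohort(cs0)
  tab0 <- run_table(co0)
  raw <- tab0[tab0$cohort_label == "raw", -1]
  adj <- tab0[tab0$cohort_label == "adjusted", -1]
  rownames(raw) <- rownames(adj) <- NULL
  expect_equal(raw, adj)
})

test_that("per-muscle exclusions touch only that muscle's analysis", {
  set.seed(83)
  co <- toy_cohort(20)
  for (g in muscle_groups()) co[[paste0("fat_", g)]] <- stats::rnorm(20, 5, 1)
  co$atrophy <- co$fat_paraspinal > 50
  rules <- exclusion_rules(per_muscle = list(trapezius = c(3, 4)))
  tab <- run_table(co, rules)
  expect_equal(tab$n_used[tab$muscle == "trapezius" &
                          tab$cohort_label == "raw"], 18)
  expect_equal(tab$n_used[tab$muscle == "psoas" &
                          tab$cohort_label == "raw"], 20)
})

test_that("stratify reports undefined strata without crashing", {
  cs <- cohort_spec(n_cases = 60, n_surgery = 0, n_atrophy = 0,
                    n_fracture = 0, n_transitional = 0, seed = 19L)
  co <- generate_cohort(cs)
  co$sex <- "F"                       # all-female cohort
  st <- stratify(co, "sex")
  male <- st[st$cohort_label == "sex=M", ]
  expect_true(all(is.na(male$r)))
  female <- st[st$cohort_label == "sex=F", ]
  expect_true(all(is.finite(female$r)))

  # strata sharing generating parameters differ only by sampling noise
  co2 <- generate_cohort(cohort_spec(n_cases = 2000, n_surgery = 0,
                                     n_atrophy = 0, n_fracture = 0,
                                     n_transitional = 0, seed = 20L))
  st2 <- stratify(co2, "sex")
  para <- st2[st2$muscle == "paraspinal", ]
  for (i in seq_len(nrow(para)))
    expect_lt(abs(para$r[i] - 0.42), 2 / sqrt(para$n_used[i]) + 0.05)
})

test_that("sensitivity drops are no-ops when no case holds the flag", {
  cs <- cohort_spec(n_cases = 50, n_surgery = 0, n_atrophy = 0,
                    n_fracture = 0, n_transitional = 0, seed = 22L)
  co <- generate_cohort(cs)
  base <- run_table(co, cohorts = "raw")
  sens <- sensitivity(co, "fracture")
  expect_equal(sens$r, base$r)
  expect_equal(sens$n_used, base$n_used)
})

test_that("summarize_fat computes per-muscle mean and sample SD", {
  co <- toy_cohort(2)
  co$fat_psoas <- c(10, 20)
  s <- summarize_fat(co)
  expect_equal(s$mean[s$muscle == "psoas"], 15)
  expect_equal(s$sd[s$muscle == "psoas"], sqrt(50), tolerance = 1e-9)
  expect_equal(round(s$sd[s$muscle == "psoas"], 2), 7.07)
  expect_equal(s$sd[s$muscle == "vastus"], 0)

  cs <- cohort_spec(n_cases = 4000, n_surgery = 0, n_atrophy = 0,
                    n_fracture = 0, n_transitional = 0, seed = 23L)
  sim <- summarize_fat(generate_cohort(cs))
  spec_mean <- cs$per_muscle_fat_mean[sim$muscle]
  # flooring at 0 biases means slightly upward for low-mean muscles
  expect_true(all(abs(sim$mean - spec_mean) < 0.6))
})

test_that("cohort analysis is deterministic end to end", {
  cs <- cohort_spec(n_cases = 100, seed = 24L)
  t1 <- run_table(generate_cohort(cs))
  t2 <- run_table(generate_cohort(cs))
  expect_identical(t1, t2)
})
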