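test_that("exclusion rules partition the fixture cohort into 23/3/15", {
  rep <- filter_cohort(fixture_cohort_41())
  expect_equal(rep$n_input, 41)
  expect_equal(rep$n_below_loq, 23)
  expect_equal(rep$n_abnormal_acr, 3)
  expect_equal(rep$n_retained, 15)
  expect_equal(rep$n_input,
               rep$n_below_loq + rep$n_abnormal_acr + rep$n_retained)
  expect_setequal(rep$excluded$reason, c("below_loq", "abnormal_acr"))
})

test_that("exclusion handles edge cohorts and counts stay conserved", {
  empty <- fixture_cohort_41()[0, ]
  rep0 <- filter_cohort(empty)
  expect_equal(c(rep0$n_input, rep0$n_below_loq, rep0$n_abnormal_acr,
                 rep0$n_retained), c(0, 0, 0, 0))

  clean <- fixture_cohort_41()
  clean$below_loq <- FALSE
  clean$ttma_mg_L <- pmax(clean$ttma_mg_L, 0.07)
  clean$acr_normal <- TRUE
  repc <- filter_cohort(clean)
  expect_equal(repc$n_retained, repc$n_input)

  # a record failing both rules is counted as below-LOQ (LOQ applied first)
  both <- clean[1:2, ]
  both$ttma_mg_L[1] <- 0.01
  both$acr_normal[1] <- FALSE
  repb <- filter_cohort(both)
  expect_equal(repb$n_below_loq, 1)
  expect_equal(repb$n_abnormal_acr, 0)

  # count conservation on random censored cohorts
  set.seed(5)
  for (i in 1:20) {
    co <- generate_cohort(cohort_gen_config(seed = i))
    r <- filter_cohort(co)
    expect_equal(r$n_input, r$n_below_loq + r$n_abnormal_acr + r$n_retained)
    expect_equal(nrow(r$retained) + nrow(r$excluded), r$n_input)
  }
})

test_that("duplicate ids and schema violations are rejected", {
  co <- fixture_cohort_41()
  co$child_id[2] <- co$child_id[1]
  expect_error(filter_cohort(co), class = "benzrisk_validation_error")
  co2 <- fixture_cohort_41()
  co2$ttma_mg_L[co2$below_loq][1] <- NA  # allowed: censored without value
  expect_silent(validate_cohort(co2))
  co2$ttma_mg_L[!co2$below_loq][1] <- NA  # not allowed
  expect_error(validate_cohort(co2), class = "benzrisk_validation_error")
})

test_that("inversion is the exact inverse of the forward chain", {
  p <- default_pbpk_parameters()
  ph <- physiology()
  for (x in c(0.5, 5.85, 50)) {
    y <- ttma_urine_forward(x, p, ph)$ttma_conc
    expect_equal(invert_air_concentration(y, p, ph), x, tolerance = 1e-6)
  }
  expect_equal(invert_air_concentration(0, p, ph), 0)
  # round trip in the other direction: forward(invert(y)) = y
  for (y in c(0.1, 0.81, 2.0)) {
    c_hat <- invert_air_concentration(y, p, ph)
    expect_equal(ttma_urine_forward(c_hat, p, ph)$ttma_conc, y,
                 tolerance = 1e-6)
  }
})

test_that("round trip holds across random parameter draws", {
  set.seed(42)
  for (i in 1:100) {
    p <- random_pbpk_parameters()
    ph <- random_physiology()
    x <- 10^runif(1, -2, 2)
    y <- ttma_urine_forward(x, p, ph)$ttma_conc
    expect_equal(invert_air_concentration(y, p, ph), x,
                 tolerance = 1e-6)
  }
})

test_that("observations above the metabolic ceiling raise a saturation error", {
  p <- default_pbpk_parameters()
  ph <- physiology()
  bound <- ttma_saturation_bound(p, ph)
  expect_error(invert_air_concentration(1.01 * bound, p, ph),
               class = "benzrisk_saturation_error")
  expect_error(invert_air_concentration(bound, p, ph),
               class = "benzrisk_saturation_error")
  expect_silent(invert_air_concentration(0.99 * bound, p, ph))
})

test_that("cohort estimate: moments, per-child inversion, degenerate cases", {
  rep <- filter_cohort(fixture_cohort_41())
  est <- cohort_estimate(rep, default_pbpk_parameters())
  expect_equal(est$n, 15)
  expect_equal(round(est$ttma_mean, 2), 0.81)
  expect_equal(round(est$ttma_sd, 2), 0.83)
  expect_length(est$air_conc_per_child, 15)
  expect_true(all(est$air_conc_per_child > 0))
  expect_gt(est$air_conc_sd, 0)

  # pooled mode inverts the mean once
  pooled <- cohort_estimate(rep, default_pbpk_parameters(), mode = "pooled")
  expect_length(pooled$air_conc_per_child, 1)
  expect_equal(pooled$air_conc_per_child,
               invert_air_concentration(est$ttma_mean,
                                        default_pbpk_parameters(),
                                        physiology()))

  # single retained child: sd reported as 0
  one <- rep
  one$retained <- rep$retained[1, ]
  est1 <- cohort_estimate(one, default_pbpk_parameters())
  expect_equal(est1$ttma_mean, rep$retained$ttma_mg_L[1])
  expect_equal(est1$ttma_sd, 0)
  expect_equal(est1$air_conc_sd, 0)

  # identical children give zero spread
  same <- rep
  same$retained <- rep$retained[c(1, 1, 1), ]
  same$retained$child_id <- c("a", "b", "c")
  expect_equal(cohort_estimate(same, default_pbpk_parameters())$air_conc_sd, 0)

  none <- rep
  none$retained <- rep$retained[0, ]
  expect_error(cohort_estimate(none, default_pbpk_parameters()),
               class = "benzrisk_empty_cohort_error")
})

test_that("raising any child's tt-MA never lowers the cohort mean estimate", {
  rep <- filter_cohort(fixture_cohort_41())
  p <- default_pbpk_parameters()
  base <- cohort_estimate(rep, p)$air_conc_mean
  bumped <- rep
  bumped$retained$ttma_mg_L[7] <- bumped$retained$ttma_mg_L[7] * 1.5
  expect_gt(cohort_estimate(bumped, p)$air_conc_mean, base)
})

test_that("cohort CSV round-trips through read/write", {
  fx <- fixture_cohort_41()
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(fx, path)
  back <- read_cohort_csv(path)
  expect_equal(back$child_id, fx$child_id)
  expect_equal(back$ttma_mg_L, fx$ttma_mg_L)
  expect_equal(back$below_loq, fx$below_loq)
  expect_equal(back$acr_normal, fx$acr_normal)
  unlink(path)
  expect_error(read_cohort_csv(tempfile()), class = "benzrisk_validation_error")
})

test_that("shipped fixture CSV matches the in-code fixture", {
  csv <- system.file("extdata", "cohort_fixture_synthetic.csv",
                     package = "benzrisk")
  expect_true(nzchar(csv))
  shipped <- read_cohort_csv(csv)
  built <- fixture_cohort_41()
  expect_equal(shipped$ttma_mg_L, built$ttma_mg_L)
  expect_equal(shipped$below_loq, built$below_loq)
})
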