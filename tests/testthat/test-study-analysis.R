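test_that("offence rates are normalised by session duration", {
  s <- driving_session("d1", "urban", "automatic", duration = 120,
                       offences = offence_events(t = seq(10, 60, by = 10),
                                                 kind = rep("over_speed", 6)))
  expect_equal(offences_per_second(s), 0.05)
  expect_equal(offences_per_second(s, kinds = "leaving_road"), 0)

  s0 <- driving_session("d2", "urban", "automatic", duration = 60)
  expect_equal(offences_per_second(s0), 0)
})

test_that("sorting the bundled urban summary by offence rate reproduces its order", {
  ref <- reference_study_summary("urban")
  shuffled <- ref[withr::with_seed(1, sample(nrow(ref))), ]
  ord <- shuffled[order(-shuffled$offences_per_s), "participant"]
  expect_equal(ord, c(7, 14, 1, 2, 3, 10, 4, 8, 13, 5, 12, 15, 11, 6, 9))
})

test_that("the normality screen applies the p > alpha convention", {
  withr::with_seed(73, {
    res <- shapiro_normality(rnorm(30))
    expect_true(res$p > 0 && res$p < 1)
    expect_identical(res$normal, res$p > 0.05)

    # type-I error calibration at alpha = 0.05
    rej <- mean(vapply(1:500, function(i) !shapiro_normality(rnorm(30))$normal,
                       NA))
    expect_lt(abs(rej - 0.05), 0.02)

    # power against a clearly non-normal alternative
    rej_exp <- mean(vapply(1:100, function(i)
      !shapiro_normality(rexp(100))$normal, NA))
    expect_gte(rej_exp, 0.95)
  })
  expect_error(shapiro_normality(c(1, 2)), "between 3 and 5000")
  expect_error(shapiro_normality(rep(1, 10)), "constant")
})

test_that("the Pearson implementation matches its defining formula and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)

  withr::with_seed(79, {
    for (rep in 1:10) {
      x <- rnorm(30); y <- rnorm(30)
      res <- pearson_correlation(x, y)
      ct <- stats::cor.test(x, y)  # independent reference implementation
      expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(res$p, ct$p.value, tolerance = 1e-12)
      # symmetry and affine invariance
      expect_equal(pearson_correlation(y, x)$r, res$r, tolerance = 1e-12)
      expect_equal(pearson_correlation(3 * x + 7, y)$r, res$r, tolerance = 1e-12)
    }
  })
  expect_error(pearson_correlation(1:5, 1:4), "equal length")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("the study table aggregates per driver and scenario with pooling", {
  co <- simulate_cohort(5, cohort_design(duration = 60,
                                         scenario_classes = c("urban", "interurban"),
                                         gears = c("automatic", "manual")),
                        seed = 83)
  tab <- build_study_table(co)
  expect_s3_class(tab, "study_table")
  expect_equal(nrow(tab), 10L)       # 5 drivers x 2 scenario classes
  expect_equal(unique(tab$n_sessions), 2L)  # both gears pooled
  expect_true(all(grepl("^rate_", names(tab)[grep("rate_", names(tab))])))
  expect_true(all(tab$offences_per_s >= 0))
  # questionnaire columns merged in
  expect_true(all(c("sss", "kss", "ess") %in% names(tab)))

  # pooled sd_w equals the sd over the concatenated samples
  ses <- co$sessions
  d1u <- ses[vapply(ses, function(s) s$driver_id == "d001" &&
                      s$scenario_class == "urban", NA)]
  allv <- unlist(lapply(d1u, function(s) s$traces$gyro$values))
  expect_equal(tab$sd_w[tab$driver_id == "d001" & tab$scenario_class == "urban"],
               sd(allv), tolerance = 1e-9)
})

test_that("correlation study recovers a planted link and respects the gate", {
  co <- simulate_cohort(100, cohort_design(plant = "sdw_leaving_road",
                                           rho_plant = 0.6), seed = 89)
  tab <- build_study_table(co)
  cs <- correlation_study(tab, scenario_class = "urban")
  row <- cs[cs$variable == "sd_w" & cs$offence == "leaving_road", ]
  expect_true(row$tested)
  expect_true(row$significant)
  expect_gt(row$r, 0.4)
  expect_lt(row$r, 0.8)
  # r equals the direct defining-formula computation on the same columns
  expect_equal(row$r, pearson_correlation(tab$sd_w, tab$rate_leaving_road)$r)

  # alpha only changes flags, not r
  cs2 <- correlation_study(tab, scenario_class = "urban", alpha = 0.001)
  m <- merge(cs, cs2, by = c("variable", "offence"))
  expect_equal(m$r.x, m$r.y)

  expect_error(correlation_study(tab[1:2, ]), "at least 3")
})

test_that("the low-attention study links sleepiness to quiescent steering", {
  co <- simulate_cohort(60, cohort_design(plant = "sss_offences",
                                          rho_plant = 0.6, duration = 300),
                        seed = 97)
  la <- low_attention_study(co)
  row <- la[la$outcome == "n_low_attention" & la$covariate == "sss", ]
  expect_true(row$tested)
  expect_gt(row$r, 0)
  expect_true(row$significant)

  # an all-alert cohort yields a (near-)constant outcome handled gracefully
  co0 <- simulate_cohort(5, cohort_design(plant = "none", duration = 60), seed = 101)
  la0 <- low_attention_study(co0)
  expect_s3_class(la0, "data.frame")
  expect_true(all(c("outcome", "covariate", "r", "p", "tested") %in% names(la0)))
})

test_that("gear-shift comparison pairs automatic and manual sessions", {
  mk <- function(id, gear, seed, bias) {
    simulate_session(driver_profile(id, seed = seed), gear = gear,
                     duration = 60, include_physio = FALSE, speed_bias = bias)
  }
  # automatic biased 8 km/h faster
  sessions <- unlist(lapply(1:3, function(i) {
    list(mk(sprintf("d%d", i), "automatic", 200 + i, 8),
         mk(sprintf("d%d", i), "manual", 300 + i, 0))
  }), recursive = FALSE)
  tab <- build_study_table(sessions, by = "driver_scenario_gear")
  cmp <- gearshift_comparison(tab)
  expect_equal(nrow(cmp), 3L)
  expect_true(all(cmp$d_mean_speed > 0))

  # identical sessions in both gears -> zero differences
  same <- list(mk("dz", "automatic", 7, 0), mk("dz", "manual", 7, 0))
  cmp0 <- gearshift_comparison(build_study_table(same, by = "driver_scenario_gear"))
  expect_equal(cmp0$d_mean_speed, 0)
  expect_equal(cmp0$d_mean_w, 0)
  expect_equal(cmp0$d_sd_w, 0)

  expect_error(gearshift_comparison(build_study_table(same[1],
                                                      by = "driver_scenario_gear")),
               "exactly one automatic")
})
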