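test_that("zero-noise observations report the source end-members exactly", {
  des <- small_design()
  st <- simulate_pools(des, zero_noise_config())
  con0 <- as.list(st[st$treatment == "CON" & st$month == 0, ])
  obs <- observe(con0, des, noise_off())
  expect_equal(obs$coarse_d13c, des$delta_old_poc)
  expect_equal(obs$fine_d13c, des$delta_old_maoc)

  # a fraction with equal new and old C sits exactly at the midpoint
  half <- list(treatment = "X", month = 1, poc_new = 0.05, poc_old = 0.05,
               maoc_new = 0.1, maoc_old = 0.1)
  obs2 <- observe(half, des, noise_off())
  expect_equal(obs2$coarse_d13c, (des$delta_litter + des$delta_old_poc) / 2)
  expect_equal(obs2$fine_d13c, (des$delta_litter + des$delta_old_maoc) / 2)
})

test_that("delta noise has the configured spread", {
  des <- small_design()
  st <- as.list(simulate_pools(des, zero_noise_config())[4, ])
  nm <- noise_model(cv_concentration = 0, sd_delta = 0.2,
                    mass_recovery_mean = 1, mass_recovery_sd = 0)
  set.seed(101)
  draws <- vapply(1:1000, function(i) observe(st, des, nm)$fine_d13c,
                  numeric(1))
  expect_gt(sd(draws), 0.18)
  expect_lt(sd(draws), 0.22)
})

test_that("fractionation mass recovery scatters around its configured mean", {
  des <- small_design()
  st <- as.list(simulate_pools(des, zero_noise_config())[2, ])
  set.seed(202)
  rec <- vapply(1:1000, function(i) {
    o <- observe(st, des, noise_model())
    100 * (o$coarse_mass_g + o$fine_mass_g) / o$input_mass_g
  }, numeric(1))
  expect_gt(mean(rec), 97.5)
  expect_lt(mean(rec), 98.9)
})

test_that("the default design yields 30 jars sampled on 3 post-start occasions", {
  ds <- generate_experiment(experiment_design(), zero_noise_config())
  obs <- ds$observations
  post <- obs[obs$month > 0, ]
  expect_equal(nrow(unique(post[, c("treatment", "replicate")])), 30)
  expect_equal(sort(unique(post$month)), c(6, 12, 24))
  expect_equal(nrow(post), 90)
  # plus the control reference at the start
  expect_equal(nrow(obs[obs$month == 0, ]), 5)
  expect_setequal(unique(obs$treatment[obs$month == 0]), "CON")
})

test_that("a single-treatment, single-replicate design emits one jar per occasion", {
  des <- experiment_design(treatments = list(control_batch("CON"),
                                             litter_batch("CN50", 44.17, 0.89)),
                           replicates = 1)
  ds <- generate_experiment(des, zero_noise_config())
  cn50 <- ds$observations[ds$observations$treatment == "CN50", ]
  expect_equal(nrow(cn50), 3)
  expect_equal(cn50$replicate, rep(1L, 3))
})

test_that("generation is deterministic: same seed, byte-identical files", {
  des <- small_design()
  cfg <- simulation_config(seed = 99L)
  d1 <- generate_experiment(des, cfg)
  d2 <- generate_experiment(des, cfg)
  expect_identical(d1, d2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_observations(d1$observations, f1)
  write_observations(d2$observations, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("observation tables and run configs round-trip through disk", {
  des <- small_design()
  cfg <- simulation_config(seed = 3L)
  ds <- generate_experiment(des, cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_observations(ds$observations, f)
  back <- read_observations(f)
  expect_equal(as.data.frame(back), as.data.frame(ds$observations))

  fy <- withr::local_tempfile(fileext = ".yml")
  write_run_config(des, cfg, fy)
  restored <- read_run_config(fy)
  expect_equal(restored$design, des)
  expect_equal(restored$config, cfg)

  # implausible delta13C values are flagged on read
  bad <- ds$observations
  bad$bulk_d13c[1] <- 3
  write_observations(bad, f)
  expect_warning(read_observations(f), "plausible")
})
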