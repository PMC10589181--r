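test_that("zero decay rates leave every pool at its initial state", {
  des <- small_design()
  cfg <- zero_noise_config(k_poc_new = 0, k_poc_old = 0, k_maoc_new = 0,
                           k_maoc_old = 0)
  st <- simulate_pools(des, cfg)
  t0 <- st[st$month == 0, ]
  for (m in cfg$months) {
    now <- st[st$month == m, ]
    expect_equal(now$poc_new, t0$poc_new)
    expect_equal(now$maoc_old, t0$maoc_old)
    expect_equal(now$respired_new + now$respired_old, rep(0, nrow(now)))
  }
})

test_that("without transfer, litter POC follows a single exponential", {
  des <- small_design()
  k <- 0.05
  cfg <- zero_noise_config(k_poc_new = k, h_transfer = 0)
  st <- simulate_pools(des, cfg)
  cn50 <- st[st$treatment == "CN50", ]
  p0 <- cn50$poc_new[cn50$month == 0]
  expect_equal(cn50$poc_new, p0 * exp(-k * cn50$month), tolerance = 1e-12)
  expect_equal(cn50$maoc_new, rep(0, nrow(cn50)))
})

test_that("mass and source identity are conserved to numerical tolerance", {
  des <- experiment_design()
  st <- simulate_pools(des, zero_noise_config())
  soil_c <- des$soil_mass_g * des$soil_c_gkg / 1000
  batches <- des$treatments
  names(batches) <- vapply(batches, `[[`, character(1), "label")
  for (i in seq_len(nrow(st))) {
    b <- batches[[st$treatment[i]]]
    litter_c <- if (b$is_control) 0 else des$litter_mass_g * b$c_pct / 100
    total <- st$poc_new[i] + st$poc_old[i] + st$maoc_new[i] +
      st$maoc_old[i] + st$respired_new[i] + st$respired_old[i]
    expect_lt(abs(total - (soil_c + litter_c)) / (soil_c + litter_c), 1e-9)
    new_total <- st$poc_new[i] + st$maoc_new[i] + st$respired_new[i]
    expect_lt(abs(new_total - litter_c), 1e-9 * max(litter_c, 1e-9))
  }
})

test_that("closed-form trajectories match an independent stiff integrator", {
  skip_if_not_installed("deSolve")
  des <- small_design()
  cfg <- zero_noise_config()
  st <- simulate_pools(des, cfg)
  batches <- des$treatments
  names(batches) <- vapply(batches, `[[`, character(1), "label")
  for (tr in c("CN50", "CN124")) {
    b <- batches[[tr]]
    m_m <- priming_multiplier(cfg$alpha_priming, b$cn_ratio, cfg$cn_reference)
    m_p <- priming_multiplier(cfg$alpha_priming_poc, b$cn_ratio,
                              cfg$cn_reference)
    rhs <- function(t, y, p) {
      dp_n <- -cfg$k_poc_new * y[1]
      dm_n <- -cfg$k_maoc_new * y[2] + cfg$h_transfer * cfg$k_poc_new * y[1]
      dp_o <- -cfg$k_poc_old * m_p * y[3]
      dm_o <- -cfg$k_maoc_old * m_m * y[4] +
        cfg$h_transfer * cfg$k_poc_old * m_p * y[3]
      list(c(dp_n, dm_n, dp_o, dm_o))
    }
    soil_c <- des$soil_mass_g * des$soil_c_gkg / 1000
    y0 <- c(des$litter_mass_g * b$c_pct / 100, 0,
            des$initial_old_split * soil_c,
            (1 - des$initial_old_split) * soil_c)
    num <- deSolve::lsoda(y0, times = c(0, cfg$months[-1]), func = rhs,
                          parms = NULL, rtol = 1e-11, atol = 1e-13)
    got <- st[st$treatment == tr, ]
    for (j in seq_along(cfg$months)) {
      exact <- c(got$poc_new[j], got$maoc_new[j], got$poc_old[j],
                 got$maoc_old[j])
      expect_lt(max(abs(exact - num[j, 2:5]) / pmax(abs(exact), 1e-12)),
                1e-6)
    }
  }
})

test_that("priming multiplier is clamped and the control stays neutral", {
  expect_equal(priming_multiplier(0.15, NA, 25), 1)
  expect_equal(priming_multiplier(0.15, 25, 25), 1)
  expect_equal(priming_multiplier(-2, 124, 25), 0)  # clamped
  expect_gt(priming_multiplier(0.15, 124, 25), priming_multiplier(0.15, 50, 25))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(k_poc_new = -0.1), "rates")
  expect_error(simulation_config(h_transfer = 1.5), "h_transfer")
  expect_error(simulation_config(months = c(6, 12)), "months")
  expect_error(simulation_config(months = c(0, 12, 6)), "months")
  expect_error(experiment_design(treatments = list(control_batch("A"),
                                                   control_batch("A"))),
               "duplicate")
})
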