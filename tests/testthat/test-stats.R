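test_that("linear_fit recovers exact lines and degenerate responses", {
  x <- c(1, 2, 3, 4, 5)
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  expect_lt(f$p_value, 1e-10)
  const <- linear_fit(x, rep(3, 5))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)
  expect_equal(const$p_value, 1)
  expect_error(linear_fit(rep(1, 5), x), "constant")
  expect_error(linear_fit(1:2, 1:2), "at least 3")
})

test_that("r_squared is invariant under affine transforms of x and y", {
  set.seed(9)
  x <- rnorm(20); y <- 1.5 * x + rnorm(20, 0, 0.5)
  base <- linear_fit(x, y)$r_squared
  expect_equal(linear_fit(3 * x - 7, y)$r_squared, base)
  expect_equal(linear_fit(x, -2 * y + 11)$r_squared, base)
})

test_that("the polysaccharide:lignin ratio tracks litter C:N almost perfectly", {
  ref <- reference_compound_ratios()
  f <- linear_fit(ref$cn_ratio, ref$polysaccharide_lignin)
  expect_lt(abs(f$r_squared - 0.99), 0.01)
  expect_true(f$significant)
})

test_that("pool regressions find the built-in priming gradient", {
  ds <- generate_experiment(experiment_design(), zero_noise_config())
  part <- partition_pools(ds$observations,
                          reference_from_control(ds$observations))
  des <- experiment_design()
  cn <- vapply(des$treatments, function(b) b$cn_ratio, numeric(1))
  names(cn) <- vapply(des$treatments, `[[`, character(1), "label")
  res <- regress_pools(part, cn[!is.na(cn)])
  maoc24 <- res[res$pool == "maoc_old" & res$month == 24, ]
  expect_lt(maoc24$slope, 0)
  expect_true(maoc24$significant)
  expect_equal(maoc24$n, 20)  # CN124N excluded, control has no indicator

  set.seed(2)
  shuffled <- part[sample(nrow(part)), ]
  expect_equal(regress_pools(shuffled, cn[!is.na(cn)]), res)
  expect_error(regress_pools(part, cn[c("CN50", "CN65")],
                             exclude_labels = "CN124N"), "fewer than 3")
})

test_that("noise-free inversion recovers the configured priming slope", {
  cfg <- zero_noise_config(h_transfer = 0)
  des <- experiment_design()
  ds <- generate_experiment(des, cfg)
  part <- partition_pools(ds$observations,
                          reference_from_control(ds$observations))
  rows <- part[part$month == 24 &
                 part$treatment %in% c("CN50", "CN65", "CN85", "CN124"), ]
  ctl0 <- part[part$treatment == "CON" & part$month == 0, ]
  cn <- c(CN50 = 44.17 / 0.89, CN65 = 43.64 / 0.67, CN85 = 44.39 / 0.52,
          CN124 = 43.43 / 0.35)
  # with no transfer, MAOC_old(t) = MAOC_old(0) exp(-k m t): invert for m
  m_hat <- -log(rows$maoc_old / mean(ctl0$maoc_total)) /
    (cfg$k_maoc_old * 24)
  z <- (cn[rows$treatment] - cfg$cn_reference) / cfg$cn_reference
  fit <- linear_fit(z, m_hat)
  expect_lt(abs(fit$slope - cfg$alpha_priming) / cfg$alpha_priming, 1e-6)
  expect_lt(abs(fit$intercept - 1), 1e-6)
})

test_that("well-separated groups earn distinct letters; identical ones share", {
  set.seed(31)
  val <- c(rnorm(5, 0, 1), rnorm(5, 100, 1))
  tk <- anova_tukey(val, rep(c("lo", "hi"), each = 5))
  expect_equal(unname(tk$letters[c("hi", "lo")]), c("a", "b"))
  expect_lt(tk$anova_p, 1e-6)

  same <- anova_tukey(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(same$letters == "a"))
  expect_error(anova_tukey(rep(1, 6), rep(c("a", "b"), each = 3)),
               "variance")
  expect_error(anova_tukey(1:3, c("a", "b", "c")), "observations")
})

test_that("a chain pattern produces the classic a / ab / b letters", {
  # three groups where only the extremes differ significantly
  set.seed(17)
  found <- FALSE
  for (i in 1:50) {
    val <- c(rnorm(5, 0), rnorm(5, 1.9), rnorm(5, 3.8))
    grp <- rep(c("low", "mid", "high"), each = 5)
    tk <- anova_tukey(val, grp)
    pw <- tk$pairwise
    p_of <- function(a, b) pw$p_adj[(pw$group1 == a & pw$group2 == b) |
                                      (pw$group1 == b & pw$group2 == a)]
    if (p_of("low", "mid") >= 0.05 && p_of("mid", "high") >= 0.05 &&
        p_of("low", "high") < 0.05) {
      expect_equal(unname(tk$letters[c("high", "mid", "low")]),
                   c("a", "ab", "b"))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("compact letters agree with pairwise significance on random layouts", {
  set.seed(55)
  for (i in 1:40) {
    k <- sample(3:6, 1)
    n <- sample(3:6, 1)
    means <- rnorm(k, 0, sample(c(0.5, 1.5, 3), 1))
    val <- unlist(lapply(means, function(m) rnorm(n, m, 1)))
    grp <- rep(paste0("g", seq_len(k)), each = n)
    tk <- anova_tukey(val, grp)
    expect_true(cld_consistent(tk))
    expect_true(all(nchar(tk$letters) >= 1))
  }
})

test_that("the residual-normality note flags skewed residuals only", {
  set.seed(6)
  normal <- residual_normality_note(rnorm(500))
  expect_true(normal$assessable)
  expect_lt(abs(normal$skewness), 0.3)
  skewed <- residual_normality_note(rexp(500))
  expect_gt(skewed$skewness, 1)
  tiny <- residual_normality_note(c(0.1, -0.2, 0.05))
  expect_false(tiny$assessable)
})
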