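test_that("model-59 fit reproduces the two OLS equations exactly", {
  set.seed(61)
  d <- generate_model59_cohort(200, list(a1 = 0.3, a2 = -0.2, a3 = 0.15,
                                         b1 = 0.25, b2 = 0.1, c1 = 0.1,
                                         c2 = 0.2, c3 = -0.1))
  fit <- fit_model59(d, "x", "m", "y", "w")
  z <- as.data.frame(scale(d[, c("x", "m", "y", "w")]))
  med_eq <- lm(m ~ x + w + I(x * w), data = z)
  out_eq <- lm(y ~ x + w + I(x * w) + m + I(m * w), data = z)
  expect_equal(unname(fit$a1), unname(coef(med_eq)["x"]), tolerance = 1e-10)
  expect_equal(unname(fit$a3), unname(coef(med_eq)["I(x * w)"]),
               tolerance = 1e-10)
  expect_equal(unname(fit$b1), unname(coef(out_eq)["m"]), tolerance = 1e-10)
  expect_equal(unname(fit$b2), unname(coef(out_eq)["I(m * w)"]),
               tolerance = 1e-10)
  expect_equal(unname(fit$c1p), unname(coef(out_eq)["x"]), tolerance = 1e-10)
})

test_that("conditional indirect effect follows the path product", {
  paths <- list(a1 = 0.5, a3 = 0.2, b1 = 0.4, b2 = 0.1)
  expect_equal(conditional_indirect(paths, 1), 0.7 * 0.5)
  expect_equal(conditional_indirect(paths, 0), 0.5 * 0.4)
  flat <- list(a1 = 0.5, a3 = 0, b1 = 0.4, b2 = 0)
  expect_equal(conditional_indirect(flat, c(-2, 0, 3)), rep(0.2, 3))
})

test_that("indirect effect matches a re-centering refit oracle", {
  set.seed(62)
  d <- generate_model59_cohort(300, list(a1 = 0.3, a2 = -0.2, a3 = 0.15,
                                         b1 = 0.25, b2 = 0.1, c1 = 0.1,
                                         c2 = 0.2, c3 = -0.1))
  fit <- fit_model59(d, "x", "m", "y", "w")
  z <- as.data.frame(scale(d[, c("x", "m", "y", "w")]))
  for (w0 in c(-1, 0.5, 1)) {
    z$ws <- z$w - w0
    a_slope <- coef(lm(m ~ x + ws + I(x * ws), data = z))["x"]
    b_slope <- coef(lm(y ~ x + ws + I(x * ws) + m + I(m * ws), data = z))["m"]
    expect_equal(conditional_indirect(fit, w0),
                 unname(a_slope * b_slope), tolerance = 1e-10)
  }
})

test_that("null a-paths give a null indirect effect at every level", {
  set.seed(63)
  d <- generate_model59_cohort(4000, list(a1 = 0, a2 = -0.3, a3 = 0,
                                          b1 = 0.3, b2 = 0.1, c1 = 0.2,
                                          c2 = 0.2, c3 = 0))
  fit <- fit_model59(d, "x", "m", "y", "w")
  for (w0 in c(-1, 0, 1))
    expect_lt(abs(conditional_indirect(fit, w0)), 0.02)
})

test_that("unmoderated paths reduce to simple mediation", {
  set.seed(64)
  d <- generate_model59_cohort(500, list(a1 = 0.4, a2 = 0, a3 = 0,
                                         b1 = 0.3, b2 = 0, c1 = 0.1,
                                         c2 = 0, c3 = 0))
  fit <- fit_model59(d, "x", "m", "y", "w")
  expect_equal(conditional_indirect(fit, 0), unname(fit$a1 * fit$b1))
  # estimated moderation paths are near zero, so the effect is ~flat
  expect_lt(abs(conditional_indirect(fit, 1) - conditional_indirect(fit, -1)),
            0.1)
})

test_that("mediation bootstrap is seed-reproducible", {
  set.seed(65)
  d <- generate_model59_cohort(120, list(a1 = 0.3, a2 = 0, a3 = 0.2,
                                         b1 = 0.3, b2 = 0.1, c1 = 0,
                                         c2 = 0, c3 = 0))
  r1 <- mediation_bootstrap(d, "x", "m", "y", "w", B = 200, seed = 3)
  r2 <- mediation_bootstrap(d, "x", "m", "y", "w", B = 200, seed = 3)
  expect_identical(r1, r2)
  expect_equal(r1$w_level, c(-1, 0, 1))
  expect_true(all(r1$ci_low <= r1$indirect & r1$indirect <= r1$ci_high))
})

test_that("bootstrap intervals separate real from null conditional effects", {
  # generating structure: strong indirect at +1 SD, none at -1 SD
  paths <- list(a1 = 0.3, a2 = 0, a3 = 0.3, b1 = 0.25, b2 = 0.25,
                c1 = 0, c2 = 0, c3 = 0)
  gen_hi <- (paths$a1 + paths$a3) * (paths$b1 + paths$b2)
  gen_lo <- (paths$a1 - paths$a3) * (paths$b1 - paths$b2)
  expect_equal(gen_hi, 0.3)
  expect_equal(gen_lo, 0)
  set.seed(66)
  res <- t(vapply(1:100, function(i) {
    d <- generate_model59_cohort(250, paths)
    ci <- mediation_bootstrap(d, "x", "m", "y", "w", B = 150,
                              w_levels = c(-1, 1))
    c(hi_sig = ci$significant[2], lo_sig = ci$significant[1])
  }, c(hi_sig = TRUE, lo_sig = TRUE)))
  expect_gt(mean(res[, "hi_sig"] & !res[, "lo_sig"]), 0.75)
})

test_that("null indirect effects are rejected near the nominal 10% rate", {
  # partial null: the b-path is real, the a-path is zero, so the
  # product test behaves like a one-parameter test of the a-path; the
  # complete null (both paths zero) is checked for conservativeness
  partial <- list(a1 = 0, a2 = 0, a3 = 0, b1 = 0.4, b2 = 0,
                  c1 = 0.2, c2 = 0.2, c3 = 0)
  set.seed(67)
  hits <- vapply(1:150, function(i) {
    d <- generate_model59_cohort(150, partial)
    mediation_bootstrap(d, "x", "m", "y", "w", B = 150,
                        w_levels = 0)$significant
  }, logical(1))
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.2)

  complete <- list(a1 = 0, a2 = 0, a3 = 0, b1 = 0, b2 = 0,
                   c1 = 0.2, c2 = 0.2, c3 = 0)
  hits0 <- vapply(1:60, function(i) {
    d <- generate_model59_cohort(150, complete)
    mediation_bootstrap(d, "x", "m", "y", "w", B = 150,
                        w_levels = 0)$significant
  }, logical(1))
  expect_lt(mean(hits0), 0.1)
})
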