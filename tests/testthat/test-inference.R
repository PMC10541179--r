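test_that("per-age-group screening removes exactly the planted outlier", {
  tab <- data.frame(participant_id = sprintf("p%02d", 1:20),
                    score = c(rnorm(19, 0, 0.1) * 0 + c(seq(-0.5, 0.5,
                                                            length.out = 19)),
                              10))
  grp <- rep("6-7", 20)
  z <- (tab$score - mean(tab$score)) / sd(tab$score)
  expect_gt(abs(z[20]), 3)
  out <- screen_outliers(tab, "score", grp)
  expect_true(is.na(out$table$score[20]))
  expect_equal(out$log$participant_id, "p20")
  # re-running on the screened output leaves it unchanged
  again <- screen_outliers(out$table, "score", grp)
  expect_equal(nrow(again$log), 0)
  expect_identical(again$table$score, out$table$score)
})

test_that("screening skips degenerate and tiny groups", {
  tab <- data.frame(participant_id = c("a", "b", "c", "d"),
                    score = c(1, 1, 1, 1))
  out <- screen_outliers(tab, "score", rep("g", 4))
  expect_equal(nrow(out$log), 0)
  expect_warning(screen_outliers(data.frame(participant_id = "a", score = 1),
                                 "score", "g"), "skipped")
})

test_that("standardize gives exact z-scores and is idempotent", {
  tab <- data.frame(x = c(2, 4, 6, 8, 10))
  out <- standardize(tab, "x")
  expect_equal(mean(out$x), 0, tolerance = 1e-12)
  expect_equal(sd(out$x), 1, tolerance = 1e-12)
  expect_equal(out$x, (tab$x - 6) / sd(tab$x))
  expect_equal(standardize(out, "x")$x, out$x)
  expect_error(standardize(data.frame(x = rep(1, 5)), "x"), "zero variance")
})

test_that("standardized simple-regression beta equals the Pearson correlation", {
  set.seed(51)
  d <- data.frame(x = rnorm(300))
  d$y <- 0.4 * d$x + rnorm(300)
  fit <- fit_moderated_model(model_spec("y", "x"), d)
  expect_equal(unname(fit$coefficients["x"]), cor(d$x, d$y),
               tolerance = 1e-12)
})

test_that("orthogonal nuisance predictors leave the focal beta unchanged", {
  set.seed(52)
  n <- 200
  x <- rnorm(n); x <- (x - mean(x)) / sd(x)
  z <- rnorm(n)
  z <- resid(lm(z ~ x))                  # exactly orthogonal to x
  z <- (z - mean(z)) / sd(z)
  y <- 0.5 * x + rnorm(n)
  d <- data.frame(x = x, z = z, y = y)
  b1 <- fit_moderated_model(model_spec("y", "x"), d)$coefficients["x"]
  b2 <- fit_moderated_model(model_spec("y", c("x", "z")), d)$coefficients["x"]
  expect_lt(abs(b1 - b2), 1e-10)
})

test_that("collinear designs fail loudly with the offending terms", {
  d <- data.frame(x = rnorm(50))
  d$w <- d$x
  d$y <- rnorm(50)
  expect_error(fit_moderated_model(model_spec("y", c("x", "w")), d),
               "collinear")
})

test_that("interaction coefficients are recovered without bias", {
  set.seed(53)
  betas <- vapply(1:200, function(i) {
    n <- 500
    x <- rnorm(n); w <- rnorm(n)
    y <- 0.2 * x + 0.3 * w + 0.25 * x * w + rnorm(n, sd = sqrt(1 - 0.2325))
    d <- data.frame(x = x, w = w, y = y)
    fit_moderated_model(model_spec("y", c("x", "w", "x:w")), d)$coefficients[["x:w"]]
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.25), 0.02)
})

test_that("bootstrap intervals are reproducible and collapse when exact", {
  set.seed(54)
  d <- data.frame(x = rnorm(60))
  d$y <- d$x                      # deterministic relation
  fit <- fit_moderated_model(model_spec("y", "x"), d)
  b1 <- bootstrap_inference(fit, B = 300, seed = 9)
  b2 <- bootstrap_inference(fit, B = 300, seed = 9)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$p_bo, b2$p_bo)
  expect_lt(b1$ci_high["x"] - b1$ci_low["x"], 1e-10)
  expect_equal(unname(b1$p_bo["x"]), 2 / 300)
})

test_that("bootstrap p-values hold their nominal size under the null", {
  set.seed(55)
  hits <- vapply(1:400, function(i) {
    n <- 150
    d <- data.frame(x = rnorm(n), w = rnorm(n), y = rnorm(n))
    fit <- fit_moderated_model(model_spec("y", c("x", "w", "x:w")), d)
    bootstrap_inference(fit, B = 199)$p_bo[["x:w"]] <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("residual exclusion removes planted contamination and refits", {
  set.seed(56)
  n <- 120
  d <- data.frame(participant_id = sprintf("p%03d", 1:n), x = rnorm(n))
  d$y <- 0.5 * d$x + rnorm(n, sd = 0.3)
  d$y[7] <- d$y[7] + 6                    # gross outlier in y
  fit <- fit_moderated_model(model_spec("y", "x"), d)
  refit <- exclude_by_residuals(fit)
  expect_equal(refit$excluded_ids, "p007")
  expect_lt(abs(refit$coefficients["x"] - cor(d$x[-7], d$y[-7])), 1e-10)
  # clean data: exclusion is the identity
  d2 <- d[-7, ]
  fit2 <- fit_moderated_model(model_spec("y", "x"), d2)
  expect_identical(exclude_by_residuals(fit2)$n_used, fit2$n_used)
})

test_that("family enumeration reproduces the design multiplicities", {
  expect_length(family_main(), 36)
  expect_length(family_supplementary(), 180)
  one <- build_family(list(a = "x", b = "y"))
  expect_equal(attr(one, "family_size"), 1)
  expect_error(build_family(list(a = character(0))), "empty factor")
})

test_that("family specs encode the moderated-model pattern", {
  specs <- family_main()
  s <- specs[[1]]
  expect_s3_class(s, "cogchain_spec")
  expect_true(s$dependent %in% c("v", "a", "ter"))
  expect_length(s$predictors, 5)          # chem + age + product + 2 controls
  hyp <- vapply(specs, function(x) x$hypothesis, character(1))
  expect_equal(sum(grepl(":", hyp)), 18)  # half the family tests interactions
})

test_that("BH adjustment agrees with a brute-force step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.07, 5)), rep(0.07, 5))
  pool <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 1)
  for (p in pvec_grid(pool, 6))
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("interaction probing reproduces the simple-slope algebra", {
  set.seed(57)
  n <- 400
  x <- rnorm(n); w <- rnorm(n)
  y <- 0.1 * x + 0.2 * w - 0.2 * x * w + rnorm(n, sd = 0.6)
  d <- data.frame(x = x, w = w, y = y)
  fit <- fit_moderated_model(model_spec("y", c("x", "w", "x:w")), d)
  pr <- probe_interaction(fit, "x", "w")
  b <- fit$coefficients
  expect_equal(pr$slopes$slope,
               b[["x"]] + c(-1, 0, 1) * b[["x:w"]])
  # crossover: refit with the moderator centered at the crossover level
  # (independent lm route) and check the focal slope vanishes
  zd <- data.frame(scale(d))
  zd$wc <- zd$w - pr$crossover
  ref <- lm(y ~ x + wc + x:wc, data = zd)
  expect_lt(abs(coef(ref)[["x"]]), 1e-10)
})

test_that("a zero interaction yields level-independent slopes", {
  fit <- structure(list(coefficients = c(x = 0.3, w = 0.1, `x:w` = 0),
                        intercept = 0),
                   class = "cogchain_fit")
  pr <- probe_interaction(fit, "x", "w")
  expect_equal(unique(pr$slopes$slope), 0.3)
  expect_true(is.na(pr$crossover))
})
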