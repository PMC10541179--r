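test_that("trial filter removes anticipations below the 200 ms floor", {
  tr <- data.frame(correct = TRUE, rt = c(0.150, seq(0.3, 0.7, length.out = 9)))
  out <- filter_trials(tr)
  expect_equal(nrow(out), 9)
  expect_equal(attr(out, "n_removed_fast"), 1)
  expect_equal(attr(out, "n_removed_sd"), 0)
})

test_that("trial filter is the identity on clean data and idempotent", {
  set.seed(11)
  tr <- data.frame(correct = runif(40) < 0.9, rt = runif(40, 0.3, 0.6))
  out <- filter_trials(tr)
  expect_equal(out$rt, tr$rt)
  again <- filter_trials(out)
  expect_equal(again$rt, out$rt)
})

test_that("trial filter removes a constructed 4-sd outlier by the band rule", {
  set.seed(7)
  base <- 0.5 + rnorm(100, sd = 0.02)
  s <- sd(c(base, 0.5))        # close to the final sd; construct explicitly
  tr <- data.frame(correct = TRUE, rt = c(base, 0.5 + 4 * sd(base)))
  # direct computation of the rule on the constructed set
  expect_true(abs(tr$rt[101] - mean(tr$rt)) > 3 * sd(tr$rt))
  out <- filter_trials(tr)
  expect_equal(nrow(out), 100)
  expect_equal(attr(out, "n_removed_sd"), 1)
  expect_false(101 %in% as.integer(rownames(out)))
})

test_that("trial filter signals unusable input", {
  expect_error(filter_trials(data.frame(correct = logical(), rt = numeric())),
               "no trials")
  expect_error(filter_trials(data.frame(correct = TRUE, rt = c(0.1, 0.15))),
               "unusable")
})

test_that("moments: correct-only RT statistics with unbiased variance", {
  tr <- data.frame(correct = TRUE, rt = c(0.4, 0.6, 0.4, 0.6))
  sm <- summarize_trials(tr)
  expect_equal(sm$pc, 1)
  expect_equal(sm$mrt, 0.5)
  expect_equal(sm$vrt, 0.04 / 3)   # 4 squared deviations of 0.01, n-1 = 3
  tr2 <- data.frame(correct = c(TRUE, TRUE, FALSE, FALSE),
                    rt = c(0.4, 0.6, 0.5, 0.5))
  expect_equal(summarize_trials(tr2)$pc, 0.5)
  expect_error(summarize_trials(data.frame(correct = c(TRUE, FALSE),
                                           rt = c(0.4, 0.5))),
               "single correct trial")
  expect_error(summarize_trials(data.frame(correct = FALSE, rt = 0.4)),
               "no correct RTs")
})

test_that("EZ estimate inverts the forward model to machine precision", {
  p <- canonical_params()
  est <- ez_estimate(ez_forward(p))
  expect_equal(est$v, p$v, tolerance = 1e-12)
  expect_equal(est$a, p$a, tolerance = 1e-12)
  expect_equal(est$ter, p$ter, tolerance = 1e-12)
})

test_that("EZ round trip holds over random parameter sets", {
  set.seed(42)
  for (p in random_params(1000)) {
    est <- ez_estimate(ez_forward(p))
    expect_lt(abs(est$v - p$v), 1e-10)
    expect_lt(abs(est$a - p$a), 1e-10)
    expect_lt(abs(est$ter - p$ter), 1e-10)
  }
})

test_that("drift rate co-signs with accuracy", {
  below <- ez_estimate(list(pc = 0.3, mrt = 0.6, vrt = 0.02, n = 50))
  above <- ez_estimate(list(pc = 0.7, mrt = 0.6, vrt = 0.02, n = 50))
  expect_lt(below$v, 0)
  expect_gt(above$v, 0)
  expect_lt(below$ter, 0.6)   # Ter < MRT always
  expect_lt(above$ter, 0.6)
})

test_that("perfect accuracy uses the half-count edge correction", {
  est <- ez_estimate(list(pc = 1, mrt = 0.5, vrt = 0.01, n = 50))
  manual <- ez_estimate(list(pc = 0.99, mrt = 0.5, vrt = 0.01, n = 50))
  expect_equal(est$v, manual$v)
  expect_equal(est$a, manual$a)
  expect_error(ez_estimate(list(pc = 0.8, mrt = 0.5, vrt = 0, n = 50)),
               "variance")
})

test_that("forward model: sign symmetry and boundary monotonicity", {
  pos <- ez_forward(list(v = 0.2, a = 0.1, ter = 0.3, s = 0.1))
  neg <- ez_forward(list(v = -0.2, a = 0.1, ter = 0.3, s = 0.1))
  expect_gt(pos$pc, 0.5)
  expect_lt(neg$pc, 0.5)
  m1 <- ez_forward(list(v = 0.15, a = 0.08, ter = 0.3, s = 0.1))
  m2 <- ez_forward(list(v = 0.15, a = 0.16, ter = 0.3, s = 0.1))
  expect_gt(m2$mrt - 0.3, m1$mrt - 0.3)
  expect_error(ez_forward(list(v = 0, a = 0.1, ter = 0.3, s = 0.1)), "v = 0")
})

test_that("condition contrasts follow the cognitive-subtraction definitions", {
  par_a <- list(v = 1.2, a = 0.10, ter = 0.35)
  par_b <- list(v = 1.5, a = 0.10, ter = 0.30)
  cs <- condition_contrast(list(no_cue = par_a, double_cue = par_b),
                           "alerting")
  expect_equal(cs$value[cs$parameter == "ter"], 0.05)
  cs2 <- condition_contrast(list(incongruent = par_a, congruent = par_b),
                            "executive")
  expect_equal(cs2$value[cs2$parameter == "v"], -0.3)
  same <- condition_contrast(list(far = par_a, near = par_a), "distance")
  expect_equal(same$value, c(0, 0, 0))
  expect_error(condition_contrast(list(no_cue = par_a), "alerting"),
               "double_cue")
})

test_that("composite visuomotor score averages per-task z-scores", {
  tab <- data.frame(participant_id = c("p1", "p2", "p3"),
                    attention = c(0.30, 0.35, 0.40),
                    digit = c(0.32, 0.36, 0.40),
                    rotation = c(0.45, 0.40, 0.35))
  out <- composite_visuomotor(tab)
  hand <- rowMeans(cbind(scale(tab$attention), scale(tab$digit),
                         scale(tab$rotation)))
  expect_equal(out$composite_ter, hand)
  expect_equal(mean(out$composite_ter), 0, tolerance = 1e-12)
  bad <- tab; bad$digit <- 0.3
  expect_error(composite_visuomotor(bad), "zero variance")
})

test_that("composite requires the full three-task battery", {
  tab <- data.frame(participant_id = c("p1", "p2", "p3", "p4"),
                    attention = c(0.30, 0.35, 0.40, NA),
                    digit = c(0.32, 0.36, 0.40, 0.38),
                    rotation = c(0.45, 0.40, 0.35, 0.37))
  out <- composite_visuomotor(tab)
  expect_equal(nrow(out), 3)
  expect_false("p4" %in% out$participant_id)
})
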