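small_cfg <- function(seed = 2) {
  cohort_config(n_per_band = c(4, 4, 4, 4, 4), seed = seed)
}

test_that("task designs reproduce the printed trial counts", {
  co <- generate_cohort(small_cfg())
  att <- co$trials[co$trials$task == "attention", ]
  per_p <- table(att$participant_id)
  expect_true(all(per_p == 96))
  expect_equal(length(unique(att$condition)), 12)
  expect_true(all(table(att$participant_id, att$condition) == 8))

  dig <- co$trials[co$trials$task == "digit", ]
  expect_true(all(table(dig$participant_id) == 72))
  one <- dig[dig$participant_id == dig$participant_id[1], ]
  grid <- expand.grid(lo = 1:9, hi = 1:9)
  pairs <- grid[grid$lo < grid$hi, ]
  expect_equal(sort(unique(one$condition)),
               sort(sprintf("d%d_%d", pairs$lo, pairs$hi)))
  expect_true(all(table(one$condition) == 2))
  expect_equal(length(unique(one$condition)), 36)

  rot <- co$trials_by_task$rotation
  one_r <- rot[rot$participant_id == rot$participant_id[1], ]
  expect_true(all(table(one_r$figure) == 24))
  expect_true(all(table(one_r$condition) == 24))
})

test_that("cohorts regenerate identically from (config, seed)", {
  c1 <- generate_cohort(small_cfg(seed = 9))
  c2 <- generate_cohort(small_cfg(seed = 9))
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$mrs, c2$mrs)
  c3 <- generate_cohort(small_cfg(seed = 10))
  expect_false(identical(c1$trials$rt, c3$trials$rt))
})

test_that("noiseless spectroscopy observables invert the tissue correction", {
  set.seed(71)
  cfg <- small_cfg()
  truth <- cogchain:::.generate_truth(cfg)
  obs <- generate_mrs_observables(truth, cfg, noise_sd = 0)
  rec <- obs$records
  back <- tissue_correct(rec$raw_conc, rec$f_gm, rec$f_wm, rec$f_csf)
  expect_equal(back, rec$conc_true, tolerance = 1e-10)
})

test_that("water-reference series round-trip through the T2 fit", {
  set.seed(72)
  cfg <- cohort_config(n_per_band = c(1, 1, 1, 1, 1), water_noise_sd = 0)
  truth <- cogchain:::.generate_truth(cfg)
  obs <- generate_mrs_observables(truth, cfg, noise_sd = 0)
  w1 <- obs$water[obs$water$participant_id == "P001" &
                    obs$water$region == "IPS", ]
  fit <- fit_water_t2(w1$te_ms, w1$integral)
  expect_equal(fit$t2_tissue, w1$t2_true[1], tolerance = 1e-4)
})

test_that("planted quality violators are caught by the exclusion rules", {
  set.seed(73)
  cfg <- small_cfg()
  truth <- cogchain:::.generate_truth(cfg)
  obs <- generate_mrs_observables(truth, cfg)
  rec <- obs$records
  rec$crlb_pct[3] <- 60
  out <- apply_mrs_exclusions(rec)
  expect_true(out$records$not_detectable[
    out$records$participant_id == rec$participant_id[3] &
      out$records$metabolite == rec$metabolite[3] &
      out$records$region == rec$region[3]])
})

test_that("intelligence scores live on the bounded 30-item support", {
  set.seed(74)
  cfg <- small_cfg()
  truth <- cogchain:::.generate_truth(cfg)
  iq <- generate_intelligence(truth, cfg)
  expect_true(all(iq >= 0 & iq <= 30))
  expect_true(is.integer(iq))
})

test_that("zeroed paths make intelligence independent of neurochemistry", {
  set.seed(75)
  cfg <- cohort_config(n_per_band = c(400, 400, 400, 400, 400),
                       iq_chem_main = c(IPS_glutamate = 0, IPS_gaba = 0),
                       iq_chem_int = c(IPS_glutamate = 0, IPS_gaba = 0),
                       iq_age = 0, iq_ter = 0, iq_ter_age = 0)
  truth <- cogchain:::.generate_truth(cfg)
  iq <- generate_intelligence(truth, cfg)
  expect_lt(abs(cor(iq, truth$IPS_glutamate)), 0.06)
  expect_lt(abs(cor(iq, truth$age_z)), 0.06)
})

test_that("moderated-cohort generator delivers unit-variance standardized structure", {
  d <- generate_moderated_cohort(20000, beta_int = -0.22, seed = 76)
  expect_equal(sd(d$ter), 1, tolerance = 0.03)
  expect_equal(sd(d$IPS_glutamate), 1, tolerance = 0.03)
  expect_equal(as.numeric(cor(d$IPS_glutamate, d$age)), -0.4,
               tolerance = 0.05)
  expect_error(generate_moderated_cohort(100, beta_int = 2), "variance")
})

test_that("model-59 generator matches its declared population structure", {
  d <- generate_model59_cohort(40000, list(a1 = 0.3, a2 = -0.2, a3 = 0.15,
                                           b1 = 0.25, b2 = 0.1, c1 = 0.1,
                                           c2 = 0.2, c3 = -0.1), seed = 77)
  expect_equal(sd(d$m), 1, tolerance = 0.02)
  expect_equal(sd(d$y), 1, tolerance = 0.02)
  expect_lt(abs(cor(d$x, d$w)), 0.02)
  expect_error(generate_model59_cohort(10, list(a1 = 0.9, a2 = 0.5, a3 = 0,
                                                b1 = 0, b2 = 0, c1 = 0,
                                                c2 = 0, c3 = 0)),
               "variance")
})

test_that("the noiseless behavior chain recovers parameters end to end", {
  # truth -> exact forward moments -> estimator returns truth; this is
  # the zero-observation-noise route the generator is built on
  set.seed(78)
  for (p in random_params(50)) {
    est <- ez_estimate(ez_forward(p))
    expect_lt(max(abs(c(est$v - p$v, est$a - p$a, est$ter - p$ter))), 1e-10)
  }
})

test_that("follow-up waves retain ids, age participants, and stay reproducible", {
  co <- generate_cohort(small_cfg(seed = 12))
  f1 <- generate_followup(co, seed = 99)
  f2 <- generate_followup(co, seed = 99)
  expect_identical(f1$participants, f2$participants)
  expect_true(all(f1$participants$participant_id %in%
                    co$participants$participant_id))
  a1 <- co$participants$age[match(f1$participants$participant_id,
                                  co$participants$participant_id)]
  expect_equal(f1$participants$age - a1, rep(1.75, nrow(f1$participants)))
  expect_lt(nrow(f1$participants), nrow(co$participants))
})
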