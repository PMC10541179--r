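#' Configuration of the synthetic developmental cohort
#'
#' Bundles the generating conditions of the synthetic study: recruitment
#' band sizes and age ranges, standardized age trends of the diffusion
#' parameters and neurochemicals, the cross-level interaction
#' coefficients linking neurochemistry, connectivity and behavior, task
#' designs, and the observation-noise distributions for the
#' spectroscopy, connectivity, and behavioral streams. The defaults are
#' the packaged study-like calibration: a 293-participant cohort over
#' five bands, the reported interaction coefficients for the
#' intraparietal-sulcus neurotransmitters, and the printed task designs
#' (96-trial/12-condition attention block, 72 digit-comparison trials
#' over the 36 digit pairs, 72 animal-figure rotation trials).
#'
#' @param n_per_band participants per age band (6-7, 10-11, 14-15,
#'   16-17, 18+).
#' @param seed integer seed stored with the config.
#' @param ... overrides of the defaults listed in the function body.
#' @return list of class `cogchain_config`.
#' @export
cohort_config <- function(n_per_band = c(60, 60, 60, 57, 56), seed = 1L, ...) {
  cfg <- list(
    n_per_band = n_per_band,
    bands = c("6-7", "10-11", "14-15", "16-17", "18+"),
    band_age_ranges = list(c(6, 8), c(10, 12), c(14, 16), c(16, 18), c(18, 22)),
    seed = seed,
    # standardized age trends (latent scale)
    trend_v = 0.5, trend_a = -0.4, trend_ter = -0.5,
    chem_trend = c(glutamate = -0.4, gaba = 0.4, naa = 0.15),
    # neurochemical effects on non-decision time (IPS only; MFG null)
    ter_chem_main = c(IPS_glutamate = -0.05, IPS_gaba = 0.05),
    ter_chem_int = c(IPS_glutamate = -0.22, IPS_gaba = 0.23),
    # connectivity structure: neurochemical-by-age in, behavior out
    conn_chem_main = c(IPS_glutamate = -0.05, IPS_gaba = -0.05),
    conn_chem_int = c(IPS_glutamate = -0.18, IPS_gaba = 0.15),
    conn_age = -0.2,
    conn_to_ter = -0.01, conn_age_to_ter = -0.16,
    # intelligence outcome (model-59 structure, mediator = visuomotor)
    iq_chem_main = c(IPS_glutamate = 0.0, IPS_gaba = 0.0),
    iq_chem_int = c(IPS_glutamate = 0.16, IPS_gaba = -0.05),
    iq_age = 0.3, iq_ter = 0.1, iq_ter_age = 0.1,
    # natural scales of the diffusion parameters (s = 0.1 convention)
    v_mean = 0.20, v_sd = 0.04,
    a_mean = 0.12, a_sd = 0.015,
    ter_mean = 0.32, ter_sd = 0.05, ter_floor = 0.1,
    task_ter_offset = c(attention = 0, digit = 0.02, rotation = 0.05),
    task_v_offset = c(attention = 0, digit = 0.02, rotation = -0.04),
    # per-condition offsets (attention cue -> ter; flanker/distance -> v)
    cue_ter_offset = c(no_cue = 0.02, central_cue = 0.01,
                       spatial_cue = 0, double_cue = 0),
    flanker_v_offset = c(congruent = 0.02, neutral = 0.01,
                         incongruent = -0.02),
    distance_v_offset = c(far = 0.03, near = -0.03),
    angle_v_offset = c(deg45 = 0.03, deg90 = 0, deg135 = -0.03),
    dt = 0.001, s = 0.1,
    # spectroscopy observation model
    chem_scale = list(glutamate = c(9, 1.2), gaba = c(1.8, 0.35),
                      naa = c(11, 1.2)),
    crlb_meanlog = c(glutamate = log(8), gaba = log(25), naa = log(4)),
    crlb_sdlog = 0.35,
    snr_mean = 40, snr_sd = 8,
    mrs_noise_sd = 0.02,
    f_csf_mean = 0.10, f_csf_sd = 0.03, gm_share_mean = 0.62,
    gm_share_sd = 0.05,
    water_t2_mean = 65, water_t2_sd = 5, water_amp = 1000,
    water_noise_sd = 0.01,
    # resting-state observation model
    n_frames = 380, tr = 0.933,
    conn_z_mean = 0.30, conn_z_slope = 0.10,
    fd_base_mean = 0.15, fd_base_sd = 0.08,
    high_motion_prob = c(0.25, 0.05, 0.02, 0.02, 0),
    high_motion_frames = c(20, 40),
    # intelligence link
    iq_link_center = 15, iq_link_scale = 5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (any(cfg$n_per_band < 1)) stop("band sizes must be >= 1")
  structure(cfg, class = "cogchain_config")
}

# deterministic proportional split of n over the five bands
.split_bands <- function(n, weights = c(60, 60, 60, 57, 56)) {
  raw <- n * weights / sum(weights)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  }
  k
}

# ages uniform within bands, standardized over the sample
.sample_ages <- function(n_per_band, ranges) {
  unlist(lapply(seq_along(n_per_band), function(i)
    runif(n_per_band[i], ranges[[i]][1], ranges[[i]][2])))
}

#' Generate a participant table with the moderated-regression structure
#'
#' Draws a cohort whose non-decision time follows the single-
#' neurotransmitter moderated model: banded ages, a neurochemical with a
#' standardized age trend `rho`, drift rate and boundary separation as
#' age-trended controls, and
#' `ter = b_chem chem + b_age age + b_int chem*age + b_v v + b_a a + e`,
#' with all variables unit-variance on the standardized-age scale and
#' the residual scaled so the outcome has (population) variance one --
#' so the generating coefficients are directly comparable with the
#' standardized betas recovered by [fit_moderated_model()].
#'
#' @param n cohort size.
#' @param beta_int generating standardized interaction coefficient.
#' @param beta_chem,beta_age,beta_v,beta_a main-effect coefficients.
#' @param rho standardized age trend of the neurochemical.
#' @param trend_v,trend_a age trends of the control parameters.
#' @param chem_name column name for the neurochemical.
#' @param seed optional integer seed.
#' @return data.frame with `participant_id`, `age` (years), the
#'   neurochemical, `v`, `a`, `ter` (all on the standardized latent
#'   scale).
#' @export
generate_moderated_cohort <- function(n, beta_int, beta_chem = -0.05,
                                beta_age = -0.5, beta_v = 0.15,
                                beta_a = 0.2, rho = -0.4, trend_v = 0.5,
                                trend_a = -0.4,
                                chem_name = "IPS_glutamate", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- .split_bands(n)
  cfg <- cohort_config()
  age <- .sample_ages(nb, cfg$band_age_ranges)
  age_z <- drop(scale(age))
  chem <- rho * age_z + sqrt(1 - rho^2) * rnorm(n)
  v <- trend_v * age_z + sqrt(1 - trend_v^2) * rnorm(n)
  a <- trend_a * age_z + sqrt(1 - trend_a^2) * rnorm(n)
  u <- chem * age_z

  # population covariance of (chem, age, v, a): all unit variance, the
  # product term uncorrelated with the mains under the trend structure
  Sigma <- matrix(c(
    1,            rho,          rho * trend_v, rho * trend_a,
    rho,          1,            trend_v,       trend_a,
    rho * trend_v, trend_v,     1,             trend_v * trend_a,
    rho * trend_a, trend_a,     trend_v * trend_a, 1), 4, 4)
  bvec <- c(beta_chem, beta_age, beta_v, beta_a)
  expl <- drop(t(bvec) %*% Sigma %*% bvec) + beta_int^2 * (1 + rho^2)
  if (expl >= 1)
    stop("generating coefficients imply explained variance >= 1")
  ter <- beta_chem * chem + beta_age * age_z + beta_int * u +
    beta_v * v + beta_a * a + sqrt(1 - expl) * rnorm(n)

  out <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                    age = age, v = v, a = a, ter = ter)
  out[[chem_name]] <- chem
  out
}

#' Generate a cohort with a fully moderated mediation structure
#'
#' Draws independent standard-normal `x` (e.g. a neurochemical) and `w`
#' (standardized age), the mediator
#' `m = a1 x + a2 w + a3 xw + e_M`, and the outcome
#' `y = c1' x + c2' w + c3' xw + b1 m + b2 mw + e_Y`, with both
#' residuals scaled so `m` and `y` have population variance one. The
#' generating paths are then directly comparable with standardized
#' estimates from [fit_model59()], and the population conditional
#' indirect effect at moderator `w0` is `(a1 + a3 w0)(b1 + b2 w0)`.
#'
#' @param n cohort size.
#' @param paths named list/vector with `a1, a2, a3, b1, b2, c1, c2, c3`.
#' @param roles character vector naming the output columns for x, m, y,
#'   w (in that order).
#' @param seed optional integer seed.
#' @return data.frame with the four role columns plus `participant_id`.
#' @export
generate_model59_cohort <- function(n, paths,
                                    roles = c("x", "m", "y", "w"),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- as.list(paths)
  need <- c("a1", "a2", "a3", "b1", "b2", "c1", "c2", "c3")
  if (!all(need %in% names(p)))
    stop("paths must contain ", paste(need, collapse = ", "))
  sig_m2 <- 1 - (p$a1^2 + p$a2^2 + p$a3^2)
  if (sig_m2 <= 0) stop("a-paths imply mediator variance >= 1")
  x <- rnorm(n)
  w <- rnorm(n)
  m <- p$a1 * x + p$a2 * w + p$a3 * x * w + sqrt(sig_m2) * rnorm(n)
  # moments of the m*w regressor under the generating law
  var_mw <- p$a1^2 + 2 * p$a2^2 + 3 * p$a3^2 + sig_m2
  expl_y <- p$c1^2 + p$c2^2 + p$c3^2 + p$b1^2 + p$b2^2 * var_mw +
    2 * (p$c1 * p$b1 * p$a1 + p$c2 * p$b1 * p$a2 + p$c3 * p$b1 * p$a3 +
           p$c1 * p$b2 * p$a3 + p$c3 * p$b2 * p$a1 +
           2 * p$b1 * p$b2 * p$a1 * p$a3)
  if (expl_y >= 1) stop("paths imply outcome variance >= 1")
  y <- p$c1 * x + p$c2 * w + p$c3 * x * w + p$b1 * m + p$b2 * m * w +
    sqrt(1 - expl_y) * rnorm(n)
  out <- data.frame(sprintf("P%03d", seq_len(n)), x, m, y, w)
  names(out) <- c("participant_id", roles)
  out
}

#' Packaged study-like calibrations
#'
#' Generating configurations whose coefficients are set to the
#' first-assessment estimates the package's recovery simulations are
#' benchmarked against: the intraparietal-sulcus glutamate-by-age
#' (-0.22) and GABA-by-age (+0.23) interactions on non-decision time,
#' and three moderated-mediation path sets calibrated so the
#' conditional indirect effects at the probed moderator levels equal
#' the benchmark values (GABA -> intelligence via visuomotor processing
#' at +1 SD = 0.04; glutamate -> intelligence via visuomotor processing
#' at +1 SD = -0.06; GABA -> visuomotor processing via visuomotor
#' connectivity at -1 SD = -0.03).
#'
#' @return named list of profiles consumed by [recover_interaction()]
#'   and [recover_indirect()].
#' @export
study_calibrations <- function() {
  list(
    glutamate_by_age = list(kind = "moderated", n = 258, beta_int = -0.22,
                         beta_chem = -0.05, rho = -0.4,
                         chem_name = "IPS_glutamate"),
    gaba_by_age = list(kind = "moderated", n = 258, beta_int = 0.23,
                    beta_chem = 0.05, rho = 0.4, chem_name = "IPS_gaba"),
    med_gaba_intelligence = list(
      kind = "model59", n = 250, w_level = 1,
      roles = c("IPS_gaba", "composite_ter", "intelligence", "age"),
      paths = list(a1 = -0.03, a2 = -0.5, a3 = 0.23,
                   b1 = 0.1, b2 = 0.1, c1 = 0, c2 = 0.3, c3 = -0.05)),
    med_glutamate_intelligence = list(
      kind = "model59", n = 250, w_level = 1,
      roles = c("IPS_glutamate", "composite_ter", "intelligence", "age"),
      paths = list(a1 = -0.08, a2 = -0.5, a3 = -0.22,
                   b1 = 0.1, b2 = 0.1, c1 = 0, c2 = 0.3, c3 = 0.16)),
    med_gaba_connectivity = list(
      kind = "model59", n = 250, w_level = -1,
      roles = c("IPS_gaba", "connectivity", "composite_ter", "age"),
      paths = list(a1 = -0.05, a2 = -0.2, a3 = 0.15,
                   b1 = -0.01, b2 = -0.16, c1 = 0.05, c2 = -0.5,
                   c3 = 0.23))
  )
}

#' Interaction-recovery simulation
#'
#' Repeatedly generates cohorts with the moderated-regression structure
#' of a calibration profile, fits the moderated model on z-scored
#' variables, and averages the recovered standardized interaction
#' coefficient.
#'
#' @param profile an `moderated` profile from [study_calibrations()] (or a
#'   compatible list).
#' @param n_reps number of replicate cohorts (default 200).
#' @param n cohort size per replicate (profile default).
#' @param seed integer seed.
#' @return list with `mean_beta`, `sd_beta`, `betas`, `n`, `n_reps`,
#'   `generating` (the generating coefficient).
#' @export
recover_interaction <- function(profile, n_reps = 200, n = profile$n,
                                seed = 1L) {
  stopifnot(identical(profile$kind, "moderated"))
  set.seed(seed)
  spec <- model_spec(
    dependent = "ter",
    predictors = c(profile$chem_name, "age",
                   paste(profile$chem_name, "age", sep = ":"), "v", "a"))
  betas <- vapply(seq_len(n_reps), function(i) {
    d <- generate_moderated_cohort(n, beta_int = profile$beta_int,
                             beta_chem = profile$beta_chem,
                             rho = profile$rho,
                             chem_name = profile$chem_name)
    fit <- fit_moderated_model(spec, d)
    fit$coefficients[[spec$hypothesis]]
  }, numeric(1))
  list(mean_beta = mean(betas), sd_beta = sd(betas), betas = betas,
       n = n, n_reps = n_reps, generating = profile$beta_int)
}

#' Conditional-indirect-effect recovery simulation
#'
#' Repeatedly generates cohorts with a model-59 structure, fits the two
#' mediation equations, and averages the estimated conditional indirect
#' effect at the probed moderator level.
#'
#' @param profile a `model59` profile from [study_calibrations()].
#' @param n_reps number of replicate cohorts (default 200).
#' @param n cohort size per replicate (profile default).
#' @param w_level moderator level in SD units (profile default).
#' @param seed integer seed.
#' @return list with `mean_indirect`, `sd_indirect`, `indirects`, `n`,
#'   `n_reps`, `w_level`, `generating` (the population value).
#' @export
recover_indirect <- function(profile, n_reps = 200, n = profile$n,
                             w_level = profile$w_level, seed = 1L) {
  stopifnot(identical(profile$kind, "model59"))
  set.seed(seed)
  p <- profile$paths
  gen <- (p$a1 + p$a3 * w_level) * (p$b1 + p$b2 * w_level)
  r <- profile$roles
  vals <- vapply(seq_len(n_reps), function(i) {
    d <- generate_model59_cohort(n, p, roles = r)
    fit <- fit_model59(d, x = r[1], m = r[2], y = r[3], w = r[4])
    conditional_indirect(fit, w_level)
  }, numeric(1))
  list(mean_indirect = mean(vals), sd_indirect = sd(vals),
       indirects = vals, n = n, n_reps = n_reps, w_level = w_level,
       generating = gen)
}

# ---- full multi-stream cohort ------------------------------------------

# truth-level latent table: ages, neurochemistry, diffusion parameters,
# connectivity, intelligence latent -- all standardized
.generate_truth <- function(cfg) {
  n <- sum(cfg$n_per_band)
  age <- .sample_ages(cfg$n_per_band, cfg$band_age_ranges)
  age_z <- drop(scale(age))
  band <- rep(cfg$bands, cfg$n_per_band)

  chems <- list()
  for (region in c("IPS", "MFG"))
    for (met in names(cfg$chem_trend)) {
      rho <- cfg$chem_trend[[met]]
      chems[[paste(region, met, sep = "_")]] <-
        rho * age_z + sqrt(1 - rho^2) * rnorm(n)
    }

  v_z <- cfg$trend_v * age_z + sqrt(1 - cfg$trend_v^2) * rnorm(n)
  a_z <- cfg$trend_a * age_z + sqrt(1 - cfg$trend_a^2) * rnorm(n)

  conn_lin <- cfg$conn_age * age_z
  for (cv in names(cfg$conn_chem_main))
    conn_lin <- conn_lin + cfg$conn_chem_main[[cv]] * chems[[cv]] +
      cfg$conn_chem_int[[cv]] * chems[[cv]] * age_z
  expl <- min(var(conn_lin), 0.9)
  conn_z <- conn_lin + sqrt(1 - expl) * rnorm(n)
  conn_z <- drop(scale(conn_z))

  ter_lin <- cfg$trend_ter * age_z +
    cfg$conn_to_ter * conn_z + cfg$conn_age_to_ter * conn_z * age_z
  for (cv in names(cfg$ter_chem_main))
    ter_lin <- ter_lin + cfg$ter_chem_main[[cv]] * chems[[cv]] +
      cfg$ter_chem_int[[cv]] * chems[[cv]] * age_z
  expl <- min(var(ter_lin), 0.9)
  ter_z <- ter_lin + sqrt(1 - expl) * rnorm(n)
  ter_z <- drop(scale(ter_z))

  out <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                    band = band, age = age, age_z = age_z,
                    v_z = v_z, a_z = a_z, ter_z = ter_z, conn_z = conn_z)
  for (nm in names(chems)) out[[nm]] <- chems[[nm]]
  out
}

# natural diffusion parameters for one task from the latent truth
.task_params <- function(truth, cfg, task) {
  v <- pmax(cfg$v_mean + cfg$v_sd * truth$v_z + cfg$task_v_offset[[task]],
            0.03)
  a <- pmax(cfg$a_mean + cfg$a_sd * truth$a_z, 0.06)
  ter <- cfg$ter_mean + cfg$ter_sd * truth$ter_z + cfg$task_ter_offset[[task]]
  n_floor <- sum(ter < cfg$ter_floor)
  ter <- pmax(ter, cfg$ter_floor)
  list(v = v, a = a, ter = ter, n_floored = n_floor)
}

# condition grids per task design
.attention_cells <- function() {
  expand.grid(cue = c("no_cue", "central_cue", "double_cue", "spatial_cue"),
              flanker = c("congruent", "incongruent", "neutral"),
              stringsAsFactors = FALSE)
}

.digit_pairs <- function() {
  g <- expand.grid(lo = 1:9, hi = 1:9)
  g <- g[g$lo < g$hi, ]
  g[order(g$lo, g$hi), ]
}

#' Classify digit pairs into distance bins
#'
#' `far` for numerical distance of 5 or more, `near` for 4 or less; the
#' split used when collapsing the 36 digit pairs into the two
#' distance-effect cells.
#' @param lo,hi the two digits.
#' @return `"far"` or `"near"`.
#' @export
digit_distance_bin <- function(lo, hi) {
  ifelse(abs(hi - lo) >= 5, "far", "near")
}

# simulate one participant's trials for one task
.simulate_task_trials <- function(pid, task, v, a, ter, cfg) {
  s <- cfg$s
  sim_cell <- function(cond, n_cell, dv = 0, dter = 0, extra = NULL) {
    tr <- simulate_wiener_trials(
      list(v = v + dv, a = a, ter = max(ter + dter, 0.05), s = s),
      n_cell, dt = cfg$dt)
    out <- data.frame(participant_id = pid, task = task, condition = cond,
                      correct = tr$correct, rt = tr$rt)
    if (!is.null(extra)) out <- cbind(out, extra)
    out
  }
  if (task == "attention") {
    cells <- .attention_cells()
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      cue <- cells$cue[i]; fl <- cells$flanker[i]
      sim_cell(paste(cue, fl, sep = "."), 8L,
               dv = cfg$flanker_v_offset[[fl]],
               dter = cfg$cue_ter_offset[[cue]])
    }))
  } else if (task == "digit") {
    pairs <- .digit_pairs()
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      bin <- digit_distance_bin(pairs$lo[i], pairs$hi[i])
      sim_cell(sprintf("d%d_%d", pairs$lo[i], pairs$hi[i]), 2L,
               dv = cfg$distance_v_offset[[bin]])
    }))
  } else if (task == "rotation") {
    grid <- expand.grid(figure = c("giraffe", "zebra", "raccoon"),
                        angle = c("deg45", "deg90", "deg135"),
                        stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      sim_cell(grid$angle[i], 8L, dv = cfg$angle_v_offset[[grid$angle[i]]],
               extra = data.frame(figure = grid$figure[i]))
    }))
  } else stop("unknown task: ", task)
}

#' Generate spectroscopy observables from truth concentrations
#'
#' Constructs raw metabolite-to-water ratios by *inverting* the
#' partial-volume correction from the truth concentration and sampled
#' tissue fractions -- so with `noise_sd = 0` the correction chain
#' recovers truth exactly -- and samples quantification-quality
#' covariates (CRLB, SNR) and multi-echo water-reference integrals from
#' the configured distributions.
#'
#' @param truth truth participant table from the cohort generator
#'   (needs the standardized region-metabolite columns).
#' @param cfg a [cohort_config()].
#' @param noise_sd multiplicative log-normal observation noise on the
#'   raw concentration (config default when `NULL`).
#' @return list with `records` (the metabolite rows) and `water` (the
#'   echo-time integrals per participant and region).
#' @export
generate_mrs_observables <- function(truth, cfg, noise_sd = NULL) {
  if (is.null(noise_sd)) noise_sd <- cfg$mrs_noise_sd
  regions <- c("IPS", "MFG")
  mets <- names(cfg$chem_trend)
  n <- nrow(truth)
  te <- water_te_grid()

  rec <- list(); wat <- list()
  for (region in regions) {
    f_csf <- pmin(pmax(rnorm(n, cfg$f_csf_mean, cfg$f_csf_sd), 0.01), 0.5)
    gm_share <- pmin(pmax(rnorm(n, cfg$gm_share_mean, cfg$gm_share_sd),
                          0.3), 0.9)
    f_gm <- (1 - f_csf) * gm_share
    f_wm <- 1 - f_csf - f_gm
    factor <- tissue_correct(1, f_gm, f_wm, f_csf)
    snr <- pmax(rnorm(n, cfg$snr_mean, cfg$snr_sd), 5)
    for (met in mets) {
      zcol <- truth[[paste(region, met, sep = "_")]]
      sc <- cfg$chem_scale[[met]]
      conc_true <- pmax(sc[1] + sc[2] * zcol, 0.1)
      raw <- conc_true / factor *
        if (noise_sd > 0) exp(rnorm(n, 0, noise_sd)) else 1
      rec[[paste(region, met)]] <- data.frame(
        participant_id = truth$participant_id, region = region,
        metabolite = met, raw_conc = raw,
        crlb_pct = exp(rnorm(n, cfg$crlb_meanlog[[met]], cfg$crlb_sdlog)),
        snr = snr, f_gm = f_gm, f_wm = f_wm, f_csf = f_csf,
        te_s = 0.032, conc_true = conc_true)
    }
    t2t <- pmin(pmax(rnorm(n, cfg$water_t2_mean, cfg$water_t2_sd), 30), 150)
    at <- cfg$water_amp * (1 - f_csf)
    ac <- cfg$water_amp * f_csf
    for (i in seq_len(n)) {
      s <- at[i] * exp(-te / t2t[i]) + ac[i] * exp(-te / 740)
      if (cfg$water_noise_sd > 0)
        s <- s * exp(rnorm(length(te), 0, cfg$water_noise_sd))
      wat[[paste(region, i)]] <- data.frame(
        participant_id = truth$participant_id[i], region = region,
        te_ms = te, integral = s, t2_true = t2t[i])
    }
  }
  list(records = do.call(rbind, rec), water = do.call(rbind, wat))
}

#' Generate intelligence scores from the model-59 outcome structure
#'
#' Builds a latent fluid-intelligence outcome from the configured
#' neurochemical, age, and visuomotor-processing paths (mediator = the
#' standardized non-decision-time latent) and maps it through a
#' monotone link to an integer 0-30 item count, the bounded support of
#' a 30-item matrix-reasoning test with a discontinue rule.
#'
#' @param truth truth participant table.
#' @param cfg a [cohort_config()].
#' @return integer vector of scores in `[0, 30]`.
#' @export
generate_intelligence <- function(truth, cfg) {
  lat <- cfg$iq_age * truth$age_z +
    cfg$iq_ter * truth$ter_z + cfg$iq_ter_age * truth$ter_z * truth$age_z
  for (cv in names(cfg$iq_chem_main))
    lat <- lat + cfg$iq_chem_main[[cv]] * truth[[cv]] +
      cfg$iq_chem_int[[cv]] * truth[[cv]] * truth$age_z
  expl <- min(var(lat), 0.9)
  lat <- lat + sqrt(1 - expl) * rnorm(nrow(truth))
  score <- round(cfg$iq_link_center + cfg$iq_link_scale * drop(scale(lat)))
  as.integer(pmin(pmax(score, 0), 30))
}

# latent-factor ROI time series whose pairwise correlation tracks the
# participant's connectivity truth
.generate_roi <- function(truth, cfg) {
  n_roi <- length(visuomotor_rois())
  band_idx <- match(truth$band, cfg$bands)
  lapply(seq_len(nrow(truth)), function(i) {
    z_target <- cfg$conn_z_mean + cfg$conn_z_slope * truth$conn_z[i]
    r <- tanh(max(z_target, 0.02))
    lambda <- sqrt(r / (1 - r))
    f <- rnorm(cfg$n_frames)
    ts <- sapply(seq_len(n_roi), function(j)
      lambda * f + rnorm(cfg$n_frames))
    colnames(ts) <- visuomotor_rois()
    fd <- abs(rnorm(cfg$n_frames, cfg$fd_base_mean, cfg$fd_base_sd))
    if (runif(1) < cfg$high_motion_prob[band_idx[i]]) {
      k <- sample(cfg$high_motion_frames[1]:cfg$high_motion_frames[2], 1)
      fd[sample.int(cfg$n_frames, k)] <- runif(k, 2.2, 4)
    }
    list(ts = ts, fd = fd)
  })
}

#' Generate a full synthetic developmental cohort
#'
#' Draws the complete multi-stream study the analysis chain consumes:
#' a truth participant table (ages in five bands, standardized
#' neurochemical concentrations with age trends, diffusion-parameter
#' latents carrying the configured neurochemical-by-age interactions,
#' connectivity and intelligence latents with the configured moderated
#' paths), trial tables for the three behavioral tasks produced by the
#' Wiener simulator under the printed designs, spectroscopy records
#' whose raw values invert the partial-volume correction, multi-echo
#' water-reference series, and ROI time series with framewise
#' displacement traces. Outputs regenerate bit-identically from
#' `(config, seed)`.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed (config seed by default).
#' @return object of class `cogchain_cohort`: `participants`, `trials`,
#'   `mrs`, `water`, `roi`, `config`, `seed`.
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "cogchain_config"))
  set.seed(seed)
  truth <- .generate_truth(cfg)
  n <- nrow(truth)

  trials <- list()
  for (task in c("attention", "digit", "rotation")) {
    par <- .task_params(truth, cfg, task)
    trials[[task]] <- do.call(rbind, lapply(seq_len(n), function(i) {
      tt <- .simulate_task_trials(truth$participant_id[i], task,
                                  par$v[i], par$a[i], par$ter[i], cfg)
      tt
    }))
    truth[[paste0("v_true_", task)]] <- par$v
    truth[[paste0("a_true_", task)]] <- par$a
    truth[[paste0("ter_true_", task)]] <- par$ter
  }
  trial_df <- do.call(rbind, lapply(trials, function(d) {
    d$figure <- NULL
    d
  }))
  rownames(trial_df) <- NULL

  mrs <- generate_mrs_observables(truth, cfg)
  roi <- .generate_roi(truth, cfg)
  truth$intelligence <- generate_intelligence(truth, cfg)

  structure(list(participants = truth, trials = trial_df,
                 trials_by_task = trials, mrs = mrs$records,
                 water = mrs$water, roi = roi, config = cfg, seed = seed),
            class = "cogchain_cohort")
}

#' @export
print.cogchain_cohort <- function(x, ...) {
  cat("Synthetic developmental cohort:", nrow(x$participants),
      "participants in", length(unique(x$participants$band)), "age bands\n")
  cat(" trials:", nrow(x$trials), " spectroscopy records:", nrow(x$mrs),
      "\n resting-state series:", length(x$roi), "x",
      x$config$n_frames, "frames\n")
  invisible(x)
}

#' Write a synthetic cohort to CSV streams
#'
#' Emits the four input streams consumed by [run_pipeline()] plus a
#' truth table: `participants.csv`, `trials.csv`, `mrs.csv`,
#' `water.csv`, `roi.csv` (long format with framewise displacement).
#'
#' @param cohort a `cogchain_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cogchain_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(participants = file.path(dir, "participants.csv"),
             trials = file.path(dir, "trials.csv"),
             mrs = file.path(dir, "mrs.csv"),
             water = file.path(dir, "water.csv"),
             roi = file.path(dir, "roi.csv"))
  write.csv(cohort$participants, paths["participants"], row.names = FALSE)
  tr <- cohort$trials
  names(tr)[names(tr) == "rt"] <- "rt_s"
  write.csv(tr, paths["trials"], row.names = FALSE)
  write.csv(cohort$mrs, paths["mrs"], row.names = FALSE)
  write.csv(cohort$water, paths["water"], row.names = FALSE)
  roi_long <- do.call(rbind, lapply(seq_along(cohort$roi), function(i) {
    r <- cohort$roi[[i]]
    cbind(data.frame(participant_id = cohort$participants$participant_id[i],
                     frame = seq_len(nrow(r$ts)), fd_mm = r$fd),
          as.data.frame(r$ts))
  }))
  write.csv(roi_long, paths["roi"], row.names = FALSE)
  invisible(paths)
}

#' Generate a second-assessment follow-up of a cohort
#'
#' Emulates the retest wave of a cross-sectional longitudinal design:
#' a retained subsample is re-assessed `years` later, with each
#' standardized latent carried forward with autocorrelation
#' `stability` (new = stability * old + sqrt(1 - stability^2) * noise)
#' before the observable streams are regenerated with the same
#' machinery as the first assessment.
#'
#' @param cohort a `cogchain_cohort` (first assessment).
#' @param retention fraction of participants re-assessed.
#' @param stability latent test-retest autocorrelation.
#' @param years inter-assessment interval in years.
#' @param seed integer seed.
#' @return a `cogchain_cohort` for the second assessment (participant
#'   ids preserved; `wave` column set to `"A2"`).
#' @export
generate_followup <- function(cohort, retention = 0.7, stability = 0.7,
                              years = 1.75, seed = cohort$seed + 1L) {
  stopifnot(inherits(cohort, "cogchain_cohort"))
  set.seed(seed)
  cfg <- cohort$config
  t1 <- cohort$participants
  keep <- sort(sample.int(nrow(t1), round(retention * nrow(t1))))
  truth <- t1[keep, c("participant_id", "band", "age", "age_z", "v_z",
                      "a_z", "ter_z", "conn_z",
                      grep("^(IPS|MFG)_", names(t1), value = TRUE))]
  truth$age <- truth$age + years
  truth$age_z <- drop(scale(truth$age))
  lat <- c("v_z", "a_z", "ter_z", "conn_z",
           grep("^(IPS|MFG)_", names(truth), value = TRUE))
  for (nm in lat)
    truth[[nm]] <- stability * truth[[nm]] +
      sqrt(1 - stability^2) * rnorm(nrow(truth))
  truth$wave <- "A2"

  n <- nrow(truth)
  trials <- list()
  for (task in c("attention", "digit", "rotation")) {
    par <- .task_params(truth, cfg, task)
    trials[[task]] <- do.call(rbind, lapply(seq_len(n), function(i)
      .simulate_task_trials(truth$participant_id[i], task,
                            par$v[i], par$a[i], par$ter[i], cfg)))
  }
  trial_df <- do.call(rbind, lapply(trials, function(d) { d$figure <- NULL; d }))
  rownames(trial_df) <- NULL
  mrs <- generate_mrs_observables(truth, cfg)
  roi <- .generate_roi(truth, cfg)
  truth$intelligence <- generate_intelligence(truth, cfg)
  structure(list(participants = truth, trials = trial_df,
                 trials_by_task = trials, mrs = mrs$records,
                 water = mrs$water, roi = roi, config = cfg, seed = seed),
            class = "cogchain_cohort")
}
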