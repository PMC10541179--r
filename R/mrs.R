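#' Partial-volume (tissue) correction of a metabolite concentration
#'
#' Rescales a raw metabolite-to-water amplitude ratio for the voxel's
#' gray-matter, white-matter, and CSF composition using the standard
#' water-concentration constants (43300, 35880 and 55556 mmol/L for GM,
#' WM, and CSF):
#' \deqn{conc = \frac{43300/55556 \, f_{GM} + 35880/55556 \, f_{WM} +
#'   f_{CSF}}{1 - f_{CSF}} \times raw}
#' The numerator corrects for differing tissue water concentrations of
#' the unsuppressed water reference; the `1/(1 - fCSF)` factor corrects
#' for the assumption that CSF is free of metabolites.
#'
#' @param raw raw metabolite-to-water amplitude ratio (>= 0); vectorized.
#' @param f_gm,f_wm,f_csf tissue fractions in `[0, 1]`.
#' @return tissue-corrected concentration, same length as `raw`.
#' @export
tissue_correct <- function(raw, f_gm, f_wm, f_csf) {
  if (any(!is.finite(c(f_gm, f_wm, f_csf))) ||
      any(c(f_gm, f_wm, f_csf) < 0) || any(c(f_gm, f_wm, f_csf) > 1))
    stop("tissue fractions must lie in [0, 1]")
  if (any(f_csf >= 1)) stop("pure-CSF voxel: fCSF must be < 1")
  ((43300 / 55556 * f_gm + 35880 / 55556 * f_wm + 1 * f_csf) /
     (1 - f_csf)) * raw
}

#' T2 correction of a tissue-corrected concentration
#'
#' Applies `conc * exp(-TE / T2)` with the echo time and the tissue-water
#' T2 in the same units. Note that this attenuates the concentration as
#' the relaxation weighting itself would (a conventional relaxation
#' *correction* divides by the attenuation factor); the multiplicative
#' form is retained deliberately for fidelity with the quantification
#' chain this package mirrors, and is flagged here so users comparing
#' against other pipelines are not surprised.
#'
#' @param conc tissue-corrected concentration (vectorized).
#' @param te echo time (seconds; 0.032 for the acquisitions modeled here).
#' @param t2_tissue tissue-water T2 (seconds, > 0).
#' @return corrected concentration.
#' @export
t2_correct <- function(conc, te, t2_tissue) {
  if (any(!is.finite(t2_tissue)) || any(t2_tissue <= 0))
    stop("t2_tissue must be positive")
  if (any(te < 0)) stop("te must be non-negative")
  conc * exp(-te / t2_tissue)
}

#' Echo-time grid of the multi-TE water-reference acquisition (ms)
#' @export
water_te_grid <- function() {
  c(32, 42, 52, 85, 100, 115, 150, 250, 450, 850, 1650, 3250, 4040)
}

#' Biexponential water-T2 fit
#'
#' Fits unsuppressed water-reference integrals acquired at multiple echo
#' times with `S(TE) = A_t exp(-TE/T2_t) + A_c exp(-TE/T2_csf)`, the CSF
#' water T2 fixed at 740 ms and three free parameters (tissue-water T2,
#' tissue amplitude, CSF amplitude). Trust-region (Levenberg-Marquardt)
#' least squares with T2_t bounded to `[10, 300]` ms, non-negative
#' amplitudes, and starting values from a log-linear fit of the earliest
#' echoes.
#'
#' @param te_ms echo times (ms), at least 4.
#' @param integrals positive water integrals, same length.
#' @param t2_csf_ms fixed CSF water T2 (ms).
#' @return list with `t2_tissue` (ms), `amp_tissue`, `amp_csf`,
#'   `csf_percent` (= `100 A_c / (A_t + A_c)`), `t2_csf_ms`, `fitted`.
#' @export
fit_water_t2 <- function(te_ms, integrals, t2_csf_ms = 740) {
  stopifnot(length(te_ms) == length(integrals))
  if (length(te_ms) < 4L) stop("need at least 4 echo points")
  if (any(integrals <= 0)) stop("water integrals must be positive")

  k <- seq_len(min(6L, length(te_ms)))
  init <- lm(log(integrals[k]) ~ te_ms[k])
  t2_0 <- unname(min(max(-1 / coef(init)[2], 10), 300))
  at_0 <- unname(exp(coef(init)[1]))
  # at long TE the tissue pool has decayed; back-extrapolate the CSF pool
  ac_0 <- max(integrals[length(integrals)] /
                exp(-te_ms[length(te_ms)] / t2_csf_ms), at_0 * 1e-4)

  df <- data.frame(te = te_ms, y = integrals)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ at * exp(-te / t2t) + ac * exp(-te / t2_csf_ms),
      data = df,
      start = list(t2t = t2_0, at = at_0, ac = ac_0),
      lower = c(t2t = 10, at = 0, ac = 0),
      upper = c(t2t = 300, at = Inf, ac = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("water-T2 fit did not converge: ",
                             conditionMessage(e))
  )
  est <- coef(fit)
  list(t2_tissue = unname(est["t2t"]),
       amp_tissue = unname(est["at"]),
       amp_csf = unname(est["ac"]),
       csf_percent = 100 * unname(est["ac"] / (est["at"] + est["ac"])),
       t2_csf_ms = t2_csf_ms,
       fitted = predict(fit))
}

#' Quality-based exclusions for spectroscopy records
#'
#' Two rules, applied per region (and per assessment wave when a `wave`
#' column is present): metabolites quantified with a Cramer-Rao lower
#' bound above `crlb_max` percent are flagged not-detectable (that
#' metabolite only -- other metabolites of the same spectrum are kept),
#' and spectra whose signal-to-noise ratio lies beyond `snr_sd_mult`
#' standard deviations of the region's SNR distribution are removed
#' entirely. The SNR distribution is computed over unique spectra
#' (participant x region), not over metabolite rows, so regions with more
#' quantified metabolites do not dominate.
#'
#' @param records data.frame with columns `participant_id`, `region`,
#'   `metabolite`, `crlb_pct`, `snr` (and optionally `wave`).
#' @param crlb_max not-detectable threshold, percent (default 50).
#' @param snr_sd_mult SNR exclusion band in SDs (default 3).
#' @return list with `records` (survivors, plus a logical
#'   `not_detectable` flag) and `log` (one row per flagged or removed
#'   record: participant, region, metabolite, rule, value).
#' @export
apply_mrs_exclusions <- function(records, crlb_max = 50, snr_sd_mult = 3) {
  stopifnot(all(c("participant_id", "region", "metabolite",
                  "crlb_pct", "snr") %in% names(records)))
  if (nrow(records) == 0L)
    return(list(records = records, log = data.frame()))
  recs <- records
  recs$not_detectable <- recs$crlb_pct > crlb_max

  log_rows <- list()
  if (any(recs$not_detectable)) {
    nd <- recs[recs$not_detectable, ]
    log_rows[[1]] <- data.frame(
      participant_id = nd$participant_id, region = nd$region,
      metabolite = nd$metabolite, rule = "crlb_not_detectable",
      value = nd$crlb_pct)
  }

  grp <- recs$region
  if ("wave" %in% names(recs)) grp <- paste(recs$region, recs$wave)
  drop <- rep(FALSE, nrow(recs))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    spectra <- unique(recs[idx, c("participant_id", "snr")])
    m <- mean(spectra$snr)
    s <- sd(spectra$snr)
    if (is.na(s) || s == 0) next
    z <- (recs$snr[idx] - m) / s
    drop[idx[abs(z) > snr_sd_mult]] <- TRUE
  }
  if (any(drop)) {
    dr <- recs[drop, ]
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      participant_id = dr$participant_id, region = dr$region,
      metabolite = dr$metabolite, rule = "snr_outlier", value = dr$snr)
  }
  list(records = recs[!drop, , drop = FALSE],
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(participant_id = character(), region = character(),
                    metabolite = character(), rule = character(),
                    value = numeric()))
}
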