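#' The seven visuomotor network nodes
#'
#' Four visual-network and three sensorimotor-network regions whose
#' pairwise couplings define the within-network visuomotor connectivity
#' score (21 region pairs).
#' @export
visuomotor_rois <- function() {
  c("Visual.Medial", "Visual.Occipital", "Visual.Lateral.L",
    "Visual.Lateral.R", "SensoriMotor.Lateral.L",
    "SensoriMotor.Lateral.R", "SensoriMotor.Superior")
}

#' Motion scrubbing of resting-state frames
#'
#' Censors frames whose framewise displacement exceeds `fd_threshold`
#' and marks the participant excluded when more than `max_frac` of the
#' frames were removed (strictly more: removing exactly 5% of the frames
#' keeps the participant).
#'
#' @param fd per-frame framewise displacement (mm).
#' @param n_frames expected series length; `fd` must match.
#' @param fd_threshold scrubbing threshold (mm, default 2).
#' @param max_frac maximum tolerated censored fraction (default 0.05).
#' @return list with `mask` (logical, TRUE = retained), `frac_censored`,
#'   and `excluded`.
#' @export
censor_frames <- function(fd, n_frames = length(fd), fd_threshold = 2,
                          max_frac = 0.05) {
  if (length(fd) != n_frames)
    stop("framewise-displacement trace length does not match the series")
  if (any(!is.finite(fd))) stop("fd must be finite")
  mask <- fd <= fd_threshold
  frac <- mean(!mask)
  list(mask = mask, frac_censored = frac, excluded = frac > max_frac)
}

#' Within-network visuomotor connectivity score
#'
#' High-pass filters each region's time series (zero-phase Butterworth,
#' applied forward and backward for a 4th-order magnitude response),
#' optionally regresses out supplied nuisance signals, computes the
#' Pearson correlation of every region pair on the retained (uncensored)
#' frames, Fisher r-to-z transforms each pair, and returns the mean z
#' over the 21 pairs.
#'
#' @param ts numeric matrix, frames x regions (nominally 380 x 7).
#' @param fd optional framewise displacement trace; when given, frames
#'   are censored via [censor_frames()] before correlation.
#' @param tr repetition time in seconds (default 0.933).
#' @param highpass_hz high-pass cutoff (default 0.01 Hz).
#' @param confounds optional matrix of nuisance regressors (frames x k)
#'   removed by least squares before correlation.
#' @param fd_threshold,max_frac scrubbing parameters, see
#'   [censor_frames()].
#' @param min_frames minimum retained frames required (default 30).
#' @return list with `z` (mean pairwise Fisher z), `n_pairs`,
#'   `frac_censored`, `excluded`, and the pairwise `r` matrix.
#' @export
connectivity_score <- function(ts, fd = NULL, tr = 0.933, highpass_hz = 0.01,
                               confounds = NULL, fd_threshold = 2,
                               max_frac = 0.05, min_frames = 30) {
  ts <- as.matrix(ts)
  n_t <- nrow(ts)
  n_roi <- ncol(ts)
  if (n_roi < 2L) stop("need at least two regions")

  cens <- if (!is.null(fd))
    censor_frames(fd, n_t, fd_threshold, max_frac)
  else list(mask = rep(TRUE, n_t), frac_censored = 0, excluded = FALSE)

  # zero-phase Butterworth high-pass on the full series, then censor
  w <- highpass_hz / (1 / (2 * tr))
  bf <- signal::butter(2, W = w, type = "high")
  filt <- apply(ts, 2, function(x) signal::filtfilt(bf, x - mean(x)))

  kept <- filt[cens$mask, , drop = FALSE]
  if (nrow(kept) < min_frames)
    stop("too few retained frames for a connectivity estimate")

  if (!is.null(confounds)) {
    cf <- as.matrix(confounds)[cens$mask, , drop = FALSE]
    kept <- apply(kept, 2, function(x) resid(lm.fit(cbind(1, cf), x)))
  }

  sds <- apply(kept, 2, sd)
  if (any(sds == 0)) stop("degenerate series: constant region signal")
  r <- cor(kept)
  ut <- upper.tri(r)
  if (any(abs(r[ut]) >= 1)) stop("degenerate series: |r| = 1 for a pair")
  list(z = mean(atanh(r[ut])),
       n_pairs = sum(ut),
       frac_censored = cens$frac_censored,
       excluded = cens$excluded,
       r = r)
}
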