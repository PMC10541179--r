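#' Trial-level quality control for one participant and task
#'
#' Applies the two standard reaction-time exclusions for two-choice tasks:
#' an absolute floor (anticipatory responses) followed by an individual
#' mean +/- k standard-deviation band computed across *all* conditions of
#' the task. The band is computed on the floor-filtered trials and applied
#' in a single pass (no re-iteration).
#'
#' @param trials data.frame with at least columns `correct` (logical or
#'   0/1) and `rt` (seconds); one participant x task.
#' @param min_rt absolute reaction-time floor in seconds (default 0.200).
#' @param sd_mult width of the individual outlier band in standard
#'   deviations (default 3).
#' @return The surviving trials, with attributes `n_removed_fast` and
#'   `n_removed_sd` giving the count removed by each rule.
#' @examples
#' tr <- data.frame(correct = TRUE, rt = c(0.15, runif(20, 0.3, 0.7)))
#' nrow(filter_trials(tr)) # the 150 ms trial is gone
#' @export
filter_trials <- function(trials, min_rt = 0.200, sd_mult = 3) {
  stopifnot(is.data.frame(trials), all(c("correct", "rt") %in% names(trials)))
  if (nrow(trials) == 0L) stop("no trials")
  if (any(!is.finite(trials$rt)) || any(trials$rt <= 0))
    stop("reaction times must be finite and positive")

  keep_fast <- trials$rt >= min_rt
  n_fast <- sum(!keep_fast)
  kept <- trials[keep_fast, , drop = FALSE]
  if (nrow(kept) == 0L) stop("participant unusable: all trials removed")

  m <- mean(kept$rt)
  s <- sd(kept$rt)
  # sd() is NA for a single trial; a lone trial cannot be an outlier of
  # its own distribution, so the band rule passes it through.
  keep_sd <- if (is.na(s) || s == 0) rep(TRUE, nrow(kept)) else
    abs(kept$rt - m) <= sd_mult * s
  n_sd <- sum(!keep_sd)
  out <- kept[keep_sd, , drop = FALSE]
  if (nrow(out) == 0L) stop("participant unusable: all trials removed")

  attr(out, "n_removed_fast") <- n_fast
  attr(out, "n_removed_sd") <- n_sd
  out
}

#' Observed response moments of a trial set
#'
#' Computes the three summary statistics consumed by the EZ-diffusion
#' estimator: the proportion of correct responses over all trials, and the
#' mean and unbiased variance of the reaction times of the *correct*
#' trials only.
#'
#' @param trials filtered trials of one participant x task (or one
#'   condition cell when condition-based parameters are wanted).
#' @return list with elements `pc`, `mrt` (s), `vrt` (s^2), `n`.
#' @export
summarize_trials <- function(trials) {
  stopifnot(is.data.frame(trials), all(c("correct", "rt") %in% names(trials)))
  n <- nrow(trials)
  if (n == 0L) stop("no trials")
  correct <- as.logical(trials$correct)
  rts <- trials$rt[correct]
  if (length(rts) == 0L) stop("no correct RTs")
  if (length(rts) == 1L)
    stop("no correct RTs: a single correct trial leaves the RT variance undefined")
  list(pc = sum(correct) / n, mrt = mean(rts), vrt = var(rts), n = n)
}

#' EZ-diffusion parameter estimates from observed moments
#'
#' The closed-form EZ-diffusion estimator maps accuracy, mean correct RT
#' and correct-RT variance to drift rate `v`, boundary separation `a` and
#' non-decision time `ter`. With the logit `L = ln(Pc/(1-Pc))`:
#' \deqn{x = L (L Pc^2 - L Pc + Pc - 1/2) / VRT}
#' \deqn{v = sign(Pc - 1/2) \, s \, x^{1/4}, \quad a = s^2 L / v}
#' \deqn{MDT = \frac{a}{2v} \frac{1 - e^{-va/s^2}}{1 + e^{-va/s^2}}, \quad
#'       Ter = MRT - MDT}
#' Edge cases are moved off the boundary by the half-count rule before the
#' logit is taken: `Pc = 1` becomes `1 - 1/(2n)`, `Pc = 0` becomes
#' `1/(2n)`, and exact chance `Pc = 0.5` becomes `0.5 + 1/(2n)`.
#'
#' @param summary list as returned by [summarize_trials()] (`pc`, `mrt`,
#'   `vrt`, `n`).
#' @param s diffusion scaling constant (evidence units per sqrt-second);
#'   the conventional 0.1 by default.
#' @return list with elements `v`, `a`, `ter`, `s`.
#' @seealso [ez_forward()] for the exact algebraic inverse.
#' @export
ez_estimate <- function(summary, s = 0.1) {
  stopifnot(is.list(summary), all(c("pc", "mrt", "vrt", "n") %in% names(summary)))
  pc <- summary$pc; mrt <- summary$mrt; vrt <- summary$vrt; n <- summary$n
  if (!is.finite(vrt) || vrt <= 0) stop("RT variance must be positive")
  if (n < 1) stop("need at least one trial")
  if (pc < 0 || pc > 1) stop("Pc must lie in [0, 1]")

  half <- 1 / (2 * n)
  if (pc == 1) pc <- 1 - half
  else if (pc == 0) pc <- half
  else if (pc == 0.5) pc <- 0.5 + half
  if (pc <= 0 || pc >= 1 || pc == 0.5)
    stop("chance-level participant: edge correction cannot move Pc off 0.5")

  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  y <- -v * a / s^2
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  list(v = v, a = a, ter = mrt - mdt, s = s)
}

#' Exact forward moments of the EZ-diffusion model
#'
#' Maps diffusion parameters to the population accuracy, mean correct RT
#' and correct-RT variance implied by the EZ equations. By construction
#' `ez_estimate(ez_forward(p))` returns `p` to machine precision, which
#' makes this the algebraic oracle for the estimator and the backend of
#' the synthetic generator.
#'
#' @param params list with `v` (non-zero), `a` (> 0), `ter`, and `s`.
#' @return list with `pc`, `mrt`, `vrt`, `n = Inf` (population moments).
#' @export
ez_forward <- function(params) {
  v <- params$v; a <- params$a; ter <- params$ter
  s <- if (is.null(params$s)) 0.1 else params$s
  if (!is.finite(v) || v == 0) stop("forward moments undefined for v = 0")
  if (!is.finite(a) || a <= 0) stop("boundary separation must be positive")
  y <- exp(-v * a / s^2)
  pc <- 1 / (1 + y)
  mrt <- ter + (a / (2 * v)) * (1 - y) / (1 + y)
  L <- log(pc / (1 - pc))
  vrt <- L * (L * pc^2 - L * pc + pc - 0.5) / (v / s)^4
  list(pc = pc, mrt = mrt, vrt = vrt, n = Inf)
}

#' Simulate two-choice trials from a Wiener diffusion process
#'
#' Stochastic oracle for the EZ machinery: evidence starts at `a/2`
#' (unbiased), accrues Normal(`v dt`, `s^2 dt`) increments, and is
#' absorbed at `a` (correct) or 0 (error); the reaction time is the
#' first-passage time plus `ter`. Because drift and diffusion are
#' constant, the sampled increments are exact in distribution; the
#' within-step boundary-crossing probability is resolved from the
#' Brownian-bridge law (`bridge = TRUE`, default), which removes the
#' leading-order first-passage bias of naive fixed-step simulation.
#'
#' @param params list with `v`, `a`, `ter`, `s` (as [ez_estimate()]).
#' @param n_trials number of trials (> 0).
#' @param dt time step in seconds (default 0.001).
#' @param seed optional integer; same seed, same trial table.
#' @param bridge logical; apply the Brownian-bridge crossing correction.
#' @param max_time guard on the decision time of a single trial (s).
#' @return data.frame with columns `correct` (logical) and `rt` (s).
#' @export
simulate_wiener_trials <- function(params, n_trials, dt = 0.001, seed = NULL,
                                   bridge = TRUE, max_time = 300) {
  stopifnot(is.list(params))
  v <- params$v; a <- params$a; ter <- params$ter
  s <- if (is.null(params$s)) 0.1 else params$s
  if (!is.numeric(n_trials) || n_trials < 1) stop("n_trials must be positive")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (a <= 0 || s <= 0) stop("need a > 0 and s > 0")
  if (!is.null(seed)) set.seed(seed)
  m <- .wiener_fpt(as.integer(n_trials), v, a, s, dt, isTRUE(bridge), max_time)
  data.frame(correct = m[, 2] == 1, rt = m[, 1] + ter)
}

# canonical minuend/subtrahend cells for each contrast
.contrast_cells <- list(
  alerting  = c("no_cue", "double_cue"),
  orienting = c("central_cue", "spatial_cue"),
  executive = c("incongruent", "congruent"),
  distance  = c("far", "near")
)

#' Condition contrast on diffusion parameters
#'
#' Difference scores on each diffusion parameter between two condition
#' cells, following the cognitive-subtraction definitions of the attention
#' networks and the distance effect: alerting = no-cue minus double-cue,
#' orienting = central-cue minus spatial-cue, executive = incongruent
#' minus congruent, distance = high-distance minus low-distance (far vs
#' near digit pairs; 135-degree vs 45-degree rotations).
#'
#' @param by_condition named list of parameter lists (as returned by
#'   [ez_estimate()]), one element per condition cell.
#' @param contrast one of `"alerting"`, `"orienting"`, `"executive"`,
#'   `"distance"`.
#' @param cells optional length-2 character vector `c(minuend,
#'   subtrahend)` overriding the canonical cell labels.
#' @return data.frame with columns `parameter` (`v`, `a`, `ter`),
#'   `contrast`, `value`.
#' @export
condition_contrast <- function(by_condition,
                               contrast = c("alerting", "orienting",
                                            "executive", "distance"),
                               cells = NULL) {
  contrast <- match.arg(contrast)
  if (is.null(cells)) cells <- .contrast_cells[[contrast]]
  for (cell in cells)
    if (is.null(by_condition[[cell]]))
      stop(sprintf("missing condition cell '%s' for %s contrast", cell, contrast))
  minuend <- by_condition[[cells[1]]]
  subtrahend <- by_condition[[cells[2]]]
  data.frame(
    parameter = c("v", "a", "ter"),
    contrast = contrast,
    value = c(minuend$v - subtrahend$v,
              minuend$a - subtrahend$a,
              minuend$ter - subtrahend$ter)
  )
}

#' Composite visuomotor score across tasks
#'
#' z-scores the non-decision time of each task across the analysis sample
#' and averages the per-task z-scores within participant. Participants
#' missing any task are dropped (listwise): the score is a mean of three
#' z-scores and no imputation rule is defined for partial batteries.
#'
#' @param ter_by_task data.frame or matrix, one row per participant and
#'   one column per task, containing non-decision times (s). Row names or
#'   a `participant_id` column identify participants.
#' @return data.frame with `participant_id` and `composite_ter` for the
#'   complete-battery participants.
#' @export
composite_visuomotor <- function(ter_by_task) {
  df <- as.data.frame(ter_by_task)
  ids <- if ("participant_id" %in% names(df)) {
    out_ids <- df$participant_id
    df$participant_id <- NULL
    out_ids
  } else if (!is.null(rownames(df))) rownames(df) else seq_len(nrow(df))
  if (ncol(df) < 1L) stop("need at least one task column")
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2L) stop("need at least two complete participants")
  z <- vapply(df, function(col) {
    s <- sd(col)
    if (s == 0) stop("zero variance in a task's non-decision time")
    (col - mean(col)) / s
  }, numeric(nrow(df)))
  data.frame(participant_id = ids[keep], composite_ter = rowMeans(z))
}
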