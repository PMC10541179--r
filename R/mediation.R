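#' Fit a fully moderated mediation model ("model 59")
#'
#' Both the mediator path, the mediator-to-outcome path, and the direct
#' path are moderated by `w`. Two OLS equations are fit on z-scored
#' variables (products formed after z-scoring the components):
#' \deqn{M = i_M + a_1 X + a_2 W + a_3 XW + e_M}
#' \deqn{Y = i_Y + c_1' X + c_2' W + c_3' XW + b_1 M + b_2 MW + e_Y}
#'
#' @param data data.frame with the role columns.
#' @param x,m,y,w column names of the independent variable, mediator,
#'   outcome, and moderator.
#' @return object of class `cogchain_med59`: path coefficients `a1, a2,
#'   a3, b1, b2, c1p, c2p, c3p`, intercepts, residual SDs, `n_used`, and
#'   the analysis sample.
#' @export
fit_model59 <- function(data, x, m, y, w) {
  stopifnot(is.data.frame(data))
  vars <- c(x, m, y, w)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing variables: ", paste(miss, collapse = ", "))
  keep <- complete.cases(data[, vars, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 8L) stop("too few complete rows")
  z <- lapply(d[vars], function(col) {
    s <- sd(col)
    if (s == 0) stop("zero variance in an analysis variable")
    (col - mean(col)) / s
  })
  names(z) <- c("x", "m", "y", "w")
  Xm <- cbind(1, z$x, z$w, z$x * z$w)
  if (qr(Xm)$rank < 4L) stop("rank-deficient mediator equation")
  fm <- .lm.fit(Xm, z$m)
  Xy <- cbind(1, z$x, z$w, z$x * z$w, z$m, z$m * z$w)
  if (qr(Xy)$rank < 6L) stop("rank-deficient outcome equation")
  fy <- .lm.fit(Xy, z$y)
  cm <- fm$coefficients
  cy <- fy$coefficients
  structure(list(
    a1 = cm[2], a2 = cm[3], a3 = cm[4],
    c1p = cy[2], c2p = cy[3], c3p = cy[4], b1 = cy[5], b2 = cy[6],
    i_m = cm[1], i_y = cy[1],
    sigma_m = sd(fm$residuals), sigma_y = sd(fy$residuals),
    roles = c(x = x, m = m, y = y, w = w),
    n_used = nrow(d), data = d),
    class = "cogchain_med59")
}

#' @export
print.cogchain_med59 <- function(x, ...) {
  cat("Moderated mediation (model 59):",
      x$roles["x"], "->", x$roles["m"], "->", x$roles["y"],
      "moderated by", x$roles["w"], "\n")
  cat(sprintf("n = %d\n a-paths: a1 = %.3f, a2 = %.3f, a3 = %.3f\n",
              x$n_used, x$a1, x$a2, x$a3))
  cat(sprintf(" b-paths: b1 = %.3f, b2 = %.3f\n", x$b1, x$b2))
  cat(sprintf(" direct : c1' = %.3f, c2' = %.3f, c3' = %.3f\n",
              x$c1p, x$c2p, x$c3p))
  for (wl in c(-1, 0, 1))
    cat(sprintf(" indirect at W = %+d SD: %.4f\n", wl,
                conditional_indirect(x, wl)))
  invisible(x)
}

#' Conditional indirect effect at a moderator value
#'
#' The product of the conditional paths,
#' `omega(w) = (a1 + a3 w)(b1 + b2 w)`, on the standardized moderator
#' scale. Constant in `w` when both moderation paths are zero; reduces
#' to the simple-mediation product `a1 b1` at the moderator mean.
#'
#' @param paths a `cogchain_med59` fit (or any list with `a1, a3, b1,
#'   b2`).
#' @param w moderator value in SD units.
#' @return the conditional indirect effect (vectorized over `w`).
#' @export
conditional_indirect <- function(paths, w) {
  (paths$a1 + paths$a3 * w) * (paths$b1 + paths$b2 * w)
}

#' Conditional direct effect at a moderator value
#'
#' `c1' + c3' w` on the standardized moderator scale.
#'
#' @inheritParams conditional_indirect
#' @export
conditional_direct <- function(paths, w) {
  paths$c1p + paths$c3p * w
}

#' Bootstrap conditional indirect effects
#'
#' Case-resamples participants, refits both model-59 equations per
#' resample, and reports percentile confidence bounds of the
#' conditional indirect effect at each moderator level (mean and +/-1 SD
#' by default). Significance of an indirect effect is judged by whether
#' its interval excludes zero; mediation chains are conventionally
#' tested at 90% intervals, the default here.
#'
#' @inheritParams fit_model59
#' @param B bootstrap samples (default 5000).
#' @param level confidence level in percent (default 90).
#' @param w_levels moderator levels in SD units.
#' @param seed optional integer seed.
#' @return data.frame with one row per level: `w_level`, `indirect`,
#'   `ci_low`, `ci_high`, `direct`, `significant`, `n_used`, `B`,
#'   `level`.
#' @export
mediation_bootstrap <- function(data, x, m, y, w, B = 5000, level = 90,
                                w_levels = c(-1, 0, 1), seed = NULL) {
  if (B < 100) warning("B < 100 gives unstable percentile intervals")
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_model59(data, x, m, y, w)
  d <- fit$data
  n <- nrow(d)
  omega <- matrix(NA_real_, B, length(w_levels))
  for (b in seq_len(B)) {
    pb <- NULL
    for (try in 1:1000) {
      pb <- tryCatch(fit_model59(d[sample.int(n, n, replace = TRUE), ,
                                   drop = FALSE], x, m, y, w),
                     error = function(e) NULL)
      if (!is.null(pb)) break
    }
    if (is.null(pb)) stop("could not draw a non-degenerate resample")
    omega[b, ] <- conditional_indirect(pb, w_levels)
  }
  alpha <- (1 - level / 100) / 2
  ci <- apply(omega, 2, quantile, probs = c(alpha, 1 - alpha))
  data.frame(
    w_level = w_levels,
    indirect = conditional_indirect(fit, w_levels),
    ci_low = ci[1, ], ci_high = ci[2, ],
    direct = conditional_direct(fit, w_levels),
    significant = ci[1, ] > 0 | ci[2, ] < 0,
    n_used = fit$n_used, B = B, level = level)
}
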