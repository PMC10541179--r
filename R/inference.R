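#' Assign developmental age bands
#'
#' Maps chronological age (years) onto the five recruitment bands used
#' for outlier screening: early childhood (6-7), late childhood (10-11),
#' early adolescence (14-15), late adolescence (16-17), early adulthood
#' (18+). Ages falling between bands are assigned to the nearest band.
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels `"6-7"`, `"10-11"`, `"14-15"`, `"16-17"`,
#'   `"18+"`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(0, 9, 13, 16, 18, Inf), right = FALSE,
      labels = c("6-7", "10-11", "14-15", "16-17", "18+"))
}

#' Per-age-group 3-SD screening of analysis variables
#'
#' For each variable and each age group, values beyond `sd_mult`
#' standard deviations of the group mean are set to `NA` (the case is
#' excluded for analyses of that variable) and logged. Groups with fewer
#' than 3 non-missing members are skipped with a warning. A single pass
#' is made: the screen is not re-applied to the screened sample.
#'
#' @param table participant data.frame.
#' @param vars character vector of column names to screen.
#' @param group grouping labels (e.g. [age_band()] of the age column).
#' @param sd_mult exclusion band in standard deviations (default 3).
#' @return list with `table` (values blanked to `NA`) and `log`
#'   (participant_id, variable, group, value, z).
#' @export
screen_outliers <- function(table, vars, group, sd_mult = 3) {
  stopifnot(is.data.frame(table), length(group) == nrow(table))
  ids <- if ("participant_id" %in% names(table)) table$participant_id
         else seq_len(nrow(table))
  log_rows <- list()
  for (v in vars) {
    if (!v %in% names(table)) stop(sprintf("variable '%s' not in table", v))
    for (g in unique(group)) {
      idx <- which(group == g & !is.na(table[[v]]))
      if (length(idx) < 3L) {
        if (length(idx) > 0L)
          warning(sprintf("group '%s' has < 3 members for '%s'; screening skipped",
                          g, v))
        next
      }
      x <- table[[v]][idx]
      s <- sd(x)
      if (s == 0) next
      z <- (x - mean(x)) / s
      bad <- which(abs(z) > sd_mult)
      if (length(bad)) {
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          participant_id = ids[idx[bad]], variable = v, group = as.character(g),
          value = x[bad], z = z[bad])
        table[[v]][idx[bad]] <- NA
      }
    }
  }
  list(table = table,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(participant_id = character(), variable = character(),
                    group = character(), value = numeric(), z = numeric()))
}

#' z-score columns of a data frame
#'
#' Centers and scales the named continuous columns to mean 0, SD 1 on
#' the rows present (the model's analysis sample). Idempotent.
#'
#' @param table data.frame.
#' @param vars columns to standardize.
#' @return `table` with the named columns standardized.
#' @export
standardize <- function(table, vars) {
  for (v in vars) {
    x <- table[[v]]
    if (is.null(x)) stop(sprintf("variable '%s' not in table", v))
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) stop(sprintf("zero variance in '%s'", v))
    table[[v]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Specify one member of a regression family
#'
#' A model specification names the dependent variable, the predictors
#' (interactions as `"a:b"`; every product term's components must also
#' appear as main effects), the single hypothesis term the family tests,
#' and the family the hypothesis is corrected within.
#'
#' @param dependent dependent-variable column name.
#' @param predictors character vector of predictor terms.
#' @param hypothesis the term whose coefficient is the family hypothesis
#'   (defaults to the first interaction, else the first predictor).
#' @param family_id optional family label.
#' @param spec_id optional unique id.
#' @return object of class `cogchain_spec`.
#' @export
model_spec <- function(dependent, predictors, hypothesis = NULL,
                       family_id = NA_character_, spec_id = NULL) {
  stopifnot(is.character(dependent), length(dependent) == 1L,
            is.character(predictors), length(predictors) >= 1L)
  ints <- grep(":", predictors, value = TRUE)
  for (term in ints) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% predictors))
      stop(sprintf("components of '%s' must appear as main effects", term))
  }
  if (is.null(hypothesis))
    hypothesis <- if (length(ints)) ints[1] else predictors[1]
  if (!hypothesis %in% predictors)
    stop("hypothesis term must be one of the predictors")
  if (is.null(spec_id))
    spec_id <- paste(dependent, hypothesis, sep = "~")
  structure(list(dependent = dependent, predictors = predictors,
                 hypothesis = hypothesis, family_id = family_id,
                 spec_id = spec_id),
            class = "cogchain_spec")
}

# base variables referenced by a spec
.spec_vars <- function(spec) {
  unique(c(spec$dependent,
           unlist(strsplit(spec$predictors, ":", fixed = TRUE))))
}

# z-score base variables and assemble the design matrix; product columns
# are products of the z-scored components (not z-scored products), which
# keeps the simple-slope algebra of interaction probing exact.
.design <- function(data, spec) {
  vars <- .spec_vars(spec)
  zs <- lapply(vars, function(v) {
    x <- data[[v]]
    s <- sd(x)
    if (is.na(s) || s == 0) return(NULL)
    (x - mean(x)) / s
  })
  if (any(vapply(zs, is.null, logical(1)))) return(NULL)
  names(zs) <- vars
  cols <- lapply(spec$predictors, function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    Reduce(`*`, zs[parts])
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", spec$predictors)
  list(X = X, y = zs[[spec$dependent]])
}

#' Fit a moderated regression on z-scored variables
#'
#' Ordinary least squares on listwise-complete rows after z-scoring
#' dependent and predictor components on the analysis sample; product
#' terms are formed from the z-scored components, so the returned
#' coefficients are standardized betas and the simple-slope algebra of
#' [probe_interaction()] is exact. Optional polynomial age trends are
#' expressed by adding, e.g., `"I(age^2)"`-style columns to the table
#' beforehand.
#'
#' @param spec a [model_spec()].
#' @param data participant data.frame.
#' @return object of class `cogchain_fit`: spec, `n_used`,
#'   `coefficients` (standardized, without intercept), `residuals`,
#'   `fitted`, the analysis sample, and row ids.
#' @export
fit_moderated_model <- function(spec, data) {
  stopifnot(inherits(spec, "cogchain_spec"), is.data.frame(data))
  vars <- .spec_vars(spec)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing variables: ", paste(miss, collapse = ", "))
  keep <- complete.cases(data[, vars, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < length(spec$predictors) + 2L)
    stop("too few complete rows to fit the model")
  des <- .design(d, spec)
  if (is.null(des)) stop("zero variance in an analysis variable")
  qx <- qr(des$X)
  if (qx$rank < ncol(des$X)) {
    bad <- colnames(des$X)[qx$pivot[(qx$rank + 1):ncol(des$X)]]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, des$y)
  fitted <- drop(des$X %*% beta)
  ids <- if ("participant_id" %in% names(d)) d$participant_id else which(keep)
  structure(list(spec = spec, n_used = nrow(d),
                 coefficients = beta[-1],
                 intercept = beta[1],
                 residuals = des$y - fitted, fitted = fitted,
                 data = d, participant_ids = ids,
                 excluded_ids = character(0)),
            class = "cogchain_fit")
}

#' @export
print.cogchain_fit <- function(x, ...) {
  cat("Moderated regression:", x$spec$dependent, "~",
      paste(x$spec$predictors, collapse = " + "), "\n")
  cat("n =", x$n_used, "  hypothesis term:", x$spec$hypothesis, "\n")
  tab <- data.frame(beta = round(x$coefficients, 4))
  if (!is.null(x$ci_low)) {
    tab$ci_low <- round(x$ci_low, 4)
    tab$ci_high <- round(x$ci_high, 4)
    tab$p_bo <- signif(x$p_bo, 3)
  }
  print(tab)
  invisible(x)
}

#' Case-bootstrap confidence intervals and p-values
#'
#' Resamples participants (rows of the analysis sample) with
#' replacement, refits the full standardization-plus-OLS procedure per
#' resample, and reports percentile confidence bounds per coefficient
#' plus a two-sided sign-crossing bootstrap p-value
#' `p = 2 min(#\{b* <= 0\}, #\{b* >= 0\}) / B`, floored at `2/B`.
#' Resamples in which an analysis variable collapses to zero variance
#' are redrawn (their count is reported).
#'
#' @param fit a `cogchain_fit` from [fit_moderated_model()].
#' @param B bootstrap samples (default 5000).
#' @param level confidence level in percent (default 95).
#' @param seed optional integer seed.
#' @return the fit augmented with `ci_low`, `ci_high`, `p_bo`, `B`,
#'   `level`, `n_redrawn`.
#' @export
bootstrap_inference <- function(fit, B = 5000, level = 95, seed = NULL) {
  stopifnot(inherits(fit, "cogchain_fit"))
  if (B < 100) warning("B < 100 gives unstable percentile intervals")
  if (!is.null(seed)) set.seed(seed)
  spec <- fit$spec
  d <- fit$data
  n <- nrow(d)
  p <- length(spec$predictors)
  boots <- matrix(NA_real_, B, p, dimnames = list(NULL, spec$predictors))
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    for (try in 1:1000) {
      des <- .design(d[sample.int(n, n, replace = TRUE), , drop = FALSE], spec)
      if (!is.null(des)) break
      n_redrawn <- n_redrawn + 1L
    }
    if (is.null(des)) stop("could not draw a non-degenerate resample")
    boots[b, ] <- .lm.fit(des$X, des$y)$coefficients[-1]
  }
  alpha <- (1 - level / 100) / 2
  fit$ci_low <- apply(boots, 2, quantile, probs = alpha)
  fit$ci_high <- apply(boots, 2, quantile, probs = 1 - alpha)
  fit$p_bo <- apply(boots, 2, function(bb)
    max(2 * min(mean(bb <= 0), mean(bb >= 0)), 2 / B))
  fit$B <- B
  fit$level <- level
  fit$n_redrawn <- n_redrawn
  fit
}

#' Refit after removing large standardized residuals
#'
#' Removes rows whose standardized residual exceeds `sd_mult` in
#' absolute value, then re-standardizes on the reduced sample and refits
#' once (a single pass, no re-iteration). When the original fit carried
#' bootstrap inference, the bootstrap is rerun on the reduced sample with
#' the same settings.
#'
#' @param fit a `cogchain_fit`.
#' @param sd_mult residual exclusion band (default 3).
#' @param seed optional seed for the rerun bootstrap.
#' @return a new `cogchain_fit`; `excluded_ids` lists the removals.
#' @export
exclude_by_residuals <- function(fit, sd_mult = 3, seed = NULL) {
  stopifnot(inherits(fit, "cogchain_fit"))
  z <- fit$residuals / sd(fit$residuals)
  bad <- abs(z) > sd_mult
  if (!any(bad)) return(fit)
  d2 <- fit$data[!bad, , drop = FALSE]
  refit <- fit_moderated_model(fit$spec, d2)
  refit$excluded_ids <- fit$participant_ids[bad]
  if (!is.null(fit$B))
    refit <- bootstrap_inference(refit, B = fit$B, level = fit$level,
                                 seed = seed)
  refit
}

#' Enumerate a hypothesis family as the product of design factors
#'
#' Builds the Cartesian product of the factor levels and instantiates
#' one model specification per cell via the template function. This is
#' how the correction families are enumerated: 3 diffusion parameters x
#' 3 neurochemicals x 2 regions x 2 effect types = 36 hypotheses for the
#' main assessment, times 5 cognitive functions = 180 for the
#' supplementary condition-based analyses.
#'
#' @param factors named list of character level vectors.
#' @param template function taking a one-row data.frame (one cell) and
#'   returning a [model_spec()]. When `NULL` the grid itself is
#'   returned with one row per hypothesis.
#' @return list of specs (or the grid), with attribute `family_size`.
#' @export
build_family <- function(factors, template = NULL) {
  stopifnot(is.list(factors), length(factors) >= 1L)
  if (any(!vapply(factors, length, 1L)))
    stop("empty factor in family descriptor")
  grid <- expand.grid(factors, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  out <- if (is.null(template)) grid else
    lapply(seq_len(nrow(grid)), function(i) template(grid[i, , drop = FALSE]))
  attr(out, "family_size") <- nrow(grid)
  out
}

# template shared by the main and supplementary families: the dependent
# variable is a diffusion parameter (optionally within a condition
# contrast), the model is neurochemical + age + their product + the other
# two diffusion parameters as controls, and the hypothesis is either the
# interaction or the neurochemical main effect.
.diffusion_spec_template <- function(family_id, contrast_suffix = NULL) {
  function(cell) {
    chemvar <- paste(cell$region, cell$neurochemical, sep = "_")
    suffix <- if (!is.null(contrast_suffix)) paste0("_", cell$cognitive_function)
              else ""
    dep <- paste0(cell$parameter, suffix)
    controls <- paste0(setdiff(c("v", "a", "ter"), cell$parameter), suffix)
    int <- paste(chemvar, "age", sep = ":")
    model_spec(
      dependent = dep,
      predictors = c(chemvar, "age", int, controls),
      hypothesis = if (cell$effect == "interaction") int else chemvar,
      family_id = family_id,
      spec_id = paste(family_id, dep, chemvar, cell$effect, sep = "."))
  }
}

#' The main-assessment hypothesis family (36 members)
#'
#' Diffusion parameter (3) x neurochemical (3) x voxel region (2) x
#' effect type (2: neurochemical main effect, neurochemical-by-age
#' interaction).
#'
#' @param family_id family label.
#' @return list of 36 [model_spec()] objects.
#' @export
family_main <- function(family_id = "main") {
  build_family(
    list(parameter = c("v", "a", "ter"),
         neurochemical = c("glutamate", "gaba", "naa"),
         region = c("IPS", "MFG"),
         effect = c("interaction", "main")),
    .diffusion_spec_template(family_id))
}

#' The supplementary condition-based hypothesis family (180 members)
#'
#' As [family_main()] with a fifth factor crossing the five cognitive
#' functions (alerting, orienting, executive networks; distance and
#' SNARC effects); the dependent variables are the per-function contrast
#' scores of each diffusion parameter.
#'
#' @param family_id family label.
#' @return list of 180 [model_spec()] objects.
#' @export
family_supplementary <- function(family_id = "supplementary") {
  build_family(
    list(parameter = c("v", "a", "ter"),
         neurochemical = c("glutamate", "gaba", "naa"),
         region = c("IPS", "MFG"),
         effect = c("interaction", "main"),
         cognitive_function = c("alerting", "orienting", "executive",
                                "distance", "snarc")),
    .diffusion_spec_template(family_id, contrast_suffix = TRUE))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values over an enumerated hypothesis family;
#' monotone and capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted q-values, same order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Probe an interaction at moderator levels
#'
#' Simple slopes of the focal predictor at moderator values mean + k SD
#' on the standardized scale: `slope(k) = b_focal + k * b_interaction`.
#' Also emits a plotting table of regression lines over a +/-2 SD range
#' of the focal predictor (other covariates at their means).
#'
#' @param fit a `cogchain_fit` containing focal, moderator and their
#'   product term.
#' @param focal focal predictor name.
#' @param moderator moderator name (typically `"age"`).
#' @param k moderator levels in SD units (default -1, 0, +1).
#' @return list with `slopes` (level, slope, and bootstrap bounds when
#'   available via the delta of resampled coefficients), `lines`
#'   (level, x, y) and `crossover` (moderator value where the simple
#'   slope is zero, `NA` when the interaction is zero).
#' @export
probe_interaction <- function(fit, focal, moderator = "age",
                              k = c(-1, 0, 1)) {
  stopifnot(inherits(fit, "cogchain_fit"))
  b <- fit$coefficients
  int_term <- intersect(c(paste(focal, moderator, sep = ":"),
                          paste(moderator, focal, sep = ":")),
                        names(b))
  if (!length(int_term))
    stop("no product term of ", focal, " and ", moderator, " in the fit")
  if (!focal %in% names(b) || !moderator %in% names(b))
    stop("focal and moderator must be main effects in the fit")
  b_f <- b[[focal]]; b_m <- b[[moderator]]; b_i <- b[[int_term[1]]]
  slopes <- data.frame(level = k, slope = b_f + k * b_i)
  xg <- seq(-2, 2, length.out = 25)
  lines <- do.call(rbind, lapply(k, function(kk)
    data.frame(level = kk, x = xg,
               y = fit$intercept + b_m * kk + (b_f + kk * b_i) * xg)))
  list(slopes = slopes, lines = lines,
       crossover = if (b_i != 0) -b_f / b_i else NA_real_)
}

#' Plot simple slopes at moderator levels
#'
#' A basic interaction plot of the probing table: one regression line
#' per moderator level (mean and +/-1 SD by default), on the
#' standardized scale.
#'
#' @param probe result of [probe_interaction()].
#' @param xlab,ylab axis labels.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_interaction <- function(probe, xlab = "focal predictor (z)",
                             ylab = "outcome (z)") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  dat <- probe$lines
  dat$level <- factor(dat$level, labels = paste0(
    ifelse(sort(unique(dat$level)) > 0, "+", ""),
    sort(unique(dat$level)), " SD"))
  ggplot2::ggplot(dat, ggplot2::aes(x = x, y = y, colour = level)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = ylab, colour = "moderator") +
    ggplot2::theme_minimal()
}
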