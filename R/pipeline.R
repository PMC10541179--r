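# ---- stage helpers ------------------------------------------------------

#' Estimate diffusion parameters for every participant of a trial table
#'
#' Applies trial-level quality control, computes the observed moments,
#' and runs the EZ estimator per participant (collapsed across
#' conditions). Participants whose trials cannot support estimation
#' (all trials removed, no correct responses, chance-level accuracy)
#' are logged rather than fatal.
#'
#' @param trials trial data.frame (`participant_id`, `task`,
#'   `condition`, `correct`, `rt`), one task.
#' @param min_rt,sd_mult quality-control settings, see
#'   [filter_trials()].
#' @param s diffusion scaling constant.
#' @return list with `params` (one row per estimable participant:
#'   participant_id, task, v, a, ter, pc, mrt, vrt, n_trials,
#'   n_removed_fast, n_removed_sd) and `log` (participant, reason).
#' @export
estimate_task_parameters <- function(trials, min_rt = 0.2, sd_mult = 3,
                                     s = 0.1) {
  stopifnot(all(c("participant_id", "correct", "rt") %in% names(trials)))
  task <- if ("task" %in% names(trials)) trials$task[1] else NA_character_
  ids <- unique(trials$participant_id)
  rows <- list(); logs <- list()
  for (pid in ids) {
    tt <- trials[trials$participant_id == pid, , drop = FALSE]
    res <- tryCatch({
      ft <- filter_trials(tt, min_rt = min_rt, sd_mult = sd_mult)
      sm <- summarize_trials(ft)
      ez <- ez_estimate(sm, s = s)
      data.frame(participant_id = pid, task = task,
                 v = ez$v, a = ez$a, ter = ez$ter,
                 pc = sm$pc, mrt = sm$mrt, vrt = sm$vrt, n_trials = sm$n,
                 n_removed_fast = attr(ft, "n_removed_fast"),
                 n_removed_sd = attr(ft, "n_removed_sd"))
    }, error = function(e) e)
    if (inherits(res, "error"))
      logs[[length(logs) + 1L]] <- data.frame(
        participant_id = pid, task = task, reason = conditionMessage(res))
    else rows[[length(rows) + 1L]] <- res
  }
  list(params = if (length(rows)) do.call(rbind, rows) else NULL,
       log = if (length(logs)) do.call(rbind, logs) else
         data.frame(participant_id = character(), task = character(),
                    reason = character()))
}

# map a trial's condition label onto the grouping needed by a contrast
.contrast_grouping <- function(task, contrast, condition) {
  if (task == "attention") {
    parts <- strsplit(condition, ".", fixed = TRUE)
    cue <- vapply(parts, `[`, "", 1)
    flanker <- vapply(parts, `[`, "", 2)
    switch(contrast,
           alerting = , orienting = cue,
           executive = flanker,
           stop("contrast not defined for the attention task: ", contrast))
  } else if (task == "digit") {
    lo <- as.integer(sub("^d(\\d)_(\\d)$", "\\1", condition))
    hi <- as.integer(sub("^d(\\d)_(\\d)$", "\\2", condition))
    digit_distance_bin(lo, hi)
  } else if (task == "rotation") {
    ifelse(condition == "deg135", "far",
           ifelse(condition == "deg45", "near", NA_character_))
  } else stop("unknown task: ", task)
}

#' Condition-based contrast scores for every participant
#'
#' Estimates diffusion parameters within the two condition cells a
#' contrast compares (collapsing the task's other factors) and takes the
#' difference per parameter. The attention task supports `alerting`,
#' `orienting`, and `executive`; the digit and rotation tasks support
#' `distance` (far minus near pairs; 135-degree minus 45-degree
#' rotations).
#'
#' @param trials one task's trial table (already quality-controlled or
#'   raw; the per-cell moments are computed on the rows given).
#' @param contrast contrast name.
#' @param s diffusion scaling constant.
#' @return data.frame: participant_id, parameter, contrast, value; rows
#'   missing when a cell was not estimable.
#' @export
contrast_scores <- function(trials, contrast, s = 0.1) {
  task <- trials$task[1]
  grp <- .contrast_grouping(task, contrast, trials$condition)
  cells <- if (task == "attention") .contrast_cells[[contrast]]
           else c("far", "near")
  rows <- list()
  for (pid in unique(trials$participant_id)) {
    by_cond <- list()
    ok <- TRUE
    for (cell in cells) {
      idx <- which(trials$participant_id == pid & grp == cell)
      est <- tryCatch(
        ez_estimate(summarize_trials(trials[idx, , drop = FALSE]), s = s),
        error = function(e) NULL)
      if (is.null(est)) { ok <- FALSE; break }
      by_cond[[cell]] <- est
    }
    if (!ok) next
    cs <- condition_contrast(by_cond,
                             contrast = if (task == "attention") contrast
                                        else "distance",
                             cells = cells)
    cs$participant_id <- pid
    rows[[length(rows) + 1L]] <- cs
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# fit + bootstrap + one-pass residual exclusion for one spec; returns a
# result row (or NULL when the model is not estimable on this sample)
.run_spec <- function(spec, table, B, level, seed) {
  fit <- tryCatch(fit_moderated_model(spec, table), error = function(e) e)
  if (inherits(fit, "error"))
    return(data.frame(family_id = spec$family_id, spec_id = spec$spec_id,
                      term = spec$hypothesis, beta = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      p_bo = NA_real_, n_used = 0L, n_excluded = 0L,
                      note = conditionMessage(fit)))
  fit <- bootstrap_inference(fit, B = B, level = level, seed = seed)
  fit <- exclude_by_residuals(fit, seed = seed + 1L)
  h <- spec$hypothesis
  data.frame(family_id = spec$family_id, spec_id = spec$spec_id, term = h,
             beta = fit$coefficients[[h]],
             ci_low = fit$ci_low[[h]], ci_high = fit$ci_high[[h]],
             p_bo = fit$p_bo[[h]], n_used = fit$n_used,
             n_excluded = length(fit$excluded_ids), note = "")
}

#' Fit an enumerated hypothesis family with bootstrap and FDR
#'
#' Runs every model of a family on the participant table (fit,
#' case-bootstrap inference, one-pass residual exclusion with refit)
#' and appends Benjamini-Hochberg q-values over the family's
#' non-missing bootstrap p-values.
#'
#' @param specs list of [model_spec()] objects (e.g. [family_main()]).
#' @param table participant analysis table.
#' @param B,level bootstrap settings.
#' @param seed integer seed.
#' @return data.frame, one row per hypothesis, with `q` appended.
#' @export
run_family <- function(specs, table, B = 5000, level = 95, seed = 1L) {
  res <- do.call(rbind, lapply(seq_along(specs), function(i)
    .run_spec(specs[[i]], table, B, level, seed + i)))
  res$q <- NA_real_
  ok <- !is.na(res$p_bo)
  if (any(ok)) res$q[ok] <- fdr_adjust(res$p_bo[ok])
  res
}

# ---- end-to-end orchestration ------------------------------------------

#' Run the full analysis pipeline on a cohort
#'
#' Executes the stages in a fixed order: trial quality control and EZ
#' estimation per task; condition contrasts; composite visuomotor
#' score; spectroscopy corrections and exclusions; connectivity scoring
#' with motion scrubbing; per-age-band 3-SD screening; the 36-member
#' main hypothesis family with bootstrap and FDR; the
#' connectivity-behavior and neurochemical-connectivity moderated
#' models; interaction probing of the headline effects; and the two
#' moderated mediations (neurochemical to visuomotor processing via
#' connectivity; neurochemical to intelligence via visuomotor
#' processing). All randomness flows from `seed`; rerunning with the
#' same cohort and seed reproduces every table.
#'
#' @param cohort a `cogchain_cohort` from [generate_cohort()] (or a
#'   compatible list of input tables).
#' @param B bootstrap samples per model (default 5000).
#' @param seed integer seed for the inferential resampling.
#' @param t2_correction apply the water-T2 correction chain to the
#'   spectroscopy concentrations (default FALSE: the partial-volume
#'   corrected values are the primary quantification).
#' @param contrasts also compute the supplementary condition-based
#'   contrast scores (default TRUE).
#' @return object of class `cogchain_run`: `table` (the merged analysis
#'   table), `behavior`, `contrasts`, `mrs`, `connectivity`,
#'   `family_main`, `conn_behavior`, `chem_conn`, `probes`, `mediation`, and
#'   `manifest` (stage order, exclusion tallies, seeds, versions).
#' @export
run_pipeline <- function(cohort, B = 5000, seed = 1L,
                         t2_correction = FALSE, contrasts = TRUE) {
  stopifnot(inherits(cohort, "cogchain_cohort"))
  cfg <- cohort$config
  manifest <- list(seed = seed, B = B,
                   package_version = as.character(utils::packageVersion("cogchain")),
                   stages = character(0), exclusions = list())
  note_stage <- function(name) manifest$stages <<- c(manifest$stages, name)

  # 1. behavior ----------------------------------------------------------
  note_stage("behavior")
  tasks <- c("attention", "digit", "rotation")
  behavior <- list(); behavior_log <- list()
  for (task in tasks) {
    tt <- cohort$trials[cohort$trials$task == task, , drop = FALSE]
    if (nrow(tt) == 0L) next
    est <- estimate_task_parameters(tt, s = cfg$s)
    behavior[[task]] <- est$params
    behavior_log[[task]] <- est$log
  }
  missing_tasks <- setdiff(tasks, names(behavior))
  if (length(missing_tasks))
    stop("composite visuomotor scoring requires all three tasks; missing: ",
         paste(missing_tasks, collapse = ", "))
  manifest$exclusions$behavior <- vapply(behavior_log, nrow, 1L)

  # 2. contrasts ---------------------------------------------------------
  contrast_tab <- NULL
  if (contrasts) {
    note_stage("contrasts")
    cl <- list()
    att <- cohort$trials[cohort$trials$task == "attention", , drop = FALSE]
    for (cn in c("alerting", "orienting", "executive"))
      cl[[cn]] <- contrast_scores(att, cn, s = cfg$s)
    for (task in c("digit", "rotation"))
      cl[[paste0("distance_", task)]] <- contrast_scores(
        cohort$trials[cohort$trials$task == task, , drop = FALSE],
        "distance", s = cfg$s)
    contrast_tab <- do.call(rbind, cl[!vapply(cl, is.null, TRUE)])
  }

  # 3. composite visuomotor ---------------------------------------------
  note_stage("composite")
  ter_wide <- Reduce(function(x, y) merge(x, y, by = "participant_id"),
                     lapply(tasks, function(task) {
                       d <- behavior[[task]][, c("participant_id", "ter")]
                       names(d)[2] <- paste0("ter_", task)
                       d
                     }))
  if (is.null(ter_wide) || nrow(ter_wide) == 0L)
    stop("composite stage: no participant completed all three tasks")
  composite <- composite_visuomotor(ter_wide)

  # 4. spectroscopy ------------------------------------------------------
  note_stage("mrs")
  mrs <- cohort$mrs
  mrs$conc <- tissue_correct(mrs$raw_conc, mrs$f_gm, mrs$f_wm, mrs$f_csf)
  if (t2_correction) {
    t2fits <- list()
    for (key in unique(paste(cohort$water$participant_id,
                             cohort$water$region))) {
      wv <- cohort$water[paste(cohort$water$participant_id,
                               cohort$water$region) == key, ]
      t2fits[[key]] <- tryCatch(
        fit_water_t2(wv$te_ms, wv$integral)$t2_tissue,
        error = function(e) NA_real_)
    }
    t2 <- unlist(t2fits)[paste(mrs$participant_id, mrs$region)]
    mrs$conc <- ifelse(is.na(t2), NA_real_,
                       t2_correct(mrs$conc, mrs$te_s, t2 / 1000))
  }
  excl <- apply_mrs_exclusions(mrs)
  mrs_kept <- excl$records
  mrs_kept$conc[mrs_kept$not_detectable] <- NA
  manifest$exclusions$mrs <- nrow(excl$log)
  mrs_kept$region_metabolite <- paste(mrs_kept$region, mrs_kept$metabolite,
                                      sep = "_")
  chem_wide <- stats::reshape(
    mrs_kept[, c("participant_id", "region_metabolite", "conc")],
    idvar = "participant_id", timevar = "region_metabolite",
    direction = "wide", v.names = "conc")
  names(chem_wide) <- sub("^conc\\.", "", names(chem_wide))

  # 5. connectivity ------------------------------------------------------
  note_stage("connectivity")
  conn_rows <- lapply(seq_along(cohort$roi), function(i) {
    r <- cohort$roi[[i]]
    sc <- tryCatch(connectivity_score(r$ts, fd = r$fd, tr = cfg$tr),
                   error = function(e) NULL)
    pid <- cohort$participants$participant_id[i]
    if (is.null(sc))
      return(data.frame(participant_id = pid, connectivity = NA_real_,
                        frac_censored = NA_real_, excluded = TRUE))
    data.frame(participant_id = pid,
               connectivity = if (sc$excluded) NA_real_ else sc$z,
               frac_censored = sc$frac_censored, excluded = sc$excluded)
  })
  connectivity <- do.call(rbind, conn_rows)
  manifest$exclusions$connectivity <- sum(connectivity$excluded)

  # 6. merge + screening --------------------------------------------------
  note_stage("screen")
  tab <- cohort$participants[, c("participant_id", "band", "age")]
  tab$intelligence <- cohort$participants$intelligence
  att <- behavior$attention[, c("participant_id", "v", "a", "ter")]
  tab <- merge(tab, att, by = "participant_id", all.x = TRUE)
  tab <- merge(tab, composite, by = "participant_id", all.x = TRUE)
  tab <- merge(tab, chem_wide, by = "participant_id", all.x = TRUE)
  tab <- merge(tab, connectivity[, c("participant_id", "connectivity")],
               by = "participant_id", all.x = TRUE)
  screen_vars <- intersect(
    c("v", "a", "ter", "composite_ter", "connectivity", "intelligence",
      paste(rep(c("IPS", "MFG"), each = 3),
            c("glutamate", "gaba", "naa"), sep = "_")),
    names(tab))
  scr <- screen_outliers(tab, screen_vars, age_band(tab$age))
  tab <- scr$table
  manifest$exclusions$screen <- nrow(scr$log)

  # 7. main family + FDR --------------------------------------------------
  note_stage("family_main")
  fam <- run_family(family_main("main_A1"), tab, B = B, seed = seed)

  # 8. connectivity-level moderated models ------------------------
  note_stage("connectivity_models")
  conn_behavior <- .run_spec(model_spec("composite_ter",
                              c("connectivity", "age", "connectivity:age"),
                              family_id = "connectivity"),
                   tab, B, 95, seed + 100L)
  chem_conn <- do.call(rbind, lapply(c("IPS_glutamate", "IPS_gaba"), function(cv)
    .run_spec(model_spec("connectivity",
                         c(cv, "age", paste0(cv, ":age")),
                         family_id = "connectivity"),
              tab, B, 95, seed + 101L)))

  # 9. probing ------------------------------------------------------------
  note_stage("probing")
  probes <- lapply(c("IPS_glutamate", "IPS_gaba"), function(cv) {
    spec <- model_spec("ter", c(cv, "age", paste0(cv, ":age"), "v", "a"))
    tryCatch(probe_interaction(fit_moderated_model(spec, tab), cv, "age"),
             error = function(e) NULL)
  })
  names(probes) <- c("IPS_glutamate", "IPS_gaba")

  # 10. moderated mediations ----------------------------------------------
  note_stage("mediation")
  med <- list()
  for (cv in c("IPS_glutamate", "IPS_gaba")) {
    med[[paste0(cv, "_via_connectivity")]] <- tryCatch(
      mediation_bootstrap(tab, x = cv, m = "connectivity",
                          y = "composite_ter", w = "age", B = B,
                          seed = seed + 200L),
      error = function(e) NULL)
    med[[paste0(cv, "_to_intelligence")]] <- tryCatch(
      mediation_bootstrap(tab, x = cv, m = "composite_ter",
                          y = "intelligence", w = "age", B = B,
                          seed = seed + 201L),
      error = function(e) NULL)
  }

  structure(list(table = tab, behavior = behavior,
                 behavior_log = behavior_log, contrasts = contrast_tab,
                 mrs = mrs_kept, mrs_log = excl$log,
                 connectivity = connectivity, screen_log = scr$log,
                 family_main = fam, conn_behavior = conn_behavior, chem_conn = chem_conn,
                 probes = probes, mediation = med, manifest = manifest),
            class = "cogchain_run")
}

#' @export
print.cogchain_run <- function(x, ...) {
  cat("cogchain pipeline run:", nrow(x$table), "participants;",
      "stages:", paste(x$manifest$stages, collapse = " -> "), "\n")
  cat("main family:", nrow(x$family_main), "hypotheses;",
      sum(x$family_main$q < 0.05, na.rm = TRUE), "survive FDR at q < 0.05\n")
  invisible(x)
}

#' Write pipeline result tables to CSV
#'
#' @param run a `cogchain_run`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "cogchain_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(obj, name) {
    if (is.null(obj)) return()
    p <- file.path(dir, paste0(name, ".csv"))
    write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  emit(run$table, "analysis_table")
  emit(run$family_main, "family_main")
  emit(run$conn_behavior, "connectivity_behavior")
  emit(run$chem_conn, "neurochemical_connectivity")
  emit(do.call(rbind, lapply(names(run$mediation), function(nm) {
    m <- run$mediation[[nm]]
    if (is.null(m)) return(NULL)
    cbind(model = nm, m)
  })), "mediation")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, file.path(dir, "manifest.json")))
}

# longitudinal spec: second-assessment outcome predicted from
# first-assessment neurochemistry and its age interaction, controlling
# for the other two diffusion parameters at both assessments and age at
# both assessments
.longitudinal_spec_template <- function(family_id) {
  function(cell) {
    chemvar <- paste(cell$region, cell$neurochemical, sep = "_")
    controls1 <- setdiff(c("v", "a", "ter"), cell$parameter)
    int <- paste(chemvar, "age", sep = ":")
    model_spec(
      dependent = paste0(cell$parameter, "_A2"),
      predictors = c(chemvar, "age", int, controls1,
                     paste0(controls1, "_A2"), "age_A2"),
      hypothesis = if (cell$effect == "interaction") int else chemvar,
      family_id = family_id,
      spec_id = paste(family_id, cell$parameter, chemvar, cell$effect,
                      sep = "."))
  }
}

#' The longitudinal prediction family (36 members)
#'
#' Second-assessment diffusion parameters predicted from
#' first-assessment neurochemistry, age, and their product, with the
#' other two diffusion parameters at both assessments and
#' second-assessment age as controls.
#'
#' @param family_id family label.
#' @return list of 36 [model_spec()] objects.
#' @export
family_longitudinal <- function(family_id = "longitudinal") {
  build_family(
    list(parameter = c("v", "a", "ter"),
         neurochemical = c("glutamate", "gaba", "naa"),
         region = c("IPS", "MFG"),
         effect = c("interaction", "main")),
    .longitudinal_spec_template(family_id))
}

#' Run the second-assessment and longitudinal hypothesis families
#'
#' Merges a first- and a second-assessment analysis table (the latter's
#' analysis variables suffixed `_A2`), then runs the 36-member family on
#' the second-assessment variables (the replication pattern) and the
#' 36-member longitudinal prediction family, each with its own FDR
#' correction.
#'
#' @param table_a1,table_a2 analysis tables from two [run_pipeline()]
#'   runs.
#' @param B,seed bootstrap settings.
#' @return list with `family_a2`, `family_longitudinal`, and the merged
#'   table.
#' @export
run_followup_families <- function(table_a1, table_a2, B = 5000, seed = 1L) {
  keep <- setdiff(names(table_a2), c("band", "age"))
  a2 <- table_a2[, keep, drop = FALSE]
  a2$age_A2 <- table_a2$age
  names(a2)[names(a2) != "participant_id" & names(a2) != "age_A2"] <-
    paste0(setdiff(names(a2), c("participant_id", "age_A2")), "_A2")
  merged <- merge(table_a1, a2, by = "participant_id")

  fam_a2 <- run_family(family_main("main_A2"), table_a2, B = B, seed = seed)
  fam_long <- run_family(family_longitudinal(), merged, B = B,
                         seed = seed + 50L)
  list(family_a2 = fam_a2, family_longitudinal = fam_long, table = merged)
}
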