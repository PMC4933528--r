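#' Code decisions against the normative model
#'
#' For every logged decision, looks up the two actions' expected values in
#' the condition's backward-induction table and codes (a) the agent's choice
#' and (b) the model's choice on the worse/better-position scale used for
#' analysis: 1 = the goal in the worse position (larger
#' distance-to-resolution, i.e. lower score in both frames) was prioritized,
#' 0 = the better-position goal was. Rows where the coding is undefined are
#' marked for exclusion: a goal already resolved, level scores (no worse
#' position), or an expected-value tie (no optimal choice).
#'
#' @param logs Decision log from [generate_dataset()] (or any table with the
#'   same columns).
#' @param design The `goal_design` the logs were generated under.
#' @return The log tibble with added columns `ev1`, `ev2`, `optimal_action`
#'   (`"goal1"`/`"goal2"`/`"tie"`, `NA` once both goals are resolved),
#'   `worse_coded` (0/1, `NA` when undefined), `optimal_coded` (0/1, `NA`
#'   at ties or when undefined) and `exclusion_reason`
#'   (`"none"`, `"goal_resolved"`, `"equal_scores"`, `"ev_tie"`).
#' @export
code_decisions <- function(logs, design) {
  stopifnot(inherits(design, "goal_design"))
  need <- c("condition_id", "lead_goal", "frame", "horizon",
            "stages_remaining", "d1", "d2", "chosen")
  if (!all(need %in% names(logs)))
    stop("logs are missing columns: ",
         paste(setdiff(need, names(logs)), collapse = ", "), call. = FALSE)
  p_pri <- attr(design, "p_prioritized"); p_non <- attr(design, "p_nonprioritized")

  logs$ev1 <- NA_real_; logs$ev2 <- NA_real_
  logs$optimal_action <- NA_character_
  key <- paste(logs$condition_id, logs$lead_goal)
  for (grp in unique(key)) {
    sel <- key == grp
    cid <- logs$condition_id[sel][1]; lead <- logs$lead_goal[sel][1]
    drow <- design[design$condition_id == cid, ]
    if (nrow(drow) != 1)
      stop("log refers to condition_id absent from the design: ", cid,
           call. = FALSE)
    d0 <- c(drow$d1_start, drow$d2_start)
    if (lead == 2L) d0 <- rev(d0)
    spec <- task_spec(drow$frame, drow$horizon, d0, p_pri, p_non)
    bad <- logs$d1[sel] > d0[1] | logs$d2[sel] > d0[2] |
      logs$stages_remaining[sel] > drow$horizon
    if (any(bad))
      stop("log contains states outside condition ", cid, "'s state space",
           call. = FALSE)
    tab <- cached_table(spec)
    idx <- cbind(logs$d1[sel] + 1L, logs$d2[sel] + 1L, logs$stages_remaining[sel])
    logs$ev1[sel] <- tab$ev1[idx]
    logs$ev2[sel] <- tab$ev2[idx]
    logs$optimal_action[sel] <- c("tie", "goal1", "goal2")[tab$action[idx] + 1L]
  }

  resolved <- logs$d1 == 0 | logs$d2 == 0
  equal <- logs$d1 == logs$d2
  tie <- !is.na(logs$optimal_action) & logs$optimal_action == "tie"
  logs$exclusion_reason <- ifelse(resolved, "goal_resolved",
                           ifelse(equal, "equal_scores",
                           ifelse(tie, "ev_tie", "none")))
  # worse position = lower score in both frames: larger deficit under
  # approach, smaller loss buffer under avoidance
  worse1 <- ifelse(logs$frame == "approach", logs$d1 > logs$d2,
                   logs$d1 < logs$d2)
  codable <- !resolved & !equal
  logs$worse_coded <- ifelse(codable,
                             as.integer((logs$chosen == 1L) == worse1), NA_integer_)
  logs$optimal_coded <- ifelse(codable & !tie,
                               as.integer((logs$optimal_action == "goal1") == worse1),
                               NA_integer_)
  logs
}

#' Apply the analysis exclusion rules
#'
#' Keeps only decisions offering a genuine better-vs-worse choice: both
#' goals still pending, unequal scores, and distinct expected values.
#'
#' @param records Coded decisions from [code_decisions()].
#' @return A list with `records` (kept rows, all `exclusion_reason ==
#'   "none"`), `tally` (tibble of counts per reason, summing to the input
#'   size) and `kept_fraction`.
#' @export
apply_exclusions <- function(records) {
  stopifnot("exclusion_reason" %in% names(records))
  reasons <- c("none", "goal_resolved", "equal_scores", "ev_tie")
  counts <- vapply(reasons, function(r) sum(records$exclusion_reason == r), 0L)
  list(records = records[records$exclusion_reason == "none", ],
       tally = tibble::tibble(reason = reasons, n = as.integer(counts)),
       kept_fraction = counts[["none"]] / max(1L, nrow(records)))
}

#' Stack participant and model decisions for modelling
#'
#' Every kept decision contributes two rows to the modelling table: the
#' agent's coded choice and the normative model's coded choice for the same
#' state, distinguished by a decision-source predictor. Predictors use +/-1
#' coding: frame 1 = approach, -1 = avoidance; source 1 = participant,
#' -1 = optimal model.
#'
#' @param records Kept records from [apply_exclusions()].
#' @return A tibble with `participant`, `trial`, `condition_id`, `frame`,
#'   `frame_code`, `source`, `source_code` and the binary outcome `worse`
#'   (1 = prioritized the worse-position goal); exactly twice as many rows
#'   as `records`.
#' @export
stack_sources <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(participant = integer(), trial = integer(),
                          condition_id = integer(), frame = character(),
                          frame_code = numeric(), source = character(),
                          source_code = numeric(), worse = integer()))
  }
  if (any(records$exclusion_reason != "none"))
    stop("`records` still contains excluded decisions; run apply_exclusions() first",
         call. = FALSE)
  one <- function(source, code, outcome) {
    tibble::tibble(
      participant = records$participant, trial = records$trial,
      condition_id = records$condition_id, frame = records$frame,
      frame_code = ifelse(records$frame == "approach", 1, -1),
      source = source, source_code = code, worse = as.integer(outcome))
  }
  rbind(one("participant", 1, records$worse_coded),
        one("model", -1, records$optimal_coded))
}

new_goal_fit <- function(fit, cluster, n_obs) {
  beta <- stats::coef(fit)
  vc <- sandwich::vcovCL(fit, cluster = cluster)
  se <- sqrt(diag(vc))
  z <- beta / se
  structure(
    list(coefficients = tibble::tibble(
           term = names(beta), estimate = unname(beta),
           std_error = unname(se), statistic = unname(z),
           p_value = unname(2 * stats::pnorm(-abs(z)))),
         n_obs = n_obs, converged = fit$converged,
         separation = any(abs(beta) > 15), vcov = vc),
    class = "goal_fit")
}

#' @export
print.goal_fit <- function(x, ...) {
  cat(sprintf("<goal_fit> logistic regression, n = %d%s%s\n", x$n_obs,
              if (x$converged) "" else " (NOT converged)",
              if (x$separation) " (possible separation)" else ""))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Fit the goal frame x decision source interaction model
#'
#' Logistic regression of the worse-position outcome on goal frame, decision
#' source and their interaction (all +/-1 coded), fitted by iteratively
#' reweighted least squares with standard errors clustered on participant.
#' Clustered fixed-effects estimation approximates a mixed model with random
#' participant effects: the interaction's sign and approximate magnitude are
#' the inferential targets, not digit-level coefficient agreement.
#'
#' A negative interaction means the participant-minus-model gap in
#' prioritizing the trailing goal is more negative under approach than under
#' avoidance — the risk-averse/risk-seeking signature.
#'
#' @param table Modelling table from [stack_sources()].
#' @return A `goal_fit`: coefficient tibble (`term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`), `n_obs`, `converged`,
#'   `separation` flag and the clustered `vcov`.
#' @export
fit_interaction_model <- function(table) {
  if (nrow(table) == 0) stop("empty modelling table", call. = FALSE)
  fit <- stats::glm(worse ~ frame_code * source_code, family = stats::binomial(),
                    data = table, control = stats::glm.control(epsilon = 1e-8,
                                                               maxit = 100))
  if (!fit$converged) warning("IRLS did not converge within 100 iterations")
  new_goal_fit(fit, table$participant, nrow(table))
}

#' Per-frame decision-source contrasts
#'
#' Follow-up models fitted separately to the approach and avoidance subsets,
#' each with the single predictor decision source (+/-1 coded), mirroring
#' the interaction decomposition. Standard errors are clustered on
#' participant.
#'
#' @param table Modelling table from [stack_sources()].
#' @return Named list of two `goal_fit` objects (`approach`, `avoidance`).
#' @export
fit_per_frame_models <- function(table) {
  fits <- lapply(c(approach = "approach", avoidance = "avoidance"), function(fr) {
    sub <- table[table$frame == fr, ]
    if (nrow(sub) == 0)
      stop("no decisions in the ", fr, " frame subset", call. = FALSE)
    fit <- stats::glm(worse ~ source_code, family = stats::binomial(), data = sub,
                      control = stats::glm.control(epsilon = 1e-8, maxit = 100))
    new_goal_fit(fit, sub$participant, nrow(sub))
  })
  fits
}

#' Worse-position prioritization proportions by frame and source
#'
#' The descriptive complement of the interaction model: the proportion of
#' coded decisions prioritizing the worse-position goal in each goal frame x
#' decision source cell, with exact binomial confidence intervals.
#'
#' @param table Modelling table from [stack_sources()].
#' @param conf_level Confidence level for the intervals.
#' @return A tibble with one row per (frame, source): `n`, `successes`,
#'   `proportion`, `conf_low`, `conf_high`.
#' @export
summarize_proportions <- function(table, conf_level = 0.95) {
  cells <- expand.grid(frame = c("approach", "avoidance"),
                       source = c("participant", "model"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- table[table$frame == cells$frame[i] & table$source == cells$source[i], ]
    n <- nrow(sub); s <- sum(sub$worse)
    ci <- if (n > 0) stats::binom.test(s, n, conf.level = conf_level)$conf.int
          else c(NA_real_, NA_real_)
    tibble::tibble(frame = cells$frame[i], source = cells$source[i],
                   n = n, successes = s,
                   proportion = if (n > 0) s / n else NA_real_,
                   conf_low = ci[1], conf_high = ci[2])
  })
  do.call(rbind, rows)
}
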