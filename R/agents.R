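.table_cache <- new.env(parent = emptyenv())

# Policy tables are pure functions of (spec, terminal utility); cache them so
# simulation and coding reuse one solve per condition/orientation.
cached_table <- function(spec, utility = c(0, 1, 2)) {
  key <- paste(spec$frame, spec$horizon, spec$d_start[1], spec$d_start[2],
               spec$p_prioritized, spec$p_nonprioritized,
               paste(utility, collapse = ","), sep = "|")
  hit <- .table_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- backward_induction(spec, utility = utility)
  assign(key, val, envir = .table_cache)
  val
}

#' Define an agent's choice rule
#'
#' Agents stand in for participants when generating synthetic decision logs.
#' Three kinds are available:
#' \describe{
#'   \item{`optimal`}{plays the argmax-expected-value action from the
#'     backward-induction table; expected-value ties are broken uniformly at
#'     random.}
#'   \item{`logistic_biased`}{chooses the goal in the worse position (larger
#'     distance-to-resolution) with probability
#'     `plogis(inverse_temperature * (EV_worse - EV_better) + bias)`, where
#'     `bias` is `bias_approach` or `bias_avoidance` depending on the trial's
#'     frame. A negative approach bias yields risk-averse play
#'     (under-prioritizing the trailing goal); a positive avoidance bias
#'     yields risk-seeking play. With both biases 0 and large inverse
#'     temperature the rule converges on optimal play. When the goals are
#'     level (no worse position) the bias does not apply and choice follows
#'     the expected-value difference alone.}
#'   \item{`diminishing_returns`}{re-solves the task with concave subjective
#'     terminal utility `u(0) = 0`, `u(1) = 1`,
#'     `u(2) = 1 + utility_second_goal`, and plays that table's argmax;
#'     `utility_second_goal = 1` recovers the objective model.}
#' }
#'
#' @param kind Agent kind (see above).
#' @param inverse_temperature Sensitivity of the logistic rule to the
#'   expected-value difference (>= 0). Ignored by the other kinds.
#' @param bias_approach,bias_avoidance Additive logit preference for the
#'   worse-position goal in each frame (logistic agent only).
#' @param utility_second_goal Marginal utility of the second attained goal,
#'   in (0, 1] (diminishing-returns agent only).
#' @return An object of class `agent_params`.
#' @examples
#' agent_params("logistic_biased", inverse_temperature = 5,
#'              bias_approach = -0.5, bias_avoidance = 0.5)
#' @export
agent_params <- function(kind = c("optimal", "logistic_biased", "diminishing_returns"),
                         inverse_temperature = 5, bias_approach = 0,
                         bias_avoidance = 0, utility_second_goal = 1) {
  kind <- match.arg(kind)
  if (inverse_temperature < 0) stop("`inverse_temperature` must be >= 0", call. = FALSE)
  if (utility_second_goal <= 0 || utility_second_goal > 1)
    stop("`utility_second_goal` must lie in (0, 1]", call. = FALSE)
  structure(list(kind = kind, inverse_temperature = inverse_temperature,
                 bias_approach = bias_approach, bias_avoidance = bias_avoidance,
                 utility_second_goal = utility_second_goal),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("<agent_params> %s (it = %g, bias = %g/%g, u2 = %g)\n", x$kind,
              x$inverse_temperature, x$bias_approach, x$bias_avoidance,
              x$utility_second_goal))
  invisible(x)
}

agent_bias <- function(agent, frame) {
  if (frame == "approach") agent$bias_approach else agent$bias_avoidance
}

# Vectorized P(choose goal 1) for one spec/agent across states (d1, d2) at
# stages-remaining k (all vectors). States with both goals resolved get 0.5
# (no decision exists; the simulator keeps the log length honest, analysis
# drops those rows).
prob_goal1 <- function(agent, spec, d1, d2, k, tab, sub_tab = NULL) {
  idx <- cbind(d1 + 1L, d2 + 1L, k)
  n <- length(d1)
  p <- numeric(n)
  one_resolved <- (d1 == 0) != (d2 == 0)
  both_resolved <- d1 == 0 & d2 == 0
  live <- !one_resolved & !both_resolved
  # once one goal is resolved the pending goal is prioritized
  p[one_resolved] <- as.numeric(d1[one_resolved] > 0)
  p[both_resolved] <- 0.5
  if (any(live)) {
    if (agent$kind == "optimal" || agent$kind == "diminishing_returns") {
      use <- if (agent$kind == "optimal") tab else sub_tab
      a <- use$action[idx]
      p[live] <- c(`1` = 1, `2` = 0, `0` = 0.5)[as.character(a[live])]
    } else {
      ev1 <- tab$ev1[idx]; ev2 <- tab$ev2[idx]
      bias <- agent_bias(agent, spec$frame)
      # worse position = lower score: larger deficit (approach) or smaller
      # remaining buffer (avoidance)
      worse1 <- if (spec$frame == "approach") d1 > d2 else d1 < d2
      dv <- ifelse(worse1, ev1 - ev2, ev2 - ev1)  # EV(worse) - EV(better)
      z <- agent$inverse_temperature * dv
      z[is.nan(z)] <- 0                  # Inf * 0 at exact ties
      pw <- stats::plogis(z + bias)
      pl <- ifelse(worse1, pw, 1 - pw)
      eq <- d1 == d2                     # level scores: no worse position
      zeq <- agent$inverse_temperature * (ev1 - ev2)
      zeq[is.nan(zeq)] <- 0
      pl[eq] <- stats::plogis(zeq[eq])
      p[live] <- pl[live]
    }
  }
  p
}

#' Probability that an agent prioritizes goal 1 in a state
#'
#' @param agent An [agent_params()].
#' @param spec A [task_spec()].
#' @param state Length-2 vector `(d1, d2)`.
#' @param stages_remaining Stages left including the current decision.
#' @param table Optional precomputed `policy_table` for `spec`.
#' @return Probability in `[0, 1]`.
#' @export
choice_probability <- function(agent, spec, state, stages_remaining, table = NULL) {
  stopifnot(inherits(agent, "agent_params"), inherits(spec, "task_spec"))
  if (all(state == 0))
    stop("both goals are already resolved: no decision exists in this state",
         call. = FALSE)
  if (is.null(table)) table <- cached_table(spec)
  sub <- if (agent$kind == "diminishing_returns")
    cached_table(spec, utility = c(0, 1, 1 + agent$utility_second_goal))
  prob_goal1(agent, spec, state[1], state[2], stages_remaining, table, sub)
}

#' Sample one prioritization decision
#'
#' @inheritParams choice_probability
#' @return 1 or 2: the prioritized goal.
#' @export
choose_action <- function(agent, spec, state, stages_remaining, table = NULL) {
  p1 <- choice_probability(agent, spec, state, stages_remaining, table)
  if (stats::runif(1) < p1) 1L else 2L
}

# Simulate n trials of one spec in lockstep (all share the horizon). Returns
# a tibble of n * horizon decision rows ordered trial-major. RNG state is the
# caller's responsibility.
simulate_block <- function(spec, agent, n, tab = NULL, sub_tab = NULL) {
  if (is.null(tab)) tab <- cached_table(spec)
  if (is.null(sub_tab) && agent$kind == "diminishing_returns")
    sub_tab <- cached_table(spec, utility = c(0, 1, 1 + agent$utility_second_goal))
  TT <- spec$horizon
  d1 <- rep(spec$d_start[1], n); d2 <- rep(spec$d_start[2], n)
  rows <- vector("list", TT)
  for (stage in seq_len(TT)) {
    k <- TT - stage + 1L
    p1 <- prob_goal1(agent, spec, d1, d2, rep(k, n), tab, sub_tab)
    chosen <- ifelse(stats::runif(n) < p1, 1L, 2L)
    q1 <- ifelse(d1 == 0, 0, ifelse(chosen == 1L,
                                    step_down_prob(spec, TRUE),
                                    step_down_prob(spec, FALSE)))
    q2 <- ifelse(d2 == 0, 0, ifelse(chosen == 2L,
                                    step_down_prob(spec, TRUE),
                                    step_down_prob(spec, FALSE)))
    move1 <- as.integer(stats::runif(n) < q1)
    move2 <- as.integer(stats::runif(n) < q2)
    rows[[stage]] <- tibble::tibble(
      block_trial = seq_len(n), stage = stage, stages_remaining = k,
      d1 = d1, d2 = d2, chosen = chosen, move1 = move1, move2 = move2)
    d1 <- d1 - move1; d2 <- d2 - move2
  }
  out <- do.call(rbind, rows)
  out[order(out$block_trial, out$stage), ]
}

#' Simulate one trial
#'
#' Plays a single trial decision-by-decision: the agent picks a goal, then
#' each goal's counter moves by an independent Bernoulli draw (prioritized
#' goal: success probability `p_prioritized`; other goal:
#' `p_nonprioritized`; in the avoidance frame a counter move is a point
#' *lost*, which happens on a failure).
#'
#' @param condition A `goal_condition` from [calibrate_condition()] or a
#'   bare [task_spec()].
#' @param agent An [agent_params()].
#' @param seed Integer seed; the same seed reproduces the trial exactly.
#' @return A tibble with one row per decision (`stage`, `stages_remaining`,
#'   `d1`, `d2`, `score1`, `score2`, `chosen`, `move1`, `move2`) and
#'   attributes `goals_attained` (0-2) and `pence_delta` (+3 per achieved
#'   goal in approach, -3 per failed goal in avoidance).
#' @examples
#' cond <- task_spec("approach", 5, c(2, 3))
#' simulate_trial(cond, agent_params("optimal"), seed = 42)
#' @export
simulate_trial <- function(condition, agent = agent_params("optimal"), seed = 1L) {
  spec <- if (inherits(condition, "goal_condition")) condition$spec else condition
  stopifnot(inherits(spec, "task_spec"))
  log <- with_seed(seed, simulate_block(spec, agent, n = 1L))
  log$score1 <- score_from_distance(spec$frame, log$d1)
  log$score2 <- score_from_distance(spec$frame, log$d2)
  log <- log[c("stage", "stages_remaining", "d1", "d2", "score1", "score2",
               "chosen", "move1", "move2")]
  final <- c(log$d1[nrow(log)] - log$move1[nrow(log)],
             log$d2[nrow(log)] - log$move2[nrow(log)])
  attained <- terminal_value(spec, final[1], final[2])
  attr(log, "final_d") <- as.integer(final)
  attr(log, "goals_attained") <- attained
  attr(log, "pence_delta") <-
    if (spec$frame == "approach") 3L * attained else -3L * (2L - attained)
  log
}

#' Generate a synthetic decision-log dataset
#'
#' Simulates the full experiment: every participant works through the
#' shuffled schedule from [build_schedule()], and every decision is logged.
#' Trials are simulated in per-(participant, condition, orientation) blocks
#' whose RNG seeds derive deterministically from the master seed, so the
#' dataset is reproducible and unaffected by block evaluation order.
#'
#' @param design A `goal_design` from [build_design()].
#' @param agents A single [agent_params()] applied to every participant, or
#'   a list with one `agent_params` per participant.
#' @param seed Master integer seed.
#' @return A tibble with one row per decision: schedule columns
#'   (`participant`, `trial`, `condition_id`, `repetition`, `lead_goal`),
#'   condition columns (`frame`, `difficulty`, `relative_position`,
#'   `horizon`), and decision columns (`stage`, `stages_remaining`, `d1`,
#'   `d2`, `score1`, `score2`, `chosen`, `move1`, `move2`).
#' @examples
#' \donttest{
#' design <- build_design(n_participants = 2, repetitions = 1)
#' logs <- generate_dataset(design, agent_params("optimal"), seed = 7)
#' }
#' @export
generate_dataset <- function(design, agents = agent_params("optimal"), seed = 1L) {
  stopifnot(inherits(design, "goal_design"))
  n_part <- attr(design, "n_participants")
  if (inherits(agents, "agent_params")) {
    agents <- rep(list(agents), n_part)
  } else if (!is.list(agents) || length(agents) != n_part) {
    stop("`agents` must be one agent_params or a list of one per participant",
         call. = FALSE)
  }
  schedule <- build_schedule(design, seed = seed)
  p_pri <- attr(design, "p_prioritized"); p_non <- attr(design, "p_nonprioritized")

  spec_for <- function(row, lead) {
    d <- c(row$d1_start, row$d2_start)
    if (lead == 2L) d <- rev(d)
    task_spec(row$frame, row$horizon, d, p_pri, p_non)
  }

  chunks <- list()
  for (p in seq_len(n_part)) {
    for (cid in design$condition_id) {
      drow <- design[design$condition_id == cid, ]
      for (lead in c(1L, 2L)) {
        sched <- schedule[schedule$participant == p &
                            schedule$condition_id == cid &
                            schedule$lead_goal == lead, ]
        if (nrow(sched) == 0) next
        sched <- sched[order(sched$trial), ]
        spec <- spec_for(drow, lead)
        blk <- with_seed(derive_seed(seed, p, cid, lead),
                         simulate_block(spec, agents[[p]], n = nrow(sched)))
        blk$participant <- p
        blk$trial <- sched$trial[blk$block_trial]
        blk$repetition <- sched$repetition[blk$block_trial]
        blk$lead_goal <- lead
        blk$condition_id <- cid
        blk$frame <- drow$frame
        blk$difficulty <- drow$difficulty
        blk$relative_position <- drow$relative_position
        blk$horizon <- drow$horizon
        blk$score1 <- score_from_distance(drow$frame, blk$d1)
        blk$score2 <- score_from_distance(drow$frame, blk$d2)
        chunks[[length(chunks) + 1L]] <- blk
      }
    }
  }
  out <- do.call(rbind, chunks)
  out <- out[order(out$participant, out$trial, out$stage),
             c("participant", "trial", "condition_id", "repetition",
               "lead_goal", "frame", "difficulty", "relative_position",
               "horizon", "stage", "stages_remaining", "d1", "d2",
               "score1", "score2", "chosen", "move1", "move2")]
  tibble::as_tibble(out)
}

#' Per-trial outcome summary of a decision log
#'
#' Collapses a decision log to one row per trial with the number of goals
#' attained and the monetary consequence (+3 pence per achieved goal under
#' approach, -3 pence per failed goal under avoidance).
#'
#' @param logs A decision log from [generate_dataset()].
#' @return A tibble with one row per (participant, trial).
#' @export
summarize_trials <- function(logs) {
  last <- logs[logs$stage == logs$horizon, ]
  fd1 <- last$d1 - last$move1
  fd2 <- last$d2 - last$move2
  attained <- ifelse(last$frame == "approach",
                     (fd1 == 0) + (fd2 == 0), (fd1 > 0) + (fd2 > 0))
  tibble::tibble(
    participant = last$participant, trial = last$trial,
    condition_id = last$condition_id, frame = last$frame,
    difficulty = last$difficulty, relative_position = last$relative_position,
    goals_attained = as.integer(attained),
    pence_delta = ifelse(last$frame == "approach",
                         3L * attained, -3L * (2L - attained))
  )
}
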