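#' Define a two-goal multistage decision task
#'
#' A trial of multiple-goal pursuit is modelled as a finite-horizon Markov
#' decision process over two goals. Each goal is tracked by its
#' distance-to-resolution `d`: the number of one-unit steps separating the
#' current score from the point at which the goal resolves. An approach goal
#' is *achieved* the moment its `d` reaches 0 (enough points gained); an
#' avoidance goal is *failed* the moment its `d` reaches 0 (its loss buffer
#' exhausted). Resolution is absorbing: a resolved goal's counter is frozen.
#'
#' At every stage the decision maker prioritizes one goal. Per-goal outcomes
#' are independent Bernoulli draws: the prioritized goal moves one unit
#' toward resolution-as-success with probability `p_prioritized`, the other
#' with probability `p_nonprioritized`. In the approach frame "success"
#' decrements `d` (a point gained); in the avoidance frame a *failure*
#' (probability `1 - p`) decrements `d` (a point lost), so prioritizing an
#' avoidance goal protects it.
#'
#' @param frame `"approach"` or `"avoidance"`.
#' @param horizon Number of decision stages in the trial (integer, >= 1).
#' @param d_start Length-2 non-negative integer vector: starting
#'   distance-to-resolution of goal 1 and goal 2.
#' @param p_prioritized Probability that a stage's action succeeds with
#'   respect to the prioritized goal. Default 0.8, the task's published value.
#' @param p_nonprioritized Same for the non-prioritized goal. Default 0.2.
#' @return An object of class `task_spec`.
#' @examples
#' task_spec("approach", horizon = 10, d_start = c(3, 3), p_nonprioritized = 0.3)
#' @seealso [task_from_scores()] for the score-based parameterization,
#'   [backward_induction()] to solve the task.
#' @export
task_spec <- function(frame = c("approach", "avoidance"), horizon, d_start,
                      p_prioritized = 0.8, p_nonprioritized = 0.2) {
  frame <- match.arg(frame)
  if (length(horizon) != 1L || is.na(horizon) || horizon < 1 || horizon != floor(horizon))
    stop("`horizon` must be a single integer >= 1", call. = FALSE)
  if (length(d_start) != 2L || any(is.na(d_start)) || any(d_start < 0) ||
      any(d_start != floor(d_start)))
    stop("`d_start` must be two non-negative integers", call. = FALSE)
  for (p in c(p_prioritized, p_nonprioritized))
    if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  structure(
    list(frame = frame, horizon = as.integer(horizon),
         d_start = as.integer(d_start),
         p_prioritized = p_prioritized, p_nonprioritized = p_nonprioritized),
    class = "task_spec"
  )
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s frame, horizon %d, d_start (%d, %d), p = (%.3g, %.3g)\n",
              x$frame, x$horizon, x$d_start[1], x$d_start[2],
              x$p_prioritized, x$p_nonprioritized))
  invisible(x)
}

#' Build a task specification from on-screen scores
#'
#' Maps the task's score display onto distance-to-resolution counters. In the
#' approach frame the goal is to reach `threshold` (default 10) points or
#' more, so `d = threshold - score`. In the avoidance frame the goal is to
#' avoid dropping to `threshold` (default 9) points or less, so
#' `d = score - threshold` is the number of losses the goal can absorb.
#'
#' @inheritParams task_spec
#' @param start_scores Length-2 vector of starting scores.
#' @param threshold Goal threshold on the score scale (scalar, applied to
#'   both goals). Defaults: 10 for approach, 9 for avoidance.
#' @return A `task_spec`.
#' @examples
#' # approach: scores 7 and 9, need 10 or more -> deficits 3 and 1
#' task_from_scores("approach", start_scores = c(7, 9), horizon = 12)
#' @export
task_from_scores <- function(frame = c("approach", "avoidance"), start_scores,
                             horizon, threshold = NULL,
                             p_prioritized = 0.8, p_nonprioritized = 0.2) {
  frame <- match.arg(frame)
  if (is.null(threshold)) threshold <- if (frame == "approach") 10 else 9
  d <- if (frame == "approach") threshold - start_scores else start_scores - threshold
  if (any(d < 0))
    stop("starting scores already past the goal threshold", call. = FALSE)
  task_spec(frame, horizon, d, p_prioritized, p_nonprioritized)
}

#' Recover on-screen scores from distance-to-resolution
#'
#' Inverse of the mapping in [task_from_scores()].
#'
#' @param frame `"approach"` or `"avoidance"`.
#' @param d Vector of distances.
#' @param threshold Score threshold; frame-dependent default as in
#'   [task_from_scores()].
#' @return Numeric vector of scores.
#' @export
score_from_distance <- function(frame, d, threshold = NULL) {
  if (is.null(threshold)) threshold <- if (frame == "approach") 10 else 9
  if (frame == "approach") threshold - d else threshold + d
}

# Probability that one goal's counter decrements this stage, before freezing.
# Approach: a success moves the goal forward. Avoidance: a failure costs a
# point, so the prioritized goal (high success probability) is the protected one.
step_down_prob <- function(spec, prioritized) {
  p <- if (prioritized) spec$p_prioritized else spec$p_nonprioritized
  if (spec$frame == "approach") p else 1 - p
}

status_label <- function(frame, d) {
  resolved <- if (frame == "approach") "achieved" else "failed"
  ifelse(d == 0, resolved, "pending")
}

#' Enumerate the joint environmental states of a task
#'
#' The environmental state is the joint position of both goals. With starting
#' distances `(D1, D2)` each goal can sit at any distance from its start down
#' to 0 (resolved), giving `(D1 + 1) * (D2 + 1)` reachable states, e.g. 16
#' states for two goals that each pass through four progress levels.
#'
#' @param spec A [task_spec()].
#' @return A tibble with columns `d1`, `d2`, `status1`, `status2` (status is
#'   `"pending"` or the frame's absorbing resolution, `"achieved"`/`"failed"`).
#' @examples
#' nrow(enumerate_states(task_spec("approach", 10, c(3, 3)))) # 16
#' @export
enumerate_states <- function(spec) {
  stopifnot(inherits(spec, "task_spec"))
  g <- expand.grid(d1 = 0:spec$d_start[1], d2 = 0:spec$d_start[2])
  tibble::tibble(
    d1 = as.integer(g$d1), d2 = as.integer(g$d2),
    status1 = status_label(spec$frame, g$d1),
    status2 = status_label(spec$frame, g$d2)
  )
}

#' Terminal value of a joint state
#'
#' Value equates to the number of attained goals at the end of the horizon.
#' An approach goal is attained iff resolved (`d == 0`); an avoidance goal is
#' attained iff it *survived* the trial (`d > 0` throughout).
#'
#' @param spec A [task_spec()].
#' @param d1,d2 Vectors of per-goal distances at the horizon.
#' @return Integer vector of values in `{0, 1, 2}`.
#' @export
terminal_value <- function(spec, d1, d2) {
  if (spec$frame == "approach") as.integer(d1 == 0) + as.integer(d2 == 0)
  else                          as.integer(d1 > 0) + as.integer(d2 > 0)
}

#' One-stage transition distribution
#'
#' Distribution over successor states when one goal is prioritized. Per-goal
#' outcomes are independent Bernoulli moves of at most one unit; resolved
#' goals (`d == 0`) are frozen.
#'
#' @param spec A [task_spec()].
#' @param state Length-2 integer vector `(d1, d2)`.
#' @param action 1 or 2: which goal is prioritized.
#' @return A tibble with columns `d1`, `d2`, `prob`; probabilities sum to 1.
#' @examples
#' transition_distribution(task_spec("approach", 1, c(1, 1)), c(1, 1), action = 1)
#' @export
transition_distribution <- function(spec, state, action) {
  stopifnot(inherits(spec, "task_spec"), action %in% c(1, 2), length(state) == 2)
  if (all(state == 0))
    stop("both goals are already resolved: no decision exists in this state",
         call. = FALSE)
  q1 <- if (state[1] > 0) step_down_prob(spec, action == 1) else 0
  q2 <- if (state[2] > 0) step_down_prob(spec, action == 2) else 0
  out <- tibble::tibble(
    d1 = as.integer(state[1] - c(1, 1, 0, 0)),
    d2 = as.integer(state[2] - c(1, 0, 1, 0)),
    prob = c(q1 * q2, q1 * (1 - q2), (1 - q1) * q2, (1 - q1) * (1 - q2))
  )
  out <- out[out$prob > 0, , drop = FALSE]
  stats::aggregate(prob ~ d1 + d2, data = out, FUN = sum) |>
    tibble::as_tibble()
}

# Expected-value matrix for one action, vectorized over the full (d1, d2)
# grid. V is the value matrix one stage later (k - 1 stages remaining).
ev_matrix <- function(spec, V, action) {
  D1 <- spec$d_start[1]; D2 <- spec$d_start[2]
  q1 <- ifelse(0:D1 == 0, 0, step_down_prob(spec, action == 1))
  q2 <- ifelse(0:D2 == 0, 0, step_down_prob(spec, action == 2))
  Vd1  <- V[c(1, seq_len(D1)), , drop = FALSE]
  Vd2  <- V[, c(1, seq_len(D2)), drop = FALSE]
  Vd12 <- V[c(1, seq_len(D1)), c(1, seq_len(D2)), drop = FALSE]
  outer(q1, q2) * Vd12 + outer(q1, 1 - q2) * Vd1 +
    outer(1 - q1, q2) * Vd2 + outer(1 - q1, 1 - q2) * V
}

#' Expected value of prioritizing one goal (one state, one action)
#'
#' The probability-weighted value of the successor states under an action:
#' `e_a = sum_s p(s | a) v(s)`, the expected number of attained goals if the
#' action is taken and optimal play follows.
#'
#' @param spec A [task_spec()].
#' @param state Length-2 vector `(d1, d2)`.
#' @param action 1 or 2.
#' @param v_next Value matrix `(d1 + 1) x (d2 + 1)` for the following stage
#'   (one fewer stage remaining), e.g. a slice of
#'   `backward_induction(spec)$v`.
#' @return A single expected value in `[0, 2]`.
#' @export
expected_value <- function(spec, state, action, v_next) {
  if (!all(dim(v_next) == spec$d_start + 1L))
    stop("`v_next` does not cover the task's state grid", call. = FALSE)
  if (all(state == 0)) return(v_next[1, 1])   # absorbing: both goals resolved
  tr <- transition_distribution(spec, state, action)
  sum(tr$prob * v_next[cbind(tr$d1 + 1L, tr$d2 + 1L)])
}

#' Solve a task by backward induction
#'
#' Computes, for every joint state and number of stages remaining, the value
#' of the state and the expected value of prioritizing each goal, working
#' backward from the horizon: terminal values are the number of attained
#' goals, and with `k` stages remaining a state's value is the larger of the
#' two actions' expected values. The optimal action is the argmax; states
#' where the two expected values coincide are flagged as ties.
#'
#' @param spec A [task_spec()].
#' @param tie_tol Absolute tolerance for declaring the two actions' expected
#'   values equal. Symmetric states tie exactly in floating point; the
#'   tolerance guards near-ties arising elsewhere on the grid.
#' @param utility Terminal utility of attaining 0, 1 or 2 goals. The default
#'   `c(0, 1, 2)` equates value with the count of attained goals; a concave
#'   vector such as `c(0, 1, 1.5)` yields the diminishing-returns variant.
#' @return An object of class `policy_table`: a list with the `spec`, arrays
#'   `v` (`(D1+1) x (D2+1) x (horizon+1)`; slice `k + 1` holds values with
#'   `k` stages remaining), `ev1`, `ev2`, and `action` (`... x horizon`,
#'   slice `k` holds the quantities with `k` stages remaining; action codes
#'   1, 2, 0 = tie, `NA` where both goals are resolved), and `tie_tol`.
#'   Tables are indexed by stages remaining, so one table serves any trial
#'   of the same state grid regardless of calendar stage.
#' @examples
#' tab <- backward_induction(task_spec("approach", 10, c(3, 3),
#'                                     p_nonprioritized = 0.3))
#' # EVs with one stage remaining for the state d = (1, 2):
#' c(tab$ev1[2, 3, 1], tab$ev2[2, 3, 1])
#' @export
backward_induction <- function(spec, tie_tol = 1e-12, utility = c(0, 1, 2)) {
  stopifnot(inherits(spec, "task_spec"), length(utility) == 3)
  D1 <- spec$d_start[1]; D2 <- spec$d_start[2]; TT <- spec$horizon
  v <- array(NA_real_, dim = c(D1 + 1, D2 + 1, TT + 1))
  ev1 <- ev2 <- array(NA_real_, dim = c(D1 + 1, D2 + 1, TT))
  act <- array(NA_integer_, dim = c(D1 + 1, D2 + 1, TT))
  tv <- outer(0:D1, 0:D2, function(a, b) terminal_value(spec, a, b))
  v[, , 1] <- matrix(utility[tv + 1L], D1 + 1, D2 + 1)
  resolved_both <- outer(0:D1 == 0, 0:D2 == 0, "&")
  for (k in seq_len(TT)) {
    V <- matrix(v[, , k], D1 + 1, D2 + 1)
    E1 <- ev_matrix(spec, V, action = 1)
    E2 <- ev_matrix(spec, V, action = 2)
    a <- ifelse(abs(E1 - E2) < tie_tol, 0L, ifelse(E1 > E2, 1L, 2L))
    a[resolved_both] <- NA_integer_
    v[, , k + 1] <- pmax(E1, E2)
    ev1[, , k] <- E1; ev2[, , k] <- E2
    act[, , k] <- a
  }
  structure(list(spec = spec, v = v, ev1 = ev1, ev2 = ev2, action = act,
                 tie_tol = tie_tol),
            class = "policy_table")
}

#' @export
print.policy_table <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<policy_table> %s frame, %d states x %d stages, v(start) = %.4f\n",
              s$frame, prod(s$d_start + 1L), s$horizon,
              x$v[s$d_start[1] + 1L, s$d_start[2] + 1L, s$horizon + 1L]))
  invisible(x)
}

# Forward transport of a probability mass matrix through one stage under a
# fixed action. Inverse-direction counterpart of ev_matrix().
forward_step <- function(spec, M, action) {
  D1 <- nrow(M) - 1L; D2 <- ncol(M) - 1L
  q1 <- ifelse(0:D1 == 0, 0, step_down_prob(spec, action == 1))
  q2 <- ifelse(0:D2 == 0, 0, step_down_prob(spec, action == 2))
  out <- M * outer(1 - q1, 1 - q2)
  if (D1 > 0) {
    shift <- (M * outer(q1, 1 - q2))[2:(D1 + 1), , drop = FALSE]
    out[seq_len(D1), ] <- out[seq_len(D1), , drop = FALSE] + shift
  }
  if (D2 > 0) {
    shift <- (M * outer(1 - q1, q2))[, 2:(D2 + 1), drop = FALSE]
    out[, seq_len(D2)] <- out[, seq_len(D2), drop = FALSE] + shift
  }
  if (D1 > 0 && D2 > 0) {
    shift <- (M * outer(q1, q2))[2:(D1 + 1), 2:(D2 + 1), drop = FALSE]
    out[seq_len(D1), seq_len(D2)] <-
      out[seq_len(D1), seq_len(D2), drop = FALSE] + shift
  }
  out
}

#' Goal-attainment probabilities under a policy (forward pass)
#'
#' Propagates the start-state probability mass forward through the horizon
#' under the table's optimal policy and reads off the distribution of the
#' number of goals attained. Tie states split their mass half-and-half
#' between the two actions.
#'
#' @param spec A [task_spec()].
#' @param table A `policy_table` for `spec`; computed if omitted.
#' @return A list with `p_both`, `p_one`, `p_none` (summing to 1) and
#'   `expected_goals = 2 * p_both + p_one`, which equals the start state's
#'   value under the optimal policy.
#' @examples
#' attainment_probabilities(task_spec("approach", 1, c(1, 1)))
#' @export
attainment_probabilities <- function(spec, table = NULL) {
  stopifnot(inherits(spec, "task_spec"))
  if (is.null(table)) table <- backward_induction(spec)
  stopifnot(inherits(table, "policy_table"))
  D1 <- spec$d_start[1]; D2 <- spec$d_start[2]
  P <- matrix(0, D1 + 1, D2 + 1)
  P[D1 + 1, D2 + 1] <- 1
  for (k in spec$horizon:1) {
    a <- matrix(table$action[, , k], D1 + 1, D2 + 1)
    w1 <- matrix(1, D1 + 1, D2 + 1)     # both-resolved states are frozen
    w1[!is.na(a) & a == 2L] <- 0
    w1[!is.na(a) & a == 0L] <- 0.5
    P <- forward_step(spec, P * w1, action = 1) +
      forward_step(spec, P * (1 - w1), action = 2)
  }
  tv <- outer(0:D1, 0:D2, function(a, b) terminal_value(spec, a, b))
  p_both <- sum(P[tv == 2L]); p_one <- sum(P[tv == 1L]); p_none <- sum(P[tv == 0L])
  list(p_both = p_both, p_one = p_one, p_none = p_none,
       expected_goals = 2 * p_both + p_one)
}

#' Export a policy table in tidy form
#'
#' One row per (stages-remaining, state) with both actions' expected values
#' and the optimal action, suitable for writing to CSV.
#'
#' @param table A `policy_table`.
#' @return A tibble with columns `stages_remaining`, `d1`, `d2`, `status1`,
#'   `status2`, `ev_goal1`, `ev_goal2`, `optimal_action`
#'   (`"goal1"`, `"goal2"`, `"tie"`, or `NA` when both goals are resolved).
#' @export
tidy_policy <- function(table) {
  stopifnot(inherits(table, "policy_table"))
  spec <- table$spec
  D1 <- spec$d_start[1]; D2 <- spec$d_start[2]; TT <- spec$horizon
  g <- expand.grid(d1 = 0:D1, d2 = 0:D2, stages_remaining = seq_len(TT))
  idx <- cbind(g$d1 + 1L, g$d2 + 1L, g$stages_remaining)
  acode <- table$action[idx]
  tibble::tibble(
    stages_remaining = g$stages_remaining,
    d1 = as.integer(g$d1), d2 = as.integer(g$d2),
    status1 = status_label(spec$frame, g$d1),
    status2 = status_label(spec$frame, g$d2),
    ev_goal1 = table$ev1[idx], ev_goal2 = table$ev2[idx],
    optimal_action = c("tie", "goal1", "goal2")[acode + 1L]
  )
}
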