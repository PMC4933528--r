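# Independent oracles used to cross-check the dynamic-programming and
# forward-pass implementations. They deliberately avoid the package's
# vectorized matrix kernels: values are recovered by explicit recursion /
# state-mass bookkeeping over transition_distribution().

# Expected terminal value reached from `state` with `k` stages remaining,
# playing the policy stored in `tab`, by exhaustive path enumeration.
oracle_value <- function(spec, tab, state, k) {
  if (k == 0 || all(state == 0))
    return(terminal_value(spec, state[1], state[2]))
  a <- tab$action[state[1] + 1L, state[2] + 1L, k]
  a <- if (is.na(a) || a == 0L) 1L else a   # at EV ties either action serves
  tr <- transition_distribution(spec, state, a)
  sum(tr$prob * vapply(seq_len(nrow(tr)), function(i)
    oracle_value(spec, tab, c(tr$d1[i], tr$d2[i]), k - 1L), numeric(1)))
}

# Forward state-mass propagation under an arbitrary stochastic policy.
# `policy_fn(d1, d2, k)` returns P(prioritize goal 1); resolved-pair states
# are frozen. Returns the attained-goals distribution.
oracle_forward <- function(spec, policy_fn) {
  mass <- new.env(parent = emptyenv())
  put <- function(env, d1, d2, p) {
    key <- paste(d1, d2)
    env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + p
  }
  put(mass, spec$d_start[1], spec$d_start[2], 1)
  for (k in spec$horizon:1) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(mass)) {
      d <- as.integer(strsplit(key, " ")[[1]])
      p <- mass[[key]]
      if (all(d == 0)) { put(nxt, 0, 0, p); next }
      w1 <- policy_fn(d[1], d[2], k)
      for (a in c(1L, 2L)) {
        wa <- if (a == 1L) w1 else 1 - w1
        if (wa == 0) next
        tr <- transition_distribution(spec, d, a)
        for (i in seq_len(nrow(tr))) put(nxt, tr$d1[i], tr$d2[i], p * wa * tr$prob[i])
      }
    }
    mass <- nxt
  }
  out <- c(p_none = 0, p_one = 0, p_both = 0)
  for (key in ls(mass)) {
    d <- as.integer(strsplit(key, " ")[[1]])
    tv <- terminal_value(spec, d[1], d[2])
    out[tv + 1L] <- out[tv + 1L] + mass[[key]]
  }
  out
}

# The optimal policy as a policy_fn, splitting ties half-and-half.
table_policy <- function(tab) {
  function(d1, d2, k) {
    a <- tab$action[d1 + 1L, d2 + 1L, k]
    if (is.na(a)) 1 else c(`1` = 1, `2` = 0, `0` = 0.5)[as.character(a)]
  }
}

# Independent recomputation of attainment_probabilities().
oracle_attainment <- function(spec, tab = NULL) {
  if (is.null(tab)) tab <- backward_induction(spec)
  oracle_forward(spec, table_policy(tab))
}

# Small random task generator for property tests.
random_spec <- function(max_horizon = 5, max_d = 4) {
  frame <- sample(c("approach", "avoidance"), 1)
  d <- sample.int(max_d, 2, replace = TRUE)   # keep at least one unit per goal
  task_spec(frame, sample.int(max_horizon, 1), d,
            p_prioritized = round(runif(1, 0.5, 1), 2),
            p_nonprioritized = round(runif(1, 0, 0.5), 2))
}

# Heuristic comparison policies (prob of prioritizing goal 1).
policy_always_better <- function(spec) function(d1, d2, k) {
  if (d1 == d2) return(0.5)
  better1 <- if (spec$frame == "approach") d1 < d2 else d1 > d2
  as.numeric(better1)
}
policy_always_worse <- function(spec) function(d1, d2, k) {
  if (d1 == d2) return(0.5)
  worse1 <- if (spec$frame == "approach") d1 > d2 else d1 < d2
  as.numeric(worse1)
}
policy_uniform <- function(spec) function(d1, d2, k) 0.5

expected_goals_of <- function(dist) 2 * dist[["p_both"]] + dist[["p_one"]]
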