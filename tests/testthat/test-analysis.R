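# Small shared design/dataset for the coding and modelling tests.
ana_design <- function() {
  build_design(difficulties = c("moderate", "high"),
               relative_positions = c(1, 3), n_participants = 4,
               repetitions = 2)
}

test_that("worse/better coding follows the score scale in both frames", {
  des <- build_design(frames = "approach", difficulties = "moderate",
                      relative_positions = 1, n_participants = 1,
                      repetitions = 1)
  logs <- generate_dataset(des, agent_params("optimal"), seed = 2)
  rec <- code_decisions(logs, des)

  # worse position = lower score; chosen flag must match by construction
  live <- rec$exclusion_reason == "none"
  worse1 <- rec$score1 < rec$score2
  expect_equal(rec$worse_coded[live],
               as.integer((rec$chosen == 1L) == worse1)[live])
  # approach: score pair (7, 9) -> choosing the 7-point goal codes 1
  ex <- rec[live & rec$score1 < rec$score2 & rec$chosen == 1L, ]
  if (nrow(ex)) expect_true(all(ex$worse_coded == 1L))
})

test_that("hand-built decisions code and exclude as expected", {
  # approach condition, deficits (2, 3), horizon 11 at moderate settings:
  # construct a mini-log by hand (chosen/moves scripted, not simulated)
  des <- build_design(frames = "approach", bands = list(easy = c(0, 1)),
                      difficulties = "easy", relative_positions = 1,
                      n_participants = 1, repetitions = 1)
  stopifnot(des$d1_start == 1, des$d2_start == 2)  # first spec in search order
  hor <- des$horizon
  mk <- function(stage, d1, d2, chosen)
    tibble::tibble(participant = 1L, trial = 1L, condition_id = des$condition_id,
                   repetition = 1L, lead_goal = 1L, frame = "approach",
                   difficulty = des$difficulty,
                   relative_position = 1L, horizon = hor, stage = stage,
                   stages_remaining = hor - stage + 1L, d1 = d1, d2 = d2,
                   score1 = 10 - d1, score2 = 10 - d2, chosen = chosen,
                   move1 = 0L, move2 = 0L)
  logs <- rbind(mk(1L, 1L, 2L, 2L),   # both pending, unequal -> kept, worse
                mk(2L, 1L, 1L, 1L),   # equal scores -> excluded
                mk(3L, 0L, 1L, 2L))   # goal 1 resolved -> excluded
  rec <- code_decisions(logs, des)
  expect_equal(rec$exclusion_reason,
               c("none", "equal_scores", "goal_resolved"))
  expect_equal(rec$worse_coded, c(1L, NA_integer_, NA_integer_))
  # with many stages left and an easy task, prioritizing the trailing goal
  # is optimal: optimal_coded = 1
  expect_equal(rec$optimal_coded[1], 1L)
})

test_that("the worked example's optimal choice codes as better-position", {
  # final-week state: A one task from done (better), B two tasks (worse);
  # optimal prioritizes A, so the optimal decision codes 0
  des <- structure(
    tibble::tibble(condition_id = 1L, frame = "approach",
                   difficulty = "custom", relative_position = 1L,
                   horizon = 10L, d1_start = 3L, d2_start = 3L,
                   score1_start = 7, score2_start = 7,
                   p_both = NA_real_, band_met = TRUE),
    class = c("goal_design", "tbl_df", "tbl", "data.frame"),
    n_participants = 1L, repetitions = 1L,
    p_prioritized = 0.8, p_nonprioritized = 0.3)
  logs <- tibble::tibble(participant = 1L, trial = 1L, condition_id = 1L,
                         repetition = 1L, lead_goal = 1L, frame = "approach",
                         difficulty = "custom", relative_position = 1L,
                         horizon = 10L, stage = 10L, stages_remaining = 1L,
                         d1 = 1L, d2 = 2L, score1 = 9, score2 = 8,
                         chosen = 1L, move1 = 1L, move2 = 0L)
  rec <- code_decisions(logs, des)
  expect_equal(rec$optimal_action, "goal1")
  expect_equal(rec$optimal_coded, 0L)
  expect_equal(rec$worse_coded, 0L)     # the agent also chose the leader
})

test_that("coding rejects states outside the condition's space", {
  des <- build_design(frames = "approach", bands = list(easy = c(0, 1)),
                      difficulties = "easy", relative_positions = 0,
                      n_participants = 1, repetitions = 1)
  logs <- generate_dataset(des, agent_params("optimal"), seed = 3)
  bad <- logs
  bad$d1[1] <- 99L
  expect_error(code_decisions(bad, des), "state space")
  bad2 <- logs
  bad2$condition_id <- 42L
  expect_error(code_decisions(bad2, des), "absent")
})

test_that("exclusions are tallied, idempotent and order-independent", {
  des <- ana_design()
  logs <- generate_dataset(des, agent_params("optimal"), seed = 5)
  rec <- code_decisions(logs, des)
  ex <- apply_exclusions(rec)
  expect_equal(sum(ex$tally$n), nrow(rec))
  expect_true(all(ex$records$exclusion_reason == "none"))
  expect_equal(ex$kept_fraction, nrow(ex$records) / nrow(rec))
  # idempotent
  ex2 <- apply_exclusions(ex$records)
  expect_equal(nrow(ex2$records), nrow(ex$records))
  # order-independent
  shuf <- rec[sample.int(nrow(rec)), ]
  ex3 <- apply_exclusions(shuf)
  expect_equal(sort(ex3$records$stage), sort(ex$records$stage))
  expect_equal(ex3$tally$n, ex$tally$n)
})

test_that("stacking doubles kept records with balanced source codes", {
  des <- ana_design()
  logs <- generate_dataset(des, agent_params("optimal"), seed = 6)
  ex <- apply_exclusions(code_decisions(logs, des))
  tab <- stack_sources(ex$records)
  expect_equal(nrow(tab), 2 * nrow(ex$records))
  expect_equal(mean(tab$source_code), 0)
  expect_setequal(unique(tab$frame_code), c(1, -1))
  expect_equal(nrow(stack_sources(ex$records[0, ])), 0)
  expect_error(stack_sources(code_decisions(logs, des)), "apply_exclusions")
})

test_that("a null outcome yields near-zero coefficients", {
  set.seed(31)
  n <- 1000
  tab <- tibble::tibble(
    participant = rep(1:10, each = n / 10),
    frame = rep(c("approach", "avoidance"), n / 2),
    frame_code = rep(c(1, -1), n / 2),
    source = rep(c("participant", "model"), each = 2, length.out = n),
    source_code = rep(c(1, -1), each = 2, length.out = n),
    worse = rbinom(n, 1, 0.5))
  fit <- fit_interaction_model(tab)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_equal(fit$n_obs, n)
  co <- fit$coefficients
  expect_true(all(abs(co$estimate) < 3 * co$std_error))
})

test_that("generated frame biases recover a negative interaction", {
  des <- ana_design()
  biased <- agent_params("logistic_biased", inverse_temperature = 3,
                         bias_approach = -1, bias_avoidance = 1)
  logs <- generate_dataset(des, biased, seed = 8)
  tab <- stack_sources(apply_exclusions(code_decisions(logs, des))$records)
  fit <- fit_interaction_model(tab)
  co <- fit$coefficients
  inter <- co[co$term == "frame_code:source_code", ]
  expect_lt(inter$estimate, 0)
  expect_lt(inter$p_value, 0.05)

  pf <- fit_per_frame_models(tab)
  expect_lt(pf$approach$coefficients$estimate[2], 0)
  expect_gt(pf$avoidance$coefficients$estimate[2], 0)
})

test_that("optimal-agent data show no decision-source effect", {
  des <- ana_design()
  logs <- generate_dataset(des, agent_params("optimal"), seed = 9)
  tab <- stack_sources(apply_exclusions(code_decisions(logs, des))$records)
  fit <- fit_interaction_model(tab)
  co <- fit$coefficients
  src <- co[co$term == "source_code", ]
  expect_lt(abs(src$estimate), 3 * src$std_error)
})

test_that("per-frame fits error on an empty frame subset", {
  des <- build_design(frames = "approach", difficulties = "moderate",
                      relative_positions = 1, n_participants = 2,
                      repetitions = 1)
  logs <- generate_dataset(des, agent_params("optimal"), seed = 10)
  tab <- stack_sources(apply_exclusions(code_decisions(logs, des))$records)
  expect_error(fit_per_frame_models(tab), "avoidance")
})

test_that("proportion summaries are exact on degenerate outcomes", {
  tab <- tibble::tibble(
    participant = 1L,
    frame = rep(c("approach", "avoidance"), each = 4),
    frame_code = rep(c(1, -1), each = 4),
    source = rep(c("participant", "model"), 4),
    source_code = rep(c(1, -1), 4),
    worse = 1L)
  pr <- summarize_proportions(tab)
  expect_equal(nrow(pr), 4)
  expect_true(all(pr$proportion == 1))
  expect_true(all(pr$conf_high == 1))

  set.seed(32)
  tab$worse <- rbinom(8, 1, 0.5)
  tab2 <- tab[rep(1:8, 100), ]
  set.seed(33)
  tab2$worse <- rbinom(800, 1, 0.5)
  pr2 <- summarize_proportions(tab2)
  expect_true(all(pr2$conf_low < 0.5 & pr2$conf_high > 0.5))
})
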