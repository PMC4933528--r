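# Memoized dual-goal attainment probabilities: calibration revisits the same
# (frame, horizon, deficit) cells many times across conditions and sessions.
.pboth_cache <- new.env(parent = emptyenv())

cached_p_both <- function(frame, horizon, d1, d2, p_pri, p_non) {
  key <- paste(frame, horizon, d1, d2, p_pri, p_non, sep = "|")
  hit <- .pboth_cache[[key]]
  if (!is.null(hit)) return(hit)
  spec <- task_spec(frame, horizon, c(d1, d2), p_pri, p_non)
  val <- attainment_probabilities(spec)$p_both
  assign(key, val, envir = .pboth_cache)
  val
}

#' Dual-goal difficulty bands
#'
#' The three target intervals for the probability of attaining both goals at
#' the start of a trial, as published for the low, moderate and high
#' difficulty levels.
#'
#' @return A named list of length-2 numeric vectors.
#' @export
difficulty_bands <- function() {
  list(low = c(0.95, 0.96), moderate = c(0.57, 0.58), high = c(0.03, 0.06))
}

#' Calibrate one experimental condition
#'
#' Finds starting deficits and a horizon such that the optimal-policy
#' probability of attaining both goals falls in the difficulty label's band.
#' Goal 1 starts `relative_position` score units ahead of goal 2: deficits
#' `(d, d + relative_position)` in the approach frame, loss buffers
#' `(d + relative_position, d)` in the avoidance frame. The search runs over
#' ascending horizon, then ascending base deficit `d` — deterministic, so the
#' same arguments always reproduce the same condition.
#'
#' Because deficits and horizons are integers, the attainable probabilities
#' form a discrete set and a band two percentage points wide cannot always be
#' hit exactly. With `fallback = TRUE` (the default) the search therefore
#' proceeds in tiers: (1) the strict band; (2) the band widened by half a
#' unit of its printed precision (0.005 per side), treating the published
#' bounds as rounded values; (3) the grid point nearest the band midpoint,
#' flagged with `band_met = FALSE`. With `fallback = FALSE` only the strict
#' band is accepted and an unattainable band raises an error.
#'
#' @param frame `"approach"` or `"avoidance"`.
#' @param difficulty `"low"`, `"moderate"` or `"high"`, or a length-2
#'   numeric band.
#' @param relative_position Starting score difference between the goals
#'   (0, 1, 3 or 5 in the published design; any non-negative integer works).
#' @param bands Band list as from [difficulty_bands()].
#' @param horizon_range Allowed trial lengths (default 11 to 24 decisions).
#' @param max_deficit Largest base deficit searched.
#' @param p_prioritized,p_nonprioritized Per-stage success probabilities.
#' @param fallback Accept near-band solutions when the strict band is
#'   unattainable on the integer grid (see Details).
#' @return An object of class `goal_condition`: a list with `frame`,
#'   `difficulty`, `relative_position`, the calibrated `spec`, its `p_both`
#'   under the optimal policy, and `band_met`.
#' @examples
#' \donttest{
#' calibrate_condition("approach", "low", 0)
#' }
#' @export
calibrate_condition <- function(frame, difficulty, relative_position,
                                bands = difficulty_bands(),
                                horizon_range = c(11, 24), max_deficit = 30,
                                p_prioritized = 0.8, p_nonprioritized = 0.2,
                                fallback = TRUE) {
  band <- if (is.numeric(difficulty)) difficulty else bands[[difficulty]]
  label <- if (is.character(difficulty)) difficulty else "custom"
  if (is.null(band) || length(band) != 2 || band[1] > band[2])
    stop("unknown difficulty band", call. = FALSE)
  rp <- as.integer(relative_position)
  horizons <- seq(horizon_range[1], horizon_range[2])
  wide <- c(max(0, band[1] - 0.005), min(1, band[2] + 0.005))
  mid <- mean(band)

  grid_T <- rep(horizons, each = max_deficit)
  grid_d <- rep(seq_len(max_deficit), times = length(horizons))
  pb <- rep(NA_real_, length(grid_T))
  hit <- NA_integer_
  for (i in seq_along(grid_T)) {
    pb[i] <- cached_p_both(frame, grid_T[i], grid_d[i], grid_d[i] + rp,
                           p_prioritized, p_nonprioritized)
    if (pb[i] >= band[1] && pb[i] <= band[2]) { hit <- i; break }
  }
  band_met <- !is.na(hit)
  if (!band_met && !fallback)
    stop(sprintf("no feasible condition for band [%g, %g] with horizons %d-%d",
                 band[1], band[2], horizon_range[1], horizon_range[2]),
         call. = FALSE)
  if (!band_met) {                       # tier 2: printed-precision widening
    w <- which(pb >= wide[1] & pb <= wide[2])
    if (length(w)) { hit <- w[1]; band_met <- TRUE }
  }
  if (is.na(hit)) {                      # tier 3: nearest to band midpoint
    hit <- which.min(abs(pb - mid))
    if (!length(hit) || is.na(pb[hit]))
      stop(sprintf("no feasible condition for band [%g, %g]", band[1], band[2]),
           call. = FALSE)
  }
  d_pair <- c(grid_d[hit], grid_d[hit] + rp)
  if (frame == "avoidance") d_pair <- rev(d_pair)   # goal 1 keeps the higher score
  spec <- task_spec(frame, grid_T[hit], d_pair, p_prioritized, p_nonprioritized)
  structure(
    list(frame = frame, difficulty = label, relative_position = rp,
         spec = spec, p_both = pb[hit], band_met = band_met, band = band),
    class = "goal_condition"
  )
}

#' @export
print.goal_condition <- function(x, ...) {
  cat(sprintf(
    "<goal_condition> %s/%s, rel. position %d: horizon %d, d_start (%d, %d), p_both = %.4f%s\n",
    x$frame, x$difficulty, x$relative_position, x$spec$horizon,
    x$spec$d_start[1], x$spec$d_start[2], x$p_both,
    if (x$band_met) "" else " (outside band)"))
  invisible(x)
}

#' Reconstruct the full factorial design
#'
#' Calibrates every cell of the 2 (goal frame) x 3 (dual-goal difficulty) x
#' 4 (relative position) within-subjects design. Each participant completes
#' every condition `repetitions` times (default 6), i.e. 144 trials for the
#' default factors.
#'
#' @inheritParams calibrate_condition
#' @param frames,difficulties,relative_positions Factor levels to cross.
#' @param n_participants,repetitions Sample structure carried as attributes
#'   and used by [build_schedule()].
#' @return A `goal_design`: a tibble with one row per condition
#'   (`condition_id`, the three factors, `horizon`, `d1_start`, `d2_start`,
#'   `score1_start`, `score2_start`, `p_both`, `band_met`) with attributes
#'   `n_participants`, `repetitions`, `p_prioritized`, `p_nonprioritized`.
#' @examples
#' \donttest{
#' design <- build_design()
#' nrow(design) # 24
#' }
#' @export
build_design <- function(bands = difficulty_bands(),
                         frames = c("approach", "avoidance"),
                         difficulties = c("low", "moderate", "high"),
                         relative_positions = c(0, 1, 3, 5),
                         n_participants = 20, repetitions = 6,
                         horizon_range = c(11, 24), max_deficit = 30,
                         p_prioritized = 0.8, p_nonprioritized = 0.2,
                         fallback = TRUE) {
  cells <- expand.grid(relative_position = relative_positions,
                       difficulty = difficulties, frame = frames,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cond <- calibrate_condition(cells$frame[i], cells$difficulty[i],
                                cells$relative_position[i], bands = bands,
                                horizon_range = horizon_range,
                                max_deficit = max_deficit,
                                p_prioritized = p_prioritized,
                                p_nonprioritized = p_nonprioritized,
                                fallback = fallback)
    tibble::tibble(
      condition_id = i, frame = cond$frame, difficulty = cond$difficulty,
      relative_position = cond$relative_position,
      horizon = cond$spec$horizon,
      d1_start = cond$spec$d_start[1], d2_start = cond$spec$d_start[2],
      score1_start = score_from_distance(cond$frame, cond$spec$d_start[1]),
      score2_start = score_from_distance(cond$frame, cond$spec$d_start[2]),
      p_both = cond$p_both, band_met = cond$band_met
    )
  })
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out[c("frame", "difficulty", "relative_position")]))
  structure(out, class = c("goal_design", class(out)),
            n_participants = as.integer(n_participants),
            repetitions = as.integer(repetitions),
            p_prioritized = p_prioritized, p_nonprioritized = p_nonprioritized)
}

#' Build the per-participant trial schedule
#'
#' Expands a design into an ordered trial list: every participant receives
#' every condition exactly `repetitions` times, in an order shuffled
#' independently per participant. When the two goals start at different
#' scores, which goal leads is counterbalanced across repetitions: goal 1
#' leads on odd repetitions, goal 2 on even ones.
#'
#' @param design A `goal_design` from [build_design()].
#' @param seed Integer seed making the shuffle reproducible.
#' @return A tibble with columns `participant`, `trial` (1..n within
#'   participant, in presentation order), `condition_id`, `repetition`,
#'   `lead_goal` (1 or 2: the goal starting in the better position).
#' @export
build_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "goal_design"))
  n_part <- attr(design, "n_participants")
  reps <- attr(design, "repetitions")
  base <- expand.grid(condition_id = design$condition_id,
                      repetition = seq_len(reps))
  base$lead_goal <- ifelse(base$repetition %% 2 == 1, 1L, 2L)
  out <- lapply(seq_len(n_part), function(p) {
    ord <- with_seed(derive_seed(seed, p), sample.int(nrow(base)))
    tibble::tibble(participant = p, trial = seq_len(nrow(base)),
                   condition_id = base$condition_id[ord],
                   repetition = base$repetition[ord],
                   lead_goal = base$lead_goal[ord])
  })
  do.call(rbind, out)
}
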