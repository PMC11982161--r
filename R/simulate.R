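# Synthetic coupled turn-taking dyads and whole simulated studies.
#
# Each partner is a two-state (speech/silence) chain in 1-s steps with
# per-second start and stop hazards. Coupling modulates those hazards from
# the partner's state delay_d seconds earlier: yield_gain > 1 makes a speaker
# stop sooner when the partner was speaking, initiative_gain > 1 makes a
# silent partner start sooner when the partner was silent. Both pressures
# push the dyad toward complementary (speaker/listener) states, the pattern
# the recurrence measures are designed to detect. Asymmetric gains produce
# leader-follower asymmetry; asymmetric stop hazards produce dwell-time
# (trapping) asymmetry.

#' Configuration for one simulated dyad
#'
#' Scalar gains apply to both partners; length-2 vectors give partner A and
#' partner B their own gain, which is how lead-lag asymmetry is induced.
#'
#' @param n_seconds task length in seconds (default 300, a 5-minute task).
#' @param p_start_a,p_start_b per-second probability of starting to speak
#'   when silent.
#' @param p_stop_a,p_stop_b per-second probability of stopping when speaking.
#' @param yield_gain multiplier on the stop hazard when the partner was
#'   speaking `delay_d` seconds ago (scalar or `c(a, b)`).
#' @param initiative_gain multiplier on the start hazard when the partner was
#'   silent `delay_d` seconds ago (scalar or `c(a, b)`).
#' @param delay_d reaction delay in whole seconds (default 1).
#' @param noise_eps per-second probability of flipping the realized state.
#' @param seed optional integer seed.
#' @return A list of class `dyad_sim_config`.
#' @export
dyad_sim_config <- function(n_seconds = 300,
                            p_start_a = 0.07, p_start_b = 0.07,
                            p_stop_a = 0.13, p_stop_b = 0.13,
                            yield_gain = 3, initiative_gain = 3,
                            delay_d = 1, noise_eps = 0.02, seed = NULL) {
  two <- function(x) if (length(x) == 1) c(x, x) else x
  cfg <- list(
    n_seconds = as.integer(n_seconds),
    p_start = c(p_start_a, p_start_b),
    p_stop = c(p_stop_a, p_stop_b),
    yield_gain = two(yield_gain),
    initiative_gain = two(initiative_gain),
    delay_d = as.integer(delay_d),
    noise_eps = noise_eps,
    seed = seed
  )
  if (cfg$n_seconds < 10) stop("n_seconds must be >= 10", call. = FALSE)
  if (cfg$delay_d < 1) stop("delay_d must be >= 1", call. = FALSE)
  probs <- c(cfg$p_start, cfg$p_stop, cfg$noise_eps)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("hazards and noise_eps must be probabilities in [0, 1]",
         call. = FALSE)
  }
  if (any(cfg$yield_gain < 0) || any(cfg$initiative_gain < 0)) {
    stop("gains must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "dyad_sim_config")
}

#' Simulate one coupled turn-taking dyad
#'
#' @param cfg a [dyad_sim_config()].
#' @param dyad_id,task metadata for the resulting series.
#' @return A `dyad_series` of two aligned binary [speech_series()].
#' @export
simulate_dyad <- function(cfg = dyad_sim_config(), dyad_id = "d1",
                          task = NA_character_) {
  stopifnot(inherits(cfg, "dyad_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_seconds
  d <- cfg$delay_d
  clip <- function(p) pmin(pmax(p, 0), 1)
  s <- matrix(0L, nrow = n, ncol = 2)
  p_stat <- cfg$p_start / (cfg$p_start + cfg$p_stop)
  s[1, ] <- as.integer(stats::runif(2) < p_stat)
  u <- matrix(stats::runif(2L * (n - 1L)), nrow = n - 1L)
  for (t in 2:n) {
    lag_t <- max(t - d, 1)
    for (k in 1:2) {
      other <- s[lag_t, 3 - k]
      if (s[t - 1, k] == 1L) {
        p <- cfg$p_stop[k] * if (other == 1L) cfg$yield_gain[k] else 1
        s[t, k] <- if (u[t - 1, k] < clip(p)) 0L else 1L
      } else {
        p <- cfg$p_start[k] * if (other == 0L) cfg$initiative_gain[k] else 1
        s[t, k] <- if (u[t - 1, k] < clip(p)) 1L else 0L
      }
    }
  }
  if (cfg$noise_eps > 0) {
    flip <- matrix(stats::runif(2 * n) < cfg$noise_eps, nrow = n)
    s[flip] <- 1L - s[flip]
  }
  align_dyad(
    speech_series(s[, 1], dyad_id = dyad_id,
                  participant_id = paste0(dyad_id, "_a"), task = task),
    speech_series(s[, 2], dyad_id = dyad_id,
                  participant_id = paste0(dyad_id, "_b"), task = task)
  )
}

#' Build the exact-complement partner of a speech series
#'
#' A dyad of a series and its complement is in anti-phase at every second
#' (RR_LOS = 1) and its cross-recurrence plot is symmetric about the line of
#' synchrony, so the profile quotient is exactly 0. Useful as a definitional
#' extreme.
#'
#' @param s a [speech_series()].
#' @return A `dyad_series` pairing `s` with its elementwise complement.
#' @export
complement_dyad <- function(s) {
  stopifnot(inherits(s, "speech_series"))
  b <- speech_series(1L - s$values, dyad_id = s$dyad_id,
                     participant_id = paste0(s$participant_id, "_comp"),
                     task = s$task)
  align_dyad(s, b)
}

#' Configuration for a whole simulated study
#'
#' Emulates a laboratory design of same-sex dyads each holding three 5-minute
#' conversations (introduction, self-disclosure, argumentative), with
#' standardized Extraversion and Agreeableness scores per participant,
#' trait-dependent coupling, task-dependent coupling offsets, and 1-5 Likert
#' appraisal items generated from the computed coordination measures.
#'
#' Trait effects enter the coupling multiplicatively:
#' a participant's initiative gain is scaled by `exp(b_extra_initiative * E)`
#' and the yield gain by `exp(b_agree_yield * A)`, so positive coefficients
#' make extraverts quicker to claim silence and agreeable partners quicker to
#' yield the floor. Appraisal items are
#' `mean + b_E * E + b_A * A + b_rr_los * z(rr_los) + noise`, clipped to
#' `[1, 5]`, with `rr_los` the dyad's task-mean lag-zero coordination.
#'
#' @param n_dyads number of dyads (default 50).
#' @param n_seconds task length (default 300).
#' @param base a [dyad_sim_config()] giving the baseline hazards and gains.
#' @param task_coupling named multipliers on both gains per task.
#' @param b_extra_initiative,b_agree_yield trait-to-coupling coefficients.
#' @param appraisal_items named list of item parameter lists
#'   `(mean, b_extra, b_agree, b_rr_los, noise_sd)`.
#' @param seed master seed; every draw in [simulate_study()] derives from it.
#' @return A list of class `study_sim_config`.
#' @export
study_sim_config <- function(n_dyads = 50, n_seconds = 300,
                             base = dyad_sim_config(n_seconds = n_seconds),
                             task_coupling = c(introduction = 1,
                                               self_disclosure = 1.15,
                                               argumentative = 1.3),
                             b_extra_initiative = 0.3,
                             b_agree_yield = 0.2,
                             appraisal_items = default_appraisal_items(),
                             seed = 1L) {
  if (n_dyads < 2) stop("n_dyads must be >= 2", call. = FALSE)
  tasks <- c("introduction", "self_disclosure", "argumentative")
  if (!all(tasks %in% names(task_coupling))) {
    stop("task_coupling must name all three tasks", call. = FALSE)
  }
  structure(
    list(n_dyads = as.integer(n_dyads), n_seconds = as.integer(n_seconds),
         base = base, tasks = tasks, task_coupling = task_coupling,
         b_extra_initiative = b_extra_initiative,
         b_agree_yield = b_agree_yield,
         appraisal_items = appraisal_items, seed = as.integer(seed)),
    class = "study_sim_config"
  )
}

#' Default appraisal-item parameters for the simulated study
#'
#' Four first-person items on the 1-5 scale, with a positive dependence of
#' the social items on Extraversion and on lag-zero speech coordination.
#'
#' @return Named list of item parameter lists.
#' @export
default_appraisal_items <- function() {
  item <- function(mean, b_extra = 0, b_agree = 0, b_rr_los = 0,
                   noise_sd = 0.7) {
    list(mean = mean, b_extra = b_extra, b_agree = b_agree,
         b_rr_los = b_rr_los, noise_sd = noise_sd)
  }
  list(
    need_to_communicate = item(3.4, b_extra = 0.25, b_rr_los = 0.3),
    smooth_natural = item(3.6, b_agree = 0.2, b_rr_los = -0.15),
    enjoyment = item(3.8, b_extra = 0.3, b_rr_los = 0.25),
    future_interaction = item(3.3, b_extra = 0.3, b_rr_los = 0.35)
  )
}

#' Simulate a whole dyadic conversation study
#'
#' Draws standardized traits per participant, simulates every dyad-task
#' series with trait- and task-modulated coupling, computes the coordination
#' measures on the simulated series, and generates appraisal items from those
#' measures.
#'
#' @param cfg a [study_sim_config()].
#' @return A list with `traits` (one row per participant: `participant_id`,
#'   `dyad_id`, `extraversion`, `agreeableness`), `series` (list of
#'   `dyad_series`, one per dyad-task), `measures` (rbind of
#'   [dyad_measures()] rows), and `appraisals` (one row per participant and
#'   item, columns `participant_id`, `dyad_id`, `item`, `score`).
#' @export
simulate_study <- function(cfg = study_sim_config()) {
  stopifnot(inherits(cfg, "study_sim_config"))
  set.seed(cfg$seed)
  n_part <- 2L * cfg$n_dyads
  dyad_ids <- sprintf("d%02d", seq_len(cfg$n_dyads))
  traits <- data.frame(
    participant_id = paste0(rep(dyad_ids, each = 2), c("_a", "_b")),
    dyad_id = rep(dyad_ids, each = 2),
    extraversion = as.numeric(scale(stats::rnorm(n_part))),
    agreeableness = as.numeric(scale(stats::rnorm(n_part))),
    stringsAsFactors = FALSE
  )
  series <- list()
  measures <- vector("list", cfg$n_dyads * length(cfg$tasks))
  idx <- 0L
  for (i in seq_len(cfg$n_dyads)) {
    E <- traits$extraversion[traits$dyad_id == dyad_ids[i]]
    A <- traits$agreeableness[traits$dyad_id == dyad_ids[i]]
    for (task in cfg$tasks) {
      mult <- cfg$task_coupling[[task]]
      dcfg <- cfg$base
      dcfg$n_seconds <- cfg$n_seconds
      dcfg$initiative_gain <- dcfg$initiative_gain * mult *
        exp(cfg$b_extra_initiative * E)
      dcfg$yield_gain <- dcfg$yield_gain * mult *
        exp(cfg$b_agree_yield * A)
      dcfg$seed <- NULL  # one RNG stream from the master seed
      d <- simulate_dyad(dcfg, dyad_id = dyad_ids[i], task = task)
      idx <- idx + 1L
      series[[idx]] <- d
      measures[[idx]] <- dyad_measures(d)
    }
  }
  measures <- do.call(rbind, measures)
  # appraisals consume the computed lag-zero coordination, dyad-averaged
  # across tasks (items are answered once, after the whole conversation)
  rr_dyad <- tapply(measures$rr_los, measures$dyad_id, mean)
  z_rr <- as.numeric(scale(rr_dyad[traits$dyad_id]))
  appraisals <- do.call(rbind, lapply(names(cfg$appraisal_items), function(nm) {
    p <- cfg$appraisal_items[[nm]]
    raw <- p$mean + p$b_extra * traits$extraversion +
      p$b_agree * traits$agreeableness + p$b_rr_los * z_rr +
      stats::rnorm(n_part, sd = p$noise_sd)
    data.frame(participant_id = traits$participant_id,
               dyad_id = traits$dyad_id, item = nm,
               score = pmin(pmax(raw, 1), 5), stringsAsFactors = FALSE)
  }))
  list(traits = traits, series = series, measures = measures,
       appraisals = appraisals)
}
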