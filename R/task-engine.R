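# Monetary incentive delay (MID) task engine: trial scheduling, the adaptive
# response deadline, outcome adjudication, simulated agents, and behavioral
# scoring of the delayed old/new recognition test.

#' Calibrate the rate of a truncated shifted-exponential ITI distribution
#'
#' The inter-trial fixation durations follow an exponential distribution
#' shifted to start at `lo_s` and truncated at `hi_s`. Truncation pulls the
#' mean below `lo_s + 1/rate`, so the raw rate is solved numerically such
#' that the mean of the *truncated* distribution equals `mean_s`.
#'
#' @param mean_s target mean duration (s) after truncation.
#' @param lo_s,hi_s truncation bounds (s).
#' @return the calibrated exponential rate (1/s).
#' @export
iti_rate <- function(mean_s = 5, lo_s = 2, hi_s = 11) {
  if (!(lo_s < mean_s && mean_s < hi_s))
    stop("need lo_s < mean_s < hi_s", call. = FALSE)
  r <- hi_s - lo_s
  m <- mean_s - lo_s
  if (m >= r / 2)
    stop("target mean not reachable by a truncated exponential on these bounds",
         call. = FALSE)
  # mean above lo of Exp(rate) truncated at range r:
  #   1/rate - r * exp(-rate*r) / (1 - exp(-rate*r))
  f <- function(rate) 1 / rate - r * exp(-rate * r) / (1 - exp(-rate * r)) - m
  stats::uniroot(f, c(1e-6, 100), tol = 1e-12)$root
}

#' Draw inter-trial fixation durations
#'
#' Samples from the shifted exponential truncated to `[lo_s, hi_s]`, with the
#' rate calibrated by [iti_rate()] so the sample mean converges to `mean_s`.
#'
#' @param n number of draws.
#' @param mean_s,lo_s,hi_s distribution parameters (s).
#' @return numeric vector of durations in `[lo_s, hi_s]`.
#' @export
sample_iti <- function(n, mean_s = 5, lo_s = 2, hi_s = 11) {
  rate <- iti_rate(mean_s, lo_s, hi_s)
  r <- hi_s - lo_s
  u <- stats::runif(n)
  # inverse CDF of the truncated exponential
  lo_s - log(1 - u * (1 - exp(-rate * r))) / rate
}

#' Generate a randomized MID trial schedule
#'
#' Each run holds equal numbers of reward and neutral trials in randomized
#' order. Target numbers are drawn uniformly from {1, 4, 6, 9}. The two
#' fixation intervals are drawn from the truncated exponential ITI
#' distribution; items are shown for 2 s, the target number for 0.1 s, and
#' the outcome appears after a 1 s blank.
#'
#' @param n_runs number of runs (default 4).
#' @param trials_per_run trials per run, must be even (default 64).
#' @param reward_category which item category ("man-made" or "natural")
#'   signals a possible reward.
#' @param seed integer seed.
#' @param iti_mean_s,iti_lo_s,iti_hi_s ITI distribution parameters.
#' @return data.frame of trial records (pre-response fields), one row per
#'   trial, with 0-based `run_index` and `trial_index`.
#' @export
generate_schedule <- function(n_runs = 4, trials_per_run = 64,
                              reward_category = "man-made", seed = 1,
                              iti_mean_s = 5, iti_lo_s = 2, iti_hi_s = 11) {
  if (trials_per_run %% 2L != 0L)
    stop("`trials_per_run` must be even to balance conditions", call. = FALSE)
  stopifnot(reward_category %in% c("man-made", "natural"))
  neutral_category <- setdiff(c("man-made", "natural"), reward_category)
  with_seed(seed, {
    recs <- vector("list", n_runs)
    item_counter <- 0L
    for (run in seq_len(n_runs) - 1L) {
      condition <- sample(rep(c("reward", "neutral"), trials_per_run / 2L))
      iti1 <- sample_iti(trials_per_run, iti_mean_s, iti_lo_s, iti_hi_s)
      iti2 <- sample_iti(trials_per_run, iti_mean_s, iti_lo_s, iti_hi_s)
      target <- sample(c(1L, 4L, 6L, 9L), trials_per_run, replace = TRUE)
      item_onset <- numeric(trials_per_run)
      number_onset <- numeric(trials_per_run)
      outcome_onset <- numeric(trials_per_run)
      t_cur <- 0
      for (i in seq_len(trials_per_run)) {
        t_cur <- t_cur + iti1[i]
        item_onset[i] <- t_cur
        t_cur <- t_cur + 2            # item presentation, 2 s
        t_cur <- t_cur + iti2[i]
        number_onset[i] <- t_cur
        t_cur <- t_cur + 0.1 + 1.0    # number (0.1 s) + blank (1 s)
        outcome_onset[i] <- t_cur
        t_cur <- t_cur + 0.5          # outcome display
      }
      ids <- item_counter + seq_len(trials_per_run)
      item_counter <- item_counter + trials_per_run
      recs[[run + 1L]] <- data.frame(
        run_index = run,
        trial_index = seq_len(trials_per_run) - 1L,
        condition = condition,
        item_id = ids,
        item_category = ifelse(condition == "reward",
                               reward_category, neutral_category),
        iti1_s = iti1, iti2_s = iti2,
        target_number = target,
        item_onset_s = item_onset,
        number_onset_s = number_onset,
        outcome_onset_s = outcome_onset,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, recs)
  })
}

#' Adaptive response deadline from previous reaction times
#'
#' With no history the initial deadline is returned; otherwise the deadline
#' is the 70th percentile (linear interpolation) of all previous
#' number-classification RTs in the run, so an agent with stationary RTs
#' beats its own deadline on about 70% of trials.
#'
#' @param prior_number_rts_s previous number-classification RTs in this run.
#' @param initial_deadline_s deadline before any history (default 0.6 s).
#' @return deadline in seconds.
#' @export
titrate_deadline <- function(prior_number_rts_s, initial_deadline_s = 0.6) {
  if (length(prior_number_rts_s) == 0L) return(initial_deadline_s)
  if (any(!is.finite(prior_number_rts_s)) || any(prior_number_rts_s <= 0))
    stop("reaction times must be positive", call. = FALSE)
  unname(stats::quantile(prior_number_rts_s, 0.7, type = 7))
}

#' Adjudicate the outcome of a completed MID trial
#'
#' Reward trials earn +2 points only when both the item and the number
#' classification were correct and the number response beat the deadline;
#' any error or slow number response yields -1. Neutral trials always
#' yield 0.
#'
#' @param condition "reward" or "neutral".
#' @param item_correct,number_correct logical response-accuracy flags.
#' @param number_rt_s number-classification RT (s).
#' @param deadline_s deadline in force on this trial (s).
#' @return integer points: +2, -1, or 0.
#' @export
adjudicate_outcome <- function(condition, item_correct, number_correct,
                               number_rt_s, deadline_s) {
  if (is.na(item_correct) || is.na(number_correct) || is.na(number_rt_s))
    stop("trial has missing responses", call. = FALSE)
  if (condition == "neutral") return(0L)
  if (isTRUE(item_correct) && isTRUE(number_correct) &&
      number_rt_s <= deadline_s) 2L else -1L
}

#' Default parameters for a simulated MID participant
#'
#' Accuracy probabilities and lognormal RT parameters per condition, plus a
#' latent encoding-strength model (base level, additive reward boost,
#' Gaussian noise) feeding the recognition-memory simulation.
#'
#' @param p_item_reward,p_item_neutral item-classification accuracy.
#' @param p_number number-classification accuracy (both conditions).
#' @param rt_item_meanlog,rt_item_sdlog lognormal parameters for item RTs
#'   (named per condition where applicable).
#' @param rt_number_meanlog,rt_number_sdlog lognormal parameters for number
#'   RTs.
#' @param encode_base,encode_reward_boost,encode_noise_sd encoding-strength
#'   model (logit scale).
#' @param lure_evidence mean evidence (logit of the false-alarm rate) for
#'   lures at test.
#' @param confidence_slope slope of the monotone evidence-to-confidence map.
#' @return list of class `agent_params`.
#' @export
agent_params <- function(p_item_reward = 0.95, p_item_neutral = 0.93,
                         p_number = 0.95,
                         rt_item_meanlog = c(reward = log(0.75),
                                             neutral = log(0.85)),
                         rt_item_sdlog = 0.25,
                         rt_number_meanlog = log(0.45),
                         rt_number_sdlog = 0.25,
                         encode_base = -0.4, encode_reward_boost = 0.8,
                         encode_noise_sd = 1.0,
                         lure_evidence = -1.4,
                         confidence_slope = 1.0) {
  p <- list(p_item_reward = p_item_reward, p_item_neutral = p_item_neutral,
            p_number = p_number,
            rt_item_meanlog = rt_item_meanlog, rt_item_sdlog = rt_item_sdlog,
            rt_number_meanlog = rt_number_meanlog,
            rt_number_sdlog = rt_number_sdlog,
            encode_base = encode_base,
            encode_reward_boost = encode_reward_boost,
            encode_noise_sd = encode_noise_sd,
            lure_evidence = lure_evidence,
            confidence_slope = confidence_slope)
  probs <- c(p_item_reward, p_item_neutral, p_number)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (rt_item_sdlog < 0 || rt_number_sdlog < 0)
    stop("RT scale parameters must be non-negative")
  class(p) <- "agent_params"
  p
}

#' Simulate a participant playing the MID task
#'
#' Walks the schedule run by run: responses are Bernoulli with per-condition
#' accuracy, RTs are lognormal, the deadline is re-titrated before every
#' trial from the run's previous number RTs, and outcomes are adjudicated.
#' A latent encoding strength (base + reward boost + Gaussian noise) is
#' stored per trial for the memory-test simulation.
#'
#' @param schedule data.frame from [generate_schedule()].
#' @param params an [agent_params()] list.
#' @param seed integer seed.
#' @param initial_deadline_s deadline before any within-run history.
#' @return the schedule with response, deadline, outcome, and
#'   `encoding_strength` columns appended.
#' @export
simulate_agent <- function(schedule, params = agent_params(), seed = 1,
                           initial_deadline_s = 0.6) {
  n <- nrow(schedule)
  with_seed(seed, {
    out <- schedule
    out$item_response_correct <- NA
    out$item_rt_s <- NA_real_
    out$number_response_correct <- NA
    out$number_rt_s <- NA_real_
    out$deadline_s <- NA_real_
    out$outcome_points <- NA_integer_
    out$encoding_strength <- NA_real_
    for (run in unique(out$run_index)) {
      idx <- which(out$run_index == run)
      history <- numeric(0)
      for (i in idx) {
        cond <- out$condition[i]
        p_item <- if (cond == "reward") params$p_item_reward
                  else params$p_item_neutral
        ml_item <- if (length(params$rt_item_meanlog) > 1L)
          params$rt_item_meanlog[[cond]] else params$rt_item_meanlog
        out$item_response_correct[i] <- stats::runif(1) < p_item
        out$item_rt_s[i] <- stats::rlnorm(1, ml_item, params$rt_item_sdlog)
        out$number_response_correct[i] <- stats::runif(1) < params$p_number
        out$number_rt_s[i] <- stats::rlnorm(1, params$rt_number_meanlog,
                                            params$rt_number_sdlog)
        out$deadline_s[i] <- titrate_deadline(history, initial_deadline_s)
        out$outcome_points[i] <- adjudicate_outcome(
          cond, out$item_response_correct[i], out$number_response_correct[i],
          out$number_rt_s[i], out$deadline_s[i])
        out$encoding_strength[i] <- params$encode_base +
          params$encode_reward_boost * (cond == "reward") +
          stats::rnorm(1, 0, params$encode_noise_sd)
        history <- c(history, out$number_rt_s[i])
      }
    }
    out
  })
}

#' Simulate the delayed old/new recognition test
#'
#' Old items are called "old" with probability `plogis(encoding strength)`;
#' lures carry a weaker evidence level set by the agent's lure-evidence
#' parameter. Confidence is a bounded monotone map of the absolute evidence
#' into [0, 100].
#'
#' @param encoding_records output of [simulate_agent()].
#' @param n_lures number of new items mixed in (default half the old items).
#' @param params an [agent_params()] list.
#' @param seed integer seed.
#' @return data.frame of memory trials: `item_id`, `truth` (old/new),
#'   `response`, `confidence`, `encoding_condition`, `encoding_item_correct`.
#' @export
simulate_memory_test <- function(encoding_records, n_lures = NULL,
                                 params = agent_params(), seed = 1) {
  n_old <- nrow(encoding_records)
  if (is.null(n_lures)) n_lures <- n_old %/% 2L
  if (n_lures <= 0L) stop("`n_lures` must be positive", call. = FALSE)
  with_seed(seed, {
    ev_old <- encoding_records$encoding_strength
    ev_lure <- stats::rnorm(n_lures, params$lure_evidence,
                            params$encode_noise_sd)
    evidence <- c(ev_old, ev_lure)
    resp_old <- stats::runif(n_old + n_lures) < stats::plogis(evidence)
    confidence <- 100 * (2 * stats::plogis(params$confidence_slope *
                                           abs(evidence)) - 1)
    trials <- data.frame(
      item_id = c(encoding_records$item_id,
                  max(encoding_records$item_id) + seq_len(n_lures)),
      truth = rep(c("old", "new"), c(n_old, n_lures)),
      response = ifelse(resp_old, "old", "new"),
      confidence = confidence,
      encoding_condition = c(encoding_records$condition,
                             rep("none", n_lures)),
      encoding_item_correct = c(encoding_records$item_response_correct,
                                rep(NA, n_lures)),
      stringsAsFactors = FALSE
    )
    trials[sample.int(nrow(trials)), , drop = FALSE]
  })
}

#' Signal-detection scoring of recognition-memory trials
#'
#' Old items are classified as hits or misses, lures as false alarms or
#' correct rejections; recognition is the hit rate minus the false-alarm
#' rate. Optionally restricts old items to one encoding condition (lures,
#' which have no condition, are always kept) and/or to high-confidence
#' responses (confidence strictly greater than 66 of 100). Old items whose
#' encoding item classification was incorrect are excluded from
#' condition-restricted scoring.
#'
#' @param memory_trials data.frame from [simulate_memory_test()] (or with
#'   the same columns).
#' @param restrict_to_condition optional "reward" or "neutral".
#' @param restrict_high_confidence keep only trials with confidence > 66.
#' @return list of class `sdt_summary` with counts, `p_hit`, `p_fa`, and
#'   `recognition`.
#' @export
score_sdt <- function(memory_trials, restrict_to_condition = NULL,
                      restrict_high_confidence = FALSE) {
  tr <- memory_trials
  if (restrict_high_confidence) tr <- tr[tr$confidence > 66, , drop = FALSE]
  old <- tr[tr$truth == "old", , drop = FALSE]
  new <- tr[tr$truth == "new", , drop = FALSE]
  if (!is.null(restrict_to_condition)) {
    keep <- old$encoding_condition == restrict_to_condition &
      !isFALSE_na(old$encoding_item_correct)
    old <- old[keep, , drop = FALSE]
  }
  if (nrow(old) == 0L) stop("no old items left after filtering", call. = FALSE)
  if (nrow(new) == 0L) stop("no lures left after filtering", call. = FALSE)
  n_hits <- sum(old$response == "old")
  n_misses <- sum(old$response == "new")
  n_fa <- sum(new$response == "old")
  n_cr <- sum(new$response == "new")
  out <- list(n_hits = n_hits, n_misses = n_misses, n_fa = n_fa, n_cr = n_cr,
              p_hit = n_hits / nrow(old), p_fa = n_fa / nrow(new))
  out$recognition <- out$p_hit - out$p_fa
  class(out) <- "sdt_summary"
  out
}

# TRUE where x is FALSE or NA (missing encoding accuracy excludes a trial)
isFALSE_na <- function(x) is.na(x) | !x

#' Flag participants more than 3 SD from their condition mean
#'
#' The mean and SD are computed over all participants within each condition;
#' a participant is flagged when the absolute deviation strictly exceeds
#' 3 SD. With zero variance nothing is flagged (a warning is issued if any
#' value deviates at all, which cannot happen with a true zero-variance
#' set but guards degenerate input).
#'
#' @param values numeric scores, one per participant-condition cell.
#' @param participant participant ids aligned with `values`.
#' @param condition condition labels aligned with `values`.
#' @return character vector of flagged participant ids (unique).
#' @export
detect_outliers <- function(values, participant, condition) {
  stopifnot(length(values) == length(participant),
            length(values) == length(condition))
  if (length(unique(participant)) < 3L)
    stop("need at least 3 participants", call. = FALSE)
  flagged <- character(0)
  for (cond in unique(condition)) {
    v <- values[condition == cond]
    p <- participant[condition == cond]
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      if (any(v != m)) warning("zero variance with deviations; flagging nothing")
      next
    }
    flagged <- c(flagged, as.character(p[abs(v - m) > 3 * s]))
  }
  unique(flagged)
}

#' Per-condition behavioral summaries and paired t-tests
#'
#' Computes per-participant condition means for each measure (item accuracy,
#' item RT, number accuracy, number RT), group means and SDs, and a
#' two-sided paired t-test of reward vs neutral per measure. A
#' zero-variance set of paired differences is reported as degenerate with
#' `p = NA`.
#'
#' @param records completed trial records with a `participant` column.
#' @return list with `per_participant` (long data.frame) and `tests`
#'   (one row per measure).
#' @export
summarize_behavior <- function(records) {
  if (length(unique(records$participant)) < 2L)
    stop("need at least 2 participants", call. = FALSE)
  measures <- list(
    item_accuracy = function(d) mean(d$item_response_correct),
    item_rt_s = function(d) mean(d$item_rt_s),
    number_accuracy = function(d) mean(d$number_response_correct),
    number_rt_s = function(d) mean(d$number_rt_s)
  )
  cells <- expand.grid(participant = unique(records$participant),
                       condition = c("reward", "neutral"),
                       stringsAsFactors = FALSE)
  per <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- records[records$participant == cells$participant[i] &
                 records$condition == cells$condition[i], , drop = FALSE]
    if (nrow(d) == 0L)
      stop(sprintf("participant %s lacks %s trials", cells$participant[i],
                   cells$condition[i]), call. = FALSE)
    vals <- vapply(measures, function(f) f(d), numeric(1))
    data.frame(participant = cells$participant[i],
               condition = cells$condition[i],
               measure = names(measures), value = unname(vals),
               stringsAsFactors = FALSE)
  }))
  tests <- do.call(rbind, lapply(names(measures), function(m) {
    w <- stats::reshape(per[per$measure == m, c("participant", "condition",
                                                "value")],
                        idvar = "participant", timevar = "condition",
                        direction = "wide")
    diffs <- w$value.reward - w$value.neutral
    if (stats::sd(diffs) == 0) {
      data.frame(measure = m, mean_reward = mean(w$value.reward),
                 mean_neutral = mean(w$value.neutral),
                 t = if (all(diffs == 0)) 0 else NA_real_,
                 p = NA_real_, degenerate = TRUE)
    } else {
      tt <- stats::t.test(w$value.reward, w$value.neutral, paired = TRUE)
      data.frame(measure = m, mean_reward = mean(w$value.reward),
                 mean_neutral = mean(w$value.neutral),
                 t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
    }
  }))
  list(per_participant = per, tests = tests)
}

#' Drop runs with more than 50% incorrectly classified items
#'
#' @param records completed trial records for one participant.
#' @return list with `kept` (filtered records) and `dropped_runs`.
#' @export
exclude_bad_runs <- function(records) {
  dropped <- integer(0)
  for (run in unique(records$run_index)) {
    d <- records[records$run_index == run, , drop = FALSE]
    if (mean(!d$item_response_correct) > 0.5) dropped <- c(dropped, run)
  }
  list(kept = records[!records$run_index %in% dropped, , drop = FALSE],
       dropped_runs = dropped)
}
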