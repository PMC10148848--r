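# The five dependent measures of the patch depletion task, with the
# standard exclusion rules: a session's first patch (the rat has not yet
# experienced the COD) and final patch (truncated by session termination),
# together with their associated patch changes, are excluded; per-rat
# values average the last two cycles of the protocol, with each week's
# first 0-s session dropped.

#' Segment a session log into patch visits
#'
#' Partitions a session's reward events into patch visits (entry ->
#' rewards -> leave or session end). Each visit records its start (first
#' reward), end (the leave poke, or session end for the final visit), the
#' number and volumes of rewards collected, and the rejection volume — the
#' volume scheduled next at the moment of leaving, i.e.
#' `reward_volume(n_rewards + 1)`. The first and final visits are flagged
#' `complete = FALSE` and are excluded from the dependent measures.
#'
#' @param log A `session_log`.
#' @param config The [task_config()] that produced the log.
#' @return Data frame with one row per visit: `visit_index`, `patch_side`,
#'   `start_time`, `end_time`, `n_rewards`, `total_volume`,
#'   `rejection_volume`, `complete`.
#' @export
extract_patch_visits <- function(log, config = task_config()) {
  validate_session_log(log, config)
  ev <- log$events
  # visit id increments at each patch_entry
  visit_id <- cumsum(ev$event_type == "patch_entry")
  if (any(visit_id == 0 & ev$event_type == "reward"))
    stop("malformed log: reward before any patch entry")
  n_visits <- max(visit_id)
  rows <- lapply(seq_len(n_visits), function(v) {
    sub <- ev[visit_id == v, , drop = FALSE]
    rw <- sub[sub$event_type == "reward", , drop = FALSE]
    lv <- sub[sub$event_type == "leave", , drop = FALSE]
    end_time <- if (nrow(lv)) lv$time_s[1] else max(sub$time_s)
    data.frame(
      visit_index = v,
      patch_side = sub$patch_side[1],
      start_time = if (nrow(rw)) rw$time_s[1] else sub$time_s[1],
      end_time = end_time,
      n_rewards = nrow(rw),
      total_volume = sum(rw$volume_ul),
      rejection_volume = reward_volume(nrow(rw) + 1L, config),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$complete <- rep(TRUE, n_visits)
  out$complete[c(1L, n_visits)] <- FALSE
  out
}

#' Per-session dependent measures
#'
#' Computes one session's values of the task's dependent measures from its
#' event log:
#' * `pc` — patch changes: leaves terminating complete (included) visits;
#' * `tip_s` — time in patch: mean visit duration over complete visits;
#' * `rejection_ul` — mean rejection volume (the task's indifference
#'   point) over complete visits;
#' * `wr_ul_min_kg` — water rate: total volume earned divided by the
#'   elapsed time from session start to the final reward (minutes),
#'   divided by body weight (kg).
#'
#' Sessions with no complete visit yield `NA` for `pc`, `tip_s` and
#' `rejection_ul` (missing, never zero); a session whose rewards all fall
#' at a single instant (possible at COD 0 under idealised timing) yields
#' `NA` water rate.
#'
#' @param log A `session_log`.
#' @param body_weight Body weight in kg.
#' @param config The [task_config()] that produced the log.
#' @return One-row data frame: `session_index`, `cod_s`, `pc`, `tip_s`,
#'   `rejection_ul`, `wr_ul_min_kg`, `n_complete`.
#' @export
session_metrics <- function(log, body_weight, config = task_config()) {
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be > 0")
  visits <- extract_patch_visits(log, config)
  cv <- visits[visits$complete, , drop = FALSE]
  rw <- log$events[log$events$event_type == "reward", , drop = FALSE]
  elapsed_min <- (max(rw$time_s) - log$events$time_s[1]) / 60
  wr <- if (elapsed_min > 0)
    sum(rw$volume_ul) / elapsed_min / body_weight else NA_real_
  data.frame(
    session_index = log$session_index,
    cod_s = log$cod,
    pc = if (nrow(cv)) nrow(cv) else NA_integer_,
    tip_s = if (nrow(cv)) mean(cv$end_time - cv$start_time) else NA_real_,
    rejection_ul = if (nrow(cv)) mean(cv$rejection_volume) else NA_real_,
    wr_ul_min_kg = wr,
    n_complete = nrow(cv)
  )
}

#' Percent deviation from the optimal rejection volume
#'
#' `(optimal - observed) / optimal * 100`. Positive values indicate
#' overharvesting (the animal stayed past the optimal leave point, letting
#' the patch deplete below the rate-maximising volume); negative values
#' indicate leaving while the patch was still above the optimal volume.
#'
#' @param observed Observed mean rejection volume (uL); vectorised.
#' @param optimal MVT-optimal rejection volume (uL), > 0.
#' @return Percent deviation(s).
#' @export
percent_volume_deviation <- function(observed, optimal) {
  if (any(!is.finite(optimal) | optimal <= 0))
    stop("optimal rejection volume must be > 0")
  (optimal - observed) / optimal * 100
}

#' Percent deviation from the optimal time in patch
#'
#' `(observed - optimal) / optimal * 100`. Positive values indicate
#' staying longer than optimal. Where the optimal time in patch is zero
#' (COD 0 under the leave-after-one-reward optimum) the deviation is
#' undefined and returned as `NA`, never infinite.
#'
#' @param observed Observed mean time in patch (s); vectorised.
#' @param optimal MVT-optimal time in patch (s).
#' @return Percent deviation(s), `NA` where `optimal <= 0`.
#' @export
percent_time_deviation <- function(observed, optimal) {
  out <- ifelse(optimal > 0, (observed - optimal) / optimal * 100, NA_real_)
  out
}

# Sessions of the protocol retained for analysis: the last two cycles,
# minus each week's first session. Returns protocol session indices.
included_session_indices <- function(config) {
  week_len <- length(config$weekly_cod_sequence)
  n <- config$n_cycles
  last_two <- if (n >= 2) c(n - 1, n) else n
  idx <- unlist(lapply(last_two, function(cy) {
    (cy - 1) * week_len + seq_len(week_len)
  }))
  # drop each retained week's first session
  drop <- (last_two - 1) * week_len + 1
  as.integer(setdiff(idx, drop))
}

#' Aggregate one rat's protocol into per-COD dependent measures
#'
#' Applies the protocol's analysis rules to a rat's full set of session
#' logs: sessions from the last two cycles are retained, each week's first
#' session is excluded, and per-session measures are averaged within each
#' changeover delay. Deviation-from-optimality measures (`vd_pct`,
#' `td_pct`) are computed against the MVT [optimal_curves()].
#'
#' @param logs List of `session_log`s covering the full protocol, in
#'   session order.
#' @param rat The [rat_record()] the logs belong to.
#' @param config A [task_config()].
#' @return Data frame, one row per COD in `config$cod_set`: `rat_id`,
#'   `sex`, `cod_s`, `pc`, `tip_s`, `rejection_ul`, `wr_ul_min_kg`,
#'   `vd_pct`, `td_pct`, `n_sessions` (sessions contributing non-missing
#'   values).
#' @export
aggregate_rat <- function(logs, rat, config = task_config()) {
  validate_task_config(config)
  stopifnot(inherits(rat, "rat_record"))
  cods <- rep(config$weekly_cod_sequence, times = config$n_cycles)
  if (length(logs) != length(cods)) {
    have <- vapply(logs, function(l) l$session_index, integer(1))
    missing_idx <- setdiff(seq_along(cods), have)
    week_len <- length(config$weekly_cod_sequence)
    miss <- sprintf("(cycle %d, COD %g)",
                    (missing_idx - 1) %/% week_len + 1, cods[missing_idx])
    stop("incomplete protocol; missing sessions: ",
         paste(miss, collapse = ", "))
  }
  per_session <- do.call(rbind, lapply(logs, function(l)
    session_metrics(l, rat$body_weight, config)))
  keep <- included_session_indices(config)
  ps <- per_session[per_session$session_index %in% keep, , drop = FALSE]

  opt <- optimal_curves(config)
  rows <- lapply(config$cod_set, function(cd) {
    sub <- ps[ps$cod_s == cd, , drop = FALSE]
    mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    o <- opt[opt$cod == cd, ]
    rej <- mean_or_na(sub$rejection_ul)
    tip <- mean_or_na(sub$tip_s)
    data.frame(
      rat_id = rat$rat_id, sex = rat$sex, cod_s = cd,
      pc = mean_or_na(sub$pc),
      tip_s = tip,
      rejection_ul = rej,
      wr_ul_min_kg = mean_or_na(sub$wr_ul_min_kg),
      vd_pct = if (is.na(rej)) NA_real_ else
        percent_volume_deviation(rej, o$optimal_rejection_volume),
      td_pct = if (is.na(tip)) NA_real_ else
        percent_time_deviation(tip, o$optimal_time_in_patch),
      n_sessions = sum(stats::complete.cases(
        sub[, c("pc", "tip_s", "rejection_ul")])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify rats as over-, under-, or optimally harvesting
#'
#' Labels each rat x COD cell by the sign of the percent volume deviation:
#' `"over"` for positive (stayed too long), `"under"` for negative (left
#' too early), `"optimal"` where |VD| falls below `tol` (deviations of
#' deterministic simulations are zero up to floating-point error; noisy
#' cohorts effectively classify by exact sign). Also returns per-COD,
#' per-sex percentage frequency distributions.
#'
#' @param metrics Per-rat x per-COD metrics table ([aggregate_rat()] rows,
#'   possibly concatenated across rats).
#' @param tol Absolute VD tolerance treated as optimal.
#' @return List with `labels` (metrics rows plus `harvest` factor) and
#'   `frequencies` (per sex x COD percentages of over/under/optimal).
#' @export
harvest_classification <- function(metrics, tol = 1e-9) {
  stopifnot(all(c("rat_id", "sex", "cod_s", "vd_pct") %in% names(metrics)))
  lab <- ifelse(is.na(metrics$vd_pct), NA_character_,
         ifelse(abs(metrics$vd_pct) < tol, "optimal",
         ifelse(metrics$vd_pct > 0, "over", "under")))
  labels <- metrics
  labels$harvest <- factor(lab, levels = c("over", "under", "optimal"))
  cells <- expand.grid(sex = unique(metrics$sex),
                       cod_s = sort(unique(metrics$cod_s)),
                       stringsAsFactors = FALSE)
  freq <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- labels[labels$sex == cells$sex[i] & labels$cod_s == cells$cod_s[i] &
                    !is.na(labels$harvest), , drop = FALSE]
    tab <- table(sub$harvest)
    n <- sum(tab)
    data.frame(sex = cells$sex[i], cod_s = cells$cod_s[i], n = n,
               pct_over = if (n) 100 * tab[["over"]] / n else NA_real_,
               pct_under = if (n) 100 * tab[["under"]] / n else NA_real_,
               pct_optimal = if (n) 100 * tab[["optimal"]] / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(labels = labels, frequencies = freq)
}
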