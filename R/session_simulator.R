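# Discrete-event simulation of the sequential patch depletion task.
#
# Timing abstraction: the agent claims every reward at the earliest
# permitted instant. The session's first patch entry occurs at t = 0 with
# the immediate full reward and no changeover delay; within a patch,
# successive rewards are separated by exactly the fixed inter-reward
# interval; a leave poke is coincident with the last reward consumed, and
# the first reward of the next patch follows after exactly the COD. Event
# times are therefore non-decreasing, with (time, event_index) strictly
# increasing.

# Deterministic sub-seed for (master seed, index), kept within 32-bit range.
derive_seed <- function(master, index) {
  ((master %% 1000003) * 48271 + index * 16807) %% 2147483629 + 1
}

new_session_log <- function(rat_id, sex, session_index, cod, events,
                            termination_reason) {
  structure(list(rat_id = rat_id, sex = sex,
                 session_index = as.integer(session_index),
                 cod = as.numeric(cod), events = events,
                 termination_reason = termination_reason),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  nr <- sum(x$events$event_type == "reward")
  cat(sprintf(
    "session_log: rat %s (%s), session %d, COD %g s: %d rewards, %d leaves, %.1f uL, ended by %s\n",
    x$rat_id, x$sex, x$session_index, x$cod, nr,
    sum(x$events$event_type == "leave"),
    sum(x$events$volume_ul, na.rm = TRUE), x$termination_reason))
  invisible(x)
}

#' Simulate one session of the patch depletion task
#'
#' Runs a single session for one agent at a fixed changeover delay,
#' producing the ordered event log (patch entries, rewards, leaves, session
#' end). The task contingencies are exact: geometric within-patch
#' depletion, fixed inter-reward interval, replenishment of an abandoned
#' patch, COD travel time before the first reward of a new patch, and
#' termination at the session duration cap or once cumulative earnings
#' reach the volume cap (the crossing reward is delivered, then the
#' session ends).
#'
#' @param rat A [rat_record()].
#' @param cod Changeover delay for this session (s).
#' @param config A [task_config()].
#' @param seed Integer seed for the decision noise stream; the log is
#'   bit-identical for identical seeds. `NULL` uses the current RNG state.
#' @param session_index Session number recorded in the log (1..24 in a full
#'   protocol).
#' @return A `session_log`: rat/session identifiers plus an `events` data
#'   frame with columns `event_index`, `time_s`, `event_type`
#'   (`patch_entry`, `reward`, `leave`, `session_end`), `patch_side`
#'   (`left`/`back`), `volume_ul` (rewards only), and a
#'   `termination_reason` (`time_cap` or `volume_cap`).
#' @examples
#' rat <- rat_record("r1", "male", 0.4, agent_policy("mvt_optimal"))
#' simulate_session(rat, cod = 6, seed = 1)
#' @export
simulate_session <- function(rat, cod, config = task_config(), seed = NULL,
                             session_index = 1L) {
  stopifnot(inherits(rat, "rat_record"))
  validate_task_config(config)
  if (!is.finite(cod) || cod < 0) stop("cod must be finite and >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))

  policy <- rat$policy
  if (policy$kind == "mvt_optimal") {
    n_star <- solve_optimal_policy(cod, config)$n_star
    thr <- reward_volume(n_star + 1, config)
  } else {
    n_star <- NA_integer_
    thr <- policy_leave_threshold(policy, cod, config)
  }

  iri <- config$inter_reward_interval
  t_cap <- config$session_duration_cap
  v_cap <- config$session_volume_cap

  # pre-allocated event buffers
  cap_n <- 4L * (ceiling(t_cap / iri) + ceiling(v_cap / reward_volume(1, config)) + 8L)
  ev_time <- numeric(cap_n); ev_type <- character(cap_n)
  ev_side <- character(cap_n); ev_vol <- rep(NA_real_, cap_n)
  n_ev <- 0L
  push <- function(time, type, side, vol = NA_real_) {
    n_ev <<- n_ev + 1L
    ev_time[n_ev] <<- time; ev_type[n_ev] <<- type
    ev_side[n_ev] <<- side; ev_vol[n_ev] <<- vol
  }

  side <- "left"
  t <- 0; cum <- 0; n_in_patch <- 0L
  termination <- NULL
  push(0, "patch_entry", side)
  repeat {
    # deliver the scheduled reward at time t
    n_in_patch <- n_in_patch + 1L
    vol <- reward_volume(n_in_patch, config)
    cum <- cum + vol
    push(t, "reward", side, vol)
    if (cum >= v_cap) { termination <- "volume_cap"; break }

    next_vol <- reward_volume(n_in_patch + 1L, config)
    leave <- decide_core(policy, next_vol, n_in_patch, thr, n_star)
    if (leave) {
      push(t, "leave", side)
      side <- if (side == "left") "back" else "left"
      t_next <- t + cod
      if (t_next > t_cap) { termination <- "time_cap"; break }
      push(t_next, "patch_entry", side)
      t <- t_next
      n_in_patch <- 0L
    } else {
      t_next <- t + iri
      if (t_next > t_cap) { termination <- "time_cap"; break }
      t <- t_next
    }
  }
  end_time <- if (termination == "time_cap") t_cap else t
  push(end_time, "session_end", side)

  events <- data.frame(
    event_index = seq_len(n_ev),
    time_s = ev_time[seq_len(n_ev)],
    event_type = ev_type[seq_len(n_ev)],
    patch_side = ev_side[seq_len(n_ev)],
    volume_ul = ev_vol[seq_len(n_ev)],
    stringsAsFactors = FALSE
  )
  new_session_log(rat$rat_id, rat$sex, session_index, cod, events,
                  termination)
}

#' Simulate a full 24-session protocol
#'
#' Runs the weekly COD sequence (`config$weekly_cod_sequence`) repeated
#' `config$n_cycles` times for one agent. Per-session seeds are derived
#' deterministically from the protocol seed and the session index, so any
#' session can be reproduced in isolation and logs do not depend on
#' execution order or on the rat's identifier.
#'
#' @param rat A [rat_record()].
#' @param config A [task_config()].
#' @param seed Integer protocol seed.
#' @return List of `session_log`s, one per session, in protocol order.
#' @export
simulate_protocol <- function(rat, config = task_config(), seed = 1L) {
  validate_task_config(config)
  cods <- rep(config$weekly_cod_sequence, times = config$n_cycles)
  lapply(seq_along(cods), function(i) {
    simulate_session(rat, cods[i], config,
                     seed = derive_seed(seed, i), session_index = i)
  })
}

# Validates the structural invariants of a session log; stops with an
# informative message on violation. Returns the log invisibly.
validate_session_log <- function(log, config = task_config()) {
  stopifnot(inherits(log, "session_log"))
  ev <- log$events
  need <- c("event_index", "time_s", "event_type", "patch_side", "volume_ul")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("event log missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(ev) == 0) stop("empty event log")
  if (any(diff(ev$time_s) < 0)) {
    bad <- which(diff(ev$time_s) < 0)[1] + 1
    stop(sprintf("non-monotone event times at row %d", bad))
  }
  if (any(diff(ev$event_index) <= 0)) stop("event_index must strictly increase")
  if (!all(ev$event_type %in% c("patch_entry", "reward", "leave", "session_end")))
    stop("unknown event_type in log")
  rw <- ev[ev$event_type == "reward", , drop = FALSE]
  if (any(!is.finite(rw$volume_ul) | rw$volume_ul <= 0))
    stop("reward events must carry positive volumes")
  if (utils::tail(ev$event_type, 1) != "session_end")
    stop("log must end with a session_end event")
  if (!log$termination_reason %in% c("time_cap", "volume_cap"))
    stop("invalid termination_reason")
  cum <- sum(rw$volume_ul)
  if (nrow(rw) > 0 && cum - utils::tail(rw$volume_ul, 1) >= config$session_volume_cap)
    stop("volume cap exceeded before the final reward")
  if (max(ev$time_s) > config$session_duration_cap)
    stop("event beyond the session duration cap")
  invisible(log)
}
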