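#' Task configuration for the sequential patch depletion procedure
#'
#' Bundles every constant of the operant patch-depletion task: a patch's
#' first reward volume, the geometric per-reward depletion factor, the
#' fixed-interval spacing between successive rewards within a patch, the set
#' of changeover delays (CODs, the "travel cost" imposed after switching
#' patches), the session caps, and the weekly COD schedule of the
#' 24-session protocol.
#'
#' Defaults encode the standard procedure: patches start at 150 uL and each
#' successive "stay" reward is reduced by 20%; rewards within a patch are
#' separated by a 4-s fixed interval; CODs of 0, 6, 12, 18, and 24 s are
#' tested; a session ends after 10 min or once 5 mL has been earned,
#' whichever comes first; each test week runs the CODs in the order
#' 0, 0, 6, 12, 18, 24 s and the 6-day week repeats for 4 cycles
#' (24 sessions).
#'
#' @param initial_volume First reward volume in a fresh patch (uL).
#' @param depletion_factor Multiplier applied to the reward volume for each
#'   successive reward within a patch; must lie strictly in (0, 1).
#' @param inter_reward_interval Seconds between successive rewards in a
#'   patch (the fixed-interval requirement).
#' @param cod_set Ordered vector of changeover delays (s) under study.
#' @param session_duration_cap Maximum session length (s).
#' @param session_volume_cap Cumulative earned volume (uL) that terminates a
#'   session.
#' @param weekly_cod_sequence CODs, in order, of one test week. The first
#'   session of each week is excluded from analysis downstream.
#' @param n_cycles Number of times the weekly sequence is repeated.
#'
#' @return An object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' reward_volume(1:3, cfg)   # 150 120 96
#' @export
task_config <- function(initial_volume = 150,
                        depletion_factor = 0.8,
                        inter_reward_interval = 4,
                        cod_set = c(0, 6, 12, 18, 24),
                        session_duration_cap = 600,
                        session_volume_cap = 5000,
                        weekly_cod_sequence = c(0, 0, 6, 12, 18, 24),
                        n_cycles = 4) {
  cfg <- list(
    initial_volume = as.numeric(initial_volume),
    depletion_factor = as.numeric(depletion_factor),
    inter_reward_interval = as.numeric(inter_reward_interval),
    cod_set = as.numeric(cod_set),
    session_duration_cap = as.numeric(session_duration_cap),
    session_volume_cap = as.numeric(session_volume_cap),
    weekly_cod_sequence = as.numeric(weekly_cod_sequence),
    n_cycles = as.integer(n_cycles)
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (!(cfg$initial_volume > 0)) stop("initial_volume must be > 0")
  if (!(cfg$depletion_factor > 0 && cfg$depletion_factor < 1))
    stop("depletion_factor must lie strictly in (0, 1)")
  if (!(cfg$inter_reward_interval > 0))
    stop("inter_reward_interval must be > 0")
  if (any(cfg$cod_set < 0)) stop("all CODs must be >= 0")
  if (!(cfg$session_duration_cap > 0 && cfg$session_volume_cap > 0))
    stop("session caps must be > 0")
  if (any(is.na(cfg$weekly_cod_sequence)))
    stop("weekly_cod_sequence must not contain NA")
  if (!all(cfg$weekly_cod_sequence %in% cfg$cod_set))
    stop("weekly_cod_sequence must draw from cod_set")
  if (cfg$n_cycles < 1) stop("n_cycles must be >= 1")
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Sequential patch depletion task configuration\n")
  cat(sprintf("  initial volume        : %g uL\n", x$initial_volume))
  cat(sprintf("  depletion factor      : %g per reward\n", x$depletion_factor))
  cat(sprintf("  inter-reward interval : %g s\n", x$inter_reward_interval))
  cat(sprintf("  COD set               : %s s\n",
              paste(x$cod_set, collapse = ", ")))
  cat(sprintf("  session caps          : %g s / %g uL\n",
              x$session_duration_cap, x$session_volume_cap))
  cat(sprintf("  weekly COD sequence   : %s (x %d cycles)\n",
              paste(x$weekly_cod_sequence, collapse = ", "), x$n_cycles))
  invisible(x)
}

#' Scheduled reward volume for the n-th reward in a patch
#'
#' The patch depletes geometrically: the n-th successive reward is
#' `initial_volume * depletion_factor^(n - 1)`. With the defaults the first
#' three rewards are 150, 120, and 96 uL.
#'
#' @param n Reward index within a patch visit (integer-valued, >= 1);
#'   vectorised.
#' @param config A [task_config()].
#' @return Reward volume(s) in uL.
#' @export
reward_volume <- function(n, config = task_config()) {
  validate_task_config(config)
  if (length(n) == 0 || any(!is.finite(n)) || any(n < 1) ||
      any(n != as.integer(n)))
    stop("n must be integer-valued and >= 1")
  config$initial_volume * config$depletion_factor^(n - 1)
}

#' Cumulative rate of return from a patch
#'
#' The average reward rate (uL/s) obtained by collecting `n` rewards from a
#' patch and then leaving, with the changeover delay counted as travel time
#' preceding the first reward: total volume of the first `n` rewards divided
#' by `cod + inter_reward_interval * (n - 1)`. Under the Marginal Value
#' Theorem the optimal stay count maximises this quantity.
#'
#' At `cod = 0` the rate for `n = 1` is `+Inf` (the vanishing-travel-time
#' limit, under which leaving after every reward is optimal).
#'
#' @param n Number of rewards collected (integer-valued, >= 1); vectorised.
#' @param cod Changeover delay in seconds (>= 0).
#' @param config A [task_config()].
#' @return Rate(s) in uL/s.
#' @examples
#' cfg <- task_config()
#' cumulative_rate(1:3, cod = 6, cfg)  # 25, 27, 26.142857...
#' @export
cumulative_rate <- function(n, cod, config = task_config()) {
  validate_task_config(config)
  if (length(n) == 0 || any(!is.finite(n)) || any(n < 1) ||
      any(n != as.integer(n)))
    stop("n must be integer-valued and >= 1")
  if (!is.finite(cod) || cod < 0) stop("cod must be finite and >= 0")
  f <- config$depletion_factor
  total <- config$initial_volume * (1 - f^n) / (1 - f)
  total / (cod + config$inter_reward_interval * (n - 1))
}

#' Marginal Value Theorem optimal policy at one changeover delay
#'
#' Finds the stay count `n_star` maximising [cumulative_rate()] over
#' `n = 1..n_max` (ties broken toward smaller `n`, i.e. leaving earlier).
#' The optimal rejection volume is the volume scheduled next at the optimal
#' leave point, `reward_volume(n_star + 1)`; the optimal time in patch is
#' `inter_reward_interval * (n_star - 1)`, the span from the first reward of
#' a patch to the earliest leave opportunity (the same timing convention as
#' the rate's denominator, in which the COD precedes the first reward).
#'
#' @param cod Changeover delay in seconds (>= 0).
#' @param config A [task_config()].
#' @param n_max Upper bound of the stay-count search. Volumes decay
#'   geometrically, so the default 100 is far past any maximiser of the
#'   default schedule.
#' @return A one-row data frame of class `optimal_policy` with columns
#'   `cod`, `n_star`, `optimal_rejection_volume`, `optimal_time_in_patch`,
#'   and `max_rate`.
#' @examples
#' solve_optimal_policy(6)   # n_star = 2, rejection volume 96 uL
#' @export
solve_optimal_policy <- function(cod, config = task_config(), n_max = 100L) {
  validate_task_config(config)
  if (!is.finite(cod) || cod < 0) stop("cod must be finite and >= 0")
  rates <- cumulative_rate(seq_len(n_max), cod, config)
  n_star <- which.max(rates)  # which.max returns the first (smallest) argmax
  out <- data.frame(
    cod = cod,
    n_star = as.integer(n_star),
    optimal_rejection_volume = reward_volume(n_star + 1, config),
    optimal_time_in_patch = config$inter_reward_interval * (n_star - 1),
    max_rate = rates[n_star]
  )
  class(out) <- c("optimal_policy", "data.frame")
  out
}

#' Optimal-policy table across the configured COD set
#'
#' Solves the Marginal Value Theorem policy at every changeover delay in
#' `config$cod_set`, giving the optimal rejection-volume and time-in-patch
#' curves against which observed behaviour is scored.
#'
#' @inheritParams solve_optimal_policy
#' @return A data frame of class `optimal_policy`, one row per COD.
#' @export
optimal_curves <- function(config = task_config(), n_max = 100L) {
  validate_task_config(config)
  out <- do.call(rbind, lapply(config$cod_set, solve_optimal_policy,
                               config = config, n_max = n_max))
  rownames(out) <- NULL
  class(out) <- c("optimal_policy", "data.frame")
  out
}
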