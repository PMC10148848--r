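#' Agent decision policy
#'
#' Constructs the decision rule of a simulated forager. Three kinds are
#' supported:
#'
#' * `"mvt_optimal"` — leaves a patch exactly when the number of rewards
#'   collected reaches the Marginal Value Theorem optimum for the session's
#'   changeover delay (see [solve_optimal_policy()]).
#' * `"volume_threshold"` — leaves as soon as the next scheduled reward
#'   volume falls strictly below a fixed threshold (uL).
#' * `"hyperbolic_discounter"` — values the alternative patch's full reward
#'   `A` hyperbolically discounted by the travel delay, `b * A / (1 + k * cod)`,
#'   and leaves as soon as the next scheduled volume falls strictly below
#'   that discounted value. This is the generative counterpart of the
#'   hyperbolic indifference-point model fitted by [fit_hyperbolic()].
#'
#' Decision noise: with `choice_noise > 0` the deterministic volume
#' comparison is replaced by a logistic (softmax) choice in the value
#' difference, `P(leave) = plogis((threshold - next_volume) / choice_noise)`,
#' with `choice_noise` in uL. Independently, `lapse` flips the outcome of
#' each decision with the stated probability.
#'
#' @param kind One of `"mvt_optimal"`, `"volume_threshold"`,
#'   `"hyperbolic_discounter"`.
#' @param k Hyperbolic discount rate per second (>= 0);
#'   `hyperbolic_discounter` only.
#' @param b Bias in (0, 1]: the fraction of the alternative patch's full
#'   volume the agent would accept at zero delay; `hyperbolic_discounter`
#'   only.
#' @param threshold Leave threshold in uL; `volume_threshold` only.
#' @param choice_noise Logistic noise scale in uL (0 = deterministic).
#' @param lapse Per-decision probability of flipping the choice, in [0, 1].
#' @return An object of class `agent_policy`.
#' @examples
#' agent_policy("hyperbolic_discounter", k = 0.02, b = 0.7)
#' @export
agent_policy <- function(kind = c("mvt_optimal", "volume_threshold",
                                  "hyperbolic_discounter"),
                         k = NULL, b = NULL, threshold = NULL,
                         choice_noise = 0, lapse = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(choice_noise) || choice_noise < 0)
    stop("choice_noise must be >= 0")
  if (!is.numeric(lapse) || lapse < 0 || lapse > 1)
    stop("lapse must lie in [0, 1]")
  pol <- list(kind = kind, choice_noise = as.numeric(choice_noise),
              lapse = as.numeric(lapse))
  if (kind == "hyperbolic_discounter") {
    if (is.null(k) || is.null(b)) stop("hyperbolic_discounter needs k and b")
    if (!is.finite(k) || k < 0) stop("k must be finite and >= 0")
    if (!is.finite(b) || b <= 0 || b > 1) stop("b must lie in (0, 1]")
    pol$k <- as.numeric(k); pol$b <- as.numeric(b)
  } else if (kind == "volume_threshold") {
    if (is.null(threshold)) stop("volume_threshold needs a threshold")
    if (!is.finite(threshold) || threshold < 0)
      stop("threshold must be >= 0")
    pol$threshold <- as.numeric(threshold)
  }
  class(pol) <- "agent_policy"
  pol
}

#' A simulated rat: identifiers, body weight, and decision policy
#'
#' @param rat_id Character identifier.
#' @param sex `"male"` or `"female"`.
#' @param body_weight Body weight in kg (> 0); feeds the uL/min/kg water
#'   rate measure.
#' @param policy An [agent_policy()].
#' @return An object of class `rat_record`.
#' @export
rat_record <- function(rat_id, sex = c("male", "female"),
                       body_weight = 0.4, policy = agent_policy()) {
  sex <- match.arg(sex)
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be > 0")
  if (!inherits(policy, "agent_policy")) stop("policy must be an agent_policy")
  structure(list(rat_id = as.character(rat_id), sex = sex,
                 body_weight = as.numeric(body_weight), policy = policy),
            class = "rat_record")
}

# Leave threshold in uL implied by a policy at a given COD, or NA for the
# count-based mvt_optimal rule.
policy_leave_threshold <- function(policy, cod, config) {
  switch(policy$kind,
    hyperbolic_discounter =
      policy$b * config$initial_volume / (1 + policy$k * cod),
    volume_threshold = policy$threshold,
    mvt_optimal = NA_real_
  )
}

#' Single stay-or-leave decision
#'
#' Evaluates one patch-leaving decision: after a reward has been collected,
#' should the agent stay for the next (smaller) reward or leave for the
#' replenished alternative patch? Threshold-type policies compare the next
#' scheduled volume with their (possibly delay-discounted) leave threshold;
#' the `mvt_optimal` policy leaves exactly when the count of rewards already
#' collected reaches the optimal stay count for this COD.
#'
#' Deterministic when `choice_noise = 0` and `lapse = 0`; otherwise
#' stochastic, consuming the R random number stream.
#'
#' @param policy An [agent_policy()].
#' @param next_volume Volume (uL) scheduled for the next reward if staying.
#' @param cod Session changeover delay (s).
#' @param config A [task_config()].
#' @param n_collected Rewards already collected in this patch visit (used by
#'   `mvt_optimal`).
#' @return `"stay"` or `"leave"`.
#' @export
decide_stay_or_leave <- function(policy, next_volume, cod,
                                 config = task_config(), n_collected = 1L) {
  if (!inherits(policy, "agent_policy")) stop("unknown policy object")
  if (!is.finite(next_volume) || next_volume <= 0)
    stop("next_volume must be > 0")
  if (policy$kind == "mvt_optimal") {
    n_star <- solve_optimal_policy(cod, config)$n_star
    thr <- reward_volume(n_star + 1, config)
  } else {
    n_star <- NA_integer_
    thr <- policy_leave_threshold(policy, cod, config)
  }
  if (decide_core(policy, next_volume, n_collected, thr, n_star))
    "leave" else "stay"
}

# Shared decision kernel. `thr` is the resolved leave threshold in uL (for
# mvt_optimal, the optimal rejection volume, used only under noise);
# `n_star` the optimal stay count (mvt_optimal only). Returns TRUE to leave.
decide_core <- function(policy, next_volume, n_collected, thr, n_star) {
  if (policy$choice_noise > 0) {
    leave <- stats::runif(1) <
      stats::plogis((thr - next_volume) / policy$choice_noise)
  } else if (policy$kind == "mvt_optimal") {
    leave <- n_collected >= n_star
  } else {
    leave <- next_volume < thr
  }
  if (policy$lapse > 0 && stats::runif(1) < policy$lapse) leave <- !leave
  leave
}
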