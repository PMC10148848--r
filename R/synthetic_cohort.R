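# Synthetic cohorts emulating the study design: two sexes, per-rat
# heterogeneous discounting parameters and body weights, and the full
# 24-session protocol per rat. The generator's defaults are a desk-scale
# emulation (100 + 100 rats) of a large outbred cohort; sex differences
# are injected through the stay bias b and body weight, not through k,
# mirroring patch-utilisation differences without discounting-rate
# differences. Distributions are declared emulations, not estimates.

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Specification of a synthetic cohort
#'
#' Describes the two-sex cohort from which [generate_cohort()] draws:
#' counts, per-sex log-normal discount-rate distributions, per-sex
#' truncated-normal stay-bias distributions, body-weight distributions,
#' decision noise, and the mix of agent kinds.
#'
#' Defaults: 100 rats per sex; k log-normal with median 0.02 /s (sdlog
#' 0.5) in both sexes; stay bias b truncated normal on [0.4, 0.8] with
#' male mean 0.62 and female mean 0.70 (sd 0.08) — the upper truncation
#' keeps 0-delay leave thresholds below the second scheduled reward, so
#' every agent collects at least two rewards per patch at COD 0 under
#' idealised timing; body weight normal with male mean 0.45 kg (sd 0.05)
#' and female mean 0.30 kg (sd 0.03); logistic choice noise 5 uL and
#' lapse 0.01.
#'
#' @param n_male,n_female Rats per sex.
#' @param k_median,k_sdlog Per-sex log-normal k parameters (named vectors
#'   `male`/`female` or scalars).
#' @param b_mean,b_sd,b_range Per-sex truncated-normal stay-bias
#'   parameters; `b_range` the truncation interval within (0, 1].
#' @param weight_mean,weight_sd Per-sex body-weight normals (kg),
#'   truncated below at 0.1 kg.
#' @param choice_noise,lapse Decision-noise settings shared by all agents.
#' @param policy_mix Named proportions over agent kinds (must sum to 1).
#' @param seed Integer seed making the cohort draw deterministic.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 100, n_female = 100,
                        k_median = c(male = 0.02, female = 0.02),
                        k_sdlog = c(male = 0.5, female = 0.5),
                        b_mean = c(male = 0.62, female = 0.70),
                        b_sd = c(male = 0.08, female = 0.08),
                        b_range = c(0.4, 0.8),
                        weight_mean = c(male = 0.45, female = 0.30),
                        weight_sd = c(male = 0.05, female = 0.03),
                        choice_noise = 5, lapse = 0.01,
                        policy_mix = c(hyperbolic_discounter = 1),
                        seed = 1L) {
  per_sex <- function(x) {
    if (length(x) == 1) c(male = unname(x), female = unname(x))
    else { stopifnot(all(c("male", "female") %in% names(x))); x[c("male", "female")] }
  }
  spec <- list(n_male = as.integer(n_male), n_female = as.integer(n_female),
               k_median = per_sex(k_median), k_sdlog = per_sex(k_sdlog),
               b_mean = per_sex(b_mean), b_sd = per_sex(b_sd),
               b_range = as.numeric(b_range),
               weight_mean = per_sex(weight_mean),
               weight_sd = per_sex(weight_sd),
               choice_noise = as.numeric(choice_noise),
               lapse = as.numeric(lapse),
               policy_mix = policy_mix, seed = as.integer(seed))
  if (spec$n_male < 0 || spec$n_female < 0) stop("counts must be >= 0")
  if (any(spec$k_median <= 0) || any(spec$k_sdlog < 0))
    stop("invalid k distribution")
  if (spec$b_range[1] <= 0 || spec$b_range[2] > 1 ||
      spec$b_range[1] >= spec$b_range[2])
    stop("b_range must be an interval within (0, 1]")
  if (any(spec$weight_mean <= 0) || any(spec$weight_sd < 0))
    stop("invalid body-weight distribution")
  if (spec$choice_noise < 0 || spec$lapse < 0 || spec$lapse > 1)
    stop("invalid noise settings")
  kinds <- c("mvt_optimal", "volume_threshold", "hyperbolic_discounter")
  if (is.null(names(spec$policy_mix)) ||
      !all(names(spec$policy_mix) %in% kinds) ||
      any(spec$policy_mix < 0) || abs(sum(spec$policy_mix) - 1) > 1e-9)
    stop("policy_mix must be named proportions over agent kinds summing to 1")
  class(spec) <- "cohort_spec"
  spec
}

#' Draw a cohort of simulated rats
#'
#' Deterministic given `spec$seed`: each rat receives a sex, a body
#' weight, and an [agent_policy()] with parameters drawn from the per-sex
#' distributions in the spec.
#'
#' @param spec A [cohort_spec()].
#' @return List of [rat_record()]s; the generating ("true") parameters are
#'   also returned as the `truth` attribute (a data frame with `rat_id`,
#'   `sex`, `kind`, `k`, `b`, `threshold`, `body_weight`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  sexes <- c(rep("male", spec$n_male), rep("female", spec$n_female))
  n <- length(sexes)
  kinds <- sample(names(spec$policy_mix), n, replace = TRUE,
                  prob = spec$policy_mix)
  rats <- vector("list", n)
  truth <- data.frame(rat_id = sprintf("rat%03d", seq_len(n)), sex = sexes,
                      kind = kinds, k = NA_real_, b = NA_real_,
                      threshold = NA_real_, body_weight = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- sexes[i]
    w <- rtrunc_norm(1, spec$weight_mean[[s]], spec$weight_sd[[s]], 0.1, Inf)
    pol <- switch(kinds[i],
      mvt_optimal = agent_policy("mvt_optimal",
                                 choice_noise = spec$choice_noise,
                                 lapse = spec$lapse),
      volume_threshold = {
        truth$threshold[i] <- stats::runif(1, 40, 120)
        agent_policy("volume_threshold", threshold = truth$threshold[i],
                     choice_noise = spec$choice_noise, lapse = spec$lapse)
      },
      hyperbolic_discounter = {
        truth$k[i] <- stats::rlnorm(1, log(spec$k_median[[s]]),
                                    spec$k_sdlog[[s]])
        truth$b[i] <- rtrunc_norm(1, spec$b_mean[[s]], spec$b_sd[[s]],
                                  spec$b_range[1], spec$b_range[2])
        agent_policy("hyperbolic_discounter", k = truth$k[i], b = truth$b[i],
                     choice_noise = spec$choice_noise, lapse = spec$lapse)
      })
    truth$body_weight[i] <- w
    rats[[i]] <- rat_record(truth$rat_id[i], s, w, pol)
  }
  attr(rats, "truth") <- truth
  rats
}

#' Fit discounting models to every rat's indifference curve
#'
#' Builds each rat's indifference curve (mean rejection volume against
#' COD) from the per-COD metrics table and fits the anchored hyperbolic
#' model plus normalized AUC.
#'
#' @param metrics Concatenated [aggregate_rat()] rows for a cohort.
#' @param config A [task_config()].
#' @return Data frame: `rat_id`, `sex`, `k`, `b`, `auc`, `rss`,
#'   `converged`, `clipped`. Rats whose curves cannot be fitted (missing
#'   points) get `NA` fits.
#' @export
fit_cohort <- function(metrics, config = task_config()) {
  rats <- unique(metrics$rat_id)
  rows <- lapply(rats, function(id) {
    m <- metrics[metrics$rat_id == id, , drop = FALSE]
    m <- m[order(m$cod_s), ]
    base <- data.frame(rat_id = id, sex = m$sex[1], k = NA_real_,
                       b = NA_real_, auc = NA_real_, rss = NA_real_,
                       converged = FALSE, clipped = NA,
                       stringsAsFactors = FALSE)
    if (anyNA(m$rejection_ul)) return(base)
    fit <- tryCatch({
      cv <- indifference_curve(m$cod_s, m$rejection_ul,
                               A = config$initial_volume)
      fit_hyperbolic(cv)
    }, error = function(e) NULL)
    if (is.null(fit)) return(base)
    base$k <- fit$k; base$b <- fit$b; base$auc <- fit$auc
    base$rss <- fit$rss; base$converged <- fit$converged
    base$clipped <- fit$clipped
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full study pipeline on a synthetic cohort
#'
#' End-to-end harness: draws the cohort, simulates every rat's 24-session
#' protocol, extracts the per-COD dependent measures, fits the discounting
#' models, and computes the cohort-level analyses — per-sex delay-response
#' curves, deviation-from-optimality curves, harvest classification
#' frequencies, composite scores, per-sex Pearson matrices, the grid of
#' Meng z comparisons (patch-utilisation variable j: discounting variable
#' vs reward-maximisation variable), mixed ANOVAs with post-hocs, and the
#' normality screen. Bit-reproducible for a given spec.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @return List of class `patch_study` with elements `spec`, `config`,
#'   `truth`, `metrics`, `fits`, `composites`, `delay_curves`, `harvest`,
#'   `correlations` (per sex), `meng` (per sex), `anova`, `posthoc`,
#'   `normality`.
#' @export
run_study <- function(spec = cohort_spec(), config = task_config()) {
  rats <- generate_cohort(spec)
  metrics <- do.call(rbind, lapply(seq_along(rats), function(i) {
    logs <- simulate_protocol(rats[[i]], config,
                              seed = derive_seed(spec$seed, 100000L + i))
    aggregate_rat(logs, rats[[i]], config)
  }))
  fits <- fit_cohort(metrics, config)
  composites <- composite_scores(metrics, fits, config)

  agg <- function(v) {
    do.call(rbind, lapply(split(metrics, list(metrics$sex, metrics$cod_s)),
      function(s) data.frame(sex = s$sex[1], cod_s = s$cod_s[1],
                             mean = mean(s[[v]], na.rm = TRUE),
                             sd = stats::sd(s[[v]], na.rm = TRUE),
                             n = sum(!is.na(s[[v]])))))
  }
  measures <- c(pc = "pc", tip = "tip_s", rejection = "rejection_ul",
                wr = "wr_ul_min_kg", vd = "vd_pct", td = "td_pct")
  delay_curves <- lapply(measures, agg)

  correlations <- meng <- list()
  for (s in c("male", "female")) {
    if (is.null(composites) || sum(composites$sex == s) < 4) next
    cm <- correlation_matrix(composites, s)
    correlations[[s]] <- cm
    n_s <- sum(composites$sex == s)
    grid <- expand.grid(j = c("tip", "pc", "wr"), dd = c("k", "auc"),
                        rm = c("vd", "td"), stringsAsFactors = FALSE)
    meng[[s]] <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      j <- grid$j[i]; dd <- grid$dd[i]; rm_ <- grid$rm[i]
      res <- tryCatch(
        meng_z_test(cm[j, dd], cm[j, rm_], cm[dd, rm_], n_s),
        error = function(e) NULL)
      data.frame(shared = j, comparison = paste(dd, "vs", rm_),
                 r_dd = cm[j, dd], r_rm = cm[j, rm_],
                 z = if (is.null(res)) NA_real_ else res$z,
                 p = if (is.null(res)) NA_real_ else res$p,
                 stronger = if (is.null(res) || is.na(res$stronger)) NA_character_
                            else c(r_jx = dd, r_jy = rm_)[res$stronger],
                 stringsAsFactors = FALSE)
    }))
  }

  anova_vars <- c(pc = "pc", tip = "tip_s", rejection = "rejection_ul",
                  wr = "wr_ul_min_kg", vd = "vd_pct")
  anovas <- lapply(anova_vars, function(v)
    tryCatch(suppressMessages(mixed_anova(metrics, v)),
             error = function(e) NULL))
  posthocs <- lapply(anova_vars, function(v)
    tryCatch(posthoc_tests(metrics, v), error = function(e) NULL))
  normality <- if (!is.null(composites))
    lapply(composites[c("k", "auc", "vd", "td", "tip", "pc", "wr")],
           function(x) tryCatch(normality_screen(x), error = function(e) NULL))
  else NULL

  structure(list(spec = spec, config = config,
                 truth = attr(rats, "truth"), metrics = metrics,
                 fits = fits, composites = composites,
                 delay_curves = delay_curves,
                 harvest = harvest_classification(metrics),
                 correlations = correlations, meng = meng,
                 anova = anovas, posthoc = posthocs,
                 normality = normality),
            class = "patch_study")
}

#' Parameter-recovery experiment
#'
#' Simulates a cohort of hyperbolic-discounter agents, refits the
#' generating model to each simulated rat's indifference curve, and
#' summarises recovery of k and b: bias, RMSE, and median relative error.
#' With zero decision noise the only error source is the quantisation of
#' rejection volumes to the geometric reward schedule.
#'
#' @param spec A [cohort_spec()] whose `policy_mix` is purely
#'   `hyperbolic_discounter`.
#' @param config A [task_config()].
#' @return List of class `recovery_report`: `pairs` (per-rat true and
#'   fitted values), `summary` (per-parameter bias, RMSE,
#'   median relative error), `spec`.
#' @export
recovery_experiment <- function(spec = cohort_spec(), config = task_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!identical(names(spec$policy_mix), "hyperbolic_discounter"))
    stop("recovery_experiment requires a pure hyperbolic_discounter cohort")
  study <- run_study(spec, config)
  pairs <- merge(study$truth[, c("rat_id", "sex", "k", "b")],
                 study$fits[, c("rat_id", "k", "b", "auc", "converged")],
                 by = "rat_id", suffixes = c("_true", "_hat"))
  pairs <- pairs[pairs$converged & !is.na(pairs$k_hat), ]
  summ <- do.call(rbind, lapply(c("k", "b"), function(par) {
    tr <- pairs[[paste0(par, "_true")]]; ht <- pairs[[paste0(par, "_hat")]]
    data.frame(parameter = par,
               bias = mean(ht - tr),
               rmse = sqrt(mean((ht - tr)^2)),
               median_rel_error = stats::median(abs(ht - tr) / abs(tr)),
               n = length(tr))
  }))
  structure(list(pairs = pairs, summary = summ, spec = spec),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery (hyperbolic agents)\n")
  print(x$summary, digits = 4)
  invisible(x)
}
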