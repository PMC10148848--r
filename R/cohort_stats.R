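# Cohort-level analyses: composite scores summed across delays, Pearson
# correlation matrices by sex, Meng's z-test for dependent overlapping
# correlations, mixed ANOVA (sex between, delay within) with partial eta
# squared and Greenhouse-Geisser sphericity diagnostics, Bonferroni
# post-hocs with Cohen's d, and a skewness-based normality screen.

#' Composite scores across delays
#'
#' Collapses the per-rat x per-COD metrics to one row per rat by summing
#' each dependent measure across all delays (PC, TIP, WR, VD, TD) and
#' carrying the discounting parameters (k, AUC) through unchanged. TD is
#' undefined at delays whose optimal time in patch is zero (COD 0), so its
#' sum runs over the delays where it is defined. Rats with missing cells
#' are excluded with a message.
#'
#' @param metrics Per-rat x per-COD table (rows of [aggregate_rat()]).
#' @param fits Per-rat discounting table with columns `rat_id`, `k`, `auc`.
#' @param config The [task_config()] (determines the delays at which TD is
#'   defined).
#' @return Data frame, one row per retained rat: `rat_id`, `sex`, `k`,
#'   `auc`, `vd`, `td`, `tip`, `pc`, `wr`.
#' @export
composite_scores <- function(metrics, fits, config = task_config()) {
  opt <- optimal_curves(config)
  td_cods <- opt$cod[opt$optimal_time_in_patch > 0]
  rats <- unique(metrics$rat_id)
  rows <- lapply(rats, function(id) {
    m <- metrics[metrics$rat_id == id, , drop = FALSE]
    if (!setequal(m$cod_s, config$cod_set)) return(NULL)
    core <- m[, c("pc", "tip_s", "wr_ul_min_kg", "vd_pct")]
    td_ok <- !any(is.na(m$td_pct[m$cod_s %in% td_cods]))
    if (any(is.na(core)) || !td_ok) return(NULL)
    f <- fits[fits$rat_id == id, , drop = FALSE]
    if (nrow(f) != 1 || is.na(f$k) || is.na(f$auc)) return(NULL)
    data.frame(rat_id = id, sex = m$sex[1], k = f$k, auc = f$auc,
               vd = sum(m$vd_pct), td = sum(m$td_pct[m$cod_s %in% td_cods]),
               tip = sum(m$tip_s), pc = sum(m$pc),
               wr = sum(m$wr_ul_min_kg), stringsAsFactors = FALSE)
  })
  dropped <- rats[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    message("composite_scores: excluded ", length(dropped),
            " rat(s) with missing cells: ",
            paste(utils::head(dropped, 10), collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix of composite scores
#'
#' Pairwise-complete Pearson correlations among the composite variables
#' \{k, AUC, VD, TD, TIP, PC, WR\} for one sex. Variables with zero
#' variance are set to missing with a warning.
#'
#' @param scores [composite_scores()] output.
#' @param sex `"male"` or `"female"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(scores, sex = c("male", "female")) {
  sex <- match.arg(sex)
  vars <- c("k", "auc", "vd", "td", "tip", "pc", "wr")
  sub <- scores[scores$sex == sex, vars, drop = FALSE]
  if (nrow(sub) < 4) stop("need at least 4 rats of sex ", sex)
  sds <- vapply(sub, stats::sd, numeric(1))
  degen <- names(sds)[!is.na(sds) & sds == 0]
  if (length(degen)) {
    warning("zero-variance variable(s) set to NA: ",
            paste(degen, collapse = ", "))
    sub[degen] <- NA_real_
  }
  suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
}

#' Meng's z-test for two dependent overlapping correlations
#'
#' Compares two correlations that share one variable and were computed on
#' the same sample (e.g. cor(PC, k) versus cor(PC, VD)), following Meng,
#' Rosenthal & Rubin (1992). Both correlations are Fisher r-to-z
#' transformed; their difference is scaled by
#' `sqrt((n - 3) / (2 * (1 - r_xy) * h))`, where `r_xy` is the correlation
#' between the two non-shared variables and `h` the heteroscedasticity
#' factor `(1 - f * rbar2) / (1 - rbar2)` with
#' `rbar2 = (r_jx^2 + r_jy^2) / 2` and `f = (1 - r_xy) / (2 * (1 - rbar2))`
#' capped at 1. The p-value is two-tailed standard normal.
#'
#' @param r_jx,r_jy The two correlations sharing variable j.
#' @param r_xy Correlation between the non-shared variables x and y.
#' @param n Sample size (> 3).
#' @return Object of class `correlation_comparison`: the inputs plus `z`,
#'   `p`, and `stronger` (`"r_jx"`/`"r_jy"`, the larger-magnitude
#'   correlation, `NA` on exact ties).
#' @examples
#' meng_z_test(0.87, -0.30, -0.25, n = 896)
#' @export
meng_z_test <- function(r_jx, r_jy, r_xy, n) {
  rs <- c(r_jx = r_jx, r_jy = r_jy, r_xy = r_xy)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1))
    stop("correlations must be finite with |r| < 1")
  if (!is.finite(n) || n <= 3) stop("n must exceed 3")
  z1 <- atanh(r_jx); z2 <- atanh(r_jy)
  rbar2 <- (r_jx^2 + r_jy^2) / 2
  f <- min((1 - r_xy) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r_xy) * h))
  p <- 2 * stats::pnorm(-abs(z))
  stronger <- if (abs(r_jx) > abs(r_jy)) "r_jx" else
              if (abs(r_jy) > abs(r_jx)) "r_jy" else NA_character_
  structure(list(r_jx = r_jx, r_jy = r_jy, r_xy = r_xy, n = n,
                 z = z, p = p, stronger = stronger),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf(
    "Meng z-test: r_jx = %.3f vs r_jy = %.3f (r_xy = %.3f, n = %d): z = %.3f, p = %.4g%s\n",
    x$r_jx, x$r_jy, x$r_xy, x$n, x$z, x$p,
    if (is.na(x$stronger)) "" else paste0(" (stronger: ", x$stronger, ")")))
  invisible(x)
}

#' Mixed ANOVA: sex (between) x delay (within)
#'
#' Classical two-way mixed analysis of variance on one dependent measure,
#' with delay as the within-subject factor and sex as the between-subject
#' factor. Sums of squares come from the standard [stats::aov()] error
#' decomposition (between-subject stratum: sex against subject residuals;
#' within-subject stratum: delay and sex x delay against the within
#' residuals). Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error_for_that_effect)`. A
#' Greenhouse-Geisser epsilon (Box epsilon of the pooled within-group
#' covariance) is reported with adjusted p-values for the within effects;
#' the uncorrected F is the primary output. Rats with missing cells are
#' dropped with a message. Input with no variance at all (a constant
#' response) is reported as exactly null: zero SS, F and partial eta
#' squared, with undefined p-values.
#'
#' @param data Data frame with one row per rat x delay.
#' @param dv Name of the dependent-measure column.
#' @param subject,between,within Column names (defaults `rat_id`, `sex`,
#'   `cod_s`).
#' @return List of class `mixed_anova`: `table` (effect, df, SS, MS, F, p,
#'   pes, and `p_gg` for within effects), `gg_epsilon`, `n_dropped`.
#' @export
mixed_anova <- function(data, dv, subject = "rat_id", between = "sex",
                        within = "cod_s") {
  d <- data.frame(y = data[[dv]],
                  id = factor(data[[subject]]),
                  grp = factor(data[[between]]),
                  w = factor(data[[within]]))
  # drop subjects with any missing cell
  lv <- levels(d$w)
  ok_id <- tapply(seq_len(nrow(d)), d$id, function(i) {
    sub <- d[i, ]
    !anyNA(sub$y) && setequal(as.character(sub$w), lv) &&
      nrow(sub) == length(lv)
  })
  drop_ids <- names(ok_id)[!ok_id]
  if (length(drop_ids))
    message("mixed_anova: dropped ", length(drop_ids),
            " subject(s) with missing cells")
  d <- droplevels(d[!(as.character(d$id) %in% drop_ids), ])
  if (nlevels(d$id) < 3) stop("too few complete subjects for ANOVA")

  # degenerate input: no variance anywhere, so every effect is exactly null
  ss_tot <- sum((d$y - mean(d$y))^2)
  degenerate <- ss_tot < 1e-10 * (1 + mean(d$y)^2) * nrow(d)

  fit <- stats::aov(y ~ grp * w + Error(id), data = d)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: id"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(btw)); rn_w <- trimws(rownames(wth))
  get <- function(tab, rn, name) tab[match(name, rn), , drop = FALSE]
  sex_r <- get(btw, rn_b, "grp"); resb <- get(btw, rn_b, "Residuals")
  w_r <- get(wth, rn_w, "w"); int_r <- get(wth, rn_w, "grp:w")
  resw <- get(wth, rn_w, "Residuals")

  p <- nlevels(d$w)
  # Box/Greenhouse-Geisser epsilon from the pooled within-group covariance
  wide <- stats::reshape(d[, c("id", "grp", "w", "y")], direction = "wide",
                         idvar = c("id", "grp"), timevar = "w")
  ymat <- as.matrix(wide[, -(1:2), drop = FALSE])
  covs <- lapply(split(as.data.frame(ymat), wide$grp), function(g) {
    if (nrow(g) > 1) stats::cov(as.matrix(g)) * (nrow(g) - 1) else NULL
  })
  covs <- covs[!vapply(covs, is.null, logical(1))]
  S <- Reduce(`+`, covs) / (nrow(ymat) - length(covs))
  Sdc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  lam <- eigen(Sdc, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-12]
  eps <- if (length(lam)) sum(lam)^2 / ((p - 1) * sum(lam^2)) else NA_real_

  row_of <- function(r, effect, err_row) {
    if (is.null(r) || all(is.na(r))) return(NULL)
    data.frame(effect = effect, df = r$Df, ss = r$`Sum Sq`,
               ms = r$`Mean Sq`,
               F = if ("F value" %in% names(r)) r$`F value` else NA_real_,
               p = if ("Pr(>F)" %in% names(r)) r$`Pr(>F)` else NA_real_,
               pes = if (!is.null(err_row))
                 r$`Sum Sq` / (r$`Sum Sq` + err_row$`Sum Sq`) else NA_real_,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row_of(sex_r, "sex", resb),
    row_of(resb, "residuals_between", NULL),
    row_of(w_r, "delay", resw),
    row_of(int_r, "sex:delay", resw),
    row_of(resw, "residuals_within", NULL)
  )
  if (degenerate) {
    tab$ss <- 0; tab$ms <- 0
    tab$F <- ifelse(is.na(tab$F), NA_real_, 0)
    tab$p <- NA_real_
    tab$pes <- ifelse(is.na(tab$pes), NA_real_, 0)
  }
  # Greenhouse-Geisser adjusted p for the within effects
  tab$p_gg <- NA_real_
  for (eff in c("delay", "sex:delay")) {
    i <- which(tab$effect == eff)
    if (length(i) && is.finite(tab$F[i]) && is.finite(eps)) {
      df1 <- tab$df[i] * eps
      df2 <- tab$df[tab$effect == "residuals_within"] * eps
      tab$p_gg[i] <- stats::pf(tab$F[i], df1, df2, lower.tail = FALSE)
    }
  }
  rownames(tab) <- NULL
  structure(list(table = tab, gg_epsilon = eps,
                 n_dropped = length(drop_ids),
                 n_subjects = nlevels(d$id)),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Mixed ANOVA (%d subjects, GG epsilon = %.3f)\n",
              x$n_subjects, x$gg_epsilon))
  print(x$table, digits = 4)
  invisible(x)
}

#' Post-hoc comparisons for the mixed design
#'
#' Between-subject: independent-samples t-test (pooled variance) of the
#' sexes at each delay, Bonferroni-corrected across delays, with Cohen's d
#' from the pooled standard deviation (flagged `NA` when the pooled SD is
#' zero). Within-subject: paired t-tests for every pair of delays
#' (collapsed across sex), Bonferroni-corrected across all pairs.
#'
#' @inheritParams mixed_anova
#' @return List with data frames `between` (per delay: group means, t, df,
#'   p, p_bonferroni, cohen_d) and `within` (per delay pair: mean
#'   difference, t, df, p, p_bonferroni).
#' @export
posthoc_tests <- function(data, dv, subject = "rat_id", between = "sex",
                          within = "cod_s") {
  d <- data.frame(y = data[[dv]], id = data[[subject]],
                  grp = factor(data[[between]]), w = data[[within]])
  d <- d[!is.na(d$y), ]
  delays <- sort(unique(d$w))
  g_lv <- levels(d$grp)
  if (length(g_lv) != 2) stop("between factor must have exactly 2 levels")

  btw <- do.call(rbind, lapply(delays, function(cd) {
    y1 <- d$y[d$w == cd & d$grp == g_lv[1]]
    y2 <- d$y[d$w == cd & d$grp == g_lv[2]]
    if (length(y1) < 2 || length(y2) < 2)
      stop("need >= 2 rats per sex per delay")
    sp2 <- ((length(y1) - 1) * stats::var(y1) +
            (length(y2) - 1) * stats::var(y2)) /
           (length(y1) + length(y2) - 2)
    tt <- if (sp2 > 0) stats::t.test(y1, y2, var.equal = TRUE) else NULL
    data.frame(cod_s = cd,
               mean_1 = mean(y1), mean_2 = mean(y2),
               t = if (is.null(tt)) 0 else unname(tt$statistic),
               df = length(y1) + length(y2) - 2,
               p = if (is.null(tt)) 1 else tt$p.value,
               cohen_d = if (sp2 > 0) (mean(y1) - mean(y2)) / sqrt(sp2)
                         else NA_real_)
  }))
  btw$p_bonferroni <- pmin(btw$p * length(delays), 1)

  pairs <- utils::combn(delays, 2)
  wth <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    da <- d[d$w == a, c("id", "y")]; db <- d[d$w == b, c("id", "y")]
    m <- merge(da, db, by = "id")
    diffs <- m$y.x - m$y.y
    if (stats::sd(diffs) > 0) {
      tt <- stats::t.test(diffs)
      data.frame(delay_a = a, delay_b = b, mean_diff = mean(diffs),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    } else {
      data.frame(delay_a = a, delay_b = b, mean_diff = mean(diffs),
                 t = 0, df = nrow(m) - 1, p = 1)
    }
  }))
  wth$p_bonferroni <- pmin(wth$p * ncol(pairs), 1)
  list(between = btw, within = wth)
}

#' Skewness-based normality screen
#'
#' Bias-corrected sample skewness
#' `G1 = g1 * sqrt(n * (n - 1)) / (n - 2)` with `g1 = m3 / m2^(3/2)` (the
#' convention of common statistical packages), gated at |G1| < 1: the rule
#' used to justify parametric statistics for the task's dependent
#' measures.
#'
#' @param values Numeric vector, n >= 3.
#' @return List: `skewness`, `pass` (`NA` for zero-variance input).
#' @export
normality_screen <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(list(skewness = NA_real_, pass = NA))
  g1 <- mean((x - mean(x))^3) / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  list(skewness = G1, pass = abs(G1) < 1)
}
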