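# Hyperbolic delay discounting applied to patch-leaving: the rejection
# volume at each changeover delay is treated as an indifference point V(D)
# and fitted with V = b*A / (1 + k*D), where A is the alternative patch's
# full volume, b the bias anchored so that b*A equals the 0-delay
# indifference point, and k the discount rate. The normalized area under
# the indifference curve (AUC) summarises discounting without committing
# to a functional form.

#' Indifference curve of rejection volumes across changeover delays
#'
#' @param delays Strictly increasing delays in seconds (the COD set).
#' @param indifference_points Mean rejection volumes (uL), one per delay.
#' @param A Alternative patch's full reward volume (uL), default 150.
#' @return An object of class `indifference_curve`.
#' @export
indifference_curve <- function(delays, indifference_points, A = 150) {
  if (length(delays) != length(indifference_points))
    stop("delays and indifference_points must have equal length")
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing")
  if (any(!is.finite(indifference_points) | indifference_points < 0))
    stop("indifference points must be finite and >= 0")
  if (!is.finite(A) || A <= 0) stop("A must be > 0")
  structure(list(delays = as.numeric(delays),
                 indifference_points = as.numeric(indifference_points),
                 A = as.numeric(A),
                 above_A = any(indifference_points > A)),
            class = "indifference_curve")
}

#' Fit the anchored hyperbolic discount function
#'
#' Fits `V = b*A / (1 + k*D)` to an indifference curve. The bias `b` is
#' anchored, not estimated: `b = V(0)/A`, so the curve passes exactly
#' through the 0-delay indifference point. The discount rate `k >= 0` then
#' minimises the residual sum of squares over the remaining delays (the
#' 0-delay residual is zero by construction and is excluded from the
#' objective). The one-dimensional search is a deterministic bounded
#' minimisation in log k over [1e-6, 1e2], with the boundary case k = 0
#' (no discounting) checked explicitly.
#'
#' Points above `A` are permitted in the fit (they are clipped only for
#' AUC normalisation) and flagged via the curve's `above_A` field.
#'
#' @param curve An [indifference_curve()]; must contain a 0-delay point
#'   and at least two positive delays.
#' @return An object of class `discount_fit`: `k`, `b`, `auc`
#'   (from [normalized_auc()], independent of the hyperbolic fit), `rss`,
#'   `converged`, `clipped`.
#' @examples
#' cv <- indifference_curve(c(0, 6, 12, 18, 24), 150 / (1 + 0.1 * c(0, 6, 12, 18, 24)))
#' fit_hyperbolic(cv)   # recovers k = 0.1, b = 1
#' @export
fit_hyperbolic <- function(curve) {
  stopifnot(inherits(curve, "indifference_curve"))
  D <- curve$delays; V <- curve$indifference_points; A <- curve$A
  if (!any(D == 0)) stop("a 0-delay indifference point is required to anchor b")
  if (sum(D > 0) < 2) stop("at least two positive delays are required")
  V0 <- V[D == 0][1]
  if (V0 <= 0) stop("0-delay indifference point must be > 0 to define b")
  b <- V0 / A
  Dp <- D[D > 0]; Vp <- V[D > 0]
  rss_fun <- function(k) sum((Vp - b * A / (1 + k * Dp))^2)
  opt <- stats::optimize(function(lk) rss_fun(exp(lk)),
                         interval = log(c(1e-6, 1e2)), tol = 1e-12)
  k_hat <- exp(opt$minimum); rss <- opt$objective
  rss0 <- rss_fun(0)
  if (rss0 <= rss) { k_hat <- 0; rss <- rss0 }
  structure(list(k = k_hat, b = b, auc = normalized_auc(curve),
                 rss = rss, converged = is.finite(rss),
                 clipped = curve$above_A),
            class = "discount_fit")
}

#' @export
print.discount_fit <- function(x, ...) {
  cat(sprintf("hyperbolic discount fit: k = %.6g /s, b = %.4f, AUC = %.4f, RSS = %.4g\n",
              x$k, x$b, x$auc, x$rss))
  invisible(x)
}

#' Normalized area under the indifference curve
#'
#' Model-free discounting summary: delays are normalised by the maximum
#' delay and indifference points by `A` (clipping to [0, A] first), and
#' the area under the resulting curve is computed by the trapezoid rule.
#' Ranges over [0, 1]; smaller values indicate steeper discounting (here,
#' more overharvesting).
#'
#' @param curve An [indifference_curve()] whose delays include 0 and at
#'   least one positive delay.
#' @return Scalar in [0, 1].
#' @export
normalized_auc <- function(curve) {
  stopifnot(inherits(curve, "indifference_curve"))
  D <- curve$delays; V <- curve$indifference_points
  if (length(D) < 2) stop("at least two points are required for AUC")
  if (!any(D == 0)) stop("AUC normalisation requires a 0-delay point")
  x <- D / max(D)
  y <- pmin(pmax(V, 0), curve$A) / curve$A
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}
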