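#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Pools per-site estimates under a random-effects model with inverse
#' variance weighting. With fixed-effect weights `w_i = 1/v_i`:
#' `theta_FE = sum(w_i theta_i)/sum(w_i)`, Cochran's
#' `Q = sum(w_i (theta_i - theta_FE)^2)`,
#' `C = sum(w_i) - sum(w_i^2)/sum(w_i)`, and the DerSimonian-Laird
#' between-site variance `tau^2 = max(0, (Q - (k - 1))/C)`. Random-effects
#' weights are `w_i* = 1/(v_i + tau^2)` and the pooled 95% CI is
#' `pooled +/- 1.96 sqrt(1/sum(w_i*))`.
#'
#' @param estimates data.frame with columns `site_id`, `estimate`,
#'   `variance` (all variances strictly positive).
#' @return object of class `meta_analysis` with `pooled_estimate`,
#'   `tau_sq`, `q_statistic`, `weights`, `ci95_low`, `ci95_high`,
#'   `k_studies` and the fixed-effect estimate.
#' @examples
#' est <- data.frame(site_id = c("a", "b"), estimate = c(1, 2),
#'                   variance = c(0.5, 0.5))
#' meta_analyze(est)
#' @export
meta_analyze <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("estimate", "variance") %in% names(estimates)),
            nrow(estimates) >= 1L)
  theta <- as.numeric(estimates$estimate)
  v <- as.numeric(estimates$variance)
  if (any(!is.finite(theta)) || any(!is.finite(v)) || any(v <= 0))
    stop("all estimates must be finite with strictly positive variance")
  k <- length(theta)
  w <- 1 / v
  theta_fe <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - theta_fe)^2)
  if (k == 1L) {
    tau_sq <- 0
  } else {
    cc <- sum(w) - sum(w^2) / sum(w)
    tau_sq <- max(0, (q - (k - 1)) / cc)
  }
  w_star <- 1 / (v + tau_sq)
  pooled <- sum(w_star * theta) / sum(w_star)
  se <- sqrt(1 / sum(w_star))
  z <- qnorm(0.975)
  structure(list(
    pooled_estimate = pooled, tau_sq = tau_sq, q_statistic = q,
    weights = setNames(w_star, estimates$site_id %||% NULL),
    ci95_low = pooled - z * se, ci95_high = pooled + z * se,
    se = se, k_studies = k, fixed_effect = theta_fe,
    estimates = estimates), class = "meta_analysis")
}

#' @export
print.meta_analysis <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (DerSimonian-Laird), k = %d\n",
              x$k_studies))
  cat(sprintf("  pooled estimate: %.6g  [%.6g, %.6g]\n",
              x$pooled_estimate, x$ci95_low, x$ci95_high))
  cat(sprintf("  tau^2 = %.6g   Q = %.6g (df = %d)\n",
              x$tau_sq, x$q_statistic, x$k_studies - 1L))
  invisible(x)
}

#' Turn per-site summaries into meta-analysis inputs
#'
#' Derives a mean estimate and its sampling variance `sd^2/n` from each
#' non-suppressed site summary; for proportions use the normal
#' approximation `v = p(1-p)/n` on the raw scale.
#'
#' @param summaries named list of `summary_statistics` (continuous), names
#'   are site ids.
#' @return data.frame suitable for [meta_analyze()].
#' @export
estimates_from_summaries <- function(summaries) {
  rows <- lapply(names(summaries), function(sid) {
    s <- summaries[[sid]]
    if (s$suppressed || s$n < 2 || is.null(s$mean)) return(NULL)
    data.frame(site_id = sid, estimate = s$mean,
               variance = s$sd^2 / s$n, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no usable (non-suppressed) site summaries")
  do.call(rbind, rows)
}

#' Meta-analysis inputs for per-site proportions
#'
#' Normal approximation on the raw scale: `v = p(1-p)/n` (with a 0.5/n
#' continuity floor on p so boundary proportions keep positive variance).
#'
#' @param events,n per-site event counts and denominators.
#' @param site_id optional site labels.
#' @return data.frame suitable for [meta_analyze()].
#' @export
estimates_from_proportions <- function(events, n, site_id = NULL) {
  stopifnot(length(events) == length(n), all(n >= 1),
            all(events >= 0 & events <= n))
  p <- events / n
  pb <- pmin(pmax(p, 0.5 / n), 1 - 0.5 / n)
  data.frame(site_id = site_id %||% paste0("site-", seq_along(n)),
             estimate = p, variance = pb * (1 - pb) / n,
             stringsAsFactors = FALSE)
}
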