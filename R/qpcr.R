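#' Fit a qPCR standard curve
#'
#' Least-squares fit of quantification cycle (Cq) on log10 template quantity
#' over a dilution series (e.g. 200, 20, 2, 0.2, 0.02 ng of genomic DNA).
#' The amplification efficiency is `10^(-1/slope) - 1`; a perfect doubling
#' per cycle gives slope -3.3219 and efficiency 1 (100%).
#'
#' @param quantities_ng template quantities (> 0), same length as `cq`.
#' @param cq measured quantification cycles.
#' @return a `standard_curve` list: `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `valid` (FALSE when slope >= 0).
#' @examples
#' q <- c(200, 20, 2, 0.2, 0.02)
#' fit_standard_curve(q, 30 - 3.3219 * log10(q))
#' @export
fit_standard_curve <- function(quantities_ng, cq) {
  if (length(quantities_ng) < 3L) stop("need >= 3 dilution points")
  if (any(quantities_ng <= 0)) stop("quantities must be > 0")
  if (length(quantities_ng) != length(cq)) stop("length mismatch")
  fit <- stats::lm(cq ~ log10(quantities_ng))
  slope <- unname(stats::coef(fit)[2L])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cq - mean(cq))^2)
  curve <- list(slope = slope,
                intercept = unname(stats::coef(fit)[1L]),
                r_squared = r2,
                efficiency = 10^(-1 / slope) - 1,
                valid = slope < 0)
  if (!curve$valid) warning("non-negative slope: standard curve flagged invalid")
  class(curve) <- "standard_curve"
  curve
}

#' Absolute quantification from a standard curve
#'
#' Inverts the curve: `quantity = 10^((cq - intercept)/slope)`; at
#' `cq = intercept` the quantity is 1 ng by construction.
#'
#' @param curve a `standard_curve`.
#' @param cq measured Cq value(s).
#' @return template quantity in ng.
#' @export
quantify_unknown <- function(curve, cq) 10^((cq - curve$intercept) / curve$slope)

#' @rdname quantify_unknown
#' @param quantity_ng template quantity in ng.
#' @return `predict_cq`: the Cq the curve predicts for `quantity_ng`.
#' @export
predict_cq <- function(curve, quantity_ng) {
  curve$intercept + curve$slope * log10(quantity_ng)
}

#' Two-sample t-test from summary statistics
#'
#' The two-tailed two-sample t-test computed directly from printed
#' `mean +/- sd (n)` group summaries, as used to compare qPCR triplicates
#' across culture conditions. `variant = "pooled"` (default) is the Student
#' test with pooled variance; `"welch"` uses the Welch-Satterthwaite
#' approximation. The two agree exactly when sds and group sizes are equal.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (`n >= 2`,
#'   `sd >= 0`).
#' @param variant `"pooled"` or `"welch"`.
#' @return list `t`, `df`, `p_two_tailed`.
#' @examples
#' # qPCR triplicates 0.89 +/- 0.15 vs 0.49 +/- 0.18: p rounds to 0.04
#' t_test_from_summary(0.89, 0.15, 3, 0.49, 0.18, 3)
#' @export
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n_a < 2L || n_b < 2L) stop("need n >= 2 in both groups")
  if (sd_a < 0 || sd_b < 0) stop("sd must be >= 0")
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b)
      return(list(t = 0, df = n_a + n_b - 2, p_two_tailed = 1))
    stop("both groups have zero variance but different means")
  }
  if (variant == "pooled") {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  list(t = t, df = df, p_two_tailed = 2 * stats::pt(-abs(t), df))
}
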