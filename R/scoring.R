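#' Scoring configuration for cross-state differential calls
#'
#' @param state_a,state_b state labels; the cross-state score is
#'   state B minus state A.
#' @param cutoff call threshold on the normalized score (default 1.65, the
#'   outermost ~10% of a standard-normal population, two-sided).
#' @param normalization `"quantile_normal"` (default): rank-based
#'   inverse-normal transform of Z within its layer's population, which makes
#'   "|score| > 1.65 selects the outermost 10%" true by construction;
#'   `"noise_scaled"`: center Z at its median and scale by the replicate-noise
#'   sd propagated to a difference of two replicate means.
#' @param tie_policy ranking tie policy (only `"average_rank"` supported).
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(state_a, state_b, cutoff = 1.65,
                           normalization = c("quantile_normal", "noise_scaled"),
                           tie_policy = "average_rank") {
  normalization <- match.arg(normalization)
  if (!identical(tie_policy, "average_rank"))
    stop("only tie_policy = \"average_rank\" is supported")
  if (!is.numeric(cutoff) || cutoff <= 0) stop("`cutoff` must be > 0")
  structure(list(state_a = state_a, state_b = state_b, cutoff = cutoff,
                 normalization = normalization, tie_policy = tie_policy),
            class = "scoring_config")
}

#' Cross-state differential score Z
#'
#' Z is the log2 abundance difference between the two experimental states,
#' using the mean of each state's available replicates; it is defined only
#' for features quantified in at least one replicate of each state.
#'
#' @param x an [abundance_matrix()].
#' @param cfg a [scoring_config()].
#' @return named numeric vector of Z (state B minus state A), `NA` where a
#'   feature is unquantified in a whole state.
#' @export
cross_state_Z <- function(x, cfg) {
  a <- x[, state_columns(x, cfg$state_a), drop = FALSE]
  b <- x[, state_columns(x, cfg$state_b), drop = FALSE]
  mean_a <- rowMeans(a, na.rm = TRUE)
  mean_b <- rowMeans(b, na.rm = TRUE)
  mean_a[rowSums(!is.na(a)) == 0L] <- NA
  mean_b[rowSums(!is.na(b)) == 0L] <- NA
  z <- mean_b - mean_a
  names(z) <- rownames(x)
  z
}

#' Intra-replicate noise scores R
#'
#' R is the log2 difference between the two biological replicates within one
#' state (replicate 1 minus replicate 2); the population of R values is the
#' empirical noise distribution against which cross-state signal is judged.
#'
#' @param x an [abundance_matrix()] with exactly two replicates per state.
#' @return numeric matrix, features x states, `NA` where either replicate is
#'   unquantified.
#' @export
intra_replicate_R <- function(x) {
  s <- sample_sheet(x)
  states <- unique(s$state)
  out <- matrix(NA_real_, nrow(x), length(states),
                dimnames = list(rownames(x), states))
  for (st in states) {
    cols <- state_columns(x, st)
    if (length(cols) != 2L)
      stop("intra_replicate_R requires exactly 2 replicates per state")
    out[, st] <- x[, cols[1L]] - x[, cols[2L]]
  }
  out
}

#' Normalize a population of Z scores to Znet
#'
#' Transforms the layer's population of cross-state scores into final
#' normalized scores (conventionally Rnet for the RNA layer and Pnet for the
#' protein layer). In `quantile_normal` mode the score is the standard-normal
#' quantile of the average-rank percentile `(rank - 0.5)/n`, so the
#' `|Znet| > 1.65` rule selects the outermost ~10% of the population by
#' construction. In `noise_scaled` mode the score is
#' `(Z - median(Z)) / sigma_noise` with `sigma_noise = sd(R)/sqrt(2) *
#' sqrt(2/n_reps)`, the replicate-noise sd propagated to a difference of two
#' replicate means. Both are rank-preserving.
#'
#' @param Z numeric vector of cross-state scores (`NA` allowed).
#' @param R matrix of intra-replicate scores (required for `noise_scaled`).
#' @param cfg a [scoring_config()].
#' @param n_reps replicates per state (default 2).
#' @return numeric vector of Znet, `NA` where Z is `NA`.
#' @export
znet_transform <- function(Z, R = NULL, cfg, n_reps = 2L) {
  ok <- !is.na(Z)
  n <- sum(ok)
  if (n < 50L)
    stop("need >= 50 features with defined Z to calibrate the population (got ",
         n, ")")
  znet <- rep(NA_real_, length(Z))
  names(znet) <- names(Z)
  if (length(unique(Z[ok])) == 1L) {
    warning("degenerate population: all Z identical; Znet set to 0")
    znet[ok] <- 0
    return(znet)
  }
  if (cfg$normalization == "quantile_normal") {
    r <- rank(Z[ok], ties.method = "average")
    znet[ok] <- stats::qnorm((r - 0.5) / n)
  } else {
    if (is.null(R)) stop("noise_scaled normalization needs the R matrix")
    sigma <- stats::sd(as.vector(R), na.rm = TRUE) / sqrt(2) * sqrt(2 / n_reps)
    if (!is.finite(sigma) || sigma == 0) stop("degenerate noise population")
    znet[ok] <- (Z[ok] - stats::median(Z[ok])) / sigma
  }
  znet
}

#' Call up/down regulation from normalized scores
#'
#' Strict inequalities: `Znet > cutoff` is up, `Znet < -cutoff` is down,
#' anything else (including a score exactly at the cutoff) is `ns`.
#'
#' @param znet numeric vector of normalized scores.
#' @param cfg a [scoring_config()].
#' @return character vector in `up/down/ns` (`NA` where `znet` is `NA`).
#' @export
call_differential <- function(znet, cfg) {
  out <- rep(NA_character_, length(znet))
  ok <- !is.na(znet)
  out[ok] <- ifelse(znet[ok] > cfg$cutoff, "up",
                    ifelse(znet[ok] < -cfg$cutoff, "down", "ns"))
  names(out) <- names(znet)
  out
}

#' Presence/absence calls for features unquantified in a whole state
#'
#' Features detected in only one of the two states carry no Znet; they are
#' reported qualitatively: `present_only_in_B` (the "+" of printed tables),
#' `absent_in_B` (detected in state A only), or `undetected`. Features
#' quantified in both states are `quantified` and handled by the Znet path.
#'
#' @param x an [abundance_matrix()].
#' @param cfg a [scoring_config()].
#' @return named character vector per feature.
#' @export
presence_absence_calls <- function(x, cfg) {
  a <- x[, state_columns(x, cfg$state_a), drop = FALSE]
  b <- x[, state_columns(x, cfg$state_b), drop = FALSE]
  in_a <- rowSums(!is.na(a)) > 0L
  in_b <- rowSums(!is.na(b)) > 0L
  out <- ifelse(in_a & in_b, "quantified",
                ifelse(in_b, "present_only_in_B",
                       ifelse(in_a, "absent_in_B", "undetected")))
  names(out) <- rownames(x)
  out
}

#' Score one layer end to end
#'
#' Computes Z, per-state R, Znet, per-feature signal-to-noise and the final
#' call for every feature of one abundance matrix. Features unquantified in a
#' whole state receive a presence/absence call instead of a Znet-based one.
#'
#' @param x an [abundance_matrix()].
#' @param cfg a [scoring_config()].
#' @param snr_floor noise-floor rule for the per-feature S/N, see
#'   [feature_snr()].
#' @return data frame (one row per feature): `feature_id`, `layer`, `Z`,
#'   `R_A`, `R_B`, `Znet`, `call`, `feature_snr`, `low_snr` (TRUE where the
#'   per-feature S/N falls below the calibrated cutoff column is added by
#'   downstream reporting; here `feature_snr` is the raw value).
#' @export
score_differential <- function(x, cfg, snr_floor = c("population", "quantile05")) {
  snr_floor <- match.arg(snr_floor)
  Z <- cross_state_Z(x, cfg)
  R <- intra_replicate_R(x)
  znet <- znet_transform(Z, R, cfg)
  call <- call_differential(znet, cfg)
  pa <- presence_absence_calls(x, cfg)
  call[pa != "quantified"] <- pa[pa != "quantified"]
  ra <- R[, cfg$state_a]
  rb <- R[, cfg$state_b]
  snr <- feature_snr(Z, ra, rb, noise_floor = snr_noise_floor(ra, rb, snr_floor))
  data.frame(feature_id = rownames(x),
             layer = matrix_layer(x),
             Z = unname(Z),
             R_A = unname(ra),
             R_B = unname(rb),
             Znet = unname(znet),
             call = unname(call),
             feature_snr = unname(snr),
             stringsAsFactors = FALSE)
}
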