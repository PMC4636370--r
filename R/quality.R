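#' System signal-to-noise ratio
#'
#' An overall measurement of system quality for a two-state, two-replicate
#' layer: the ratio of the spread of the cross-state population to the mean
#' spread of the intra-replicate (noise) populations,
#' `sd(Z) / mean(sd(R_A), sd(R_B))`. Values near 1 mean the biological
#' signal is buried in replicate noise; values of 3+ mean profound
#' cross-state responses.
#'
#' @param Z numeric vector of cross-state scores (`NA` dropped).
#' @param R matrix of intra-replicate scores, one column per state (from
#'   [intra_replicate_R()]), or a list of per-state numeric vectors.
#' @return positive scalar.
#' @export
system_snr <- function(Z, R) {
  if (is.matrix(R)) R <- lapply(seq_len(ncol(R)), function(j) R[, j])
  if (sum(!is.na(Z)) < 2L || any(vapply(R, function(r) sum(!is.na(r)), 0L) < 2L))
    stop("need >= 2 defined values in each population")
  noise <- mean(vapply(R, stats::sd, 0, na.rm = TRUE))
  if (noise == 0) stop("degenerate noise population (all R identical)")
  stats::sd(Z, na.rm = TRUE) / noise
}

#' Noise floor for the per-feature signal-to-noise ratio
#'
#' The per-feature S/N divides |Z| by that feature's replicate-noise
#' magnitude; with only two replicates per state that magnitude is a 2-df
#' estimate and occasionally lands near zero by chance, which would make
#' pure-noise features look highly significant. The denominator is therefore
#' floored. `"population"` (default) floors it at the population mean rms --
#' the system's noise scale -- so a feature can be *penalized* for unusually
#' noisy replicates but never rewarded for a lucky quiet pair; this is the
#' floor under which the Monte-Carlo calibration "S/N > 2.8 keeps FDR at or
#' below 10%" holds. `"quantile05"` floors at the 5th percentile of the rms
#' population, a minimal guard that leaves the per-feature denominator
#' heavy-tailed (its null S/N is |t|-distributed with 2 df, whose tail above
#' 2.8 is ~6% regardless of the noise scale, so high-S/N selections are not
#' low-FDR under this rule; retained for comparison).
#'
#' @param R_A,R_B per-state intra-replicate scores.
#' @param method `"population"` or `"quantile05"`.
#' @return scalar noise floor (log2 units).
#' @export
snr_noise_floor <- function(R_A, R_B, method = c("population", "quantile05")) {
  method <- match.arg(method)
  rms <- sqrt((R_A^2 + R_B^2) / 2)
  rms <- rms[!is.na(rms)]
  if (!length(rms)) stop("no features with both R values defined")
  switch(method,
         population = mean(rms),
         quantile05 = stats::quantile(rms, 0.05, names = FALSE))
}

#' Per-feature signal-to-noise ratio
#'
#' `|Z| / max(rms(R_A, R_B), noise_floor)` with
#' `rms = sqrt((R_A^2 + R_B^2)/2)`: the magnitude of the cross-state change
#' relative to the feature's own replicate scatter, guarded below by the
#' population noise floor (see [snr_noise_floor()]). Dimensionless and
#' invariant to rescaling all log2 differences by a common factor.
#'
#' @param Z cross-state scores.
#' @param R_A,R_B per-state intra-replicate scores.
#' @param noise_floor scalar floor on the denominator.
#' @return nonnegative numeric vector (`NA` where Z or either R is `NA`).
#' @export
feature_snr <- function(Z, R_A, R_B, noise_floor) {
  rms <- sqrt((R_A^2 + R_B^2) / 2)
  abs(Z) / pmax(rms, noise_floor)
}

#' Monte-Carlo calibration of FDR against an S/N cutoff
#'
#' Estimates, for each cutoff `c`, the false discovery rate of the rule
#' "call every feature with per-feature S/N > c": null datasets with zero
#' cross-state effect are simulated by resampling the empirical
#' intra-replicate noise (or a Gaussian fitted to it), their S/N computed
#' exactly as for the observed features, and
#' `FDR(c) = mean_sims(#null > c) / max(1, #observed > c)`, clipped to
#' \[0, 1\] and made non-increasing in `c` by taking the running maximum
#' from the right (a conservative monotonization, in the spirit of
#' q-values).
#'
#' Under the null, `Z` is distributed as `(R' - R'')/2` for independent
#' draws from the noise population, which is how the numerator is resampled.
#'
#' @param observed_snr per-feature S/N of the observed dataset.
#' @param R_pool pooled intra-replicate scores (both states' R values).
#' @param cutoffs ascending S/N cutoffs at which to evaluate the curve.
#' @param n_sim number of null simulations (>= 100).
#' @param seed RNG seed.
#' @param noise_model `"empirical_R"` (resample `R_pool`) or
#'   `"gaussian_fit"` (draw from `N(0, sd(R_pool))`).
#' @param noise_floor denominator floor, normally the observed population's
#'   [snr_noise_floor()] so null and observed S/N are on the same scale.
#' @return data frame `cutoff`, `fdr`, plus attribute `n_observed_exceed`.
#' @export
monte_carlo_fdr <- function(observed_snr, R_pool, cutoffs, n_sim = 200L,
                            seed = 1L,
                            noise_model = c("empirical_R", "gaussian_fit"),
                            noise_floor) {
  noise_model <- match.arg(noise_model)
  if (n_sim < 100L) stop("`n_sim` must be >= 100")
  if (is.unsorted(cutoffs)) stop("`cutoffs` must be ascending")
  observed_snr <- observed_snr[!is.na(observed_snr)]
  n <- length(observed_snr)
  R_pool <- R_pool[!is.na(R_pool)]
  obs_exceed <- vapply(cutoffs, function(c) sum(observed_snr > c), 0)
  if (obs_exceed[1L] == 0L)
    warning("no observed feature exceeds the smallest cutoff; FDR denominator is empty")
  sd_R <- stats::sd(R_pool)
  null_exceed <- with_seed(seed, {
    acc <- numeric(length(cutoffs))
    for (s in seq_len(n_sim)) {
      draw <- function() {
        if (noise_model == "empirical_R") sample(R_pool, n, replace = TRUE)
        else stats::rnorm(n, 0, sd_R)
      }
      z_null <- (draw() - draw()) / 2
      snr_null <- feature_snr(z_null, draw(), draw(), noise_floor)
      acc <- acc + vapply(cutoffs, function(c) sum(snr_null > c), 0)
    }
    acc / n_sim
  })
  fdr <- pmin(1, null_exceed / pmax(1, obs_exceed))
  fdr <- rev(cummax(rev(fdr)))   # enforce non-increasing in cutoff
  structure(data.frame(cutoff = cutoffs, fdr = fdr),
            n_observed_exceed = obs_exceed)
}

#' RNA-protein correlation and dynamic-range QC
#'
#' Ordinary least-squares R^2 of protein log2 abundance on RNA log2
#' abundance over the features quantified in both layers, computed per state
#' with replicates averaged, plus each layer's dynamic range (max - min of
#' quantified log2 values). A moderate R^2 (roughly 0.2-0.5 in bacterial
#' data) confirms the two layers measure the same biology while leaving room
#' for translational regulation and measurement depth differences.
#'
#' @param rna,protein [abundance_matrix()]s sharing feature identifiers.
#' @return list: `per_state` data frame (`state`, `r_squared`, `n_features`)
#'   and `dynamic_range` named vector (rna, protein).
#' @export
correlation_report <- function(rna, protein) {
  states <- unique(sample_sheet(rna)$state)
  common <- intersect(rownames(rna), rownames(protein))
  per_state <- do.call(rbind, lapply(states, function(st) {
    x <- rowMeans(rna[common, state_columns(rna, st), drop = FALSE], na.rm = TRUE)
    y <- rowMeans(protein[common, state_columns(protein, st), drop = FALSE],
                  na.rm = TRUE)
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L)
      stop("need >= 3 features quantified in both layers (state ", st, ")")
    data.frame(state = st,
               r_squared = stats::cor(x[ok], y[ok])^2,
               n_features = sum(ok),
               stringsAsFactors = FALSE)
  }))
  dr <- c(rna = diff(range(rna, na.rm = TRUE)),
          protein = diff(range(protein, na.rm = TRUE)))
  list(per_state = per_state, dynamic_range = dr)
}

#' Assemble and write a per-layer S/N report
#'
#' @param layer layer label.
#' @param Z,R cross-state and intra-replicate scores for the layer.
#' @param fdr_curve data frame from [monte_carlo_fdr()].
#' @param correlation optional result of [correlation_report()].
#' @return list with `layer`, `system_snr`, `n_features_quantified`,
#'   `fdr_curve`, and (if given) `r_squared_rna_protein` and
#'   `dynamic_range`.
#' @export
snr_report <- function(layer, Z, R, fdr_curve = NULL, correlation = NULL) {
  rep <- list(layer = layer,
              system_snr = system_snr(Z, R),
              n_features_quantified = sum(!is.na(Z)))
  if (!is.null(fdr_curve)) rep$fdr_curve <- fdr_curve
  if (!is.null(correlation)) {
    rep$r_squared_rna_protein <- stats::setNames(
      correlation$per_state$r_squared, correlation$per_state$state)
    rep$dynamic_range <- correlation$dynamic_range
  }
  rep
}

#' @rdname snr_report
#' @param report list from `snr_report`.
#' @param path output JSON path.
#' @export
write_snr_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
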