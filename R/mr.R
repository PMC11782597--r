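CI_Z <- 1.959964  # 95% normal quantile, fixed

mr_result <- function(exposure_id, outcome_id, method, beta, se, n_snp,
                      binary_outcome = TRUE, q_stat = NA_real_,
                      q_pval = NA_real_) {
  ci_low <- beta - CI_Z * se
  ci_high <- beta + CI_Z * se
  data.frame(exposure_id = exposure_id, outcome_id = outcome_id,
             method = method, n_snp = n_snp, beta = beta, se = se,
             ci_low = ci_low, ci_high = ci_high,
             or_ = if (binary_outcome) exp(beta) else NA_real_,
             or_low = if (binary_outcome) exp(ci_low) else NA_real_,
             or_high = if (binary_outcome) exp(ci_high) else NA_real_,
             q_stat = q_stat, q_pval = q_pval,
             pval = 2 * stats::pnorm(-abs(beta / se)),
             stringsAsFactors = FALSE)
}

#' Wald-ratio causal estimate from a single harmonized SNP
#'
#' beta = beta_y / beta_x with first-order delta-method standard error
#' se_y / |beta_x|; 95% CI uses the 1.959964 normal multiplier. For binary
#' outcomes the estimate is a log odds ratio per exposure-increasing unit,
#' and odds-ratio fields are populated.
#'
#' @param row a one-row harmonized data.frame from [harmonize_pair()].
#' @param exposure_id,outcome_id trait labels carried into the result.
#' @param binary_outcome populate odds-ratio fields?
#' @return a one-row `MrResult` data.frame: `method`, `n_snp`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `or_`, `or_low`, `or_high`, `q_stat`,
#'   `q_pval`, `pval`.
#' @export
wald_ratio <- function(row, exposure_id = NA_character_,
                       outcome_id = NA_character_, binary_outcome = TRUE) {
  if (is.na(row$beta_x) || row$beta_x == 0) {
    stop("degenerate instrument: SNP-exposure association is zero")
  }
  beta <- row$beta_y / row$beta_x
  se <- row$se_y / abs(row$beta_x)
  mr_result(exposure_id, outcome_id, "wald", beta, se, n_snp = 1L,
            binary_outcome = binary_outcome)
}

#' Inverse-variance-weighted multiplicative-random-effects estimate
#'
#' Weighted regression of the outcome on the exposure associations through
#' the origin with weights 1/se_y^2: beta = sum(w bx by) / sum(w bx^2),
#' fixed-effect se 1/sqrt(sum(w bx^2)). Cochran's Q over the k SNPs feeds
#' a multiplicative variance-inflation factor phi = max(1, sqrt(Q/(k-1)))
#' so the reported se is never below the fixed-effect one.
#'
#' @param rows data.frame of >= 2 harmonized rows.
#' @inheritParams wald_ratio
#' @return a one-row `MrResult` data.frame with heterogeneity fields
#'   `q_stat` and `q_pval` (chi-square, k-1 df).
#' @export
ivw_mre <- function(rows, exposure_id = NA_character_,
                    outcome_id = NA_character_, binary_outcome = TRUE) {
  k <- nrow(rows)
  if (k < 2L) stop("IVW requires >= 2 SNPs; use wald_ratio for one")
  w <- 1 / rows$se_y^2
  beta <- sum(w * rows$beta_x * rows$beta_y) / sum(w * rows$beta_x^2)
  se_fixed <- 1 / sqrt(sum(w * rows$beta_x^2))
  q <- sum(w * (rows$beta_y - beta * rows$beta_x)^2)
  phi <- max(1, sqrt(q / (k - 1)))
  q_pval <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  mr_result(exposure_id, outcome_id, "ivw_mre", beta, phi * se_fixed,
            n_snp = k, binary_outcome = binary_outcome,
            q_stat = q, q_pval = q_pval)
}

#' Liability-model parameters for a binary trait
#'
#' @param prevalence_k population disease prevalence, in (0,1).
#' @param case_fraction_p proportion of cases in the GWAS sample, in (0,1).
#' @return list of class `liability_params`.
#' @export
liability_params <- function(prevalence_k, case_fraction_p) {
  stopifnot(prevalence_k > 0, prevalence_k < 1,
            case_fraction_p > 0, case_fraction_p < 1)
  structure(list(prevalence_k = prevalence_k,
                 case_fraction_p = case_fraction_p),
            class = "liability_params")
}

#' Convert observed-scale variance explained to the liability scale
#'
#' Applies the standard threshold-model transformation
#' r2_liab = r2_obs * K^2 (1-K)^2 / (z^2 P (1-P)), with K the population
#' prevalence, P the sample case fraction, and z the standard normal
#' density at the liability threshold qnorm(1-K).
#'
#' @param r2_obs observed-scale variance explained.
#' @param lp a [liability_params()].
#' @return liability-scale variance explained.
#' @export
observed_to_liability_r2 <- function(r2_obs, lp) {
  stopifnot(inherits(lp, "liability_params"))
  k <- lp$prevalence_k
  p <- lp$case_fraction_p
  z <- stats::dnorm(stats::qnorm(1 - k))
  r2_obs * k^2 * (1 - k)^2 / (z^2 * p * (1 - p))
}

#' Pool study-specific prevalences into a weighted prevalence
#'
#' Fixed-effect pooling on the logit scale with caller-supplied weights
#' (conventionally the contributing GWAS effective sample sizes),
#' back-transformed to a proportion.
#'
#' @param prevalences numeric vector of prevalences in (0,1).
#' @param weights positive weights, recycled if scalar; defaults to equal.
#' @return pooled prevalence.
#' @export
weighted_prevalence <- function(prevalences, weights = NULL) {
  if (length(prevalences) == 0L) stop("no prevalences supplied")
  stopifnot(all(prevalences > 0 & prevalences < 1))
  if (is.null(weights)) weights <- rep(1, length(prevalences))
  weights <- rep_len(weights, length(prevalences))
  stopifnot(all(weights > 0))
  stats::plogis(sum(weights * stats::qlogis(prevalences)) / sum(weights))
}

#' Steiger directionality test
#'
#' Sums per-SNP variance explained ([compute_r2()]) over the instrument on
#' both the exposure and the outcome side; for a binary outcome the
#' outcome-side value is converted to the liability scale with
#' [observed_to_liability_r2()]. The tested direction is supported
#' (`direction_true`) when the instrument explains strictly more variance
#' in the exposure than in the outcome. The p-value compares the
#' Fisher-transformed correlations sqrt(r2) at the two sample sizes with a
#' two-sample z-test.
#'
#' With a single SNP the test cannot distinguish causal from pleiotropic
#' models, so the result carries `single_snp = TRUE` and should be
#' interpreted jointly with bidirectional MR consistency.
#'
#' @param rows harmonized rows with exposure/outcome betas, SEs,
#'   frequencies and sample sizes.
#' @param outcome_binary is the outcome a case-control trait?
#' @param lp a [liability_params()] (required when `outcome_binary`).
#' @return one-row data.frame: `r2_exposure`, `r2_outcome`,
#'   `direction_true`, `pval`, `single_snp`.
#' @export
steiger <- function(rows, outcome_binary = TRUE, lp = NULL) {
  rows <- rows[rows$action != "dropped", , drop = FALSE]
  if (nrow(rows) == 0L) stop("no harmonized rows for Steiger test")
  r2x <- sum(compute_r2(rows$beta_x, rows$eaf, rows$se_x, rows$n_x))
  r2y <- sum(compute_r2(rows$beta_y, rows$eaf_y, rows$se_y, rows$n_y))
  if (outcome_binary) {
    if (is.null(lp)) stop("liability_params required for a binary outcome")
    r2y <- observed_to_liability_r2(r2y, lp)
  }
  r2x <- min(r2x, 1 - 1e-12)
  r2y <- min(r2y, 1 - 1e-12)
  nx <- mean(rows$n_x)
  ny <- mean(rows$n_y)
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (nx - 3) + 1 / (ny - 3))
  data.frame(r2_exposure = r2x, r2_outcome = r2y,
             direction_true = r2x > r2y,
             pval = 2 * stats::pnorm(-abs(z)),
             single_snp = nrow(rows) == 1L)
}
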