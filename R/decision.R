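#' Tier assignment from criteria booleans and colocalization evidence
#'
#' Pure function mapping the four screening criteria and the maximum h4
#' across colocalization windows to a tier:
#' \itemize{
#'   \item `not_shared` - a forward estimate is missing (protein not
#'     instrumented on both platforms);
#'   \item `inconsistent` - forward effect directions disagree;
#'   \item `suggestive` - directions agree but confidence intervals,
#'     Steiger support or reverse-MR nullity fail;
#'   \item `consistent_candidate` - all four criteria hold;
#'   \item `colocalized_candidate` - all four criteria hold and max h4
#'     exceeds the threshold.
#' }
#'
#' @param criteria named logical vector with elements
#'   `consistent_direction`, `both_ci_exclude_null`, `steiger_true`,
#'   `no_reverse_effect`; any `NA` counts as failed.
#' @param h4_max maximum posterior probability of a shared causal variant
#'   across windows (`NA` if colocalization was not run).
#' @param h4_threshold colocalization evidence bound (strict inequality;
#'   default 0.8).
#' @return tier string.
#' @export
assign_tier <- function(criteria, h4_max = NA_real_, h4_threshold = 0.8) {
  cr <- criteria[c("consistent_direction", "both_ci_exclude_null",
                   "steiger_true", "no_reverse_effect")]
  cr[is.na(cr)] <- FALSE
  if (!cr[["consistent_direction"]]) return("inconsistent")
  if (!all(cr)) return("suggestive")
  if (!is.na(h4_max) && h4_max > h4_threshold) return("colocalized_candidate")
  "consistent_candidate"
}

#' Evaluate a protein as a causal candidate
#'
#' Applies the multi-step decision rule across the two forward MR analyses
#' (one per proteomic platform): (1) effect directions agree, (2) both 95%
#' CIs exclude the null (log-odds scale), (3) both Steiger tests support
#' the protein-to-disease direction, (4) the reverse MR shows no evidence
#' of effect (absent, or every reverse CI overlaps 0). Colocalization
#' evidence (max h4 > `h4_threshold` in any window) upgrades a
#' `consistent_candidate` to `colocalized_candidate`.
#'
#' @param protein_id gene-symbol identifier.
#' @param forward_a,forward_b one-row `MrResult` data.frames (platform A
#'   and B forward MR), or `NULL` when the protein lacks an instrument on
#'   that platform.
#' @param reverse a one-row `MrResult`, a list of them (e.g. one per
#'   platform), or `NULL` when reverse MR was not assessable.
#' @param steiger_a,steiger_b one-row results from [steiger()], or `NULL`.
#' @param coloc data.frame from [windowed_coloc()], or `NULL`.
#' @param h4_threshold colocalization bound (default 0.8).
#' @return list of class `candidate_record`: inputs plus `criteria` (named
#'   logical) and `tier`.
#' @export
evaluate_candidate <- function(protein_id, forward_a, forward_b,
                               reverse = NULL, steiger_a = NULL,
                               steiger_b = NULL, coloc = NULL,
                               h4_threshold = 0.8) {
  h4_max <- if (!is.null(coloc) && any(is.finite(coloc$h4))) {
    max(coloc$h4, na.rm = TRUE)
  } else NA_real_
  if (is.null(forward_a) || is.null(forward_b)) {
    rec <- list(protein_id = protein_id, forward_a = forward_a,
                forward_b = forward_b, reverse = reverse,
                steiger_a = steiger_a, steiger_b = steiger_b, coloc = coloc,
                criteria = c(consistent_direction = NA,
                             both_ci_exclude_null = NA,
                             steiger_true = NA, no_reverse_effect = NA),
                h4_max = h4_max, tier = "not_shared")
    class(rec) <- "candidate_record"
    return(rec)
  }
  consistent <- sign(forward_a$beta) == sign(forward_b$beta) &&
    forward_a$beta != 0
  excl <- function(r) r$ci_low > 0 || r$ci_high < 0
  both_ci <- excl(forward_a) && excl(forward_b)
  st <- !is.null(steiger_a) && !is.null(steiger_b) &&
    isTRUE(steiger_a$direction_true) && isTRUE(steiger_b$direction_true)
  rev_list <- if (is.null(reverse)) list() else
    if (is.data.frame(reverse)) list(reverse) else reverse
  rev_list <- Filter(Negate(is.null), rev_list)
  no_rev <- length(rev_list) == 0L ||
    all(vapply(rev_list, function(r) r$ci_low <= 0 && r$ci_high >= 0,
               logical(1)))
  criteria <- c(consistent_direction = consistent,
                both_ci_exclude_null = both_ci,
                steiger_true = st,
                no_reverse_effect = no_rev)
  rec <- list(protein_id = protein_id, forward_a = forward_a,
              forward_b = forward_b, reverse = rev_list,
              steiger_a = steiger_a, steiger_b = steiger_b, coloc = coloc,
              criteria = criteria, h4_max = h4_max,
              tier = assign_tier(criteria, h4_max, h4_threshold))
  class(rec) <- "candidate_record"
  rec
}

#' @export
print.candidate_record <- function(x, ...) {
  cat(sprintf("<candidate_record> %s: tier %s\n", x$protein_id, x$tier))
  if (!all(is.na(x$criteria))) {
    cat("  criteria:", paste(names(x$criteria), ifelse(x$criteria, "+", "-"),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reverse Mendelian randomization: disease liability on protein levels
#'
#' Harmonizes the disease instruments against a protein summary-statistic
#' set (with LD proxy substitution when available) and estimates the
#' effect of disease liability on the protein: Wald ratio for a single
#' SNP, IVW multiplicative random effects for two or more. The estimate is
#' in protein SD units per unit of disease log-odds. When the instruments
#' came from a relaxed (sub-genome-wide) p-value threshold the result
#' carries `relaxed_threshold = TRUE` and should be read as a
#' falsification probe, not a causal estimate.
#'
#' @param disease_instruments data.frame of clumped disease association
#'   records (see [clump()]).
#' @param protein a quantitative [sumstat_set()].
#' @param cfg a [harmonize_config()].
#' @param ld optional [ld_matrix()] enabling proxy lookup.
#' @param relaxed_threshold flag propagated into the result.
#' @return a one-row `MrResult` data.frame with extra column
#'   `relaxed_threshold`, or `NULL` when no instrument could be extracted
#'   (not assessable).
#' @export
reverse_mr <- function(disease_instruments, protein,
                       cfg = harmonize_config(), ld = NULL,
                       relaxed_threshold = FALSE) {
  stopifnot(inherits(protein, "sumstat_set"))
  if (is.null(disease_instruments) || nrow(disease_instruments) == 0L) {
    return(NULL)
  }
  rows <- harmonize_set(disease_instruments, protein, ld = ld, cfg = cfg)
  rows <- rows[rows$action != "dropped", , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  res <- if (nrow(rows) == 1L) {
    wald_ratio(rows, exposure_id = "disease", outcome_id = protein$trait_id,
               binary_outcome = FALSE)
  } else {
    ivw_mre(rows, exposure_id = "disease", outcome_id = protein$trait_id,
            binary_outcome = FALSE)
  }
  res$relaxed_threshold <- relaxed_threshold
  res
}
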