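#' Harmonization configuration
#'
#' @param proxy_min_r2 minimum LD r-squared for a proxy SNP (default 0.8).
#' @param palindrome_maf_max strand inference for palindromic (A/T, C/G)
#'   pairs is attempted only when both records' minor allele frequency is
#'   below this bound (default 0.3); otherwise the pair is dropped as
#'   ambiguous.
#' @param allow_palindromes if `FALSE`, palindromic pairs are always
#'   dropped.
#' @return list of class `harmonize_config`.
#' @export
harmonize_config <- function(proxy_min_r2 = 0.8, palindrome_maf_max = 0.3,
                             allow_palindromes = TRUE) {
  stopifnot(proxy_min_r2 > 0, proxy_min_r2 <= 1,
            palindrome_maf_max > 0, palindrome_maf_max <= 0.5)
  structure(list(proxy_min_r2 = proxy_min_r2,
                 palindrome_maf_max = palindrome_maf_max,
                 allow_palindromes = allow_palindromes),
            class = "harmonize_config")
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[[a1]] == a2

harmonized_row <- function(rsid_exposure, rsid_outcome, beta_x = NA_real_,
                           se_x = NA_real_, beta_y = NA_real_, se_y = NA_real_,
                           eaf = NA_real_, eaf_y = NA_real_,
                           n_x = NA_real_, n_y = NA_real_,
                           action, drop_reason = NA_character_) {
  data.frame(rsid_exposure = rsid_exposure, rsid_outcome = rsid_outcome,
             beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
             eaf = eaf, eaf_y = eaf_y, n_x = n_x, n_y = n_y,
             action = action, drop_reason = drop_reason,
             stringsAsFactors = FALSE)
}

#' Harmonize one exposure/outcome record pair to a shared effect allele
#'
#' Aligns the outcome record to the exposure's effect allele, resolving
#' allele swaps and strand flips, inferring strand for palindromic (A/T,
#' C/G) pairs from allele frequency when both minor allele frequencies are
#' below `palindrome_maf_max`, and finally orienting the pair so the
#' exposure effect allele is the exposure-increasing allele (`beta_x >=
#' 0`). Forward MR estimates downstream are therefore per
#' exposure-increasing (normalized SD) unit.
#'
#' Actions: `direct` (alleles already aligned), `flipped` (outcome alleles
#' swapped: outcome beta negated, frequency complemented),
#' `strand_inferred` (complement-strand match or palindromic pair resolved
#' via MAF), `dropped` (`drop_reason` one of `ambiguous_palindrome`,
#' `palindrome_disallowed`, `incompatible_alleles`).
#'
#' @param exp,out one-row data.frames (or lists) with fields `rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `n`; must share
#'   the rsid.
#' @param cfg a [harmonize_config()].
#' @return a one-row data.frame (harmonized row) with fields
#'   `rsid_exposure`, `rsid_outcome`, `beta_x`, `se_x`, `beta_y`, `se_y`,
#'   `eaf` (exposure-side, aligned), `eaf_y` (outcome-side, aligned),
#'   `n_x`, `n_y`, `action`, `drop_reason`.
#' @export
harmonize_pair <- function(exp, out, cfg = harmonize_config()) {
  if (exp$rsid != out$rsid) stop("exposure and outcome rsids differ")
  e1 <- exp$effect_allele; e2 <- exp$other_allele
  o1 <- out$effect_allele; o2 <- out$other_allele
  beta_y <- out$beta; eaf_y <- out$eaf
  action <- NA_character_

  if (is_palindromic(e1, e2)) {
    same_pair <- (o1 == e1 && o2 == e2) || (o1 == e2 && o2 == e1)
    if (!same_pair) {
      return(harmonized_row(exp$rsid, out$rsid, action = "dropped",
                            drop_reason = "incompatible_alleles"))
    }
    if (!cfg$allow_palindromes) {
      return(harmonized_row(exp$rsid, out$rsid, action = "dropped",
                            drop_reason = "palindrome_disallowed"))
    }
    maf_e <- min(exp$eaf, 1 - exp$eaf)
    maf_o <- min(out$eaf, 1 - out$eaf)
    if (maf_e >= cfg$palindrome_maf_max || maf_o >= cfg$palindrome_maf_max) {
      return(harmonized_row(exp$rsid, out$rsid, action = "dropped",
                            drop_reason = "ambiguous_palindrome"))
    }
    # Allele labels cannot identify the strand; frequencies can. The
    # outcome's eaf is first expressed on the exposure's effect-allele
    # labelling, then compared: same side of 0.5 means aligned.
    if (o1 == e2) { beta_y <- -beta_y; eaf_y <- 1 - eaf_y }
    same_side <- (exp$eaf < 0.5) == (eaf_y < 0.5)
    if (!same_side) { beta_y <- -beta_y; eaf_y <- 1 - eaf_y }
    action <- "strand_inferred"
  } else if (o1 == e1 && o2 == e2) {
    action <- "direct"
  } else if (o1 == e2 && o2 == e1) {
    beta_y <- -beta_y; eaf_y <- 1 - eaf_y
    action <- "flipped"
  } else if (o1 == COMPLEMENT[[e1]] && o2 == COMPLEMENT[[e2]]) {
    action <- "strand_inferred"
  } else if (o1 == COMPLEMENT[[e2]] && o2 == COMPLEMENT[[e1]]) {
    beta_y <- -beta_y; eaf_y <- 1 - eaf_y
    action <- "strand_inferred"
  } else {
    return(harmonized_row(exp$rsid, out$rsid, action = "dropped",
                          drop_reason = "incompatible_alleles"))
  }

  beta_x <- exp$beta; eaf_x <- exp$eaf
  if (beta_x < 0) {
    beta_x <- -beta_x; beta_y <- -beta_y
    eaf_x <- 1 - eaf_x; eaf_y <- 1 - eaf_y
  }
  harmonized_row(exp$rsid, out$rsid, beta_x = beta_x, se_x = exp$se,
                 beta_y = beta_y, se_y = out$se, eaf = eaf_x, eaf_y = eaf_y,
                 n_x = exp$n, n_y = out$n, action = action)
}

#' Find an LD proxy for a SNP absent from the outcome set
#'
#' Among variants present in the outcome set with LD r-squared >=
#' `proxy_min_r2` to the target, returns the one with the highest
#' r-squared (ties broken by genomic proximity to the target). The allele
#' mapping carries the sign of r: when r < 0 the proxy's effect allele
#' tracks the target's *other* allele, and the proxy record must be
#' swapped (beta negated, eaf complemented) before standing in for the
#' target.
#'
#' @param target_rsid the missing exposure SNP.
#' @param outcome a [sumstat_set()].
#' @param ld an [ld_matrix()] covering the target and candidates; the sign
#'   of r must refer to the effect alleles of the summary statistics.
#' @param cfg a [harmonize_config()].
#' @return `NULL` if no qualifying proxy, else a list with `rsid`, `r`,
#'   `r2` and `swap` (logical: r < 0).
#' @export
find_proxy <- function(target_rsid, outcome, ld, cfg = harmonize_config()) {
  stopifnot(inherits(outcome, "sumstat_set"), inherits(ld, "ld_matrix"))
  ti <- match(target_rsid, ld$rsids)
  if (is.na(ti)) stop("target rsid absent from LD matrix: ", target_rsid)
  if (target_rsid %in% outcome$records$rsid) {
    return(list(rsid = target_rsid, r = 1, r2 = 1, swap = FALSE))
  }
  cand <- intersect(outcome$records$rsid, ld$rsids)
  cand <- setdiff(cand, target_rsid)
  if (length(cand) == 0L) return(NULL)
  ci <- match(cand, ld$rsids)
  r <- ld$r[ti, ci]
  r2 <- r^2
  ok <- r2 >= cfg$proxy_min_r2
  if (!any(ok)) return(NULL)
  cand <- cand[ok]; r <- r[ok]; r2 <- r2[ok]; ci <- ci[ok]
  dist <- abs(ld$positions[ci] - ld$positions[ti])
  best <- order(-r2, dist)[1L]
  list(rsid = cand[best], r = r[best], r2 = r2[best], swap = r[best] < 0)
}

#' Harmonize an instrument against an outcome summary-statistic set
#'
#' For each exposure record, looks up the outcome record by rsid
#' (substituting an LD proxy when absent and `ld` is supplied) and applies
#' [harmonize_pair()]. Proxy substitution keeps the exposure statistics of
#' the original sentinel; the outcome side uses the proxy's own record,
#' allele-swapped when the LD sign is negative, and the action is recorded
#' as `proxied`.
#'
#' @param exposure_records data.frame of exposure association records.
#' @param outcome a [sumstat_set()].
#' @param ld optional [ld_matrix()] enabling proxy lookup.
#' @param cfg a [harmonize_config()].
#' @return data.frame of harmonized rows, one per exposure record (dropped
#'   rows carry their reason).
#' @export
harmonize_set <- function(exposure_records, outcome, ld = NULL,
                          cfg = harmonize_config()) {
  stopifnot(inherits(outcome, "sumstat_set"))
  rows <- lapply(seq_len(nrow(exposure_records)), function(i) {
    exp <- exposure_records[i, , drop = FALSE]
    orec <- outcome$records[outcome$records$rsid == exp$rsid, , drop = FALSE]
    proxied <- FALSE
    if (nrow(orec) == 0L) {
      if (is.null(ld) || !(exp$rsid %in% ld$rsids)) {
        return(harmonized_row(exp$rsid, NA_character_, action = "dropped",
                              drop_reason = "absent_from_outcome"))
      }
      px <- find_proxy(exp$rsid, outcome, ld, cfg)
      if (is.null(px)) {
        return(harmonized_row(exp$rsid, NA_character_, action = "dropped",
                              drop_reason = "no_proxy"))
      }
      orec <- outcome$records[outcome$records$rsid == px$rsid, , drop = FALSE]
      if (px$swap) {
        orec$beta <- -orec$beta
        orec$eaf <- 1 - orec$eaf
        tmp <- orec$effect_allele
        orec$effect_allele <- orec$other_allele
        orec$other_allele <- tmp
      }
      # The proxy stands in for the target variant: alleles are matched
      # through the LD sign, so relabel to the exposure's alleles.
      orec$rsid <- exp$rsid
      proxied <- TRUE
      proxy_rsid <- px$rsid
      orec$effect_allele <- exp$effect_allele
      orec$other_allele <- exp$other_allele
    }
    h <- harmonize_pair(exp, orec[1L, , drop = FALSE], cfg)
    if (proxied) {
      h$rsid_outcome <- proxy_rsid
      if (h$action != "dropped") h$action <- "proxied"
    }
    h
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
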