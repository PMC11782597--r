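CHISQ_MEDIAN_1DF <- 0.4549364  # qchisq(0.5, 1)

#' Genomic-control adjustment of a summary-statistic set
#'
#' Computes the inflation factor lambda = median((beta/se)^2) / 0.4549 and,
#' when lambda > 1, multiplies every standard error by sqrt(lambda) and
#' recomputes two-sided normal p-values; lambda is floored at 1. With
#' fewer than 100 variants the median is unreliable: a warning is issued
#' and lambda is forced to 1.
#'
#' @param set a [sumstat_set()].
#' @return list with `set` (adjusted) and `lambda` (the factor applied).
#' @export
genomic_control <- function(set) {
  stopifnot(inherits(set, "sumstat_set"))
  rec <- set$records
  if (nrow(rec) < 100L) {
    warning("fewer than 100 variants: lambda unreliable, forced to 1")
    return(list(set = set, lambda = 1))
  }
  z2 <- (rec$beta / rec$se)^2
  lambda <- stats::median(z2) / CHISQ_MEDIAN_1DF
  lambda <- max(1, lambda)
  if (lambda > 1) {
    rec$se <- rec$se * sqrt(lambda)
    rec$pval <- 2 * stats::pnorm(-abs(rec$beta / rec$se))
    set$records <- rec
  }
  list(set = set, lambda = lambda)
}

#' Fixed-effect meta-analysis of one variant across studies
#'
#' Inverse-variance weights w_i = 1/se_i^2 give beta = sum(w b)/sum(w),
#' se = 1/sqrt(sum(w)), a two-sided normal p-value, Cochran's Q and a
#' heterogeneity p-value on n_studies - 1 degrees of freedom. Betas must
#' already refer to a shared effect allele (see [meta_analyse()] for
#' allele alignment across whole sets).
#'
#' @param betas,ses per-study effect estimates and standard errors
#'   (length >= 2).
#' @return one-row data.frame: `beta_meta`, `se_meta`, `pval_meta`,
#'   `q_stat`, `het_pval`, `n_studies`.
#' @export
meta_fixed <- function(betas, ses) {
  stopifnot(length(betas) == length(ses), length(betas) >= 2L, all(ses > 0))
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (betas - beta)^2)
  data.frame(beta_meta = beta, se_meta = se,
             pval_meta = 2 * stats::pnorm(-abs(beta / se)),
             q_stat = q,
             het_pval = stats::pchisq(q, df = length(betas) - 1,
                                      lower.tail = FALSE),
             n_studies = length(betas))
}

#' Meta-analyse two GWAS summary-statistic sets
#'
#' Applies per-study genomic control (optional), aligns study B's alleles
#' to study A's with the harmonization rules (swapped and
#' complement-strand pairs flipped; ambiguous palindromes dropped),
#' meta-analyses shared variants with [meta_fixed()], and drops variants
#' present in only one study (heterogeneity is undefined for them). The
#' pooled set keeps the effect alleles of study A; sample sizes and
#' case/control counts are summed and the pooled EAF is a sample-size
#' weighted average.
#'
#' @param set_a,set_b two [sumstat_set()] objects for the same trait.
#' @param apply_gc apply [genomic_control()] to each study first?
#' @param cfg a [harmonize_config()] governing allele alignment.
#' @return list with `set` (a pooled `sumstat_set` whose records carry the
#'   extra columns `q_stat` and `het_pval`), `lambda` (per-study factors),
#'   and `n_dropped_alignment`.
#' @export
meta_analyse <- function(set_a, set_b, apply_gc = TRUE,
                         cfg = harmonize_config()) {
  stopifnot(inherits(set_a, "sumstat_set"), inherits(set_b, "sumstat_set"))
  lambda <- c(NA_real_, NA_real_)
  if (apply_gc) {
    gc_a <- genomic_control(set_a); set_a <- gc_a$set; lambda[1] <- gc_a$lambda
    gc_b <- genomic_control(set_b); set_b <- gc_b$set; lambda[2] <- gc_b$lambda
  }
  a <- set_a$records
  b <- set_b$records
  shared <- intersect(a$rsid, b$rsid)
  a <- a[match(shared, a$rsid), , drop = FALSE]
  b <- b[match(shared, b$rsid), , drop = FALSE]

  kept <- logical(length(shared))
  res <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    h <- harmonize_pair(
      exp = a[i, , drop = FALSE],
      out = b[i, , drop = FALSE], cfg = cfg)
    if (h$action == "dropped") next
    # harmonize_pair orients to the exposure-increasing allele; undo that
    # final orientation so the meta keeps study A's original effect allele.
    flip <- a$beta[i] < 0
    b_beta <- if (flip) -h$beta_y else h$beta_y
    m <- meta_fixed(c(a$beta[i], b_beta), c(a$se[i], b$se[i]))
    b_eaf <- if (flip) 1 - h$eaf_y else h$eaf_y
    row <- a[i, , drop = FALSE]
    row$beta <- m$beta_meta
    row$se <- m$se_meta
    row$pval <- m$pval_meta
    row$eaf <- (a$eaf[i] * a$n[i] + b_eaf * b$n[i]) / (a$n[i] + b$n[i])
    row$n <- a$n[i] + b$n[i]
    row$n_case <- a$n_case[i] + b$n_case[i]
    row$n_control <- a$n_control[i] + b$n_control[i]
    row$q_stat <- m$q_stat
    row$het_pval <- m$het_pval
    res[[i]] <- row
    kept[i] <- TRUE
  }
  rec <- do.call(rbind, res[kept])
  out <- set_a
  out$trait_id <- paste0(set_a$trait_id, "_meta")
  out$platform <- paste(set_a$platform, set_b$platform, sep = "+")
  if (is.null(rec)) {
    rec <- a[0, , drop = FALSE]
    rec$q_stat <- numeric(0)
    rec$het_pval <- numeric(0)
  }
  rownames(rec) <- NULL
  out$records <- rec
  list(set = out, lambda = lambda,
       n_dropped_alignment = sum(!kept))
}

#' Remove meta-analysis variants with cross-study heterogeneity
#'
#' Variants with heterogeneity p-value less than or equal to the threshold
#' (inclusive bound) are removed.
#'
#' @param set a pooled `sumstat_set` from [meta_analyse()] whose records
#'   carry `het_pval`.
#' @param threshold removal bound (default 0.05; `het_pval <= threshold`
#'   removes).
#' @return list with `set` (filtered), `n_removed` and `removed` (the
#'   removed records).
#' @export
filter_heterogeneity <- function(set, threshold = 0.05) {
  stopifnot(inherits(set, "sumstat_set"))
  rec <- set$records
  if (!"het_pval" %in% names(rec)) stop("records lack het_pval; run meta_analyse first")
  remove <- rec$het_pval <= threshold
  set$records <- rec[!remove, , drop = FALSE]
  rownames(set$records) <- NULL
  list(set = set, n_removed = sum(remove),
       removed = rec[remove, , drop = FALSE])
}
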