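#' Instrument-selection configuration
#'
#' Thresholds governing cis-pQTL sentinel selection and LD clumping of
#' disease instruments. Defaults follow the screen's conventions: cis
#' window of 1 Mb from the transcription start site; per-platform exposure
#' significance presets (1.8e-9 for a deCODE-like platform, 1.7e-11 for a
#' UKB-PPP-like one); genome-wide 5e-8 for disease instruments with a
#' relaxed 5e-7 fallback; clumping at r-squared 0.001 within a 10 kb
#' window; regional SNPs at r-squared >= 0.8 merged into one region.
#'
#' @param cis_window_bp maximum distance (bp, closed interval) from the
#'   TSS for a cis candidate.
#' @param pthreshold_exposure exposure p-value cutoff (exclusive, p <
#'   threshold).
#' @param pthreshold_outcome disease-instrument p-value cutoff.
#' @param pthreshold_outcome_relaxed fallback cutoff when no SNP passes
#'   the primary one.
#' @param clump_r2 r-squared above which a SNP is discarded during
#'   clumping (exclusive, r2 > clump_r2 discards).
#' @param clump_window_bp pairwise-distance window (bp) within which
#'   clumping applies.
#' @param merge_r2 r-squared at/above which regional SNPs collapse into a
#'   single region during cis-region merging.
#' @param region_flank_bp flank on each side of a candidate SNP defining
#'   its region for overlap merging (half of a 1 Mb total region width).
#' @param mhc an optional `c(chrom, start, end)`-style list
#'   (`list(chrom=, start=, end=)`) treated as a single merged region
#'   (major histocompatibility complex); `NULL` disables.
#' @return a list of class `selection_config`.
#' @export
selection_config <- function(cis_window_bp = 1e6,
                             pthreshold_exposure = 1.8e-9,
                             pthreshold_outcome = 5e-8,
                             pthreshold_outcome_relaxed = 5e-7,
                             clump_r2 = 0.001,
                             clump_window_bp = 1e4,
                             merge_r2 = 0.8,
                             region_flank_bp = 5e5,
                             mhc = NULL) {
  stopifnot(cis_window_bp > 0, clump_window_bp > 0, region_flank_bp > 0,
            pthreshold_exposure > 0, pthreshold_exposure <= 1,
            pthreshold_outcome > 0, pthreshold_outcome <= 1,
            clump_r2 >= 0, clump_r2 <= 1, merge_r2 > 0, merge_r2 <= 1)
  structure(list(cis_window_bp = cis_window_bp,
                 pthreshold_exposure = pthreshold_exposure,
                 pthreshold_outcome = pthreshold_outcome,
                 pthreshold_outcome_relaxed = pthreshold_outcome_relaxed,
                 clump_r2 = clump_r2, clump_window_bp = clump_window_bp,
                 merge_r2 = merge_r2, region_flank_bp = region_flank_bp,
                 mhc = mhc),
            class = "selection_config")
}

#' Variance in the exposure explained by one SNP
#'
#' R2 = 2 b^2 q (1-q) / (2 b^2 q (1-q) + se^2 2 N q (1-q)), with b the
#' SNP-exposure association, q the effect-allele frequency, se its standard
#' error and N the GWAS sample size.
#'
#' @param beta SNP-exposure association (per effect-allele copy).
#' @param eaf effect-allele frequency in (0,1).
#' @param se standard error of `beta` (> 0).
#' @param n sample size of the exposure GWAS.
#' @return variance explained, in [0, 1). Vectorized.
#' @export
compute_r2 <- function(beta, eaf, se, n) {
  stopifnot(all(se > 0), all(eaf > 0 & eaf < 1), all(n > 0))
  num <- 2 * beta^2 * eaf * (1 - eaf)
  den <- num + se^2 * 2 * n * eaf * (1 - eaf)
  num / den
}

#' Instrument-strength F-statistic
#'
#' F = R2 (N - 1 - k) / ((1 - R2) k), with k the number of SNPs in the
#' instrument. F > 10 conventionally indicates a strong instrument.
#'
#' @param r2 variance explained in [0, 1).
#' @param n sample size; must exceed k + 1.
#' @param k number of instrument SNPs (>= 1).
#' @return the F-statistic.
#' @export
compute_f_stat <- function(r2, n, k = 1) {
  stopifnot(all(r2 >= 0), all(r2 < 1), all(k >= 1))
  if (any(n <= k + 1)) stop("sample size must exceed k + 1")
  r2 * (n - 1 - k) / ((1 - r2) * k)
}

# Order candidates by (p ascending, position ascending): deterministic
# tie-break, lower genomic position wins.
order_by_p <- function(records) {
  order(records$pval, records$pos)
}

#' Select the sentinel cis-SNP instrumenting a protein
#'
#' Candidate SNPs are those below the exposure p-threshold and within
#' `cis_window_bp` of the gene's transcription start site (closed
#' interval). A region of `2 * region_flank_bp` is defined around each
#' candidate; starting from the lowest-p SNP, overlapping regions are
#' merged until none overlap, and candidates in LD r-squared >=
#' `merge_r2` collapse into a single region. The lowest-p SNP of the
#' merged region containing the overall lowest-p candidate is returned as
#' the single sentinel, with its variance explained and F-statistic.
#'
#' @param protein_sumstats a [sumstat_set()] for the protein.
#' @param gene one row of a gene-annotation data.frame (`gene_symbol`,
#'   `chrom`, `tss`), or a list with those elements.
#' @param ld an [ld_matrix()] covering the cis region, or `NULL` (LD
#'   collapse then skipped; missing pairs treated as r2 = 0).
#' @param cfg a [selection_config()].
#' @return an object of class `mr_instrument` (list with `exposure_id`,
#'   `snps` - one-row data.frame, `r2`, `f_stat`, `is_cis`, `region`),
#'   or `NULL` when no candidate passes.
#' @export
select_cis_instrument <- function(protein_sumstats, gene, ld = NULL,
                                  cfg = selection_config()) {
  stopifnot(inherits(protein_sumstats, "sumstat_set"))
  if (is.null(gene$gene_symbol) || is.null(gene$tss) || is.null(gene$chrom)) {
    stop("gene annotation lacks gene_symbol/chrom/tss")
  }
  rec <- protein_sumstats$records
  cand <- rec[rec$chrom == gene$chrom &
              abs(rec$pos - gene$tss) <= cfg$cis_window_bp &
              rec$pval < cfg$pthreshold_exposure, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order_by_p(cand), , drop = FALSE]

  regions <- merge_regions(cand, ld, cfg)
  top_region <- regions[[1L]]  # region containing the overall lowest-p SNP
  sentinel <- top_region[order_by_p(top_region)[1L], , drop = FALSE]

  r2 <- compute_r2(sentinel$beta, sentinel$eaf, sentinel$se, sentinel$n)
  out <- list(exposure_id = protein_sumstats$trait_id,
              snps = sentinel,
              r2 = r2,
              f_stat = compute_f_stat(r2, sentinel$n, k = 1),
              is_cis = TRUE,
              region = list(chrom = gene$chrom,
                            start = min(top_region$pos) - cfg$region_flank_bp,
                            end = max(top_region$pos) + cfg$region_flank_bp))
  class(out) <- "mr_instrument"
  out
}

# Partition candidate SNPs (sorted by p) into merged regions. Seeded from
# the lowest-p SNP: a SNP joins an existing region when its flanked
# interval overlaps the region's interval, or when its LD r2 with any
# member is >= merge_r2. The MHC interval, when configured, acts as one
# region. Returns regions ordered by their best p-value.
merge_regions <- function(cand, ld, cfg) {
  flank <- cfg$region_flank_bp
  regions <- list()
  bounds <- list()
  in_mhc <- function(row) {
    !is.null(cfg$mhc) && row$chrom == cfg$mhc$chrom &&
      row$pos >= cfg$mhc$start && row$pos <= cfg$mhc$end
  }
  mhc_region_idx <- NA_integer_
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, , drop = FALSE]
    lo <- row$pos - flank
    hi <- row$pos + flank
    assigned <- NA_integer_
    if (in_mhc(row) && !is.na(mhc_region_idx)) {
      assigned <- mhc_region_idx
    } else {
      for (j in seq_along(regions)) {
        overlap <- lo <= bounds[[j]][2L] && hi >= bounds[[j]][1L]
        high_ld <- FALSE
        if (!overlap && !is.null(ld)) {
          rr <- vapply(regions[[j]]$rsid, function(r2id) {
            v <- ld_r(ld, row$rsid, r2id)
            if (is.na(v)) 0 else v^2
          }, numeric(1))
          high_ld <- any(rr >= cfg$merge_r2)
        }
        if (overlap || high_ld) { assigned <- j; break }
      }
    }
    if (is.na(assigned)) {
      regions[[length(regions) + 1L]] <- row
      bounds[[length(bounds) + 1L]] <- c(lo, hi)
      if (in_mhc(row)) mhc_region_idx <- length(regions)
    } else {
      regions[[assigned]] <- rbind(regions[[assigned]], row)
      bounds[[assigned]] <- c(min(bounds[[assigned]][1L], lo),
                              max(bounds[[assigned]][2L], hi))
    }
  }
  # Re-merge until stable: absorbing a SNP can widen a region into another.
  repeat {
    merged_any <- FALSE
    j <- 1L
    while (j < length(regions)) {
      k <- j + 1L
      while (k <= length(regions)) {
        if (bounds[[j]][1L] <= bounds[[k]][2L] &&
            bounds[[j]][2L] >= bounds[[k]][1L]) {
          regions[[j]] <- rbind(regions[[j]], regions[[k]])
          bounds[[j]] <- c(min(bounds[[j]][1L], bounds[[k]][1L]),
                           max(bounds[[j]][2L], bounds[[k]][2L]))
          regions[[k]] <- NULL
          bounds[[k]] <- NULL
          merged_any <- TRUE
        } else k <- k + 1L
      }
      j <- j + 1L
    }
    if (!merged_any) break
  }
  best <- vapply(regions, function(r) min(r$pval), numeric(1))
  regions[order(best)]
}

#' @export
print.mr_instrument <- function(x, ...) {
  cat(sprintf("<mr_instrument> %s: sentinel %s (p=%.3g, R2=%.4g, F=%.1f)\n",
              x$exposure_id, x$snps$rsid[1L], x$snps$pval[1L], x$r2, x$f_stat))
  invisible(x)
}

#' Greedy LD clumping of genome-wide instruments
#'
#' Repeatedly retains the remaining SNP with the lowest p-value passing
#' the outcome p-threshold (ties broken by lower position) and discards
#' all SNPs with r-squared > `clump_r2` to it that lie within
#' `clump_window_bp` of it. SNP pairs absent from the LD matrix are
#' treated as uncorrelated, with a warning.
#'
#' @param sumstats a [sumstat_set()].
#' @param ld an [ld_matrix()] or `NULL`.
#' @param cfg a [selection_config()].
#' @param p_threshold cutoff applied (default `cfg$pthreshold_outcome`).
#' @return data.frame of retained records (possibly zero rows), in
#'   selection order.
#' @export
clump <- function(sumstats, ld = NULL, cfg = selection_config(),
                  p_threshold = cfg$pthreshold_outcome) {
  stopifnot(inherits(sumstats, "sumstat_set"))
  rec <- sumstats$records
  rec <- rec[rec$pval < p_threshold, , drop = FALSE]
  if (nrow(rec) == 0L) return(rec)
  rec <- rec[order_by_p(rec), , drop = FALSE]
  kept <- rec[0, , drop = FALSE]
  warned <- FALSE
  while (nrow(rec) > 0L) {
    idx <- rec[1L, , drop = FALSE]
    kept <- rbind(kept, idx)
    rec <- rec[-1L, , drop = FALSE]
    if (nrow(rec) == 0L) break
    near <- rec$chrom == idx$chrom & abs(rec$pos - idx$pos) <= cfg$clump_window_bp
    if (any(near)) {
      r2 <- vapply(rec$rsid[near], function(r) {
        v <- if (is.null(ld)) NA_real_ else ld_r(ld, idx$rsid, r)
        if (is.na(v)) NA_real_ else v^2
      }, numeric(1))
      if (anyNA(r2) && !warned) {
        warning("LD unavailable for some SNP pairs during clumping; treating r2 as 0")
        warned <- TRUE
      }
      r2[is.na(r2)] <- 0
      drop <- which(near)[r2 > cfg$clump_r2]
      if (length(drop) > 0L) rec <- rec[-drop, , drop = FALSE]
    }
  }
  rownames(kept) <- NULL
  kept
}
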