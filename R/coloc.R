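#' Colocalization configuration
#'
#' Priors and windows for single-causal-variant approximate-Bayes-factor
#' colocalization: p1/p2 are the per-SNP prior probabilities of
#' association with trait 1 / trait 2 only, p12 with both. The default
#' windows (125 kb, 250 kb, 500 kb, 1 Mb total span, centered on the
#' sentinel) give a built-in sensitivity analysis to region size.
#'
#' @param p1,p2,p12 per-SNP priors (defaults 1e-6, 1e-6, 1e-7).
#' @param windows_bp ascending window widths in bp (total span).
#' @param prior_sd_quant prior effect-size SD for quantitative traits
#'   (0.15).
#' @param prior_sd_binary prior effect-size SD (log-odds) for binary
#'   traits (0.2).
#' @param window_mode `"span"` (width is the total span, the default) or
#'   `"flank"` (width is the flank on each side).
#' @return list of class `coloc_config`.
#' @export
coloc_config <- function(p1 = 1e-6, p2 = 1e-6, p12 = 1e-7,
                         windows_bp = c(125e3, 250e3, 500e3, 1e6),
                         prior_sd_quant = 0.15, prior_sd_binary = 0.2,
                         window_mode = c("span", "flank")) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 1,
            all(diff(windows_bp) > 0), all(windows_bp > 0))
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 windows_bp = windows_bp,
                 prior_sd_quant = prior_sd_quant,
                 prior_sd_binary = prior_sd_binary,
                 window_mode = match.arg(window_mode)),
            class = "coloc_config")
}

#' Log approximate Bayes factor for one variant
#'
#' Wakefield's approximation: with V = se^2, z = beta/se and W =
#' prior_sd^2, lABF = 0.5 [ log(V/(V+W)) + z^2 W/(V+W) ]. Computed in log
#' space; stable for |z| into the hundreds.
#'
#' @param beta effect estimate.
#' @param se standard error (> 0).
#' @param prior_sd prior SD of the true effect.
#' @return log Bayes factor (vectorized).
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("standard errors must be positive")
  v <- se^2
  w <- prior_sd^2
  z <- beta / se
  0.5 * (log(v / (v + w)) + z^2 * w / (v + w))
}

log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when equal within eps.
log_diff_exp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Posterior probabilities of colocalization hypotheses
#'
#' Single-causal-variant enumeration over the shared variants: H0 no
#' association with either trait; H1/H2 association with trait 1/2 only;
#' H3 both traits, distinct causal variants; H4 both traits, one shared
#' causal variant. Computed entirely in log space via log-sum-exp.
#'
#' @param trait1,trait2 data.frames with columns `rsid` and `labf`
#'   (per-variant log approximate Bayes factors); they are intersected on
#'   rsid internally.
#' @param cfg a [coloc_config()].
#' @return one-row data.frame: `n_snps`, `h0`..`h4` (summing to 1).
#' @export
coloc_abf <- function(trait1, trait2, cfg = coloc_config()) {
  shared <- intersect(trait1$rsid, trait2$rsid)
  if (length(shared) == 0L) stop("no shared variants between traits")
  l1 <- trait1$labf[match(shared, trait1$rsid)]
  l2 <- trait2$labf[match(shared, trait2$rsid)]
  s1 <- log_sum_exp(l1)
  s2 <- log_sum_exp(l2)
  s12 <- log_sum_exp(l1 + l2)
  u <- c(h0 = 0,
         h1 = log(cfg$p1) + s1,
         h2 = log(cfg$p2) + s2,
         h3 = log(cfg$p1) + log(cfg$p2) + log_diff_exp(s1 + s2, s12),
         h4 = log(cfg$p12) + s12)
  denom <- log_sum_exp(u)
  pp <- exp(u - denom)
  data.frame(n_snps = length(shared), h0 = pp[["h0"]], h1 = pp[["h1"]],
             h2 = pp[["h2"]], h3 = pp[["h3"]], h4 = pp[["h4"]])
}

#' Windowed colocalization of a protein and a disease around a cis-SNP
#'
#' For each configured window centered on the sentinel cis-SNP, intersects
#' the two sets' variants falling inside the window, computes
#' trait-appropriate log approximate Bayes factors (quantitative prior SD
#' for the protein, binary for the disease), and runs [coloc_abf()].
#' Variants lacking a finite beta, SE or EAF are excluded with a count. A
#' window with no shared variants is reported with `n_snps = 0` and `NA`
#' posteriors rather than failing.
#'
#' @param protein a quantitative [sumstat_set()].
#' @param disease a binary [sumstat_set()].
#' @param cis_snp the sentinel: an rsid present in `protein`, or a list
#'   with `rsid`/`chrom`/`pos`.
#' @param cfg a [coloc_config()].
#' @return data.frame, one row per window: `window_bp`, `n_snps`,
#'   `h0`..`h4`, plus attribute `consistent` - `TRUE` when the top
#'   hypothesis agrees across all non-empty windows.
#' @export
windowed_coloc <- function(protein, disease, cis_snp, cfg = coloc_config()) {
  stopifnot(inherits(protein, "sumstat_set"), inherits(disease, "sumstat_set"))
  if (is.character(cis_snp)) {
    hit <- protein$records[protein$records$rsid == cis_snp, , drop = FALSE]
    if (nrow(hit) == 0L) stop("cis SNP absent from protein set: ", cis_snp)
    cis_snp <- list(rsid = hit$rsid[1L], chrom = hit$chrom[1L], pos = hit$pos[1L])
  }
  prep <- function(set, sd_prior) {
    rec <- set$records
    ok <- is.finite(rec$beta) & is.finite(rec$se) & rec$se > 0 & is.finite(rec$eaf)
    rec <- rec[ok, , drop = FALSE]
    data.frame(rsid = rec$rsid, chrom = rec$chrom, pos = rec$pos,
               labf = log_abf(rec$beta, rec$se, sd_prior),
               stringsAsFactors = FALSE)
  }
  sd_for <- function(set) if (set$trait_type == "binary") cfg$prior_sd_binary else cfg$prior_sd_quant
  t1 <- prep(protein, sd_for(protein))
  t2 <- prep(disease, sd_for(disease))
  rows <- lapply(cfg$windows_bp, function(w) {
    half <- if (cfg$window_mode == "span") w / 2 else w
    in_win <- function(df) df[df$chrom == cis_snp$chrom &
                              abs(df$pos - cis_snp$pos) <= half, , drop = FALSE]
    a <- in_win(t1); b <- in_win(t2)
    if (length(intersect(a$rsid, b$rsid)) == 0L) {
      return(data.frame(window_bp = w, n_snps = 0L, h0 = NA_real_,
                        h1 = NA_real_, h2 = NA_real_, h3 = NA_real_,
                        h4 = NA_real_))
    }
    cbind(window_bp = w, coloc_abf(a, b, cfg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  nonempty <- out[out$n_snps > 0L, , drop = FALSE]
  top <- apply(nonempty[, c("h0", "h1", "h2", "h3", "h4"), drop = FALSE], 1,
               which.max)
  attr(out, "consistent") <- nrow(nonempty) > 0L && length(unique(top)) == 1L
  out
}
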