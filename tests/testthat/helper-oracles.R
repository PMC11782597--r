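# Independent brute-force oracles and fixture builders. These deliberately
# re-derive results by enumeration or naive arithmetic, not by calling the
# implementation under test.

# Minimal association records table.
make_records <- function(rsid, pos, beta, se, pval, eaf = 0.3, n = 10000,
                         chrom = "1", ea = "A", oa = "G",
                         n_case = NA_real_, n_control = NA_real_) {
  if (length(rsid) == 0L) {
    return(data.frame(rsid = character(), chrom = character(), pos = numeric(),
                      effect_allele = character(), other_allele = character(),
                      eaf = numeric(), beta = numeric(), se = numeric(),
                      pval = numeric(), n = numeric(), n_case = numeric(),
                      n_control = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(rsid = rsid, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pval = pval, n = n, n_case = n_case, n_control = n_control,
             stringsAsFactors = FALSE)
}

make_set <- function(records, trait_id = "trait",
                     trait_type = "quantitative", ...) {
  sumstat_set(records, trait_id = trait_id, trait_type = trait_type, ...)
}

# Exhaustive greedy clumping on a small instance: at each step scan all
# remaining SNPs for the p-minimum (position tie-break), then remove
# correlated neighbours by direct matrix lookup.
clump_oracle <- function(records, r, p_threshold, clump_r2, window_bp) {
  rec <- records[records$pval < p_threshold, , drop = FALSE]
  kept <- character(0)
  while (nrow(rec) > 0) {
    best <- which(rec$pval == min(rec$pval))
    best <- best[which.min(rec$pos[best])]
    idx <- rec$rsid[best]
    kept <- c(kept, idx)
    keep_mask <- rep(TRUE, nrow(rec))
    keep_mask[best] <- FALSE
    for (i in seq_len(nrow(rec))) {
      if (i == best) next
      same_chrom <- rec$chrom[i] == rec$chrom[best]
      close <- abs(rec$pos[i] - rec$pos[best]) <= window_bp
      r2 <- r[idx, rec$rsid[i]]^2
      if (same_chrom && close && r2 > clump_r2) keep_mask[i] <- FALSE
    }
    rec <- rec[keep_mask, , drop = FALSE]
  }
  kept
}

# Exhaustive region merging on a small instance: every candidate opens a
# [pos - flank, pos + flank] interval; intervals are merged to a fixed
# point (also joining pairs with r2 >= merge_r2), then the sentinel is the
# p-minimum of the region holding the global p-minimum.
sentinel_oracle <- function(cand, r, flank, merge_r2) {
  n <- nrow(cand)
  # adjacency: interval overlap or high LD
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    overlap <- abs(cand$pos[i] - cand$pos[j]) <= 2 * flank
    high_ld <- !is.null(r) && r[cand$rsid[i], cand$rsid[j]]^2 >= merge_r2
    adj[i, j] <- overlap || high_ld
  }
  # connected components by repeated expansion, then interval-hull overlap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    # hull overlap between components
    for (ci in unique(comp)) for (cj in unique(comp)) {
      if (ci == cj) next
      lo_i <- min(cand$pos[comp == ci]) - flank; hi_i <- max(cand$pos[comp == ci]) + flank
      lo_j <- min(cand$pos[comp == cj]) - flank; hi_j <- max(cand$pos[comp == cj]) + flank
      if (lo_i <= hi_j && hi_i >= lo_j) { comp[comp == cj] <- ci; changed <- TRUE }
    }
    if (!changed) break
  }
  gbest <- which(cand$pval == min(cand$pval))
  gbest <- gbest[which.min(cand$pos[gbest])]
  members <- which(comp == comp[gbest])
  best <- members[cand$pval[members] == min(cand$pval[members])]
  best <- best[which.min(cand$pos[best])]
  cand$rsid[best]
}

# Direct enumeration of colocalization posteriors over all (J+1)^2 causal
# configurations, in plain (non-log) arithmetic.
coloc_oracle <- function(bf1, bf2, p1, p2, p12) {
  j <- length(bf1)
  h <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (c1 in seq_len(j)) h["h1"] <- h["h1"] + p1 * bf1[c1]
  for (c2 in seq_len(j)) h["h2"] <- h["h2"] + p2 * bf2[c2]
  for (c1 in seq_len(j)) for (c2 in seq_len(j)) {
    if (c1 == c2) {
      h["h4"] <- h["h4"] + p12 * bf1[c1] * bf2[c2]
    } else {
      h["h3"] <- h["h3"] + p1 * p2 * bf1[c1] * bf2[c2]
    }
  }
  h / sum(h)
}

# Naive Wakefield log-ABF, written independently of log_abf().
labf_oracle <- function(beta, se, sd_prior) {
  v <- se^2; w <- sd_prior^2; z <- beta / se
  log(sqrt(v / (v + w))) + 0.5 * z^2 * (w / (v + w))
}
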