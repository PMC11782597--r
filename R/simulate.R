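# Synthetic GWAS summary statistics with known causal architecture.
#
# Haplotypes arise from a latent Gaussian AR(1) process thresholded at
# MAF-matching quantiles, so LD decays geometrically with distance. A
# standardized protein receives additive effects from its cis SNPs, and a
# binary disease arises from a liability-threshold model with logistic
# residual: liability = gamma * protein + direct SNP effects + Logistic(0,1),
# disease = 1{liability > qlogis(1 - K)}. With a logistic residual, gamma is
# the log-odds effect of one standardized-protein unit on disease, so
# Wald-ratio estimates target gamma directly (up to the negligible
# non-collapsibility of rare outcomes).

# Non-palindromic allele pairs cycled deterministically across SNPs.
ALLELE_PAIRS <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                       ncol = 2, byrow = TRUE)

#' Ground-truth parameters of a simulated scenario
#'
#' Scenario presets: `shared_causal` (cis SNP raises the protein, protein
#' raises disease liability), `distinct_causal` (protein and disease
#' signals at different, weakly linked SNPs), `pleiotropy` (the instrument
#' SNP also affects liability directly), `reverse_causation` (SNPs act on
#' liability, liability influences the protein) and `null` (no effects
#' anywhere).
#'
#' @param scenario one of the five presets.
#' @param m_snps variants in the region.
#' @param causal_snp_idx index of the protein-effect SNP.
#' @param a per-allele effect on the (pre-standardization) protein, SD
#'   units.
#' @param gamma causal effect of the standardized protein on disease
#'   liability (log-odds per SD); in `reverse_causation`, the effect of
#'   standardized liability on the protein.
#' @param delta direct per-allele SNP effect on liability (log-odds).
#' @param delta_snp_idx index carrying `delta`.
#' @param prevalence_k population disease prevalence.
#' @param n_protein,n_disease_1,n_disease_2 cohort sizes (two independent
#'   protein "platform" cohorts of `n_protein` each; two disease cohorts).
#' @param ld_rho AR(1) decay of the latent LD process.
#' @param maf_low,maf_high minor-allele-frequency bounds.
#' @param n_ref haplotypes in the LD reference panel.
#' @param spacing_bp distance between adjacent variants.
#' @param chrom,region_start chromosome label and first variant position.
#' @param seed RNG seed; all randomness of the bundle flows from it.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(scenario = c("shared_causal", "distinct_causal",
                                         "pleiotropy", "reverse_causation",
                                         "null"),
                            m_snps = 21L, causal_snp_idx = NULL,
                            a = NULL, gamma = NULL, delta = NULL,
                            delta_snp_idx = NULL,
                            prevalence_k = 0.01,
                            n_protein = 20000L, n_disease_1 = 20000L,
                            n_disease_2 = 20000L,
                            ld_rho = 0.8, maf_low = 0.1, maf_high = 0.5,
                            n_ref = 2000L, spacing_bp = 5e4,
                            chrom = "1", region_start = 1e6,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  mid <- as.integer(ceiling(m_snps / 2))
  if (is.null(causal_snp_idx)) {
    causal_snp_idx <- if (scenario == "distinct_causal") max(1L, mid - 5L) else mid
  }
  if (is.null(delta_snp_idx)) {
    delta_snp_idx <- if (scenario == "distinct_causal") min(m_snps, mid + 5L) else causal_snp_idx
  }
  defaults <- switch(scenario,
    shared_causal     = list(a = 0.3, gamma = 0.3, delta = 0),
    distinct_causal   = list(a = 0.3, gamma = 0, delta = 0.7),
    pleiotropy        = list(a = 0.3, gamma = 0.3, delta = 0.15),
    reverse_causation = list(a = 0, gamma = 0.5, delta = 0.7),
    null              = list(a = 0, gamma = 0, delta = 0))
  if (is.null(a)) a <- defaults$a
  if (is.null(gamma)) gamma <- defaults$gamma
  if (is.null(delta)) delta <- defaults$delta
  stopifnot(prevalence_k > 0, prevalence_k < 0.5,
            n_protein > 0, n_disease_1 > 0, n_disease_2 > 0,
            ld_rho >= 0, ld_rho < 1,
            maf_low > 0, maf_low < maf_high, maf_high <= 0.5)
  structure(list(scenario = scenario, m_snps = as.integer(m_snps),
                 causal_snp_idx = as.integer(causal_snp_idx),
                 a = a, gamma = gamma, delta = delta,
                 delta_snp_idx = as.integer(delta_snp_idx),
                 prevalence_k = prevalence_k,
                 n_protein = as.integer(n_protein),
                 n_disease_1 = as.integer(n_disease_1),
                 n_disease_2 = as.integer(n_disease_2),
                 ld_rho = ld_rho, maf_low = maf_low, maf_high = maf_high,
                 n_ref = as.integer(n_ref), spacing_bp = spacing_bp,
                 chrom = chrom, region_start = region_start,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Slowly varying minor-allele frequencies: a reflected random walk inside
# [low, high], so neighbouring SNPs have similar frequencies (a
# precondition for high pairwise LD on the haplotype scale).
maf_walk <- function(m, low, high) {
  step_sd <- (high - low) / 20
  x <- numeric(m)
  x[1] <- stats::runif(1, low, high)
  if (m > 1) {
    for (j in 2:m) {
      v <- x[j - 1] + stats::rnorm(1, sd = step_sd)
      while (v < low || v > high) {
        if (v < low) v <- 2 * low - v
        if (v > high) v <- 2 * high - v
      }
      x[j] <- v
    }
  }
  x
}

# P(Z1 < t1, Z2 < t2) under a bivariate standard normal with correlation
# rho, by fixed-grid quadrature over z1 (adequate for LD calibration).
biv_p11 <- function(rho, t1, t2) {
  if (abs(rho) >= 1) rho <- sign(rho) * (1 - 1e-12)
  z <- seq(-8, t1, length.out = 256L)
  dz <- z[2L] - z[1L]
  f <- stats::dnorm(z) * stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2))
  sum(f) * dz
}

# Latent correlation giving a target haplotype-scale (0/1) correlation
# between two thresholded SNPs with frequencies q1, q2. Targets above the
# frequency-mismatch ceiling (attained as latent -> 1) are capped.
calibrate_latent <- function(target_r, q1, q2) {
  if (target_r <= 0) return(max(0, target_r))
  t1 <- stats::qnorm(q1); t2 <- stats::qnorm(q2)
  denom <- sqrt(q1 * (1 - q1) * q2 * (1 - q2))
  bin_r <- function(l) (biv_p11(l, t1, t2) - q1 * q2) / denom
  r_max <- bin_r(0.9999)
  tr <- min(target_r, 0.98 * r_max)
  stats::uniroot(function(l) bin_r(l) - tr, c(0, 0.9999), tol = 1e-6)$root
}

# Latent AR coefficients for each adjacent pair, calibrated so realized
# haplotype LD tracks the requested rho.
latent_path <- function(mafs, rho) {
  m <- length(mafs)
  if (m < 2L || rho <= 0) return(rep(max(0, rho), max(m - 1L, 0L)))
  vapply(2:m, function(j) calibrate_latent(rho, mafs[j - 1L], mafs[j]),
         numeric(1))
}

# Latent-Gaussian AR haplotypes: n x m matrix of 0/1 with column j carrying
# allele 1 at frequency maf[j]; latent is the per-adjacent-pair coefficient
# vector from latent_path().
ar1_haplotypes <- function(n, mafs, latent) {
  m <- length(mafs)
  z <- matrix(0, n, m)
  z[, 1] <- stats::rnorm(n)
  if (m > 1) {
    for (j in 2:m) {
      l <- latent[j - 1L]
      z[, j] <- l * z[, j - 1] + sqrt(1 - l^2) * stats::rnorm(n)
    }
  }
  h <- sweep(z, 2, stats::qnorm(mafs), `<`)
  storage.mode(h) <- "double"
  h
}

#' Simulate an LD reference panel
#'
#' Haplotypes from a latent Gaussian AR(1) process thresholded per SNP at
#' the quantile matching a minor-allele frequency drawn uniformly from
#' `[maf_low, maf_high]`. Adjacent-SNP correlation concentrates near (a
#' thresholding-attenuated version of) `rho`.
#'
#' @param m_snps number of variants.
#' @param rho AR(1) parameter in [0, 1).
#' @param maf_low,maf_high frequency bounds, 0 < low < high <= 0.5.
#' @param n_ref number of haplotypes.
#' @param seed RNG seed.
#' @param spacing_bp base pairs between adjacent variants.
#' @param chrom,region_start coordinates of the region.
#' @param rsid_prefix prefix for generated variant IDs.
#' @return list with `haplotypes` (n_ref x m 0/1 matrix), `ld` (an
#'   [ld_matrix()] of empirical r), `mafs`, `latent` (calibrated latent AR
#'   coefficients), `rsids`, `positions`.
#' @export
simulate_ld_panel <- function(m_snps, rho, maf_low = 0.1, maf_high = 0.5,
                              n_ref = 2000L, seed = 1L, spacing_bp = 5e4,
                              chrom = "1", region_start = 1e6,
                              rsid_prefix = "rs") {
  stopifnot(rho >= 0, rho < 1, maf_low > 0, maf_low < maf_high,
            maf_high <= 0.5, m_snps >= 1, n_ref >= 2)
  set.seed(seed)
  mafs <- maf_walk(m_snps, maf_low, maf_high)
  latent <- latent_path(mafs, rho)
  h <- ar1_haplotypes(n_ref, mafs, latent)
  # Guard against monomorphic draws in small panels
  mono <- which(apply(h, 2, stats::sd) == 0)
  for (j in mono) h[sample.int(n_ref, 2L), j] <- c(0, 1)
  positions <- region_start + (seq_len(m_snps) - 1L) * spacing_bp
  rsids <- paste0(rsid_prefix, seq_len(m_snps))
  list(haplotypes = h,
       ld = ld_from_haplotypes(h, rsids, positions),
       mafs = mafs, latent = latent, rsids = rsids, positions = positions)
}

# Diploid dosages for a fresh cohort drawn from the same generating process.
ar1_genotypes <- function(n, mafs, latent) {
  ar1_haplotypes(n, mafs, latent) + ar1_haplotypes(n, mafs, latent)
}

# Assemble a records data.frame from an association scan.
records_from_assoc <- function(assoc, rsids, chrom, positions) {
  idx <- (seq_along(rsids) - 1L) %% nrow(ALLELE_PAIRS) + 1L
  cbind(data.frame(rsid = rsids, chrom = chrom, pos = positions,
                   effect_allele = ALLELE_PAIRS[idx, 1L],
                   other_allele = ALLELE_PAIRS[idx, 2L],
                   stringsAsFactors = FALSE),
        assoc)
}

# Protein from its region dosages; standardized to unit variance.
make_protein <- function(g, a_vec) {
  n <- nrow(g)
  raw <- as.vector(g %*% a_vec) + stats::rnorm(n)
  as.vector(scale(raw))
}

# Disease from standardized protein values (possibly zero effect), direct
# SNP effects and a logistic residual.
make_disease <- function(x_std, g, delta_vec, gamma, k) {
  n <- nrow(g)
  liab <- gamma * x_std + as.vector(g %*% delta_vec) + stats::rlogis(n)
  as.numeric(liab > stats::qlogis(1 - k))
}

#' Simulate a single-region scenario bundle
#'
#' Generates four independent cohorts over one cis region - two protein
#' "platform" cohorts and two disease cohorts - plus an LD reference
#' panel, and summarizes each cohort into GWAS summary statistics
#' (per-SNP OLS for the protein, per-SNP logistic regression for the
#' disease). The returned bundle is readable by every pipeline stage.
#'
#' @param truth a [synthetic_truth()].
#' @return list of class `scenario_bundle` with elements `protein_sets`
#'   (list `platform_a`, `platform_b` of quantitative [sumstat_set()]s),
#'   `disease_sets` (list of two binary sets), `ld` ([ld_matrix()]),
#'   `genes` (one-row annotation data.frame) and `truth`.
#' @export
simulate_scenario <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  m <- truth$m_snps
  panel <- simulate_ld_panel(m, truth$ld_rho, truth$maf_low, truth$maf_high,
                             truth$n_ref, seed = truth$seed,
                             spacing_bp = truth$spacing_bp,
                             chrom = truth$chrom,
                             region_start = truth$region_start)
  # simulate_ld_panel seeded the RNG; cohort draws continue the stream.
  a_vec <- rep(0, m); a_vec[truth$causal_snp_idx] <- truth$a
  d_vec <- rep(0, m); d_vec[truth$delta_snp_idx] <- truth$delta
  k <- truth$prevalence_k
  reverse <- truth$scenario == "reverse_causation"

  exp_cases <- min(truth$n_disease_1, truth$n_disease_2) * k
  if (exp_cases < 50) {
    warning(sprintf("expected case count %.1f < 50: logistic estimates may be unstable",
                    exp_cases))
  }

  protein_cohort <- function(n) {
    g <- ar1_genotypes(n, panel$mafs, panel$latent)
    if (reverse) {
      liab <- as.vector(g %*% d_vec) + stats::rlogis(n)
      raw <- truth$gamma * as.vector(scale(liab)) +
        stats::rnorm(n, sd = sqrt(max(1 - truth$gamma^2, 0.05)))
      x <- as.vector(scale(raw))
    } else {
      x <- make_protein(g, a_vec)
    }
    linear_assoc(g, x)
  }
  disease_cohort <- function(n) {
    g <- ar1_genotypes(n, panel$mafs, panel$latent)
    if (reverse) {
      d <- make_disease(0, g, d_vec, 0, k)
    } else {
      x <- make_protein(g, a_vec)
      d <- make_disease(x, g, d_vec, truth$gamma, k)
    }
    logistic_assoc(g, d)
  }

  gene <- data.frame(gene_symbol = "GENE1", chrom = truth$chrom,
                     tss = panel$positions[truth$causal_snp_idx],
                     stringsAsFactors = FALSE)
  mk_q <- function(assoc, id, platform) {
    sumstat_set(records_from_assoc(assoc, panel$rsids, truth$chrom, panel$positions),
                trait_id = id, trait_type = "quantitative", platform = platform)
  }
  mk_b <- function(assoc, id, platform) {
    sumstat_set(records_from_assoc(assoc, panel$rsids, truth$chrom, panel$positions),
                trait_id = id, trait_type = "binary", platform = platform)
  }
  out <- list(
    protein_sets = list(
      platform_a = mk_q(protein_cohort(truth$n_protein), "GENE1", "platform_a"),
      platform_b = mk_q(protein_cohort(truth$n_protein), "GENE1", "platform_b")),
    disease_sets = list(
      mk_b(disease_cohort(truth$n_disease_1), "disease", "cohort_1"),
      mk_b(disease_cohort(truth$n_disease_2), "disease", "cohort_2")),
    ld = panel$ld,
    genes = gene,
    truth = truth)
  class(out) <- "scenario_bundle"
  out
}

#' One bundle per scenario type at desk-scale defaults
#'
#' Produces five [simulate_scenario()] bundles (shared causal, distinct
#' causal, pleiotropy, reverse causation, null) sized so the full pipeline
#' runs on them in well under five minutes on one CPU.
#'
#' @param seed base seed; bundle i uses `seed + i`.
#' @param n per-cohort sample size.
#' @param prevalence_k disease prevalence used for the test suite.
#' @param m_snps variants per region.
#' @return named list of `scenario_bundle`s.
#' @export
make_test_suite <- function(seed = 1L, n = 4000L, prevalence_k = 0.05,
                            m_snps = 15L) {
  scenarios <- c("shared_causal", "distinct_causal", "pleiotropy",
                 "reverse_causation", "null")
  out <- lapply(seq_along(scenarios), function(i) {
    simulate_scenario(synthetic_truth(
      scenarios[i], m_snps = m_snps, prevalence_k = prevalence_k,
      n_protein = n, n_disease_1 = n, n_disease_2 = n,
      n_ref = 1000L, seed = seed + i))
  })
  names(out) <- scenarios
  out
}

#' Simulate a multi-protein screen with planted causal proteins
#'
#' Builds a proteome-screen bundle: each protein owns a cis region on its
#' own chromosome, two independent platform cohorts measure every protein,
#' and two independent disease cohorts contribute a GWAS spanning all cis
#' regions plus a dedicated disease-susceptibility region whose SNPs act
#' directly on liability (these become the reverse-MR instruments).
#' Liability sums the causal proteins' effects, the susceptibility-region
#' effects, and a logistic residual.
#'
#' @param n_proteins number of proteins screened.
#' @param n_causal how many of them truly affect liability.
#' @param gamma log-odds effect per standardized-protein SD for causal
#'   proteins.
#' @param a per-allele cis effect on each protein.
#' @param delta per-allele liability effect of the two
#'   susceptibility-region SNPs.
#' @param n per-cohort sample size (all four cohorts).
#' @param prevalence_k disease prevalence.
#' @param m_snps variants per cis region.
#' @param m_disease variants in the susceptibility region.
#' @param ld_rho,maf_low,maf_high,n_ref,spacing_bp LD-panel parameters as
#'   in [synthetic_truth()]; `ld_rho` applies to the cis regions.
#' @param ld_rho_disease LD decay inside the susceptibility region. The
#'   default is low so its two planted signals are effectively
#'   independent loci, the situation the clumping thresholds assume.
#' @param seed RNG seed.
#' @return list of class `screen_bundle`: `proteins` (named list; each
#'   element has `platform_a`, `platform_b` sumstat sets and `gene` row),
#'   `disease_sets` (two binary sets spanning all regions), `genes`
#'   (annotation data.frame), `ld_list` (per-region [ld_matrix()]s, named
#'   by protein plus `"disease_region"`), and `truth` (causal protein IDs
#'   and parameters).
#' @export
simulate_screen <- function(n_proteins = 20L, n_causal = 2L, gamma = 1.2,
                            a = 0.3, delta = 0.45, n = 10000L,
                            prevalence_k = 0.05, m_snps = 15L,
                            m_disease = 8L, ld_rho = 0.92,
                            maf_low = 0.15, maf_high = 0.45, n_ref = 1000L,
                            spacing_bp = 2.5e4, ld_rho_disease = 0.3,
                            seed = 1L) {
  stopifnot(n_causal <= n_proteins)
  set.seed(seed)
  prot_ids <- sprintf("PROT%02d", seq_len(n_proteins))
  causal_ids <- prot_ids[seq_len(n_causal)]
  regions <- vector("list", n_proteins + 1L)
  names(regions) <- c(prot_ids, "disease_region")
  for (i in seq_along(regions)) {
    is_cis <- i <= n_proteins
    mm <- if (is_cis) m_snps else m_disease
    mafs <- maf_walk(mm, maf_low, maf_high)
    latent <- latent_path(mafs, if (is_cis) ld_rho else ld_rho_disease)
    positions <- 1e6 + (seq_len(mm) - 1L) * spacing_bp
    rsids <- sprintf("rs%d_%d", i, seq_len(mm))
    hp <- ar1_haplotypes(n_ref, mafs, latent)
    mono <- which(apply(hp, 2, stats::sd) == 0)
    for (j in mono) hp[sample.int(n_ref, 2L), j] <- c(0, 1)
    regions[[i]] <- list(mafs = mafs, latent = latent, positions = positions,
                         rsids = rsids, chrom = as.character(i),
                         ld = ld_from_haplotypes(hp, rsids, positions))
  }
  mid <- as.integer(ceiling(m_snps / 2))
  delta_idx <- unique(pmin(m_disease, c(2L, m_disease - 1L)))
  genes <- data.frame(gene_symbol = prot_ids,
                      chrom = as.character(seq_len(n_proteins)),
                      tss = vapply(regions[seq_len(n_proteins)],
                                   function(r) r$positions[mid], numeric(1)),
                      stringsAsFactors = FALSE)

  draw_regions <- function(nind) {
    lapply(regions, function(r) ar1_genotypes(nind, r$mafs, r$latent))
  }
  proteins_of <- function(glist) {
    sapply(seq_len(n_proteins), function(i) {
      a_vec <- rep(0, m_snps); a_vec[mid] <- a
      make_protein(glist[[i]], a_vec)
    })
  }
  assoc_binary_set <- function(glist, d, platform) {
    rows <- lapply(seq_along(regions), function(i) {
      r <- regions[[i]]
      records_from_assoc(logistic_assoc(glist[[i]], d), r$rsids, r$chrom,
                         r$positions)
    })
    sumstat_set(do.call(rbind, rows), trait_id = "disease",
                trait_type = "binary", platform = platform)
  }

  # Platform cohorts: every protein measured; GWAS over own region plus
  # the susceptibility region (null there under forward causation).
  platform_cohort <- function(platform) {
    glist <- draw_regions(n)
    xs <- proteins_of(glist)
    lapply(seq_len(n_proteins), function(i) {
      r <- regions[[i]]
      own <- records_from_assoc(linear_assoc(glist[[i]], xs[, i]),
                                r$rsids, r$chrom, r$positions)
      dr <- regions[["disease_region"]]
      ext <- records_from_assoc(linear_assoc(glist[["disease_region"]], xs[, i]),
                                dr$rsids, dr$chrom, dr$positions)
      sumstat_set(rbind(own, ext), trait_id = prot_ids[i],
                  trait_type = "quantitative", platform = platform)
    })
  }
  disease_cohort <- function(platform) {
    glist <- draw_regions(n)
    xs <- proteins_of(glist)
    d_vec <- rep(0, m_disease); d_vec[delta_idx] <- delta
    liab <- as.vector(xs[, seq_len(n_causal), drop = FALSE] %*%
                        rep(gamma, n_causal)) +
      as.vector(glist[["disease_region"]] %*% d_vec) + stats::rlogis(n)
    d <- as.numeric(liab > stats::qlogis(1 - prevalence_k))
    assoc_binary_set(glist, d, platform)
  }

  pa <- platform_cohort("platform_a")
  pb <- platform_cohort("platform_b")
  proteins <- lapply(seq_len(n_proteins), function(i) {
    list(platform_a = pa[[i]], platform_b = pb[[i]],
         gene = genes[i, , drop = FALSE])
  })
  names(proteins) <- prot_ids

  out <- list(proteins = proteins,
              disease_sets = list(disease_cohort("cohort_1"),
                                  disease_cohort("cohort_2")),
              genes = genes,
              ld_list = lapply(regions, `[[`, "ld"),
              truth = list(causal_proteins = causal_ids, gamma = gamma,
                           a = a, delta = delta,
                           prevalence_k = prevalence_k, n = n, seed = seed))
  class(out) <- "screen_bundle"
  out
}
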