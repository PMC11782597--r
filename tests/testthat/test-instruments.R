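test_that("variance explained matches hand evaluation of the formula", {
  # b = 0.5, EAF = 0.5, SE = 0.01, N = 35559:
  # numerator 2*0.25*0.25 = 0.125; denominator 0.125 + 1e-4*2*35559*0.25
  num <- 2 * 0.5^2 * 0.5 * 0.5
  den <- num + 0.01^2 * 2 * 35559 * 0.5 * 0.5
  expect_equal(compute_r2(0.5, 0.5, 0.01, 35559), num / den, tolerance = 1e-10)
  expect_equal(compute_r2(0.5, 0.5, 0.01, 35559), 0.0657, tolerance = 1e-3)
  expect_identical(compute_r2(0, 0.3, 0.1, 1000), 0)
})

test_that("R2 is monotone in |b| and always in [0, 1)", {
  b <- seq(0, 5, by = 0.25)
  r2 <- compute_r2(b, 0.2, 0.05, 10000)
  expect_true(all(diff(r2) > 0))
  expect_true(all(r2 >= 0 & r2 < 1))
})

test_that("F-statistic matches hand evaluation", {
  expect_equal(compute_f_stat(0.5, 102, 1), 0.5 * 100 / 0.5)  # = 100
  r2 <- compute_r2(0.5, 0.5, 0.01, 35559)
  expect_equal(compute_f_stat(r2, 35559, 1), r2 * 35557 / (1 - r2),
               tolerance = 1e-10)
  expect_equal(compute_f_stat(0.0657, 35559, 1), 2500.6, tolerance = 1e-3)
  expect_identical(compute_f_stat(0, 100, 1), 0)
  expect_error(compute_f_stat(0.1, 3, 2), "sample size")
})

test_that("no candidate below threshold means no instrument", {
  rec <- make_records("rs1", 1e6, 0.1, 0.05, 1e-6)
  gene <- list(gene_symbol = "G", chrom = "1", tss = 1e6)
  expect_null(select_cis_instrument(make_set(rec), gene))
})

test_that("a single candidate becomes the sentinel with strength metrics", {
  rec <- make_records(c("rs1", "rs2"), c(1e6, 1.2e6), beta = c(0.5, 0.1),
                      se = 0.01, pval = c(1e-20, 1e-4), n = 35559, eaf = 0.5)
  gene <- list(gene_symbol = "G", chrom = "1", tss = 1e6)
  inst <- select_cis_instrument(make_set(rec), gene)
  expect_equal(inst$snps$rsid, "rs1")
  expect_true(inst$is_cis)
  expect_gt(inst$f_stat, 10)
  expect_equal(inst$r2, compute_r2(0.5, 0.5, 0.01, 35559))
})

test_that("cis window bounds candidates by TSS distance (closed interval)", {
  rec <- make_records(c("rs_in", "rs_edge", "rs_out"),
                      pos = c(2e6, 3e6, 3e6 + 1),
                      beta = c(0.1, 0.2, 0.9), se = 0.01,
                      pval = c(1e-12, 1e-20, 1e-40))
  gene <- list(gene_symbol = "G", chrom = "1", tss = 2e6)
  inst <- select_cis_instrument(make_set(rec), gene)
  expect_equal(inst$snps$rsid, "rs_edge")  # rs_out beyond 1 Mb despite lower p
})

test_that("sentinel equals the exhaustive region-merge oracle on small instances", {
  set.seed(7)
  gene <- list(gene_symbol = "G", chrom = "1", tss = 5e6)
  cfg <- selection_config(pthreshold_exposure = 1e-4)
  for (rep in 1:25) {
    k <- sample(3:10, 1)
    pos <- sort(sample(seq(4e6, 6e6, by = 1e4), k))
    rec <- make_records(paste0("rs", 1:k), pos, beta = runif(k, 0.05, 0.5),
                        se = 0.01, pval = 10^runif(k, -30, -5))
    r <- diag(k)
    for (i in seq_len(k - 1)) {
      r[i, i + 1] <- r[i + 1, i] <- runif(1, 0, 0.99)
    }
    dimnames(r) <- list(rec$rsid, rec$rsid)
    ld <- ld_matrix(r, rec$rsid, pos)
    inst <- select_cis_instrument(make_set(rec), gene, ld, cfg)
    expect_equal(inst$snps$rsid,
                 sentinel_oracle(rec, r, cfg$region_flank_bp, cfg$merge_r2))
  }
  # Sentinel always carries the minimum p of all candidates in its region:
  # the global minimum-p candidate is by construction in the top region.
})

test_that("clumping keeps both SNPs outside the window despite high LD", {
  rec <- make_records(c("rs1", "rs2"), pos = c(1e6, 1e6 + 5e4),
                      beta = 0.1, se = 0.01, pval = c(1e-10, 1e-9))
  r <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = list(rec$rsid, rec$rsid))
  ld <- ld_matrix(r, rec$rsid, rec$pos)
  out <- clump(make_set(rec), ld)
  expect_setequal(out$rsid, c("rs1", "rs2"))  # 50 kb apart > 10 kb window
})

test_that("clumping returns empty when nothing passes the threshold", {
  rec <- make_records(c("rs1", "rs2"), c(1e6, 2e6), 0.1, 0.05, c(1e-4, 1e-5))
  expect_equal(nrow(clump(make_set(rec), NULL)), 0L)
})

test_that("clump matches the exhaustive greedy oracle and ignores row order", {
  set.seed(11)
  cfg <- selection_config(pthreshold_outcome = 1e-3, clump_r2 = 0.1,
                          clump_window_bp = 3e4)
  for (rep in 1:20) {
    k <- 20
    pos <- sort(sample(seq(1e6, 1e6 + 4e5, by = 1e4), k))
    rec <- make_records(paste0("rs", 1:k), pos, beta = 0.1, se = 0.01,
                        pval = 10^runif(k, -12, -1))
    # AR(1)-like LD
    rho <- runif(1, 0.3, 0.95)
    r <- outer(1:k, 1:k, function(i, j) rho^abs(i - j))
    dimnames(r) <- list(rec$rsid, rec$rsid)
    ld <- ld_matrix(r, rec$rsid, pos)
    got <- clump(make_set(rec), ld, cfg)
    expect_equal(got$rsid,
                 clump_oracle(rec, r, cfg$pthreshold_outcome, cfg$clump_r2,
                              cfg$clump_window_bp))
    shuffled <- rec[sample(k), , drop = FALSE]
    got2 <- clump(make_set(shuffled), ld, cfg)
    expect_equal(got2$rsid, got$rsid)
  }
})

test_that("missing LD during clumping is permissive with a warning", {
  rec <- make_records(c("rs1", "rs2"), pos = c(1e6, 1e6 + 5e3),
                      beta = 0.1, se = 0.01, pval = c(1e-10, 1e-9))
  expect_warning(out <- clump(make_set(rec), NULL), "treating r2 as 0")
  expect_equal(nrow(out), 2L)
})

test_that("MHC-style interval is treated as a single region", {
  cfg <- selection_config(pthreshold_exposure = 1e-4,
                          mhc = list(chrom = "6", start = 25e6, end = 34e6))
  # two SNPs 4 Mb apart inside the interval: normally separate regions
  rec <- make_records(c("rs1", "rs2"), pos = c(26e6, 30e6),
                      beta = c(0.1, 0.2), se = 0.01, pval = c(1e-6, 1e-8),
                      chrom = "6")
  gene <- list(gene_symbol = "G", chrom = "6", tss = 26.5e6)
  cfg_wide <- cfg
  cfg_wide$cis_window_bp <- 5e6
  inst <- select_cis_instrument(make_set(rec), gene, NULL, cfg_wide)
  # rs1 is merged into rs2's region despite the 4 Mb gap, so the merged
  # region spans both SNPs; without the MHC interval they stay separate
  expect_equal(inst$snps$rsid, "rs2")
  expect_lte(inst$region$start, 26e6)
  cfg_plain <- cfg_wide
  cfg_plain$mhc <- NULL
  inst2 <- select_cis_instrument(make_set(rec), gene, NULL, cfg_plain)
  expect_gt(inst2$region$start, 26e6)
})
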