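test_that("fixed-effect meta matches hand evaluation", {
  m <- meta_fixed(c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(m$beta_meta, 0.2)
  expect_equal(m$se_meta, 0.1 / sqrt(2))
  expect_equal(m$q_stat, 0)

  m2 <- meta_fixed(c(0.2, 0.4), c(0.1, 0.1))
  expect_equal(m2$beta_meta, 0.3)
  expect_equal(m2$q_stat, 2.0)
  expect_equal(m2$het_pval, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(m2$het_pval, 0.157, tolerance = 5e-3)
})

test_that("fixed-effect pooling agrees with metafor", {
  set.seed(41)
  b <- rnorm(4, 0.1, 0.2); s <- runif(4, 0.05, 0.3)
  m <- meta_fixed(b, s)
  fit <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(m$beta_meta, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(m$se_meta, fit$se, tolerance = 1e-10)
  expect_equal(m$q_stat, fit$QE, tolerance = 1e-10)
  expect_equal(m$het_pval, fit$QEp, tolerance = 1e-10)
})

test_that("meta is permutation-invariant and scale-consistent", {
  b <- c(0.1, -0.3, 0.25); s <- c(0.05, 0.2, 0.12)
  m1 <- meta_fixed(b, s)
  m2 <- meta_fixed(rev(b), rev(s))
  expect_equal(m1, m2)
  m3 <- meta_fixed(3 * b, 3 * s)
  expect_equal(m3$beta_meta, 3 * m1$beta_meta)
  expect_equal(m3$se_meta, 3 * m1$se_meta)
  expect_equal(m3$q_stat, m1$q_stat)
  # pooled se never exceeds the best single study
  expect_lte(m1$se_meta, min(s))
})

test_that("genomic control floors lambda at one and rescales inflated studies", {
  n <- 1000
  z <- rep(sqrt(CHISQ_MEDIAN <- 0.4549364), n)
  rec <- make_records(paste0("rs", 1:n), seq_len(n) * 1000,
                      beta = z * 0.01, se = 0.01, pval = 0.5)
  out <- genomic_control(make_set(rec))
  expect_equal(out$lambda, 1, tolerance = 1e-6)
  expect_equal(out$set$records$se, rec$se)  # identity at lambda = 1

  rec2 <- rec
  rec2$beta <- rec2$beta * 2  # median z^2 = 4 * 0.4549 -> lambda = 4
  out2 <- genomic_control(make_set(rec2))
  expect_equal(out2$lambda, 4, tolerance = 1e-6)
  expect_equal(out2$set$records$se, rec$se * 2, tolerance = 1e-9)

  rec3 <- rec
  rec3$beta <- 0  # all z = 0: lambda floored at 1, no adjustment
  out3 <- genomic_control(make_set(rec3))
  expect_equal(out3$lambda, 1)
})

test_that("null-simulated z-scores give lambda near one", {
  set.seed(9)
  n <- 10000
  z <- rnorm(n)
  rec <- make_records(paste0("rs", 1:n), seq_len(n) * 1000,
                      beta = z * 0.02, se = 0.02,
                      pval = 2 * pnorm(-abs(z)))
  out <- genomic_control(make_set(rec))
  expect_gte(out$lambda, 0.9)  # floored at 1 when below
  expect_lte(out$lambda, 1.1)
})

test_that("small sets warn and force lambda to one", {
  rec <- make_records(c("rs1", "rs2"), c(1, 2), c(1, 2), 0.01, 0.5)
  expect_warning(out <- genomic_control(make_set(rec)), "unreliable")
  expect_equal(out$lambda, 1)
})

test_that("meta_analyse aligns alleles and drops single-study variants", {
  rec_a <- make_records(c("rs1", "rs2", "rs3"), c(100, 200, 300),
                        beta = c(0.2, 0.1, 0.3), se = 0.1, pval = 0.5,
                        eaf = 0.3, n = 1000, n_case = 100, n_control = 900)
  # rs1 allele-swapped in study B, rs3 absent
  rec_b <- make_records(c("rs1", "rs2"), c(100, 200),
                        beta = c(-0.2, 0.1), se = 0.1, pval = 0.5,
                        eaf = c(0.7, 0.3), ea = c("G", "A"), oa = c("A", "G"),
                        n = 2000, n_case = 150, n_control = 1850)
  met <- meta_analyse(make_set(rec_a, trait_type = "binary"),
                      make_set(rec_b, trait_type = "binary"),
                      apply_gc = FALSE)
  rec <- met$set$records
  expect_setequal(rec$rsid, c("rs1", "rs2"))  # rs3 dropped
  r1 <- rec[rec$rsid == "rs1", ]
  expect_equal(r1$beta, 0.2)  # -0.2 on G = +0.2 on A: perfectly concordant
  expect_equal(r1$q_stat, 0)
  expect_equal(r1$n, 3000)
  expect_equal(r1$n_case, 250)
  expect_equal(r1$effect_allele, "A")
})

test_that("meta output is invariant to allele representation of one study", {
  rec_a <- make_records("rs1", 100, beta = 0.25, se = 0.1, pval = 0.5,
                        eaf = 0.3, n = 1000)
  rec_b1 <- make_records("rs1", 100, beta = 0.15, se = 0.2, pval = 0.5,
                         eaf = 0.3, n = 1000)
  rec_b2 <- rec_b1
  rec_b2$effect_allele <- "G"; rec_b2$other_allele <- "A"
  rec_b2$beta <- -0.15; rec_b2$eaf <- 0.7
  m1 <- meta_analyse(make_set(rec_a), make_set(rec_b1), apply_gc = FALSE)
  m2 <- meta_analyse(make_set(rec_a), make_set(rec_b2), apply_gc = FALSE)
  expect_equal(m1$set$records$beta, m2$set$records$beta)
  expect_equal(m1$set$records$se, m2$set$records$se)
  expect_equal(m1$set$records$eaf, m2$set$records$eaf)
})

test_that("heterogeneity filter removes het_pval <= threshold inclusively", {
  rec <- make_records(paste0("rs", 1:5), 1:5 * 100, 0.1, 0.1, 0.5)
  rec$q_stat <- 1
  rec$het_pval <- c(0.01, 0.05, 0.06, 0.5, 1.0)
  set <- make_set(rec)
  set$records$q_stat <- rec$q_stat
  set$records$het_pval <- rec$het_pval
  out <- filter_heterogeneity(set, threshold = 0.05)
  expect_equal(out$n_removed, 2L)          # 0.01 and exactly 0.05
  expect_equal(nrow(out$set$records), 3L)  # 3 survive
  expect_true(all(out$set$records$het_pval > 0.05))
  # nothing removed when all het_pval = 1
  set2 <- set
  set2$records$het_pval <- 1
  expect_equal(filter_heterogeneity(set2)$n_removed, 0L)
})

test_that("two simulated cohorts from one population pool information", {
  # variance of the pooled beta is the harmonic combination: with equal
  # true beta and independent cohorts, meta z^2 ~ sum of per-study z^2.
  set.seed(13)
  reps <- 400
  z_meta2 <- z_sum2 <- numeric(reps)
  for (i in 1:reps) {
    b <- 0.1
    b1 <- rnorm(1, b, 0.05); b2 <- rnorm(1, b, 0.05)
    m <- meta_fixed(c(b1, b2), c(0.05, 0.05))
    z_meta2[i] <- (m$beta_meta / m$se_meta)^2
    z_sum2[i] <- (b1 / 0.05)^2 + (b2 / 0.05)^2
  }
  # E[z_meta^2] = 2*b^2/se^2/2*2 ... compare means: meta concentrates the
  # signal part (8) but not the two noise df, so the difference is ~1.
  expect_equal(mean(z_meta2), mean(z_sum2) - 1, tolerance = 0.35)
})
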