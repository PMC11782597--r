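mk_mr <- function(beta, se, exposure = "P", outcome = "D") {
  r <- data.frame(exposure_id = exposure, outcome_id = outcome,
                  method = "wald", n_snp = 1L, beta = beta, se = se,
                  ci_low = beta - 1.959964 * se, ci_high = beta + 1.959964 * se,
                  or_ = exp(beta), or_low = exp(beta - 1.959964 * se),
                  or_high = exp(beta + 1.959964 * se),
                  q_stat = NA_real_, q_pval = NA_real_,
                  pval = 2 * pnorm(-abs(beta / se)))
  r
}
mk_st <- function(dir) data.frame(r2_exposure = 0.02,
                                  r2_outcome = if (dir) 1e-4 else 0.05,
                                  direction_true = dir, pval = 0.001,
                                  single_snp = TRUE)

test_that("tier assignment is a pure function of criteria and h4, exhaustively", {
  combos <- expand.grid(cd = c(TRUE, FALSE), ci = c(TRUE, FALSE),
                        st = c(TRUE, FALSE), nr = c(TRUE, FALSE),
                        coloc = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    cr <- c(consistent_direction = combos$cd[i],
            both_ci_exclude_null = combos$ci[i],
            steiger_true = combos$st[i],
            no_reverse_effect = combos$nr[i])
    h4 <- if (combos$coloc[i]) 0.84 else 0.3
    tier <- assign_tier(cr, h4)
    want <- if (!combos$cd[i]) "inconsistent"
            else if (!all(cr)) "suggestive"
            else if (combos$coloc[i]) "colocalized_candidate"
            else "consistent_candidate"
    expect_equal(tier, want)
  }
  # NA criteria count as failed; missing h4 cannot upgrade
  expect_equal(assign_tier(c(consistent_direction = TRUE,
                             both_ci_exclude_null = NA,
                             steiger_true = TRUE,
                             no_reverse_effect = TRUE), NA_real_),
               "suggestive")
  # boundary: h4 exactly at the threshold does not upgrade
  all_true <- c(consistent_direction = TRUE, both_ci_exclude_null = TRUE,
                steiger_true = TRUE, no_reverse_effect = TRUE)
  expect_equal(assign_tier(all_true, 0.8), "consistent_candidate")
  expect_equal(assign_tier(all_true, 0.8 + 1e-9), "colocalized_candidate")
})

test_that("a consistent-direction protein with null-overlapping reverse is a candidate", {
  # concordant positive effects on both platforms, CIs clear of 0,
  # Steiger supportive, reverse CI spans 0, weak coloc: the
  # consistent-candidate pattern without colocalization support
  cand <- evaluate_candidate(
    "DPT",
    forward_a = mk_mr(0.36, 0.10), forward_b = mk_mr(0.39, 0.13),
    reverse = mk_mr(0.01, 0.05),
    steiger_a = mk_st(TRUE), steiger_b = mk_st(TRUE),
    coloc = data.frame(window_bp = 1e6, n_snps = 50, h0 = 0.1, h1 = 0.3,
                       h2 = 0.1, h3 = 0.2, h4 = 0.3))
  expect_true(all(cand$criteria))
  expect_equal(cand$tier, "consistent_candidate")
  # with strong colocalization the tier upgrades
  cand2 <- evaluate_candidate(
    "KIAA1161",
    forward_a = mk_mr(0.36, 0.10), forward_b = mk_mr(0.39, 0.13),
    reverse = NULL, steiger_a = mk_st(TRUE), steiger_b = mk_st(TRUE),
    coloc = data.frame(window_bp = c(125e3, 1e6), n_snps = c(10, 50),
                       h0 = 0.05, h1 = 0.05, h2 = 0.02, h3 = 0.04,
                       h4 = c(0.84, 0.84)))
  expect_equal(cand2$tier, "colocalized_candidate")
  expect_equal(cand2$h4_max, 0.84)
})

test_that("opposite forward directions are inconsistent; missing platform is not shared", {
  cand <- evaluate_candidate("X", mk_mr(0.2, 0.05), mk_mr(-0.2, 0.05),
                             steiger_a = mk_st(TRUE), steiger_b = mk_st(TRUE))
  expect_equal(cand$tier, "inconsistent")
  cand2 <- evaluate_candidate("Y", mk_mr(0.2, 0.05), NULL)
  expect_equal(cand2$tier, "not_shared")
  expect_true(all(is.na(cand2$criteria)))
})

test_that("any reverse CI excluding zero fails the reverse criterion", {
  cand <- evaluate_candidate(
    "Z", mk_mr(0.4, 0.1), mk_mr(0.35, 0.1),
    reverse = list(mk_mr(0.02, 0.05), mk_mr(0.4, 0.1)),
    steiger_a = mk_st(TRUE), steiger_b = mk_st(TRUE))
  expect_false(cand$criteria[["no_reverse_effect"]])
  expect_equal(cand$tier, "suggestive")
})

test_that("reverse MR picks Wald for one instrument, IVW-MRE for two or more", {
  prot_rec <- make_records(c("rs1", "rs2", "rs3"), c(100, 200, 300),
                           beta = c(0.05, -0.02, 0.01), se = 0.02, pval = 0.5,
                           n = 30000)
  prot <- make_set(prot_rec, trait_id = "P")
  inst1 <- make_records("rs1", 100, beta = 0.5, se = 0.05, pval = 1e-9,
                        n = 400000)
  r1 <- reverse_mr(inst1, prot)
  expect_equal(r1$method, "wald")
  expect_equal(r1$n_snp, 1L)
  expect_false(r1$relaxed_threshold)
  inst2 <- make_records(c("rs1", "rs2"), c(100, 200), beta = c(0.5, 0.4),
                        se = 0.05, pval = 1e-8, n = 400000)
  r2 <- reverse_mr(inst2, prot, relaxed_threshold = TRUE)
  expect_equal(r2$method, "ivw_mre")
  expect_equal(r2$n_snp, 2L)
  expect_true(r2$relaxed_threshold)
  # quantitative outcome: no odds-ratio fields
  expect_true(is.na(r2$or_))
  # zero extractable instruments: not assessable, not an error
  inst0 <- make_records("rs99", 900, beta = 0.5, se = 0.05, pval = 1e-9)
  expect_null(reverse_mr(inst0, prot))
  expect_null(reverse_mr(inst0[0, ], prot))
})
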