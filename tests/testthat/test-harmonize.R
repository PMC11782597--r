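exp_rec <- function(ea, oa, beta = 0.2, eaf = 0.3, se = 0.05, n = 30000,
                    rsid = "rs1") {
  list(rsid = rsid, effect_allele = ea, other_allele = oa, beta = beta,
       eaf = eaf, se = se, n = n)
}

test_that("identical allele pairs harmonize directly", {
  h <- harmonize_pair(exp_rec("A", "G"), exp_rec("A", "G", beta = 0.1, eaf = 0.3))
  expect_equal(h$action, "direct")
  expect_equal(h$beta_x, 0.2)
  expect_equal(h$beta_y, 0.1)
})

test_that("swapped alleles flip the outcome beta and frequency", {
  h <- harmonize_pair(exp_rec("A", "G"),
                      exp_rec("G", "A", beta = 0.1, eaf = 0.7))
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_y, -0.1)
  expect_equal(h$eaf_y, 0.3)
})

test_that("all non-palindromic orientations match a hand-written truth table", {
  # exposure A/G, beta 0.2, eaf 0.3; outcome true effect +0.1 on allele A.
  # Each representation of the same underlying association must harmonize
  # to beta_y = +0.1 on the A allele.
  cases <- list(
    list(ea = "A", oa = "G", beta = 0.1, eaf = 0.3, act = "direct"),
    list(ea = "G", oa = "A", beta = -0.1, eaf = 0.7, act = "flipped"),
    list(ea = "T", oa = "C", beta = 0.1, eaf = 0.3, act = "strand_inferred"),
    list(ea = "C", oa = "T", beta = -0.1, eaf = 0.7, act = "strand_inferred"))
  for (cs in cases) {
    h <- harmonize_pair(exp_rec("A", "G"),
                        exp_rec(cs$ea, cs$oa, beta = cs$beta, eaf = cs$eaf))
    expect_equal(h$action, cs$act)
    expect_equal(h$beta_y, 0.1)
    expect_equal(h$eaf_y, 0.3)
  }
})

test_that("incompatible allele pairs are dropped", {
  h <- harmonize_pair(exp_rec("A", "G"), exp_rec("A", "C", beta = 0.1))
  expect_equal(h$action, "dropped")
  expect_equal(h$drop_reason, "incompatible_alleles")
})

test_that("palindromic pair with informative frequencies is strand-inferred", {
  # EAFs on opposite sides of 0.5, both MAF < 0.3: outcome flipped
  h <- harmonize_pair(exp_rec("A", "T", eaf = 0.1),
                      exp_rec("A", "T", beta = 0.1, eaf = 0.88))
  expect_equal(h$action, "strand_inferred")
  expect_equal(h$beta_y, -0.1)
  expect_equal(h$eaf_y, 0.12)
  # same side: aligned as-is
  h2 <- harmonize_pair(exp_rec("C", "G", eaf = 0.1),
                       exp_rec("C", "G", beta = 0.1, eaf = 0.15))
  expect_equal(h2$action, "strand_inferred")
  expect_equal(h2$beta_y, 0.1)
})

test_that("palindromic pair with MAF >= 0.3 is dropped as ambiguous", {
  h <- harmonize_pair(exp_rec("A", "T", eaf = 0.45),
                      exp_rec("A", "T", beta = 0.1, eaf = 0.52))
  expect_equal(h$action, "dropped")
  expect_equal(h$drop_reason, "ambiguous_palindrome")
  # boundary: exactly 0.3 is not below the bound, so dropped
  h2 <- harmonize_pair(exp_rec("A", "T", eaf = 0.3),
                       exp_rec("A", "T", beta = 0.1, eaf = 0.1))
  expect_equal(h2$action, "dropped")
})

test_that("disallowing palindromes drops them outright", {
  cfg <- harmonize_config(allow_palindromes = FALSE)
  h <- harmonize_pair(exp_rec("A", "T", eaf = 0.1),
                      exp_rec("A", "T", beta = 0.1, eaf = 0.1), cfg)
  expect_equal(h$drop_reason, "palindrome_disallowed")
})

test_that("rows are oriented to the exposure-increasing allele", {
  h <- harmonize_pair(exp_rec("A", "G", beta = -0.2, eaf = 0.3),
                      exp_rec("A", "G", beta = 0.1, eaf = 0.3))
  expect_gte(h$beta_x, 0)
  expect_equal(h$beta_x, 0.2)
  expect_equal(h$beta_y, -0.1)
  expect_equal(h$eaf, 0.7)
})

test_that("harmonization is idempotent", {
  h <- harmonize_pair(exp_rec("A", "G", beta = -0.2, eaf = 0.3),
                      exp_rec("G", "A", beta = 0.1, eaf = 0.7))
  # reconstruct records from the harmonized row and harmonize again
  exp2 <- exp_rec("A", "G", beta = h$beta_x, eaf = h$eaf, se = h$se_x)
  out2 <- exp_rec("A", "G", beta = h$beta_y, eaf = h$eaf_y, se = h$se_y)
  h2 <- harmonize_pair(exp2, out2)
  expect_equal(h2$beta_x, h$beta_x)
  expect_equal(h2$beta_y, h$beta_y)
  expect_equal(h2$eaf, h$eaf)
})

test_that("relabelling the exposure alleles leaves the Wald ratio unchanged", {
  out <- exp_rec("A", "G", beta = 0.1, eaf = 0.3, se = 0.08)
  h1 <- harmonize_pair(exp_rec("A", "G", beta = 0.2, eaf = 0.3), out)
  h2 <- harmonize_pair(exp_rec("G", "A", beta = -0.2, eaf = 0.7), out)
  w1 <- wald_ratio(h1)
  w2 <- wald_ratio(h2)
  expect_equal(w1$beta, w2$beta)
  expect_equal(w1$se, w2$se)
})

test_that("every pair maps to exactly one action", {
  nucl <- c("A", "C", "G", "T")
  combos <- expand.grid(e1 = nucl, e2 = nucl, o1 = nucl, o2 = nucl,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$e1 != combos$e2 & combos$o1 != combos$o2, ]
  acts <- vapply(seq_len(nrow(combos)), function(i) {
    harmonize_pair(exp_rec(combos$e1[i], combos$e2[i], eaf = 0.2),
                   exp_rec(combos$o1[i], combos$o2[i], beta = 0.1,
                           eaf = 0.2))$action
  }, character(1))
  expect_true(all(acts %in% c("direct", "flipped", "strand_inferred", "dropped")))
})

test_that("find_proxy returns the highest-r2 qualifying candidate", {
  outcome <- make_set(make_records(c("rs2", "rs3"), c(110, 120), 0.1, 0.05, 0.5))
  r <- matrix(c(1, 0.922, 0.959,
                0.922, 1, 0.9,
                0.959, 0.9, 1), 3, 3)
  ld <- ld_matrix(r, c("rs1", "rs2", "rs3"), c(100, 110, 120))
  px <- find_proxy("rs1", outcome, ld)
  expect_equal(px$rsid, "rs3")  # r2 0.92 beats 0.85
  expect_false(px$swap)
  # target present in the outcome: identity mapping
  outcome2 <- make_set(make_records(c("rs1", "rs3"), c(100, 120), 0.1, 0.05, 0.5))
  expect_equal(find_proxy("rs1", outcome2, ld)$rsid, "rs1")
  # nothing above the bound
  cfg <- harmonize_config(proxy_min_r2 = 0.99)
  expect_null(find_proxy("rs1", outcome, ld, cfg))
})

test_that("negative-r proxies are allele-swapped, matching a haplotype oracle", {
  set.seed(5)
  n <- 6000
  h1 <- rbinom(n, 1, 0.4)
  h2 <- 1 - h1
  h2[sample(n, 200)] <- rbinom(200, 1, 0.5)  # imperfect negative LD
  panel <- cbind(h1, h2)
  ld <- ld_from_haplotypes(panel, c("rsA", "rsB"), c(100, 200))
  expect_lt(ld_r(ld, "rsA", "rsB"), -0.8)  # oracle: direct haplotype correlation
  # outcome holds only rsB; exposure instrument is rsA with positive beta
  out_rec <- make_records("rsB", 200, beta = -0.3, se = 0.05, pval = 1e-9,
                          eaf = mean(h2))
  outcome <- make_set(out_rec)
  exp_rec_df <- make_records("rsA", 100, beta = 0.5, se = 0.05, pval = 1e-12,
                             eaf = mean(h1))
  rows <- harmonize_set(exp_rec_df, outcome, ld)
  expect_equal(rows$action, "proxied")
  expect_equal(rows$rsid_outcome, "rsB")
  # rsB's effect allele is anti-correlated with rsA's, so the outcome beta
  # flips sign: -(-0.3) = +0.3
  expect_equal(rows$beta_y, 0.3)
})

test_that("rsid mismatch is a usage error", {
  expect_error(harmonize_pair(exp_rec("A", "G"),
                              exp_rec("A", "G", rsid = "rs2")), "rsids differ")
})
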