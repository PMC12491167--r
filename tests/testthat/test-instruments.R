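test_that("variance explained matches hand evaluation and its simplification", {
  expect_equal(variance_explained(0.5, 0.1, 0.01, 10000), 0.009901,
               tolerance = 1e-6)
  expect_equal(variance_explained(0.3, 0, 0.02, 5000), 0)
  # the allele-frequency factor cancels
  expect_equal(variance_explained(0.2, 0.1, 0.02, 5000),
               variance_explained(0.4, 0.1, 0.02, 5000))
  # algebraic simplification beta^2/(beta^2 + n se^2)
  expect_equal(variance_explained(0.17, 0.08, 0.015, 12000),
               0.08^2 / (0.08^2 + 12000 * 0.015^2))
  expect_error(variance_explained(0.3, 0.1, 0.02, 1), "exceed 1")
})

test_that("F statistic evaluates the printed formula and is monotone in r2", {
  expect_equal(f_statistic(0, 1000), 0)
  expect_equal(f_statistic(0.009901, 10000), 0.009901 * 9998 / (1 - 0.009901))
  expect_lt(abs(f_statistic(0.009901, 10000) - 99.97), 0.05)
  expect_lt(f_statistic(0.001, 5000), f_statistic(0.002, 5000))
  expect_error(f_statistic(1, 5000), "r2")
  expect_error(f_statistic(0.1, 2), "exceed 2")
})

test_that("clumping keeps everything when SNPs are unlinked and applies the r2 rule", {
  x <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, 0.15),
                    se = 0.02, pos = c(1e6, 1.001e6, 1.002e6))
  cl <- clump(x, ld = NULL)                 # no LD info: all r2 = 0
  expect_equal(sort(cl$retained$snp), c("rs1", "rs2", "rs3"))

  # two SNPs 1 kb apart with r2 = 0.5: only the smaller-p SNP survives
  y <- make_records(c("rsA", "rsB"), beta = c(0.2, 0.1), se = 0.02,
                    pos = c(1e6, 1.001e6))
  ld <- ld_from_pairs("rsA", "rsB", 0.5)
  cl2 <- clump(y, ld)
  expect_equal(cl2$retained$snp, "rsA")     # rsA has the larger |z|
  expect_equal(cl2$exclusions$snp, "rsB")
  expect_equal(cl2$exclusions$stage, "ld_clump")
})

test_that("clumping a mixed-LD chain matches the step-by-step greedy oracle", {
  set.seed(21)
  for (rep in 1:5) {
    k <- 5
    x <- make_records(sprintf("rs%d", 1:k), beta = rnorm(k, 0, 0.1),
                      se = 0.02, pos = (1:k) * 2e5)
    pairs <- t(combn(k, 2))
    ld <- ld_from_pairs(sprintf("rs%d", pairs[, 1]),
                        sprintf("rs%d", pairs[, 2]),
                        sample(c(0, 0.005, 0.05, 0.5, 0.9),
                               nrow(pairs), replace = TRUE))
    got <- sort(clump(x, ld, 0.01, 10000)$retained$snp)
    expect_equal(got, clump_oracle(x, ld, 0.01, 10000))
  }
})

test_that("clump output does not depend on input row order", {
  set.seed(22)
  k <- 8
  x <- make_records(sprintf("rs%d", 1:k), beta = rnorm(k, 0, 0.1),
                    se = 0.02, pos = (1:k) * 1e5)
  pairs <- t(combn(k, 2))
  ld <- ld_from_pairs(sprintf("rs%d", pairs[, 1]),
                      sprintf("rs%d", pairs[, 2]),
                      runif(nrow(pairs)))
  ref <- sort(clump(x, ld)$retained$snp)
  for (i in 1:3) {
    perm <- x[sample(k), ]
    expect_equal(sort(clump(perm, ld)$retained$snp), ref)
  }
})

test_that("LD input forms agree: square matrix file vs pair list", {
  m <- ld_from_pairs(c("rs1", "rs1"), c("rs2", "rs3"), c(0.4, 0.2))
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(rs1 = 1, rs2 = 1, rs3 = 1))
  expect_equal(m["rs2", "rs3"], 0)

  fm <- tempfile(fileext = ".tsv")
  write.table(m, fm, sep = "\t", quote = FALSE, col.names = NA)
  expect_equal(read_ld(fm)["rs1", "rs2"], 0.4)

  fp <- tempfile(fileext = ".tsv")
  write.table(data.frame(snp_a = c("rs1", "rs1"), snp_b = c("rs2", "rs3"),
                         r2 = c(0.4, 0.2)),
              fp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_ld(fp), m)
})

test_that("selection filters exclude with the correct stage labels", {
  # one violation per SNP; rs_ok passes everything
  pr <- make_pairs(beta_exp = c(0.002, 0.15, 0.002, 0.15, 0.15),
                   beta_out = rep(0.01, 5), se_exp = 0.02, se_out = 0.05)
  pr$snp <- c("rs_weakp", "rs_maf", "rs_weakf", "rs_outp", "rs_ok")
  # rs_weakp: exposure p far above 5e-6 (z = 0.1)
  pr$pval_exp <- c(0.9, 1e-10, 1e-10, 1e-10, 1e-10)
  pr$eaf_exp[2] <- 0.005                          # MAF violation
  # rs_weakf: strong printed p but tiny effect -> F below 10
  pr$pval_out <- c(0.5, 0.5, 0.5, 0.001, 0.5)     # rs_outp outcome-associated
  sel <- select_instruments(pr, criteria = instrument_criteria())
  expect_equal(sel$instruments$snp, "rs_ok")
  got <- sel$exclusions
  expect_equal(got$stage[got$snp == "rs_weakp"], "p_exposure")
  expect_equal(got$stage[got$snp == "rs_maf"], "maf")
  expect_equal(got$stage[got$snp == "rs_weakf"], "weak_instrument")
  expect_equal(got$stage[got$snp == "rs_outp"], "outcome_p")
  expect_equal(nrow(sel$instruments) + nrow(got), nrow(pr))
  expect_equal(sum(sel$stage_counts), 4L)
})

test_that("outcome-association policy direction is configurable", {
  pr <- make_pairs(beta_exp = c(0.15, 0.15), beta_out = c(0.3, 0.001),
                   se_exp = 0.02, se_out = 0.05)
  pr$pval_exp <- 1e-10
  # paper-literal mode: drop SNPs NOT associated with the outcome
  sel <- select_instruments(pr, criteria = instrument_criteria(
    outcome_p_policy = "exclude_above"))
  expect_equal(sel$instruments$snp, pr$snp[1])
  sel2 <- select_instruments(pr, criteria = instrument_criteria(
    outcome_p_policy = "exclude_below"))
  expect_equal(sel2$instruments$snp, pr$snp[2])
  sel3 <- select_instruments(pr, criteria = instrument_criteria(
    outcome_p_policy = "off"))
  expect_equal(nrow(sel3$instruments), 2)
})

test_that("the threshold filters commute: any order gives the same final set", {
  set.seed(23)
  for (rep in 1:10) {
    k <- 40
    pr <- make_pairs(beta_exp = rnorm(k, 0, 0.08),
                     beta_out = rnorm(k, 0, 0.02),
                     se_exp = 0.02, se_out = 0.05,
                     eaf = runif(k, 0.003, 0.5))
    crit <- instrument_criteria(outcome_p_policy = "off")
    ref <- select_instruments(pr, criteria = crit)$instruments$snp

    # manual filters applied in a permuted order
    pass_p <- pr$pval_exp < crit$p_exposure_max
    pass_maf <- pmin(pr$eaf_exp, 1 - pr$eaf_exp) >= crit$maf_min
    r2 <- variance_explained(pr$eaf_exp, pr$beta_exp, pr$se_exp, pr$n_exp)
    pass_f <- f_statistic(r2, pr$n_exp) > crit$f_min
    for (ord in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
      keep <- Reduce(`&`, list(pass_p, pass_maf, pass_f)[ord])
      if (!any(keep)) {
        expect_error(select_instruments(pr, criteria = crit),
                     class = "mr_no_instruments")
      } else {
        expect_equal(sort(pr$snp[keep]), sort(ref))
      }
    }
  }
})

test_that("an emptied instrument set raises a typed error carrying stage counts", {
  pr <- make_pairs(beta_exp = c(0.001, 0.002), beta_out = c(0.01, 0.01))
  pr$pval_exp <- c(0.5, 0.9)
  err <- tryCatch(select_instruments(pr), error = identity)
  expect_s3_class(err, "mr_no_instruments")
  expect_equal(unname(err$stage_counts["p_exposure"]), 2L)
})
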