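test_that("Wald ratio computes the direct ratio with delta-method se", {
  pr <- make_pairs(beta_exp = 0.1, beta_out = 0.2, se_out = 0.05)
  w <- mr_wald_ratio(pr)
  expect_equal(w$beta, 2.0)
  expect_equal(w$se, 0.5)
  expect_equal(w$n_snp, 1L)

  expect_equal(mr_wald_ratio(make_pairs(0.1, 0))$beta, 0)
  expect_error(mr_wald_ratio(make_pairs(0, 0.1)), "zero")

  # first-order se approaches the second-order value when the exposure
  # effect is precisely estimated (se_exp/|beta_exp| = 0.05 here)
  pr2 <- make_pairs(beta_exp = 1, beta_out = 0.2, se_exp = 0.05,
                    se_out = 0.1)
  se1 <- mr_wald_ratio(pr2)$se
  se2 <- mr_wald_ratio(pr2, second_order = TRUE)$se
  se2_oracle <- sqrt(0.1^2 / 1^2 + 0.2^2 * 0.05^2 / 1^4)
  expect_equal(se2, se2_oracle)
  expect_lt(abs(se1 - se2) / se2, 0.05)
})

test_that("IVW equals the closed-form weighted mean of ratios", {
  pr <- make_pairs(beta_exp = c(0.10, 0.05, 0.20),
                   beta_out = c(0.021, 0.009, 0.044),
                   se_out = c(0.05, 0.03, 0.08))
  w <- pr$beta_exp^2 / pr$se_out^2
  oracle <- sum(w * pr$beta_out / pr$beta_exp) / sum(w)
  expect_equal(mr_ivw(pr, "fixed")$beta, oracle)
  expect_equal(mr_ivw(pr, "multiplicative_random")$beta, oracle)
  # random-effects se never deflates below fixed
  expect_gte(mr_ivw(pr)$se, mr_ivw(pr, "fixed")$se)

  # single pair reduces to the Wald ratio
  one <- make_pairs(0.1, 0.25, se_out = 0.04)
  expect_equal(mr_ivw(one)$beta, mr_wald_ratio(one)$beta)
  expect_equal(mr_ivw(one)$se, mr_wald_ratio(one)$se)

  # all ratios equal r -> estimate r
  prop <- make_pairs(beta_exp = c(0.1, 0.2, 0.3),
                     beta_out = 0.7 * c(0.1, 0.2, 0.3))
  expect_equal(mr_ivw(prop)$beta, 0.7)
})

test_that("MR-Egger recovers slope and constant pleiotropy intercept exactly", {
  bx <- c(0.08, 0.12, 0.2, 0.3)
  pr <- make_pairs(beta_exp = bx, beta_out = 0.5 * bx)
  e <- mr_egger(pr)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$extra$intercept, 0, tolerance = 1e-10)

  # adding a constant c to every outcome effect shifts only the intercept
  pr2 <- make_pairs(beta_exp = bx, beta_out = 0.5 * bx + 0.03)
  e2 <- mr_egger(pr2)
  expect_equal(e2$beta, 0.5, tolerance = 1e-10)
  expect_equal(e2$extra$intercept, 0.03, tolerance = 1e-10)

  expect_error(mr_egger(make_pairs(c(0.1, 0.2), c(0.05, 0.1))),
               class = "mr_insufficient_instruments")
})

test_that("weighted median interpolates the cumulative weight function", {
  # equal weights, ratios {1,2,3} -> middle element
  pr <- make_pairs(beta_exp = c(1, 1, 1), beta_out = c(1, 2, 3),
                   se_out = 0.1)
  expect_equal(mr_weighted_median(pr, n_boot = 50, seed = 1)$beta, 2)

  # all ratios equal r; bootstrap se shrinks with the noise
  prr <- make_pairs(beta_exp = c(0.1, 0.2, 0.3),
                    beta_out = 1.5 * c(0.1, 0.2, 0.3), se_out = 0.05)
  expect_equal(mr_weighted_median(prr, n_boot = 50, seed = 1)$beta, 1.5)
  small <- make_pairs(beta_exp = c(0.1, 0.2, 0.3),
                      beta_out = 1.5 * c(0.1, 0.2, 0.3),
                      se_exp = 1e-6, se_out = 1e-6)
  expect_lt(mr_weighted_median(small, n_boot = 100, seed = 1)$se, 1e-4)

  # 4-SNP weighted instance vs an independent interpolation oracle
  pr4 <- make_pairs(beta_exp = c(0.1, 0.2, 0.15, 0.3),
                    beta_out = c(0.05, 0.01, 0.06, 0.12),
                    se_out = c(0.02, 0.05, 0.03, 0.04))
  ratio <- pr4$beta_out / pr4$beta_exp
  wts <- pr4$beta_exp^2 / pr4$se_out^2
  o <- order(ratio)
  cw <- cumsum(wts[o] / sum(wts)) - wts[o] / sum(wts) / 2
  oracle <- approx(cw, ratio[o], xout = 0.5, rule = 2)$y
  expect_equal(mr_weighted_median(pr4, n_boot = 50, seed = 1)$beta, oracle)
  expect_error(mr_weighted_median(pr4[1:2, ], n_boot = 50, seed = 1),
               class = "mr_insufficient_instruments")
})

test_that("mode estimators find the dominant ratio cluster", {
  # identical ratios -> that ratio, both variants
  pr <- make_pairs(beta_exp = c(0.1, 0.2, 0.3), beta_out = 2 * c(0.1, 0.2, 0.3))
  expect_equal(mr_mode(pr, weighted = TRUE, n_boot = 50, seed = 1)$beta, 2,
               tolerance = 1e-6)
  expect_equal(mr_mode(pr, weighted = FALSE, n_boot = 50, seed = 1)$beta, 2,
               tolerance = 1e-6)

  # equal weights make weighted and simple variants coincide
  pr2 <- make_pairs(beta_exp = rep(0.1, 5),
                    beta_out = 0.1 * c(0.9, 1.0, 1.1, 2.8, 3.1),
                    se_out = 0.05)
  expect_equal(mr_mode(pr2, weighted = TRUE, n_boot = 50, seed = 1)$beta,
               mr_mode(pr2, weighted = FALSE, n_boot = 50, seed = 1)$beta)

  # bimodal ratios (5 near 1, 2 near 3): estimate near 1, matching a
  # dense-grid kernel-density oracle at the same bandwidth
  ratios <- c(0.95, 0.99, 1.0, 1.03, 1.06, 2.95, 3.05)
  pr3 <- make_pairs(beta_exp = rep(0.2, 7), beta_out = 0.2 * ratios,
                    se_out = 0.04)
  m <- mr_mode(pr3, weighted = FALSE, n_boot = 50, seed = 1)
  s <- 0.9 * min(sd(ratios), mad(ratios)) / length(ratios)^(1 / 5)
  grid <- seq(min(ratios) - 3 * s, max(ratios) + 3 * s, length.out = 40001)
  dens <- vapply(grid, function(x) mean(dnorm(x, ratios, s)), numeric(1))
  oracle <- grid[which.max(dens)]
  expect_lt(abs(m$beta - 1), 0.2)
  expect_equal(m$beta, oracle, tolerance = 0.01)
})

test_that("estimators are order-invariant and noiseless-consistent", {
  set.seed(31)
  bx <- runif(6, 0.05, 0.3)
  pr <- make_pairs(beta_exp = bx, beta_out = -0.4 * bx,
                   se_out = runif(6, 0.02, 0.06))
  perm <- pr[sample(6), ]
  for (f in list(function(p) mr_ivw(p)$beta,
                 function(p) mr_egger(p)$beta,
                 function(p) mr_weighted_median(p, n_boot = 50, seed = 7)$beta,
                 function(p) mr_mode(p, n_boot = 50, seed = 7)$beta)) {
    expect_equal(f(perm), f(pr), tolerance = 1e-9)
  }
  # noiseless proportionality: every estimator returns the true slope
  expect_equal(mr_ivw(pr)$beta, -0.4, tolerance = 1e-12)
  expect_equal(mr_egger(pr)$beta, -0.4, tolerance = 1e-9)
  expect_equal(mr_weighted_median(pr, n_boot = 50, seed = 7)$beta, -0.4,
               tolerance = 1e-12)
  expect_equal(mr_mode(pr, n_boot = 50, seed = 7)$beta, -0.4,
               tolerance = 1e-6)
})

test_that("allele re-orientation (sign flip) leaves estimates unchanged", {
  set.seed(32)
  bx <- rnorm(5, 0, 0.2)
  pr <- make_pairs(beta_exp = bx, beta_out = 0.3 * bx + rnorm(5, 0, 0.01))
  # re-orient every SNP: swap alleles on both traits = negate both betas
  flipped <- pr
  flipped$beta_exp <- -pr$beta_exp
  flipped$beta_out <- -pr$beta_out
  expect_equal(mr_ivw(flipped)$beta, mr_ivw(pr)$beta)
  expect_equal(mr_egger(flipped)$beta, mr_egger(pr)$beta)
  expect_equal(mr_egger(flipped)$extra$intercept, mr_egger(pr)$extra$intercept)
  expect_equal(mr_weighted_median(flipped, n_boot = 50, seed = 2)$beta,
               mr_weighted_median(pr, n_boot = 50, seed = 2)$beta)
})

test_that("odds-ratio and confidence-interval fields follow the exp construction", {
  set.seed(33)
  pr <- make_pairs(beta_exp = runif(4, 0.1, 0.3),
                   beta_out = rnorm(4, 0, 0.05))
  z <- qnorm(0.975)
  for (est in list(mr_ivw(pr), mr_egger(pr),
                   mr_weighted_median(pr, n_boot = 50, seed = 3))) {
    expect_equal(est$or_, exp(est$beta))
    expect_equal(est$ci_low, exp(est$beta - z * est$se))
    expect_equal(est$ci_high, exp(est$beta + z * est$se))
    expect_true(est$ci_low < est$or_ && est$or_ < est$ci_high)
  }
})

test_that("mr_all dispatches on instrument count", {
  expect_equal(mr_all(make_pairs(0.1, 0.2))$method, "wald")
  expect_equal(mr_all(make_pairs(c(0.1, 0.2), c(0.02, 0.05)))$method, "ivw")
  tab <- mr_all(make_pairs(c(0.1, 0.2, 0.3), c(0.02, 0.05, 0.07)),
                n_boot = 50, seed = 5)
  expect_setequal(tab$method, c("ivw", "egger", "weighted_median",
                                "weighted_mode", "simple_mode"))
  expect_error(mr_all(make_pairs(c(0.1, 0.2, 0.3), c(0.02, 0.05, 0.07))),
               "seed")
})
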