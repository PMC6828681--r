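test_that("low-count filter keeps exactly genes above threshold in all samples", {
  counts <- rbind(keep = c(3, 3, 3, 3, 3, 3),
                  border = c(3, 3, 2, 3, 3, 3),
                  zero = c(0, 0, 0, 0, 0, 0),
                  high = c(50, 60, 40, 55, 45, 70))
  colnames(counts) <- paste0("s", 1:6)
  filt <- filter_low_counts(counts, min_count = 2)
  expect_identical(rownames(filt), c("keep", "high"))
  expect_identical(ncol(filt), 6L)
  expect_error(filter_low_counts(counts, min_count = 100), "threshold")
})

test_that("TMM factors absorb pure depth differences and detect composition bias", {
  set.seed(11)
  base <- rnbinom(200, size = 10, mu = exp(rnorm(200, 5, 1)))
  eq <- cbind(s1 = base, s2 = base)
  rownames(eq) <- sprintf("g%d", 1:200)
  expect_equal(unname(tmm_factors(eq)$factors), c(1, 1))

  doubled <- cbind(s1 = base, s2 = 2L * base)
  rownames(doubled) <- rownames(eq)
  expect_equal(unname(tmm_factors(doubled)$factors), c(1, 1))

  # 10 genes 8-fold inflated in B: factor_B < 1, matching the brute-force rule
  set.seed(12)
  a <- rnbinom(100, size = 20, mu = 500)
  b <- a
  b[1:10] <- 8L * b[1:10]
  m <- cbind(sA = a, sB = b)
  rownames(m) <- sprintf("g%d", 1:100)
  nf <- tmm_factors(m)$factors
  expect_lt(nf[["sB"]] / nf[["sA"]], 1)
  raw_b <- brute_tmm_pair(m[, "sB"], m[, "sA"])
  expected <- c(1, raw_b) / exp(mean(log(c(1, raw_b))))
  expect_equal(unname(nf), expected, tolerance = 1e-12)

  zero <- cbind(s1 = base, s2 = 0L * base)
  expect_error(tmm_factors(zero), "zero total count")
})

test_that("TMM factors track the reference implementation on simulated data", {
  skip_if_not_installed("edgeR")
  set.seed(13)
  mu <- exp(rnorm(500, 5, 1.5))
  m <- sapply(1:6, function(i) rnbinom(500, size = 10,
                                       mu = mu * exp(rnorm(1, 0, 0.3))))
  dimnames(m) <- list(sprintf("g%d", 1:500), paste0("s", 1:6))
  m <- m[rowSums(m > 0) == 6, ]
  ours <- tmm_factors(m)$factors
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("moment dispersion recovers Poisson and NB regimes", {
  set.seed(21)
  mu <- rlnorm(2000, log(150), 1)
  des <- small_design()
  pois <- matrix(rpois(2000 * 6, rep(mu, 6)), 2000,
                 dimnames = list(sprintf("g%d", 1:2000), paste0("s", 1:6)))
  d <- estimate_dispersion(pois, des, tmm_factors(pois))
  expect_lt(d$common, 0.02)

  nb <- matrix(rnbinom(2000 * 6, size = 10, mu = rep(mu, 6)), 2000,
               dimnames = dimnames(pois))
  d2 <- estimate_dispersion(nb, des, tmm_factors(nb))
  expect_gt(d2$common, 0.05)
  expect_lt(d2$common, 0.2)

  const <- rbind(flat = rep(5L, 6), varies = c(2L, 9L, 4L, 7L, 3L, 8L))
  colnames(const) <- paste0("s", 1:6)
  norm <- list(factors = setNames(rep(1, 6), paste0("s", 1:6)),
               lib_size = colSums(const))
  d3 <- estimate_dispersion(const, des, norm)
  expect_identical(unname(d3$raw[["flat"]]), 0)

  singleton <- des[c(1, 2, 3, 4), ]
  expect_error(estimate_dispersion(pois, singleton, tmm_factors(pois)),
               "single replicate")
})

test_that("exact NB test reduces to the binomial at zero dispersion", {
  for (tot in c(1, 2, 3, 7, 25, 120, 200)) {
    for (sa in unique(c(0, 1, tot %/% 3, tot %/% 2, tot))) {
      p <- ddixome:::nb_conditional_pvalue(sa, tot - sa, 3, 3, 0)
      expect_equal(p, binom.test(sa, tot, 0.5)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("exact NB conditional p matches independent enumeration and behaves at extremes", {
  # symmetric split is the modal outcome
  expect_equal(ddixome:::nb_conditional_pvalue(40, 40, 3, 3, 0.1), 1)
  # extreme split is very significant
  expect_lt(ddixome:::nb_conditional_pvalue(100, 1, 3, 3, 0.05), 0.001)
  # independent dnbinom-product enumeration across dispersions and splits
  for (phi in c(0.01, 0.1, 0.5)) {
    for (split in list(c(10, 3), c(55, 20), c(0, 17), c(33, 33))) {
      expect_equal(
        ddixome:::nb_conditional_pvalue(split[1], split[2], 3, 3, phi),
        brute_nb_conditional(split[1], split[2], 3, 3, phi),
        tolerance = 1e-9)
    }
  }
  # unequal replicate numbers shift the conditional centre
  p_unbal <- ddixome:::nb_conditional_pvalue(40, 20, 4, 2, 0.05)
  expect_gt(p_unbal, 0.5)
})

test_that("contrast direction flips logFC but not p-values", {
  set.seed(31)
  counts <- small_nb_counts(300, mu = rlnorm(300, 5, 1), phi = 0.05,
                            lfc = sample(c(0, 1.5, -1.5), 300, TRUE))
  des <- small_design()
  norm <- tmm_factors(counts)
  disp <- estimate_dispersion(counts, des, norm)
  fwd <- exact_test_nb(counts, des, norm, disp, "armX", "untreated", "single")
  rev <- exact_test_nb(counts, des, norm, disp, "armX", "single", "untreated")
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  expect_equal(fwd$logFC, -rev$logFC, tolerance = 1e-9)
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.1, NaN)), "NA/NaN")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("run_contrast recovers planted fold changes with FDR control", {
  set.seed(51)
  lfc <- c(rep(2, 50), rep(0, 1950))
  counts <- small_nb_counts(2000, mu = rlnorm(2000, log(150), 1), phi = 0.05,
                            lfc = lfc)
  des <- small_design()
  res <- run_contrast(counts, des, "armX", "untreated", "single")
  planted <- rownames(counts)[1:50]
  expect_gte(length(intersect(res$significant, planted)), 45)
  # false positives bounded by 5% of the null genes
  false_pos <- setdiff(res$significant, planted)
  expect_lte(length(false_pos), ceiling(0.05 * 1950))

  expect_error(run_contrast(counts, des, "armX", "single", "single"),
               "identical")
  res0 <- run_contrast(counts, des, "armX", "untreated", "single",
                       fdr_threshold = 0)
  expect_identical(length(res0$significant), 0L)
})

test_that("global-null p-values are calibrated", {
  set.seed(61)
  counts <- small_nb_counts(2000, mu = rlnorm(2000, log(150), 1), phi = 0.05)
  res <- run_contrast(counts, small_design(), "armX", "untreated", "single")
  p <- res$table$p_value
  for (alpha in c(0.01, 0.05)) {
    se <- sqrt(alpha * (1 - alpha) / length(p))
    expect_lt(abs(mean(p < alpha) - alpha), 3 * se)
  }
})
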