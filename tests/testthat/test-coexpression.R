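make_expr <- function(n_genes, n_groups, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_groups), n_genes, n_groups,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         paste0("c", seq_len(n_groups))))
}

test_that("soft-thresholded adjacency follows the power transform", {
  # orthogonal construction giving correlation exactly +/- 0.5
  u <- c(1, 1, -1, -1)
  v <- c(1, -1, 1, -1)
  e <- rbind(g1 = u, g2 = 0.5 * u + sqrt(0.75) * v,
             g3 = -(0.5 * u + sqrt(0.75) * v))
  expect_equal(cor(e["g1", ], e["g2", ]), 0.5, tolerance = 1e-12)
  a <- adjacency_matrix(e, beta = 16)
  expect_equal(a["g1", "g2"], 1.52587890625e-05, tolerance = 1e-12)  # 0.5^16
  expect_equal(a["g1", "g3"], 1.52587890625e-05, tolerance = 1e-12)  # |-0.5|^16
  expect_equal(unname(diag(a)), c(0, 0, 0))

  # perfectly correlated and anti-correlated profiles both give 1 (unsigned)
  e3 <- rbind(g1 = 1:5, g2 = 2 * (1:5) + 3, g3 = -(1:5))
  a3 <- adjacency_matrix(e3, beta = 16)
  expect_equal(a3["g1", "g2"], 1)
  expect_equal(a3["g1", "g3"], 1)
  # signed network separates the anti-correlated pair
  a3s <- adjacency_matrix(e3, beta = 2, signed = TRUE)
  expect_equal(a3s["g1", "g3"], 0)

  e4 <- rbind(g1 = 1:4, flat = rep(2, 4))
  expect_error(adjacency_matrix(e4), "flat")
})

test_that("topological overlap matches closed forms and the triple-loop oracle", {
  ones <- matrix(1, 3, 3) - diag(3)
  t1 <- tom_similarity(ones)
  expect_equal(t1[1, 2], 1)  # (1 + 1) / (2 + 1 - 1)
  expect_equal(unname(diag(t1)), rep(1, 3))

  zero <- matrix(0, 4, 4)
  t0 <- tom_similarity(zero)
  expect_equal(sum(t0) - sum(diag(t0)), 0)

  set.seed(91)
  a <- matrix(runif(36), 6, 6)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  expect_equal(tom_similarity(a), brute_tom(a), tolerance = 1e-12)

  asym <- a; asym[1, 2] <- asym[1, 2] + 0.1
  expect_error(tom_similarity(asym), "symmetric")
})

test_that("TOM stays within [0, 1] for valid adjacencies", {
  set.seed(92)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tt <- tom_similarity(a)
    expect_true(all(tt >= -1e-12 & tt <= 1 + 1e-12))
  }
})

test_that("module detection recovers planted blocks and respects min_size", {
  sim <- simulate_coexpression_profile(40, c(20, 20), within_cor = 0.9,
                                       n_groups = 20, seed = 93)
  tom <- tom_similarity(adjacency_matrix(sim$expr, beta = 16))
  mods <- detect_modules(tom, min_size = 5)
  expect_identical(length(setdiff(unique(mods), "grey")), 2L)
  expect_equal(adjusted_rand(mods, sim$truth), 1)

  # 4 correlated genes cannot form a module at min_size 5
  sim4 <- simulate_coexpression_profile(4, 4, within_cor = 0.95,
                                        n_groups = 20, seed = 94)
  tom4 <- tom_similarity(adjacency_matrix(sim4$expr, beta = 16))
  expect_warning(mods4 <- detect_modules(tom4, min_size = 5), "grey")
  expect_identical(unique(mods4), "grey")

  # identical profiles collapse into a single module holding every gene
  set.seed(95)
  prof <- rnorm(8)
  same <- matrix(rep(prof, each = 6), 6, 8,
                 dimnames = list(paste0("g", 1:6), paste0("c", 1:8)))
  tom_s <- tom_similarity(adjacency_matrix(same, beta = 16))
  mods_s <- detect_modules(tom_s, min_size = 5)
  expect_identical(unname(mods_s), rep("turquoise", 6))
})

test_that("module detection is invariant to gene input order", {
  set.seed(96)
  sim <- simulate_coexpression_profile(60, c(20, 15), within_cor = 0.85,
                                       n_groups = 20, seed = 95)
  tom <- tom_similarity(adjacency_matrix(sim$expr, beta = 16))
  mods <- detect_modules(tom, min_size = 5)
  perm <- sample(rownames(tom))
  mods_p <- detect_modules(tom[perm, perm], min_size = 5)
  expect_identical(mods_p[names(mods)], mods)
})

test_that("eigengene summarizes the module and is orientation-stable", {
  e <- make_expr(10, 8, seed = 96)
  same <- e
  same[1:5, ] <- matrix(rep(e[1, ], each = 5), 5, 8)
  eg <- module_eigengene(same, rownames(same)[1:5])
  z <- scale(e[1, ])[, 1]
  expect_equal(abs(cor(eg, z)), 1, tolerance = 1e-9)
  expect_equal(sum(eg^2), 1, tolerance = 1e-12)

  # flipping every member profile leaves the oriented eigengene's geometry
  flipped <- -same
  eg_f <- module_eigengene(flipped, rownames(same)[1:5])
  expect_equal(abs(cor(eg, eg_f)), 1, tolerance = 1e-9)

  # single-gene module: the standardized profile itself
  eg1 <- module_eigengene(e, "g03")
  expect_equal(abs(cor(eg1, e["g03", ])), 1, tolerance = 1e-9)

  # planted latent factor is recovered
  sim <- simulate_coexpression_profile(30, 30, within_cor = 0.81,
                                       n_groups = 12, seed = 97)
  eg_m <- module_eigengene(sim$expr, names(sim$truth)[sim$truth == "M1"])
  # eigengene explains at least as much module variance as any single gene
  z_mod <- t(scale(t(sim$expr[sim$truth == "M1", ])))
  var_explained <- function(v) sum((z_mod %*% v)^2)
  best_gene <- max(apply(z_mod, 1, function(g) var_explained(g / sqrt(sum(g^2)))))
  expect_gte(var_explained(eg_m) + 1e-9, best_gene)
})

test_that("module-trait correlation and top-module selection follow the min rule", {
  set.seed(98)
  eg <- list(m1 = rnorm(8), m2 = rnorm(8))
  traits <- data.frame(viability = eg$m1 + rnorm(8, 0, 1e-8),
                       apoptosis = rnorm(8))
  mt <- module_trait(eg, traits)
  r_m1v <- mt$r[mt$module == "m1" & mt$trait == "viability"]
  expect_equal(r_m1v, 1, tolerance = 1e-6)
  expect_lt(mt$p_value[mt$module == "m1" & mt$trait == "viability"], 1e-6)

  # orthogonal trait by construction
  v <- rnorm(8); v <- v - mean(v)
  w <- rnorm(8); w <- w - mean(w)
  w <- w - sum(w * v) / sum(v * v) * v
  mt2 <- module_trait(list(m = v), data.frame(t = w))
  expect_equal(mt2$r, 0, tolerance = 1e-10)

  expect_error(module_trait(list(m = 1:2), data.frame(t = 1:2)), "at least 3")

  # min-over-traits rule: (0.9, 0.8) beats (0.95, 0.3)
  mt3 <- data.frame(module = c("a", "a", "b", "b"),
                    trait = c("t1", "t2", "t1", "t2"),
                    r = c(0.9, -0.8, 0.95, 0.3))
  expect_identical(select_top_module(mt3), "a")
  mt4 <- data.frame(module = "only", trait = c("t1", "t2"), r = c(0.2, 0.1))
  expect_identical(select_top_module(mt4), "only")
})

test_that("noisy trait correlation attenuates but stays high at moderate noise", {
  set.seed(99)
  hits <- 0L
  for (i in 1:10) {
    eg <- rnorm(8)
    eg <- (eg - mean(eg)) / sd(eg)
    trait <- eg + rnorm(8, 0, 0.2)
    if (abs(cor(eg, trait)) > 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("full co-expression stage recovers a planted causal module", {
  set.seed(100)
  sim <- simulate_coexpression_profile(200, c(40, 30), within_cor = 0.8,
                                       n_groups = 20, seed = 100)
  latent <- colMeans(sim$expr[sim$truth == "M1", ])
  traits <- data.frame(viability = 70 - 10 * latent + rnorm(20, 0, 0.5),
                       apoptosis = 20 + 6 * latent + rnorm(20, 0, 0.5))
  res <- run_coexpression(sim$expr, traits, beta = 16, min_size = 5)
  top_genes <- names(res$modules)[res$modules == res$top_module]
  m1_genes <- names(sim$truth)[sim$truth == "M1"]
  expect_gt(length(intersect(top_genes, m1_genes)) / length(m1_genes), 0.9)
  expect_gte(adjusted_rand(res$modules, sim$truth), 0.9)
})
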