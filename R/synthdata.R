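# Synthetic two-arm drug-combination experiment with planted ground truth.
# Emulates the structure of the motivating study's deposited data: two
# treatment arms (cell line + primary chemotherapy drug), three conditions per
# arm (untreated, single drug, drug + interacting agent), three biological
# replicates, negative-binomial counts. DE genes are planted on two log2
# fold-change scales: L1 (single vs untreated) and L2 (combined vs single),
# with sign(L2) = sign(L1) for positive-interaction genes and opposite for
# negative-interaction genes. Each planted co-expression module has one shared
# treatment-response profile (with the cross-arm group-A signature) that its
# members follow up to a per-gene scale and small log-scale noise; the first
# module's profile drives the phenotype traits.

#' Simulation configuration
#'
#' Defaults mirror the motivating study's design: 2 arms x 3 treatments x 3
#' replicates, NB dispersion 0.1, log-normal baseline means, library sizes
#' varying log-normally (sigma 0.2) so TMM normalization has real work to do,
#' 15% DE genes with |log2 FC| uniform on `[1, 2]`, and per-arm
#' positive-interaction probabilities 0.309 and 0.129 (the arm-level fractions
#' observed in the study).
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_reps Replicates per condition (default 3).
#' @param arms Character(2): arm labels; the first is the positive-reference
#'   arm.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   mean expression (defaults `log(150)`, 1.2).
#' @param dispersion NB dispersion phi, variance = mu + phi mu^2 (default
#'   0.05, i.e. a biological coefficient of variation of ~0.22, typical of
#'   cell-line RNA-seq; 0 gives Poisson counts).
#' @param fraction_de Fraction of genes planted DE in all four contrasts
#'   (default 0.15).
#' @param logfc_min,logfc_max Range of |log2 FC| for planted effects
#'   (defaults 1 and 2).
#' @param p_positive Numeric(2): per-arm probability that a planted DE gene is
#'   a positive-interaction gene (defaults 0.309, 0.129).
#' @param libsize_sdlog Log-normal sigma of per-sample library-size factors
#'   (default 0.2).
#' @param module_sizes Integer vector of planted module sizes, drawn from the
#'   DE genes; the first module is causal for the phenotype (default
#'   `c(30, 20)`).
#' @param module_loading Loading of member genes on the shared module profile
#'   (default 0.9); the per-gene log2 noise SD is
#'   `module_amplitude * sqrt(1 - module_loading^2)`.
#' @param module_amplitude Scale of the per-gene noise around the module
#'   profile (default 1).
#' @param phenotype_noise SD of Gaussian noise added to the phenotype traits
#'   (default 2, on the percent scale).
#' @param n_gene_sets Number of gene sets including the planted one
#'   (default 20).
#' @param set_size Genes per set (default 30).
#' @param planted_set_n_de How many members of the planted set come from DE
#'   genes (default 25).
#' @param hub_degree Planted within-module degree of the hub gene
#'   (default 10).
#' @param background_edge_prob Erdos-Renyi background edge probability among
#'   module genes (default 0.05).
#' @param seed Mandatory integer seed; the whole simulation is a pure function
#'   of this configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_reps = 3,
                       arms = c("A431_dox", "MDA231_5fu"),
                       baseline_meanlog = log(150), baseline_sdlog = 1.2,
                       dispersion = 0.05, fraction_de = 0.15,
                       logfc_min = 1, logfc_max = 2,
                       p_positive = c(0.309, 0.129),
                       libsize_sdlog = 0.2,
                       module_sizes = c(30, 20), module_loading = 0.9,
                       module_amplitude = 1, phenotype_noise = 2,
                       n_gene_sets = 20, set_size = 30, planted_set_n_de = 25,
                       hub_degree = 10, background_edge_prob = 0.05,
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  if (length(arms) != 2L || anyDuplicated(arms)) stop("need two distinct arms")
  if (any(p_positive < 0 | p_positive > 1))
    stop("p_positive must be probabilities")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (fraction_de < 0 || fraction_de > 1) stop("fraction_de must be in [0, 1]")
  if (logfc_min <= 0 || logfc_max < logfc_min)
    stop("need 0 < logfc_min <= logfc_max")
  if (module_loading < 0 || module_loading > 1)
    stop("module_loading must be in [0, 1]")
  cfg <- list(n_genes = n_genes, n_reps = n_reps, arms = arms,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, dispersion = dispersion,
              fraction_de = fraction_de, logfc_min = logfc_min,
              logfc_max = logfc_max, p_positive = p_positive,
              libsize_sdlog = libsize_sdlog, module_sizes = module_sizes,
              module_loading = module_loading,
              module_amplitude = module_amplitude,
              phenotype_noise = phenotype_noise,
              n_gene_sets = n_gene_sets, set_size = set_size,
              planted_set_n_de = planted_set_n_de, hub_degree = hub_degree,
              background_edge_prob = background_edge_prob,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

rnb <- function(n, mu, phi) {
  if (phi < 1e-12) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate counts, design and planted truth
#'
#' @param config A [sim_config()].
#' @return List: `counts` (integer matrix), `design` (data.frame), `truth`
#'   (data.frame: gene_id, is_de, per-arm L1/L2 and interaction class, group,
#'   module), `latent` (list module -> latent factor over condition groups),
#'   `condition_groups` (character, `arm.treatment` order used throughout).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("G%05d", seq_len(ng))
  mu <- stats::rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)

  n_de <- round(config$fraction_de * ng)
  de_idx <- sort(sample.int(ng, n_de))
  is_de <- seq_len(ng) %in% de_idx

  # per-arm planted effects
  l1 <- l2 <- matrix(0, ng, 2L)
  for (a in 1:2) {
    mag1 <- stats::runif(n_de, config$logfc_min, config$logfc_max)
    mag2 <- stats::runif(n_de, config$logfc_min, config$logfc_max)
    s1 <- sample(c(-1, 1), n_de, replace = TRUE)
    pos <- stats::runif(n_de) < config$p_positive[[a]]
    s2 <- ifelse(pos, s1, -s1)
    l1[de_idx, a] <- s1 * mag1
    l2[de_idx, a] <- s2 * mag2
  }

  design <- expand.grid(replicate = seq_len(config$n_reps),
                        treatment = TREATMENT_LEVELS, arm = config$arms,
                        stringsAsFactors = FALSE)[, c(3, 2, 1)]
  design$sample_id <- paste(design$arm, design$treatment, design$replicate,
                            sep = ".")
  design <- design[, c("sample_id", "arm", "treatment", "replicate")]
  groups <- unique(paste(design$arm, design$treatment, sep = "."))

  # planted modules: every member follows one shared treatment-response
  # profile (scaled per gene, plus small log-scale noise), so a module is both
  # a tight co-expression block and a coherent interaction signature. The
  # shared profile carries the cross-arm group-A pattern (positive interaction
  # in arm 1, negative in arm 2) -- the group the motivating study carried
  # into co-expression analysis.
  module <- rep(NA_character_, ng)
  mod_sizes <- config$module_sizes
  if (length(mod_sizes) && sum(mod_sizes) > n_de)
    stop("module_sizes exceed the number of planted DE genes")
  pool <- de_idx
  mod_names <- paste0("M", seq_along(mod_sizes))
  mod_members <- list()
  mod_profile <- list()
  for (m in seq_along(mod_sizes)) {
    pick <- sort(sample(pool, mod_sizes[[m]]))
    pool <- setdiff(pool, pick)
    module[pick] <- mod_names[[m]]
    mod_members[[mod_names[[m]]]] <- pick
    p <- stats::setNames(numeric(length(groups)), groups)
    gamma <- stats::runif(length(pick), 0.8, 1.2)
    for (a in 1:2) {
      arm <- config$arms[[a]]
      m1 <- stats::runif(1L, config$logfc_min, config$logfc_max)
      m2 <- stats::runif(1L, config$logfc_min, config$logfc_max)
      s1 <- sample(c(-1, 1), 1L)
      s2 <- if (a == 1L) s1 else -s1
      p[paste0(arm, ".single")] <- s1 * m1
      p[paste0(arm, ".combined")] <- s1 * m1 + s2 * m2
      l1[pick, a] <- gamma * s1 * m1
      l2[pick, a] <- gamma * s2 * m2
    }
    mod_profile[[mod_names[[m]]]] <- p
  }

  # condition-group log2 offsets: planted L pattern (+ per-gene noise around
  # the module profile for module members)
  offset <- matrix(0, ng, length(groups), dimnames = list(genes, groups))
  for (a in 1:2) {
    arm <- config$arms[[a]]
    offset[, paste0(arm, ".single")] <- l1[, a]
    offset[, paste0(arm, ".combined")] <- l1[, a] + l2[, a]
  }
  noise_sd <- config$module_amplitude * sqrt(1 - config$module_loading^2)
  for (m in names(mod_members))
    for (g in mod_members[[m]])
      offset[g, ] <- offset[g, ] + stats::rnorm(length(groups), 0, noise_sd)
  latent <- mod_profile

  libfac <- stats::rlnorm(nrow(design), 0, config$libsize_sdlog)
  counts <- matrix(0L, ng, nrow(design),
                   dimnames = list(genes, design$sample_id))
  grp_of_sample <- paste(design$arm, design$treatment, sep = ".")
  for (j in seq_len(nrow(design))) {
    mean_j <- mu * 2^offset[, grp_of_sample[[j]]] * libfac[[j]]
    counts[, j] <- as.integer(rnb(ng, mean_j, config$dispersion))
  }

  iclass <- function(a) ifelse(sign(l1[de_idx, a]) == sign(l2[de_idx, a]),
                               "positive", "negative")
  truth <- data.frame(gene_id = genes, is_de = is_de,
                      l1_arm1 = l1[, 1L], l2_arm1 = l2[, 1L],
                      l1_arm2 = l1[, 2L], l2_arm2 = l2[, 2L],
                      iclass_arm1 = NA_character_,
                      iclass_arm2 = NA_character_,
                      group = NA_character_, module = module,
                      stringsAsFactors = FALSE)
  truth$iclass_arm1[de_idx] <- iclass(1L)
  truth$iclass_arm2[de_idx] <- iclass(2L)
  truth$group[de_idx] <- assign_group(truth$iclass_arm1[de_idx],
                                      truth$iclass_arm2[de_idx])
  list(counts = counts, design = design, truth = truth, latent = latent,
       condition_groups = groups)
}

#' Simulate phenotype traits driven by the causal module
#'
#' Viability and apoptosis (percent) are linear functions of the first
#' (causal) module's standardized treatment-response profile across the
#' condition groups, plus Gaussian noise.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_counts()] for the same config.
#' @return data.frame: arm, treatment, viability, apoptosis (one row per
#'   condition group, in `sim$condition_groups` order).
#' @export
simulate_phenotype <- function(config, sim) {
  if (!length(sim$latent)) stop("no planted module to drive the phenotype")
  set.seed(config$seed + 1L)
  f <- as.numeric(scale(sim$latent[[1L]]))
  groups <- sim$condition_groups
  parts <- strsplit(groups, ".", fixed = TRUE)
  noise <- config$phenotype_noise
  data.frame(
    arm = vapply(parts, `[[`, character(1L), 1L),
    treatment = vapply(parts, `[[`, character(1L), 2L),
    viability = 70 - 15 * f + stats::rnorm(length(f), 0, noise),
    apoptosis = 20 + 10 * f + stats::rnorm(length(f), 0, noise),
    stringsAsFactors = FALSE)
}

#' Simulate gene sets and a protein-interaction edge list
#'
#' One planted set is drawn preferentially from the DE genes (so it is the
#' most enriched in any DE-derived list); the remaining sets are uniform
#' background. The edge list plants one hub inside the causal module with
#' elevated degree, on top of Erdos-Renyi background edges among module genes.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_counts()].
#' @return List: `sets` (named list, planted set first, named "planted_set"),
#'   `edges` (data.frame node_a, node_b, score), `hub` (planted hub gene id).
#' @export
simulate_sets_and_edges <- function(config, sim) {
  set.seed(config$seed + 2L)
  truth <- sim$truth
  genes <- truth$gene_id
  de_genes <- genes[truth$is_de]
  non_de <- genes[!truth$is_de]
  n_de_pick <- min(config$planted_set_n_de, length(de_genes), config$set_size)
  planted <- c(sample(de_genes, n_de_pick),
               sample(non_de, config$set_size - n_de_pick))
  sets <- list(planted_set = sort(planted))
  for (i in seq_len(config$n_gene_sets - 1L))
    sets[[paste0("background_set_", i)]] <- sort(sample(genes, config$set_size))

  causal <- genes[!is.na(truth$module) & truth$module == names(sim$latent)[[1L]]]
  hub <- causal[[1L]]
  others <- setdiff(causal, hub)
  spokes <- sample(others, min(config$hub_degree, length(others)))
  e_a <- rep(hub, length(spokes))
  e_b <- spokes
  pairs <- t(utils::combn(others, 2L))
  bg <- stats::runif(nrow(pairs)) < config$background_edge_prob
  e_a <- c(e_a, pairs[bg, 1L])
  e_b <- c(e_b, pairs[bg, 2L])
  edges <- data.frame(node_a = e_a, node_b = e_b,
                      score = stats::runif(length(e_a), 0.41, 0.99),
                      stringsAsFactors = FALSE)
  swap <- edges$node_a > edges$node_b
  tmp <- edges$node_a[swap]
  edges$node_a[swap] <- edges$node_b[swap]
  edges$node_b[swap] <- tmp
  edges <- edges[!duplicated(edges[, c("node_a", "node_b")]), , drop = FALSE]
  rownames(edges) <- NULL
  list(sets = sets, edges = edges, hub = hub)
}

#' Simulate a complete experiment
#'
#' Convenience wrapper running [simulate_counts()], [simulate_phenotype()] and
#' [simulate_sets_and_edges()].
#'
#' @param config A [sim_config()].
#' @return List with counts, design, truth, latent, condition_groups,
#'   phenotype, sets, edges, hub.
#' @export
simulate_ddi_experiment <- function(config) {
  sim <- simulate_counts(config)
  sim$phenotype <- simulate_phenotype(config, sim)
  se <- simulate_sets_and_edges(config, sim)
  sim$sets <- se$sets
  sim$edges <- se$edges
  sim$hub <- se$hub
  sim
}

#' Simulate an expression profile with planted co-expression modules
#'
#' Direct expression-level generator for testing module detection: module
#' genes follow `sqrt(rho) * f + sqrt(1 - rho) * noise` for a module-specific
#' latent factor f (so the expected within-module correlation is `rho`);
#' background genes are pure noise.
#'
#' @param n_genes Total genes.
#' @param module_sizes Integer vector of planted module sizes.
#' @param within_cor Expected within-module correlation rho (default 0.8).
#' @param n_groups Number of condition-group columns (default 6).
#' @param seed Integer seed.
#' @return List: `expr` (matrix), `truth` (named character vector gene ->
#'   module or "none").
#' @export
simulate_coexpression_profile <- function(n_genes, module_sizes,
                                          within_cor = 0.8, n_groups = 6,
                                          seed) {
  if (sum(module_sizes) > n_genes) stop("modules exceed n_genes")
  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(n_genes))
  expr <- matrix(stats::rnorm(n_genes * n_groups), n_genes, n_groups,
                 dimnames = list(genes, paste0("grp", seq_len(n_groups))))
  truth <- stats::setNames(rep("none", n_genes), genes)
  start <- 1L
  for (m in seq_along(module_sizes)) {
    idx <- start:(start + module_sizes[[m]] - 1L)
    f <- stats::rnorm(n_groups)
    expr[idx, ] <- sqrt(within_cor) * matrix(f, length(idx), n_groups,
                                             byrow = TRUE) +
      sqrt(1 - within_cor) * matrix(stats::rnorm(length(idx) * n_groups),
                                    length(idx), n_groups)
    truth[idx] <- paste0("M", m)
    start <- start + module_sizes[[m]]
  }
  list(expr = expr, truth = truth)
}
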