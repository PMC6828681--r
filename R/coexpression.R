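# WGCNA-style co-expression analysis at desk scale: soft-thresholded
# correlation adjacency, topological overlap, average-linkage clustering with
# a static tree cut, module eigengenes and module-trait correlation.

# WGCNA's standard module color sequence (by decreasing module size).
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue")

#' Condition-group expression profile
#'
#' log2(CPM + 1) per sample, averaged over replicates within each
#' (arm, treatment) condition group. With the standard two-arm, three-level
#' design this yields one column per condition group.
#'
#' @param counts Count matrix (typically low-count filtered).
#' @param design Design table covering the samples.
#' @param norm Optional [tmm_factors()] result; computed from `counts` when
#'   missing.
#' @return Numeric matrix genes x condition groups; columns named
#'   `arm.treatment`.
#' @export
expression_profile <- function(counts, design, norm = NULL) {
  validate_design(design, counts, require_complete = FALSE)
  if (is.null(norm)) norm <- tmm_factors(counts)
  eff <- effective_lib_size(norm, design$sample_id)
  logcpm <- log2(sweep(counts[, design$sample_id, drop = FALSE], 2L,
                       eff / 1e6, "/") + 1)
  grp <- paste(design$arm, design$treatment, sep = ".")
  groups <- unique(grp)
  prof <- vapply(groups, function(g)
    rowMeans(logcpm[, grp == g, drop = FALSE]), numeric(nrow(counts)))
  dimnames(prof) <- list(rownames(counts), groups)
  prof
}

#' Soft-thresholded co-expression adjacency
#'
#' Pairwise Pearson correlation of gene profiles raised to the power `beta`:
#' unsigned `|r|^beta` or signed `((1 + r)/2)^beta`. The diagonal is set to 0
#' so that row sums are connectivities.
#'
#' @param expr Genes x condition-groups expression matrix.
#' @param beta Soft-thresholding power (default 16).
#' @param signed Use the signed transformation (default FALSE, unsigned).
#' @return Symmetric adjacency matrix in `[0, 1]` with zero diagonal.
#' @export
adjacency_matrix <- function(expr, beta = 16, signed = FALSE) {
  if (beta < 1) stop("beta must be >= 1")
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant (zero-variance) gene profile(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5L), collapse = ", "))
  r <- stats::cor(t(expr))
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_u a_iu`; the diagonal is 1. Counts shared network
#' neighbours, giving a similarity more robust than raw adjacency.
#'
#' @param a Symmetric adjacency with zero diagonal, entries in `[0, 1]`.
#' @return Symmetric TOM in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be 0")
  k <- rowSums(a)
  shared <- a %*% a  # diag(a)=0, so entry ij sums over u != i,j automatically
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by static tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' with the tree cut at `cut_height` times the maximum merge height. Clusters
#' smaller than `min_size` become `"grey"` (unassigned); the rest are named by
#' decreasing size along the WGCNA color sequence (turquoise, blue, brown,
#' ...). A static cut replaces WGCNA's dynamic hybrid cut: it is deterministic
#' and adequate at the gene counts this pipeline targets.
#'
#' @param tom TOM from [tom_similarity()].
#' @param min_size Minimum module size (default 5).
#' @param cut_height Fraction of the maximum merge height at which to cut
#'   (default 0.99).
#' @return Named character vector: gene -> module color.
#' @export
detect_modules <- function(tom, min_size = 5, cut_height = 0.99) {
  genes <- rownames(tom)
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  h <- cut_height * max(tree$height)
  cl <- stats::cutree(tree, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  labels <- rep("grey", length(cl))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) {
      col <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[[i]]
             else paste0("module", i)
      labels[cl == as.integer(ord[[i]])] <- col
    }
  } else {
    warning("all genes unassigned (grey): no cluster reached min_size = ", min_size)
  }
  names(labels) <- genes
  labels
}

#' Module eigengene
#'
#' First principal component of the per-gene standardized (z-scored) module
#' submatrix, unit norm, with its sign oriented so that the correlation with
#' the module's mean standardized profile is non-negative. A single-gene
#' module returns that gene's standardized profile scaled to unit norm.
#'
#' @param expr Genes x condition-groups expression matrix.
#' @param module_genes Character vector of module member genes.
#' @return Numeric vector over condition groups, unit Euclidean norm.
#' @export
module_eigengene <- function(expr, module_genes) {
  if (!length(module_genes)) stop("empty module")
  z <- expr[module_genes, , drop = FALSE]
  z <- t(scale(t(z)))
  if (nrow(z) == 1L) {
    e <- as.numeric(z)
    e <- e / sqrt(sum(e^2))
    names(e) <- colnames(expr)
    return(e)
  }
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1L]
  if (stats::cor(e, colMeans(z)) < 0) e <- -e
  e <- e / sqrt(sum(e^2))
  names(e) <- colnames(expr)
  e
}

#' Module-trait Pearson correlation
#'
#' Correlates each module eigengene with each phenotype trait across condition
#' groups; two-sided p-values from the t distribution with n - 2 degrees of
#' freedom. With few condition groups these p-values are descriptive (used
#' for ranking modules, not inference) and are not adjusted.
#'
#' @param eigengenes Named list (module -> eigengene vector) or matrix with
#'   modules as columns; condition order must match `traits` rows.
#' @param traits data.frame or matrix of numeric traits (condition groups x
#'   traits).
#' @return data.frame: module, trait, r, p_value.
#' @export
module_trait <- function(eigengenes, traits) {
  if (is.list(eigengenes)) eigengenes <- do.call(cbind, eigengenes)
  traits <- as.matrix(traits)
  n <- nrow(traits)
  if (n < 3L) stop("need at least 3 condition groups for correlation")
  if (nrow(eigengenes) != n)
    stop("eigengene length does not match number of condition groups")
  out <- expand.grid(module = colnames(eigengenes), trait = colnames(traits),
                     stringsAsFactors = FALSE)
  rp <- mapply(function(m, tr) {
    r <- stats::cor(eigengenes[, m], traits[, tr])
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r, 2 * stats::pt(-abs(tstat), df = n - 2))
  }, out$module, out$trait)
  out$r <- rp[1L, ]
  out$p_value <- rp[2L, ]
  out
}

#' Select the module most correlated with all traits
#'
#' The module maximizing the minimum over traits of `|r|` — the strongest
#' association "with both traits". Ties break toward the larger module, then
#' the lexicographically smaller label.
#'
#' @param mt Result of [module_trait()].
#' @param module_sizes Named integer vector of module sizes (for tie-breaks);
#'   optional.
#' @return Module label (character scalar).
#' @export
select_top_module <- function(mt, module_sizes = NULL) {
  if (!nrow(mt)) stop("no module-trait results")
  score <- tapply(abs(mt$r), mt$module, min)
  mods <- names(score)
  sizes <- if (is.null(module_sizes)) rep(0L, length(mods))
           else as.integer(module_sizes[mods])
  sizes[is.na(sizes)] <- 0L
  ord <- order(-score, -sizes, mods)
  mods[ord[[1L]]]
}

#' Run the full co-expression stage
#'
#' Adjacency, TOM, module detection, eigengenes and module-trait correlation
#' in one call, on a precomputed expression profile restricted to the genes of
#' interest (typically one interaction group).
#'
#' @param expr Genes x condition-groups matrix (see [expression_profile()]).
#' @param traits Numeric trait matrix/data.frame with rows aligned to the
#'   columns of `expr`.
#' @param beta Soft-thresholding power (default 16).
#' @param min_size Minimum module size (default 5).
#' @param cut_height Static cut height fraction (default 0.99).
#' @param signed Signed network flag (default FALSE).
#' @return List: `modules` (gene -> color), `eigengenes` (matrix), `trait_cor`
#'   (data.frame), `top_module` (label or NA when no module was found).
#' @export
run_coexpression <- function(expr, traits, beta = 16, min_size = 5,
                             cut_height = 0.99, signed = FALSE) {
  a <- adjacency_matrix(expr, beta = beta, signed = signed)
  tom <- tom_similarity(a)
  modules <- detect_modules(tom, min_size = min_size, cut_height = cut_height)
  real <- setdiff(unique(modules), "grey")
  if (!length(real))
    return(list(modules = modules, eigengenes = NULL, trait_cor = NULL,
                top_module = NA_character_))
  eig <- vapply(real, function(m)
    module_eigengene(expr, names(modules)[modules == m]),
    numeric(ncol(expr)))
  mt <- module_trait(eig, traits)
  sizes <- table(modules)[real]
  list(modules = modules, eigengenes = eig, trait_cor = mt,
       top_module = select_top_module(mt, sizes))
}
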