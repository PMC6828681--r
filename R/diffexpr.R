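# Negative-binomial differential expression, approximating edgeR's classic
# pipeline: strict low-count filter, TMM normalization, method-of-moments
# dispersion with shrinkage toward a common value, and an exact conditional
# test on depth-equalized group sums.

#' Filter genes by a strict per-sample count threshold
#'
#' Retains exactly the genes whose count exceeds `min_count` in every sample
#' (strictly greater: a gene with a count equal to `min_count` in any sample is
#' dropped).
#'
#' @param counts Validated count matrix.
#' @param min_count Integer threshold; genes must have count > min_count in all
#'   samples (default 2).
#' @return The filtered count matrix (samples unchanged).
#' @export
filter_low_counts <- function(counts, min_count = 2) {
  validate_counts(counts)
  keep <- rowSums(counts > min_count) == ncol(counts)
  if (!any(keep))
    stop("no genes pass the low-count filter (count > ", min_count,
         " in all samples); review the threshold")
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization. The reference sample
#' is the one whose upper-quartile of library-size-scaled counts is closest to
#' the mean of that statistic. For each sample, gene-wise log2 ratios (M) and
#' average log2 abundances (A) versus the reference are computed over genes
#' non-zero in both samples, doubly trimmed (by default 30% of M values and 5%
#' of A values at each end), and combined in a precision-weighted mean. Factors
#' are rescaled so their geometric mean is 1.
#'
#' @param counts Count matrix (typically already low-count filtered).
#' @param trim_logratio Fraction of M values trimmed at each tail (default 0.3).
#' @param trim_abs Fraction of A values trimmed at each tail (default 0.05).
#' @return A list with `factors` (named positive numeric, geometric mean 1) and
#'   `lib_size` (named total counts per sample).
#' @export
tmm_factors <- function(counts, trim_logratio = 0.3, trim_abs = 0.05) {
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  uq <- apply(counts, 2L, function(y) stats::quantile(y / sum(y), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  yr <- counts[, ref]
  nr <- lib[ref]
  f <- vapply(seq_len(ncol(counts)), function(i) {
    if (i == ref) return(1)
    yi <- counts[, i]
    ni <- lib[i]
    ok <- yi > 0 & yr > 0
    if (!any(ok)) return(1)
    m <- log2((yi[ok] / ni) / (yr[ok] / nr))
    a <- 0.5 * log2((yi[ok] / ni) * (yr[ok] / nr))
    w <- 1 / ((ni - yi[ok]) / (ni * yi[ok]) + (nr - yr[ok]) / (nr * yr[ok]))
    n <- length(m)
    lo_m <- floor(n * trim_logratio) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_abs) + 1
    hi_a <- n + 1 - lo_a
    rm_ <- rank(m, ties.method = "first")
    ra_ <- rank(a, ties.method = "first")
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(keep)) return(1)
    2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  list(factors = f, lib_size = lib)
}

effective_lib_size <- function(norm, samples) {
  norm$lib_size[samples] * norm$factors[samples]
}

#' Method-of-moments NB dispersion with shrinkage
#'
#' Counts are rescaled to a common effective library size (geometric mean of
#' effective sizes). For each gene the moment estimator
#' `(s^2 - m) / m^2` is computed, where `s^2` pools within-group residual
#' variance across the (arm, treatment) groups in `design` and `m` is the mean
#' normalized count. The common dispersion is the across-gene mean of the raw
#' (untruncated) estimates, clamped at zero; per-gene values are shrunk toward
#' it: `phi_g = max(0, w * common + (1 - w) * raw_g)`.
#'
#' @param counts Filtered count matrix.
#' @param design Design table; only its samples are used, each
#'   (arm, treatment) group needing >= 2 replicates.
#' @param norm Output of [tmm_factors()].
#' @param shrink_weight Weight on the common dispersion in `[0, 1]`
#'   (default 0.7).
#' @return List with `common` (scalar >= 0), `per_gene` (named numeric >= 0,
#'   shrunk), `raw` (named numeric >= 0, unshrunk truncated moment estimates)
#'   and `shrink_weight`.
#' @export
estimate_dispersion <- function(counts, design, norm, shrink_weight = 0.7) {
  if (shrink_weight < 0 || shrink_weight > 1)
    stop("shrink_weight must be in [0, 1]")
  samples <- design$sample_id
  absent <- setdiff(samples, colnames(counts))
  if (length(absent))
    stop("design sample(s) absent from counts: ", paste(absent, collapse = ", "))
  grp <- paste(design$arm, design$treatment, sep = ".")
  tab <- table(grp)
  if (any(tab < 2L))
    stop("group(s) with a single replicate: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  eff <- effective_lib_size(norm, samples)
  scale_to <- exp(mean(log(eff)))
  y <- sweep(counts[, samples, drop = FALSE], 2L, scale_to / eff, "*")
  n <- length(samples)
  k <- length(tab)
  m <- rowMeans(y)
  ss <- 0
  for (g in names(tab)) {
    yg <- y[, grp == g, drop = FALSE]
    ss <- ss + rowSums((yg - rowMeans(yg))^2)
  }
  s2 <- ss / (n - k)
  raw_unc <- ifelse(m > 0, (s2 - m) / m^2, 0)
  common <- max(0, mean(raw_unc))
  per_gene <- pmax(0, shrink_weight * common + (1 - shrink_weight) * raw_unc)
  raw <- pmax(0, raw_unc)
  names(per_gene) <- names(raw) <- rownames(counts)
  list(common = common, per_gene = per_gene, raw = raw,
       shrink_weight = shrink_weight)
}

# Conditional two-sided p-value for an observed split (sa, sb) of the total
# n = sa + sb between groups with na and nb replicates and NB dispersion phi.
# Conditioning on the total, the split follows a beta-binomial-type law with
# sizes na/phi and nb/phi; phi = 0 reduces to Binomial(n, na/(na+nb)).
# Two-sided by probability-mass ordering: sum of probabilities of outcomes no
# more likely than the observed one (tie mass counted once).
nb_conditional_pvalue <- function(sa, sb, na, nb, phi) {
  n <- sa + sb
  if (n == 0) return(1)
  x <- 0:n
  if (phi < 1e-10) {
    logp <- stats::dbinom(x, n, na / (na + nb), log = TRUE)
  } else {
    ra <- na / phi
    rb <- nb / phi
    logw <- lchoose(x + ra - 1, x) + lchoose(n - x + rb - 1, n - x)
    mx <- max(logw)
    logp <- logw - (mx + log(sum(exp(logw - mx))))
  }
  obs <- logp[sa + 1L]
  min(1, sum(exp(logp[logp <= obs + 1e-10])))
}

#' Exact NB test between two treatment groups of one arm
#'
#' Counts are rescaled to the geometric-mean effective library size
#' (depth-equalized pseudo-counts), summed within each group and rounded; the
#' two-sided p-value conditions on the total per gene (see Details). The log2
#' fold change is `log2((sum_b + 0.5) / (sum_a + 0.5))` on the equalized sums,
#' with `group_a` as baseline.
#'
#' @param counts Filtered count matrix.
#' @param design Design table.
#' @param norm Output of [tmm_factors()].
#' @param disp Output of [estimate_dispersion()]; must cover all tested genes.
#' @param arm Arm label selecting the samples.
#' @param group_a Baseline treatment level.
#' @param group_b Target treatment level.
#' @return data.frame: gene_id, logFC, p_value, mean_cpm (no FDR; see
#'   [bh_adjust()]).
#' @export
exact_test_nb <- function(counts, design, norm, disp, arm, group_a, group_b) {
  if (identical(group_a, group_b))
    stop("cannot contrast a treatment group against itself ('", group_a, "')")
  sel_a <- design$sample_id[design$arm == arm & design$treatment == group_a]
  sel_b <- design$sample_id[design$arm == arm & design$treatment == group_b]
  if (length(sel_a) < 2L || length(sel_b) < 2L)
    stop("both groups need >= 2 replicates in arm '", arm, "'")
  genes <- rownames(counts)
  missing_phi <- setdiff(genes, names(disp$per_gene))
  if (length(missing_phi))
    stop("dispersion missing for gene(s): ",
         paste(utils::head(missing_phi, 5L), collapse = ", "))
  samples <- c(sel_a, sel_b)
  eff <- effective_lib_size(norm, samples)
  scale_to <- exp(mean(log(eff)))
  y <- sweep(counts[, samples, drop = FALSE], 2L, scale_to / eff, "*")
  sa <- round(rowSums(y[, sel_a, drop = FALSE]))
  sb <- round(rowSums(y[, sel_b, drop = FALSE]))
  phi <- disp$per_gene[genes]
  na <- length(sel_a)
  nb <- length(sel_b)
  p <- vapply(seq_along(genes), function(g) {
    nb_conditional_pvalue(sa[[g]], sb[[g]], na, nb, phi[[g]])
  }, numeric(1L))
  cpm <- sweep(counts[, samples, drop = FALSE], 2L, eff / 1e6, "/")
  data.frame(gene_id = genes,
             logFC = log2((sb + 0.5) / (sa + 0.5)),
             p_value = p,
             mean_cpm = rowMeans(cpm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values, capped at 1 and monotone in the sorted order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`; NA/NaN is an error.
#' @return Vector of q-values of the same length.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values))
    stop("NA/NaN p-value passed to bh_adjust")
  if (any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Run one differential-expression contrast
#'
#' Full pipeline for one arm and one (baseline, target) treatment pair: global
#' low-count filter, TMM factors over all samples, dispersion from the arm's
#' replicate groups, exact NB test, BH FDR. Significance is `fdr < threshold`
#' with no fold-change cut-off.
#'
#' @param counts Raw count matrix (filtering is applied here).
#' @param design Full design table.
#' @param arm Arm to test.
#' @param baseline,target Treatment levels contrasted (target vs baseline).
#' @param fdr_threshold Significance threshold on BH FDR (default 0.05).
#' @param min_count Low-count filter threshold (default 2).
#' @param shrink_weight Dispersion shrinkage weight (default 0.7).
#' @return List with `table` (data.frame gene_id, logFC, p_value, fdr,
#'   mean_cpm) and `significant` (character vector of gene ids).
#' @export
run_contrast <- function(counts, design, arm, baseline, target,
                         fdr_threshold = 0.05, min_count = 2,
                         shrink_weight = 0.7) {
  if (identical(baseline, target))
    stop("baseline and target treatments are identical ('", baseline, "')")
  validate_design(design, counts, require_complete = FALSE)
  if (!arm %in% design$arm) stop("unknown arm '", arm, "'")
  filt <- filter_low_counts(counts, min_count)
  norm <- tmm_factors(filt)
  arm_design <- design[design$arm == arm, , drop = FALSE]
  disp <- estimate_dispersion(filt, arm_design, norm, shrink_weight)
  de <- exact_test_nb(filt, design, norm, disp, arm, baseline, target)
  de$fdr <- bh_adjust(de$p_value)
  de <- de[, c("gene_id", "logFC", "p_value", "fdr", "mean_cpm")]
  list(table = de, significant = de$gene_id[de$fdr < fdr_threshold])
}
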