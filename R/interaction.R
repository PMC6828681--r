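# Directional interaction classification of shared DE genes. A gene whose
# combined-vs-single log fold change has the same sign as its
# single-vs-untreated log fold change is a positive-interaction (synergistic)
# gene: the single-treatment expression level is intermediate between
# untreated and combined. Opposite signs mean negative interaction
# (antagonism): the single treatment is the extreme.

#' Intersect significant gene sets across the four contrasts
#'
#' @param sig_sets List of four character vectors (significant genes for
#'   single-vs-untreated and combined-vs-single in each arm).
#' @return Lexicographically sorted character vector of genes present in all
#'   four sets; an empty intersection warns and returns `character(0)`.
#' @export
shared_de_genes <- function(sig_sets) {
  if (length(sig_sets) != 4L)
    stop("expected exactly four significant gene sets")
  if (any(vapply(sig_sets, length, integer(1L)) == 0L))
    stop("all four significant gene sets must be non-empty")
  shared <- Reduce(intersect, sig_sets)
  if (!length(shared)) {
    warning("no genes shared across the four DE sets")
    return(character(0))
  }
  sort(shared)
}

#' Classify interaction direction from the two log fold changes
#'
#' Vectorized sign rule: positive when `sign(logfc_single) ==
#' sign(logfc_combined)`, negative otherwise. A log fold change of exactly
#' zero is indeterminate and raises an error (significant genes never have an
#' exactly-zero logFC in practice, but callers must exclude such genes rather
#' than silently misclassify them).
#'
#' @param logfc_single log2 FC of single treatment vs untreated.
#' @param logfc_combined log2 FC of combined treatment vs single.
#' @return Character vector in `{"positive", "negative"}`.
#' @export
classify_interaction <- function(logfc_single, logfc_combined) {
  if (length(logfc_single) != length(logfc_combined))
    stop("logFC vectors must have equal length")
  if (any(logfc_single == 0 | logfc_combined == 0))
    stop("indeterminate interaction: log fold change of exactly 0")
  ifelse(sign(logfc_single) == sign(logfc_combined), "positive", "negative")
}

#' Assign the four-group label from per-arm interaction classes
#'
#' Group A = positive in arm 1, negative in arm 2; B = negative/positive;
#' C = negative in both; D = positive in both. Arm 1 is the positive-reference
#' arm (doxorubicin in the motivating study).
#'
#' @param iclass_arm1,iclass_arm2 Character vectors in
#'   `{"positive", "negative"}`.
#' @return Character vector of group labels in `{"A", "B", "C", "D"}`.
#' @export
assign_group <- function(iclass_arm1, iclass_arm2) {
  ok <- c("positive", "negative")
  if (!all(iclass_arm1 %in% ok) || !all(iclass_arm2 %in% ok))
    stop("interaction classes must be 'positive' or 'negative'")
  pos1 <- iclass_arm1 == "positive"
  pos2 <- iclass_arm2 == "positive"
  out <- character(length(pos1))
  out[pos1 & !pos2] <- "A"
  out[!pos1 & pos2] <- "B"
  out[!pos1 & !pos2] <- "C"
  out[pos1 & pos2] <- "D"
  out
}

#' Percentage of positive-interaction calls
#'
#' @param iclass Character vector of interaction classes for one arm.
#' @return Percentage of `"positive"` calls, rounded to one decimal.
#' @export
positive_fraction <- function(iclass) {
  if (!length(iclass)) stop("empty interaction call set")
  round(100 * mean(iclass == "positive"), 1)
}

#' Interaction class from the three condition means
#'
#' Equivalent formulation of the sign rule: a gene interacts positively when
#' the single-treatment mean lies strictly between the untreated and combined
#' means, negatively when the single treatment is the extreme. Ties are
#' indeterminate.
#'
#' @param expr_untreated,expr_single,expr_combined Per-gene replicate means.
#' @return `"positive"` or `"negative"` per gene.
#' @export
equivalence_check <- function(expr_untreated, expr_single, expr_combined) {
  if (any(expr_untreated == expr_single | expr_single == expr_combined))
    stop("indeterminate: tied condition means")
  intermediate <-
    (expr_single > expr_untreated & expr_single < expr_combined) |
    (expr_single < expr_untreated & expr_single > expr_combined)
  ifelse(intermediate, "positive", "negative")
}

#' Build the per-gene interaction table for shared DE genes
#'
#' Joins the single-vs-untreated and combined-vs-single DE tables of both arms
#' on the shared genes, classifies the interaction per arm from the logFC
#' signs and assigns the four-group label. Genes with an exactly-zero logFC in
#' any contrast are excluded with a message (count reported).
#'
#' @param shared Character vector of shared DE genes (see [shared_de_genes()]).
#' @param de_single_arm1,de_combined_arm1 DE tables (data.frames with gene_id,
#'   logFC) for arm 1.
#' @param de_single_arm2,de_combined_arm2 Same for arm 2.
#' @param arm_names Character(2): labels of arm 1 (positive reference) and
#'   arm 2.
#' @return data.frame: gene_id, dir_single_arm1, dir_combined_arm1,
#'   iclass_arm1, dir_single_arm2, dir_combined_arm2, iclass_arm2, group.
#' @export
interaction_table <- function(shared, de_single_arm1, de_combined_arm1,
                              de_single_arm2, de_combined_arm2,
                              arm_names = c("arm1", "arm2")) {
  get_lfc <- function(de, genes) {
    idx <- match(genes, de$gene_id)
    if (anyNA(idx))
      stop("shared gene(s) missing from a DE table: ",
           paste(utils::head(genes[is.na(idx)], 5L), collapse = ", "))
    de$logFC[idx]
  }
  l1s <- get_lfc(de_single_arm1, shared)
  l1c <- get_lfc(de_combined_arm1, shared)
  l2s <- get_lfc(de_single_arm2, shared)
  l2c <- get_lfc(de_combined_arm2, shared)
  zero <- l1s == 0 | l1c == 0 | l2s == 0 | l2c == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with an exactly-zero logFC excluded as indeterminate")
    shared <- shared[!zero]
    l1s <- l1s[!zero]; l1c <- l1c[!zero]; l2s <- l2s[!zero]; l2c <- l2c[!zero]
  }
  ic1 <- classify_interaction(l1s, l1c)
  ic2 <- classify_interaction(l2s, l2c)
  dir_of <- function(x) ifelse(x > 0, "up", "down")
  out <- data.frame(gene_id = shared,
                    dir_single_arm1 = dir_of(l1s),
                    dir_combined_arm1 = dir_of(l1c),
                    iclass_arm1 = ic1,
                    dir_single_arm2 = dir_of(l2s),
                    dir_combined_arm2 = dir_of(l2c),
                    iclass_arm2 = ic2,
                    group = assign_group(ic1, ic2),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "arm_names") <- arm_names
  out
}
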