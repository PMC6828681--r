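# Right-sided hypergeometric over-representation analysis with BH correction,
# plus pathway-level interaction-direction statistics against the one-third
# null (with exchangeable condition means, a third of genes land in the
# positive class by chance, so only pathways strictly above that fraction are
# called positive-interaction pathways).

#' Right-sided hypergeometric over-representation analysis
#'
#' For each gene set, tests whether its overlap with `gene_list` is larger
#' than expected when drawing `length(gene_list)` genes from `universe`
#' without replacement: `p = P(X >= overlap)` under
#' Hypergeometric(universe, set, list). Sets are intersected with the
#' universe before testing; BH adjustment is applied across the tested sets.
#'
#' @param gene_list Character vector of genes of interest (must be a subset of
#'   the universe).
#' @param universe Character vector: the testable population (typically all
#'   genes surviving the low-count filter).
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @return data.frame: set_name, overlap, set_size (within universe),
#'   list_size, universe_size, p_value, fdr; sets with an empty
#'   universe-intersection are skipped.
#' @export
hypergeom_ora <- function(gene_list, universe, gene_sets) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  offenders <- setdiff(gene_list, universe)
  if (length(offenders))
    stop("gene(s) in list absent from universe: ",
         paste(utils::head(offenders, 5L), collapse = ", "))
  n_u <- length(universe)
  n_l <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    if (!length(members)) return(NULL)
    k <- length(intersect(members, gene_list))
    p <- stats::phyper(k - 1, length(members), n_u - length(members), n_l,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(members),
               list_size = n_l, universe_size = n_u, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(set_name = character(0), overlap = integer(0),
                      set_size = integer(0), list_size = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      fdr = numeric(0)))
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Pathway-level interaction directionality
#'
#' For one gene set, computes the percentage of member genes called positive
#' in each arm and labels the pathway `positive-interaction` in an arm when
#' that percentage is strictly above `cutoff` (default one third, the
#' expectation under exchangeable condition means; a pathway at exactly the
#' null fraction is not called positive).
#'
#' @param set_name Name of the gene set.
#' @param members Character vector of member genes.
#' @param calls Interaction table from [interaction_table()].
#' @param cutoff Percentage cutoff (default `100/3`).
#' @return One-row data.frame: set_name, n_called, positive_fraction_arm1/2,
#'   direction_arm1/2; or `NULL` (with a message) when no member gene was
#'   called.
#' @export
pathway_direction <- function(set_name, members, calls, cutoff = 100 / 3) {
  hit <- calls[calls$gene_id %in% members, , drop = FALSE]
  if (!nrow(hit)) {
    message("no called genes in set '", set_name, "'; skipped")
    return(NULL)
  }
  frac1 <- 100 * mean(hit$iclass_arm1 == "positive")
  frac2 <- 100 * mean(hit$iclass_arm2 == "positive")
  lab <- function(f) {
    if (f / 100 > cutoff / 100 + 1e-9) "positive-interaction" else "negative-interaction"
  }
  data.frame(set_name = set_name, n_called = nrow(hit),
             positive_fraction_arm1 = frac1, positive_fraction_arm2 = frac2,
             direction_arm1 = lab(frac1), direction_arm2 = lab(frac2),
             stringsAsFactors = FALSE)
}

#' Up/down split of a pathway under single-drug treatment
#'
#' Among a set's member genes that are significantly DE in the
#' single-vs-untreated contrast, the percentage up- and down-regulated by
#' logFC sign.
#'
#' @param set_name Name of the gene set.
#' @param members Character vector of member genes.
#' @param de_table DE table (gene_id, logFC) for single vs untreated.
#' @param significant Character vector of significant genes in that contrast.
#' @return One-row data.frame: set_name, n_members_de, up_fraction,
#'   down_fraction (percent); `NULL` when no member is significant.
#' @export
single_drug_direction <- function(set_name, members, de_table, significant) {
  sel <- intersect(intersect(members, significant), de_table$gene_id)
  if (!length(sel)) return(NULL)
  lfc <- de_table$logFC[match(sel, de_table$gene_id)]
  up <- 100 * mean(lfc > 0)
  data.frame(set_name = set_name, n_members_de = length(sel),
             up_fraction = up, down_fraction = 100 - up,
             stringsAsFactors = FALSE)
}

#' Directionality statistics for a whole collection
#'
#' Applies [pathway_direction()] (and optionally [single_drug_direction()]) to
#' every set in a collection, by default restricted to sets significantly
#' enriched in the shared-gene list.
#'
#' @param gene_sets Named list of gene sets.
#' @param calls Interaction table.
#' @param ora Optional result of [hypergeom_ora()]; when given with
#'   `enriched_only = TRUE`, only sets with `fdr < fdr_threshold` are scored.
#' @param enriched_only Score only enriched sets (default TRUE).
#' @param fdr_threshold Enrichment FDR threshold (default 0.05).
#' @param cutoff Positive-direction percentage cutoff (default `100/3`).
#' @return data.frame of per-set direction rows (possibly zero rows).
#' @export
collection_direction <- function(gene_sets, calls, ora = NULL,
                                 enriched_only = TRUE, fdr_threshold = 0.05,
                                 cutoff = 100 / 3) {
  names_to_score <- names(gene_sets)
  if (enriched_only && !is.null(ora))
    names_to_score <- intersect(names_to_score,
                                ora$set_name[ora$fdr < fdr_threshold])
  rows <- lapply(names_to_score, function(nm)
    pathway_direction(nm, gene_sets[[nm]], calls, cutoff))
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(set_name = character(0), n_called = integer(0),
                      positive_fraction_arm1 = numeric(0),
                      positive_fraction_arm2 = numeric(0),
                      direction_arm1 = character(0),
                      direction_arm2 = character(0)))
  do.call(rbind, rows)
}
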