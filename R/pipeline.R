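# End-to-end pipeline runner: differential expression for the four contrasts,
# shared-gene interaction classification, enrichment and pathway
# directionality, co-expression on one interaction group, hub ranking.
# Writes every intermediate as TSV plus one JSON run summary; the whole run is
# deterministic given its inputs.

#' Pipeline configuration
#'
#' Defaults are the motivating study's stated parameters: FDR < 0.05, count
#' filter > 2 in all samples, one-third direction cutoff, soft-threshold
#' power 16, minimum module size 5, minimum interaction score 0.4.
#'
#' @param counts,design Paths to the count and design TSVs (or in-memory
#'   objects).
#' @param gmt,edges,phenotype Optional paths (or objects) for the enrichment,
#'   hub and co-expression stages; stages lacking inputs are skipped.
#' @param arms Character(2) ordering of arms, first = positive reference;
#'   defaults to design order.
#' @param fdr_threshold,min_count,direction_cutoff,beta,min_module_size,min_edge_score
#'   Stage parameters (see module functions).
#' @param coexpr_group Interaction group analysed for co-expression
#'   (default "A").
#' @param out_dir Output directory; created if needed. `NULL` disables
#'   writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts, design, gmt = NULL, edges = NULL,
                       phenotype = NULL, arms = NULL, fdr_threshold = 0.05,
                       min_count = 2, direction_cutoff = 100 / 3, beta = 16,
                       min_module_size = 5, min_edge_score = 0.4,
                       coexpr_group = "A", out_dir = NULL) {
  cfg <- list(counts = counts, design = design, gmt = gmt, edges = edges,
              phenotype = phenotype, arms = arms,
              fdr_threshold = fdr_threshold, min_count = min_count,
              direction_cutoff = direction_cutoff, beta = beta,
              min_module_size = min_module_size,
              min_edge_score = min_edge_score, coexpr_group = coexpr_group,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

load_or_pass <- function(x, reader, ...) {
  if (is.null(x) || !is.character(x)) return(x)
  if (!file.exists(x)) stop("input file not found: ", x)
  reader(x, ...)
}

write_stage <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full drug-drug interaction pipeline
#'
#' Executes, in order: the four DE contrasts (single vs untreated and combined
#' vs single in each arm), shared-gene intersection, interaction
#' classification and four-group assignment, over-representation and pathway
#' directionality (when gene sets are supplied), co-expression with
#' module-trait correlation (when a phenotype is supplied), and hub ranking
#' (when an edge list is supplied). Any stage error aborts with the stage
#' name; outputs written before the failure are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all stage results and `summary` (the JSON
#'   run summary as a list).
#' @export
run_ddi_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  counts <- stage("input", load_or_pass(config$counts, read_counts))
  design <- stage("input", load_or_pass(config$design, read_design))
  stage("input", validate_design(design, counts))
  arms <- config$arms
  if (is.null(arms)) arms <- unique(design$arm)
  if (length(arms) != 2L) stop("pipeline requires exactly two arms")

  # --- differential expression: four contrasts -------------------------------
  de <- stage("de", {
    res <- list()
    for (a in arms) {
      res[[paste0(a, ".single_vs_untreated")]] <-
        run_contrast(counts, design, a, "untreated", "single",
                     config$fdr_threshold, config$min_count)
      res[[paste0(a, ".combined_vs_single")]] <-
        run_contrast(counts, design, a, "single", "combined",
                     config$fdr_threshold, config$min_count)
    }
    res
  })
  for (nm in names(de))
    write_stage(de[[nm]]$table, out_dir, paste0("de_", nm, ".tsv"))
  filtered <- filter_low_counts(counts, config$min_count)

  # --- interaction classification -------------------------------------------
  inter <- stage("interact", {
    shared <- shared_de_genes(lapply(de, `[[`, "significant"))
    calls <- interaction_table(
      shared,
      de[[paste0(arms[[1L]], ".single_vs_untreated")]]$table,
      de[[paste0(arms[[1L]], ".combined_vs_single")]]$table,
      de[[paste0(arms[[2L]], ".single_vs_untreated")]]$table,
      de[[paste0(arms[[2L]], ".combined_vs_single")]]$table,
      arm_names = arms)
    calls
  })
  write_stage(inter, out_dir, "interaction_calls.tsv")
  group_sizes <- as.list(table(factor(inter$group, levels = c("A", "B", "C", "D"))))
  pos_frac <- list()
  if (nrow(inter)) {
    pos_frac[[arms[[1L]]]] <- positive_fraction(inter$iclass_arm1)
    pos_frac[[arms[[2L]]]] <- positive_fraction(inter$iclass_arm2)
  }

  # --- enrichment ------------------------------------------------------------
  enrich <- NULL
  direction <- NULL
  sets <- load_or_pass(config$gmt, read_gmt)
  if (!is.null(sets) && nrow(inter)) {
    enrich <- stage("enrich",
      hypergeom_ora(inter$gene_id, rownames(filtered), sets))
    direction <- stage("enrich",
      collection_direction(sets, inter, ora = enrich,
                           fdr_threshold = config$fdr_threshold,
                           cutoff = config$direction_cutoff))
    write_stage(enrich, out_dir, "enrichment.tsv")
    write_stage(direction, out_dir, "pathway_direction.tsv")
  }

  # --- co-expression ---------------------------------------------------------
  coexpr <- NULL
  if (!is.null(config$phenotype)) {
    coexpr <- stage("coexpr", {
      phenotype <- load_or_pass(config$phenotype, read_phenotype)
      genes <- inter$gene_id[inter$group == config$coexpr_group]
      if (length(genes) < 2 * config$min_module_size)
        stop("too few genes in group ", config$coexpr_group,
             " for module detection (", length(genes), ")")
      expr <- expression_profile(filtered, design)[genes, , drop = FALSE]
      keyp <- paste(phenotype$arm, phenotype$treatment, sep = ".")
      idx <- match(colnames(expr), keyp)
      if (anyNA(idx))
        stop("phenotype missing condition group(s): ",
             paste(colnames(expr)[is.na(idx)], collapse = ", "))
      traits <- phenotype[idx, setdiff(colnames(phenotype), c("arm", "treatment")),
                          drop = FALSE]
      res <- run_coexpression(expr, traits, beta = config$beta,
                              min_size = config$min_module_size)
      res$expr <- expr
      res
    })
    write_stage(data.frame(gene_id = names(coexpr$modules),
                           module = unname(coexpr$modules)),
                out_dir, "modules.tsv")
    if (!is.null(coexpr$trait_cor))
      write_stage(coexpr$trait_cor, out_dir, "module_trait.tsv")
  }

  # --- hub ranking -----------------------------------------------------------
  hubs <- NULL
  if (!is.null(config$edges) && !is.null(coexpr) &&
      !is.na(coexpr$top_module)) {
    hubs <- stage("hubs", {
      edges <- load_or_pass(config$edges, read_edges,
                            min_score = config$min_edge_score)
      mod_genes <- names(coexpr$modules)[coexpr$modules == coexpr$top_module]
      tc <- if (!is.null(sets)) count_terms(sets, mod_genes) else integer(0)
      rank_hubs(induced_subgraph(edges, mod_genes), tc)
    })
    write_stage(hubs, out_dir, "hub_ranking.tsv")
  }

  summary <- list(
    parameters = config[c("fdr_threshold", "min_count", "direction_cutoff",
                          "beta", "min_module_size", "min_edge_score",
                          "coexpr_group")],
    arms = as.list(stats::setNames(arms, c("positive_reference", "arm2"))),
    n_genes_input = nrow(counts),
    n_genes_filtered = nrow(filtered),
    n_significant = lapply(de, function(x) length(x$significant)),
    n_shared = nrow(inter),
    group_sizes = group_sizes,
    positive_fraction = pos_frac,
    n_modules = if (!is.null(coexpr))
      length(setdiff(unique(coexpr$modules), "grey")) else NULL,
    top_module = if (!is.null(coexpr)) coexpr$top_module else NULL,
    top_hub = if (!is.null(hubs) && nrow(hubs)) hubs$gene_id[[1L]] else NULL)
  if (!is.null(out_dir))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  invisible(list(de = de, interaction = inter, enrichment = enrich,
                 direction = direction, coexpression = coexpr, hubs = hubs,
                 summary = summary))
}

#' Write all simulated inputs of an experiment to a directory
#'
#' @param sim Output of [simulate_ddi_experiment()].
#' @param dir Target directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulated_inputs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_design(sim$design, file.path(dir, "design.tsv"))
  write_phenotype(sim$phenotype, file.path(dir, "phenotype.tsv"))
  write_gmt(sim$sets, file.path(dir, "gene_sets.gmt"))
  write_edges(sim$edges, file.path(dir, "edges.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
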