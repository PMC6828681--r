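# Readers/writers for the plain-text formats the pipeline touches: count TSV,
# design TSV, GMT gene sets, STRING-style edge lists and phenotype tables.
# All TSVs are tab-separated UTF-8; lines starting with '#' are comments.

TREATMENT_LEVELS <- c("untreated", "single", "combined")

read_tsv_raw <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read a gene-by-sample count matrix
#'
#' Reads a tab-separated count file (first column gene identifiers, header row
#' sample identifiers) and validates it: identifiers must be unique, every cell
#' a non-negative integer, at least one gene and two samples.
#'
#' @param path Path to a tab-separated count file. Lines starting with `#` are
#'   ignored.
#' @return An integer matrix with gene rownames and sample colnames, in file
#'   order.
#' @export
read_counts <- function(path) {
  df <- read_tsv_raw(path)
  if (ncol(df) < 3L)
    stop("count file must have a gene-id column and at least 2 samples")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene id(s) in count file: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop("duplicate sample id(s) in count file: ", paste(dup_s, collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-integer or missing count '%s' at row %d (gene %s), column %d (sample %s)",
      raw[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], gene_ids[bad[1L, 1L]],
      bad[1L, 2L], sample_ids[bad[1L, 2L]]))
  }
  counts <- matrix(as.integer(num), nrow = nrow(num),
                   dimnames = list(gene_ids, sample_ids))
  validate_counts(counts)
  counts
}

#' Validate a count matrix
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must be a matrix with gene rownames and sample colnames")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stop("count matrix needs at least 1 gene and 2 samples")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers with no missing values")
  invisible(counts)
}

#' Write a count matrix as TSV
#' @param counts Integer count matrix with dimnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' The design maps each sample to a treatment arm (cell line + primary drug), a
#' treatment level (`untreated`, `single` or `combined`) and a replicate
#' number. When `counts` is supplied the design is validated against it: every
#' design sample must exist in the count matrix, each (arm, treatment) group
#' needs at least two replicates and each arm all three treatment levels.
#'
#' @param path Path to a tab-separated file with columns `sample_id`, `arm`,
#'   `treatment`, `replicate`.
#' @param counts Optional count matrix to cross-validate sample ids against.
#' @return A data.frame with columns sample_id, arm, treatment, replicate.
#' @export
read_design <- function(path, counts = NULL) {
  df <- read_tsv_raw(path)
  need <- c("sample_id", "arm", "treatment", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("design file missing column(s): ", paste(miss, collapse = ", "))
  design <- df[, need]
  design$replicate <- suppressWarnings(as.integer(design$replicate))
  validate_design(design, counts)
  design
}

#' Validate a design table (optionally against a count matrix)
#'
#' @param design data.frame with sample_id, arm, treatment, replicate.
#' @param counts Optional count matrix whose samples the design must match.
#' @param require_complete Require each arm to contain all three treatment
#'   levels with >= 2 replicates each (the full-experiment contract; default
#'   TRUE). Single-contrast helpers relax this.
#' @return The design, invisibly.
#' @export
validate_design <- function(design, counts = NULL, require_complete = TRUE) {
  bad_t <- setdiff(unique(design$treatment), TREATMENT_LEVELS)
  if (length(bad_t))
    stop("unknown treatment label(s): ", paste(bad_t, collapse = ", "),
         "; allowed: ", paste(TREATMENT_LEVELS, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  if (anyNA(design$replicate) || any(design$replicate < 1L))
    stop("replicate must be a positive integer")
  if (!is.null(counts)) {
    absent <- setdiff(design$sample_id, colnames(counts))
    if (length(absent))
      stop("design sample(s) absent from counts: ", paste(absent, collapse = ", "))
  }
  if (require_complete) {
    for (a in unique(design$arm)) {
      lev <- design$treatment[design$arm == a]
      miss <- setdiff(TREATMENT_LEVELS, lev)
      if (length(miss))
        stop("arm '", a, "' is missing treatment level(s): ",
             paste(miss, collapse = ", "))
      tab <- table(lev)
      if (any(tab < 2L))
        stop("arm '", a, "' has < 2 replicates for treatment(s): ",
             paste(names(tab)[tab < 2L], collapse = ", "))
    }
  }
  invisible(design)
}

#' Write a design table as TSV
#' @param design Design data.frame.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member genes. Duplicate members within a set are dropped with a
#' warning; a duplicated set name is an error (the collection would be
#' ambiguous).
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of member gene ids; each element
#'   carries its description in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    name <- fields[[1L]]
    if (name %in% names(sets))
      stop("duplicate gene-set name '", name, "' in GMT (ambiguous collection)")
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate member gene(s) in set '", name, "'; de-duplicated")
      members <- unique(members)
    }
    if (!length(members))
      stop("gene set '", name, "' on GMT line ", i, " has no members")
    attr(members, "description") <- fields[[2L]]
    sets[[name]] <- members
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors (optionally with a
#'   `"description"` attribute each).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-interaction edge list
#'
#' Reads a STRING-style tab-separated edge list with columns `node_a`,
#' `node_b`, `combined_score`. Scores may be on STRING's 0-1000 integer scale,
#' auto-detected (any score > 1 divides all scores by 1000, with a message).
#' Self-loops are dropped; duplicate undirected pairs are collapsed keeping the
#' maximum score; edges below `min_score` are removed.
#'
#' @param path Path to the edge TSV.
#' @param min_score Minimum combined score to retain an edge (default 0.4, the
#'   STRING "medium confidence" threshold).
#' @return data.frame with columns node_a, node_b, score (all scores in
#'   `[0, 1]`, `>= min_score`, canonical node order node_a < node_b).
#' @export
read_edges <- function(path, min_score = 0.4) {
  df <- read_tsv_raw(path)
  need <- c("node_a", "node_b", "combined_score")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("edge file missing column(s): ", paste(miss, collapse = ", "))
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score)) stop("non-numeric combined_score in edge file")
  if (any(score < 0)) stop("negative combined_score in edge file")
  if (any(score > 1)) {
    message("edge scores > 1 detected; assuming STRING 0-1000 convention, dividing by 1000")
    score <- score / 1000
  }
  if (any(score > 1)) stop("edge scores exceed 1 even after 0-1000 rescaling")
  edges <- data.frame(node_a = as.character(df$node_a),
                      node_b = as.character(df$node_b),
                      score = score, stringsAsFactors = FALSE)
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  swap <- edges$node_a > edges$node_b
  tmp <- edges$node_a[swap]
  edges$node_a[swap] <- edges$node_b[swap]
  edges$node_b[swap] <- tmp
  key <- paste(edges$node_a, edges$node_b, sep = "\r")
  edges <- edges[order(key, -edges$score), , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$node_a, edges$node_b, sep = "\r")), ,
                 drop = FALSE]
  edges <- edges[edges$score >= min_score, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Write an edge list as TSV
#' @param edges data.frame with node_a, node_b, score.
#' @param path Output path.
#' @export
write_edges <- function(edges, path) {
  out <- data.frame(node_a = edges$node_a, node_b = edges$node_b,
                    combined_score = edges$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' One row per (arm, treatment) condition group, one column per trait (e.g.
#' `viability`, `apoptosis`, in percent).
#'
#' @param path Path to a TSV with columns `arm`, `treatment`, then traits.
#' @return data.frame with arm, treatment and numeric trait columns.
#' @export
read_phenotype <- function(path) {
  df <- read_tsv_raw(path)
  need <- c("arm", "treatment")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("phenotype file missing column(s): ", paste(miss, collapse = ", "))
  traits <- setdiff(colnames(df), need)
  if (!length(traits)) stop("phenotype file has no trait columns")
  for (tr in traits) {
    v <- suppressWarnings(as.numeric(df[[tr]]))
    if (anyNA(v)) stop("non-numeric or missing value in trait '", tr, "'")
    df[[tr]] <- v
  }
  bad_t <- setdiff(unique(df$treatment), TREATMENT_LEVELS)
  if (length(bad_t))
    stop("unknown treatment label(s) in phenotype: ", paste(bad_t, collapse = ", "))
  df
}

#' Write a phenotype table as TSV
#' @param phenotype data.frame with arm, treatment and trait columns.
#' @param path Output path.
#' @export
write_phenotype <- function(phenotype, path) {
  utils::write.table(phenotype, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
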