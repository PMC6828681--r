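# Small in-code fixtures written to temp files on demand.

tmp_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

fixture_counts_file <- function() {
  tmp_tsv(c(
    "gene_id\ts1\ts2\ts3\ts4\ts5\ts6",
    "G1\t10\t12\t9\t30\t28\t33",
    "G2\t5\t6\t4\t5\t7\t6",
    "G3\t100\t110\t95\t40\t45\t42"))
}

fixture_design_file <- function() {
  lines <- c("sample_id\tarm\ttreatment\treplicate")
  for (arm in c("armX", "armY"))
    for (tr in c("untreated", "single", "combined"))
      for (r in 1:3)
        lines <- c(lines, sprintf("%s.%s.%d\t%s\t%s\t%d", arm, tr, r, arm, tr, r))
  tmp_tsv(lines)
}

# Balanced 6-sample, one-arm design used in small DE tests.
small_design <- function(samples = paste0("s", 1:6), arm = "armX") {
  data.frame(sample_id = samples, arm = arm,
             treatment = rep(c("untreated", "single"), each = 3),
             replicate = rep(1:3, 2), stringsAsFactors = FALSE)
}

# NB count matrix for one 3v3 comparison with optional planted fold changes.
small_nb_counts <- function(n_genes, mu, phi, lfc = rep(0, n_genes),
                            samples = paste0("s", 1:6)) {
  m <- matrix(0L, n_genes, 6,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)), samples))
  for (j in 1:3) m[, j] <- rnbinom(n_genes, size = 1 / phi, mu = mu)
  for (j in 4:6) m[, j] <- rnbinom(n_genes, size = 1 / phi, mu = mu * 2^lfc)
  m
}
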