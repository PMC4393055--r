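# Shared fixture builders: everything is generated in code, no stored files.

# quick count_matrix from a genes x lanes matrix and a condition per lane
make_cm <- function(mat, condition, gene_prefix = "g", lane_prefix = "lane") {
  rn <- rownames(mat)
  if (is.null(rn) || anyDuplicated(rn) || !all(nzchar(rn))) {
    rownames(mat) <- paste0(gene_prefix, seq_len(nrow(mat)))
  }
  cn <- colnames(mat)
  if (is.null(cn) || anyDuplicated(cn) || !all(nzchar(cn))) {
    colnames(mat) <- paste0(lane_prefix, seq_len(ncol(mat)))
  }
  count_matrix(mat, stats::setNames(condition, colnames(mat)))
}

# write a count TSV + sample sheet into tempdir; returns the two paths
write_fixture_files <- function(mat, condition, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("lane", seq_len(ncol(mat)))
  counts_path <- file.path(dir, "counts.tsv")
  sheet_path <- file.path(dir, "samples.tsv")
  header <- paste(c("gene_id", colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], mat[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), counts_path)
  writeLines(c("lane_id\tcondition",
               paste(colnames(mat), condition, sep = "\t")),
             sheet_path)
  list(counts = counts_path, sheet = sheet_path)
}

# Independent route to the predictive probability: the ratio of two direct
# evaluations of the joint chain formula
#   p~(x_1..x_k) = (sum x_i)! / (prod x_i! * k^(sum x_i + 1)),
# all in log-gamma space. Never calls the package's negative-binomial path.
chain_log_joint <- function(x) {
  k <- length(x)
  s <- sum(x)
  lgamma(s + 1) - sum(lgamma(x + 1)) - (s + 1) * log(k)
}

chain_log_conditional <- function(x_rest, x_next) {
  chain_log_joint(c(x_rest, x_next)) - chain_log_joint(x_rest)
}
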