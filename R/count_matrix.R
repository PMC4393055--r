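#' Construct a validated gene-by-lane count matrix
#'
#' The container every stage of the package consumes and produces: a numeric
#' gene x lane matrix together with a lane-to-condition assignment. Raw read
#' counts are non-negative integers; normalized matrices reuse the same type
#' with real values, and the `raw` flag records which of the two a given
#' object holds.
#'
#' @param counts Numeric matrix, genes in rows and lanes in columns, with
#'   row names (gene identifiers) and column names (lane identifiers). All
#'   entries must be finite and non-negative; identifiers must be unique.
#' @param condition Character vector assigning each lane to a biological
#'   condition, either named by lane id or given in column order. At most
#'   two distinct condition labels are allowed.
#' @param raw Logical; `TRUE` if the matrix holds unmodified integer read
#'   counts. Defaults to whether all entries are whole numbers.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `condition` (named by lane) and `raw`.
#'
#' @examples
#' m <- matrix(c(1, 3, 2, 4), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("laneA", "laneB")))
#' cm <- count_matrix(m, c(laneA = "normal", laneB = "tumour"))
#' gene_ids(cm)
#' @export
count_matrix <- function(counts, condition, raw = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort_format("'counts' must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_format("'counts' must carry gene ids as row names and lane ids as column names")
  }
  if (anyDuplicated(rownames(counts))) {
    abort_format("duplicate gene ids in count matrix")
  }
  if (anyDuplicated(colnames(counts))) {
    abort_format("duplicate lane ids in count matrix")
  }
  if (any(!is.finite(counts))) {
    abort_format("count matrix contains non-finite or missing entries")
  }
  if (any(counts < 0)) {
    abort_format("count matrix contains negative entries")
  }
  lanes <- colnames(counts)
  if (!is.character(condition)) condition <- as.character(condition)
  if (is.null(names(condition))) {
    if (length(condition) != ncol(counts)) {
      abort_mapping("unnamed 'condition' must have one entry per lane")
    }
    names(condition) <- lanes
  }
  missing_lane <- setdiff(lanes, names(condition))
  if (length(missing_lane) > 0) {
    abort_mapping(sprintf(
      "lane(s) not in sample sheet: %s", paste(missing_lane, collapse = ", ")))
  }
  condition <- condition[lanes]
  if (anyNA(condition)) abort_mapping("condition labels contain NA")
  if (length(unique(condition)) > 2) {
    abort_mapping("more than two condition labels; two-condition designs only")
  }
  if (is.null(raw)) raw <- all(is_whole(counts))
  structure(
    list(counts = counts, condition = condition, raw = isTRUE(raw)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d lanes (%s)\n",
    nrow(x$counts), ncol(x$counts),
    if (x$raw) "raw integer counts" else "normalized values"))
  lev <- condition_levels(x)  # first level is condition-1 in the tests
  cat("conditions:",
      paste(sprintf("%s (%d lanes)", lev,
                    vapply(lev, function(l) sum(x$condition == l), integer(1))),
            collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Accessors for count_matrix components
#'
#' @param x A `count_matrix`.
#' @return `gene_ids` and `lane_ids` return character vectors in stored
#'   order; `lane_conditions` returns the lane-to-condition assignment named
#'   by lane id.
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname gene_ids
#' @export
lane_ids <- function(x) colnames(x$counts)

#' @rdname gene_ids
#' @export
lane_conditions <- function(x) x$condition

# Condition labels in order of first appearance across lanes; the first is
# "condition-1" everywhere (pooled count x), the second "condition-2" (y).
condition_levels <- function(x) unique(unname(x$condition))

# Per-gene pooled counts and replicate numbers for the two conditions.
pool_by_condition <- function(x) {
  lev <- condition_levels(x)
  if (length(lev) != 2) {
    abort_mapping("both conditions must be present in the sample sheet")
  }
  in1 <- x$condition == lev[1]
  list(
    x = rowSums(x$counts[, in1, drop = FALSE]),
    y = rowSums(x$counts[, !in1, drop = FALSE]),
    m = sum(in1),
    n = sum(!in1),
    conditions = lev
  )
}

#' Read a count matrix and sample sheet from tab-separated files
#'
#' The count file is TSV with a header row of lane ids and a first column of
#' gene ids; the sample sheet is TSV with columns `lane_id` and `condition`.
#' Lines starting with `#` are ignored in both files. Lane order follows the
#' count-file header; gene order follows the file and is preserved by every
#' downstream operation, so outputs are diffable against inputs.
#'
#' @param count_path Path to the count TSV.
#' @param samplesheet_path Path to the sample-sheet TSV.
#' @return A validated [count_matrix()].
#' @export
read_counts <- function(count_path, samplesheet_path) {
  if (!file.exists(count_path)) abort_io(sprintf("count file not found: %s", count_path))
  if (!file.exists(samplesheet_path)) {
    abort_io(sprintf("sample sheet not found: %s", samplesheet_path))
  }
  raw <- tryCatch(
    utils::read.delim(count_path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) abort_format(sprintf("cannot parse count file: %s", conditionMessage(e)))
  )
  if (ncol(raw) < 2) abort_format("count file needs a gene-id column and at least one lane")
  gene <- as.character(raw[[1]])
  lane_names <- colnames(raw)[-1]
  if (anyDuplicated(lane_names)) abort_format("count file header repeats a lane id")
  if (anyDuplicated(gene)) abort_format("count file repeats a gene id")
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    suppressWarnings(storage.mode(mat) <- "double")
  }
  if (anyNA(mat)) abort_format("count file contains non-numeric or missing entries")
  rownames(mat) <- gene

  sheet <- tryCatch(
    utils::read.delim(samplesheet_path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) abort_format(sprintf("cannot parse sample sheet: %s", conditionMessage(e)))
  )
  if (!all(c("lane_id", "condition") %in% colnames(sheet))) {
    abort_format("sample sheet must have columns 'lane_id' and 'condition'")
  }
  if (anyDuplicated(sheet$lane_id)) abort_format("sample sheet repeats a lane id")
  cond <- stats::setNames(as.character(sheet$condition), as.character(sheet$lane_id))
  count_matrix(mat, cond)
}

#' Write a count matrix to a tab-separated file
#'
#' @param x A `count_matrix`.
#' @param path Output path. The file has a `gene_id` column followed by one
#'   column per lane, re-readable by [read_counts()].
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = gene_ids(x), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table_full(df, path)
}

# Shortest decimal representation of each double that still round-trips
# exactly, so written tables re-read to identical values without the noise
# of a fixed 17-digit format.
format_double_full <- function(v) {
  out <- character(length(v))
  for (i in seq_along(v)) {
    if (is.na(v[i])) { out[i] <- "NA"; next }
    s <- trimws(formatC(v[i], digits = 15, format = "g"))
    if (as.numeric(s) != v[i]) s <- trimws(formatC(v[i], digits = 16, format = "g"))
    if (as.numeric(s) != v[i]) s <- trimws(formatC(v[i], digits = 17, format = "g"))
    out[i] <- s
  }
  out
}

write_table_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_double_full(out[[j]])
  }
  ok <- tryCatch({
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write to: %s", path))
  invisible(NULL)
}

#' Write and re-read per-gene result tables
#'
#' Result tables (from [de_lrt()], [run_de()], ...) are written as TSV with
#' one row per gene and a stable column order; doubles are written with
#' enough digits to re-read without loss.
#'
#' @param table A data frame of per-gene results.
#' @param path Output (or input) path.
#' @return `read_results` returns the data frame; `write_results` is called
#'   for its side effect.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table)) abort_format("'table' must be a data frame")
  if ("p_value" %in% colnames(table)) {
    p <- table$p_value
    if (any(!is.na(p) & (p < 0 | p > 1))) abort_format("p-values outside [0, 1]")
  }
  write_table_full(table, path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("results file not found: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
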