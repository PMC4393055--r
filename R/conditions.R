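# Classed conditions so callers (and the CLI) can distinguish bad input
# formats from bad science without parsing message strings.

poisde_abort <- function(message, class) {
  stop(structure(
    class = c(class, "poisde_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_format <- function(message) poisde_abort(message, "poisde_format_error")
abort_mapping <- function(message) poisde_abort(message, "poisde_mapping_error")
abort_domain <- function(message) poisde_abort(message, "poisde_domain_error")
abort_degenerate <- function(message) poisde_abort(message, "poisde_degenerate_error")
abort_insufficient <- function(message) poisde_abort(message, "poisde_insufficient_genes_error")
abort_unequal_reps <- function(message) poisde_abort(message, "poisde_unequal_replicates_error")
abort_io <- function(message) poisde_abort(message, "poisde_io_error")
abort_usage <- function(message) poisde_abort(message, "poisde_usage_error")

is_whole <- function(x, tol = 0) {
  x == floor(x)
}

# x * log(x) with the limit convention 0 * log(0) = 0, so likelihood-ratio
# statistics stay finite (and exact) at zero counts.
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}
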