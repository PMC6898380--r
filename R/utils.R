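# Internal helpers shared across modules.

# Abort with a classed condition so callers can distinguish argument errors
# from parse errors.
stop_arg <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "hicreg_argument_error")
}

stop_parse <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "hicreg_parse_error")
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_arg("`%s` must be a single number", name)
  }
  if (positive && x <= 0) {
    stop_arg("`%s` must be positive (got %s)", name, format(x))
  }
  invisible(x)
}

check_columns <- function(x, cols, name) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    stop_arg(
      "`%s` is missing required column(s): %s",
      name, paste(missing, collapse = ", ")
    )
  }
  invisible(x)
}

# Round half away from zero; used where continuous normalized counts must be
# coerced to integer successes for the binomial model.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Distance-preserving subsample: draw ~n rows, keeping the per-distance-bin
# proportions of the input.
stratified_subsample_idx <- function(distance_bins, n, seed) {
  total <- length(distance_bins)
  if (n >= total) {
    return(seq_len(total))
  }
  prop <- n / total
  with_seed(seed, {
    unlist(lapply(split(seq_len(total), distance_bins), function(idx) {
      take <- round(length(idx) * prop)
      if (take < 1L) take <- 1L
      sample(idx, min(take, length(idx)))
    }), use.names = FALSE)
  })
}
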