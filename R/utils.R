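# internal helpers shared across modules

vlp_abort <- function(msg, class = "validation_error") {
  abort(msg, class = paste0("vlpmix_", class))
}

# row-wise log-sum-exp of a matrix, guarded against underflow
row_logsumexp <- function(m) {
  mx <- do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
  mx + log(rowSums(exp(m - mx)))
}

# evaluate `expr` under a temporary RNG state when a seed is supplied
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    vlp_abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

# extract a numeric measurement vector from a data frame or numeric vector;
# enforces finite values and a uniform unit within the set
measurement_values <- function(data, allow_empty = FALSE) {
  if (is.data.frame(data)) {
    if (!"value" %in% names(data)) {
      vlp_abort("`data` must contain a `value` column.")
    }
    if ("unit" %in% names(data)) {
      u <- unique(data$unit)
      if (length(u) > 1L) {
        vlp_abort(
          paste0("Measurements mix units (", toString(u),
                 "); area and width sets are never merged silently.")
        )
      }
    }
    x <- data$value
  } else if (is.numeric(data)) {
    x <- data
  } else {
    vlp_abort("`data` must be a data frame with a `value` column or a numeric vector.")
  }
  x <- as.numeric(x)
  if (!allow_empty && length(x) < 1L) {
    vlp_abort("At least one measurement is required.")
  }
  if (any(!is.finite(x))) {
    vlp_abort("All measurement values must be finite.")
  }
  x
}

measurement_unit <- function(data) {
  if (is.data.frame(data) && "unit" %in% names(data)) unique(data$unit)[1] else NA_character_
}

measurement_condition <- function(data) {
  if (is.data.frame(data) && "condition" %in% names(data)) {
    u <- unique(data$condition)
    if (length(u) == 1L) as.character(u) else NA_character_
  } else {
    NA_character_
  }
}
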