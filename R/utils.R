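# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is untouched. All exported stochastic functions route through this so
# they are pure functions of their arguments.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Split a root seed into `n` reproducible stage seeds (all < 2^31).
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_input <- function(msg, class = "dtpd_input_error") {
  abort(msg, class = c(class, "dtpd_error"))
}

stop_degenerate <- function(msg) {
  abort(msg, class = c("dtpd_degenerate_error", "dtpd_error"))
}

# Upper-triangle (i < j) index pairs of an N x N matrix, column-major order.
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# Normalise a yes/no/na token column to lower case and validate.
normalize_token <- function(x, allowed, what, rows = NULL) {
  x_chr <- tolower(trimws(as.character(x)))
  x_chr[is.na(x)] <- "na"
  bad <- !(x_chr %in% allowed)
  if (any(bad)) {
    where <- if (!is.null(rows)) paste0(" at row ", rows[which(bad)[1]]) else ""
    stop_input(sprintf(
      "Invalid value '%s' for %s%s; expected one of: %s.",
      x_chr[which(bad)[1]], what, where, paste(allowed, collapse = ", ")
    ))
  }
  x_chr
}
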