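#' Kruskal stress-1 of a map configuration
#'
#' Measures how faithfully a low-dimensional configuration reproduces the
#' rank order of the input dissimilarities:
#' \deqn{\sigma_1 = \sqrt{\sum_{i<j}(d_{ij}-\hat d_{ij})^2 / \sum_{i<j} d_{ij}^2}}
#' where \eqn{d_{ij}} are Euclidean map distances and \eqn{\hat d_{ij}} the
#' disparities obtained by least-squares monotone regression of the distances
#' on the rank order of the dissimilarities (pool-adjacent-violators, primary
#' approach to ties: tied dissimilarities may receive unequal disparities).
#' 0 means a perfect ordinal fit; values between 0.20 and 0.35 are considered
#' a reasonable fit in concept mapping.
#'
#' @param coords Numeric matrix (or data frame) of map coordinates, one row
#'   per item.
#' @param dissimilarities Symmetric numeric dissimilarity matrix (or `dist`).
#' @return Stress-1, a number in \[0, 1\].
#' @export
stress1 <- function(coords, dissimilarities) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  delta <- as.matrix(dissimilarities)
  if (nrow(delta) != n || ncol(delta) != n) {
    stop_input("Dissimilarity matrix does not match the number of coordinate rows.")
  }
  if (max(abs(delta - t(delta))) > 1e-8) {
    stop_input("Dissimilarity matrix must be symmetric.")
  }
  pairs <- upper_pairs(n)
  d <- as.vector(dist(coords))
  if (all(d < .Machine$double.eps)) {
    stop_degenerate("All map distances are zero; stress is undefined.")
  }
  dhat <- monotone_disparities(d, delta[pairs])
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

# Least-squares monotone (isotonic) fit of distances d on the rank order of
# delta. Primary tie approach: within a tie block of delta the distances are
# pre-sorted ascending, so tied dissimilarities are free to take unequal
# disparities. Returns disparities in the original pair order.
monotone_disparities <- function(d, delta) {
  ord <- order(delta, d)
  fit <- isoreg(d[ord])$yf
  out <- numeric(length(d))
  out[ord] <- fit
  out
}

#' Nonmetric multidimensional scaling of a co-sort similarity matrix
#'
#' Embeds the items in a plane so that items frequently co-piled lie close
#' together. Dissimilarities are \eqn{(S - c_{ij})/S} (see
#' [sort_dissimilarity()]). The configuration is found by iterative
#' majorization (SMACOF): alternate a Guttman transform of the coordinates
#' with a monotone-regression update of the disparities, which decreases
#' stress-1 at every iteration. Because the loss surface is multimodal the
#' optimisation is restarted from `n_starts` random configurations and the
#' lowest-stress solution is kept.
#'
#' @param sim A `dtpd_similarity` object, or a symmetric dissimilarity matrix.
#' @param n_dims Embedding dimension, default 2 (the concept-mapping plane).
#' @param seed Integer seed controlling the random starts.
#' @param n_starts Number of random restarts, default 8.
#' @param max_iter Maximum majorization iterations per start.
#' @param tol Convergence tolerance on the per-iteration stress decrease.
#' @return An object of class `dtpd_map`: `coords` (matrix with item row
#'   names), `stress`, `stress_trace` (per-iteration stress of the winning
#'   start, non-increasing), `diss`, `items`, `seed`, `n_starts`. [tidy()]
#'   returns a tibble `item_id`, `x`, `y`.
#' @export
embed_map <- function(sim, n_dims = 2, seed = 1, n_starts = 8,
                      max_iter = 500, tol = 1e-10) {
  if (inherits(sim, "dtpd_similarity")) {
    delta <- sort_dissimilarity(sim)
    items <- sim$items
  } else {
    delta <- as.matrix(sim)
    items <- rownames(delta) %||% paste0("item_", seq_len(nrow(delta)))
  }
  n <- nrow(delta)
  if (n < 3) stop_input("At least 3 items are required for a map.")
  off <- delta[upper.tri(delta)]
  if (max(off) - min(off) < 1e-12) {
    stop_degenerate("All dissimilarities are equal; the map is unidentified.")
  }
  pairs <- upper_pairs(n)
  delta_vec <- delta[pairs]

  best <- NULL
  start_seeds <- split_seed(seed, n_starts)
  for (s in seq_len(n_starts)) {
    X <- with_seed(start_seeds[s],
                   matrix(runif(n * n_dims, -1, 1), n, n_dims))
    res <- smacof_run(X, delta_vec, pairs, n, max_iter, tol)
    if (is.null(best) || res$stress < best$stress) best <- res
  }

  rownames(best$coords) <- items
  colnames(best$coords) <- if (n_dims == 2) c("x", "y") else paste0("dim", seq_len(n_dims))
  structure(
    list(coords = best$coords, stress = best$stress,
         stress_trace = best$trace, diss = delta, items = items,
         seed = seed, n_starts = n_starts, n_dims = n_dims),
    class = "dtpd_map"
  )
}

# One majorization run from a fixed start. Alternates monotone regression
# (optimal disparities for the current distances) with the Guttman transform
# (optimal coordinates for the current disparities); each half-step cannot
# increase stress-1, and the recorded trace stops at the first non-decrease.
smacof_run <- function(X, delta_vec, pairs, n, max_iter, tol) {
  d <- as.vector(dist(X))
  if (all(d < .Machine$double.eps)) {
    # collapse at the start: nudge apart deterministically
    X <- X + matrix(seq_len(length(X)), nrow(X)) * 1e-6
    d <- as.vector(dist(X))
  }
  stress_of <- function(d) {
    dhat <- monotone_disparities(d, delta_vec)
    list(stress = sqrt(sum((d - dhat)^2) / sum(d^2)), dhat = dhat)
  }
  cur <- stress_of(d)
  trace <- cur$stress
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(d > 0, cur$dhat / d, 0)
    B <- matrix(0, n, n)
    B[cbind(pairs[, 1], pairs[, 2])] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    X_new <- (B %*% X) / n
    d_new <- as.vector(dist(X_new))
    if (all(d_new < .Machine$double.eps)) break
    nxt <- stress_of(d_new)
    if (nxt$stress > cur$stress + 1e-12) break   # numerically converged
    X <- X_new
    d <- d_new
    improved <- cur$stress - nxt$stress
    cur <- nxt
    trace <- c(trace, cur$stress)
    if (improved < tol) break
  }
  list(coords = X, stress = cur$stress, trace = trace)
}

#' @export
print.dtpd_map <- function(x, ...) {
  cat(sprintf("<dtpd_map> %d items in %d-D, stress-1 = %.4f (%d starts, seed %d)\n",
              length(x$items), x$n_dims, x$stress, x$n_starts, x$seed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dtpd_map <- function(x, ...) {
  xs <- x$coords[, 1]
  ys <- x$coords[, 2]
  tibble::tibble(item_id = x$items, x = unname(xs), y = unname(ys))
}

#' @exportS3Method generics::glance
glance.dtpd_map <- function(x, ...) {
  tibble::tibble(n_items = length(x$items), stress = x$stress,
                 n_starts = x$n_starts, seed = x$seed,
                 iterations = length(x$stress_trace))
}
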