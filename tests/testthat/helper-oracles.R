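# Independent brute-force oracles and small constructors used across the
# suite. Everything here is deliberately naive (loops, direct formulas) so
# that it shares no code path with the implementation it checks.

# Build a long sort tibble from a named list: sorter -> integer vector of
# pile labels (one per item, in item order).
make_sorts <- function(partitions, items = NULL) {
  n <- length(partitions[[1]])
  if (is.null(items)) items <- sprintf("it%02d", seq_len(n))
  purrr::map_dfr(names(partitions), function(s) {
    tibble::tibble(sorter_id = s, item_id = items,
                   pile = paste0("p", partitions[[s]]))
  })
}

# Minimal dtpd_similarity / dtpd_map objects built from raw pieces, for
# hand-set fixtures.
make_sim_obj <- function(counts, n_sorters) {
  items <- rownames(counts)
  structure(list(counts = counts, n_sorters = n_sorters, items = items,
                 excluded = character(0)),
            class = "dtpd_similarity")
}

make_map_obj <- function(coords, items = rownames(coords), stress = NA_real_) {
  if (is.null(items)) items <- sprintf("it%02d", seq_len(nrow(coords)))
  rownames(coords) <- items
  structure(list(coords = coords, stress = stress, stress_trace = stress,
                 diss = NULL, items = items, seed = 0, n_starts = 0,
                 n_dims = ncol(coords)),
            class = "dtpd_map")
}

# Pair-by-pair, sorter-by-sorter co-pile counting.
oracle_similarity <- function(sorts) {
  items <- sort(unique(sorts$item_id))
  sorters <- unique(sorts$sorter_id)
  n <- length(items)
  counts <- matrix(0L, n, n, dimnames = list(items, items))
  for (s in sorters) {
    one <- sorts[sorts$sorter_id == s, ]
    pile_of <- setNames(one$pile, one$item_id)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (pile_of[items[i]] == pile_of[items[j]]) {
          counts[i, j] <- counts[i, j] + 1L
        }
      }
    }
  }
  counts
}

# Co-sort-weighted mean distance, double loop, plus min-max normalisation.
oracle_bridging <- function(counts, coords) {
  n <- nrow(counts)
  d <- as.matrix(stats::dist(coords))
  raw <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      num <- num + counts[i, j] * d[i, j]
      den <- den + counts[i, j]
    }
    raw[i] <- if (den > 0) num / den else NA
  }
  rng <- range(raw, na.rm = TRUE)
  if (diff(rng) == 0) return(ifelse(is.na(raw), NA, 0))
  (raw - rng[1]) / (rng[2] - rng[1])
}

# Plain sums-based Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Leave-one-out sorter reliability by explicit pair enumeration.
oracle_reliability <- function(sorts) {
  items <- sort(unique(sorts$item_id))
  sorters <- unique(sorts$sorter_id)
  n <- length(items)
  binmats <- lapply(sorters, function(s) {
    one <- sorts[sorts$sorter_id == s, ]
    pile_of <- setNames(one$pile, one$item_id)
    v <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        v <- c(v, as.integer(pile_of[items[i]] == pile_of[items[j]]))
      }
    }
    v
  })
  total <- Reduce(`+`, binmats)
  vapply(seq_along(sorters), function(k) {
    oracle_pearson(binmats[[k]], total - binmats[[k]])
  }, numeric(1))
}

# Unweighted pool-adjacent-violators, written as the textbook block merge.
oracle_pav <- function(y) {
  vals <- as.numeric(y)
  wts <- rep(1, length(y))
  i <- 1
  while (i < length(vals)) {
    if (vals[i] > vals[i + 1] + 1e-15) {
      new_val <- (vals[i] * wts[i] + vals[i + 1] * wts[i + 1]) / (wts[i] + wts[i + 1])
      vals <- c(vals[seq_len(i - 1)], new_val, vals[-seq_len(i + 1)])
      wts <- c(wts[seq_len(i - 1)], wts[i] + wts[i + 1], wts[-seq_len(i + 1)])
      i <- max(i - 1, 1)
    } else {
      i <- i + 1
    }
  }
  rep(vals, times = wts)
}

# Independent stress-1 evaluator: own PAV, primary tie handling.
oracle_stress1 <- function(coords, delta_mat) {
  n <- nrow(coords)
  d <- c(); delta <- c()
  cm <- as.matrix(stats::dist(coords))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(d, cm[i, j]); delta <- c(delta, delta_mat[i, j])
    }
  }
  ord <- order(delta, d)
  dhat <- numeric(length(d))
  dhat[ord] <- oracle_pav(d[ord])
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

# Pairwise Mann-Whitney concordance with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Agglomerative Ward (ward.D2 Lance-Williams update on Euclidean distances);
# returns the partition with k clusters as an integer label vector.
oracle_ward <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  repeat {
    m <- length(active)
    if (m == k) break
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    ni <- sizes[i]; nj <- sizes[j]
    newd <- numeric(m)
    for (h in seq_len(m)) {
      if (h == i || h == j) next
      nh <- sizes[h]
      newd[h] <- sqrt(((ni + nh) * d[i, h]^2 + (nj + nh) * d[j, h]^2 -
                         nh * d[i, j]^2) / (ni + nj + nh))
    }
    d[i, ] <- newd; d[, i] <- newd; d[i, i] <- 0
    active[[i]] <- c(active[[i]], active[[j]])
    sizes[i] <- ni + nj
    d <- d[-j, -j, drop = FALSE]
    active[[j]] <- NULL
    sizes <- sizes[-j]
  }
  labels <- integer(n)
  for (c in seq_along(active)) labels[active[[c]]] <- c
  labels
}

# Two partitions identical up to relabelling?
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    nrow(unique(cbind(a, b))) == length(unique(a))
}

# Independent referral-rule table (exhaustive semantics of the instrument).
oracle_decide <- function(answers, q8, cutoff = 4) {
  score <- sum(answers == "yes")
  if (score < cutoff) return(FALSE)
  if (q8 == "no") return(FALSE)
  TRUE                                  # yes or not-applicable
}
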