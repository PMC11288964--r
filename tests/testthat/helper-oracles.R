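# Independent oracles and small fixture builders shared across the suite.

# random proteins-by-samples quant tibble (positive intensities, optional
# missingness), protein ids drawn from the built-in catalog so filter_rp
# recognizes them
random_quant <- function(n_p = 8, n_s = 4, miss_rate = 0) {
  syms <- rp_catalog()$symbol[seq_len(n_p)]
  m <- matrix(exp(rnorm(n_p * n_s, 10, 1)), n_p, n_s)
  if (miss_rate > 0) {
    m[runif(length(m)) < miss_rate] <- NA_real_
  }
  colnames(m) <- paste0("s", seq_len(n_s))
  dplyr::bind_cols(
    tibble::tibble(protein = syms),
    tibble::as_tibble(as.data.frame(m))
  )
}

# closed-form pooled-variance (Student) two-sample t
student_t_closed <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# closed-form Welch two-sample t
welch_t_closed <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  va <- var(a) / na
  vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# literal step-up BH by enumeration: adj_(i) = min_{j >= i} m * p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# naive O(n^3) UPGMA on a distance matrix; returns merge heights (ascending)
# and the partition (list of leaf-index sets) after each merge
naive_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  cluster_dist <- function(ci, cj) {
    mean(d[ci, cj, drop = FALSE])
  }
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dd < best[1]) best <- c(dd, i, j)
      }
    }
    i <- best[2]
    j <- best[3]
    heights <- c(heights, best[1])
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    clusters <- c(clusters[-c(i, j)], list(merged))
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (list of index sets) for set equality
canon_partition <- function(parts) {
  parts <- lapply(parts, sort)
  keys <- vapply(parts, paste, "", collapse = ",")
  sort(keys)
}

# partition of hclust leaves (by index) at k clusters
hclust_partition <- function(hc, k) {
  cl <- cutree(hc, k = k)
  unname(split(seq_along(cl), cl))
}

# tibble <-> matrix shims for building fixtures
mat_as_tbl <- function(m, ids = NULL) {
  ids <- ids %||% paste0("P", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(protein = ids),
                   tibble::as_tibble(as.data.frame(m)))
}

qt_as_matrix <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
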