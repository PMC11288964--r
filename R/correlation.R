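#' Pairwise-complete Pearson correlation between samples
#'
#' Correlates the RP ratio vectors of every pair of samples using the
#' Pearson coefficient over the RPs quantified in both (pairwise-complete
#' observations). The number of shared RPs behind each coefficient is
#' recorded; coefficients resting on fewer than 3 shared RPs are set to
#' missing with a warning.
#'
#' @param ratios proteins-by-samples tibble (typically from
#'   [compute_ribor()]).
#' @return An object of class `ribor_cor`: list with `r` (symmetric
#'   correlation matrix, unit diagonal), `n_shared` (pairwise-complete
#'   counts), and `sample_ids`.
#' @export
pearson_correlation <- function(ratios) {
  m <- qt_matrix(ratios)
  if (ncol(m) < 2) abort("at least 2 samples are required")
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  n_shared <- crossprod(!is.na(m))
  low <- n_shared < 3
  diag(low) <- FALSE
  if (any(low & !is.na(r))) {
    warn("correlations with fewer than 3 shared RPs set to missing")
  }
  r[low] <- NA_real_
  diag(r) <- 1
  structure(
    list(r = r, n_shared = n_shared, sample_ids = colnames(m)),
    class = "ribor_cor"
  )
}

#' @export
print.ribor_cor <- function(x, ...) {
  cat("Pearson correlation over ", length(x$sample_ids), " samples\n",
    sep = ""
  )
  off <- x$r[upper.tri(x$r)]
  cat("off-diagonal range: ",
    paste(round(range(off, na.rm = TRUE), 3), collapse = " to "), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname pearson_correlation
#' @param x a `ribor_cor` object.
#' @param ... unused.
#' @export
tidy.ribor_cor <- function(x, ...) {
  r <- x$r
  tibble(
    sample_1 = rep(rownames(r), times = ncol(r)),
    sample_2 = rep(colnames(r), each = nrow(r)),
    r = as.vector(r),
    n_shared = as.vector(x$n_shared)
  )
}

#' Correlation distance between profiles
#'
#' Distance `d = 1 - r` with `r` the Pearson correlation between item
#' profiles, so `d` lies in `[0, 2]`: 0 for identical profiles, 2 for
#' perfectly anti-correlated ones. Rows give RP-wise distances; columns give
#' sample-wise distances. A constant profile has no defined correlation and
#' raises an error (constant rows are dropped by [scale_rows()] upstream).
#'
#' @param x proteins-by-samples tibble (scaled or ratio), or a `ribor_cor`
#'   object (then `d = 1 - r` directly).
#' @param axis cluster `"columns"` (samples, default) or `"rows"` (RPs).
#' @return A [stats::dist] object.
#' @export
correlation_distance <- function(x, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  if (inherits(x, "ribor_cor")) {
    r <- x$r
  } else {
    m <- qt_matrix(x)
    if (axis == "rows") m <- t(m)
    if (ncol(m) < 2) abort("at least 2 items are required on the chosen axis")
    sds <- apply(m, 2, sd, na.rm = TRUE)
    if (any(is.na(sds) | sds == 0)) {
      abort(paste0(
        "constant profiles have no defined correlation: ",
        paste(colnames(m)[is.na(sds) | sds == 0], collapse = ", ")
      ))
    }
    r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  }
  if (anyNA(r)) abort("undefined correlations; cannot build distances")
  as.dist(1 - r)
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between two clusters is the
#' unweighted mean of all cross-pair distances. With correlation distances
#' this is the row/column clustering used for ratio heatmaps.
#'
#' @param d a [stats::dist] object or a symmetric matrix with zero diagonal.
#' @return An [stats::hclust] tree (method `"average"`).
#' @export
average_linkage <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-12)) {
      abort("distance matrix must be symmetric")
    }
    if (any(abs(diag(d)) > 1e-12)) {
      abort("distance matrix must have a zero diagonal")
    }
    d <- as.dist(d)
  }
  if (!inherits(d, "dist")) abort("`d` must be a dist object or matrix")
  hclust(d, method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' @param dend an [stats::hclust] tree (e.g. from [average_linkage()]).
#' @param k number of clusters, between 1 and the number of leaves.
#' @param groups optional sample-to-group mapping; when given, the
#'   per-cluster group composition is attached as attribute `composition`.
#' @return Tibble with columns `sample` and `cluster`.
#' @export
cut_tree <- function(dend, k, groups = NULL) {
  n <- length(dend$labels %||% dend$order)
  if (k < 1 || k > n) {
    abort(paste0("`k` must be between 1 and ", n))
  }
  cl <- cutree(dend, k = k)
  out <- tibble(sample = names(cl), cluster = unname(cl))
  if (!is.null(groups)) {
    gt <- as_groups_tbl(groups)
    comp <- dplyr::count(
      dplyr::inner_join(out, gt, by = "sample"),
      .data$cluster, .data$group,
      name = "n"
    )
    attr(out, "composition") <- comp
  }
  out
}

#' Cluster purity against known groups
#'
#' Fraction of samples whose cluster's majority group is their own group:
#' `sum over clusters of max group count / n`.
#'
#' @param clusters tibble from [cut_tree()].
#' @param groups sample-to-group mapping.
#' @return A single number in (0, 1].
#' @export
cluster_purity <- function(clusters, groups) {
  gt <- as_groups_tbl(groups)
  d <- dplyr::inner_join(clusters, gt, by = "sample")
  if (nrow(d) == 0) abort("no samples shared between clusters and groups")
  tab <- table(d$cluster, d$group)
  sum(apply(tab, 1, max)) / sum(tab)
}

#' Serialize a dendrogram as Newick text
#'
#' @param dend an [stats::hclust] tree.
#' @return A Newick string (requires the \pkg{ape} package).
#' @export
as_newick <- function(dend) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(dend))
}
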