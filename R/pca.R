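#' Principal component analysis with iterative SVD imputation
#'
#' PCA of the samples on a row-scaled RP-by-sample matrix, with missing
#' entries handled by iterative SVD imputation: missing cells are
#' initialized with their row means; then, at each iteration, the k leading
#' right singular vectors of the current matrix are computed and every
#' incomplete row is regressed on them using only its observed coordinates,
#' the fitted model supplying that row's missing values. The loop stops when
#' the imputed values change by less than `tol` (relative Frobenius norm) or
#' `max_iter` is reached. Regressing on observed coordinates only (rather
#' than replacing missing cells with the low-rank reconstruction of the full
#' matrix) prevents wrongly imputed cells from locking themselves in, so
#' exact low-rank matrices are recovered to numerical precision.
#' Observed entries are never altered. Samples are the observations: with
#' rows centered upstream (see [scale_rows()]) the SVD of the transposed
#' matrix yields the principal-component scores directly.
#'
#' @param scaled row-scaled proteins-by-samples tibble from [scale_rows()].
#' @param n_components rank used for imputation and number of score/loading
#'   columns returned (>= 2).
#' @param tol relative-change convergence tolerance for the imputed entries.
#' @param max_iter iteration cap; non-convergence yields a warning and
#'   `converged = FALSE`, never an error.
#' @return An object of class `ribor_pca`: list with `scores` (tibble,
#'   samples x PCs), `loadings` (tibble, proteins x PCs), `explained_var`
#'   (proportion of variance per component, full spectrum), `converged`,
#'   `n_iter`, and `n_imputed`.
#' @export
pca_svd_impute <- function(scaled, n_components = 2, tol = 1e-6,
                           max_iter = 200) {
  if (n_components < 2) abort("`n_components` must be at least 2")
  m <- qt_matrix(scaled)
  if (any(rowSums(!is.na(m)) == 0)) {
    abort("rows with all values missing cannot be imputed")
  }
  if (any(colSums(!is.na(m)) == 0)) {
    abort("samples with all values missing cannot be imputed")
  }
  k <- min(n_components, nrow(m) - 1L, ncol(m) - 1L)
  if (k < 1) abort("matrix too small for PCA")

  miss <- is.na(m)
  n_imputed <- sum(miss)
  mf <- m
  if (n_imputed > 0) {
    rmeans <- rowMeans(m, na.rm = TRUE)
    mf[miss] <- rmeans[row(m)[miss]]
  }

  converged <- TRUE
  n_iter <- 0L
  if (n_imputed > 0) {
    converged <- FALSE
    incomplete <- which(rowSums(miss) > 0)
    for (it in seq_len(max_iter)) {
      sv <- svd(mf, nu = 0, nv = k)
      new_mf <- mf
      for (i in incomplete) {
        obs <- !miss[i, ]
        ki <- min(k, sum(obs))
        basis <- sv$v[, seq_len(ki), drop = FALSE]
        beta <- qr.coef(qr(basis[obs, , drop = FALSE]), mf[i, obs])
        beta[is.na(beta)] <- 0
        new_mf[i, miss[i, ]] <- basis[miss[i, ], , drop = FALSE] %*% beta
      }
      new_vals <- new_mf[miss]
      old_vals <- mf[miss]
      rel <- sqrt(sum((new_vals - old_vals)^2)) /
        max(sqrt(sum(old_vals^2)), .Machine$double.eps)
      mf <- new_mf
      n_iter <- it
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warn(paste0("SVD imputation did not converge in ", max_iter,
                  " iterations"))
    }
  }

  # samples as observations; rows were centered upstream, which makes the
  # columns of t(mf) mean-zero
  a <- t(mf)
  sv <- svd(a)
  d2 <- sv$d^2
  explained_var <- d2 / sum(d2)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  pc_names <- paste0("PC", seq_len(k))

  structure(
    list(
      scores = dplyr::bind_cols(
        tibble(sample = colnames(m)),
        as_tibble(`colnames<-`(scores, pc_names))
      ),
      loadings = dplyr::bind_cols(
        tibble(protein = rownames(m)),
        as_tibble(`colnames<-`(loadings, pc_names))
      ),
      explained_var = explained_var,
      converged = converged,
      n_iter = n_iter,
      n_imputed = n_imputed
    ),
    class = "ribor_pca"
  )
}

#' @export
print.ribor_pca <- function(x, ...) {
  cat("PCA (SVD with imputation): ", nrow(x$scores), " samples, ",
      nrow(x$loadings), " features\n", sep = "")
  ev <- round(100 * x$explained_var[1:min(3, length(x$explained_var))], 1)
  cat("explained variance: ", paste0(ev, "%", collapse = ", "), "\n", sep = "")
  if (x$n_imputed > 0) {
    cat(x$n_imputed, " entries imputed in ", x$n_iter, " iterations (",
        if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  }
  invisible(x)
}

#' @rdname pca_svd_impute
#' @param x,object a `ribor_pca` object.
#' @param matrix which component to tidy: `"scores"`, `"loadings"`, or
#'   `"eigenvalues"`.
#' @param ... unused.
#' @export
tidy.ribor_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                           ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tidyr::pivot_longer(x$scores, -"sample",
      names_to = "PC", values_to = "score"
    ),
    loadings = tidyr::pivot_longer(x$loadings, -"protein",
      names_to = "PC", values_to = "loading"
    ),
    eigenvalues = tibble(
      PC = paste0("PC", seq_along(x$explained_var)),
      percent = 100 * x$explained_var,
      cumulative = 100 * cumsum(x$explained_var)
    )
  )
}

#' @rdname pca_svd_impute
#' @export
glance.ribor_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_features = nrow(x$loadings),
    n_imputed = x$n_imputed,
    n_iter = x$n_iter,
    converged = x$converged,
    var_pc1 = x$explained_var[1],
    var_pc2 = x$explained_var[2]
  )
}

#' Group prediction ellipses in PC score space
#'
#' For each sample group, the bivariate-normal prediction ellipse in the
#' first two principal components: the region expected to contain a new
#' observation from the same group with probability `prob` (default 0.95).
#' With small groups the correct prediction quantile is the Hotelling-type
#' F form, `2 (n-1)(n+1) / (n (n-2)) * qf(prob, 2, n-2)`; the large-n
#' chi-square(2) quantile is available via `method = "chisq"`.
#'
#' @param scores tibble with columns `sample`, `PC1`, `PC2` (e.g. from
#'   [pca_svd_impute()]), or a `ribor_pca` object.
#' @param groups sample-to-group mapping (two-column data frame or named
#'   vector); every group needs at least 3 samples.
#' @param prob coverage probability of the ellipse.
#' @param method `"f"` (default, exact for normal samples at any n > 2) or
#'   `"chisq"` (known-parameter limit).
#' @return A tibble with one row per group: center (`x0`, `y0`), semi-axes
#'   (`a` major, `b` minor), orientation `angle` (radians, major axis vs
#'   PC1), `prob`, and `n`.
#' @export
prediction_ellipse <- function(scores, groups, prob = 0.95,
                               method = c("f", "chisq")) {
  method <- match.arg(method)
  check_prob(prob, "prob")
  if (inherits(scores, "ribor_pca")) scores <- scores$scores
  if (!all(c("PC1", "PC2") %in% names(scores))) {
    abort("`scores` must contain PC1 and PC2 columns")
  }
  gt <- as_groups_tbl(groups)
  dat <- dplyr::inner_join(scores, gt, by = "sample")

  purrr::map_dfr(split(dat, dat$group), function(d) {
    g <- d$group[1]
    n <- nrow(d)
    if (n < 3) {
      abort(paste0("group '", g, "' has fewer than 3 samples"))
    }
    xy <- cbind(d$PC1, d$PC2)
    ctr <- colMeans(xy)
    s <- stats::cov(xy)
    ev <- eigen(s, symmetric = TRUE)
    if (min(ev$values) <= max(ev$values) * 1e-12 || max(ev$values) <= 0) {
      abort(paste0("group '", g, "' has a degenerate (singular) covariance"))
    }
    r2 <- if (method == "f") {
      2 * (n - 1) * (n + 1) / (n * (n - 2)) * qf(prob, 2, n - 2)
    } else {
      qchisq(prob, 2)
    }
    tibble(
      group = g,
      x0 = ctr[1], y0 = ctr[2],
      a = sqrt(ev$values[1] * r2),
      b = sqrt(ev$values[2] * r2),
      angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
      prob = prob,
      n = n
    )
  })
}

#' Test points against prediction ellipses
#'
#' @param ellipses tibble from [prediction_ellipse()] (one row used per call
#'   via its `group`), or a single-row subset.
#' @param points two-column matrix or data frame of (PC1, PC2) coordinates.
#' @return Logical vector: is each point inside (or on) the ellipse? For a
#'   multi-row `ellipses` the first row is used.
#' @export
ellipse_contains <- function(ellipses, points) {
  e <- ellipses[1, ]
  pts <- as.matrix(points)
  dx <- pts[, 1] - e$x0
  dy <- pts[, 2] - e$y0
  ca <- cos(e$angle)
  sa <- sin(e$angle)
  u <- ca * dx + sa * dy
  v <- -sa * dx + ca * dy
  (u / e$a)^2 + (v / e$b)^2 <= 1
}

#' Outline coordinates of prediction ellipses (for plotting)
#'
#' @param ellipses tibble from [prediction_ellipse()].
#' @param n_points points per outline.
#' @return Tibble with columns `group`, `x`, `y`.
#' @export
ellipse_outline <- function(ellipses, n_points = 181) {
  theta <- seq(0, 2 * pi, length.out = n_points)
  purrr::map_dfr(seq_len(nrow(ellipses)), function(i) {
    e <- ellipses[i, ]
    u <- e$a * cos(theta)
    v <- e$b * sin(theta)
    tibble(
      group = e$group,
      x = e$x0 + cos(e$angle) * u - sin(e$angle) * v,
      y = e$y0 + sin(e$angle) * u + cos(e$angle) * v
    )
  })
}
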