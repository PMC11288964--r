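test_that("row scaling centers, unit-scales, and drops constant rows", {
  x <- tibble::tibble(
    protein = c("A", "B", "C"),
    s1 = c(1, -1, 5), s2 = c(2, 0, 5), s3 = c(3, 1, 5)
  )
  expect_warning(s <- scale_rows(x), "unscalable")
  m <- as.matrix(s[-1])
  expect_equal(unname(rowMeans(m)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(m, 1, var)), c(1, 1), tolerance = 1e-10)
  expect_equal(attr(s, "scaling_record")$protein, "C")
  expect_equal(attr(s, "scaling_record")$reason, "zero variance")

  # centered-only arithmetic
  c_only <- scale_rows(x[1, ], unit_variance = FALSE)
  expect_equal(unlist(c_only[1, -1], use.names = FALSE), c(-1, 0, 1))
  # a row already at unit variance is unchanged by scaling
  u <- scale_rows(tibble::tibble(protein = "A",
                                 s1 = -1, s2 = 0, s3 = 1))
  expect_equal(unlist(u[1, -1], use.names = FALSE), c(-1, 0, 1))
})

test_that("all-constant input cannot be scaled", {
  x <- tibble::tibble(protein = c("A", "B"), s1 = c(1, 2), s2 = c(1, 2))
  expect_error(suppressWarnings(scale_rows(x)), "all rows")
})

test_that("PCA on complete data equals direct SVD PCA up to sign", {
  withr::local_seed(5)
  for (i in 1:5) {
    m <- matrix(rnorm(9 * 6), 9, 6)
    x <- mat_as_tbl(m)
    s <- scale_rows(x)
    p <- pca_svd_impute(s, n_components = 2)
    expect_equal(p$n_iter, 0L) # imputation loop is a no-op
    ref <- prcomp(t(qt_as_matrix(s)), center = FALSE, scale. = FALSE)
    for (k in 1:2) {
      got <- p$scores[[paste0("PC", k)]]
      want <- ref$x[, k]
      expect_equal(min(max(abs(got - want)), max(abs(got + want))), 0,
                   tolerance = 1e-8)
    }
    ev <- p$explained_var
    expect_true(all(diff(ev) <= 1e-12))
    expect_lte(sum(ev), 1 + 1e-10)
    expect_true(all(ev >= 0))
  }
})

test_that("masked entries of an exact rank-1 matrix are recovered", {
  withr::local_seed(8)
  u <- rnorm(10)
  v <- rnorm(6)
  m <- u %*% t(v)
  mask <- matrix(runif(60) < 0.1, 10, 6)
  # keep every row/column partly observed
  mask[, 1] <- FALSE
  mask[1, ] <- FALSE
  mm <- m
  mm[mask] <- NA
  x <- mat_as_tbl(mm)
  p <- pca_svd_impute(x, n_components = 2, tol = 1e-10, max_iter = 500)
  expect_true(p$converged)
  # reconstruct the imputed matrix from the full SVD of the result
  sc <- as.matrix(p$scores[-1])
  ld <- as.matrix(p$loadings[-1])
  recon <- t(sc %*% t(ld))
  expect_lt(max(abs(recon[mask] - m[mask])), 1e-6)
  expect_equal(recon[!mask], m[!mask], tolerance = 1e-6)
})

test_that("masked-entry error is non-increasing over iterations", {
  withr::local_seed(19)
  u <- matrix(rnorm(20), 10, 2)
  v <- matrix(rnorm(12), 6, 2)
  m <- u %*% t(v) # exact rank 2
  mask <- matrix(runif(60) < 0.15, 10, 6)
  mask[, 1] <- FALSE
  mask[1, ] <- FALSE
  mm <- m
  mm[mask] <- NA
  x <- mat_as_tbl(mm)
  errs <- sapply(1:8, function(t_max) {
    p <- suppressWarnings(
      pca_svd_impute(x, n_components = 2, tol = 0, max_iter = t_max)
    )
    sc <- as.matrix(p$scores[-1])
    ld <- as.matrix(p$loadings[-1])
    recon <- t(sc %*% t(ld))
    sqrt(mean((recon[mask] - m[mask])^2))
  })
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("fully missing rows or samples are rejected", {
  x <- tibble::tibble(protein = c("A", "B", "C"),
                      s1 = c(1, NA, 2), s2 = c(2, NA, 1), s3 = c(0, NA, 3))
  expect_error(pca_svd_impute(x), "rows with all values missing")
  expect_error(pca_svd_impute(x, n_components = 1), "at least 2")
})

test_that("prediction ellipse approaches the chi-square circle at large n", {
  withr::local_seed(12)
  n <- 20000
  scores <- tibble::tibble(
    sample = paste0("s", 1:n),
    PC1 = rnorm(n), PC2 = rnorm(n)
  )
  groups <- tibble::tibble(sample = scores$sample, group = "g")
  e <- prediction_ellipse(scores, groups, prob = 0.95)
  r <- sqrt(qchisq(0.95, 2))
  expect_equal(e$a, r, tolerance = 0.02)
  expect_equal(e$b, r, tolerance = 0.02)
  e_chi <- prediction_ellipse(scores, groups, prob = 0.95,
                              method = "chisq")
  expect_equal(e_chi$a / e$a, 1, tolerance = 0.001)
})

test_that("ellipse degenerate and small-group inputs error by name", {
  scores <- tibble::tibble(
    sample = paste0("s", 1:3),
    PC1 = c(0, 1, 2), PC2 = c(0, 1, 2) # collinear
  )
  g <- tibble::tibble(sample = scores$sample, group = "line")
  expect_error(prediction_ellipse(scores, g), "line")
  g2 <- tibble::tibble(sample = scores$sample[1:2], group = "tiny")
  expect_error(prediction_ellipse(scores[1:2, ], g2), "tiny")
})

test_that("pairwise-complete Pearson correlation matches the closed form", {
  x <- tibble::tibble(
    protein = c("A", "B", "C"),
    s1 = c(0.2, 0.3, 0.5),
    s2 = c(0.5, 0.3, 0.2)
  )
  cc <- pearson_correlation(x)
  # hand-computed on 3 points: Sxy = -39/900, Sxx = Syy = 42/900
  expect_equal(cc$r["s1", "s2"], -13 / 14, tolerance = 1e-12)
  expect_equal(diag(cc$r), c(s1 = 1, s2 = 1))
  expect_true(isSymmetric(cc$r))
  expect_equal(cc$n_shared["s1", "s2"], 3)
})

test_that("correlation ignores RP order once aligned by id, and gates n<3", {
  withr::local_seed(2)
  q <- random_quant(8, 2)
  q_perm <- q[sample(nrow(q)), ]
  q2 <- tibble::tibble(protein = q$protein, a = q$s1,
                       b = q_perm$s2[match(q$protein, q_perm$protein)])
  cc <- pearson_correlation(q2)
  expect_equal(cc$r["a", "b"], cor(q$s1, q$s2))

  sparse <- tibble::tibble(
    protein = c("A", "B", "C"),
    s1 = c(1, 2, NA), s2 = c(2, 1, NA), s3 = c(1, 2, 3)
  )
  expect_warning(c2 <- pearson_correlation(sparse), "fewer than 3")
  expect_true(is.na(c2$r["s1", "s2"]))
  expect_false(is.na(c2$r["s1", "s1"]))
})

test_that("correlation distance follows d = 1 - r on both axes", {
  x <- tibble::tibble(
    protein = c("A", "B"),
    s1 = c(1, 2), s2 = c(2, 4), s3 = c(3, 1)
  )
  d <- correlation_distance(x, axis = "rows")
  m <- as.matrix(d)
  expect_equal(m["A", "B"], 1 - cor(c(1, 2, 3), c(2, 4, 1)))
  # identical profiles at distance 0; anti-correlated at 2
  y <- tibble::tibble(protein = c("A", "B", "C"),
                      s1 = c(1, 1, 3), s2 = c(2, 2, 2), s3 = c(3, 3, 1))
  dm <- as.matrix(correlation_distance(y, axis = "rows"))
  expect_equal(dm["A", "B"], 0, tolerance = 1e-14)
  expect_equal(dm["A", "C"], 2, tolerance = 1e-14)
  expect_error(
    correlation_distance(tibble::tibble(protein = c("A", "B"),
                                        s1 = c(1, 5), s2 = c(1, 5)),
                         axis = "rows"),
    "constant"
  )
})

test_that("average linkage matches the naive UPGMA oracle", {
  withr::local_seed(21)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    rownames(m) <- colnames(m) <- paste0("L", 1:n)
    hc <- average_linkage(m)
    oracle <- naive_upgma(m)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
    for (step in seq_len(n - 1)) {
      k <- n - step
      expect_identical(
        canon_partition(hclust_partition(hc, k)),
        canon_partition(oracle$partitions[[step]])
      )
    }
  }
})

test_that("UPGMA base cases: two leaves, duplicates merge first at 0", {
  m2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  hc <- average_linkage(m2)
  expect_equal(hc$height, 0.4)

  x <- tibble::tibble(protein = c("A", "B"),
                      s1 = c(1, 2), s2 = c(2, 3), s3 = c(3, 1),
                      s4 = c(1, 2), s5 = c(2, 3))
  # s1/s4 and s2/s5 are duplicate profiles
  hc2 <- average_linkage(correlation_distance(x, axis = "columns"))
  expect_equal(hc2$height[1:2], c(0, 0), tolerance = 1e-12)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(average_linkage(bad), "symmetric")
})

test_that("cut_tree spans the full k range and reports composition", {
  withr::local_seed(4)
  q <- random_quant(10, 5)
  hc <- average_linkage(correlation_distance(scale_rows(compute_ribor(q))))
  expect_equal(sort(unique(cut_tree(hc, 1)$cluster)), 1)
  expect_equal(nrow(dplyr::distinct(cut_tree(hc, 5)["cluster"])), 5)
  expect_error(cut_tree(hc, 6), "between 1 and 5")
  g <- tibble::tibble(sample = paste0("s", 1:5),
                      group = c("x", "x", "x", "y", "y"))
  cl <- cut_tree(hc, 2, groups = g)
  comp <- attr(cl, "composition")
  expect_equal(sum(comp$n), 5)
})

test_that("strong two-population cohort separates at k = 2", {
  sim <- generate_dataset(ribor_preset("gastric_cohort", seed = 2))
  r <- compute_ribor(sim$quant)
  s <- suppressWarnings(scale_rows(r))
  hc <- average_linkage(correlation_distance(s, axis = "columns"))
  cl <- cut_tree(hc, 2, groups = sim$groups)
  expect_gte(cluster_purity(cl, sim$groups), 0.9)
})
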