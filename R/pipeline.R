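#' Run the full ratio-omics pipeline
#'
#' One call from an intensity table to every downstream result: RP filtering,
#' stoichiometry barcode, row scaling, PCA with SVD imputation (plus 95%
#' prediction ellipses for groups with at least 3 samples), sample-sample
#' Pearson correlation, correlation-distance / average-linkage clustering of
#' rows and columns (optionally cut into `k` clusters), and -- when a
#' contrast is given -- differential testing with a volcano table. All
#' thresholds default to the conventional analysis settings (alpha 0.05,
#' 0.95 ellipses, correlation distance with average linkage), so the
#' zero-configuration call reproduces the standard analysis sequence.
#'
#' @param quant proteins-by-samples tibble (see [read_quant_table()]).
#' @param groups sample-to-group mapping (two-column data frame or named
#'   vector).
#' @param catalog RP catalog, default [rp_catalog()].
#' @param contrast optional length-2 character vector
#'   `c(group_a, group_b)` for differential testing.
#' @param mode `"ratio"` (test stoichiometry) or `"level"` (test raw
#'   intensity).
#' @param alpha significance threshold for adjusted p values.
#' @param variant t-test variant.
#' @param n_components,pca_tol,pca_max_iter PCA settings, see
#'   [pca_svd_impute()].
#' @param ellipse_prob prediction-ellipse coverage probability.
#' @param k optional number of clusters to cut the sample dendrogram into.
#' @param min_detected optional detected-RP QC threshold; failing samples are
#'   dropped before the ratio step.
#' @param out_dir optional directory; when given, all artifacts are written
#'   there (TSV tables, JSON run report, Newick dendrograms if \pkg{ape} is
#'   installed).
#' @return An object of class `ribor_run`: list with `rp_quant`, `qc`,
#'   `ratios`, `scaled`, `pca`, `ellipses`, `correlation`, `sample_tree`,
#'   `protein_tree`, `clusters` (if `k`), `diff` and `volcano` (if
#'   `contrast`), and `report` (a summary list).
#' @export
run_pipeline <- function(quant, groups, catalog = rp_catalog(),
                         contrast = NULL, mode = c("ratio", "level"),
                         alpha = 0.05, variant = c("student", "welch"),
                         n_components = 2, pca_tol = 1e-6,
                         pca_max_iter = 200, ellipse_prob = 0.95,
                         k = NULL, min_detected = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  check_prob(alpha, "alpha")
  check_prob(ellipse_prob, "ellipse_prob")
  gt <- as_groups_tbl(groups)

  rp_quant <- filter_rp(quant, catalog)
  if (!is.null(min_detected)) {
    rp_quant <- drop_low_detection(rp_quant, min_detected)
  }
  qc <- detected_rp_counts(rp_quant, threshold = min_detected)
  ratios <- compute_ribor(rp_quant)
  scaled <- scale_rows(ratios)

  pca <- pca_svd_impute(scaled, n_components = n_components,
                        tol = pca_tol, max_iter = pca_max_iter)
  gv <- group_vector(ratios, gt)
  big_groups <- names(which(table(gv) >= 3))
  small <- setdiff(unique(gv), big_groups)
  if (length(small) > 0) {
    warn(paste0("no prediction ellipse for groups with < 3 samples: ",
                paste(small, collapse = ", ")))
  }
  ellipses <- if (length(big_groups) > 0) {
    prediction_ellipse(
      pca$scores, gt[gt$group %in% big_groups, ], prob = ellipse_prob
    )
  } else {
    NULL
  }

  correlation <- pearson_correlation(ratios)
  sample_tree <- average_linkage(correlation_distance(scaled, "columns"))
  protein_tree <- average_linkage(correlation_distance(scaled, "rows"))
  clusters <- if (!is.null(k)) cut_tree(sample_tree, k, groups = gt) else NULL

  diff <- NULL
  volcano <- NULL
  if (!is.null(contrast)) {
    stopifnot(length(contrast) == 2)
    dat <- if (mode == "ratio") ratios else rp_quant
    diff <- differential_ratio(dat, gt, contrast[1], contrast[2],
                               mode = mode, alpha = alpha, variant = variant)
    volcano <- volcano_table(diff)
  }

  report <- list(
    n_proteins_input = nrow(quant),
    n_rp = nrow(rp_quant),
    n_samples = ncol(rp_quant) - 1,
    n_scaled_rows = nrow(scaled),
    dropped_rows = attr(scaled, "scaling_record")$protein,
    pca = list(converged = pca$converged, n_iter = pca$n_iter,
               n_imputed = pca$n_imputed,
               explained_var = pca$explained_var[seq_len(n_components)]),
    settings = list(mode = mode, alpha = alpha, variant = variant,
                    ellipse_prob = ellipse_prob, n_components = n_components)
  )
  if (!is.null(diff)) {
    g <- glance(diff)
    report$differential <- list(
      contrast = contrast, n_tested = g$n_tested,
      n_up = g$n_up, n_down = g$n_down
    )
  }
  if (!is.null(clusters)) {
    report$clusters <- as.data.frame(attr(clusters, "composition"))
  }

  run <- structure(
    list(rp_quant = rp_quant, qc = qc, ratios = ratios, scaled = scaled,
         pca = pca, ellipses = ellipses, correlation = correlation,
         sample_tree = sample_tree, protein_tree = protein_tree,
         clusters = clusters, diff = diff, volcano = volcano,
         groups = gt, report = report),
    class = "ribor_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.ribor_run <- function(x, ...) {
  r <- x$report
  cat("ratio-omics run: ", r$n_rp, " RPs x ", r$n_samples, " samples\n",
      sep = "")
  cat("PC1/PC2 explained variance: ",
      paste0(round(100 * r$pca$explained_var, 1), "%", collapse = ", "),
      "\n", sep = "")
  if (!is.null(r$differential)) {
    cat("differential (", paste(r$differential$contrast, collapse = " vs "),
        "): ", r$differential$n_up, " up, ", r$differential$n_down,
        " down of ", r$differential$n_tested, " tested\n", sep = "")
  }
  invisible(x)
}

#' Write all artifacts of a pipeline run
#'
#' @param run a `ribor_run` from [run_pipeline()].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_quant_table(run$ratios, p("ratios.tsv"))
  write_quant_table(run$scaled, p("scaled.tsv"))
  readr::write_tsv(run$qc, p("qc_detected_rp.tsv"))
  readr::write_tsv(run$pca$scores, p("pca_scores.tsv"))
  readr::write_tsv(run$pca$loadings, p("pca_loadings.tsv"))
  readr::write_tsv(
    tidy(run$pca, "eigenvalues"), p("pca_explained_variance.tsv")
  )
  readr::write_tsv(tidy(run$correlation), p("correlation.tsv"))
  if (!is.null(run$ellipses)) {
    jsonlite::write_json(run$ellipses, p("ellipses.json"),
                         dataframe = "rows", digits = NA)
  }
  if (requireNamespace("ape", quietly = TRUE)) {
    writeLines(as_newick(run$sample_tree), p("sample_tree.nwk"))
    writeLines(as_newick(run$protein_tree), p("protein_tree.nwk"))
  }
  if (!is.null(run$clusters)) {
    readr::write_tsv(run$clusters, p("clusters.tsv"))
  }
  if (!is.null(run$diff)) {
    readr::write_tsv(run$diff, p("differential.tsv"))
    readr::write_tsv(run$volcano, p("volcano.tsv"))
  }
  jsonlite::write_json(run$report, p("report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
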