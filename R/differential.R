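#' Two-sample t test with degenerate-variance handling
#'
#' Two-tailed t test between two vectors, either Student's pooled-variance
#' form or Welch's unequal-variance form. Degenerate inputs are handled
#' explicitly rather than producing a fabricated p value: identical constant
#' groups give `t = 0, p = 1`; zero variance with unequal means is flagged
#' untestable (`tested = FALSE`).
#'
#' @param a,b numeric vectors (missing values dropped).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return List with `t_stat`, `p_raw`, `df`, `tested`, and `reason` (NA when
#'   tested).
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  untestable <- function(reason) {
    list(t_stat = NA_real_, p_raw = NA_real_, df = NA_real_,
         tested = FALSE, reason = reason)
  }
  if (length(a) < 2 || length(b) < 2) {
    return(untestable("fewer than 2 values in a group"))
  }
  va <- var(a)
  vb <- var(b)
  se2 <- if (variant == "student") {
    ((length(a) - 1) * va + (length(b) - 1) * vb) /
      (length(a) + length(b) - 2) * (1 / length(a) + 1 / length(b))
  } else {
    va / length(a) + vb / length(b)
  }
  if (se2 <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t_stat = 0, p_raw = 1,
                  df = length(a) + length(b) - 2,
                  tested = TRUE, reason = NA_character_))
    }
    return(untestable("zero variance with unequal means"))
  }
  ht <- tryCatch(
    t.test(a, b, var.equal = (variant == "student"),
           alternative = "two.sided"),
    error = function(e) NULL
  )
  if (is.null(ht)) return(untestable("degenerate data"))
  list(t_stat = unname(ht$statistic), p_raw = ht$p.value,
       df = unname(ht$parameter), tested = TRUE, reason = NA_character_)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: p values are sorted ascending and
#' `p_adj[(i)] = min over j >= i of m * p[(j)] / j`, capped at 1, returned in
#' the original order. Missing entries stay missing and do not count toward
#' the family size m.
#'
#' @param p raw p values in (0, 1]; NA allowed.
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) {
    abort("p values must lie in (0, 1]")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Differential RP stoichiometry (or abundance) between two groups
#'
#' Per-RP two-tailed t tests between two sample groups, with
#' Benjamini-Hochberg correction across all RPs tested in this comparison.
#' In `"ratio"` mode the input is the stoichiometry barcode from
#' [compute_ribor()] and the test asks whether an RP's share of the ribosome
#' pool differs; in `"level"` mode the input is the RP-filtered intensity
#' table and the test compares absolute abundance. An RP is tested only with
#' at least 2 non-missing values per group. The fold change is
#' `log2(mean_a / mean_b)` of the group arithmetic means in linear space, so
#' `direction = "up"` means higher in `group_a`. Significance is strict:
#' `p_adj < alpha`.
#'
#' @param ratios proteins-by-samples tibble (ratios or, in level mode,
#'   intensities).
#' @param groups sample-to-group mapping (two-column data frame or named
#'   vector).
#' @param group_a,group_b the two group labels to compare; `group_a` is the
#'   numerator of the fold change.
#' @param mode `"ratio"` (default) or `"level"`; recorded in the result.
#' @param alpha significance threshold on the adjusted p value.
#' @param variant t-test variant, `"student"` (default) or `"welch"`.
#' @return A tibble of class `ribor_diff`, one row per RP: `protein`,
#'   `mean_a`, `mean_b`, `log2fc`, `t_stat`, `p_raw`, `p_adj`, `n_a`, `n_b`,
#'   `tested`, `direction` (`"up"`/`"down"`/`"ns"`, NA when untested).
#'   Attributes record the comparison (`groups`, `alpha`, `variant`, `mode`).
#' @export
differential_ratio <- function(ratios, groups, group_a, group_b,
                               mode = c("ratio", "level"), alpha = 0.05,
                               variant = c("student", "welch")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  check_prob(alpha, "alpha")
  gv <- group_vector(ratios, groups)
  for (g in c(group_a, group_b)) {
    if (sum(gv == g) == 0) abort(paste0("group label not found: ", g))
    if (sum(gv == g) < 2) {
      abort(paste0("group '", g, "' has fewer than 2 samples"))
    }
  }
  m <- qt_matrix(ratios)
  ma <- m[, gv == group_a, drop = FALSE]
  mb <- m[, gv == group_b, drop = FALSE]

  rows <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    a <- ma[i, ]
    b <- mb[i, ]
    tt <- two_sample_t(a, b, variant = variant)
    mean_a <- if (sum(!is.na(a)) > 0) mean(a, na.rm = TRUE) else NA_real_
    mean_b <- if (sum(!is.na(b)) > 0) mean(b, na.rm = TRUE) else NA_real_
    tibble(
      protein = rownames(m)[i],
      mean_a = mean_a,
      mean_b = mean_b,
      log2fc = log2(mean_a / mean_b),
      t_stat = tt$t_stat,
      p_raw = tt$p_raw,
      n_a = sum(!is.na(a)),
      n_b = sum(!is.na(b)),
      tested = tt$tested
    )
  })
  if (!any(rows$tested)) abort("no RPs could be tested in this comparison")

  rows$p_adj <- bh_adjust(ifelse(rows$tested, rows$p_raw, NA_real_))
  rows$direction <- dplyr::case_when(
    !rows$tested ~ NA_character_,
    rows$p_adj < alpha & rows$log2fc > 0 ~ "up",
    rows$p_adj < alpha & rows$log2fc < 0 ~ "down",
    TRUE ~ "ns"
  )
  rows <- rows[, c("protein", "mean_a", "mean_b", "log2fc", "t_stat",
                   "p_raw", "p_adj", "n_a", "n_b", "tested", "direction")]
  structure(
    rows,
    class = c("ribor_diff", class(rows)),
    groups = c(a = group_a, b = group_b),
    alpha = alpha, variant = variant, mode = mode
  )
}

#' @rdname differential_ratio
#' @param x a `ribor_diff` table.
#' @param ... unused.
#' @export
glance.ribor_diff <- function(x, ...) {
  tibble(
    n_rp = nrow(x),
    n_tested = sum(x$tested),
    n_up = sum(x$direction == "up", na.rm = TRUE),
    n_down = sum(x$direction == "down", na.rm = TRUE),
    alpha = attr(x, "alpha"),
    variant = attr(x, "variant"),
    mode = attr(x, "mode"),
    group_a = attr(x, "groups")[["a"]],
    group_b = attr(x, "groups")[["b"]]
  )
}

#' Volcano table
#'
#' Plot-ready long table of effect size versus significance for the tested
#' RPs: no thresholding beyond the direction calls already present.
#'
#' @param diff a `ribor_diff` table from [differential_ratio()].
#' @return Tibble with `protein`, `log2fc`, `neg_log10_p_adj`, `direction`.
#' @export
volcano_table <- function(diff) {
  if (nrow(diff) == 0) abort("empty differential table")
  d <- diff[diff$tested, , drop = FALSE]
  tibble(
    protein = d$protein,
    log2fc = d$log2fc,
    neg_log10_p_adj = -log10(d$p_adj),
    direction = d$direction
  )
}
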