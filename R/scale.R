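#' Center and unit-variance scale rows
#'
#' Per-RP standardization across samples, computed on each row's non-missing
#' values: rows are centered and divided by their standard deviation so that
#' every RP contributes equally to PCA and clustering regardless of its
#' absolute share. Rows with fewer than two observations or zero variance
#' carry no usable signal and are dropped with a warning; they are listed in
#' the `scaling_record` attribute of the result.
#'
#' @param x proteins-by-samples tibble (typically ratios from
#'   [compute_ribor()]).
#' @param center subtract the row mean (default `TRUE`).
#' @param unit_variance divide by the row standard deviation (default `TRUE`).
#' @return The scaled tibble, with attributes `scaling` (the transforms
#'   applied) and `scaling_record` (tibble of dropped rows and reasons).
#' @export
scale_rows <- function(x, center = TRUE, unit_variance = TRUE) {
  m <- qt_matrix(x)
  if (nrow(m) == 0) abort("empty table")

  n_obs <- rowSums(!is.na(m))
  row_sd <- apply(m, 1, sd, na.rm = TRUE)
  too_few <- n_obs < 2
  constant <- !too_few & (is.na(row_sd) | row_sd == 0)
  drop <- too_few | constant

  record <- tibble(
    protein = rownames(m)[drop],
    reason = unname(ifelse(too_few[drop], "fewer than 2 observations",
                           "zero variance"))
  )
  if (all(drop)) abort("all rows are constant or too sparse to scale")
  if (any(drop)) {
    warn(paste0(
      "dropping ", sum(drop), " unscalable row(s): ",
      paste(utils::head(rownames(m)[drop], 10), collapse = ", ")
    ))
  }

  m <- m[!drop, , drop = FALSE]
  if (center) m <- m - rowMeans(m, na.rm = TRUE)
  if (unit_variance) m <- m / apply(m, 1, sd, na.rm = TRUE)

  out <- mat_tbl(m, id_name = names(x)[1])
  attr(out, "scaling") <- list(center = center, unit_variance = unit_variance)
  attr(out, "scaling_record") <- record
  out
}
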