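#' Compute the ribosome stoichiometry barcode
#'
#' Converts an RP-filtered intensity table into per-sample stoichiometry
#' ratios: each RP's intensity divided by the summed intensity of all RPs
#' detected in that sample. Because iBAQ intensities are proportional to
#' molar amounts, the ratio vector is the molar composition of the detected
#' ribosomal-protein pool -- a per-sample "barcode" on the simplex. The
#' ratios are scale-free: multiplying a sample's intensities by any positive
#' constant (loading, instrument response) leaves its barcode unchanged.
#'
#' The denominator is recomputed per sample over that sample's detected RPs
#' only. Consequently the ratios of shared RPs shift when detection differs
#' between samples (the usual subcompositional effect of relative data);
#' no pseudocounts and no imputation are applied here.
#'
#' @param rp_quant RP-filtered proteins-by-samples tibble from [filter_rp()].
#' @return A tibble of the same shape with ratios in (0, 1]; per sample, the
#'   non-missing ratios sum to 1.
#' @examples
#' q <- tibble::tibble(protein = c("RPL5", "RPS19"), s1 = c(3, 1))
#' compute_ribor(q)
#' @export
compute_ribor <- function(rp_quant) {
  m <- qt_matrix(rp_quant)
  if (nrow(m) == 0) abort("empty table")
  totals <- colSums(m, na.rm = TRUE)
  none <- colSums(!is.na(m)) == 0
  if (any(none)) {
    abort(paste0(
      "samples with zero detected RPs: ",
      paste(colnames(m)[none], collapse = ", ")
    ))
  }
  ratios <- sweep(m, 2, totals, "/")
  out <- rp_quant
  out[, -1] <- as.data.frame(ratios)
  out
}

#' Per-sample detected-RP counts and QC gate
#'
#' Counts the RPs quantified in each sample and, when a threshold is given,
#' flags samples below it. Single-cell ribosome proteomes are conventionally
#' gated at >50 detected RPs per cell; flagged samples are reported, not
#' removed (see [drop_low_detection()]).
#'
#' @param rp_quant RP-filtered proteins-by-samples tibble.
#' @param threshold optional minimum detected-RP count; adds a `pass` column.
#' @return A tibble with columns `sample`, `n_detected` and (if gated) `pass`.
#' @export
detected_rp_counts <- function(rp_quant, threshold = NULL) {
  m <- qt_matrix(rp_quant)
  out <- tibble(
    sample = colnames(m),
    n_detected = as.integer(colSums(!is.na(m)))
  )
  if (!is.null(threshold)) {
    out$pass <- out$n_detected >= threshold
  }
  out
}

#' Drop samples below a detected-RP threshold
#'
#' @param rp_quant RP-filtered proteins-by-samples tibble.
#' @param threshold minimum detected-RP count a sample must reach.
#' @return The tibble without the failing sample columns; a warning lists
#'   what was dropped.
#' @export
drop_low_detection <- function(rp_quant, threshold) {
  qc <- detected_rp_counts(rp_quant, threshold = threshold)
  fail <- qc$sample[!qc$pass]
  if (length(fail) > 0) {
    warn(paste0(
      "dropping ", length(fail), " sample(s) below ", threshold,
      " detected RPs: ", paste(fail, collapse = ", ")
    ))
  }
  rp_quant[, c(TRUE, !(colnames(rp_quant)[-1] %in% fail)), drop = FALSE]
}
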