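#' Read a protein quantification table
#'
#' Reads a proteins-by-samples intensity matrix from delimited text. Two
#' dialects are supported: `"generic"` (first column gene symbol, remaining
#' columns per-sample intensities; TSV or CSV, auto-detected from the file
#' extension) and `"maxquant"` (a MaxQuant `proteinGroups.txt`: gene symbols
#' from the `Gene names` column, intensities from the `iBAQ <sample>`
#' columns, with reverse-database and contaminant rows dropped).
#'
#' Intensities must be non-negative. Empty cells and `NA` are recorded as
#' missing; by default exact zeros are too, because an iBAQ of zero means
#' "not detected" rather than a measured abundance of zero.
#'
#' @param path file to read.
#' @param format `"auto"` (MaxQuant detected from its header), `"generic"`,
#'   or `"maxquant"`.
#' @param id_column name of the gene-symbol column. Defaults to the first
#'   column (generic) or `"Gene names"` (MaxQuant).
#' @param intensity_prefix column prefix selecting intensity columns in the
#'   MaxQuant dialect; the sample name is the remainder of the column name.
#' @param zeros_as_missing treat exact zeros as missing (default `TRUE`).
#' @param sum_duplicates if several rows map to one gene symbol, sum them
#'   instead of erroring. Off by default: the aggregation is logged when used.
#' @return A tibble whose first column `protein` holds upper-cased gene
#'   symbols and whose remaining columns are per-sample intensities.
#' @export
read_quant_table <- function(path,
                             format = c("auto", "generic", "maxquant"),
                             id_column = NULL,
                             intensity_prefix = "iBAQ ",
                             zeros_as_missing = TRUE,
                             sum_duplicates = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))

  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA", "NaN"), progress = FALSE, show_col_types = FALSE
  )
  if (format == "auto") {
    format <- if (any(startsWith(names(raw), intensity_prefix)) &&
      ("Gene names" %in% names(raw) || !is.null(id_column))) {
      "maxquant"
    } else {
      "generic"
    }
  }

  if (format == "maxquant") {
    id_column <- id_column %||% "Gene names"
    if (!id_column %in% names(raw)) {
      abort(paste0("id column not found: ", id_column))
    }
    flagged <- rep(FALSE, nrow(raw))
    for (fc in intersect(c("Reverse", "Potential contaminant"), names(raw))) {
      flagged <- flagged | (!is.na(raw[[fc]]) & raw[[fc]] == "+")
    }
    if (any(flagged)) {
      inform(paste0(
        "dropped ", sum(flagged), " reverse/contaminant protein groups"
      ))
    }
    raw <- raw[!flagged, , drop = FALSE]
    int_cols <- setdiff(
      names(raw)[startsWith(names(raw), intensity_prefix)],
      trimws(intensity_prefix)
    )
    # "iBAQ peptides" style bookkeeping columns are not per-sample intensities
    int_cols <- int_cols[!grepl("peptides", int_cols, ignore.case = TRUE)]
    if (length(int_cols) == 0) {
      abort(paste0("no intensity columns matching prefix '",
                   intensity_prefix, "'"))
    }
    ids <- raw[[id_column]]
    # protein groups list several gene names separated by ';' -- keep the
    # leading (majority) gene
    ids <- sub(";.*$", "", ids)
    keep <- !is.na(ids) & ids != ""
    raw <- raw[keep, c(id_column, int_cols), drop = FALSE]
    raw[[id_column]] <- ids[keep]
    sample_names <- substring(int_cols, nchar(intensity_prefix) + 1)
    names(raw) <- c("protein", sample_names)
  } else {
    id_column <- id_column %||% names(raw)[1]
    if (!id_column %in% names(raw)) {
      abort(paste0("id column not found: ", id_column))
    }
    int_cols <- setdiff(names(raw), id_column)
    if (length(int_cols) == 0) abort("no intensity columns found")
    raw <- raw[, c(id_column, int_cols), drop = FALSE]
    names(raw)[1] <- "protein"
  }

  out <- raw
  out$protein <- toupper(out$protein)
  for (j in seq_along(out)[-1]) {
    txt <- out[[j]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- !is.na(txt) & is.na(val)
    if (any(bad)) {
      abort(paste0(
        "non-numeric intensity in column '", names(out)[j], "', row ",
        which(bad)[1], ": '", txt[which(bad)[1]], "'"
      ))
    }
    neg <- !is.na(val) & val < 0
    if (any(neg)) {
      abort(paste0(
        "negative intensity in column '", names(out)[j], "', row ",
        which(neg)[1]
      ))
    }
    if (zeros_as_missing) val[!is.na(val) & val == 0] <- NA_real_
    out[[j]] <- val
  }

  dup <- unique(out$protein[duplicated(out$protein)])
  if (length(dup) > 0) {
    if (!sum_duplicates) {
      abort(paste0(
        "duplicate gene symbols: ", paste(dup, collapse = ", "),
        " (use sum_duplicates = TRUE to aggregate)"
      ))
    }
    inform(paste0(
      "summing intensities over duplicated symbols: ",
      paste(dup, collapse = ", ")
    ))
    out <- out |>
      dplyr::group_by(.data$protein) |>
      dplyr::summarise(dplyr::across(
        dplyr::everything(),
        ~ if (all(is.na(.x))) NA_real_ else sum(.x, na.rm = TRUE)
      ), .groups = "drop")
  }

  m <- qt_matrix(out)
  empty <- colnames(m)[colSums(!is.na(m)) == 0]
  if (length(empty) > 0) {
    warn(paste0(
      "samples with no quantified proteins: ", paste(empty, collapse = ", ")
    ))
  }
  out
}

#' Read a sample-to-group metadata table
#'
#' Two-column delimited text (sample id, group label), with or without a
#' header line.
#'
#' @param path file to read.
#' @return A tibble with columns `sample` and `group`.
#' @export
read_sample_groups <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(x) < 2) abort("metadata must have two columns: sample, group")
  # headerless files get their first record parsed as the header; recover it
  if (!all(tolower(names(x)[1:2]) %in% c("sample", "sample_id", "group"))) {
    x <- dplyr::bind_rows(
      setNames(as.list(names(x)[1:2]), c("sample", "group")),
      setNames(x[, 1:2], c("sample", "group"))
    )
  } else {
    x <- setNames(x[, 1:2], c("sample", "group"))
  }
  as_groups_tbl(x)
}

#' Write a quantification or ratio table as TSV
#'
#' Missing values are written as empty cells, so a write/read round trip
#' preserves both the finite values and the missingness pattern.
#'
#' @param x proteins-by-samples tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(path)
}

#' Restrict a quantification table to ribosomal proteins
#'
#' Keeps the proteins that are in the catalog and detected (at least one
#' non-missing intensity) in at least one sample, and reports the resulting
#' RP count. The detected-RP count is dataset-dependent: typical published
#' RP proteomes report 71 to 86 of the catalog.
#'
#' @param quant proteins-by-samples tibble (see [read_quant_table()]).
#' @param catalog RP catalog tibble from [rp_catalog()].
#' @return The filtered tibble; idempotent under re-application.
#' @export
filter_rp <- function(quant, catalog = rp_catalog()) {
  if (nrow(quant) == 0) abort("empty quantification table")
  sym <- toupper(quant$protein)
  in_cat <- sym %in% toupper(catalog$symbol)
  m <- qt_matrix(quant)
  detected <- rowSums(!is.na(m)) > 0
  keep <- in_cat & detected
  if (!any(keep)) abort("no ribosomal proteins found in the table")
  out <- quant[keep, , drop = FALSE]
  out$protein <- toupper(out$protein)
  inform(paste0(sum(keep), " ribosomal proteins detected"))
  out
}
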