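# Built-in catalog of cytosolic ribosomal-protein gene symbols.
#
# The eukaryotic 80S ribosome carries ~80 conserved core RPs; tissue-restricted
# paralogs (RPL10L, RPL39L, RPS4Y1, ...) substitute for core RPs in specific
# contexts. Symbols are HGNC-style upper case; mouse symbols (Rpl10l) match
# after case normalization. UBA52 and FAU are the ubiquitin fusion genes
# encoding RPL40 and RPS30.

.rpl_core <- c(
  "RPL3", "RPL4", "RPL5", "RPL6", "RPL7", "RPL7A", "RPL8", "RPL9",
  "RPL10", "RPL10A", "RPL11", "RPL12", "RPL13", "RPL13A", "RPL14",
  "RPL15", "RPL17", "RPL18", "RPL18A", "RPL19", "RPL21", "RPL22",
  "RPL23", "RPL23A", "RPL24", "RPL26", "RPL27", "RPL27A", "RPL28",
  "RPL29", "RPL30", "RPL31", "RPL32", "RPL34", "RPL35", "RPL35A",
  "RPL36", "RPL36A", "RPL37", "RPL37A", "RPL38", "RPL39", "RPL41",
  "RPLP0", "RPLP1", "RPLP2", "UBA52"
)

.rpl_paralogs <- c(
  "RPL3L", "RPL7L1", "RPL10L", "RPL22L1", "RPL26L1", "RPL36AL", "RPL39L"
)

.rps_core <- c(
  "RPSA", "RPS2", "RPS3", "RPS3A", "RPS4X", "RPS5", "RPS6", "RPS7",
  "RPS8", "RPS9", "RPS10", "RPS11", "RPS12", "RPS13", "RPS14", "RPS15",
  "RPS15A", "RPS16", "RPS17", "RPS18", "RPS19", "RPS20", "RPS21",
  "RPS23", "RPS24", "RPS25", "RPS26", "RPS27", "RPS27A", "RPS28",
  "RPS29", "FAU"
)

.rps_paralogs <- c("RPS4Y1", "RPS4Y2", "RPS27L")

#' Catalog of ribosomal-protein gene symbols
#'
#' Returns the set of recognized cytosolic ribosomal-protein (RP) gene
#' symbols used to restrict a quantification table to the ribosome. The
#' default catalog holds the ~80 conserved core RPs of the eukaryotic 80S
#' ribosome plus known paralogs (e.g. `RPL10L`, `RPL39L`, `RPS27L`).
#' Mitochondrial ribosomal proteins (`MRPL*`/`MRPS*`) are never part of the
#' default catalog. Symbols are matched case-insensitively downstream, so
#' mouse-style symbols (`Rpl10l`) hit the same entries.
#'
#' @param config optional extension: either a path to a JSON file or a list,
#'   with elements `large_subunit` and/or `small_subunit` holding character
#'   vectors of extra symbols to include.
#' @param include_rack1 logical; add RACK1, the 40S-associated scaffold
#'   protein, to the small subunit. Off by default because RACK1 is not one
#'   of the core RPs.
#' @param exclude_mitochondrial logical; when `TRUE` (default) any
#'   `MRPL*`/`MRPS*` symbol (including ones supplied via `config`) is
#'   rejected with an error.
#' @return A tibble with columns `symbol`, `subunit` (`"large"`/`"small"`)
#'   and `paralog` (logical).
#' @examples
#' cat <- rp_catalog()
#' sum(cat$subunit == "large")
#' rp_catalog(config = list(small_subunit = "RACK1"))
#' @export
rp_catalog <- function(config = NULL, include_rack1 = FALSE,
                       exclude_mitochondrial = TRUE) {
  large <- c(.rpl_core, .rpl_paralogs)
  small <- c(.rps_core, .rps_paralogs)
  paralog <- c(
    setNames(rep(FALSE, length(.rpl_core)), .rpl_core),
    setNames(rep(TRUE, length(.rpl_paralogs)), .rpl_paralogs),
    setNames(rep(FALSE, length(.rps_core)), .rps_core),
    setNames(rep(TRUE, length(.rps_paralogs)), .rps_paralogs)
  )

  if (include_rack1) {
    small <- c(small, "RACK1")
    paralog <- c(paralog, RACK1 = FALSE)
  }

  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1) {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
    if (!is.list(config)) {
      abort("`config` must be a list or a path to a JSON file.")
    }
    extra_l <- toupper(as.character(config$large_subunit %||% character()))
    extra_s <- toupper(as.character(config$small_subunit %||% character()))
    both <- intersect(extra_l, extra_s)
    if (length(both) > 0) {
      abort(paste0(
        "symbols assigned to both subunits: ", paste(both, collapse = ", ")
      ))
    }
    large <- union(large, extra_l)
    small <- union(small, extra_s)
    new <- setdiff(c(extra_l, extra_s), names(paralog))
    paralog <- c(paralog, setNames(rep(FALSE, length(new)), new))
  }

  clash <- intersect(large, small)
  if (length(clash) > 0) {
    abort(paste0(
      "symbols assigned to both subunits: ", paste(clash, collapse = ", ")
    ))
  }

  out <- tibble(
    symbol = c(large, small),
    subunit = rep(c("large", "small"), c(length(large), length(small))),
    paralog = unname(paralog[c(large, small)])
  )

  if (exclude_mitochondrial) {
    mito <- grepl("^MRP[LS]", out$symbol)
    if (any(mito)) {
      abort(paste0(
        "mitochondrial RP symbols are excluded from the cytosolic catalog: ",
        paste(out$symbol[mito], collapse = ", "),
        " (set exclude_mitochondrial = FALSE to allow)"
      ))
    }
  }

  out
}

#' Write a catalog to JSON
#'
#' @param catalog a tibble from [rp_catalog()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  obj <- list(
    large_subunit = catalog$symbol[catalog$subunit == "large"],
    small_subunit = catalog$symbol[catalog$subunit == "small"]
  )
  jsonlite::write_json(obj, path, pretty = TRUE)
  invisible(path)
}
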