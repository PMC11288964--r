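#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor var sd qf qchisq pt plogis rlnorm rnorm runif rgamma
#'   p.adjust t.test hclust cutree as.dist prcomp quantile median setNames
#' @importFrom utils head
NULL

# proteins-x-samples tibble (first column = protein ids) -> numeric matrix
qt_matrix <- function(x) {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x[[1]])
  m
}

# numeric matrix -> proteins-x-samples tibble
mat_tbl <- function(m, id_name = "protein") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!id_name := rownames(m)), out)
  out
}

# normalize a sample-group mapping to a tibble(sample, group)
as_groups_tbl <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(ncol(groups) >= 2)
    out <- tibble(
      sample = as.character(groups[[1]]),
      group = as.character(groups[[2]])
    )
  } else if (!is.null(names(groups))) {
    out <- tibble(sample = names(groups), group = as.character(groups))
  } else {
    abort("`groups` must be a two-column data frame or a named vector.")
  }
  if (anyDuplicated(out$sample) > 0) {
    abort("duplicate sample ids in group mapping.")
  }
  out
}

# group labels aligned to the sample columns of a quant/ratio tibble
group_vector <- function(x, groups) {
  gt <- as_groups_tbl(groups)
  samples <- colnames(x)[-1]
  missing <- setdiff(samples, gt$sample)
  if (length(missing) > 0) {
    abort(paste0(
      "samples without a group label: ",
      paste(missing, collapse = ", ")
    ))
  }
  setNames(gt$group[match(samples, gt$sample)], samples)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x >= 1) {
    abort(paste0("`", name, "` must be a single number in (0, 1)."))
  }
  invisible(x)
}
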