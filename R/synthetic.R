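#' Specification for a synthetic RP proteome dataset
#'
#' Defines a ground-truth generative model for iBAQ-like ribosomal-protein
#' quantifications. Each group has a true stoichiometry on the simplex:
#' the baseline composition times the group's planted fold effects,
#' renormalized. A sample from that group is generated as
#' `Dirichlet-resampled composition x total abundance x lognormal
#' measurement noise`, optionally followed by abundance-dependent dropout
#' (detection probability logistic in log10 intensity) and
#' missing-at-random cells. All randomness flows from `seed`.
#'
#' @param n_rp number of ribosomal proteins.
#' @param groups named integer vector of group sizes, e.g.
#'   `c(control = 10, LPS = 38)`.
#' @param baseline baseline stoichiometry: a positive vector of length
#'   `n_rp` (normalized internally), a single Dirichlet concentration from
#'   which a baseline is drawn at generation time, or `NULL` for a
#'   deterministic lognormal-spread composition (`sdlog = 1.2`, spanning the
#'   2-3 orders of magnitude typical of RP iBAQ values).
#' @param planted named list: group label -> named vector of fold changes on
#'   the baseline stoichiometry (all > 0). Groups absent from the list keep
#'   the baseline.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   measurement noise (0 disables it).
#' @param bio_concentration Dirichlet concentration for between-sample
#'   biological variability around the group composition; `Inf` (default)
#'   disables it, smaller values mean noisier compositions.
#' @param total_log10_mean,total_log10_sd per-sample total RP abundance is
#'   `10^rnorm(1, total_log10_mean, total_log10_sd)` (cell size / loading).
#' @param dropout `NULL` (none) or `list(midpoint =, steepness =)`:
#'   detection probability `plogis(steepness * (log10(intensity) -
#'   midpoint))`.
#' @param mar_rate probability that any cell is additionally missing at
#'   random (exercises missing-data paths in bulk designs).
#' @param seed integer seed; same spec + same seed gives a bit-identical
#'   dataset.
#' @param proteins optional symbol vector of length `n_rp`; defaults to
#'   catalog symbols.
#' @return An object of class `ribor_spec`.
#' @export
ribor_spec <- function(n_rp, groups, baseline = NULL, planted = list(),
                       noise_cv = 0.2, bio_concentration = Inf,
                       total_log10_mean = 9, total_log10_sd = 0.15,
                       dropout = NULL, mar_rate = 0, seed = 1,
                       proteins = NULL) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named vector of group sizes")
  }
  if (any(groups < 1)) abort("every group needs at least 1 sample")
  if (is.null(proteins)) {
    planted_syms <- unique(toupper(unlist(lapply(planted, names))))
    pool <- rp_catalog()$symbol
    proteins <- unique(c(planted_syms, pool))[seq_len(n_rp)]
  }
  if (length(proteins) != n_rp || anyDuplicated(proteins) > 0) {
    abort("`proteins` must hold n_rp unique symbols")
  }
  if (is.numeric(baseline) && length(baseline) > 1) {
    if (length(baseline) != n_rp || any(baseline <= 0)) {
      abort("vector `baseline` must be positive and of length n_rp")
    }
    baseline <- baseline / sum(baseline)
  }
  for (g in names(planted)) {
    if (!g %in% names(groups)) {
      abort(paste0("planted effects refer to unknown group: ", g))
    }
    f <- planted[[g]]
    if (any(f <= 0)) abort("fold changes must be > 0")
    if (!all(toupper(names(f)) %in% toupper(proteins))) {
      abort(paste0("planted effects refer to proteins outside the set (",
                   g, ")"))
    }
  }
  if (!is.null(dropout)) {
    stopifnot(is.list(dropout), !is.null(dropout$midpoint),
              !is.null(dropout$steepness))
  }
  stopifnot(noise_cv >= 0, mar_rate >= 0, mar_rate < 1,
            bio_concentration > 0)
  structure(
    list(
      n_rp = as.integer(n_rp), groups = groups, baseline = baseline,
      planted = planted, noise_cv = noise_cv,
      bio_concentration = bio_concentration,
      total_log10_mean = total_log10_mean,
      total_log10_sd = total_log10_sd,
      dropout = dropout, mar_rate = mar_rate,
      seed = as.integer(seed), proteins = proteins
    ),
    class = "ribor_spec"
  )
}

# deterministic lognormal-spread baseline composition
default_baseline <- function(n, sdlog = 1.2) {
  b <- exp(stats::qnorm(stats::ppoints(n), 0, sdlog))
  b / sum(b)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a synthetic RP quantification dataset
#'
#' Draws intensities under the model in [ribor_spec()] and records the
#' ground truth. With `noise_cv = 0`, no planted effects, no biological
#' variability and no dropout, the recovered stoichiometry barcode of every
#' sample equals the baseline exactly.
#'
#' @param spec a `ribor_spec`.
#' @return An object of class `ribor_sim`: list with `quant`
#'   (proteins-by-samples tibble in the generic input dialect), `groups`
#'   (tibble `sample`, `group`), `truth` (tibble `protein`, `group`, `fold`,
#'   `true_ratio`; per-group true stoichiometries sum to 1), and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "ribor_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_rp
    base <- spec$baseline
    if (is.null(base)) {
      base <- default_baseline(n)
    } else if (length(base) == 1) {
      base <- rdirichlet1(rep(base, n))
    }
    names(base) <- spec$proteins

    glabels <- names(spec$groups)
    stoich <- lapply(glabels, function(g) {
      f <- rep(1, n)
      names(f) <- spec$proteins
      pf <- spec$planted[[g]]
      if (!is.null(pf)) {
        f[match(toupper(names(pf)), toupper(spec$proteins))] <- unname(pf)
      }
      s <- base * f
      list(fold = f, ratio = s / sum(s))
    })
    names(stoich) <- glabels

    truth <- purrr::map_dfr(glabels, function(g) {
      tibble(
        protein = spec$proteins, group = g,
        fold = unname(stoich[[g]]$fold),
        true_ratio = unname(stoich[[g]]$ratio)
      )
    })

    sdlog <- if (spec$noise_cv > 0) sqrt(log(1 + spec$noise_cv^2)) else 0
    cols <- list()
    meta <- list()
    for (g in glabels) {
      for (i in seq_len(spec$groups[[g]])) {
        sid <- paste0(g, "_", i)
        w <- if (is.finite(spec$bio_concentration)) {
          rdirichlet1(spec$bio_concentration * stoich[[g]]$ratio)
        } else {
          stoich[[g]]$ratio
        }
        total <- 10^rnorm(1, spec$total_log10_mean, spec$total_log10_sd)
        e <- if (sdlog > 0) rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
        v <- w * total * e
        if (!is.null(spec$dropout)) {
          p_det <- plogis(
            spec$dropout$steepness * (log10(v) - spec$dropout$midpoint)
          )
          v[runif(n) >= p_det] <- NA_real_
        }
        if (spec$mar_rate > 0) {
          v[runif(n) < spec$mar_rate] <- NA_real_
        }
        cols[[sid]] <- v
        meta[[sid]] <- g
      }
    }

    quant <- dplyr::bind_cols(
      tibble(protein = spec$proteins),
      as_tibble(cols)
    )
    groups <- tibble(
      sample = names(meta),
      group = unname(unlist(meta))
    )
    structure(
      list(quant = quant, groups = groups, truth = truth, spec = spec),
      class = "ribor_sim"
    )
  })
}

#' @export
print.ribor_sim <- function(x, ...) {
  cat("synthetic RP dataset: ", x$spec$n_rp, " RPs, ",
      nrow(x$groups), " samples (",
      paste0(names(x$spec$groups), "=", x$spec$groups, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# fold vector planting `up` at fold_up and solving the fold on `down` so the
# planted mass is balanced: sum(baseline * folds) = 1 and unplanted ratios
# are unchanged by renormalization
balanced_folds <- function(baseline, up, down, fold_up) {
  delta <- sum(baseline[up]) * (fold_up - 1)
  fold_down <- 1 - delta / sum(baseline[down])
  if (fold_down <= 0) abort("cannot balance: down-set mass too small")
  c(
    setNames(rep(fold_up, length(up)), up),
    setNames(rep(fold_down, length(down)), down)
  )
}

#' Preset synthetic study designs
#'
#' Ready-made [ribor_spec()]s emulating the structure of published RP
#' ratio-omics study designs: group sizes, detected-RP counts and (for the
#' single-cell preset) detection depth. Planted effect sizes are didactic
#' defaults, not estimates of any real dataset's effects. Planted fold sets
#' are mass-balanced on the simplex so that unplanted RPs have truly
#' unchanged ratios (a well-defined null under compositional closure).
#'
#' * `tissues6` -- six tissues (fat, spleen, liver, kidney, heart, muscle),
#'   n = 3 each, 82 RPs; each tissue gets a distinct block of shifted RPs.
#' * `testis4` -- four developmental stages (d7, d14, d28, adult), n = 3
#'   each, 81 RPs; RPL10L rises stage over stage and RPL39L steps up once,
#'   the known testis paralog pattern.
#' * `neuron2` -- two maturation stages, n = 3 each, 81 RPs; 4 RPs up and
#'   3 down in the mature group.
#' * `gastric_cohort` -- 82 normal vs 58 tumor samples, 86 RPs; 34 RPs up
#'   and 23 down in tumor.
#' * `macrophage_sc` -- single cells, 10 control vs 38 LPS-treated, 71 RPs;
#'   9 RPs up (2-fold) and 9 down (0.5-fold) in LPS, 20% measurement noise,
#'   and abundance-dependent dropout calibrated to a median of ~55 detected
#'   RPs per cell.
#'
#' @param name one of `"tissues6"`, `"testis4"`, `"neuron2"`,
#'   `"gastric_cohort"`, `"macrophage_sc"`.
#' @param seed seed stored in the spec.
#' @return A `ribor_spec`.
#' @export
ribor_preset <- function(name = c("tissues6", "testis4", "neuron2",
                                  "gastric_cohort", "macrophage_sc"),
                         seed = 1) {
  if (is.character(name) && length(name) == 1 &&
      !name %in% c("tissues6", "testis4", "neuron2", "gastric_cohort",
                   "macrophage_sc")) {
    abort(paste0(
      "unknown preset '", name, "'; available: tissues6, testis4, ",
      "neuron2, gastric_cohort, macrophage_sc"
    ))
  }
  name <- match.arg(name)
  pool <- rp_catalog()$symbol

  if (name == "tissues6") {
    n_rp <- 82
    proteins <- pool[seq_len(n_rp)]
    base <- setNames(default_baseline(n_rp), proteins)
    tissues <- c("fat", "spleen", "liver", "kidney", "heart", "muscle")
    planted <- list()
    # each tissue shifts its own block of mid-to-high-abundance RPs
    for (i in seq_along(tissues)) {
      up <- proteins[10 + (12 * (i - 1) + 1):(12 * (i - 1) + 6)]
      down <- proteins[10 + (12 * (i - 1) + 7):(12 * i)]
      planted[[tissues[i]]] <- balanced_folds(base, up, down, 1.8)
    }
    return(ribor_spec(
      n_rp = n_rp, groups = setNames(rep(3L, 6), tissues),
      baseline = unname(base), planted = planted,
      noise_cv = 0.1, bio_concentration = 20000,
      total_log10_mean = 9, total_log10_sd = 0.2,
      mar_rate = 0.01, seed = seed, proteins = proteins
    ))
  }

  if (name == "testis4") {
    n_rp <- 81
    others <- setdiff(pool, c("RPL10L", "RPL39L"))
    proteins <- c("RPL10L", "RPL39L", others[seq_len(n_rp - 2)])
    # the testis paralogs are nearly absent pre-meiotically and switch on
    # during spermatogenesis: tiny baseline share, large stagewise folds
    base <- numeric(n_rp)
    names(base) <- proteins
    base[c("RPL10L", "RPL39L")] <- 5e-4
    base[-(1:2)] <- default_baseline(n_rp - 2) * (1 - 2 * 5e-4)
    down <- names(sort(base, decreasing = TRUE))[1:12] # high-share sink
    stage_folds <- function(f10l, f39l) {
      up <- c(RPL10L = f10l, RPL39L = f39l)
      delta <- sum(base[names(up)] * (up - 1))
      fd <- 1 - delta / sum(base[down])
      c(up, setNames(rep(fd, length(down)), down))
    }
    planted <- list(
      d14 = stage_folds(8, 10),
      d28 = stage_folds(40, 10),
      adult = stage_folds(80, 10)
    )
    return(ribor_spec(
      n_rp = n_rp,
      groups = c(d7 = 3L, d14 = 3L, d28 = 3L, adult = 3L),
      baseline = unname(base), planted = planted,
      noise_cv = 0.1, bio_concentration = 20000,
      total_log10_mean = 9, total_log10_sd = 0.2,
      mar_rate = 0.01, seed = seed, proteins = proteins
    ))
  }

  if (name == "neuron2") {
    n_rp <- 81
    proteins <- pool[seq_len(n_rp)]
    base <- setNames(default_baseline(n_rp), proteins)
    planted <- list(
      DIV15 = balanced_folds(base, proteins[40:43], proteins[75:77], 2.5)
    )
    return(ribor_spec(
      n_rp = n_rp, groups = c(DIV5 = 3L, DIV15 = 3L),
      baseline = unname(base), planted = planted,
      noise_cv = 0.1, bio_concentration = 20000,
      total_log10_mean = 9, total_log10_sd = 0.2,
      mar_rate = 0.01, seed = seed, proteins = proteins
    ))
  }

  if (name == "gastric_cohort") {
    n_rp <- 86
    proteins <- pool[seq_len(n_rp)]
    base <- setNames(default_baseline(n_rp), proteins)
    planted <- list(
      tumor = balanced_folds(base, proteins[20:53], proteins[54:76], 1.6)
    )
    return(ribor_spec(
      n_rp = n_rp, groups = c(normal = 82L, tumor = 58L),
      baseline = unname(base), planted = planted,
      noise_cv = 0.2, bio_concentration = 1500,
      total_log10_mean = 9, total_log10_sd = 0.25,
      mar_rate = 0.02, seed = seed, proteins = proteins
    ))
  }

  # macrophage_sc: exact 2-fold both ways requires the up-set baseline mass
  # to be half the down-set mass (9*0.008 vs 9*0.016)
  n_rp <- 71
  proteins <- pool[seq_len(n_rp)]
  up <- proteins[1:9]
  down <- proteins[10:18]
  rest <- proteins[19:n_rp]
  base <- numeric(n_rp)
  names(base) <- proteins
  base[up] <- 0.008
  base[down] <- 0.016
  base[rest] <- default_baseline(length(rest)) * (1 - 0.072 - 0.144)
  planted <- list(
    LPS = c(setNames(rep(2, 9), up), setNames(rep(0.5, 9), down))
  )
  ribor_spec(
    n_rp = n_rp, groups = c(control = 10L, LPS = 38L),
    baseline = unname(base), planted = planted,
    noise_cv = 0.2, bio_concentration = Inf,
    total_log10_mean = 7, total_log10_sd = 0.25,
    dropout = list(midpoint = 3.9, steepness = 1.5),
    seed = seed, proteins = proteins
  )
}

#' Write a synthetic dataset to disk
#'
#' Emits the quantification table in the generic TSV input dialect of
#' [read_quant_table()], the sample metadata, and the ground-truth table.
#'
#' @param sim a `ribor_sim` from [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ribor_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_quant_table(sim$quant, file.path(dir, "quant.tsv"))
  readr::write_tsv(sim$groups, file.path(dir, "groups.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Recovery metrics against planted ground truth
#'
#' Compares a differential table's direction calls with the planted truth of
#' a synthetic dataset for the same contrast. An RP's planted direction is
#' `up`/`down`/`null` according to the ratio of its planted folds in the two
#' groups. A false positive is any `up`/`down` call whose planted direction
#' is `null` or opposite.
#'
#' @param diff a `ribor_diff` table from [differential_ratio()].
#' @param truth the `truth` tibble of a [generate_dataset()] result.
#' @param group_a,group_b contrast labels; default to the ones recorded in
#'   `diff`.
#' @return One-row tibble: `n_true_up`, `n_true_down`, `tp_up`, `tp_down`,
#'   `sensitivity_up`, `sensitivity_down`, `false_positives`, `n_called`,
#'   `fdp` (NA when nothing was called).
#' @export
evaluate_recovery <- function(diff, truth, group_a = NULL, group_b = NULL) {
  group_a <- group_a %||% attr(diff, "groups")[["a"]]
  group_b <- group_b %||% attr(diff, "groups")[["b"]]
  ta <- truth[truth$group == group_a, c("protein", "fold")]
  tb <- truth[truth$group == group_b, c("protein", "fold")]
  if (nrow(ta) == 0 || nrow(tb) == 0) {
    abort("contrast groups not present in the truth table")
  }
  tt <- dplyr::inner_join(ta, tb, by = "protein", suffix = c("_a", "_b"))
  if (!setequal(tt$protein, diff$protein)) {
    abort("differential table and truth cover different RP sets")
  }
  tt$planted <- dplyr::case_when(
    abs(tt$fold_a / tt$fold_b - 1) < 1e-9 ~ "null",
    tt$fold_a / tt$fold_b > 1 ~ "up",
    TRUE ~ "down"
  )
  d <- dplyr::inner_join(
    diff[, c("protein", "direction")], tt[, c("protein", "planted")],
    by = "protein"
  )
  called <- !is.na(d$direction) & d$direction %in% c("up", "down")
  n_true_up <- sum(d$planted == "up")
  n_true_down <- sum(d$planted == "down")
  tp_up <- sum(called & d$direction == "up" & d$planted == "up")
  tp_down <- sum(called & d$direction == "down" & d$planted == "down")
  fp <- sum(called & d$direction != d$planted)
  n_called <- sum(called)
  tibble(
    n_true_up = n_true_up, n_true_down = n_true_down,
    tp_up = tp_up, tp_down = tp_down,
    sensitivity_up = if (n_true_up > 0) tp_up / n_true_up else NA_real_,
    sensitivity_down = if (n_true_down > 0) tp_down / n_true_down
                       else NA_real_,
    false_positives = fp,
    n_called = n_called,
    fdp = if (n_called > 0) fp / n_called else NA_real_
  )
}
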