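test_that("t statistics match the closed-form pooled and Welch formulas", {
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6), variant = "student")
  want <- student_t_closed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t_stat, want$t, tolerance = 1e-10)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_raw, want$p, tolerance = 1e-10)
  expect_equal(tt$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(tt$p_raw, 0.0214, tolerance = 1e-2)

  withr::local_seed(9)
  for (i in 1:25) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 2))
    s <- two_sample_t(a, b, "student")
    w <- two_sample_t(a, b, "welch")
    so <- student_t_closed(a, b)
    wo <- welch_t_closed(a, b)
    expect_equal(s$t_stat, so$t, tolerance = 1e-10)
    expect_equal(s$p_raw, so$p, tolerance = 1e-10)
    expect_equal(w$t_stat, wo$t, tolerance = 1e-10)
    expect_equal(w$df, wo$df, tolerance = 1e-8)
    expect_equal(w$p_raw, wo$p, tolerance = 1e-10)
  }
})

test_that("degenerate variance cases are explicit, never fabricated", {
  same <- two_sample_t(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_raw, 1)

  const_eq <- two_sample_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(const_eq$p_raw, 1)

  const_neq <- two_sample_t(c(1, 1, 1), c(2, 2, 2))
  expect_false(const_neq$tested)
  expect_true(is.na(const_neq$p_raw))

  short <- two_sample_t(1, c(2, 3))
  expect_false(short$tested)
})

test_that("BH adjustment equals brute-force step-up enumeration", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))

  withr::local_seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-15)
  }

  # missing entries stay missing and shrink the family
  p <- c(0.01, NA, 0.04)
  got <- bh_adjust(p)
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], brute_bh(c(0.01, 0.04)))

  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("p_adj dominates p_raw and calls follow strict thresholds", {
  withr::local_seed(31)
  sim <- generate_dataset(ribor_preset("neuron2", seed = 31))
  d <- differential_ratio(compute_ribor(sim$quant), sim$groups,
                          "DIV15", "DIV5")
  expect_true(all(d$p_adj >= d$p_raw - 1e-15, na.rm = TRUE))
  expect_true(all(
    d$direction[which(d$p_adj < 0.05 & d$log2fc > 0)] == "up"
  ))
  expect_true(all(is.na(d$direction[!d$tested])))
})

test_that("an exact null comparison calls nothing", {
  withr::local_seed(17)
  q <- random_quant(10, 3)
  q2 <- dplyr::bind_cols(q, setNames(q[-1], paste0("c", 1:3)))
  g <- tibble::tibble(sample = names(q2)[-1],
                      group = rep(c("a", "b"), each = 3))
  d <- differential_ratio(compute_ribor(q2), g, "a", "b")
  expect_true(all(d$direction[d$tested] == "ns"))
  expect_true(all(d$t_stat[d$tested] == 0))
  expect_true(all(d$p_raw[d$tested] == 1))
})

test_that("significance calls are invariant to within-group permutation", {
  sim <- generate_dataset(ribor_preset("macrophage_sc", seed = 6))
  r <- compute_ribor(sim$quant)
  d1 <- differential_ratio(r, sim$groups, "LPS", "control")
  withr::local_seed(1)
  perm <- c("protein",
            sample(sim$groups$sample[sim$groups$group == "control"]),
            sample(sim$groups$sample[sim$groups$group == "LPS"]))
  d2 <- differential_ratio(r[perm], sim$groups, "LPS", "control")
  expect_equal(d1$p_adj, d2$p_adj[match(d1$protein, d2$protein)])
  expect_identical(d1$direction, d2$direction[match(d1$protein, d2$protein)])
})

test_that("scaling one group's RP cannot jump from up to down without ns", {
  withr::local_seed(23)
  base_a <- rlnorm(5, 0, 0.05)
  base_b <- rlnorm(5, 0, 0.05)
  states <- character(0)
  for (f in c(0.5, 0.7, 0.85, 1, 1.15, 1.4, 2)) {
    tt <- two_sample_t(log(base_a), log(base_b * f))
    call <- if (tt$p_raw < 0.05) {
      if (mean(log(base_a)) > mean(log(base_b * f))) "up" else "down"
    } else {
      "ns"
    }
    states <- c(states, call)
  }
  rl <- rle(states)$values
  for (i in seq_along(rl)[-1]) {
    expect_false(rl[i - 1] == "up" && rl[i] == "down")
  }
})

test_that("volcano table carries effects and boundary semantics", {
  sim <- generate_dataset(ribor_preset("macrophage_sc", seed = 2))
  d <- differential_ratio(compute_ribor(sim$quant), sim$groups,
                          "LPS", "control")
  v <- volcano_table(d)
  expect_equal(nrow(v), sum(d$tested))
  expect_equal(v$neg_log10_p_adj, -log10(d$p_adj[d$tested]))
  # boundary semantics: alpha equal to an observed p_adj -> that RP is ns
  p_star <- min(d$p_adj, na.rm = TRUE)
  d2 <- differential_ratio(compute_ribor(sim$quant), sim$groups,
                           "LPS", "control", alpha = p_star)
  expect_true(all(d2$direction[d2$p_adj == p_star] == "ns"))
})

test_that("group handling errors are informative", {
  sim <- generate_dataset(ribor_preset("neuron2", seed = 1))
  r <- compute_ribor(sim$quant)
  expect_error(differential_ratio(r, sim$groups, "DIV15", "nope"),
               "not found")
  expect_error(differential_ratio(r, sim$groups, "DIV15", "DIV5",
                                  alpha = 0), "alpha")
})

test_that("testis-like planted paralog shift is recovered as up", {
  sim <- generate_dataset(ribor_preset("testis4", seed = 5))
  r <- compute_ribor(sim$quant)
  d <- differential_ratio(r, sim$groups, "d28", "d14")
  expect_equal(d$direction[d$protein == "RPL10L"], "up")
})
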