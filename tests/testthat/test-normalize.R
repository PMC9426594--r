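test_that("interquartile mean matches the sort-and-interpolate oracle", {
  expect_equal(interquartile_mean(rep(5, 6)), 5)
  # Q1 = 2.75, Q3 = 6.25 -> mean of {3, 4, 5, 6}
  expect_equal(interquartile_mean(1:8), 4.5)
  expect_equal(interquartile_mean(1:8 * 10), 45)  # scale equivariance
  expect_error(interquartile_mean(c(1, 2, 3)), "at least 4")
  expect_error(interquartile_mean(c(1, 2, 3, NA)), "at least 4")

  set.seed(42)
  for (i in 1:25) {
    x <- rlnorm(sample(4:40, 1))
    expect_equal(interquartile_mean(x), iqm_oracle(x))
    c <- runif(1, 0.1, 10)
    expect_equal(interquartile_mean(c * x), c * interquartile_mean(x))
  }
})

test_that("edge correction removes a planted ring bias and is idempotent", {
  fmt <- plate_format(rows = 8, cols = 12)
  base <- matrix(100, fmt$rows, fmt$cols)
  ring <- ring_index(row(base), col(base), fmt$rows, fmt$cols)
  biased <- base * ifelse(ring == 0, 1.25, ifelse(ring == 1, 1.10, 1))
  g <- plate_grid(biased, "P1", "c1")

  fixed <- correct_edge_effect(g, max_ring = 1)
  expect_equal(fixed$values, base)  # planted factors exactly undone

  # uniform plates are left alone; correction is idempotent
  gu <- plate_grid(base, "P1", "c1")
  expect_equal(correct_edge_effect(gu)$values, base)
  twice <- correct_edge_effect(fixed, max_ring = 1)
  expect_equal(twice$values, fixed$values, tolerance = 1e-9)
})

test_that("an all-missing ring passes through with a warning", {
  fmt <- plate_format(rows = 8, cols = 12)
  m <- matrix(100, fmt$rows, fmt$cols)
  ring <- ring_index(row(m), col(m), fmt$rows, fmt$cols)
  m[ring == 0] <- NA
  expect_warning(out <- correct_edge_effect(plate_grid(m, "P", "c")),
                 "ring 0")
  expect_equal(out$values, m)
})

test_that("plate normalization is scale-invariant and recovers outliers", {
  fmt <- plate_format(rows = 8, cols = 12)
  layout <- tibble::tibble(
    row = rep(1:8, times = 12), col = rep(1:12, each = 8),
    strain_id = sprintf("s%02d", seq_len(96)))
  vals <- matrix(1000, 8, 12)
  g <- plate_grid(vals, "P1", "c1")
  out <- normalize_plate(g, layout, max_ring = 0)
  expect_equal(out$value, rep(1, 96))

  # one colony at double density stands out; the rest stay at 1
  vals2 <- vals
  vals2[4, 6] <- 2000
  out2 <- normalize_plate(plate_grid(vals2, "P1", "c1"), layout,
                          max_ring = 0)
  expect_equal(out2$value[out2$row == 4 & out2$col == 6], 2,
               tolerance = 1e-6)
  expect_equal(out2$value[!(out2$row == 4 & out2$col == 6)], rep(1, 95),
               tolerance = 1e-6)

  # multiplying the raw plate by 7 changes nothing
  out7 <- normalize_plate(plate_grid(vals2 * 7, "P1", "c1"), layout,
                          max_ring = 0)
  expect_equal(out7$value, out2$value)

  expect_error(
    normalize_plate(g, layout[layout$row < 8, ]), "layout is")
})

test_that("leave-strain-out excludes all technical replicates of a strain", {
  # a strain with many heavy replicate colonies must not inflate its own
  # reference set
  layout <- tibble::tibble(
    row = rep(1:8, times = 12), col = rep(1:12, each = 8),
    strain_id = sprintf("s%02d", rep(1:12, each = 8)))
  layout$strain_id[layout$row %in% 3:4 & layout$col %in% 4:7] <- "heavy"
  vals <- matrix(100, 8, 12)
  vals[cbind(layout$row, layout$col)[layout$strain_id == "heavy", ]] <- 500
  g <- plate_grid(vals, "P1", "c1")
  out <- normalize_plate(g, layout, max_ring = 0, exclude = "strain")
  expect_equal(out$value[out$strain_id == "heavy"], rep(5, 8))
  expect_equal(out$value[out$strain_id != "heavy"], rep(1, 88))
})

test_that("growth summaries report WT-relative mean, sample SD and n", {
  norm <- tibble::tibble(
    plate_id = "P1", condition = "c1", replicate = 1, configuration = 1,
    strain_id = c(rep("WT", 4), rep("mut", 3)),
    norm = c(1, 1, 1, 1, 0.4, 0.5, 0.6))
  s <- summarize_growth(norm)
  mut <- s[s$strain_id == "mut", ]
  expect_equal(mut$growth, 0.5)
  expect_equal(mut$sd, 0.1)  # sample SD, n - 1 denominator
  expect_equal(mut$n, 3L)
  wt <- s[s$strain_id == "WT", ]
  expect_identical(wt$growth, 1)
  expect_equal(wt$n, 4L)
})

test_that("single-replicate strains get NA sd; WT scarcity is an error", {
  norm <- tibble::tibble(
    plate_id = "P1", condition = "c1", replicate = 1, configuration = 1,
    strain_id = c(rep("WT", 3), "solo"),
    norm = c(1, 1.1, 0.9, 0.5))
  s <- summarize_growth(norm)
  expect_true(is.na(s$sd[s$strain_id == "solo"]))
  expect_equal(s$n[s$strain_id == "solo"], 1L)

  bad <- norm[norm$strain_id != "WT", ]
  expect_error(summarize_growth(bad), "WT")
})

test_that("noise-free screens recover true relative fitness exactly", {
  genes <- c("a", "b", "c")
  sf <- tidyr::expand_grid(gene = genes, condition = "c1") |>
    dplyr::mutate(fitness = c(0.9, 0.7, 1.1))
  cfg <- sim_config(genes, "c1", single_fitness = sf,
                    interactions = tibble::tibble(
                      gene_a = "a", gene_b = "b", condition = "c1",
                      epsilon = -0.25),
                    noise_cv = 0, edge_factors = numeric(), seed = 6)
  strains <- make_strains(genes)
  lay <- make_layouts(strains, plate_format(rows = 8, cols = 12),
                      n_replicate_colonies = 4, n_configurations = 1,
                      wt_colonies = 8, seed = 6)
  scr <- simulate_screen(cfg, lay)
  summ <- summarize_growth(normalize_screen(scr$colonies, max_ring = -1,
                                            exclude = "none"))
  truth <- scr$truth$fitness
  m <- dplyr::inner_join(summ, truth, by = c("strain_id", "condition"))
  expect_equal(m$growth, m$fitness, tolerance = 1e-10)
})

test_that("edge and interior replicates of a genotype agree after normalization", {
  # planted ring biases + mild noise; after correction the position of a
  # colony must not matter
  res <- simulate_and_call(genes = 16, conditions = "c1", noise_cv = 0.05,
                           seed = 21)
  col <- normalize_screen(res$screen$colonies)
  fmt <- plate_format(1536)
  col$ring <- ring_index(col$row, col$col, fmt$rows, fmt$cols)
  col <- col[!is.na(col$strain_id), ]
  by_strain <- col |>
    dplyr::mutate(where = ifelse(.data$ring == 0, "edge", "interior")) |>
    dplyr::group_by(.data$strain_id, .data$where) |>
    dplyr::summarise(g = mean(.data$norm), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "where", values_from = c("g", "n"))
  both <- by_strain[!is.na(by_strain$g_edge) & !is.na(by_strain$g_interior), ]
  # systematic residual: per-strain replicate noise averages out over strains,
  # any surviving edge bias does not
  residual <- mean(both$g_edge / both$g_interior - 1)
  expect_lte(abs(residual), 0.02)
})
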