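# Shared fixture builders and independent oracles for the test suite.

# Simulate a full screen (simulate -> normalize -> summarize -> call) on a
# 1,536-density plate set with 4 technical replicate colonies per strain.
simulate_and_call <- function(genes, conditions, interactions = NULL,
                              noise_cv = 0.1, seed = 1,
                              n_configurations = 1, alpha = 0.05,
                              edge_factors = c(1.25, 1.10)) {
  cfg <- sim_config(genes, conditions, interactions = interactions,
                    noise_cv = noise_cv, edge_factors = edge_factors,
                    seed = seed)
  strains <- make_strains(cfg$genes)
  layouts <- make_layouts(strains, plate_format(1536),
                          n_replicate_colonies = 4,
                          n_configurations = n_configurations,
                          wt_colonies = 16, seed = seed)
  screen <- simulate_screen(cfg, layouts)
  summaries <- summarize_growth(normalize_screen(screen$colonies))
  list(screen = screen,
       interactions = call_interactions(summaries, screen$strains,
                                        alpha = alpha))
}

# Minimal classified record set for tally/network fixtures.
fake_records <- function(gene_a, gene_b, condition, class,
                         deviation_ratio, q_value = 0.01) {
  tibble::tibble(
    gene_a = gene_a, gene_b = gene_b,
    strain_id = paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = ":"),
    condition = condition,
    observed = deviation_ratio, observed_sd = 0.05, n_obs = 4L,
    expected = 1, expected_sd = 0.05, n_expected = 4L,
    t_stat = 0, df = 4, p_value = q_value, q_value = q_value,
    deviation_ratio = deviation_ratio, class = class, testable = TRUE)
}

# Exhaustive step-up BH oracle: q_(i) = min_{j >= i} m p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * p[o][i:m] / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# All set partitions of 1..n (recursive), for the brute-force modularity
# oracle on tiny graphs.
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

# Interquartile-mean oracle by explicit sort-and-interpolate percentiles.
iqm_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  interp <- function(prob) {
    h <- (n - 1) * prob + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  }
  q1 <- interp(0.25); q3 <- interp(0.75)
  mean(x[x >= q1 & x <= q3])
}

# One acceptance-scale screen: 20 genes, 4 conditions, 4 replicate
# colonies, CV 10%, optionally planting interactions on a fraction of the
# (pair, condition) combinations. Returns per-record calls joined with the
# planted truth plus the screen-level false-discovery proportion.
run_acceptance_screen <- function(seed, planted_frac = 0, magnitudes = 0.5) {
  genes <- sprintf("g%02d", 1:20)
  conds <- sprintf("c%d", 1:4)
  pairs <- enumerate_pairs(genes)
  ints <- NULL
  if (planted_frac > 0) {
    ints <- withr::with_seed(seed + 1L, dplyr::bind_rows(
      lapply(conds, function(cc) {
        idx <- sample.int(nrow(pairs), round(planted_frac * nrow(pairs)))
        tibble::tibble(
          gene_a = pairs$gene_a[idx], gene_b = pairs$gene_b[idx],
          condition = cc,
          epsilon = sample(c(-1, 1), length(idx), TRUE) *
            sample(magnitudes, length(idx), TRUE))
      })))
  }
  cfg <- sim_config(genes, conds, interactions = ints, noise_cv = 0.1,
                    seed = seed)
  strains <- make_strains(genes)
  lay <- make_layouts(strains, plate_format(1536), n_replicate_colonies = 4,
                      n_configurations = 1, wt_colonies = 16, seed = seed)
  scr <- simulate_screen(cfg, lay)
  summ <- summarize_growth(normalize_screen(scr$colonies))
  rec <- tidy(call_interactions(summ, scr$strains))
  truth <- scr$truth$interactions
  key <- paste(truth$gene_a, truth$gene_b, truth$condition)
  rec$true_eps <- truth$epsilon[
    match(paste(rec$gene_a, rec$gene_b, rec$condition), key)]
  sig <- rec$class != "none"
  rec$correct_call <- sig &
    ((rec$true_eps < 0 & rec$class == "enhancing") |
       (rec$true_eps > 0 & rec$class == "suppressing"))
  list(records = rec,
       fdp = sum(sig & rec$true_eps == 0) / max(1, sum(sig)))
}
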