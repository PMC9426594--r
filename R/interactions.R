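#' Expected double-mutant growth under the multiplicative rule
#'
#' The null expectation for a double mutant's relative growth is the
#' product of the two single mutants' relative growths: absent any genetic
#' interaction, fitness defects combine independently.
#'
#' @param growth_a,growth_b Single-mutant normalized growths (>= 0;
#'   vectorized).
#' @return `growth_a * growth_b`.
#' @examples
#' expected_growth(0.8, 0.5)  # 0.4
#' @export
expected_growth <- function(growth_a, growth_b) {
  if (any(growth_a < 0, na.rm = TRUE) || any(growth_b < 0, na.rm = TRUE)) {
    abort("growth values must be >= 0")
  }
  growth_a * growth_b
}

#' Propagated standard deviation of the expected growth
#'
#' First-order propagation of errors for a product of two independent
#' measurements: the relative variances add, so
#' `sigma = |g_a * g_b| * sqrt((sd_a/g_a)^2 + (sd_b/g_b)^2)`.
#' Symmetric in the two mutants. A zero growth with a nonzero sd has no
#' defined relative error and is an error; zero growth with zero sd
#' propagates to 0.
#'
#' @param growth_a,sd_a Mean and standard deviation of the first single
#'   mutant's growth.
#' @param growth_b,sd_b Same for the second single mutant.
#' @return The propagated standard deviation (vectorized).
#' @examples
#' propagated_sigma(0.8, 0.1, 0.5, 0.05)  # 0.4 * sqrt(0.125^2 + 0.1^2)
#' @export
propagated_sigma <- function(growth_a, sd_a, growth_b, sd_b) {
  if (any(sd_a < 0, na.rm = TRUE) || any(sd_b < 0, na.rm = TRUE)) {
    abort("standard deviations must be >= 0")
  }
  bad <- (growth_a == 0 & sd_a > 0) | (growth_b == 0 & sd_b > 0)
  if (any(bad, na.rm = TRUE)) {
    abort("zero growth with nonzero sd: relative error undefined")
  }
  out <- abs(growth_a * growth_b) *
    sqrt((sd_a / growth_a)^2 + (sd_b / growth_b)^2)
  # zero growth with zero sd: 0 * sqrt(NaN) -> define as 0
  out[(growth_a == 0 & sd_a == 0) | (growth_b == 0 & sd_b == 0)] <- 0
  out
}

#' Welch's t-test from summary statistics
#'
#' Two-sample t-test without the equal-variance assumption, computed from
#' means, standard deviations and sample sizes, with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. Used to compare observed
#' double-mutant growth against the multiplicative expectation (whose
#' "sample" is the propagated sigma with a conservative effective n).
#'
#' @param mean1,sd1,n1 First sample's mean, sd, size (n >= 2).
#' @param mean2,sd2,n2 Second sample's mean, sd, size.
#' @return A tibble with columns `t`, `df`, `p` (vectorized over inputs).
#'   When both sds are 0: equal means give `t = 0, p = 1`; unequal means
#'   give an infinite `t` with `p = 0`.
#' @examples
#' welch_test(0.5, 0.05, 4, 0.4, 0.064, 3)
#' @export
welch_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(n1, n2) < 2, na.rm = TRUE)) abort("sample sizes must be >= 2")
  if (any(c(sd1, sd2) < 0, na.rm = TRUE)) abort("sds must be >= 0")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  degenerate <- is.finite(mean1) & is.finite(mean2) & se2 == 0
  t[degenerate] <- ifelse(mean1[degenerate] == mean2[degenerate], 0,
                          sign(mean1[degenerate] - mean2[degenerate]) * Inf)
  df[degenerate] <- n1[degenerate] + n2[degenerate] - 2
  p[degenerate] <- ifelse(t[degenerate] == 0, 1, 0)
  tibble(t = t, df = df, p = p)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_(j >= i) (m * p_(j) / j)`, clipped at 1, returned in the
#' input order. Missing entries are excluded from the family and returned
#' as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Score genetic interactions for every double mutant
#'
#' The screen's statistical engine. For each double mutant x condition it
#' computes the multiplicative expectation from the two single-mutant
#' growths, the propagated sigma of that expectation, a Welch test of the
#' observed replicates against the expectation, Benjamini-Hochberg
#' q-values over the whole record family (all pairs x conditions jointly),
#' the deviation ratio `observed / expected`, and an interaction class:
#' `"enhancing"` when growth is significantly below expectation,
#' `"suppressing"` when significantly above, `"none"` otherwise.
#'
#' Records that cannot be tested (a missing single mutant, fewer than 2
#' replicates on either side, or a zero/degenerate expectation) are
#' emitted with `testable = FALSE` and are excluded from the BH family
#' rather than being assigned `p = 1`.
#'
#' @param summaries Growth-summary tibble from [summarize_growth()]
#'   (`strain_id`, `condition`, `growth`, `sd`, `n`).
#' @param genotypes Strain table from [make_strains()] mapping
#'   `strain_id` to deleted genes.
#' @param alpha Significance threshold on the q-value (`q <= alpha`).
#'   Default 0.05.
#' @param n_expected Effective sample size attributed to the propagated
#'   expectation in the Welch test: `"min"` (default, conservative
#'   `min(n_a, n_b)`) or `"mean"`.
#' @return An object of class `sga_interactions`; use [tidy()] for the
#'   per-record tibble and [glance()] for the one-row summary. Records
#'   carry `gene_a`, `gene_b`, `strain_id`, `condition`, `observed`,
#'   `observed_sd`, `n_obs`, `expected`, `expected_sd`, `n_expected`,
#'   `t_stat`, `df`, `p_value`, `q_value`, `deviation_ratio`, `class`,
#'   `testable`.
#' @export
call_interactions <- function(summaries, genotypes, alpha = 0.05,
                              n_expected = c("min", "mean")) {
  n_expected <- match.arg(n_expected)
  gt <- as_tibble(genotypes)
  doubles <- gt[gt$n_deleted == 2L, ]
  if (nrow(doubles) == 0) abort("no double-deletion strains in `genotypes`")
  singles <- gt[gt$n_deleted == 1L, ]

  skey <- function(strain, cond) paste(strain, cond, sep = "\r")
  sm <- as_tibble(summaries)
  lookup <- function(strain, cond, what) {
    sm[[what]][match(skey(strain, cond), skey(sm$strain_id, sm$condition))]
  }

  rec <- tidyr::expand_grid(strain_id = doubles$strain_id,
                            condition = unique(sm$condition)) |>
    dplyr::left_join(doubles[c("strain_id", "gene_a", "gene_b")],
                     by = "strain_id")
  # single-mutant strain ids are the gene names themselves
  single_id <- function(gene) {
    singles$strain_id[match(gene, singles$gene_a)]
  }
  rec <- rec |>
    dplyr::mutate(
      observed = lookup(.data$strain_id, .data$condition, "growth"),
      observed_sd = lookup(.data$strain_id, .data$condition, "sd"),
      n_obs = dplyr::coalesce(
        lookup(.data$strain_id, .data$condition, "n"), 0L),
      growth_a = lookup(single_id(.data$gene_a), .data$condition, "growth"),
      sd_a = lookup(single_id(.data$gene_a), .data$condition, "sd"),
      n_a = lookup(single_id(.data$gene_a), .data$condition, "n"),
      growth_b = lookup(single_id(.data$gene_b), .data$condition, "growth"),
      sd_b = lookup(single_id(.data$gene_b), .data$condition, "sd"),
      n_b = lookup(single_id(.data$gene_b), .data$condition, "n")
    ) |>
    # only pairs actually present in the screen summaries produce records
    dplyr::filter(skey(.data$strain_id, .data$condition) %in%
                    skey(sm$strain_id, sm$condition))

  testable <- with(rec,
    !is.na(observed) & n_obs >= 2 & !is.na(observed_sd) &
      !is.na(growth_a) & !is.na(growth_b) &
      !is.na(sd_a) & !is.na(sd_b) &
      !is.na(n_a) & n_a >= 2 & !is.na(n_b) & n_b >= 2 &
      growth_a > 0 & growth_b > 0)

  rec$expected <- NA_real_
  rec$expected_sd <- NA_real_
  rec$n_expected <- NA_integer_
  rec$t_stat <- NA_real_
  rec$df <- NA_real_
  rec$p_value <- NA_real_

  if (any(testable)) {
    tt <- rec[testable, ]
    exp_g <- expected_growth(tt$growth_a, tt$growth_b)
    exp_sd <- propagated_sigma(tt$growth_a, tt$sd_a, tt$growth_b, tt$sd_b)
    n_exp <- switch(n_expected,
                    min = pmin(tt$n_a, tt$n_b),
                    mean = as.integer(round((tt$n_a + tt$n_b) / 2)))
    w <- welch_test(tt$observed, tt$observed_sd, tt$n_obs,
                    exp_g, exp_sd, n_exp)
    rec$expected[testable] <- exp_g
    rec$expected_sd[testable] <- exp_sd
    rec$n_expected[testable] <- as.integer(n_exp)
    rec$t_stat[testable] <- w$t
    rec$df[testable] <- w$df
    rec$p_value[testable] <- w$p
  }
  # untestable pairs still get the point expectation where it exists
  pt_exp <- !testable & !is.na(rec$growth_a) & !is.na(rec$growth_b)
  rec$expected[pt_exp] <- rec$growth_a[pt_exp] * rec$growth_b[pt_exp]

  rec$q_value <- bh_adjust(rec$p_value)
  rec$deviation_ratio <- ifelse(rec$expected > 0,
                                rec$observed / rec$expected, NA_real_)
  sig <- !is.na(rec$q_value) & rec$q_value <= alpha
  rec$class <- dplyr::case_when(
    sig & rec$observed < rec$expected ~ "enhancing",
    sig & rec$observed > rec$expected ~ "suppressing",
    .default = "none")
  rec$testable <- testable

  keep <- c("gene_a", "gene_b", "strain_id", "condition",
            "observed", "observed_sd", "n_obs",
            "growth_a", "sd_a", "n_a", "growth_b", "sd_b", "n_b",
            "expected", "expected_sd", "n_expected",
            "t_stat", "df", "p_value", "q_value",
            "deviation_ratio", "class", "testable")
  structure(
    list(records = rec[keep], alpha = alpha, n_expected_rule = n_expected),
    class = "sga_interactions"
  )
}

#' @export
print.sga_interactions <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<sga_interactions> %d records (%d testable); %d significant at q <= %g (%d enhancing, %d suppressing)\n",
    g$n_records, g$n_tested, g$n_significant, x$alpha,
    g$n_enhancing, g$n_suppressing))
  invisible(x)
}

#' Tidy the per-record interaction table
#'
#' @param x An `sga_interactions` object.
#' @param ... Unused.
#' @return The records tibble (one row per pair x condition).
#' @method tidy sga_interactions
#' @export
tidy.sga_interactions <- function(x, ...) x$records

#' One-row summary of an interaction scan
#'
#' @param x An `sga_interactions` object.
#' @param ... Unused.
#' @return A one-row tibble: record/tested/significant counts, class
#'   counts, proportion significant, `alpha`.
#' @method glance sga_interactions
#' @export
glance.sga_interactions <- function(x, ...) {
  r <- x$records
  n_sig <- sum(r$class != "none")
  tibble(
    n_records = nrow(r),
    n_tested = sum(r$testable),
    n_significant = n_sig,
    prop_significant = n_sig / max(1, sum(r$testable)),
    n_enhancing = sum(r$class == "enhancing"),
    n_suppressing = sum(r$class == "suppressing"),
    alpha = x$alpha
  )
}

#' Write / read an interaction record TSV
#'
#' @param interactions An `sga_interactions` object (or its [tidy()]
#'   tibble).
#' @param path File path.
#' @return `read_interaction_records()` returns the records tibble.
#' @export
write_interaction_records <- function(interactions, path) {
  rec <- if (inherits(interactions, "sga_interactions")) {
    tidy(interactions)
  } else {
    interactions
  }
  readr::write_tsv(rec, path, na = "NA")
  invisible(path)
}

#' @rdname write_interaction_records
#' @export
read_interaction_records <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE)
}
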