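#' Tally classified genetic interactions
#'
#' Summarizes a scored record set the way screening studies report it:
#' overall significant/enhancing/suppressing counts with percentages, the
#' "strong" subset deviating from expectation by more than a cutoff
#' (default 20%), the "severe" enhancers with observed/expected below a
#' ratio (default 0.4), per-gene interaction counts (a record counts once
#' for each of its two genes) with their mean and median, per-condition
#' counts, and a deviation-ratio histogram.
#'
#' @param interactions An `sga_interactions` object or its [tidy()]
#'   records tibble (classified records).
#' @param strong_cutoff Deviation magnitude `|observed/expected - 1|`
#'   beyond which an interaction counts as strong. Default 0.20.
#' @param severe_ratio `observed/expected` below which a significant
#'   interaction counts as a severe growth defect. Default 0.4.
#' @param binwidth Histogram bin width on the deviation ratio. Default
#'   0.05.
#' @return An object of class `sga_tally`: a list with tibbles `counts`,
#'   `strong`, `severe` (the severe records), `per_gene`, `per_condition`,
#'   `histogram`, and scalars `per_gene_mean`, `per_gene_median`.
#' @export
tally_interactions <- function(interactions, strong_cutoff = 0.20,
                               severe_ratio = 0.4, binwidth = 0.05) {
  rec <- if (inherits(interactions, "sga_interactions")) {
    tidy(interactions)
  } else {
    as_tibble(interactions)
  }
  sig <- rec[rec$class %in% c("enhancing", "suppressing"), ]
  n_meas <- nrow(rec)
  n_sig <- nrow(sig)
  n_enh <- sum(sig$class == "enhancing")
  n_sup <- sum(sig$class == "suppressing")

  dev <- abs(sig$deviation_ratio - 1)
  strong <- sig[!is.na(dev) & dev > strong_cutoff, ]
  severe <- sig[!is.na(sig$deviation_ratio) &
                  sig$deviation_ratio < severe_ratio, ]

  counts <- tibble(
    n_measurements = n_meas,
    n_significant = n_sig,
    pct_significant = 100 * n_sig / max(1, n_meas),
    n_enhancing = n_enh,
    pct_enhancing = 100 * n_enh / max(1, n_sig),
    n_suppressing = n_sup,
    pct_suppressing = 100 * n_sup / max(1, n_sig),
    n_strong = nrow(strong),
    n_strong_enhancing = sum(strong$class == "enhancing"),
    n_strong_suppressing = sum(strong$class == "suppressing"),
    n_severe = nrow(severe)
  )

  per_gene <- tibble(gene = c(sig$gene_a, sig$gene_b)) |>
    dplyr::count(.data$gene, name = "n_interactions") |>
    dplyr::arrange(dplyr::desc(.data$n_interactions), .data$gene)
  per_condition <- sig |>
    dplyr::count(.data$condition, name = "n_interactions") |>
    dplyr::arrange(dplyr::desc(.data$n_interactions), .data$condition)

  histogram <- if (n_sig > 0) {
    d <- sig$deviation_ratio[is.finite(sig$deviation_ratio)]
    breaks <- seq(floor(min(d) / binwidth) * binwidth,
                  ceiling(max(d) / binwidth) * binwidth + binwidth / 2,
                  by = binwidth)
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    tibble(bin_low = h$breaks[-length(h$breaks)],
           bin_high = h$breaks[-1], count = h$counts)
  } else {
    tibble(bin_low = numeric(), bin_high = numeric(), count = integer())
  }

  structure(
    list(counts = counts, strong = strong, severe = severe,
         per_gene = per_gene,
         per_gene_mean = if (nrow(per_gene)) mean(per_gene$n_interactions)
                         else NA_real_,
         per_gene_median = if (nrow(per_gene)) median(per_gene$n_interactions)
                           else NA_real_,
         per_condition = per_condition, histogram = histogram,
         strong_cutoff = strong_cutoff, severe_ratio = severe_ratio),
    class = "sga_tally"
  )
}

#' @export
print.sga_tally <- function(x, ...) {
  c <- x$counts
  cat(sprintf("<sga_tally> %d measurements; %d significant (%.2f%%)\n",
              c$n_measurements, c$n_significant, c$pct_significant))
  cat(sprintf("  enhancing:  %d (%.1f%% of significant)\n",
              c$n_enhancing, c$pct_enhancing))
  cat(sprintf("  suppressing: %d (%.1f%% of significant)\n",
              c$n_suppressing, c$pct_suppressing))
  cat(sprintf("  strong (>%.0f%% deviation): %d (%d enhancing, %d suppressing)\n",
              100 * x$strong_cutoff, c$n_strong, c$n_strong_enhancing,
              c$n_strong_suppressing))
  cat(sprintf("  severe (observed/expected < %.2g): %d\n",
              x$severe_ratio, c$n_severe))
  if (nrow(x$per_gene)) {
    cat(sprintf("  per-gene interactions: mean %.3g, median %.3g\n",
                x$per_gene_mean, x$per_gene_median))
  }
  invisible(x)
}
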