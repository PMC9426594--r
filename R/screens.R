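#' Phenocopy filter over a genome-scale deletion screen
#'
#' Identifies deletion strains whose growth is impaired (more than `z`
#' standard deviations below the per-condition mean over all strains)
#' under every test condition but not under the control condition --
#' the signature of a strain that phenocopies a query mutant's
#' conditional growth defect. Per-condition impaired sets are returned
#' for Venn-style reporting of partial overlaps.
#'
#' @param table Wide screen table: one row per strain with a `strain_id`
#'   column and one numeric normalized-growth column per condition.
#' @param test_conditions Condition columns in which impairment is
#'   required.
#' @param control_condition Condition column in which impairment vetoes a
#'   hit.
#' @param z Impairment threshold in standard deviations. Default 2.
#' @param trim Trimming fraction for the per-condition mean/SD (0 =
#'   untrimmed). Default 0.
#' @return A list with `hits` (character vector of strain ids, sorted),
#'   `impaired` (long tibble `condition`, `strain_id` of every impaired
#'   strain per condition, control included) and `thresholds` (tibble
#'   `condition`, `mean`, `sd`, `cutoff`).
#' @export
phenocopy_filter <- function(table, test_conditions, control_condition,
                             z = 2, trim = 0) {
  conds <- c(test_conditions, control_condition)
  missing_cond <- setdiff(conds, names(table))
  if (length(missing_cond) > 0) {
    abort(paste0("condition column(s) not in table: ",
                 paste(missing_cond, collapse = ", ")))
  }
  trimmed_sd <- function(x) {
    if (trim > 0) {
      q <- quantile(x, c(trim, 1 - trim), na.rm = TRUE, names = FALSE)
      x <- x[x >= q[1] & x <= q[2]]
    }
    sd(x, na.rm = TRUE)
  }
  thresholds <- purrr::map_dfr(conds, function(cc) {
    x <- table[[cc]]
    m <- mean(x, trim = trim, na.rm = TRUE)
    s <- trimmed_sd(x)
    tibble(condition = cc, mean = m, sd = s, cutoff = m - z * s)
  })
  impaired <- purrr::map_dfr(conds, function(cc) {
    cut <- thresholds$cutoff[thresholds$condition == cc]
    tibble(condition = cc,
           strain_id = table$strain_id[!is.na(table[[cc]]) &
                                         table[[cc]] < cut])
  })
  imp_set <- function(cc) impaired$strain_id[impaired$condition == cc]
  hits <- Reduce(intersect, lapply(test_conditions, imp_set))
  hits <- sort(setdiff(hits, imp_set(control_condition)))
  list(hits = hits, impaired = impaired, thresholds = thresholds)
}

#' Rank suppressor strains from a stress-versus-reference screen
#'
#' Ranks deletion strains by how well they grow under a stress condition,
#' among strains that grow acceptably under the reference condition (so
#' generally sick strains cannot masquerade as suppressors). The default
#' score is the absolute normalized growth under stress; `"ratio"` scores
#' stress growth relative to reference growth.
#'
#' @param table Wide screen table (see [phenocopy_filter()]).
#' @param stress_condition Column with growth under the stress.
#' @param reference_condition Column with growth under the permissive
#'   reference.
#' @param min_reference_growth Reference-growth gate for candidacy.
#'   Default 0.5.
#' @param score `"stress"` (default) or `"ratio"`.
#' @return A tibble `strain_id`, `reference_growth`, `stress_growth`,
#'   `score`, `rank`, sorted by decreasing score with lexicographic
#'   tie-break on `strain_id`.
#' @export
suppressor_rank <- function(table, stress_condition, reference_condition,
                            min_reference_growth = 0.5,
                            score = c("stress", "ratio")) {
  score <- match.arg(score)
  missing_cond <- setdiff(c(stress_condition, reference_condition),
                          names(table))
  if (length(missing_cond) > 0) {
    abort(paste0("condition column(s) not in table: ",
                 paste(missing_cond, collapse = ", ")))
  }
  out <- tibble(
    strain_id = table$strain_id,
    reference_growth = table[[reference_condition]],
    stress_growth = table[[stress_condition]]
  ) |>
    dplyr::filter(!is.na(.data$reference_growth),
                  !is.na(.data$stress_growth),
                  .data$reference_growth >= min_reference_growth) |>
    dplyr::mutate(score = if (score == "stress") .data$stress_growth
                  else .data$stress_growth / .data$reference_growth) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$strain_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}

#' Read / write a wide screen table TSV
#'
#' @param table Wide screen tibble (`strain_id` + one column per
#'   condition).
#' @param path File path.
#' @return `read_screen_table()` returns the tibble.
#' @export
write_screen_table <- function(table, path) {
  readr::write_tsv(table, path, na = "NA")
  invisible(path)
}

#' @rdname write_screen_table
#' @export
read_screen_table <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE)
}
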