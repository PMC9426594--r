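#' Interquartile mean
#'
#' Mean of the sample values lying between the first and third quartiles
#' (inclusive), with quartiles computed by linear interpolation on the
#' sorted sample (the "type 7" convention). A robust estimate of the
#' typical colony size on a plate: resistant to the dead and the jackpot
#' colonies alike, and scale-equivariant (`iqm(c * x) == c * iqm(x)`).
#'
#' @param x Numeric vector; at least 4 finite values required.
#' @return The interquartile mean (a single number).
#' @examples
#' interquartile_mean(1:8)  # Q1 = 2.75, Q3 = 6.25 -> mean(3:6) = 4.5
#' @export
interquartile_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4) abort("need at least 4 finite values")
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  mean(x[x >= q[1] & x <= q[2]])
}

# Per-ring scale factors: interior_median / ring_median for rings
# 0..max_ring, computed from finite values only. A ring with no finite
# values gets factor 1 (pass-through) with a warning.
ring_factors <- function(value, ring, max_ring) {
  interior <- value[ring > max_ring & is.finite(value)]
  if (length(interior) < 10) {
    abort("interior (ring > max_ring) must contain at least 10 finite values")
  }
  med_int <- median(interior)
  vapply(0:max_ring, function(r) {
    v <- value[ring == r & is.finite(value)]
    if (length(v) == 0) {
      warn(sprintf("ring %d has no finite values; left unscaled", r))
      return(1)
    }
    med_int / median(v)
  }, numeric(1))
}

# Vector core of the edge correction, shared by the plate_grid method and
# the screen-level normalizer.
edge_correct_values <- function(value, ring, max_ring) {
  if (max_ring < 0) return(value)
  f <- ring_factors(value, ring, max_ring)
  scale <- rep(1, length(value))
  idx <- ring <= max_ring
  scale[idx] <- f[ring[idx] + 1]
  value * scale
}

#' Correct the plate edge effect
#'
#' Colonies on the border rings of a high-density array grow systematically
#' larger than interior colonies. Each ring `r <= max_ring` is rescaled by
#' `median(interior) / median(ring r)` so that after correction every
#' corrected ring's median matches the interior median. The correction is
#' idempotent on noiseless input and leaves unbiased plates unchanged.
#'
#' @param grid A [plate_grid()].
#' @param max_ring Outermost rings to correct (0-based ring index; `1`
#'   corrects the two border rings). Default 1.
#' @return The corrected [plate_grid()].
#' @export
correct_edge_effect <- function(grid, max_ring = 1) {
  stopifnot(inherits(grid, "plate_grid"))
  v <- grid$values
  ring <- ring_index(row(v), col(v), nrow(v), ncol(v))
  grid$values <- matrix(edge_correct_values(as.vector(v), as.vector(ring),
                                            max_ring),
                        nrow(v), ncol(v))
  grid
}

#' Normalize one plate to dimensionless relative growth
#'
#' Applies the edge-effect correction, then divides each colony by the
#' interquartile mean of the remaining colonies on the plate. With the
#' default `exclude = "strain"` dialect, all technical-replicate colonies
#' of the focal strain are left out of its reference set (so a strain
#' cannot drag its own reference); `exclude = "colony"` leaves out only the
#' colony itself. The output is invariant to any positive rescaling of the
#' raw plate.
#'
#' @param grid A [plate_grid()].
#' @param layout Layout tibble rows for this plate and configuration
#'   (columns `row`, `col`, `strain_id`).
#' @param max_ring Rings corrected for the edge effect; a negative value
#'   disables the correction. Default 1.
#' @param exclude Reference-set dialect: `"strain"` (default, leave out
#'   all colonies of the focal strain), `"colony"` (leave out only the
#'   colony itself), or `"none"` (one shared plate-level reference; makes
#'   normalization an exact common rescaling).
#' @return A tibble with columns `row`, `col`, `strain_id`, `value`
#'   (normalized, dimensionless; `NA` where the colony was missing).
#' @export
normalize_plate <- function(grid, layout, max_ring = 1,
                            exclude = c("strain", "colony", "none")) {
  stopifnot(inherits(grid, "plate_grid"))
  exclude <- match.arg(exclude)
  v <- grid$values
  if (max(layout$row) != nrow(v) || max(layout$col) != ncol(v)) {
    abort(sprintf("layout is %d x %d but grid is %d x %d",
                  max(layout$row), max(layout$col), nrow(v), ncol(v)))
  }
  value <- as.vector(v[cbind(layout$row, layout$col)])
  ring <- ring_index(layout$row, layout$col, nrow(v), ncol(v))
  norm <- normalize_values(value, layout$strain_id, ring, max_ring, exclude)
  tibble(row = layout$row, col = layout$col,
         strain_id = layout$strain_id, value = norm)
}

# Shared normalization core on parallel vectors for one plate.
normalize_values <- function(value, strain_id, ring, max_ring, exclude) {
  value <- edge_correct_values(value, ring, max_ring)
  finite <- is.finite(value)
  if (exclude == "none") {
    return(value / interquartile_mean(value[finite]))
  }
  if (exclude == "colony") {
    ref <- vapply(which(finite), function(i) {
      interquartile_mean(value[finite][-match(i, which(finite))])
    }, numeric(1))
    out <- rep(NA_real_, length(value))
    out[finite] <- value[finite] / ref
    return(out)
  }
  # leave-strain-out: one reference IQM per strain present on the plate
  out <- rep(NA_real_, length(value))
  for (s in unique(strain_id[finite & !is.na(strain_id)])) {
    own <- !is.na(strain_id) & strain_id == s
    ref <- interquartile_mean(value[finite & !own])
    out[own & finite] <- value[own & finite] / ref
  }
  out
}

#' Normalize every plate of a screen
#'
#' Applies [normalize_plate()] to each (plate, condition, replicate,
#' configuration) grid of a long colony table, adding a `norm` column.
#'
#' @param colonies Colony tibble with columns `plate_id`, `condition`,
#'   `replicate`, `configuration`, `row`, `col`, `strain_id`, `value`
#'   (as produced by [simulate_screen()]).
#' @param max_ring Rings corrected for the edge effect. Default 1.
#' @param exclude Reference-set dialect; see [normalize_plate()].
#' @return The input tibble with an additional `norm` column.
#' @export
normalize_screen <- function(colonies, max_ring = 1,
                             exclude = c("strain", "colony", "none")) {
  exclude <- match.arg(exclude)
  key <- paste(colonies$plate_id, colonies$condition,
               colonies$replicate, colonies$configuration, sep = "\r")
  norm <- rep(NA_real_, nrow(colonies))
  for (idx in split(seq_len(nrow(colonies)), key)) {
    rows <- max(colonies$row[idx]); cols <- max(colonies$col[idx])
    ring <- ring_index(colonies$row[idx], colonies$col[idx], rows, cols)
    norm[idx] <- normalize_values(colonies$value[idx],
                                  colonies$strain_id[idx],
                                  ring, max_ring, exclude)
  }
  dplyr::mutate(colonies, norm = norm)
}

#' Summarize normalized growth per strain and condition, relative to WT
#'
#' Divides each normalized replicate by the mean WT value of its scope
#' group (by default, pooled over the plates of the same condition and
#' configuration), then reports the per-strain mean, sample standard
#' deviation (n - 1 denominator) and replicate count. WT growth is 1 by
#' construction. Strains with a single replicate get `sd = NA`; strains
#' with no finite replicates are emitted with `n = 0` and flagged
#' untestable rather than dropped.
#'
#' @param normalized Output of [normalize_screen()] (needs `strain_id`,
#'   `condition`, `configuration`, `norm`).
#' @param wt_id Wild-type strain id. Default `"WT"`.
#' @param wt_scope Pooling scope for the WT reference mean:
#'   `"condition_configuration"` (default), `"condition"`, or `"plate"`.
#' @return A growth-summary tibble: `strain_id`, `condition`, `growth`,
#'   `sd`, `n`.
#' @export
summarize_growth <- function(normalized, wt_id = "WT",
                             wt_scope = c("condition_configuration",
                                          "condition", "plate")) {
  wt_scope <- match.arg(wt_scope)
  scope_cols <- switch(wt_scope,
    condition_configuration = c("condition", "configuration"),
    condition = "condition",
    plate = c("condition", "configuration", "replicate", "plate_id"))
  d <- dplyr::filter(normalized, !is.na(.data$strain_id))
  wt <- d |>
    dplyr::filter(.data$strain_id == wt_id, is.finite(.data$norm)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(scope_cols))) |>
    dplyr::summarise(wt_mean = mean(.data$norm), wt_n = dplyr::n(),
                     .groups = "drop")
  if (nrow(wt) == 0 || any(wt$wt_n < 2)) {
    abort(sprintf("WT strain '%s' needs >= 2 replicates in every scope group",
                  wt_id))
  }
  missing_scope <- dplyr::anti_join(
    dplyr::distinct(d, dplyr::across(dplyr::all_of(scope_cols))), wt,
    by = scope_cols)
  if (nrow(missing_scope) > 0) {
    abort(sprintf("WT strain '%s' absent from %d scope group(s)",
                  wt_id, nrow(missing_scope)))
  }
  out <- d |>
    dplyr::left_join(wt, by = scope_cols) |>
    dplyr::mutate(rel = .data$norm / .data$wt_mean) |>
    dplyr::group_by(.data$strain_id, .data$condition) |>
    dplyr::summarise(
      growth = mean(.data$rel[is.finite(.data$rel)]),
      sd = sd(.data$rel[is.finite(.data$rel)]),
      n = sum(is.finite(.data$rel)), .groups = "drop") |>
    dplyr::mutate(growth = ifelse(.data$n == 0, NA_real_, .data$growth),
                  growth = ifelse(.data$strain_id == wt_id, 1, .data$growth))
  out
}
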