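#' Plate grid objects
#'
#' A `plate_grid` couples a rows x cols matrix of colony integrated
#' densities (arbitrary units, `NA` = missing colony) with the plate
#' metadata needed downstream: plate id, growth condition, replicate and
#' spatial configuration.
#'
#' @param values Numeric matrix of integrated densities; `NA` marks a
#'   missing/empty position (never silently zero).
#' @param plate_id,condition Metadata labels.
#' @param replicate,configuration Integer metadata labels.
#' @return An object of class `plate_grid`.
#' @examples
#' g <- plate_grid(matrix(100, 4, 6), "P1", "glucose")
#' @export
plate_grid <- function(values, plate_id, condition,
                       replicate = 1L, configuration = 1L) {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("`values` must be a numeric matrix")
  if (any(values < 0, na.rm = TRUE)) abort("densities must be >= 0")
  dimnames(values) <- NULL
  structure(
    list(values = values, plate_id = as.character(plate_id),
         condition = as.character(condition),
         replicate = as.integer(replicate),
         configuration = as.integer(configuration)),
    class = "plate_grid"
  )
}

#' @export
print.plate_grid <- function(x, ...) {
  cat(sprintf(
    "<plate_grid> %s | %s | replicate %d | configuration %d | %d x %d (%d missing)\n",
    x$plate_id, x$condition, x$replicate, x$configuration,
    nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @method as_tibble plate_grid
#' @export
as_tibble.plate_grid <- function(x, ...) {
  tibble(
    plate_id = x$plate_id, condition = x$condition,
    replicate = x$replicate, configuration = x$configuration,
    row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Split screen colony measurements into plate grids
#'
#' @param colonies Colony tibble, e.g. `simulate_screen(...)$colonies`.
#' @return A list of [plate_grid()] objects, one per
#'   (plate, condition, replicate, configuration).
#' @export
as_plate_grids <- function(colonies) {
  key <- paste(colonies$plate_id, colonies$condition,
               colonies$replicate, colonies$configuration, sep = "\r")
  lapply(split(colonies, key), function(d) {
    m <- matrix(NA_real_, max(d$row), max(d$col))
    m[cbind(d$row, d$col)] <- d$value
    plate_grid(m, d$plate_id[1], d$condition[1], d$replicate[1],
               d$configuration[1])
  }) |> unname()
}

#' Write / read a plate grid TSV
#'
#' The on-disk dialect is a plain TSV numeric matrix preceded by `#`-prefixed
#' metadata header lines (`plate_id`, `condition`, `replicate`,
#' `configuration`, `rows`, `cols`). The first column holds row indices and
#' the header row holds column indices; missing colonies are written as
#' `NA`. Write-then-read round-trips values and metadata exactly.
#'
#' @param grid A [plate_grid()].
#' @param path File path.
#' @return `read_plate_grid()` returns a [plate_grid()];
#'   `write_plate_grid()` returns `path` invisibly.
#' @export
write_plate_grid <- function(grid, path) {
  stopifnot(inherits(grid, "plate_grid"))
  v <- grid$values
  meta <- c(plate_id = grid$plate_id, condition = grid$condition,
            replicate = grid$replicate, configuration = grid$configuration,
            rows = nrow(v), cols = ncol(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  writeLines(paste(c("row", seq_len(ncol(v))), collapse = "\t"), con)
  body <- apply(format(v, trim = TRUE, digits = 15), 1, paste,
                collapse = "\t")
  writeLines(paste(seq_len(nrow(v)), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_plate_grid
#' @export
read_plate_grid <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_raw <- lines[is_meta]
  m <- regmatches(meta_raw, regexec("^#\\s*([^:]+):\\s*(.*)$", meta_raw))
  meta <- setNames(vapply(m, `[`, character(1), 3),
                   trimws(vapply(m, `[`, character(1), 2)))
  need <- c("plate_id", "condition", "replicate", "configuration",
            "rows", "cols")
  missing_meta <- setdiff(need, names(meta))
  if (length(missing_meta) > 0) {
    abort(paste0(path, ": missing metadata line(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  nrows <- as.integer(meta["rows"]); ncols <- as.integer(meta["cols"])

  body <- lines[!is_meta]
  body <- body[nzchar(body)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(header) != ncols + 1) {
    abort(sprintf("%s: expected %d columns but header has %d",
                  path, ncols, length(header) - 1))
  }
  rows <- body[-1]
  if (length(rows) != nrows) {
    abort(sprintf("%s: expected %d rows but found %d",
                  path, nrows, length(rows)))
  }
  vals <- matrix(NA_real_, nrows, ncols)
  for (i in seq_along(rows)) {
    fields <- strsplit(rows[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != ncols + 1) {
      abort(sprintf("%s: row %d has %d cells, expected %d",
                    path, i, length(fields) - 1, ncols))
    }
    x <- suppressWarnings(as.numeric(fields[-1]))
    bad <- which(is.na(x) & fields[-1] != "NA")
    if (length(bad) > 0) {
      abort(sprintf("%s: non-numeric cell at row %d, column %d: '%s'",
                    path, i, bad[1], fields[-1][bad[1]]))
    }
    vals[i, ] <- x
  }
  plate_grid(vals, meta["plate_id"], meta["condition"],
             as.integer(meta["replicate"]), as.integer(meta["configuration"]))
}
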