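#' Plate format presets
#'
#' Describes the geometry of a colony array plate. The two standard
#' high-density formats are 384 (16 x 24) and 1,536 (32 x 48) colonies;
#' arbitrary rectangular formats are accepted via `rows`/`cols`.
#'
#' @param density Total colony count; 384 and 1536 map to the standard
#'   16 x 24 and 32 x 48 geometries. Ignored when `rows` and `cols` are
#'   given.
#' @param rows,cols Explicit geometry (both or neither).
#' @return A list with elements `rows`, `cols` and `density`.
#' @examples
#' plate_format(1536)
#' plate_format(rows = 8, cols = 12)
#' @export
plate_format <- function(density = 1536, rows = NULL, cols = NULL) {
  if (!is.null(rows) || !is.null(cols)) {
    if (is.null(rows) || is.null(cols)) {
      abort("supply both `rows` and `cols`, or neither")
    }
  } else if (density == 384) {
    rows <- 16L; cols <- 24L
  } else if (density == 1536) {
    rows <- 32L; cols <- 48L
  } else {
    abort("no preset for this density; supply `rows` and `cols`")
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1 || cols < 1) abort("`rows` and `cols` must be positive")
  list(rows = rows, cols = cols, density = rows * cols)
}

#' Ring index of plate positions
#'
#' The ring index counts how far a position sits from the plate border:
#' 0 for the outermost ring, 1 for the next, and so on. Border colonies
#' (low ring index) enjoy a systematic growth advantage on high-density
#' arrays; the edge-effect correction is parameterized per ring.
#'
#' @param row,col 1-based position coordinates (vectorized).
#' @param rows,cols Plate geometry.
#' @return Integer vector of ring indices.
#' @examples
#' ring_index(1, 5, 16, 24)   # border -> 0
#' ring_index(3, 10, 16, 24)  # two steps in -> 2
#' @export
ring_index <- function(row, col, rows, cols) {
  pmin(row - 1L, col - 1L, rows - row, cols - col)
}

#' Arrange strains on plates in one or more spatial configurations
#'
#' Randomly assigns strain colonies (plus a fixed number of wild-type
#' reference colonies per plate) to plate positions. When two or more
#' configurations are requested, colonies on the outermost ring of the
#' first configuration are deliberately relocated to interior positions
#' in the later ones, so that edge-effect correction can be validated by
#' comparing configurations: a strain should get the same normalized
#' growth regardless of where it sat on the plate.
#'
#' A strain's technical replicate colonies are kept on the same plate,
#' and plate membership is shared by all configurations (only positions
#' within a plate are permuted).
#'
#' @param strains Strain table, e.g. from [make_strains()]; only
#'   `strain_id` is used, and any row equal to `wt_id` is dropped (WT
#'   reference colonies are placed separately).
#' @param format Plate geometry from [plate_format()].
#' @param n_replicate_colonies Technical replicate colonies per strain per
#'   plate set. Default 1.
#' @param n_configurations Number of alternate spatial arrangements.
#'   Default 2.
#' @param wt_colonies Wild-type reference colonies per plate. Default 16.
#' @param wt_id Wild-type strain id. Default `"WT"`.
#' @param n_plates Number of plates; default (`NULL`) uses the fewest
#'   plates that hold all colonies. An explicit value that is too small is
#'   an error reporting required vs available positions.
#' @param seed Integer seed for reproducible layouts, or `NULL` to use the
#'   current RNG stream.
#' @return A layout tibble with columns `plate_id`, `configuration`,
#'   `row`, `col`, `strain_id` (`NA` for empty positions). Every position
#'   of every plate appears once per configuration.
#' @examples
#' strains <- make_strains(c("a", "b", "c"))
#' make_layouts(strains, plate_format(rows = 4, cols = 6),
#'              n_replicate_colonies = 2, n_configurations = 2,
#'              wt_colonies = 2, seed = 1)
#' @export
make_layouts <- function(strains, format, n_replicate_colonies = 1,
                         n_configurations = 2, wt_colonies = 16,
                         wt_id = "WT", n_plates = NULL, seed = NULL) {
  ids <- setdiff(unique(as.character(strains$strain_id)), wt_id)
  if (length(ids) == 0) abort("no non-WT strains to array")
  if (wt_colonies >= format$density) {
    abort("`wt_colonies` leaves no room for strains on a plate")
  }
  per_plate_free <- format$density - wt_colonies
  n_colonies <- length(ids) * n_replicate_colonies
  need_plates <- ceiling(n_colonies / per_plate_free)
  if (is.null(n_plates)) {
    n_plates <- need_plates
  } else if (n_plates * per_plate_free < n_colonies) {
    abort(sprintf(
      "capacity exceeded: %d colonies required but only %d positions available on %d plate(s)",
      n_colonies, n_plates * per_plate_free, n_plates))
  }

  with_seed_if(seed, {
    # partition strains across plates, keeping a strain's replicates together
    ids <- sample(ids)
    per_plate_strains <- floor(per_plate_free / n_replicate_colonies)
    plate_of <- rep(seq_len(n_plates),
                    each = per_plate_strains, length.out = length(ids))
    pos <- expand.grid(row = seq_len(format$rows), col = seq_len(format$cols))
    ring <- ring_index(pos$row, pos$col, format$rows, format$cols)

    layouts <- vector("list", n_plates)
    for (p in seq_len(n_plates)) {
      colonies <- c(rep(ids[plate_of == p], each = n_replicate_colonies),
                    rep(wt_id, wt_colonies))
      colonies <- c(colonies,
                    rep(NA_character_, format$density - length(colonies)))
      # configuration 1: uniform random placement
      assign1 <- colonies[sample.int(format$density)]
      cfgs <- list(assign1)
      if (n_configurations > 1) {
        edge_idx <- which(ring == 0 & !is.na(assign1))
        for (k in seq_len(n_configurations - 1)) {
          cfgs[[k + 1]] <- reseat_edges(assign1, edge_idx, ring)
        }
      }
      layouts[[p]] <- purrr::imap_dfr(cfgs, function(a, cfg) {
        tibble(plate_id = sprintf("P%d", p), configuration = as.integer(cfg),
               row = as.integer(pos$row), col = as.integer(pos$col),
               strain_id = a)
      })
    }
    dplyr::bind_rows(layouts)
  })
}

# Build a permutation of `assign` in which the colonies at `edge_idx`
# (outermost-ring occupants of the reference arrangement) land on interior
# positions, preferring ring >= 2 so they clear both corrected rings.
reseat_edges <- function(assign, edge_idx, ring) {
  n <- length(assign)
  interior <- which(ring >= 2)
  if (length(interior) < length(edge_idx)) interior <- which(ring >= 1)
  if (length(edge_idx) == 0) {
    return(assign[sample.int(n)])
  }
  new_assign <- rep(NA_character_, n)
  # on tiny plates the interior may not hold every edge colony; move as
  # many as fit and place the rest with the general pool
  k <- min(length(edge_idx), length(interior))
  shuffled <- edge_idx[sample.int(length(edge_idx))]
  target <- interior[sample.int(length(interior), k)]
  new_assign[target] <- assign[shuffled[seq_len(k)]]
  remaining <- assign[-shuffled[seq_len(k)]]
  open <- setdiff(seq_len(n), target)
  new_assign[open[sample.int(length(open))]] <- remaining
  new_assign
}

#' Read or write a plate layout TSV
#'
#' Plain TSV with columns `plate_id`, `configuration`, `row`, `col`,
#' `strain_id`; empty positions carry an empty `strain_id` field.
#'
#' @param layout Layout tibble from [make_layouts()].
#' @param path File path.
#' @return `read_layout()` returns the layout tibble;
#'   `write_layout()` returns `path` invisibly.
#' @export
write_layout <- function(layout, path) {
  readr::write_tsv(layout, path, na = "")
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  readr::read_tsv(
    path, na = "",
    col_types = readr::cols(
      plate_id = readr::col_character(),
      configuration = readr::col_integer(),
      row = readr::col_integer(),
      col = readr::col_integer(),
      strain_id = readr::col_character()
    )
  )
}
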