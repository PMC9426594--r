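#' Enumerate all unordered gene pairs
#'
#' Lists every unordered pair that can be formed from a gene panel, in
#' lexicographic order. For a panel of `n` genes this yields `n(n-1)/2`
#' pairs -- e.g. the 54-gene panel of a typical small-RNA deletion
#' collection gives 1,431 candidate double deletions.
#'
#' @param genes Character vector of unique gene names.
#' @return A tibble with columns `gene_a` and `gene_b`, where
#'   `gene_a < gene_b` within each row and rows are sorted
#'   lexicographically by (`gene_a`, `gene_b`).
#' @examples
#' enumerate_pairs(c("arcZ", "csrC", "dsrA"))
#' @export
enumerate_pairs <- function(genes) {
  genes <- as.character(genes)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene names: ", paste(dup, collapse = ", ")))
  }
  if (length(genes) < 2) {
    return(tibble(gene_a = character(), gene_b = character()))
  }
  genes <- sort(genes)
  idx <- combn(length(genes), 2)
  tibble(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]])
}

# Canonical "a:b" key for an unordered pair (a < b lexicographically).
pair_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = ":")
}

#' Build the strain table for a double-deletion screen
#'
#' Enumerates the wild-type reference, every single-deletion strain, and
#' every double-deletion strain of a gene panel, optionally dropping pairs
#' that are absent from the screened collection (strains that could not be
#' constructed).
#'
#' @param genes Character vector of unique gene names (the deletion panel).
#' @param exclude_pairs Pairs missing from the collection: either a
#'   two-column data frame (`gene_a`, `gene_b`) or a character vector of
#'   `"a:b"` keys. Order within a pair is ignored. Default none.
#' @param wt_id Strain id used for the wild type. Default `"WT"`.
#' @return A tibble with columns `strain_id`, `gene_a`, `gene_b` and
#'   `n_deleted` (0 for WT, 1 for singles, 2 for doubles). Double-strain
#'   ids are `"a:b"` with genes in lexicographic order.
#' @examples
#' make_strains(c("arcZ", "csrC", "dsrA"))
#' @export
make_strains <- function(genes, exclude_pairs = NULL, wt_id = "WT") {
  pairs <- enumerate_pairs(genes)
  if (!is.null(exclude_pairs)) {
    excl <- if (is.data.frame(exclude_pairs)) {
      pair_key(exclude_pairs[[1]], exclude_pairs[[2]])
    } else {
      # already "a:b" strings; canonicalize order
      parts <- strsplit(as.character(exclude_pairs), ":", fixed = TRUE)
      vapply(parts, function(p) pair_key(p[1], p[2]), character(1))
    }
    unknown <- setdiff(excl, pair_key(pairs$gene_a, pairs$gene_b))
    if (length(unknown) > 0) {
      abort(paste0("exclude_pairs not in the panel: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    pairs <- pairs[!pair_key(pairs$gene_a, pairs$gene_b) %in% excl, ]
  }
  genes <- sort(as.character(genes))
  dplyr::bind_rows(
    tibble(strain_id = wt_id, gene_a = NA_character_,
           gene_b = NA_character_, n_deleted = 0L),
    tibble(strain_id = genes, gene_a = genes,
           gene_b = NA_character_, n_deleted = 1L),
    tibble(strain_id = pair_key(pairs$gene_a, pairs$gene_b),
           gene_a = pairs$gene_a, gene_b = pairs$gene_b, n_deleted = 2L)
  )
}
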