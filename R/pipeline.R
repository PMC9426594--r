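#' Run the end-to-end screen analysis pipeline
#'
#' Wires the stages together: (optionally) simulate a colony screen, then
#' normalize plates, summarize growth relative to WT, score genetic
#' interactions, tally them, and build the interaction network with
#' communities and a force-directed layout. All randomness derives from
#' one master seed (sub-seeds are drawn per stage), so identical config +
#' seed reproduces identical outputs byte for byte. Stage artifacts and a
#' run log (resolved config, seed, per-stage counts) are written to
#' `out_dir` when given.
#'
#' @param config A named list or the path of a YAML file. Recognized
#'   keys: `simulation` (arguments of [sim_config()] plus optional
#'   `format_density`, `n_replicate_colonies`, `n_configurations`,
#'   `wt_colonies`), `wt_id`, `wt_scope`, `max_ring`, `exclude`, `alpha`,
#'   `n_expected`, `min_deviation`, `strong_cutoff`, `severe_ratio`,
#'   `resolution`, `seed`. Unknown keys are rejected.
#' @param out_dir Directory for artifacts (`growth_summary.tsv`,
#'   `interaction_records.tsv`, `tally_counts.tsv`, `network.graphml`,
#'   `network_edges.tsv`, `run_log.yaml`), or `NULL` to skip writing.
#' @param seed Master seed; overrides `config$seed` when given.
#' @return (Invisibly) a list with `screen`, `summaries`, `interactions`,
#'   `tally`, `network`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  known <- c("simulation", "wt_id", "wt_scope", "max_ring", "exclude",
             "alpha", "n_expected", "min_deviation", "strong_cutoff",
             "severe_ratio", "resolution", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$wt_id)) abort("config must name `wt_id`")
  if (is.null(config$simulation)) {
    abort("config must contain a `simulation` block")
  }
  seed <- seed %||% config$seed %||% 1L
  get <- function(key, default) config[[key]] %||% default

  # per-stage sub-seeds from the master seed
  sub <- withr::with_seed(as.integer(seed),
                          sample.int(.Machine$integer.max, 3))

  simargs <- config$simulation
  layout_keys <- c("format_density", "n_replicate_colonies",
                   "n_configurations", "wt_colonies")
  lay <- simargs[intersect(layout_keys, names(simargs))]
  simargs <- simargs[setdiff(names(simargs), layout_keys)]
  if (!is.null(simargs$interactions)) {
    simargs$interactions <- as_tibble(
      purrr::map_dfr(simargs$interactions, as_tibble))
  }
  if (!is.null(simargs$single_fitness) && is.list(simargs$single_fitness)) {
    simargs$single_fitness <- as_tibble(
      purrr::map_dfr(simargs$single_fitness, as_tibble))
  }
  cfg <- do.call(sim_config, c(simargs, list(wt_id = config$wt_id,
                                             seed = sub[1])))
  strains <- make_strains(cfg$genes, cfg$exclude_pairs, cfg$wt_id)
  layouts <- make_layouts(
    strains,
    plate_format(lay$format_density %||% 1536),
    n_replicate_colonies = lay$n_replicate_colonies %||% 1,
    n_configurations = lay$n_configurations %||% 2,
    wt_colonies = lay$wt_colonies %||% 16,
    wt_id = cfg$wt_id, seed = sub[2])
  screen <- simulate_screen(cfg, layouts)

  normalized <- normalize_screen(screen$colonies,
                                 max_ring = get("max_ring", 1),
                                 exclude = get("exclude", "strain"))
  summaries <- summarize_growth(normalized, wt_id = config$wt_id,
                                wt_scope = get("wt_scope",
                                               "condition_configuration"))
  ints <- call_interactions(summaries, screen$strains,
                            alpha = get("alpha", 0.05),
                            n_expected = get("n_expected", "min"))
  tl <- tally_interactions(ints,
                           strong_cutoff = get("strong_cutoff", 0.20),
                           severe_ratio = get("severe_ratio", 0.4))
  net <- build_network(ints, genes = cfg$genes,
                       min_deviation = get("min_deviation", 0.15),
                       alpha = get("alpha", 0.05)) |>
    detect_communities(seed = sub[3],
                       resolution = get("resolution", 1)) |>
    layout_network(seed = sub[3])

  log <- list(
    seed = as.integer(seed),
    config = config,
    counts = list(
      plates = length(unique(screen$colonies$plate_id)),
      colonies = sum(!is.na(screen$colonies$strain_id)),
      colonies_missing = sum(is.na(screen$colonies$value) &
                               !is.na(screen$colonies$strain_id)),
      records = nrow(tidy(ints)),
      records_tested = sum(tidy(ints)$testable),
      records_excluded = sum(!tidy(ints)$testable),
      significant = tl$counts$n_significant,
      network_edges = nrow(net$edges)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(summaries, file.path(out_dir, "growth_summary.tsv"))
    write_interaction_records(ints,
                              file.path(out_dir, "interaction_records.tsv"))
    readr::write_tsv(tl$counts, file.path(out_dir, "tally_counts.tsv"))
    readr::write_tsv(tl$per_gene, file.path(out_dir, "tally_per_gene.tsv"))
    readr::write_tsv(tl$per_condition,
                     file.path(out_dir, "tally_per_condition.tsv"))
    export_network(net, file.path(out_dir, "network.graphml"), "graphml")
    export_network(net, file.path(out_dir, "network_edges.tsv"), "tsv")
    yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  }

  invisible(list(screen = screen, summaries = summaries,
                 interactions = ints, tally = tl, network = net, log = log))
}
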