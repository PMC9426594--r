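#' Configure a simulated double-deletion colony screen
#'
#' Collects the fitness model for a synthetic screen: per-gene single-mutant
#' fitness under each condition, planted genetic interactions (multiplicative
#' deviations), spatial edge bias per plate ring, and multiplicative
#' measurement noise. Under the multiplicative null the true relative fitness
#' of a double mutant is the product of the two single-mutant fitnesses; a
#' planted interaction multiplies this by `1 + epsilon` (`epsilon < 0`
#' enhances the growth defect, `epsilon > 0` suppresses it). WT fitness is
#' fixed at 1 under every condition.
#'
#' @param genes Character vector of gene names, or a single integer `n`
#'   to use a default panel `g01 ... gNN`.
#' @param conditions Character vector of condition labels.
#' @param exclude_pairs Pairs absent from the collection (see
#'   [make_strains()]); their plate positions are left empty.
#' @param single_fitness Either a single number applied to every
#'   (gene, condition), or a tibble with columns `gene`, `condition`,
#'   `fitness`. Default 1.
#' @param interactions Planted interactions: tibble with columns `gene_a`,
#'   `gene_b`, `condition`, `epsilon` (`epsilon` in (-1, Inf); pair order
#'   ignored). Default none (`epsilon = 0` everywhere).
#' @param edge_factors Multiplicative growth bias per ring, outermost first;
#'   rings beyond the vector are unbiased. Default `c(1.25, 1.10)`,
#'   mirroring the border growth advantage seen on high-density arrays.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise. `0` gives deterministic output. Default 0.1.
#' @param replicates Independent replicate measurements of each arrangement
#'   (number of plate scans per configuration). Default 1.
#' @param plate_scale Arbitrary-unit scale of raw integrated densities.
#'   Default 1e4.
#' @param wt_id Wild-type strain id. Default `"WT"`.
#' @param seed Integer master seed for the simulation, or `NULL`.
#' @return A `sim_config` list; pass to [simulate_screen()].
#' @examples
#' cfg <- sim_config(genes = 4, conditions = c("glucose", "pyruvate"),
#'                   noise_cv = 0, seed = 1)
#' @export
sim_config <- function(genes, conditions, exclude_pairs = NULL,
                       single_fitness = 1, interactions = NULL,
                       edge_factors = c(1.25, 1.10), noise_cv = 0.1,
                       replicates = 1, plate_scale = 1e4,
                       wt_id = "WT", seed = NULL) {
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- sprintf("g%02d", seq_len(genes))
  }
  conditions <- as.character(conditions)
  if (length(conditions) == 0) abort("at least one condition is required")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0")
  if (any(edge_factors < 0)) abort("`edge_factors` must be >= 0")

  if (is.numeric(single_fitness) && length(single_fitness) == 1) {
    single_fitness <- tidyr::expand_grid(gene = genes, condition = conditions) |>
      dplyr::mutate(fitness = as.numeric(.env$single_fitness))
  }
  single_fitness <- as_tibble(single_fitness)
  if (any(single_fitness$fitness < 0)) abort("fitness must be >= 0")

  if (is.null(interactions)) {
    interactions <- tibble(gene_a = character(), gene_b = character(),
                           condition = character(), epsilon = numeric())
  }
  interactions <- as_tibble(interactions)
  if (nrow(interactions) > 0) {
    if (any(interactions$epsilon <= -1)) abort("`epsilon` must be > -1")
    interactions <- interactions |>
      dplyr::mutate(pair = pair_key(.data$gene_a, .data$gene_b))
    if (anyDuplicated(interactions[c("pair", "condition")])) {
      abort("duplicate (pair, condition) entries in `interactions`")
    }
  } else {
    interactions$pair <- character()
  }

  structure(
    list(genes = genes, conditions = conditions,
         exclude_pairs = exclude_pairs, single_fitness = single_fitness,
         interactions = interactions, edge_factors = edge_factors,
         noise_cv = noise_cv, replicates = as.integer(replicates),
         plate_scale = plate_scale, wt_id = wt_id, seed = seed),
    class = "sim_config"
  )
}

# True relative fitness of every strain under every condition, and the
# per-pair interaction table (epsilon = 0 where nothing was planted).
screen_truth <- function(config, strains) {
  singles <- config$single_fitness
  doubles <- strains[strains$n_deleted == 2L, ]
  pair_eps <- tidyr::expand_grid(
    strain_id = doubles$strain_id, condition = config$conditions) |>
    dplyr::left_join(doubles[c("strain_id", "gene_a", "gene_b")],
                     by = "strain_id") |>
    dplyr::left_join(
      config$interactions[c("pair", "condition", "epsilon")],
      by = c("strain_id" = "pair", "condition")) |>
    dplyr::mutate(epsilon = dplyr::coalesce(.data$epsilon, 0))

  f <- function(gene, condition) {
    m <- match(paste(gene, condition), paste(singles$gene, singles$condition))
    singles$fitness[m]
  }
  fitness <- dplyr::bind_rows(
    tidyr::expand_grid(strain_id = config$wt_id,
                       condition = config$conditions) |>
      dplyr::mutate(fitness = 1),
    tidyr::expand_grid(
      strain_id = strains$strain_id[strains$n_deleted == 1L],
      condition = config$conditions) |>
      dplyr::mutate(fitness = f(.data$strain_id, .data$condition)),
    pair_eps |>
      dplyr::mutate(fitness = f(.data$gene_a, .data$condition) *
                      f(.data$gene_b, .data$condition) *
                      (1 + .data$epsilon)) |>
      dplyr::select("strain_id", "condition", "fitness")
  )
  if (anyNA(fitness$fitness)) {
    bad <- fitness[is.na(fitness$fitness), ][1, ]
    abort(sprintf("no fitness defined for strain '%s' under condition '%s'",
                  bad$strain_id, bad$condition))
  }
  list(fitness = fitness,
       interactions = pair_eps[c("gene_a", "gene_b", "condition", "epsilon")])
}

#' Simulate a colony-array screen with known ground truth
#'
#' Generates raw integrated-density measurements for every plate position
#' of every (condition, configuration, replicate) combination. The
#' measurement model is
#' `plate_scale * edge_factor(ring) * fitness(strain, condition) * noise`,
#' with independent multiplicative lognormal noise whose coefficient of
#' variation is `noise_cv` (mean 1, so noise-free values are unbiased).
#' With `noise_cv = 0` and unit edge factors the grid equals
#' `plate_scale * fitness` exactly.
#'
#' @param config A [sim_config()] object.
#' @param layouts Layout tibble from [make_layouts()]; if `NULL`, a
#'   default layout is generated (1,536-density plates, 1 technical
#'   replicate colony per strain, 2 configurations).
#' @return An object of class `sga_screen`: a list with
#'   \describe{
#'     \item{colonies}{tibble of raw measurements: `plate_id`, `condition`,
#'       `replicate`, `configuration`, `row`, `col`, `strain_id`, `value`
#'       (`NA` strain/value for empty positions).}
#'     \item{truth}{list with `fitness` (strain x condition true relative
#'       fitness) and `interactions` (pair x condition true `epsilon`,
#'       0 for non-planted pairs).}
#'     \item{strains}{the strain genotype table.}
#'   }
#' @examples
#' cfg <- sim_config(genes = 3, conditions = "glucose", noise_cv = 0,
#'                   edge_factors = numeric(), seed = 1)
#' scr <- simulate_screen(cfg)
#' head(scr$colonies)
#' @export
simulate_screen <- function(config, layouts = NULL) {
  stopifnot(inherits(config, "sim_config"))
  strains <- make_strains(config$genes, config$exclude_pairs, config$wt_id)
  truth <- screen_truth(config, strains)

  with_seed_if(config$seed, {
    if (is.null(layouts)) {
      layouts <- make_layouts(strains, plate_format(1536),
                              n_replicate_colonies = 1,
                              n_configurations = 2, wt_id = config$wt_id)
    }
    extra <- setdiff(unique(stats::na.omit(layouts$strain_id)),
                     truth$fitness$strain_id)
    if (length(extra) > 0) {
      abort(paste0("layout strains without fitness: ",
                   paste(head(extra, 5), collapse = ", ")))
    }

    grid <- tidyr::expand_grid(condition = config$conditions,
                               replicate = seq_len(config$replicates))
    colonies <- purrr::pmap_dfr(grid, function(condition, replicate) {
      dplyr::mutate(layouts, condition = condition, replicate = replicate)
    })

    rows_per_plate <- tapply(layouts$row, layouts$plate_id, max)
    cols_per_plate <- tapply(layouts$col, layouts$plate_id, max)
    ring <- ring_index(colonies$row, colonies$col,
                       rows_per_plate[colonies$plate_id],
                       cols_per_plate[colonies$plate_id])
    ef <- rep(1, nrow(colonies))
    in_ring <- ring + 1 <= length(config$edge_factors)
    ef[in_ring] <- config$edge_factors[ring[in_ring] + 1]

    fit_key <- paste(truth$fitness$strain_id, truth$fitness$condition)
    fit <- truth$fitness$fitness[
      match(paste(colonies$strain_id, colonies$condition), fit_key)]

    value <- config$plate_scale * ef * fit
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      value <- value * rlnorm(length(value), -sdlog^2 / 2, sdlog)
    }
    value[is.na(colonies$strain_id)] <- NA_real_
    colonies$value <- value
    colonies <- colonies[c("plate_id", "condition", "replicate",
                           "configuration", "row", "col", "strain_id",
                           "value")]
    structure(list(colonies = as_tibble(colonies), truth = truth,
                   strains = strains),
              class = "sga_screen")
  })
}

#' Simulate an OD600 growth curve
#'
#' Logistic growth `baseline + K / (1 + exp(-r (t - t0)))` with optional
#' additive Gaussian noise, for exercising the growth-kinetics metrics.
#' The analytic maximum of the first derivative is `r K / 4`, reached at
#' `t = t0`.
#'
#' @param times Strictly increasing time points (hours).
#' @param amplitude Logistic amplitude `K` (OD600), > 0.
#' @param rate Logistic rate `r` (1/hour), > 0.
#' @param midpoint Inflection time `t0` (hours).
#' @param baseline Baseline OD600. Default 0.05.
#' @param noise_sd Additive noise SD. Default 0.
#' @param seed Integer seed or `NULL`.
#' @return A tibble with columns `time` and `od`.
#' @examples
#' simulate_growth_curve(0:48, amplitude = 1, rate = 0.8, midpoint = 12)
#' @export
simulate_growth_curve <- function(times, amplitude, rate, midpoint,
                                  baseline = 0.05, noise_sd = 0,
                                  seed = NULL) {
  if (amplitude <= 0) abort("`amplitude` must be > 0")
  if (rate <= 0) abort("`rate` must be > 0")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing")
  od <- baseline + amplitude / (1 + exp(-rate * (times - midpoint)))
  if (noise_sd > 0) {
    od <- with_seed_if(seed, od + rnorm(length(od), 0, noise_sd))
  }
  tibble(time = as.numeric(times), od = od)
}
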