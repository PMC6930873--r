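# Seed-reproducible synthetic scenarios with the statistical structure the
# screening pipeline assumes: a scale-free background interactome, drug and
# disease seed sets with controlled overlap, planted high-degree hubs among
# the shared seeds, and gene-set annotations with one planted
# over-represented set. Every stage draws from its own sub-seed derived
# from the single scenario seed, so artifacts are byte-identical across
# runs.

#' Scenario configuration
#'
#' Defaults describe a study-sized scenario: a 500-node preferential-
#' attachment interactome (3 edges per arriving node), 30 drug-target
#' seeds (plus an equal number of low-fit-score decoys exercised by the
#' score filter), 60 disease seeds, 15 shared seeds of which 8 are planted
#' hubs boosted by 30 extra edges each, and 20 annotation sets of 10-50
#' genes with 80% of the planted hubs inserted into one designated set.
#'
#' @param rng_seed integer master seed driving every stochastic stage.
#' @param n_background number of interactome nodes.
#' @param attachment_m edges attached by each arriving node during
#'   preferential attachment.
#' @param n_drug_seeds,n_disease_seeds seed-set sizes.
#' @param n_shared_seeds seeds common to both sets (`<=` both sizes).
#' @param n_decoy_drug_targets extra drug-list entries with fit scores
#'   below the conventional 4.5 cut, removed by score filtering.
#' @param n_planted_hubs planted hubs, drawn among the shared seeds
#'   (`<=` `n_shared_seeds`).
#' @param hub_boost extra random edges attached to each planted hub.
#' @param n_gene_sets number of annotation sets.
#' @param set_size_range integer `c(min, max)` set sizes.
#' @param planted_set_overlap fraction of planted hubs inserted into the
#'   designated set, in \[0, 1\].
#' @return a validated `scenario_config` list.
#' @export
scenario_config <- function(rng_seed = 1L,
                            n_background = 500L,
                            attachment_m = 3L,
                            n_drug_seeds = 30L,
                            n_disease_seeds = 60L,
                            n_shared_seeds = 15L,
                            n_decoy_drug_targets = 30L,
                            n_planted_hubs = 8L,
                            hub_boost = 30L,
                            n_gene_sets = 20L,
                            set_size_range = c(10L, 50L),
                            planted_set_overlap = 0.8) {
  cfg <- list(rng_seed = as.integer(rng_seed),
              n_background = as.integer(n_background),
              attachment_m = as.integer(attachment_m),
              n_drug_seeds = as.integer(n_drug_seeds),
              n_disease_seeds = as.integer(n_disease_seeds),
              n_shared_seeds = as.integer(n_shared_seeds),
              n_decoy_drug_targets = as.integer(n_decoy_drug_targets),
              n_planted_hubs = as.integer(n_planted_hubs),
              hub_boost = as.integer(hub_boost),
              n_gene_sets = as.integer(n_gene_sets),
              set_size_range = as.integer(set_size_range),
              planted_set_overlap = as.numeric(planted_set_overlap))
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  fail <- function(msg) np_error("netpharm_validation_error", msg)
  counts <- unlist(cfg[c("n_background", "attachment_m", "n_drug_seeds",
                         "n_disease_seeds", "n_shared_seeds",
                         "n_decoy_drug_targets", "n_planted_hubs",
                         "hub_boost", "n_gene_sets")])
  if (anyNA(counts) || any(counts < 0)) fail("counts must be nonnegative")
  if (cfg$n_background < cfg$attachment_m + 1L)
    fail("n_background must be at least attachment_m + 1")
  if (cfg$attachment_m < 1L) fail("attachment_m must be >= 1")
  if (cfg$n_shared_seeds > min(cfg$n_drug_seeds, cfg$n_disease_seeds))
    fail("n_shared_seeds exceeds a seed-set size")
  if (cfg$n_drug_seeds + cfg$n_disease_seeds - cfg$n_shared_seeds +
      cfg$n_decoy_drug_targets > cfg$n_background)
    fail("seed counts exceed the background size")
  if (cfg$n_planted_hubs > cfg$n_shared_seeds)
    fail("n_planted_hubs exceeds n_shared_seeds")
  if (cfg$hub_boost > cfg$n_background - 1L)
    fail("hub_boost exceeds n_background - 1")
  if (length(cfg$set_size_range) != 2L || any(cfg$set_size_range < 1L) ||
      cfg$set_size_range[1] > cfg$set_size_range[2] ||
      cfg$set_size_range[2] > cfg$n_background)
    fail("set_size_range must be c(min, max) within [1, n_background]")
  if (is.na(cfg$planted_set_overlap) || cfg$planted_set_overlap < 0 ||
      cfg$planted_set_overlap > 1)
    fail("planted_set_overlap must lie in [0, 1]")
  structure(cfg, class = "scenario_config")
}

# fixed offsets give each stage an independent, reproducible substream
stage_seed <- function(cfg, stage) {
  offs <- c(background = 101L, seeds = 211L, hubs = 307L,
            annotations = 401L, scores = 503L)
  (cfg$rng_seed + offs[[stage]]) %% .Machine$integer.max
}

scenario_node_names <- function(n) {
  sprintf("G%0*d", nchar(as.character(n)), seq_len(n))
}

#' Generate a scale-free background interactome
#'
#' Preferential attachment: a complete core of `attachment_m + 1` nodes,
#' then each arriving node attaches `attachment_m` edges to distinct
#' existing nodes chosen with probability proportional to current degree.
#' The result is connected, simple, and right-skewed in degree — the
#' regime in which median-based hub screening is informative. Total edges:
#' `choose(m+1, 2) + m * (n - m - 1)`.
#'
#' @param config a [scenario_config].
#' @return an undirected simple igraph with nodes `G001...`.
#' @export
generate_background <- function(config) {
  config <- validate_scenario_config(config)
  n <- config$n_background; m <- config$attachment_m
  with_rng(stage_seed(config, "background"), {
    deg <- integer(n)
    core <- seq_len(m + 1L)
    from <- integer(0); to <- integer(0)
    for (i in core) for (j in core) if (i < j) {
      from <- c(from, i); to <- c(to, j)
    }
    deg[core] <- m
    e_from <- integer(m * max(0L, n - m - 1L))
    e_to <- integer(length(e_from))
    pos <- 0L
    for (v in seq(m + 2L, length.out = max(0L, n - m - 1L))) {
      existing <- seq_len(v - 1L)
      targets <- sample(existing, m, replace = FALSE, prob = deg[existing])
      e_from[pos + seq_len(m)] <- v
      e_to[pos + seq_len(m)] <- targets
      pos <- pos + m
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
    }
    nm <- scenario_node_names(n)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    igraph::V(g)$name <- nm
    igraph::add_edges(g, rbind(nm[c(from, e_from)], nm[c(to, e_to)]))
  })
}

#' Plant drug and disease seed sets
#'
#' Draws `n_shared_seeds` common nodes plus disjoint remainders, uniformly
#' without replacement from the background nodes.
#'
#' @param background interactome from [generate_background].
#' @param config a [scenario_config].
#' @return list with character vectors `drug_seeds`, `disease_seeds`,
#'   `shared_seeds`.
#' @export
plant_seed_sets <- function(background, config) {
  config <- validate_scenario_config(config)
  nodes <- igraph::V(background)$name
  need <- config$n_drug_seeds + config$n_disease_seeds - config$n_shared_seeds
  if (need > length(nodes)) {
    np_error("netpharm_validation_error",
             "seed counts exceed the number of background nodes")
  }
  with_rng(stage_seed(config, "seeds"), {
    pool <- sample(nodes, need)
    shared <- pool[seq_len(config$n_shared_seeds)]
    drug_only <- pool[config$n_shared_seeds +
                        seq_len(config$n_drug_seeds - config$n_shared_seeds)]
    disease_only <- pool[config$n_drug_seeds +
                           seq_len(config$n_disease_seeds - config$n_shared_seeds)]
    list(drug_seeds = sort(c(shared, drug_only)),
         disease_seeds = sort(c(shared, disease_only)),
         shared_seeds = sort(shared))
  })
}

#' Plant high-degree hubs among the shared seeds
#'
#' Selects `n_planted_hubs` shared seeds and attaches `hub_boost` extra
#' random simple edges from each to other nodes (existing edges are
#' skipped, so a hub's degree rises by at most `hub_boost`).
#'
#' @param background interactome.
#' @param shared character vector of shared seeds (or a [target_set]).
#' @param config a [scenario_config].
#' @return list with the modified `background` and `planted_hubs`
#'   (character vector).
#' @export
plant_hubs <- function(background, shared, config) {
  config <- validate_scenario_config(config)
  ids <- if (inherits(shared, "target_set")) shared$gene_id else shared
  if (config$n_planted_hubs > length(ids)) {
    np_error("netpharm_validation_error",
             "n_planted_hubs exceeds the number of shared seeds")
  }
  with_rng(stage_seed(config, "hubs"), {
    hubs <- sort(sample(ids, config$n_planted_hubs))
    g <- background
    for (h in hubs) {
      nbr <- igraph::neighbors(g, h)$name
      # other planted hubs are excluded as targets so each hub's degree
      # rises by at most hub_boost
      cand <- setdiff(igraph::V(g)$name, c(h, nbr, hubs))
      add <- sample(cand, min(config$hub_boost, length(cand)))
      if (length(add)) g <- igraph::add_edges(g, rbind(h, add))
    }
    list(background = g, planted_hubs = hubs)
  })
}

#' Plant gene-set annotations with one enriched set
#'
#' Draws `n_gene_sets` uniform random sets over the background nodes; one
#' designated set additionally receives
#' `ceiling(planted_set_overlap * n_hubs)` planted hubs. The universe is
#' the full background node set.
#'
#' @param background interactome (defines the annotation universe).
#' @param hubs planted hubs (character vector or [target_set]).
#' @param config a [scenario_config].
#' @return list with `collection` (a `gene_set_collection`) and
#'   `designated_set` (its name).
#' @export
plant_annotations <- function(background, hubs, config) {
  config <- validate_scenario_config(config)
  ids <- if (inherits(hubs, "target_set")) hubs$gene_id else hubs
  nodes <- igraph::V(background)$name
  with_rng(stage_seed(config, "annotations"), {
    sets <- list()
    for (i in seq_len(config$n_gene_sets)) {
      size <- sample(seq(config$set_size_range[1], config$set_size_range[2]), 1L)
      sets[[sprintf("SET%03d", i)]] <-
        list(description = sprintf("random annotation set %d", i),
             members = sample(nodes, size))
    }
    designated <- names(sets)[1]
    n_in <- ceiling(config$planted_set_overlap * length(ids))
    if (n_in > 0) {
      planted <- if (n_in >= length(ids)) ids else sample(ids, n_in)
      sets[[designated]]$members <-
        unique(c(sets[[designated]]$members, planted))
      sets[[designated]]$description <- "designated set (planted enrichment)"
    }
    list(collection = gene_set_collection(sets, universe = nodes),
         designated_set = designated)
  })
}

#' Generate a complete synthetic scenario
#'
#' Composes the background, seed-set, hub and annotation generators, and
#' attaches fit scores to the drug list: true drug seeds draw scores from
#' U(5, 10) and decoy entries from U(1, 4.4), so the conventional
#' fit-score cut of 4.5 separates them. Optionally writes all artifacts to
#' a fixture directory in the pipeline's file formats.
#'
#' @param config a [scenario_config].
#' @param out_dir optional directory; when given, writes `background.sif`,
#'   `drug_targets.tsv`, `disease_targets.tsv`, `gene_sets.gmt` and
#'   `truth.json` (the record of all planted structure).
#' @return object of class `scenario`: list with `background` (igraph),
#'   `drug_targets` (scored [target_set] incl. decoys), `disease_targets`,
#'   `planted_hubs` ([target_set]), `gene_sets`
#'   (`gene_set_collection`), `designated_set`, `truth` (list), `config`.
#' @export
generate_scenario <- function(config = scenario_config(), out_dir = NULL) {
  config <- validate_scenario_config(config)
  bg <- generate_background(config)
  seeds <- plant_seed_sets(bg, config)
  planted <- plant_hubs(bg, seeds$shared_seeds, config)
  bg <- planted$background
  ann <- plant_annotations(bg, planted$planted_hubs, config)
  scored <- with_rng(stage_seed(config, "scores"), {
    decoy_pool <- setdiff(igraph::V(bg)$name,
                          c(seeds$drug_seeds, seeds$disease_seeds))
    decoys <- sample(decoy_pool, min(config$n_decoy_drug_targets,
                                     length(decoy_pool)))
    list(decoys = sort(decoys),
         seed_scores = round(runif(length(seeds$drug_seeds), 5, 10), 3),
         decoy_scores = round(runif(length(decoys), 1, 4.4), 3))
  })
  drug_targets <- target_set(c(seeds$drug_seeds, scored$decoys),
                             c(scored$seed_scores, scored$decoy_scores),
                             name = "drug_targets")
  disease_targets <- target_set(seeds$disease_seeds, name = "disease_targets")
  truth <- list(config = unclass(config),
                drug_seeds = seeds$drug_seeds,
                disease_seeds = seeds$disease_seeds,
                shared_seeds = seeds$shared_seeds,
                decoy_drug_targets = scored$decoys,
                planted_hubs = planted$planted_hubs,
                designated_set = ann$designated_set)
  sc <- structure(list(background = bg,
                       drug_targets = drug_targets,
                       disease_targets = disease_targets,
                       planted_hubs = target_set(planted$planted_hubs,
                                                 name = "planted_hubs"),
                       gene_sets = ann$collection,
                       designated_set = ann$designated_set,
                       truth = truth,
                       config = config),
                  class = "scenario")
  if (!is.null(out_dir)) write_scenario(sc, out_dir)
  sc
}

#' Write scenario artifacts to a fixture directory
#'
#' @param scenario a `scenario`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_scenario <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(scenario$background, file.path(out_dir, "background.sif"),
                  format = "sif")
  drug <- as.data.frame(scenario$drug_targets)
  names(drug) <- c("gene_id", "fit_score")
  utils::write.table(drug[order(drug$gene_id), ],
                     file.path(out_dir, "drug_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_target_list(scenario$disease_targets,
                    file.path(out_dir, "disease_targets.tsv"))
  write_gmt(scenario$gene_sets, file.path(out_dir, "gene_sets.gmt"))
  jsonlite::write_json(scenario$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(paste0("Synthetic scenario (seed %d): %d-node background, ",
                     "%d edges\n"),
              x$config$rng_seed, igraph::vcount(x$background),
              igraph::ecount(x$background)))
  cat(sprintf("  drug targets: %d (incl. %d decoys)  disease targets: %d  shared seeds: %d\n",
              nrow(x$drug_targets), length(x$truth$decoy_drug_targets),
              nrow(x$disease_targets), length(x$truth$shared_seeds)))
  cat(sprintf("  planted hubs: %d   gene sets: %d (designated: %s)\n",
              nrow(x$planted_hubs), length(x$gene_sets$sets),
              x$designated_set))
  invisible(x)
}
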