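# Synthetic scenario generator: deterministic, structurally consistent,
# and loadable by the package's own readers.

small_config <- function(seed = 1L, ...) {
  base <- list(rng_seed = seed, n_background = 120L, attachment_m = 2L,
               n_drug_seeds = 10L, n_disease_seeds = 15L,
               n_shared_seeds = 5L, n_decoy_drug_targets = 5L,
               n_planted_hubs = 3L, hub_boost = 10L,
               n_gene_sets = 8L, set_size_range = c(5L, 15L))
  do.call(scenario_config, utils::modifyList(base, list(...)))
}

test_that("preferential attachment yields the exact edge-count formula", {
  cfg1 <- scenario_config(rng_seed = 4, n_background = 10, attachment_m = 1,
                          n_drug_seeds = 2, n_disease_seeds = 2,
                          n_shared_seeds = 1, n_decoy_drug_targets = 0,
                          n_planted_hubs = 1, hub_boost = 2,
                          n_gene_sets = 2, set_size_range = c(2, 4))
  tree <- generate_background(cfg1)
  expect_equal(igraph::ecount(tree), 9L)  # m = 1 grows a tree: n - 1 edges
  expect_true(igraph::is_connected(tree))

  cfg3 <- small_config(seed = 4, n_background = 100L, attachment_m = 3L)
  g <- generate_background(cfg3)
  # complete core of m+1 = 4 nodes (6 edges) plus 3 per arriving node
  expect_equal(igraph::ecount(g), choose(4, 2) + 3 * 96)
  expect_true(igraph::is_connected(g))
  expect_false(igraph::any_multiple(g) || any(igraph::which_loop(g)))
})

test_that("the same seed reproduces byte-identical scenario fixtures", {
  d1 <- file.path(tempdir(), "scen-a"); d2 <- file.path(tempdir(), "scen-b")
  generate_scenario(small_config(seed = 9), out_dir = d1)
  generate_scenario(small_config(seed = 9), out_dir = d2)
  files <- list.files(d1)
  expect_setequal(files,
                  c("background.sif", "drug_targets.tsv", "disease_targets.tsv",
                    "gene_sets.gmt", "truth.json"))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # different seed, different background
  g9 <- generate_background(small_config(seed = 9))
  g10 <- generate_background(small_config(seed = 10))
  expect_false(identical(edge_keys_of(g9), edge_keys_of(g10)))
})

test_that("seed sets have the configured overlap across many seeds", {
  for (s in 1:25) {
    cfg <- small_config(seed = s)
    bg <- generate_background(cfg)
    seeds <- plant_seed_sets(bg, cfg)
    expect_length(seeds$drug_seeds, 10L)
    expect_length(seeds$disease_seeds, 15L)
    expect_length(intersect(seeds$drug_seeds, seeds$disease_seeds), 5L)
    expect_setequal(seeds$shared_seeds,
                    intersect(seeds$drug_seeds, seeds$disease_seeds))
  }
  # degenerate overlaps
  cfg_same <- small_config(seed = 1, n_drug_seeds = 6L, n_disease_seeds = 6L,
                           n_shared_seeds = 6L)
  s1 <- plant_seed_sets(generate_background(cfg_same), cfg_same)
  expect_setequal(s1$drug_seeds, s1$disease_seeds)
  cfg_disj <- small_config(seed = 1, n_shared_seeds = 0L, n_planted_hubs = 0L)
  s0 <- plant_seed_sets(generate_background(cfg_disj), cfg_disj)
  expect_length(intersect(s0$drug_seeds, s0$disease_seeds), 0L)
})

test_that("hub planting boosts degree by at most hub_boost and targets shared seeds", {
  boost_gain <- numeric(0); base_deg <- numeric(0)
  for (s in 1:25) {
    cfg <- small_config(seed = s)
    bg <- generate_background(cfg)
    seeds <- plant_seed_sets(bg, cfg)
    planted <- plant_hubs(bg, seeds$shared_seeds, cfg)
    expect_true(all(planted$planted_hubs %in% seeds$shared_seeds))
    d0 <- igraph::degree(bg); d1 <- igraph::degree(planted$background)
    gain <- d1[planted$planted_hubs] - d0[planted$planted_hubs]
    expect_true(all(gain >= 0 & gain <= cfg$hub_boost))
    expect_false(igraph::any_multiple(planted$background))
    boost_gain <- c(boost_gain, d1[planted$planted_hubs])
    others <- setdiff(seeds$shared_seeds, planted$planted_hubs)
    base_deg <- c(base_deg, d1[others])
  }
  # planted hubs end up far more connected than unboosted shared seeds
  expect_gt(mean(boost_gain), mean(base_deg))

  cfg0 <- small_config(seed = 2, hub_boost = 0L)
  bg <- generate_background(cfg0)
  seeds <- plant_seed_sets(bg, cfg0)
  p0 <- plant_hubs(bg, seeds$shared_seeds, cfg0)
  expect_setequal(edge_keys_of(p0$background), edge_keys_of(bg))
})

test_that("annotation planting controls the designated set's hub content", {
  cfg <- small_config(seed = 6)
  bg <- generate_background(cfg)
  seeds <- plant_seed_sets(bg, cfg)
  planted <- plant_hubs(bg, seeds$shared_seeds, cfg)

  full <- plant_annotations(planted$background, planted$planted_hubs,
                            small_config(seed = 6, planted_set_overlap = 1))
  expect_true(all(planted$planted_hubs %in%
                    full$collection$sets[[full$designated_set]]$members))
  none <- plant_annotations(planted$background, planted$planted_hubs,
                            small_config(seed = 6, planted_set_overlap = 0))
  sizes <- vapply(none$collection$sets, function(s) length(s$members), integer(1))
  expect_true(all(sizes >= 5 & sizes <= 15))
  expect_setequal(full$collection$universe, igraph::V(bg)$name)
})

test_that("generated artifacts load cleanly through the package readers", {
  d <- file.path(tempdir(), "scen-load")
  sc <- generate_scenario(small_config(seed = 3), out_dir = d)
  expect_no_warning({
    bg <- read_edge_list(file.path(d, "background.sif"))
    drug <- read_target_list(file.path(d, "drug_targets.tsv"),
                             score_column = "fit_score")
    dis <- read_target_list(file.path(d, "disease_targets.tsv"))
    gmt <- read_gmt(file.path(d, "gene_sets.gmt"))
  })
  expect_setequal(igraph::V(bg)$name, igraph::V(sc$background)$name)
  expect_setequal(edge_keys_of(bg), edge_keys_of(sc$background))
  expect_setequal(drug$gene_id, sc$drug_targets$gene_id)
  expect_setequal(dis$gene_id, sc$disease_targets$gene_id)
  expect_equal(length(gmt$sets), 8L)
  truth <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  expect_setequal(truth$planted_hubs, sc$planted_hubs$gene_id)
  # decoys are scored strictly below the 4.5 fit-score cut, seeds above
  expect_true(all(drug$score[drug$gene_id %in% truth$decoy_drug_targets] < 4.5))
  expect_true(all(drug$score[drug$gene_id %in% truth$drug_seeds] > 4.5))
})

test_that("background degree distribution is right-skewed at n >= 200", {
  for (s in 1:5) {
    cfg <- scenario_config(rng_seed = s, n_background = 250)
    d <- igraph::degree(generate_background(cfg))
    expect_gt(max(d), 3 * stats::median(d))
  }
})

test_that("inconsistent configurations are rejected", {
  expect_error(scenario_config(n_background = 3, attachment_m = 3),
               class = "netpharm_validation_error")
  expect_error(scenario_config(n_shared_seeds = 40, n_drug_seeds = 30),
               class = "netpharm_validation_error")
  expect_error(scenario_config(n_planted_hubs = 20, n_shared_seeds = 15),
               class = "netpharm_validation_error")
  expect_error(scenario_config(hub_boost = 500),
               class = "netpharm_validation_error")
  expect_error(scenario_config(planted_set_overlap = 1.5),
               class = "netpharm_validation_error")
  expect_error(scenario_config(set_size_range = c(50, 10)),
               class = "netpharm_validation_error")
})
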