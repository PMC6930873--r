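# Format round-trips, identifier normalization and target-list handling.

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("SIF parsing builds a simple graph and drops loops/duplicates", {
  f <- write_tmp("A pp B", ".sif")
  g <- read_edge_list(f)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::ecount(g), 1L)

  f2 <- write_tmp(c("A pp B", "B pp A", "A pp A"), ".sif")
  expect_message(g2 <- read_edge_list(f2), "dropped 2")
  expect_equal(igraph::vcount(g2), 2L)
  expect_equal(igraph::ecount(g2), 1L)

  # multi-target SIF line and isolated-node line
  f3 <- write_tmp(c("A pp B C D", "LONER"), ".sif")
  g3 <- read_edge_list(f3)
  expect_setequal(igraph::V(g3)$name, c("A", "B", "C", "D", "LONER"))
  expect_equal(igraph::ecount(g3), 3L)
  expect_equal(igraph::degree(g3)[["LONER"]], 0)

  f4 <- write_tmp(c("A pp B", "A B"), ".sif")
  err <- tryCatch(read_edge_list(f4), error = identity)
  expect_s3_class(err, "netpharm_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("edge-list round trips preserve node and edge sets in all dialects", {
  withr::local_seed(42)
  for (fmt in c("sif", "tsv", "graphml")) {
    g <- random_test_graph(10, p = 0.4)
    f <- tempfile(fileext = paste0(".", fmt))
    write_edge_list(g, f, format = fmt)
    g2 <- read_edge_list(f, format = fmt)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    expect_setequal(edge_keys_of(g2), edge_keys_of(g))
  }
})

test_that("identifier normalization trims, uppercases and is idempotent", {
  x <- c(" tp53", "Akt1 ", "\tIL6\t")
  once <- normalize_gene_ids(x)
  expect_equal(once, c("TP53", "AKT1", "IL6"))
  expect_equal(normalize_gene_ids(once), once)
})

test_that("target lists dedupe on normalized ids keeping the max score", {
  f <- write_tmp(c("gene\tfit", "tp53\t5.1", "TP53\t4.0", "akt1\t6.2"), ".tsv")
  ts <- read_target_list(f, score_column = "fit")
  expect_equal(nrow(ts), 2L)
  expect_equal(ts$score[ts$gene_id == "TP53"], 5.1)

  empty <- read_target_list(write_tmp("gene", ".tsv"))
  expect_equal(nrow(empty), 0L)
  three <- read_target_list(write_tmp(c("gene", "A", "B", "C"), ".tsv"))
  expect_equal(nrow(three), 3L)

  expect_error(read_target_list(f, id_column = "nope"),
               class = "netpharm_schema_error")
})

test_that("score filtering is strict, identity at -Inf, and monotone", {
  ts <- target_set(c("A", "B"), c(4.5, 4.6))
  expect_equal(filter_targets_by_score(ts, 4.5)$gene_id, "B")
  expect_equal(nrow(filter_targets_by_score(ts, -Inf)), 2L)
  ts2 <- target_set(c("X", "Y", "Z"), c(1, 2, 3))
  expect_equal(filter_targets_by_score(ts2, 2)$gene_id, "Z")
  expect_error(filter_targets_by_score(target_set("A"), 1),
               class = "netpharm_validation_error")

  withr::local_seed(11)
  for (rep in 1:20) {
    ts3 <- target_set(sprintf("G%02d", 1:15), runif(15, 0, 10))
    cuts <- sort(runif(2, 0, 10))
    lo <- filter_targets_by_score(ts3, cuts[1])
    hi <- filter_targets_by_score(ts3, cuts[2])
    expect_true(all(hi$gene_id %in% lo$gene_id))
  }
})

test_that("GMT parsing normalizes members and rejects malformed input", {
  f <- write_tmp(c("S1\tdesc\tG1\tG2", "S2\tdesc\tg1\tG1\tG3"), ".gmt")
  gs <- read_gmt(f)
  expect_equal(length(gs$sets), 2L)
  expect_equal(length(gs$sets$S1$members), 2L)
  expect_equal(sort(gs$sets$S2$members), c("G1", "G3"))  # g1 == G1, deduped
  expect_setequal(gs$universe, c("G1", "G2", "G3"))

  expect_error(read_gmt(write_tmp(c("S1\td\tG1", "S1\td\tG2"), ".gmt")),
               class = "netpharm_schema_error")
  expect_error(read_gmt(write_tmp("S1\tdesc", ".gmt")),
               class = "netpharm_parse_error")
})

test_that("id mapping translates, collapses many-to-one, honours on_missing", {
  ts <- target_set(c("P04637", "Q12345"), c(5, 4))
  id_identity <- structure(setNames(c("P04637", "Q12345"),
                                    c("P04637", "Q12345")), class = "id_map")
  expect_equal(apply_id_map(ts, id_identity)$gene_id, ts$gene_id)

  m <- c(P04637 = "TP53")
  out <- suppressMessages(apply_id_map(target_set("P04637"), m))
  expect_equal(out$gene_id, "TP53")

  # two raw ids collapsing onto one symbol keep the max score
  m2 <- c(A1 = "TP53", A2 = "TP53")
  out2 <- apply_id_map(target_set(c("A1", "A2"), c(3, 7)), m2)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$score, 7)

  expect_message(dropped <- apply_id_map(ts, m, on_missing = "drop"),
                 "not in map")
  expect_equal(dropped$gene_id, "TP53")
  expect_error(apply_id_map(ts, m, on_missing = "error"),
               class = "netpharm_mapping_error")
})

test_that("id maps read from TSV and round-trip through target sets", {
  f <- write_tmp(c("from\tto", "p04637\ttp53", "q00001\tAKT1"), ".tsv")
  m <- read_id_map(f)
  expect_equal(unname(m[c("P04637", "Q00001")]), c("TP53", "AKT1"))
})
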