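# helpers to build small tool sets directly at gene level
mk_set <- function(tool, a, b, scores = NULL) {
  tool_pair_set(tool, "fly", "human",
                data.frame(gene_a = a, gene_b = b),
                original_scores = scores)
}

test_that("ingestion collapses isoforms and preserves tool scores verbatim", {
  map_a <- load_id_map(data.frame(
    raw_id = c("pA.1", "pA.2", "7"), id_type = c("refseq_protein",
                                                 "refseq_protein", "entrez"),
    gene_id = c(1L, 1L, 7L)), species = "fly")
  map_b <- load_id_map(data.frame(raw_id = c("pB.1", "9"),
                                  id_type = c("refseq_protein", "entrez"),
                                  gene_id = c(2L, 9L)), species = "human")
  raw <- data.frame(a = c("pA.1", "pA.2", "7"), b = c("pB.1", "pB.1", "9"),
                    s = c("0.87", "0.87", "12"))
  ts <- ingest_tool_predictions("toolX", raw, map_a, map_b,
                                dialect = list(col_a = 1, col_b = 2,
                                               col_score = 3))
  expect_equal(nrow(ts$pairs), 2L)
  expect_equal(unname(ts$original_scores[["1|2"]]), "0.87")
  expect_equal(unname(ts$original_scores[["7|9"]]), "12")

  empty <- ingest_tool_predictions("toolX", raw[0, ], map_a, map_b)
  expect_equal(nrow(empty$pairs), 0L)
})

test_that("integration is the union with simple score = supporting tool count", {
  s1 <- mk_set("t1", c(1L, 2L), c(11L, 12L))
  s2 <- mk_set("t2", c(1L, 3L), c(11L, 13L))
  s3 <- mk_set("t3", 1L, 11L)
  int <- integrate_tools(list(s1, s2, s3))
  expect_equal(nrow(int), 3L)
  row <- int[int$gene_a == 1L, ]
  expect_equal(row$simple_score, 3L)
  expect_equal(row$supporting_tools, "t1,t2,t3")
  expect_equal(int$simple_score[int$gene_a == 2L], 1L)

  # single-tool integration is that tool's set with all scores 1
  solo <- integrate_tools(list(s1, s2, s3), selected_tools = "t1")
  expect_equal(as.data.frame(solo)[, c("gene_a", "gene_b")],
               as.data.frame(s1$pairs[, c("gene_a", "gene_b")]))
  expect_true(all(solo$simple_score == 1L))

  # removing a tool never increases any score
  sub <- integrate_tools(list(s1, s2, s3), selected_tools = c("t1", "t2"))
  both <- merge(as.data.frame(int), as.data.frame(sub),
                by = c("gene_a", "gene_b"))
  expect_true(all(both$simple_score.y <= both$simple_score.x))

  expect_error(integrate_tools(list(
    s1, tool_pair_set("t9", "human", "fly",
                      data.frame(gene_a = 1L, gene_b = 2L)))),
    "species pair")
  expect_error(integrate_tools(list(s1), selected_tools = "ghost"),
               "unknown tool")
})

test_that("output order is canonical and deterministic", {
  s1 <- mk_set("t1", c(5L, 1L, 1L), c(50L, 12L, 11L))
  s2 <- mk_set("t2", 1L, 12L)
  int <- integrate_tools(list(s1, s2))
  expect_equal(int$gene_a, c(1L, 1L, 5L))
  # within a gene: descending score, then gene_b
  expect_equal(int$gene_b[1:2], c(12L, 11L))
  expect_identical(int, integrate_tools(list(s1, s2)))
})

test_that("score filter keeps passing pairs and rescues a sole weak match", {
  s <- list(mk_set("t1", c(1L, 1L, 2L, 3L, 3L), c(11L, 12L, 21L, 31L, 32L)),
            mk_set("t2", 1L, 11L),
            mk_set("t3", c(1L, 1L, 1L, 1L, 1L), c(11L, 11L, 11L, 11L, 11L)))
  # gene 1: 11 scores 3, 12 scores 1; gene 2: single candidate score 1;
  # gene 3: two candidates score 1 each
  int <- integrate_tools(s)
  f2 <- apply_score_filter(int, 2L)
  expect_setequal(f2$gene_b[f2$gene_a == 1L], 11L)
  expect_equal(f2$gene_b[f2$gene_a == 2L], 21L)
  expect_true(grepl("low_score_only_match", f2$flags[f2$gene_a == 2L]))
  expect_equal(sum(f2$gene_a == 3L), 0L)

  # alternative rescue keeps best sub-threshold candidates
  fb <- apply_score_filter(int, 2L, rescue = "best_below_threshold")
  expect_equal(sum(fb$gene_a == 3L), 2L)

  expect_error(apply_score_filter(int, 5L), "threshold")
  expect_equal(nrow(apply_score_filter(int, 5L, allow_any_threshold = TRUE)),
               1L)
})

test_that("best-match filter keeps exactly the per-gene maxima, ties included", {
  s <- list(
    mk_set("t1", c(1L, 1L, 1L), c(11L, 12L, 13L)),
    mk_set("t2", c(1L, 1L), c(11L, 12L)),
    mk_set("t3", c(1L, 1L), c(11L, 12L)),
    mk_set("t4", c(1L, 1L), c(11L, 12L)))
  int <- integrate_tools(s)  # B:4, C:4, D:1
  bm <- apply_best_match_filter(int)
  expect_setequal(bm$gene_b, c(11L, 12L))
  expect_true(all(grepl("best_match", bm$flags)))

  single <- integrate_tools(list(mk_set("t1", 9L, 99L)))
  expect_equal(nrow(apply_best_match_filter(single)), 1L)
  expect_equal(nrow(apply_best_match_filter(single[0, ])), 0L)
})

test_that("relationship classes follow partner counts, oriented input->output", {
  one <- classify_relationships(data.frame(gene_a = 1L, gene_b = 11L))
  expect_equal(one$relationship_class, "one-to-one")

  m2o <- classify_relationships(data.frame(gene_a = c(1L, 2L),
                                           gene_b = c(11L, 11L)))
  expect_true(all(m2o$relationship_class == "many-to-one"))

  # hand enumeration for {(a1,b1),(a1,b2),(a2,b1)}: a1 has 2 partners, b1
  # has 2 partners, a2 and b2 have 1 each
  mixed <- classify_relationships(data.frame(gene_a = c(1L, 1L, 2L),
                                             gene_b = c(11L, 12L, 11L)))
  expect_equal(mixed$relationship_class[mixed$gene_a == 1L & mixed$gene_b == 11L],
               "many-to-many")
  expect_equal(mixed$relationship_class[mixed$gene_a == 1L & mixed$gene_b == 12L],
               "one-to-many")
  expect_equal(mixed$relationship_class[mixed$gene_a == 2L & mixed$gene_b == 11L],
               "many-to-one")
  expect_equal(sum(attr(mixed, "class_counts")), nrow(mixed))
})

test_that("filter monotonicity holds on a generated world", {
  w <- tiny_world(seed = 303, n_genes = 50)$world
  int <- integrate_tools(w$tool_sets)
  f2 <- apply_score_filter(int, 2L)
  f3 <- apply_score_filter(int, 3L)
  bm <- apply_best_match_filter(int)
  key <- function(d) paste(d$gene_a, d$gene_b)
  expect_true(all(key(f3) %in% key(f2)))
  expect_true(all(key(f2) %in% key(int)))
  expect_true(all(key(bm) %in% key(int)))
  expect_true(all(int$simple_score >= 1L &
                  int$simple_score <= length(w$tool_sets)))
})

test_that("transposing swaps orientation without re-integrating", {
  int <- integrate_tools(list(mk_set("t1", c(1L, 2L), c(11L, 11L))))
  tr <- transpose_ortho_table(int)
  expect_equal(attr(tr, "species_pair"), c("human", "fly"))
  expect_setequal(tr$gene_a, 11L)
  expect_setequal(tr$gene_b, c(1L, 2L))
  expect_equal(as.data.frame(transpose_ortho_table(tr))[
    order(transpose_ortho_table(tr)$gene_a), c("gene_a", "gene_b")],
    as.data.frame(int)[, c("gene_a", "gene_b")])
})
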