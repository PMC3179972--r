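# a small hand-built ontology used throughout: root -> t1 -> t2 chain plus
# a sibling branch
chain_obo <- c(
  "format-version: 1.2", "",
  "[Term]", "id: GO:0003674", "name: molecular_function",
  "namespace: molecular_function", "",
  "[Term]", "id: GO:0000001", "name: t1",
  "namespace: molecular_function", "is_a: GO:0003674 ! root", "",
  "[Term]", "id: GO:0000002", "name: t2",
  "namespace: molecular_function", "is_a: GO:0000001 ! t1", "",
  "[Term]", "id: GO:0000003", "name: sibling",
  "namespace: molecular_function", "is_a: GO:0003674 ! root", "",
  "[Term]", "id: GO:0000009", "name: gone",
  "namespace: molecular_function", "is_obsolete: true", "")

read_chain_dag <- function() {
  f <- withr::local_tempfile(lines = chain_obo, .local_envir = parent.frame())
  read_obo(f)
}

test_that("OBO parsing keeps is_a structure and drops obsolete terms", {
  dag <- read_chain_dag()
  expect_setequal(dag$terms,
                  c("GO:0003674", "GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(dag$root, "GO:0003674")
  expect_setequal(dag$ancestors[["GO:0000002"]],
                  c("GO:0000002", "GO:0000001", "GO:0003674"))
})

test_that("GAF parsing keeps molecular-function rows with gene, term, evidence", {
  gaf <- c("!gaf-version: 2.1",
           "DB\t10\tG10\t\tGO:0000002\tREF\tIDA\t\tF\t\t\tprotein\ttaxon:1\t20110101\tDB\t\t",
           "DB\t10\tG10\t\tGO:0000001\tREF\tIEA\t\tP\t\t\tprotein\ttaxon:1\t20110101\tDB\t\t",
           "DB\t11\tG11\t\tGO:0000001\tREF\tTAS\t\tF\t\t\tprotein\ttaxon:1\t20110101\tDB\t\t")
  f <- withr::local_tempfile(lines = gaf)
  ann <- read_gaf(f)
  expect_equal(nrow(ann), 2L)  # the aspect-P row is dropped
  expect_setequal(ann$gene_id, c(10L, 11L))
})

test_that("evidence subsets nest: MF1 identity, MF2 drops IEA, MF3 experimental only", {
  ann <- go_annotations(data.frame(
    gene_id = c(1L, 2L, 3L), term = "GO:0000001",
    evidence = c("IEA", "TAS", "IDA")))
  expect_equal(nrow(filter_by_evidence(ann, "MF1")), 3L)
  mf2 <- filter_by_evidence(ann, "MF2")
  expect_setequal(mf2$gene_id, c(2L, 3L))  # IEA-only gene absent
  mf3 <- filter_by_evidence(ann, "MF3")
  expect_equal(mf3$gene_id, 3L)  # TAS is a curator code, not experimental
  expect_error(filter_by_evidence(ann, "MF9"), "subset")
})

test_that("information content follows propagated annotation frequency", {
  dag <- read_chain_dag()
  # counts {t2: 1, t1: 1}: p(t1) = 2/2 -> ic 0; p(t2) = 1/2 -> ln 2
  ann <- go_annotations(data.frame(
    gene_id = c(1L, 2L), term = c("GO:0000002", "GO:0000001"),
    evidence = "IDA"))
  ic <- compute_term_ic(ann, dag)
  expect_equal(unname(ic["GO:0003674"]), 0)
  expect_equal(unname(ic["GO:0000001"]), 0)
  expect_equal(unname(ic["GO:0000002"]), log(2))
  expect_false("GO:0000003" %in% names(ic))  # p = 0: excluded
  expect_error(compute_term_ic(ann[0, ], dag), "empty")
})

test_that("term similarity is the Lin measure with defined edge cases", {
  dag <- read_chain_dag()
  ann <- go_annotations(data.frame(
    gene_id = 1:4,
    term = c("GO:0000002", "GO:0000002", "GO:0000001", "GO:0000003"),
    evidence = "IDA"))
  ic <- compute_term_ic(ann, dag)
  expect_equal(term_similarity("GO:0000002", "GO:0000002", dag, ic), 1)
  # only common ancestor is the root (ic 0)
  expect_equal(term_similarity("GO:0000002", "GO:0000003", dag, ic), 0)
  expect_equal(term_similarity("GO:0003674", "GO:0003674", dag, ic), 0)
  # t1 is the MICA of (t1, t2)
  expect_equal(term_similarity("GO:0000001", "GO:0000002", dag, ic),
               2 * ic[["GO:0000001"]] / (ic[["GO:0000001"]] + ic[["GO:0000002"]]))
  expect_error(term_similarity("GO:9999999", "GO:0000001", dag, ic),
               "absent")
})

test_that("similarity matches the brute-force oracle on a generated DAG", {
  tw <- tiny_world(seed = 505, n_genes = 30)
  go <- generate_go_fixture(tw$spec, tw$world)
  dag <- go$dag
  ic <- compute_term_ic(go$annotations, dag)
  o_ic <- oracle_ic(as.data.frame(go$annotations), dag$terms, dag$parents)
  expect_equal(ic[sort(names(ic))], o_ic[sort(names(o_ic))], tolerance = 1e-12)

  set.seed(99)
  terms <- names(ic)
  for (k in 1:50) {
    t1 <- sample(terms, 1); t2 <- sample(terms, 1)
    expect_equal(term_similarity(t1, t2, dag, ic),
                 unname(oracle_lin(t1, t2, dag$parents, ic)),
                 tolerance = 1e-9)
    # symmetry
    expect_equal(term_similarity(t1, t2, dag, ic),
                 term_similarity(t2, t1, dag, ic))
  }
})

test_that("gene-pair similarity is the symmetrized best-match average", {
  dag <- read_chain_dag()
  ann <- go_annotations(data.frame(
    gene_id = 1:4,
    term = c("GO:0000002", "GO:0000002", "GO:0000001", "GO:0000003"),
    evidence = "IDA"))
  ic <- compute_term_ic(ann, dag)
  ts <- c("GO:0000001", "GO:0000002")
  expect_equal(gene_pair_similarity(ts, ts, dag, ic), 1)
  expect_equal(gene_pair_similarity("GO:0000001", "GO:0000002", dag, ic),
               term_similarity("GO:0000001", "GO:0000002", dag, ic))
  expect_true(is.na(gene_pair_similarity(character(0), ts, dag, ic)))

  # non-trivial sets against the exhaustive oracle
  tw <- tiny_world(seed = 606, n_genes = 30)
  go <- generate_go_fixture(tw$spec, tw$world)
  ic2 <- compute_term_ic(go$annotations, go$dag)
  sets <- gene_term_sets(go$annotations)
  set.seed(7)
  genes <- sample(names(sets), 12)
  for (i in seq(1, 11, by = 2)) {
    ta <- sets[[genes[i]]]; tb <- sets[[genes[i + 1]]]
    expect_equal(gene_pair_similarity(ta, tb, go$dag, ic2),
                 oracle_bma(ta, tb, go$dag$parents, ic2), tolerance = 1e-9)
  }
})

test_that("tool weights are median-normalized and scale-invariant", {
  w <- compute_tool_weights(c(a = 0.6, b = 0.7, c = 0.8))
  expect_equal(w$weight, c(0.6, 0.7, 0.8) / 0.7)
  expect_equal(stats::median(w$weight), 1)
  # even count: midpoint median
  w4 <- compute_tool_weights(c(a = 0.5, b = 0.6, c = 0.7, d = 0.9))
  expect_equal(stats::median(w4$weight), 1)
  expect_equal(w4$weight[2] + w4$weight[3], 2 * 0.65 / 0.65)
  # scale invariance
  w_scaled <- compute_tool_weights(c(a = 6, b = 7, c = 8))
  expect_equal(w_scaled$weight, w$weight)
  # single tool is its own median
  expect_equal(compute_tool_weights(c(solo = 0.42))$weight, 1)
  expect_error(compute_tool_weights(c(a = NA_real_)), "computable")
  # ordering of weights matches ordering of means
  expect_equal(order(w4$weight), order(w4$mean_sim))
})

test_that("weighted score sums supporting tools' weights", {
  w <- compute_tool_weights(c(t1 = 0.7, t2 = 0.63, t3 = 0.7))
  expect_equal(weighted_score(c("t1", "t2"), w), 1.0 + 0.9)
  expect_error(weighted_score(c("t1", "ghost"), w), "ghost")

  ones <- compute_tool_weights(c(t1 = 0.5, t2 = 0.5, t3 = 0.5))
  int <- integrate_tools(list(
    tool_pair_set("t1", "fly", "human", data.frame(gene_a = 1L, gene_b = 2L)),
    tool_pair_set("t2", "fly", "human", data.frame(gene_a = 1L, gene_b = 2L)),
    tool_pair_set("t3", "fly", "human", data.frame(gene_a = 3L, gene_b = 4L))))
  scored <- add_weighted_scores(int, ones)
  expect_equal(scored$weighted_score, as.numeric(scored$simple_score))
})

test_that("per-tool mean similarity averages computable pairs only", {
  dag <- read_chain_dag()
  # third gene keeps the corpus informative (p(t2) < 1, so ic(t2) > 0)
  ann <- go_annotations(data.frame(
    gene_id = c(1L, 2L, 3L),
    term = c("GO:0000002", "GO:0000002", "GO:0000003"), evidence = "IDA"))
  ic <- compute_term_ic(ann, dag)
  ts <- tool_pair_set("t", "fly", "human",
                      data.frame(gene_a = c(1L, 5L), gene_b = c(2L, 6L)))
  res <- tool_mean_similarity(ts, ann, ann, dag, ic)
  expect_equal(res$mean_sim, 1)       # identical singleton annotation sets
  expect_equal(res$n_computable, 1L)  # the unannotated pair is excluded
  none <- tool_pair_set("t", "fly", "human",
                        data.frame(gene_a = 5L, gene_b = 6L))
  expect_true(is.na(tool_mean_similarity(none, ann, ann, dag, ic)$mean_sim))
})
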