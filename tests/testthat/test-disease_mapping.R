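mini_lookup <- function() {
  mesh_lookup(
    entry_terms = data.frame(
      entry_term = c("breast cancer", "breast tumor", "diabetes mellitus"),
      mesh_term = c("breast neoplasms", "breast neoplasms",
                    "diabetes mellitus"),
      codes = c("C04", "C04", "C18,C19")),
    cs_heading_map = data.frame(cs_heading = "Cardiovascular",
                                code = "C14"),
    manual_overrides = data.frame(raw_term = "zyzzyva syndrome",
                                  code = "C16"),
    y01_keywords = c("hdl cholesterol", "telomere length", "tanning"),
    y02_keywords = c("hair color", "eye color"))
}

test_that("term simplification lower-cases, strips qualifiers and collapses space", {
  expect_equal(simplify_term("Breast cancer"), "breast cancer")
  expect_equal(simplify_term("Diabetes mellitus, susceptibility to"),
               "diabetes mellitus")
  expect_equal(simplify_term("  Eye   color "), "eye color")
  expect_equal(simplify_term("Alzheimer disease (early onset)"),
               "alzheimer disease")
  expect_equal(simplify_term("X-linked thing [qualifier]"),
               "x-linked thing")
  # deterministic and idempotent
  terms <- c("A, susceptibility to", "B (x)", "  c  d ")
  expect_equal(simplify_term(simplify_term(terms)), simplify_term(terms))
})

test_that("category assignment follows the route precedence and reports routes", {
  lk <- mini_lookup()
  recs <- data.frame(
    source = c("OMIM_phenotype", "GWAS", "GWAS", "GWAS", "OMIM_phenotype",
               "GWAS"),
    omim_id = c(100L, NA, NA, NA, 101L, NA),
    raw_term = c("anything at all", "Breast cancer", "HDL cholesterol",
                 "hair color", "zyzzyva syndrome", "totally unknown xyz"),
    cs_heading = c("Cardiovascular", "", "", "", "", ""),
    genes = "1", stringsAsFactors = FALSE)
  out <- assign_category(recs, lk)
  expect_equal(out$mapping_route,
               c("cs_heading", "entry_term", "y01_rule", "y02_rule",
                 "manual", "unmapped"))
  expect_equal(out$categories[1], "C14")
  expect_equal(out$categories[2], "C04")
  expect_equal(out$categories[3], "Y01")
  expect_equal(out$categories[4], "Y02")
  expect_equal(out$categories[5], "C16")
  expect_equal(out$categories[6], "")
  # exactly one route per record, and route counts account for all records
  expect_equal(sum(table(out$mapping_route)), nrow(recs))
  # poly-hierarchic terms keep all categories
  multi <- assign_category(data.frame(
    source = "GWAS", omim_id = NA_integer_,
    raw_term = "Diabetes mellitus, susceptibility to", cs_heading = "",
    genes = "1", stringsAsFactors = FALSE), lk)
  expect_equal(multi$categories, "C18,C19")
  # idempotent on its own output
  expect_equal(assign_category(out[, names(recs)], lk)$categories,
               out$categories)
})

mk_human_table <- function() {
  # human -> fly, gene 1 has candidates scoring 4, 4, 2; gene 2 one of 1
  sets <- list(
    tool_pair_set("t1", "human", "fly",
                  data.frame(gene_a = c(1L, 1L, 1L, 2L),
                             gene_b = c(11L, 12L, 13L, 21L))),
    tool_pair_set("t2", "human", "fly",
                  data.frame(gene_a = c(1L, 1L), gene_b = c(11L, 12L))),
    tool_pair_set("t3", "human", "fly",
                  data.frame(gene_a = c(1L, 1L, 1L),
                             gene_b = c(11L, 12L, 13L))),
    tool_pair_set("t4", "human", "fly",
                  data.frame(gene_a = c(1L, 1L), gene_b = c(11L, 12L))))
  integrate_tools(sets)
}

test_that("disease-ortholog join selects records and applies filters", {
  tab <- mk_human_table()
  recs <- assign_category(data.frame(
    source = c("OMIM_phenotype", "GWAS"),
    omim_id = c(610251L, NA),
    raw_term = c("acute alcohol sensitivity", "Breast cancer"),
    cs_heading = "", genes = c("1", "2"), stringsAsFactors = FALSE),
    mini_lookup())
  by_omim <- join_disease_orthologs(recs, tab, "none", omim_ids = 610251L)
  expect_equal(sort(by_omim$target_gene), c(11L, 12L, 13L))
  expect_equal(nrow(join_disease_orthologs(recs, tab, "none",
                                           term = "nomatch")), 0L)
  # best-match on candidates {4,4,2} keeps the two tied best
  bm <- join_disease_orthologs(recs, tab, "best_match", omim_ids = 610251L)
  expect_setequal(bm$target_gene, c(11L, 12L))
  # monotonicity: ge3 subset of ge2 subset of none
  j0 <- join_disease_orthologs(recs, tab, "none")
  j2 <- join_disease_orthologs(recs, tab, "score_ge2")
  j3 <- join_disease_orthologs(recs, tab, "score_ge3")
  key <- function(d) paste(d$human_gene, d$target_gene)
  real <- function(d) key(d[!d$no_ortholog, ])
  expect_true(all(real(j3) %in% real(j2)))
  expect_true(all(real(j2) %in% real(j0)))
  # term query is a case-insensitive substring match
  expect_equal(unique(join_disease_orthologs(recs, tab, "none",
                                             term = "BREAST")$raw_term),
               "Breast cancer")
  expect_error(join_disease_orthologs(recs, tab, "none", category = "Z99"),
               "unknown category")
})

test_that("per-category summaries recompute from row-level join output", {
  tab <- mk_human_table()
  recs <- assign_category(data.frame(
    source = c("GWAS", "GWAS"), omim_id = NA_integer_,
    raw_term = c("Breast cancer", "diabetes mellitus"),
    cs_heading = "", genes = c("1", "1,2"), stringsAsFactors = FALSE),
    mini_lookup())
  rows <- join_disease_orthologs(recs, tab, "none")
  summ <- disease_category_summary(rows)
  # recompute by hand from the row table
  for (code in summ$code) {
    in_cat <- vapply(strsplit(rows$categories, ","), function(cc)
      code %in% cc, logical(1))
    expect_equal(summ$n_human_genes[summ$code == code],
                 length(unique(rows$human_gene[in_cat])))
    expect_equal(summ$n_terms[summ$code == code],
                 length(unique(rows$raw_term[in_cat])))
  }
})

test_that("shared literature categories intersect gene and ortholog sets", {
  lit <- list(`1` = c("C04", "C10"), `11` = "C04", `12` = "C16")
  expect_equal(shared_disease_categories(1L, c(11L, 12L), lit)$shared, "C04")
  expect_equal(shared_disease_categories(1L, 12L, lit)$shared, character(0))
  expect_equal(shared_disease_categories(99L, 11L, lit)$shared, character(0))
})

test_that("planted disease fixture routes and shared categories are recovered", {
  tw <- tiny_world(seed = 707, n_genes = 50)
  dz <- generate_disease_fixture(tw$spec, tw$world, n_records = 80)
  out <- assign_category(dz$records, dz$lookup)
  planted <- c(cs = "cs_heading", entry = "entry_term", y01 = "y01_rule",
               y02 = "y02_rule", unmapped = "unmapped")
  expect_equal(out$mapping_route, unname(planted[dz$truth$routes]))
  # shared-category census equals the planted count exactly
  p <- tw$world$truth$pairs
  got <- vapply(seq_len(nrow(p)), function(i) {
    length(shared_disease_categories(p$gene_a[i], p$gene_b[i],
                                     dz$literature)$shared) > 0
  }, logical(1))
  expect_equal(got, dz$truth$shared)
})

test_that("record files round-trip through the readers", {
  tw <- tiny_world(seed = 711, n_genes = 30)
  dir <- withr::local_tempdir()
  dz <- generate_disease_fixture(tw$spec, tw$world, n_records = 40,
                                 dir = dir)
  omim <- read_omim_records(file.path(dir, "omim_records.tsv"))
  gwas <- read_gwas_records(file.path(dir, "gwas_records.tsv"))
  expect_equal(nrow(omim), nrow(dz$omim))
  expect_equal(nrow(gwas), nrow(dz$gwas))
  expect_equal(omim$raw_term, dz$omim$raw_term)
  lk <- read_mesh_lookup(file.path(dir, "mesh_lookup.tsv"))
  expect_equal(nrow(lk$entry_terms), nrow(dz$lookup$entry_terms))
  lit <- read_literature_mesh(file.path(dir, "literature_mesh.tsv"))
  expect_equal(lit[order(names(lit))],
               dz$literature[order(names(dz$literature))])
})
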