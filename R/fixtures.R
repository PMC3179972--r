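# Synthetic fixture world: gene catalogs, tool outputs with controlled
# recall and false-positive rates, a GO DAG with annotations, sequences with
# planted conserved domains, and disease records -- all with known ground
# truth, so the whole pipeline is testable without any download.

#' Specify a synthetic orthology world
#'
#' All randomness flows from `seed`; each sub-generator draws from a named
#' sub-stream derived from it, so identical seeds give byte-identical
#' outputs and adding one generator does not perturb the others.
#'
#' Defaults emulate the study conditions the integrated-tool setting
#' implies: nine source tools whose per-tool recall spans the 0.4--0.8 band
#' reported for individual predictors, a small false-positive rate, a fly
#' genome less redundant than the human one (more one-to-many than
#' many-to-one pairs reading fly to human), and a minority of orphan genes
#' on both sides so negative sets exist.
#'
#' @param seed Integer seed.
#' @param n_genes Genes per species (default 200).
#' @param n_tools Number of source tools (default 9).
#' @param recall Per-tool true-pair recall, recycled to `n_tools` (default
#'   an even spread over 0.4--0.8).
#' @param fp_rate Per-tool false-pair rate, relative to the number of true
#'   pairs (default 0.05).
#' @param frac_one_to_many Fraction of input-species genes with two output
#'   partners (default 0.2).
#' @param frac_many_to_one Fraction of output-species genes with two input
#'   partners (default 0.08).
#' @param frac_orphan Fraction of genes per species without any ortholog
#'   (default 0.15).
#' @param isoform_fraction Fraction of tool rows emitted with isoform-level
#'   protein accessions instead of gene IDs (default 0.3).
#' @param annotation_density Probability that a gene carries GO annotations
#'   (default 0.8).
#' @param evidence_mix Named probability vector over GO evidence codes
#'   (default mixes IEA with experimental and curator codes so the
#'   MF1/MF2/MF3 strata differ).
#' @param seq_len_range Protein length range in residues (default 120--240).
#' @param domain_len Planted conserved-domain length (default 60).
#' @param domain_conservation Per-residue identity of the planted domain
#'   between orthologs (default 0.95).
#' @param flank_conservation Per-residue identity of the sequence outside
#'   the domain (default 0.35): flanks are diverged copies, not unrelated
#'   sequence, so alignments extend past the domain and overall identity
#'   falls between the flank and domain levels.
#' @param species_in,species_out Ordered species pair (default fly ->
#'   human).
#' @return A `world_spec` object.
#' @export
world_spec <- function(seed = 1L, n_genes = 200L, n_tools = 9L,
                       recall = NULL, fp_rate = 0.05,
                       frac_one_to_many = 0.2, frac_many_to_one = 0.08,
                       frac_orphan = 0.15, isoform_fraction = 0.3,
                       annotation_density = 0.8,
                       evidence_mix = c(IEA = 0.45, ISS = 0.05, IDA = 0.2,
                                        IMP = 0.1, IGI = 0.05, TAS = 0.1,
                                        NAS = 0.05),
                       seq_len_range = c(120L, 240L), domain_len = 60L,
                       domain_conservation = 0.95, flank_conservation = 0.35,
                       species_in = "fly", species_out = "human") {
  recall <- rep(recall %||% seq(0.4, 0.8, length.out = n_tools),
                length.out = n_tools)
  fp_rate <- rep(fp_rate, length.out = n_tools)
  rates <- c(recall, fp_rate, frac_one_to_many, frac_many_to_one,
             frac_orphan, isoform_fraction, annotation_density,
             domain_conservation, flank_conservation)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  assert_species(species_in); assert_species(species_out)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_tools = as.integer(n_tools), recall = recall,
                 fp_rate = fp_rate, frac_one_to_many = frac_one_to_many,
                 frac_many_to_one = frac_many_to_one,
                 frac_orphan = frac_orphan,
                 isoform_fraction = isoform_fraction,
                 annotation_density = annotation_density,
                 evidence_mix = evidence_mix / sum(evidence_mix),
                 seq_len_range = as.integer(seq_len_range),
                 domain_len = as.integer(domain_len),
                 domain_conservation = domain_conservation,
                 flank_conservation = flank_conservation,
                 species_in = species_in, species_out = species_out,
                 tools = sprintf("tool%02d", seq_len(n_tools))),
            class = "world_spec")
}

world_subseed <- function(spec, stream) {
  derive_subseeds(spec$seed, c("truth", "tools", "ids", "go", "seq",
                               "disease"))[[stream]]
}

# gene-ID blocks per side keep the two namespaces visibly distinct
GENE_BASE_A <- 10000L
GENE_BASE_B <- 20000L

#' Generate the orthology world: truth, tool tables and ID maps
#'
#' Builds a ground-truth pair set with the requested relationship-class
#' mixture, then samples each tool's predictions as a Bernoulli subsample
#' of the truth (per-tool recall) plus uniformly drawn false pairs
#' (per-tool rate). Tool tables are emitted with mixed identifier types --
#' a configurable fraction of rows carries isoform-level protein
#' accessions, and a further fraction is duplicated at the other isoform so
#' gene-level collapsing is exercised.
#'
#' @param spec A [world_spec()].
#' @param dir Optional directory; when given, tool tables, ID maps and the
#'   ground-truth bundle are written there as TSV.
#' @return A `world` object: list with `spec`, `truth` (pairs data.frame,
#'   per-tool membership matrix over true pairs, per-tool false-pair
#'   data.frames), `tool_tables` (raw data.frames), `tool_sets` (parsed
#'   [tool_pair_set()]s), `id_map_a`, `id_map_b`, `id_table_a`,
#'   `id_table_b`, `symbols_a`, `symbols_b`, and `files` when `dir` given.
#' @export
generate_orthology_world <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "world_spec"))
  n <- spec$n_genes
  genes_a <- GENE_BASE_A + seq_len(n)
  genes_b <- GENE_BASE_B + seq_len(n)

  set.seed(world_subseed(spec, "truth"))
  pool_a <- sample(genes_a)
  pool_b <- sample(genes_b)
  n_orph <- round(spec$frac_orphan * n)
  orphan_a <- pool_a[seq_len(n_orph)]; pool_a <- pool_a[-seq_len(n_orph)]
  orphan_b <- pool_b[seq_len(n_orph)]; pool_b <- pool_b[-seq_len(n_orph)]
  take <- function(pool, k) list(got = pool[seq_len(k)], rest = pool[-seq_len(k)])
  pairs <- data.frame(gene_a = integer(0), gene_b = integer(0))
  n12 <- round(spec$frac_one_to_many * length(pool_a) / 2)
  n21 <- round(spec$frac_many_to_one * length(pool_b) / 2)
  # one-to-many: one input gene, two output partners
  if (n12 > 0L) {
    a <- take(pool_a, n12); pool_a <- a$rest
    b <- take(pool_b, 2L * n12); pool_b <- b$rest
    pairs <- rbind(pairs,
                   data.frame(gene_a = rep(a$got, each = 2L), gene_b = b$got))
  }
  # many-to-one: two input genes, one output partner
  if (n21 > 0L) {
    a <- take(pool_a, 2L * n21); pool_a <- a$rest
    b <- take(pool_b, n21); pool_b <- b$rest
    pairs <- rbind(pairs,
                   data.frame(gene_a = a$got, gene_b = rep(b$got, each = 2L)))
  }
  m <- min(length(pool_a), length(pool_b))
  pairs <- rbind(pairs, data.frame(gene_a = pool_a[seq_len(m)],
                                   gene_b = pool_b[seq_len(m)]))
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  n_true <- nrow(pairs)

  # per-tool membership over true pairs + false pairs
  set.seed(world_subseed(spec, "tools"))
  membership <- matrix(FALSE, n_true, spec$n_tools,
                       dimnames = list(NULL, spec$tools))
  false_pairs <- vector("list", spec$n_tools)
  names(false_pairs) <- spec$tools
  true_keys <- ordered_key(pairs$gene_a, pairs$gene_b)
  for (t in seq_len(spec$n_tools)) {
    membership[, t] <- stats::runif(n_true) < spec$recall[t]
    n_fp <- stats::rbinom(1L, n_true, spec$fp_rate[t])
    fp <- data.frame(gene_a = integer(0), gene_b = integer(0))
    while (nrow(fp) < n_fp) {
      cand <- data.frame(gene_a = sample(genes_a, n_fp, replace = TRUE),
                         gene_b = sample(genes_b, n_fp, replace = TRUE))
      cand <- cand[!(ordered_key(cand$gene_a, cand$gene_b) %in% true_keys), ]
      fp <- unique(rbind(fp, cand))
    }
    false_pairs[[t]] <- fp[seq_len(n_fp), , drop = FALSE]
    rownames(false_pairs[[t]]) <- NULL
  }

  # identifier catalogs: entrez + symbol per gene, two protein isoforms
  set.seed(world_subseed(spec, "ids"))
  make_ids <- function(genes, prefix) {
    i <- genes - (if (prefix == "FLY") GENE_BASE_A else GENE_BASE_B)
    sym <- sprintf("%sG%04d", prefix, i)
    iso1 <- sprintf("%sP%04d.1", prefix, i)
    iso2 <- sprintf("%sP%04d.2", prefix, i)
    len1 <- sample(seq(spec$seq_len_range[1L], spec$seq_len_range[2L]),
                   length(genes), replace = TRUE)
    len2 <- pmax(30L, as.integer(len1 * 0.7))
    tab <- rbind(
      data.frame(raw_id = as.character(genes), id_type = "entrez",
                 gene_id = genes, protein_length = NA_integer_),
      data.frame(raw_id = sym, id_type = "symbol", gene_id = genes,
                 protein_length = NA_integer_),
      data.frame(raw_id = iso1, id_type = "refseq_protein", gene_id = genes,
                 protein_length = len1),
      data.frame(raw_id = iso2, id_type = "refseq_protein", gene_id = genes,
                 protein_length = len2))
    list(table = tab, symbols = stats::setNames(sym, genes),
         iso = data.frame(gene_id = genes, iso1 = iso1, iso2 = iso2,
                          len1 = len1, len2 = len2))
  }
  prefix_a <- toupper(substr(spec$species_in, 1L, 3L))
  prefix_b <- toupper(substr(spec$species_out, 1L, 3L))
  ids_a <- make_ids(genes_a, "FLY"); ids_b <- make_ids(genes_b, "HUM")
  id_map_a <- load_id_map(ids_a$table, spec$species_in)
  id_map_b <- load_id_map(ids_b$table, spec$species_out)

  # raw tool tables with mixed identifier levels
  iso_of <- function(iso_tab, genes) {
    i <- match(genes, iso_tab$gene_id)
    ifelse(stats::runif(length(genes)) < 0.5, iso_tab$iso1[i], iso_tab$iso2[i])
  }
  tool_tables <- vector("list", spec$n_tools)
  names(tool_tables) <- spec$tools
  for (t in seq_len(spec$n_tools)) {
    tp <- rbind(pairs[membership[, t], , drop = FALSE], false_pairs[[t]])
    use_iso <- stats::runif(nrow(tp)) < spec$isoform_fraction
    raw_a <- ifelse(use_iso, iso_of(ids_a$iso, tp$gene_a),
                    as.character(tp$gene_a))
    raw_b <- ifelse(use_iso, iso_of(ids_b$iso, tp$gene_b),
                    as.character(tp$gene_b))
    score <- sprintf("%.3f", stats::runif(nrow(tp)))
    tab <- data.frame(raw_a = raw_a, raw_b = raw_b, score = score,
                      stringsAsFactors = FALSE)
    # duplicate ~10% of isoform rows at the other isoform level to force
    # gene-level collapsing
    dup <- which(use_iso)[stats::runif(sum(use_iso)) < 0.34]
    if (length(dup) > 0L) {
      extra <- data.frame(raw_a = iso_of(ids_a$iso, tp$gene_a[dup]),
                          raw_b = iso_of(ids_b$iso, tp$gene_b[dup]),
                          score = score[dup], stringsAsFactors = FALSE)
      tab <- rbind(tab, extra)
    }
    tool_tables[[t]] <- tab
  }
  tool_sets <- lapply(spec$tools, function(tn) {
    ingest_tool_predictions(tn, tool_tables[[tn]], id_map_a, id_map_b,
                            dialect = list(col_a = 1L, col_b = 2L,
                                           col_score = 3L))
  })
  names(tool_sets) <- spec$tools

  world <- structure(
    list(spec = spec,
         genes_a = genes_a, genes_b = genes_b,
         orphan_a = sort(orphan_a), orphan_b = sort(orphan_b),
         truth = list(pairs = pairs, membership = membership,
                      false_pairs = false_pairs),
         tool_tables = tool_tables, tool_sets = tool_sets,
         id_table_a = ids_a$table, id_table_b = ids_b$table,
         id_map_a = id_map_a, id_map_b = id_map_b,
         isoforms_a = ids_a$iso, isoforms_b = ids_b$iso,
         symbols_a = ids_a$symbols, symbols_b = ids_b$symbols),
    class = "ortho_world")
  if (!is.null(dir)) world$files <- write_world_files(world, dir)
  world
}

write_world_files <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  p <- file.path(dir, "id_map_a.tsv")
  utils::write.table(world$id_table_a, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "")
  files["id_map_a"] <- p
  p <- file.path(dir, "id_map_b.tsv")
  utils::write.table(world$id_table_b, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "")
  files["id_map_b"] <- p
  for (tn in names(world$tool_tables)) {
    p <- file.path(dir, paste0(tn, ".tsv"))
    utils::write.table(world$tool_tables[[tn]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files[tn] <- p
  }
  p <- file.path(dir, "truth_pairs.tsv")
  write_report_tsv(world$truth$pairs, p)
  files["truth_pairs"] <- p
  files
}

#' @export
print.ortho_world <- function(x, ...) {
  cat("ortho_world [", x$spec$species_in, " -> ", x$spec$species_out, "]: ",
      x$spec$n_genes, " genes/species, ", nrow(x$truth$pairs),
      " true pairs, ", x$spec$n_tools, " tools\n", sep = "")
  invisible(x)
}

# connected components of the true-pair graph; orthologous families share a
# GO branch so true pairs look functionally consistent
truth_families <- function(world) {
  pairs <- world$truth$pairs
  nodes <- unique(c(paste0("a", pairs$gene_a), paste0("b", pairs$gene_b)))
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(pairs))) {
      na <- paste0("a", pairs$gene_a[i]); nb <- paste0("b", pairs$gene_b[i])
      if (comp[na] != comp[nb]) {
        comp[c(na, nb)] <- min(comp[na], comp[nb])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Generate a GO ontology and annotation fixture
#'
#' Emits a rooted molecular-function DAG (root, branches, mid-level terms,
#' leaves -- at least three levels) in OBO text, and GAF-formatted
#' annotations in which true ortholog families are annotated to leaves of a
#' shared branch (so true pairs score high) while orphan genes draw random
#' branches. Evidence codes are sampled from the spec's mix, making the
#' MF1 / MF2 / MF3 strata strictly nested in practice.
#'
#' @param spec A [world_spec()].
#' @param world The matching [generate_orthology_world()] output.
#' @param n_branches Number of top-level branches (default 10).
#' @param dir Optional output directory (writes `go.obo`, `annotations.gaf`).
#' @return List with `obo_lines`, `gaf_lines`, `dag` (parsed `go_dag`),
#'   `annotations` (parsed `go_annotations`), `gene_branch` (named vector),
#'   and `files` when `dir` given.
#' @export
generate_go_fixture <- function(spec, world, n_branches = 10L, dir = NULL) {
  set.seed(world_subseed(spec, "go"))
  root <- "GO:0003674"
  branch <- sprintf("GO:%07d", 1000000L + seq_len(n_branches))
  terms <- root; parents <- list(); namespace <- character(0)
  parents[[root]] <- character(0); namespace[root] <- "molecular_function"
  leaves_of <- list()
  tid <- 1100000L
  for (b in seq_len(n_branches)) {
    terms <- c(terms, branch[b])
    parents[[branch[b]]] <- root
    namespace[branch[b]] <- "molecular_function"
    leaves <- character(0)
    for (mid in seq_len(3L)) {
      tid <- tid + 1L
      m <- sprintf("GO:%07d", tid)
      terms <- c(terms, m); parents[[m]] <- branch[b]
      namespace[m] <- "molecular_function"
      for (lf in seq_len(2L)) {
        tid <- tid + 1L
        l <- sprintf("GO:%07d", tid)
        terms <- c(terms, l); parents[[l]] <- m
        namespace[l] <- "molecular_function"
        leaves <- c(leaves, l)
      }
    }
    leaves_of[[branch[b]]] <- leaves
  }
  obo <- c("format-version: 1.2", "")
  for (t in terms) {
    obo <- c(obo, "[Term]", paste0("id: ", t),
             paste0("name: fixture term ", t),
             "namespace: molecular_function",
             if (length(parents[[t]]))
               paste0("is_a: ", parents[[t]], " ! parent") else NULL,
             "")
  }

  # branch index = family id cycled over branches
  fam <- truth_families(world)
  fam_ids <- match(fam, sort(unique(fam)))
  fam_branch <- stats::setNames(branch[(fam_ids - 1L) %% n_branches + 1L],
                                names(fam))
  all_genes <- c(world$genes_a, world$genes_b)
  side <- rep(c("a", "b"), c(length(world$genes_a), length(world$genes_b)))
  gene_branch <- character(length(all_genes))
  names(gene_branch) <- all_genes
  for (i in seq_along(all_genes)) {
    key <- paste0(side[i], all_genes[i])
    gene_branch[i] <- if (key %in% names(fam_branch)) fam_branch[[key]] else
      sample(branch, 1L)
  }
  rows <- list()
  codes <- names(spec$evidence_mix)
  for (i in seq_along(all_genes)) {
    if (stats::runif(1) > spec$annotation_density) next
    lv <- leaves_of[[gene_branch[i]]]
    k <- sample(2:3, 1L)
    tset <- sample(lv, min(k, length(lv)))
    ev <- sample(codes, length(tset), replace = TRUE,
                 prob = spec$evidence_mix)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = all_genes[i], term = tset, evidence = ev,
      stringsAsFactors = FALSE)
  }
  ann_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = integer(0), term = character(0),
               evidence = character(0))
  gaf <- c("!gaf-version: 2.1")
  if (nrow(ann_df) > 0L) {
    gaf <- c(gaf, sprintf(
      "FIX\t%d\tG%d\t\t%s\tFIX:ref\t%s\t\tF\tfixture gene\t\tprotein\ttaxon:0000\t20110831\tFIX\t\t",
      ann_df$gene_id, ann_df$gene_id, ann_df$term, ann_df$evidence))
  }
  dag <- build_go_dag(terms, namespace, parents)
  out <- list(obo_lines = obo, gaf_lines = gaf, dag = dag,
              annotations = go_annotations(ann_df),
              gene_branch = gene_branch)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(obo, file.path(dir, "go.obo"))
    writeLines(gaf, file.path(dir, "annotations.gaf"))
    out$files <- c(obo = file.path(dir, "go.obo"),
                   gaf = file.path(dir, "annotations.gaf"))
  }
  out
}

random_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

mutate_protein <- function(seq, keep_prob) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  ch <- strsplit(seq, "")[[1L]]
  flip <- stats::runif(length(ch)) >= keep_prob
  for (i in which(flip)) ch[i] <- sample(setdiff(aa, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate protein sequences with planted conserved domains
#'
#' For every true ortholog pair, emits two isoforms per gene (the longer
#' carries the full sequence; the shorter is an N-terminal truncation) in
#' which both orthologs share a planted "domain" block copied at the spec's
#' per-residue conservation level inside otherwise independent random
#' flanks. The planted construction guarantees domain identity above
#' overall identity. A domain-interval table and the realized per-pair
#' expected statistics accompany the FASTA text.
#'
#' @param spec A [world_spec()].
#' @param world The matching world.
#' @param n_pairs Number of true pairs to emit sequences for (default 50;
#'   pairs are taken in truth order).
#' @param dir Optional output directory (writes `proteins.fasta`,
#'   `domains.tsv`).
#' @return List with `fasta_lines`, `domains` (data.frame), `expected`
#'   (per-pair accessions, domain coordinates and realized domain
#'   identity), `sequences` (named residue strings), and `files` when
#'   `dir` given.
#' @export
generate_sequence_fixture <- function(spec, world, n_pairs = 50L,
                                      dir = NULL) {
  set.seed(world_subseed(spec, "seq"))
  pairs <- utils::head(world$truth$pairs, n_pairs)
  fasta <- character(0); seqs <- character(0)
  dom_rows <- list(); exp_rows <- list()
  dl <- spec$domain_len
  # each gene's sequence is generated once; genes in several pairs (the
  # one-to-many / many-to-one families) keep one sequence and partners are
  # derived from it
  made <- new.env(parent = emptyenv())  # side+gene -> list(seq, start)
  fresh_seq <- function(len) {
    start <- sample(seq_len(len - dl - 5L), 1L) + 2L
    list(seq = paste0(random_protein(start - 1L), random_protein(dl),
                      random_protein(len - start + 1L - dl)),
         start = start)
  }
  derive_partner <- function(src, len) {
    # domain: mutated copy at domain conservation; flanks: diverged copies
    # (inner part adjacent to the domain shared) at flank conservation
    start <- sample(seq_len(len - dl - 5L), 1L) + 2L
    dom_src <- substr(src$seq, src$start, src$start + dl - 1L)
    left_src <- substr(src$seq, 1L, src$start - 1L)
    right_src <- substr(src$seq, src$start + dl, nchar(src$seq))
    left_len <- start - 1L
    right_len <- len - start + 1L - dl
    li <- min(nchar(left_src), left_len)
    left <- paste0(random_protein(left_len - li),
                   if (li > 0L) mutate_protein(
                     substr(left_src, nchar(left_src) - li + 1L,
                            nchar(left_src)), spec$flank_conservation)
                   else "")
    ri <- min(nchar(right_src), right_len)
    right <- paste0(
      if (ri > 0L) mutate_protein(substr(right_src, 1L, ri),
                                  spec$flank_conservation) else "",
      random_protein(right_len - ri))
    list(seq = paste0(left, mutate_protein(dom_src, spec$domain_conservation),
                      right),
         start = start)
  }
  emit_gene <- function(key, rec, iso) {
    seqs[iso$iso1] <<- rec$seq
    seqs[iso$iso2] <<- substr(rec$seq, 1L,
                              max(30L, floor(nchar(rec$seq) * 0.7)))
    dom_rows[[length(dom_rows) + 1L]] <<- data.frame(
      accession = iso$iso1, name = "planted_domain",
      start = rec$start, end = rec$start + dl - 1L, stringsAsFactors = FALSE)
    assign(key, rec, envir = made)
  }
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    iso_a <- world$isoforms_a[match(ga, world$isoforms_a$gene_id), ]
    iso_b <- world$isoforms_b[match(gb, world$isoforms_b$gene_id), ]
    len_a <- max(iso_a$len1, dl + 20L); len_b <- max(iso_b$len1, dl + 20L)
    ka <- paste0("a", ga); kb <- paste0("b", gb)
    have_a <- exists(ka, envir = made); have_b <- exists(kb, envir = made)
    if (!have_a && !have_b) {
      rec_a <- fresh_seq(len_a)
      emit_gene(ka, rec_a, iso_a)
      rec_b <- derive_partner(rec_a, len_b)
      emit_gene(kb, rec_b, iso_b)
    } else if (have_a && !have_b) {
      rec_a <- get(ka, envir = made)
      rec_b <- derive_partner(rec_a, len_b)
      emit_gene(kb, rec_b, iso_b)
    } else if (!have_a && have_b) {
      rec_b <- get(kb, envir = made)
      rec_a <- derive_partner(rec_b, len_a)
      emit_gene(ka, rec_a, iso_a)
    } else {
      rec_a <- get(ka, envir = made); rec_b <- get(kb, envir = made)
    }
    da <- strsplit(substr(rec_a$seq, rec_a$start, rec_a$start + dl - 1L),
                   "")[[1L]]
    db <- strsplit(substr(rec_b$seq, rec_b$start, rec_b$start + dl - 1L),
                   "")[[1L]]
    exp_rows[[length(exp_rows) + 1L]] <- data.frame(
      gene_a = ga, gene_b = gb, acc_a = iso_a$iso1, acc_b = iso_b$iso1,
      domain_start_a = rec_a$start, domain_start_b = rec_b$start,
      domain_len = dl, domain_identity = mean(da == db),
      stringsAsFactors = FALSE)
  }
  for (acc in names(seqs)) {
    fasta <- c(fasta, paste0(">", acc, " synthetic fixture protein"),
               seqs[[acc]])
  }
  out <- list(fasta_lines = fasta,
              domains = do.call(rbind, dom_rows),
              expected = do.call(rbind, exp_rows),
              sequences = seqs)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(fasta, file.path(dir, "proteins.fasta"))
    utils::write.table(out$domains, file.path(dir, "domains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    out$files <- c(fasta = file.path(dir, "proteins.fasta"),
                   domains = file.path(dir, "domains.tsv"))
  }
  out
}

#' Generate disease/trait records with planted mapping routes
#'
#' Emits OMIM-like and GWAS-like record tables, a MeSH entry-term lookup, a
#' clinical-synopsis heading map, Y01/Y02 keyword lists and a
#' gene-to-literature-MeSH table. Every record is planted on one mapping
#' route (CS heading, entry term, Y01 rule, Y02 rule, or unmapped) in the
#' proportions of `route_mix`, and a stated fraction of true ortholog pairs
#' shares a planted literature disease category.
#'
#' @param spec A [world_spec()].
#' @param world The matching world.
#' @param n_records Number of disease/trait records (default 120).
#' @param route_mix Named proportions over routes cs, entry, y01, y02,
#'   unmapped.
#' @param shared_fraction Fraction of true pairs planted with a shared
#'   literature category (default 0.5).
#' @param dir Optional output directory.
#' @return List with `omim`, `gwas` (record data.frames), `lookup`
#'   (a [mesh_lookup()]), `literature` (named list), `truth` (per-record
#'   planted route; per-pair planted shared flag), and `files` when `dir`
#'   given.
#' @export
generate_disease_fixture <- function(spec, world, n_records = 120L,
                                     route_mix = c(cs = 0.25, entry = 0.35,
                                                   y01 = 0.12, y02 = 0.12,
                                                   unmapped = 0.16),
                                     shared_fraction = 0.5, dir = NULL) {
  set.seed(world_subseed(spec, "disease"))
  route_mix <- route_mix / sum(route_mix)
  cat_codes <- setdiff(mesh_category_table()$code, c("Y01", "Y02"))

  mesh_terms <- sprintf("fixture disease %02d", seq_len(30L))
  entry_tab <- data.frame(
    entry_term = c(mesh_terms, paste(mesh_terms, "synonym")),
    mesh_term = rep(mesh_terms, 2L),
    codes = rep(sample(cat_codes, 30L, replace = TRUE), 2L),
    stringsAsFactors = FALSE)
  cs_headings <- sprintf("CSHEAD_%s", sample(cat_codes, 12L))
  cs_map <- data.frame(cs_heading = cs_headings,
                       code = sub("CSHEAD_", "", cs_headings),
                       stringsAsFactors = FALSE)
  y01_kw <- c("cholesterol", "telomere length", "bone size", "tanning",
              "blood pressure measurement")
  y02_kw <- c("hair color", "eye color", "height", "freckling")
  lookup <- mesh_lookup(entry_terms = entry_tab, cs_heading_map = cs_map,
                        y01_keywords = y01_kw, y02_keywords = y02_kw)

  human_genes <- if (spec$species_out == "human") world$genes_b else
    world$genes_a
  routes <- sample(names(route_mix), n_records, replace = TRUE,
                   prob = route_mix)
  recs <- list()
  for (i in seq_len(n_records)) {
    genes <- sample(human_genes, sample(1:3, 1L))
    genes_str <- paste(genes, collapse = ",")
    r <- routes[i]
    if (r == "cs") {
      recs[[i]] <- data.frame(
        source = "OMIM_phenotype", omim_id = 600000L + i,
        raw_term = sprintf("csonly disorder %03d", i),
        cs_heading = sample(cs_headings, 1L), genes = genes_str,
        stringsAsFactors = FALSE)
    } else if (r == "entry") {
      base <- sample(mesh_terms, 1L)
      decorated <- paste0(toupper(substr(base, 1, 1)),
                          substr(base, 2, nchar(base)),
                          sample(c("", ", susceptibility to", " (finding)"),
                                 1L))
      recs[[i]] <- data.frame(
        source = sample(c("OMIM_phenotype", "GWAS"), 1L),
        omim_id = if (stats::runif(1) < 0.5) 600000L + i else NA_integer_,
        raw_term = decorated, cs_heading = "", genes = genes_str,
        stringsAsFactors = FALSE)
    } else if (r == "y01") {
      recs[[i]] <- data.frame(
        source = "GWAS", omim_id = NA_integer_,
        raw_term = paste(sample(c("HDL", "LDL", "serum"), 1L),
                         sample(y01_kw, 1L)),
        cs_heading = "", genes = genes_str, stringsAsFactors = FALSE)
    } else if (r == "y02") {
      recs[[i]] <- data.frame(
        source = "GWAS", omim_id = NA_integer_,
        raw_term = sample(y02_kw, 1L), cs_heading = "",
        genes = genes_str, stringsAsFactors = FALSE)
    } else {
      recs[[i]] <- data.frame(
        source = sample(c("OMIM_phenotype", "GWAS"), 1L),
        omim_id = NA_integer_,
        raw_term = sprintf("zqxv rare disorder %03d", i), cs_heading = "",
        genes = genes_str, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  omim <- records[records$source != "GWAS", , drop = FALSE]
  gwas <- records[records$source == "GWAS", , drop = FALSE]

  # literature categories: planted shared category for a fraction of pairs
  pairs <- world$truth$pairs
  shared <- stats::runif(nrow(pairs)) < shared_fraction
  lit <- list()
  add_lit <- function(lit, gene, code) {
    key <- as.character(gene)
    lit[[key]] <- unique(c(lit[[key]], code))
    lit
  }
  for (i in seq_len(nrow(pairs))) {
    if (shared[i]) {
      code <- sample(cat_codes, 1L)
      lit <- add_lit(lit, pairs$gene_a[i], code)
      lit <- add_lit(lit, pairs$gene_b[i], code)
    } else {
      two <- sample(cat_codes, 2L)  # distinct, so nothing shared is planted
      lit <- add_lit(lit, pairs$gene_a[i], two[1L])
      lit <- add_lit(lit, pairs$gene_b[i], two[2L])
    }
  }
  out <- list(omim = omim, gwas = gwas, records = records, lookup = lookup,
              literature = lit,
              truth = list(routes = routes, shared = shared))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    omim_out <- omim
    omim_out$record_type <- ifelse(omim_out$source == "OMIM_gene_locus",
                                   "gene_locus", "phenotype")
    utils::write.table(
      omim_out[, c("omim_id", "record_type", "raw_term", "cs_heading",
                   "genes")],
      file.path(dir, "omim_records.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE, na = "")
    utils::write.table(gwas[, c("raw_term", "genes")],
                       file.path(dir, "gwas_records.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(entry_tab, file.path(dir, "mesh_lookup.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    lit_df <- data.frame(
      gene_id = rep(names(lit), lengths(lit)),
      code = unlist(lit, use.names = FALSE), stringsAsFactors = FALSE)
    utils::write.table(lit_df, file.path(dir, "literature_mesh.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    out$files <- c(omim = file.path(dir, "omim_records.tsv"),
                   gwas = file.path(dir, "gwas_records.tsv"),
                   mesh = file.path(dir, "mesh_lookup.tsv"),
                   literature = file.path(dir, "literature_mesh.tsv"))
  }
  out
}
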