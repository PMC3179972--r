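# GO molecular-function semantic similarity: evidence-code stratification,
# information content, Lin/Resnik term similarity with best-match-average
# combination, per-tool weights and weighted pair scores.

# evidence-code subsets; MF2 = experimental + author/curator statement,
# MF3 = experimental only
GO_EXPERIMENTAL_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")
GO_CURATOR_CODES <- c("TAS", "NAS", "IC")

#' Read a GO ontology in OBO 1.2 format
#'
#' Parses `[Term]` stanzas, keeping the term ID, name, namespace and `is_a`
#' parents. Obsolete terms are dropped; `part_of` and other relationship
#' types are ignored. Only the subgraph reachable from the
#' molecular_function root is relevant to the similarity functions.
#'
#' @param path Path to an OBO file.
#' @return A `go_dag`: list with `terms` (character), `namespace` (named),
#'   `parents` (named list of is_a parents), `ancestors` (named list of
#'   ancestor sets, each including the term itself) and `root` (the
#'   molecular_function root if present).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(0); namespace <- character(0)
  parents <- list()
  cur_id <- NULL; cur_ns <- NA_character_; cur_par <- character(0)
  cur_obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur_id) && !cur_obsolete) {
      terms <<- c(terms, cur_id)
      namespace[cur_id] <<- cur_ns
      parents[[cur_id]] <<- cur_par
    }
  }
  for (ln in c(lines, "[end]")) {
    ln <- trimws(ln)
    if (grepl("^\\[", ln)) {
      if (in_term) flush()
      in_term <- identical(ln, "[Term]")
      cur_id <- NULL; cur_ns <- NA_character_; cur_par <- character(0)
      cur_obsolete <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur_id <- trimws(sub("^id:", "", ln))
    else if (grepl("^namespace:", ln)) cur_ns <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_obsolete: *true", ln)) cur_obsolete <- TRUE
    else if (grepl("^is_a:", ln)) {
      p <- trimws(sub("^is_a:", "", ln))
      p <- trimws(strsplit(p, "!", fixed = TRUE)[[1L]][1L])
      cur_par <- c(cur_par, p)
    }
  }
  build_go_dag(terms, namespace, parents)
}

# assemble + validate a DAG from parsed pieces; shared by read_obo and the
# fixture generator
build_go_dag <- function(terms, namespace, parents) {
  parents <- lapply(parents, function(p) intersect(p, terms))
  names(parents) <- terms
  mf_roots <- terms[vapply(parents, length, integer(1)) == 0L &
                    namespace[terms] %in% c("molecular_function", NA)]
  root <- if (length(mf_roots) >= 1L) mf_roots[[1L]] else NA_character_
  anc <- compute_ancestors(terms, parents)
  structure(list(terms = terms, namespace = namespace, parents = parents,
                 ancestors = anc, root = root),
            class = "go_dag")
}

# transitive closure of is_a, each term's set including itself; cycle-safe
# via DFS with an on-stack check
compute_ancestors <- function(terms, parents) {
  anc <- vector("list", length(terms))
  names(anc) <- terms
  visiting <- stats::setNames(rep(FALSE, length(terms)), terms)
  visit <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    if (visiting[[t]]) stop("cycle detected in ontology at ", t, call. = FALSE)
    visiting[[t]] <<- TRUE
    res <- t
    for (p in parents[[t]]) res <- union(res, visit(p))
    visiting[[t]] <<- FALSE
    anc[[t]] <<- res
    res
  }
  for (t in terms) visit(t)
  anc
}

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag: ", length(x$terms), " terms, root ", x$root, "\n", sep = "")
  invisible(x)
}

#' Read molecular-function annotations from a GAF 2.x file
#'
#' Uses columns 2 (gene/product ID), 5 (GO term), 7 (evidence code) and
#' 9 (aspect); only aspect `F` rows are kept. Comment lines (`!` or `#`)
#' are skipped.
#'
#' @param path Path to a GAF file.
#' @param dag Optional `go_dag`; if given, annotations to unknown terms are
#'   dropped.
#' @return A `go_annotations` object: data.frame with columns gene_id, term,
#'   evidence plus a `subset` attribute (`"MF1"`, i.e. unfiltered).
#' @export
read_gaf <- function(path, dag = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[!#]", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(go_annotations(data.frame(gene_id = integer(0),
                                     term = character(0),
                                     evidence = character(0))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 9L
  fields <- fields[ok]
  df <- data.frame(
    gene_id = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L))),
    term = vapply(fields, `[[`, character(1), 5L),
    evidence = vapply(fields, `[[`, character(1), 7L),
    aspect = vapply(fields, `[[`, character(1), 9L),
    stringsAsFactors = FALSE)
  df <- df[df$aspect == "F" & !is.na(df$gene_id), c("gene_id", "term", "evidence")]
  if (!is.null(dag)) df <- df[df$term %in% dag$terms, , drop = FALSE]
  go_annotations(df)
}

#' Construct a molecular-function annotation set
#'
#' @param df data.frame with columns gene_id (integer), term, evidence.
#' @param subset Label of the evidence subset the set represents.
#' @return A `go_annotations` object (data.frame subclass, de-duplicated).
#' @export
go_annotations <- function(df, subset = "MF1") {
  df <- unique(as.data.frame(df, stringsAsFactors = FALSE)[,
    c("gene_id", "term", "evidence")])
  df <- df[order(df$gene_id, df$term, df$evidence), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, subset = subset, class = c("go_annotations", "data.frame"))
}

#' Filter annotations by evidence-code subset
#'
#' `MF1` keeps all annotations. `MF2` keeps annotations supported by
#' experimental data or author/curator statements (EXP, IDA, IPI, IMP, IGI,
#' IEP, TAS, NAS, IC). `MF3` keeps only the experimental codes (EXP, IDA,
#' IPI, IMP, IGI, IEP). Genes left without any annotation drop out of the
#' set entirely; electronically inferred (IEA) annotations survive only MF1.
#'
#' @param annotations A `go_annotations` set.
#' @param subset `"MF1"`, `"MF2"` or `"MF3"`.
#' @return The filtered `go_annotations` set.
#' @export
filter_by_evidence <- function(annotations, subset = c("MF1", "MF2", "MF3")) {
  if (!(subset[1L] %in% c("MF1", "MF2", "MF3"))) {
    stop("unknown evidence subset '", subset[1L],
         "'; expected MF1, MF2 or MF3", call. = FALSE)
  }
  subset <- subset[1L]
  keep <- switch(subset,
    MF1 = rep(TRUE, nrow(annotations)),
    MF2 = annotations$evidence %in% c(GO_EXPERIMENTAL_CODES, GO_CURATOR_CODES),
    MF3 = annotations$evidence %in% GO_EXPERIMENTAL_CODES)
  go_annotations(as.data.frame(annotations)[keep, , drop = FALSE], subset)
}

#' Gene-to-term assignment list
#'
#' @param annotations A `go_annotations` set.
#' @return Named list: gene_id (as character) -> character vector of terms.
#' @export
gene_term_sets <- function(annotations) {
  if (nrow(annotations) == 0L) return(list())
  lapply(split(annotations$term, annotations$gene_id), unique)
}

#' Compute term information content over an annotation corpus
#'
#' Annotation counts are propagated up the DAG: a term's frequency `p(t)` is
#' the fraction of all (gene, term) annotations made to `t` or any of its
#' descendants, and `ic(t) = -ln p(t)`. The root therefore has IC 0 and IC
#' never decreases from parent to child. Terms with no annotation in the
#' corpus (p = 0) get no IC and are excluded from similarity computations.
#'
#' @param annotations A `go_annotations` corpus (use the subset you will
#'   score with).
#' @param dag A `go_dag`.
#' @return Named numeric vector of IC values for terms with p > 0.
#' @export
compute_term_ic <- function(annotations, dag) {
  ann <- unique(as.data.frame(annotations)[, c("gene_id", "term")])
  ann <- ann[ann$term %in% dag$terms, , drop = FALSE]
  if (nrow(ann) == 0L) stop("empty annotation corpus", call. = FALSE)
  total <- nrow(ann)
  # each annotation to t counts for every ancestor of t
  counts <- stats::setNames(rep(0L, length(dag$terms)), dag$terms)
  tab <- table(ann$term)
  for (t in names(tab)) {
    a <- dag$ancestors[[t]]
    counts[a] <- counts[a] + as.integer(tab[[t]])
  }
  counts <- counts[counts > 0L]
  -log(counts / total)
}

#' Semantic similarity of two GO terms
#'
#' Lin similarity: `2 * ic(MICA) / (ic(t1) + ic(t2))`, where the MICA is the
#' common ancestor with maximal information content. Identical terms with
#' positive IC score 1; if both terms have IC 0 (e.g. the root with itself)
#' the similarity is defined as 0. `method = "resnik"` returns `ic(MICA)`
#' unnormalized.
#'
#' @param t1,t2 Term IDs.
#' @param dag A `go_dag`.
#' @param ic IC vector from [compute_term_ic()].
#' @param method `"lin"` (default) or `"resnik"`.
#' @return Similarity value; Lin values lie in [0, 1].
#' @export
term_similarity <- function(t1, t2, dag, ic, method = c("lin", "resnik")) {
  method <- match.arg(method)
  if (!(t1 %in% dag$terms) || !(t2 %in% dag$terms)) {
    stop("term absent from DAG: ", if (t1 %in% dag$terms) t2 else t1,
         call. = FALSE)
  }
  if (is.na(ic[t1]) || is.na(ic[t2])) {
    stop("term without defined IC: ", if (is.na(ic[t1])) t1 else t2,
         call. = FALSE)
  }
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  common <- common[common %in% names(ic)]
  mica_ic <- if (length(common) == 0L) 0 else max(ic[common])
  if (method == "resnik") return(unname(mica_ic))
  denom <- unname(ic[t1] + ic[t2])
  if (denom == 0) return(0)
  if (t1 == t2) return(1)
  unname(2 * mica_ic / denom)
}

#' Functional similarity of two genes' term sets
#'
#' Best-match average (BMA): for every term of gene A take its best
#' similarity against gene B's terms, average these row maxima; do the same
#' for gene B against A; the score is the mean of the two averages. Empty
#' term sets make the score undefined (`NA`); callers exclude such pairs
#' from averages rather than treating them as zero.
#'
#' @param terms_a,terms_b Character vectors of GO terms.
#' @param dag A `go_dag`.
#' @param ic IC vector from [compute_term_ic()].
#' @param method Passed to [term_similarity()].
#' @return Similarity in [0, 1] for Lin, or `NA_real_` if not computable.
#' @export
gene_pair_similarity <- function(terms_a, terms_b, dag, ic,
                                 method = c("lin", "resnik")) {
  method <- match.arg(method)
  terms_a <- intersect(unique(terms_a), names(ic))
  terms_b <- intersect(unique(terms_b), names(ic))
  if (length(terms_a) == 0L || length(terms_b) == 0L) return(NA_real_)
  m <- matrix(0, length(terms_a), length(terms_b))
  for (i in seq_along(terms_a)) {
    for (j in seq_along(terms_b)) {
      m[i, j] <- term_similarity(terms_a[i], terms_b[j], dag, ic, method)
    }
  }
  (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2
}

#' Mean functional similarity of a tool's predicted pairs
#'
#' Averages [gene_pair_similarity()] over the pairs of one
#' [tool_pair_set()] for which both genes carry annotations in the given
#' set. Pairs with an unannotated side are excluded from the mean, and their
#' number is reported.
#'
#' @param tool_set A [tool_pair_set()].
#' @param annotations_a,annotations_b `go_annotations` for input and output
#'   species (may be the same object for a shared corpus).
#' @param dag A `go_dag`.
#' @param ic IC vector.
#' @param method Similarity method.
#' @return List with `mean_sim` (NA if no pair computable), `n_computable`,
#'   `n_pairs`.
#' @export
tool_mean_similarity <- function(tool_set, annotations_a, annotations_b,
                                 dag, ic, method = "lin") {
  sets_a <- gene_term_sets(annotations_a)
  sets_b <- gene_term_sets(annotations_b)
  sims <- numeric(0)
  n <- nrow(tool_set$pairs)
  for (i in seq_len(n)) {
    ta <- sets_a[[as.character(tool_set$pairs$gene_a[i])]]
    tb <- sets_b[[as.character(tool_set$pairs$gene_b[i])]]
    if (is.null(ta) || is.null(tb)) next
    s <- gene_pair_similarity(ta, tb, dag, ic, method)
    if (!is.na(s)) sims <- c(sims, s)
  }
  list(mean_sim = if (length(sims) == 0L) NA_real_ else mean(sims),
       n_computable = length(sims), n_pairs = n)
}

#' Derive per-tool weights from mean similarities
#'
#' Tools are weighted by their mean GO semantic similarity, normalized so
#' the median weight is exactly 1: `weight(tool) = mean_sim(tool) /
#' median(mean_sims)` (even counts use the midpoint of the two central
#' values). Tools whose mean is not computable are dropped.
#'
#' @param mean_sims Named numeric vector, tool -> mean similarity.
#' @return A `tool_weights` object: data.frame with columns tool, mean_sim,
#'   weight.
#' @export
compute_tool_weights <- function(mean_sims) {
  mean_sims <- mean_sims[!is.na(mean_sims)]
  if (length(mean_sims) == 0L) {
    stop("no tool has a computable mean similarity", call. = FALSE)
  }
  med <- stats::median(mean_sims)
  if (med <= 0) stop("median mean similarity is not positive", call. = FALSE)
  out <- data.frame(tool = names(mean_sims),
                    mean_sim = unname(mean_sims),
                    weight = unname(mean_sims / med),
                    stringsAsFactors = FALSE)
  structure(out, class = c("tool_weights", "data.frame"))
}

#' Weighted score of an ortholog pair
#'
#' The weighted score is the sum of the supporting tools' weights; with all
#' weights equal to 1 it coincides with the simple count score.
#'
#' @param supporting_tools Character vector of tool names (or a single
#'   comma-joined string).
#' @param weights A [compute_tool_weights()] result.
#' @return Numeric weighted score.
#' @export
weighted_score <- function(supporting_tools, weights) {
  if (length(supporting_tools) == 1L && grepl(",", supporting_tools)) {
    supporting_tools <- strsplit(supporting_tools, ",", fixed = TRUE)[[1L]]
  }
  supporting_tools <- supporting_tools[nzchar(supporting_tools)]
  idx <- match(supporting_tools, weights$tool)
  if (anyNA(idx)) {
    stop("no weight for tool(s): ",
         paste(supporting_tools[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sum(weights$weight[idx])
}

#' Fill the weighted-score column of an integrated table
#'
#' @param pairs An `ortho_table`.
#' @param weights A [compute_tool_weights()] result covering every
#'   supporting tool in the table.
#' @return The table with `weighted_score` populated.
#' @export
add_weighted_scores <- function(pairs, weights) {
  out <- as.data.frame(pairs)
  out$weighted_score <- vapply(out$supporting_tools, weighted_score,
                               numeric(1), weights = weights,
                               USE.NAMES = FALSE)
  restore_ortho_attrs(out, pairs)
}
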