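# Benchmarking: sensitivity and specificity of any predictor against curated
# reference pair sets and a lineage-specific negative gene set, plus
# coverage/increase statistics.

#' Read a curated reference pair set
#'
#' Tab-separated `(gene_a, gene_b, subset_label)`; the labeled subsets
#' partition the pairs (e.g. transmembrane / kinase / oxphos).
#'
#' @param path File path.
#' @return A `reference_pairs` object: data.frame with columns gene_a,
#'   gene_b, subset; attribute `subset_sizes`.
#' @export
read_reference_pairs <- function(path) {
  parsed <- read_tsv_plain(path)
  rows <- lapply(parsed$fields, function(f) {
    data.frame(gene_a = as.integer(f[1L]), gene_b = as.integer(f[2L]),
               subset = if (length(f) >= 3L) f[3L] else "default",
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(gene_a = integer(0), gene_b = integer(0),
               subset = character(0))
  reference_pairs(df)
}

#' @rdname read_reference_pairs
#' @param df data.frame with columns gene_a, gene_b and optionally subset.
#' @export
reference_pairs <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$subset)) df$subset <- "default"
  df <- unique(df[, c("gene_a", "gene_b", "subset")])
  rownames(df) <- NULL
  structure(df, subset_sizes = table(df$subset),
            class = c("reference_pairs", "data.frame"))
}

#' Read a lineage-specific negative gene set
#'
#' One gene ID per line; genes asserted to have no ortholog outside their
#' lineage, used to measure false-positive ortholog calls.
#'
#' @param path File path.
#' @param species Species the genes belong to.
#' @return A `negative_genes` object (integer vector with a species
#'   attribute).
#' @export
read_negative_genes <- function(path, species) {
  assert_species(species)
  parsed <- read_tsv_plain(path)
  genes <- unique(as.integer(vapply(parsed$fields, `[[`, character(1), 1L)))
  if (length(genes) == 0L) stop("empty negative gene set", call. = FALSE)
  structure(genes, species = species, class = "negative_genes")
}

pred_pairs_df <- function(predicted) {
  if (inherits(predicted, "tool_pair_set")) return(predicted$pairs)
  as.data.frame(predicted, stringsAsFactors = FALSE)
}

#' Sensitivity against a reference pair set
#'
#' The percentage of reference pairs recovered by the predictor. Matching
#' is unordered: a predicted (b, a) recovers reference (a, b).
#'
#' @param predicted An `ortho_table`, [tool_pair_set()] or data.frame with
#'   gene_a, gene_b.
#' @param reference A [reference_pairs()] set.
#' @return List with `pct` (rounded half-up), `pct_raw`, `recovered`,
#'   `total`.
#' @export
sensitivity <- function(predicted, reference) {
  if (nrow(reference) == 0L) stop("empty reference set", call. = FALSE)
  pred <- pred_pairs_df(predicted)
  ref_keys <- unordered_key(reference$gene_a, reference$gene_b)
  pred_keys <- unique(unordered_key(pred$gene_a, pred$gene_b))
  recovered <- sum(ref_keys %in% pred_keys)
  total <- length(ref_keys)
  list(pct = round_half_up(100 * recovered / total),
       pct_raw = 100 * recovered / total,
       recovered = recovered, total = total)
}

#' Specificity against a reference pair set
#'
#' Queries the predictor with every gene appearing in the reference set (on
#' either species' side) and measures what fraction of the returned pairs
#' are reference pairs. Returned pairs are de-duplicated as unordered
#' pairs, so a pair reached from both of its genes counts once.
#'
#' @inheritParams sensitivity
#' @return List with `pct` (rounded half-up, `NA` if nothing returned),
#'   `pct_raw`, `numerator`, `denominator`.
#' @export
specificity_vs_reference <- function(predicted, reference) {
  pred <- pred_pairs_df(predicted)
  q_genes <- unique(c(reference$gene_a, reference$gene_b))
  hit <- pred$gene_a %in% q_genes | pred$gene_b %in% q_genes
  returned <- unique(unordered_key(pred$gene_a[hit], pred$gene_b[hit]))
  ref_keys <- unordered_key(reference$gene_a, reference$gene_b)
  num <- sum(returned %in% ref_keys)
  den <- length(returned)
  list(pct = if (den == 0L) NA_real_ else round_half_up(100 * num / den),
       pct_raw = if (den == 0L) NA_real_ else 100 * num / den,
       numerator = num, denominator = den)
}

#' Specificity against a lineage-specific negative set
#'
#' The percentage of negative (lineage-specific) genes for which the
#' predictor returns no ortholog in the target species -- genes it
#' correctly leaves partnerless.
#'
#' @inheritParams sensitivity
#' @param negatives A [read_negative_genes()] set (genes on the input-species
#'   side of the predictor's table).
#' @return List with `pct` (rounded half-up), `pct_raw`,
#'   `without_ortholog`, `total`.
#' @export
specificity_vs_negative <- function(predicted, negatives) {
  if (length(negatives) == 0L) stop("empty negative set", call. = FALSE)
  pred <- pred_pairs_df(predicted)
  with_orth <- unique(pred$gene_a)
  n_without <- sum(!(as.integer(negatives) %in% with_orth))
  total <- length(negatives)
  list(pct = round_half_up(100 * n_without / total),
       pct_raw = 100 * n_without / total,
       without_ortholog = n_without, total = total)
}

#' Coverage and per-tool increase statistics
#'
#' For the integrated table and each contributing tool: distinct genes
#' covered on each species' side, total pair counts, relationship-class
#' counts, and the integrated tool's percent increase in coverage over each
#' individual tool, `100 * (integrated / tool - 1)`, rounded half-up.
#'
#' @param integrated An `ortho_table`.
#' @param tool_sets List of [tool_pair_set()] objects.
#' @return List with `coverage` (data.frame: source, n_pairs,
#'   genes_covered_a, genes_covered_b), `increase` (data.frame: tool,
#'   increase_pct_a, increase_pct_b, increase_pct_pairs; `NA` where a tool
#'   has zero pairs) and `class_counts`.
#' @export
coverage_and_increase <- function(integrated, tool_sets) {
  cov_row <- function(source, df) {
    data.frame(source = source, n_pairs = nrow(df),
               genes_covered_a = length(unique(df$gene_a)),
               genes_covered_b = length(unique(df$gene_b)),
               stringsAsFactors = FALSE)
  }
  cov <- rbind(
    do.call(rbind, lapply(tool_sets, function(s) cov_row(s$tool, s$pairs))),
    cov_row("integrated", integrated))
  rownames(cov) <- NULL
  int_row <- cov[cov$source == "integrated", ]
  inc <- do.call(rbind, lapply(tool_sets, function(s) {
    row <- cov[cov$source == s$tool, ]
    pct <- function(int_n, tool_n) {
      if (tool_n == 0L) NA_real_ else round_half_up(100 * (int_n / tool_n - 1))
    }
    data.frame(tool = s$tool,
               increase_pct_a = pct(int_row$genes_covered_a, row$genes_covered_a),
               increase_pct_b = pct(int_row$genes_covered_b, row$genes_covered_b),
               increase_pct_pairs = pct(int_row$n_pairs, row$n_pairs),
               stringsAsFactors = FALSE)
  }))
  rownames(inc) <- NULL
  cls <- attr(classify_relationships(integrated), "class_counts")
  list(coverage = cov, increase = inc, class_counts = cls)
}

#' Full evaluation of predictors against reference and negative sets
#'
#' Scores the integrated table and every individual tool with
#' [sensitivity()], [specificity_vs_reference()] and (optionally)
#' [specificity_vs_negative()], and appends [coverage_and_increase()].
#'
#' @param integrated An `ortho_table`.
#' @param tool_sets List of [tool_pair_set()] objects.
#' @param reference A [reference_pairs()] set.
#' @param negatives Optional [read_negative_genes()] set.
#' @return An `evaluation_report`: list with `by_predictor` (data.frame of
#'   per-predictor statistics), `coverage`, `increase`, `class_counts`.
#' @export
evaluation_report <- function(integrated, tool_sets, reference,
                              negatives = NULL) {
  preds <- c(stats::setNames(tool_sets,
                             vapply(tool_sets, function(s) s$tool,
                                    character(1))),
             list(integrated = integrated))
  rows <- lapply(names(preds), function(nm) {
    p <- preds[[nm]]
    sens <- sensitivity(p, reference)
    spec <- specificity_vs_reference(p, reference)
    neg <- if (is.null(negatives)) NULL else specificity_vs_negative(p, negatives)
    data.frame(predictor = nm,
               sensitivity_pct = sens$pct,
               sens_recovered = sens$recovered, sens_total = sens$total,
               specificity_pct = spec$pct,
               spec_numerator = spec$numerator,
               spec_denominator = spec$denominator,
               neg_specificity_pct = if (is.null(neg)) NA_real_ else neg$pct,
               neg_without_ortholog = if (is.null(neg)) NA_integer_ else
                 neg$without_ortholog,
               neg_total = if (is.null(neg)) NA_integer_ else neg$total,
               stringsAsFactors = FALSE)
  })
  ci <- coverage_and_increase(integrated, tool_sets)
  structure(list(by_predictor = do.call(rbind, rows),
                 coverage = ci$coverage, increase = ci$increase,
                 class_counts = ci$class_counts),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  print(x$by_predictor, row.names = FALSE)
  cat("\nRelationship classes:\n")
  print(x$class_counts)
  invisible(x)
}
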