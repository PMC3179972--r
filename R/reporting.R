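# Pipeline entry points: validated run configuration and the end-to-end
# query, evaluation and disease-query drivers the command-line script wraps.

#' Validated run configuration
#'
#' Bundles the knobs of an integration run. Unknown keys are rejected so a
#' typo never silently falls back to a default.
#'
#' @param species_in,species_out Ordered species pair.
#' @param tool_sets Named list of [tool_pair_set()] objects (already
#'   ingested), or `NULL` if `tool_files` is given.
#' @param tool_files Named character vector of per-tool TSV paths.
#' @param id_map_a,id_map_b `id_map` objects, or file paths.
#' @param selected_tools Tools to include (default all).
#' @param filter `"none"`, `"score_ge2"`, `"score_ge3"` or `"best_match"`.
#' @param go_subset Evidence subset for weighting, `"MF1"`/`"MF2"`/`"MF3"`
#'   (default `"MF2"`).
#' @param similarity_method `"lin"` (default) or `"resnik"`.
#' @param weights Optional precomputed [compute_tool_weights()] result.
#' @param seed Optional integer seed for fixture subcommands.
#' @param out_dir Optional output directory.
#' @param ... Unknown keys: always an error.
#' @return A `run_config` object.
#' @export
run_config <- function(species_in, species_out, tool_sets = NULL,
                       tool_files = NULL, id_map_a = NULL, id_map_b = NULL,
                       selected_tools = NULL,
                       filter = c("none", "score_ge2", "score_ge3",
                                  "best_match"),
                       go_subset = "MF2",
                       similarity_method = c("lin", "resnik"),
                       weights = NULL, seed = NULL, out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0L) {
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  }
  assert_species(species_in); assert_species(species_out)
  filter <- match.arg(filter)
  similarity_method <- match.arg(similarity_method)
  if (!(go_subset %in% c("MF1", "MF2", "MF3"))) {
    stop("invalid config key go_subset: '", go_subset, "'", call. = FALSE)
  }
  if (is.character(id_map_a)) id_map_a <- load_id_map(id_map_a, species_in)
  if (is.character(id_map_b)) id_map_b <- load_id_map(id_map_b, species_out)
  if (is.null(tool_sets)) {
    if (is.null(tool_files)) {
      stop("config needs tool_sets or tool_files", call. = FALSE)
    }
    tool_sets <- lapply(names(tool_files), function(tn) {
      ingest_tool_predictions(tn, tool_files[[tn]], id_map_a, id_map_b,
                              dialect = list(col_a = 1L, col_b = 2L,
                                             col_score = 3L))
    })
    names(tool_sets) <- names(tool_files)
  }
  structure(list(species_in = species_in, species_out = species_out,
                 tool_sets = tool_sets,
                 id_map_a = id_map_a, id_map_b = id_map_b,
                 selected_tools = selected_tools %||% names(tool_sets),
                 filter = filter, go_subset = go_subset,
                 similarity_method = similarity_method, weights = weights,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

apply_config_filter <- function(pairs, filter) {
  switch(filter,
         none = pairs,
         score_ge2 = apply_score_filter(pairs, 2L),
         score_ge3 = apply_score_filter(pairs, 3L),
         best_match = apply_best_match_filter(pairs))
}

#' End-to-end ortholog query
#'
#' Normalizes the input identifiers, integrates the selected tools, fills
#' weighted scores when weights are available, applies the configured
#' filter, classifies relationships, and returns the result rows for the
#' queried genes together with the unmapped-identifier report. Batch mode:
#' any number of IDs, of mixed types.
#'
#' @param config A [run_config()].
#' @param input_ids Character vector of raw identifiers (input species).
#' @param declared_type Optional identifier type restriction for the whole
#'   batch.
#' @return List with `table` (result rows, `ortho_table` columns plus
#'   relationship_class), `unmapped` (data.frame), `query_genes` (resolved
#'   gene IDs).
#' @export
run_ortholog_query <- function(config, input_ids, declared_type = NULL) {
  stopifnot(inherits(config, "run_config"))
  report <- unmapped_report()
  genes <- sort(unique(unlist(lapply(input_ids, normalize_identifier,
                                     id_map = config$id_map_a,
                                     declared_type = declared_type,
                                     report = report))))
  integrated <- integrate_tools(config$tool_sets, config$selected_tools)
  if (!is.null(config$weights)) {
    integrated <- add_weighted_scores(integrated, config$weights)
  }
  filtered <- apply_config_filter(integrated, config$filter)
  classified <- classify_relationships(filtered)
  res <- classified[classified$gene_a %in% genes, , drop = FALSE]
  res <- restore_ortho_attrs(as.data.frame(res), filtered)
  list(table = res, unmapped = as.data.frame(report), query_genes = genes)
}

#' End-to-end evaluation run
#'
#' Integrates the configured tools and scores the integrated table plus
#' every individual tool against a reference pair set and an optional
#' negative gene set, appending coverage/increase statistics.
#'
#' @param config A [run_config()].
#' @param reference A [reference_pairs()] set or file path.
#' @param negatives Optional [read_negative_genes()] set or file path
#'   (input-species genes).
#' @return An [evaluation_report()].
#' @export
run_evaluation <- function(config, reference, negatives = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(reference)) reference <- read_reference_pairs(reference)
  if (is.character(negatives)) {
    negatives <- read_negative_genes(negatives, config$species_in)
  }
  integrated <- apply_config_filter(
    integrate_tools(config$tool_sets, config$selected_tools), config$filter)
  evaluation_report(integrated, config$tool_sets[config$selected_tools],
                    reference, negatives)
}

#' End-to-end disease/trait query
#'
#' Two directions: query with a disease term, category or OMIM IDs to get
#' human genes and their model-organism orthologs; or query with
#' model-organism genes to get their human orthologs and disease
#' annotations (rows without a human ortholog are flagged).
#'
#' @param config A [run_config()] whose species pair is human -> model
#'   organism (tables oriented the other way are transposed via
#'   [transpose_ortho_table()] by the caller).
#' @param records Disease records with categories assigned
#'   ([assign_category()]).
#' @param term,category,omim_ids Disease-side query selectors.
#' @param model_genes Gene-side query: integer IDs in the model organism.
#' @return For disease-side queries, the [join_disease_orthologs()] table.
#'   For gene-side queries, a data.frame (model_gene, human_gene,
#'   simple_score, raw_term, categories, no_ortholog).
#' @export
run_disease_query <- function(config, records, term = NULL, category = NULL,
                              omim_ids = NULL, model_genes = NULL) {
  stopifnot(inherits(config, "run_config"))
  integrated <- integrate_tools(config$tool_sets, config$selected_tools)
  if (!is.null(config$weights)) {
    integrated <- add_weighted_scores(integrated, config$weights)
  }
  if (is.null(model_genes)) {
    if (is.null(term) && is.null(category) && is.null(omim_ids)) {
      stop("empty query: give term, category, omim_ids or model_genes",
           call. = FALSE)
    }
    return(join_disease_orthologs(
      records, integrated,
      filter_mode = if (config$filter == "none") "none" else config$filter,
      term = term, category = category, omim_ids = omim_ids))
  }
  # gene-side: model organism -> human diseases
  rev_tab <- transpose_ortho_table(
    apply_config_filter(integrated, config$filter))
  gene_lists <- split_genes(records$genes)
  out <- list()
  for (g in model_genes) {
    partners <- rev_tab[rev_tab$gene_a == g, , drop = FALSE]
    if (nrow(partners) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        model_gene = g, human_gene = NA_integer_,
        simple_score = NA_integer_, raw_term = "", categories = "",
        no_ortholog = TRUE, stringsAsFactors = FALSE)
      next
    }
    for (j in seq_len(nrow(partners))) {
      hg <- partners$gene_b[j]
      hit <- vapply(gene_lists, function(gl) hg %in% gl, logical(1))
      if (!any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          model_gene = g, human_gene = hg,
          simple_score = partners$simple_score[j], raw_term = "",
          categories = "", no_ortholog = FALSE, stringsAsFactors = FALSE)
      } else {
        for (r in which(hit)) {
          out[[length(out) + 1L]] <- data.frame(
            model_gene = g, human_gene = hg,
            simple_score = partners$simple_score[j],
            raw_term = records$raw_term[r],
            categories = records$categories[r] %||% "",
            no_ortholog = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
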