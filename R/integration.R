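# Consensus integration: merge gene-level pair sets from several source tools
# into one table with the simple count score, provenance, filters and
# relationship classification.

#' Construct a tool pair set
#'
#' Container for the gene-level ortholog pairs predicted by one source tool
#' for one ordered species pair. The pair list is stored as a set (duplicates
#' collapsed); any tool-native scores are preserved verbatim as strings.
#'
#' @param tool_name Name of the source tool.
#' @param species_in,species_out Ordered species pair (input, output).
#' @param pairs data.frame with integer columns gene_a, gene_b and optionally
#'   a logical `ambiguous` column from [collapse_to_gene_level()].
#' @param original_scores Optional character vector of tool-native scores,
#'   one per row of `pairs` (kept verbatim).
#' @return An object of class `tool_pair_set`.
#' @export
tool_pair_set <- function(tool_name, species_in, species_out, pairs,
                          original_scores = NULL) {
  assert_species(species_in); assert_species(species_out)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) > 0L) {
    stopifnot(is.numeric(pairs$gene_a), is.numeric(pairs$gene_b))
  } else {
    pairs <- data.frame(gene_a = integer(0), gene_b = integer(0),
                        ambiguous = logical(0))
  }
  if (is.null(pairs$ambiguous)) pairs$ambiguous <- FALSE
  key <- ordered_key(pairs$gene_a, pairs$gene_b)
  scores <- NULL
  if (!is.null(original_scores) && nrow(pairs) > 0L) {
    scores <- stats::setNames(as.character(original_scores), key)
    scores <- scores[!duplicated(names(scores))]
  }
  dup <- duplicated(key)
  if (any(dup)) {
    amb <- tapply(pairs$ambiguous, key, any)
    pairs <- pairs[!dup, , drop = FALSE]
    pairs$ambiguous <- as.logical(amb[ordered_key(pairs$gene_a, pairs$gene_b)])
  }
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b),
                 c("gene_a", "gene_b", "ambiguous"), drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(tool = tool_name,
                 species_pair = c(species_in, species_out),
                 pairs = pairs,
                 original_scores = scores),
            class = "tool_pair_set")
}

#' @export
print.tool_pair_set <- function(x, ...) {
  cat("tool_pair_set '", x$tool, "' [", x$species_pair[1], " -> ",
      x$species_pair[2], "]: ", nrow(x$pairs), " gene pairs\n", sep = "")
  invisible(x)
}

#' Ingest one tool's raw prediction table
#'
#' Parses a tab-separated prediction table in a tool's declared dialect,
#' normalizes identifiers on both sides through the species ID maps, and
#' collapses isoform-level rows to gene level. The dialect is a list naming
#' the relevant columns: `col_a`, `col_b` (required), `col_score` (optional),
#' `type_a`, `type_b` (optional declared identifier types).
#'
#' @param tool_name Tool name.
#' @param table File path or data.frame of raw predictions.
#' @param id_map_a,id_map_b `id_map`s for input and output species.
#' @param dialect List with elements col_a, col_b and optionally col_score,
#'   type_a, type_b. Defaults to columns 1 and 2, score in column 3 if
#'   present.
#' @param report Optional [unmapped_report()].
#' @return A [tool_pair_set()].
#' @export
ingest_tool_predictions <- function(tool_name, table, id_map_a, id_map_b,
                                    dialect = list(col_a = 1L, col_b = 2L),
                                    report = NULL) {
  if (is.character(table) && length(table) == 1L) {
    parsed <- read_tsv_plain(table)
    fields <- parsed$fields
    lnum <- parsed$line_numbers
  } else {
    tab <- as.data.frame(table, stringsAsFactors = FALSE)
    fields <- lapply(seq_len(nrow(tab)),
                     function(i) as.character(unlist(tab[i, , drop = TRUE])))
    lnum <- seq_along(fields)
  }
  ca <- dialect$col_a %||% 1L
  cb <- dialect$col_b %||% 2L
  cs <- dialect$col_score
  need <- max(ca, cb, cs %||% 0L)
  raw_a <- character(0); raw_b <- character(0); raw_s <- character(0)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < need) {
      stop("unparseable row for tool '", tool_name, "' at line ", lnum[i],
           ": expected at least ", need, " columns, got ", length(f),
           call. = FALSE)
    }
    raw_a <- c(raw_a, f[ca]); raw_b <- c(raw_b, f[cb])
    raw_s <- c(raw_s, if (is.null(cs)) NA_character_ else f[cs])
  }
  # resolve row by row so tool scores follow their pair through the collapse
  out <- data.frame(gene_a = integer(0), gene_b = integer(0),
                    ambiguous = logical(0))
  score_of <- character(0)
  for (i in seq_along(raw_a)) {
    g <- collapse_to_gene_level(
      data.frame(a = raw_a[i], b = raw_b[i], stringsAsFactors = FALSE),
      id_map_a, id_map_b, dialect$type_a, dialect$type_b, report)
    if (nrow(g) == 0L) next
    out <- rbind(out, g)
    k <- ordered_key(g$gene_a, g$gene_b)
    new <- !(k %in% names(score_of))
    if (!is.null(cs)) {
      score_of[k[new]] <- raw_s[i]
    }
  }
  scores <- if (is.null(cs) || nrow(out) == 0L) NULL else
    unname(score_of[ordered_key(out$gene_a, out$gene_b)])
  tool_pair_set(tool_name, id_map_a$species, id_map_b$species, out,
                original_scores = scores)
}

#' Integrate tool pair sets into a scored union table
#'
#' Forms the union of the selected tools' gene-pair sets. Each output pair
#' carries a simple score equal to the number of selected tools predicting
#' it, the full list of supporting tools, any tool-native scores, and an
#' `ambiguous_source_id` flag if any contributing tool record was ambiguous.
#' Output order is canonical: by gene_a, then descending simple score, then
#' gene_b.
#'
#' @param tool_sets List of [tool_pair_set()] objects over the same ordered
#'   species pair.
#' @param selected_tools Character vector of tool names to include; defaults
#'   to all tools present.
#' @return An `ortho_table`: a data.frame with columns gene_a, gene_b,
#'   simple_score, weighted_score (NA until [add_weighted_scores()]),
#'   supporting_tools (comma-joined), original_scores (semicolon-joined
#'   `tool:score`), flags (comma-joined); attributes `species_pair` and
#'   `selected_tools`.
#' @export
integrate_tools <- function(tool_sets, selected_tools = NULL) {
  stopifnot(length(tool_sets) > 0L)
  names(tool_sets) <- vapply(tool_sets, function(s) s$tool, character(1))
  sp <- tool_sets[[1L]]$species_pair
  for (s in tool_sets) {
    if (!identical(s$species_pair, sp)) {
      stop("all tool pair sets must share the same ordered species pair",
           call. = FALSE)
    }
  }
  selected_tools <- selected_tools %||% names(tool_sets)
  if (length(selected_tools) == 0L) stop("selected_tools is empty", call. = FALSE)
  missing <- setdiff(selected_tools, names(tool_sets))
  if (length(missing) > 0L) {
    stop("unknown tool(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sets <- tool_sets[selected_tools]
  support <- list(); amb <- list(); orig <- list()
  for (s in sets) {
    k <- ordered_key(s$pairs$gene_a, s$pairs$gene_b)
    for (j in seq_along(k)) {
      support[[k[j]]] <- c(support[[k[j]]], s$tool)
      amb[[k[j]]] <- isTRUE(amb[[k[j]]]) || s$pairs$ambiguous[j]
      sc <- s$original_scores[k[j]]
      if (!is.null(s$original_scores) && !is.na(sc)) {
        orig[[k[j]]] <- c(orig[[k[j]]], paste0(s$tool, ":", sc))
      }
    }
  }
  keys <- names(support)
  if (length(keys) == 0L) {
    out <- data.frame(gene_a = integer(0), gene_b = integer(0),
                      simple_score = integer(0), weighted_score = numeric(0),
                      supporting_tools = character(0),
                      original_scores = character(0), flags = character(0),
                      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(keys, "|", fixed = TRUE)
    out <- data.frame(
      gene_a = as.integer(vapply(parts, `[[`, character(1), 1L)),
      gene_b = as.integer(vapply(parts, `[[`, character(1), 2L)),
      simple_score = vapply(support, length, integer(1)),
      weighted_score = NA_real_,
      supporting_tools = vapply(support, function(v)
        paste(selected_tools[selected_tools %in% v], collapse = ","),
        character(1)),
      original_scores = vapply(keys, function(k)
        paste(orig[[k]] %||% character(0), collapse = ";"), character(1)),
      flags = vapply(keys, function(k)
        if (isTRUE(amb[[k]])) "ambiguous_source_id" else "", character(1)),
      stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_a, -out$simple_score, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, species_pair = sp, selected_tools = selected_tools,
            class = c("ortho_table", "data.frame"))
}

restore_ortho_attrs <- function(out, template) {
  rownames(out) <- NULL
  structure(out, species_pair = attr(template, "species_pair"),
            selected_tools = attr(template, "selected_tools"),
            class = c("ortho_table", "data.frame"))
}

add_flag <- function(flags, flag) {
  ifelse(nzchar(flags), paste(flags, flag, sep = ","), flag)
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ",", fixed = TRUE), function(f) flag %in% f,
         logical(1))
}

#' Filter an integrated table by simple score
#'
#' Keeps every pair supported by at least `threshold` tools. A query gene
#' whose single candidate falls below the threshold keeps that candidate,
#' flagged `low_score_only_match`, so a gene is never left partnerless by the
#' filter when it had exactly one (weak) prediction. With
#' `rescue = "best_below_threshold"` the rescue instead keeps the
#' best-scoring sub-threshold candidates of genes with no passing candidate.
#'
#' @param pairs An `ortho_table`.
#' @param threshold Integer threshold, 2 or 3 (other values only with
#'   `allow_any_threshold = TRUE`).
#' @param rescue `"only_match"` (default) or `"best_below_threshold"`.
#' @param allow_any_threshold Permit thresholds outside {2, 3}.
#' @return The filtered `ortho_table`.
#' @export
apply_score_filter <- function(pairs, threshold = 2L,
                               rescue = c("only_match",
                                          "best_below_threshold"),
                               allow_any_threshold = FALSE) {
  rescue <- match.arg(rescue)
  if (!(threshold %in% c(2L, 3L)) && !allow_any_threshold) {
    stop("score filter threshold must be 2 or 3 (use allow_any_threshold ",
         "to override)", call. = FALSE)
  }
  if (nrow(pairs) == 0L) return(pairs)
  keep <- pairs$simple_score >= threshold
  flags <- pairs$flags
  by_gene <- split(seq_len(nrow(pairs)), pairs$gene_a)
  for (idx in by_gene) {
    if (any(pairs$simple_score[idx] >= threshold)) next
    if (rescue == "only_match") {
      if (length(idx) == 1L) {
        keep[idx] <- TRUE
        flags[idx] <- add_flag(flags[idx], "low_score_only_match")
      }
    } else {
      best <- idx[pairs$simple_score[idx] == max(pairs$simple_score[idx])]
      keep[best] <- TRUE
      flags[best] <- add_flag(flags[best], "low_score_only_match")
    }
  }
  out <- pairs
  out$flags <- flags
  restore_ortho_attrs(as.data.frame(out)[keep, , drop = FALSE], pairs)
}

#' Keep only each query gene's best-scoring ortholog(s)
#'
#' The most stringent filter: per input-species gene, retains exactly the
#' pairs whose simple score equals that gene's maximum. Ties are all kept
#' (a gene can have several equally supported orthologs); every retained
#' pair is flagged `best_match`.
#'
#' @param pairs An `ortho_table`.
#' @return The filtered `ortho_table`.
#' @export
apply_best_match_filter <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  mx <- tapply(pairs$simple_score, pairs$gene_a, max)
  keep <- pairs$simple_score == as.integer(mx[as.character(pairs$gene_a)])
  out <- as.data.frame(pairs)[keep, , drop = FALSE]
  out$flags <- add_flag(out$flags, "best_match")
  restore_ortho_attrs(out, pairs)
}

#' Classify ortholog relationships
#'
#' Labels each pair one-to-one, one-to-many, many-to-one or many-to-many by
#' partner counts within the table as given (apply filters first if wanted).
#' Orientation reads input species to output species: one-to-many means one
#' input-species gene with several output-species partners.
#'
#' @param pairs An `ortho_table` (or data.frame with gene_a, gene_b).
#' @return The table with a `relationship_class` column added; attribute
#'   `class_counts` holds the per-class tally.
#' @export
classify_relationships <- function(pairs) {
  lab <- character(nrow(pairs))
  if (nrow(pairs) > 0L) {
    na <- table(pairs$gene_a)  # partners of each input gene
    nb <- table(pairs$gene_b)
    deg_a <- as.integer(na[as.character(pairs$gene_a)])
    deg_b <- as.integer(nb[as.character(pairs$gene_b)])
    # deg_a > 1: the input gene has several output partners (one-to-many)
    lab <- ifelse(deg_a == 1L & deg_b == 1L, "one-to-one",
           ifelse(deg_a > 1L & deg_b == 1L, "one-to-many",
           ifelse(deg_a == 1L & deg_b > 1L, "many-to-one", "many-to-many")))
  }
  out <- pairs
  out$relationship_class <- lab
  counts <- c("one-to-one" = sum(lab == "one-to-one"),
              "one-to-many" = sum(lab == "one-to-many"),
              "many-to-one" = sum(lab == "many-to-one"),
              "many-to-many" = sum(lab == "many-to-many"))
  if (inherits(pairs, "ortho_table")) out <- restore_ortho_attrs(out, pairs)
  attr(out, "class_counts") <- counts
  out
}

#' Transpose an integrated table to the reverse species direction
#'
#' Pairs are stored once per ordered species pair; querying the reverse
#' direction swaps the gene columns and the species-pair attribute rather
#' than re-integrating.
#'
#' @param pairs An `ortho_table`.
#' @return The transposed `ortho_table`.
#' @export
transpose_ortho_table <- function(pairs) {
  out <- as.data.frame(pairs)
  tmp <- out$gene_a; out$gene_a <- out$gene_b; out$gene_b <- tmp
  out <- out[order(out$gene_a, -out$simple_score, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, species_pair = rev(attr(pairs, "species_pair")),
            selected_tools = attr(pairs, "selected_tools"),
            class = c("ortho_table", "data.frame"))
}

#' Write an integrated ortholog table as TSV
#'
#' Tab-separated output with one commented header line naming the columns.
#'
#' @param pairs An `ortho_table`.
#' @param path Output file path.
#' @param symbols_a,symbols_b Optional named vectors mapping gene IDs to
#'   display symbols.
#' @export
write_ortho_table <- function(pairs, path, symbols_a = NULL, symbols_b = NULL) {
  sp <- attr(pairs, "species_pair") %||% c(NA, NA)
  df <- data.frame(
    input_species = sp[1], gene_a = pairs$gene_a,
    symbol_a = if (is.null(symbols_a)) "" else
      unname(symbols_a[as.character(pairs$gene_a)]),
    output_species = sp[2], gene_b = pairs$gene_b,
    symbol_b = if (is.null(symbols_b)) "" else
      unname(symbols_b[as.character(pairs$gene_b)]),
    simple_score = pairs$simple_score,
    weighted_score = ifelse(is.na(pairs$weighted_score), "",
                            format(pairs$weighted_score, digits = 6)),
    supporting_tools = pairs$supporting_tools,
    original_scores = pairs$original_scores,
    relationship_class = pairs$relationship_class %||% "",
    flags = pairs$flags,
    stringsAsFactors = FALSE)
  write_report_tsv(df, path)
}
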