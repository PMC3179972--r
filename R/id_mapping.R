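# Identifier normalization: map heterogeneous gene/protein identifiers onto a
# single integer (Entrez-style) gene-ID namespace and collapse isoform-level
# predictions to gene level.

#' Load an identifier mapping table
#'
#' Reads a tab-separated mapping table with 3--4 columns
#' `(raw_id, id_type, gene_id[, protein_length])` into an `id_map` object.
#' Lines starting with `#` are ignored. Duplicate rows mapping a raw ID to the
#' same gene are de-duplicated; rows mapping the same raw ID to different
#' genes are retained as a multi-valued entry, so lookups may return more than
#' one gene ID.
#'
#' Symbols are matched case-insensitively; accession-style identifiers
#' (Ensembl/RefSeq protein, UniProt, species-database IDs) are matched
#' case-sensitively, following the conventions of the source databases.
#'
#' @param table A file path, or a data.frame/matrix with columns raw_id,
#'   id_type, gene_id and optionally protein_length.
#' @param species Species tag, one of [ortho_species()].
#' @return An object of class `id_map` with elements `species`, `entries`
#'   (data.frame: raw_id, id_type, gene_id, key) and `isoform_lengths`
#'   (data.frame: accession, gene_id, length).
#' @export
load_id_map <- function(table, species) {
  assert_species(species)
  if (is.character(table) && length(table) == 1L) {
    parsed <- read_tsv_plain(table)
    fields <- parsed$fields
    lnum <- parsed$line_numbers
  } else {
    tab <- as.data.frame(table, stringsAsFactors = FALSE)
    fields <- lapply(seq_len(nrow(tab)), function(i) {
      as.character(unlist(tab[i, , drop = TRUE]))
    })
    lnum <- seq_along(fields)
  }
  n <- length(fields)
  raw_id <- character(n); id_type <- character(n); gene_id <- integer(n)
  plen <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    f <- f[!is.na(f)]
    if (length(f) < 3L || length(f) > 4L) {
      stop("malformed mapping row at line ", lnum[i], ": expected 3-4 columns, got ",
           length(f), call. = FALSE)
    }
    if (!(f[2L] %in% ortho_id_types())) {
      stop("malformed mapping row at line ", lnum[i], ": unknown id_type '",
           f[2L], "'", call. = FALSE)
    }
    g <- suppressWarnings(as.integer(f[3L]))
    if (is.na(g) || as.character(g) != trimws(f[3L]) || g <= 0L) {
      stop("malformed mapping row at line ", lnum[i],
           ": gene_id must be a positive integer, got '", f[3L], "'",
           call. = FALSE)
    }
    raw_id[i] <- trimws(f[1L]); id_type[i] <- f[2L]; gene_id[i] <- g
    if (length(f) == 4L) plen[i] <- suppressWarnings(as.integer(f[4L]))
  }
  entries <- data.frame(raw_id = raw_id, id_type = id_type, gene_id = gene_id,
                        stringsAsFactors = FALSE)
  entries$key <- ifelse(entries$id_type == "symbol",
                        tolower(entries$raw_id), entries$raw_id)
  entries <- unique(entries)
  iso <- data.frame(accession = raw_id[!is.na(plen)],
                    gene_id = gene_id[!is.na(plen)],
                    length = plen[!is.na(plen)],
                    stringsAsFactors = FALSE)
  structure(list(species = species, entries = entries, isoform_lengths = iso),
            class = "id_map")
}

#' @export
print.id_map <- function(x, ...) {
  cat("id_map [", x$species, "]: ", nrow(x$entries), " entries (",
      length(unique(x$entries$gene_id)), " genes)\n", sep = "")
  invisible(x)
}

#' Create a collector for unmapped identifiers
#'
#' Unmatched identifiers never abort a run; they are accumulated into a
#' machine-readable report with columns `(raw_id, species, reason)`.
#'
#' @return An `unmapped_report` collector; retrieve its contents with
#'   [as.data.frame()] and write them with [write_unmapped_report()].
#' @export
unmapped_report <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  structure(e, class = "unmapped_report")
}

report_unmapped <- function(report, raw_id, species, reason) {
  if (is.null(report)) return(invisible(NULL))
  report$rows[[length(report$rows) + 1L]] <-
    data.frame(raw_id = raw_id, species = species, reason = reason,
               stringsAsFactors = FALSE)
  invisible(NULL)
}

#' @export
as.data.frame.unmapped_report <- function(x, ...) {
  if (length(x$rows) == 0L) {
    return(data.frame(raw_id = character(0), species = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, x$rows)
}

#' Write an unmapped-identifier report as TSV
#' @param report An [unmapped_report()] collector.
#' @param path Output file path.
#' @export
write_unmapped_report <- function(report, path) {
  write_report_tsv(as.data.frame(report), path)
}

#' Normalize a raw identifier to gene IDs
#'
#' Resolves a raw identifier against an [load_id_map()] map and returns every
#' matching integer gene ID. When `declared_type` is given only entries of
#' that identifier type are consulted, so e.g. a string that is both a symbol
#' and a UniProt accession can be disambiguated. An unmatched identifier
#' returns an empty integer vector and adds a row to `report`; it is a
#' reported outcome, not an error.
#'
#' @param raw_id Identifier string.
#' @param id_map An `id_map`.
#' @param declared_type Optional identifier type (see [ortho_id_types()]).
#' @param report Optional [unmapped_report()] collector.
#' @return Integer vector of gene IDs (possibly empty, possibly length > 1).
#' @export
normalize_identifier <- function(raw_id, id_map, declared_type = NULL,
                                 report = NULL) {
  stopifnot(inherits(id_map, "id_map"))
  e <- id_map$entries
  if (!is.null(declared_type)) {
    if (!(declared_type %in% ortho_id_types())) {
      stop("unknown declared_type '", declared_type, "'", call. = FALSE)
    }
    e <- e[e$id_type == declared_type, , drop = FALSE]
  }
  raw <- trimws(raw_id)
  hit <- e$key == raw | (e$id_type == "symbol" & e$key == tolower(raw))
  ids <- sort(unique(e$gene_id[hit]))
  if (length(ids) == 0L) {
    report_unmapped(report, raw_id, id_map$species, "unmapped")
  }
  ids
}

#' Collapse protein- or mixed-level pairs to unique gene-level pairs
#'
#' Resolves both sides of each raw-identifier pair through the species ID
#' maps and collapses the result to a unique set of `(gene_a, gene_b)` pairs.
#' Multiple isoform-level records of the same underlying gene pair yield one
#' output record. A raw ID resolving to several genes fans out to all of
#' them, each flagged `ambiguous_source_id` (inclusive policy: orthologs that
#' might be relevant are never silently dropped). Pairs with an unresolvable
#' side are dropped and reported.
#'
#' @param pairs data.frame (or 2-column matrix) of raw identifier pairs, side
#'   a then side b.
#' @param id_map_a,id_map_b `id_map`s for the two species.
#' @param type_a,type_b Optional declared identifier types per side.
#' @param report Optional [unmapped_report()] collector.
#' @return data.frame with columns gene_a, gene_b, ambiguous (logical),
#'   one row per unique gene pair.
#' @export
collapse_to_gene_level <- function(pairs, id_map_a, id_map_b,
                                   type_a = NULL, type_b = NULL,
                                   report = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  out_a <- integer(0); out_b <- integer(0); out_amb <- logical(0)
  for (i in seq_len(nrow(pairs))) {
    ga <- normalize_identifier(pairs[[1L]][i], id_map_a, type_a, report)
    gb <- normalize_identifier(pairs[[2L]][i], id_map_b, type_b, report)
    if (length(ga) == 0L || length(gb) == 0L) {
      report_unmapped(report,
                      paste(pairs[[1L]][i], pairs[[2L]][i], sep = "|"),
                      paste(id_map_a$species, id_map_b$species, sep = "-"),
                      "pair_dropped_unmapped")
      next
    }
    amb <- length(ga) > 1L || length(gb) > 1L
    grid <- expand.grid(gene_a = ga, gene_b = gb)
    out_a <- c(out_a, grid$gene_a)
    out_b <- c(out_b, grid$gene_b)
    out_amb <- c(out_amb, rep(amb, nrow(grid)))
  }
  df <- data.frame(gene_a = out_a, gene_b = out_b, ambiguous = out_amb)
  if (nrow(df) == 0L) return(df)
  # a pair is ambiguous if any contributing raw record was ambiguous
  agg <- stats::aggregate(ambiguous ~ gene_a + gene_b, data = df, FUN = any)
  agg <- agg[order(agg$gene_a, agg$gene_b), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
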