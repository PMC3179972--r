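# Disease/trait term normalization to MeSH disease categories (plus the
# added Y01/Y02 categories), the disease-gene to model-organism-ortholog
# join, and comparison of literature-derived disease categories between
# orthologs.

#' Default MeSH disease category table
#'
#' The MeSH disease categories C01--C26, mental disorders F03, and the two
#' added term-like categories: Y01 "Disease risk factor, diagnosis or
#' treatment" and Y02 "Trait", which cover frequent GWAS entries that are
#' not diseases and so have no MeSH disease heading.
#'
#' @return data.frame with columns code, label.
#' @export
mesh_category_table <- function() {
  data.frame(
    code = c(sprintf("C%02d", 1:26), "F03", "Y01", "Y02"),
    label = c(
      "Bacterial Infections and Mycoses", "Virus Diseases",
      "Parasitic Diseases", "Neoplasms", "Musculoskeletal Diseases",
      "Digestive System Diseases", "Stomatognathic Diseases",
      "Respiratory Tract Diseases", "Otorhinolaryngologic Diseases",
      "Nervous System Diseases", "Eye Diseases",
      "Male Urogenital Diseases",
      "Female Urogenital Diseases and Pregnancy Complications",
      "Cardiovascular Diseases", "Hemic and Lymphatic Diseases",
      "Congenital, Hereditary, and Neonatal Diseases and Abnormalities",
      "Skin and Connective Tissue Diseases",
      "Nutritional and Metabolic Diseases", "Endocrine System Diseases",
      "Immune System Diseases", "Disorders of Environmental Origin",
      "Animal Diseases", "Pathological Conditions, Signs and Symptoms",
      "Occupational Diseases", "Substance-Related Disorders",
      "Wounds and Injuries", "Mental Disorders",
      "Disease risk factor, diagnosis or treatment", "Trait"),
    stringsAsFactors = FALSE)
}

# trailing qualifier phrases stripped after a comma during simplification;
# extend via the qualifiers argument of simplify_term
default_qualifiers <- function() {
  c("susceptibility to", "susceptibility", "resistance to",
    "protection against", "modifier of", "risk of", "association with",
    "autosomal dominant", "autosomal recessive", "x-linked", "somatic",
    "familial", "type", "included")
}

#' Simplify a free-text disease or trait term
#'
#' Deterministic normalization applied before dictionary lookups:
#' lower-casing, removal of bracketed or parenthesized qualifiers,
#' punctuation stripping (hyphens kept), whitespace collapsing, and removal
#' of trailing comma-separated qualifier phrases such as
#' ", susceptibility to".
#'
#' @param raw Character vector of free-text terms.
#' @param qualifiers Character vector of trailing qualifier phrases to
#'   strip (matched against each trailing comma segment after
#'   normalization).
#' @return Character vector of simplified terms.
#' @export
simplify_term <- function(raw, qualifiers = default_qualifiers()) {
  vapply(raw, function(x) {
    x <- tolower(x)
    x <- gsub("\\[[^]]*\\]|\\([^)]*\\)|\\{[^}]*\\}", " ", x)
    segs <- strsplit(x, ",", fixed = TRUE)[[1L]]
    clean <- function(s) {
      s <- gsub("[^a-z0-9 -]", " ", s)
      trimws(gsub("\\s+", " ", s))
    }
    segs <- vapply(segs, clean, character(1))
    # drop trailing qualifier segments (e.g. "diabetes, susceptibility to,
    # type 2" -> "diabetes") but never the leading segment
    while (length(segs) > 1L) {
      last <- segs[length(segs)]
      is_qual <- last %in% qualifiers ||
        any(startsWith(last, paste0(qualifiers, " "))) || !nzchar(last)
      if (!is_qual) break
      segs <- segs[-length(segs)]
    }
    s <- paste(segs[nzchar(segs)], collapse = " ")
    trimws(gsub("\\s+", " ", s))
  }, character(1), USE.NAMES = FALSE)
}

#' Build a MeSH lookup
#'
#' Bundles the dictionaries used to route a disease/trait term to MeSH
#' categories: the entry-term table (simplified entry term -> MeSH term ->
#' category codes), the clinical-synopsis heading map, curated manual
#' overrides, and the Y01/Y02 keyword lists.
#'
#' @param entry_terms data.frame (entry_term, mesh_term, codes) where codes
#'   is a comma-joined list of category codes; entry terms are simplified
#'   on construction.
#' @param cs_heading_map data.frame (cs_heading, code).
#' @param manual_overrides data.frame (raw_term, code); matched on the
#'   simplified term.
#' @param y01_keywords,y02_keywords Keyword vectors for the added
#'   "Disease risk factor, diagnosis or treatment" (Y01) and "Trait" (Y02)
#'   categories; a term containing any keyword as a substring routes there.
#' @param categories Category table, defaults to [mesh_category_table()].
#' @return A `mesh_lookup` object.
#' @export
mesh_lookup <- function(entry_terms = NULL, cs_heading_map = NULL,
                        manual_overrides = NULL,
                        y01_keywords = character(0),
                        y02_keywords = character(0),
                        categories = mesh_category_table()) {
  empty <- function(...) {
    df <- data.frame(..., stringsAsFactors = FALSE)
    df[0L, , drop = FALSE]
  }
  et <- if (is.null(entry_terms)) {
    empty(entry_term = "", mesh_term = "", codes = "")
  } else {
    df <- as.data.frame(entry_terms, stringsAsFactors = FALSE)
    df$entry_term <- simplify_term(df$entry_term)
    df
  }
  cs <- if (is.null(cs_heading_map)) empty(cs_heading = "", code = "") else
    as.data.frame(cs_heading_map, stringsAsFactors = FALSE)
  mo <- if (is.null(manual_overrides)) empty(raw_term = "", code = "") else {
    df <- as.data.frame(manual_overrides, stringsAsFactors = FALSE)
    df$raw_term <- simplify_term(df$raw_term)
    df
  }
  bad <- setdiff(unique(unlist(strsplit(c(et$codes, cs$code, mo$code), ","))),
                 c(categories$code, ""))
  if (length(bad) > 0L) {
    stop("unknown category code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(entry_terms = et, cs_heading_map = cs,
                 manual_overrides = mo,
                 y01_keywords = tolower(y01_keywords),
                 y02_keywords = tolower(y02_keywords),
                 categories = categories),
            class = "mesh_lookup")
}

#' Read a MeSH entry-term lookup file
#'
#' Tab-separated `(entry_term, mesh_term, codes)`, codes comma-joined.
#'
#' @param path File path.
#' @param ... Passed to [mesh_lookup()] (cs_heading_map, keyword lists...).
#' @return A `mesh_lookup`.
#' @export
read_mesh_lookup <- function(path, ...) {
  parsed <- read_tsv_plain(path)
  rows <- lapply(parsed$fields, function(f) {
    data.frame(entry_term = f[1L], mesh_term = f[2L], codes = f[3L],
               stringsAsFactors = FALSE)
  })
  et <- if (length(rows)) do.call(rbind, rows) else NULL
  mesh_lookup(entry_terms = et, ...)
}

#' Read OMIM-like disease records
#'
#' Tab-separated `(omim_id, record_type, raw_term, cs_heading, gene_ids)`;
#' record_type is `phenotype` or `gene_locus`, cs_heading may be empty,
#' gene_ids comma-joined.
#'
#' @param path File path.
#' @return data.frame of disease records (source, omim_id, raw_term,
#'   cs_heading, genes).
#' @export
read_omim_records <- function(path) {
  parsed <- read_tsv_plain(path)
  rows <- lapply(parsed$fields, function(f) {
    f <- c(f, rep("", 5L - length(f)))
    data.frame(
      source = if (f[2L] == "gene_locus") "OMIM_gene_locus" else "OMIM_phenotype",
      omim_id = suppressWarnings(as.integer(f[1L])),
      raw_term = f[3L],
      cs_heading = f[4L],
      genes = f[5L], stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(source = character(0), omim_id = integer(0),
                      raw_term = character(0), cs_heading = character(0),
                      genes = character(0)))
  }
  do.call(rbind, rows)
}

#' Read GWAS-like trait records
#'
#' Tab-separated `(raw_term, gene_ids)`, gene_ids comma-joined.
#'
#' @param path File path.
#' @return data.frame of disease records in the same shape as
#'   [read_omim_records()].
#' @export
read_gwas_records <- function(path) {
  parsed <- read_tsv_plain(path)
  rows <- lapply(parsed$fields, function(f) {
    data.frame(source = "GWAS", omim_id = NA_integer_, raw_term = f[1L],
               cs_heading = "", genes = if (length(f) >= 2L) f[2L] else "",
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(read_omim_records(path))  # same empty shape
  }
  do.call(rbind, rows)
}

split_genes <- function(genes) {
  lapply(strsplit(genes, ",", fixed = TRUE),
         function(g) as.integer(g[nzchar(trimws(g))]))
}

#' Assign MeSH categories to disease records
#'
#' Routes each record through a fixed precedence of rules and reports which
#' rule fired: (1) the clinical-synopsis heading map when a CS heading is
#' present and known; (2) the entry-term dictionary on the simplified term;
#' (3) curated manual overrides; (4) the Y01/Y02 keyword lists; (5)
#' unmapped. A term may map to several categories (MeSH is
#' poly-hierarchic); all are kept.
#'
#' @param records data.frame of disease records ([read_omim_records()]
#'   shape).
#' @param lookup A [mesh_lookup()].
#' @return The records with columns `categories` (comma-joined codes, empty
#'   if unmapped) and `mapping_route` (one of cs_heading, entry_term,
#'   manual, y01_rule, y02_rule, unmapped) added.
#' @export
assign_category <- function(records, lookup) {
  stopifnot(inherits(lookup, "mesh_lookup"))
  n <- nrow(records)
  categories <- character(n); route <- character(n)
  simp <- simplify_term(records$raw_term)
  for (i in seq_len(n)) {
    cs <- records$cs_heading[i]
    if (nzchar(cs) && cs %in% lookup$cs_heading_map$cs_heading) {
      hits <- lookup$cs_heading_map$code[lookup$cs_heading_map$cs_heading == cs]
      categories[i] <- paste(sort(unique(hits)), collapse = ",")
      route[i] <- "cs_heading"
      next
    }
    et <- lookup$entry_terms[lookup$entry_terms$entry_term == simp[i], ]
    if (nrow(et) > 0L) {
      codes <- unlist(strsplit(et$codes, ",", fixed = TRUE))
      categories[i] <- paste(sort(unique(codes)), collapse = ",")
      route[i] <- "entry_term"
      next
    }
    mo <- lookup$manual_overrides[lookup$manual_overrides$raw_term == simp[i], ]
    if (nrow(mo) > 0L) {
      categories[i] <- paste(sort(unique(mo$code)), collapse = ",")
      route[i] <- "manual"
      next
    }
    if (length(lookup$y01_keywords) &&
        any(vapply(lookup$y01_keywords, grepl, logical(1), x = simp[i],
                   fixed = TRUE))) {
      categories[i] <- "Y01"; route[i] <- "y01_rule"
      next
    }
    if (length(lookup$y02_keywords) &&
        any(vapply(lookup$y02_keywords, grepl, logical(1), x = simp[i],
                   fixed = TRUE))) {
      categories[i] <- "Y02"; route[i] <- "y02_rule"
      next
    }
    categories[i] <- ""; route[i] <- "unmapped"
  }
  records$categories <- categories
  records$mapping_route <- route
  records
}

#' Join disease records to model-organism orthologs
#'
#' Selects disease records by a query (case-insensitive term substring,
#' category code, or a set of OMIM IDs; absent query selects everything),
#' resolves their human genes, applies the requested ortholog filter and
#' returns one row per (record, human gene, ortholog).
#'
#' @param records Disease records with categories assigned
#'   ([assign_category()]).
#' @param ortho_table An `ortho_table` oriented human -> target species.
#' @param filter_mode `"none"`, `"score_ge2"`, `"score_ge3"` or
#'   `"best_match"`.
#' @param term,category,omim_ids Query selectors (at most one used; all
#'   `NULL` selects every record).
#' @return data.frame with columns raw_term, categories, omim_id,
#'   human_gene, target_gene, simple_score, weighted_score,
#'   supporting_tools; a human gene without surviving ortholog yields a row
#'   with `NA` target columns flagged by `no_ortholog = TRUE`.
#' @export
join_disease_orthologs <- function(records, ortho_table,
                                   filter_mode = c("none", "score_ge2",
                                                   "score_ge3", "best_match"),
                                   term = NULL, category = NULL,
                                   omim_ids = NULL) {
  filter_mode <- match.arg(filter_mode)
  filtered <- switch(filter_mode,
    none = ortho_table,
    score_ge2 = apply_score_filter(ortho_table, 2L),
    score_ge3 = apply_score_filter(ortho_table, 3L),
    best_match = apply_best_match_filter(ortho_table))
  sel <- rep(TRUE, nrow(records))
  if (!is.null(term)) {
    sel <- grepl(tolower(term), tolower(records$raw_term), fixed = TRUE)
  } else if (!is.null(category)) {
    if (!(category %in% mesh_category_table()$code)) {
      stop("unknown category code '", category, "'; valid codes: ",
           paste(mesh_category_table()$code, collapse = ", "), call. = FALSE)
    }
    sel <- vapply(strsplit(records$categories, ",", fixed = TRUE),
                  function(cc) category %in% cc, logical(1))
  } else if (!is.null(omim_ids)) {
    sel <- records$omim_id %in% omim_ids
  }
  hits <- records[sel, , drop = FALSE]
  out <- list()
  gene_lists <- split_genes(hits$genes)
  for (i in seq_len(nrow(hits))) {
    for (g in gene_lists[[i]]) {
      rows <- filtered[filtered$gene_a == g, , drop = FALSE]
      if (nrow(rows) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          raw_term = hits$raw_term[i], categories = hits$categories[i],
          omim_id = hits$omim_id[i], human_gene = g,
          target_gene = NA_integer_, simple_score = NA_integer_,
          weighted_score = NA_real_, supporting_tools = "",
          no_ortholog = TRUE, stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          raw_term = hits$raw_term[i], categories = hits$categories[i],
          omim_id = hits$omim_id[i], human_gene = g,
          target_gene = rows$gene_b, simple_score = rows$simple_score,
          weighted_score = rows$weighted_score,
          supporting_tools = rows$supporting_tools,
          no_ortholog = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(raw_term = character(0), categories = character(0),
                      omim_id = integer(0), human_gene = integer(0),
                      target_gene = integer(0), simple_score = integer(0),
                      weighted_score = numeric(0),
                      supporting_tools = character(0),
                      no_ortholog = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-category summary of a disease-ortholog join
#'
#' Counts, per MeSH category, the distinct disease terms, human genes and
#' target-species genes in a row-level [join_disease_orthologs()] output.
#' Records mapping to several categories contribute to each.
#'
#' @param join_rows Output of [join_disease_orthologs()].
#' @return data.frame with columns code, n_terms, n_human_genes,
#'   n_target_genes.
#' @export
disease_category_summary <- function(join_rows) {
  codes <- strsplit(join_rows$categories, ",", fixed = TRUE)
  long <- data.frame(
    code = unlist(lapply(seq_len(nrow(join_rows)),
                         function(i) codes[[i]] %||% character(0))),
    raw_term = rep(join_rows$raw_term, lengths(codes)),
    human_gene = rep(join_rows$human_gene, lengths(codes)),
    target_gene = rep(join_rows$target_gene, lengths(codes)),
    stringsAsFactors = FALSE)
  long <- long[nzchar(long$code), , drop = FALSE]
  if (nrow(long) == 0L) {
    return(data.frame(code = character(0), n_terms = integer(0),
                      n_human_genes = integer(0), n_target_genes = integer(0)))
  }
  agg <- lapply(split(long, long$code), function(d) {
    data.frame(code = d$code[1L],
               n_terms = length(unique(d$raw_term)),
               n_human_genes = length(unique(d$human_gene)),
               n_target_genes = length(unique(d$target_gene[!is.na(d$target_gene)])),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  res <- res[order(-res$n_human_genes, res$code), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a gene-to-literature-MeSH table
#'
#' Tab-separated `(gene_id, category_code)`: the MeSH disease categories
#' co-cited with each gene in the literature.
#'
#' @param path File path.
#' @return Named list gene_id (character) -> character vector of codes.
#' @export
read_literature_mesh <- function(path) {
  parsed <- read_tsv_plain(path)
  if (length(parsed$fields) == 0L) return(list())
  df <- data.frame(
    gene_id = vapply(parsed$fields, `[[`, character(1), 1L),
    code = vapply(parsed$fields, `[[`, character(1), 2L),
    stringsAsFactors = FALSE)
  lapply(split(df$code, df$gene_id), unique)
}

#' Disease categories shared between a gene and its orthologs
#'
#' Intersects a gene's literature-derived disease categories with the union
#' of its orthologs' categories; genes absent from the literature table
#' contribute empty sets.
#'
#' @param gene Gene ID.
#' @param orthologs Integer vector of ortholog gene IDs.
#' @param lit Literature table from [read_literature_mesh()] (or an
#'   equivalently shaped named list).
#' @return List with `shared` (character vector of codes), `gene_categories`
#'   and `ortholog_categories`.
#' @export
shared_disease_categories <- function(gene, orthologs, lit) {
  gc <- lit[[as.character(gene)]] %||% character(0)
  oc <- unique(unlist(lapply(as.character(orthologs),
                             function(g) lit[[g]] %||% character(0))))
  list(shared = sort(intersect(gc, oc)),
       gene_categories = sort(gc),
       ortholog_categories = sort(oc %||% character(0)))
}
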