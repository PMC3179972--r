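# shared constants and small helpers

#' Supported species tags
#'
#' The six taxa the gene-ID namespace covers.
#' @export
ortho_species <- function() c("human", "mouse", "zebrafish", "fly", "worm", "yeast")

#' Recognized identifier types
#' @export
ortho_id_types <- function() {
  c("symbol", "entrez", "ensembl_protein", "uniprot", "species_db",
    "refseq_protein")
}

#' Half-up rounding
#'
#' Rounds `.5` away from zero for non-negative inputs, the convention used
#' for every reported integer percentage in the package (base `round()` is
#' half-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical unordered key for a gene pair (orthology is symmetric)
unordered_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

ordered_key <- function(a, b) paste(a, b, sep = "|")

assert_species <- function(species) {
  if (!(is.character(species) && length(species) == 1L &&
        species %in% ortho_species())) {
    stop("unknown species '", paste(species, collapse = ","),
         "'; expected one of: ", paste(ortho_species(), collapse = ", "),
         call. = FALSE)
  }
  invisible(species)
}

# read a tab-separated file, ignoring '#'-prefixed comment lines; columns
# returned as character, no header row expected
read_tsv_plain <- function(path, n_min_cols = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(list(fields = list(), line_numbers = integer(0)))
  }
  all_lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", all_lines) & nzchar(trimws(all_lines)))
  list(fields = strsplit(all_lines[keep], "\t", fixed = TRUE),
       line_numbers = keep)
}

# write a data.frame as TSV with a single commented header line naming columns
write_report_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0L) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_report_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty report file: ", path, call. = FALSE)
  header <- sub("^#\\s*", "", lines[[1L]])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(body) & !grepl("^#", body)]
  if (length(body) == 0L) {
    df <- as.data.frame(matrix(character(0), ncol = length(cols)),
                        stringsAsFactors = FALSE)
    names(df) <- cols
    return(df)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) c(f, rep("", length(cols) - length(f))))
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

# split a seed into named reproducible sub-seeds so independent fixture
# generators draw from independent streams
derive_subseeds <- function(seed, names) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  stats::setNames(s, names)
}
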