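# Pairwise local protein alignment: Smith-Waterman with affine gaps,
# EMBOSS-style match line, overall and domain-region percent identity.

ALIGN_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                    "P","S","T","W","Y","V","B","Z","X","U")

# BLOSUM62 restricted to the residue alphabet; U (selenocysteine) is scored
# through the wildcard X row, the convention of the common matrix files
get_substitution_matrix <- function(name = "BLOSUM62") {
  if (is.matrix(name)) return(name)
  m <- get(data(list = name, package = "Biostrings",
                envir = environment())[[1L]], envir = environment())
  full <- matrix(m["X", "X"], length(ALIGN_ALPHABET), length(ALIGN_ALPHABET),
                 dimnames = list(ALIGN_ALPHABET, ALIGN_ALPHABET))
  have <- intersect(ALIGN_ALPHABET, rownames(m))
  full[have, have] <- m[have, have]
  miss <- setdiff(ALIGN_ALPHABET, rownames(m))
  for (r in miss) {
    full[r, have] <- m["X", have]
    full[have, r] <- m[have, "X"]
  }
  full
}

#' Construct a protein sequence record
#'
#' @param accession Protein accession string.
#' @param residues Amino-acid string over the 20-letter alphabet plus
#'   X/B/Z/U.
#' @param gene_id Optional integer gene ID the protein belongs to.
#' @return A `protein_seq` object.
#' @export
protein_seq <- function(accession, residues, gene_id = NA_integer_) {
  residues <- toupper(gsub("\\s", "", residues))
  if (nchar(residues) == 0L) stop("empty protein sequence", call. = FALSE)
  bad <- setdiff(unique(strsplit(residues, "")[[1L]]), ALIGN_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid residue(s) in ", accession, ": ",
         paste(bad, collapse = ""), call. = FALSE)
  }
  structure(list(accession = accession, gene_id = as.integer(gene_id),
                 residues = residues, length = nchar(residues)),
            class = "protein_seq")
}

#' Read protein sequences from a FASTA file
#'
#' The accession is the first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @param id_map Optional `id_map` whose isoform table links accessions to
#'   gene IDs.
#' @return Named list of [protein_seq()] records.
#' @export
read_protein_fasta <- function(path, id_map = NULL) {
  set <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    gid <- NA_integer_
    if (!is.null(id_map)) {
      hit <- match(acc[i], id_map$isoform_lengths$accession)
      if (!is.na(hit)) gid <- id_map$isoform_lengths$gene_id[hit]
    }
    out[[i]] <- protein_seq(acc[i], as.character(set[[i]]), gid)
  }
  stats::setNames(out, acc)
}

#' Select the longest isoform of a gene
#'
#' Among multiple protein records of one gene, returns the longest; length
#' ties go to the lexicographically smallest accession so the choice is
#' deterministic.
#'
#' @param records Non-empty list of [protein_seq()] records for one gene.
#' @return The selected `protein_seq`.
#' @export
select_longest_isoform <- function(records) {
  if (length(records) == 0L) stop("no protein records supplied", call. = FALSE)
  lens <- vapply(records, function(r) r$length, integer(1))
  accs <- vapply(records, function(r) r$accession, character(1))
  cand <- which(lens == max(lens))
  records[[cand[order(accs[cand])][1L]]]
}

#' Render an EMBOSS-style match line
#'
#' Per alignment column: `*` for an exact residue match, `:` for a mismatch
#' scoring positively in the substitution matrix, `.` for any other aligned
#' residue pair, and a space where either row has a gap.
#'
#' @param aligned_a,aligned_b Equal-length aligned strings (gaps as `-`).
#' @param substitution_matrix Matrix name or matrix (default BLOSUM62).
#' @return The match-line string.
#' @export
render_match_line <- function(aligned_a, aligned_b,
                              substitution_matrix = "BLOSUM62") {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned strings differ in length", call. = FALSE)
  }
  sub <- get_substitution_matrix(substitution_matrix)
  ca <- strsplit(aligned_a, "")[[1L]]
  cb <- strsplit(aligned_b, "")[[1L]]
  out <- character(length(ca))
  for (k in seq_along(ca)) {
    if (ca[k] == "-" || cb[k] == "-") out[k] <- " "
    else if (ca[k] == cb[k]) out[k] <- "*"
    else if (sub[ca[k], cb[k]] > 0) out[k] <- ":"
    else out[k] <- "."
  }
  paste(out, collapse = "")
}

#' Local protein alignment
#'
#' Smith-Waterman local alignment with affine gap costs (a gap of length L
#' costs `gap_open + (L-1) * gap_extend`) under BLOSUM62 by default,
#' matching the classic EMBOSS `water` parameterization. One optimal
#' alignment is returned, with ties resolved by a fixed traceback
#' preference (diagonal, then gap-in-subject, then gap-in-query). Percent
#' identity and similarity use the full alignment length, gap columns
#' included, in the denominator.
#'
#' @param seq_a,seq_b [protein_seq()] records or plain residue strings.
#' @param substitution_matrix Matrix name or matrix.
#' @param gap_open,gap_extend Gap costs (default 10.0 / 0.5).
#' @return An `alignment_result`: list with aligned_a, aligned_b,
#'   match_line, score, identity_pct, similarity_pct (full precision),
#'   start/end coordinates on both sequences (1-based), and the two input
#'   records.
#' @export
local_align <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                        gap_open = 10.0, gap_extend = 0.5) {
  if (is.character(seq_a)) seq_a <- protein_seq("seq_a", seq_a)
  if (is.character(seq_b)) seq_b <- protein_seq("seq_b", seq_b)
  sub <- get_substitution_matrix(substitution_matrix)
  enc <- function(s) {
    idx <- match(strsplit(s, "")[[1L]], ALIGN_ALPHABET)
    if (anyNA(idx)) stop("residue absent from matrix alphabet", call. = FALSE)
    idx
  }
  res <- .sw_align_cpp(enc(seq_a$residues), enc(seq_b$residues),
                       sub[ALIGN_ALPHABET, ALIGN_ALPHABET],
                       paste(ALIGN_ALPHABET, collapse = ""),
                       gap_open, gap_extend)
  ml <- render_match_line(res$aligned_a, res$aligned_b, sub)
  len <- nchar(ml)
  n_id <- sum(strsplit(ml, "")[[1L]] == "*")
  n_sim <- n_id + sum(strsplit(ml, "")[[1L]] == ":")
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 match_line = ml, score = res$score,
                 identity_pct = if (len == 0L) 0 else 100 * n_id / len,
                 similarity_pct = if (len == 0L) 0 else 100 * n_sim / len,
                 start_a = res$start_a, end_a = res$end_a,
                 start_b = res$start_b, end_b = res$end_b,
                 seq_a = seq_a, seq_b = seq_b),
            class = "alignment_result")
}

#' Overall identity and similarity of an alignment
#'
#' Identity is the percentage of exactly matching columns and similarity
#' the percentage of matching-or-positive columns, both over the full
#' alignment length (gap columns count in the denominator). Values are
#' rounded half-up to integers at this reporting interface; the
#' `alignment_result` keeps full precision.
#'
#' @param result An [local_align()] result.
#' @return Named numeric vector `c(identity_pct, similarity_pct)`, integer
#'   valued.
#' @export
alignment_identity_stats <- function(result) {
  c(identity_pct = round_half_up(result$identity_pct),
    similarity_pct = round_half_up(result$similarity_pct))
}

#' Read a domain-interval table
#'
#' Tab-separated `(accession, name, start, end)`, 1-based inclusive
#' residue coordinates; `#` comment lines ignored.
#'
#' @param path File path.
#' @return data.frame with columns accession, name, start, end.
#' @export
read_domain_table <- function(path) {
  parsed <- read_tsv_plain(path)
  rows <- lapply(seq_along(parsed$fields), function(i) {
    f <- parsed$fields[[i]]
    if (length(f) < 4L) {
      stop("malformed domain row at line ", parsed$line_numbers[i],
           call. = FALSE)
    }
    data.frame(accession = f[1L], name = f[2L],
               start = as.integer(f[3L]), end = as.integer(f[4L]),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(accession = character(0), name = character(0),
                      start = integer(0), end = integer(0)))
  }
  do.call(rbind, rows)
}

# map each alignment column to the 1-based residue index it carries on one
# side (NA for gap columns)
column_residue_index <- function(aligned, start) {
  ch <- strsplit(aligned, "")[[1L]]
  idx <- rep(NA_integer_, length(ch))
  idx[ch != "-"] <- seq(from = start, length.out = sum(ch != "-"))
  idx
}

#' Per-domain identity within an alignment
#'
#' Maps each domain's residue interval (1-based inclusive on the source
#' sequence) through the alignment to a column span -- gap columns inside
#' the span included -- and computes percent identity over that span the
#' same way as [alignment_identity_stats()]. Domains wholly outside the
#' aligned region yield a record with `NA` identity and span.
#'
#' @param result An [local_align()] result.
#' @param domains data.frame as from [read_domain_table()]; rows for other
#'   accessions are ignored.
#' @param source `"a"` or `"b"`: which sequence the domain coordinates
#'   refer to.
#' @return data.frame with columns name, source, col_start, col_end,
#'   identity_pct (full precision; round with [round_half_up()] callers).
#' @export
domain_identity <- function(result, domains, source = c("a", "b")) {
  source <- match.arg(source)
  seq <- if (source == "a") result$seq_a else result$seq_b
  aligned <- if (source == "a") result$aligned_a else result$aligned_b
  start <- if (source == "a") result$start_a else result$start_b
  domains <- domains[domains$accession == seq$accession, , drop = FALSE]
  col_idx <- column_residue_index(aligned, start)
  ml <- strsplit(result$match_line, "")[[1L]]
  out <- lapply(seq_len(nrow(domains)), function(i) {
    s <- domains$start[i]; e <- domains$end[i]
    if (is.na(s) || is.na(e) || s < 1L || e < s || e > seq$length) {
      stop("invalid domain coordinates for '", domains$name[i], "' on ",
           seq$accession, call. = FALSE)
    }
    cols <- which(!is.na(col_idx) & col_idx >= s & col_idx <= e)
    if (length(cols) == 0L) {
      return(data.frame(name = domains$name[i], source = source,
                        col_start = NA_integer_, col_end = NA_integer_,
                        identity_pct = NA_real_, stringsAsFactors = FALSE))
    }
    span <- seq(min(cols), max(cols))
    data.frame(name = domains$name[i], source = source,
               col_start = min(cols), col_end = max(cols),
               identity_pct = 100 * sum(ml[span] == "*") / length(span),
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0L) {
    return(data.frame(name = character(0), source = character(0),
                      col_start = integer(0), col_end = integer(0),
                      identity_pct = numeric(0)))
  }
  do.call(rbind, out)
}

#' @export
print.alignment_result <- function(x, width = 60L, ...) {
  cat(sprintf("Local alignment: %s (%d-%d) vs %s (%d-%d)\n",
              x$seq_a$accession, x$start_a, x$end_a,
              x$seq_b$accession, x$start_b, x$end_b))
  cat(sprintf("Score: %.1f  Length: %d  Identity: %d%%  Similarity: %d%%\n",
              x$score, nchar(x$match_line),
              round_half_up(x$identity_pct),
              round_half_up(x$similarity_pct)))
  n <- nchar(x$match_line)
  for (off in seq(1L, max(n, 1L), by = width)) {
    end <- min(off + width - 1L, n)
    if (n == 0L) break
    cat(substr(x$aligned_a, off, end), "\n")
    cat(substr(x$match_line, off, end), "\n")
    cat(substr(x$aligned_b, off, end), "\n\n")
  }
  invisible(x)
}
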