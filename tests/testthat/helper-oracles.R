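# Independent oracles used across the suite. These deliberately share no
# code with the package: the alignment oracle is a plain-R Gotoh recursion,
# and the GO oracle recomputes ancestors, IC and BMA by direct enumeration.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# plain-R affine-gap Smith-Waterman oracle; same documented conventions
# (gap of length L costs open + (L-1)*extend; traceback prefers diagonal,
# then gap-in-b, then gap-in-a; best end cell = first in row-major order)
oracle_sw <- function(a, b, open = 10, extend = 0.5, mat = blosum62) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[ca[i], cb[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j], 0) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open, Y[i + 1, j] - extend)
    }
  }
  best <- 0; bi <- 0; bj <- 0; bs <- "M"
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      for (st in c("M", "X", "Y")) {
        v <- switch(st, M = M[i + 1, j + 1], X = X[i + 1, j + 1],
                    Y = Y[i + 1, j + 1])
        if (v > best + 1e-9) { best <- v; bi <- i; bj <- j; bs <- st }
      }
    }
  }
  if (best <= 1e-9) {
    return(list(score = 0, aligned_a = "", aligned_b = "", n_ident = 0L,
                length = 0L))
  }
  i <- bi; j <- bj; st <- bs
  ra <- character(0); rb <- character(0)
  repeat {
    if (st == "M") {
      s <- mat[ca[i], cb[j]]
      prev <- M[i + 1, j + 1] - s
      ra <- c(ca[i], ra); rb <- c(cb[j], rb)
      i <- i - 1; j <- j - 1
      if (prev <= 1e-9) break
      if (abs(M[i + 1, j + 1] - prev) <= 1e-9) st <- "M"
      else if (abs(X[i + 1, j + 1] - prev) <= 1e-9) st <- "X"
      else st <- "Y"
    } else if (st == "X") {
      ra <- c(ca[i], ra); rb <- c("-", rb)
      st <- if (abs(X[i + 1, j + 1] - (M[i, j + 1] - open)) <= 1e-9) "M" else "X"
      i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(cb[j], rb)
      st <- if (abs(Y[i + 1, j + 1] - (M[i + 1, j] - open)) <= 1e-9) "M" else "Y"
      j <- j - 1
    }
  }
  list(score = best, aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""),
       n_ident = sum(ra == rb & ra != "-"), length = length(ra))
}

# --- GO oracle: recursive ancestor enumeration + naive IC + exhaustive BMA

oracle_ancestors <- function(term, parents) {
  out <- term
  for (p in parents[[term]]) out <- union(out, oracle_ancestors(p, parents))
  out
}

oracle_ic <- function(ann_df, terms, parents) {
  ann <- unique(ann_df[, c("gene_id", "term")])
  total <- nrow(ann)
  ic <- numeric(0)
  for (t in terms) {
    # descendants of t = terms whose ancestor set contains t
    desc <- terms[vapply(terms, function(u)
      t %in% oracle_ancestors(u, parents), logical(1))]
    cnt <- sum(ann$term %in% desc)
    if (cnt > 0) ic[t] <- -log(cnt / total)
  }
  ic
}

oracle_lin <- function(t1, t2, parents, ic) {
  common <- intersect(oracle_ancestors(t1, parents),
                      oracle_ancestors(t2, parents))
  common <- common[common %in% names(ic)]
  mica <- if (length(common) == 0) 0 else max(ic[common])
  denom <- ic[[t1]] + ic[[t2]]
  if (denom == 0) return(0)
  if (t1 == t2) return(1)
  2 * mica / denom
}

oracle_bma <- function(ta, tb, parents, ic) {
  ta <- intersect(unique(ta), names(ic)); tb <- intersect(unique(tb), names(ic))
  if (length(ta) == 0 || length(tb) == 0) return(NA_real_)
  m <- outer(ta, tb, Vectorize(function(x, y) oracle_lin(x, y, parents, ic)))
  m <- matrix(m, length(ta), length(tb))
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

# small shared fixture world for tests that just need one
tiny_world <- function(seed = 101, n_genes = 40, ...) {
  spec <- world_spec(seed = seed, n_genes = n_genes, ...)
  list(spec = spec, world = generate_orthology_world(spec))
}
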