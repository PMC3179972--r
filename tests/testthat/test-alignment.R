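test_that("longest isoform wins; ties go to the smallest accession", {
  recs <- list(protein_seq("NP_3", random_aa(300)),
               protein_seq("NP_1", random_aa(450)),
               protein_seq("NP_2", random_aa(450)))
  expect_equal(select_longest_isoform(recs)$accession, "NP_1")
  expect_equal(select_longest_isoform(recs[1])$accession, "NP_3")
  expect_equal(select_longest_isoform(
    list(protein_seq("a", random_aa(10)),
         protein_seq("b", random_aa(11))))$accession, "b")
  expect_error(select_longest_isoform(list()), "no protein")
})

test_that("identical sequences self-align at 100% identity with an all-star line", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  aln <- local_align(s, s)
  expect_equal(aln$aligned_a, s)
  expect_equal(aln$match_line, strrep("*", nchar(s)))
  expect_equal(aln$identity_pct, 100)
  expect_equal(unname(alignment_identity_stats(aln)["identity_pct"]), 100)
})

test_that("match line columns follow the star/colon/dot/space convention", {
  expect_equal(render_match_line("K", "K"), "*")
  expect_equal(render_match_line("K", "R"), ":")  # BLOSUM62[K,R] = 2 > 0
  expect_equal(render_match_line("W", "G"), ".")  # negative score
  expect_equal(render_match_line("A-", "-A"), "  ")
  expect_error(render_match_line("AA", "A"), "length")
  # conservation: symbol counts sum to alignment length
  set.seed(1)
  a <- random_aa(40); b <- random_aa(40)
  aln <- local_align(a, b)
  counts <- table(factor(strsplit(aln$match_line, "")[[1]],
                         levels = c("*", ":", ".", " ")))
  expect_equal(sum(counts), nchar(aln$match_line))
})

test_that("score and identity match the plain-R affine DP oracle", {
  set.seed(2024)
  for (k in 1:60) {
    a <- random_aa(sample(8:30, 1))
    b <- random_aa(sample(8:30, 1))
    got <- local_align(a, b)
    want <- oracle_sw(a, b)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    n_ident <- sum(strsplit(got$match_line, "")[[1]] == "*")
    expect_equal(n_ident, want$n_ident)
    expect_equal(nchar(got$match_line), want$length)
  }
})

test_that("alignment scores agree with an independent aligner", {
  # Biostrings charges open + L*extend for a length-L gap; open 9.5 /
  # extend 0.5 reproduces the open-covers-first-residue convention at 10/0.5
  set.seed(77)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  for (k in 1:10) {
    a <- random_aa(60); b <- random_aa(60)
    got <- local_align(a, b)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = BLOSUM62, gapOpening = 9.5, gapExtension = 0.5,
      type = "local")
    expect_equal(got$score, Biostrings::score(ref), tolerance = 1e-9)
  }
})

test_that("alignment score is symmetric and grows under local extension", {
  set.seed(3)
  for (k in 1:10) {
    a <- random_aa(25); b <- random_aa(25)
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
    # appending unrelated residues never decreases the local score
    expect_gte(local_align(paste0(a, random_aa(15)), b)$score,
               local_align(a, b)$score)
  }
})

test_that("identity and similarity percentages count over full alignment length", {
  # engineered alignment: force one known gap via oracle on a constructed
  # pair, then recount from the emitted match line
  a <- "MKWVTFISLLFLFSSAYS"
  b <- "MKWVTFLLFLFSSAYS"  # two residues deleted
  aln <- local_align(a, b)
  ml <- strsplit(aln$match_line, "")[[1]]
  expect_equal(aln$identity_pct, 100 * sum(ml == "*") / length(ml))
  expect_equal(aln$similarity_pct,
               100 * (sum(ml == "*") + sum(ml == ":")) / length(ml))
  expect_gte(aln$similarity_pct, aln$identity_pct)
  expect_true(any(ml == " "))  # the gap columns are in the denominator
})

test_that("rounding at the reporting interface is half-up", {
  expect_equal(round_half_up(46.5), 47)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(46.4999), 46)
  expect_equal(round_half_up(87.5), 88)
})

test_that("domain identity maps residue intervals through the alignment", {
  # planted conserved 20-residue block inside diverged flanks
  set.seed(11)
  block <- random_aa(20)
  a <- paste0(random_aa(30), block, random_aa(30))
  b <- paste0(random_aa(30), block, random_aa(30))
  pa <- protein_seq("PA", a); pb <- protein_seq("PB", b)
  aln <- local_align(pa, pb)
  doms <- data.frame(accession = "PA", name = "block",
                     start = 31L, end = 50L)
  ds <- domain_identity(aln, doms, "a")
  expect_equal(ds$identity_pct, 100)
  expect_gt(ds$identity_pct, aln$identity_pct)

  # a domain spanning the whole aligned region equals overall identity
  full <- data.frame(accession = "PA", name = "full",
                     start = aln$start_a, end = aln$end_a)
  expect_equal(domain_identity(aln, full, "a")$identity_pct,
               aln$identity_pct)

  # domain wholly outside the aligned region: not-aligned record
  if (aln$start_a > 3L) {
    outside <- data.frame(accession = "PA", name = "out",
                          start = 1L, end = aln$start_a - 1L)
    expect_true(is.na(domain_identity(aln, outside, "a")$identity_pct))
  }
  bad <- data.frame(accession = "PA", name = "bad", start = 5L,
                    end = nchar(a) + 10L)
  expect_error(domain_identity(aln, bad, "a"), "coordinates")
})

test_that("FASTA round trip preserves accessions and residues", {
  tw <- tiny_world(seed = 909, n_genes = 20)
  sq <- generate_sequence_fixture(tw$spec, tw$world, n_pairs = 4)
  f <- withr::local_tempfile(lines = sq$fasta_lines)
  seqs <- read_protein_fasta(f, id_map = tw$world$id_map_a)
  acc <- sq$expected$acc_a[1]
  expect_equal(seqs[[acc]]$residues, unname(sq$sequences[acc]))
  expect_equal(seqs[[acc]]$gene_id, sq$expected$gene_a[1])
  # longest-isoform selection over the two emitted isoforms
  gid <- sq$expected$gene_a[1]
  iso <- seqs[vapply(seqs, function(s) identical(s$gene_id, gid), logical(1))]
  expect_equal(select_longest_isoform(iso)$accession, acc)
})
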