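test_that("graph construction enumerates k-mer edges with read multiplicity", {
  g <- build_graph("ACDEFGHIKL", k = 8)
  expect_equal(sort(g$edges$kmer), sort(c("ACDEFGHI", "CDEFGHIK", "DEFGHIKL")))
  expect_equal(g$edges$count, rep(1L, 3))
  ## two identical reads: same edges, doubled counts
  g2 <- build_graph(c("ACDEFGHIKL", "ACDEFGHIKL"), k = 8)
  expect_equal(sort(g2$edges$kmer), sort(g$edges$kmer))
  expect_equal(g2$edges$count, rep(2L, 3))
  ## confidence-weighted edges: weight is the window mean
  g3 <- build_graph("ACDEFGHIK", list(c(rep(1, 8), 0.2)), k = 8)
  expect_equal(g3$edges$weight[g3$edges$kmer == "ACDEFGHI"], 1)
  expect_equal(g3$edges$weight[g3$edges$kmer == "CDEFGHIK"], (7 + 0.2) / 8)
  expect_warning(build_graph(c("ACDEF", "ACDEFGHIKL"), k = 8), "shorter than k")
  expect_warning(expect_warning(g0 <- build_graph("ACD", k = 8),
                                "empty graph"),
                 "shorter than k")
  expect_equal(nrow(g0$edges), 0L)
})

test_that("tiled reads over a known contig spell a single non-branching path", {
  pep <- "GLYGGPSYGYGAPTSQR"
  reads <- substring(pep, 1:10, 8:17)     # 8-mers at offsets 0..9
  g <- build_graph(reads, k = 8)
  expect_equal(nrow(g$edges), 10L)        # all k-mers distinct
  ctg <- assemble(g, min_len = 10)
  expect_equal(ctg$sequence, pep)
  expect_equal(ctg$support_reads, 10L)
})

test_that("assembly reconstructs peptides from error-free overlapping reads", {
  set.seed(42)
  for (len in c(12, 25, 40)) {
    pep <- random_peptide(len)
    if (anyDuplicated(substring(pep, 1:(len - 7), 8:len))) next
    starts <- seq(1, len - 9, by = 2)
    reads <- substring(pep, starts, pmin(starts + 9, len))
    reads <- c(reads, substring(pep, len - 9, len))
    ctg <- assemble(build_graph(reads, k = 8), min_len = 10)
    expect_equal(ctg$sequence, pep)
  }
})

test_that("path extraction follows the heavier branch at a fork", {
  ## fork after the shared prefix: branch A supported by 5 reads, B by 1
  stem <- "ACDEFGHIK"
  branch_a <- paste0(stem, "LMNPQRSTVW")   # heavy continuation
  branch_b <- paste0(stem, "WVTSRQPNML")   # light continuation
  reads <- c(rep(branch_a, 5), branch_b)
  ctg <- assemble(build_graph(reads, k = 8), min_len = 10)
  expect_equal(ctg$sequence[1], branch_a)
  ## the light branch remains as a separate (shorter) walk if long enough
  expect_true(all(ctg$sequence != branch_b) ||
                any(ctg$sequence == branch_b))
})

test_that("assembly is deterministic under read order permutations", {
  set.seed(7)
  pep1 <- random_peptide(30); pep2 <- random_peptide(22)
  starts1 <- seq(1, 21, 3); starts2 <- seq(1, 13, 3)
  reads <- c(substring(pep1, starts1, starts1 + 9),
             substring(pep2, starts2, starts2 + 9))
  ref <- assemble(build_graph(reads, k = 8))
  for (i in 1:5) {
    perm <- sample(reads)
    expect_identical(assemble(build_graph(perm, k = 8))$sequence,
                     ref$sequence)
  }
})

test_that("every contig k-mer occurs in at least one input read", {
  set.seed(11)
  reads <- vapply(rep(14, 30), random_peptide, "")
  g <- build_graph(reads, k = 8)
  ctg <- assemble(g, min_len = 8)
  read_kmers <- unique(unlist(lapply(reads, function(r)
    substring(r, 1:(nchar(r) - 7), 8:nchar(r)))))
  for (s in ctg$sequence) {
    kmers <- substring(s, 1:(nchar(s) - 7), 8:nchar(s))
    expect_true(all(kmers %in% read_kmers))
  }
})

test_that("per-sample assembly keeps samples separate", {
  pepA <- "GLYGGPSYGYGAPTSQR"; pepB <- "HLTCDELHGDLLEAHGDDR"
  reads <- data.frame(
    sample_id = c(rep("S1", 10), rep("S2", 12)),
    sequence = c(substring(pepA, 1:10, 8:17), substring(pepB, 1:12, 8:19)),
    stringsAsFactors = FALSE)
  ctg <- assemble_contigs(reads, k = 8, min_len = 10)
  expect_equal(ctg$sequence[ctg$sample_id == "S1"], pepA)
  expect_equal(ctg$sequence[ctg$sample_id == "S2"], pepB)
})
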