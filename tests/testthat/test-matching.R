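test_that("contig mapping classifies canonical, variant and unmatched", {
  set.seed(21)
  base <- random_peptide(60)
  db <- toy_db(c(base, random_peptide(50)))
  ## exact tryptic fragment: canonical
  frag <- substr(base, 11, 30)
  m <- map_contig(frag, db)
  expect_equal(m$class, "canonical")
  expect_equal(m$alignment$target_accession, db$accession[1])

  ## 2 substitutions in 20 positions: 90% identity, noncanonical variant
  var <- frag
  for (p in c(5L, 12L)) {
    old <- substr(var, p, p)
    substr(var, p, p) <- setdiff(c("G", "W"), old)[1]
  }
  m2 <- map_contig(var, db)
  expect_equal(m2$class, "noncanonical_variant")
  expect_equal(m2$alignment$identity_pct, 90)

  ## a sequence with no >= 75% window anywhere
  m3 <- map_contig("YGEEMADHCPS", toy_db(paste(rep("KGKGKGKGKG", 6),
                                               collapse = "")))
  expect_equal(m3$class, "unmatched")
})

test_that("mapping at the 100% gate accepts exactly substrings (up to I/L)", {
  set.seed(22)
  base <- random_peptide(80)
  db <- toy_db(base)
  sub <- substr(base, 20, 39)
  expect_equal(map_contig(sub, db, min_identity = 100)$class, "canonical")
  swapped <- chartr("IL", "LI", sub)
  expect_equal(map_contig(swapped, db, min_identity = 100)$class, "canonical")
  mut <- sub
  substr(mut, 4, 4) <- if (substr(mut, 4, 4) == "W") "F" else "W"
  expect_false(map_contig(mut, db, min_identity = 100)$class == "canonical")
})

test_that("nested and extended sequences cluster together at 95%", {
  ## missed-cleavage extension: identical over the shorter sequence
  cl <- cluster_greedy(c("a", "b"), c("PEPTIDEK", "PEPTIDEKR"))
  expect_equal(length(unique(cl$cluster)), 1L)
  expect_equal(unique(cl$centroid), "PEPTIDEKR")  # longest member is centroid
  ## a peptide nested inside a longer contig
  cl2 <- cluster_greedy(c("pep", "contig"),
                        c("GLYGGPSYGYG", "AAGLYGGPSYGYGAPTSQR"))
  expect_equal(length(unique(cl2$cluster)), 1L)
})

test_that("dissimilar sequences form singletons", {
  set.seed(31)
  seqs <- unique(vapply(rep(12, 25), random_peptide, ""))[1:20]
  ids <- paste0("s", seq_along(seqs))
  ## verify the premise pairwise, then the clustering
  sim <- outer(seq_along(seqs), seq_along(seqs), Vectorize(function(i, j)
    if (i == j) 100 else identity_minlen(seqs[i], seqs[j])))
  keep <- !apply(upper.tri(sim) & sim >= 95, 2, any)
  seqs <- seqs[keep]; ids <- ids[keep]
  cl <- cluster_greedy(ids, seqs)
  expect_equal(length(unique(cl$cluster)), length(seqs))
})

test_that("clustering partitions the input deterministically", {
  set.seed(33)
  fams <- lapply(1:4, function(i) {
    base <- random_peptide(20)
    mut <- base
    substr(mut, 7, 7) <- if (substr(mut, 7, 7) == "A") "G" else "A"
    c(base, mut, substr(base, 3, 20))
  })
  seqs <- unlist(fams)
  ids <- paste0("q", seq_along(seqs))
  cl1 <- cluster_greedy(ids, seqs)
  expect_setequal(cl1$id, ids)
  expect_equal(anyDuplicated(cl1$id), 0L)
  ## permuting the input does not change the partition
  perm <- sample(seq_along(seqs))
  cl2 <- cluster_greedy(ids[perm], seqs[perm])
  part1 <- split(cl1$id, cl1$cluster)
  part2 <- split(cl2$id, cl2$cluster)
  norm <- function(p) sort(vapply(p, function(x) paste(sort(x), collapse = ","), ""))
  expect_equal(norm(part1), norm(part2))
})

test_that("proteotypic peptides are counted only for unique occurrences", {
  set.seed(41)
  a <- random_peptide(60); b <- random_peptide(60)
  shared <- substr(a, 10, 25)
  b2 <- paste0(substr(b, 1, 20), shared, substr(b, 21, 60))
  db <- toy_db(c(a, b2))
  uniq_pep <- substr(a, 40, 55)
  counts <- count_proteotypic(c(uniq_pep, shared), db)
  expect_equal(unname(counts[db$accession[1]]), 1L)  # unique peptide counts
  expect_equal(unname(counts[db$accession[2]]), 0L)  # shared contributes nowhere
})
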