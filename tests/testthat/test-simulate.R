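test_that("proteome generation is deterministic and tier-faithful", {
  cfg <- sim_config(n_proteins = 100, n_group_specific = 2,
                    n_noncanonical = 2, seed = 5)
  gp1 <- generate_proteome(cfg)
  gp2 <- generate_proteome(cfg)
  expect_identical(gp1, gp2)
  expect_true(all(nchar(gp1$db$sequence) >= cfg$len_range[1]))
  expect_true(all(nchar(gp1$db$sequence) <= cfg$len_range[2]))
  ## concentrations respect their assigned tier bounds
  expect_equal(unname(assign_tier(gp1$abundance, pipeline_config())),
               unname(gp1$tier))
  ## degenerate fractions: everything high-abundance
  gp3 <- generate_proteome(sim_config(n_proteins = 50, n_group_specific = 1,
                                      n_noncanonical = 1, seed = 6,
                                      tier_fractions = c(1, 0, 0)))
  expect_true(all(gp3$abundance > 1e-3))
  ## empirical tier proportions within 3 binomial sd at n = 1000
  gp4 <- generate_proteome(sim_config(n_proteins = 1000, n_group_specific = 1,
                                      n_noncanonical = 1, seed = 7,
                                      len_range = c(50, 60)))
  for (tr in c("high", "mid", "low")) {
    p <- c(high = 0.23, mid = 0.20, low = 0.57)[[tr]]
    expect_lt(abs(sum(gp4$tier == tr) - 1000 * p),
              3 * sqrt(1000 * p * (1 - p)))
  }
})

test_that("tryptic digestion applies the K/R rule with the proline veto", {
  d <- digest_tryptic("AAAKGGGR", missed_max = 1, min_len = 1)
  expect_setequal(d$peptide[d$n_missed == 0], c("AAAK", "GGGR"))
  expect_equal(d$peptide[d$n_missed == 1], "AAAKGGGR")
  ## no cleavage when K precedes P
  expect_equal(digest_tryptic("AAKPGGR", missed_max = 2, min_len = 1)$peptide,
               "AAKPGGR")
  ## C-terminal fragment keeps its non-tryptic end
  d2 <- digest_tryptic("AAAKGGGQ", missed_max = 0, min_len = 1)
  expect_setequal(d2$peptide, c("AAAK", "GGGQ"))
})

test_that("digestion matches an independent enumeration oracle", {
  set.seed(13)
  for (i in 1:5) {
    prot <- random_peptide(1000)
    ours <- sort(digest_tryptic(prot)$peptide)
    expect_equal(ours, digest_oracle(prot))
  }
})

test_that("noise-free reads are substrings of their source proteins", {
  cfg <- sim_config(n_case = 3, n_control = 3, n_proteins = 8,
                    len_range = c(60, 200), n_group_specific = 2,
                    n_noncanonical = 0, seed = 17)
  sim <- simulate_cohort(cfg)
  pooled <- paste(sim$db$sequence, collapse = "|")
  for (r in sim$denovo_reads$sequence)
    expect_true(grepl(r, pooled, fixed = TRUE))
  ## planted group-specific proteins appear in every case, never in controls
  for (acc in sim$truth$group_specific) {
    det <- sim$truth$detected[[acc]]
    expect_setequal(det, sim$samples$sample_id[sim$samples$group == "case"])
  }
})

test_that("the same seed reproduces a cohort byte for byte", {
  cfg <- sim_config(n_case = 3, n_control = 3, n_proteins = 8,
                    len_range = c(60, 200), n_group_specific = 2,
                    n_noncanonical = 1, seed = 23)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_cohort(cfg), d1)
  write_simulation(simulate_cohort(cfg), d2)
  for (f in c("ref.fasta", "abundance.tsv", "library.tsv",
              "denovo_reads.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("planted noncanonical windows carry the declared edits", {
  cfg <- sim_config(n_case = 2, n_control = 2, n_proteins = 8,
                    len_range = c(80, 200), n_group_specific = 2,
                    n_noncanonical = 3, sap_edits = 2, seed = 29)
  sim <- simulate_cohort(cfg)
  nc <- sim$truth$noncanonical
  expect_equal(nrow(nc), 3L)
  for (i in seq_len(nrow(nc))) {
    src <- sim$db$sequence[sim$db$accession == nc$accession[i]]
    orig <- substr(src, nc$start[i], nc$start[i] + nchar(nc$sequence[i]) - 1L)
    diffs <- sum(seq_chars(orig) != seq_chars(nc$sequence[i]))
    expect_equal(diffs, 2L)
    ## identity of the variant window stays in the noncanonical band
    idp <- 100 * (nchar(orig) - diffs) / nchar(orig)
    expect_gte(idp, 75)
    expect_lt(idp, 100)
  }
})

test_that("detection counts in stochastic mode track the binomial model", {
  cfg <- sim_config(n_case = 25, n_control = 25, n_proteins = 10,
                    len_range = c(60, 120), n_group_specific = 0,
                    n_noncanonical = 0, noise_free = FALSE, dropout = 0.3,
                    seed = 31)
  sim <- simulate_cohort(cfg)
  n_det <- lengths(sim$truth$detected)
  p <- 0.7; n <- 50
  expect_true(all(abs(n_det - n * p) <= 4 * sqrt(n * p * (1 - p))))
})

test_that("simulation config rejects inconsistent settings", {
  expect_error(sim_config(tier_fractions = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(sim_config(n_proteins = 3, n_group_specific = 3,
                          n_noncanonical = 2), "n_proteins")
  expect_error(sim_config(denovo_sub_rate = 1.5), "\\[0, 1\\]")
  expect_error(pipeline_config(kmer_size = 1), "k")
  expect_error(pipeline_config(tier_high_min = 1e-6), "tier")
})
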