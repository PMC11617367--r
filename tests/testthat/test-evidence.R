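test_that("coverage percent rounds half-up to the reported integer", {
  expect_equal(coverage_percent(565, 609), 93)
  expect_equal(coverage_percent(34, 106), 32)
  expect_equal(coverage_percent(555, 698), 80)
  expect_equal(coverage_percent(0, 500), 0)
  expect_equal(coverage_percent(1, 200, rounded = FALSE), 0.5)
  expect_equal(coverage_percent(1, 200), 1)   # 0.5 rounds up, not to even
  expect_error(coverage_percent(5, 0), "positive")
})

test_that("abundance tiers follow the plasma concentration brackets", {
  cfg <- pipeline_config()
  ## 50 ug/L (serum amyloid A-2) is mid; 11 ng/L (ephrin-B3) is low
  expect_equal(assign_tier(50e-6, cfg), "mid")
  expect_equal(assign_tier(11e-9, cfg), "low")
  ## boundaries: exactly 1 ug/mL stays mid, exactly 10 ng/mL is mid
  expect_equal(assign_tier(1e-3, cfg), "mid")
  expect_equal(assign_tier(1e-5, cfg), "mid")
  expect_equal(assign_tier(1.0001e-3, cfg), "high")
  expect_equal(assign_tier(0.9999e-5, cfg), "low")
  expect_equal(assign_tier(NA_real_, cfg), "unknown")
  expect_error(assign_tier(-1, cfg), "negative")
  ## monotone in concentration
  conc <- sort(10^runif(50, -9, 1))
  tiers <- assign_tier(conc, cfg)
  ranks <- c(low = 1, mid = 2, high = 3)[tiers]
  expect_true(all(diff(ranks) >= 0))
})

test_that("evidence merging unions footprints and splits sample counts", {
  set.seed(51)
  prot <- random_peptide(100)
  db <- toy_db(prot, "P00001")
  pep <- substr(prot, 11, 21)  # covers 0-based residues 10..20
  hits <- data.frame(sample_id = c("S1", "S2", "C1"),
                     group = c("case", "case", "control"),
                     sequence = pep,
                     proteins = I(replicate(3, "P00001", simplify = FALSE)),
                     modifications = I(replicate(3,
                       data.frame(position = integer(0),
                                  mod_type = character(0)), simplify = FALSE)),
                     strategy = "library", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = c("S1", "S2", "C1"),
                        group = c("case", "case", "control"))
  no_contigs <- data.frame(sample_id = character(0), sequence = character(0),
                           accession = character(0), class = character(0),
                           identity_pct = numeric(0), covered = I(list()))
  ev <- merge_evidence(hits, no_contigs, db, samples,
                       abundance = c(P00001 = 2e-3))
  expect_equal(ev$covered_library[[1]], 10:20)
  expect_equal(coverage_percent(length(ev$covered_library[[1]]),
                                ev$length_aa[1]), 11)
  expect_equal(ev$samples_case, 2L)
  expect_equal(ev$samples_control, 1L)
  expect_equal(ev$strategies, "library")
  expect_equal(ev$tier, "high")
  expect_equal(ev$ptp_count, 1L)

  bad <- hits; bad$proteins <- I(replicate(3, "NOPE", simplify = FALSE))
  expect_error(merge_evidence(bad, no_contigs, db, samples), "unknown accession")
})

test_that("strategy overlap counts are disjoint and sum to the total", {
  ev <- data.frame(accession = c("A", "B", "C", "D"),
                   strategies = c("library", "denovo", "denovo+library",
                                  "denovo+library"))
  ov <- strategy_overlap(ev)
  expect_equal(unname(ov$proteins), c(1L, 1L, 2L))
  expect_equal(sum(ov$proteins), nrow(ev))
  cl <- data.frame(cluster = c(1, 1, 2, 3), strategy = c("library", "denovo",
                                                         "library", "denovo"))
  ov2 <- strategy_overlap(ev, cl)
  expect_equal(unname(ov2$peptides), c(1L, 1L, 1L))
})

test_that("group-specific selection applies the Sz/Cnt/PTP rule", {
  cfg <- pipeline_config()
  ev <- data.frame(
    accession = c("KEEP", "TOO_FEW_CASES", "TOO_MANY_CONTROLS", "NO_PTP"),
    samples_case = c(9L, 8L, 9L, 20L),
    samples_control = c(1L, 0L, 6L, 0L),
    ptp_count = c(2L, 5L, 5L, 0L))
  expect_equal(select_group_specific(ev, cfg), "KEEP")
})

test_that("length bins and coverage augmentation recount correctly", {
  ev <- data.frame(
    accession = c("A", "B"), length_aa = c(500L, 60L),
    covered_library = I(list(0:49, integer(0))),
    covered_denovo = I(list(100:149, 0:29)),
    covered_noncanonical = I(list(30:79, 10:19)),
    samples_case = c(10L, 10L), samples_control = c(10L, 10L),
    strategies = c("denovo+library", "denovo"),
    ptp_count = c(1L, 1L), tier = "unknown",
    group_specific = FALSE, stringsAsFactors = FALSE)
  bins <- summarize_length_bins(ev)
  expect_equal(bins$bins$library[bins$bins$bin == "100-1000"], 1L)
  expect_equal(bins$bins$denovo[bins$bins$bin == "100-1000"], 1L)
  expect_equal(bins$bins$denovo[bins$bins$bin == "10-100"], 1L)
  expect_equal(sum(bins$bins$library), 1L)

  aug <- coverage_augmentation(ev)
  ## A: noncanonical 30..79 minus library 0..49 leaves 50..79 (30 residues)
  expect_equal(aug$additional_aa[1], 30L)
  expect_equal(aug$additional_pct[1], 6)
  ## B: noncanonical inside denovo coverage adds nothing
  expect_equal(aug$additional_aa[2], 0L)
  ## merged coverage dominates each single strategy
  for (i in 1:2) {
    merged <- length(union(union(ev$covered_library[[i]], ev$covered_denovo[[i]]),
                           ev$covered_noncanonical[[i]]))
    expect_gte(merged, length(ev$covered_library[[i]]))
    expect_gte(merged, length(ev$covered_denovo[[i]]))
    expect_lte(coverage_percent(merged, ev$length_aa[i]), 100)
  }
})

test_that("detection filter honours pooled and per-group readings", {
  ev <- data.frame(accession = c("A", "B"), samples_case = c(9L, 6L),
                   samples_control = c(1L, 6L))
  pooled <- filter_detected(ev, pipeline_config(min_samples_detected = 10))
  expect_setequal(pooled$accession, c("A", "B"))
  strict <- filter_detected(ev, pipeline_config(min_samples_detected = 6,
                                                per_group_filter = TRUE))
  expect_equal(strict$accession, "B")
})
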