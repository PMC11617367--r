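#' Simulation configuration
#'
#' Study conditions for the synthetic cohort generator. The cohort shape
#' follows the study this pipeline targets: 48 case and 50 control plasma
#' samples, protein lengths log-uniform over 50-3,000 aa, and the three
#' plasma abundance tiers in roughly the observed proportions (high 23%,
#' mid 20%, low 57%) with per-tier detection probabilities 0.9/0.5/0.15.
#'
#' @param n_case,n_control cohort sizes (defaults 48, 50).
#' @param n_proteins reference proteome size (default 30; desk-scale while
#'   still populating all three tiers).
#' @param len_range protein length range in aa, sampled log-uniformly
#'   (default `c(50, 3000)`).
#' @param tier_fractions named or positional fractions `(high, mid, low)`
#'   summing to 1 (default `c(0.23, 0.20, 0.57)`).
#' @param detect_prob_by_tier detection probability per tier in the
#'   stochastic mode (default `c(0.9, 0.5, 0.15)`).
#' @param n_group_specific proteins present only in case samples (default 5).
#' @param n_noncanonical proteins whose de novo evidence is a planted
#'   single-residue variant window, never seen by the library search
#'   (default 3).
#' @param library_miss_rate probability that a detected noncanonical-variant
#'   protein emits no library peptides (default 1: such proteins are outside
#'   the library search's reach).
#' @param denovo_sub_rate per-read probability of one substitution
#'   (I<->L preferred) (default 0).
#' @param denovo_transpose_rate per-read probability of one adjacent
#'   transposition (default 0).
#' @param sap_edits substitutions planted in each noncanonical variant
#'   window (default 2).
#' @param phospho_rate probability that an emitted library peptide with an
#'   S/T/Y residue carries a planted phosphosite annotation (default 0).
#' @param pep_detect_prob per-peptide emission probability for a detected
#'   protein in stochastic mode (default 0.25).
#' @param read_length,window_length de novo read length and the length of
#'   the per-protein window the reads tile (defaults 14, 24).
#' @param noise_free when TRUE (default), detection is deterministic —
#'   background and noncanonical proteins appear in every sample, planted
#'   group-specific proteins in every case sample and no control sample —
#'   and all sequencing-error rates are forced to 0. When FALSE, detection
#'   follows `detect_prob_by_tier` (or `1 - dropout` when `dropout` is set).
#' @param dropout optional uniform detection-dropout probability overriding
#'   the tier model (e.g. 0.2 for the 20%-dropout recovery experiment).
#' @param seed integer seed.
#' @return a list of class `dualprot_sim_config`.
#' @export
sim_config <- function(n_case = 48L, n_control = 50L, n_proteins = 30L,
                       len_range = c(50L, 3000L),
                       tier_fractions = c(high = 0.23, mid = 0.20, low = 0.57),
                       detect_prob_by_tier = c(high = 0.9, mid = 0.5, low = 0.15),
                       n_group_specific = 5L, n_noncanonical = 3L,
                       library_miss_rate = 1.0,
                       denovo_sub_rate = 0, denovo_transpose_rate = 0,
                       sap_edits = 2L, phospho_rate = 0,
                       pep_detect_prob = 0.25,
                       read_length = 14L, window_length = 24L,
                       noise_free = TRUE, dropout = NULL, seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(tier_fractions) - 1) > 1e-8)
    dp_config_error("tier_fractions must sum to 1")
  probs <- c(detect_prob_by_tier, library_miss_rate, denovo_sub_rate,
             denovo_transpose_rate, phospho_rate, pep_detect_prob)
  if (any(probs < 0 | probs > 1))
    dp_config_error("probabilities must lie in [0, 1]")
  if (n_case < 1L || n_control < 1L)
    dp_config_error("cohort sizes must be positive")
  if (n_proteins < n_group_specific + n_noncanonical)
    dp_config_error("n_proteins must be >= n_group_specific + n_noncanonical")
  if (window_length < read_length)
    dp_config_error("window_length must be >= read_length")
  class(cfg) <- "dualprot_sim_config"
  cfg
}

#' Generate a synthetic reference proteome with plasma concentrations
#'
#' Sequences are i.i.d. residues at Swiss-Prot background frequencies;
#' lengths are log-uniform over `len_range`; each protein is assigned an
#' abundance tier by `tier_fractions` and a concentration drawn log-uniform
#' within that tier's bounds (high: 1 ug/mL - 50 g/L, mid: 10 ng/mL -
#' 1 ug/mL, low: 1 ng/L - 10 ng/mL).
#'
#' @param config a [sim_config()]. The RNG is seeded from `config$seed`.
#' @return list with `db` (data.frame as from [read_fasta()]), `abundance`
#'   (named vector, g/L) and `tier` (named character).
#' @export
generate_proteome <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_proteins
  lens <- round(exp(runif(n, log(config$len_range[1]), log(config$len_range[2]))))
  seqs <- vapply(lens, function(L)
    paste(sample(names(AA_BACKGROUND_FREQ), L, replace = TRUE,
                 prob = AA_BACKGROUND_FREQ), collapse = ""), "")
  acc <- sprintf("SIM%04d", seq_len(n))
  db <- data.frame(accession = acc, name = sprintf("SIMP%d_SYNTH", seq_len(n)),
                   sequence = seqs, length_aa = nchar(seqs),
                   stringsAsFactors = FALSE)
  tier <- sample(c("high", "mid", "low"), n, replace = TRUE,
                 prob = config$tier_fractions)
  bounds <- list(high = c(1e-3, 50), mid = c(1e-5, 1e-3), low = c(1e-9, 1e-5))
  conc <- vapply(tier, function(tr)
    exp(runif(1, log(bounds[[tr]][1]), log(bounds[[tr]][2]))), 0.0)
  list(db = db, abundance = setNames(conc, acc), tier = setNames(tier, acc))
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, and emits every
#' peptide with 0 to `missed_max` missed cleavages whose length is at least
#' `min_len`.
#'
#' @param sequence protein sequence.
#' @param missed_max maximum missed cleavages (default 2).
#' @param min_len minimum peptide length (default 6).
#' @return data.frame with `peptide`, `start` (1-based), `n_missed`.
#' @export
digest_tryptic <- function(sequence, missed_max = 2L, min_len = 6L) {
  ch <- seq_chars(sequence)
  n <- length(ch)
  cut_after <- which(ch %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & ch[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  nfrag <- length(starts)
  out <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:min(missed_max, nfrag - i)) {
      s <- starts[i]; e <- ends[i + m]
      if (e - s + 1L < min_len) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(sequence, s, e), start = s, n_missed = m,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(peptide = character(0), start = integer(0),
                      n_missed = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a dual-strategy cohort with ground truth
#'
#' Generates the proteome, plants group-specific and noncanonical-variant
#' proteins, then emits per-sample library peptide identifications and
#' de novo reads (overlapping windows with Beta(8,2) per-residue
#' confidences, optional substitution/transposition errors). See
#' [sim_config()] for the detection model and the meaning of `noise_free`.
#'
#' @param config a [sim_config()].
#' @return list of class `dualprot_sim`: `db`, `abundance`, `tier`,
#'   `samples` (data.frame `sample_id`, `group`), `library_hits`,
#'   `denovo_reads` (data.frames in the reader formats) and `truth`
#'   (planted group-specific accessions, noncanonical variants with their
#'   edits, per-protein detection lists, planted phospho sites, per-protein
#'   de novo windows).
#' @export
simulate_cohort <- function(config = sim_config()) {
  gp <- generate_proteome(config)   # seeds the RNG
  db <- gp$db
  n <- config$n_proteins
  group_specific <- db$accession[seq_len(config$n_group_specific)]
  noncanonical <- db$accession[config$n_group_specific +
                                 seq_len(config$n_noncanonical)]
  samples <- data.frame(
    sample_id = c(sprintf("SZ%03d", seq_len(config$n_case)),
                  sprintf("CNT%03d", seq_len(config$n_control))),
    group = c(rep("case", config$n_case), rep("control", config$n_control)),
    stringsAsFactors = FALSE)

  ## per-protein de novo source window (the variant version for planted
  ## noncanonical proteins)
  windows <- data.frame(accession = db$accession, start = NA_integer_,
                        sequence = NA_character_, edits = NA_integer_,
                        stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    L <- db$length_aa[i]
    w <- min(config$window_length, L)
    st <- if (L == w) 1L else sample(L - w + 1L, 1L)
    wseq <- substr(db$sequence[i], st, st + w - 1L)
    edits <- 0L
    if (db$accession[i] %in% noncanonical) {
      ## interior positions only: an edit at the window margin would be
      ## trimmed by local alignment and the variant lost
      interior <- if (w >= 10L) 4:(w - 3L) else seq_len(w)
      pos <- sample(interior, min(config$sap_edits, length(interior)))
      for (p in pos) {
        old <- substr(wseq, p, p)
        repl <- sample(setdiff(AA20, c(old, "I", "L")), 1L)
        substr(wseq, p, p) <- repl
      }
      edits <- length(pos)
    }
    windows$start[i] <- st
    windows$sequence[i] <- wseq
    windows$edits[i] <- edits
  }

  digests <- lapply(seq_len(n), function(i)
    digest_tryptic(db$sequence[i], missed_max = 2L, min_len = 6L))
  det_prob_of <- function(acc) {
    if (!is.null(config$dropout)) return(1 - config$dropout)
    unname(config$detect_prob_by_tier[gp$tier[acc]])
  }

  lib_rows <- list(); read_rows <- list()
  detected <- setNames(vector("list", n), db$accession)
  phospho_truth <- list()
  sub_rate <- if (config$noise_free) 0 else config$denovo_sub_rate
  tr_rate <- if (config$noise_free) 0 else config$denovo_transpose_rate
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    grpv <- samples$group[s]
    for (i in seq_len(n)) {
      acc <- db$accession[i]
      is_gs <- acc %in% group_specific
      det <- if (config$noise_free) {
        if (is_gs) grpv == "case" else TRUE
      } else {
        p <- det_prob_of(acc)
        if (is_gs && grpv == "control") p <- 0
        runif(1) < p
      }
      if (!det) next
      detected[[acc]] <- c(detected[[acc]], sid)
      ## library strategy
      emit_lib <- !(acc %in% noncanonical &&
                      runif(1) < config$library_miss_rate)
      dig <- digests[[i]]
      if (emit_lib && nrow(dig) > 0L) {
        zero_missed <- dig[dig$n_missed == 0L, , drop = FALSE]
        if (config$noise_free) {
          sel <- seq_len(min(3L, nrow(zero_missed)))
          peps <- zero_missed$peptide[sel]
        } else {
          keep <- runif(nrow(zero_missed)) < config$pep_detect_prob
          if (!any(keep)) keep[1] <- TRUE
          peps <- zero_missed$peptide[keep]
        }
        for (pep in peps) {
          mods <- ""
          if (config$phospho_rate > 0 && runif(1) < config$phospho_rate) {
            sty <- which(seq_chars(pep) %in% c("S", "T", "Y"))
            if (length(sty)) {
              pos <- sty[sample.int(length(sty), 1L)]
              mod <- c(S = "SEP", T = "TPO", Y = "PTR")[substr(pep, pos, pos)]
              mods <- sprintf("%d:%s", pos, mod)
              phospho_truth[[length(phospho_truth) + 1L]] <- data.frame(
                accession = acc, peptide = pep, position = pos,
                mod_type = unname(mod), sample_id = sid,
                stringsAsFactors = FALSE)
            }
          }
          lib_rows[[length(lib_rows) + 1L]] <- data.frame(
            sample_id = sid, group = grpv, peptide = pep, proteins = acc,
            mods = mods, stringsAsFactors = FALSE)
        }
      }
      ## de novo strategy: reads tiling the protein's window
      wseq <- windows$sequence[i]
      rl <- min(config$read_length, nchar(wseq))
      starts <- unique(c(seq(1L, nchar(wseq) - rl + 1L, by = 2L),
                         nchar(wseq) - rl + 1L))
      for (st in starts) {
        r <- substr(wseq, st, st + rl - 1L)
        if (sub_rate > 0 && runif(1) < sub_rate) {
          p <- sample(nchar(r), 1L)
          old <- substr(r, p, p)
          repl <- if (old == "I") {
            "L"
          } else if (old == "L") {
            "I"
          } else {
            sample(setdiff(AA20, old), 1L)
          }
          substr(r, p, p) <- repl
        }
        if (tr_rate > 0 && runif(1) < tr_rate && nchar(r) >= 2L) {
          p <- sample(nchar(r) - 1L, 1L)
          r <- paste0(substr(r, 1L, p - 1L), substr(r, p + 1L, p + 1L),
                      substr(r, p, p), substr(r, p + 2L, nchar(r)))
        }
        read_rows[[length(read_rows) + 1L]] <- data.frame(
          sample_id = sid, sequence = r,
          confidence = I(list(round(stats::rbeta(nchar(r), 8, 2), 4))),
          stringsAsFactors = FALSE)
      }
    }
  }

  library_hits <- if (length(lib_rows)) {
    raw <- do.call(rbind, lib_rows)
    data.frame(sample_id = raw$sample_id, group = raw$group,
               sequence = raw$peptide,
               proteins = I(as.list(raw$proteins)),
               modifications = I(lapply(raw$mods, function(m) {
                 if (!nzchar(m)) return(data.frame(position = integer(0),
                                                   mod_type = character(0)))
                 kv <- strsplit(m, ":", fixed = TRUE)[[1]]
                 data.frame(position = as.integer(kv[1]), mod_type = kv[2],
                            stringsAsFactors = FALSE)
               })),
               strategy = "library", stringsAsFactors = FALSE)
  } else empty_library_hits()
  denovo_reads <- if (length(read_rows)) {
    out <- do.call(rbind, read_rows); rownames(out) <- NULL; out
  } else data.frame(sample_id = character(0), sequence = character(0),
                    confidence = I(list()), stringsAsFactors = FALSE)

  structure(list(
    db = db, abundance = gp$abundance, tier = gp$tier, samples = samples,
    library_hits = library_hits, denovo_reads = denovo_reads,
    truth = list(
      group_specific = group_specific,
      noncanonical = windows[windows$accession %in% noncanonical, ,
                             drop = FALSE],
      windows = windows,
      detected = detected,
      phospho = if (length(phospho_truth)) do.call(rbind, phospho_truth)
                else NULL)),
    class = "dualprot_sim")
}

#' Write a simulated cohort to a directory
#'
#' Emits `ref.fasta`, `abundance.tsv`, `samples.tsv`, `library.tsv`,
#' `denovo_reads.tsv` and `truth.json` in the reader formats of the
#' pipeline, so a simulation round-trips through the file interfaces.
#'
#' @param sim a `dualprot_sim` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$db, file.path(dir, "ref.fasta"))
  utils::write.table(
    data.frame(accession = names(sim$abundance),
               concentration_g_per_L = format(sim$abundance, digits = 8,
                                              scientific = TRUE)),
    file.path(dir, "abundance.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_library_hits(sim$library_hits, file.path(dir, "library.tsv"))
  write_denovo_reads(sim$denovo_reads, file.path(dir, "denovo_reads.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(group_specific = truth$group_specific,
         noncanonical = truth$noncanonical,
         windows = truth$windows,
         detected = truth$detected,
         phospho = truth$phospho),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
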