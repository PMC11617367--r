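#' Map every contig of a contig table onto the reference database
#'
#' Convenience wrapper over [map_contig()] that records, per contig, the best
#' hit, its class, and the 0-based target residues it covers. For a canonical
#' hit the full alignment footprint counts as covered; for a noncanonical
#' variant only the matched columns do (a mismatched column is evidence of a
#' variant, not of the reference residue).
#'
#' @param contigs data.frame with `sample_id` and `sequence` (e.g. from
#'   [assemble_contigs()]).
#' @param db reference data.frame from [read_fasta()].
#' @param config a [pipeline_config()].
#' @return data.frame with `sample_id`, `sequence`, `accession` (NA when
#'   unmatched), `class`, `identity_pct`, `covered` (list column of 0-based
#'   residue indices).
#' @export
map_contigs <- function(contigs, db, config = pipeline_config()) {
  ## identical contig sequences recur across samples; map each once
  uniq <- unique(contigs$sequence)
  mapped <- lapply(uniq, function(s) {
    m <- map_contig(s, db,
                    min_identity = config$map_identity_min,
                    il_equivalent = config$il_equivalent,
                    match = config$match, mismatch = config$mismatch,
                    gap_open = config$gap_open, gap_extend = config$gap_extend)
    if (m$class == "unmatched")
      list(acc = NA_character_, cls = m$class,
           idp = if (is.null(m$alignment)) NA_real_ else m$alignment$identity_pct,
           cov = integer(0))
    else
      list(acc = m$alignment$target_accession, cls = m$class,
           idp = m$alignment$identity_pct,
           cov = alignment_footprint(
             m$alignment, matched_only = (m$class == "noncanonical_variant")))
  })
  names(mapped) <- uniq
  hit <- mapped[contigs$sequence]
  data.frame(sample_id = contigs$sample_id, sequence = contigs$sequence,
             accession = vapply(hit, `[[`, "", "acc"),
             class = vapply(hit, `[[`, "", "cls"),
             identity_pct = vapply(hit, `[[`, 0.0, "idp"),
             covered = I(lapply(hit, `[[`, "cov")),
             row.names = NULL, stringsAsFactors = FALSE)
}

## 0-based target residues covered by an alignment.
alignment_footprint <- function(al, matched_only = FALSE) {
  if (!matched_only) return(al$target_start:(al$target_end - 1L))
  aq <- seq_chars(al$aligned_query); at <- seq_chars(al$aligned_target)
  tpos <- cumsum(at != "-") - 1L + al$target_start
  sort(unique(tpos[aq != "-" & at != "-" & aq == at]))
}

#' Merge both identification strategies into per-protein evidence
#'
#' Library coverage is the union of exact peptide-occurrence footprints;
#' de novo coverage the union of canonical contig alignment footprints;
#' noncanonical coverage the union of matched columns of sub-100%-identity
#' alignments. Sample counts are distinct sample ids with at least one
#' supporting identification of either strategy, split by group.
#' Proteotypic-peptide counts are computed over library peptides plus
#' canonically mapped contig sequences.
#'
#' @param library_hits data.frame from [read_library_hits()] (may have zero
#'   rows).
#' @param contig_hits data.frame from [map_contigs()].
#' @param db reference data.frame from [read_fasta()].
#' @param samples data.frame with `sample_id`, `group` mapping every sample
#'   to `"case"` or `"control"`.
#' @param abundance optional named vector (g/L) from [read_abundance()].
#' @param config a [pipeline_config()].
#' @return data.frame with one row per detected protein: `accession`,
#'   `length_aa`, list columns `covered_library`, `covered_denovo`,
#'   `covered_noncanonical` (0-based residue sets), `samples_case` (Sz),
#'   `samples_control` (Cnt), `strategies`, `tier`, `ptp_count`,
#'   `group_specific`.
#' @export
merge_evidence <- function(library_hits, contig_hits, db, samples,
                           abundance = NULL, config = pipeline_config()) {
  acc_index <- setNames(seq_len(nrow(db)), db$accession)
  grp <- setNames(samples$group, samples$sample_id)
  ev <- new.env(parent = emptyenv())
  touch <- function(acc) {
    if (is.null(ev[[acc]]))
      ev[[acc]] <- list(lib = integer(0), dn = integer(0), nc = integer(0),
                        s_lib = character(0), s_dn = character(0),
                        strategies = character(0))
    invisible(NULL)
  }
  ## library peptides: exact substring footprints in each claimed protein
  for (i in seq_len(nrow(library_hits))) {
    pep <- library_hits$sequence[i]
    for (acc in library_hits$proteins[[i]]) {
      if (is.na(acc_index[acc]))
        dp_input_error("library peptide assigned to unknown accession '%s'", acc)
      touch(acc)
      rec <- ev[[acc]]
      occ <- gregexpr(pep, db$sequence[acc_index[acc]], fixed = TRUE)[[1]]
      if (occ[1] != -1L)
        for (st in occ)
          rec$lib <- union(rec$lib, (st - 1L):(st + nchar(pep) - 2L))
      rec$s_lib <- union(rec$s_lib, library_hits$sample_id[i])
      rec$strategies <- union(rec$strategies, "library")
      ev[[acc]] <- rec
    }
  }
  ## contig hits
  for (i in seq_len(nrow(contig_hits))) {
    acc <- contig_hits$accession[i]
    if (is.na(acc)) next
    touch(acc)
    rec <- ev[[acc]]
    if (contig_hits$class[i] == "canonical") {
      rec$dn <- union(rec$dn, contig_hits$covered[[i]])
    } else {
      rec$nc <- union(rec$nc, contig_hits$covered[[i]])
    }
    rec$s_dn <- union(rec$s_dn, contig_hits$sample_id[i])
    rec$strategies <- union(rec$strategies, "denovo")
    ev[[acc]] <- rec
  }
  accs <- sort(ls(ev))
  if (length(accs) == 0L)
    return(empty_evidence())
  ptp_peps <- unique(c(
    library_hits$sequence,
    contig_hits$sequence[contig_hits$class == "canonical"]))
  ptp <- if (length(ptp_peps))
    count_proteotypic(ptp_peps, db, il_equivalent = config$il_equivalent)
  else setNames(integer(nrow(db)), db$accession)

  rows <- lapply(accs, function(acc) {
    rec <- ev[[acc]]
    len <- db$length_aa[acc_index[acc]]
    if (any(c(rec$lib, rec$dn, rec$nc) >= len))
      dp_internal_error("coverage index beyond protein length for %s", acc)
    all_samples <- union(rec$s_lib, rec$s_dn)
    g <- grp[all_samples]
    data.frame(
      accession = acc, length_aa = len,
      covered_library = I(list(sort(rec$lib))),
      covered_denovo = I(list(sort(rec$dn))),
      covered_noncanonical = I(list(sort(rec$nc))),
      samples_case = sum(g == "case", na.rm = TRUE),
      samples_control = sum(g == "control", na.rm = TRUE),
      strategies = paste(sort(rec$strategies), collapse = "+"),
      ptp_count = unname(ptp[acc]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$tier <- assign_tier(
    if (is.null(abundance)) rep(NA_real_, nrow(out))
    else unname(abundance[out$accession]),
    config)
  out$group_specific <- out$accession %in% select_group_specific(out, config)
  out
}

empty_evidence <- function() {
  data.frame(accession = character(0), length_aa = integer(0),
             covered_library = I(list()), covered_denovo = I(list()),
             covered_noncanonical = I(list()),
             samples_case = integer(0), samples_control = integer(0),
             strategies = character(0), ptp_count = integer(0),
             tier = character(0), group_specific = logical(0),
             stringsAsFactors = FALSE)
}

#' Sequence coverage percent
#'
#' @param n_covered number of covered residues.
#' @param length_aa protein length (> 0).
#' @param rounded round half-up to integer for reporting (default TRUE);
#'   `FALSE` returns the unrounded percent.
#' @return numeric percent.
#' @examples
#' coverage_percent(565, 609)  # 93
#' @export
coverage_percent <- function(n_covered, length_aa, rounded = TRUE) {
  if (any(length_aa <= 0)) dp_input_error("length_aa must be positive")
  pct <- 100 * n_covered / length_aa
  if (rounded) round_half_up(pct) else pct
}

#' Assign plasma abundance tiers
#'
#' High above 1 ug/mL; mid from 10 ng/mL up to and including 1 ug/mL (the
#' conventional bracket is closed at both ends, so the boundary value goes
#' to mid); low below 10 ng/mL; `NA` concentration gives `"unknown"`.
#'
#' @param conc numeric vector of concentrations in g/L (NA allowed).
#' @param config a [pipeline_config()] (tier bounds).
#' @return character vector over `c("high", "mid", "low", "unknown")`.
#' @examples
#' assign_tier(c(5e-5, 1.1e-8), pipeline_config())  # "mid", "low"
#' @export
assign_tier <- function(conc, config = pipeline_config()) {
  if (any(conc < 0, na.rm = TRUE))
    dp_input_error("negative concentration")
  ifelse(is.na(conc), "unknown",
         ifelse(conc > config$tier_high_min, "high",
                ifelse(conc >= config$tier_mid_min, "mid", "low")))
}

#' Apply the cohort detection filter
#'
#' Keeps proteins detected in at least `min_samples_detected` samples,
#' pooled across groups by default or per group when the configuration sets
#' `per_group_filter`.
#'
#' @param evidence data.frame from [merge_evidence()].
#' @param config a [pipeline_config()].
#' @return filtered evidence data.frame.
#' @export
filter_detected <- function(evidence, config = pipeline_config()) {
  keep <- if (config$per_group_filter)
    evidence$samples_case >= config$min_samples_detected &
      evidence$samples_control >= config$min_samples_detected
  else
    (evidence$samples_case + evidence$samples_control) >=
      config$min_samples_detected
  evidence[keep, , drop = FALSE]
}

#' Select group-specific proteins
#'
#' A protein is group-specific when it was detected in at least
#' `group_specific_min_case` case samples, in at most
#' `group_specific_max_control` control samples, and has at least one
#' proteotypic peptide.
#'
#' @param evidence data.frame from [merge_evidence()].
#' @param config a [pipeline_config()].
#' @return character vector of selected accessions.
#' @export
select_group_specific <- function(evidence, config = pipeline_config()) {
  sel <- evidence$samples_case >= config$group_specific_min_case &
    evidence$samples_control <= config$group_specific_max_control &
    evidence$ptp_count >= 1L
  evidence$accession[sel]
}

#' Protein- and peptide-level overlap between strategies
#'
#' Protein counts come from the evidence table's `strategies` field; peptide
#' counts are computed on clusters, a cluster being "shared" when it holds
#' members detected by both strategies.
#'
#' @param evidence data.frame from [merge_evidence()].
#' @param clusters optional data.frame from [cluster_greedy()] with an added
#'   `strategy` column per member.
#' @return list with `proteins` and (when clusters are given) `peptides`,
#'   each a named vector `c(library_only, denovo_only, both)`.
#' @export
strategy_overlap <- function(evidence, clusters = NULL) {
  prot <- c(library_only = sum(evidence$strategies == "library"),
            denovo_only = sum(evidence$strategies == "denovo"),
            both = sum(evidence$strategies == "denovo+library"))
  out <- list(proteins = prot)
  if (!is.null(clusters)) {
    per_cluster <- tapply(clusters$strategy, clusters$cluster,
                          function(s) paste(sort(unique(s)), collapse = "+"))
    out$peptides <- c(library_only = sum(per_cluster == "library"),
                      denovo_only = sum(per_cluster == "denovo"),
                      both = sum(per_cluster == "denovo+library"))
  }
  out
}

#' Protein counts and coverage by log-spaced length bins
#'
#' Bins protein lengths into decades (10-100, 100-1,000, 1,000-10,000 aa)
#' and counts identifications per strategy in each bin; also returns the
#' per-protein (length, coverage, strategy) tuples behind the scatter.
#'
#' @param evidence data.frame from [merge_evidence()].
#' @return list with `bins` (data.frame: `bin`, `library`, `denovo`) and
#'   `points` (data.frame: `accession`, `length_aa`, `strategy`,
#'   `coverage_pct` unrounded).
#' @export
summarize_length_bins <- function(evidence) {
  breaks <- c(10, 100, 1000, 10000)
  labs <- c("10-100", "100-1000", "1000-10000")
  bin_of <- cut(evidence$length_aa, breaks = breaks, labels = labs,
                right = FALSE)
  has_lib <- grepl("library", evidence$strategies, fixed = TRUE)
  has_dn <- grepl("denovo", evidence$strategies, fixed = TRUE)
  bins <- data.frame(
    bin = labs,
    library = vapply(labs, function(b) sum(has_lib & !is.na(bin_of) & bin_of == b), 0L),
    denovo = vapply(labs, function(b) sum(has_dn & !is.na(bin_of) & bin_of == b), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  pts <- list()
  for (i in seq_len(nrow(evidence))) {
    if (has_lib[i])
      pts[[length(pts) + 1L]] <- data.frame(
        accession = evidence$accession[i], length_aa = evidence$length_aa[i],
        strategy = "library",
        coverage_pct = coverage_percent(length(evidence$covered_library[[i]]),
                                        evidence$length_aa[i], rounded = FALSE),
        stringsAsFactors = FALSE)
    if (has_dn[i])
      pts[[length(pts) + 1L]] <- data.frame(
        accession = evidence$accession[i], length_aa = evidence$length_aa[i],
        strategy = "denovo",
        coverage_pct = coverage_percent(length(evidence$covered_denovo[[i]]),
                                        evidence$length_aa[i], rounded = FALSE),
        stringsAsFactors = FALSE)
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(accession = character(0), length_aa = integer(0),
               strategy = character(0), coverage_pct = numeric(0))
  list(bins = bins, points = points)
}

#' Coverage augmentation by putative noncanonical sequences
#'
#' For each protein, how many residues the noncanonical (sub-100%-identity)
#' contig footprints add beyond the union of canonical library and de novo
#' coverage.
#'
#' @param evidence data.frame from [merge_evidence()].
#' @return data.frame with per-protein covered counts and half-up-rounded
#'   percentages: `library_aa/pct`, `denovo_aa/pct`, `noncanonical_aa/pct`,
#'   `additional_aa/pct`.
#' @export
coverage_augmentation <- function(evidence) {
  if (nrow(evidence) == 0L)
    return(data.frame(accession = character(0), length_aa = integer(0),
                      library_aa = integer(0), library_pct = numeric(0),
                      denovo_aa = integer(0), denovo_pct = numeric(0),
                      noncanonical_aa = integer(0), noncanonical_pct = numeric(0),
                      additional_aa = integer(0), additional_pct = numeric(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    lib <- evidence$covered_library[[i]]
    dn <- evidence$covered_denovo[[i]]
    nc <- evidence$covered_noncanonical[[i]]
    len <- evidence$length_aa[i]
    addl <- setdiff(nc, union(lib, dn))
    data.frame(
      accession = evidence$accession[i], length_aa = len,
      library_aa = length(lib), library_pct = coverage_percent(length(lib), len),
      denovo_aa = length(dn), denovo_pct = coverage_percent(length(dn), len),
      noncanonical_aa = length(nc),
      noncanonical_pct = coverage_percent(length(nc), len),
      additional_aa = length(addl),
      additional_pct = coverage_percent(length(addl), len),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
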