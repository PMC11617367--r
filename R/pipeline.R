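#' Run the dual-strategy pipeline end to end
#'
#' Stages, in order: read inputs, assemble per-sample de novo contigs, map
#' contigs to the reference with the identity gate, cluster peptides and
#' contigs, compute peptide properties, merge per-protein evidence, and
#' write every report table plus a run manifest. Tables are TSVs with a
#' leading `#` comment naming the producing stage and its parameters.
#'
#' @param ref_fasta reference proteome FASTA.
#' @param library_tsv library-search identifications TSV
#'   (see [read_library_hits()]).
#' @param denovo_tsv de novo reads TSV (see [read_denovo_reads()]).
#' @param out_dir report directory (created).
#' @param abundance_tsv optional concentration TSV; when absent all tiers
#'   are `"unknown"` (a warning is emitted).
#' @param samples_tsv optional TSV with `sample_id`, `group`; when absent
#'   the sample-to-group map is derived from the library table.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (`evidence`,
#'   `contigs`, `contig_hits`, `clusters`, `overlap`, `props`, `manifest`).
#' @export
run_pipeline <- function(ref_fasta, library_tsv, denovo_tsv, out_dir,
                         abundance_tsv = NULL, samples_tsv = NULL,
                         config = pipeline_config()) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  db <- read_fasta(ref_fasta)
  library_hits <- read_library_hits(library_tsv)
  reads <- read_denovo_reads(denovo_tsv)
  abundance <- NULL
  if (!is.null(abundance_tsv)) {
    abundance <- read_abundance(abundance_tsv)
  } else {
    warning("no abundance table given; all tiers will be 'unknown'")
  }
  samples <- if (!is.null(samples_tsv)) {
    utils::read.delim(samples_tsv, sep = "\t", colClasses = "character",
                      comment.char = "#")
  } else {
    unique(data.frame(sample_id = library_hits$sample_id,
                      group = library_hits$group, stringsAsFactors = FALSE))
  }

  ## stage: assemble
  contigs <- assemble_contigs(reads, k = config$kmer_size,
                              min_len = config$min_contig_len)
  ## stage: map
  contig_hits <- map_contigs(contigs, db, config)
  ## stage: cluster (unique peptide/contig sequences, strategy-tagged)
  seq_tab <- unique(rbind(
    data.frame(sequence = library_hits$sequence, strategy = "library",
               stringsAsFactors = FALSE),
    data.frame(sequence = contigs$sequence, strategy = "denovo",
               stringsAsFactors = FALSE)))
  clusters <- if (nrow(seq_tab)) {
    cl <- cluster_greedy(paste0("s", seq_len(nrow(seq_tab))), seq_tab$sequence,
                         min_identity = config$cluster_identity_min,
                         il_equivalent = config$il_equivalent,
                         match = config$match, mismatch = config$mismatch,
                         gap_open = config$gap_open,
                         gap_extend = config$gap_extend)
    cl$strategy <- seq_tab$strategy
    cl
  } else NULL
  ## stage: props
  props <- if (nrow(contigs))
    peptide_properties(unique(contigs$sequence))
  else peptide_properties(character(0))
  ## stage: compare
  evidence <- merge_evidence(library_hits, contig_hits, db, samples,
                             abundance, config)
  detected <- filter_detected(evidence, config)
  overlap <- strategy_overlap(detected, clusters)
  augmentation <- coverage_augmentation(detected)
  bins <- summarize_length_bins(detected)
  gs <- select_group_specific(evidence, config)

  manifest <- list(
    tool = "dualprot", version = as.character(utils::packageVersion("dualprot")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    inputs = input_digests(c(ref_fasta, library_tsv, denovo_tsv,
                             abundance_tsv, samples_tsv)))

  write_report_tsv(evidence_table(evidence), file.path(out_dir, "evidence.tsv"),
                   "compare", config)
  write_report_tsv(data.frame(level = c(rep("protein", 3),
                                        if (!is.null(overlap$peptides)) rep("peptide_cluster", 3)),
                              category = c(names(overlap$proteins),
                                           names(overlap$peptides)),
                              count = c(overlap$proteins, overlap$peptides)),
                   file.path(out_dir, "overlap.tsv"), "compare", config)
  write_report_tsv(data.frame(accession = detected$accession,
                              tier = detected$tier,
                              strategies = detected$strategies),
                   file.path(out_dir, "tiers.tsv"), "compare", config)
  write_report_tsv(evidence_table(evidence[evidence$accession %in% gs, ,
                                           drop = FALSE]),
                   file.path(out_dir, "group_specific.tsv"), "compare", config)
  write_report_tsv(augmentation,
                   file.path(out_dir, "coverage_augmentation.tsv"),
                   "compare", config)
  write_report_tsv(bins$bins, file.path(out_dir, "fig1_bins.tsv"),
                   "compare", config)
  write_report_tsv(bins$points, file.path(out_dir, "fig2_points.tsv"),
                   "compare", config)
  write_report_tsv(contigs, file.path(out_dir, "contigs.tsv"),
                   "assemble", config)
  write_report_tsv(contig_hit_table(contig_hits),
                   file.path(out_dir, "contig_hits.tsv"), "map", config)
  if (!is.null(clusters))
    write_report_tsv(clusters, file.path(out_dir, "clusters.tsv"),
                     "cluster", config)
  write_report_tsv(props, file.path(out_dir, "props.tsv"), "props", config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(evidence = evidence, contigs = contigs,
                 contig_hits = contig_hits, clusters = clusters,
                 overlap = overlap, augmentation = augmentation,
                 bins = bins, group_specific = gs, props = props,
                 manifest = manifest))
}

## flatten evidence list columns for TSV output
evidence_table <- function(evidence) {
  data.frame(
    accession = evidence$accession,
    length_aa = evidence$length_aa,
    library_aa = vapply(evidence$covered_library, length, 0L),
    library_pct = coverage_percent(
      vapply(evidence$covered_library, length, 0L), pmax(evidence$length_aa, 1L)),
    denovo_aa = vapply(evidence$covered_denovo, length, 0L),
    denovo_pct = coverage_percent(
      vapply(evidence$covered_denovo, length, 0L), pmax(evidence$length_aa, 1L)),
    noncanonical_aa = vapply(evidence$covered_noncanonical, length, 0L),
    samples_case = evidence$samples_case,
    samples_control = evidence$samples_control,
    strategies = evidence$strategies,
    tier = evidence$tier,
    ptp_count = evidence$ptp_count,
    group_specific = evidence$group_specific,
    stringsAsFactors = FALSE)
}

contig_hit_table <- function(contig_hits) {
  data.frame(sample_id = contig_hits$sample_id,
             sequence = contig_hits$sequence,
             accession = contig_hits$accession,
             class = contig_hits$class,
             identity_pct = contig_hits$identity_pct,
             covered_aa = vapply(contig_hits$covered, length, 0L),
             stringsAsFactors = FALSE)
}

write_report_tsv <- function(df, path, stage, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# dualprot stage=%s k=%d map_identity_min=%g cluster_identity_min=%g seed=%d",
    stage, config$kmer_size, config$map_identity_min,
    config$cluster_identity_min, config$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

input_digests <- function(paths) {
  paths <- paths[!vapply(paths, is.null, TRUE)]
  paths <- unlist(paths)
  if (length(paths) == 0L) return(list())
  md5 <- tools::md5sum(paths)
  as.list(setNames(as.character(md5), basename(paths)))
}
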