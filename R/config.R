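#' Pipeline configuration
#'
#' Collects every tunable threshold of the dual-strategy pipeline in one
#' validated object. Concentrations are stored in SI units (g/L); the display
#' helpers convert to the conventional plasma units (ug/mL, ng/mL).
#'
#' @param kmer_size k-mer size of the de Bruijn assembler (edges are k-mers,
#'   nodes are (k-1)-mers). Default 8.
#' @param map_identity_min minimum percent identity for a contig-to-reference
#'   alignment to be retained. Default 75.
#' @param cluster_identity_min percent identity threshold of the greedy
#'   centroid clustering. Default 95.
#' @param tier_high_min concentration (g/L) above which a protein is
#'   high-abundance. Default 1e-3 g/L (= 1 ug/mL).
#' @param tier_mid_min concentration (g/L) at or above which a protein is
#'   mid-abundance. Default 1e-5 g/L (= 10 ng/mL).
#' @param min_samples_detected pooled-cohort detection filter: a protein must
#'   be seen in at least this many samples to enter the comparison summaries.
#'   Default 10.
#' @param per_group_filter if TRUE the detection filter is applied per group
#'   (the stricter reading) instead of pooled. Default FALSE.
#' @param group_specific_min_case minimum number of case samples for
#'   group-specific selection. Default 9.
#' @param group_specific_max_control maximum number of control samples allowed
#'   for group-specific selection. Default 5.
#' @param missed_cleavages_max maximum missed cleavages in the in-silico
#'   tryptic digest. Default 2.
#' @param sasa_probe_radius solvent probe radius in Angstrom. Default 1.4.
#' @param sasa_n_points sphere sample points per atom for Shrake-Rupley.
#'   Default 960.
#' @param il_equivalent treat Ile and Leu as equivalent in matching and
#'   proteotypic counting (de novo sequencing cannot distinguish the isobaric
#'   pair). Default TRUE.
#' @param match,mismatch,gap_open,gap_extend local-alignment scoring
#'   parameters. Defaults +2/-1/-3/-1; a gap of length L costs
#'   `gap_open + (L-1) * gap_extend`.
#' @param min_contig_len minimum assembled contig length (aa). Default 10.
#' @param seed integer seed recorded in run manifests.
#'
#' @return an object of class `dualprot_config` (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$kmer_size
#' @export
pipeline_config <- function(kmer_size = 8L,
                            map_identity_min = 75,
                            cluster_identity_min = 95,
                            tier_high_min = 1e-3,
                            tier_mid_min = 1e-5,
                            min_samples_detected = 10L,
                            per_group_filter = FALSE,
                            group_specific_min_case = 9L,
                            group_specific_max_control = 5L,
                            missed_cleavages_max = 2L,
                            sasa_probe_radius = 1.4,
                            sasa_n_points = 960L,
                            il_equivalent = TRUE,
                            match = 2, mismatch = -1,
                            gap_open = -3, gap_extend = -1,
                            min_contig_len = 10L,
                            seed = 1L) {
  cfg <- list(
    kmer_size = as.integer(kmer_size),
    map_identity_min = map_identity_min,
    cluster_identity_min = cluster_identity_min,
    tier_high_min = tier_high_min,
    tier_mid_min = tier_mid_min,
    min_samples_detected = as.integer(min_samples_detected),
    per_group_filter = isTRUE(per_group_filter),
    group_specific_min_case = as.integer(group_specific_min_case),
    group_specific_max_control = as.integer(group_specific_max_control),
    missed_cleavages_max = as.integer(missed_cleavages_max),
    sasa_probe_radius = sasa_probe_radius,
    sasa_n_points = as.integer(sasa_n_points),
    il_equivalent = isTRUE(il_equivalent),
    match = match, mismatch = mismatch,
    gap_open = gap_open, gap_extend = gap_extend,
    min_contig_len = as.integer(min_contig_len),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "dualprot_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$kmer_size < 2L)
    dp_config_error("kmer_size must be >= 2 (got %d)", cfg$kmer_size)
  if (!(cfg$tier_mid_min > 0 && cfg$tier_mid_min < cfg$tier_high_min))
    dp_config_error("tier bounds must satisfy 0 < tier_mid_min < tier_high_min")
  if (!(cfg$map_identity_min > 0 &&
        cfg$map_identity_min <= cfg$cluster_identity_min &&
        cfg$cluster_identity_min <= 100))
    dp_config_error(
      "identity gates must satisfy 0 < map_identity_min <= cluster_identity_min <= 100")
  if (cfg$sasa_probe_radius <= 0)
    dp_config_error("sasa_probe_radius must be positive")
  if (cfg$missed_cleavages_max < 0L)
    dp_config_error("missed_cleavages_max must be >= 0")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; absent keys take their defaults.
#'
#' @param path YAML file with any subset of [pipeline_config()] arguments.
#' @return a `dualprot_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) dp_config_error("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    dp_config_error("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.dualprot_config <- function(x, ...) {
  cat("dualprot pipeline configuration\n")
  cat(sprintf("  assembly: k = %d, min contig length = %d aa\n",
              x$kmer_size, x$min_contig_len))
  cat(sprintf("  identity gates: mapping >= %g%%, clustering >= %g%% (I/L %s)\n",
              x$map_identity_min, x$cluster_identity_min,
              if (x$il_equivalent) "equivalent" else "distinct"))
  cat(sprintf("  abundance tiers: high > %g ug/mL, mid >= %g ng/mL\n",
              x$tier_high_min * 1e3, x$tier_mid_min * 1e6))
  cat(sprintf("  group-specific rule: cases >= %d, controls <= %d, PTPs >= 1\n",
              x$group_specific_min_case, x$group_specific_max_control))
  invisible(x)
}
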