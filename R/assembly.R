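#' Build a confidence-weighted de Bruijn graph from de novo reads
#'
#' Nodes are (k-1)-mers, edges are k-mers. Each k-mer window of each read
#' contributes its mean per-residue confidence to the edge weight and 1 to
#' the edge count, so heavily and confidently observed k-mers dominate path
#' extraction. Reads shorter than k are skipped with a warning.
#'
#' @param sequences character vector of read sequences.
#' @param confidences optional list of numeric per-residue confidence vectors
#'   (each matching its read length); when `NULL`, every residue counts 1.
#' @param k k-mer size (default 8).
#' @return object of class `dualprot_dbg`: list with `k`, `edges`
#'   (data.frame: `kmer`, `weight`, `count`) and `edge_reads` (list of
#'   supporting read indices per edge, parallel to `edges`).
#' @export
build_graph <- function(sequences, confidences = NULL, k = 8L) {
  k <- as.integer(k)
  if (k < 2L) dp_config_error("k must be >= 2 (got %d)", k)
  if (!is.null(confidences) && length(confidences) != length(sequences))
    dp_input_error("confidences must have one vector per read")
  short <- nchar(sequences) < k
  if (any(short))
    warning(sum(short), " read(s) shorter than k = ", k, " skipped")
  kmers <- character(0); wts <- numeric(0); rid <- integer(0)
  for (i in which(!short)) {
    s <- sequences[i]
    n <- nchar(s) - k + 1L
    starts <- seq_len(n)
    km <- substring(s, starts, starts + k - 1L)
    if (is.null(confidences)) {
      w <- rep(1, n)
    } else {
      conf <- confidences[[i]]
      if (length(conf) != nchar(s))
        dp_input_error("read %d: confidence length %d != read length %d",
                       i, length(conf), nchar(s))
      cs <- c(0, cumsum(conf))
      w <- (cs[starts + k] - cs[starts]) / k
    }
    kmers <- c(kmers, km); wts <- c(wts, w); rid <- c(rid, rep.int(i, n))
  }
  if (length(kmers) == 0L) {
    warning("no reads of length >= k; empty graph")
    return(empty_graph(k))
  }
  f <- factor(kmers)
  edges <- data.frame(
    kmer = levels(f),
    weight = as.numeric(tapply(wts, f, sum)),
    count = as.integer(tabulate(f)),
    stringsAsFactors = FALSE)
  edge_reads <- lapply(split(rid, f), unique)
  structure(list(k = k, edges = edges, edge_reads = edge_reads),
            class = "dualprot_dbg")
}

empty_graph <- function(k) {
  structure(list(k = k,
                 edges = data.frame(kmer = character(0), weight = numeric(0),
                                    count = integer(0), stringsAsFactors = FALSE),
                 edge_reads = list()),
            class = "dualprot_dbg")
}

#' @export
print.dualprot_dbg <- function(x, ...) {
  cat(sprintf("de Bruijn graph: k = %d, %d edges, total weight %.1f\n",
              x$k, nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Assemble contigs by greedy heaviest-path extraction
#'
#' Repeatedly seeds a path at the unused edge of highest weight (ties broken
#' lexicographically by k-mer), extends it in both directions along the
#' highest-weight unused edge at each step, and retires the consumed edges.
#' Each edge is used in at most one contig, which also guarantees termination
#' on cyclic graphs (a repeated k-mer stops the walk before reuse). Contigs
#' shorter than `min_len` are discarded.
#'
#' @param graph a `dualprot_dbg` from [build_graph()].
#' @param min_len minimum contig length in aa (default 10).
#' @return data.frame sorted by (`support_reads` desc, `sequence` asc) with
#'   columns `sequence`, `support_reads` (distinct reads sharing a k-mer with
#'   the contig) and `mean_confidence` (mean over contig edges of
#'   weight/count).
#' @export
assemble <- function(graph, min_len = 10L) {
  stopifnot(inherits(graph, "dualprot_dbg"))
  ed <- graph$edges
  k <- graph$k
  if (nrow(ed) == 0L)
    return(data.frame(sequence = character(0), support_reads = integer(0),
                      mean_confidence = numeric(0), stringsAsFactors = FALSE))
  pref <- substr(ed$kmer, 1L, k - 1L)
  suff <- substr(ed$kmer, 2L, k)
  by_pref <- split(seq_len(nrow(ed)), pref)
  by_suff <- split(seq_len(nrow(ed)), suff)
  used <- rep(FALSE, nrow(ed))
  ## seeds in greedy order: weight desc, k-mer asc
  seed_order <- order(-ed$weight, ed$kmer)
  pick <- function(cand) {
    cand <- cand[!used[cand]]
    if (length(cand) == 0L) return(NA_integer_)
    cand[order(-ed$weight[cand], ed$kmer[cand])][1]
  }
  out_seq <- character(0); out_sup <- integer(0); out_conf <- numeric(0)
  for (s in seed_order) {
    if (used[s]) next
    used[s] <- TRUE
    path_edges <- s
    seqn <- ed$kmer[s]
    ## extend right
    repeat {
      nxt <- pick(by_pref[[substr(seqn, nchar(seqn) - k + 2L, nchar(seqn))]] %||% integer(0))
      if (is.na(nxt)) break
      used[nxt] <- TRUE
      path_edges <- c(path_edges, nxt)
      seqn <- paste0(seqn, substr(ed$kmer[nxt], k, k))
    }
    ## extend left
    repeat {
      prv <- pick(by_suff[[substr(seqn, 1L, k - 1L)]] %||% integer(0))
      if (is.na(prv)) break
      used[prv] <- TRUE
      path_edges <- c(path_edges, prv)
      seqn <- paste0(substr(ed$kmer[prv], 1L, 1L), seqn)
    }
    if (nchar(seqn) < min_len) next
    out_seq <- c(out_seq, seqn)
    out_sup <- c(out_sup,
                 length(unique(unlist(graph$edge_reads[path_edges]))))
    out_conf <- c(out_conf,
                  mean(ed$weight[path_edges] / ed$count[path_edges]))
  }
  res <- data.frame(sequence = out_seq, support_reads = out_sup,
                    mean_confidence = out_conf, stringsAsFactors = FALSE)
  res[order(-res$support_reads, res$sequence), , drop = FALSE]
}

#' Assemble per-sample contigs from a de novo read table
#'
#' Reads are assembled separately within each sample (contig occurrence
#' counts per sample drive the downstream group comparison), then combined.
#'
#' @param reads data.frame from [read_denovo_reads()] (`sample_id`,
#'   `sequence`, `confidence` list column).
#' @param k k-mer size (default 8).
#' @param min_len minimum contig length (default 10).
#' @return data.frame with `sample_id`, `sequence`, `support_reads`,
#'   `mean_confidence`.
#' @export
assemble_contigs <- function(reads, k = 8L, min_len = 10L) {
  pieces <- lapply(split(seq_len(nrow(reads)), reads$sample_id), function(ix) {
    g <- build_graph(reads$sequence[ix],
                     if ("confidence" %in% names(reads)) reads$confidence[ix]
                     else NULL,
                     k = k)
    ctg <- assemble(g, min_len = min_len)
    if (nrow(ctg)) ctg$sample_id <- reads$sample_id[ix[1]]
    ctg
  })
  pieces <- pieces[vapply(pieces, nrow, 0L) > 0L]
  if (length(pieces) == 0L)
    return(data.frame(sample_id = character(0), sequence = character(0),
                      support_reads = integer(0), mean_confidence = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c("sample_id", "sequence", "support_reads", "mean_confidence")]
}
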