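## Independent oracles and fixture builders used across the suite.
## These deliberately take different computational routes from the package
## code they check.

## Numerical SASA by latitude-longitude quadrature (area-weighted grid),
## independent of the package's Fibonacci-spiral sampling.
grid_sasa <- function(model, probe = 1.4, n_theta = 90L) {
  a <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- ifelse(a$element %in% names(dualprot:::VDW_RADII),
                  dualprot:::VDW_RADII[a$element], dualprot:::VDW_DEFAULT)
  ext <- radii + probe
  n <- nrow(xyz)
  out <- numeric(n)
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  dtheta <- pi / n_theta
  for (i in seq_len(n)) {
    R <- ext[i]
    area <- 0
    for (t in theta) {
      n_phi <- max(8L, round(2 * n_theta * sin(t)))
      phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
      pts <- cbind(R * sin(t) * cos(phi),
                   R * sin(t) * sin(phi),
                   rep(R * cos(t), n_phi))
      pts <- sweep(pts, 2L, xyz[i, ], `+`)
      w <- R^2 * sin(t) * dtheta * (2 * pi / n_phi)
      exposed <- rep(TRUE, n_phi)
      for (j in seq_len(n)) {
        if (j == i) next
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        exposed <- exposed & d2 >= ext[j]^2
      }
      area <- area + sum(exposed) * w
    }
    out[i] <- area
  }
  out
}

## Exhaustive single-linkage clustering at a min-length-denominator identity
## threshold: union-find over all pairs.
brute_force_single_link <- function(seqs, min_identity, il_equivalent = TRUE) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (identity_minlen(seqs[i], seqs[j],
                          il_equivalent = il_equivalent) >= min_identity) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

## Random peptide at background residue frequencies.
random_peptide <- function(len) {
  paste(sample(names(dualprot:::AA_BACKGROUND_FREQ), len, replace = TRUE,
               prob = dualprot:::AA_BACKGROUND_FREQ), collapse = "")
}

## Tiny reference database from explicit sequences.
toy_db <- function(seqs, acc = sprintf("P%05d", seq_along(seqs))) {
  data.frame(accession = acc, name = paste0("TOY", seq_along(seqs)),
             sequence = seqs, length_aa = nchar(seqs),
             stringsAsFactors = FALSE)
}

## A single-atom structure, for closed-form SASA checks.
atom_structure <- function(elements, xyz, b = 90) {
  dualprot:::new_structure(data.frame(
    atom_name = elements, element = elements,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = b,
    residue_index = seq_along(elements), residue_name = "UNK", chain = "A",
    stringsAsFactors = FALSE))
}

## Minimal mmCIF encoding of an atom table (the second encoding used to
## check PDB/mmCIF reader equivalence).
write_toy_cif <- function(model, path) {
  a <- model$atoms
  hdr <- c("data_TOY", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
           "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
           "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
            i, a$element[i], a$atom_name[i], a$residue_name[i], a$chain[i],
            a$residue_index[i], a$x[i], a$y[i], a$z[i], a$occupancy[i],
            a$b_factor[i], a$residue_index[i], a$residue_name[i], a$chain[i],
            a$atom_name[i])
  }, "")
  writeLines(c(hdr, rows, "#"), path)
  path
}

## In-silico digest oracle: an independent enumeration using regex-located
## cleavage sites.
digest_oracle <- function(sequence, missed_max = 2L, min_len = 6L) {
  sites <- gregexpr("[KR](?!P)", sequence, perl = TRUE)[[1]]
  sites <- sites[sites > 0 & sites < nchar(sequence)]
  bounds <- c(0L, sites, nchar(sequence))
  peps <- character(0)
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in i:min(length(bounds) - 1L, i + missed_max)) {
      p <- substr(sequence, bounds[i] + 1L, bounds[j + 1L])
      if (nchar(p) >= min_len) peps <- c(peps, p)
    }
  }
  sort(peps)
}
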