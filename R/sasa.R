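#' Shrake-Rupley solvent-accessible surface area
#'
#' Deterministic golden-section (Fibonacci spiral) sampling of each atom's
#' solvent-expanded sphere. A sample point is buried when it falls inside
#' any neighbouring atom's expanded sphere; per-atom SASA is the exposed
#' fraction times `4 * pi * (r + probe)^2`. Hydrogens are ignored (crystal
#' and predicted models generally lack them); van der Waals radii:
#' C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 A, anything else 1.70 with a
#' warning.
#'
#' @param model a `dualprot_structure`.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return numeric vector of per-atom SASA (A^2), one per heavy atom of the
#'   model, named by atom row; hydrogen rows get `NA`.
#' @export
sasa_shrake_rupley <- function(model, probe = 1.4, n_points = 960L) {
  a <- model$atoms
  if (nrow(a) == 0L) dp_input_error("structure has no atoms")
  heavy <- a$element != "H"
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  elem <- a$element[heavy]
  if (nrow(xyz) == 0L) dp_input_error("structure has no heavy atoms")
  known <- elem %in% names(VDW_RADII)
  if (any(!known))
    warning("unknown element(s) ", paste(unique(elem[!known]), collapse = ","),
            "; using default vdW radius ", VDW_DEFAULT, " A")
  radii <- ifelse(known, VDW_RADII[elem], VDW_DEFAULT)
  pts <- golden_sphere_points(n_points)
  n <- nrow(xyz)
  ext <- radii + probe
  out <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    sp <- sweep(pts * ext[i], 2L, xyz[i, ], `+`)
    nb <- which(d2[i, ] < (ext[i] + ext)^2 & seq_len(n) != i)
    exposed <- rep(TRUE, nrow(sp))
    for (j in nb) {
      if (!any(exposed)) break
      dx <- sp[exposed, 1L] - xyz[j, 1L]
      dy <- sp[exposed, 2L] - xyz[j, 2L]
      dz <- sp[exposed, 3L] - xyz[j, 3L]
      exposed[exposed] <- (dx * dx + dy * dy + dz * dz) >= ext[j]^2
    }
    out[i] <- mean(exposed) * 4 * pi * ext[i]^2
  }
  res <- rep(NA_real_, nrow(a))
  res[heavy] <- out
  res
}

## Deterministic Fibonacci-spiral unit sphere points.
golden_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Attach a phosphate group at a Ser/Thr/Tyr hydroxyl
#'
#' Models the phosphorylated proteoform by placing a phosphorus atom 1.6 A
#' from the side-chain hydroxyl oxygen, extended along the bond from the
#' hydroxyl's parent carbon, and three terminal oxygens in tetrahedral
#' geometry (P-O 1.5 A). No other atom moves and no minimization is
#' performed; this is an explicit, reproducible stand-in for however a
#' phosphoproteoform might relax in reality.
#'
#' @param model a `dualprot_structure`.
#' @param residue_index residue number of the site.
#' @param chain chain id (default: first chain).
#' @return a new `dualprot_structure` with four added atoms (`P`, `O1P`,
#'   `O2P`, `O3P`) on the site residue.
#' @export
attach_phosphate <- function(model, residue_index, chain = NULL) {
  a <- model$atoms
  chain <- chain %||% a$chain[1]
  in_res <- a$chain == chain & a$residue_index == residue_index
  if (!any(in_res))
    dp_input_error("residue %d (chain %s) not in structure", residue_index, chain)
  if (any(a$atom_name[in_res] == "P"))
    dp_input_error("residue %d is already phosphorylated", residue_index)
  resname <- a$residue_name[in_res][1]
  hydroxyl <- switch(resname, SER = "OG", THR = "OG1", TYR = "OH", NA_character_)
  if (is.na(hydroxyl) || !any(in_res & a$atom_name == hydroxyl))
    dp_input_error("residue %d (%s) lacks a side-chain hydroxyl oxygen",
                   residue_index, resname)
  parent_name <- switch(resname, SER = "CB", THR = "CB", TYR = "CZ")
  o <- as.numeric(a[in_res & a$atom_name == hydroxyl, c("x", "y", "z")][1, ])
  if (any(in_res & a$atom_name == parent_name)) {
    p0 <- as.numeric(a[in_res & a$atom_name == parent_name, c("x", "y", "z")][1, ])
  } else {
    p0 <- as.numeric(a[in_res & a$atom_name == "CA", c("x", "y", "z")][1, ])
  }
  u <- o - p0
  u <- u / sqrt(sum(u^2))
  p_atom <- o + 1.6 * u
  ## tetrahedral terminal oxygens: 109.47 deg away from the O-P bond axis
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  theta <- pi - acos(-1 / 3)          # angle from +u axis: 180 - 109.47 deg
  oxy <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(az) {
    dirv <- cos(theta) * (-u) + sin(theta) * (cos(az) * e1 + sin(az) * e2)
    ## directions make 109.47 deg with the P->O(hydroxyl) vector (-u)
    p_atom + 1.5 * -dirv
  })
  add <- data.frame(
    atom_name = c("P", "O1P", "O2P", "O3P"),
    element = c("P", "O", "O", "O"),
    x = c(p_atom[1], oxy[[1]][1], oxy[[2]][1], oxy[[3]][1]),
    y = c(p_atom[2], oxy[[1]][2], oxy[[2]][2], oxy[[3]][2]),
    z = c(p_atom[3], oxy[[1]][3], oxy[[2]][3], oxy[[3]][3]),
    occupancy = 1, b_factor = 0,
    residue_index = residue_index, residue_name = resname, chain = chain,
    stringsAsFactors = FALSE)
  new_structure(rbind(a, add), model$path)
}

#' Structural effect of phosphorylation on peptide exposure (K_SASA)
#'
#' Computes the identified peptide's solvent-accessible surface area in the
#' intact protein and in the same protein with a modeled phosphate at the
#' site, and returns their ratio `K_SASA = intact / phospho`. A ratio below
#' 1 means phosphorylation increased the peptide's exposed surface.
#' Phosphate atoms count toward the phospho-state peptide surface.
#'
#' @param model a `dualprot_structure` (intact).
#' @param residue_index phosphosite residue number (Ser/Thr/Tyr).
#' @param peptide_range integer length-2 vector: first and last residue
#'   number of the identified peptide (inclusive).
#' @param chain chain id (default: first chain).
#' @param probe probe radius (default 1.4 A).
#' @param n_points sphere points per atom (default 960).
#' @return list of class `dualprot_ksasa`: `peptide_sasa_intact`,
#'   `peptide_sasa_phospho` (A^2), `k_sasa`, plus the site description.
#' @export
k_sasa <- function(model, residue_index, peptide_range, chain = NULL,
                   probe = 1.4, n_points = 960L) {
  chain <- chain %||% model$atoms$chain[1]
  if (length(peptide_range) != 2L || peptide_range[1] > peptide_range[2])
    dp_input_error("peptide_range must be c(first, last) residue numbers")
  in_pep <- function(atoms) atoms$chain == chain &
    atoms$residue_index >= peptide_range[1] &
    atoms$residue_index <= peptide_range[2]
  if (!any(in_pep(model$atoms)))
    dp_input_error("peptide_range [%d, %d] covers no residues of chain %s",
                   peptide_range[1], peptide_range[2], chain)
  sasa0 <- sasa_shrake_rupley(model, probe = probe, n_points = n_points)
  intact <- sum(sasa0[in_pep(model$atoms)], na.rm = TRUE)
  phospho_model <- attach_phosphate(model, residue_index, chain = chain)
  sasa1 <- sasa_shrake_rupley(phospho_model, probe = probe, n_points = n_points)
  phospho <- sum(sasa1[in_pep(phospho_model$atoms)], na.rm = TRUE)
  if (phospho <= 0) dp_internal_error("phospho-state peptide SASA is zero")
  structure(list(peptide_sasa_intact = intact,
                 peptide_sasa_phospho = phospho,
                 k_sasa = intact / phospho,
                 residue_index = residue_index,
                 peptide_range = peptide_range, chain = chain),
            class = "dualprot_ksasa")
}

#' @export
print.dualprot_ksasa <- function(x, ...) {
  cat(sprintf(
    "K_SASA at residue %d (peptide %d-%d): intact %.1f A^2, phospho %.1f A^2, ratio %.2f\n",
    x$residue_index, x$peptide_range[1], x$peptide_range[2],
    x$peptide_sasa_intact, x$peptide_sasa_phospho, x$k_sasa))
  invisible(x)
}

#' Secondary-structure label at a residue
#'
#' Classifies the site from backbone phi/psi torsions of the site and both
#' flanking residues: all three in the helical window (phi in (-100, -30),
#' psi in (-80, -5) degrees) gives `"alpha-helix"`; all three in the strand
#' window (phi in (-180, -90), psi in (90, 180)) gives `"beta-strand"`;
#' otherwise `"coil"`. When backbone atoms for the site +/- 2 residues are
#' incomplete the label is `"n/d"`.
#'
#' @param model a `dualprot_structure`.
#' @param residue_index site residue number.
#' @param chain chain id (default: first chain).
#' @return one of `"alpha-helix"`, `"beta-strand"`, `"coil"`, `"n/d"`.
#' @export
secondary_structure_at <- function(model, residue_index, chain = NULL) {
  chain <- chain %||% model$atoms$chain[1]
  tor <- tryCatch(
    lapply((residue_index - 1L):(residue_index + 1L),
           function(r) backbone_torsions(model, r, chain)),
    error = function(e) NULL)
  if (is.null(tor) || any(vapply(tor, function(t) anyNA(unlist(t)), TRUE)))
    return("n/d")
  phi <- vapply(tor, `[[`, 0.0, "phi")
  psi <- vapply(tor, `[[`, 0.0, "psi")
  if (all(phi > -100 & phi < -30) && all(psi > -80 & psi < -5))
    return("alpha-helix")
  if (all(phi > -180 & phi < -90) && all(psi > 90 & psi < 180))
    return("beta-strand")
  "coil"
}

backbone_torsions <- function(model, residue_index, chain) {
  at <- function(r, name) {
    a <- model$atoms
    row <- a[a$chain == chain & a$residue_index == r & a$atom_name == name, ,
             drop = FALSE]
    if (nrow(row) == 0L) return(NULL)
    as.numeric(row[1, c("x", "y", "z")])
  }
  c_prev <- at(residue_index - 1L, "C")
  n0 <- at(residue_index, "N"); ca0 <- at(residue_index, "CA")
  c0 <- at(residue_index, "C"); n_next <- at(residue_index + 1L, "N")
  if (is.null(n0) || is.null(ca0) || is.null(c0))
    return(list(phi = NA_real_, psi = NA_real_))
  list(
    phi = if (is.null(c_prev)) NA_real_ else dihedral(c_prev, n0, ca0, c0),
    psi = if (is.null(n_next)) NA_real_ else dihedral(n0, ca0, c0, n_next))
}

## Signed dihedral angle (degrees) of four points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- crossp(b1, b2); n2 <- crossp(b2, b3)
  m1 <- crossp(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Mean per-residue model confidence over a peptide
#'
#' AlphaFold-style models carry per-residue confidence (pLDDT) in the
#' B-factor column; this reports its mean and population standard deviation
#' over the peptide's residues.
#'
#' @param model a `dualprot_structure`.
#' @param peptide_range integer length-2 vector of first/last residue number.
#' @param chain chain id (default: first chain).
#' @return list with `mean` and `sd`.
#' @export
mean_confidence <- function(model, peptide_range, chain = NULL) {
  chain <- chain %||% model$atoms$chain[1]
  a <- model$atoms
  sel <- a$chain == chain & a$residue_index >= peptide_range[1] &
    a$residue_index <= peptide_range[2]
  if (!any(sel)) dp_input_error("peptide_range covers no residues")
  per_res <- vapply(split(a$b_factor[sel], a$residue_index[sel]), mean, 0.0)
  list(mean = mean(per_res),
       sd = sqrt(mean((per_res - mean(per_res))^2)))
}
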