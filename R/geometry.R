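## Internal-coordinate (NeRF) construction of synthetic peptide structures.
## These models carry idealized backbone geometry and minimal side chains
## (CB plus the hydroxyl-bearing atoms of Ser/Thr/Tyr); they exist so that
## SASA, phosphate-attachment and secondary-structure code can be exercised
## on fully known geometry without downloading any reference structure.

## Place atom D given positions A, B, C, a bond length C-D, the angle
## B-C-D (degrees) and the torsion A-B-C-D (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- crossp(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- crossp(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a synthetic peptide structure from backbone torsions
#'
#' Constructs an idealized all-heavy-atom backbone (N, CA, C, O) at the
#' requested phi/psi torsions, with a CB for every non-glycine residue and
#' the hydroxyl-bearing side-chain atoms of Ser (OG), Thr (OG1) and Tyr
#' (CZ pseudo-atom + OH) so phosphosites can be modeled. Side chains beyond
#' those atoms are not built. Standard bond lengths and angles are used
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 A; omega fixed at 180 degrees).
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi backbone torsions in degrees, recycled along the chain.
#'   Defaults are the textbook alpha-helix (-57, -47).
#' @param b_factor per-residue confidence written to the B-factor column,
#'   recycled (default 90).
#' @param chain chain id (default "A").
#' @return a `dualprot_structure`.
#' @examples
#' helix <- build_peptide_structure("AASAA")
#' secondary_structure_at(helix, 3)
#' @export
build_peptide_structure <- function(sequence, phi = -57, psi = -47,
                                    b_factor = 90, chain = "A") {
  res <- seq_chars(toupper(sequence))
  n_res <- length(res)
  if (n_res < 1L) dp_input_error("empty sequence")
  bad <- which(!(res %in% AA20))
  if (length(bad))
    dp_input_error("non-canonical residue '%s' at position %d", res[bad[1]], bad[1])
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  b_factor <- rep_len(b_factor, n_res)
  three <- setNames(bio3d::aa123(res), NULL)

  rows <- list()
  add <- function(name, elem, xyz, i) {
    rows[[length(rows) + 1L]] <<- data.frame(
      atom_name = name, element = elem,
      x = xyz[1], y = xyz[2], z = xyz[3],
      occupancy = 1, b_factor = b_factor[i],
      residue_index = i, residue_name = three[i], chain = chain,
      stringsAsFactors = FALSE)
  }

  ## first residue backbone seeded explicitly
  n_xyz <- c(0, 0, 0)
  ca_xyz <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  c_xyz <- ca_xyz + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      prev <- backbone_of(rows, i - 1L)
      n_xyz <- place_atom(prev$n, prev$ca, prev$c, 1.329, 116.2, psi[i - 1L])
      ca_xyz <- place_atom(prev$ca, prev$c, n_xyz, 1.458, 121.7, 180) # omega
      c_xyz <- place_atom(prev$c, n_xyz, ca_xyz, 1.525, 111.2, phi[i])
    }
    add("N", "N", n_xyz, i)
    add("CA", "C", ca_xyz, i)
    add("C", "C", c_xyz, i)
    ## carbonyl O in the peptide plane, opposite the next N
    o_xyz <- place_atom(n_xyz, ca_xyz, c_xyz, 1.231, 120.5, psi[i] + 180)
    add("O", "O", o_xyz, i)
    if (res[i] != "G") {
      cb <- place_atom(c_xyz, n_xyz, ca_xyz, 1.530, 110.5, 122.7)
      add("CB", "C", cb, i)
      if (res[i] == "S") {
        add("OG", "O", place_atom(n_xyz, ca_xyz, cb, 1.417, 110.8, -60), i)
      } else if (res[i] == "T") {
        add("OG1", "O", place_atom(n_xyz, ca_xyz, cb, 1.433, 109.6, -60), i)
      } else if (res[i] == "Y") {
        ## pseudo side chain: CZ stands in for the ring, OH beyond it
        cz <- place_atom(n_xyz, ca_xyz, cb, 4.20, 113.9, 180)
        add("CZ", "C", cz, i)
        add("OH", "O", place_atom(ca_xyz, cb, cz, 1.376, 180, 0), i)
      }
    }
  }
  new_structure(do.call(rbind, rows))
}

## Backbone coordinates of residue i from the accumulating row list.
backbone_of <- function(rows, i) {
  df <- do.call(rbind, rows)
  df <- df[df$residue_index == i, , drop = FALSE]
  list(n = as.numeric(df[df$atom_name == "N", c("x", "y", "z")]),
       ca = as.numeric(df[df$atom_name == "CA", c("x", "y", "z")]),
       c = as.numeric(df[df$atom_name == "C", c("x", "y", "z")]))
}

#' Rigidly transform a structure
#'
#' Applies a rotation (by Euler angles, degrees) followed by a translation.
#' SASA must be invariant under such motions; exposed for testing and fixture
#' construction.
#'
#' @param model a `dualprot_structure`.
#' @param angles length-3 numeric, rotations about x, y, z in degrees.
#' @param translation length-3 numeric shift in Angstrom.
#' @return transformed `dualprot_structure`.
#' @export
transform_structure <- function(model, angles = c(0, 0, 0),
                                translation = c(0, 0, 0)) {
  r <- angles * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  rot <- rz %*% ry %*% rx
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2L, translation, `+`)
  out <- model
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  out
}
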