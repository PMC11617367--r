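test_that("isolated spheres reproduce the closed-form surface area", {
  probe <- 1.4
  m <- atom_structure("C", cbind(0, 0, 0))
  expect_equal(sasa_shrake_rupley(m, probe), 4 * pi * (1.70 + probe)^2,
               tolerance = 1e-9)
  ## two atoms beyond occlusion range: both fully exposed
  m2 <- atom_structure(c("N", "O"), rbind(c(0, 0, 0), c(0, 0, 12)))
  s2 <- sasa_shrake_rupley(m2, probe)
  expect_equal(s2[1], 4 * pi * (1.55 + probe)^2, tolerance = 1e-9)
  expect_equal(s2[2], 4 * pi * (1.52 + probe)^2, tolerance = 1e-9)
  ## a convex set of well-separated atoms sums to the sphere-area total
  xyz <- 15 * rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m4 <- atom_structure(rep("C", 4), xyz)
  expect_equal(sum(sasa_shrake_rupley(m4, probe)),
               4 * 4 * pi * (1.70 + probe)^2, tolerance = 1e-9)
})

test_that("an atom caged by a tight icosahedral shell is buried", {
  gr <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(0, 1, gr), c(0, -1, gr), c(0, 1, -gr), c(0, -1, -gr),
    c(1, gr, 0), c(-1, gr, 0), c(1, -gr, 0), c(-1, -gr, 0),
    c(gr, 0, 1), c(-gr, 0, 1), c(gr, 0, -1), c(-gr, 0, -1))
  verts <- verts / sqrt(1 + gr^2) * 3.0   # shell radius 3 A around the centre
  m <- atom_structure(rep("C", 13), rbind(c(0, 0, 0), verts))
  s <- sasa_shrake_rupley(m)
  expect_lt(s[1], 1e-6)
  ## removing one shell atom re-exposes the centre and can only increase
  ## every remaining atom's SASA (monotonicity under atom removal)
  m_open <- atom_structure(rep("C", 12), rbind(c(0, 0, 0), verts[-1, ]))
  s_open <- sasa_shrake_rupley(m_open)
  expect_gt(s_open[1], s[1])
  expect_true(all(s_open[-1] >= s[-c(1, 2)] - 1e-9))
})

test_that("SASA is invariant under rigid motions", {
  model <- build_peptide_structure("GASTG")
  base <- sasa_shrake_rupley(model)
  set.seed(14)
  for (i in 1:4) {
    moved <- transform_structure(model, angles = runif(3, -180, 180),
                                 translation = runif(3, -20, 20))
    s <- sasa_shrake_rupley(moved)
    ## invariance holds up to the finite angular sampling resolution
    expect_equal(sum(s), sum(base), tolerance = 0.005)
    expect_lt(max(abs(s - base)), 3)
  }
})

test_that("spiral sampling agrees with a fine-grid quadrature oracle", {
  model <- build_peptide_structure("AASTA")
  ours <- sum(sasa_shrake_rupley(model), na.rm = TRUE)
  oracle <- sum(grid_sasa(model))
  expect_lt(abs(ours - oracle) / oracle, 0.02)
})

test_that("phosphate attachment builds tetrahedral geometry in place", {
  model <- build_peptide_structure("AASAA", phi = -120, psi = 120)
  ph <- attach_phosphate(model, 3)
  expect_equal(nrow(ph$atoms), nrow(model$atoms) + 4L)
  ## pre-existing coordinates untouched
  expect_identical(ph$atoms[seq_len(nrow(model$atoms)), c("x", "y", "z")],
                   model$atoms[, c("x", "y", "z")])
  a <- ph$atoms
  p <- as.numeric(a[a$atom_name == "P", c("x", "y", "z")])
  og <- as.numeric(a[a$atom_name == "OG" & a$residue_index == 3,
                     c("x", "y", "z")])
  expect_equal(sqrt(sum((p - og)^2)), 1.6, tolerance = 1e-9)
  oxy <- as.matrix(a[a$atom_name %in% c("O1P", "O2P", "O3P"),
                     c("x", "y", "z")])
  for (i in 1:3)
    expect_equal(sqrt(sum((oxy[i, ] - p)^2)), 1.5, tolerance = 1e-9)
  ## terminal O-O separation of an ideal tetrahedron with P-O = 1.5 A
  dd <- as.numeric(dist(oxy))
  expect_equal(dd, rep(2 * 1.5 * sin(acos(-1 / 3) / 2), 3), tolerance = 1e-6)
  ## re-application is refused
  expect_error(attach_phosphate(ph, 3), "already phosphorylated")
  ## glycine has no hydroxyl to phosphorylate
  expect_error(attach_phosphate(build_peptide_structure("AAGAA"), 3),
               "hydroxyl")
})

test_that("phosphorylation of an exposed site increases peptide SASA", {
  ## K_SASA = intact / phospho <= 1 on exposed-site fixtures
  for (seqn in c("AASAA", "GGTGG", "AAYAA")) {
    model <- build_peptide_structure(seqn, phi = -120, psi = 120)
    res <- k_sasa(model, 3, c(1, 5))
    expect_gt(res$peptide_sasa_phospho, res$peptide_sasa_intact)
    expect_lte(res$k_sasa, 1)
  }
})

test_that("a phosphate far from the scored peptide leaves its SASA alone", {
  model <- build_peptide_structure("SAAAAAAAAAAAAAAA", phi = -120, psi = 120)
  res <- k_sasa(model, 1, c(10, 16))
  expect_equal(res$k_sasa, 1, tolerance = 0.01)
})

test_that("torsion windows label ideal helix, strand and short fragments", {
  expect_equal(secondary_structure_at(build_peptide_structure("AAASAAA"), 4),
               "alpha-helix")
  expect_equal(secondary_structure_at(
    build_peptide_structure("AAASAAA", phi = -139, psi = 135), 4),
    "beta-strand")
  expect_equal(secondary_structure_at(
    build_peptide_structure("AAASAAA", phi = -75, psi = 150), 4), "coil")
  expect_equal(secondary_structure_at(build_peptide_structure("AS"), 2), "n/d")
})

test_that("mean model confidence summarizes the B-factor channel", {
  m <- build_peptide_structure("AAAA", b_factor = 90)
  expect_equal(mean_confidence(m, c(1, 4)), list(mean = 90, sd = 0))
  m2 <- build_peptide_structure("AAAA", b_factor = c(80, 100, 80, 100))
  mc <- mean_confidence(m2, c(1, 2))
  expect_equal(mc$mean, 90)
  expect_equal(mc$sd, 10)   # population sd
  expect_error(mean_confidence(m, c(10, 12)), "no residues")
})
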