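test_that("motif parsing extracts ligand and residue monomers from PDB text", {
  benz <- benzene_motif <- gen_ring_pair(0, 3.5)$motif
  lig <- benz$monomers$A$atoms
  lig <- lig[lig$element == "C", ]            # 6 carbons, no hydrogens
  ala <- alanine_atoms(31L)
  motif <- motif_record(monomer("ligand-fragment", "LIG", lig),
                        monomer("residue", "A31", ala))
  text <- write_motif_pdb(motif)

  parsed <- parse_motif_pdb(text, ligand_code = "LIG", residue_seq = 31L)
  expect_equal(nrow(parsed$monomers$A$atoms), 6L)
  expect_equal(nrow(parsed$monomers$B$atoms), 5L)
  expect_equal(parsed$monomers$A$label, "LIG")
  expect_equal(parsed$monomers$B$label, "A31")
  expect_equal(parsed$monomers$A$multiplicity, 1L)

  expect_error(parse_motif_pdb(text, "XYZ", 31L),
               class = "nbibench_monomer_not_found")
  expect_error(parse_motif_pdb(text, "LIG", 999L),
               class = "nbibench_monomer_not_found")
})

test_that("alternate locations resolve to highest occupancy, ties to A", {
  serial <- 0L
  line <- function(alt, occ, x) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d  CA %sALA A  31    %8.3f   0.000   0.000  %4.2f  0.00           C",
            serial, alt, x, occ)
  }
  hdr <- "HETATM    9  C1  LIG A   1       0.000   5.000   0.000  1.00  0.00           C"
  # B copy has higher occupancy -> keep B's coordinate
  txt <- c(hdr, line("B", 0.70, 2.0), line("A", 0.30, 1.0), "END")
  parsed <- parse_motif_pdb(txt, "LIG", 31L)
  expect_equal(nrow(parsed$monomers$B$atoms), 1L)
  expect_equal(parsed$monomers$B$atoms$x, 2.0)
  # tie -> keep altloc A
  txt <- c(hdr, line("B", 0.50, 2.0), line("A", 0.50, 1.0), "END")
  parsed <- parse_motif_pdb(txt, "LIG", 31L)
  expect_equal(parsed$monomers$B$atoms$x, 1.0)
})

test_that("bond perception uses covalent radii with a 1.3 scale factor", {
  two_c <- function(d) atom_table(c("C", "C"), c(0, d), c(0, 0), c(0, 0),
                                  name = c("C1", "C2"))
  expect_equal(nrow(perceive_bonds(two_c(1.4))), 1L)
  expect_equal(nrow(perceive_bonds(two_c(3.0))), 0L)

  ring <- gen_ring_pair(0, 3.5)$motif$monomers$A$atoms
  bonds <- perceive_bonds(ring)
  cc <- bonds[ring$element[bonds$i] == "C" & ring$element[bonds$j] == "C", ]
  expect_equal(nrow(cc), 6L)                  # exactly the 6 ring bonds
  expect_true(all(bonds$i < bonds$j))

  expect_error(perceive_bonds(data.frame(element = "Xx", x = 0, y = 0,
                                         z = 0)),
               class = "nbibench_unknown_element")
})

test_that("ring perception finds planar 5/6-cycles and nothing else", {
  ring <- find_aromatic_rings(gen_ring_pair(0, 3.5)$motif$monomers$A)
  expect_length(ring, 1L)
  expect_lt(ring[[1]]$planarity_rms, 1e-8)
  expect_equal(sqrt(sum(ring[[1]]$unit_normal^2)), 1, tolerance = 1e-10)

  expect_length(find_aromatic_rings(alanine_atoms()), 0L)

  rings <- find_aromatic_rings(indole_atoms())
  expect_length(rings, 2L)
  sizes <- sort(vapply(rings, function(r) length(r$member_atoms),
                       integer(1)))
  expect_equal(sizes, c(5L, 6L))
  shared <- intersect(rings[[1]]$member_atoms, rings[[2]]$member_atoms)
  expect_length(shared, 2L)                   # fused edge
})

test_that("ring perception recovers every ring of multi-ring fixtures", {
  # n separated benzene rings -> exactly n rings (cycle count is known by
  # construction)
  for (n in 1:3) {
    atoms <- do.call(rbind, lapply(seq_len(n), function(k) {
      a <- gen_ring_pair(0, 3.5)$motif$monomers$A$atoms
      a$x <- a$x + 10 * (k - 1)
      a$name <- paste0(a$name, k)
      a
    }))
    expect_length(find_aromatic_rings(atoms), n)
  }
})

test_that("closest heavy-atom distance is restricted to C/N/O", {
  a <- monomer("ligand-fragment", "LIG",
               atom_table(c("S", "C"), c(0, 10), c(0, 0), c(0, 0),
                          name = c("S1", "C1")))
  b <- monomer("residue", "X1",
               atom_table(c("S", "C"), c(0, 10), c(3.0, 3.4), c(0, 0),
                          name = c("S2", "C2")))
  expect_equal(closest_heavy_distance(motif_record(a, b)), 3.4)

  c1 <- monomer("ligand-fragment", "LIG",
                atom_table("C", 0, 0, 0))
  c2 <- monomer("residue", "X1", atom_table("C", 3.5, 0, 0))
  expect_equal(closest_heavy_distance(motif_record(c1, c2)), 3.5)

  s_only <- monomer("residue", "X1", atom_table("S", 3, 0, 0))
  expect_error(closest_heavy_distance(motif_record(c1, s_only)),
               class = "nbibench_no_heavy_atoms")
})

test_that("plane angle is folded to [0, 90], symmetric, rigid-invariant", {
  par <- gen_ring_pair(0, 3.5)$motif
  ra <- find_aromatic_rings(par$monomers$A)[[1]]
  rb <- find_aromatic_rings(par$monomers$B)[[1]]
  expect_equal(plane_angle(ra, rb), 0, tolerance = 1e-8)

  perp <- gen_ring_pair(90, 5.0)$motif
  ra <- find_aromatic_rings(perp$monomers$A)[[1]]
  rb <- find_aromatic_rings(perp$monomers$B)[[1]]
  expect_equal(plane_angle(ra, rb), 90, tolerance = 1e-8)

  tilt <- gen_ring_pair(43.85, 3.55)$motif
  ra <- find_aromatic_rings(tilt$monomers$A)[[1]]
  rb <- find_aromatic_rings(tilt$monomers$B)[[1]]
  expect_equal(plane_angle(ra, rb), 43.85, tolerance = 0.01)
  expect_equal(plane_angle(rb, ra), plane_angle(ra, rb))

  set.seed(11)
  for (k in 1:5) {
    moved <- rigid_motif(tilt, random_rot(), rnorm(3, 0, 5))
    ra2 <- find_aromatic_rings(moved$monomers$A)[[1]]
    rb2 <- find_aromatic_rings(moved$monomers$B)[[1]]
    expect_equal(plane_angle(ra2, rb2), plane_angle(ra, rb),
                 tolerance = 1e-8)
    expect_equal(closest_heavy_distance(moved),
                 closest_heavy_distance(tilt), tolerance = 1e-8)
  }
})

test_that("hydrogen-bond geometry recovers constructed triples", {
  lin <- gen_hbond_pair(180, 2.90)
  hb <- hbond_geometry(lin$motif)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$dha_angle, 180, tolerance = 1e-6)
  expect_equal(hb$da_distance, 2.90, tolerance = 1e-6)

  dual <- gen_hbond_pair(c(158.59, 166.51), c(2.88, 2.94))
  hb <- hbond_geometry(dual$motif)
  expect_equal(nrow(hb), 2L)
  expect_equal(hb$dha_angle, c(166.51, 158.59), tolerance = 0.05)
  expect_equal(hb$da_distance, c(2.94, 2.88), tolerance = 0.05)
  expect_true(all(diff(hb$dha_angle) <= 0))   # sorted descending

  chpi <- gen_chpi_pair(2.8)
  expect_equal(nrow(hbond_geometry(chpi$motif)), 0L)

  no_h <- motif_record(
    monomer("ligand-fragment", "LIG", atom_table("N", 0, 0, 0)),
    monomer("residue", "X1", atom_table("O", 2.9, 0, 0)))
  expect_error(hbond_geometry(no_h),
               class = "nbibench_hydrogens_required")
})

test_that("mode classification follows the charged-first cascade", {
  expect_equal(classify_mode(gen_charged_pair("salt-bridge", 3.4)$motif),
               "salt-bridge")
  expect_equal(classify_mode(gen_charged_pair("salt-bridge", 9.0)$motif),
               "unclassified")
  expect_equal(classify_mode(gen_charged_pair("cation-pi", 4.62)$motif),
               "cation-pi")
  expect_equal(classify_mode(gen_hbond_pair(c(170, 160),
                                            c(2.9, 3.0))$motif),
               "H-bond")
  # perpendicular neutral rings at 5.0 A: rules 1-3 cannot fire
  expect_equal(classify_mode(gen_ring_pair(90, 5.0)$motif), "pi-pi")
  expect_equal(classify_mode(gen_chpi_pair(2.8)$motif), "CH-pi")
})

test_that("geometry report carries the mode-specific descriptors", {
  rep_pp <- geometry_report(gen_ring_pair(43.85, 3.55)$motif)
  expect_equal(rep_pp$mode, "pi-pi")
  expect_equal(rep_pp$plane_angle, 43.85, tolerance = 0.01)
  expect_true(rep_pp$closest_heavy_distance > 0)

  rep_hb <- geometry_report(gen_hbond_pair(c(170, 150),
                                           c(2.9, 3.1))$motif)
  expect_equal(rep_hb$mode, "H-bond")
  expect_equal(nrow(rep_hb$hbonds), 2L)
  expect_true(is.na(rep_hb$plane_angle))
})
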