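test_that("generators are reproducible for a fixed seed", {
  expect_identical(gen_ring_pair(30, 3.8, seed = 5),
                   gen_ring_pair(30, 3.8, seed = 5))
  expect_identical(gen_cluster(12, seed = 5), gen_cluster(12, seed = 5))
  s1 <- gen_ledger(ledger_spec(seed = 9L))
  s2 <- gen_ledger(ledger_spec(seed = 9L))
  expect_identical(s1, s2)
})

test_that("fixtures survive the PDB writer/reader round trip", {
  fix <- gen_ring_pair(43.85, 3.55, seed = 2)
  parsed <- parse_motif_pdb(fix$text, "LIG", 90L)
  for (id in c("A", "B")) {
    a <- fix$motif$monomers[[id]]$atoms
    b <- parsed$monomers[[id]]$atoms
    expect_equal(nrow(b), nrow(a))
    expect_lt(max(abs(as.matrix(a[, c("x", "y", "z")]) -
                        as.matrix(b[, c("x", "y", "z")]))), 1e-3)
  }
  # descriptors recovered from the quantized text
  ra <- find_aromatic_rings(parsed$monomers$A)[[1]]
  rb <- find_aromatic_rings(parsed$monomers$B)[[1]]
  expect_equal(plane_angle(ra, rb), 43.85, tolerance = 0.05)
})

test_that("constructed geometries hit their promised descriptors", {
  # ring pair: plane angle and centroid separation exact in memory
  fix <- gen_ring_pair(27.3, 4.1, displacement = 1.2, seed = 3)
  ra <- find_aromatic_rings(fix$motif$monomers$A)[[1]]
  rb <- find_aromatic_rings(fix$motif$monomers$B)[[1]]
  expect_equal(plane_angle(ra, rb), 27.3, tolerance = 1e-6)
  expect_equal(sqrt(sum((ra$centroid - rb$centroid)^2)), 4.1,
               tolerance = 1e-6)
  expect_error(gen_ring_pair(10, 3, displacement = 4),
               class = "nbibench_infeasible_geometry")

  # H-bond pair: both triples at the requested angle/distance
  hb <- gen_hbond_pair(c(158.59, 166.51), c(2.88, 2.94), seed = 4)
  got <- hbond_geometry(hb$motif)
  expect_equal(got$dha_angle, hb$truth$dha_angle, tolerance = 1e-6)
  expect_equal(got$da_distance, hb$truth$da_distance, tolerance = 1e-6)
  expect_equal(nrow(hbond_geometry(gen_hbond_pair(161.45, 3.14)$motif)),
               1L)
  expect_error(gen_hbond_pair(80, 2.9),
               class = "nbibench_infeasible_geometry")

  # charged pairs: closest heavy distance equals the request
  sb <- gen_charged_pair("salt-bridge", 3.38, seed = 5)
  expect_equal(closest_heavy_distance(sb$motif), 3.38, tolerance = 1e-6)
  cp <- gen_charged_pair("cation-pi", 4.62, seed = 6)
  expect_equal(closest_heavy_distance(cp$motif), 4.62, tolerance = 1e-6)
})

test_that("in-envelope fixtures classify as the requested mode", {
  for (i in 1:20) {
    set.seed(1000 + i)
    expect_equal(classify_mode(
      gen_ring_pair(runif(1, 0, 90), runif(1, 3.3, 5.2))$motif), "pi-pi")
    expect_equal(classify_mode(
      gen_chpi_pair(runif(1, 2.2, 3.4))$motif), "CH-pi")
    expect_equal(classify_mode(
      gen_hbond_pair(runif(2, 125, 180), runif(2, 2.6, 3.4))$motif),
      "H-bond")
    expect_equal(classify_mode(
      gen_charged_pair("salt-bridge", runif(1, 2.9, 5.3))$motif),
      "salt-bridge")
    expect_equal(classify_mode(
      gen_charged_pair("cation-pi", runif(1, 3.3, 5.8))$motif),
      "cation-pi")
  }
})

test_that("synthetic ledgers realize the requested bias and noise", {
  # deterministic: sd = 0, bias = 0 gives a perfect method
  clean <- gen_ledger(ledger_spec(
    n_motifs = 30L,
    methods = data.frame(method_label = "perfect", basis_label = "TZ",
                         bias = 0, sd = 0), seed = 2L))
  ref <- assemble_interactions(clean$ledger, clean$solvation,
                               "CCSD(T)/CBS", "CBS")
  calc <- assemble_interactions(clean$ledger, clean$solvation,
                                "perfect", "TZ")
  m <- error_metrics(calc$dE_gas, ref$dE_gas)
  expect_equal(m$rmsd, 0, tolerance = 1e-8)
  expect_equal(m$max_pct, 0, tolerance = 1e-6)

  # pure shift: avg = mae = rmsd = bias
  shifted <- gen_ledger(ledger_spec(
    n_motifs = 30L,
    methods = data.frame(method_label = "sh", basis_label = "TZ",
                         bias = 0.3, sd = 0), seed = 3L))
  calc <- assemble_interactions(shifted$ledger, shifted$solvation,
                                "sh", "TZ")
  ref <- assemble_interactions(shifted$ledger, shifted$solvation,
                               "CCSD(T)/CBS", "CBS")
  m <- error_metrics(calc$dE_gas, ref$dE_gas)
  expect_equal(m$avg, 0.3, tolerance = 1e-8)
  expect_equal(m$mae, 0.3, tolerance = 1e-8)
  expect_equal(m$rmsd, 0.3, tolerance = 1e-8)

  # artificial BSSE lowers ghost energies below isolated ones, so the CP
  # value sits above the uncorrected one
  bsse <- gen_ledger(ledger_spec(
    n_motifs = 5L,
    methods = data.frame(method_label = "D", basis_label = "SVP",
                         bias = 0, sd = 0), bsse = 1.5, seed = 4L))
  id <- bsse$truth$motif_id[1]
  expect_equal(cp_corrected_delta(bsse$ledger, id, "D", "SVP") -
                 uncorrected_delta(bsse$ledger, id, "D", "SVP"),
               3.0, tolerance = 1e-8)

  # mode mix defaults follow the 13/12/8/8/8 library proportions
  expect_equal(unname(table(clean$truth$mode)[interaction_modes()]),
               c(8L, 7L, 5L, 5L, 5L), ignore_attr = TRUE)
})

test_that("ledger bundles round-trip through the delimited schema", {
  bundle <- gen_ledger(ledger_spec(n_motifs = 8L, seed = 6L))
  dir <- tempfile("bundle_")
  paths <- write_ledger_bundle(bundle, dir)
  led <- read_energy_ledger(paths[["ledger"]])
  sol <- read_solvation_table(paths[["solvation"]])
  expect_equal(nrow(led), nrow(bundle$ledger))
  expect_equal(
    assemble_interactions(led, sol, "CCSD(T)/CBS", "CBS")$dE_gas,
    assemble_interactions(bundle$ledger, bundle$solvation,
                          "CCSD(T)/CBS", "CBS")$dE_gas,
    tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
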