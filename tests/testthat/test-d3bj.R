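refdata <- d3_reference_data()

test_that("coordination numbers follow the smooth counting function", {
  expect_equal(coordination_numbers(atom_table("C", 0, 0, 0), refdata), 0)

  # two carbons exactly at 4/3 (Rcov + Rcov): sigmoid midpoint, CN = 1/2
  d_mid <- 4 / 3 * (0.75 + 0.75)
  two <- atom_table(c("C", "C"), c(0, d_mid), c(0, 0), c(0, 0),
                    name = c("C1", "C2"))
  expect_equal(coordination_numbers(two, refdata), c(0.5, 0.5),
               tolerance = 1e-12)

  methane <- gen_chpi_pair(2.8)$motif$monomers$B$atoms
  cn <- coordination_numbers(methane, refdata)
  expect_equal(cn[1], 4, tolerance = 0.05)
  expect_true(all(cn >= 0))

  expect_error(
    coordination_numbers(data.frame(element = "Zz", x = 0, y = 0, z = 0),
                         refdata),
    class = "nbibench_unknown_element")
})

test_that("C6 interpolation matches a brute-force weighted average", {
  # weight collapses onto a single reference point
  single <- structure(list(rcov = c(C = 0.75),
                           refs = data.frame(elem = "C", cn = 2, c6 = 30),
                           r4r2 = c(C = 3.1)),
                      class = "nbi_d3_refdata")
  expect_equal(pair_c6("C", "C", 2, 2, single), 30)
  expect_equal(pair_c6("C", "C", 0.3, 3.7, single), 30)

  # symmetry and equality with the naive double loop on random CN pairs
  set.seed(4)
  for (k in 1:20) {
    ea <- sample(c("H", "C", "N", "O", "S", "Cl"), 1)
    eb <- sample(c("H", "C", "N", "O", "S", "Cl"), 1)
    ca <- runif(1, 0, 4)
    cb <- runif(1, 0, 4)
    got <- pair_c6(ea, eb, ca, cb, refdata)
    expect_equal(got, pair_c6(eb, ea, cb, ca, refdata), tolerance = 1e-12)
    ra <- refdata$refs[refdata$refs$elem == ea, ]
    rb <- refdata$refs[refdata$refs$elem == eb, ]
    num <- den <- 0
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
      w <- exp(-4 * ((ca - ra$cn[i])^2 + (cb - rb$cn[j])^2))
      num <- num + w * sqrt(ra$c6[i] * rb$c6[j])
      den <- den + w
    }
    expect_equal(got, num / den, tolerance = 1e-12)
    expect_gt(got, 0)
  }
  expect_error(pair_c6("C", "C", 1, 1,
                       structure(list(rcov = c(C = 0.75),
                                      refs = data.frame(elem = character(0),
                                                        cn = numeric(0),
                                                        c6 = numeric(0)),
                                      r4r2 = c(C = 3.1)),
                                 class = "nbi_d3_refdata")),
               class = "nbibench_missing_reference")
})

test_that("C8 follows 3 C6 sqrt(QA QB) and is symmetric", {
  unit_q <- structure(list(r4r2 = c(A = 1, B = 1)), class = "nbi_d3_refdata")
  expect_equal(pair_c8(2, "A", "B", unit_q), 6)
  expect_equal(pair_c8(10, "C", "N", refdata),
               3 * 10 * sqrt(refdata$r4r2[["C"]] * refdata$r4r2[["N"]]))
  expect_equal(pair_c8(10, "C", "N", refdata), pair_c8(10, "N", "C", refdata))
})

test_that("dispersion energy matches the naive double-loop oracle", {
  params <- d3_functional_params("B3LYP")
  set.seed(9)
  for (k in 1:10) {
    atoms <- gen_cluster(sample(4:12, 1), seed = 100 + k)
    got <- d3bj_energy(atoms, params, refdata)
    expect_equal(got$total_energy, naive_d3(atoms, params, refdata),
                 tolerance = 1e-10)
    # additive per-pair breakdown
    expect_equal(got$total_energy,
                 sum(got$pair_terms$e6) + sum(got$pair_terms$e8),
                 tolerance = 1e-12)
    # pair terms reproducible from the frozen coefficients
    pt <- got$pair_terms
    f0 <- params$a1 * sqrt(pt$c8_ab / pt$c6_ab) + params$a2
    expect_equal(pt$e6, -params$s6 * pt$c6_ab / (pt$r_ab^6 + f0^6) * KCAL,
                 tolerance = 1e-12)
    expect_lte(got$total_energy, 0)
  }
})

test_that("dispersion energy is invariant under rigid motion and atom order", {
  params <- d3_functional_params("TPSS")
  atoms <- gen_cluster(10, seed = 17)
  base <- d3bj_energy(atoms, params, refdata)$total_energy
  set.seed(18)
  for (k in 1:5) {
    moved <- rigid_atoms(atoms, random_rot(), rnorm(3, 0, 10))
    expect_equal(d3bj_energy(moved, params, refdata)$total_energy, base,
                 tolerance = 1e-10)
    perm <- atoms[sample(nrow(atoms)), ]
    expect_equal(d3bj_energy(perm, params, refdata)$total_energy, base,
                 tolerance = 1e-12)
  }
})

test_that("dispersion limits: single atom, asymptotics, short range", {
  params <- d3_functional_params("B3LYP")
  expect_equal(d3bj_energy(atom_table("C", 0, 0, 0), params,
                           refdata)$total_energy, 0)

  # far pair: damping negligible, e6 -> -s6 C6 / R^6
  r_bohr <- 40
  far <- atom_table(c("C", "C"), c(0, r_bohr / BOHR), c(0, 0), c(0, 0),
                    name = c("C1", "C2"))
  res <- d3bj_energy(far, params, refdata)
  asym <- -params$s6 * res$pair_terms$c6_ab / r_bohr^6 * KCAL
  expect_lt(abs(res$pair_terms$e6 / asym - 1), 1e-3)

  # finite at near-coincidence (0.01 bohr) thanks to BJ damping
  near <- atom_table(c("C", "C"), c(0, 0.01 / BOHR), c(0, 0), c(0, 0),
                     name = c("C1", "C2"))
  expect_true(is.finite(d3bj_energy(near, params, refdata)$total_energy))

  expect_error(
    d3bj_energy(atom_table(c("C", "C"), c(0, 1e-9), c(0, 0), c(0, 0),
                           name = c("C1", "C2")), params, refdata),
    class = "nbibench_coincident_atoms")

  # |E| strictly decreasing with separation beyond 1 bohr once the
  # dispersion coefficients are frozen (a single reference point removes
  # the coordination dependence of C6, which otherwise rises through the
  # covalent transition region)
  frozen <- structure(list(rcov = c(C = 0.75),
                           refs = data.frame(elem = "C", cn = 0,
                                             c6 = 49.11),
                           r4r2 = c(C = 3.1049)),
                      class = "nbi_d3_refdata")
  rs <- seq(1.2, 12, length.out = 25)
  es <- vapply(rs, function(r) {
    abs(d3bj_energy(atom_table(c("C", "C"), c(0, r / BOHR), c(0, 0),
                               c(0, 0), name = c("C1", "C2")),
                    params, frozen)$total_energy)
  }, numeric(1))
  expect_true(all(diff(es) < 0))
})

test_that("functional parameter sets load and validate", {
  p <- d3_functional_params("B3LYP")
  expect_equal(p$s6, 1.0)
  expect_gt(p$a2, 0)
  expect_error(d3_functional_params("NOPE"),
               class = "nbibench_unknown_functional")
  expect_error(d3_params("bad", s6 = -1, s8 = 1, a1 = 0.4, a2 = 4),
               class = "nbibench_invalid_parameters")
  # every packaged functional yields a non-positive dispersion energy
  atoms <- gen_cluster(8, seed = 33)
  for (f in c("BLYP", "TPSS", "B97", "wB97X", "B3LYP", "M062X",
              "PW6B95", "B2PLYP", "PWPB95")) {
    expect_lte(d3bj_energy(atoms, d3_functional_params(f),
                           refdata)$total_energy, 0)
  }
})
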