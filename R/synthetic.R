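## Generators for every pipeline input, with known ground truth. All
## geometry is constructed analytically (exact to machine precision in
## memory); writing through the PDB fixed-width format quantizes
## coordinates to 3 decimals, so round-tripped descriptors are recovered
## to ~1e-3 A / ~0.05 deg.

BENZENE_CC <- 1.3915
BENZENE_CH <- 1.087

# regular benzene ring in the z = 0 plane, centered at the origin,
# optionally spun about its normal
benzene_atoms <- function(spin = 0, res_name = "LIG", res_seq = 1L,
                          name_prefix = "") {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6] + spin
  rc <- BENZENE_CC
  rh <- BENZENE_CC + BENZENE_CH
  atom_table(
    element = c(rep("C", 6), rep("H", 6)),
    x = c(rc * cos(ang), rh * cos(ang)),
    y = c(rc * sin(ang), rh * sin(ang)),
    z = rep(0, 12),
    name = paste0(name_prefix, c(paste0("C", 1:6), paste0("H", 1:6))),
    res_name = res_name, res_seq = res_seq
  )
}

# tetrahedral bond directions (unit vectors, first one along -z)
TETRAHEDRAL <- rbind(
  c(0, 0, -1),
  c(2 * sqrt(2) / 3, 0, 1 / 3),
  c(-sqrt(2) / 3, sqrt(6) / 3, 1 / 3),
  c(-sqrt(2) / 3, -sqrt(6) / 3, 1 / 3)
)

transform_atoms <- function(atoms, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  xyz <- apply_rigid(coords_of(atoms), rotation, translation)
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}

#' Generate an ideal stacked ring pair (pi-pi fixture)
#'
#' Two ideal benzene rings whose least-squares plane angle and centroid
#' separation equal the request exactly (up to machine precision in the
#' returned motif; up to PDB quantization in the text).
#'
#' @param angle Plane-plane angle in degrees, in \[0, 90\].
#' @param centroid_sep Centroid-centroid separation in Angstrom.
#' @param displacement Lateral (in-plane) displacement of the second ring
#'   centroid in Angstrom; must not exceed `centroid_sep`.
#' @param seed Optional seed; randomizes the in-plane spin of both rings
#'   without changing the promised descriptors.
#' @return List with `motif` ([motif_record()]), `text` (PDB lines) and
#'   `truth` (requested `plane_angle`, `centroid_sep`).
#' @export
gen_ring_pair <- function(angle, centroid_sep = 3.8, displacement = 0,
                          seed = NULL) {
  stopifnot(angle >= 0, angle <= 90)
  if (displacement > centroid_sep) {
    nbi_stop("infeasible-geometry",
             "displacement cannot exceed the centroid separation")
  }
  if (!is.null(seed)) set.seed(seed)
  spin_a <- if (is.null(seed)) 0 else runif(1, 0, 2 * pi)
  spin_b <- if (is.null(seed)) 0 else runif(1, 0, 2 * pi)
  ring_a <- benzene_atoms(spin_a, res_name = "LIG", res_seq = 1L)
  height <- sqrt(centroid_sep^2 - displacement^2)
  ring_b <- transform_atoms(
    benzene_atoms(spin_b, res_name = "PHE", res_seq = 90L),
    rotation = rot_x(angle * pi / 180),
    translation = c(displacement, 0, height))
  motif <- motif_record(
    monomer("ligand-fragment", "LIG", ring_a),
    monomer("residue", "F90", ring_b))
  list(motif = motif, text = write_motif_pdb(motif),
       truth = list(plane_angle = angle, centroid_sep = centroid_sep))
}

#' Generate an ideal CH-pi fixture
#'
#' A benzene ring with a methane probe whose first C-H bond points at the
#' ring centroid; the H-to-centroid distance equals the request.
#'
#' @param h_to_centroid H-to-ring-centroid distance in Angstrom.
#' @param seed Optional seed (randomizes the ring spin only).
#' @return List with `motif`, `text` and `truth` (`h_to_centroid`).
#' @export
gen_chpi_pair <- function(h_to_centroid = 2.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spin <- if (is.null(seed)) 0 else runif(1, 0, 2 * pi)
  ring <- benzene_atoms(spin, res_name = "LIG", res_seq = 1L)
  c_pos <- c(0, 0, h_to_centroid + 1.09)
  h_xyz <- sweep(1.09 * TETRAHEDRAL, 2, c_pos, "+")
  methane <- atom_table(
    element = c("C", rep("H", 4)),
    x = c(c_pos[1], h_xyz[, 1]), y = c(c_pos[2], h_xyz[, 2]),
    z = c(c_pos[3], h_xyz[, 3]),
    name = c("CB", paste0("HB", 1:4)),
    res_name = "ALA", res_seq = 70L)
  motif <- motif_record(
    monomer("ligand-fragment", "LIG", ring),
    monomer("residue", "A70", methane))
  list(motif = motif, text = write_motif_pdb(motif),
       truth = list(h_to_centroid = h_to_centroid))
}

# place H realizing a D-H...A triple with angle `theta` (deg) at H and
# donor-acceptor distance `d`, donor at origin, acceptor at (d, 0, 0);
# law of sines in the D-H-A triangle with N-H = 1.01 A
place_hbond_h <- function(theta, d, nh = 1.01) {
  th <- theta * pi / 180
  sin_a <- nh * sin(th) / d
  if (sin_a > 1) nbi_stop("infeasible-geometry", "no H position exists")
  ang_a <- asin(sin_a)
  ang_d <- pi - th - ang_a
  nh * c(cos(ang_d), sin(ang_d), 0)
}

#' Generate an ideal dual (or single) hydrogen-bond fixture
#'
#' Amide-like donor/acceptor units realizing each requested D-H...A angle
#' and donor-acceptor distance exactly; multiple units are separated far
#' enough that no cross-unit triple qualifies.
#'
#' @param angles D-H...A angles in degrees (one per H-bond), each in
#'   \[90, 180\].
#' @param distances Donor-acceptor distances in Angstrom, each in
#'   \[2.5, 3.5\].
#' @param seed Optional seed (orientation jitter of the whole motif).
#' @return List with `motif`, `text` and `truth` (data frame of
#'   `dha_angle`, `da_distance` sorted by descending angle).
#' @export
gen_hbond_pair <- function(angles = c(170, 160), distances = c(2.9, 3.0),
                           seed = NULL) {
  if (length(angles) != length(distances) || length(angles) < 1L) {
    nbi_stop("shape-mismatch",
             "angles and distances must have equal length >= 1")
  }
  if (any(angles < 90 | angles > 180) ||
      any(distances < 2.5 | distances > 3.5) || any(distances <= 1.01)) {
    nbi_stop("infeasible-geometry",
             "require angles in [90, 180] and distances in [2.5, 3.5]")
  }
  don <- list()
  acc <- list()
  for (k in seq_along(angles)) {
    off <- c(0, (k - 1) * 5.0, 0)
    h <- place_hbond_h(angles[k], distances[k]) + off
    n <- off
    cd <- off + c(-1.02, -1.02, 0)           # donor substituent carbon
    a <- off + c(distances[k], 0, 0)
    ca <- a + c(1.23, 0, 0)                  # carbonyl carbon past O
    don[[k]] <- data.frame(
      element = c("N", "H", "C"),
      name = paste0(c("N", "H", "C"), k),
      x = c(n[1], h[1], cd[1]), y = c(n[2], h[2], cd[2]),
      z = c(n[3], h[3], cd[3]))
    acc[[k]] <- data.frame(
      element = c("O", "C"),
      name = paste0(c("O", "CA"), k),
      x = c(a[1], ca[1]), y = c(a[2], ca[2]), z = c(a[3], ca[3]))
  }
  dd <- do.call(rbind, don)
  aa <- do.call(rbind, acc)
  rot <- diag(3)
  if (!is.null(seed)) {
    set.seed(seed)
    rot <- random_rotation()
  }
  lig <- transform_atoms(
    atom_table(dd$element, dd$x, dd$y, dd$z, name = dd$name,
               res_name = "LIG", res_seq = 1L), rot)
  res <- transform_atoms(
    atom_table(aa$element, aa$x, aa$y, aa$z, name = aa$name,
               res_name = "LEU", res_seq = 83L), rot)
  motif <- motif_record(monomer("ligand-fragment", "LIG", lig),
                        monomer("residue", "L83", res))
  ord <- order(-angles)
  list(motif = motif, text = write_motif_pdb(motif),
       truth = data.frame(dha_angle = angles[ord],
                          da_distance = distances[ord]))
}

#' Generate an ideal charged-pair fixture (salt bridge or cation-pi)
#'
#' Salt bridge: ammonium versus a carboxylate with the requested closest
#' N...O heavy-atom distance, charges +1/-1. Cation-pi: benzene versus an
#' ammonium whose nitrogen sits on the ring axis with the requested
#' closest N...C(ring) distance, charge +1 on the ammonium side.
#'
#' @param mode `"salt-bridge"` or `"cation-pi"`.
#' @param distance Closest heavy-atom distance in Angstrom.
#' @param seed Optional seed (rigid-orientation jitter).
#' @return List with `motif`, `text` and `truth` (`mode`, `distance`).
#' @export
gen_charged_pair <- function(mode = c("salt-bridge", "cation-pi"),
                             distance = 3.4, seed = NULL) {
  mode <- match.arg(mode)
  rot <- diag(3)
  if (!is.null(seed)) {
    set.seed(seed)
    rot <- random_rotation()
  }
  if (mode == "salt-bridge") {
    h_xyz <- 1.03 * TETRAHEDRAL
    lig <- atom_table(
      element = c("N", rep("H", 4)),
      x = c(0, h_xyz[, 1]), y = c(0, h_xyz[, 2]), z = c(0, h_xyz[, 3]),
      name = c("N1", paste0("HN", 1:4)), res_name = "LIG", res_seq = 1L)
    d <- distance
    res <- atom_table(
      element = c("O", "C", "O", "C"),
      x = c(d, d + 0.63, d + 1.71, d + 0.63),
      y = c(0, 1.08, 1.71, 2.58),
      z = c(0, 0, 0, 0),
      name = c("OD1", "CG", "OD2", "CB"),
      res_name = "ASP", res_seq = 148L)
    motif <- motif_record(
      monomer("ligand-fragment", "LIG",
              transform_atoms(lig, rot), formal_charge = 1L),
      monomer("residue", "D148",
              transform_atoms(res, rot), formal_charge = -1L))
  } else {
    if (distance <= BENZENE_CC) {
      nbi_stop("infeasible-geometry",
               "cation-pi distance must exceed the ring radius")
    }
    ring <- benzene_atoms(0, res_name = "LIG", res_seq = 1L)
    h <- sqrt(distance^2 - BENZENE_CC^2)
    n_pos <- c(0, 0, h)
    hn <- sweep(1.03 * TETRAHEDRAL[2:4, ], 2, n_pos, "+")
    ce <- n_pos + c(0, 0, 1.49)
    amm <- atom_table(
      element = c("N", rep("H", 3), "C"),
      x = c(n_pos[1], hn[, 1], ce[1]),
      y = c(n_pos[2], hn[, 2], ce[2]),
      z = c(n_pos[3], hn[, 3], ce[3]),
      name = c("NZ", paste0("HZ", 1:3), "CE"),
      res_name = "LYS", res_seq = 33L)
    motif <- motif_record(
      monomer("ligand-fragment", "LIG", transform_atoms(ring, rot)),
      monomer("residue", "K33", transform_atoms(amm, rot),
              formal_charge = 1L))
  }
  list(motif = motif, text = write_motif_pdb(motif),
       truth = list(mode = mode, distance = distance))
}

#' Generate a correlation-energy series with exact X^-3 convergence
#'
#' `E(X) = E_inf + A X^-3` exactly, so the two-point extrapolation
#' recovers `E_inf` identically.
#'
#' @param e_inf Basis-set-limit correlation energy.
#' @param a Convergence coefficient.
#' @param cardinals Integer cardinal numbers (default T/Q = 3, 4).
#' @return A [correlation_series()].
#' @export
gen_cbs_series <- function(e_inf, a, cardinals = c(3L, 4L)) {
  correlation_series(cardinals, e_inf + a * as.numeric(cardinals)^-3)
}

#' Generate a random atom cluster
#'
#' Rejection-samples positions inside a cubic box subject to a minimum
#' pairwise separation; used as input for dispersion-energy oracles.
#'
#' @param n Number of atoms.
#' @param elements Element pool to draw from.
#' @param box Box edge length in Angstrom.
#' @param min_sep Minimum pairwise distance in Angstrom.
#' @param seed Optional seed.
#' @return An [atom_table()].
#' @export
gen_cluster <- function(n = 10, elements = c("C", "H", "N", "O"),
                        box = 6, min_sep = 1.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(NA_real_, n, 3)
  k <- 0L
  tries <- 0L
  while (k < n) {
    cand <- runif(3, 0, box)
    ok <- k == 0L ||
      min(sqrt(rowSums(sweep(pts[seq_len(k), , drop = FALSE], 2,
                             cand)^2))) >= min_sep
    if (ok) {
      k <- k + 1L
      pts[k, ] <- cand
    }
    tries <- tries + 1L
    if (tries > 10000L * n) {
      nbi_stop("infeasible-geometry",
               "cannot place atoms at the requested density")
    }
  }
  atom_table(sample(elements, n, replace = TRUE),
             pts[, 1], pts[, 2], pts[, 3],
             name = paste0("X", seq_len(n)))
}

DEFAULT_MODE_COUNTS <- c("CH-pi" = 13L, "pi-pi" = 12L, "cation-pi" = 8L,
                         "H-bond" = 8L, "salt-bridge" = 8L)

## per-mode reference scales (kcal/mol): means/sds of the gas-phase and
## dehydration energies in the packaged 49-motif reference set
DEFAULT_GAS_SCALE <- data.frame(
  mode = names(DEFAULT_MODE_COUNTS),
  mean = c(-2.1, -1.8, -4.5, -5.5, -99.5),
  sd = c(0.8, 1.0, 2.9, 1.1, 14.6),
  deh_mean = c(0.3, 0.5, 2.9, 3.6, 95.1),
  deh_sd = c(0.4, 0.4, 2.9, 1.4, 12.6),
  stringsAsFactors = FALSE)

#' Specify a synthetic energy ledger
#'
#' @param n_motifs Number of motifs; the mode mix is scaled from the
#'   reference library's 13/12/8/8/8 proportions unless `mode_counts` is
#'   given.
#' @param mode_counts Named integer vector of motifs per mode.
#' @param methods Data frame with columns `method_label`, `basis_label`,
#'   `bias`, `sd` (kcal/mol): each synthetic method computes
#'   `ref + bias + Normal(0, sd)`.
#' @param bsse Artificial basis-set superposition error per monomer
#'   (kcal/mol, `>= 0`); ghost-basis energies sit this far below the
#'   isolated-monomer energies.
#' @param seed Integer seed; the generator is reproducible for a fixed
#'   seed.
#' @return List of class `nbi_ledger_spec`.
#' @export
ledger_spec <- function(n_motifs = 49L, mode_counts = NULL,
                        methods = data.frame(method_label = "DFT",
                                             basis_label = "TZ",
                                             bias = 0, sd = 0),
                        bsse = 0, seed = 1L) {
  if (is.null(mode_counts)) {
    if (n_motifs == 49L) {
      mode_counts <- DEFAULT_MODE_COUNTS
    } else {
      mode_counts <- pmax(round(DEFAULT_MODE_COUNTS / 49 * n_motifs), 1L)
    }
  }
  if (any(methods$sd < 0) || bsse < 0) {
    nbi_stop("invalid-parameters", "noise sd and bsse must be >= 0")
  }
  structure(list(n_motifs = sum(mode_counts), mode_counts = mode_counts,
                 methods = methods, bsse = bsse, seed = as.integer(seed)),
            class = "nbi_ledger_spec")
}

#' Generate a synthetic counterpoise energy ledger with known truth
#'
#' Draws per-motif reference interaction energies at the scale of the
#' 49-motif reference library (per-mode means and spreads), adds a
#' per-method bias and Gaussian noise, and decomposes each interaction
#' energy into consistent dimer/ghost/monomer ledger entries (the whole
#' interaction lives in the dimer entry; monomer electronic energies are
#' fixed constants, which suffices because only differences matter).
#' Matching solvation triplets realize per-mode dehydration energies.
#'
#' @param spec A [ledger_spec()].
#' @return List with `ledger` (hartree energies, 5 roles per motif and
#'   method), `solvation` (kcal/mol triplets), and `truth` (per-motif
#'   `motif_id`, `mode`, `ref` gas-phase kcal/mol, `deh`, plus the
#'   per-method columns of realized calculated energies).
#' @export
gen_ledger <- function(spec = ledger_spec()) {
  stopifnot(inherits(spec, "nbi_ledger_spec"))
  set.seed(spec$seed)
  modes <- rep(names(spec$mode_counts), spec$mode_counts)
  n <- length(modes)
  ids <- sprintf("m%03d", seq_len(n))
  sc <- DEFAULT_GAS_SCALE[match(modes, DEFAULT_GAS_SCALE$mode), ]
  ref <- pmin(rnorm(n, sc$mean, sc$sd), -0.1)
  deh <- rnorm(n, sc$deh_mean, sc$deh_sd)

  e_a <- -100.0
  e_b <- -150.0
  bsse_h <- spec$bsse / HARTREE_TO_KCAL
  mk_rows <- function(method_label, basis_label, delta_kcal) {
    delta_h <- delta_kcal / HARTREE_TO_KCAL
    data.frame(
      motif_id = rep(ids, each = 5L),
      method_label = method_label, basis_label = basis_label,
      role = rep(LEDGER_ROLES, times = n),
      energy = as.vector(vapply(delta_h, function(dh) {
        c(e_a + e_b - 2 * bsse_h + dh,   # dimer_AB
          e_a - bsse_h,                  # monoA_ghostB
          e_b - bsse_h,                  # monoB_ghostA
          e_a,                           # monoA_alone
          e_b)                           # monoB_alone
      }, numeric(5))),
      stringsAsFactors = FALSE)
  }

  ledger <- mk_rows("CCSD(T)/CBS", "CBS", ref)
  truth <- data.frame(motif_id = ids, mode = modes, ref = ref, deh = deh,
                      stringsAsFactors = FALSE)
  for (k in seq_len(nrow(spec$methods))) {
    m <- spec$methods[k, ]
    calc <- ref + m$bias + rnorm(n, 0, m$sd)
    ledger <- rbind(ledger, mk_rows(m$method_label, m$basis_label, calc))
    truth[[paste(m$method_label, m$basis_label, sep = "/")]] <- calc
  }

  g_a <- -10.0
  g_b <- -15.0
  solvation <- data.frame(motif_id = ids, g_sol_ab = deh + g_a + g_b,
                          g_sol_a = g_a, g_sol_b = g_b,
                          stringsAsFactors = FALSE)
  list(ledger = validate_ledger(ledger), solvation = solvation,
       truth = truth)
}

#' Write a ledger bundle to delimited files
#'
#' @param bundle Output of [gen_ledger()].
#' @param dir Directory to write `ledger.tsv`, `solvation.tsv` and
#'   `truth.tsv` into.
#' @return Invisibly, the paths written.
#' @export
write_ledger_bundle <- function(bundle, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ledger = file.path(dir, "ledger.tsv"),
             solvation = file.path(dir, "solvation.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write.table(bundle$ledger, paths["ledger"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$solvation, paths["solvation"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$truth, paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
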