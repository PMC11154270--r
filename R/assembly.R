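#' Supramolecular interaction energy
#'
#' Difference between the dimer energy and the two monomer energies,
#' `E_AB - E_A - E_B`. Units follow the inputs.
#'
#' @param e_ab Dimer energy.
#' @param e_a,e_b Monomer energies.
#' @return Interaction energy.
#' @export
supramolecular_delta <- function(e_ab, e_a, e_b) {
  e_ab - e_a - e_b
}

LEDGER_ROLES <- c("dimer_AB", "monoA_ghostB", "monoB_ghostA",
                  "monoA_alone", "monoB_alone")

#' Counterpoise fragment specifications for a motif
#'
#' Emits the five fragments of the Boys-Bernardi counterpoise scheme: the
#' dimer, each monomer in the full dimer basis (the other monomer's atoms
#' ghosted), and each isolated monomer. Ghost fragments carry the real
#' monomer's charge and multiplicity.
#'
#' @param motif An [motif_record()].
#' @return Named list of five fragment specs, each with `role`, `atoms`
#'   (atom table with logical `real` column), `charge`, `multiplicity`.
#' @export
counterpoise_fragments <- function(motif) {
  a <- motif$monomers$A
  b <- motif$monomers$B
  dimer_atoms <- rbind(cbind(a$atoms, real = TRUE),
                       cbind(b$atoms, real = TRUE))
  ghost_b <- rbind(cbind(a$atoms, real = TRUE),
                   cbind(b$atoms, real = FALSE))
  ghost_a <- rbind(cbind(a$atoms, real = FALSE),
                   cbind(b$atoms, real = TRUE))
  frags <- list(
    dimer_AB = list(role = "dimer_AB", atoms = dimer_atoms,
                    charge = a$formal_charge + b$formal_charge,
                    multiplicity = max(a$multiplicity, b$multiplicity)),
    monoA_ghostB = list(role = "monoA_ghostB", atoms = ghost_b,
                        charge = a$formal_charge,
                        multiplicity = a$multiplicity),
    monoB_ghostA = list(role = "monoB_ghostA", atoms = ghost_a,
                        charge = b$formal_charge,
                        multiplicity = b$multiplicity),
    monoA_alone = list(role = "monoA_alone",
                       atoms = cbind(a$atoms, real = TRUE),
                       charge = a$formal_charge,
                       multiplicity = a$multiplicity),
    monoB_alone = list(role = "monoB_alone",
                       atoms = cbind(b$atoms, real = TRUE),
                       charge = b$formal_charge,
                       multiplicity = b$multiplicity)
  )
  lapply(frags, function(f) structure(f, class = "nbi_cp_fragment"))
}

#' Write counterpoise fragments as XYZ files
#'
#' One XYZ file per fragment role. Ghost atoms are marked with a trailing
#' colon on the element symbol (`C:`), the convention understood by common
#' quantum-chemistry inputs.
#'
#' @param motif An [motif_record()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_cp_fragments <- function(motif, dir = ".", prefix = "fragment") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frags <- counterpoise_fragments(motif)
  paths <- vapply(frags, function(f) {
    path <- file.path(dir, sprintf("%s_%s.xyz", prefix, f$role))
    at <- f$atoms
    sym <- ifelse(at$real, at$element, paste0(at$element, ":"))
    lines <- c(
      sprintf("%d", nrow(at)),
      sprintf("%s charge=%d multiplicity=%d", f$role, f$charge,
              f$multiplicity),
      sprintf("%-4s %12.6f %12.6f %12.6f", sym, at$x, at$y, at$z)
    )
    writeLines(lines, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read an energy ledger table
#'
#' The ledger is the boundary to external quantum chemistry: a delimited
#' table of electronic energies with columns `motif_id`, `method_label`,
#' `basis_label`, `role` (one of dimer_AB, monoA_ghostB, monoB_ghostA,
#' monoA_alone, monoB_alone) and `energy` (hartree). The
#' (motif, method, basis, role) key must be unique.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return Validated ledger data frame.
#' @export
read_energy_ledger <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_ledger(tab)
}

validate_ledger <- function(tab) {
  need <- c("motif_id", "method_label", "basis_label", "role", "energy")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    nbi_stop("schema-mismatch",
             sprintf("ledger lacks column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }
  bad_roles <- setdiff(unique(tab$role), LEDGER_ROLES)
  if (length(bad_roles)) {
    nbi_stop("schema-mismatch",
             sprintf("unknown ledger role(s): %s",
                     paste(bad_roles, collapse = ", ")))
  }
  key <- paste(tab$motif_id, tab$method_label, tab$basis_label, tab$role)
  if (anyDuplicated(key)) {
    nbi_stop("duplicate-ledger-entry",
             "duplicated (motif, method, basis, role) entries in ledger")
  }
  tab
}

#' Counterpoise-corrected interaction energy from a ledger
#'
#' `dE_CP = E(dimer_AB) - E(monoA_ghostB) - E(monoB_ghostA)`, i.e. each
#' monomer is evaluated in the full dimer basis, removing the basis-set
#' superposition error. Ledger energies are hartree; the result is
#' kcal/mol.
#'
#' @param ledger Ledger data frame (see [read_energy_ledger()]).
#' @param motif_id,method_label,basis_label Key of the calculation to
#'   assemble.
#' @return Interaction energy in kcal/mol.
#' @export
cp_corrected_delta <- function(ledger, motif_id, method_label,
                               basis_label) {
  sub <- ledger[ledger$motif_id == motif_id &
                  ledger$method_label == method_label &
                  ledger$basis_label == basis_label, , drop = FALSE]
  need <- c("dimer_AB", "monoA_ghostB", "monoB_ghostA")
  e <- sub$energy[match(need, sub$role)]
  if (anyNA(e)) {
    nbi_stop("incomplete-ledger",
             sprintf("ledger for motif %s / %s / %s lacks role(s): %s",
                     motif_id, method_label, basis_label,
                     paste(need[is.na(e)], collapse = ", ")))
  }
  supramolecular_delta(e[1], e[2], e[3]) * HARTREE_TO_KCAL
}

#' Uncorrected interaction energy from a ledger
#'
#' `dE = E(dimer_AB) - E(monoA_alone) - E(monoB_alone)` in kcal/mol, for
#' comparison against the counterpoise-corrected value.
#'
#' @inheritParams cp_corrected_delta
#' @return Interaction energy in kcal/mol.
#' @export
uncorrected_delta <- function(ledger, motif_id, method_label,
                              basis_label) {
  sub <- ledger[ledger$motif_id == motif_id &
                  ledger$method_label == method_label &
                  ledger$basis_label == basis_label, , drop = FALSE]
  need <- c("dimer_AB", "monoA_alone", "monoB_alone")
  e <- sub$energy[match(need, sub$role)]
  if (anyNA(e)) {
    nbi_stop("incomplete-ledger",
             sprintf("ledger for motif %s / %s / %s lacks role(s): %s",
                     motif_id, method_label, basis_label,
                     paste(need[is.na(e)], collapse = ", ")))
  }
  supramolecular_delta(e[1], e[2], e[3]) * HARTREE_TO_KCAL
}

#' Dehydration energy from a solvation triplet
#'
#' `dE_Deh = dG_sol(AB) - dG_sol(A) - dG_sol(B)`: the solvation free-energy
#' penalty of complex formation. All inputs and the result in kcal/mol.
#'
#' @param g_sol_ab,g_sol_a,g_sol_b Free energies of solvation of the
#'   complex and the monomers.
#' @return Dehydration energy.
#' @export
dehydration <- function(g_sol_ab, g_sol_a, g_sol_b) {
  g_sol_ab - g_sol_a - g_sol_b
}

#' Solution-phase interaction energy via the thermodynamic cycle
#'
#' `dE_aq = dE_gas + dE_Deh`.
#'
#' @param de_gas Gas-phase interaction energy (kcal/mol).
#' @param de_deh Dehydration energy (kcal/mol).
#' @return Solution-phase interaction energy (kcal/mol).
#' @export
aqueous <- function(de_gas, de_deh) {
  de_gas + de_deh
}

#' Read a solvation table
#'
#' Columns: `motif_id`, `g_sol_ab`, `g_sol_a`, `g_sol_b` (kcal/mol).
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return Data frame.
#' @export
read_solvation_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("motif_id", "g_sol_ab", "g_sol_a", "g_sol_b")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    nbi_stop("schema-mismatch",
             sprintf("solvation table lacks column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }
  tab
}

#' Assemble gas- and solution-phase interaction records
#'
#' Combines counterpoise-corrected gas-phase energies from a ledger with
#' dehydration energies from a solvation table into one record per motif:
#' `dE_gas`, `dE_deh` and `dE_aq = dE_gas + dE_deh` (all kcal/mol; the
#' additivity holds exactly before any rounding).
#'
#' @param ledger Ledger data frame ([read_energy_ledger()]).
#' @param solvation Solvation data frame ([read_solvation_table()]).
#' @param method_label,basis_label Calculation to assemble.
#' @return Data frame with columns `motif_id`, `dE_gas`, `dE_deh`,
#'   `dE_aq`.
#' @export
assemble_interactions <- function(ledger, solvation, method_label,
                                  basis_label) {
  validate_ledger(ledger)
  sub <- ledger[ledger$method_label == method_label &
                  ledger$basis_label == basis_label, , drop = FALSE]
  ids <- sort(unique(sub$motif_id))
  if (length(ids) == 0L) {
    nbi_stop("incomplete-ledger",
             sprintf("no ledger entries for %s / %s", method_label,
                     basis_label))
  }
  role_col <- function(role) {
    rows <- sub[sub$role == role, , drop = FALSE]
    e <- rows$energy[match(ids, rows$motif_id)]
    if (anyNA(e)) {
      nbi_stop("incomplete-ledger",
               sprintf("role %s missing for motif(s): %s", role,
                       paste(ids[is.na(e)], collapse = ", ")))
    }
    e
  }
  de_gas <- supramolecular_delta(role_col("dimer_AB"),
                                 role_col("monoA_ghostB"),
                                 role_col("monoB_ghostA")) *
    HARTREE_TO_KCAL
  srow <- match(ids, solvation$motif_id)
  if (anyNA(srow)) {
    nbi_stop("incomplete-ledger",
             sprintf("solvation table lacks motif(s): %s",
                     paste(ids[is.na(srow)], collapse = ", ")))
  }
  de_deh <- dehydration(solvation$g_sol_ab[srow], solvation$g_sol_a[srow],
                        solvation$g_sol_b[srow])
  data.frame(motif_id = ids, dE_gas = de_gas, dE_deh = de_deh,
             dE_aq = aqueous(de_gas, de_deh), stringsAsFactors = FALSE,
             row.names = NULL)
}
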