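#' Build an atom table
#'
#' Constructs the atom data frame used throughout the package. Coordinates
#' are Cartesian, in Angstrom.
#'
#' @param element Chemical symbols.
#' @param x,y,z Coordinates in Angstrom.
#' @param name PDB atom names; defaults to the element symbols.
#' @param res_name Three-letter residue/ligand code.
#' @param res_seq Integer residue number.
#' @param occupancy Occupancy fraction.
#' @param altloc Alternate-location indicator ("" when absent).
#' @return A data frame with one row per atom.
#' @export
atom_table <- function(element, x, y, z, name = element, res_name = "UNK",
                       res_seq = 1L, occupancy = 1, altloc = "") {
  stopifnot(length(x) == length(element), length(y) == length(element),
            length(z) == length(element))
  if (!all(is.finite(c(x, y, z)))) {
    nbi_stop("invalid-coordinates", "atom coordinates must be finite")
  }
  bad <- setdiff(unique(element), names(COVALENT_RADII))
  if (length(bad)) {
    nbi_stop("unknown-element",
             sprintf("unrecognized element symbol(s): %s",
                     paste(bad, collapse = ", ")))
  }
  data.frame(element = element, name = name,
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             res_name = res_name, res_seq = as.integer(res_seq),
             occupancy = as.numeric(occupancy), altloc = altloc,
             stringsAsFactors = FALSE)
}

#' Build a monomer
#'
#' A monomer is one of the two interacting partners of a motif: either the
#' extracted ligand functional group or a single protein residue.
#'
#' @param role `"ligand-fragment"` or `"residue"`.
#' @param label Ligand three-letter ID or residue ID (e.g. `"2A6"`, `"A31"`).
#' @param atoms Atom table (see [atom_table()]).
#' @param formal_charge Integer formal charge in elementary charges.
#' @param multiplicity Spin multiplicity (1 for all packaged motifs).
#' @return An object of class `nbi_monomer`.
#' @export
monomer <- function(role = c("ligand-fragment", "residue"), label, atoms,
                    formal_charge = 0L, multiplicity = 1L) {
  role <- match.arg(role)
  if (nrow(atoms) == 0L) {
    nbi_stop("empty-monomer", sprintf("monomer '%s' has no atoms", label))
  }
  structure(list(role = role, label = label, atoms = atoms,
                 formal_charge = as.integer(formal_charge),
                 multiplicity = as.integer(multiplicity)),
            class = "nbi_monomer")
}

#' Build a two-monomer interaction motif
#'
#' @param monomer_a,monomer_b The two partners ([monomer()]); by convention
#'   A is the ligand fragment and B the residue.
#' @param mode Interaction mode label or `NA` when not yet classified.
#' @param pdb_id Four-character PDB code of the parent complex, or `NA`.
#' @param motif_no Motif number in the reference library (1-49), or `NA`.
#' @return An object of class `nbi_motif`.
#' @export
motif_record <- function(monomer_a, monomer_b, mode = NA_character_,
                         pdb_id = NA_character_, motif_no = NA_integer_) {
  stopifnot(inherits(monomer_a, "nbi_monomer"),
            inherits(monomer_b, "nbi_monomer"))
  if (!is.na(mode) && !mode %in% interaction_modes()) {
    nbi_stop("unknown-mode", sprintf("unknown interaction mode '%s'", mode))
  }
  structure(list(monomers = list(A = monomer_a, B = monomer_b),
                 mode = mode, pdb_id = pdb_id,
                 motif_no = as.integer(motif_no)),
            class = "nbi_motif")
}

#' @export
print.nbi_motif <- function(x, ...) {
  cat(sprintf("<nbi_motif> mode=%s pdb=%s\n", x$mode, x$pdb_id))
  for (id in c("A", "B")) {
    m <- x$monomers[[id]]
    cat(sprintf("  %s %-15s %-12s %3d atoms  charge %+d  mult %d\n",
                id, m$label, m$role, nrow(m$atoms), m$formal_charge,
                m$multiplicity))
  }
  invisible(x)
}

# resolve alternate locations: one copy per (res_name, res_seq, atom name),
# keeping the highest occupancy; ties broken toward altloc 'A' (blank counts
# as 'A')
resolve_altloc <- function(atoms) {
  if (nrow(atoms) == 0L) return(atoms)
  key <- paste(atoms$res_name, atoms$res_seq, atoms$name, sep = "|")
  alt_rank <- ifelse(atoms$altloc %in% c("", "A"), 0L,
                     match(atoms$altloc, LETTERS))
  ord <- order(key, -atoms$occupancy, alt_rank)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Parse a two-monomer motif from PDB-format text
#'
#' Extracts the ligand fragment (HETATM records matching `ligand_code`) and a
#' single residue (ATOM records at `residue_seq`) from one chain of a
#' PDB-format fragment. Alternate locations are resolved to the highest
#' occupancy copy (ties toward altloc 'A'); hydrogens are retained when
#' present. Residue numbering is taken as-is from the file.
#'
#' @param text PDB-format content as a single string or character vector of
#'   lines. Alternatively a path to a PDB file via `file`.
#' @param ligand_code Three-letter ligand ID carried by the HETATM records.
#' @param residue_seq Integer residue number of the interacting residue.
#' @param chain Chain identifier (default `"A"`, the convention for the
#'   packaged motif library).
#' @param file Optional path; used instead of `text` when given.
#' @param ligand_charge,residue_charge Formal charges to assign to the two
#'   monomers (elementary charges).
#' @return An [motif_record()] with monomer A the ligand fragment and
#'   monomer B the residue.
#' @export
parse_motif_pdb <- function(text = NULL, ligand_code, residue_seq,
                            chain = "A", file = NULL,
                            ligand_charge = 0L, residue_charge = 0L) {
  if (is.null(file)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(paste(text, collapse = "\n"), file)
  }
  pdb <- bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  miss <- is.na(elem) | !nzchar(trimws(elem))
  elem[miss] <- guess_element(at$elety[miss])
  elem <- paste0(toupper(substr(trimws(elem), 1, 1)),
                 tolower(substr(trimws(elem), 2, 2)))
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1

  atoms <- data.frame(element = elem, name = trimws(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      res_name = trimws(at$resid), res_seq = at$resno,
                      occupancy = occ, altloc = alt,
                      type = at$type, chain = at$chain,
                      stringsAsFactors = FALSE)

  lig <- atoms[atoms$type == "HETATM" & atoms$res_name == ligand_code &
                 atoms$chain %in% chain, , drop = FALSE]
  res <- atoms[atoms$type == "ATOM" & atoms$res_seq == residue_seq &
                 atoms$chain %in% chain, , drop = FALSE]
  if (nrow(lig) == 0L) {
    nbi_stop("monomer-not-found",
             sprintf("no HETATM records for ligand '%s' on chain %s",
                     ligand_code, chain))
  }
  if (nrow(res) == 0L) {
    nbi_stop("monomer-not-found",
             sprintf("no ATOM records for residue %d on chain %s",
                     residue_seq, chain))
  }
  lig <- resolve_altloc(lig)
  res <- resolve_altloc(res)
  if (nrow(lig) == 0L || nrow(res) == 0L) {
    nbi_stop("empty-monomer", "no atoms left after altloc filtering")
  }

  res_code <- unname(AA_321[res$res_name[1]])
  res_label <- paste0(if (is.na(res_code)) res$res_name[1] else res_code,
                      residue_seq)
  keep <- c("element", "name", "x", "y", "z", "res_name", "res_seq",
            "occupancy", "altloc")
  motif_record(
    monomer("ligand-fragment", ligand_code, lig[, keep],
            formal_charge = ligand_charge),
    monomer("residue", res_label, res[, keep],
            formal_charge = residue_charge)
  )
}

#' Write a motif as PDB-format text
#'
#' Monomer A is written as HETATM records, monomer B as ATOM records, both on
#' chain A. Coordinates are quantized to the fixed-width PDB precision of
#' three decimal places.
#'
#' @param motif An [motif_record()].
#' @param file Optional path to write to; when `NULL` the text is returned.
#' @return Character vector of PDB lines (invisibly when `file` is given).
#' @export
write_motif_pdb <- function(motif, file = NULL) {
  tmp <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  a <- motif$monomers$A$atoms
  b <- motif$monomers$B$atoms
  all_at <- rbind(a, b)
  type <- c(rep("HETATM", nrow(a)), rep("ATOM", nrow(b)))
  resno <- c(rep(a$res_seq[1], nrow(a)), rep(b$res_seq[1], nrow(b)))
  resid <- c(rep(a$res_name[1], nrow(a)), rep(b$res_name[1], nrow(b)))
  bio3d::write.pdb(file = tmp,
                   xyz = as.vector(t(coords_of(all_at))),
                   type = type, resno = resno, resid = resid,
                   eleno = seq_len(nrow(all_at)), elety = all_at$name,
                   chain = rep("A", nrow(all_at)),
                   o = all_at$occupancy, b = rep(0, nrow(all_at)),
                   elesy = all_at$element)
  lines <- readLines(tmp)
  if (is.null(file)) {
    unlink(tmp)
    lines
  } else {
    invisible(lines)
  }
}
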