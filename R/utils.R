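#' @keywords internal
"_PACKAGE"

## unit constants: coordinates are carried in Angstrom, quantum energies in
## hartree; reports are in kcal/mol
HARTREE_TO_KCAL <- 627.509
ANGSTROM_TO_BOHR <- 1 / 0.52917721067

#' @importFrom stats rnorm runif sd setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

# classed error so callers can dispatch on machine-readable codes
# ("monomer-not-found" -> class nbibench_monomer_not_found)
nbi_stop <- function(code, message, call = sys.call(-1)) {
  cls <- paste0("nbibench_", gsub("-", "_", code, fixed = TRUE))
  stop(errorCondition(message, class = c(cls, "nbibench_error"),
                      call = call))
}

#' Canonical nonbonded interaction mode labels
#'
#' The five interaction modes recognised throughout the package, in the
#' order used for reporting: CH-pi, pi-pi stacking, cation-pi, hydrogen
#' bond, and salt bridge.
#'
#' @return Character vector of the five mode labels.
#' @export
interaction_modes <- function() {
  c("CH-pi", "pi-pi", "cation-pi", "H-bond", "salt-bridge")
}

## covalent radii in Angstrom (single-bond radii), used for bond perception
## and D3-style coordination counting
COVALENT_RADII <- c(
  H = 0.32, B = 0.85, C = 0.75, N = 0.71, O = 0.63, F = 0.64,
  Na = 1.55, Mg = 1.39, Si = 1.16, P = 1.11, S = 1.03, Cl = 0.99,
  K = 1.96, Ca = 1.71, Br = 1.14, I = 1.33
)

HEAVY_ELEMENTS <- c("C", "N", "O")

covalent_radius <- function(element) {
  r <- COVALENT_RADII[element]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    nbi_stop("unknown-element",
             sprintf("no covalent radius for element(s): %s",
                     paste(bad, collapse = ", ")))
  }
  unname(r)
}

AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

TWO_LETTER_ELEMENTS <- c("CL", "BR", "NA", "MG", "SI", "CA", "FE", "ZN", "SE")

# derive an element symbol from a PDB atom name when the element column is
# absent; strips leading digits, then prefers recognised two-letter symbols
guess_element <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9'\\*]", "", trimws(nm))
    if (nchar(nm) == 0L) return(NA_character_)
    two <- toupper(substr(nm, 1, 2))
    if (nchar(nm) >= 2L && two %in% TWO_LETTER_ELEMENTS) {
      return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
    }
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

coords_of <- function(atoms) {
  unname(as.matrix(atoms[, c("x", "y", "z"), drop = FALSE]))
}

# rotation matrices about the coordinate axes; theta in radians
rot_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), -sin(theta),
           0, sin(theta), cos(theta)), 3, 3, byrow = TRUE)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# uniform random rotation (QR of a Gaussian matrix, sign-fixed)
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_m <- qr(m)
  q <- qr.Q(qr_m)
  q <- q %*% diag(sign(diag(qr.R(qr_m))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(xyz, rotation = diag(3), translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, translation, "+")
}
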