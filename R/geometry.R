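#' Perceive covalent bonds from interatomic distances
#'
#' PDB fragments carry no connectivity, so bonds are inferred geometrically:
#' two atoms are bonded iff their distance does not exceed 1.3 times the sum
#' of their covalent radii.
#'
#' @param atoms Atom table ([atom_table()]).
#' @return Data frame with columns `i`, `j` (atom row indices, `i < j`) and
#'   `dist` (Angstrom). Symmetric by construction; no self bonds.
#' @export
perceive_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 1L) nbi_stop("empty-monomer", "at least one atom required")
  radii <- covalent_radius(atoms$element)
  if (n == 1L) {
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  d <- as.matrix(stats::dist(coords_of(atoms)))
  cutoff <- outer(radii, radii, "+") * 1.3
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  out <- data.frame(i = hit[, 1], j = hit[, 2], dist = d[hit])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# least-squares plane of a set of points: centroid, unit normal (smallest
# singular direction), and RMS out-of-plane deviation
ls_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  centered <- sweep(xyz, 2, ctr)
  sv <- svd(centered)
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  rms <- sqrt(mean((centered %*% normal)^2))
  list(centroid = ctr, unit_normal = normal, planarity_rms = rms)
}

ring_descriptor <- function(atoms, members) {
  pl <- ls_plane(coords_of(atoms[members, , drop = FALSE]))
  structure(list(member_atoms = members, centroid = pl$centroid,
                 unit_normal = pl$unit_normal,
                 planarity_rms = pl$planarity_rms),
            class = "nbi_ring")
}

# unique 5- and 6-cycles of the bond graph: for every edge, the shortest
# cycle through it (edge + shortest path in the graph minus that edge)
small_cycles <- function(bonds, n_atoms) {
  if (nrow(bonds) == 0L) return(list())
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_atoms - igraph::vcount(g)))
  seen <- character(0)
  cycles <- list()
  for (k in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, c(bonds$i[k], bonds$j[k])))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = bonds$i[k], to = bonds$j[k]))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) %in% c(5L, 6L)) {
      key <- paste(sort(path), collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        cycles[[length(cycles) + 1L]] <- path
      }
    }
  }
  cycles
}

#' Find aromatic rings in a monomer
#'
#' Rings are 5- or 6-cycles of the perceived bond graph whose member atoms
#' are ring-forming elements (C, N, O, S) and fit a least-squares plane with
#' RMS deviation at most 0.1 Angstrom. Fragments carry no bond orders, so
#' planarity is the aromaticity signal.
#'
#' @param mono A [monomer()] or an atom table.
#' @return List of ring descriptors, each with `member_atoms` (row indices),
#'   `centroid`, `unit_normal` (unit length) and `planarity_rms` (Angstrom).
#'   Empty list when no ring is found.
#' @export
find_aromatic_rings <- function(mono) {
  atoms <- if (inherits(mono, "nbi_monomer")) mono$atoms else mono
  bonds <- perceive_bonds(atoms)
  cycles <- small_cycles(bonds, nrow(atoms))
  out <- list()
  for (cyc in cycles) {
    if (!all(atoms$element[cyc] %in% c("C", "N", "O", "S"))) next
    rd <- ring_descriptor(atoms, cyc)
    if (rd$planarity_rms <= 0.1) out[[length(out) + 1L]] <- rd
  }
  out
}

#' Closest heavy-atom distance between the two monomers
#'
#' Minimum cross-monomer distance restricted to C, N and O atoms (the
#' element set used for the reference library's distance column; S and
#' halogens are excluded).
#'
#' @param motif An [motif_record()].
#' @return Distance in Angstrom.
#' @export
closest_heavy_distance <- function(motif) {
  a <- motif$monomers$A$atoms
  b <- motif$monomers$B$atoms
  ha <- a[a$element %in% HEAVY_ELEMENTS, , drop = FALSE]
  hb <- b[b$element %in% HEAVY_ELEMENTS, , drop = FALSE]
  if (nrow(ha) == 0L || nrow(hb) == 0L) {
    nbi_stop("no-heavy-atoms",
             "both monomers must contain at least one C, N or O atom")
  }
  min(cross_distances(coords_of(ha), coords_of(hb)))
}

cross_distances <- function(xa, xb) {
  sq <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(pmax(sq, 0))
}

#' Angle between two ring planes
#'
#' Arc-cosine of the absolute dot product of the two unit normals, in
#' degrees, folded to \[0, 90\]. Symmetric in its arguments and invariant
#' under rigid motions of the motif.
#'
#' @param ring_a,ring_b Ring descriptors from [find_aromatic_rings()].
#' @return Angle in degrees.
#' @export
plane_angle <- function(ring_a, ring_b) {
  d <- abs(sum(ring_a$unit_normal * ring_b$unit_normal))
  acos(min(1, d)) * 180 / pi
}

#' Hydrogen-bond geometry between the two monomers
#'
#' Enumerates donor-H...acceptor triples with the donor (N, O or S bearing a
#' covalently bonded hydrogen) on one monomer and the acceptor (N or O) on
#' the other, subject to a donor-acceptor distance of at most 3.5 Angstrom
#' and a D-H...A angle of at least 120 degrees.
#'
#' @param motif An [motif_record()]; hydrogens must be present on donors.
#' @return Data frame with columns `dha_angle` (degrees) and `da_distance`
#'   (Angstrom), sorted by descending angle. Zero rows when no triple
#'   qualifies.
#' @export
hbond_geometry <- function(motif) {
  a <- motif$monomers$A$atoms
  b <- motif$monomers$B$atoms
  if (!any(c(a$element, b$element) == "H")) {
    nbi_stop("hydrogens-required",
             "hydrogen-bond geometry requires hydrogens on donors")
  }
  res <- rbind(hbond_scan(a, b), hbond_scan(b, a))
  res <- res[order(-res$dha_angle), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# donor side `don`, acceptor side `acc`
hbond_scan <- function(don, acc) {
  out <- data.frame(dha_angle = numeric(0), da_distance = numeric(0))
  acc_idx <- which(acc$element %in% c("N", "O"))
  if (length(acc_idx) == 0L) return(out)
  bonds <- perceive_bonds(don)
  if (nrow(bonds) == 0L) return(out)
  is_h <- don$element == "H"
  is_don_elem <- don$element %in% c("N", "O", "S")
  dh <- rbind(
    data.frame(d = bonds$i[is_don_elem[bonds$i] & is_h[bonds$j]],
               h = bonds$j[is_don_elem[bonds$i] & is_h[bonds$j]]),
    data.frame(d = bonds$j[is_h[bonds$i] & is_don_elem[bonds$j]],
               h = bonds$i[is_h[bonds$i] & is_don_elem[bonds$j]])
  )
  if (nrow(dh) == 0L) return(out)
  xd <- coords_of(don)
  xa <- coords_of(acc)
  for (k in seq_len(nrow(dh))) {
    dpos <- xd[dh$d[k], ]
    hpos <- xd[dh$h[k], ]
    for (ai in acc_idx) {
      apos <- xa[ai, ]
      da <- sqrt(sum((apos - dpos)^2))
      if (da > 3.5) next
      v1 <- dpos - hpos
      v2 <- apos - hpos
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= 120) {
        out <- rbind(out, data.frame(dha_angle = ang, da_distance = da))
      }
    }
  }
  out
}

#' Classify the interaction mode of a motif
#'
#' Decision cascade, first match wins: (1) salt bridge when the monomers
#' carry charges +1/-1 and the closest charged-group heavy-atom (N/O)
#' distance is at most 5.5 Angstrom; (2) cation-pi when one monomer carries
#' +1 with a nitrogen within 6.0 Angstrom of an aromatic ring centroid of
#' the other; (3) hydrogen bond when at least one donor-H...acceptor triple
#' passes the [hbond_geometry()] thresholds; (4) pi-pi when both monomers
#' carry aromatic rings with centroid-centroid distance at most 5.5
#' Angstrom; (5) CH-pi when an aliphatic C-H hydrogen lies within 3.5
#' Angstrom of a ring centroid of the other monomer. Charged interactions
#' are tested first because they dominate energetically.
#'
#' @param motif An [motif_record()] with formal charges assigned.
#' @return One of [interaction_modes()] or `"unclassified"`.
#' @export
classify_mode <- function(motif) {
  a <- motif$monomers$A
  b <- motif$monomers$B
  charges <- sort(c(a$formal_charge, b$formal_charge))

  rings_a <- find_aromatic_rings(a)
  rings_b <- find_aromatic_rings(b)

  ## 1. salt bridge
  if (identical(charges, c(-1L, 1L))) {
    if (isTRUE(charged_group_distance(a$atoms, b$atoms) <= 5.5)) {
      return("salt-bridge")
    }
  }

  ## 2. cation-pi
  cat_mon <- if (a$formal_charge == 1L && b$formal_charge == 0L) {
    list(cat = a, other_rings = rings_b)
  } else if (b$formal_charge == 1L && a$formal_charge == 0L) {
    list(cat = b, other_rings = rings_a)
  } else NULL
  if (!is.null(cat_mon) && length(cat_mon$other_rings)) {
    n_xyz <- coords_of(
      cat_mon$cat$atoms[cat_mon$cat$atoms$element == "N", , drop = FALSE])
    if (nrow(n_xyz)) {
      cent <- do.call(rbind, lapply(cat_mon$other_rings, `[[`, "centroid"))
      if (min(cross_distances(n_xyz, cent)) <= 6.0) return("cation-pi")
    }
  }

  ## 3. hydrogen bond
  hb <- tryCatch(hbond_geometry(motif), nbibench_hydrogens_required =
                   function(e) NULL)
  if (!is.null(hb) && nrow(hb) > 0L) return("H-bond")

  ## 4. pi-pi stacking
  if (length(rings_a) && length(rings_b)) {
    ca <- do.call(rbind, lapply(rings_a, `[[`, "centroid"))
    cb <- do.call(rbind, lapply(rings_b, `[[`, "centroid"))
    if (min(cross_distances(ca, cb)) <= 5.5) return("pi-pi")
  }

  ## 5. CH-pi
  if (chpi_contact(a, rings_b) || chpi_contact(b, rings_a)) return("CH-pi")

  "unclassified"
}

# minimum N/O cross distance between the charged groups; falls back to the
# C/N/O closest distance when one side has no N/O
charged_group_distance <- function(atoms_a, atoms_b) {
  pa <- atoms_a[atoms_a$element %in% c("N", "O"), , drop = FALSE]
  pb <- atoms_b[atoms_b$element %in% c("N", "O"), , drop = FALSE]
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    pa <- atoms_a[atoms_a$element %in% HEAVY_ELEMENTS, , drop = FALSE]
    pb <- atoms_b[atoms_b$element %in% HEAVY_ELEMENTS, , drop = FALSE]
  }
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(NA_real_)
  min(cross_distances(coords_of(pa), coords_of(pb)))
}

# TRUE when an aliphatic (non-ring) C-H hydrogen of `mono` is within 3.5 A
# of a ring centroid of the other monomer
chpi_contact <- function(mono, other_rings) {
  if (!length(other_rings)) return(FALSE)
  atoms <- mono$atoms
  if (!any(atoms$element == "H")) return(FALSE)
  bonds <- perceive_bonds(atoms)
  if (nrow(bonds) == 0L) return(FALSE)
  ring_members <- unlist(lapply(find_aromatic_rings(mono), `[[`,
                                "member_atoms"))
  is_c <- atoms$element == "C" & !(seq_len(nrow(atoms)) %in% ring_members)
  is_h <- atoms$element == "H"
  h_on_c <- unique(c(bonds$j[is_c[bonds$i] & is_h[bonds$j]],
                     bonds$i[is_h[bonds$i] & is_c[bonds$j]]))
  if (length(h_on_c) == 0L) return(FALSE)
  cent <- do.call(rbind, lapply(other_rings, `[[`, "centroid"))
  min(cross_distances(coords_of(atoms)[h_on_c, , drop = FALSE],
                      cent)) <= 3.5
}

#' Geometric descriptor report for a motif
#'
#' Measures the descriptors used by the reference library: interaction mode,
#' closest C/N/O cross-monomer distance, the angle between ring planes for
#' pi-pi motifs, and donor-H...acceptor angles/distances for hydrogen-bond
#' motifs.
#'
#' @param motif An [motif_record()].
#' @return List of class `nbi_geometry_report` with fields `mode`,
#'   `closest_heavy_distance`, `plane_angle` (or `NA`), and `hbonds` (data
#'   frame, possibly empty).
#' @export
geometry_report <- function(motif) {
  mode <- classify_mode(motif)
  dist <- closest_heavy_distance(motif)
  pa <- NA_real_
  if (mode == "pi-pi") {
    rings_a <- find_aromatic_rings(motif$monomers$A)
    rings_b <- find_aromatic_rings(motif$monomers$B)
    pa <- plane_angle(rings_a[[1]], rings_b[[1]])
  }
  hb <- data.frame(dha_angle = numeric(0), da_distance = numeric(0))
  if (mode == "H-bond") hb <- hbond_geometry(motif)
  structure(list(mode = mode, closest_heavy_distance = dist,
                 plane_angle = pa, hbonds = hb),
            class = "nbi_geometry_report")
}

#' @export
print.nbi_geometry_report <- function(x, ...) {
  cat(sprintf("<geometry report> mode=%s  closest C/N/O distance %.2f A\n",
              x$mode, x$closest_heavy_distance))
  if (!is.na(x$plane_angle)) {
    cat(sprintf("  plane angle %.2f deg\n", x$plane_angle))
  }
  if (nrow(x$hbonds)) {
    for (k in seq_len(nrow(x$hbonds))) {
      cat(sprintf("  H-bond %d: D-H...A %.1f deg, D...A %.2f A\n",
                  k, x$hbonds$dha_angle[k], x$hbonds$da_distance[k]))
    }
  }
  invisible(x)
}
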