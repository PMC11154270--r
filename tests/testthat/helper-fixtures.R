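# Shared fixture builders and independent oracles. Everything here is
# constructed in code at test time; no binary fixtures.

KCAL <- 627.509
BOHR <- 1 / 0.52917721067

# planar fused 6+5 ring system (indole-like skeleton, no hydrogens):
# regular hexagon of side 1.40 A plus a regular pentagon sharing one edge
indole_atoms <- function() {
  s <- 1.40
  hex <- t(vapply(seq(0, 300, by = 60) * pi / 180,
                  function(a) s * c(cos(a), sin(a)), numeric(2)))
  c1 <- hex[1, ]                      # shared edge c1-c2
  c2 <- hex[2, ]
  mid <- (c1 + c2) / 2
  u <- mid / sqrt(sum(mid^2))         # outward perpendicular direction
  r5 <- s / (2 * sin(36 * pi / 180))
  a5 <- r5 * cos(36 * pi / 180)
  ctr5 <- mid + a5 * u
  th1 <- atan2(c1[2] - ctr5[2], c1[1] - ctr5[1])
  pent_new <- t(vapply(th1 + (1:3) * 72 * pi / 180,
                       function(a) ctr5 + r5 * c(cos(a), sin(a)),
                       numeric(2)))
  xy <- rbind(hex, pent_new)
  atom_table(element = c(rep("C", 6), "N", "C", "C"),
             x = xy[, 1], y = xy[, 2], z = rep(0, 9),
             name = paste0("R", seq_len(9)))
}

# alanine-like residue heavy atoms (acyclic, 5 heavy atoms)
alanine_atoms <- function(res_seq = 31L) {
  atom_table(element = c("N", "C", "C", "O", "C"),
             x = c(0, 1.46, 2.02, 3.23, 2.02),
             y = c(0, 0, 1.33, 1.52, -0.73),
             z = c(0, 0, 0, 0, 1.23),
             name = c("N", "CA", "C", "O", "CB"),
             res_name = "ALA", res_seq = res_seq)
}

rigid_motif <- function(motif, rotation, translation) {
  for (id in c("A", "B")) {
    at <- motif$monomers[[id]]$atoms
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rotation)
    xyz <- sweep(xyz, 2, translation, "+")
    motif$monomers[[id]]$atoms$x <- xyz[, 1]
    motif$monomers[[id]]$atoms$y <- xyz[, 2]
    motif$monomers[[id]]$atoms$z <- xyz[, 3]
  }
  motif
}

rigid_atoms <- function(atoms, rotation, translation) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}

random_rot <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent naive dispersion oracle: explicit double loops over all
# ordered atom pairs (-1/2 sum over A != B) and explicit loops over all
# reference-point combinations for the C6 interpolation
naive_d3 <- function(atoms, params, refdata) {
  n <- nrow(atoms)
  if (n < 2L) return(0)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rcov <- refdata$rcov[atoms$element]
  cn <- numeric(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      r <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      cn[a] <- cn[a] +
        1 / (1 + exp(-16 * (4 / 3 * (rcov[a] + rcov[b]) / r - 1)))
    }
  }
  c6_of <- function(ea, eb, ca, cb) {
    ra <- refdata$refs[refdata$refs$elem == ea, ]
    rb <- refdata$refs[refdata$refs$elem == eb, ]
    num <- 0
    den <- 0
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(rb))) {
        w <- exp(-4 * ((ca - ra$cn[i])^2 + (cb - rb$cn[j])^2))
        num <- num + w * sqrt(ra$c6[i] * rb$c6[j])
        den <- den + w
      }
    }
    num / den
  }
  e <- 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      r <- sqrt(sum((xyz[a, ] - xyz[b, ])^2)) * BOHR
      c6 <- c6_of(atoms$element[a], atoms$element[b], cn[a], cn[b])
      c8 <- 3 * c6 * sqrt(refdata$r4r2[[atoms$element[a]]] *
                            refdata$r4r2[[atoms$element[b]]])
      f0 <- params$a1 * sqrt(c8 / c6) + params$a2
      e <- e - 0.5 * (params$s6 * c6 / (r^6 + f0^6) +
                        params$s8 * c8 / (r^8 + f0^8))
    }
  }
  e * KCAL
}
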