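# Internal 3D geometry helpers: dihedrals, bend angles, NeRF atom placement,
# and least-squares superposition. All angles in degrees; IUPAC sign for
# torsions (right-handed).

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

# IUPAC torsion p1-p2-p3-p4; returns degrees in (-180, 180], 0 if degenerate
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) return(0)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * b2) / vnorm(b2)
  atan2(y, x) * 180 / pi
}

# bend angle at p2 over p1, p2, p3 in [0, 180]
bend_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  d <- vnorm(v1) * vnorm(v2)
  if (d < 1e-12) return(0)
  cc <- sum(v1 * v2) / d
  acos(min(1, max(-1, cc))) * 180 / pi
}

# place atom D from A, B, C with |CD| = bond, angle(BCD) = ang (deg),
# torsion(ABCD) = tor (deg); natural extension reference frame
place_atom <- function(a, b, c3, bond, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  bc <- c3 - b; bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc); n <- n / vnorm(n)
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c3 + d[1] * bc + d[2] * m + d[3] * n
}

# full-backbone builder from phi/psi (degrees); returns n x 3 Ca matrix.
# standard ideal internal coordinates, omega fixed trans.
build_ca_from_torsions <- function(phi, psi) {
  n <- length(phi)
  stopifnot(n == length(psi), n >= 1)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bNCA, 0, 0)
  th <- aNCAC * pi / 180
  C[1, ] <- CA[1, ] + c(-bCAC * cos(th), bCAC * sin(th), 0)
  if (n > 1) for (i in 2:n) {
    N[i, ]  <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bCN, aCACN, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], bNCA, aCNCA, 180)
    C[i, ]  <- place_atom(C[i - 1, ], N[i, ], CA[i, ], bCAC, aNCAC, phi[i])
  }
  CA
}

# Rigid superposition (least squares, via bio3d): returns `mobile` (m x 3)
# transformed so that its rows `mob_idx` best fit `fixed` rows `fix_idx`.
superpose_onto <- function(fixed, mobile, fix_idx, mob_idx) {
  stopifnot(length(fix_idx) == length(mob_idx), length(fix_idx) >= 3)
  moved <- bio3d::fit.xyz(fixed = as.vector(t(fixed)),
                          mobile = as.vector(t(mobile)),
                          fixed.inds = bio3d::atom2xyz(fix_idx),
                          mobile.inds = bio3d::atom2xyz(mob_idx))
  matrix(moved, ncol = 3, byrow = TRUE)
}

rmsd_xyz <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}
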