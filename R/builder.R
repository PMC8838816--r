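# Construction of ideal CG cellulose chains and fibrils.
#
# A chain is an exact 2-fold screw along z: residue i is the base residue
# rotated by 180*i degrees about the screw axis and translated by i*rise.
# This symmetry fixes most of the geometry directly from the bonded table:
#   - the 2nd-neighbour distance of every site is exactly 2*rise, so
#     rise = r0(2nd)/2 (and the three 2nd-neighbour r0 must be equal);
#   - the 1st-neighbour distance of site a is sqrt(4*rho_a^2 + rise^2),
#     where rho_a is the site's radial distance from the screw axis, so the
#     1st-neighbour r0 fix rho(O2), rho(O3), rho(C6);
#   - the six intra-residue distances close the system up to one leftover
#     orientational degree of freedom (the height of O3 above O2 along the
#     axis), which is fixed by requiring the junction twist dihedral
#     (O2_i, C6_i, C6_{i+1}, O2_{i+1}) of the ideal chain to be exactly 0:
#     the built chain is untwisted.
# O6 carries no inter-residue bonds and is placed by trilateration from its
# three intra-residue distances (fixed branch; the choice sets the chain's
# handedness).

.crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# signed dihedral (degrees) of four points, atan2 convention
.dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .crossv(b1, b2); n2 <- .crossv(b2, b3)
  m1 <- .crossv(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# pull a named list of the 10 independent r0 values out of a bonded table
.bondedR0 <- function(bonded) {
  get1 <- function(lab, nb) {
    v <- bonded$r0[bonded$label == lab & bonded$neighbours == nb]
    if (length(v) != 1L)
      stop(sprintf("bonded table needs exactly one (%s, %s) entry", lab, nb))
    v
  }
  s2 <- c(get1("O2-O2", "2nd"), get1("O3-O3", "2nd"), get1("C6-C6", "2nd"))
  if (max(s2) - min(s2) > 1e-9)
    stop("the three 2nd-neighbour r0 must be equal (they are all 2*rise ",
         "under the chain's screw symmetry)")
  list(d23 = get1("O2-O3", "none"), d2C = get1("O2-C6", "none"),
       d3C = get1("O3-C6", "none"), dC6 = get1("C6-O6", "none"),
       d26 = get1("O2-O6", "none"), d36 = get1("O3-O6", "none"),
       f22 = get1("O2-O2", "1st"), f33 = get1("O3-O3", "1st"),
       fCC = get1("C6-C6", "1st"), s22 = s2[1])
}

# base residue (4 x 3, rows O2,O3,C6,O6) for a given O3 height s, or NULL
.baseForS <- function(s, rr, rho1, rho2, rho3, a3_bracket) {
  ca2 <- (rho1^2 + rho2^2 + s^2 - rr$d23^2) / (2 * rho1 * rho2)
  if (abs(ca2) > 1) return(NULL)
  a2 <- -acos(ca2)
  E1 <- function(a3) rr$d2C^2 - rho1^2 - rho3^2 + 2 * rho1 * rho3 * cos(a3)
  E2 <- function(a3) rr$d3C^2 - rho2^2 - rho3^2 + 2 * rho2 * rho3 * cos(a3 - a2)
  f <- function(a3) {
    z3 <- (E1(a3) - E2(a3) + s^2) / (2 * s)
    z3^2 - E1(a3)
  }
  lo <- f(a3_bracket[1]); hi <- f(a3_bracket[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) return(NULL)
  a3 <- stats::uniroot(f, a3_bracket, tol = 1e-14)$root
  z3 <- (E1(a3) - E2(a3) + s^2) / (2 * s)
  O2 <- c(rho1, 0, 0)
  O3 <- c(rho2 * cos(a2), rho2 * sin(a2), s)
  C6 <- c(rho3 * cos(a3), rho3 * sin(a3), z3)
  # trilaterate O6 from O2, O3, C6 (positive branch of the local frame)
  ex <- (O3 - O2) / sqrt(sum((O3 - O2)^2))
  i1 <- sum(ex * (C6 - O2))
  ey <- C6 - O2 - i1 * ex
  ey <- ey / sqrt(sum(ey^2))
  ez <- .crossv(ex, ey)
  d <- sqrt(sum((O3 - O2)^2))
  j1 <- sum(ey * (C6 - O2))
  x <- (rr$d26^2 - rr$d36^2 + d^2) / (2 * d)
  y <- (rr$d26^2 - rr$dC6^2 + i1^2 + j1^2 - 2 * i1 * x) / (2 * j1)
  z2 <- rr$d26^2 - x^2 - y^2
  if (z2 < 0) return(NULL)
  O6 <- O2 + x * ex + y * ey + sqrt(z2) * ez
  out <- rbind(O2 = O2, O3 = O3, C6 = C6, O6 = O6)
  colnames(out) <- c("x", "y", "z")
  out
}

# junction twist of the ideal chain built from a base residue
.baseTwist <- function(base, rise) {
  nxt <- base * rep(c(-1, -1, 1), each = 4)  # C2 about z
  nxt[, 3] <- nxt[, 3] + rise
  .dihedral4(base["O2", ], base["C6", ], nxt["C6", ], nxt["O2", ])
}

# solve the chain geometry for a bonded table; returns list(base, rise)
.chainGeometry <- function(bonded = bondedParameterTable()) {
  rr <- .bondedR0(bonded)
  rise <- rr$s22 / 2
  rad <- function(f) {
    v <- (f^2 - rise^2) / 4
    if (v <= 0) stop("1st-neighbour r0 smaller than the rise; no screw ",
                     "geometry exists for this bonded table")
    sqrt(v)
  }
  rho1 <- rad(rr$f22); rho2 <- rad(rr$f33); rho3 <- rad(rr$fCC)
  a3_bracket <- c(-0.6, 0.6)
  tw <- function(s) {
    b <- .baseForS(s, rr, rho1, rho2, rho3, a3_bracket)
    if (is.null(b)) return(NA_real_)
    .baseTwist(b, rise)
  }
  # locate a sign change of the junction twist along the feasible s range
  smax <- sqrt(max(rr$d23^2 - (rho1 - rho2)^2, 0))
  grid <- seq(-smax + 1e-6, smax - 1e-6, length.out = 241)
  tws <- vapply(grid, tw, 0)
  ok <- which(!is.na(tws))
  bracket <- NULL
  for (idx in seq_along(ok)[-1]) {
    i0 <- ok[idx - 1]; i1 <- ok[idx]
    if (i1 - i0 == 1L && tws[i0] * tws[i1] <= 0 &&
        abs(tws[i0]) < 45 && abs(tws[i1]) < 45) {
      bracket <- c(grid[i0], grid[i1])
      break
    }
  }
  if (is.null(bracket))
    stop("no untwisted chain geometry found for this bonded table")
  s0 <- stats::uniroot(tw, bracket, tol = 1e-13)$root
  base <- .baseForS(s0, rr, rho1, rho2, rho3, a3_bracket)
  list(base = base, rise = rise)
}

# coordinates of an n-residue ideal chain from a geometry, screw along z
.chainCoords <- function(geom, n_residues) {
  out <- matrix(0, n_residues * 4L, 3L)
  for (i in seq_len(n_residues) - 1L) {
    X <- geom$base
    if (i %% 2L == 1L) {
      X[, 1] <- -X[, 1]
      X[, 2] <- -X[, 2]
    }
    X[, 3] <- X[, 3] + i * geom$rise
    out[i * 4L + 1:4, ] <- X
  }
  colnames(out) <- c("x", "y", "z")
  out
}

.beadFrame <- function(n_chains, n_residues) {
  n <- n_chains * n_residues * 4L
  data.frame(
    chain = rep(seq_len(n_chains) - 1L, each = n_residues * 4L),
    residue = rep(rep(seq_len(n_residues) - 1L, each = 4L), n_chains),
    site = rep(.SITE_LEVELS, n_chains * n_residues),
    atom = rep(unname(.SITE_ATOM), n_chains * n_residues),
    type = rep(NA_character_, n),
    mass = rep(NA_real_, n),
    charge = rep(0, n),
    stringsAsFactors = FALSE
  )
}

#' Build an ideal single CG cellulose chain
#'
#' Constructs an n-residue chain with exact ideal geometry: every bonded
#' pair of the elastic network sits exactly at its reference distance, and
#' the chain is untwisted (all junction twist dihedrals are 0).  The fibril
#' axis is z; residues follow a 2-fold screw (each residue is the previous
#' one rotated 180 degrees about the axis and advanced by half the
#' second-neighbour repeat).
#'
#' @param n_residues integer >= 1.
#' @param allomorph \code{"Ialpha"}, \code{"Ibeta"} or \code{"II"}.  The
#'   single-chain geometry is identical for all three (the bonded model is
#'   transferable); the tag records which fibril family the chain belongs
#'   to.
#' @param bonded bonded parameter table (see
#'   \code{\link{bondedParameterTable}}); override to build chains for a
#'   modified elastic network.
#' @return A \linkS4class{FibrilModel} with one chain and
#'   \code{provenance = "built"}.
#' @export
#' @examples
#' ch <- buildChain(5, "Ibeta")
#' nBeads(ch)  # 20
buildChain <- function(n_residues,
                       allomorph = c("Ibeta", "Ialpha", "II"),
                       bonded = bondedParameterTable()) {
  allomorph <- match.arg(allomorph)
  n_residues <- as.integer(n_residues)
  if (length(n_residues) != 1L || is.na(n_residues) || n_residues < 1L)
    stop("n_residues must be a single integer >= 1")
  geom <- .chainGeometry(bonded)
  xyz <- .chainCoords(geom, n_residues)
  box <- diag(c(60, 60, n_residues * geom$rise + 60))
  new("FibrilModel", allomorph = allomorph,
      beads = .beadFrame(1L, n_residues), coords = xyz, box = box,
      provenance = "built")
}

#' Default lattice packing for a fibril allomorph
#'
#' The crystallographic unit cells are not part of the CG model; chains
#' are packed on a simplified rectangular two-direction lattice whose
#' spacings are adapted to the CG bead sizes: sheets of side-by-side chains
#' along x, sheets stacked along y, with a per-sheet axial stagger of a
#' quarter repeat as in the native crystals.  The three allomorphs differ
#' in stagger pattern and chain polarity: Ialpha staggers sheets
#' progressively, Ibeta alternates the stagger, and type II additionally
#' packs alternate sheets antiparallel (the regenerated allomorph).  All
#' values are overridable.
#'
#' @param allomorph \code{"Ialpha"}, \code{"Ibeta"} or \code{"II"}.
#' @return A list with elements \code{dx}, \code{dy} (chain spacings within
#'   and between sheets, Angstrom), \code{shear} (x offset per sheet,
#'   Angstrom), \code{zstag} (axial stagger per sheet, Angstrom),
#'   \code{stagger} (\code{"progressive"} or \code{"alternating"}) and
#'   \code{antiparallel} (logical).
#' @export
#' @examples
#' defaultLattice("II")
defaultLattice <- function(allomorph = c("Ibeta", "Ialpha", "II")) {
  allomorph <- match.arg(allomorph)
  switch(allomorph,
    Ialpha = list(dx = 8.3, dy = 4.6, shear = 0, zstag = 2.61,
                  stagger = "progressive", antiparallel = FALSE),
    Ibeta = list(dx = 8.3, dy = 4.6, shear = 0, zstag = 2.61,
                 stagger = "alternating", antiparallel = FALSE),
    II = list(dx = 8.3, dy = 4.6, shear = 0, zstag = 2.58,
              stagger = "alternating", antiparallel = TRUE)
  )
}

#' Build a CG cellulose fibril on a 2-D lattice
#'
#' Replicates the ideal chain of \code{\link{buildChain}} on an
#' \code{nx * ny} lattice (nx chains per sheet, ny sheets) with
#' allomorph-specific offsets; see \code{\link{defaultLattice}}.
#' Antiparallel sheets (type II) are built by rotating every other sheet's
#' chains 180 degrees about x through their centroid, which reverses the
#' chain direction without changing any internal distance.
#'
#' @param n_chains integer; must equal \code{prod(layout)}.
#' @param layout integer 2-vector \code{c(nx, ny)}.
#' @param n_residues residues per chain.
#' @param allomorph allomorph tag.
#' @param lattice lattice spec, default \code{defaultLattice(allomorph)}.
#' @param bonded bonded parameter table.
#' @return A \linkS4class{FibrilModel}.  An error is raised if any two
#'   beads from different chains are closer than 2 Angstrom (overlapping
#'   lattice).
#' @export
#' @examples
#' fib <- buildFibril(4, c(2, 2), 5, "Ialpha")
#' nBeads(fib)  # 80
buildFibril <- function(n_chains, layout, n_residues,
                        allomorph = c("Ibeta", "Ialpha", "II"),
                        lattice = NULL,
                        bonded = bondedParameterTable()) {
  allomorph <- match.arg(allomorph)
  n_chains <- as.integer(n_chains)
  layout <- as.integer(layout)
  if (n_chains < 1L) stop("n_chains must be >= 1")
  if (length(layout) != 2L || any(layout < 1L) || prod(layout) != n_chains)
    stop("layout must be c(nx, ny) with nx*ny == n_chains")
  if (is.null(lattice)) lattice <- defaultLattice(allomorph)
  geom <- .chainGeometry(bonded)
  one <- .chainCoords(geom, n_residues)
  nb1 <- nrow(one)
  nx <- layout[1]; ny <- layout[2]
  xyz <- matrix(0, n_chains * nb1, 3L)
  cc <- 0L
  zc <- mean(range(one[, 3]))
  for (iy in seq_len(ny) - 1L) {
    flip <- isTRUE(lattice$antiparallel) && iy %% 2L == 1L
    zs <- if (identical(lattice$stagger, "progressive")) iy * lattice$zstag
          else (iy %% 2L) * lattice$zstag
    for (ix in seq_len(nx) - 1L) {
      X <- one
      if (flip) {  # 180 deg about x through the chain centre: antiparallel
        X[, 2] <- -X[, 2]
        X[, 3] <- 2 * zc - X[, 3]
        if (n_residues %% 2L == 1L) {
          # odd chains: an extra half-turn about the chain axis restores
          # the residue-parity interleaving of the reversed chain
          X[, 1] <- -X[, 1]
          X[, 2] <- -X[, 2]
        }
      }
      X[, 1] <- X[, 1] + ix * lattice$dx + iy * lattice$shear
      X[, 2] <- X[, 2] + iy * lattice$dy
      X[, 3] <- X[, 3] + zs
      xyz[cc * nb1 + seq_len(nb1), ] <- X
      cc <- cc + 1L
    }
  }
  colnames(xyz) <- c("x", "y", "z")
  # overlap check between lattice-adjacent chains (the closest by construction)
  if (n_chains > 1L) {
    mind <- .minInterchainDistance(xyz, nb1, nx, ny)
    if (mind < 2)
      stop(sprintf(
        "overlapping lattice spec: interchain bead distance %.3f A < 2 A", mind))
  }
  box <- diag(c(max(xyz[, 1]) - min(xyz[, 1]) + 60,
                max(xyz[, 2]) - min(xyz[, 2]) + 60,
                max(xyz[, 3]) - min(xyz[, 3]) + 60))
  new("FibrilModel", allomorph = allomorph,
      beads = .beadFrame(n_chains, as.integer(n_residues)), coords = xyz,
      box = box, provenance = "built")
}

# minimum bead-bead distance between chains adjacent on the lattice
.minInterchainDistance <- function(xyz, nb1, nx, ny) {
  chainXYZ <- function(ix, iy) xyz[(iy * nx + ix) * nb1 + seq_len(nb1), , drop = FALSE]
  mind <- Inf
  for (iy in seq_len(ny) - 1L) for (ix in seq_len(nx) - 1L) {
    A <- chainXYZ(ix, iy)
    for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
      jx <- ix + d[1]; jy <- iy + d[2]
      if (jx < 0L || jx >= nx || jy >= ny) next
      B <- chainXYZ(jx, jy)
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      mind <- min(mind, sqrt(max(min(d2), 0)))
    }
  }
  mind
}

#' Elastic-network connectivity of built chains
#'
#' Enumerates the bonded pair pattern of the ribbon triangulation for each
#' chain of a model: per residue the six intra-residue pairs, per adjacent
#' residue pair the three 1st-neighbour pairs (O2-O2, O3-O3, C6-C6), and
#' per second-neighbour residue pair the same three site pairs.  The O6
#' site has no inter-residue pairs.  For an n-residue chain this yields
#' 6n + 3(n-1) + 3(n-2) = 12n - 9 pairs (n >= 2; 6 pairs for n = 1).
#'
#' @param model a \linkS4class{FibrilModel}.
#' @param chains optional integer vector of 0-based chain ids to restrict to.
#' @return data.frame with columns \code{i}, \code{j} (1-based bead row
#'   indices), \code{class} (\code{"none"}, \code{"1st"}, \code{"2nd"}) and
#'   \code{label} (site pair, e.g. \code{"O2-O6"}).
#' @export
#' @examples
#' nrow(schConnectivity(buildChain(3)))  # 27
schConnectivity <- function(model, chains = NULL) {
  b <- model@beads
  if (!nrow(b)) stop("model has no beads")
  if (is.null(chains)) chains <- unique(b$chain)
  # bead row index by (chain, residue, atom); models are in canonical order
  # but look rows up explicitly so subsetted/mapped models also work
  row_of <- new.env(hash = TRUE, parent = emptyenv())
  keys <- paste(b$chain, b$residue, b$atom)
  for (idx in seq_len(nrow(b))) assign(keys[idx], idx, envir = row_of)
  intra_a <- c("O2", "O2", "O3", "C6", "O2", "O3")
  intra_b <- c("O3", "C6", "C6", "O6", "O6", "O6")
  inter <- c("O2", "O3", "C6")
  parts <- vector("list", length(chains))
  for (ci in seq_along(chains)) {
    ch <- chains[ci]
    nres <- length(unique(b$residue[b$chain == ch]))
    res_intra <- rep(seq_len(nres) - 1L, each = 6L)
    ka <- paste(ch, res_intra, rep(intra_a, nres))
    kb <- paste(ch, res_intra, rep(intra_b, nres))
    lab <- paste(rep(intra_a, nres), rep(intra_b, nres), sep = "-")
    cls <- rep("none", length(ka))
    for (off in 1:2) {
      r0 <- seq_len(max(nres - off, 0L)) - 1L
      if (!length(r0)) next
      ra <- rep(r0, each = 3L)
      at <- rep(inter, length(r0))
      ka <- c(ka, paste(ch, ra, at))
      kb <- c(kb, paste(ch, ra + off, at))
      lab <- c(lab, paste(at, at, sep = "-"))
      cls <- c(cls, rep(c("1st", "2nd")[off], length(ra)))
    }
    parts[[ci]] <- data.frame(
      i = vapply(ka, get, 0L, envir = row_of, USE.NAMES = FALSE),
      j = vapply(kb, get, 0L, envir = row_of, USE.NAMES = FALSE),
      class = cls, label = lab, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Map an atomistic cellulose structure onto the 4-bead representation
#'
#' Takes an atomistic structure with CHARMM-style D-glucose atom naming and
#' places one CG bead on each of the O2, O3, C6 and O6 atom positions of
#' every residue (positions copied exactly).  Chain and residue ordering is
#' preserved; residues are renumbered consecutively from 0 within each
#' chain.
#'
#' @param x an atom-records data.frame (as returned by
#'   \code{\link{readStructure}} for a non-CG file: columns \code{chain},
#'   \code{residue}, \code{atom}, \code{x}, \code{y}, \code{z} in
#'   Angstrom), a \code{bio3d} \code{pdb} object, or a path to a PDB/GRO
#'   file.
#' @param allomorph allomorph tag to record on the result.
#' @return A \linkS4class{FibrilModel} with \code{provenance = "mapped"}.
#'   A residue missing any of the four atoms is a mapping error naming the
#'   chain and residue; an empty selection is an error.
#' @export
#' @examples
#' ch <- buildChain(3)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(ch, f)
#' mapped <- mapAtomistic(f, allomorph = "Ibeta")
#' max(abs(coords(mapped) - coords(ch))) < 1e-2
mapAtomistic <- function(x, allomorph = c("Ibeta", "Ialpha", "II")) {
  allomorph <- match.arg(allomorph)
  if (is.character(x) && length(x) == 1L) x <- readStructure(x, as = "atoms")
  if (is(x, "FibrilModel")) {
    rec <- data.frame(chain = x@beads$chain, residue = x@beads$residue,
                      atom = x@beads$atom, x = x@coords[, 1],
                      y = x@coords[, 2], z = x@coords[, 3],
                      stringsAsFactors = FALSE)
    x <- rec
  } else if (is(x, "pdb")) {
    a <- x$atom
    x <- data.frame(chain = a$chain, residue = a$resno,
                    atom = trimws(a$elety), x = a$x, y = a$y, z = a$z,
                    stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) ||
      !all(c("chain", "residue", "atom", "x", "y", "z") %in% names(x)))
    stop("cannot interpret input as an atomistic structure")
  if (!nrow(x)) stop("empty selection: no atoms to map")
  cg_atoms <- unname(.SITE_ATOM)
  chains <- unique(x$chain)
  parts <- vector("list", length(chains))
  for (ci in seq_along(chains)) {
    xc <- x[x$chain == chains[ci], , drop = FALSE]
    res_ids <- unique(xc$residue)
    m <- matrix(NA_real_, length(res_ids) * 4L, 3L)
    for (ri in seq_along(res_ids)) {
      xr <- xc[xc$residue == res_ids[ri], , drop = FALSE]
      hit <- match(cg_atoms, xr$atom)
      if (anyNA(hit))
        stop(sprintf(
          "mapping error: chain %s residue %s lacks atom(s) %s",
          chains[ci], res_ids[ri],
          paste(cg_atoms[is.na(hit)], collapse = ", ")))
      m[(ri - 1L) * 4L + 1:4, ] <- as.matrix(xr[hit, c("x", "y", "z")])
    }
    parts[[ci]] <- m
  }
  xyz <- do.call(rbind, parts)
  colnames(xyz) <- c("x", "y", "z")
  nres <- vapply(chains, function(ch) length(unique(x$residue[x$chain == ch])), 0L)
  bd <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    f <- .beadFrame(1L, nres[ci])
    f$chain <- ci - 1L
    f
  }))
  rownames(bd) <- NULL
  box <- diag(apply(xyz, 2, function(v) diff(range(v)) + 60))
  new("FibrilModel", allomorph = allomorph, beads = bd, coords = xyz,
      box = box, provenance = "mapped")
}
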