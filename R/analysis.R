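# Validation statistics: RMSD, twist dihedrals, pair-distance distributions.

#' Root-mean-square deviation with optional Kabsch superposition
#'
#' With \code{superpose = TRUE} the minimum RMSD over all rigid rotations
#' and translations (optimal least-squares superposition, computed with the
#' Kabsch SVD algorithm including the reflection correction); with
#' \code{superpose = FALSE} the raw RMSD of matched rows.
#'
#' @param X,Y numeric n x 3 matrices with matched row ordering, Angstrom.
#' @param superpose logical.
#' @return RMSD in Angstrom.
#' @export
#' @examples
#' X <- matrix(rnorm(30), 10, 3)
#' kabschRMSD(X, X + 5)  # 0: rigid translation
kabschRMSD <- function(X, Y, superpose = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!identical(dim(X), dim(Y)) || ncol(X) != 3L)
    stop("X and Y must be n x 3 matrices of equal size")
  if (nrow(X) < 1L) stop("need at least one point")
  if (superpose) {
    xc <- colMeans(X); yc <- colMeans(Y)
    Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
    s <- svd(crossprod(Yc, Xc))
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    Yr <- Yc %*% R
    sqrt(max(sum((Xc - Yr)^2), 0) / nrow(X))
  } else {
    sqrt(sum((X - Y)^2) / nrow(X))
  }
}

.refFrame <- function(traj, reference) {
  if (is.matrix(reference)) return(reference)
  if (is.numeric(reference) && length(reference) == 1L)
    return(getFrame(traj, as.integer(reference)))
  if (identical(reference, "first")) return(getFrame(traj, 1L))
  if (identical(reference, "last")) return(getFrame(traj, nFrames(traj)))
  stop("reference must be a frame matrix, a frame index, 'first' or 'last'")
}

#' Time-average RMSD of a trajectory against a fixed reference
#'
#' Per-frame (optionally superposed) RMSD versus a fixed reference
#' structure, summarized as mean and standard deviation.
#'
#' @param traj a \linkS4class{CGTrajectory}.
#' @param reference an n x 3 matrix, a frame index, \code{"first"} or
#'   \code{"last"}.
#' @param superpose logical; superposition removes rigid-body drift, which
#'   otherwise dominates long thermostatted runs.
#' @return list with \code{mean}, \code{sd} (Angstrom) and the per-frame
#'   \code{rmsd} vector.
#' @export
#' @examples
#' sys <- buildTopology(buildChain(3))
#' tr <- runDynamics(sys$model, sys$topology, engineConfig(seed = 1L), 200, 20)
#' trajectoryRMSD(tr, coords(sys$model))$mean
trajectoryRMSD <- function(traj, reference = "last", superpose = TRUE) {
  ref <- .refFrame(traj, reference)
  if (nrow(ref) != nBeads(traj))
    stop("reference and trajectory bead counts differ")
  r <- vapply(seq_len(nFrames(traj)),
              function(i) kabschRMSD(ref, getFrame(traj, i), superpose),
              0)
  list(mean = mean(r), sd = if (length(r) > 1) sd(r) else 0, rmsd = r)
}

#' Cross-RMSD between two trajectories
#'
#' Evaluates the (optionally superposed) RMSD for every pair of frames
#' (one from each trajectory, optionally strided) and returns the mean,
#' standard deviation and pair count.  Used to quantify the structural
#' distance between two simulated systems: self pairs of an equilibrated
#' trajectory give small values, pairs across different crystal forms give
#' large ones.
#'
#' @param trajA,trajB \linkS4class{CGTrajectory} objects with mappable
#'   (equal-count, matched-order) bead sets.
#' @param superpose logical.
#' @param stride evaluate every \code{stride}-th frame of each trajectory.
#' @return list with \code{mean}, \code{sd}, \code{n_pairs}.
#' @export
#' @examples
#' sys <- buildTopology(buildChain(3))
#' tr <- runDynamics(sys$model, sys$topology, engineConfig(seed = 1L), 100, 20)
#' crossRMSD(tr, tr)$n_pairs  # 25
crossRMSD <- function(trajA, trajB, superpose = TRUE, stride = 1L) {
  if (nBeads(trajA) != nBeads(trajB))
    stop("trajectories have unmappable bead sets (bead counts differ)")
  ia <- seq(1L, nFrames(trajA), by = stride)
  ib <- seq(1L, nFrames(trajB), by = stride)
  r <- numeric(length(ia) * length(ib))
  k <- 0L
  for (i in ia) {
    A <- getFrame(trajA, i)
    for (j in ib) {
      k <- k + 1L
      r[k] <- kabschRMSD(A, getFrame(trajB, j), superpose)
    }
  }
  list(mean = mean(r), sd = if (k > 1) sd(r) else 0, n_pairs = k)
}

#' Signed dihedral angle of four points
#'
#' Standard atan2 dihedral over the ordered quadruple, in degrees in
#' (-180, 180].  Used for the fibril twist angle, whose quadruple is
#' (O2_i, C6_i, C6_{i+1}, O2_{i+1}) for consecutive residues i, i+1.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in degrees.
#' @export
#' @examples
#' twistAngle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))  # 0: cis
twistAngle <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12) stop("undefined dihedral: central points coincide")
  n1 <- .crossv(p2 - p1, b2)
  n2 <- .crossv(b2, p4 - p3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("undefined dihedral: collinear points")
  ang <- atan2(sum(.crossv(n1, b2 / nb2) * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Twist-angle statistics of a trajectory
#'
#' Computes the twist dihedral for every consecutive-residue junction in
#' every chain and every frame, pooled into one series, and reports its
#' average, standard deviation, maximum and minimum.  The pooled mean
#' measures the handedness of the fibril twist (positive right-handed
#' under this quadruple convention).
#'
#' @param traj a \linkS4class{CGTrajectory} (or NULL to evaluate a single
#'   structure).
#' @param model the matching \linkS4class{FibrilModel} (carries chain and
#'   residue ordering).
#' @return list with \code{average}, \code{sd}, \code{max}, \code{min}
#'   (degrees), \code{n} (series length) and \code{angles} (the pooled
#'   series).  Chains with fewer than 2 residues are skipped with a
#'   warning.
#' @export
#' @examples
#' ch <- buildChain(4)
#' twistStats(NULL, ch)$average  # 0: built chains are untwisted
twistStats <- function(traj, model) {
  b <- model@beads
  frames <- if (is.null(traj)) 1L else seq_len(nFrames(traj))
  # bead row indices of (O2, C6) per residue, per chain
  chains <- unique(b$chain)
  quads <- list()
  for (ch in chains) {
    sel <- which(b$chain == ch)
    res <- sort(unique(b$residue[sel]))
    if (length(res) < 2L) {
      warning(sprintf("chain %s has < 2 residues; skipped", ch))
      next
    }
    o2 <- sel[match(paste(res, "O2"), paste(b$residue[sel], b$atom[sel]))]
    c6 <- sel[match(paste(res, "C6"), paste(b$residue[sel], b$atom[sel]))]
    nj <- length(res) - 1L
    quads[[length(quads) + 1L]] <-
      cbind(o2[seq_len(nj)], c6[seq_len(nj)], c6[seq_len(nj) + 1L],
            o2[seq_len(nj) + 1L])
  }
  if (!length(quads)) stop("no chain with >= 2 residues")
  Q <- do.call(rbind, quads)
  angles <- numeric(0)
  for (fr in frames) {
    X <- if (is.null(traj)) model@coords else getFrame(traj, fr)
    a <- vapply(seq_len(nrow(Q)), function(q)
      twistAngle(X[Q[q, 1], ], X[Q[q, 2], ], X[Q[q, 3], ], X[Q[q, 4], ]),
      0)
    angles <- c(angles, a)
  }
  list(average = mean(angles), sd = if (length(angles) > 1) sd(angles) else 0,
       max = max(angles), min = min(angles), n = length(angles),
       angles = angles)
}

#' Pair-distance statistics of a trajectory
#'
#' Pools the per-frame distances of all pairs matching a bonded pair spec
#' (pair label + neighbour class) over all chains and frames and reports
#' mean, standard deviation and a normalized histogram.  This is the
#' statistic used to check that dynamics preserves the reference bond
#' geometry.
#'
#' @param traj a \linkS4class{CGTrajectory}, or NULL to evaluate the
#'   static model.
#' @param model the matching \linkS4class{FibrilModel}.
#' @param label pair label, e.g. \code{"O2-O3"}.
#' @param neighbours \code{"none"}, \code{"1st"} or \code{"2nd"}.
#' @param breaks histogram breaks; default Freedman-Diaconis.
#' @return list with \code{label}, \code{neighbours}, \code{mean},
#'   \code{sd} (Angstrom), \code{histogram} (a \code{hist} object whose
#'   density integrates to 1) and \code{distances} (the pooled series).
#' @export
#' @examples
#' ch <- buildChain(3)
#' pairDistanceStats(NULL, ch, "O2-O3")$mean  # 2.88
pairDistanceStats <- function(traj, model, label, neighbours = NULL,
                              breaks = "FD") {
  conn <- schConnectivity(model)
  if (is.null(neighbours)) {
    cand <- unique(conn$class[conn$label == label])
    if (!length(cand))
      stop(sprintf("unknown pair spec: no '%s' pairs in this model", label))
    if (length(cand) > 1L)
      stop(sprintf("pair label '%s' is ambiguous (classes: %s); give 'neighbours'",
                   label, paste(cand, collapse = ", ")))
    neighbours <- cand
  }
  sel <- conn$label == label & conn$class == neighbours
  if (!any(sel))
    stop(sprintf("unknown pair spec: (%s, %s)", label, neighbours))
  ii <- conn$i[sel]; jj <- conn$j[sel]
  frames <- if (is.null(traj)) 1L else seq_len(nFrames(traj))
  dists <- numeric(length(frames) * length(ii))
  k <- 0L
  for (fr in frames) {
    X <- if (is.null(traj)) model@coords else getFrame(traj, fr)
    d <- sqrt(rowSums((X[ii, , drop = FALSE] - X[jj, , drop = FALSE])^2))
    dists[k + seq_along(d)] <- d
    k <- k + length(d)
  }
  h <- if (diff(range(dists)) < 1e-8) {
    graphics::hist(dists, breaks = c(dists[1] - 0.5, dists[1] + 0.5),
                   plot = FALSE)
  } else {
    graphics::hist(dists, breaks = breaks, plot = FALSE)
  }
  list(label = label, neighbours = neighbours, mean = mean(dists),
       sd = if (length(dists) > 1) sd(dists) else 0, histogram = h,
       distances = dists)
}
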