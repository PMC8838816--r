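# Shared fixtures, built in code and cached for the session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small typed chain system (model + topology)
chain_system <- function(n = 5, allomorph = "Ibeta") {
  memo(paste0("chain_", n, "_", allomorph),
       buildTopology(buildChain(n, allomorph)))
}

quick_cfg <- function(...) engineConfig(seed = 1L, ...)

# brute-force pair enumeration and classification used as the oracle for
# the elastic-network connectivity: classify every bead pair of a chain by
# residue separation and site labels, keep exactly the pairs the ribbon
# triangulation prescribes
brute_force_pairs <- function(model) {
  b <- beads(model)
  n <- nrow(b)
  out <- list()
  intra_ok <- c("O2-O3", "O2-C6", "O3-C6", "C6-O6", "O2-O6", "O3-O6")
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (b$chain[i] != b$chain[j]) next
    dres <- abs(b$residue[j] - b$residue[i])
    lab1 <- paste(b$atom[i], b$atom[j], sep = "-")
    lab2 <- paste(b$atom[j], b$atom[i], sep = "-")
    if (dres == 0) {
      lab <- if (lab1 %in% intra_ok) lab1 else lab2
      if (lab %in% intra_ok)
        out[[length(out) + 1]] <- data.frame(i = i, j = j, class = "none",
                                             label = lab)
    } else if (dres <= 2 && b$atom[i] == b$atom[j] && b$atom[i] != "O6") {
      out[[length(out) + 1]] <- data.frame(
        i = i, j = j, class = c("1st", "2nd")[dres],
        label = paste(b$atom[i], b$atom[j], sep = "-"))
    }
  }
  do.call(rbind, out)
}

# independent dihedral oracle: rotate the quadruple so the central bond is
# +z, then read the angle between the projections of the outer bonds.
# Sense: positive when, viewed from p2 towards p3, the far bond projection
# is rotated clockwise from the near one (the package's convention; some
# packages, e.g. bio3d, use the opposite sign)
dihedral_oracle <- function(p1, p2, p3, p4) {
  axis <- p3 - p2
  axis <- axis / sqrt(sum(axis^2))
  # rotation matrix taking `axis` to +z (Rodrigues)
  z <- c(0, 0, 1)
  v <- c(axis[2] * z[3] - axis[3] * z[2],
         axis[3] * z[1] - axis[1] * z[3],
         axis[1] * z[2] - axis[2] * z[1])
  cth <- sum(axis * z)
  if (sum(v^2) < 1e-24) {
    R <- if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx * (1 / (1 + cth))
  }
  a <- R %*% (p1 - p2)
  b <- R %*% (p4 - p3)
  # clockwise-positive angle from a_xy to b_xy about +z
  a2 <- a[1:2]; b2 <- b[1:2]
  ang <- atan2(-(a2[1] * b2[2] - a2[2] * b2[1]), sum(a2 * b2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# a bare two-bead harmonic dimer driven through the low-level engine
# (FibrilModel requires whole 4-bead residues, so the dimer bypasses it)
two_bead_run <- function(r_init, n_steps = 1000, report_every = 20,
                         seed = 4L, temperature = 300, minimize = FALSE) {
  pos <- matrix(c(0, 0, 0, r_init / 10, 0, 0), 2, 3, byrow = TRUE)
  args <- list(pos = pos, bi = 0L, bj = 1L, r0 = 0.288, bk = 30000,
               tidx = c(0L, 0L), sigma = matrix(0.41, 1, 1),
               epsilon = matrix(4.29, 1, 1), ei = 0L, ej = 1L,
               cutoff = 1.1, shift = TRUE, pbc = FALSE,
               box = c(100, 100, 100))
  if (minimize) {
    res <- do.call(cgcellulose:::cpp_minimize,
                   c(args, list(max_steps = 50000L, ftol = 1e-4,
                                step0 = 0.01)))
    return(sqrt(sum(diff(res$pos)^2)) * 10)  # final bond length, Angstrom
  }
  set.seed(seed)
  res <- do.call(cgcellulose:::cpp_run_md,
                 c(list(pos = args$pos, mass = c(54, 54)), args[-1],
                   list(dt = 0.02, temperature = temperature,
                        thermostat = 1L, gamma = 1, tau_t = 1,
                        n_steps = as.integer(n_steps),
                        report_every = as.integer(report_every),
                        skin = 0.3, n_inner = 4L)))
  # per-frame bond lengths, Angstrom
  apply(res$frames, 3, function(X) sqrt(sum((X[1, ] - X[2, ])^2))) * 10
}

# --- long runs shared by the validation-protocol tests (memoised) ---

# the reference single-chain protocol: 20-residue Ialpha chain in vacuum,
# Langevin 300 K, 0.02 ps timestep, 1 ns equilibration + 5 ns production
acceptance_chain_run <- function() {
  memo("acc_chain", {
    sys <- buildTopology(buildChain(20, "Ialpha"))
    eq <- runDynamics(sys$model, sys$topology, engineConfig(seed = 101L),
                      n_steps = 50000, report_every = 1000)
    m_eq <- sys$model
    coords(m_eq) <- eq@config$final_pos
    traj <- runDynamics(m_eq, sys$topology, engineConfig(seed = 102L),
                        n_steps = 250000, report_every = 250)
    list(sys = sys, start = m_eq, traj = traj)
  })
}

# reduced solvent-free fibril protocol: 3x3 chains x 20 residues,
# minimized, 1 ns equilibration + 5 ns production
acceptance_fibril_run <- function(allomorph) {
  memo(paste0("acc_fibril_", allomorph), {
    fib <- buildFibril(9, c(3, 3), 20, allomorph)
    sys <- buildTopology(fib)
    mn <- minimizeEnergy(sys$model, sys$topology, max_steps = 3000,
                         ftol = 50)
    eq <- runDynamics(mn$model, sys$topology, engineConfig(seed = 111L),
                      n_steps = 50000, report_every = 1000)
    m_eq <- mn$model
    coords(m_eq) <- eq@config$final_pos
    traj <- runDynamics(m_eq, sys$topology, engineConfig(seed = 112L),
                        n_steps = 250000, report_every = 500)
    list(sys = sys, ideal = fib, start = m_eq, traj = traj)
  })
}
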