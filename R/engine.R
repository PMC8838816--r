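# R front end of the compiled CG engine.
#
# User-facing coordinates and distances are Angstrom; the engine itself
# works in GROMACS-style units (nm, ps, amu, kJ/mol), so positions and
# bond/LJ lengths are converted on the way in and out.

.KB <- 0.0083144621  # kJ/mol/K

#' Harmonic bond energy
#'
#' \eqn{V = k/2 (r - r_0)^2} with distances converted to nm, so that the
#' printed elastic constants (kJ mol^-1 nm^-2) give energies in kJ/mol.
#'
#' @param r,r0 distances, Angstrom (vectorized over \code{r}).
#' @param k elastic constant, kJ mol^-1 nm^-2.
#' @return energy, kJ/mol.
#' @export
#' @examples
#' bondEnergy(2.98, 2.88, 30000)  # 1.5
bondEnergy <- function(r, r0, k) {
  if (any(r <= 0)) stop("r must be > 0")
  0.5 * k * ((r - r0) / 10)^2
}

#' Truncated, potential-shifted Lennard-Jones energy
#'
#' \eqn{V = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] - V(r_c)} for
#' \eqn{r \le r_c} and exactly 0 beyond the cutoff.  The potential shift
#' removes the discontinuity at the cutoff.
#'
#' @param r distance, Angstrom (vectorized).
#' @param sigma LJ sigma, Angstrom.
#' @param epsilon LJ epsilon, kJ/mol.
#' @param cutoff cutoff, nm (note the unit; default \code{Inf} = no
#'   truncation).
#' @param shift apply the potential shift (default TRUE; ignored for an
#'   infinite cutoff).
#' @return energy, kJ/mol.
#' @export
#' @examples
#' ljEnergy(2^(1/6) * 4.1, 4.1, 4.29)  # -4.29 at the minimum
ljEnergy <- function(r, sigma, epsilon, cutoff = Inf, shift = TRUE) {
  if (any(r <= 0)) stop("r must be > 0")
  rc <- cutoff * 10  # nm -> Angstrom
  lj <- function(x) 4 * epsilon * ((sigma / x)^12 - (sigma / x)^6)
  vs <- if (shift && is.finite(rc)) lj(rc) else 0
  out <- ifelse(r <= rc, lj(r) - vs, 0)
  out
}

# assemble the C++ argument list shared by all engine entry points
.engineArgs <- function(model, topology, config) {
  stopifnot(is(model, "FibrilModel"), is(topology, "CGTopology"),
            is(config, "EngineConfig"))
  validObject(config)
  types <- topology@types
  if (anyNA(types)) stop("invalid model: bead types not assigned")
  utypes <- unique(types)
  nt <- length(utypes)
  sig <- matrix(0, nt, nt); eps <- matrix(0, nt, nt)
  for (a in seq_len(nt)) for (b in seq_len(nt)) {
    se <- nonbondedLookup(utypes[a], utypes[b], topology@nonbonded)
    sig[a, b] <- se[["sigma"]] / 10  # Angstrom -> nm
    eps[a, b] <- se[["epsilon"]]
  }
  bd <- topology@bonds
  list(pos = unname(model@coords) / 10,
       bi = as.integer(bd$i - 1L), bj = as.integer(bd$j - 1L),
       r0 = bd$r0 / 10, bk = bd$k,
       tidx = as.integer(match(types, utypes) - 1L),
       sigma = sig, epsilon = eps,
       ei = as.integer(topology@exclusions$i - 1L),
       ej = as.integer(topology@exclusions$j - 1L),
       cutoff = config@cutoff, shift = TRUE, pbc = config@pbc,
       box = diag(config@box))
}

#' Total energy and forces of a CG system
#'
#' Sum of all harmonic bond terms and all non-excluded LJ pairs within the
#' cutoff (the topology's exclusion list - by default the elastic-network
#' neighbourhood of each bead - is omitted from LJ).  Forces are the
#' exact negative gradient of that energy.
#'
#' @param model a typed \linkS4class{FibrilModel}.
#' @param topology the matching \linkS4class{CGTopology}.
#' @param config an \linkS4class{EngineConfig}.
#' @return list with \code{energy}, \code{bond}, \code{lj} (kJ/mol) and
#'   \code{forces} (n beads x 3 matrix, kJ mol^-1 nm^-1).
#' @export
#' @examples
#' sys <- buildTopology(buildChain(3))
#' energyForces(sys$model, sys$topology, engineConfig())$bond  # ~0: ideal
energyForces <- function(model, topology, config = engineConfig()) {
  a <- .engineArgs(model, topology, config)
  cpp_energy_forces(a$pos, a$bi, a$bj, a$r0, a$bk, a$tidx, a$sigma,
                    a$epsilon, a$ei, a$ej, a$cutoff, a$shift, a$pbc, a$box)
}

#' Steepest-descent energy minimization
#'
#' Monotone non-increasing energy; stops when the largest force component
#' falls below \code{ftol} or after \code{max_steps} step attempts.
#'
#' @param model,topology,config as in \code{\link{energyForces}}.
#' @param max_steps maximum number of step attempts.
#' @param ftol force tolerance, kJ mol^-1 nm^-1.
#' @return list with \code{model} (relaxed coordinates), \code{energy}
#'   (kJ/mol), \code{fmax}, \code{steps}, \code{converged}.
#' @export
#' @examples
#' sys <- buildTopology(buildChain(2))
#' m <- sys$model
#' cc <- coords(m); cc[1, 1] <- cc[1, 1] + 0.5; coords(m) <- cc
#' res <- minimizeEnergy(m, sys$topology)
#' res$energy < energyForces(m, sys$topology)$energy
minimizeEnergy <- function(model, topology, config = engineConfig(),
                           max_steps = 2000, ftol = 10) {
  a <- .engineArgs(model, topology, config)
  res <- cpp_minimize(a$pos, a$bi, a$bj, a$r0, a$bk, a$tidx, a$sigma,
                      a$epsilon, a$ei, a$ej, a$cutoff, a$shift, a$pbc,
                      a$box, as.integer(max_steps), ftol, 0.01)
  out <- model
  xyz <- res$pos * 10
  colnames(xyz) <- c("x", "y", "z")
  out@coords <- xyz
  list(model = out, energy = res$energy, fmax = res$fmax,
       steps = res$steps, converged = res$converged)
}

#' Run CG dynamics
#'
#' Velocity-Verlet integration with one of three temperature controls:
#' BAOAB Langevin (default), Bussi stochastic velocity rescale, or none
#' (NVE).  Initial velocities are drawn from the Maxwell-Boltzmann
#' distribution at the target temperature (zero at 0 K) with the
#' centre-of-mass motion removed; the Langevin thermostat re-removes
#' centre-of-mass motion every step.  With \code{config@seed} set the run
#' is bit-reproducible.
#'
#' @param model a typed \linkS4class{FibrilModel} (minimized or
#'   near-equilibrium start recommended).
#' @param topology the matching \linkS4class{CGTopology}.
#' @param config an \linkS4class{EngineConfig}.
#' @param n_steps number of integration steps.
#' @param report_every store a frame every this many steps (must divide
#'   \code{n_steps}).
#' @return A \linkS4class{CGTrajectory}.  The energy/temperature log is in
#'   \code{@config$log} (a data.frame with \code{time}, \code{epot},
#'   \code{ekin}, \code{temperature}); the final positions (Angstrom) in
#'   \code{@config$final_pos}, so runs can be chained.
#' @export
#' @examples
#' sys <- buildTopology(buildChain(3))
#' tr <- runDynamics(sys$model, sys$topology,
#'                   engineConfig(seed = 1L), n_steps = 200, report_every = 20)
#' nFrames(tr)
runDynamics <- function(model, topology, config = engineConfig(),
                        n_steps = 1000, report_every = 10) {
  n_steps <- as.integer(n_steps)
  report_every <- as.integer(report_every)
  if (n_steps < 1 || report_every < 1 || n_steps %% report_every != 0)
    stop("n_steps must be a positive multiple of report_every")
  if (anyDuplicated(round(model@coords, 6)))
    stop("degenerate input: two beads at identical positions")
  a <- .engineArgs(model, topology, config)
  thermo <- match(config@thermostat, c("none", "langevin", "v_rescale")) - 1L
  if (!is.na(config@seed)) set.seed(config@seed)
  res <- cpp_run_md(a$pos, topology@masses, a$bi, a$bj, a$r0, a$bk, a$tidx,
                    a$sigma, a$epsilon, a$ei, a$ej, a$cutoff, a$shift,
                    a$pbc, a$box, config@timestep, config@temperature,
                    thermo, config@friction, config@tau_t, n_steps,
                    report_every, 0.3, config@n_inner)
  frames <- res$frames * 10  # nm -> Angstrom
  log <- data.frame(time = res$times, epot = res$epot, ekin = res$ekin,
                    temperature = res$temperature)
  new("CGTrajectory",
      coords = frames,
      times = res$times,
      box = model@box,
      seed = config@seed,
      config = list(
        timestep = config@timestep, temperature = config@temperature,
        thermostat = config@thermostat, friction = config@friction,
        tau_t = config@tau_t, cutoff = config@cutoff,
        n_inner = config@n_inner, pbc = config@pbc,
        log = log, final_pos = res$final_pos * 10))
}
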