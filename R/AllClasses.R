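#' FibrilModel: a coarse-grained cellulose structure
#'
#' Ordered chains of 4-bead D-glucose residues together with bead metadata,
#' coordinates (Angstrom) and a box.  Bead order is row order: chains in
#' order, residues consecutively 0-indexed within each chain, and the four
#' sites CG1..CG4 (mapped from O2, O3, C6, O6) in order within each residue.
#'
#' @slot allomorph character, one of \code{"Ialpha"}, \code{"Ibeta"},
#'   \code{"II"}.
#' @slot beads data.frame with one row per bead: \code{chain} and
#'   \code{residue} (0-based integers), \code{site} (\code{"CG1"}..\code{"CG4"}),
#'   \code{atom} (\code{"O2"}, \code{"O3"}, \code{"C6"}, \code{"O6"}),
#'   \code{type} (Martini bead type, \code{NA} until assigned), \code{mass}
#'   (amu, \code{NA} until assigned), \code{charge} (elementary charges,
#'   always 0 for cellulose).
#' @slot coords numeric matrix, one row per bead, columns x, y, z in
#'   Angstrom.
#' @slot box 3x3 numeric matrix of box vectors (rows), Angstrom.
#' @slot provenance character, \code{"built"} (ideal geometry) or
#'   \code{"mapped"} (from an atomistic structure).
#' @seealso \code{\link{buildChain}}, \code{\link{buildFibril}},
#'   \code{\link{mapAtomistic}}
#' @export
setClass("FibrilModel",
  representation(
    allomorph = "character",
    beads = "data.frame",
    coords = "matrix",
    box = "matrix",
    provenance = "character"
  ),
  prototype(
    allomorph = "Ibeta",
    beads = data.frame(),
    coords = matrix(numeric(0), 0, 3),
    box = diag(3) * 100,
    provenance = "built"
  )
)

.ALLOMORPHS <- c("Ialpha", "Ibeta", "II")

setValidity("FibrilModel", function(object) {
  msg <- character(0)
  if (length(object@allomorph) != 1L || !object@allomorph %in% .ALLOMORPHS)
    msg <- c(msg, sprintf("allomorph must be one of %s",
                          paste(.ALLOMORPHS, collapse = ", ")))
  if (!length(object@provenance) == 1L ||
      !object@provenance %in% c("built", "mapped"))
    msg <- c(msg, "provenance must be 'built' or 'mapped'")
  b <- object@beads
  need <- c("chain", "residue", "site", "atom", "type", "mass", "charge")
  if (!all(need %in% names(b))) {
    msg <- c(msg, paste("beads must have columns:", paste(need, collapse = ", ")))
    return(if (length(msg)) msg else TRUE)
  }
  if (nrow(object@coords) != nrow(b) || ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be an (n beads) x 3 matrix")
  if (!identical(dim(object@box), c(3L, 3L)))
    msg <- c(msg, "box must be a 3x3 matrix")
  if (nrow(b)) {
    if (!all(b$site %in% .SITE_LEVELS))
      msg <- c(msg, "unknown site labels in beads")
    else if (!all(b$atom == .SITE_ATOM[b$site]))
      msg <- c(msg, "site/atom correspondence violated (CG1-O2, CG2-O3, CG3-C6, CG4-O6)")
    if (any(b$charge != 0)) msg <- c(msg, "cellulose beads must be uncharged")
    if (any(!is.na(b$mass) & b$mass <= 0)) msg <- c(msg, "bead masses must be > 0")
    # every (chain, residue) must hold the four sites exactly once,
    # residues consecutive from 0 within each chain
    for (ch in unique(b$chain)) {
      res <- b$residue[b$chain == ch]
      ur <- sort(unique(as.integer(res)))
      if (!identical(ur, seq_along(ur) - 1L)) {
        msg <- c(msg, sprintf("chain %s: residues not consecutively 0-indexed", ch))
        break
      }
      tab <- table(res)
      if (any(tab != 4L)) {
        msg <- c(msg, sprintf("chain %s: every residue needs exactly 4 beads", ch))
        break
      }
    }
    if (anyDuplicated(b[, c("chain", "residue", "site")]))
      msg <- c(msg, "duplicated (chain, residue, site) bead")
  }
  if (length(msg)) msg else TRUE
})

#' CGTopology: bonded terms, bead types and nonbonded table
#'
#' The interaction description of a \linkS4class{FibrilModel}: one harmonic
#' bond per elastic-network pair, the per-bead Martini types/masses/charges,
#' and the nonbonded LJ table.  All bonded pairs are excluded from
#' nonbonded interactions.
#'
#' @slot bonds data.frame with columns \code{i}, \code{j} (1-based bead
#'   indices into the model), \code{r0} (Angstrom), \code{k}
#'   (kJ mol^-1 nm^-2), \code{class} (\code{"none"}, \code{"1st"},
#'   \code{"2nd"}), \code{label} (pair label such as \code{"O2-O3"}).
#' @slot nonbonded data.frame as \code{\link{nonbondedParameterTable}}.
#' @slot exclusions data.frame with columns \code{i}, \code{j} (1-based
#'   bead indices): pairs excluded from nonbonded interactions.  The
#'   default policy excludes every intra-chain pair between residues
#'   within two of each other - the elastic-network neighbourhood - so
#'   intra-chain structure is governed by the network and LJ acts between
#'   chains and across longer intra-chain separations.
#' @slot types character vector, Martini type per bead.
#' @slot masses numeric vector, amu per bead.
#' @slot charges numeric vector, elementary charges per bead (all 0 here).
#' @seealso \code{\link{buildTopology}}, \code{\link{makeBondTerms}}
#' @export
setClass("CGTopology",
  representation(
    bonds = "data.frame",
    nonbonded = "data.frame",
    exclusions = "data.frame",
    types = "character",
    masses = "numeric",
    charges = "numeric"
  ),
  prototype(
    exclusions = data.frame(i = integer(0), j = integer(0))
  )
)

setValidity("CGTopology", function(object) {
  msg <- character(0)
  bd <- object@bonds
  need <- c("i", "j", "r0", "k", "class", "label")
  if (!all(need %in% names(bd)))
    msg <- c(msg, paste("bonds must have columns:", paste(need, collapse = ", ")))
  else if (nrow(bd)) {
    if (any(bd$r0 <= 0) || any(bd$k <= 0))
      msg <- c(msg, "bond r0 and k must be > 0")
    if (any(bd$i == bd$j)) msg <- c(msg, "self-bond found")
    n <- length(object@types)
    if (any(bd$i < 1 | bd$i > n | bd$j < 1 | bd$j > n))
      msg <- c(msg, "bond indices out of range")
  }
  nb <- object@nonbonded
  if (!all(c("type_a", "type_b", "sigma", "epsilon") %in% names(nb)))
    msg <- c(msg, "nonbonded must have columns type_a, type_b, sigma, epsilon")
  ex <- object@exclusions
  if (!all(c("i", "j") %in% names(ex)))
    msg <- c(msg, "exclusions must have columns i, j")
  n <- length(object@types)
  if (length(object@masses) != n || length(object@charges) != n)
    msg <- c(msg, "types, masses, charges must have equal length")
  if (length(object@masses) && any(object@masses <= 0))
    msg <- c(msg, "masses must be > 0")
  if (length(msg)) msg else TRUE
})

#' EngineConfig: settings for the CG dynamics engine
#'
#' @slot timestep ps; default 0.02, the production timestep of the model.
#' @slot temperature K.
#' @slot thermostat \code{"langevin"}, \code{"v_rescale"} or \code{"none"}
#'   (plain velocity-Verlet NVE).
#' @slot friction ps^-1, Langevin friction (default 1).
#' @slot tau_t ps, velocity-rescale coupling time (default 1).
#' @slot cutoff nm, LJ cutoff with potential-shift truncation (default 1.1).
#' @slot n_inner integer; number of inner sub-steps per timestep for the
#'   stiff bonded forces (RESPA splitting, default 4).  The soft LJ forces
#'   act at the outer timestep.
#' @slot seed integer or NA; if set, the RNG is seeded at the start of a run
#'   so trajectories are bit-reproducible.
#' @slot pbc logical; rectangular minimum-image periodic boundaries.
#' @slot box 3x3 matrix, nm; used only when \code{pbc} is \code{TRUE}.
#' @seealso \code{\link{engineConfig}}, \code{\link{runDynamics}}
#' @export
setClass("EngineConfig",
  representation(
    timestep = "numeric",
    temperature = "numeric",
    thermostat = "character",
    friction = "numeric",
    tau_t = "numeric",
    cutoff = "numeric",
    n_inner = "integer",
    seed = "integer",
    pbc = "logical",
    box = "matrix"
  ),
  prototype(
    timestep = 0.02,
    temperature = 300,
    thermostat = "langevin",
    friction = 1,
    tau_t = 1,
    cutoff = 1.1,
    n_inner = 4L,
    seed = NA_integer_,
    pbc = FALSE,
    box = diag(3) * 100
  )
)

setValidity("EngineConfig", function(object) {
  msg <- character(0)
  if (object@timestep <= 0) msg <- c(msg, "timestep must be > 0")
  if (object@temperature < 0) msg <- c(msg, "temperature must be >= 0")
  if (object@cutoff <= 0) msg <- c(msg, "cutoff must be > 0")
  if (object@n_inner < 1L) msg <- c(msg, "n_inner must be >= 1")
  if (!object@thermostat %in% c("langevin", "v_rescale", "none"))
    msg <- c(msg, "thermostat must be 'langevin', 'v_rescale' or 'none'")
  if (object@friction < 0) msg <- c(msg, "friction must be >= 0")
  if (object@tau_t <= 0) msg <- c(msg, "tau_t must be > 0")
  if (!identical(dim(object@box), c(3L, 3L))) msg <- c(msg, "box must be 3x3")
  if (length(msg)) msg else TRUE
})

#' CGTrajectory: time-ordered frames of bead positions
#'
#' @slot coords numeric array of dimension (n beads, 3, n frames), Angstrom.
#' @slot times numeric vector, ps, one per frame.
#' @slot box 3x3 matrix, Angstrom.
#' @slot seed integer (NA if the run was not explicitly seeded).
#' @slot config list of engine settings the trajectory was generated with
#'   (empty for trajectories read from file).
#' @seealso \code{\link{runDynamics}}, \code{\link{readTrajectoryGRO}}
#' @export
setClass("CGTrajectory",
  representation(
    coords = "array",
    times = "numeric",
    box = "matrix",
    seed = "integer",
    config = "list"
  )
)

setValidity("CGTrajectory", function(object) {
  msg <- character(0)
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an (n beads) x 3 x (n frames) array")
  else {
    if (d[3] < 1L) msg <- c(msg, "trajectory needs at least one frame")
    if (length(object@times) != d[3])
      msg <- c(msg, "times must have one entry per frame")
  }
  if (length(msg)) msg else TRUE
})
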