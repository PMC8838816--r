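# Package configuration (YAML round-trip) and deterministic test fixtures.

#' Package configuration
#'
#' A plain list of the package's tunable defaults: units policy (Angstrom
#' in memory and PDB, nm in GRO/topology files), per-allomorph lattice
#' defaults, engine defaults, a top-level seed and verbosity.  Round-trips
#' losslessly through \code{\link{writeConfig}} / \code{\link{readConfig}}.
#'
#' @param seed integer top-level seed.
#' @param verbosity integer, 0 = quiet.
#' @param engine named list of \code{\link{engineConfig}} arguments.
#' @param lattices named list of per-allomorph lattice specs.
#' @return list of class \code{"cgConfig"}.
#' @export
#' @examples
#' cfg <- cgConfig(seed = 7L)
#' cfg$engine$timestep
cgConfig <- function(seed = 1L, verbosity = 0L,
                     engine = list(timestep = 0.02, temperature = 300,
                                   thermostat = "langevin", friction = 1,
                                   tau_t = 1, cutoff = 1.1),
                     lattices = list(Ialpha = defaultLattice("Ialpha"),
                                     Ibeta = defaultLattice("Ibeta"),
                                     II = defaultLattice("II"))) {
  structure(list(units = list(coordinates = "angstrom",
                              topology_files = "nm"),
                 seed = as.integer(seed), verbosity = as.integer(verbosity),
                 engine = engine, lattices = lattices),
            class = "cgConfig")
}

#' @rdname cgConfig
#' @param config a \code{cgConfig} list.
#' @param path YAML file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname cgConfig
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  structure(yaml::read_yaml(path), class = "cgConfig")
}

#' Generate deterministic structure fixtures
#'
#' Small structure files for tests and demonstrations, deterministic given
#' the seed:
#' \describe{
#'   \item{ideal_chain}{an n-residue ideal chain;}
#'   \item{perturbed_chain}{the same with i.i.d. Gaussian displacements of
#'     standard deviation \code{sigma} Angstrom;}
#'   \item{mini_fibril}{a 2 x 2 chain, n-residue fibril;}
#'   \item{rotated_copy}{an ideal chain plus a rigidly rotated and
#'     translated copy (transform recorded), for RMSD invariance checks.}
#' }
#'
#' @param kind fixture kind.
#' @param seed integer seed.
#' @param dir output directory.
#' @param n_residues residues per chain.
#' @param sigma perturbation SD, Angstrom.
#' @param allomorph allomorph tag.
#' @return list with \code{kind}, \code{files} (paths to the written GRO
#'   files), \code{models} (the \linkS4class{FibrilModel} objects) and for
#'   \code{rotated_copy} the applied \code{rotation} and
#'   \code{translation}.
#' @export
#' @examples
#' fx <- makeFixture("perturbed_chain", seed = 7L, dir = tempdir())
#' fx$files
makeFixture <- function(kind = c("ideal_chain", "perturbed_chain",
                                 "mini_fibril", "rotated_copy"),
                        seed = 1L, dir = tempdir(), n_residues = 5,
                        sigma = 0.1, allomorph = "Ibeta") {
  kind <- match.arg(kind)
  set.seed(seed)
  out <- list(kind = kind, seed = seed)
  write1 <- function(model, name) {
    p <- file.path(dir, paste0(name, ".gro"))
    writeStructure(model, p)
    p
  }
  if (kind == "ideal_chain") {
    m <- buildChain(n_residues, allomorph)
    out$models <- list(m)
    out$files <- write1(m, sprintf("ideal_chain_n%d", n_residues))
  } else if (kind == "perturbed_chain") {
    m <- buildChain(n_residues, allomorph)
    coords(m) <- coords(m) + matrix(rnorm(3 * nBeads(m), sd = sigma),
                                    ncol = 3)
    out$models <- list(m)
    out$sigma <- sigma
    out$files <- write1(m, sprintf("perturbed_chain_n%d_s%d",
                                   n_residues, seed))
  } else if (kind == "mini_fibril") {
    m <- buildFibril(4, c(2, 2), n_residues, allomorph)
    out$models <- list(m)
    out$files <- write1(m, sprintf("mini_fibril_n%d", n_residues))
  } else {
    m <- buildChain(n_residues, allomorph)
    # random rotation via QR of a Gaussian matrix, det +1
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    tvec <- rnorm(3, sd = 5)
    m2 <- m
    coords(m2) <- coords(m) %*% R + matrix(tvec, nBeads(m), 3, byrow = TRUE)
    out$models <- list(m, m2)
    out$rotation <- R
    out$translation <- tvec
    out$files <- c(write1(m, sprintf("rotated_copy_ref_n%d", n_residues)),
                   write1(m2, sprintf("rotated_copy_rot_n%d", n_residues)))
  }
  out
}
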