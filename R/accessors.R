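# Accessors and show() methods.

#' @rdname cgcellulose-generics
#' @aliases nBeads,FibrilModel-method
setMethod("nBeads", "FibrilModel", function(x) nrow(x@beads))

#' @rdname cgcellulose-generics
setMethod("nChains", "FibrilModel", function(x) length(unique(x@beads$chain)))

#' @rdname cgcellulose-generics
setMethod("nResidues", "FibrilModel", function(x) {
  b <- x@beads
  vapply(split(b$residue, b$chain), function(r) length(unique(r)), 0L)
})

#' @rdname cgcellulose-generics
setMethod("coords", "FibrilModel", function(x, ...) x@coords)

#' @rdname cgcellulose-generics
setMethod("coords<-", "FibrilModel", function(x, value) {
  value <- as.matrix(value)
  stopifnot(identical(dim(value), dim(x@coords)))
  x@coords <- value
  x
})

#' @rdname cgcellulose-generics
setMethod("beads", "FibrilModel", function(x) x@beads)

#' @rdname cgcellulose-generics
setMethod("allomorph", "FibrilModel", function(x) x@allomorph)

#' @rdname cgcellulose-generics
setMethod("nBeads", "CGTrajectory", function(x) dim(x@coords)[1])

#' @rdname cgcellulose-generics
setMethod("nFrames", "CGTrajectory", function(x) dim(x@coords)[3])

#' @rdname cgcellulose-generics
setMethod("getFrame", "CGTrajectory", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1, i <= nFrames(x))
  x@coords[, , i, drop = TRUE]
})

#' @rdname cgcellulose-generics
setMethod("coords", "CGTrajectory", function(x, ...) x@coords)

setMethod("show", "FibrilModel", function(object) {
  nres <- nResidues(object)
  typed <- !anyNA(object@beads$type)
  cat(sprintf("FibrilModel (%s, %s)\n", object@allomorph, object@provenance))
  cat(sprintf("  %d chain(s) x %s residue(s), %d beads%s\n",
              nChains(object),
              paste(unique(nres), collapse = "/"),
              nBeads(object),
              if (typed) " [typed]" else ""))
  invisible(object)
})

setMethod("show", "CGTopology", function(object) {
  cat(sprintf("CGTopology: %d beads, %d bonds (%s), %d nonbonded pair entries\n",
              length(object@types), nrow(object@bonds),
              paste(sprintf("%s: %d", names(table(object@bonds$class)),
                            as.integer(table(object@bonds$class))),
                    collapse = ", "),
              nrow(object@nonbonded)))
  invisible(object)
})

setMethod("show", "CGTrajectory", function(object) {
  cat(sprintf("CGTrajectory: %d beads, %d frames, t = %g..%g ps\n",
              nBeads(object), nFrames(object),
              min(object@times), max(object@times)))
  invisible(object)
})

setMethod("show", "EngineConfig", function(object) {
  cat(sprintf(
    "EngineConfig: dt = %g ps, T = %g K, thermostat = %s, cutoff = %g nm%s\n",
    object@timestep, object@temperature, object@thermostat, object@cutoff,
    if (!is.na(object@seed)) sprintf(", seed = %d", object@seed) else ""))
  invisible(object)
})

#' Create an engine configuration
#'
#' Convenience constructor for \linkS4class{EngineConfig}.  Defaults match
#' the model's production settings: 0.02 ps timestep, 300 K, 1.1 nm LJ
#' cutoff with potential-shift truncation, Langevin thermostat with
#' friction 1 ps^-1, vacuum (no periodic boundaries).
#'
#' @param timestep ps.
#' @param temperature K.
#' @param thermostat \code{"langevin"}, \code{"v_rescale"} or \code{"none"}.
#' @param friction ps^-1 (Langevin).
#' @param tau_t ps (velocity rescale coupling time).
#' @param cutoff nm.
#' @param n_inner inner (RESPA) sub-steps for the bonded forces per
#'   timestep.
#' @param seed integer or NA.
#' @param pbc logical.
#' @param box 3x3 matrix in nm (only used with \code{pbc = TRUE}).
#' @return An \linkS4class{EngineConfig}.
#' @export
#' @examples
#' engineConfig(temperature = 350, seed = 7L)
engineConfig <- function(timestep = 0.02, temperature = 300,
                         thermostat = c("langevin", "v_rescale", "none"),
                         friction = 1, tau_t = 1, cutoff = 1.1,
                         n_inner = 4L, seed = NA_integer_, pbc = FALSE,
                         box = diag(3) * 100) {
  thermostat <- match.arg(thermostat)
  new("EngineConfig", timestep = timestep, temperature = temperature,
      thermostat = thermostat, friction = friction, tau_t = tau_t,
      cutoff = cutoff, n_inner = as.integer(n_inner),
      seed = as.integer(seed), pbc = pbc, box = box)
}
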