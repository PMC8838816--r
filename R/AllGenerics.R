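#' @name cgcellulose-generics
#' @title Accessor generics for cgcellulose classes
#' @description Small accessor generics shared by the package's S4 classes.
#' @param x an object.
#' @param ... passed to methods.
#' @return \code{nBeads}, \code{nChains}, \code{nFrames} return integers;
#'   \code{nResidues} an integer vector (one per chain); \code{coords} a
#'   numeric matrix (Angstrom); \code{beads} the bead metadata data.frame;
#'   \code{allomorph} a character scalar; \code{getFrame} an (n beads) x 3
#'   matrix.
NULL

#' @rdname cgcellulose-generics
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' @rdname cgcellulose-generics
#' @export
setGeneric("nChains", function(x) standardGeneric("nChains"))

#' @rdname cgcellulose-generics
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname cgcellulose-generics
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname cgcellulose-generics
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname cgcellulose-generics
#' @param value replacement value.
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' @rdname cgcellulose-generics
#' @export
setGeneric("beads", function(x) standardGeneric("beads"))

#' @rdname cgcellulose-generics
#' @export
setGeneric("allomorph", function(x) standardGeneric("allomorph"))

#' @rdname cgcellulose-generics
#' @param i frame index (1-based).
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
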