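# GROMACS-dialect topology writer/reader.
#
# writeTopology emits PREFIX.itp ([moleculetype], [atoms], [bonds],
# [exclusions]) and PREFIX.top ([defaults], [atomtypes],
# [nonbond_params], #include, [system], [molecules]).  Bond lengths are
# written in nm and sigma in nm (internal Angstrom divided by 10); k stays
# in kJ mol^-1 nm^-2 and epsilon in kJ/mol.  The files round-trip through
# readTopology.

#' Write a GROMACS-dialect topology
#'
#' @param model a typed \linkS4class{FibrilModel}.
#' @param topology the matching \linkS4class{CGTopology}.
#' @param prefix output path prefix; \code{PREFIX.itp} and
#'   \code{PREFIX.top} are written.
#' @return character vector of the two paths, invisibly.
#' @export
#' @examples
#' sys <- buildTopology(buildChain(2))
#' writeTopology(sys$model, sys$topology, tempfile())
writeTopology <- function(model, topology, prefix) {
  if (anyNA(topology@types) || !length(topology@types))
    stop("invalid model: bead types not assigned")
  b <- model@beads
  itp <- c(
    "; CG cellulose elastic-network topology",
    "[ moleculetype ]",
    "; name  nrexcl",
    "CELLU   0",
    "",
    "[ atoms ]",
    ";  nr  type  resnr  resid  atom  cgnr  charge  mass",
    sprintf("%6d %6s %6d %6s %6s %6d %8.3f %8.3f",
            seq_len(nrow(b)), topology@types, b$residue + 1L, "BGC",
            b$atom, seq_len(nrow(b)), topology@charges, topology@masses),
    "",
    "[ bonds ]",
    ";   i     j  func      r0(nm)      k(kJ/mol/nm2) ; class label",
    sprintf("%6d %6d %4d %12.6f %14.4f ; %s %s",
            topology@bonds$i, topology@bonds$j, 1L,
            topology@bonds$r0 / 10, topology@bonds$k,
            topology@bonds$class, topology@bonds$label),
    "",
    "[ exclusions ]",
    "; elastic-network neighbourhood pairs, excluded from nonbonded terms",
    sprintf("%6d %6d", topology@exclusions$i, topology@exclusions$j))
  nb <- topology@nonbonded
  utypes <- sort(unique(c(nb$type_a, nb$type_b)))
  top <- c(
    "; CG cellulose system topology",
    "[ defaults ]",
    "; nbfunc  comb-rule",
    "1 1",
    "",
    "[ atomtypes ]",
    "; name  mass  charge  ptype  sigma(nm)  epsilon",
    sprintf("%6s %8.3f %8.3f %3s %10.6f %10.6f",
            utypes,
            ifelse(is.na(.TYPE_MASS[utypes]), 72, .TYPE_MASS[utypes]),
            0, "A", 0, 0),
    "",
    "[ nonbond_params ]",
    ";  i  j  func  sigma(nm)  epsilon(kJ/mol)",
    sprintf("%6s %6s %4d %10.6f %10.6f",
            nb$type_a, nb$type_b, 1L, nb$sigma / 10, nb$epsilon),
    "",
    sprintf("#include \"%s.itp\"", basename(prefix)),
    "",
    "[ system ]",
    sprintf("CG cellulose %s", model@allomorph),
    "",
    "[ molecules ]",
    "CELLU 1")
  itp_path <- paste0(prefix, ".itp")
  top_path <- paste0(prefix, ".top")
  writeLines(itp, itp_path)
  writeLines(top, top_path)
  invisible(c(itp = itp_path, top = top_path))
}

.topoSection <- function(lines, name, keep_comments = FALSE) {
  starts <- grep(sprintf("^\\[\\s*%s\\s*\\]", name), lines)
  if (!length(starts)) return(character(0))
  out <- character(0)
  for (s in starts) {
    i <- s + 1L
    while (i <= length(lines) && !grepl("^\\[", lines[i])) {
      ln <- if (keep_comments) lines[i] else sub(";.*$", "", lines[i])
      if (nzchar(trimws(sub(";.*$", "", lines[i]))))
        out <- c(out, trimws(ln))
      i <- i + 1L
    }
  }
  out
}

#' Read a GROMACS-dialect topology written by \code{\link{writeTopology}}
#'
#' @param prefix path prefix used when writing.
#' @return A \linkS4class{CGTopology} (distances converted back to
#'   Angstrom).
#' @export
readTopology <- function(prefix) {
  itp_path <- paste0(prefix, ".itp")
  top_path <- paste0(prefix, ".top")
  for (p in c(itp_path, top_path))
    if (!file.exists(p)) stop("no such file: ", p)
  itp <- readLines(itp_path)
  top <- readLines(top_path)
  atoms <- .topoSection(itp, "atoms")
  af <- read.table(text = atoms, stringsAsFactors = FALSE)
  types <- af$V2
  masses <- af$V8
  charges <- af$V7
  # the [bonds] comment fields carry class/label
  raw_bonds <- .topoSection(itp, "bonds", keep_comments = TRUE)
  comment <- sub("^[^;]*;\\s*", "", raw_bonds)
  cls <- vapply(strsplit(comment, "\\s+"), `[`, "", 1)
  lab <- vapply(strsplit(comment, "\\s+"), `[`, "", 2)
  bf <- read.table(text = sub(";.*$", "", raw_bonds),
                   stringsAsFactors = FALSE)
  bonds <- data.frame(i = bf$V1, j = bf$V2, r0 = bf$V4 * 10, k = bf$V5,
                      class = cls, label = lab, stringsAsFactors = FALSE)
  exl <- .topoSection(itp, "exclusions")
  ex <- if (length(exl)) {
    ef <- read.table(text = exl, stringsAsFactors = FALSE)
    data.frame(i = ef$V1, j = ef$V2)
  } else data.frame(i = integer(0), j = integer(0))
  nbl <- .topoSection(top, "nonbond_params")
  nf <- read.table(text = nbl, stringsAsFactors = FALSE)
  nonbonded <- data.frame(type_a = nf$V1, type_b = nf$V2,
                          sigma = nf$V4 * 10, epsilon = nf$V5,
                          stringsAsFactors = FALSE)
  new("CGTopology", bonds = bonds, nonbonded = nonbonded, exclusions = ex,
      types = types, masses = masses, charges = charges)
}
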