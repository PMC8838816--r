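# Structure and trajectory I/O: PDB (via bio3d) and GRO (native parser).
#
# Conventions: coordinates are Angstrom in memory and in PDB files, nm in
# GRO files (converted on I/O, factor 10).  Chains are written as one
# letter per cellulose chain and residues 1-based; internally chains and
# residues are 0-based.  CG beads keep their source-atom names
# (O2/O3/C6/O6) so built and mapped models are interchangeable.

.CHAIN_IDS <- c(LETTERS, letters, as.character(0:9))

.chainLetter <- function(chain0) {
  .CHAIN_IDS[(chain0 %% length(.CHAIN_IDS)) + 1L]
}

#' Write a structure file (PDB or GRO)
#'
#' @param model a \linkS4class{FibrilModel}.
#' @param path output path; format chosen by extension (\code{.pdb} or
#'   \code{.gro}).
#' @return \code{path}, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".gro")
#' writeStructure(buildChain(2), f)
writeStructure <- function(model, path) {
  ext <- tolower(tools::file_ext(path))
  b <- model@beads
  if (ext == "pdb") {
    n <- nrow(b)
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(model@coords)),
                     resno = b$residue + 1L,
                     chain = .chainLetter(b$chain),
                     resid = rep("BGC", n),
                     elety = b$atom,
                     o = rep(1, n), b = rep(0, n))
  } else if (ext == "gro") {
    .writeGroFrame(path, model@coords, b, model@box,
                   title = sprintf("CG cellulose %s", model@allomorph),
                   append = FALSE)
  } else stop("unsupported structure format: ", ext)
  invisible(path)
}

.writeGroFrame <- function(path, xyz, beadtab, box, title, append) {
  n <- nrow(xyz)
  lines <- character(n + 3L)
  lines[1] <- title
  lines[2] <- sprintf("%d", n)
  resnr <- (beadtab$residue + 1L)
  lines[2 + seq_len(n)] <- sprintf(
    "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
    ((resnr - 1L) %% 100000L) + 1L, "BGC", beadtab$atom,
    ((seq_len(n) - 1L) %% 100000L) + 1L,
    xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10)
  lines[n + 3L] <- sprintf("%10.5f%10.5f%10.5f",
                           box[1, 1] / 10, box[2, 2] / 10, box[3, 3] / 10)
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# parse one GRO frame starting at line `at`; returns NULL at EOF
.parseGroFrame <- function(lines, at, path) {
  if (at > length(lines)) return(NULL)
  if (at + 1L > length(lines))
    stop(sprintf("parse error in %s, line %d: truncated header", path, at))
  natoms <- suppressWarnings(as.integer(trimws(lines[at + 1L])))
  if (is.na(natoms) || natoms < 1L)
    stop(sprintf("parse error in %s, line %d: bad atom count", path, at + 1L))
  last <- at + 1L + natoms + 1L
  if (last > length(lines))
    stop(sprintf("parse error in %s, line %d: truncated frame (expected %d atoms)",
                 path, length(lines), natoms))
  atl <- lines[at + 1L + seq_len(natoms)]
  resnr <- suppressWarnings(as.integer(substr(atl, 1, 5)))
  resnm <- trimws(substr(atl, 6, 10))
  atnm <- trimws(substr(atl, 11, 15))
  x <- suppressWarnings(as.numeric(substr(atl, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(atl, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(atl, 37, 44)))
  bad <- which(is.na(resnr) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop(sprintf("parse error in %s, line %d: malformed atom record",
                 path, at + 1L + bad[1]))
  bx <- suppressWarnings(as.numeric(strsplit(trimws(lines[last]), "\\s+")[[1]]))
  if (length(bx) < 3L || anyNA(bx[1:3]))
    stop(sprintf("parse error in %s, line %d: malformed box line", path, last))
  tm <- regmatches(lines[at], regexpr("t=\\s*[-0-9.eE+]+", lines[at]))
  time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
  list(resnr = resnr, resname = resnm, atom = atnm,
       xyz = cbind(x, y, z) * 10, box = diag(bx[1:3] * 10),
       time = time, next_at = last + 1L)
}

#' Read a structure file (PDB or GRO)
#'
#' Coordinates are returned in Angstrom (GRO nm values are multiplied by
#' 10).  If every residue carries exactly the four CG atoms (O2, O3, C6,
#' O6) the file is interpreted as a CG model and a
#' \linkS4class{FibrilModel} is returned; otherwise (or with
#' \code{as = "atoms"}) an atom-records data.frame is returned, suitable
#' for \code{\link{mapAtomistic}}.  In GRO files (which carry no chain
#' ids) a new chain starts where the residue number does not increase.
#'
#' @param path input path.
#' @param as \code{"auto"}, \code{"model"} or \code{"atoms"}.
#' @param allomorph allomorph tag for a returned model.
#' @return A \linkS4class{FibrilModel} or a data.frame with columns
#'   \code{chain}, \code{residue}, \code{atom}, \code{x}, \code{y},
#'   \code{z}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".gro")
#' writeStructure(buildChain(2), f)
#' readStructure(f)
readStructure <- function(path, as = c("auto", "model", "atoms"),
                          allomorph = c("Ibeta", "Ialpha", "II")) {
  as <- match.arg(as)
  allomorph <- match.arg(allomorph)
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e)
                      stop(sprintf("parse error in %s: %s", path,
                                   conditionMessage(e))))
    a <- pdb$atom
    chain <- a$chain
    chain[is.na(chain)] <- "A"
    rec <- data.frame(chain = match(chain, unique(chain)) - 1L,
                      residue = a$resno, atom = trimws(a$elety),
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  } else if (ext == "gro") {
    lines <- readLines(path)
    if (length(lines) < 3L)
      stop(sprintf("parse error in %s: truncated file", path))
    fr <- .parseGroFrame(lines, 1L, path)
    # chain break where the residue number does not increase
    newres <- c(TRUE, fr$resnr[-1] != fr$resnr[-length(fr$resnr)])
    res_ord <- cumsum(newres)                     # residue ordinal per atom
    chain_of_res <- cumsum(c(TRUE, diff(fr$resnr[newres]) <= 0))
    rec <- data.frame(chain = chain_of_res[res_ord] - 1L,
                      residue = fr$resnr, atom = fr$atom,
                      x = fr$xyz[, 1], y = fr$xyz[, 2], z = fr$xyz[, 3],
                      stringsAsFactors = FALSE)
  } else stop("unsupported structure format: ", ext)
  if (as == "atoms") return(rec)
  is_cg <- tryCatch({
    ok <- TRUE
    for (ch in unique(rec$chain)) {
      sub <- rec[rec$chain == ch, ]
      for (rr in unique(sub$residue)) {
        at <- sub$atom[sub$residue == rr]
        if (length(at) != 4L || !setequal(at, unname(.SITE_ATOM))) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    ok
  }, error = function(e) FALSE)
  if (!is_cg) {
    if (as == "model") stop("file is not a 4-bead CG structure")
    return(rec)
  }
  mod <- mapAtomistic(rec, allomorph = allomorph)
  mod
}

#' Write a trajectory as multi-frame GRO
#'
#' One GRO block per frame, with the frame time recorded as \code{t=} in
#' the title line.  Precision is the GRO fixed format (0.001 nm = 0.01
#' Angstrom).
#'
#' @param traj a \linkS4class{CGTrajectory}.
#' @param model the matching \linkS4class{FibrilModel} (provides residue
#'   and atom names).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectoryGRO <- function(traj, model, path) {
  if (nFrames(traj) < 1L) stop("format error: empty trajectory")
  if (nBeads(traj) != nBeads(model))
    stop("format error: trajectory and model bead counts differ")
  if (file.exists(path)) file.remove(path)
  for (fr in seq_len(nFrames(traj))) {
    .writeGroFrame(path, getFrame(traj, fr), model@beads, traj@box,
                   title = sprintf("frame %d t= %.6f", fr, traj@times[fr]),
                   append = fr > 1L)
  }
  invisible(path)
}

#' Read a multi-frame GRO trajectory
#'
#' @param path input path.
#' @return A \linkS4class{CGTrajectory} (coordinates Angstrom; frame
#'   times from the \code{t=} title fields, or frame indices if absent).
#' @export
readTrajectoryGRO <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop(sprintf("format error in %s: empty trajectory", path))
  frames <- list(); times <- numeric(0); box <- diag(3) * 100
  at <- 1L
  repeat {
    fr <- .parseGroFrame(lines, at, path)
    if (is.null(fr)) break
    if (length(frames) && nrow(fr$xyz) != nrow(frames[[1]]))
      stop(sprintf("format error in %s: frame %d has %d atoms, expected %d",
                   path, length(frames) + 1L, nrow(fr$xyz),
                   nrow(frames[[1]])))
    frames[[length(frames) + 1L]] <- fr$xyz
    times <- c(times, if (is.na(fr$time)) length(frames) else fr$time)
    box <- fr$box
    at <- fr$next_at
    if (at > length(lines)) break
  }
  n <- nrow(frames[[1]])
  arr <- array(0, dim = c(n, 3L, length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  new("CGTrajectory", coords = arr, times = times, box = box,
      seed = NA_integer_, config = list())
}
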