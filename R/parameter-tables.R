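# Canonical parameter tables of the CG cellulose model.  All distances are
# in Angstrom, elastic constants in kJ mol^-1 nm^-2 (the harmonic form is
# V = 1/2 k (r - r0)^2 with r in nm), LJ epsilon in kJ/mol.

# site <-> source-atom correspondence is fixed by the mapping
.SITE_LEVELS <- c("CG1", "CG2", "CG3", "CG4")
.SITE_ATOM <- c(CG1 = "O2", CG2 = "O3", CG3 = "C6", CG4 = "O6")
.ATOM_SITE <- setNames(names(.SITE_ATOM), .SITE_ATOM)

# Martini 3 bead type per site: the C6 site is a tiny apolar bead, the three
# oxygen-centred sites are small polar beads
.SITE_TYPE <- c(CG1 = "SP6", CG2 = "SP6", CG3 = "TC1", CG4 = "SP6")

# Standard Martini 3 masses for small (S) and tiny (T) beads, amu
.TYPE_MASS <- c(SP6 = 54, TC1 = 36)

.NEIGHBOUR_LEVELS <- c("none", "1st", "2nd")

#' Bonded (elastic-network) parameter table
#'
#' The optimal harmonic bond parameters of the CG cellulose model: six
#' intra-residue pairs, three first-neighbour pairs and three
#' second-neighbour pairs per residue junction.  The two flexible
#' intra-residue pairs (O2-O6, O3-O6), whose atomistic distance
#' distributions are bimodal, carry a soft 2500 kJ mol^-1 nm^-2 spring; all
#' other pairs are stiff (30000 kJ mol^-1 nm^-2).  The O6 site has no
#' inter-residue bonds.  The same table is used for all three allomorphs,
#' which is what makes the model transferable between them.
#'
#' @return A data.frame with columns \code{neighbours} (\code{"none"},
#'   \code{"1st"}, \code{"2nd"}), \code{label} (e.g. \code{"O2-O3"}),
#'   \code{r0} (Angstrom) and \code{k} (kJ mol^-1 nm^-2).
#' @seealso \code{\link{nonbondedParameterTable}}, \code{\link{makeBondTerms}}
#' @export
#' @examples
#' bondedParameterTable()
bondedParameterTable <- function() {
  data.frame(
    neighbours = c(rep("none", 6), rep("1st", 3), rep("2nd", 3)),
    label = c("O2-O3", "O2-C6", "O3-C6", "C6-O6", "O2-O6", "O3-O6",
              "O2-O2", "O3-O3", "C6-C6",
              "O2-O2", "O3-O3", "C6-C6"),
    r0 = c(2.88, 5.62, 4.94, 1.43, 6.42, 5.76,
           7.56, 6.69, 7.47,
           10.44, 10.44, 10.44),
    k = c(30000, 30000, 30000, 30000, 2500, 2500,
          30000, 30000, 30000,
          30000, 30000, 30000),
    stringsAsFactors = FALSE
  )
}

#' Nonbonded (Martini 3) parameter table
#'
#' The Lennard-Jones (12-6) parameters of the model for the bead types it
#' uses: SP6 (the O2/O3/O6 sites), TC1 (the C6 site) and their cross terms
#' with Martini water (W).  Only these printed pairs are defined; there are
#' no combining rules, and looking up an absent pair is an error.  All
#' cellulose beads are uncharged.
#'
#' @return A data.frame with columns \code{type_a}, \code{type_b},
#'   \code{sigma} (Angstrom) and \code{epsilon} (kJ/mol).
#' @seealso \code{\link{nonbondedLookup}}
#' @export
#' @examples
#' nonbondedParameterTable()
nonbondedParameterTable <- function() {
  data.frame(
    type_a = c("W", "SP6", "W", "TC1", "SP6"),
    type_b = c("SP6", "SP6", "TC1", "TC1", "TC1"),
    sigma = c(4.250, 4.100, 4.150, 3.400, 4.840),
    epsilon = c(4.530, 4.290, 0.550, 1.510, 0.890),
    stringsAsFactors = FALSE
  )
}

#' Site/atom/bead-type correspondence of the 4-bead mapping
#'
#' @return A data.frame with one row per CG site giving the site label, the
#'   source atom whose position the bead inherits, the Martini 3 bead type
#'   and the bead mass (amu).
#' @export
#' @examples
#' siteTable()
siteTable <- function() {
  data.frame(
    site = .SITE_LEVELS,
    atom = unname(.SITE_ATOM),
    type = unname(.SITE_TYPE),
    mass = unname(.TYPE_MASS[.SITE_TYPE]),
    stringsAsFactors = FALSE
  )
}

# fast (label, neighbours) -> row lookup into bondedParameterTable()
.bondedKey <- function(label, neighbours) paste(neighbours, label, sep = "|")

.bondedMap <- function(table = bondedParameterTable()) {
  setNames(seq_len(nrow(table)), .bondedKey(table$label, table$neighbours))
}
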