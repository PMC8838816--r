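# Bead typing, bonded terms and nonbonded lookups.

#' Assign Martini 3 bead types, masses and charges to a model
#'
#' The C6-centred site (CG3) is a tiny apolar TC1 bead; the three
#' oxygen-centred sites (CG1, CG2, CG4) are small polar SP6 beads.  Masses
#' are the standard Martini 3 small/tiny bead masses (54 and 36 amu,
#' overridable); all cellulose beads are uncharged.
#'
#' @param model a \linkS4class{FibrilModel}.
#' @param site_types named character vector mapping site labels to bead
#'   types; default \code{c(CG1 = "SP6", CG2 = "SP6", CG3 = "TC1",
#'   CG4 = "SP6")}.  Used by the bead-type scan to try candidate types.
#' @param masses named numeric vector mapping bead types to masses (amu).
#'   Types missing from this vector get the mass of their size class
#'   (72 regular, 54 small (S), 36 tiny (T)).
#' @return The model with \code{type} and \code{mass} filled in.
#' @export
#' @examples
#' ch <- assignBeadTypes(buildChain(2))
#' table(beads(ch)$type)
assignBeadTypes <- function(model, site_types = .SITE_TYPE,
                            masses = .TYPE_MASS) {
  b <- model@beads
  if (!all(b$site %in% names(site_types)))
    stop("invalid model: unknown site label(s) ",
         paste(setdiff(unique(b$site), names(site_types)), collapse = ", "))
  b$type <- unname(site_types[b$site])
  b$mass <- unname(masses[b$type])
  miss <- is.na(b$mass)
  if (any(miss)) b$mass[miss] <- .massFromTypeName(b$type[miss])
  b$charge <- 0
  model@beads <- b
  validObject(model)
  model
}

# Martini 3 size-class masses: S* -> 54, T* -> 36, otherwise 72 amu
.massFromTypeName <- function(type) {
  first <- substr(type, 1, 1)
  ifelse(first == "S", 54, ifelse(first == "T", 36, 72))
}

#' Generate the elastic-network bond terms for a model
#'
#' One harmonic bond per \code{\link{schConnectivity}} pair, with
#' \code{(r0, k)} looked up from the bonded parameter table by (pair label,
#' neighbour class).  Bonds are intra-chain only: chains interact solely
#' through nonbonded terms.
#'
#' @param model a \linkS4class{FibrilModel}.
#' @param bonded bonded parameter table.
#' @return data.frame of bond terms (columns \code{i}, \code{j}, \code{r0}
#'   in Angstrom, \code{k} in kJ mol^-1 nm^-2, \code{class}, \code{label}).
#' @export
#' @examples
#' bt <- makeBondTerms(buildChain(1))
#' nrow(bt)  # 6
makeBondTerms <- function(model, bonded = bondedParameterTable()) {
  conn <- schConnectivity(model)
  map <- .bondedMap(bonded)
  idx <- map[.bondedKey(conn$label, conn$class)]
  if (anyNA(idx)) {
    bad <- unique(paste0("(", conn$label, ", ", conn$class, ")")[is.na(idx)])
    stop("missing parameter: no bonded entry for ",
         paste(bad, collapse = ", "))
  }
  data.frame(i = conn$i, j = conn$j,
             r0 = bonded$r0[idx], k = bonded$k[idx],
             class = conn$class, label = conn$label,
             stringsAsFactors = FALSE)
}

#' Look up a nonbonded (sigma, epsilon) pair
#'
#' Symmetric exact lookup in the nonbonded table; there are no combining
#' rules, so a pair absent from the table is an error.
#'
#' @param a,b bead type names.
#' @param table nonbonded table (default
#'   \code{\link{nonbondedParameterTable}}).
#' @return named numeric vector \code{c(sigma = , epsilon = )}, Angstrom
#'   and kJ/mol.
#' @export
#' @examples
#' nonbondedLookup("TC1", "SP6")
nonbondedLookup <- function(a, b, table = nonbondedParameterTable()) {
  hit <- (table$type_a == a & table$type_b == b) |
         (table$type_a == b & table$type_b == a)
  if (!any(hit))
    stop(sprintf("missing parameter: no nonbonded entry for (%s, %s)", a, b))
  row <- table[which(hit)[1], ]
  c(sigma = row$sigma, epsilon = row$epsilon)
}

#' Nonbonded exclusions of a model
#'
#' By default every intra-chain bead pair is excluded from nonbonded
#' interactions: a chain's internal structure is governed entirely by its
#' elastic network, and the LJ matrix acts between chains - which is how
#' the model is constructed (excluding at least the bonded pairs is
#' obligatory in any case: several sit far inside the LJ sigma).  A
#' finite \code{depth} limits the exclusions to intra-chain pairs whose
#' residues are within \code{depth} of each other (2 = the
#' elastic-network neighbourhood), re-enabling long-range intra-chain LJ
#' for studies of chain self-contact.
#'
#' @param model a \linkS4class{FibrilModel}.
#' @param depth residue separation up to which intra-chain pairs are
#'   excluded; \code{Inf} (default) excludes all intra-chain pairs.
#' @return data.frame with columns \code{i}, \code{j} (1-based bead row
#'   indices, \code{i < j}).
#' @export
#' @examples
#' nrow(makeExclusions(buildChain(1)))  # 6: all intra-residue pairs
makeExclusions <- function(model, depth = Inf) {
  b <- model@beads
  parts <- list()
  for (ch in unique(b$chain)) {
    rows <- which(b$chain == ch)
    if (is.infinite(depth)) {
      pp <- expand.grid(i = rows, j = rows, KEEP.OUT.ATTRS = FALSE)
      parts[[length(parts) + 1L]] <- pp[pp$i < pp$j, , drop = FALSE]
      next
    }
    by_res <- split(rows, b$residue[rows])
    keys <- sort(as.integer(names(by_res)))
    for (dr in 0:depth) {
      for (r in keys) {
        r2 <- as.character(r + dr)
        if (!r2 %in% names(by_res)) next
        pp <- expand.grid(i = by_res[[as.character(r)]],
                          j = by_res[[r2]],
                          KEEP.OUT.ATTRS = FALSE)
        pp <- pp[pp$i < pp$j, , drop = FALSE]
        parts[[length(parts) + 1L]] <- pp
      }
    }
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the full interaction topology of a model
#'
#' Convenience wrapper: assigns bead types (unless already assigned),
#' generates the bond terms and attaches the nonbonded table.
#'
#' @param model a \linkS4class{FibrilModel}.
#' @param bonded bonded parameter table.
#' @param nonbonded nonbonded parameter table.
#' @param site_types,masses passed to \code{\link{assignBeadTypes}}.
#' @param exclusion_depth passed to \code{\link{makeExclusions}}.
#' @return A list with elements \code{model} (the typed model) and
#'   \code{topology} (a \linkS4class{CGTopology}).
#' @export
#' @examples
#' sys <- buildTopology(buildChain(3))
#' sys$topology
buildTopology <- function(model, bonded = bondedParameterTable(),
                          nonbonded = nonbondedParameterTable(),
                          site_types = .SITE_TYPE, masses = .TYPE_MASS,
                          exclusion_depth = Inf) {
  if (anyNA(model@beads$type))
    model <- assignBeadTypes(model, site_types, masses)
  topo <- new("CGTopology",
              bonds = makeBondTerms(model, bonded),
              nonbonded = nonbonded,
              exclusions = makeExclusions(model, depth = exclusion_depth),
              types = model@beads$type,
              masses = model@beads$mass,
              charges = model@beads$charge)
  list(model = model, topology = topo)
}
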