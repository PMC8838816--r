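# Bead-type / elastic-constant selection protocol: sweep candidate Martini
# types for the oxygen sites and soft-spring constants for the two flexible
# intra-residue bonds, score every grid point by time-average RMSD from the
# reference structure, and pick the grid point whose worst-case (over
# systems) RMSD is smallest.

#' Scan specification
#'
#' Defaults reproduce the selection grid of the model's parameterization:
#' 18 candidate Martini 3 interaction types for the oxygen-centred beads
#' (the C6 bead is held fixed at TC1) crossed with three soft elastic
#' constants (25, 250, 2500 kJ mol^-1 nm^-2) for the O2-O6 and O3-O6
#' bonds, evaluated on all three allomorphs.  Each grid point simulates a
#' small fibril (the selection protocol scored fibril systems; a free
#' chain's RMSD is dominated by its zero-energy network mechanism and
#' does not discriminate between candidates).  System size and run
#' length are desk-scale defaults; the protocol, not the absolute
#' scale, is what the scan machinery implements.
#'
#' @param candidate_types character vector of candidate bead types.
#' @param elastic_candidates numeric vector of soft-spring constants,
#'   kJ mol^-1 nm^-2.
#' @param systems allomorphs to evaluate each grid point on.
#' @param n_chains,layout fibril size of the test system.
#' @param n_residues chain length of the test system.
#' @param n_steps,report_every dynamics length per run.  The 1 ns default
#'   is the shortest length at which the RMSD ranking of the soft-spring
#'   candidates is converged rather than noise-dominated.
#' @param temperature K.
#' @param seed integer; every run's seed is derived deterministically from
#'   it.
#' @param scan_cg3 if TRUE the candidate type is also applied to the C6
#'   site instead of holding it at TC1.
#' @return list of class \code{"scanSpec"}.
#' @export
#' @examples
#' length(scanSpec()$candidate_types)  # 18
scanSpec <- function(candidate_types = c("P1", "P6", "SP1", "SP6", "TP1",
                                         "TP6", "N1", "N6", "SN1", "SN6",
                                         "TN1", "TN6", "C1", "C6", "SC1",
                                         "SC6", "TC1", "TC6"),
                     elastic_candidates = c(25, 250, 2500),
                     systems = c("Ialpha", "Ibeta", "II"),
                     n_chains = 4L, layout = c(2L, 2L),
                     n_residues = 10, n_steps = 50000, report_every = 250,
                     temperature = 300, seed = 1L, scan_cg3 = FALSE) {
  structure(list(candidate_types = candidate_types,
                 elastic_candidates = elastic_candidates,
                 systems = systems, n_chains = as.integer(n_chains),
                 layout = as.integer(layout),
                 n_residues = as.integer(n_residues),
                 n_steps = as.integer(n_steps),
                 report_every = as.integer(report_every),
                 temperature = temperature, seed = as.integer(seed),
                 scan_cg3 = isTRUE(scan_cg3)),
            class = "scanSpec")
}

.scanPairsNeeded <- function(type, scan_cg3) {
  if (scan_cg3) list(c(type, type))
  else list(c(type, type), c(type, "TC1"), c("TC1", "TC1"))
}

.hasPair <- function(params, a, b) {
  any((params$type_a == a & params$type_b == b) |
      (params$type_a == b & params$type_b == a))
}

#' Run the bead-type / elastic-constant scan
#'
#' For every (candidate type, soft constant) grid point and every system in
#' the spec: build a small ideal fibril, assign the candidate type to the
#' oxygen sites, soften the O2-O6/O3-O6 springs to the candidate constant,
#' minimize, run short thermostatted dynamics and compute the
#' Kabsch-superposed time-average RMSD against the minimized start
#' structure.  Grid points whose
#' nonbonded parameters are not supplied are marked
#' \code{"missing-parameters"}; runs that blow up numerically are marked
#' \code{"unstable"} and excluded from ranking, and the scan continues.
#'
#' @param spec a \code{\link{scanSpec}}.
#' @param params nonbonded parameter data.frame (\code{type_a},
#'   \code{type_b}, \code{sigma} Angstrom, \code{epsilon} kJ/mol) covering
#'   the candidate types; defaults to the packaged table, which only
#'   covers the SP6/TC1 subset.
#' @return list with \code{results} (one row per type x k x system:
#'   \code{type}, \code{k}, \code{system}, \code{mean_rmsd}, \code{sd},
#'   \code{status}), \code{ranking} (from \code{\link{rankScan}}) and
#'   \code{selected} (list with \code{type} and \code{k} of the best grid
#'   point, or NULL if none completed).
#' @export
#' @examples
#' sp <- scanSpec(candidate_types = "SP6", systems = "Ibeta",
#'                n_residues = 4, n_steps = 200, report_every = 20)
#' beadTypeScan(sp)$selected
beadTypeScan <- function(spec = scanSpec(),
                         params = nonbondedParameterTable()) {
  stopifnot(inherits(spec, "scanSpec"))
  grid <- expand.grid(type = spec$candidate_types,
                      k = spec$elastic_candidates,
                      stringsAsFactors = FALSE)
  rows <- list()
  run_id <- 0L
  for (g in seq_len(nrow(grid))) {
    type <- grid$type[g]; ks <- grid$k[g]
    needed <- .scanPairsNeeded(type, spec$scan_cg3)
    have <- all(vapply(needed, function(p) .hasPair(params, p[1], p[2]),
                       TRUE))
    bonded <- bondedParameterTable()
    soft <- bonded$label %in% c("O2-O6", "O3-O6") & bonded$neighbours == "none"
    bonded$k[soft] <- ks
    site_types <- if (spec$scan_cg3)
      c(CG1 = type, CG2 = type, CG3 = type, CG4 = type)
    else c(CG1 = type, CG2 = type, CG3 = "TC1", CG4 = type)
    for (sys_name in spec$systems) {
      run_id <- run_id + 1L
      row <- data.frame(type = type, k = ks, system = sys_name,
                        mean_rmsd = NA_real_, sd = NA_real_,
                        status = "ok", stringsAsFactors = FALSE)
      if (!have) {
        row$status <- "missing-parameters"
        rows[[length(rows) + 1L]] <- row
        next
      }
      res <- try({
        model <- if (spec$n_chains > 1L)
          buildFibril(spec$n_chains, spec$layout, spec$n_residues,
                      sys_name, bonded = bonded)
        else buildChain(spec$n_residues, sys_name, bonded = bonded)
        model <- assignBeadTypes(model, site_types = site_types,
                                 masses = .TYPE_MASS)
        sys <- buildTopology(model, bonded = bonded, nonbonded = params,
                             site_types = site_types)
        mn <- minimizeEnergy(sys$model, sys$topology, max_steps = 2000,
                             ftol = 100)
        cfg <- engineConfig(temperature = spec$temperature,
                            seed = spec$seed + run_id)
        tr <- runDynamics(mn$model, sys$topology, cfg,
                          n_steps = spec$n_steps,
                          report_every = spec$report_every)
        trajectoryRMSD(tr, coords(mn$model), superpose = TRUE)
      }, silent = TRUE)
      if (inherits(res, "try-error") || !is.finite(res$mean)) {
        row$status <- "unstable"
      } else {
        row$mean_rmsd <- res$mean
        row$sd <- res$sd
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ranking <- rankScan(results)
  selected <- if (nrow(ranking)) list(type = ranking$type[1],
                                      k = ranking$k[1]) else NULL
  list(results = results, ranking = ranking, selected = selected)
}

#' Rank scan results
#'
#' Pure re-ranking of a saved results table.  A grid point qualifies only
#' if every system completed (\code{status == "ok"}); its score is the
#' aggregated per-system mean RMSD ("simultaneously small for all
#' fibrils"), by default the maximum over systems, so lowering any
#' system's RMSD can only improve (never worsen) a candidate's rank.
#'
#' @param results results data.frame from \code{\link{beadTypeScan}}.
#' @param aggregate \code{"max"} (default) or \code{"mean"}.
#' @return data.frame with \code{type}, \code{k}, \code{score}, sorted
#'   ascending by score.
#' @export
rankScan <- function(results, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "max") max else mean
  key <- paste(results$type, results$k)
  out <- list()
  for (kk in unique(key)) {
    sub <- results[key == kk, , drop = FALSE]
    if (any(sub$status != "ok")) next
    out[[length(out) + 1L]] <- data.frame(
      type = sub$type[1], k = sub$k[1],
      score = agg_fun(sub$mean_rmsd), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(type = character(0), k = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out <- out[order(out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
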