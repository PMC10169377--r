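# Reproducible demonstration breeding program and file-based entry points.
#
# These functions are the scriptable surface of the package: a founder
# simulation that writes standard files, a small but complete breeding
# program exercising the whole stack, and tabular/VCF exporters. Everything
# is driven by a serializable configuration, so a run is exactly
# reproducible from (config, seed).

#' Default demonstration configuration
#'
#' Small dimensions chosen for a fast demonstration; real simulations scale
#' all of these up.
#'
#' @return A named list understood by [runBreedingDemo()].
#' @export
demoConfig <- function() {
  list(
    seed = 1L,
    nFounders = 12L, nChr = 3L, nSegSites = 100L, nCsdAlleles = 16L,
    nColonies = 3L, nYears = 2L,
    nWorkers = 40L, nDrones = 12L, nFathers = 10L, nVirginQueens = 6L,
    pSwarm = 0.3, pCollapse = 0.1,
    selectProp = 0.67,
    traitMean = c(10, 0), traitVar = c(1, 1), traitCorA = -0.5,
    traitVarE = c(1, 2)
  )
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to [demoConfig()]
#' defaults.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- demoConfig()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

#' Simulate founders and write them to standard files
#'
#' Runs the founder-genome simulator and writes a phased VCF plus a
#' tab-separated site map (chromosome, site index, bp position).
#'
#' @param config configuration list (see [demoConfig()]); uses `seed`,
#'   `nFounders`, `nChr`, `nSegSites`.
#' @param outDir output directory (created if missing).
#' @return Invisibly, the `FounderGenomes` object.
#' @export
simulateFounders <- function(config = demoConfig(), outDir = ".") {
  if (config$nSegSites < 1) stopf("'nSegSites' must be positive")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config$seed))
  founders <- simulateFounderGenomes(nCar = config$nFounders,
                                     nChr = config$nChr,
                                     nSegSites = config$nSegSites)
  writePhasedVcf(founders, file.path(outDir, "founders.vcf"))
  map <- do.call(rbind, lapply(seq_len(founders$genome$nChr), function(c) {
    data.frame(chr = c, site = seq_along(founders$genome$lociPos[[c]]),
               pos = founders$genome$lociPos[[c]])
  }))
  utils::write.table(map, file.path(outDir, "founders_sites.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  message(sprintf("wrote %d founders, %s sites/chr to %s",
                  founders$nInd,
                  paste(vapply(founders$haplo, ncol, 1L), collapse = "/"),
                  outDir))
  invisible(founders)
}

#' Run a demonstration breeding program
#'
#' A complete, reproducible program on a small apiary: founder genomes, two
#' negatively correlated queen/worker-effect traits, base virgin queens, a
#' drone congregation area, colony creation, crossing and build-up, then
#' yearly cycles of stochastic swarming and collapse, colony-value
#' evaluation, truncation selection, and apiary replenishment by
#' supersedure-derived requeening. Writes per-year apiary summaries and
#' colony values, a final pedigree, and a one-line-per-event log.
#'
#' @param config configuration list (see [demoConfig()]).
#' @param outDir output directory.
#' @return Invisibly, a list with the final `MultiColony` and the paths
#'   written.
#' @export
runBreedingDemo <- function(config = demoConfig(), outDir = ".") {
  stopifnot(config$nColonies >= 1, config$nYears >= 1,
            config$selectProp > 0, config$selectProp <= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "events.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  logEvent <- function(year, event, id, detail = "") {
    writeLines(sprintf("year=%d event=%s colony=%s %s", year, event, id, detail), logCon)
  }

  set.seed(as.integer(config$seed))
  founders <- simulateFounderGenomes(nCar = config$nFounders,
                                     nChr = config$nChr,
                                     nSegSites = config$nSegSites)
  sp <- newSimParamBee(founders,
                       nWorkers = config$nWorkers, nDrones = config$nDrones,
                       nVirginQueens = config$nVirginQueens,
                       nFathers = config$nFathers,
                       nCsdAlleles = config$nCsdAlleles,
                       seed = config$seed)
  corA <- matrix(c(1, config$traitCorA, config$traitCorA, 1), 2L)
  addTraitA(nQtlPerChr = max(2L, config$nSegSites %/% 10L),
            mean = config$traitMean, var = config$traitVar, corA = corA,
            varE = config$traitVarE, simParamBee = sp)
  basePop <- createVirginQueens(founders, simParamBee = sp)
  if (nInd(basePop) < config$nColonies + 1L) {
    stopf("need at least nColonies + 1 founders for the demo")
  }
  queenLine <- basePop[seq_len(config$nColonies)]
  droneLine <- basePop[(config$nColonies + 1L):nInd(basePop)]
  dca <- createDrones(droneLine, nInd = 10L * config$nFathers, simParamBee = sp)

  apiary <- createMultiColony(queenLine, simParamBee = sp)
  pulled <- pullDroneGroupsFromDCA(dca, nColonies(apiary), simParamBee = sp)
  apiary <- cross(apiary, drones = pulled$groups, simParamBee = sp)
  dca <- pulled$dca
  apiary <- buildUp(apiary, simParamBee = sp)
  for (cl in apiary$colonies) logEvent(0L, "crossed+builtUp", cl$id)

  paths <- character(0)
  for (year in seq_len(config$nYears)) {
    # stochastic events
    nextCols <- list()
    for (cl in apiary$colonies) {
      u <- stats::runif(1L)
      if (u < config$pCollapse) {
        cl <- collapse(cl)
        logEvent(year, "collapse", cl$id)
        next # collapsed colonies leave the managed apiary
      } else if (u < config$pCollapse + config$pSwarm) {
        sw <- swarm(cl, simParamBee = sp)
        logEvent(year, "swarm", cl$id)
        # the beekeeper keeps the remnant and lets it requeen from the DCA
        g <- pullDroneGroupsFromDCA(dca, 1L, simParamBee = sp)
        dca <- g$dca
        cl <- cross(sw$remnant, drones = g$groups[[1L]], simParamBee = sp)
      }
      cl <- buildUp(cl, simParamBee = sp)
      nextCols[[length(nextCols) + 1L]] <- cl
    }
    if (!length(nextCols)) stopf("all colonies were lost in year %d", year)
    apiary <- createMultiColony(nextCols, simParamBee = sp)
    apiary <- setPheno(apiary, simParamBee = sp)
    gvals <- calcColonyValue(apiary, use = "gv", simParamBee = sp)
    pvals <- calcColonyValue(apiary, use = "pheno", simParamBee = sp)
    vals <- data.frame(year = year, colony = colonyIds(apiary),
                       gv = as.numeric(gvals), pheno = as.numeric(pvals))
    valPath <- file.path(outDir, sprintf("colony_values_year%d.csv", year))
    utils::write.csv(vals, valPath, row.names = FALSE)
    paths <- c(paths, valPath)

    nKeep <- max(1L, as.integer(ceiling(config$selectProp * nColonies(apiary))))
    apiary <- selectColonies(apiary, nKeep, use = pvals)
    for (id in colonyIds(apiary)) logEvent(year, "selected", id)
    # replenish to the target apiary size by splitting the best colony
    while (nColonies(apiary) < config$nColonies) {
      spl <- split.Colony(apiary$colonies[[1L]], simParamBee = sp)
      g <- pullDroneGroupsFromDCA(dca, 1L, simParamBee = sp)
      dca <- g$dca
      newCl <- cross(spl$split, drones = g$groups[[1L]], simParamBee = sp)
      newCl <- buildUp(newCl, simParamBee = sp)
      apiary$colonies[[1L]] <- spl$remnant
      apiary <- c(apiary, createMultiColony(list(newCl), simParamBee = sp))
      logEvent(year, "split+requeen", newCl$id)
    }
    sumPath <- file.path(outDir, sprintf("apiary_year%d.csv", year))
    utils::write.csv(apiarySummary(apiary), sumPath, row.names = FALSE)
    paths <- c(paths, sumPath)
  }
  pedPath <- file.path(outDir, "pedigree.csv")
  exportPedigree(pedPath, simParamBee = sp)
  paths <- c(paths, pedPath, logPath)
  invisible(list(apiary = apiary, simParamBee = sp, paths = paths))
}

#' Apiary summary table
#'
#' One row per colony: id, queen id, caste counts, and status flags.
#'
#' @param mc a `MultiColony`.
#' @return A data.frame.
#' @export
apiarySummary <- function(mc) {
  stopifnot(inherits(mc, "MultiColony"))
  do.call(rbind, lapply(mc$colonies, function(cl) {
    if (is.null(cl)) return(NULL)
    data.frame(colony = cl$id,
               queen = if (nQueens(cl)) cl$queen$id else NA_character_,
               nFathers = nFathers(cl), nWorkers = nWorkers(cl),
               nDrones = nDrones(cl), nVirginQueens = nVirginQueens(cl),
               swarmed = hasSwarmed(cl), split = hasSplit(cl),
               superseded = hasSuperseded(cl), collapsed = hasCollapsed(cl),
               productive = isProductive(cl))
  }))
}

#' Export the pedigree to CSV
#'
#' @param file output path.
#' @param simParamBee simulation parameters (default: global).
#' @return `file`, invisibly.
#' @export
exportPedigree <- function(file, simParamBee = NULL) {
  ped <- getPedigree(simParamBee)
  utils::write.csv(ped, file, row.names = FALSE)
  invisible(file)
}

#' Export colony values to CSV
#'
#' @param mc a `MultiColony` with phenotypes set.
#' @param file output path.
#' @param simParamBee simulation parameters (default: global).
#' @return `file`, invisibly.
#' @export
exportColonyValues <- function(mc, file, simParamBee = NULL) {
  sp <- getSimParamBee(simParamBee)
  if (is.null(sp$traits)) stopf("no traits defined; nothing to export")
  df <- data.frame(colony = colonyIds(mc),
                   gv = as.numeric(calcColonyValue(mc, "gv", simParamBee = sp)),
                   pheno = as.numeric(calcColonyValue(mc, "pheno", simParamBee = sp)))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
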