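## End-to-end orchestration: simulate (or load) -> filter -> windowed
## stats -> introgression scan -> ancestry dosage -> sweep scan -> beta
## scan -> joint outlier report, with deterministic seeded execution,
## TSV/BED/JSON artifacts, a MANIFEST of checksums and a log.

#' Full scan configuration
#'
#' Aggregates every module's parameters with the scan thresholds
#' (iSAFE > 0.1, introgression FDR, balancing-selection FDR 0.01, ADD
#' quantile 0.75, >= 100 SNPs per 10-kb window, >= 15 shared sites per
#' 10-kb bin).  The configuration fully determines a run; it is
#' serialized (YAML) next to the outputs.
#'
#' @param sim a [simConfig()] (the cohort to simulate), or NULL when
#'   reading `input` files.
#' @param input optional list(vcf=, popmap=, roles=) to scan an existing
#'   cohort instead of simulating.
#' @param filters a [filterConfig()].
#' @param fourTaxon list(P1=, P2=, P3=, O=) population labels; defaults
#'   to the roles recorded in the population map when NULL.
#' @param windowBp scan window size (default 10000).
#' @param minSnps minimum SNPs per introgression window (default 100).
#' @param introgressionFdr window FDR threshold (default 0.05).
#' @param hmm an [hmmConfig()].
#' @param hybridPop hybrid population for dosage/ADD (default: role P2).
#' @param isafe list(windowSize=, unit=, threshold=, casePop=,
#'   controlPop=).
#' @param beta list(minFreq=, halfwidthBp=, maxDiff=, fdr=, populations=)
#'   (`populations` NULL = all non-outgroup populations).
#' @param bs list(binBp=, minSites=).
#' @param addQuantile ADD quantile cutoff (default 0.75).
#' @param addMin donor-derived ADD cutoff (default 0.5).
#' @param seed top-level seed; every stochastic stage derives from it.
#' @return a `scan_config` list.
#' @export
scanConfig <- function(sim = simConfig(), input = NULL,
                       filters = filterConfig(), fourTaxon = NULL,
                       windowBp = 10000L, minSnps = 100L,
                       introgressionFdr = 0.05, hmm = hmmConfig(),
                       hybridPop = NULL,
                       isafe = list(windowSize = 300L, unit = "variants",
                                    threshold = 0.1, casePop = NULL,
                                    controlPop = NULL),
                       beta = list(minFreq = 0.1, halfwidthBp = 1000L,
                                   maxDiff = 0.1, fdr = 0.01,
                                   populations = NULL),
                       bs = list(binBp = 10000L, minSites = 15L),
                       addQuantile = 0.75, addMin = 0.5, seed = 42L) {
  structure(list(sim = sim, input = input, filters = filters,
                 fourTaxon = fourTaxon, windowBp = as.integer(windowBp),
                 minSnps = as.integer(minSnps),
                 introgressionFdr = introgressionFdr, hmm = hmm,
                 hybridPop = hybridPop, isafe = isafe, beta = beta,
                 bs = bs, addQuantile = addQuantile, addMin = addMin,
                 seed = as.integer(seed)),
            class = "scan_config")
}

#' Read / write a scan configuration as YAML
#'
#' @param path YAML file.
#' @return a `scan_config` (reader) or `path` invisibly (writer).
#' @export
readScanConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(simConfig, y$sim) else NULL
  cfg <- scanConfig(sim = sim, input = y$input,
                    filters = do.call(filterConfig, y$filters %||% list()),
                    fourTaxon = y$fourTaxon,
                    windowBp = y$windowBp %||% 10000L,
                    minSnps = y$minSnps %||% 100L,
                    introgressionFdr = y$introgressionFdr %||% 0.05,
                    hmm = do.call(hmmConfig, y$hmm %||% list()),
                    hybridPop = y$hybridPop,
                    isafe = y$isafe %||% list(windowSize = 300L,
                                              unit = "variants",
                                              threshold = 0.1),
                    beta = y$beta %||% list(minFreq = 0.1,
                                            halfwidthBp = 1000L,
                                            maxDiff = 0.1, fdr = 0.01),
                    bs = y$bs %||% list(binBp = 10000L, minSites = 15L),
                    addQuantile = y$addQuantile %||% 0.75,
                    addMin = y$addMin %||% 0.5,
                    seed = y$seed %||% 42L)
  cfg
}

#' @rdname readScanConfig
#' @param cfg a `scan_config`.
#' @export
writeScanConfig <- function(cfg, path) {
  yamlify <- function(x) {
    if (is.list(x)) lapply(unclass(x), yamlify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(yamlify(unclass(cfg)), path)
  invisible(path)
}

#' Joint outlier report (sweep x ancestry x introgression)
#'
#' Site level: the intersection of sweep candidates (iSAFE strictly
#' greater than the threshold) with high-ADD sites (ADD at or above the
#' genome-wide `addQuantile` threshold).  Window level: introgression
#' outlier windows (q < FDR) that also contain at least one high-ADD
#' site; joint sites are counted per window.
#'
#' @param isafeTab data.frame from [isafeScan()] (with `pos`).
#' @param track a [DosageTrack-class].
#' @param introgTab data.frame from [outlierWindows()].
#' @param isafeThreshold strict iSAFE cutoff (default 0.1).
#' @param addQuantile ADD quantile (default 0.75).
#' @return list with `sites` (joint outlier sites), `windows`
#'   (introgression outliers with `n_high_add`, `n_joint_sites`,
#'   `joint` flag), `addThreshold` and `summary` (counts per
#'   chromosome).  Empty inputs give an empty report.
#' @export
jointOutliers <- function(isafeTab, track, introgTab,
                          isafeThreshold = 0.1, addQuantile = 0.75) {
  empty <- list(sites = data.frame(chrom = character(), pos = integer(),
                                   isafe = numeric(), add = numeric()),
                windows = introgTab[0, , drop = FALSE],
                addThreshold = NA_real_,
                summary = data.frame(chrom = character(),
                                     n_joint_sites = integer(),
                                     n_joint_windows = integer()))
  if (!nrow(isafeTab) || !length(addScores(track))) return(empty)
  qm <- addQuantileMask(track, addQuantile)
  add <- addScores(track)
  m <- match(isafeTab$pos, positions(track))
  siteAdd <- add[m]
  hit <- isafeTab$isafe > isafeThreshold & !is.na(siteAdd) &
    siteAdd >= qm$threshold
  sites <- data.frame(chrom = track@chrom[m][hit], pos = isafeTab$pos[hit],
                      isafe = isafeTab$isafe[hit], add = siteAdd[hit])
  win <- introgTab
  highAddPos <- positions(track)[qm$mask]
  highAddChrom <- track@chrom[qm$mask]
  win$n_high_add <- vapply(seq_len(nrow(win)), function(i)
    sum(highAddChrom == win$chrom[i] & highAddPos > win$start[i] &
        highAddPos <= win$end[i]), integer(1))
  win$n_joint_sites <- vapply(seq_len(nrow(win)), function(i)
    sum(sites$chrom == win$chrom[i] & sites$pos > win$start[i] &
        sites$pos <= win$end[i]), integer(1))
  win$joint <- !is.na(win$outlier) & win$outlier & win$n_high_add > 0L
  summary <- do.call(rbind, lapply(unique(win$chrom), function(cc)
    data.frame(chrom = cc,
               n_joint_sites = sum(sites$chrom == cc),
               n_joint_windows = sum(win$joint[win$chrom == cc]))))
  list(sites = sites, windows = win, addThreshold = qm$threshold,
       summary = summary)
}

#' Run the full scan pipeline
#'
#' Executes simulate (or load) -> site filters -> LD pruning ->
#' supervised admixture -> windowed diversity -> introgression scan ->
#' ancestry dosage + ADD -> iSAFE sweep scan -> beta scan (per
#' population) -> shared-site intersection -> bins -> beta-ADD classes
#' -> joint outlier report, writing every stage's artifact under
#' `outDir` plus `MANIFEST.tsv` (md5 checksums of the data artifacts; a
#' failed run retains partial outputs and marks the manifest
#' incomplete), `config.yaml` and `pipeline.log`.  Deterministic for a
#' fixed configuration and seed.
#'
#' @param cfg a [scanConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
runPipeline <- function(cfg, outDir) {
  stopifnot(inherits(cfg, "scan_config"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "pipeline.log")
  logCon <- file(logPath, open = "wt")
  t0 <- Sys.time()
  logmsg <- function(...) {
    line <- sprintf("[%6.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(...))
    writeLines(line, logCon); message(line)
  }
  artifacts <- character()
  res <- list()
  stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      logmsg("stage %s: FAILED (%s)", name, conditionMessage(e))
      .write_manifest(outDir, artifacts, complete = FALSE)
      close(logCon)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    logmsg("stage %s: done", name)
    out
  }
  emit <- function(path) artifacts <<- c(artifacts, path)

  writeScanConfig(cfg, file.path(outDir, "config.yaml"))
  emit(file.path(outDir, "config.yaml"))
  logmsg("admixscan %s, seed %d",
         as.character(utils::packageVersion("admixscan")), cfg$seed)

  ## --- cohort ---------------------------------------------------------
  if (!is.null(cfg$input)) {
    res$cohort <- stage("load", {
      gd <- readVcfGT(cfg$input$vcf)
      pm <- readPopMap(cfg$input$popmap, cfg$input$roles)
      list(genotypes = gd, popmap = pm, truth = NULL)
    })
  } else {
    simCfg <- cfg$sim
    simCfg$seed <- cfg$seed
    res$cohort <- stage("simulate", simulateCohort(simCfg))
    stage("write-cohort", {
      writeVcfGT(res$cohort$genotypes, file.path(outDir, "cohort.vcf"))
      writePopMap(res$cohort$popmap, file.path(outDir, "popmap.tsv"),
                  file.path(outDir, "roles.tsv"))
      writeTruthJson(res$cohort$truth, file.path(outDir, "truth.json"))
      emit(file.path(outDir, "cohort.vcf"))
      emit(file.path(outDir, "popmap.tsv"))
      emit(file.path(outDir, "roles.tsv"))
      emit(file.path(outDir, "truth.json"))
    })
  }
  gd <- res$cohort$genotypes
  pm <- res$cohort$popmap
  if (nSites(gd) == 0L) {
    .warnf("runPipeline: cohort has 0 sites; writing empty reports")
    logmsg("cohort empty: 0 sites")
    for (f in c("diversity_windows.tsv", "introgression_windows.tsv",
                "dosage_add.tsv", "isafe_sites.tsv"))
      writeLines("chrom", file.path(outDir, f))
    .write_manifest(outDir, artifacts, complete = TRUE)
    close(logCon)
    return(invisible(res))
  }
  logmsg("cohort: %d sites x %d samples", nSites(gd), nSamples(gd))

  ## --- filters + pruning ----------------------------------------------
  res$filtered <- stage("filter", applySiteFilters(gd, cfg$filters))
  logmsg("filters: kept %d/%d (removed: %s)", res$filtered$nKept,
         res$filtered$nInput,
         paste(names(res$filtered$removed), res$filtered$removed,
               sep = "=", collapse = ", "))
  gd <- res$filtered$data
  res$pruned <- stage("ld-prune", ldPrune(gd))
  logmsg("ld-prune: %d/%d sites retained", length(res$pruned), nSites(gd))

  ## roles / populations
  p2 <- popsWithRole(pm, "P2"); p1 <- popsWithRole(pm, "P1")
  p3 <- popsWithRole(pm, "P3"); og <- popsWithRole(pm, "O")
  ft <- cfg$fourTaxon %||% list(P1 = p1[1], P2 = p2[1], P3 = p3[1], O = og[1])
  hybridPop <- cfg$hybridPop %||% p2[1]

  ## --- supervised admixture -------------------------------------------
  donors <- unname(hybridDonors(pm, hybridPop))
  res$admixture <- stage("admixture",
    supervisedAdmixture(gd, pm, donors, siteIdx = res$pruned))
  adf <- data.frame(sample = rownames(res$admixture), res$admixture,
                    check.names = FALSE)
  write.table(.fmt_num_cols(adf), file.path(outDir, "admixture.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  emit(file.path(outDir, "admixture.tsv"))

  ## --- windowed diversity ---------------------------------------------
  chromLengths <- NULL
  if (!is.null(cfg$sim))
    chromLengths <- setNames(as.numeric(cfg$sim$chromLengthBp), cfg$sim$chrom)
  res$diversity <- stage("diversity",
    windowedDiversity(gd, pm, windowBp = cfg$windowBp,
                      chromLengths = chromLengths))
  writeWindowTable(res$diversity, file.path(outDir, "diversity_windows.tsv"))
  emit(file.path(outDir, "diversity_windows.tsv"))

  ## --- introgression scan ---------------------------------------------
  ftc <- fourTaxonConfig(ft$P1, ft$P2, ft$P3, ft$O, windowBp = cfg$windowBp,
                         minSnps = cfg$minSnps)
  res$introg <- stage("introgression", {
    w <- windowDstats(gd, pm, ftc, chromLengths = chromLengths)
    outlierWindows(w, statistic = "d_f", fdr = cfg$introgressionFdr)
  })
  writeWindowTable(res$introg, file.path(outDir, "introgression_windows.tsv"))
  emit(file.path(outDir, "introgression_windows.tsv"))
  logmsg("introgression: %d/%d windows flagged",
         sum(res$introg$outlier, na.rm = TRUE), nrow(res$introg))

  ## --- ancestry dosage / ADD ------------------------------------------
  res$dosage <- stage("ancestry",
    ancestryDosageHmm(gd, pm, hybridPop, cfg = cfg$hmm))
  writeSiteTable(donorMeans(res$dosage), file.path(outDir, "dosage_add.tsv"))
  emit(file.path(outDir, "dosage_add.tsv"))
  logmsg("ancestry: ADD mean %.3f q75 %.3f max %.3f",
         mean(addScores(res$dosage)),
         quantile(addScores(res$dosage), 0.75, names = FALSE),
         max(addScores(res$dosage)))

  ## --- sweep scan ------------------------------------------------------
  casePop <- cfg$isafe$casePop %||% hybridPop
  controlPop <- cfg$isafe$controlPop %||% p1[1]
  res$isafe <- stage("sweep", {
    dh <- derivedHaplotypes(gd, pm, samplesOf(pm, casePop))
    ctl <- if (!is.null(controlPop) && !is.na(controlPop)) {
      dhc <- derivedHaplotypes(gd, pm, samplesOf(pm, controlPop))
      dhc$hap
    } else NULL
    tab <- isafeScan(dh$hap, dh$pos,
                     windowSize = cfg$isafe$windowSize %||% 300L,
                     unit = cfg$isafe$unit %||% "variants",
                     threshold = cfg$isafe$threshold %||% 0.1,
                     control = ctl)
    tab$chrom <- chroms(gd)[dh$siteIdx]
    tab
  })
  writeSiteTable(res$isafe, file.path(outDir, "isafe_sites.tsv"))
  emit(file.path(outDir, "isafe_sites.tsv"))
  logmsg("sweep: %d site(s) above iSAFE threshold",
         sum(res$isafe$significant))

  ## --- beta scan -------------------------------------------------------
  betaPops <- cfg$beta$populations %||%
    setdiff(populations(pm), popsWithRole(pm, "O"))
  res$beta <- stage("beta", {
    tabs <- lapply(betaPops, function(p)
      betaScores(gd, pm, p, minFreq = cfg$beta$minFreq %||% 0.1,
                 halfwidthBp = cfg$beta$halfwidthBp %||% 1000L,
                 maxDiff = cfg$beta$maxDiff %||% 0.1))
    names(tabs) <- betaPops
    tabs
  })
  for (p in betaPops) {
    writeSiteTable(res$beta[[p]], file.path(outDir, sprintf("beta_%s.tsv", p)))
    emit(file.path(outDir, sprintf("beta_%s.tsv", p)))
  }
  res$sharedBs <- stage("shared-bs",
    sharedBsSites(res$beta, fdr = cfg$beta$fdr %||% 0.01))
  writeSiteTable(data.frame(chrom = chroms(gd)[match(res$sharedBs$shared,
                                                     positions(gd))],
                            pos = res$sharedBs$shared),
                 file.path(outDir, "shared_bs_sites.tsv"))
  emit(file.path(outDir, "shared_bs_sites.tsv"))
  logmsg("beta: %d shared significant site(s)", length(res$sharedBs$shared))

  res$bsBins <- stage("bs-bins",
    bsBins(res$sharedBs$shared,
           chromLengths %||% setNames(
             vapply(unique(chroms(gd)), function(cc)
               as.numeric(ceiling(max(positions(gd)[chroms(gd) == cc]) /
                                    cfg$bs$binBp) * cfg$bs$binBp), 0),
             unique(chroms(gd))),
           binBp = cfg$bs$binBp %||% 10000L,
           minSites = cfg$bs$minSites %||% 15L,
           diversity = res$diversity))
  writeWindowTable(res$bsBins$bins, file.path(outDir, "bs_bins.tsv"))
  emit(file.path(outDir, "bs_bins.tsv"))

  res$betaClasses <- stage("beta-classify",
    betaAddClassify(res$beta[[hybridPop]], res$dosage,
                    fdr = cfg$beta$fdr %||% 0.01, addMin = cfg$addMin,
                    addQuantile = cfg$addQuantile))
  writeSiteTable(res$betaClasses, file.path(outDir, "beta_classes.tsv"))
  emit(file.path(outDir, "beta_classes.tsv"))

  ## --- joint report ----------------------------------------------------
  res$joint <- stage("joint",
    jointOutliers(res$isafe, res$dosage, res$introg,
                  isafeThreshold = cfg$isafe$threshold %||% 0.1,
                  addQuantile = cfg$addQuantile))
  jointOut <- list(add_threshold = res$joint$addThreshold,
                   n_joint_sites = nrow(res$joint$sites),
                   joint_sites = res$joint$sites,
                   summary = res$joint$summary)
  jsonlite::write_json(jointOut, file.path(outDir, "joint_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  emit(file.path(outDir, "joint_report.json"))
  writeWindowTable(res$joint$windows, file.path(outDir, "joint_windows.tsv"))
  emit(file.path(outDir, "joint_windows.tsv"))
  logmsg("joint: %d site(s), %d window(s)", nrow(res$joint$sites),
         sum(res$joint$windows$joint))

  .write_manifest(outDir, artifacts, complete = TRUE)
  logmsg("pipeline complete")
  close(logCon)
  invisible(res)
}

.write_manifest <- function(outDir, artifacts, complete) {
  df <- data.frame(file = basename(artifacts),
                   md5 = unname(tools::md5sum(artifacts)))
  df <- df[order(df$file), , drop = FALSE]
  lines <- c(sprintf("# status: %s", if (complete) "complete" else "INCOMPLETE"),
             paste(df$file, df$md5, sep = "\t"))
  writeLines(lines, file.path(outDir, "MANIFEST.tsv"))
}
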