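.PIPELINE_STAGES <- c("simulate", "count", "correct", "footprint", "dynamics")

#' Validate a pipeline configuration
#'
#' Reads a declarative JSON configuration for the synthetic end-to-end
#' pipeline, fills in defaults, and either returns the validated
#' configuration or aborts with the full list of violations.
#'
#' The schema (all stage blocks optional unless the stage is selected):
#' \preformatted{
#' {
#'   "seed": 1, "outdir": "out",
#'   "stages": ["simulate", "count", "correct", "footprint", "dynamics"],
#'   "simulate": {
#'     "genomeLength": 20000, "gc": 0.5, "contig": "synth1",
#'     "baseline": 1, "readLength": 50,
#'     "footprints": [{"start": 5000, "end": 5014, "depletion": 0}],
#'     "bias": {"hexamer": "AAAAAA", "preference": 2},
#'     "samples": [{"id": "t0", "nEvents": 50000}],
#'     "nakedEvents": 200000
#'   },
#'   "correct": {"method": "poisson", "alpha": 0.01, "genomeSize": null},
#'   "footprint": {"threshold": 100, "minLen": 5, "maxLen": 50},
#'   "dynamics": {"nBins": 9, "flank": 5, "normScale": 1e6}
#' }
#' }
#'
#' @param config Path to a JSON file, or an equivalent named list.
#' @return The validated configuration (class \code{"RunConfig"}).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  bad <- character(0)
  note <- function(...) bad <<- c(bad, sprintf(...))

  if (is.null(config$seed) || !is.numeric(config$seed))
    note("seed: required integer")
  if (is.null(config$outdir) || !is.character(config$outdir))
    note("outdir: required path")
  stages <- unlist(config$stages)
  if (is.null(stages)) stages <- character(0)
  unknown <- setdiff(stages, .PIPELINE_STAGES)
  if (length(unknown)) note("stages: unknown stage(s) %s",
                            paste(unknown, collapse = ", "))
  config$stages <- stages

  sim <- config$simulate
  if (length(intersect(stages, .PIPELINE_STAGES))) {
    if (is.null(sim)) note("simulate: block required for the synthetic pipeline")
  }
  if (!is.null(sim)) {
    if (is.null(sim$genomeLength) || sim$genomeLength < 6)
      note("simulate.genomeLength: required, >= 6")
    if (is.null(sim$gc)) sim$gc <- 0.5
    if (sim$gc < 0 || sim$gc > 1) note("simulate.gc: must lie in [0, 1]")
    if (is.null(sim$contig)) sim$contig <- "synth1"
    if (is.null(sim$baseline)) sim$baseline <- 1
    if (is.null(sim$readLength)) sim$readLength <- 50
    fps <- sim$footprints
    if (!is.null(fps) && length(fps)) {
      st <- vapply(fps, function(f) as.numeric(f$start %||% NA), numeric(1))
      en <- vapply(fps, function(f) as.numeric(f$end %||% NA), numeric(1))
      dp <- vapply(fps, function(f) as.numeric(f$depletion %||% 0), numeric(1))
      if (any(is.na(st)) || any(is.na(en)))
        note("simulate.footprints: each needs start and end")
      else {
        if (!is.null(sim$genomeLength) &&
            (any(st < 1) || any(en > sim$genomeLength) || any(en < st)))
          note("simulate.footprints: intervals must lie within the genome")
        o <- order(st)
        if (length(st) > 1L && any(st[o][-1] <= en[o][-length(en)]))
          note("simulate.footprints: intervals must not overlap")
      }
      if (any(dp < 0) || any(dp > 1))
        note("simulate.footprints: depletion must lie in [0, 1]")
    }
    if (!is.null(sim$bias)) {
      if (is.null(sim$bias$hexamer) ||
          !grepl("^[ACGT]{6}$", sim$bias$hexamer))
        note("simulate.bias.hexamer: must be a 6-mer over ACGT")
      if (is.null(sim$bias$preference) || sim$bias$preference <= 0)
        note("simulate.bias.preference: must be positive")
    }
    if (is.null(sim$samples) || !length(sim$samples))
      note("simulate.samples: at least one sample required")
    else {
      ne <- vapply(sim$samples, function(s) as.numeric(s$nEvents %||% NA),
                   numeric(1))
      if (any(is.na(ne)) || any(ne < 0))
        note("simulate.samples: each sample needs nEvents >= 0")
    }
    if (is.null(sim$nakedEvents)) sim$nakedEvents <- 2e5
    config$simulate <- sim
  }
  if ("correct" %in% stages) {
    cr <- config$correct %||% list()
    if (is.null(cr$method)) cr$method <- "poisson"
    if (!cr$method %in% c("poisson", "bagfoot", "hint"))
      note("correct.method: one of poisson, bagfoot, hint")
    if (is.null(cr$alpha)) cr$alpha <- 0.01
    if (cr$alpha <= 0) note("correct.alpha: must be positive")
    config$correct <- cr
  }
  if ("footprint" %in% stages) {
    fp <- config$footprint %||% list()
    if (is.null(fp$threshold) || fp$threshold <= 0)
      note("footprint.threshold: required, positive")
    if (is.null(fp$minLen)) fp$minLen <- 5
    if (is.null(fp$maxLen)) fp$maxLen <- 50
    if (fp$minLen > fp$maxLen) note("footprint: minLen must be <= maxLen")
    config$footprint <- fp
  }
  if ("dynamics" %in% stages) {
    dy <- config$dynamics %||% list()
    if (is.null(dy$nBins)) dy$nBins <- 9
    if (dy$nBins < 1) note("dynamics.nBins: must be >= 1")
    if (is.null(dy$flank)) dy$flank <- 5
    if (is.null(dy$normScale)) dy$normScale <- 1e6
    config$dynamics <- dy
  }
  if (length(bad))
    stop("invalid configuration:\n  - ", paste(bad, collapse = "\n  - "))
  class(config) <- c("RunConfig", class(config))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the synthetic end-to-end pipeline
#'
#' Executes the selected stages in dependency order: \code{simulate}
#' (genome, landscape with planted footprints, per-sample Tn5 fragments and
#' SAM/BAM, plus a naked-DNA library for bias estimation),
#' \code{count} (per-sample cut profiles from the BAM files),
#' \code{correct} (bias estimation from the naked library and correction of
#' the pooled profile), \code{footprint} (protected-region calls on the
#' pooled raw counts) and \code{dynamics} (per-bin accessibility series and
#' site-adjacent change vs the planted truth). All text outputs are listed
#' in a JSON manifest with their MD5 hashes; a fixed seed makes the
#' manifest hash-identical across runs.
#'
#' @param config A \code{"RunConfig"} (from \code{\link{validateConfig}}),
#'   a path to a JSON configuration, or an equivalent list.
#' @return Invisibly, the manifest (also written to
#'   \code{<outdir>/manifest.json}).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "RunConfig")) config <- validateConfig(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stages <- config$stages
  files <- character(0)
  addFile <- function(path) files <<- c(files, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  genome <- NULL; landscape <- NULL; frags <- list(); naked <- NULL
  profiles <- list(); pooled <- NULL; biasTab <- NULL
  sim <- config$simulate

  if ("simulate" %in% stages) stage("simulate", {
    genome <- generateGenome(sim$genomeLength, sim$gc, seed = seed)
    fpList <- sim$footprints
    fpIR <- if (!is.null(fpList) && length(fpList))
      IRanges::IRanges(
        vapply(fpList, function(f) as.integer(f$start), integer(1)),
        vapply(fpList, function(f) as.integer(f$end), integer(1)))
    else IRanges::IRanges()
    dep <- if (length(fpIR))
      vapply(fpList, function(f) as.numeric(f$depletion %||% 0), numeric(1))
    else numeric(0)
    landscape <- plantLandscape(genome, fpIR, dep, baseline = sim$baseline)
    biasModel <- if (!is.null(sim$bias)) {
      pref <- sim$bias$preference
      names(pref) <- sim$bias$hexamer
      BiasTable(pref)
    } else BiasTable()
    addFile(writeGenomeFasta(genome, file.path(outdir, "genome.fa"),
                             contig = sim$contig))
    addFile(writeTruthBed(landscape, file.path(outdir, "truth.bed"),
                          contig = sim$contig))
    for (i in seq_along(sim$samples)) {
      s <- sim$samples[[i]]
      fs <- simulateFragments(genome, landscape, biasModel,
                              nEvents = as.integer(s$nEvents),
                              seed = seed + 7919L * i,
                              contig = sim$contig, sampleId = s$id)
      sam <- file.path(outdir, sprintf("%s.sam", s$id))
      writeAlignments(fs, genome, sam, readLength = sim$readLength)
      addFile(sam)
      frags[[s$id]] <- fs
    }
    # naked-DNA library: uniform landscape, same bias model
    naked <- simulateFragments(genome, plantLandscape(genome), biasModel,
                                nEvents = as.integer(sim$nakedEvents),
                                seed = seed + 104729L,
                                contig = sim$contig, sampleId = "naked")
  })

  if ("count" %in% stages) stage("count", {
    if (!length(frags)) stop("no simulated fragments; include the simulate stage")
    L <- length(genome)
    for (id in names(frags)) {
      sam <- file.path(outdir, sprintf("%s.sam", id))
      bam <- Rsamtools::asBam(sam, file.path(outdir, id),
                              overwrite = TRUE, indexDestination = TRUE)
      profiles[[id]] <- countCuts(bam, sim$contig, 1L, L, sampleId = id)
      bg <- file.path(outdir, sprintf("%s.cuts.bedGraph", id))
      writeBedGraph(profiles[[id]], bg)
      addFile(bg)
    }
    pooled <- if (length(profiles) > 1L) poolProfiles(profiles)
    else profiles[[1]]
    bg <- file.path(outdir, "pooled.cuts.bedGraph")
    writeBedGraph(pooled, bg)
    addFile(bg)
  })

  if ("correct" %in% stages) stage("correct", {
    if (is.null(pooled)) stop("no cut profiles; include the count stage")
    L <- length(genome)
    nakedProf <- countCuts(naked, start = 1L, end = L)
    biasTab <- estimateBias(nakedProf, genome)
    bt <- file.path(outdir, "bias.tsv")
    writeBiasTable(biasTab, bt)
    addFile(bt)
    cr <- config$correct
    G <- cr$genomeSize %||% L
    corrected <- switch(cr$method,
      poisson = correctPoissonGated(pooled, biasTab, genome,
                                    genomeSize = G, alpha = cr$alpha),
      bagfoot = correctBagfoot(pooled, biasTab, genome),
      hint = correctHint(pooled, biasTab, genome))
    bg <- file.path(outdir, sprintf("pooled.%s.bedGraph", cr$method))
    writeBedGraph(corrected, bg)
    addFile(bg)
  })

  calls <- NULL
  if ("footprint" %in% stages) stage("footprint", {
    if (is.null(pooled)) stop("no pooled profile; include the count stage")
    fp <- config$footprint
    calls <- callProtectedRegions(pooled, fp$threshold,
                                   minLen = fp$minLen, maxLen = fp$maxLen)
    bed <- file.path(outdir, "footprints.bed")
    rtracklayer::export(calls, bed, format = "BED")
    addFile(bed)
  })

  if ("dynamics" %in% stages) stage("dynamics", {
    if (!length(profiles)) stop("no cut profiles; include the count stage")
    dy <- config$dynamics
    norm <- lapply(profiles, normalizeLibrary, scale = dy$normScale)
    bs <- binRegion(norm, nBins = as.integer(dy$nBins))
    df <- data.frame(bin = seq_len(length(binRanges(bs))),
                     start = IRanges::start(binRanges(bs)),
                     end = IRanges::end(binRanges(bs)))
    df <- cbind(df, as.data.frame(binMeans(bs)))
    tsv <- file.path(outdir, "bins.tsv")
    write.table(format(df, digits = 10), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    addFile(tsv)
    if (length(norm) >= 2L && length(landscape@footprints)) {
      sac <- siteAdjacentChange(norm, landscape@footprints, flank = dy$flank)
      tsv2 <- file.path(outdir, "site_adjacent_change.tsv")
      write.table(format(sac, digits = 10), tsv2, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      addFile(tsv2)
    }
  })

  manifest <- list(
    parameters = unclass(config),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
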