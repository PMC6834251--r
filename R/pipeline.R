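#' Configuration for the end-to-end synthetic pipeline
#'
#' Collects the simulation design and every stage threshold.  Unknown
#' arguments are rejected by normal R argument matching.
#'
#' @param outDir output directory (created if absent).
#' @param seed global seed; per-stage seeds are fanned out from it by a
#'   counter scheme and recorded in the run manifest.
#' @param nAccessions,nMarkers,nSubpops,fst,conditions,nReplicates,days,nChromosomes
#'   passed to [simConfig()].
#' @param mafThreshold minimum MAF for tested markers.
#' @param alpha family-wise level for the Bonferroni threshold.
#' @param window candidate-gene half-window in bp.
#' @param negLog10P relaxed `-log10(p)` screening threshold for the
#'   cross-trait overlap and module mining.
#' @param minModuleSize,minScore module-extraction parameters.
#' @param minRefSlope reference-slope guard for trait normalization
#'   (`NULL` = 10% of the panel-median control slope).
#' @param nGenes,geneLength,geneSpacing toy-annotation parameters.
#' @param nTerms number of background annotation terms.
#' @param overlapResamples resamples for the overlap empirical p-value.
#' @param reference control-condition label.
#' @param arch optional [architectureSpec()]; `NULL` uses
#'   [defaultArchitecture()] on the simulated genotypes.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(outDir, seed = 1, nAccessions = 227,
                           nMarkers = 5000, nSubpops = 3, fst = 0.1,
                           conditions = c("Ct", "-P", "-Fe", "-Zn",
                                          "-P-Fe", "-P-Zn"),
                           nReplicates = 12, days = 3:5, nChromosomes = 5,
                           mafThreshold = 0.05, alpha = 0.05,
                           window = 10000, negLog10P = 4,
                           minModuleSize = 3, minScore = 0,
                           minRefSlope = NULL, nGenes = 1000,
                           geneLength = 2000, geneSpacing = 18000,
                           nTerms = 15, overlapResamples = 1000,
                           reference = "Ct", arch = NULL) {
  stopifnot(mafThreshold >= 0, mafThreshold < 0.5, alpha > 0, alpha <= 1,
            window >= 0, negLog10P >= 0, minModuleSize >= 1)
  if (!reference %in% conditions) stop("reference must be one of conditions")
  structure(list(outDir = outDir, seed = as.integer(seed),
                 sim = simConfig(nAccessions, nMarkers, nSubpops, fst,
                                 conditions, nReplicates, days, nChromosomes,
                                 seed = seed),
                 mafThreshold = mafThreshold, alpha = alpha, window = window,
                 negLog10P = negLog10P, minModuleSize = minModuleSize,
                 minScore = minScore, minRefSlope = minRefSlope,
                 nGenes = nGenes, geneLength = geneLength,
                 geneSpacing = geneSpacing, nTerms = nTerms,
                 overlapResamples = overlapResamples, reference = reference,
                 arch = arch),
            class = "PipelineConfig")
}

#' Default planted architecture for the synthetic pipeline
#'
#' Baseline growth rates (mm/day) emulate the qualitative physiology of the
#' system: P starvation mildly promotes early primary root growth, Fe or Zn
#' starvation inhibits it, and the combined deficiencies are alleviated back
#' towards control.  Polygenic heritability is condition-specific (high on
#' control, low on -Fe).  Nine QTLs are planted on common markers
#' (MAF >= 0.3), spread over the genome: a P-response QTL, a Zn-response
#' QTL, three interaction QTLs each acting only under -P-Fe resp. -P-Zn,
#' and two interaction QTLs shared between the combined stresses — exactly
#' the kind of architecture the delta traits are built to expose, with
#' effect sizes chosen to be detectable at the default panel size of 227
#' accessions.
#'
#' @param geno a [GenotypeMatrix-class] (used to pick common markers).
#' @return an [architectureSpec()].
#' @export
defaultArchitecture <- function(geno) {
  maf <- computeMAF(geno)
  pool <- which(!is.na(maf) & maf >= 0.3)
  if (length(pool) < 9)
    stop("too few common markers to plant the default architecture")
  qtl <- pool[round(stats::quantile(seq_along(pool), seq(0.1, 0.9, by = 0.1)))]
  architectureSpec(
    causalMarkers = list(
      list(marker = qtl[1], effects = c("-P" = 0.3, "-P-Fe" = 0.3,
                                        "-P-Zn" = 0.3)),
      list(marker = qtl[2], effects = c("-Zn" = 0.35, "-P-Zn" = 0.35)),
      list(marker = qtl[3], effects = c("-P-Fe" = 0.6)),
      list(marker = qtl[4], effects = c("-P-Fe" = 0.6)),
      list(marker = qtl[5], effects = c("-P-Fe" = 0.6)),
      list(marker = qtl[6], effects = c("-P-Zn" = 0.6)),
      list(marker = qtl[7], effects = c("-P-Zn" = 0.6)),
      list(marker = qtl[8], effects = c("-P-Fe" = 0.45, "-P-Zn" = 0.45)),
      list(marker = qtl[9], effects = c("-P-Fe" = 0.45, "-P-Zn" = 0.45))),
    polygenicH2 = c("Ct" = 0.8, "-P" = 0.5, "-Fe" = 0.1, "-Zn" = 0.3,
                    "-P-Fe" = 0.4, "-P-Zn" = 0.3),
    residualSd = 0.25, germinationOffsetSd = 0.5, measurementSd = 0.4,
    baselineRgr = c("Ct" = 2.5, "-P" = 2.8, "-Fe" = 1.8, "-Zn" = 2.0,
                    "-P-Fe" = 2.4, "-P-Zn" = 2.4))
}

fileSafe <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)

#' Run the full synthetic analysis pipeline
#'
#' Executes, in order: genotype simulation, kinship, phenotype and
#' replicate-length simulation, growth-rate estimation, trait construction
#' (one normalized trait per deficiency condition plus the two delta
#' traits), one mixed-model GWAS per trait, Bonferroni thresholding, region
#' merging, candidate-gene mapping, cross-trait Venn counts, the delta-trait
#' overlap test, module extraction and term enrichment.  Every stage writes
#' its artifact into `outDir` through the declared file formats, and a run
#' manifest (tool version, configuration, input checksums, per-stage seeds
#' and runtimes, summary counts) is written atomically at the end.  All
#' randomness derives from the configuration seed, so a re-run with the same
#' configuration reproduces every output bit-for-bit (the manifest's
#' runtimes aside).
#'
#' @param config a [pipelineConfig()].
#' @param verbose print stage progress and applied thresholds.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  manifest <- list(tool = "nutriGWAS",
                   version = as.character(packageVersion("nutriGWAS")),
                   seed = config$seed, stageSeeds = list(), runtimes = list(),
                   checksums = list(), counts = list())
  tic <- function() Sys.time()
  toc <- function(stage, t0)
    manifest$runtimes[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
  seedOf <- function(stage, counter) {
    s <- stageSeed(config$seed, counter)
    manifest$stageSeeds[[stage]] <<- s
    s
  }
  outfile <- function(...) file.path(config$outDir, ...)

  ## --- simulate -----------------------------------------------------------
  t0 <- tic()
  geno <- simulateGenotypes(config$sim)
  kin <- computeKinship(geno, "grm")
  arch <- config$arch %||% defaultArchitecture(geno)
  truth <- simulatePhenotypes(geno, arch, kin, seed = seedOf("phenotypes", 1))
  pheno <- simulateLengths(truth, config$sim, seed = seedOf("lengths", 2))
  genes <- simulateAnnotation(config$nGenes, config$geneLength,
                              config$geneSpacing, config$sim$nChromosomes)
  ## plant one co-function module on the genes tagged (within the mapping
  ## window) by the -P-Fe-affecting QTLs, so that module mining has a
  ## recoverable ground truth
  pfe <- which(vapply(truth$causalMarkers, function(cm)
    "-P-Fe" %in% names(cm$effects), logical(1)))
  near <- character(0)
  if (length(pfe)) {
    idx <- vapply(truth$causalMarkers[pfe], `[[`, integer(1), "index")
    qpos <- markerRanges(geno)[idx]
    win <- GRanges(seqnames(qpos),
                   IRanges(pmax(start(qpos) - config$window, 1),
                           start(qpos) + config$window))
    near <- unique(genes$gene_id[subjectHits(findOverlaps(win, genes))])
  }
  set.seed(seedOf("network", 3))
  extra <- sample(setdiff(genes$gene_id, near),
                  max(0, 10 - length(near)))
  planted <- sort(c(near, extra))
  net <- simulateNetwork(genes, plantedModules = list(planted),
                         backgroundEdgeProb = 0.005,
                         seed = seedOf("networkEdges", 4))
  go <- simulateGOTable(genes, nTerms = config$nTerms,
                        enriched = list("TERM:ENRICHED" =
                          list(genes = planted, coverage = 0.8)),
                        backgroundProb = 0.1, seed = seedOf("go", 5))
  writeGenotypesTSV(geno, outfile("genotypes.tsv"))
  writePhenotypeCSV(pheno, outfile("phenotypes.csv"))
  writeAnnotationGFF3(genes, outfile("annotation.gff3"))
  writeNetworkTSV(net, outfile("network.tsv"))
  writeGOTSV(go, outfile("go.tsv"))
  write_json(list(causalMarkers = truth$causalMarkers,
                  realizedH2 = as.list(truth$realizedH2),
                  plantedModule = planted),
             outfile("truth.json"), auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  toc("simulate", t0)
  say("simulated ", nrow(dosage(geno)), " accessions x ", ncol(dosage(geno)),
      " markers; ", nrow(pheno), " length records")

  ## --- growth rates and traits -------------------------------------------
  t0 <- tic()
  rgr <- estimateRGR(pheno)
  write.table(rgr, outfile("rgr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  defic <- setdiff(config$sim$conditions, config$reference)
  traits <- list()
  for (cond in defic) {
    tv <- normalizeRGR(rgr, cond, config$reference, config$minRefSlope)
    traits[[traitName(tv)]] <- tv
  }
  norm <- function(cond)
    traits[[sprintf("RGRnorm(%s/%s)", cond, config$reference)]]
  if (all(c("-P-Fe", "-Fe", "-P-Zn", "-Zn") %in% defic)) {
    d1 <- deltaTrait(norm("-P-Fe"), norm("-Fe"), "deltaRGR(-P-Fe,-Fe)")
    d2 <- deltaTrait(norm("-P-Zn"), norm("-Zn"), "deltaRGR(-P-Zn,-Zn)")
    traits[[traitName(d1)]] <- d1
    traits[[traitName(d2)]] <- d2
  }
  dir.create(outfile("traits"), showWarnings = FALSE)
  for (tn in names(traits))
    writeTraitTSV(traits[[tn]], outfile("traits", paste0(fileSafe(tn), ".tsv")))
  toc("traits", t0)
  say(length(traits), " traits built (guard minRefSlope = ",
      format(traits[[1]]@provenance$minRefSlope), ")")

  ## --- GWAS per trait ------------------------------------------------------
  t0 <- tic()
  dir.create(outfile("assoc"), showWarnings = FALSE)
  dir.create(outfile("candidates"), showWarnings = FALSE)
  dir.create(outfile("regions"), showWarnings = FALSE)
  scans <- list(); nullfits <- list(); candTabs <- list()
  for (tn in names(traits)) {
    vc <- fitNullModel(traits[[tn]], kin)
    scan <- gwasScan(traits[[tn]], geno, kin, vc, config$mafThreshold)
    scans[[tn]] <- scan
    nullfits[[tn]] <- list(VG = varG(vc), VE = varE(vc), delta = vc@delta,
                           H2 = heritability(vc), logREML = vc@logLik)
    writeAssociationTSV(scan, outfile("assoc", paste0(fileSafe(tn), ".tsv")))
    bf <- bonferroniThreshold(scan, config$alpha)
    say(tn, ": ", bf$nTested, " tested markers, Bonferroni threshold ",
        format(bf$threshold, digits = 3), ", ", nrow(bf$significant),
        " significant")
    if (nrow(bf$significant)) {
      reg <- mergeRegions(bf$significant, config$window)
      writeRegionsBED(reg, outfile("regions", paste0(fileSafe(tn), ".bed")))
      cand <- mapCandidates(bf$significant, genes, config$window, trait = tn)
    } else {
      cand <- mapCandidates(bf$significant[0, ], genes, config$window,
                            trait = tn)
    }
    candTabs[[tn]] <- cand
    write.table(cand, outfile("candidates", paste0(fileSafe(tn), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_json(nullfits, outfile("nullmodels.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  toc("gwas", t0)
  manifest$counts$nTraitGWAS <- length(scans)
  manifest$counts$nTested <- vapply(scans, function(s) s@nTested, integer(1))

  ## --- venn, overlap, modules ----------------------------------------------
  t0 <- tic()
  normNames <- vapply(defic, function(cond)
    sprintf("RGRnorm(%s/%s)", cond, config$reference), character(1))
  venn <- vennCounts(candTabs[intersect(normNames, names(candTabs))])
  write.table(venn, outfile("venn.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  deltaNames <- grep("^deltaRGR", names(traits), value = TRUE)
  if (length(deltaNames) == 2) {
    sA <- subthresholdSet(scans[[deltaNames[1]]], config$negLog10P)
    sB <- subthresholdSet(scans[[deltaNames[2]]], config$negLog10P)
    universe <- subthresholdSet(scans[[deltaNames[1]]], 0)
    ov <- overlapTest(sA, sB, universe,
                      nResamples = config$overlapResamples,
                      seed = seedOf("overlap", 6))
    write_json(unclass(ov), outfile("overlap.json"), auto_unbox = TRUE,
               digits = NA, pretty = TRUE)
    say("delta-trait overlap: k = ", ov$k, ", analytic p = ",
        format(ov$analyticP, digits = 3))

    ## module mining on the relaxed-threshold candidates of the first delta
    sub <- assocTable(scans[[deltaNames[1]]])
    sub <- sub[sub$marker %in% sA, , drop = FALSE]
    modCand <- mapCandidates(sub, genes, config$window,
                             trait = deltaNames[1])
    mods <- extractModules(modCand$gene, net, config$minModuleSize,
                           config$minScore)
    modTab <- if (length(mods))
      do.call(rbind, lapply(seq_along(mods), function(i)
        data.frame(module = i, gene = mods[[i]]$genes, size = mods[[i]]$size,
                   stringsAsFactors = FALSE)))
      else data.frame(module = integer(0), gene = character(0),
                      size = integer(0))
    write.table(modTab, outfile("modules.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (length(mods)) {
      edges <- do.call(rbind, lapply(seq_along(mods), function(i)
        cbind(module = i, mods[[i]]$edges)))
      edges$score <- fmtNum(edges$score)
      write.table(edges, outfile("module_edges.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      bg <- intersect(unique(go$gene), networkGenes(net))
      enr <- enrichTerms(intersect(mods[[1]]$genes, bg), go, bg)
      enrOut <- enr
      enrOut$pvalue <- fmtNum(enrOut$pvalue)
      enrOut$qvalue <- fmtNum(enrOut$qvalue)
      write.table(enrOut, outfile("enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      say("largest module: ", mods[[1]]$size, " genes; top term p = ",
          format(enr$pvalue[1], digits = 3))
      manifest$counts$largestModule <- mods[[1]]$size
      manifest$counts$topEnrichmentP <- enr$pvalue[1]
    }
    manifest$counts$overlapK <- ov$k
    manifest$counts$overlapAnalyticP <- ov$analyticP
  }
  toc("downstream", t0)

  ## --- manifest -------------------------------------------------------------
  inputs <- c("genotypes.tsv", "phenotypes.csv", "annotation.gff3",
              "network.tsv", "go.tsv")
  manifest$checksums <- as.list(md5sum(vapply(inputs, outfile, character(1))))
  names(manifest$checksums) <- inputs
  manifest$counts$nSignificant <- vapply(scans, function(s)
    nrow(bonferroniThreshold(s, config$alpha)$significant), integer(1))
  manifest$config <- config[setdiff(names(config), "arch")]
  tmp <- outfile("manifest.json.tmp")
  write_json(manifest, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
             force = TRUE)
  file.rename(tmp, outfile("manifest.json"))
  invisible(manifest)
}
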