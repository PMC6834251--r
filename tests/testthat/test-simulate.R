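test_that("genotype simulation is a pure function of its seed", {
  cfg <- simConfig(nAccessions = 30, nMarkers = 100, seed = 5)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(dosage(g1), dosage(g2))
  expect_identical(as.character(GenomicRanges::seqnames(markerRanges(g1))),
                   as.character(GenomicRanges::seqnames(markerRanges(g2))))
  g3 <- simulateGenotypes(simConfig(nAccessions = 30, nMarkers = 100, seed = 6))
  expect_false(identical(dosage(g1), dosage(g3)))
})

test_that("subpopulation frequencies converge to ancestral ones as Fst -> 0", {
  cfg0 <- simConfig(nAccessions = 2000, nMarkers = 400, nSubpops = 2,
                    fst = 1e-13, seed = 3)
  g <- simulateGenotypes(cfg0)
  pop <- attr(g, "subpop")
  f1 <- colMeans(dosage(g)[pop == 1, ])
  f2 <- colMeans(dosage(g)[pop == 2, ])
  expect_lt(mean(abs(f1 - f2)), 0.05)       # sampling noise only
  expect_error(simConfig(fst = 1), "fst")
  expect_error(simConfig(nAccessions = 1), "dimensions")
  expect_error(simConfig(days = c(5, 4)), "days")
})

test_that("the Hudson Fst estimate recovers the Balding-Nichols parameter", {
  cfg <- simConfig(nAccessions = 500, nMarkers = 1000, nSubpops = 2,
                   fst = 0.2, seed = 17)
  g <- simulateGenotypes(cfg)
  pop <- attr(g, "subpop")
  D <- dosage(g)
  n1 <- sum(pop == 1); n2 <- sum(pop == 2)
  p1 <- colMeans(D[pop == 1, ]); p2 <- colMeans(D[pop == 2, ])
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fstHat <- mean(num) / mean(den)
  expect_lt(abs(fstHat - 0.2), 0.05)
})

test_that("marker positions are strictly increasing and dosages are inbred 0/1", {
  g <- simulateGenotypes(simConfig(nAccessions = 20, nMarkers = 200,
                                   nChromosomes = 3, seed = 2))
  mk <- markerRanges(g)
  for (cc in unique(as.character(GenomicRanges::seqnames(mk)))) {
    p <- GenomicRanges::start(mk[as.character(GenomicRanges::seqnames(mk)) == cc])
    expect_true(all(diff(p) > 0))
  }
  expect_true(all(dosage(g) %in% c(0, 1)))
})

test_that("degenerate architecture returns the per-condition baselines exactly", {
  g <- randomGeno(25, 40, seed = 8)
  k <- computeKinship(g, "grm")
  arch <- architectureSpec(polygenicH2 = 0, residualSd = 0,
                           baselineRgr = c(Ct = 2.5, "-P" = 3.1))
  tr <- simulatePhenotypes(g, arch, k, seed = 1)
  expect_equal(unname(tr$trueRGR[, "Ct"]), rep(2.5, 25))
  expect_equal(unname(tr$trueRGR[, "-P"]), rep(3.1, 25))
  expect_error(simulatePhenotypes(g, architectureSpec(
    causalMarkers = list(list(marker = 999, effects = c(Ct = 1))),
    baselineRgr = c(Ct = 1)), k), "out of range")
})

test_that("a condition-specific QTL shifts carriers only under that condition", {
  g <- randomGeno(40, 30, seed = 12)
  k <- computeKinship(g, "grm")
  arch <- architectureSpec(
    causalMarkers = list(list(marker = 7, effects = c("-P-Fe" = 0.8))),
    polygenicH2 = 0, residualSd = 0,
    baselineRgr = c("-Fe" = 1.8, "-P-Fe" = 2.4))
  tr <- simulatePhenotypes(g, arch, k, seed = 1)
  carrier <- dosage(g)[, 7] == 1
  d1 <- mean(tr$trueRGR[carrier, "-P-Fe"]) - mean(tr$trueRGR[!carrier, "-P-Fe"])
  d0 <- mean(tr$trueRGR[carrier, "-Fe"]) - mean(tr$trueRGR[!carrier, "-Fe"])
  expect_equal(d1, 0.8, tolerance = 1e-12)
  expect_equal(d0, 0, tolerance = 1e-12)
})

test_that("realized variance decomposition sums to the total phenotypic variance", {
  g <- randomGeno(60, 80, seed = 3)
  k <- computeKinship(g, "grm")
  arch <- architectureSpec(
    causalMarkers = list(list(marker = 3, effects = c(Ct = 0.5))),
    polygenicH2 = 0.4, residualSd = 0.3, baselineRgr = c(Ct = 2.5))
  tr <- simulatePhenotypes(g, arch, k, seed = 4)
  cmp <- tr$components$Ct
  expect_equal(cmp$varTotal,
               cmp$varGenetic + cmp$varResidual + 2 * cmp$covGeneticResidual,
               tolerance = 1e-10)
  expect_true(tr$realizedH2["Ct"] >= 0 && tr$realizedH2["Ct"] <= 1)
})

test_that("length records are exact noise-free lines with the right cardinality", {
  g <- randomGeno(5, 10, seed = 2)
  k <- computeKinship(g, "ibs")
  arch <- architectureSpec(polygenicH2 = 0, residualSd = 0,
                           germinationOffsetSd = 0, measurementSd = 0,
                           baselineRgr = c(Ct = 10))
  cfg <- simConfig(nAccessions = 5, nMarkers = 10, conditions = "Ct",
                   nReplicates = 3, days = 3:5, seed = 2)
  tr <- simulatePhenotypes(g, arch, k, seed = 1)
  ph <- simulateLengths(tr, cfg, seed = 1)
  expect_equal(nrow(ph), 5 * 1 * 3 * 3)
  expect_equal(sort(unique(ph$length)), c(30, 40, 50))
})

test_that("per-replicate germination offsets leave the pooled slope exact", {
  g <- randomGeno(8, 10, seed = 6)
  k <- computeKinship(g, "ibs")
  arch <- architectureSpec(polygenicH2 = 0.3, residualSd = 0.2,
                           germinationOffsetSd = 2, measurementSd = 0,
                           baselineRgr = c(Ct = 12))
  cfg <- simConfig(nAccessions = 8, nMarkers = 10, conditions = "Ct",
                   nReplicates = 12, days = 3:5, seed = 6)
  tr <- simulatePhenotypes(g, arch, k, seed = 2)
  ph <- simulateLengths(tr, cfg, seed = 3)
  r <- estimateRGR(ph)
  ## offsets are constant within replicate and the day grid is balanced, so
  ## they are exactly orthogonal to the slope
  expect_equal(r$slope[match(rownames(tr$trueRGR), r$accession)],
               unname(tr$trueRGR[, "Ct"]), tolerance = 1e-10)
})

test_that("toy annotation tiles non-overlapping genes and round-trips GFF3", {
  ann <- simulateAnnotation(10, geneLength = 2000, spacing = 5000,
                            chromosomes = 1)
  expect_length(ann, 10)
  expect_equal(diff(GenomicRanges::start(ann)), rep(7000, 9))
  expect_true(all(GenomicRanges::width(ann) == 2000))
  ## no overlap within a chromosome
  ann2 <- simulateAnnotation(25, 1500, 500, chromosomes = 3)
  hits <- GenomicRanges::findOverlaps(ann2, drop.self = TRUE)
  expect_length(hits, 0)
  tf <- tempfile(fileext = ".gff3")
  writeAnnotationGFF3(ann2, tf)
  back <- readAnnotationGFF3(tf)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ann2))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(ann2))
  expect_equal(back$gene_id, ann2$gene_id)
})

test_that("planted network modules are connected; background off isolates them", {
  ann <- simulateAnnotation(20, 1000, 1000, 1)
  mod <- ann$gene_id[1:5]
  net <- simulateNetwork(ann, plantedModules = list(mod),
                         backgroundEdgeProb = 0, seed = 9)
  mods <- extractModules(networkGenes(net), net, minSize = 2)
  expect_length(mods, 1)
  expect_equal(mods[[1]]$genes, sort(mod))
  net2 <- simulateNetwork(ann, plantedModules = list(mod),
                          backgroundEdgeProb = 0, seed = 9)
  expect_identical(networkEdges(net), networkEdges(net2))
})

test_that("planted term enrichment is recovered by the hypergeometric test", {
  ann <- simulateAnnotation(100, 1000, 1000, 1)
  mod <- ann$gene_id[1:10]
  go <- simulateGOTable(ann, nTerms = 8,
                        enriched = list("TERM:HIT" = list(genes = mod,
                                                          coverage = 0.8)),
                        backgroundProb = 0.1, seed = 21)
  enr <- enrichTerms(intersect(mod, unique(go$gene)), go)
  hit <- enr[enr$term == "TERM:HIT", ]
  expect_lt(hit$pvalue, 0.01)
  expect_equal(hit$pvalue, enumHyperTail(hit$k, hit$N, hit$K, hit$n),
               tolerance = 1e-12)
})
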