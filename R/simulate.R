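#' Simulation configuration for the synthetic study design
#'
#' Describes the panel and measurement design that the synthetic-data
#' generator emulates: a structured panel of fully inbred accessions grown on
#' six media (control plus single and combined P/Fe/Zn deficiencies) with 12
#' replicate seedlings each, primary root length measured on days 3-5.
#'
#' @param nAccessions number of inbred accessions (default 227).
#' @param nMarkers number of biallelic markers.
#' @param nSubpops number of subpopulations in the Balding-Nichols structure.
#' @param fst divergence parameter in `[0, 1)`.
#' @param conditions growth-condition labels.
#' @param nReplicates replicate seedlings per accession and condition.
#' @param days measurement ages in days (strictly increasing).
#' @param nChromosomes chromosomes markers are spread over.
#' @param seed integer seed fixing all downstream randomness.
#' @return a `SimConfig` list.
#' @examples
#' cfg <- simConfig(nAccessions = 50, nMarkers = 200, seed = 1)
#' @export
simConfig <- function(nAccessions = 227, nMarkers = 5000, nSubpops = 3,
                      fst = 0.1,
                      conditions = c("Ct", "-P", "-Fe", "-Zn", "-P-Fe", "-P-Zn"),
                      nReplicates = 12, days = 3:5, nChromosomes = 5,
                      seed = 1) {
  if (nAccessions < 2 || nMarkers < 1 || nSubpops < 1 || nChromosomes < 1)
    stop("non-positive or degenerate dimensions in simulation config")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (length(days) < 1 || any(days <= 0) || any(diff(days) <= 0))
    stop("days must be positive and strictly increasing")
  structure(list(nAccessions = as.integer(nAccessions),
                 nMarkers = as.integer(nMarkers),
                 nSubpops = as.integer(nSubpops), fst = fst,
                 conditions = conditions,
                 nReplicates = as.integer(nReplicates),
                 days = as.numeric(days),
                 nChromosomes = as.integer(nChromosomes),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Planted genetic architecture for the phenotype generator
#'
#' @param causalMarkers list of planted QTLs; each element is
#'   `list(marker = <index or name>, effects = c(condition = effect, ...))`
#'   with effects in growth-rate units per alternate allele.  Conditions not
#'   named get effect 0 (this is how condition-specific and interaction QTLs
#'   are planted).
#' @param polygenicH2 polygenic heritability per condition (scalar or named
#'   per-condition vector), the fraction `V_u / (V_u + V_e)` of non-QTL
#'   variance that follows the kinship.
#' @param residualSd independent residual SD of the true growth rate (scalar
#'   or named per condition), growth-rate units.
#' @param germinationOffsetSd SD of per-replicate germination offsets
#'   (length units; constant across days within a replicate).
#' @param measurementSd SD of per-measurement noise (length units).
#' @param baselineRgr named per-condition mean growth rate (length/day).
#' @return an `ArchitectureSpec` list.
#' @export
architectureSpec <- function(causalMarkers = list(), polygenicH2 = 0,
                             residualSd = 0.3, germinationOffsetSd = 0,
                             measurementSd = 0, baselineRgr) {
  if (is.null(names(baselineRgr)))
    stop("baselineRgr must be named by condition")
  if (any(polygenicH2 < 0) || any(polygenicH2 >= 1))
    stop("polygenicH2 must lie in [0, 1)")
  if (any(residualSd < 0) || germinationOffsetSd < 0 || measurementSd < 0)
    stop("standard deviations must be >= 0")
  structure(list(causalMarkers = causalMarkers, polygenicH2 = polygenicH2,
                 residualSd = residualSd,
                 germinationOffsetSd = germinationOffsetSd,
                 measurementSd = measurementSd, baselineRgr = baselineRgr),
            class = "ArchitectureSpec")
}

## per-condition lookup with scalar recycling
condParam <- function(x, cond) {
  if (is.null(names(x))) return(rep_len(x, 1))
  if (cond %in% names(x)) x[[cond]] else 0
}

#' Simulate structured inbred genotypes (Balding-Nichols model)
#'
#' Ancestral allele frequencies are uniform on `[0.1, 0.9]`; each
#' subpopulation draws its frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral `p` with divergence
#' `F = fst` (at `fst = 0` the subpopulation frequencies equal the ancestral
#' ones).  Accessions are assigned round-robin to subpopulations and, being
#' fully inbred, carry haploid dosages in \{0, 1\}.  Marker positions are
#' strictly increasing within chromosomes with random gaps.
#'
#' @param config a [simConfig()] object.
#' @return a [GenotypeMatrix-class]; the subpopulation assignment is stored
#'   in `attr(, "subpop")`.
#' @examples
#' g <- simulateGenotypes(simConfig(nAccessions = 20, nMarkers = 50, seed = 1))
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$nAccessions
  m <- config$nMarkers
  k <- config$nSubpops
  F <- config$fst
  p <- runif(m, 0.1, 0.9)
  if (F < 1e-12) {
    psub <- matrix(rep(p, each = k), nrow = k)
  } else {
    a <- (1 - F) / F
    psub <- matrix(rbeta(k * m, shape1 = rep(p, each = k) * a,
                         shape2 = rep(1 - p, each = k) * a), nrow = k)
  }
  pop <- rep_len(seq_len(k), n)
  dos <- matrix(rbinom(n * m, 1L, psub[pop, , drop = FALSE]), nrow = n)
  rownames(dos) <- sprintf("acc%04d", seq_len(n))
  chrom <- rep(seq_len(config$nChromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- cumsum(sample(200:8000, length(idx), replace = TRUE))
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  mk <- GRanges(paste0("chr", chrom), IRanges(pos, pos),
                ref = ref, alt = unname(alt))
  names(mk) <- sprintf("chr%d_%d", chrom, pos)
  g <- genotypeMatrix(dos, mk)
  attr(g, "subpop") <- pop
  g
}

#' Simulate true per-condition growth rates with planted architecture
#'
#' For accession i and condition c the true growth rate is
#' `baseline_c + sum_j beta_jc g_ij + u_ic + e_ic` where `u_c` is a polygenic
#' term drawn through the symmetric square root of the kinship matrix, scaled
#' so that its expected variance relative to the residual hits the requested
#' `polygenicH2` (relative to `residualSd^2`; when `residualSd` is 0 the
#' polygenic variance is 0 too), and `e_c` is independent Gaussian noise.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param arch an [architectureSpec()].
#' @param kinship a [KinshipMatrix-class] on the same accessions.
#' @param seed integer seed.
#' @return a `SimulationTruth` list: `trueRGR` (accessions x conditions
#'   matrix), per-condition component lists, the causal-marker table, and the
#'   realized per-condition variance decomposition and heritability.
#' @export
simulatePhenotypes <- function(geno, arch, kinship, seed = 1) {
  stopifnot(inherits(arch, "ArchitectureSpec"))
  set.seed(seed)
  D <- dosage(geno)
  n <- nrow(D)
  conditions <- names(arch$baselineRgr)
  K <- kinship(kinship)[accessions(geno), accessions(geno)]
  ## symmetric square root, negative rounding clipped
  eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  Ksqrt <- eig$vectors %*% (sqrt(lam) * t(eig$vectors))
  meanDiag <- mean(diag(K))

  idx <- vapply(arch$causalMarkers, function(cm) {
    i <- cm$marker
    if (is.character(i)) i <- match(i, names(markerRanges(geno)))
    if (is.na(i) || i < 1 || i > ncol(D))
      stop("causal marker index out of range")
    as.integer(i)
  }, integer(1))

  trueRGR <- matrix(NA_real_, n, length(conditions),
                    dimnames = list(rownames(D), conditions))
  comp <- list()
  for (cond in conditions) {
    beta <- vapply(arch$causalMarkers, function(cm)
      if (cond %in% names(cm$effects)) cm$effects[[cond]] else 0, numeric(1))
    gpart <- if (length(idx)) as.numeric(D[, idx, drop = FALSE] %*% beta)
             else numeric(n)
    h2 <- condParam(arch$polygenicH2, cond)
    rsd <- if (is.null(names(arch$residualSd))) arch$residualSd[[1]]
           else condParam(arch$residualSd, cond)
    Vu <- rsd^2 * h2 / (1 - h2)
    u <- if (Vu > 0 && meanDiag > 0)
      sqrt(Vu / meanDiag) * as.numeric(Ksqrt %*% rnorm(n)) else numeric(n)
    eps <- if (rsd > 0) rnorm(n, 0, rsd) else numeric(n)
    total <- arch$baselineRgr[[cond]] + gpart + u + eps
    trueRGR[, cond] <- total
    genetic <- gpart + u
    vg <- var(genetic); ve <- var(eps); cge <- cov(genetic, eps)
    comp[[cond]] <- list(marker = gpart, polygenic = u, residual = eps,
                         varGenetic = vg, varResidual = ve,
                         covGeneticResidual = cge,
                         varTotal = var(total),
                         realizedH2 = if (var(total) > 0) vg / var(total) else 0)
  }
  structure(list(geno = geno, trueRGR = trueRGR, components = comp,
                 causalMarkers = Map(function(cm, i)
                   list(marker = names(markerRanges(geno))[i], index = i,
                        effects = cm$effects),
                   arch$causalMarkers, as.list(idx)),
                 arch = arch,
                 realizedH2 = vapply(comp, `[[`, numeric(1), "realizedH2")),
            class = "SimulationTruth")
}

#' Simulate replicate-level primary-root length measurements
#'
#' One record per accession x condition x replicate x day.  Length is
#' `max(0, offset_ir + trueRGR_ic * day + measurement noise)`; the
#' germination offset is drawn once per (accession, condition, replicate) and
#' is constant across days, emulating germination-timing differences between
#' seedlings.
#'
#' @param truth a `SimulationTruth` from [simulatePhenotypes()].
#' @param config the [simConfig()] describing replicates and days.
#' @param seed integer seed.
#' @return a phenotype data.frame with columns `accession`, `condition`,
#'   `replicate`, `day`, `length`.
#' @export
simulateLengths <- function(truth, config, seed = 1) {
  stopifnot(inherits(truth, "SimulationTruth"), inherits(config, "SimConfig"))
  set.seed(seed)
  arch <- truth$arch
  acc <- rownames(truth$trueRGR)
  conditions <- colnames(truth$trueRGR)
  reps <- seq_len(config$nReplicates)
  days <- config$days
  cell <- expand.grid(replicate = reps, condition = conditions,
                      accession = acc, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  offs <- rnorm(nrow(cell), 0, arch$germinationOffsetSd)
  rec <- cell[rep(seq_len(nrow(cell)), each = length(days)), ]
  rec$day <- rep(days, times = nrow(cell))
  rec$offset <- rep(offs, each = length(days))
  rgr <- truth$trueRGR[cbind(rec$accession, rec$condition)]
  noise <- if (arch$measurementSd > 0)
    rnorm(nrow(rec), 0, arch$measurementSd) else 0
  rec$length <- pmax(0, rec$offset + rgr * rec$day + noise)
  out <- rec[, c("accession", "condition", "replicate", "day", "length")]
  rownames(out) <- NULL
  out
}

#' Simulate a toy gene annotation
#'
#' Non-overlapping genes of equal length tiled along chromosomes with a fixed
#' intergenic spacing; suitable as a substrate for window-based
#' candidate-gene mapping and GFF3 round-trips.
#'
#' @param nGenes number of genes.
#' @param geneLength gene length in bp.
#' @param spacing intergenic spacing in bp.
#' @param chromosomes number of chromosomes to distribute genes over.
#' @param chromPrefix chromosome-name prefix.
#' @return a `GRanges` with mcols `gene_id` and `type = "gene"`; 1-based
#'   inclusive coordinates.
#' @examples
#' simulateAnnotation(10, geneLength = 2000, spacing = 5000, chromosomes = 1)
#' @export
simulateAnnotation <- function(nGenes, geneLength = 2000, spacing = 5000,
                               chromosomes = 1, chromPrefix = "chr") {
  stopifnot(nGenes >= 1, geneLength >= 1, spacing >= 0)
  chrom <- sort(rep(seq_len(chromosomes), length.out = nGenes))
  j <- sequence(tabulate(chrom))            # index within chromosome
  start <- 1 + (j - 1) * (geneLength + spacing)
  gr <- GRanges(paste0(chromPrefix, chrom),
                IRanges(start, start + geneLength - 1),
                strand = rep_len(c("+", "-"), nGenes),
                gene_id = sprintf("g%04d", seq_len(nGenes)),
                type = "gene")
  names(gr) <- gr$gene_id
  gr
}

## map a linear index over unordered pairs of 1..n (combn order) to (i, j)
pairFromIndex <- function(ix, n) {
  cum <- cumsum(c(0, (n - 1):1))
  i <- findInterval(ix - 1, cum)
  j <- i + (ix - cum[i])
  cbind(i, j)
}

#' Simulate a weighted co-function network with planted modules
#'
#' Each planted module is made internally connected by a random spanning tree
#' plus additional intra-module edges; background edges follow an
#' Erdos-Renyi model over all gene pairs.  Scores are positive uniforms.
#'
#' @param genes gene identifiers (character) or an annotation `GRanges` with
#'   a `gene_id` column.
#' @param plantedModules list of character vectors (gene sets to connect).
#' @param backgroundEdgeProb Erdos-Renyi edge probability.
#' @param intraEdgeProb probability of extra intra-module edges beyond the
#'   spanning tree.
#' @param seed integer seed.
#' @return a [CoFunctionNetwork-class].
#' @export
simulateNetwork <- function(genes, plantedModules = list(),
                            backgroundEdgeProb = 0.01, intraEdgeProb = 0.3,
                            seed = 1) {
  if (is(genes, "GRanges")) genes <- genes$gene_id
  genes <- as.character(genes)
  set.seed(seed)
  ea <- character(0); eb <- character(0)
  for (mod in plantedModules) {
    mod <- as.character(mod)
    stopifnot(all(mod %in% genes), length(mod) >= 2)
    ord <- sample(mod)
    for (i in 2:length(ord)) {       # random tree: connect to an earlier node
      ea <- c(ea, ord[sample.int(i - 1, 1)]); eb <- c(eb, ord[i])
    }
    if (length(mod) > 2 && intraEdgeProb > 0) {
      prs <- utils::combn(sort(mod), 2)
      keep <- runif(ncol(prs)) < intraEdgeProb
      ea <- c(ea, prs[1, keep]); eb <- c(eb, prs[2, keep])
    }
  }
  n <- length(genes)
  if (backgroundEdgeProb > 0 && n >= 2) {
    npair <- n * (n - 1) / 2
    ne <- rbinom(1, npair, backgroundEdgeProb)
    if (ne > 0) {
      ix <- sample(npair, ne)
      ij <- pairFromIndex(ix, n)
      ea <- c(ea, genes[ij[, 1]]); eb <- c(eb, genes[ij[, 2]])
    }
  }
  if (!length(ea))
    return(coFunctionNetwork(data.frame(gene_a = character(0),
                                        gene_b = character(0),
                                        score = numeric(0)), genes = genes))
  ed <- data.frame(gene_a = ea, gene_b = eb,
                   score = runif(length(ea), 0.5, 3),
                   stringsAsFactors = FALSE)
  coFunctionNetwork(ed, genes = genes)
}

#' Simulate a gene-to-term annotation table with planted enrichment
#'
#' Every term annotates a random `backgroundProb` fraction of all genes;
#' terms listed in `enriched` additionally cover a chosen fraction of a given
#' gene set, planting the enrichment signal that term-enrichment tests should
#' recover.
#'
#' @param genes gene identifiers (character) or annotation `GRanges`.
#' @param nTerms number of background terms.
#' @param enriched named list: `term id -> list(genes = <set>, coverage = f)`.
#' @param backgroundProb per-gene annotation probability for each term.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `term`.
#' @export
simulateGOTable <- function(genes, nTerms = 10, enriched = list(),
                            backgroundProb = 0.1, seed = 1) {
  if (is(genes, "GRanges")) genes <- genes$gene_id
  genes <- as.character(genes)
  set.seed(seed)
  terms <- sprintf("TERM:%04d", seq_len(nTerms))
  gs <- character(0); ts <- character(0)
  for (t in terms) {
    hit <- genes[runif(length(genes)) < backgroundProb]
    gs <- c(gs, hit); ts <- c(ts, rep(t, length(hit)))
  }
  for (t in names(enriched)) {
    spec <- enriched[[t]]
    tgt <- as.character(spec$genes)
    nsel <- max(1L, floor(spec$coverage * length(tgt)))
    hit <- sample(tgt, nsel)
    gs <- c(gs, hit); ts <- c(ts, rep(t, length(hit)))
  }
  out <- unique(data.frame(gene = gs, term = ts, stringsAsFactors = FALSE))
  out <- out[order(out$term, out$gene), ]
  rownames(out) <- NULL
  out
}
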