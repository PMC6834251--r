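sigTab <- function(chrom, pos, p = NULL) {
  data.frame(marker = sprintf("m%03d", seq_along(pos)), chrom = chrom,
             pos = pos, pvalue = p %||% runif(length(pos), 1e-12, 1e-8),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("window merging joins overlapping windows and splits over gaps", {
  r1 <- mergeRegions(sigTab("chr1", c(100000, 115000)), window = 10000)
  expect_length(r1, 1)
  expect_equal(GenomicRanges::start(r1), 90000)
  expect_equal(GenomicRanges::end(r1), 125000)
  expect_equal(r1$n_markers, 2L)

  r2 <- mergeRegions(sigTab("chr1", c(100000, 130000)), window = 10000)
  expect_length(r2, 2)

  ## touching windows (markers exactly 2*window apart) share a base: merged;
  ## one bp further apart: separate
  expect_length(mergeRegions(sigTab("chr1", c(100000, 120000)), 10000), 1)
  expect_length(mergeRegions(sigTab("chr1", c(100000, 120001)), 10000), 2)
})

test_that("region merging equals a brute-force union-find partition", {
  set.seed(123)
  for (rep in 1:200) {
    nm <- sample(2:25, 1)
    chrom <- sample(paste0("chr", 1:3), nm, replace = TRUE)
    pos <- sample(1:500000, nm)
    w <- sample(c(5000, 10000, 20000), 1)
    tab <- sigTab(chrom, pos)
    reg <- mergeRegions(tab, w)
    ## our partition: region index per marker
    win <- GenomicRanges::GRanges(chrom,
             IRanges::IRanges(pmax(pos - w, 1), pos + w))
    ours <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(win, reg))
    oracle <- unionFindRegions(chrom, pos, w)
    expect_equal(length(unique(ours)), length(unique(oracle)))
    ## identical partition, not just identical counts
    expect_equal(as.integer(factor(ours, levels = unique(ours))),
                 as.integer(factor(oracle, levels = unique(oracle))))
  }
})

test_that("candidate mapping uses closed intervals with exact boundaries", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100000, 102000),
                                  gene_id = "g1", type = "gene")
  inGene <- mapCandidates(sigTab("chr1", 101000), genes, 10000, "t")
  expect_equal(inGene$gene, "g1")
  near <- mapCandidates(sigTab("chr1", 90000), genes, 10000, "t")
  expect_equal(near$gene, "g1")                  # distance exactly 10,000
  far <- mapCandidates(sigTab("chr1", 89999), genes, 10000, "t")
  expect_equal(nrow(far), 0L)
  expect_error(mapCandidates(sigTab("chrX", 100), genes, 10000, "t"),
               "chrX")
})

test_that("candidate mapping equals an exhaustive all-pairs scan", {
  set.seed(321)
  for (rep in 1:200) {
    ng <- sample(3:20, 1); nm <- sample(1:15, 1)
    genes <- simulateAnnotation(ng, geneLength = sample(500:3000, 1),
                                spacing = sample(500:20000, 1),
                                chromosomes = 2)
    chrom <- sample(paste0("chr", 1:2), nm, replace = TRUE)
    pos <- sample(1:300000, nm)
    w <- sample(c(2000, 10000), 1)
    got <- mapCandidates(sigTab(chrom, pos), genes, w, "t")$gene
    expect_equal(got, bruteCandidates(chrom, pos, genes, w))
  }
})

test_that("merged-region genes equal raw-marker genes and windows are monotone", {
  set.seed(11)
  genes <- simulateAnnotation(40, 2000, 6000, 2)
  chrom <- sample(paste0("chr", 1:2), 12, replace = TRUE)
  pos <- sample(1:250000, 12)
  tab <- sigTab(chrom, pos)
  byMarker <- mapCandidates(tab, genes, 10000, "t")$gene
  ## windows are preserved by merging, so the union of genes is unchanged
  reg <- mergeRegions(tab, 10000)
  regTab <- data.frame(marker = sprintf("r%02d", seq_along(reg)),
                       chrom = as.character(GenomicRanges::seqnames(reg)),
                       pos = NA, pvalue = NA)
  regGenes <- sort(unique(genes$gene_id[S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(reg, genes))]))
  expect_equal(byMarker, regGenes)
  ## shrinking the window never adds candidates
  small <- mapCandidates(tab, genes, 2000, "t")$gene
  expect_true(all(small %in% byMarker))
})

test_that("Venn counts classify genes into exact trait combinations", {
  tA <- data.frame(gene = c("g1", "g2"), trait = "A", chrom = "chr1",
                   min_p = 1e-9, n_snps = 1L, markers = c("m1", "m2"))
  tB <- data.frame(gene = c("g2", "g3"), trait = "B", chrom = "chr1",
                   min_p = 1e-9, n_snps = 1L, markers = c("m2", "m3"))
  v <- vennCounts(list(A = tA, B = tB))
  expect_equal(v$n_genes[v$combination == "A"], 1L)
  expect_equal(v$n_genes[v$combination == "B"], 1L)
  expect_equal(v$n_genes[v$combination == "A&B"], 1L)
  ## a single table puts all genes in the one-trait cell
  v1 <- vennCounts(list(A = tA))
  expect_equal(v1$n_genes, 2L)
  expect_equal(v1$n_traits, 1L)
})

test_that("Venn counts equal brute-force powerset classification", {
  set.seed(55)
  genesAll <- sprintf("g%02d", 1:25)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    tabs <- lapply(seq_len(k), function(i) {
      gs <- sample(genesAll, sample(3:12, 1))
      data.frame(gene = gs, trait = LETTERS[i], chrom = "chr1", min_p = 1e-8,
                 n_snps = 1L, markers = paste0("m_", gs))
    })
    names(tabs) <- LETTERS[seq_len(k)]
    v <- vennCounts(tabs)
    ## oracle: classify every gene by its exact membership pattern
    uni <- unique(unlist(lapply(tabs, `[[`, "gene")))
    combo <- vapply(uni, function(g)
      paste(sort(names(tabs)[vapply(tabs, function(t) g %in% t$gene,
                                    logical(1))]), collapse = "&"),
      character(1))
    oracle <- table(combo)
    for (cmb in names(oracle))
      expect_equal(v$n_genes[v$combination == cmb],
                   as.integer(oracle[[cmb]]))
    ## cells partition the union
    expect_equal(sum(v$n_genes), length(uni))
  }
})
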