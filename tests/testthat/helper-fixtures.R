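# Fixture builders and independent oracles used across test files.

# small genotype matrix with explicit dosages
makeGeno <- function(dosage, chrom = NULL, pos = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("a%03d", seq_len(n))
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) {
    pos <- integer(m)
    for (cc in unique(chrom)) {
      i <- which(chrom == cc)
      pos[i] <- seq(1000, by = 1000, length.out = length(i))
    }
  }
  mk <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                               ref = rep("A", m), alt = rep("T", m))
  genotypeMatrix(dosage, mk)
}

randomGeno <- function(n, m, seed = 1, maf = 0.3) {
  set.seed(seed)
  makeGeno(matrix(rbinom(n * m, 1, runif(m, maf, 1 - maf)[rep(seq_len(m),
                                                              each = n)]),
                  n, m))
}

# dense GLS oracle for the mixed-model scan: inverts V explicitly per marker
denseGLSOracle <- function(y, G, K, VG, VE) {
  n <- length(y)
  V <- VG * K + VE * diag(n)
  Vi <- solve(V)
  m <- ncol(G)
  p <- numeric(m)
  beta <- numeric(m)
  for (j in seq_len(m)) {
    W <- cbind(1, G[, j])
    A <- solve(t(W) %*% Vi %*% W)
    b <- A %*% t(W) %*% Vi %*% y
    r <- y - W %*% b
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - 2)
    se <- sqrt(s2 * A[2, 2])
    Fstat <- (b[2] / se)^2
    p[j] <- pf(Fstat, 1, n - 2, lower.tail = FALSE)
    beta[j] <- b[2]
  }
  list(pvalue = p, beta = beta)
}

# brute-force union-find over pairwise window overlap (region-merge oracle)
unionFindRegions <- function(chrom, pos, window) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= 2 * window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# exhaustive all-pairs marker-to-gene scan (window-mapping oracle)
bruteCandidates <- function(chrom, pos, genes, window) {
  hits <- character(0)
  for (i in seq_along(pos)) {
    lo <- pos[i] - window; hi <- pos[i] + window
    for (g in seq_along(genes)) {
      if (as.character(GenomicRanges::seqnames(genes))[g] == chrom[i] &&
          GenomicRanges::start(genes)[g] <= hi &&
          GenomicRanges::end(genes)[g] >= lo)
        hits <- c(hits, genes$gene_id[g])
    }
  }
  sort(unique(hits))
}

# plain breadth-first search connected components (module oracle)
bfsComponents <- function(nodes, edgeA, edgeB) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edgeA)) {
    adj[[edgeA[i]]] <- c(adj[[edgeA[i]]], edgeB[i])
    adj[[edgeB[i]]] <- c(adj[[edgeB[i]]], edgeA[i])
  }
  seen <- character(0)
  comps <- list()
  for (s in nodes) {
    if (s %in% seen) next
    queue <- s; comp <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# exact hypergeometric upper tail by explicit enumeration over the support
enumHyperTail <- function(k, M, K, n) {
  sum(vapply(max(0, K + n - M):min(K, n), function(j)
    if (j >= k) choose(K, j) * choose(M - K, n - j) / choose(M, n) else 0,
    numeric(1)))
}
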