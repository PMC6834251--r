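#' Sub-threshold marker set from an association scan
#'
#' Tested markers with `p <= 10^-negLog10P` (boundary inclusive), i.e. the
#' markers retained at a relaxed `-log10(p)` screening threshold.
#'
#' @param result an [AssociationResult-class].
#' @param negLog10P `-log10(p)` threshold (default 4).
#' @return character vector of marker identifiers.
#' @export
subthresholdSet <- function(result, negLog10P = 4) {
  tab <- assocTable(result)
  tab$marker[tab$tested & !is.na(tab$pvalue) &
             tab$pvalue <= 10^(-negLog10P)]
}

#' Test the overlap of two marker sets against chance
#'
#' With universe size `M` (all tested markers), set sizes `a` and `b` and
#' observed overlap `k`, the analytic p-value is the hypergeometric upper
#' tail `P(X >= k)`, `X ~ Hypergeometric(M, a, b)`, computed by direct
#' log-space summation.  The random-markers empirical p-value redraws size-b
#' sets uniformly from the universe and applies the add-one rule
#' `(1 + #{overlap >= k}) / (1 + nResamples)`, which can never return 0.
#'
#' @param setA,setB marker identifier vectors, subsets of `universe`.
#' @param universe all eligible marker identifiers.
#' @param nResamples number of random-marker resamples (0 skips the
#'   empirical p-value).
#' @param seed integer seed for the resampling.
#' @return an `OverlapTestResult` list: `M`, `a`, `b`, `k`, `analyticP`,
#'   `empiricalP`, `nResamples`, `method`, `seed`.
#' @examples
#' overlapTest(letters[1:3], letters[1:3], letters[1:10], nResamples = 0)
#' @export
overlapTest <- function(setA, setB, universe, nResamples = 1000,
                        seed = 1) {
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  universe <- unique(as.character(universe))
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("both sets must be subsets of the universe")
  M <- length(universe); a <- length(setA); b <- length(setB)
  k <- length(intersect(setA, setB))
  analytic <- hyperUpperTail(k, M, a, b)
  empirical <- NA_real_
  if (nResamples > 0) {
    set.seed(seed)
    amask <- universe %in% setA
    cnt <- 0L
    for (r in seq_len(nResamples)) {
      idx <- sample.int(M, b)
      if (sum(amask[idx]) >= k) cnt <- cnt + 1L
    }
    empirical <- (1 + cnt) / (1 + nResamples)
  }
  structure(list(M = M, a = a, b = b, k = k, analyticP = analytic,
                 empiricalP = empirical, nResamples = nResamples,
                 method = "random-markers", seed = seed),
            class = "OverlapTestResult")
}

#' @export
print.OverlapTestResult <- function(x, ...) {
  cat(sprintf(
    "Overlap test (%s): k = %d of a = %d, b = %d in M = %d\n  analytic p = %.3g",
    x$method, x$k, x$a, x$b, x$M, x$analyticP))
  if (!is.na(x$empiricalP))
    cat(sprintf(", empirical p = %.3g (%d resamples)", x$empiricalP,
                x$nResamples))
  cat("\n")
  invisible(x)
}

#' Phenotype-permutation null for the overlap of two traits' hit sets
#'
#' Re-runs both association scans on accession-label-permuted trait values
#' (one shared permutation per iteration, genotypes untouched, so genotype
#' structure is preserved) and counts permutations whose sub-threshold
#' overlap reaches the observed one.  Expensive; intended for small
#' instances.
#'
#' @param traitA,traitB [TraitVector-class] objects.
#' @param geno a [GenotypeMatrix-class].
#' @param kin a [KinshipMatrix-class].
#' @param negLog10P screening threshold for the hit sets.
#' @param nPerms number of permutations.
#' @param seed integer seed.
#' @param mafThreshold MAF threshold passed to the scans.
#' @return an `OverlapTestResult` with `method = "phenotype-permutation"`.
#' @export
overlapTestPermuted <- function(traitA, traitB, geno, kin, negLog10P = 4,
                                nPerms = 100, seed = 1, mafThreshold = 0.05) {
  scanSet <- function(tv) {
    vc <- fitNullModel(tv, kin)
    subthresholdSet(gwasScan(tv, geno, kin, vc, mafThreshold), negLog10P)
  }
  sA <- scanSet(traitA); sB <- scanSet(traitB)
  k <- length(intersect(sA, sB))
  universe <- subthresholdSet(
    gwasScan(traitA, geno, kin, fitNullModel(traitA, kin), mafThreshold), 0)
  set.seed(seed)
  cnt <- 0L
  acc <- intersect(names(traitValues(traitA)), names(traitValues(traitB)))
  vA <- traitValues(traitA)[acc]; vB <- traitValues(traitB)[acc]
  for (r in seq_len(nPerms)) {
    perm <- sample(acc)                     # one shared label permutation
    pa <- traitVector(setNames(unname(vA), perm), traitName(traitA))
    pb <- traitVector(setNames(unname(vB), perm), traitName(traitB))
    ko <- length(intersect(scanSet(pa), scanSet(pb)))
    if (ko >= k) cnt <- cnt + 1L
  }
  structure(list(M = length(universe), a = length(sA), b = length(sB), k = k,
                 analyticP = hyperUpperTail(k, length(universe), length(sA),
                                            length(sB)),
                 empiricalP = (1 + cnt) / (1 + nPerms),
                 nResamples = nPerms, method = "phenotype-permutation",
                 seed = seed),
            class = "OverlapTestResult")
}
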