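#' GenotypeMatrix: inbred biallelic genotypes with marker coordinates
#'
#' Dosages are coded on the haploid scale, 0 (reference homozygote) or 1
#' (alternate homozygote), with `NA` for missing calls; rows are accessions
#' (inbred lines), columns are markers.  Marker coordinates (1-based) live in
#' a [GenomicRanges::GRanges] parallel to the columns, with `ref` and `alt`
#' alleles in its metadata columns.
#'
#' @slot dosage numeric matrix, accessions x markers, entries in \{0, 1, NA\}.
#' @slot markers `GRanges` of length `ncol(dosage)` with mcols `ref`, `alt`.
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", markers = "GRanges"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  mk <- object@markers
  msg <- character()
  if (ncol(d) != length(mk))
    msg <- c(msg, "ncol(dosage) must equal length(markers)")
  if (is.null(rownames(d)))
    msg <- c(msg, "dosage must have accession rownames")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1)))
    msg <- c(msg, "dosages must be 0, 1 or NA (inbred haploid coding)")
  if (!all(c("ref", "alt") %in% colnames(mcols(mk))))
    msg <- c(msg, "markers must carry 'ref' and 'alt' metadata columns")
  # strictly increasing positions within each chromosome
  bychr <- split(start(mk), as.character(seqnames(mk)))
  if (any(vapply(bychr, function(p) any(diff(p) <= 0), logical(1))))
    msg <- c(msg, "marker positions must be strictly increasing within chromosome")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage accessions x markers matrix with entries in \{0, 1, NA\};
#'   must have accession rownames.
#' @param markers `GRanges` with one range per marker (width-1 positions) and
#'   metadata columns `ref` and `alt`.  Names are used as marker identifiers;
#'   generated as `chrom_pos` when absent.
#' @return a [GenotypeMatrix-class] object.
#' @export
genotypeMatrix <- function(dosage, markers) {
  if (is.null(names(markers)))
    names(markers) <- paste(as.character(seqnames(markers)), start(markers),
                            sep = "_")
  colnames(dosage) <- names(markers)
  new("GenotypeMatrix", dosage = dosage, markers = markers)
}

#' KinshipMatrix: genetic relatedness between accessions
#'
#' @slot values symmetric n x n numeric matrix with accession dimnames.
#' @slot method `"grm"` (centered/scaled realized-relationship matrix) or
#'   `"ibs"` (allele-sharing proportion).
#' @export
setClass("KinshipMatrix",
  representation(values = "matrix", method = "character"))

setValidity("KinshipMatrix", function(object) {
  K <- object@values
  msg <- character()
  if (nrow(K) != ncol(K)) msg <- c(msg, "kinship must be square")
  if (is.null(rownames(K)) || !identical(rownames(K), colnames(K)))
    msg <- c(msg, "kinship must have matching accession dimnames")
  if (max(abs(K - t(K))) > 1e-8) msg <- c(msg, "kinship must be symmetric")
  if (!object@method %in% c("grm", "ibs"))
    msg <- c(msg, "method must be 'grm' or 'ibs'")
  if (length(msg)) msg else TRUE
})

#' VarianceComponents: REML/ML fit of the polygenic null model
#'
#' Components of `y = Xb + u + e`, `u ~ N(0, V_G K)`, `e ~ N(0, V_E I)`.
#' `delta = V_E / V_G` and the pseudo-heritability is
#' `H2 = V_G / (V_G + V_E) = 1 / (1 + delta)`.
#'
#' @slot VG genetic variance (>= 0).
#' @slot VE residual variance (>= 0).
#' @slot delta `VE / VG` (`Inf` when `VG == 0`).
#' @slot H2 pseudo-heritability.
#' @slot logLik restricted (or full, for ML) log-likelihood at the optimum.
#' @slot n number of accessions used.
#' @slot method `"REML"` or `"ML"`.
#' @export
setClass("VarianceComponents",
  representation(VG = "numeric", VE = "numeric", delta = "numeric",
                 H2 = "numeric", logLik = "numeric", n = "integer",
                 method = "character"))

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (object@VG < 0 || object@VE < 0) msg <- c(msg, "variances must be >= 0")
  tot <- object@VG + object@VE
  if (tot > 0 && abs(object@H2 - object@VG / tot) > 1e-10)
    msg <- c(msg, "H2 must equal VG/(VG+VE)")
  if (length(msg)) msg else TRUE
})

#' Construct a VarianceComponents object
#'
#' @param VG,VE genetic and residual variance.
#' @param logLik log-likelihood at the optimum (`NA` if not from a fit).
#' @param n number of accessions (`NA` if not from a fit).
#' @param method `"REML"` or `"ML"`.
#' @return a [VarianceComponents-class] object.
#' @export
varianceComponents <- function(VG, VE, logLik = NA_real_, n = NA_integer_,
                               method = "REML") {
  tot <- VG + VE
  new("VarianceComponents", VG = VG, VE = VE,
      delta = if (VG > 0) VE / VG else Inf,
      H2 = if (tot > 0) VG / tot else 0,
      logLik = logLik, n = as.integer(n), method = method)
}

#' AssociationResult: per-marker mixed-model association statistics
#'
#' @slot table data.frame with one row per marker: `marker`, `chrom`, `pos`,
#'   `ref`, `alt`, `maf`, `missing`, `beta`, `se`, `stat`, `pvalue`,
#'   `tested`.  Untested (MAF-filtered, monomorphic or high-missingness)
#'   markers carry `NA` statistics.
#' @slot trait trait name.
#' @slot nTested number of markers actually tested.
#' @slot nAccessions number of accessions in the scan.
#' @export
setClass("AssociationResult",
  representation(table = "data.frame", trait = "character",
                 nTested = "integer", nAccessions = "integer"))

setValidity("AssociationResult", function(object) {
  tab <- object@table
  need <- c("marker", "chrom", "pos", "maf", "pvalue", "tested")
  msg <- character()
  if (!all(need %in% colnames(tab)))
    msg <- c(msg, paste("table must contain columns:", paste(need, collapse = ", ")))
  else {
    p <- tab$pvalue[tab$tested]
    if (length(p) && (any(is.na(p)) || any(p <= 0) || any(p > 1)))
      msg <- c(msg, "tested p-values must lie in (0, 1]")
    if (any(!is.na(tab$pvalue[!tab$tested])))
      msg <- c(msg, "untested markers must carry NA p-values")
    mafs <- tab$maf[!is.na(tab$maf)]
    if (length(mafs) && (any(mafs < 0) || any(mafs > 0.5)))
      msg <- c(msg, "MAF must lie in [0, 0.5]")
  }
  if (length(msg)) msg else TRUE
})

#' TraitVector: one quantitative trait over accessions
#'
#' @slot values named numeric vector (accession -> value), all finite.
#' @slot name trait label, e.g. `"RGRnorm(-P/Ct)"`.
#' @slot provenance list describing how the trait was derived (conditions,
#'   formula, guard thresholds, dropped accessions).
#' @export
setClass("TraitVector",
  representation(values = "numeric", name = "character",
                 provenance = "list"))

setValidity("TraitVector", function(object) {
  v <- object@values
  msg <- character()
  if (length(v) && is.null(names(v))) msg <- c(msg, "values must be named by accession")
  if (length(v) && any(!is.finite(v))) msg <- c(msg, "trait values must be finite")
  if (anyDuplicated(names(v))) msg <- c(msg, "duplicated accession names")
  if (length(msg)) msg else TRUE
})

#' Construct a TraitVector
#'
#' @param values named numeric vector of trait values (accession -> value).
#' @param name trait label.
#' @param provenance free-form list recording how the trait was derived.
#' @return a [TraitVector-class] object.
#' @export
traitVector <- function(values, name, provenance = list()) {
  new("TraitVector", values = values, name = name, provenance = provenance)
}

#' CoFunctionNetwork: weighted undirected gene graph
#'
#' Edges score the likelihood that two genes act in the same biological
#' process (AraNet-style).  At most one edge per unordered pair; self-loops
#' are disallowed.
#'
#' @slot edges data.frame with columns `gene_a`, `gene_b`, `score` (> 0);
#'   pairs stored with `gene_a < gene_b`.
#' @slot genes character vector of node identifiers (may include isolated
#'   genes).
#' @export
setClass("CoFunctionNetwork",
  representation(edges = "data.frame", genes = "character"))

setValidity("CoFunctionNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("gene_a", "gene_b", "score") %in% colnames(e)))
    msg <- c(msg, "edges need columns gene_a, gene_b, score")
  else if (nrow(e)) {
    if (any(e$score <= 0)) msg <- c(msg, "edge scores must be > 0")
    if (any(e$gene_a == e$gene_b)) msg <- c(msg, "self-loops are not allowed")
    if (anyDuplicated(paste(e$gene_a, e$gene_b))) msg <- c(msg, "duplicate edges")
    if (!all(c(e$gene_a, e$gene_b) %in% object@genes))
      msg <- c(msg, "edge endpoints must be in the gene set")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CoFunctionNetwork
#'
#' Pairs are canonicalized to `gene_a < gene_b`; duplicate edges keep the
#' maximum score; self-loops are dropped with a warning.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `score`.
#' @param genes optional node set; defaults to all genes seen in `edges`.
#' @return a [CoFunctionNetwork-class] object.
#' @export
coFunctionNetwork <- function(edges, genes = NULL) {
  stopifnot(all(c("gene_a", "gene_b", "score") %in% colnames(edges)))
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  loop <- edges$gene_a == edges$gene_b
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped")
    edges <- edges[!loop, , drop = FALSE]
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges <- data.frame(gene_a = a, gene_b = b, score = edges$score,
                      stringsAsFactors = FALSE)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    sc <- tapply(edges$score, key, max)
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    edges$score <- as.numeric(sc[paste(edges$gene_a, edges$gene_b, sep = "\r")])
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(genes)) genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  new("CoFunctionNetwork", edges = edges, genes = sort(unique(as.character(genes))))
}
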