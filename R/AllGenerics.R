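#' @include AllClasses.R
NULL

#' Accession identifiers
#' @param x a GenotypeMatrix or KinshipMatrix.
#' @return character vector of accession labels.
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' Dosage matrix (accessions x markers, haploid 0/1 coding)
#' @param x a GenotypeMatrix.
#' @return numeric matrix.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' Marker coordinates
#' @param x a GenotypeMatrix or AssociationResult.
#' @return `GRanges` of marker positions.
#' @export
setGeneric("markerRanges", function(x) standardGeneric("markerRanges"))

#' Kinship values
#' @param x a KinshipMatrix.
#' @return symmetric numeric matrix.
#' @export
setGeneric("kinship", function(x) standardGeneric("kinship"))

#' Genetic variance component
#' @param x a VarianceComponents.
#' @return numeric scalar.
#' @export
setGeneric("varG", function(x) standardGeneric("varG"))

#' Residual variance component
#' @param x a VarianceComponents.
#' @return numeric scalar.
#' @export
setGeneric("varE", function(x) standardGeneric("varE"))

#' Pseudo-heritability H2 = V_G / (V_G + V_E)
#' @param x a VarianceComponents.
#' @return numeric scalar in [0, 1].
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' Association table
#' @param x an AssociationResult.
#' @return data.frame of per-marker statistics.
#' @export
setGeneric("assocTable", function(x) standardGeneric("assocTable"))

#' Trait values
#' @param x a TraitVector.
#' @return named numeric vector.
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' Trait name
#' @param x a TraitVector or AssociationResult.
#' @return character scalar.
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' Network edge list
#' @param x a CoFunctionNetwork.
#' @return data.frame `gene_a`, `gene_b`, `score`.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Network gene set
#' @param x a CoFunctionNetwork.
#' @return character vector of gene identifiers.
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

## ---- methods -------------------------------------------------------------

#' @describeIn GenotypeMatrix accession labels.
#' @param x a GenotypeMatrix.
#' @export
setMethod("accessions", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @describeIn KinshipMatrix accession labels.
#' @param x a KinshipMatrix.
#' @export
setMethod("accessions", "KinshipMatrix", function(x) rownames(x@values))

#' @describeIn GenotypeMatrix dosage matrix.
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @describeIn GenotypeMatrix marker coordinates as `GRanges`.
#' @export
setMethod("markerRanges", "GenotypeMatrix", function(x) x@markers)

#' @describeIn KinshipMatrix kinship values.
#' @export
setMethod("kinship", "KinshipMatrix", function(x) x@values)

#' @describeIn VarianceComponents genetic variance.
#' @param x a VarianceComponents.
#' @export
setMethod("varG", "VarianceComponents", function(x) x@VG)

#' @describeIn VarianceComponents residual variance.
#' @export
setMethod("varE", "VarianceComponents", function(x) x@VE)

#' @describeIn VarianceComponents pseudo-heritability.
#' @export
setMethod("heritability", "VarianceComponents", function(x) x@H2)

#' @describeIn AssociationResult per-marker statistics.
#' @param x an AssociationResult.
#' @export
setMethod("assocTable", "AssociationResult", function(x) x@table)

#' @describeIn AssociationResult trait name.
#' @export
setMethod("traitName", "AssociationResult", function(x) x@trait)

#' @describeIn TraitVector trait values.
#' @param x a TraitVector.
#' @export
setMethod("traitValues", "TraitVector", function(x) x@values)

#' @describeIn TraitVector trait name.
#' @export
setMethod("traitName", "TraitVector", function(x) x@name)

#' @describeIn CoFunctionNetwork edge list.
#' @param x a CoFunctionNetwork.
#' @export
setMethod("networkEdges", "CoFunctionNetwork", function(x) x@edges)

#' @describeIn CoFunctionNetwork gene set.
#' @export
setMethod("networkGenes", "CoFunctionNetwork", function(x) x@genes)

#' Subset a GenotypeMatrix by accessions (i) and/or markers (j)
#' @param x a GenotypeMatrix.
#' @param i accession index/names.
#' @param j marker index/names.
#' @param ... ignored.
#' @param drop ignored (never drops).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosage
  mk <- x@markers
  if (!missing(i)) d <- d[i, , drop = FALSE]
  if (!missing(j)) {
    d <- d[, j, drop = FALSE]
    mk <- mk[j]
  }
  new("GenotypeMatrix", dosage = d, markers = mk)
})

#' @describeIn GenotypeMatrix number of accessions.
#' @export
setMethod("nrow", "GenotypeMatrix", function(x) nrow(x@dosage))

#' @describeIn GenotypeMatrix number of markers.
#' @export
setMethod("ncol", "GenotypeMatrix", function(x) ncol(x@dosage))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "accessions x",
      ncol(object@dosage), "markers on",
      length(unique(as.character(seqnames(object@markers)))),
      "chromosome(s)\n")
  miss <- mean(is.na(object@dosage))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
})

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix (", object@method, "): ", nrow(object@values), " x ",
      ncol(object@values), " accessions\n", sep = "")
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents (%s): V_G = %.4g, V_E = %.4g, H2 = %.3f\n",
              object@method, object@VG, object@VE, object@H2))
})

setMethod("show", "AssociationResult", function(object) {
  cat("AssociationResult for trait '", object@trait, "': ",
      nrow(object@table), " markers (", object@nTested, " tested), ",
      object@nAccessions, " accessions\n", sep = "")
  p <- object@table$pvalue
  if (any(!is.na(p)))
    cat(sprintf("  min p = %.3g\n", min(p, na.rm = TRUE)))
})

setMethod("show", "TraitVector", function(object) {
  cat("TraitVector '", object@name, "': ", length(object@values),
      " accessions\n", sep = "")
})

setMethod("show", "CoFunctionNetwork", function(object) {
  cat("CoFunctionNetwork:", length(object@genes), "genes,",
      nrow(object@edges), "edges\n")
})
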