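#' Estimate root growth rate by pooled regression per accession and condition
#'
#' For every (accession, condition) cell, all replicate measurements are
#' pooled into one ordinary least-squares regression of primary root length
#' on seedling age; the slope is the root growth rate (RGR, length/day).
#' Cells with fewer than two distinct measurement days get `NA` estimates and
#' are flagged missing rather than erroring the run.  The slope standard
#' error and two-sided t-test p-value (slope = 0, `n - 2` df) are reported;
#' both are `NA` when the residual degrees of freedom are zero.
#'
#' @param pheno data.frame with columns `accession`, `condition`,
#'   `replicate`, `day`, `length`.
#' @return data.frame with one row per cell: `accession`, `condition`,
#'   `slope`, `intercept`, `se`, `pvalue`, `n`.
#' @examples
#' ph <- data.frame(accession = "a1", condition = "Ct", replicate = 1,
#'                  day = 3:5, length = c(30, 40, 50))
#' estimateRGR(ph)
#' @export
estimateRGR <- function(pheno) {
  need <- c("accession", "condition", "day", "length")
  if (!is.data.frame(pheno) || !all(need %in% colnames(pheno)))
    stop("phenotype table needs columns accession, condition, day, length")
  if (!nrow(pheno)) stop("empty phenotype table")
  if (any(pheno$day <= 0)) stop("days must be positive")
  if (any(pheno$length < 0)) stop("lengths must be >= 0")
  g <- factor(paste(pheno$accession, pheno$condition, sep = "\r"))
  x <- as.numeric(pheno$day)
  y <- as.numeric(pheno$length)
  one <- rep(1, length(x))
  n   <- as.numeric(rowsum(one, g))
  sx  <- as.numeric(rowsum(x, g))
  sy  <- as.numeric(rowsum(y, g))
  sxx <- as.numeric(rowsum(x * x, g))
  sxy <- as.numeric(rowsum(x * y, g))
  syy <- as.numeric(rowsum(y * y, g))
  Sxx <- sxx - sx^2 / n
  Sxy <- sxy - sx * sy / n
  Syy <- syy - sy^2 / n
  ok <- Sxx > 1e-12                        # >= 2 distinct days
  slope <- ifelse(ok, Sxy / Sxx, NA_real_)
  intercept <- ifelse(ok, (sy - slope * sx) / n, NA_real_)
  rss <- pmax(Syy - Sxy^2 / ifelse(ok, Sxx, NA_real_), 0)
  df <- n - 2
  se <- ifelse(ok & df > 0, sqrt(rss / df / Sxx), NA_real_)
  tstat <- slope / se
  pval <- ifelse(ok & df > 0, 2 * pt(abs(tstat), df, lower.tail = FALSE),
                 NA_real_)
  key <- strsplit(levels(g), "\r", fixed = TRUE)
  out <- data.frame(accession = vapply(key, `[`, character(1), 1),
                    condition = vapply(key, `[`, character(1), 2),
                    slope = slope, intercept = intercept, se = se,
                    pvalue = pval, n = as.integer(n),
                    stringsAsFactors = FALSE)
  out[order(out$accession, out$condition), , drop = FALSE]
}

#' Fraction of accessions with a significant growth-rate slope, per condition
#'
#' @param rgr output of [estimateRGR()].
#' @param alpha significance level for the two-sided slope t-test.
#' @return data.frame `condition`, `fraction`, `n` (accessions with a
#'   non-missing slope and p-value).  Conditions without any usable cell are
#'   omitted.
#' @export
slopeSignificanceSummary <- function(rgr, alpha = 0.05) {
  ok <- !is.na(rgr$slope) & !is.na(rgr$pvalue)
  use <- rgr[ok, , drop = FALSE]
  if (!nrow(use))
    return(data.frame(condition = character(0), fraction = numeric(0),
                      n = integer(0)))
  sp <- split(use$pvalue, use$condition)
  data.frame(condition = names(sp),
             fraction = vapply(sp, function(p) mean(p < alpha), numeric(1)),
             n = vapply(sp, length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalized growth-rate trait: deficiency RGR relative to control
#'
#' Per accession, the trait is `slope[condition] / slope[reference]`.
#' Accessions with a missing slope in either condition, or whose reference
#' slope is smaller in absolute value than `minRefSlope`, are dropped and
#' recorded in the trait's provenance (a guard against ratio blow-up when
#' control growth is near zero).
#'
#' @param rgr output of [estimateRGR()].
#' @param condition condition whose RGR is normalized.
#' @param reference reference (control) condition.
#' @param minRefSlope reference-slope guard; default 10% of the panel-median
#'   reference slope.
#' @return a [TraitVector-class] named `RGRnorm(condition/reference)`.
#' @export
normalizeRGR <- function(rgr, condition, reference = "Ct",
                         minRefSlope = NULL) {
  for (lab in c(condition, reference))
    if (!lab %in% rgr$condition) stop("unknown condition label: ", lab)
  a <- rgr[rgr$condition == condition, c("accession", "slope")]
  b <- rgr[rgr$condition == reference, c("accession", "slope")]
  mg <- merge(a, b, by = "accession", suffixes = c(".cond", ".ref"))
  if (is.null(minRefSlope))
    minRefSlope <- 0.1 * median(b$slope, na.rm = TRUE)
  keep <- !is.na(mg$slope.cond) & !is.na(mg$slope.ref) &
    abs(mg$slope.ref) >= minRefSlope
  dropped <- mg$accession[!keep]
  mg <- mg[keep, , drop = FALSE]
  vals <- setNames(mg$slope.cond / mg$slope.ref, mg$accession)
  traitVector(vals,
              name = sprintf("RGRnorm(%s/%s)", condition, reference),
              provenance = list(condition = condition, reference = reference,
                                minRefSlope = minRefSlope,
                                dropped = dropped))
}

#' Delta trait: difference of two normalized growth-rate traits
#'
#' Isolates the interaction between a combined and a single deficiency,
#' e.g. `delta = RGRnorm(-P-Fe/Ct) - RGRnorm(-Fe/Ct)`.  Computed on the
#' intersection of the two traits' accessions; an empty intersection yields
#' an empty trait with a warning.
#'
#' @param normA,normB [TraitVector-class] objects (minuend, subtrahend).
#' @param name trait label; defaults to `delta(nameA - nameB)`.
#' @return a [TraitVector-class] with both parents in its provenance.
#' @export
deltaTrait <- function(normA, normB, name = NULL) {
  stopifnot(is(normA, "TraitVector"), is(normB, "TraitVector"))
  common <- intersect(names(traitValues(normA)), names(traitValues(normB)))
  if (!length(common))
    warning("no accessions shared between the two traits")
  vals <- traitValues(normA)[common] - traitValues(normB)[common]
  if (is.null(name))
    name <- sprintf("delta(%s - %s)", traitName(normA), traitName(normB))
  traitVector(vals, name = name,
              provenance = list(parentA = traitName(normA),
                                parentB = traitName(normB),
                                provenanceA = normA@provenance,
                                provenanceB = normB@provenance))
}
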