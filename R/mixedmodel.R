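#' Per-marker minor allele frequency
#'
#' Alt-allele frequency `f` over non-missing entries (haploid inbred coding);
#' MAF is `min(f, 1 - f)`.  Markers with no non-missing calls get `NA`.
#'
#' @param geno a [GenotypeMatrix-class].
#' @return named numeric vector of MAFs in `[0, 0.5]`.
#' @export
computeMAF <- function(geno) {
  f <- colMeans(dosage(geno), na.rm = TRUE)
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Filter markers by minor allele frequency
#'
#' Keeps markers with `MAF >= threshold` (inclusive, matching an
#' "at least 5%" rule at the default threshold used in association panels).
#' Idempotent.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param threshold MAF threshold (inclusive).
#' @return the filtered [GenotypeMatrix-class].
#' @export
filterMAF <- function(geno, threshold = 0.05) {
  maf <- computeMAF(geno)
  keep <- !is.na(maf) & maf >= threshold
  geno[, which(keep)]
}

#' Kinship matrix under the infinitesimal model
#'
#' `method = "grm"`: realized relationship matrix `W W' / m` where columns of
#' `W` are dosage columns centered and scaled by their standard deviation
#' (zero-variance markers are skipped with a warning).  `method = "ibs"`:
#' expected proportion of shared alleles.  Missing dosages are mean-imputed
#' per marker.  The result is symmetrized and, if its smallest eigenvalue
#' falls below `1e-8`, shifted on the diagonal by the smallest amount that
#' restores it (stabilization for downstream REML).
#'
#' @param geno a [GenotypeMatrix-class].
#' @param method `"grm"` or `"ibs"`.
#' @return a [KinshipMatrix-class].
#' @export
computeKinship <- function(geno, method = c("grm", "ibs")) {
  method <- match.arg(method)
  D <- dosage(geno)
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    na <- which(is.na(D), arr.ind = TRUE)
    D[na] <- mu[na[, 2]]
  }
  if (method == "grm") {
    sds <- apply(D, 2, sd)
    zero <- sds < 1e-12
    if (any(zero))
      warning(sum(zero), " zero-variance marker(s) skipped in GRM scaling")
    W <- scale(D[, !zero, drop = FALSE])
    K <- tcrossprod(W) / ncol(W)
  } else {
    m <- ncol(D)
    A <- tcrossprod(D)
    rs <- rowSums(D)
    K <- 1 - (outer(rs, rs, "+") - 2 * A) / m
  }
  K <- (K + t(K)) / 2
  minEv <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (minEv < 1e-8) {
    message("kinship stabilized: diagonal shifted by ", format(1e-8 - minEv))
    K <- K + diag(1e-8 - minEv, nrow(K))
  }
  dimnames(K) <- list(accessions(geno), accessions(geno))
  new("KinshipMatrix", values = K, method = method)
}

## shared spectral machinery for the null model: eigendecompose S K S
## (S projects out the fixed effects) and return the pieces the profiled
## (restricted) likelihood needs
nullSpectral <- function(y, K, X) {
  n <- length(y)
  q <- ncol(X)
  XtXi <- solve(crossprod(X))
  S <- diag(n) - X %*% XtXi %*% t(X)
  ## eigen of S(K+I)S - I is numerically steadier than S K S directly
  M <- S %*% (K + diag(n)) %*% S
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  xi <- eig$values[seq_len(n - q)] - 1
  xi <- pmax(xi, 0)
  eta <- as.numeric(crossprod(eig$vectors[, seq_len(n - q), drop = FALSE], y))
  lamK <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(n = n, q = q, xi = xi, eta2 = eta^2, lamK = pmax(lamK, 0))
}

## restricted log-likelihood profiled over delta = VE/VG
remlLL <- function(delta, sp) {
  nq <- sp$n - sp$q
  s <- sum(sp$eta2 / (sp$xi + delta))
  0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(s)) - sum(log(sp$xi + delta)))
}

## full (ML) log-likelihood profiled over delta
mlLL <- function(delta, sp) {
  n <- sp$n
  s <- sum(sp$eta2 / (sp$xi + delta))
  0.5 * (n * (log(n / (2 * pi)) - 1 - log(s)) - sum(log(sp$lamK + delta)))
}

#' Profile of the restricted log-likelihood over delta
#'
#' Diagnostic helper exposing the profiled (restricted) log-likelihood of
#' the polygenic null model at given variance ratios `delta = V_E / V_G`.
#'
#' @param trait a [TraitVector-class] or named numeric vector.
#' @param kin a [KinshipMatrix-class].
#' @param deltas vector of delta values to evaluate.
#' @param covariates optional accession-named covariate matrix.
#' @param method `"REML"` (default) or `"ML"`.
#' @return numeric vector of log-likelihood values, one per delta.
#' @export
nullProfile <- function(trait, kin, deltas, covariates = NULL,
                        method = c("REML", "ML")) {
  method <- match.arg(method)
  al <- alignTraitKinship(trait, kin, covariates)
  sp <- nullSpectral(al$y, al$K, al$X)
  ll <- if (method == "REML") remlLL else mlLL
  vapply(deltas, ll, numeric(1), sp = sp)
}

## align a trait with kinship (and optional covariates) by accession label
alignTraitKinship <- function(trait, kin, covariates = NULL, minShared = 10) {
  y <- if (is(trait, "TraitVector")) traitValues(trait) else trait
  if (is.null(names(y))) stop("trait must be named by accession")
  common <- intersect(names(y), accessions(kin))
  if (!is.null(covariates)) common <- intersect(common, rownames(covariates))
  if (length(common) < minShared)
    stop("fewer than ", minShared, " accessions shared between trait and kinship")
  y <- y[common]
  if (var(y) <= 0) stop("trait has zero variance")
  X <- cbind(`(Intercept)` = rep(1, length(common)))
  if (!is.null(covariates))
    X <- cbind(X, as.matrix(covariates)[common, , drop = FALSE])
  list(y = y, K = kinship(kin)[common, common], X = X, accessions = common)
}

#' Fit the polygenic null model by REML (spectral 1-D profile)
#'
#' Model `y = Xb + u + e` with `u ~ N(0, V_G K)` and `e ~ N(0, V_E I)`.
#' The (restricted) likelihood is profiled over `delta = V_E / V_G` on the
#' eigenbasis of the projected kinship: one eigendecomposition, then a
#' log-spaced grid over `delta` in `[1e-5, 1e5]` followed by bounded local
#' refinement around every grid-local maximum; the global optimum over the
#' grid cells is returned.  The pseudo-heritability is
#' `H2 = V_G / (V_G + V_E)`.
#'
#' @param trait a [TraitVector-class] or named numeric vector (>= 10
#'   accessions shared with the kinship; non-zero variance).
#' @param kin a [KinshipMatrix-class].
#' @param covariates optional accession-named covariate matrix (an intercept
#'   is always included).
#' @param method `"REML"` (default, the convention of EMMA-style
#'   association software) or `"ML"`.
#' @param nGrid number of grid points for the delta search.
#' @param bounds search bounds for delta.
#' @return a [VarianceComponents-class].
#' @export
fitNullModel <- function(trait, kin, covariates = NULL,
                         method = c("REML", "ML"), nGrid = 100,
                         bounds = c(1e-5, 1e5)) {
  method <- match.arg(method)
  al <- alignTraitKinship(trait, kin, covariates)
  sp <- nullSpectral(al$y, al$K, al$X)
  ll <- if (method == "REML") remlLL else mlLL
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = nGrid))
  vals <- vapply(grid, ll, numeric(1), sp = sp)
  ## refine every local maximum (the profile can be multimodal)
  locmax <- which(vals >= c(-Inf, vals[-nGrid]) & vals >= c(vals[-1], -Inf))
  best <- list(delta = grid[which.max(vals)], ll = max(vals))
  for (i in locmax) {
    lo <- grid[max(1, i - 1)]; hi <- grid[min(nGrid, i + 1)]
    opt <- optimize(function(d) ll(d, sp), interval = c(lo, hi),
                    maximum = TRUE, tol = 1e-10)
    if (opt$objective > best$ll)
      best <- list(delta = opt$maximum, ll = opt$objective)
  }
  delta <- best$delta
  denom <- if (method == "REML") sp$n - sp$q else sp$n
  VG <- sum(sp$eta2 / (sp$xi + delta)) / denom
  VE <- delta * VG
  varianceComponents(VG, VE, logLik = best$ll, n = sp$n, method = method)
}

#' Mixed-model association scan with fixed variance components (EMMAX)
#'
#' The covariance `V = V_G K + V_E I` is held fixed from the null fit; each
#' marker is tested by generalized least squares on the rotated system (the
#' eigenbasis of K is computed once and reused for all markers), with an F
#' statistic on `(1, n - q)` degrees of freedom where `q` counts all fixed
#' effects including the marker.  When `V_G == 0` the weights are exactly
#' constant and the scan reduces bit-for-bit to ordinary least squares.
#'
#' Markers are aligned to the trait's accessions first; MAF is computed
#' after alignment.  Markers below the MAF threshold, monomorphic markers,
#' and markers with more than `maxMissing` missingness are flagged untested
#' (`NA` statistics); remaining missing dosages are mean-imputed.
#'
#' @param trait a [TraitVector-class] or named numeric vector.
#' @param geno a [GenotypeMatrix-class].
#' @param kin a [KinshipMatrix-class].
#' @param vc a [VarianceComponents-class] fitted on the same trait/kinship.
#' @param mafThreshold minimum MAF (inclusive) for a marker to be tested.
#' @param covariates optional accession-named covariate matrix.
#' @param maxMissing maximum per-marker missingness fraction.
#' @return an [AssociationResult-class].
#' @export
gwasScan <- function(trait, geno, kin, vc, mafThreshold = 0.05,
                     covariates = NULL, maxMissing = 0.2) {
  stopifnot(is(vc, "VarianceComponents"))
  y0 <- if (is(trait, "TraitVector")) traitValues(trait) else trait
  common <- intersect(intersect(names(y0), accessions(geno)),
                      accessions(kin))
  if (!is.null(covariates)) common <- intersect(common, rownames(covariates))
  if (length(common) < 10)
    stop("fewer than 10 accessions shared between trait, genotypes and kinship")
  y <- y0[common]
  G <- dosage(geno)[common, , drop = FALSE]
  K <- kinship(kin)[common, common]
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates))
    X <- cbind(X, as.matrix(covariates)[common, , drop = FALSE])
  q <- ncol(X) + 1L                     # fixed effects incl. the marker

  missFrac <- colMeans(is.na(G))
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na <- which(is.na(G), arr.ind = TRUE)
    G[na] <- mu[na[, 2]]
  }
  f <- colMeans(G)
  maf <- pmin(f, 1 - f)
  gvar <- colSums((G - rep(f, each = n))^2)
  tested <- maf >= mafThreshold & gvar > 1e-10 & missFrac <= maxMissing
  nDroppedMiss <- sum(missFrac > maxMissing)
  if (nDroppedMiss)
    message(nDroppedMiss, " marker(s) dropped for missingness > ", maxMissing)

  mk <- markerRanges(geno)
  tab <- data.frame(marker = names(mk),
                    chrom = as.character(seqnames(mk)),
                    pos = start(mk),
                    ref = mk$ref, alt = mk$alt,
                    maf = maf, missing = missFrac,
                    beta = NA_real_, se = NA_real_, stat = NA_real_,
                    pvalue = NA_real_, tested = tested,
                    stringsAsFactors = FALSE)

  ti <- which(tested)
  if (length(ti)) {
    if (vc@VG == 0) {                   # exact OLS degenerate path
      yt <- y; Xt <- X; Gt <- G[, ti, drop = FALSE]
    } else {
      eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
      w <- 1 / (vc@VG * pmax(eig$values, 0) + vc@VE)
      sw <- sqrt(w)
      U <- eig$vectors
      yt <- sw * as.numeric(crossprod(U, y))
      Xt <- sw * crossprod(U, X)
      Gt <- sw * crossprod(U, G[, ti, drop = FALSE])
    }
    qrX <- qr(Xt)
    ry <- qr.resid(qrX, yt)
    RG <- qr.resid(qrX, Gt)
    sxx <- colSums(RG^2)
    sxy <- as.numeric(crossprod(RG, ry))
    syy <- sum(ry^2)
    usable <- sxx > 1e-10               # not collinear with covariates
    beta <- sxy / sxx
    ess <- sxy^2 / sxx
    df2 <- n - q
    rss <- pmax(syy - ess, 0)
    Fstat <- ess / (rss / df2)
    pval <- pf(Fstat, 1, df2, lower.tail = FALSE)
    pval <- pmax(pval, .Machine$double.xmin)
    se <- sqrt(rss / df2 / sxx)
    keep <- ti[usable]
    tab$beta[keep] <- beta[usable]
    tab$se[keep] <- se[usable]
    tab$stat[keep] <- Fstat[usable]
    tab$pvalue[keep] <- pval[usable]
    tab$tested[ti[!usable]] <- FALSE
  }
  new("AssociationResult", table = tab,
      trait = if (is(trait, "TraitVector")) traitName(trait) else "trait",
      nTested = sum(tab$tested), nAccessions = n)
}

#' Bonferroni family-wise significance threshold
#'
#' `threshold = alpha / (number of tested markers)`; the significant set is
#' every tested marker with `p <= threshold`.
#'
#' @param result an [AssociationResult-class].
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `threshold`, `nTested`, and `significant` (data.frame
#'   of significant markers with their statistics).
#' @export
bonferroniThreshold <- function(result, alpha = 0.05) {
  stopifnot(is(result, "AssociationResult"))
  m <- result@nTested
  if (m == 0) stop("no tested markers: cannot form a Bonferroni threshold")
  thr <- alpha / m
  tab <- assocTable(result)
  sig <- tab[tab$tested & !is.na(tab$pvalue) & tab$pvalue <= thr, ,
             drop = FALSE]
  list(threshold = thr, nTested = m, alpha = alpha, significant = sig)
}

#' Genomic inflation factor lambda_GC
#'
#' Median of the chi-square(1)-transformed p-values divided by the
#' chi-square(1) median (0.45494...).  Values near 1 indicate well-calibrated
#' tests; inflation above 1 indicates residual confounding such as
#' uncorrected population structure.
#'
#' @param result an [AssociationResult-class] or a numeric p-value vector.
#' @return numeric scalar lambda.
#' @export
genomicInflation <- function(result) {
  p <- if (is(result, "AssociationResult")) {
    tab <- assocTable(result)
    tab$pvalue[tab$tested]
  } else result
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}
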