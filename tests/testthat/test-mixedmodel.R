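test_that("MAF arithmetic matches direct counts at the 5% threshold", {
  n <- 227
  d11 <- matrix(0, n, 2); d11[1:11, 1] <- 1; d11[1:12, 2] <- 1
  rownames(d11) <- sprintf("a%03d", 1:n)
  g <- makeGeno(d11)
  maf <- computeMAF(g)
  expect_equal(unname(maf), c(11 / 227, 12 / 227))
  kept <- filterMAF(g, 0.05)
  expect_equal(ncol(dosage(kept)), 1L)       # 11/227 = 4.85% removed
  ## monomorphic marker: MAF 0, removed at any positive threshold
  gm <- makeGeno(cbind(rep(0, 20), rbinom(20, 1, 0.5)))
  expect_equal(unname(computeMAF(gm)[1]), 0)
  expect_equal(ncol(dosage(filterMAF(gm, 1e-9))), 1L)
  ## idempotence
  g2 <- filterMAF(filterMAF(g, 0.05), 0.05)
  expect_identical(dosage(g2), dosage(kept))
})

test_that("GRM kinship equals the brute-force double-sum definition", {
  g <- randomGeno(20, 100, seed = 14)
  K <- kinship(suppressWarnings(computeKinship(g, "grm")))
  D <- dosage(g)
  mu <- colMeans(D); s <- apply(D, 2, sd)
  use <- s > 1e-12
  Kb <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    Kb[i, j] <- mean(((D[i, use] - mu[use]) / s[use]) *
                     ((D[j, use] - mu[use]) / s[use]))
  ## undo any PSD stabilization shift before comparing off-diagonals
  shift <- K[1, 1] - Kb[1, 1]
  expect_lt(abs(shift), 1e-6 + 1e-8)
  expect_equal(unname(K - diag(shift, 20)), Kb, tolerance = 1e-12)
})

test_that("IBS kinship is 1 for identical accessions and K is stabilized PSD", {
  set.seed(31)
  D <- matrix(rbinom(10 * 50, 1, 0.4), 10, 50)
  D[2, ] <- D[1, ]
  rownames(D) <- sprintf("a%02d", 1:10)
  K <- kinship(computeKinship(makeGeno(D), "ibs"))
  expect_equal(K[1, 2], 1)
  expect_equal(K, t(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  Kg <- kinship(suppressWarnings(computeKinship(makeGeno(D), "grm")))
  expect_gt(min(eigen(Kg, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("the returned delta is the global optimum of the REML profile", {
  g <- randomGeno(60, 200, seed = 22)
  k <- suppressWarnings(computeKinship(g, "grm"))
  set.seed(1)
  y <- setNames(rnorm(60), accessions(g))
  vc <- fitNullModel(y, k)
  grid <- exp(seq(log(1e-5), log(1e5), length.out = 100))
  prof <- nullProfile(y, k, grid)
  expect_true(all(vc@logLik >= prof - 1e-6))
  ## H2 bookkeeping is exact
  expect_identical(heritability(vc), varG(vc) / (varG(vc) + varE(vc)))
})

test_that("a trait independent of the kinship yields near-zero heritability", {
  g <- randomGeno(150, 300, seed = 33)
  k <- suppressWarnings(computeKinship(g, "grm"))
  h2 <- replicate(10, {
    y <- setNames(rnorm(150), accessions(g))
    heritability(fitNullModel(y, k))
  })
  expect_lt(median(h2), 0.1)
})

test_that("EMMAX p-values match the dense GLS oracle", {
  g <- randomGeno(30, 80, seed = 44)
  k <- suppressWarnings(computeKinship(g, "grm"))
  K <- kinship(k)
  set.seed(2)
  y <- setNames(as.numeric(0.7 * (chol(K + diag(0.1, 30)) %*% rnorm(30))) +
                  rnorm(30), accessions(g))
  vc <- fitNullModel(y, k)
  scan <- gwasScan(y, g, k, vc, mafThreshold = 0.05)
  tab <- assocTable(scan)
  oracle <- denseGLSOracle(y, dosage(g)[, tab$tested, drop = FALSE],
                           K, varG(vc), varE(vc))
  expect_lt(max(abs(log10(tab$pvalue[tab$tested]) - log10(oracle$pvalue))),
            1e-6)
  expect_equal(tab$beta[tab$tested], oracle$beta, tolerance = 1e-8)
})

test_that("with V_G = 0 the mixed model degenerates to simple regression", {
  g <- randomGeno(40, 50, seed = 55)
  k <- suppressWarnings(computeKinship(g, "grm"))
  set.seed(3)
  y <- setNames(rnorm(40), accessions(g))
  scan <- gwasScan(y, g, k, varianceComponents(0, 1), mafThreshold = 0)
  tab <- assocTable(scan)
  for (j in which(tab$tested)) {
    fit <- summary(lm(y ~ dosage(g)[, j]))$coefficients
    expect_equal(tab$pvalue[j], fit[2, "Pr(>|t|)"], tolerance = 1e-8)
  }
})

test_that("degenerate markers are flagged untested without numerical errors", {
  D <- cbind(rep(0, 20), rbinom(20, 1, 0.5), rep(1, 20))
  rownames(D) <- sprintf("a%02d", 1:20)
  g <- makeGeno(D)
  k <- suppressWarnings(computeKinship(g, "ibs"))
  set.seed(4)
  y <- setNames(rnorm(20), accessions(g))
  scan <- gwasScan(y, g, k, varianceComponents(0.1, 0.9), mafThreshold = 0)
  tab <- assocTable(scan)
  expect_false(tab$tested[1])
  expect_false(tab$tested[3])
  expect_true(all(is.na(tab$pvalue[!tab$tested])))
})

test_that("association p-values are invariant under consistent label permutation", {
  g <- randomGeno(35, 60, seed = 66)
  k <- suppressWarnings(computeKinship(g, "grm"))
  set.seed(5)
  y <- setNames(rnorm(35), accessions(g))
  vc <- fitNullModel(y, k)
  p1 <- assocTable(gwasScan(y, g, k, vc))$pvalue
  perm <- sample(35)
  D2 <- dosage(g)[perm, ]; rownames(D2) <- sprintf("b%03d", 1:35)
  g2 <- makeGeno(D2)
  K2 <- kinship(k)[perm, perm]
  dimnames(K2) <- list(rownames(D2), rownames(D2))
  k2 <- new("KinshipMatrix", values = K2, method = "grm")
  y2 <- setNames(unname(y)[perm], rownames(D2))
  p2 <- assocTable(gwasScan(y2, g2, k2, vc))$pvalue
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("Bonferroni thresholding divides by the tested marker count", {
  tab <- data.frame(marker = c("m1", "m2", "m3"), chrom = "chr1",
                    pos = c(100, 200, 300), ref = "A", alt = "T",
                    maf = 0.2, missing = 0,
                    beta = 1, se = 1, stat = 1,
                    pvalue = c(1e-9, 0.5, NA),
                    tested = c(TRUE, TRUE, FALSE))
  res <- new("AssociationResult", table = tab, trait = "t",
             nTested = 2L, nAccessions = 100L)
  bf <- bonferroniThreshold(res, 0.05)
  expect_equal(bf$threshold, 0.025)
  expect_equal(bf$significant$marker, "m1")
  ## at the scale of a real panel: 5% over 1,739,142 tested markers
  res2 <- res
  res2@nTested <- 1739142L
  expect_equal(bonferroniThreshold(res2, 0.05)$threshold, 0.05 / 1739142)
  expect_lt(abs(bonferroniThreshold(res2, 0.05)$threshold - 2.875e-8), 1e-10)
  ## all p = 1: empty significant set
  tab$pvalue <- c(1, 1, NA)
  res3 <- new("AssociationResult", table = tab, trait = "t",
              nTested = 2L, nAccessions = 100L)
  expect_equal(nrow(bonferroniThreshold(res3, 0.05)$significant), 0L)
  ## no tested markers: error
  tab$tested <- FALSE; tab$pvalue <- NA_real_
  res4 <- new("AssociationResult", table = tab, trait = "t",
              nTested = 0L, nAccessions = 100L)
  expect_error(bonferroniThreshold(res4), "no tested markers")
})

test_that("genomic inflation has its definitional fixed point and null level", {
  expect_equal(genomicInflation(rep(0.5, 100)), 1, tolerance = 1e-12)
  set.seed(77)
  lam <- genomicInflation(runif(1e5))
  expect_gt(lam, 0.95); expect_lt(lam, 1.05)
})
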