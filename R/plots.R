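#' Manhattan plot of an association scan
#'
#' Markers are plotted at a cumulative genome coordinate, colours alternate
#' between black and grey per chromosome, and the Bonferroni threshold is
#' drawn as a dashed line.
#'
#' @param result an [AssociationResult-class].
#' @param alpha family-wise level for the threshold line (NULL to omit).
#' @param ... passed to [plot()].
#' @return invisibly, the data.frame of plotted points.
#' @export
plotManhattan <- function(result, alpha = 0.05, ...) {
  tab <- assocTable(result)
  tab <- tab[tab$tested, , drop = FALSE]
  chroms <- unique(tab$chrom)
  offset <- 0
  tab$x <- NA_real_
  for (cc in chroms) {
    i <- tab$chrom == cc
    tab$x[i] <- tab$pos[i] + offset
    offset <- max(tab$x[i]) + 1e5
  }
  cols <- c("black", "grey50")[(match(tab$chrom, chroms) - 1) %% 2 + 1]
  plot(tab$x, -log10(tab$pvalue), pch = 20, cex = 0.5, col = cols,
       xlab = "genome position", ylab = expression(-log[10](p)),
       main = traitName(result), xaxt = "n", ...)
  if (!is.null(alpha))
    abline(h = -log10(alpha / result@nTested), lty = 2)
  invisible(tab)
}

#' Quantile-quantile plot of association p-values
#'
#' Observed versus expected `-log10(p)` under the uniform null, with the
#' identity line; the genomic inflation factor is printed in the title.
#'
#' @param result an [AssociationResult-class] or numeric p-value vector.
#' @param ... passed to [plot()].
#' @return invisibly, the lambda value.
#' @export
plotQQ <- function(result, ...) {
  p <- if (is(result, "AssociationResult")) {
    tab <- assocTable(result)
    tab$pvalue[tab$tested]
  } else result
  p <- sort(p[!is.na(p)])
  expd <- -log10(stats::ppoints(length(p)))
  lam <- genomicInflation(p)
  plot(expd, -log10(p), pch = 20, cex = 0.5,
       xlab = expression(expected ~ -log[10](p)),
       ylab = expression(observed ~ -log[10](p)),
       main = sprintf("lambda[GC] = %.3f", lam), ...)
  abline(0, 1, lty = 2)
  invisible(lam)
}
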