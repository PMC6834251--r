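## markers argument: data.frame with marker, chrom, pos, pvalue (e.g. the
## `significant` element of bonferroniThreshold(), or any assoc subset)
markerWindows <- function(markers, window) {
  GRanges(markers$chrom,
          IRanges(pmax(markers$pos - window, 1), markers$pos + window))
}

#' Merge significant markers into distinct genomic regions
#'
#' Each marker is expanded to a closed interval `pos +/- window`; intervals
#' that overlap (share at least one base) are merged transitively into one
#' region — equivalently, markers at most `2 * window` apart end up in the
#' same region.  Region span is the union of member windows, clipped at 1.
#'
#' @param markers data.frame with columns `marker`, `chrom`, `pos` and
#'   optionally `pvalue`.
#' @param window half-width in bp (default 10000, i.e. a 10-kb window).
#' @return `GRanges` of regions with mcols `n_markers`, `min_p` and a
#'   comma-separated `members` list; regions on one chromosome are pairwise
#'   disjoint.
#' @export
mergeRegions <- function(markers, window = 10000) {
  if (!nrow(markers))
    return(GRanges(n_markers = integer(0), min_p = numeric(0),
                   members = character(0)))
  win <- markerWindows(markers, window)
  ## min.gapwidth = 0: merge overlapping (closed-interval touching) windows
  ## only, never merely adjacent ones
  reg <- reduce(win, min.gapwidth = 0)
  ov <- findOverlaps(win, reg)
  byreg <- split(queryHits(ov), subjectHits(ov))
  pv <- if ("pvalue" %in% colnames(markers)) markers$pvalue
        else rep(NA_real_, nrow(markers))
  mcols(reg)$n_markers <- unname(vapply(byreg, length, integer(1)))
  mcols(reg)$min_p <- unname(vapply(byreg, function(i)
    if (all(is.na(pv[i]))) NA_real_ else min(pv[i], na.rm = TRUE),
    numeric(1)))
  mcols(reg)$members <- unname(vapply(byreg, function(i)
    paste(markers$marker[i], collapse = ","), character(1)))
  reg
}

#' Map significant markers to candidate genes via fixed-width windows
#'
#' A gene is a candidate for a marker iff the gene body (1-based closed
#' interval) intersects the closed interval `[pos - window, pos + window]`.
#' The table is deduplicated per gene, keeping the minimum supporting
#' p-value and the full supporting-marker list.
#'
#' @param markers data.frame with columns `marker`, `chrom`, `pos`,
#'   optionally `pvalue`.
#' @param genes gene annotation `GRanges` with a `gene_id` column.
#' @param window half-width in bp (default 10000).
#' @param trait trait label recorded in the table.
#' @return data.frame `gene`, `trait`, `chrom`, `min_p`, `n_snps`,
#'   `markers` (comma-separated).
#' @export
mapCandidates <- function(markers, genes, window = 10000, trait = "trait") {
  stopifnot(is(genes, "GRanges"), "gene_id" %in% colnames(mcols(genes)))
  if (!nrow(markers))
    return(data.frame(gene = character(0), trait = character(0),
                      chrom = character(0), min_p = numeric(0),
                      n_snps = integer(0), markers = character(0),
                      stringsAsFactors = FALSE))
  unmatched <- setdiff(unique(as.character(markers$chrom)),
                       as.character(seqlevels(genes)))
  if (length(unmatched))
    stop("marker chromosome(s) absent from the annotation: ",
         paste(unmatched, collapse = ", "))
  win <- markerWindows(markers, window)
  ov <- findOverlaps(win, genes)
  if (!length(ov))
    return(data.frame(gene = character(0), trait = character(0),
                      chrom = character(0), min_p = numeric(0),
                      n_snps = integer(0), markers = character(0),
                      stringsAsFactors = FALSE))
  pv <- if ("pvalue" %in% colnames(markers)) markers$pvalue
        else rep(NA_real_, nrow(markers))
  gid <- genes$gene_id[subjectHits(ov)]
  bygene <- split(queryHits(ov), gid)
  out <- data.frame(
    gene = names(bygene),
    trait = trait,
    chrom = as.character(seqnames(genes))[match(names(bygene), genes$gene_id)],
    min_p = vapply(bygene, function(i)
      if (all(is.na(pv[i]))) NA_real_ else min(pv[i], na.rm = TRUE),
      numeric(1)),
    n_snps = vapply(bygene, function(i) length(unique(markers$marker[i])),
                    integer(1)),
    markers = vapply(bygene, function(i)
      paste(sort(unique(markers$marker[i])), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Venn counts of candidate genes (and markers) across traits
#'
#' Each gene is counted once, in the cell of exactly the set of traits it
#' appears in; supporting markers are classified the same way.
#'
#' @param tables named list of [mapCandidates()] tables (names are trait
#'   labels; unnamed lists fall back to the tables' `trait` columns).
#' @return data.frame `combination` (trait labels joined by `&`),
#'   `n_traits`, `n_genes`, `n_markers`.
#' @export
vennCounts <- function(tables) {
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t)
      if (nrow(t)) t$trait[1] else "?", character(1))
  classify <- function(itemsPerTrait) {
    all <- unique(unlist(itemsPerTrait))
    if (!length(all)) return(character(0))
    member <- vapply(itemsPerTrait, function(s) all %in% s,
                     logical(length(all)))
    member <- matrix(member, nrow = length(all),
                     dimnames = list(all, names(itemsPerTrait)))
    apply(member, 1, function(r)
      paste(sort(names(itemsPerTrait)[r]), collapse = "&"))
  }
  geneSets <- lapply(tables, function(t) unique(t$gene))
  markerSets <- lapply(tables, function(t)
    unique(unlist(strsplit(t$markers, ",", fixed = TRUE))))
  gc <- classify(geneSets)
  mc <- classify(markerSets)
  combos <- sort(unique(c(gc, mc)))
  data.frame(combination = combos,
             n_traits = lengths(strsplit(combos, "&", fixed = TRUE)),
             n_genes = as.integer(table(factor(gc, levels = combos))),
             n_markers = as.integer(table(factor(mc, levels = combos))),
             stringsAsFactors = FALSE)
}
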