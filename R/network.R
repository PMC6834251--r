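#' Extract connected candidate-gene modules from a co-function network
#'
#' Modules are the connected components of the subgraph induced by the
#' candidate genes (candidate-candidate edges only, restricted to edges with
#' `score >= minScore`); components smaller than `minSize` are discarded.
#' Modules are sorted by size descending, ties broken by the
#' lexicographically smallest member.
#'
#' @param candidates character vector of candidate gene identifiers.
#' @param net a [CoFunctionNetwork-class].
#' @param minSize minimum module size (default 3; a single edge is not
#'   called a module).
#' @param minScore minimum edge score.
#' @return list of modules; each is a list with `genes` (sorted), `edges`
#'   (induced edge data.frame) and `size`.
#' @export
extractModules <- function(candidates, net, minSize = 3, minScore = 0) {
  stopifnot(is(net, "CoFunctionNetwork"))
  candidates <- unique(as.character(candidates))
  nodes <- sort(intersect(candidates, networkGenes(net)))
  if (!length(nodes)) return(list())
  ed <- networkEdges(net)
  ed <- ed[ed$gene_a %in% nodes & ed$gene_b %in% nodes &
           ed$score >= minScore, , drop = FALSE]
  g <- graph_from_data_frame(ed[, c("gene_a", "gene_b")],
                             directed = FALSE, vertices = nodes)
  comp <- components(g)
  mods <- split(names(comp$membership), comp$membership)
  mods <- Filter(function(m) length(m) >= minSize, mods)
  mods <- lapply(mods, function(m) {
    m <- sort(m)
    list(genes = m,
         edges = ed[ed$gene_a %in% m & ed$gene_b %in% m, , drop = FALSE],
         size = length(m))
  })
  ord <- order(-vapply(mods, `[[`, integer(1), "size"),
               vapply(mods, function(m) m$genes[1], character(1)))
  unname(mods[ord])
}

#' Annotation-term enrichment of a gene module (hypergeometric upper tail)
#'
#' For every term annotating at least one background gene:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, where `N` is the
#' background size, `K` the term's background genes, `n` the module size and
#' `k` the module genes carrying the term; computed by direct log-space
#' summation.  Raw p-values are reported (Benjamini-Hochberg q-values are
#' attached as a convenience column).
#'
#' @param module a module from [extractModules()] or a character vector of
#'   genes.
#' @param annotation data.frame with columns `gene`, `term`.
#' @param background character vector of background genes (default: all
#'   annotated genes); the module must be a subset of it.
#' @return data.frame `term`, `k`, `K`, `n`, `N`, `pvalue`, `qvalue`,
#'   ordered by increasing p.
#' @export
enrichTerms <- function(module, annotation, background = NULL) {
  genes <- if (is.list(module)) module$genes else as.character(module)
  stopifnot(all(c("gene", "term") %in% colnames(annotation)))
  if (is.null(background)) background <- unique(annotation$gene)
  background <- unique(as.character(background))
  if (!all(genes %in% background))
    stop("module must be a subset of the background gene set")
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(genes)
  byterm <- split(unique(ann[, c("gene", "term")])$gene,
                  unique(ann[, c("gene", "term")])$term)
  if (!length(byterm))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), pvalue = numeric(0),
                      qvalue = numeric(0), stringsAsFactors = FALSE))
  K <- lengths(byterm)
  k <- vapply(byterm, function(gs) length(intersect(gs, genes)), integer(1))
  p <- mapply(hyperUpperTail, k = k, K = K,
              MoreArgs = list(M = N, n = n))
  out <- data.frame(term = names(byterm), k = k, K = as.integer(K), n = n,
                    N = N, pvalue = p, qvalue = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
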