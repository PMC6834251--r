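## ---- genotypes: VCF ------------------------------------------------------

#' Write genotypes as a minimal plain-text VCF
#'
#' Inbred haploid dosages are written as homozygous diploid calls (`0/0` for
#' dosage 0, `1/1` for dosage 1, `./.` for missing), VCFv4.2, 1-based
#' positions.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypesVCF <- function(geno, path) {
  mk <- markerRanges(geno)
  D <- dosage(geno)
  gt <- matrix("./.", nrow = ncol(D), ncol = nrow(D))
  gt[t(D) == 0] <- "0/0"
  gt[t(D) == 1] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=nutriGWAS",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", accessions(geno)), collapse = "\t")),
             con)
  body <- cbind(as.character(seqnames(mk)), start(mk), names(mk),
                mk$ref, mk$alt, ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Homozygous diploid calls map to haploid dosages (`0/0` or `0|0` to 0,
#' `1/1` or `1|1` to 1; `./.` to missing).  Heterozygous calls are rejected
#' with an error naming the first offending record (`het = "error"`,
#' default, appropriate for fully inbred lines) or set missing
#' (`het = "missing"`).
#'
#' @param path VCF file (plain or bgzipped).
#' @param het `"error"` or `"missing"`.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypesVCF <- function(path, het = c("error", "missing")) {
  het <- match.arg(het)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  g <- t(gt)
  dos[g %in% c("0/0", "0|0", "0")] <- 0
  dos[g %in% c("1/1", "1|1", "1")] <- 1
  hetmask <- matrix(g %in% c("0/1", "1/0", "0|1", "1|0"), nrow = nrow(dos))
  if (any(hetmask)) {
    if (het == "error") {
      bad <- which(hetmask, arr.ind = TRUE)[1, ]
      stop("heterozygous call at marker ", colnames(dos)[bad[2]],
           ", accession ", rownames(dos)[bad[1]],
           " (inbred lines expected; use het = 'missing' to mask)")
    }
    dos[hetmask] <- NA_real_
  }
  mk <- GRanges(fix[, "CHROM"], IRanges(as.integer(fix[, "POS"]),
                                        as.integer(fix[, "POS"])),
                ref = fix[, "REF"], alt = fix[, "ALT"])
  names(mk) <- fix[, "ID"]
  genotypeMatrix(dos, mk)
}

## ---- genotypes: TSV matrix ----------------------------------------------

#' Write genotypes as a TSV matrix
#'
#' Columns `marker`, `chrom`, `pos`, `ref`, `alt`, then one column per
#' accession with dosages 0/1 (`NA` for missing).
#'
#' @param geno a [GenotypeMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypesTSV <- function(geno, path) {
  mk <- markerRanges(geno)
  df <- data.frame(marker = names(mk), chrom = as.character(seqnames(mk)),
                   pos = start(mk), ref = mk$ref, alt = mk$alt,
                   t(dosage(geno)), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a TSV matrix (see [writeGenotypesTSV()] for schema)
#' @param path input file.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypesTSV <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- c("marker", "chrom", "pos", "ref", "alt")
  if (!all(meta %in% colnames(df)))
    stop("genotype TSV must start with columns ", paste(meta, collapse = ", "))
  acc <- setdiff(colnames(df), meta)
  dos <- t(as.matrix(df[, acc, drop = FALSE]))
  mk <- GRanges(df$chrom, IRanges(df$pos, df$pos), ref = df$ref,
                alt = df$alt)
  names(mk) <- df$marker
  genotypeMatrix(dos, mk)
}

## ---- phenotypes and traits ----------------------------------------------

#' Write a replicate-level phenotype table as CSV
#' @param pheno data.frame `accession,condition,replicate,day,length`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePhenotypeCSV <- function(pheno, path) {
  out <- pheno
  out$length <- fmtNum(out$length)
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a replicate-level phenotype CSV
#'
#' Expects header `accession,condition,replicate,day,length`; duplicate
#' (accession, condition, replicate, day) records are a structured error.
#'
#' @param path input file.
#' @return phenotype data.frame.
#' @export
readPhenotypeCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "condition", "replicate", "day", "length")
  if (!all(need %in% colnames(df)))
    stop("phenotype CSV must have header ", paste(need, collapse = ","))
  key <- do.call(paste, df[, need[1:4]])
  if (anyDuplicated(key))
    stop("duplicate phenotype record(s), first at line ",
         which(duplicated(key))[1] + 1)
  df
}

#' Write a trait vector as a two-column TSV (`accession`, `value`)
#' @param trait a [TraitVector-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTraitTSV <- function(trait, path) {
  v <- traitValues(trait)
  df <- data.frame(accession = names(v), value = fmtNum(unname(v)),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait vector from TSV (`accession`, `value`)
#' @param path input file.
#' @param name trait label (default: the file base name).
#' @return a [TraitVector-class].
#' @export
readTraitTSV <- function(path, name = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  traitVector(setNames(df$value, df$accession),
              name = name %||% sub("\\.tsv$", "", basename(path)),
              provenance = list(file = path))
}

## ---- annotation, network, GO --------------------------------------------

#' Write a gene annotation as GFF3 (type `gene`, 1-based inclusive)
#' @param genes annotation `GRanges` with a `gene_id` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotationGFF3 <- function(genes, path) {
  gr <- genes
  mcols(gr) <- DataFrame(source = "nutriGWAS", type = "gene",
                         ID = genes$gene_id, Name = genes$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene annotation from GFF3 (keeps records of type `gene`)
#' @param path input file.
#' @return `GRanges` with mcols `gene_id`, `type`.
#' @export
readAnnotationGFF3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  gene_id <- if ("ID" %in% colnames(mcols(gr))) gr$ID else gr$Name
  mcols(gr) <- DataFrame(gene_id = as.character(gene_id), type = "gene")
  names(gr) <- gr$gene_id
  gr
}

#' Write a co-function network as TSV (`gene_a`, `gene_b`, `score`)
#' @param net a [CoFunctionNetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNetworkTSV <- function(net, path) {
  ed <- networkEdges(net)
  ed$score <- fmtNum(ed$score)
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a co-function network from TSV (`gene_a`, `gene_b`, `score`)
#' @param path input file.
#' @param genes optional full node set (isolated genes are lost by the edge
#'   list otherwise).
#' @return a [CoFunctionNetwork-class].
#' @export
readNetworkTSV <- function(path, genes = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  coFunctionNetwork(df, genes = genes)
}

#' Write a gene-to-term annotation table as TSV (`gene`, `term`)
#' @param go data.frame `gene`, `term`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGOTSV <- function(go, path) {
  write.table(go, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation table from TSV (`gene`, `term`)
#' @param path input file.
#' @return data.frame `gene`, `term`.
#' @export
readGOTSV <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "term") %in% colnames(df)))
  df
}

## ---- association results and regions ------------------------------------

#' Write an association result as TSV
#' @param result an [AssociationResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAssociationTSV <- function(result, path) {
  tab <- assocTable(result)
  for (col in c("maf", "missing", "beta", "se", "stat", "pvalue"))
    tab[[col]] <- fmtNum(tab[[col]])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association result from TSV
#' @param path input file.
#' @param trait trait label (default: file base name).
#' @return an [AssociationResult-class].
#' @export
readAssociationTSV <- function(path, trait = NULL) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  tab$tested <- as.logical(tab$tested)
  new("AssociationResult", table = tab,
      trait = trait %||% sub("\\.tsv$", "", basename(path)),
      nTested = sum(tab$tested), nAccessions = NA_integer_)
}

#' Export regions as BED
#'
#' Internal coordinates are 1-based closed; on-disk BED is 0-based
#' half-open.  The conversion is delegated to `rtracklayer::export`.
#'
#' @param regions `GRanges` from [mergeRegions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRegionsBED <- function(regions, path) {
  gr <- granges(regions)
  names(gr) <- sprintf("region%03d", seq_along(gr))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
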