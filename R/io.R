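## Readers/writers for the standard formats the pipeline touches.
## Coordinates are 0-based half-open internally (BED convention); VCF
## positions are converted on read and back on write.

#' Construct a genotype table
#'
#' The central container for line-level SNP calls: biallelic sites with one
#' call per inbred line coded 0 (ref), 1 (alt), 0.5 (residual heterozygote)
#' or NA (missing). Missingness is a first-class state and is never imputed
#' at construction; heterozygotes are retained and resolved only by
#' [haploidize_and_impute()].
#'
#' @param sites data frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`.
#' @param calls numeric matrix, `nrow(sites)` x number of lines, values in
#'   \{0, 0.5, 1, NA\}; column names are line names.
#' @param line_pops named character vector mapping line name to population.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(sites, calls, line_pops) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(calls), nrow(calls) == nrow(sites))
  if (is.null(colnames(calls))) stop("calls must have line names as colnames")
  if (!all(colnames(calls) %in% names(line_pops)))
    stop("lines missing from population map: ",
         paste(setdiff(colnames(calls), names(line_pops)), collapse = ", "))
  line_pops <- line_pops[colnames(calls)]
  ok <- is.na(calls) | calls %in% c(0, 0.5, 1)
  if (!all(ok)) stop("calls must be 0, 0.5, 1 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within arm ", ch)
  }
  sites$chrom_class <- ifelse(sites$chrom %in% c("X", "chrX"), "X", "autosome")
  structure(list(sites = sites, calls = calls, line_pops = line_pops),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$sites), "sites x", ncol(x$calls), "lines;",
      length(unique(x$line_pops)), "population(s)\n")
  invisible(x)
}

#' Number of sites / lines in a genotype table
#' @param x a `genotype_table`.
#' @return integer.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_lines <- function(x) ncol(x$calls)

gt_codes <- c("0/0" = 0, "0|0" = 0, "1/1" = 1, "1|1" = 1,
              "0/1" = 0.5, "1/0" = 0.5, "0|1" = 0.5, "1|0" = 0.5,
              "0" = 0, "1" = 1)

#' Read biallelic SNPs from a VCF into a genotype table
#'
#' Restricts to biallelic SNP records; multi-allelic records are dropped
#' with a logged count. Positions are converted to the internal 0-based
#' convention.
#'
#' @param path VCF file (plain or gzipped).
#' @param pop_map named character vector (or two-column data frame
#'   `line`, `population`) assigning every VCF sample to one population;
#'   an unknown sample name is a hard error.
#' @return a [genotype_table].
#' @export
read_snp_vcf <- function(path, pop_map) {
  if (is.data.frame(pop_map)) {
    pop_map <- setNames(as.character(pop_map[[2]]), as.character(pop_map[[1]]))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixmat <- vcfR::getFIX(v)
  if (is.null(dim(fixmat))) fixmat <- t(fixmat)  # single-record VCF
  fix <- as.data.frame(fixmat, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samples <- colnames(v@gt)[-1]
    if (!is.null(samples) && length(samples) &&
        !all(samples %in% names(pop_map)))
      stop("unknown sample name(s) in population map: ",
           paste(setdiff(samples, names(pop_map)), collapse = ", "))
    lp <- if (length(samples)) pop_map[samples] else pop_map
    return(genotype_table(
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      matrix(numeric(0), 0, length(lp), dimnames = list(NULL, names(lp))),
      lp))
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    stop("malformed VCF record at data line ", which(is.na(pos))[1],
         ": non-numeric POS")
  }
  gt <- vcfR::extract.gt(v)
  samples <- colnames(gt)
  if (!all(samples %in% names(pop_map)))
    stop("unknown sample name(s) in population map: ",
         paste(setdiff(samples, names(pop_map)), collapse = ", "))
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | is.na(fix$ALT) |
    (nchar(fix$ALT) != 1)
  if (any(multi)) log_counter("read_snp_vcf", dropped_multiallelic = sum(multi))
  keep <- !multi
  calls <- matrix(unname(gt_codes[gsub("\\|", "/", gt[keep, , drop = FALSE])]),
                  nrow = sum(keep), ncol = length(samples),
                  dimnames = list(NULL, samples))
  genotype_table(data.frame(chrom = fix$CHROM[keep], pos = pos[keep] - 1L,
                            ref = fix$REF[keep], alt = fix$ALT[keep]),
                 calls, pop_map[samples])
}

#' Write a genotype table as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT-only genotype columns; the inverse of
#' [read_snp_vcf()] (positions converted back to 1-based).
#'
#' @param gt a [genotype_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=famsel",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(gt$calls)),
                     collapse = "\t")), con)
  if (nrow(gt$sites) > 0) {
    code <- function(x) {
      out <- rep("./.", length(x))
      out[!is.na(x) & x == 0] <- "0/0"
      out[!is.na(x) & x == 1] <- "1/1"
      out[!is.na(x) & x == 0.5] <- "0/1"
      out
    }
    gtxt <- apply(gt$calls, 1, function(row) paste(code(row), collapse = "\t"))
    writeLines(paste(gt$sites$chrom, gt$sites$pos + 1L, ".", gt$sites$ref,
                     gt$sites$alt, ".", "PASS", ".", "GT", gtxt, sep = "\t"),
               con)
  }
  invisible(path)
}

#' Construct a gene annotation
#'
#' Gene models with family membership, subgroup tags and (optionally) the
#' codon sequence / per-coding-site degeneracy used for site-length
#' calculations. One canonical transcript per gene.
#'
#' @param genes data frame: `gene`, `chrom`, `strand`, `family`, `subgroup`.
#' @param exons data frame: `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param codons optional named list: per gene, a character vector of codons
#'   in transcript order (terminal stop codon excluded).
#' @param large_families character vector of family ids flagged "large";
#'   each must have at least 20 member genes.
#' @param strict validate that each gene's coding length is divisible by 3.
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons, codons = NULL,
                            large_families = character(0), strict = TRUE) {
  stopifnot(all(c("gene", "chrom", "strand", "family") %in% names(genes)),
            all(c("gene", "chrom", "start", "end") %in% names(exons)))
  if (!"subgroup" %in% names(genes)) genes$subgroup <- "none"
  for (g in unique(exons$gene)) {
    e <- exons[exons$gene == g, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons within gene ", g)
  }
  len <- tapply(exons$end - exons$start, exons$gene, sum)
  genes$coding_length <- as.integer(len[genes$gene])
  if (strict && any(genes$coding_length %% 3 != 0))
    stop("coding length not divisible by 3 for gene(s): ",
         paste(genes$gene[genes$coding_length %% 3 != 0], collapse = ", "))
  for (fam in large_families) {
    nmem <- sum(genes$family == fam)
    if (nmem < 20)
      stop("family ", fam, " is flagged large but has only ", nmem,
           " members (>= 20 required)")
  }
  if (!is.null(codons)) {
    bad <- names(codons)[vapply(names(codons), function(g) {
      3L * length(codons[[g]]) != genes$coding_length[match(g, genes$gene)]
    }, logical(1))]
    if (length(bad)) stop("codon count inconsistent with coding length: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(genes = genes, exons = exons, codons = codons,
                 large_families = large_families),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,",
      length(unique(x$genes$family)), "families\n")
  invisible(x)
}

#' Read gene models from a BED6 exon file plus a family table
#'
#' Each BED row is one exon; the `name` column keys the gene. Genes missing
#' from the family table are assigned family `"background"`.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @param family_table data frame (or TSV path) with columns `gene`,
#'   `family`, optional `subgroup` and logical `large` (flagging the
#'   family as requiring >= 20 members).
#' @param strict see [gene_annotation()].
#' @return a [gene_annotation].
#' @export
read_gene_bed <- function(path, family_table = NULL, strict = TRUE) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "gene", "score",
                                  "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "character", "character"))
  if (is.character(family_table) && length(family_table) == 1)
    family_table <- read.table(family_table, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  ids <- unique(bed$gene)
  fam <- setNames(rep("background", length(ids)), ids)
  sub <- setNames(rep("none", length(ids)), ids)
  large <- character(0)
  if (!is.null(family_table)) {
    hit <- intersect(ids, family_table$gene)
    fam[hit] <- family_table$family[match(hit, family_table$gene)]
    if ("subgroup" %in% names(family_table))
      sub[hit] <- family_table$subgroup[match(hit, family_table$gene)]
    if ("large" %in% names(family_table))
      large <- unique(family_table$family[as.logical(family_table$large)])
  }
  strands <- tapply(bed$strand, bed$gene, function(s) s[1])
  chroms <- tapply(bed$chrom, bed$gene, function(s) s[1])
  genes <- data.frame(gene = ids, chrom = unname(chroms[ids]),
                      strand = unname(strands[ids]),
                      family = unname(fam[ids]), subgroup = unname(sub[ids]),
                      stringsAsFactors = FALSE)
  gene_annotation(genes, bed[, c("gene", "chrom", "start", "end")],
                  large_families = large, strict = strict)
}

#' Write gene exons as BED6
#' @param ann a [gene_annotation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(ann, path) {
  ex <- ann$exons
  strand <- ann$genes$strand[match(ex$gene, ann$genes$gene)]
  ex <- ex[order(ex$chrom, ex$start), ]
  strand <- ann$genes$strand[match(ex$gene, ann$genes$gene)]
  write.table(data.frame(ex$chrom, ex$start, ex$end, ex$gene, 0, strand),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Coding-site genomic positions of a gene, in transcript order
#'
#' For minus-strand genes positions run 3' to 5' genomically so that the
#' first element is the first coding base of the transcript.
#'
#' @param ann a [gene_annotation].
#' @param gene gene id.
#' @return integer vector of 0-based genomic positions.
#' @export
coding_sites <- function(ann, gene) {
  e <- ann$exons[ann$exons$gene == gene, , drop = FALSE]
  if (nrow(e) == 0) stop("unknown gene: ", gene)
  e <- e[order(e$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(e)), function(i) e$start[i]:(e$end[i] - 1L)))
  strand <- ann$genes$strand[match(gene, ann$genes$gene)]
  if (identical(strand, "-")) rev(pos) else pos
}

#' Assign variants to overlapping genes
#'
#' Interval intersection of variant positions against exon models; a
#' variant inside k overlapping genes is listed under all k. The assignment
#' is deterministic and independent of input order.
#'
#' @param gt a [genotype_table].
#' @param ann a [gene_annotation].
#' @return named list: per gene, the integer row indices of `gt$sites`
#'   falling in its exons (possibly empty).
#' @export
intersect_variants_genes <- function(gt, ann) {
  stopifnot(inherits(gt, "genotype_table"), inherits(ann, "gene_annotation"))
  out <- setNames(vector("list", nrow(ann$genes)), ann$genes$gene)
  for (g in names(out)) out[[g]] <- integer(0)
  if (nrow(gt$sites) == 0 || nrow(ann$exons) == 0) return(out)
  vr <- GenomicRanges::GRanges(gt$sites$chrom,
                               IRanges::IRanges(gt$sites$pos + 1L, width = 1L))
  er <- GenomicRanges::GRanges(ann$exons$chrom,
                               IRanges::IRanges(ann$exons$start + 1L,
                                                ann$exons$end))
  hits <- GenomicRanges::findOverlaps(vr, er)
  qg <- ann$exons$gene[S4Vectors::subjectHits(hits)]
  qi <- S4Vectors::queryHits(hits)
  for (g in unique(qg)) out[[g]] <- sort(unique(qi[qg == g]))
  out
}

#' Per-population alternate-allele frequencies
#'
#' Computed from non-missing calls, heterozygotes contributing 1/2.
#'
#' @param gt a [genotype_table].
#' @param sites optional integer site indices (default all).
#' @return matrix sites x populations of alt-allele frequencies (NaN where
#'   a population has no non-missing call).
#' @export
pop_allele_freqs <- function(gt, sites = seq_len(nrow(gt$sites))) {
  pops <- sort(unique(gt$line_pops))
  sapply(pops, function(p) {
    m <- gt$calls[sites, gt$line_pops == p, drop = FALSE]
    rowMeans(m, na.rm = TRUE)
  }, simplify = TRUE) |>
    matrix(nrow = length(sites), dimnames = list(NULL, pops))
}

#' Per-population non-missing sample counts
#' @inheritParams pop_allele_freqs
#' @return matrix sites x populations of non-missing call counts.
#' @export
pop_sample_sizes <- function(gt, sites = seq_len(nrow(gt$sites))) {
  pops <- sort(unique(gt$line_pops))
  sapply(pops, function(p) {
    m <- gt$calls[sites, gt$line_pops == p, drop = FALSE]
    rowSums(!is.na(m))
  }, simplify = TRUE) |>
    matrix(nrow = length(sites), dimnames = list(NULL, pops))
}

#' Subset a genotype table by site indices
#' @param gt a [genotype_table].
#' @param sites integer site indices (in current order).
#' @return a [genotype_table].
#' @export
subset_sites <- function(gt, sites) {
  genotype_table(gt$sites[sites, c("chrom", "pos", "ref", "alt"),
                          drop = FALSE],
                 gt$calls[sites, , drop = FALSE], gt$line_pops)
}
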