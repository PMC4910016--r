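## Functional effect classification, synonymous/nonsynonymous site lengths,
## allele polarization and haploidization/imputation.

BASES <- c("A", "C", "G", "T")

# standard genetic code, cached as a plain named vector (the S4 accessor is
# far too slow for per-site calls)
GC_TABLE <- Biostrings::GENETIC_CODE

codon_to_aa <- function(codon) {
  aa <- GC_TABLE[codon]
  if (anyNA(aa)) stop("invalid codon: ", codon[is.na(aa)][1])
  unname(aa)
}

# vectorised effect classification used by the data generator; the scalar
# classify_site_effect is the documented per-site entry point
classify_effects_vec <- function(codons, pos_in_codon, alt) {
  alt_codons <- codons
  substr(alt_codons, pos_in_codon, pos_in_codon) <- alt
  aa_ref <- GC_TABLE[codons]
  aa_alt <- GC_TABLE[alt_codons]
  ifelse(aa_alt == aa_ref, "synonymous",
         ifelse(aa_alt == "*", "nonsense", "replacement"))
}

#' Classify the functional effect of a coding SNP
#'
#' Compares the amino acid encoded by the reference codon with the codon
#' carrying the alternate base: synonymous if unchanged, nonsense if the
#' alternate codon is a stop, replacement otherwise.
#'
#' @param codon reference codon (3 bases, in-frame, transcript strand).
#' @param pos_in_codon position of the variant within the codon (1-3).
#' @param ref reference base at that position (must match the codon).
#' @param alt alternate base.
#' @return one of `"synonymous"`, `"nonsense"`, `"replacement"`.
#' @export
#' @examples
#' classify_site_effect("GGA", 3, "A", "G")  # Gly -> Gly, synonymous
#' classify_site_effect("TGG", 3, "G", "A")  # Trp -> stop, nonsense
classify_site_effect <- function(codon, pos_in_codon, ref, alt) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3, pos_in_codon %in% 1:3,
            ref %in% BASES, alt %in% BASES, ref != alt)
  if (substr(codon, pos_in_codon, pos_in_codon) != ref)
    stop("ref base does not match codon position")
  alt_codon <- codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt
  aa_ref <- codon_to_aa(codon)
  aa_alt <- codon_to_aa(alt_codon)
  if (aa_alt == aa_ref) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "replacement"
}

#' Degeneracy fold of each position of a codon
#'
#' A position is x-fold degenerate when x of the four possible bases leave
#' the encoded amino acid unchanged (stop codons count as a distinct
#' "amino acid").
#'
#' @param codon 3-base codon.
#' @return integer vector of length 3 with values in 1..4 (for a vector of
#'   codons, the concatenation of the per-codon triples).
#' @export
codon_degeneracy <- function(codon) {
  codon <- toupper(codon)
  as.vector(DEGEN_TABLE[, codon])
}

# 3 x 64 degeneracy lookup, enumerated once from the genetic code
DEGEN_TABLE <- local({
  cods <- names(GC_TABLE)
  m <- sapply(cods, function(codon) {
    vapply(1:3, function(p) {
      aa <- vapply(BASES, function(b) {
        cd <- codon
        substr(cd, p, p) <- b
        unname(GC_TABLE[cd])
      }, character(1))
      sum(aa == GC_TABLE[[codon]])
    }, integer(1))
  })
  colnames(m) <- cods
  m
})

#' Effective synonymous and nonsynonymous site counts of a gene
#'
#' Counts 1-/2-/3-/4-fold degenerate coding positions and combines them as
#' length_ns = L1 + 2/3 L2 + 1/3 L3 and length_s = L4 + 1/3 L2 + 2/3 L3,
#' so that length_ns + length_s equals the coding length. The terminal stop
#' codon is excluded from the gene model entirely.
#'
#' @param gene gene id (looked up in `ann`), or ignored when `degeneracy`
#'   is supplied directly.
#' @param ann a [gene_annotation] carrying codon sequences.
#' @param degeneracy optional integer vector of per-coding-site degeneracy
#'   folds, overriding the lookup.
#' @return list of class `site_lengths`: `L1`..`L4`, `length_ns`,
#'   `length_s`, `coding_length`.
#' @export
compute_site_lengths <- function(gene = NULL, ann = NULL, degeneracy = NULL) {
  if (is.null(degeneracy)) {
    stopifnot(inherits(ann, "gene_annotation"), !is.null(ann$codons),
              gene %in% names(ann$codons))
    degeneracy <- codon_degeneracy(ann$codons[[gene]])
  }
  stopifnot(all(degeneracy %in% 1:4))
  L <- tabulate(degeneracy, nbins = 4)
  structure(list(L1 = L[1], L2 = L[2], L3 = L[3], L4 = L[4],
                 length_ns = L[1] + 2 / 3 * L[2] + 1 / 3 * L[3],
                 length_s = L[4] + 1 / 3 * L[2] + 2 / 3 * L[3],
                 coding_length = sum(L)),
            class = "site_lengths")
}

#' Polarize a site into ancestral/derived alleles
#'
#' Uses probabilistic ancestral-state calls: the allele whose posterior
#' probability of being ancestral is at least 0.85 (inclusive) determines
#' the derived state; otherwise the site is unpolarized and excluded from
#' polarized analyses.
#'
#' @param p_ref_ancestral posterior probability that the reference allele is
#'   ancestral (the alternate allele has 1 - p).
#' @param threshold posterior cutoff, default 0.85.
#' @return `"alt"` (derived = alt), `"ref"` (derived = ref), or
#'   `"unpolarized"`.
#' @export
polarize_alleles <- function(p_ref_ancestral, threshold = 0.85) {
  if (any(p_ref_ancestral < 0 | p_ref_ancestral > 1, na.rm = TRUE))
    stop("posterior probability outside [0, 1]")
  out <- rep("unpolarized", length(p_ref_ancestral))
  out[!is.na(p_ref_ancestral) & p_ref_ancestral >= threshold] <- "alt"
  out[!is.na(p_ref_ancestral) & (1 - p_ref_ancestral) >= threshold] <- "ref"
  out
}

#' Resolve heterozygotes and impute missing calls to haploid alleles
#'
#' Inbred lines are treated as haploid samples: residual heterozygous calls
#' are resolved by choosing one of the two alleles uniformly at random,
#' independently per site and line, and missing calls are drawn Bernoulli
#' with the population-specific alternate-allele frequency (computed from
#' the non-missing calls, after heterozygote resolution ordering documented
#' in the methods vignette). Deterministic given `seed`.
#'
#' @param gt a [genotype_table] (typically a per-gene slice).
#' @param seed optional integer seed.
#' @return a [genotype_table] whose calls are all 0 or 1.
#' @export
haploidize_and_impute <- function(gt, seed = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  with_seed(seed, {
    calls <- gt$calls
    het <- which(!is.na(calls) & calls == 0.5)
    if (length(het)) calls[het] <- rbinom(length(het), 1, 0.5)
    miss <- which(is.na(calls))
    if (length(miss)) {
      pops <- unique(gt$line_pops)
      freqs <- matrix(NA_real_, nrow(calls), length(pops),
                      dimnames = list(NULL, pops))
      for (p in pops) {
        m <- calls[, gt$line_pops == p, drop = FALSE]
        nn <- rowSums(!is.na(m))
        if (any(nn == 0 & rowSums(is.na(m)) > 0)) {
          bad <- which(nn == 0)[1]
          stop("all calls missing at site ", gt$sites$chrom[bad], ":",
               gt$sites$pos[bad], " in population ", p,
               "; population frequency undefined")
        }
        freqs[, p] <- rowMeans(m, na.rm = TRUE)
      }
      idx <- arrayInd(miss, dim(calls))
      f <- freqs[cbind(idx[, 1], match(gt$line_pops[idx[, 2]], pops))]
      calls[miss] <- rbinom(length(miss), 1, f)
    }
    genotype_table(gt$sites[, c("chrom", "pos", "ref", "alt")], calls,
                   gt$line_pops)
  })
}

#' Flag disruptive (frameshifting) indels within exons
#'
#' An indel is disruptive when it falls inside a coding exon and its length
#' is not a multiple of 3; in-frame or intronic/intergenic indels are
#' class `"other"`.
#'
#' @param indels data frame with columns `chrom`, `pos` (0-based),
#'   `ref`, `alt` (sequences; length difference defines the indel length),
#'   or a VCF path read with the same columns.
#' @param ann a [gene_annotation].
#' @return data frame: one row per (indel, overlapped gene) plus rows with
#'   `gene = NA` for non-exonic indels; columns `chrom`, `pos`, `gene`,
#'   `indel_len`, `class`.
#' @export
detect_disruptive_indels <- function(indels, ann) {
  if (is.character(indels) && length(indels) == 1) {
    v <- vcfR::read.vcfR(indels, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    indels <- data.frame(chrom = fix$CHROM,
                         pos = as.integer(fix$POS) - 1L,
                         ref = fix$REF, alt = fix$ALT)
  }
  len <- abs(nchar(indels$alt) - nchar(indels$ref))
  if (nrow(indels) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      gene = character(0), indel_len = integer(0),
                      class = character(0)))
  vr <- GenomicRanges::GRanges(indels$chrom,
                               IRanges::IRanges(indels$pos + 1L, width = 1L))
  er <- GenomicRanges::GRanges(ann$exons$chrom,
                               IRanges::IRanges(ann$exons$start + 1L,
                                                ann$exons$end))
  hits <- GenomicRanges::findOverlaps(vr, er)
  qi <- S4Vectors::queryHits(hits)
  gene <- ann$exons$gene[S4Vectors::subjectHits(hits)]
  exonic <- data.frame(i = qi, gene = gene)
  exonic <- exonic[!duplicated(exonic), , drop = FALSE]
  rows <- lapply(seq_len(nrow(indels)), function(i) {
    gs <- exonic$gene[exonic$i == i]
    if (length(gs) == 0) {
      data.frame(chrom = indels$chrom[i], pos = indels$pos[i],
                 gene = NA_character_, indel_len = len[i], class = "other")
    } else {
      data.frame(chrom = indels$chrom[i], pos = indels$pos[i], gene = gs,
                 indel_len = len[i],
                 class = if (len[i] %% 3 != 0) "frameshift_indel" else "other")
    }
  })
  do.call(rbind, rows)
}
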