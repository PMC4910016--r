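## Relaxed-constraint stage: replacement/silent diversity ratios, family
## comparisons, CNV gene-event classification and null-allele summaries.

#' Replacement/silent per-site diversity ratio of a gene
#'
#' (pi_R / length_ns) / (pi_S / length_s): values below 1 indicate
#' purifying selection on protein sequence; elevated values indicate
#' relaxed constraint.
#'
#' @param pi_r summed nucleotide diversity at replacement sites.
#' @param pi_s summed nucleotide diversity at silent sites.
#' @param lengths a `site_lengths` for the gene.
#' @return the ratio (NA when silent per-site diversity is zero).
#' @export
pr_ps_ratio <- function(pi_r, pi_s, lengths) {
  stopifnot(inherits(lengths, "site_lengths"), pi_r >= 0, pi_s >= 0)
  dR <- pi_r / lengths$length_ns
  dS <- pi_s / lengths$length_s
  if (!is.finite(dS) || dS == 0) return(NA_real_)
  dR / dS
}

#' Compare constraint (P_R/P_S) distributions among families
#'
#' Kruskal-Wallis test for heterogeneity across families, followed by
#' pairwise Wilcoxon rank-sum tests with multiple-testing correction.
#'
#' @param ratios numeric vector of per-gene P_R/P_S ratios.
#' @param families character vector of family ids parallel to `ratios`.
#' @param p_adjust_method correction for the pairwise tests (default
#'   `"holm"`).
#' @return list: `kw_p`, `kw_stat`, `pairwise` (matrix of adjusted p),
#'   `n_families`.
#' @export
family_constraint_compare <- function(ratios, families,
                                      p_adjust_method = "holm") {
  keep <- !is.na(ratios)
  ratios <- ratios[keep]
  families <- families[keep]
  tab <- table(families)
  if (length(tab) < 2)
    stop("constraint comparison needs >= 2 families with >= 2 genes")
  if (any(tab < 2))
    stop("families with < 2 genes: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  kw <- kruskal.test(ratios, factor(families))
  pw <- pairwise.wilcox.test(ratios, factor(families),
                             p.adjust.method = p_adjust_method, exact = FALSE)
  list(kw_p = kw$p.value, kw_stat = unname(kw$statistic),
       pairwise = pw$p.value, n_families = length(tab))
}

#' Construct a CNV record table
#'
#' @param events data frame: `event_id`, `type` (duplication | deletion |
#'   insertion), `chrom`, `start`, `end` (0-based half-open),
#'   plus per-line presence columns (0/1) named by line.
#' @param line_pops named character vector line -> population.
#' @return data frame of class `cnv_table` with a `size` column and
#'   per-population frequency columns `freq_<pop>`.
#' @export
cnv_table <- function(events, line_pops) {
  stopifnot(all(c("event_id", "type", "chrom", "start", "end") %in%
                  names(events)),
            all(events$type %in% c("duplication", "deletion", "insertion")))
  events$size <- events$end - events$start
  if (any(events$size < 25 | events$size > 25000))
    stop("CNV size out of bounds [25, 25000] bp for event(s): ",
         paste(events$event_id[events$size < 25 | events$size > 25000],
               collapse = ", "))
  lines <- intersect(names(line_pops), names(events))
  if (length(lines) == 0) stop("no per-line presence columns found")
  for (p in sort(unique(line_pops))) {
    ln <- lines[line_pops[lines] == p]
    events[[paste0("freq_", p)]] <-
      rowSums(events[, ln, drop = FALSE]) / length(ln)
  }
  class(events) <- c("cnv_table", "data.frame")
  events
}

#' Classify CNV-derived gene structures
#'
#' Applies the rule set for novel gene structures, per (CNV, gene-context)
#' pair, exhaustively and mutually exclusively:
#' \itemize{
#' \item complete duplication: a duplication spanning an entire gene;
#' \item chimera: a duplication partially covering two genes (it must
#'   overlap, but not fully contain, each of two distinct genes);
#' \item gene fusion: a deletion that removes the facing ends of two tandem
#'   genes plus the gap between them, joining their remaining portions
#'   (strand concordance recorded);
#' \item gene deletion: a deletion removing at least one coding exon base of
#'   a gene without fusing it to another.
#' }
#'
#' @param cnvs a [cnv_table].
#' @param ann a [gene_annotation].
#' @return data frame: `event_id`, `type`, `class`, `genes`
#'   (comma-separated), `same_strand` (fusions only).
#' @export
classify_cnv_gene_events <- function(cnvs, ann) {
  gene_rng <- do.call(rbind, lapply(split(ann$exons, ann$exons$gene),
                                    function(e) data.frame(
                                      gene = e$gene[1], chrom = e$chrom[1],
                                      start = min(e$start), end = max(e$end))))
  gene_rng$strand <- ann$genes$strand[match(gene_rng$gene, ann$genes$gene)]
  out <- lapply(seq_len(nrow(cnvs)), function(i) {
    ev <- cnvs[i, ]
    g <- gene_rng[gene_rng$chrom == ev$chrom &
                    gene_rng$start < ev$end & gene_rng$end > ev$start, ,
                  drop = FALSE]
    if (nrow(g) == 0 || ev$type == "insertion") {
      return(data.frame(event_id = ev$event_id, type = ev$type,
                        class = "intergenic", genes = "",
                        same_strand = NA))
    }
    g <- g[order(g$start), , drop = FALSE]
    complete <- ev$start <= g$start & ev$end >= g$end
    partial <- !complete
    if (ev$type == "duplication") {
      if (sum(partial) >= 2) {
        cls <- "chimera"
        genes <- g$gene[partial]
      } else if (any(complete)) {
        cls <- "complete_duplication"
        genes <- g$gene[complete]
      } else {
        cls <- "partial_duplication"
        genes <- g$gene
      }
      return(data.frame(event_id = ev$event_id, type = ev$type, class = cls,
                        genes = paste(genes, collapse = ","),
                        same_strand = if (cls == "chimera")
                          length(unique(g$strand[partial])) == 1 else NA))
    }
    # deletion
    if (sum(partial) >= 2) {
      # joins the facing portions of two tandem genes
      return(data.frame(event_id = ev$event_id, type = ev$type,
                        class = "fusion",
                        genes = paste(g$gene[partial], collapse = ","),
                        same_strand =
                          length(unique(g$strand[partial])) == 1))
    }
    # does it remove coding exon sequence?
    ex <- ann$exons[ann$exons$gene %in% g$gene, , drop = FALSE]
    removes_coding <- any(ex$start < ev$end & ex$end > ev$start)
    data.frame(event_id = ev$event_id, type = ev$type,
               class = if (removes_coding) "gene_deletion"
               else "noncoding_deletion",
               genes = paste(g$gene, collapse = ","), same_strand = NA)
  })
  do.call(rbind, out)
}

#' Per-gene null-allele summary and family roll-up
#'
#' A gene is flagged as carrying a high-frequency null allele in a
#' population when at least one single class of disruptive mutation
#' (nonsense SNP, frameshift indel, or CNV deletion removing coding
#' sequence) segregates at or above the frequency threshold in that
#' population; frequencies are never summed across classes.
#'
#' @param disruptions data frame: `gene`, `class` (`nonsense`,
#'   `frameshift_indel`, `cnv_deletion`), and one frequency column per
#'   population named `freq_<pop>`.
#' @param families named character vector gene -> family (genes absent from
#'   `disruptions` count as intact).
#' @param threshold per-population frequency cutoff (inclusive), default
#'   0.10.
#' @return list: `per_gene` (gene x population logical flags),
#'   `family_fraction` (family x population fraction of member genes
#'   flagged), `population_span` (per family: genes with nulls in 0 and in
#'   all populations).
#' @export
null_allele_summary <- function(disruptions, families, threshold = 0.10) {
  pops <- sub("^freq_", "", grep("^freq_", names(disruptions), value = TRUE))
  genes <- names(families)
  flags <- matrix(FALSE, length(genes), length(pops),
                  dimnames = list(genes, pops))
  for (r in seq_len(nrow(disruptions))) {
    g <- disruptions$gene[r]
    if (!g %in% genes) next
    for (p in pops) {
      f <- disruptions[[paste0("freq_", p)]][r]
      if (!is.na(f) && f >= threshold) flags[g, p] <- TRUE
    }
  }
  fams <- sort(unique(families))
  fam_frac <- t(vapply(fams, function(fm) {
    colMeans(flags[families == fm, , drop = FALSE])
  }, numeric(length(pops))))
  dimnames(fam_frac) <- list(fams, pops)
  span <- t(vapply(fams, function(fm) {
    fl <- flags[families == fm, , drop = FALSE]
    npop_hit <- rowSums(fl)
    c(none = sum(npop_hit == 0), all = sum(npop_hit == length(pops)),
      any = sum(npop_hit > 0), size = nrow(fl))
  }, numeric(4)))
  list(per_gene = flags, family_fraction = fam_frac,
       population_span = as.data.frame(span))
}

#' Deletion:duplication ratio for a family
#'
#' Counts classified deletion and duplication events touching a family's
#' genes, overall and restricted to events above a frequency floor, and
#' reports the gcd-reduced ratio ("19:0" conventions: a zero denominator is
#' reported with ratio +Inf).
#'
#' @param classified data frame from [classify_cnv_gene_events()] joined
#'   with a `family` column and a `max_freq` column (maximum per-population
#'   frequency of the event).
#' @param family family id.
#' @param freq_floor frequency floor for the restricted count (default 0.10,
#'   strict >).
#' @return list: `overall` and `above_floor`, each with `deletions`,
#'   `duplications`, `label` (reduced "d:u"), `ratio`.
#' @export
del_dup_ratio <- function(classified, family, freq_floor = 0.10) {
  d <- classified[classified$family == family, , drop = FALSE]
  del_classes <- c("gene_deletion", "fusion")
  dup_classes <- c("complete_duplication", "chimera", "partial_duplication")
  count <- function(rows) {
    ndel <- sum(rows$class %in% del_classes)
    ndup <- sum(rows$class %in% dup_classes)
    g <- function(a, b) if (b == 0) a else g(b, a %% b)
    # reduce only when both sides are positive ("19:0" stays as printed)
    cd <- if (ndel > 0 && ndup > 0) g(ndel, ndup) else 1
    list(deletions = ndel, duplications = ndup,
         label = paste0(ndel / cd, ":", ndup / cd),
         ratio = if (ndup == 0) {
           if (ndel == 0) NA_real_ else Inf
         } else ndel / ndup)
  }
  list(overall = count(d),
       above_floor = count(d[!is.na(d$max_freq) & d$max_freq > freq_floor, ,
                             drop = FALSE]))
}
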