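## Synthetic multi-population dataset generator with known ground truth.
## Emulates an inbred-line diversity panel: five populations, gene families
## on a toy genome, coalescent-backed SNPs with residual heterozygosity and
## missingness, probabilistic ancestral calls, divergence counts, CNV/indel
## tables and receptor response matrices. Every planted signal is recorded
## in a truth sidecar consumed by the test suite.

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

#' Scenario configuration for the synthetic dataset generator
#'
#' Defaults emulate the five-population inbred panel design (Beijing 15,
#' Ithaca 19, Netherlands 19, Tasmania 18, Zimbabwe 13 lines) with four
#' large receptor/binding-protein families of at least 20 genes each and a
#' genome-wide background gene set for the empirical Fst tails.
#'
#' @param pops named integer vector of lines per population.
#' @param families named list; each entry a list with `n_genes`, `gene_bp`
#'   (coding length), `large` flag and `alpha_true` (adaptive substitution
#'   fraction used by the divergence generator).
#' @param n_background number of background genes.
#' @param background_bp coding length of background genes.
#' @param theta_bp scaled mutation rate per coding site.
#' @param rho_bp scaled recombination rate per coding site.
#' @param demography name of the [demography_preset()] used for SNP
#'   genealogies.
#' @param het_rate probability a haploid call is recorded as a residual
#'   heterozygote.
#' @param missing_rate probability a call is missing.
#' @param frac_unpolarized fraction of sites whose ancestral posterior falls
#'   below the 0.85 polarization threshold.
#' @param div_f effectively-neutral replacement fraction used by the
#'   divergence generator.
#' @param fst_inflation `NULL`, or list(`family`, `intensity`, `graded`):
#'   inflate between-population differentiation of that family's
#'   replacement SNPs (graded = per-gene intensities spread over
#'   \[0, intensity\], for tuning-breadth coupling).
#' @param sweeps `NULL`, or data frame (`family`, `gene_index`, `pop`,
#'   `intensity`) of selective sweeps to inject.
#' @param kl_coupling coupling in \[-1, 0\] between tuning breadth and the
#'   injected per-gene differentiation of the receptor family (0 = none).
#' @param n_odorants number of odorants in the response matrix.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(pops = c(B = 15, I = 19, N = 19, T = 18, Z = 13),
                            families = list(
                              Or = list(n_genes = 22, gene_bp = 1500,
                                        large = TRUE, alpha_true = 0.4),
                              Gr = list(n_genes = 20, gene_bp = 1500,
                                        large = TRUE, alpha_true = 0.2),
                              Ir = list(n_genes = 20, gene_bp = 2001,
                                        large = TRUE, alpha_true = 0),
                              Obp = list(n_genes = 20, gene_bp = 600,
                                         large = TRUE, alpha_true = 0.1)),
                            n_background = 500, background_bp = 1500,
                            theta_bp = 0.008, rho_bp = 0.01,
                            demography = "bottleneck",
                            het_rate = 0.01, missing_rate = 0.02,
                            frac_unpolarized = 0.10, div_f = 1,
                            fst_inflation = NULL, sweeps = NULL,
                            kl_coupling = 0, n_odorants = 50) {
  stopifnot(all(pops >= 2), n_background >= 0,
            theta_bp > 0, rho_bp >= 0,
            het_rate >= 0, missing_rate >= 0, frac_unpolarized >= 0,
            kl_coupling <= 0, kl_coupling >= -1)
  for (f in names(families)) {
    if (isTRUE(families[[f]]$large) && families[[f]]$n_genes < 20)
      stop("family ", f, " flagged large must have >= 20 genes")
    families[[f]]$gene_bp <- 3L * (families[[f]]$gene_bp %/% 3L)
  }
  structure(list(pops = pops, families = families,
                 n_background = n_background,
                 background_bp = 3L * (background_bp %/% 3L),
                 theta_bp = theta_bp, rho_bp = rho_bp,
                 demography = demography, het_rate = het_rate,
                 missing_rate = missing_rate,
                 frac_unpolarized = frac_unpolarized, div_f = div_f,
                 fst_inflation = fst_inflation, sweeps = sweeps,
                 kl_coupling = kl_coupling, n_odorants = n_odorants),
            class = "scenario_config")
}

#' Generate the toy genome annotation
#'
#' Places family genes and background genes on arms 2L, 2R, 3L, 3R and X
#' with random codon sequences (sense codons only; the terminal stop is not
#' modelled), assigning strands at random so tandem same-strand pairs exist
#' for fusion events. Deterministic given the seed.
#'
#' @param config a [scenario_config].
#' @param seed integer seed.
#' @return a [gene_annotation] with codons attached; family genes carry
#'   their family id, background genes family `"background"`.
#' @export
generate_genome <- function(config, seed = 1) {
  with_seed(seed, {
    arms <- c("2L", "2R", "3L", "3R", "X")
    specs <- list()
    for (f in names(config$families)) {
      ff <- config$families[[f]]
      for (i in seq_len(ff$n_genes))
        specs[[length(specs) + 1]] <- list(
          gene = sprintf("%s%02d", f, i), family = f, bp = ff$gene_bp)
    }
    for (i in seq_len(config$n_background))
      specs[[length(specs) + 1]] <- list(
        gene = sprintf("bg%04d", i), family = "background",
        bp = config$background_bp)
    arm_of <- rep(arms, length.out = length(specs))
    cursor <- setNames(rep(10000L, length(arms)), arms)
    genes <- exons <- vector("list", length(specs))
    codons <- list()
    for (k in seq_along(specs)) {
      sp <- specs[[k]]
      arm <- arm_of[k]
      start <- cursor[[arm]]
      end <- start + sp$bp
      cursor[[arm]] <- end + 2000L
      strand <- sample(c("+", "-"), 1)
      genes[[k]] <- data.frame(gene = sp$gene, chrom = arm, strand = strand,
                               family = sp$family,
                               subgroup = if (sp$family == "background")
                                 "none" else
                                   sample(c("adult-only", "larval-only",
                                            "none"), 1),
                               stringsAsFactors = FALSE)
      exons[[k]] <- data.frame(gene = sp$gene, chrom = arm, start = start,
                               end = end)
      codons[[sp$gene]] <- sample(SENSE_CODONS, sp$bp / 3, replace = TRUE)
    }
    large <- names(config$families)[vapply(config$families,
                                           function(x) isTRUE(x$large),
                                           logical(1))]
    gene_annotation(do.call(rbind, genes), do.call(rbind, exons),
                    codons = codons, large_families = large)
  })
}

# per-gene coalescent haplotypes for the whole panel
sim_gene_haplotypes <- function(model_a, model_x, chrom, theta, rho) {
  model <- if (chrom == "X") model_x else model_a
  arg <- simulate_genealogy(model, rho = rho)
  drop_mutations_theta(arg, theta)
}

#' Generate panel SNPs for every gene (with ancestral posteriors)
#'
#' Simulates one neutral genealogy per gene under the configured demographic
#' preset (X-linked genes use 3/4-scaled sizes), maps mutations to coding
#' positions, classifies each SNP's functional effect from its codon
#' context, and injects residual heterozygosity, missingness and the
#' configured family differentiation inflation. Ancestral states are the
#' reference alleles; posteriors are emitted with a configured fraction
#' below the 0.85 polarization threshold.
#'
#' @param config a [scenario_config].
#' @param ann a [gene_annotation] from [generate_genome()].
#' @param seed integer seed.
#' @return list: `genotypes` (a [genotype_table]), `effects` (data frame
#'   site/gene/family/class/codon context), `anc_posterior` (numeric,
#'   probability that ref is ancestral, per site), `truth` (list of
#'   injected signals).
#' @export
generate_population_snps <- function(config, ann, seed = 1) {
  with_seed(seed, {
    model_a <- demography_preset(config$demography, sample_sizes = config$pops)
    model_x <- demography_preset(config$demography, sample_sizes = config$pops,
                                 chrom_scale = 3 / 4)
    line_names <- unlist(lapply(names(config$pops), function(p)
      sprintf("%s%d", p, seq_len(config$pops[[p]]))))
    line_pops <- setNames(rep(names(config$pops), config$pops), line_names)

    infl <- config$fst_inflation
    infl_gene_intensity <- NULL
    if (!is.null(infl)) {
      fam_genes <- ann$genes$gene[ann$genes$family == infl$family]
      infl_gene_intensity <- if (isTRUE(infl$graded)) {
        setNames(infl$intensity * seq(0.1, 1, length.out = length(fam_genes)),
                 fam_genes)
      } else setNames(rep(infl$intensity, length(fam_genes)), fam_genes)
    }

    site_rows <- list()
    call_rows <- list()
    eff_rows <- list()
    for (k in seq_len(nrow(ann$genes))) {
      g <- ann$genes$gene[k]
      chrom <- ann$genes$chrom[k]
      L <- ann$genes$coding_length[k]
      rep1 <- sim_gene_haplotypes(model_a, model_x, chrom,
                                  theta = config$theta_bp * L,
                                  rho = config$rho_bp * L)
      H <- rep1$haplotypes
      if (ncol(H) == 0) next
      cidx_all <- pmin(floor(rep1$positions * L), L - 1)
      keep <- !duplicated(cidx_all)
      cidx <- cidx_all[keep]
      H <- H[, keep, drop = FALSE]
      tx_pos <- coding_sites(ann, g)
      codon_i <- cidx %/% 3 + 1
      pos_in_codon <- cidx %% 3 + 1
      cods <- ann$codons[[g]][codon_i]
      ref <- substr(cods, pos_in_codon, pos_in_codon)
      alt_shift <- sample.int(3, length(ref), replace = TRUE)
      alt <- BASES[(match(ref, BASES) - 1L + alt_shift) %% 4L + 1L]
      class <- classify_effects_vec(cods, pos_in_codon, alt)
      gpos <- tx_pos[cidx + 1]

      # differentiation inflation: push replacement SNPs of the target
      # family toward fixation of the derived allele in one population
      if (!is.null(infl_gene_intensity) && g %in% names(infl_gene_intensity)) {
        ii <- infl_gene_intensity[[g]]
        for (s in which(class == "replacement")) {
          if (runif(1) < ii) {
            pop <- sample(names(config$pops), 1)
            rows <- which(line_pops == pop)
            H[rows, s] <- 1
          }
        }
      }

      ord <- order(gpos)
      site_rows[[g]] <- data.frame(chrom = chrom, pos = gpos[ord],
                                   ref = ref[ord], alt = alt[ord],
                                   stringsAsFactors = FALSE)
      call_rows[[g]] <- t(H[, ord, drop = FALSE])
      eff_rows[[g]] <- data.frame(gene = g,
                                  family = ann$genes$family[k],
                                  chrom = chrom, pos = gpos[ord],
                                  class = class[ord],
                                  codon = cods[ord],
                                  pos_in_codon = pos_in_codon[ord],
                                  stringsAsFactors = FALSE)
    }

    sites <- do.call(rbind, site_rows)
    calls <- do.call(rbind, call_rows)
    effects <- do.call(rbind, eff_rows)
    colnames(calls) <- line_names
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[ord, , drop = FALSE]
    effects <- effects[ord, , drop = FALSE]
    rownames(sites) <- rownames(effects) <- NULL
    effects$site <- seq_len(nrow(effects))
    calls <- matrix(as.numeric(calls), nrow(calls), ncol(calls),
                    dimnames = list(NULL, line_names))

    # residual heterozygosity, then missingness
    nhet <- rbinom(1, length(calls), config$het_rate)
    if (nhet > 0) calls[sample(length(calls), nhet)] <- 0.5
    nmiss <- rbinom(1, length(calls), config$missing_rate)
    if (nmiss > 0) calls[sample(length(calls), nmiss)] <- NA

    anc <- ifelse(runif(nrow(sites)) < config$frac_unpolarized,
                  runif(nrow(sites), 0.5, 0.85 - 1e-9),
                  runif(nrow(sites), 0.85, 1))
    gt <- genotype_table(sites, calls, line_pops)

    truth <- list(fst_inflation = config$fst_inflation,
                  inflation_per_gene = infl_gene_intensity)

    # sweep injection happens on the assembled table so ground truth refers
    # to final site indices
    if (!is.null(config$sweeps)) {
      swept <- list()
      for (r in seq_len(nrow(config$sweeps))) {
        sw <- config$sweeps[r, ]
        fam_genes <- ann$genes$gene[ann$genes$family == sw$family]
        gene <- fam_genes[sw$gene_index]
        sidx <- effects$site[effects$gene == gene]
        res <- inject_sweep(gt, sidx, sw$pop, sw$intensity)
        gt <- res$table
        swept[[length(swept) + 1]] <- data.frame(
          gene = gene, pop = sw$pop, intensity = sw$intensity,
          n_sites_pushed = res$n_pushed)
      }
      truth$sweeps <- do.call(rbind, swept)
    }

    list(genotypes = gt, effects = effects, anc_posterior = anc,
         truth = truth)
  })
}

#' Inject a selective-sweep signature into a genotype table
#'
#' Pushes a fraction (`intensity`) of the gene's derived (alt) alleles that
#' segregate in the target population to frequency (n-1)/n there, by
#' setting every line of the population except one random carrier of the
#' ancestral allele to the derived state. This deterministic frequency
#' transformation emulates the excess of high-frequency derived alleles
#' left by a sweep without forward simulation.
#'
#' @param gt a [genotype_table].
#' @param site_idx site indices of the gene's (polarized) SNPs.
#' @param pop target population label.
#' @param intensity fraction of eligible sites pushed (0..1).
#' @param seed optional integer seed.
#' @return list: `table` (modified [genotype_table]), `n_pushed`.
#' @export
inject_sweep <- function(gt, site_idx, pop, intensity, seed = NULL) {
  stopifnot(intensity >= 0, intensity <= 1, pop %in% gt$line_pops)
  with_seed(seed, {
    cols <- which(gt$line_pops == pop)
    n <- length(cols)
    calls <- gt$calls
    pushed <- 0L
    for (s in site_idx) {
      cnt <- sum(calls[s, cols] == 1, na.rm = TRUE)
      if (cnt < 1 || cnt > n - 2) next  # not segregating or already at edge
      if (runif(1) <= intensity) {
        anc_line <- sample(cols, 1)
        calls[s, cols] <- 1
        calls[s, anc_line] <- 0
        pushed <- pushed + 1L
      }
    }
    gt$calls <- calls
    list(table = gt, n_pushed = pushed)
  })
}

#' Generate per-gene divergence (and model-consistent polymorphism) counts
#'
#' Draws MK counts from the Poisson factorization used by
#' [alpha_family_ml()]: per-gene polymorphism and divergence rates are
#' lognormal, the replacement fraction f is shared, and each family's true
#' alpha inflates replacement divergence by 1/(1-alpha). Ground truth is
#' returned alongside.
#'
#' @param config a [scenario_config] (per-family `alpha_true`, shared
#'   `div_f`).
#' @param ann a [gene_annotation] with codons (for site lengths).
#' @param seed integer seed.
#' @param theta_s mean per-silent-site polymorphism rate.
#' @param t_s mean per-silent-site divergence rate.
#' @return list: `counts` (data frame gene/family/P_S/P_R/D_S/D_R),
#'   `site_lengths` (named list of `site_lengths`), `truth` (alpha_true per
#'   family, f).
#' @export
generate_divergence <- function(config, ann, seed = 1, theta_s = 0.03,
                                t_s = 0.12) {
  with_seed(seed, {
    alpha_of <- vapply(names(config$families), function(f)
      config$families[[f]]$alpha_true %||% 0, numeric(1))
    f_sh <- config$div_f
    sl <- list()
    rows <- lapply(seq_len(nrow(ann$genes)), function(k) {
      g <- ann$genes$gene[k]
      fam <- ann$genes$family[k]
      a <- if (fam %in% names(alpha_of)) alpha_of[[fam]] else 0
      lens <- compute_site_lengths(g, ann)
      sl[[g]] <<- lens
      th <- theta_s * exp(rnorm(1, 0, 0.3))
      tt <- t_s * exp(rnorm(1, 0, 0.3))
      data.frame(gene = g, family = fam,
                 P_S = rpois(1, th * lens$length_s),
                 P_R = rpois(1, f_sh * th * lens$length_ns),
                 D_S = rpois(1, tt * lens$length_s),
                 D_R = rpois(1, f_sh * tt * lens$length_ns / (1 - a)))
    })
    list(counts = do.call(rbind, rows), site_lengths = sl,
         truth = list(alpha_true = alpha_of, f = f_sh))
  })
}

#' Generate the CNV and disruptive-indel set with planted ground truth
#'
#' Plants complete duplications, chimeras (duplications partially covering
#' two adjacent genes), tandem same-strand gene fusions (deletions joining
#' two genes), coding gene deletions at high (>= 10%) frequency, low-
#' frequency gene deletions, intergenic noise CNVs, frameshift indels and
#' nonsense SNPs. Event sizes respect the 25 bp - 25 kb CNV bounds.
#'
#' @param config a [scenario_config].
#' @param ann a [gene_annotation].
#' @param seed integer seed.
#' @param n_complete_dup,n_chimera,n_fusion,n_hf_null,n_lf_del,n_noise
#'   planted event counts.
#' @return list: `cnvs` (a [cnv_table]), `indels` (data frame), `disruptions`
#'   (per gene/class per-population frequencies for
#'   [null_allele_summary()]), `truth` (planted labels).
#' @export
generate_cnv_indel_set <- function(config, ann, seed = 1,
                                   n_complete_dup = 3, n_chimera = 2,
                                   n_fusion = 2, n_hf_null = 4,
                                   n_lf_del = 4, n_noise = 10) {
  with_seed(seed, {
    pops <- names(config$pops)
    line_names <- unlist(lapply(pops, function(p)
      sprintf("%s%d", p, seq_len(config$pops[[p]]))))
    line_pops <- setNames(rep(pops, config$pops), line_names)
    fam_genes <- ann$genes[ann$genes$family != "background", , drop = FALSE]
    rng <- do.call(rbind, lapply(split(ann$exons, ann$exons$gene),
                                 function(e) data.frame(
                                   gene = e$gene[1], chrom = e$chrom[1],
                                   start = min(e$start), end = max(e$end))))
    rng$strand <- ann$genes$strand[match(rng$gene, ann$genes$gene)]
    rng <- rng[order(rng$chrom, rng$start), , drop = FALSE]
    fam_of <- setNames(ann$genes$family, ann$genes$gene)

    events <- list()
    truth <- list(complete_duplication = character(0),
                  chimera = list(), fusion = list(),
                  hf_null = list())
    carriers <- function(pop, k) sample(line_names[line_pops == pop], k)
    presence_row <- function(who) as.integer(line_names %in% who)
    eid <- 0
    add_event <- function(type, chrom, start, end, who) {
      eid <<- eid + 1
      events[[eid]] <<- c(list(event_id = sprintf("cnv%03d", eid),
                               type = type, chrom = chrom,
                               start = start, end = end),
                          setNames(as.list(presence_row(who)), line_names))
      sprintf("cnv%03d", eid)
    }

    # complete duplications of whole family genes (1 carrier, low freq)
    pick <- sample(seq_len(nrow(fam_genes)), n_complete_dup)
    for (k in pick) {
      g <- fam_genes$gene[k]
      r <- rng[rng$gene == g, ]
      add_event("duplication", r$chrom, max(0, r$start - 50), r$end + 50,
                carriers(sample(pops, 1), 1))
      truth$complete_duplication <- c(truth$complete_duplication, g)
    }
    # chimeras: adjacent gene pairs, duplication from mid-A to mid-B
    adj <- which(rng$chrom[-nrow(rng)] == rng$chrom[-1])
    used <- integer(0)
    ch <- sample(adj, n_chimera)
    for (k in ch) {
      a <- rng[k, ]; b <- rng[k + 1, ]
      add_event("duplication", a$chrom,
                floor((a$start + a$end) / 2), floor((b$start + b$end) / 2),
                carriers(sample(pops, 1), 1))
      truth$chimera[[length(truth$chimera) + 1]] <-
        list(genes = c(a$gene, b$gene))
      used <- c(used, k, k + 1)
    }
    # fusions: adjacent same-strand pairs, deletion joining them
    same <- setdiff(adj[rng$strand[adj] == rng$strand[adj + 1]],
                    c(used, used - 1))
    fu <- sample(same, n_fusion)
    for (k in fu) {
      a <- rng[k, ]; b <- rng[k + 1, ]
      add_event("deletion", a$chrom,
                floor((a$start + a$end) / 2), floor((b$start + b$end) / 2),
                carriers(sample(pops, 1), 1))
      truth$fusion[[length(truth$fusion) + 1]] <-
        list(genes = c(a$gene, b$gene), same_strand = TRUE)
      used <- c(used, k, k + 1)
    }
    # high-frequency (>= 10%) coding deletions: the planted null alleles
    hf_pool <- setdiff(fam_genes$gene, c(truth$complete_duplication,
                                         unlist(lapply(truth$chimera, `[[`,
                                                       "genes")),
                                         unlist(lapply(truth$fusion, `[[`,
                                                       "genes"))))
    hf <- sample(hf_pool, n_hf_null)
    for (g in hf) {
      r <- rng[rng$gene == g, ]
      pop <- sample(pops, 1)
      k <- max(2L, ceiling(0.12 * config$pops[[pop]]))
      add_event("deletion", r$chrom, r$start + 10,
                min(r$start + 10 + 400, r$end), carriers(pop, k))
      truth$hf_null[[length(truth$hf_null) + 1]] <-
        list(gene = g, pop = pop, class = "cnv_deletion",
             freq = k / config$pops[[pop]])
    }
    # low-frequency coding deletions (single carrier: always < 10%)
    lf <- sample(setdiff(hf_pool, hf), n_lf_del)
    for (g in lf) {
      r <- rng[rng$gene == g, ]
      add_event("deletion", r$chrom, r$start + 20,
                min(r$start + 20 + 300, r$end), carriers(sample(pops, 1), 1))
    }
    # intergenic noise CNVs (between the padded gene intervals)
    for (i in seq_len(n_noise)) {
      k <- sample(seq_len(nrow(rng) - 1), 1)
      if (rng$chrom[k] != rng$chrom[k + 1]) next
      gap_s <- rng$end[k] + 200
      gap_e <- rng$start[k + 1] - 200
      if (gap_e - gap_s < 100) next
      sz <- sample(25:min(900, gap_e - gap_s), 1)
      add_event(sample(c("duplication", "deletion", "insertion"), 1),
                rng$chrom[k], gap_s, gap_s + sz,
                carriers(sample(pops, 1), 1))
    }
    cnvs <- cnv_table(do.call(rbind, lapply(events, function(e)
      as.data.frame(e, stringsAsFactors = FALSE))), line_pops)

    # frameshift indels: plant some at >= 10% in one population
    indels <- list()
    fs <- sample(setdiff(hf_pool, c(hf, lf)), 3)
    for (i in seq_along(fs)) {
      g <- fs[i]
      r <- rng[rng$gene == g, ]
      pop <- sample(pops, 1)
      hf_this <- i == 1
      k <- if (hf_this) max(2L, ceiling(0.12 * config$pops[[pop]])) else 1L
      indels[[i]] <- data.frame(chrom = r$chrom, pos = r$start + 33,
                                ref = "ACGTA", alt = "A", gene = g,
                                pop = pop, carriers = k,
                                freq = k / config$pops[[pop]])
      if (hf_this)
        truth$hf_null[[length(truth$hf_null) + 1]] <-
          list(gene = g, pop = pop, class = "frameshift_indel",
               freq = k / config$pops[[pop]])
    }
    indels <- do.call(rbind, indels)

    # nonsense SNPs: one planted high-frequency, one low
    ns <- sample(setdiff(hf_pool, c(hf, lf, fs)), 2)
    nonsense <- do.call(rbind, lapply(seq_along(ns), function(i) {
      pop <- sample(pops, 1)
      k <- if (i == 1) max(2L, ceiling(0.12 * config$pops[[pop]])) else 1L
      data.frame(gene = ns[i], pop = pop, carriers = k,
                 freq = k / config$pops[[pop]])
    }))
    truth$hf_null[[length(truth$hf_null) + 1]] <-
      list(gene = ns[1], pop = nonsense$pop[1], class = "nonsense",
           freq = nonsense$freq[1])

    # per-gene, per-class, per-population frequency table
    disr <- list()
    add_disr <- function(gene, class, pop, freq) {
      row <- setNames(as.list(rep(0, length(pops))), paste0("freq_", pops))
      row[[paste0("freq_", pop)]] <- freq
      disr[[length(disr) + 1]] <<- c(list(gene = gene, class = class), row)
    }
    cls <- classify_cnv_gene_events(cnvs, ann)
    for (r in seq_len(nrow(cls))) {
      if (cls$class[r] != "gene_deletion") next
      ev <- cnvs[cnvs$event_id == cls$event_id[r], ]
      for (p in pops) {
        f <- ev[[paste0("freq_", p)]]
        if (f > 0) add_disr(strsplit(cls$genes[r], ",")[[1]][1],
                            "cnv_deletion", p, f)
      }
    }
    for (r in seq_len(nrow(indels)))
      add_disr(indels$gene[r], "frameshift_indel", indels$pop[r],
               indels$freq[r])
    for (r in seq_len(nrow(nonsense)))
      add_disr(nonsense$gene[r], "nonsense", nonsense$pop[r],
               nonsense$freq[r])
    disruptions <- do.call(rbind, lapply(disr, function(d)
      as.data.frame(d, stringsAsFactors = FALSE)))

    list(cnvs = cnvs, indels = indels, disruptions = disruptions,
         truth = truth)
  })
}

#' Generate a receptor x odorant response matrix
#'
#' Response profiles span narrow (one strong ligand) to broad (many
#' ligands) tuning; when `config$kl_coupling` is negative, breadth is
#' coupled to the per-gene differentiation intensities so that strongly
#' differentiated receptor genes are broadly tuned (low lifetime kurtosis).
#'
#' @param config a [scenario_config].
#' @param receptor_genes character vector of receptor gene ids.
#' @param d_g optional named differentiation intensities per receptor gene
#'   (from the SNP generator truth); required when coupling is nonzero.
#' @param seed integer seed.
#' @return list: `responses` (matrix receptors x odorants), `truth`
#'   (breadth per receptor, coupling).
#' @export
generate_response_matrix <- function(config, receptor_genes, d_g = NULL,
                                     seed = 1) {
  with_seed(seed, {
    M <- config$n_odorants
    cpl <- abs(config$kl_coupling)
    nr <- length(receptor_genes)
    if (cpl > 0) {
      stopifnot(!is.null(d_g))
      u <- rank(d_g[receptor_genes]) / nr
      lat <- cpl * u + (1 - cpl) * runif(nr)
    } else {
      lat <- runif(nr)
    }
    breadth <- pmax(1L, pmin(M - 1L, round(1 + lat * (M * 0.6))))
    resp <- t(vapply(seq_len(nr), function(i) {
      r <- abs(rnorm(M, 0, 0.03))
      on <- sample(M, breadth[i])
      r[on] <- rnorm(breadth[i], 1, 0.1)
      r
    }, numeric(M)))
    rownames(resp) <- receptor_genes
    colnames(resp) <- sprintf("odorant%02d", seq_len(M))
    list(responses = resp,
         truth = list(breadth = setNames(breadth, receptor_genes),
                      coupling = config$kl_coupling))
  })
}

#' Generate the complete synthetic dataset
#'
#' Orchestrates genome, SNPs, divergence, CNV/indel and response-matrix
#' generation under a single master seed and assembles the truth sidecar.
#'
#' @param config a [scenario_config].
#' @param seed master integer seed.
#' @return list of class `famsel_dataset`: `annotation`, `snps` (list from
#'   [generate_population_snps()]), `divergence`, `cnv`, `responses`,
#'   `truth`, `config`.
#' @export
generate_dataset <- function(config = scenario_config(), seed = 1) {
  seeds <- derive_seeds(seed, 5)
  ann <- generate_genome(config, seed = seeds[[1]])
  snps <- generate_population_snps(config, ann, seed = seeds[[2]])
  divr <- generate_divergence(config, ann, seed = seeds[[3]])
  cnv <- generate_cnv_indel_set(config, ann, seed = seeds[[4]])
  receptor_fam <- names(config$families)[1]
  rgenes <- ann$genes$gene[ann$genes$family == receptor_fam]
  d_g <- snps$truth$inflation_per_gene
  resp <- generate_response_matrix(config, rgenes, d_g = d_g,
                                   seed = seeds[[5]])
  structure(list(annotation = ann, snps = snps, divergence = divr,
                 cnv = cnv, responses = resp,
                 truth = c(snps$truth, cnv["truth"],
                           list(divergence = divr$truth,
                                responses = resp$truth)),
                 config = config),
            class = "famsel_dataset")
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Emits the SNP VCF, gene/exon BED, family TSV, CNV TSV, indel TSV,
#' ancestral-posterior TSV, response-matrix TSV and a JSON truth sidecar.
#'
#' @param dataset a `famsel_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_snp_vcf(dataset$snps$genotypes, file.path(dir, "snps.vcf"))
  write_gene_bed(dataset$annotation, file.path(dir, "genes.bed"))
  g <- dataset$annotation$genes
  write.table(data.frame(gene = g$gene, family = g$family,
                         subgroup = g$subgroup,
                         large = g$family %in%
                           dataset$annotation$large_families),
              file.path(dir, "families.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(dataset$snps$genotypes$sites[, c("chrom", "pos")],
                         p_ref_ancestral = dataset$snps$anc_posterior),
              file.path(dir, "ancestral.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$snps$effects, file.path(dir, "effects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$cnv$cnvs, file.path(dir, "cnvs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$cnv$indels, file.path(dir, "indels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$divergence$counts, file.path(dir, "divergence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(receptor = rownames(dataset$responses$responses),
                         dataset$responses$responses),
              file.path(dir, "responses.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
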