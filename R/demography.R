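#' Construct a multi-population demographic model
#'
#' Describes the neutral null model used by the coalescent engine, in
#' ms-style scaled units: time in units of 4N0 generations, population sizes
#' relative to N0, migration entries M_ij = 4*N0*m_ij (per-lineage backward
#' rate of moving from deme i to deme j), and backward-time exponential
#' shrink rates for growth (size x(t) = x_ref * exp(-g * (t - t_ref))).
#'
#' Events happen backward in time and must be supplied sorted (they are
#' re-sorted defensively). Supported types: `"merge"` (all lineages of
#' population `i` move into `j`; `i` is retired), `"size"` (set relative size
#' of `i` to `value`, resetting growth), `"growth"` (set growth rate of `i`),
#' `"migration"` (set M\[i,j\] to `value`), `"migration_all"` (set every
#' off-diagonal entry among still-active populations). A multi-way polytomy
#' is expressed as several merge events sharing one time; they are applied
#' simultaneously in the deterministic order given.
#'
#' @param populations character vector of population labels.
#' @param sample_sizes integer haploid sample sizes, one per population.
#' @param sizes relative present-day population sizes (default all 1).
#' @param growth backward exponential shrink rates (default 0).
#' @param migration square matrix of scaled migration rates (default 0).
#' @param events data frame with columns `time`, `type`, `i`, `j`, `value`
#'   (`i`, `j` are population labels or indices; unused fields may be NA).
#' @param chrom_scale scaling factor applied to every population size,
#'   e.g. 3/4 for X-linked loci; default 1 (autosomes).
#' @return an object of class `demography_model`.
#' @export
#' @examples
#' m <- demography_model("pop1", 10)
#' m2 <- demography_model(c("A", "B"), c(5, 5),
#'   events = data.frame(time = 0.5, type = "merge", i = "A", j = "B",
#'                       value = NA))
demography_model <- function(populations, sample_sizes,
                             sizes = rep(1, length(populations)),
                             growth = rep(0, length(populations)),
                             migration = matrix(0, length(populations),
                                                length(populations)),
                             events = NULL, chrom_scale = 1) {
  npop <- length(populations)
  stopifnot(length(sample_sizes) == npop, length(sizes) == npop,
            length(growth) == npop, all(sample_sizes >= 0),
            all(sizes > 0), chrom_scale > 0)
  migration <- as.matrix(migration)
  stopifnot(nrow(migration) == npop, ncol(migration) == npop,
            all(migration >= 0))
  diag(migration) <- 0
  ev <- normalize_events(events, populations)
  if (any(ev$time < 0)) stop("event times must be non-negative")
  structure(list(populations = as.character(populations),
                 sample_sizes = as.integer(sample_sizes),
                 sizes = as.numeric(sizes) * chrom_scale,
                 growth = as.numeric(growth),
                 migration = migration, events = ev,
                 chrom_scale = chrom_scale),
            class = "demography_model")
}

normalize_events <- function(events, populations) {
  if (is.null(events) || nrow(events) == 0) {
    return(data.frame(time = numeric(0), type = integer(0), i = integer(0),
                      j = integer(0), value = numeric(0)))
  }
  type_codes <- c(merge = 1L, size = 2L, growth = 3L, migration = 4L,
                  migration_all = 5L)
  tp <- events$type
  if (is.character(tp) || is.factor(tp)) {
    tp <- type_codes[as.character(tp)]
    if (anyNA(tp)) stop("unknown event type; use one of: ",
                        paste(names(type_codes), collapse = ", "))
  }
  as_idx <- function(x) {
    if (is.character(x) || is.factor(x)) {
      ix <- match(as.character(x), populations)
      ix[is.na(x)] <- 1L
      if (anyNA(ix)) stop("event references unknown population")
      ix
    } else {
      x[is.na(x)] <- 1L
      as.integer(x)
    }
  }
  ev <- data.frame(time = as.numeric(events$time), type = as.integer(tp),
                   i = as_idx(events$i),
                   j = as_idx(if ("j" %in% names(events)) events$j else NA),
                   value = as.numeric(if ("value" %in% names(events))
                     events$value else NA))
  ev$value[is.na(ev$value)] <- 0
  ev[order(ev$time), , drop = FALSE]
}

#' @export
print.demography_model <- function(x, ...) {
  cat("Demographic model:", length(x$populations), "population(s)\n")
  cat("  samples:", paste0(x$populations, "=", x$sample_sizes,
                           collapse = ", "), "\n")
  cat("  events:", nrow(x$events), " chrom_scale:", x$chrom_scale, "\n")
  invisible(x)
}

# verify every sampled population can reach a common ancestor through
# merges or nonzero migration; returns isolated components or NULL
check_coalescible <- function(model) {
  npop <- length(model$populations)
  adj <- (model$migration > 0) | t(model$migration > 0)
  ev <- model$events
  for (r in seq_len(nrow(ev))) {
    if (ev$type[r] == 1L) adj[ev$i[r], ev$j[r]] <- adj[ev$j[r], ev$i[r]] <- TRUE
    if (ev$type[r] == 4L && ev$value[r] > 0)
      adj[ev$i[r], ev$j[r]] <- adj[ev$j[r], ev$i[r]] <- TRUE
    if (ev$type[r] == 5L && ev$value[r] > 0) adj[, ] <- TRUE
  }
  comp <- seq_len(npop)
  repeat {
    new <- comp
    for (i in seq_len(npop)) for (j in seq_len(npop))
      if (adj[i, j]) new[j] <- min(new[j], new[i])
    if (identical(new, comp)) break
    comp <- new
  }
  sampled <- which(model$sample_sizes > 0)
  if (length(unique(comp[sampled])) > 1) {
    split(model$populations[sampled], comp[sampled])
  } else NULL
}

#' Built-in demographic presets for a five-population diversity panel
#'
#' Three editable neutral null models for a panel of five populations
#' (Beijing, Ithaca, Netherlands, Tasmania, Zimbabwe; 15/19/19/18/13 lines)
#' with an African ancestral range: a forced polytomy joins the short
#' terminal branches of the Netherlands, Ithaca and Tasmania populations,
#' and the bottleneck-with-growth model allows migration between the African
#' branch and the ancestral out-of-Africa branch. Parameter values are
#' package defaults intended to be overridden for any particular dataset.
#'
#' @param name one of `"constant"`, `"bottleneck"`, `"bottleneck_growth"`.
#' @param sample_sizes haploid line counts per population, named
#'   B/I/N/T/Z order; defaults to the panel design.
#' @param chrom_scale population-size multiplier (3/4 for X-linked loci).
#' @return a [demography_model].
#' @export
#' @examples
#' demography_preset("bottleneck")
demography_preset <- function(name = c("constant", "bottleneck",
                                       "bottleneck_growth"),
                              sample_sizes = c(B = 15, I = 19, N = 19,
                                               T = 18, Z = 13),
                              chrom_scale = 1) {
  name <- match.arg(name)
  pops <- c("B", "I", "N", "T", "Z")
  stopifnot(length(sample_sizes) == 5)
  # backward-time topology: polytomy (N,T -> I) at t1, OOA split (I -> B)
  # at t2, out-of-Africa origin (B -> Z) at t3
  t1 <- 0.02; t2 <- 0.06; t3 <- 0.15
  merges <- data.frame(
    time = c(t1, t1, t2, t3),
    type = "merge",
    i = c("N", "T", "I", "B"),
    j = c("I", "I", "B", "Z"),
    value = NA)
  if (name == "constant") {
    ev <- merges
    sizes <- rep(1, 5); growth <- rep(0, 5)
    mig <- matrix(0, 5, 5)
  } else if (name == "bottleneck") {
    # out-of-Africa ancestor passes through a 10x bottleneck on [t2, t3]
    ev <- rbind(merges,
                data.frame(time = t2, type = "size", i = "B", j = NA,
                           value = 0.1),
                data.frame(time = t3, type = "size", i = "Z", j = NA,
                           value = 1))
    sizes <- c(1, 1, 1, 1, 1); growth <- rep(0, 5)
    mig <- matrix(0, 5, 5)
  } else {
    # bottleneck followed by growth in the derived populations, plus
    # symmetric migration between Africa and the ancestral OOA branch
    sizes <- c(2, 2, 2, 2, 1)
    growth <- c(rep(log(2 / 0.5) / t1, 4), 0)  # shrink back to 0.5 by t1
    mig <- matrix(0, 5, 5)
    ev <- rbind(merges,
                data.frame(time = t1, type = "growth", i = c("I", "B"),
                           j = NA, value = 0),
                data.frame(time = t2, type = "size", i = "B", j = NA,
                           value = 0.1),
                data.frame(time = t2, type = "migration", i = "B", j = "Z",
                           value = 0.5),
                data.frame(time = t2, type = "migration", i = "Z", j = "B",
                           value = 0.5),
                data.frame(time = t3, type = "size", i = "Z", j = NA,
                           value = 1))
  }
  ev$value[ev$type == "size"] <- ev$value[ev$type == "size"] * chrom_scale
  demography_model(pops, sample_sizes, sizes = sizes, growth = growth,
                   migration = mig, events = ev, chrom_scale = chrom_scale)
}
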