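## Synthetic data generation: diploid cohorts under Hardy-Weinberg
## pairing, noisy peak observations through the assay forward model, and
## aligned sequence triplets with planted recombination breakpoints.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a diploid cohort
#'
#' Draws haplotypes i.i.d. from a frequency table and pairs them at
#' random (Hardy-Weinberg).
#'
#' @param n Number of individuals.
#' @param frequencies Named numeric vector of haplotype frequencies
#'   (default: the packaged catalog frequencies).
#' @param catalog Catalog the haplotype names must belong to.
#' @param seed Integer seed (reproducible draws; RNG state is restored).
#' @return data.frame with columns `sample_id`, `hap1`, `hap2`.
#' @export
sample_cohort <- function(n, frequencies = NULL, catalog = kir_catalog(),
                          seed = NULL) {
  if (is.null(frequencies))
    frequencies <- stats::setNames(catalog$frequency, catalog$name)
  unknown <- setdiff(names(frequencies), catalog$name)
  if (length(unknown))
    stop("frequency table references unknown haplotype(s): ",
         paste(unknown, collapse = ", "))
  if (abs(sum(frequencies) - 1) > 1e-6)
    stop("frequencies must sum to 1")
  with_seed(seed, {
    draws <- sample(names(frequencies), 2L * n, replace = TRUE,
                    prob = frequencies)
    data.frame(sample_id = sprintf("S%05d", seq_len(n)),
               hap1 = draws[seq_len(n)],
               hap2 = draws[n + seq_len(n)],
               stringsAsFactors = FALSE)
  })
}

#' Simulate peak observations for one diplotype
#'
#' Applies the noiseless forward model ([expected_peaks()]) and then a
#' per-assay gain and multiplicative lognormal peak noise.
#'
#' @param hap1,hap2 Haplotype names (in `catalog`).
#' @param sample_id Sample identifier for the output rows.
#' @param assay_defs `kir_assays` bundle.
#' @param catalog `kir_catalog`.
#' @param sigma Lognormal noise sigma on heights (0 = exact forward
#'   model; default 0.1, dye-terminator peak variability is
#'   scale-proportional).
#' @param gain_range Per-assay gain drawn uniformly from this range
#'   (times `base_gain`); ratios within an assay are gain-invariant.
#' @param base_gain Height of a single copy at gain 1.
#' @param seed Integer seed.
#' @return data.frame (sample_id, assay, position, base, height).
#' @export
simulate_peaks <- function(hap1, hap2, sample_id = "S1",
                           assay_defs = kir_assays(),
                           catalog = kir_catalog(), sigma = 0.1,
                           gain_range = c(0.5, 2), base_gain = 1000,
                           seed = NULL) {
  d <- diplotype_vector(catalog_haplotype(catalog, hap1),
                        catalog_haplotype(catalog, hap2))
  pk <- expected_peaks(d, assay_defs, gain = 1)
  with_seed(seed, {
    gains <- stats::setNames(
      stats::runif(length(unique(pk$assay)), gain_range[1L], gain_range[2L]) *
        base_gain,
      unique(pk$assay))
    h <- pk$height * gains[pk$assay]
    if (sigma > 0) h <- h * stats::rlnorm(length(h), 0, sigma)
    data.frame(sample_id = sample_id, assay = pk$assay,
               position = pk$position, base = pk$base, height = h,
               stringsAsFactors = FALSE)
  })
}

#' Simulate peak observations for a whole cohort
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param ... Passed to [simulate_peaks()].
#' @param seed Integer seed (one stream for the whole cohort).
#' @return data.frame of stacked peak observations.
#' @export
simulate_cohort_peaks <- function(cohort, ..., seed = NULL) {
  with_seed(seed, {
    out <- lapply(seq_len(nrow(cohort)), function(i)
      simulate_peaks(cohort$hap1[i], cohort$hap2[i],
                     sample_id = cohort$sample_id[i], ...))
    do.call(rbind, out)
  })
}

#' Simulate an aligned triplet with planted breakpoints
#'
#' Generates two parent sequences at a given divergence and a query that
#' copies parent A left of the first breakpoint, switching parent at
#' each successive breakpoint; optional query-private substitutions add
#' realistic mismatch noise.
#'
#' @param length Alignment length in columns.
#' @param divergence Substitution rate between the parents (in (0, 1)).
#' @param breakpoints Integer vector of 0-based crossover columns
#'   (strictly inside the alignment); empty for a non-recombinant query.
#' @param query_divergence Query-private substitution rate.
#' @param seed Integer seed.
#' @return Object of class `kir_triplet`: list with `query`, `parent_a`,
#'   `parent_b` (character vectors of bases), `names`, `length`, `truth`
#'   (planted breakpoints and rates).
#' @export
simulate_triplet <- function(length = 5000, divergence = 0.05,
                             breakpoints = 2500, query_divergence = 0.005,
                             seed = NULL) {
  if (divergence <= 0 || divergence >= 1)
    stop("divergence must lie strictly inside (0, 1)")
  breakpoints <- sort(as.integer(breakpoints))
  if (base::length(breakpoints) &&
      (min(breakpoints) <= 0L || max(breakpoints) >= length))
    stop("breakpoints must lie strictly inside the alignment")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    pa <- sample(bases, length, replace = TRUE)
    pb <- pa
    mut <- stats::runif(length) < divergence
    pb[mut] <- vapply(pa[mut], function(b)
      sample(setdiff(bases, b), 1L), "")
    seg <- findInterval(seq_len(length) - 1L, breakpoints)  # 0-based cols
    q <- ifelse(seg %% 2L == 0L, pa, pb)
    if (query_divergence > 0) {
      qm <- stats::runif(length) < query_divergence
      q[qm] <- vapply(q[qm], function(b) sample(setdiff(bases, b), 1L), "")
    }
    structure(list(query = q, parent_a = pa, parent_b = pb,
                   names = c("query", "parentA", "parentB"),
                   length = length,
                   truth = list(breakpoints = breakpoints,
                                divergence = divergence,
                                query_divergence = query_divergence)),
              class = "kir_triplet")
  })
}
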