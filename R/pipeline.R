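## End-to-end workflow: simulate (or load) a cohort, call genotypes from
## peaks, resolve diplotypes, estimate frequencies.

#' Genotype a cohort of peak observations
#'
#' Splits a peak table by sample and integrates each sample's assays.
#'
#' @param peaks data.frame (sample_id, assay, position, base, height).
#' @param assay_defs,catalog,... Passed to [integrate_assays()].
#' @return Named list of `kir_genotype` objects.
#' @export
genotype_cohort <- function(peaks, assay_defs = kir_assays(),
                            catalog = kir_catalog(), ...) {
  out <- lapply(split(peaks, peaks$sample_id), function(p)
    integrate_assays(p, assay_defs, catalog, ...))
  out[unique(peaks$sample_id)]
}

#' Simulate-genotype-resolve-estimate pipeline
#'
#' Draws a diploid cohort at the given haplotype frequencies, simulates
#' peak observations, integrates them into copy-number calls, resolves
#' catalog pair sets and estimates haplotype frequencies by EM.  With
#' `sigma = 0` (noiseless peaks) identical diplotypes yield identical
#' observations, so each distinct diplotype is genotyped once.
#'
#' @param n Number of individuals.
#' @param seed Integer seed for all randomness.
#' @param frequencies Named haplotype frequencies (default packaged).
#' @param sigma Peak noise sigma (default 0: noiseless).
#' @param catalog,assay_defs Reference bundles.
#' @param em_tol,em_max_iter EM controls.
#' @return List with `cohort`, `pair_sets`, `resolutions` (statuses),
#'   `estimate` (`kir_freq_estimate`), `summary` (motif table),
#'   `n_excluded`.
#' @export
kir_pipeline <- function(n, seed, frequencies = NULL, sigma = 0,
                         catalog = kir_catalog(),
                         assay_defs = kir_assays(), em_tol = 1e-8,
                         em_max_iter = 1000L) {
  cohort <- sample_cohort(n, frequencies, catalog, seed = seed)
  key <- function(h1, h2) paste(pmin(h1, h2), pmax(h1, h2), sep = "~")
  ck <- key(cohort$hap1, cohort$hap2)
  if (sigma == 0) {
    uk <- unique(ck)
    per_dip <- lapply(uk, function(k) {
      hp <- strsplit(k, "~", fixed = TRUE)[[1L]]
      pk <- simulate_peaks(hp[1L], hp[2L], sample_id = "U",
                           assay_defs = assay_defs, catalog = catalog,
                           sigma = 0)
      g <- integrate_assays(pk, assay_defs, catalog)
      list(genotype = g, pairs = enumerate_pairs(g, catalog))
    })
    names(per_dip) <- uk
    pair_sets <- lapply(ck, function(k) per_dip[[k]]$pairs)
    statuses <- vapply(ck, function(k) {
      np <- nrow(per_dip[[k]]$pairs)
      if (np == 1L) "unambiguous" else if (np > 1L) "ambiguous" else "unresolved"
    }, "")
  } else {
    peaks <- simulate_cohort_peaks(cohort, assay_defs = assay_defs,
                                   catalog = catalog, sigma = sigma,
                                   seed = seed + 1L)
    genos <- genotype_cohort(peaks, assay_defs, catalog)
    pair_sets <- lapply(genos, function(g)
      if (is.null(g$copies)) data.frame(hap1 = character(),
                                        hap2 = character()) else
        enumerate_pairs(g, catalog))
    statuses <- vapply(pair_sets, function(p)
      if (nrow(p) == 1L) "unambiguous" else if (nrow(p) > 1L) "ambiguous"
      else "unresolved", "")
  }
  est <- em_frequencies(pair_sets, catalog, tol = em_tol,
                        max_iter = em_max_iter)
  list(cohort = cohort, pair_sets = pair_sets, resolutions = statuses,
       estimate = est, summary = motif_summary(est, catalog),
       n_excluded = est$n_excluded)
}
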