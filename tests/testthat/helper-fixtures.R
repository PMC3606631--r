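## Shared fixtures: the packaged reference bundles, loaded once.

CAT <- kir_catalog()
AD <- kir_assays()

## diploid copy vector of a named catalog pair
dip <- function(h1, h2, catalog = CAT)
  diplotype_vector(catalog_haplotype(catalog, h1),
                   catalog_haplotype(catalog, h2))

## noiseless peaks -> genotype call for a named pair
noiseless_call <- function(h1, h2)
  integrate_assays(simulate_peaks(h1, h2, assay_defs = AD, catalog = CAT,
                                  sigma = 0),
                   AD, CAT)

## brute-force pair enumeration oracle: direct double loop over the
## catalog, independent of the package's pair table machinery
oracle_pairs <- function(v, catalog = CAT) {
  m <- catalog_matrix(catalog)
  out <- list()
  for (i in seq_len(nrow(m))) for (j in i:nrow(m)) {
    if (all(m[i, ] + m[j, ] == v[colnames(m)]))
      out[[length(out) + 1L]] <- sort(c(rownames(m)[i], rownames(m)[j]))
  }
  out
}
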