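## Population genetics: EM haplotype-frequency estimation from unphased
## genotypes, motif-level aggregation, and pairwise gene-content LD.

#' EM haplotype frequency estimation
#'
#' Maximum-likelihood haplotype frequencies from a cohort of unphased
#' genotypes.  Each genotype contributes a likelihood
#' sum over its consistent haplotype pairs (h1, h2) of
#' f(h1) f(h2) (x2 when h1 != h2); the EM iteration alternates a
#' posterior allocation of each genotype over its pairs (E) with
#' chromosome-count re-estimation (M).  Initialisation is uniform over
#' the catalog.
#'
#' @param pair_sets List with one element per individual: a data.frame
#'   with columns `hap1`, `hap2` of catalog pairs consistent with that
#'   individual (as from [enumerate_pairs()]).  Individuals with zero
#'   pairs are excluded and counted.
#' @param catalog `kir_catalog`.
#' @param tol Convergence threshold on the log-likelihood increment.
#' @param max_iter Maximum EM iterations.
#' @return Object of class `kir_freq_estimate`: list with `frequencies`
#'   (named, sums to 1), `loglik_trace`, `n_individuals`,
#'   `n_chromosomes`, `n_excluded`, `converged`.
#' @export
em_frequencies <- function(pair_sets, catalog = kir_catalog(), tol = 1e-8,
                           max_iter = 1000L) {
  if (!length(pair_sets)) stop("empty cohort")
  sizes <- vapply(pair_sets, nrow, 0L)
  n_excluded <- sum(sizes == 0L)
  pair_sets <- pair_sets[sizes > 0L]
  if (!length(pair_sets))
    stop("no genotype in the cohort is consistent with any catalog pair")
  nm <- catalog$name
  ## collapse identical pair patterns (huge speedup on large cohorts)
  keys <- vapply(pair_sets, function(p)
    paste(sort(paste(p$hap1, p$hap2)), collapse = ";"), "")
  tab <- table(keys)
  uniq <- pair_sets[match(names(tab), keys)]
  w <- as.numeric(tab)
  i_idx <- lapply(uniq, function(p) match(p$hap1, nm))
  j_idx <- lapply(uniq, function(p) match(p$hap2, nm))
  mult <- lapply(seq_along(uniq), function(k)
    ifelse(i_idx[[k]] == j_idx[[k]], 1, 2))
  n <- sum(w)
  f <- stats::setNames(rep(1 / length(nm), length(nm)), nm)
  trace <- numeric()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    counts <- numeric(length(nm))
    ll <- 0
    for (k in seq_along(uniq)) {
      pk <- f[i_idx[[k]]] * f[j_idx[[k]]] * mult[[k]]
      lik <- sum(pk)
      ll <- ll + w[k] * log(lik)
      post <- pk / lik
      inc <- w[k] * post
      agg <- tapply(c(inc, inc), c(i_idx[[k]], j_idx[[k]]), sum)
      ai <- as.integer(names(agg))
      counts[ai] <- counts[ai] + as.numeric(agg)
    }
    f_new <- counts / (2 * n)
    trace <- c(trace, ll)
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) {
      converged <- TRUE
      f <- stats::setNames(f_new, nm)
      break
    }
    f <- stats::setNames(f_new, nm)
  }
  structure(list(frequencies = f / sum(f), loglik_trace = trace,
                 n_individuals = n, n_chromosomes = 2L * as.integer(n),
                 n_excluded = n_excluded, converged = converged),
            class = "kir_freq_estimate")
}

#' @export
print.kir_freq_estimate <- function(x, ...) {
  cat("KIR haplotype frequency estimate:", x$n_chromosomes, "chromosomes,",
      length(x$loglik_trace), "EM iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  top <- sort(x$frequencies, decreasing = TRUE)
  top <- top[top > 0.001]
  print(round(top, 4))
  invisible(x)
}

## submotifs that disrupt the telomeric half / 3DP1-2DL4 boundary block
TEL_ALTERING <- c("del5", "del6", "del7", "del8", "ins3", "ins4", "ins5",
                  "hybd1")

#' Motif-level frequency summary
#'
#' Aggregates haplotype frequencies into the motif table layout: major
#' centromeric and telomeric motif rows (chromosomes whose respective
#' half is unaltered by any submotif), one row per submotif (haplotypes
#' carrying exactly that submotif), and a combined row for haplotypes
#' carrying two or more submotifs.
#'
#' @param estimate `kir_freq_estimate` (or named frequency vector over
#'   catalog names).
#' @param catalog `kir_catalog`.
#' @return data.frame with columns `category`, `name`, `frequency`,
#'   `percent`.
#' @export
motif_summary <- function(estimate, catalog = kir_catalog()) {
  f <- if (inherits(estimate, "kir_freq_estimate")) estimate$frequencies
       else estimate
  f <- f[catalog$name]
  f[is.na(f)] <- 0
  subs <- lapply(catalog$name, function(n) parse_hap_name(n)$submotifs)
  nsub <- lengths(subs)
  cen <- catalog$cen_motif
  tel <- catalog$tel_motif
  rows <- list()
  add <- function(category, name, freq)
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, name = name, frequency = freq,
      percent = 100 * freq, stringsAsFactors = FALSE)
  for (cm in c("cA01", "cB01", "cB02"))
    add("centromere", cm, sum(f[cen == cm & nsub == 0L]))
  ## a chromosome counts in a telomeric major row when its telomeric
  ## half is unaltered (cen-only submotifs do not remove it)
  for (tm in c("tA01", "tB01")) {
    intact <- tel == tm & !vapply(subs, function(s)
      any(s %in% TEL_ALTERING), NA)
    add("telomere", tm, sum(f[intact]))
  }
  add("submotif", "cB03", sum(f[cen == "cB03" & nsub == 0L]))
  for (s in c("del3", "del4", "del9", "del10", "hybd1", "del5", "del6",
              "del7", "del8", "ins3", "ins4", "ins5"))
    add("submotif", s, sum(f[vapply(subs, function(x)
      identical(x, s), NA)]))
  add("submotif", "combined", sum(f[nsub >= 2L]))
  do.call(rbind, rows)
}

#' Summed frequency of haplotypes carrying a submotif
#'
#' Counts every haplotype whose submotif list contains the rule (the
#' cB03 motif counts as carrying the cB03 insertion), including
#' combined-submotif haplotypes.
#'
#' @param estimate `kir_freq_estimate` or named frequency vector.
#' @param submotif Rule name (e.g. `"del6"`), or several.
#' @param catalog `kir_catalog`.
#' @return Summed frequency (fraction).
#' @export
submotif_frequency <- function(estimate, submotif,
                               catalog = kir_catalog()) {
  f <- if (inherits(estimate, "kir_freq_estimate")) estimate$frequencies
       else estimate
  f <- f[catalog$name]
  f[is.na(f)] <- 0
  carries <- vapply(catalog$name, function(n) {
    rep <- normalize_rep(n)
    any(submotif %in% rep$subs)
  }, NA)
  sum(f[carries])
}

#' Pairwise gene-content linkage disequilibrium
#'
#' Tabulates presence/absence (copy count >= 1) of each gene pair across
#' haplotypes into a frequency-weighted 2x2 table and computes
#' D' = D / Dmax and r-squared.  Monomorphic genes are masked as
#' undefined.
#'
#' @param catalog `kir_catalog` (its `frequency` column supplies the
#'   weights), or a subset of its rows.
#' @param weighted If FALSE each haplotype counts once (sequence-panel
#'   weighting) instead of by population frequency.
#' @param loci Loci to compare (default all catalog-level loci).
#' @return Object of class `kir_ld`: list with `genes`, `dprime`, `rsq`
#'   (symmetric matrices, NA where undefined), `presence_freq`.
#' @export
ld_pairwise <- function(catalog = kir_catalog(), weighted = TRUE,
                        loci = KIR_LOCI_COLLAPSED) {
  if (nrow(catalog) < 2L) stop("need at least two haplotypes for LD")
  m <- catalog_matrix(catalog)[, loci, drop = FALSE] >= 1L
  wt <- if (weighted) catalog$frequency else rep(1, nrow(catalog))
  wt <- wt / sum(wt)
  p <- as.numeric(crossprod(m, wt))  # presence frequency per gene
  names(p) <- loci
  k <- length(loci)
  dprime <- rsq <- matrix(NA_real_, k, k, dimnames = list(loci, loci))
  poly <- p > 1e-12 & p < 1 - 1e-12
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (!poly[a] || !poly[b]) next
    pa <- p[a]; pb <- p[b]
    p11 <- sum(wt[m[, a] & m[, b]])
    D <- p11 - pa * pb
    dmax <- if (D >= 0) min(pa * (1 - pb), pb * (1 - pa)) else
      min(pa * pb, (1 - pa) * (1 - pb))
    dprime[a, b] <- if (dmax > 0) D / dmax else NA_real_
    rsq[a, b] <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  }
  structure(list(genes = loci, dprime = dprime, rsq = rsq,
                 presence_freq = p, weighted = weighted,
                 note = "no multiple-testing correction applied"),
            class = "kir_ld")
}

#' @export
print.kir_ld <- function(x, ...) {
  cat("KIR pairwise LD over", length(x$genes), "genes (",
      if (x$weighted) "frequency-weighted" else "unweighted", ")\n")
  cat("  polymorphic:", sum(!is.na(diag(x$rsq))), "genes\n")
  invisible(x)
}
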