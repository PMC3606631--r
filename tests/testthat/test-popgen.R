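pairs_of <- function(cohort) {
  lapply(seq_len(nrow(cohort)), function(i)
    enumerate_pairs(dip(cohort$hap1[i], cohort$hap2[i]), CAT))
}

test_that("EM degenerates correctly on a single-haplotype cohort", {
  ps <- replicate(100L, data.frame(hap1 = "cA01|tA01", hap2 = "cA01|tA01",
                                   stringsAsFactors = FALSE),
                  simplify = FALSE)
  est <- em_frequencies(ps, CAT)
  expect_equal(unname(est$frequencies["cA01|tA01"]), 1, tolerance = 1e-12)
  expect_true(est$converged)
})

test_that("EM equals direct chromosome counting on unambiguous cohorts", {
  ## a two-haplotype synthetic cohort where every genotype is phased by
  ## direct counting
  set.seed(5)
  coh <- sample_cohort(400L, c("cA01|tA01" = 0.65, "cB02|tB01" = 0.35),
                       CAT, seed = 5)
  ps <- lapply(seq_len(nrow(coh)), function(i)
    data.frame(hap1 = pmin(coh$hap1[i], coh$hap2[i]),
               hap2 = pmax(coh$hap1[i], coh$hap2[i]),
               stringsAsFactors = FALSE))
  est <- em_frequencies(ps, CAT)
  direct <- table(factor(c(coh$hap1, coh$hap2), levels = CAT$name)) / 800
  expect_equal(unname(est$frequencies), as.numeric(direct),
               tolerance = 1e-9)
})

test_that("EM log-likelihood is monotone and frequencies stay a simplex", {
  coh <- sample_cohort(300L, seed = 11)
  est <- em_frequencies(pairs_of(coh), CAT)
  expect_true(all(diff(est$loglik_trace) > -1e-9))
  expect_lt(abs(sum(est$frequencies) - 1), 1e-9)
  expect_true(all(est$frequencies >= 0))
})

test_that("EM recovers arbitrary frequency vectors within binomial error", {
  ## parameter recovery at n = 2,000 over random frequency vectors: the
  ## estimate must sit within 4 standard errors of the realised draw
  ## (pair-set ambiguity is integrated out by the EM)
  set.seed(202)
  for (rep in 1:4) {
    f <- stats::rgamma(37L, 0.5) ; f <- f / sum(f)
    names(f) <- CAT$name
    n <- 2000L
    coh <- sample_cohort(n, f, CAT, seed = 300 + rep)
    est <- em_frequencies(pairs_of(coh), CAT)
    ## haplotypes sharing one content vector (del7/del8) are only
    ## identifiable as a class; compare the identifiable class sums
    cls <- apply(catalog_matrix(CAT), 1L, paste, collapse = ",")
    fc <- tapply(f, cls, sum)
    ec <- tapply(est$frequencies, cls, sum)[names(fc)]
    se <- sqrt(pmax(fc * (1 - fc), 1e-6) / (2 * n))
    expect_true(all(abs(ec - fc) <= 4 * se + 0.012),
                info = paste("replicate", rep))
  }
})

test_that("motif summary reproduces the table layout", {
  ## all mass on the major A haplotype
  f <- stats::setNames(rep(0, 37L), CAT$name)
  f["cA01|tA01"] <- 1
  ms <- motif_summary(f, CAT)
  expect_equal(ms$percent[ms$name == "cA01"], 100)
  expect_equal(ms$percent[ms$name == "tA01"], 100)
  expect_true(all(ms$percent[ms$category == "submotif"] == 0))

  ## packaged frequencies: submotif mass sums to about 7 percent
  ms2 <- motif_summary(stats::setNames(CAT$frequency, CAT$name), CAT)
  sub_pct <- sum(ms2$percent[ms2$category == "submotif"])
  expect_identical(round(sub_pct), 7)

  ## additivity: splitting one haplotype's mass among duplicates of
  ## itself leaves the aggregation unchanged (frequencies are summed,
  ## never re-weighted per record)
  f3 <- stats::setNames(CAT$frequency, CAT$name)
  half <- f3 / 2
  expect_equal(motif_summary(f3, CAT)$frequency,
               motif_summary(half, CAT)$frequency * 2)
})

test_that("pairwise LD satisfies its bounds and exclusivity structure", {
  ## random frequency vectors: |D'| <= 1 and 0 <= r2 <= 1 everywhere
  set.seed(77)
  for (rep in 1:10) {
    w <- stats::rgamma(37L, 1); w <- w / sum(w)
    cc <- CAT; cc$frequency <- w
    ld <- ld_pairwise(cc)
    expect_true(all(abs(ld$dprime) <= 1 + 1e-9, na.rm = TRUE))
    expect_true(all(ld$rsq >= -1e-9 & ld$rsq <= 1 + 1e-9, na.rm = TRUE))
  }

  ## at the motif level 2DL3 and 2DS2 are mutually exclusive and jointly
  ## exhaustive: perfect (negative) association
  majors <- CAT[CAT$submotifs == "." & CAT$cen_motif != "cB03", ]
  class(majors) <- class(CAT)
  ld <- ld_pairwise(majors)
  expect_equal(abs(ld$dprime["2DL3", "2DS2"]), 1, tolerance = 1e-9)
  expect_equal(ld$rsq["2DL3", "2DS2"], 1, tolerance = 1e-9)

  ## monomorphic framework gene is masked
  expect_true(all(is.na(ld$dprime["3DL3", ])))

  ## closed-form r2 equals the squared weighted Pearson correlation of
  ## the presence indicators
  m <- catalog_matrix(CAT) >= 1L
  for (rep in 1:20) {
    w <- stats::rgamma(37L, 1); w <- w / sum(w)
    cc <- CAT; cc$frequency <- w
    ld <- ld_pairwise(cc)
    a <- m[, "2DL3"]; b <- m[, "2DL4"]
    wcor <- function(x, y, w) {
      mx <- sum(w * x); my <- sum(w * y)
      sum(w * (x - mx) * (y - my)) /
        sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
    }
    expect_equal(ld$rsq["2DL3", "2DL4"], wcor(a, b, w)^2, tolerance = 1e-9)
  }
})
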