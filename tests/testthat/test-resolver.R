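test_that("enumerate_pairs finds exactly the vector-consistent catalog pairs", {
  ## homozygote
  p <- enumerate_pairs(dip("cA01|tA01", "cA01|tA01"), CAT)
  expect_true(any(p$hap1 == "cA01|tA01" & p$hap2 == "cA01|tA01"))

  ## mixed genotype: mutually exclusive genes always land on different
  ## haplotypes in every returned pair
  p2 <- enumerate_pairs(dip("cA01|tA01", "cB02|tB01"), CAT)
  for (k in seq_len(nrow(p2))) {
    c1 <- catalog_haplotype(CAT, p2$hap1[k])$content
    c2 <- catalog_haplotype(CAT, p2$hap2[k])$content
    expect_false(c1[["2DL3"]] >= 1 && c1[["2DS2"]] >= 1)
    expect_false(c2[["2DL3"]] >= 1 && c2[["2DS2"]] >= 1)
  }

  ## soundness: every reported pair reproduces the genotype vector
  for (k in seq_len(nrow(p2)))
    expect_identical(dip(p2$hap1[k], p2$hap2[k]),
                     dip("cA01|tA01", "cB02|tB01"))
})

test_that("enumeration agrees with the brute-force oracle on random genotypes", {
  set.seed(99)
  for (rep in seq_len(60L)) {
    h <- sample(CAT$name, 2L, replace = TRUE)
    v <- dip(h[1L], h[2L])
    fast <- enumerate_pairs(v, CAT)
    slow <- oracle_pairs(v, CAT)
    expect_identical(nrow(fast), length(slow))
    expect_setequal(paste(fast$hap1, fast$hap2),
                    vapply(slow, paste, "", collapse = " "))
  }
})

test_that("resolution status and traces are deterministic", {
  g <- dip("cA01|tB01-del6", "cA01|tA01")
  r1 <- phase_with_rules(enumerate_pairs(g, CAT), g, CAT)
  r2 <- phase_with_rules(enumerate_pairs(g, CAT), g, CAT)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$rule_trace, r2$rule_trace)
  expect_identical(r1$status, "unambiguous")
  expect_identical(r1$chosen_pair, c("cA01|tA01", "cA01|tB01-del6"))

  ## empty pair list -> unresolved
  empty <- data.frame(hap1 = character(), hap2 = character())
  expect_identical(phase_with_rules(empty, g, CAT)$status, "unresolved")
})

test_that("2DL5-2DS35 placement audit reflects flanking gene support", {
  g <- dip("cB01|tA01", "cA01|tA01")  # centromeric block, 2DP1 = 2
  r <- phase_with_rules(enumerate_pairs(g, CAT), g, CAT)
  tr <- grep("rule-ii:", r$rule_trace, value = TRUE, fixed = TRUE)
  expect_true(length(tr) == 1L && grepl("cen=TRUE", tr))
  ## every surviving pair places the block centromerically (no 3DS1/2DS1)
  for (k in seq_len(nrow(r$pairs))) {
    for (h in c(r$pairs$hap1[k], r$pairs$hap2[k])) {
      cc <- catalog_haplotype(CAT, h)$content
      if (cc[["2DL5"]] >= 1L)
        expect_true(cc[["2DP1"]] >= 1L || cc[["2DL1"]] >= 1L, info = h)
    }
  }
})

test_that("novel inference reconstructs a removed haplotype at one edit", {
  ## leave-one-out over every single-submotif record (and the cB03
  ## motif): the removed structure must surface as the top candidate
  singles <- CAT$name[vapply(CAT$name, function(n) {
    r <- kirhap:::normalize_rep(n)
    length(r$subs) == 1L
  }, NA)]
  for (nm in singles) {
    cat36 <- CAT[CAT$name != nm, ]
    class(cat36) <- class(CAT)
    target <- catalog_haplotype(CAT, nm)$content
    gv <- target + catalog_haplotype(CAT, "cA01|tA01")$content
    if (nrow(enumerate_pairs(gv, cat36))) next  # still explainable
    nov <- infer_novel(gv, cat36, max_edits = 2L)
    expect_gt(nrow(nov), 0L)
    top <- nov[nov$edit_count == min(nov$edit_count), ]
    uni <- kirhap:::grammar_universe()
    keys <- vapply(uni, `[[`, "", "key")
    hit <- uni[[match(kirhap:::vector_key(target), keys)]]
    expect_true(any(top$edit_count == 1L), info = nm)
    ## at least one top candidate has exactly the removed content
    match_content <- vapply(seq_len(nrow(top)), function(i) {
      u <- uni[vapply(uni, function(x) {
        nmx <- paste0(x$cen, "|", x$tel,
                      if (length(x$subs)) paste0("-", paste(x$subs,
                                                            collapse = "-"))
                      else "")
        nmx == top$residual[i]
      }, NA)]
      length(u) > 0 && identical(u[[1L]]$content, target)
    }, NA)
    expect_true(any(match_content), info = nm)
  }
})

test_that("novel inference guards and framework screening work", {
  g <- dip("cA01|tA01", "cA01|tA01")
  expect_error(infer_novel(g, CAT), "refused")

  ## residual missing the 3DL2 framework end is rejected into diagnostics
  v <- dip("cA01|tA01", "cA01|tA01")
  v["3DL2"] <- 1L  # one chromosome would lack 3DL2 entirely
  v["2DS4"] <- 1L
  nov <- infer_novel(v, CAT)
  expect_identical(nrow(nov), 0L)
  expect_true(any(grepl("3DL2", attr(nov, "diagnostics"))))
})
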