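test_that("informative sites are classified and filtered correctly", {
  ## query identical to parent A: every informative site supports A
  tr <- simulate_triplet(2000L, 0.05, breakpoints = integer(),
                         query_divergence = 0, seed = 3)
  s <- informative_sites(tr)
  expect_true(nrow(s) > 0L)
  expect_true(all(s$supports == "A"))
  expect_true(all(diff(s$column) > 0L))

  ## three-way mismatches are excluded and counted
  tr$query[tr$parent_a != tr$parent_b][1:5] <- "N"
  tr2 <- tr
  cols <- which(tr2$parent_a != tr2$parent_b)[1:3]
  for (cl in cols) {
    other <- setdiff(c("A", "C", "G", "T"),
                     c(tr2$parent_a[cl], tr2$parent_b[cl]))
    tr2$query[cl] <- other[1L]
  }
  s2 <- informative_sites(tr2)
  expect_gte(attr(s2, "n_unresolved"), 3L)

  ## site count tracks the planted divergence (column-scan oracle)
  tr3 <- simulate_triplet(10000L, 0.08, breakpoints = integer(),
                          query_divergence = 0, seed = 9)
  manual <- sum(tr3$parent_a != tr3$parent_b)
  expect_identical(nrow(informative_sites(tr3)), manual)

  ## identical parents: explicit empty result with diagnostic
  tr4 <- list(query = rep("A", 100L), parent_a = rep("A", 100L),
              parent_b = rep("A", 100L), names = c("q", "a", "b"),
              length = 100L, truth = NULL)
  class(tr4) <- "kir_triplet"
  s4 <- informative_sites(tr4)
  expect_identical(nrow(s4), 0L)
  expect_match(attr(s4, "diagnostic"), "no informative sites")
})

test_that("scan_triplet finds a planted breakpoint and nothing in null data", {
  ## null: query equals parent A
  tr0 <- simulate_triplet(5000L, 0.05, breakpoints = integer(),
                          query_divergence = 0.005, seed = 21)
  expect_identical(nrow(scan_triplet(tr0)), 0L)

  ## planted crossover at column 2,500 recovered within the informative
  ## site spacing
  tr <- simulate_triplet(5000L, 0.05, breakpoints = 2500L, seed = 22)
  calls <- scan_triplet(tr)
  expect_identical(nrow(calls), 1L)
  sites <- informative_sites(tr)
  spacing <- stats::median(diff(sites$column))
  expect_lte(calls$start - spacing, 2500)
  expect_gte(calls$end + spacing, 2500)
  expect_lte(calls$p_adjusted, 0.001)

  ## two planted crossovers (gene-conversion-like tract): two ordered,
  ## non-overlapping calls
  tr2 <- simulate_triplet(9000L, 0.05, breakpoints = c(3000L, 6000L),
                          seed = 23)
  calls2 <- scan_triplet(tr2)
  expect_identical(nrow(calls2), 2L)
  expect_true(all(diff(calls2$start) > 0))
  expect_true(all(calls2$end[-nrow(calls2)] <= calls2$start[-1L]))

  ## documented defaults: 20-unit window, alpha 0.001, Bonferroni
  expect_identical(eval(formals(scan_triplet)$window), 20L)
  expect_identical(eval(formals(scan_triplet)$alpha), 0.001)

  ## window larger than the alignment is a parameter error
  expect_error(scan_triplet(tr, window = 5000L), "window")
})

test_that("identity profiles localise the parent switch", {
  tr <- simulate_triplet(5000L, 0.05, breakpoints = 2500L,
                         query_divergence = 0, seed = 31)
  ## identical reference scores 100 everywhere
  prof_self <- identity_profile(tr$query, list(self = tr$query),
                                window = 400L, step = 100L)
  expect_true(all(prof_self$self == 100))
  expect_identical(nrow(prof_self), 47L)  # (5000 - 400) / 100 + 1

  ## nearest reference switches from A to B within a window of the
  ## planted column
  prof <- identity_profile(tr, window = 400L, step = 100L)
  nearer_a <- prof$parentA >= prof$parentB
  switch_idx <- max(which(nearer_a[seq_len(sum(prof$start < 2500))]))
  switch_col <- prof$start[switch_idx]
  expect_lt(abs(switch_col - 2500), 800)

  ## gap columns are excluded; an all-gap window is masked
  q <- tr$query; q[1:500] <- "-"
  prof_gap <- identity_profile(q, list(a = tr$parent_a), window = 400L,
                               step = 100L)
  expect_true(is.na(prof_gap$a[1L]))
})

test_that("FASTA round trip preserves the triplet", {
  tr <- simulate_triplet(600L, 0.05, 300L, seed = 41)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_triplet_fasta(tr, tmp)
  tr2 <- read_triplet_fasta(tmp)
  expect_identical(tr2$query, tr$query)
  expect_identical(tr2$parent_a, tr$parent_a)
  expect_identical(tr2$parent_b, tr$parent_b)
  ## named-record override
  tr3 <- read_triplet_fasta(tmp, query = "parentA", parent_a = "query",
                            parent_b = "parentB")
  expect_identical(tr3$query, tr$parent_a)
})
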