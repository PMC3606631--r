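## Integration of peak observations across the 14 assays into a diploid
## gene copy-number call.
##
## Within one amplicon all peak heights share a single (unknown) gain, so
## the information content of an assay is the set of height ratios among
## its scored bases plus presence/absence of each base.  The solver
## enumerates, per assay, all integer copy configurations of the loci the
## assay interrogates that reproduce the observed ratios within
## tolerance, then intersects the per-assay solution sets on their shared
## loci.  Two structural facts close the remaining degrees of freedom:
## the framework anchor (every individual carries exactly two 3DL2 ends,
## free-standing or fused into a 3DL1/L2 hybrid) and, because within-assay
## ratios are scale-free, a final screen keeping only copy vectors
## expressible as the sum of two known haplotypes (the "haplotype
## structure rule set" step).  3DL3 is not interrogated by any assay and
## is fixed at 2; 3DP1 and 2DL4 are inserted and deleted as one block by
## every known rearrangement and are carried as a single block count.

SOLVER_COLS <- c("2DS2", "2DL2", "2DL3", "2DL5", "2DS3", "2DS5", "2DP1",
                 "2DL1", "BLK", "3DL1", "3DS1", "2DS1", "2DS4", "3DL2",
                 KIR_HYBRIDS)

solver_caps <- function() {
  caps <- stats::setNames(rep(4L, length(SOLVER_COLS)), SOLVER_COLS)
  caps[c("2DL5", "2DS3", "2DS5")] <- 6L
  caps
}

## target carrier matrix mapped onto solver columns (BLK = 3DP1 + 2DL4)
solver_matrix <- function(assay_defs) {
  M <- assay_defs$target_matrix
  S <- matrix(0L, nrow(M), length(SOLVER_COLS),
              dimnames = list(NULL, SOLVER_COLS))
  shared <- intersect(colnames(M), SOLVER_COLS)
  S[, shared] <- M[, shared]
  S[, "BLK"] <- M[, "3DP1"] + M[, "2DL4"]
  stopifnot(all(M[, "3DL3"] == 0L))
  S
}

## catalog pair-sum lookup: key -> rows of unordered haplotype pairs
catalog_pair_table <- function(catalog = kir_catalog()) {
  key <- digest_key(catalog)
  if (!is.null(.kirhap_cache$pairs) && identical(.kirhap_cache$pairs_key, key))
    return(.kirhap_cache$pairs)
  m <- catalog_matrix(catalog)
  n <- nrow(m)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  sums <- m[idx[, 1L], , drop = FALSE] + m[idx[, 2L], , drop = FALSE]
  tab <- data.frame(i = idx[, 1L], j = idx[, 2L],
                    key = apply(sums, 1L, paste, collapse = ","),
                    stringsAsFactors = FALSE)
  .kirhap_cache$pairs <- tab
  .kirhap_cache$pairs_key <- key
  tab
}

digest_key <- function(catalog) paste(catalog$name, collapse = "|")

vector_key <- function(v) paste(as.integer(v[KIR_VECTOR_COLS]), collapse = ",")

## solver solution (SOLVER_COLS) -> catalog-level collapsed vector
solver_to_collapsed <- function(x) {
  v <- empty_copy_vector()
  v["3DL3"] <- 2L
  v["2DS35"] <- x[["2DS3"]] + x[["2DS5"]]
  v["3DP1"] <- x[["BLK"]]
  v["2DL4"] <- x[["BLK"]]
  for (nm in setdiff(SOLVER_COLS, c("2DS3", "2DS5", "BLK")))
    v[nm] <- x[[nm]]
  v
}

#' Integrate peak observations into a diploid genotype call
#'
#' Combines presence calls and peak-height ratios from all 14 assays
#' into the diploid copy-number vector, requiring at least two
#' independent confirmation targets for every present locus and
#' recording (rather than silently resolving) any inconsistency.
#'
#' @param observations data.frame with columns `sample_id`, `assay`,
#'   `position`, `base`, `height` covering all scored targets of all 14
#'   assays for one sample.
#' @param assay_defs `kir_assays` bundle.
#' @param catalog `kir_catalog` used for the structural screen (within-
#'   amplicon ratios are scale-free; only copy vectors expressible as a
#'   sum of two known haplotypes are retained).
#' @param tolerance Log-space ratio tolerance (default 0.2).
#' @param detection_floor Presence floor as a fraction of the tallest
#'   peak at a position (default 0.05).
#' @param structural_screen Set FALSE to skip the known-haplotype screen
#'   (all ratio/presence-consistent vectors are then reported).
#' @return Object of class `kir_genotype`: list with `sample_id`,
#'   `copies` (collapsed catalog-level diploid vector), `copies_full`
#'   (2DS3/2DS5 split, 3DP1/2DL4 as block count), `evidence` (per-locus
#'   confirmation counts), `provisional` (present loci with < 2
#'   confirmations), `discordances`, `status`
#'   (`"ok"`, `"ambiguous"`, `"unresolved"`), `n_solutions`,
#'   `solutions` (alternate vectors when ambiguous).
#' @export
integrate_assays <- function(observations, assay_defs = kir_assays(),
                             catalog = kir_catalog(), tolerance = 0.2,
                             detection_floor = 0.05,
                             structural_screen = TRUE) {
  sid <- unique(observations$sample_id)
  if (length(sid) != 1L)
    stop("integrate_assays expects observations of exactly one sample")
  tg <- assay_defs$targets
  key_t <- paste(tg$assay, tg$position, tg$base)
  key_o <- paste(observations$assay, observations$position, observations$base)
  hit <- match(key_t, key_o)
  covered <- tapply(!is.na(hit), tg$assay, any)
  if (!all(covered)) {
    stop("sample ", sid, ": observations missing for assay(s) ",
         paste(names(covered)[!covered], collapse = ", "))
  }
  measured <- !is.na(hit)  # individual dropped targets are unconstrained
  h <- ifelse(measured, observations$height[hit], NA_real_)
  S <- solver_matrix(assay_defs)

  ## presence per target (floor relative to tallest peak at the position)
  grp <- paste(tg$assay, tg$position)
  gmax <- stats::ave(ifelse(measured, h, 0), grp, FUN = max)
  present <- measured & gmax > 0 & h >= detection_floor * gmax
  absent <- measured & !present

  ## absent target => every carrier locus has zero copies
  zeros <- colnames(S)[colSums(S[absent, , drop = FALSE]) > 0L]
  caps <- solver_caps()
  caps[zeros] <- 0L

  ## Per assay, enumerate integer copy configurations of the loci the
  ## assay sees, gate them on the root-mean-square log-ratio residual
  ## over all within-amplicon peak pairs (the gain cancels), and carry
  ## the residual forward; configurations are then intersected across
  ## assays and the best-fitting copy vector(s) selected by total
  ## residual.  The RMS gate is robust to per-pair noise in a way a hard
  ## per-pair cut is not.
  solve_once <- function(tol) {
    sol <- NULL  # data.frame of partial solutions with score columns
    scorecols <- character()
    for (a in unique(tg$assay)) {
      rows <- which(tg$assay == a & present)
      if (!length(rows)) next
      cols <- colnames(S)[colSums(S[rows, , drop = FALSE] != 0L) > 0L]
      cols <- cols[caps[cols] > 0L]
      if (!length(cols)) return(NULL)  # signal with no possible carrier
      Sa <- S[rows, cols, drop = FALSE]
      grid <- as.matrix(expand.grid(lapply(caps[cols], function(k) 0:k)))
      P <- grid %*% t(Sa)
      ok <- rowSums(P < 1L) == 0L  # every present target needs >= 1 copy
      if (!any(ok)) return(NULL)
      score <- numeric(sum(ok))
      if (length(rows) > 1L) {
        ## gain-profiled least-squares fit: within an amplicon only
        ## ratios are informative, so the per-assay gain (the mean log
        ## offset) is profiled out and the residual sum of squares of
        ## log heights against log predicted copies scores the fit
        d <- matrix(log(h[rows]), nrow = sum(ok), ncol = length(rows),
                    byrow = TRUE) - log(P[ok, , drop = FALSE])
        score <- rowSums((d - rowMeans(d))^2)
        ## absolute gate sized to the residual's n-1 degrees of freedom
        ## (plus slack), and a relative prune against the local best to
        ## keep the cross-assay join tractable
        keep <- score <= pmin((length(rows) + 1L) * tol^2,
                              min(score) + 2 * tol^2)
        if (!any(keep)) return(NULL)
        ok[ok] <- keep
        score <- score[keep]
      }
      local <- as.data.frame(grid[ok, , drop = FALSE])
      names(local) <- cols
      sc <- paste0(".score.", a)
      local[[sc]] <- score
      scorecols <- c(scorecols, sc)
      ## identical copy configurations have identical scores
      local <- unique(local)
      sol <- if (is.null(sol)) local else {
        shared <- intersect(names(sol), names(local))
        shared <- shared[!startsWith(shared, ".score.")]
        if (length(shared)) merge(sol, local, by = shared) else
          merge(sol, local, by = NULL)
      }
      if (!is.null(sol) && nrow(sol) == 0L) return(NULL)
      ## safety valve: truncate a pathological solution space by
      ## cumulative residual before it can grow combinatorially
      if (nrow(sol) > 200000L) {
        cum <- rowSums(sol[, intersect(names(sol), scorecols), drop = FALSE])
        sol <- sol[order(cum)[seq_len(30000L)], , drop = FALSE]
      }
    }
    if (is.null(sol)) sol <- data.frame(row.names = 1L)
    total <- if (length(scorecols))
      rowSums(sol[, scorecols, drop = FALSE]) else numeric(nrow(sol))
    sol <- sol[, setdiff(names(sol), scorecols), drop = FALSE]
    for (z in setdiff(SOLVER_COLS, names(sol))) sol[[z]] <- 0L
    sol <- sol[, SOLVER_COLS, drop = FALSE]
    sol$.total <- total
    ## framework anchor: two 3DL2 3' ends per individual
    sol <- sol[sol$`3DL2` + sol$`3DL1/L2` == 2L, , drop = FALSE]
    unique(sol)
  }

  discord <- character()
  tol_used <- tolerance
  ptab <- if (structural_screen) catalog_pair_table(catalog) else NULL
  sol <- NULL; vecs <- NULL; total <- NULL; screened <- FALSE
  ## widen the tolerance until some candidate matches a known haplotype
  ## pair (the "logically match with consistent pairs of known
  ## haplotypes" step); within-amplicon ratios are scale-free, so the
  ## screen - not the fit alone - anchors the copy scale
  for (f in c(1, 2, 3.4)) {
    cand <- solve_once(tolerance * f)
    if (is.null(cand) || nrow(cand) == 0L) next
    ctotal <- cand$.total
    cand$.total <- NULL
    cvecs <- lapply(seq_len(nrow(cand)), function(i)
      solver_to_collapsed(stats::setNames(as.integer(cand[i, ]), SOLVER_COLS)))
    if (structural_screen) {
      match_cat <- vapply(cvecs, function(v) vector_key(v) %in% ptab$key, NA)
      if (any(match_cat)) {
        if (!all(match_cat))
          discord <- c(discord, sprintf(
            "%d ratio-consistent vector(s) rejected by the known-haplotype screen",
            sum(!match_cat)))
        sol <- cand[match_cat, , drop = FALSE]
        vecs <- cvecs[match_cat]
        total <- ctotal[match_cat]
        screened <- TRUE
      } else {
        ## remember the best unscreened fit in case no widening helps
        if (is.null(sol)) { sol <- cand; vecs <- cvecs; total <- ctotal }
      }
    } else {
      sol <- cand; vecs <- cvecs; total <- ctotal; screened <- TRUE
    }
    if (screened) {
      tol_used <- tolerance * f
      if (f > 1) discord <- c(discord, sprintf(
        "ratio-tolerance widened to %.3f to reach a consistent solution",
        tol_used))
      break
    }
  }
  if (is.null(sol) || nrow(sol) == 0L)
    return(structure(list(sample_id = sid, copies = NULL, copies_full = NULL,
                          evidence = NULL, provisional = character(),
                          discordances = c(discord,
                            "no copy vector satisfies the concordant constraints"),
                          status = "unresolved", n_solutions = 0L,
                          solutions = list()),
                     class = "kir_genotype"))
  if (!screened)
    discord <- c(discord,
                 "no ratio-consistent vector matches a known haplotype pair")
  ## least-squares selection among the survivors; exact structural ties
  ## (identical predicted ratios) survive as genuine ambiguity
  best <- total <= min(total) + 1e-9
  vecs <- vecs[best]
  sol <- sol[best, , drop = FALSE]
  status <- "ok"
  if (length(vecs) > 1L) {
    status <- "ambiguous"
    discord <- c(discord, sprintf("%d copy vectors remain consistent",
                                  length(vecs)))
    ## order by population plausibility (frequency mass of the catalog
    ## pairs explaining each vector), then lexicographically
    ptab <- catalog_pair_table(catalog)
    f <- catalog$frequency
    mass <- vapply(vecs, function(v) {
      hit <- ptab[ptab$key == vector_key(v), , drop = FALSE]
      if (!nrow(hit)) return(0)
      sum(f[hit$i] * f[hit$j] * ifelse(hit$i == hit$j, 1, 2))
    }, 0)
    ord <- order(-mass, vapply(vecs, function(v) paste(v, collapse = ","), ""))
    vecs <- vecs[ord]
    sol <- sol[ord, , drop = FALSE]
  }

  ## evidence audit: confirmation targets are those whose carriers all
  ## belong to one locus unit (3DP1-2DL4 and 2DS3/2DS5 merged as units)
  canon_M <- assay_defs$target_matrix[, KIR_LOCI, drop = FALSE]
  evid <- stats::setNames(integer(length(KIR_LOCI)), KIR_LOCI)
  for (i in which(present)) {
    carriers <- KIR_LOCI[canon_M[i, ] > 0L]
    if (!length(carriers)) next
    units <- unique(vapply(carriers, function(g)
      if (g %in% c("3DP1", "2DL4")) "3DP1-2DL4" else
        if (g %in% c("2DS3", "2DS5")) "2DS35" else g, ""))
    if (length(units) == 1L) evid[carriers] <- evid[carriers] + 1L
  }
  full <- stats::setNames(as.integer(sol[1L, ]), SOLVER_COLS)
  copies <- vecs[[1L]]
  prov <- intersect(names(full)[full > 0L], KIR_LOCI)
  prov <- prov[evid[prov] < 2L]
  if (length(prov))
    discord <- c(discord, paste0("provisional presence (<2 confirmations): ",
                                 paste(prov, collapse = ", ")))
  structure(list(sample_id = sid, copies = copies, copies_full = full,
                 evidence = evid, provisional = prov,
                 discordances = discord, status = status,
                 n_solutions = length(vecs), solutions = vecs,
                 tolerance_used = tol_used),
            class = "kir_genotype")
}

#' @export
print.kir_genotype <- function(x, ...) {
  cat("KIR genotype call for sample", x$sample_id, "- status:", x$status, "\n")
  if (!is.null(x$copies)) {
    pres <- x$copies[x$copies > 0L]
    cat(" ", paste(sprintf("%s:%d", names(pres), pres), collapse = " "), "\n")
  }
  if (length(x$discordances))
    cat("  discordances:", paste(x$discordances, collapse = "; "), "\n")
  invisible(x)
}
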