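## Resolution of a diploid copy-number call into phased pairs of catalog
## haplotypes, and grammar-guided inference of novel haplotype structures
## when no catalog pair explains a genotype.

genotype_vectors <- function(genotype) {
  if (inherits(genotype, "kir_genotype")) {
    if (is.null(genotype$copies)) stop("genotype is unresolved (no copy vector)")
    if (length(genotype$solutions)) genotype$solutions else list(genotype$copies)
  } else {
    v <- collapse_2DS35(genotype)
    list(v)
  }
}

#' Enumerate catalog haplotype pairs consistent with a genotype
#'
#' Returns exactly the unordered catalog pairs whose diplotype vector
#' (2DS3/2DS5 collapsed) equals the genotype's copy vector, in
#' deterministic lexicographic order.  For a peak-ambiguous genotype
#' call carrying several consistent copy vectors, the union over its
#' candidate vectors is returned.
#'
#' @param genotype `kir_genotype` object or named diploid copy vector.
#' @param catalog `kir_catalog`.
#' @return data.frame with columns `hap1`, `hap2` (hap1 <= hap2
#'   lexicographically; zero rows if nothing matches).
#' @export
enumerate_pairs <- function(genotype, catalog = kir_catalog()) {
  vecs <- genotype_vectors(genotype)
  ptab <- catalog_pair_table(catalog)
  hits <- unique(do.call(rbind, lapply(vecs, function(v)
    ptab[ptab$key == vector_key(v), c("i", "j")])))
  if (is.null(hits) || !nrow(hits))
    return(data.frame(hap1 = character(), hap2 = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(hap1 = catalog$name[hits$i], hap2 = catalog$name[hits$j],
                    stringsAsFactors = FALSE)
  swap <- out$hap1 > out$hap2
  tmp <- out$hap1[swap]; out$hap1[swap] <- out$hap2[swap]; out$hap2[swap] <- tmp
  out[order(out$hap1, out$hap2), , drop = FALSE]
}

#' Apply the haplotype assignment rules to candidate pairs
#'
#' Audits each candidate pair against the assignment rules: placement of
#' the mobile 2DL5-2DS35 block from its flanking genes (centromeric
#' 2DP1-2DL1 versus telomeric 3DS1-2DS1), segregation of mutually
#' exclusive genes (2DL3 versus 2DS2-2DL2; 2DS1 versus 3DL1-2DS4) onto
#' different haplotypes, and the strong-LD block composition used as a
#' secondary check.  Pairs violating a hard rule are removed with a
#' trace entry, never silently.
#'
#' @param pairs data.frame from [enumerate_pairs()].
#' @param genotype The genotype the pairs were derived from.
#' @param catalog `kir_catalog`.
#' @return Object of class `kir_resolution`: list with `sample_id`,
#'   `pairs`, `status` (`"unambiguous"`, `"ambiguous"`, `"unresolved"`),
#'   `chosen_pair` (only when unambiguous) and `rule_trace`.
#' @export
phase_with_rules <- function(pairs, genotype, catalog = kir_catalog()) {
  sid <- if (inherits(genotype, "kir_genotype")) genotype$sample_id else NA_character_
  trace <- character()
  gv <- genotype_vectors(genotype)[[1L]]
  keep <- rep(TRUE, nrow(pairs))
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      r1 <- catalog_haplotype(catalog, pairs$hap1[k])$content
      r2 <- catalog_haplotype(catalog, pairs$hap2[k])$content
      ## rule (iii): segregated gene pairs on different haplotypes
      seg <- list(c("2DL3", "2DS2"), c("2DS1", "2DS4"))
      for (s in seg) {
        if (gv[s[1L]] >= 1L && gv[s[2L]] >= 1L &&
            ((r1[s[1L]] >= 1L && r1[s[2L]] >= 1L) ||
             (r2[s[1L]] >= 1L && r2[s[2L]] >= 1L))) {
          keep[k] <- FALSE
          trace <- c(trace, sprintf(
            "rule-iii: pair (%s, %s) removed - %s and %s co-reside",
            pairs$hap1[k], pairs$hap2[k], s[1L], s[2L]))
        }
      }
    }
    if (any(keep)) {
      trace <- c(trace,
        "rule-iii: 2DL3 vs 2DS2-2DL2 and 2DS1 vs 3DL1-2DS4 segregation checked")
      ## rule (ii): the 2DL5-2DS35 block resides where its flanking
      ## genes are (audit on the genotype vector)
      if (gv[["2DL5"]] >= 1L) {
        cen_support <- gv[["2DP1"]] >= 1L || gv[["2DL1"]] >= 1L
        tel_support <- gv[["3DS1"]] >= 1L || gv[["2DS1"]] >= 1L
        trace <- c(trace, sprintf(
          "rule-ii: 2DL5-2DS35 block present; flanking support cen=%s tel=%s",
          cen_support, tel_support))
      }
      trace <- c(trace, "rule-iv: strong-LD block composition audited")
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  status <- if (nrow(pairs) == 1L) "unambiguous" else
    if (nrow(pairs) > 1L) "ambiguous" else "unresolved"
  structure(list(sample_id = sid, pairs = pairs, status = status,
                 chosen_pair = if (status == "unambiguous")
                   c(pairs$hap1[1L], pairs$hap2[1L]) else NULL,
                 rule_trace = trace),
            class = "kir_resolution")
}

#' Resolve a genotype end to end
#'
#' Convenience wrapper: [enumerate_pairs()] then [phase_with_rules()].
#'
#' @inheritParams enumerate_pairs
#' @return `kir_resolution`.
#' @export
resolve_diplotype <- function(genotype, catalog = kir_catalog()) {
  phase_with_rules(enumerate_pairs(genotype, catalog), genotype, catalog)
}

#' @export
print.kir_resolution <- function(x, ...) {
  cat("KIR diplotype resolution -", x$status, "\n")
  if (nrow(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}

## ---------------------------------------------------------------------
## grammar universe for novel-structure inference

grammar_universe <- function(max_submotifs = 3L) {
  key <- paste0("universe", max_submotifs)
  if (!is.null(.kirhap_cache[[key]])) return(.kirhap_cache[[key]])
  rules <- kir_submotif_rules()
  out <- list()
  for (cen in c("cA01", "cB01", "cB02")) for (tel in c("tA01", "tB01")) {
    applicable <- function(cen_now)
      names(rules)[vapply(names(rules), function(s)
        submotif_applicable(rules[[s]], cen_now, tel), NA)]
    ## candidate submotif sets, applied with cB03 (if chosen) first so
    ## later applicability sees the evolved centromeric motif
    base_ok <- applicable(cen)
    subs_pool <- unique(c(base_ok, if (cen == "cA01") {
      c("cB03", applicable("cB03"))
    }))
    sets <- list(character())
    for (k in seq_len(min(max_submotifs, length(subs_pool))))
      sets <- c(sets, utils::combn(subs_pool, k, simplify = FALSE))
    for (s in sets) {
      s <- c(intersect(s, "cB03"), sort(setdiff(s, "cB03")))
      cen_eff <- cen
      v <- tryCatch({
        vv <- NULL
        cen_now <- cen
        remaining <- s
        ## sequential application with evolving cen label
        h <- build_haplotype(cen, tel)$content
        for (sm in s) {
          r <- rules[[sm]]
          if (!submotif_applicable(r, cen_now, tel)) stop("inapplicable")
          for (g in r$minus) h[g] <- h[g] - 1L
          for (g in r$plus) h[g] <- h[g] + 1L
          if (any(h < 0L)) stop("negative")
          if (sm == "cB03") cen_now <- "cB03"
        }
        validate_haploid_vector(h)
        h
      }, error = function(e) NULL)
      if (is.null(v)) next
      out[[length(out) + 1L]] <- list(cen = cen, tel = tel, subs = s,
                                      content = v, key = vector_key(v))
    }
  }
  .kirhap_cache[[key]] <- out
  out
}

## normalised (cen, tel, submotif-set) representation of a catalog name
normalize_rep <- function(name) {
  p <- parse_hap_name(name)
  if (p$cen == "cB03") list(cen = "cA01", tel = p$tel,
                            subs = c("cB03", p$submotifs))
  else list(cen = p$cen, tel = p$tel, subs = p$submotifs)
}

#' Infer novel haplotype structures for an unexplained genotype
#'
#' When no catalog pair reproduces a genotype, each catalog haplotype
#' whose content fits under the genotype is tried as the known partner;
#' the residual chromosome is screened against the haplotype grammar
#' (framework genes, the 2DP1-connection rule, block operations) and
#' candidates are ranked by the number of submotif edits separating them
#' from the nearest catalog haplotype.
#'
#' @param genotype `kir_genotype` or named diploid copy vector.
#' @param catalog `kir_catalog`.
#' @param max_edits Maximum submotif-edit distance to report (default 2).
#' @return data.frame with columns `known_partner`, `residual` (name of
#'   the grammar structure), `edit_count`, `grammar_edits`, plus
#'   attribute `"diagnostics"` listing rejected residuals.  Zero rows if
#'   nothing passes the grammar.
#' @export
infer_novel <- function(genotype, catalog = kir_catalog(), max_edits = 2L) {
  pairs <- enumerate_pairs(genotype, catalog)
  if (nrow(pairs))
    stop("genotype is explained by catalog pairs; novel inference refused")
  gvs <- genotype_vectors(genotype)
  uni <- grammar_universe()
  ukeys <- vapply(uni, `[[`, "", "key")
  reps <- lapply(catalog$name, normalize_rep)
  diagnostics <- character()
  rows <- list()
  for (gv in gvs) {
    for (i in seq_len(nrow(catalog))) {
      h <- catalog_haplotype(catalog, catalog$name[i])$content
      resid <- gv - h
      if (any(resid < 0L)) next
      ok <- tryCatch({ validate_haploid_vector(resid); TRUE },
                     error = function(e) {
                       diagnostics <<- c(diagnostics, sprintf(
                         "partner %s: residual rejected (%s)",
                         catalog$name[i], conditionMessage(e)))
                       FALSE
                     })
      if (!ok) next
      hit <- which(ukeys == vector_key(resid))
      for (u in hit) {
        cand <- uni[[u]]
        dists <- vapply(reps, function(r) {
          if (r$cen != cand$cen || r$tel != cand$tel) return(NA_integer_)
          length(union(setdiff(r$subs, cand$subs),
                       setdiff(cand$subs, r$subs)))
        }, 0L)
        if (all(is.na(dists))) next
        ec <- min(dists, na.rm = TRUE)
        nearest <- catalog$name[which.min(ifelse(is.na(dists), Inf, dists))]
        if (ec > max_edits) next
        nm <- paste0(cand$cen, "|", cand$tel,
                     if (length(cand$subs))
                       paste0("-", paste(cand$subs, collapse = "-")) else "")
        rows[[length(rows) + 1L]] <- data.frame(
          known_partner = catalog$name[i], residual = nm,
          edit_count = ec,
          grammar_edits = paste(union(
            setdiff(normalize_rep(nearest)$subs, cand$subs),
            setdiff(cand$subs, normalize_rep(nearest)$subs)),
            collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(known_partner = character(), residual = character(),
               edit_count = integer(), grammar_edits = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$edit_count, out$residual, out$known_partner), ,
             drop = FALSE]
  attr(out, "diagnostics") <- diagnostics
  out
}
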