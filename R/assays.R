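## Amplicon assay model: the 14 multiplex PCR-sequencing assays, the
## forward model predicting dye-terminator peak heights from a diploid
## copy vector, and integer-ratio classification of observed peaks.

## Column layout of the forward model / solver: all 16 canonical loci
## (2DS3 and 2DS5 separate) plus the four hybrids.
FWD_COLS <- c(KIR_LOCI, KIR_HYBRIDS)

#' Load the amplicon assay definitions
#'
#' Reads the packaged assay tables (amplicons, scored SNP targets,
#' peak-ratio rules, hybrid base carriage) and cross-checks coverage:
#' every non-incidental gene interrogated by the assay set must have at
#' least two independent confirmation targets (the 3DP1-2DL4 block and
#' the 2DS3/2DS5 pair are counted as the units the assays resolve).
#'
#' @param dir Directory holding `kir_assays.tsv`,
#'   `kir_assay_targets.tsv`, `kir_ratio_rules.tsv` and
#'   `kir_hybrid_carriage.tsv`.  Default: the packaged tables.
#' @return Object of class `kir_assays`: list with `assays`, `targets`
#'   (with per-target carrier matrix), `rules`, `carriage`, `coverage`.
#' @export
load_assay_definitions <- function(dir = system.file("extdata",
                                                     package = "kirhap")) {
  rd <- function(f) utils::read.delim(file.path(dir, f), check.names = FALSE,
                                      stringsAsFactors = FALSE)
  assays <- rd("kir_assays.tsv")
  targets <- rd("kir_assay_targets.tsv")
  rules <- rd("kir_ratio_rules.tsv")
  carriage <- rd("kir_hybrid_carriage.tsv")
  if (nrow(assays) != 14L)
    stop("expected 14 amplicon assays, found ", nrow(assays))
  if (!all(targets$assay %in% assays$assay))
    stop("target rows reference unknown assays")

  ## per-target effective carrier matrix over FWD_COLS: a hybrid
  ## contributes wherever the parental allele it presents in that
  ## amplicon carries the scored base
  M <- matrix(0L, nrow(targets), length(FWD_COLS),
              dimnames = list(NULL, FWD_COLS))
  for (i in seq_len(nrow(targets))) {
    genes <- strsplit(targets$genes[i], ",", fixed = TRUE)[[1L]]
    M[i, genes] <- 1L
    hy <- carriage[carriage$assay == targets$assay[i] &
                   carriage$presents_as %in% genes, "hybrid"]
    if (length(hy)) M[i, hy] <- 1L
  }

  ## coverage audit (confirmation units: 3DP1+2DL4 block, 2DS35 pair)
  unit_of <- function(g) {
    if (g %in% c("3DP1", "2DL4")) return("3DP1-2DL4")
    if (g %in% c("2DS3", "2DS5")) return("2DS35")
    g
  }
  interrogated <- unique(unlist(lapply(assays$genes_amplified, function(s) {
    g <- strsplit(s, ",", fixed = TRUE)[[1L]]
    g[!grepl("^\\(", g)]
  })))
  cov <- vapply(interrogated, function(g) {
    u <- unit_of(g)
    sum(vapply(seq_len(nrow(targets)), function(i) {
      genes <- strsplit(targets$genes[i], ",", fixed = TRUE)[[1L]]
      g %in% genes && all(vapply(genes, unit_of, "") == u)
    }, NA))
  }, 0L)
  low <- names(cov)[cov < 2L]
  if (length(low))
    stop("assay coverage violation: fewer than 2 confirmation targets for ",
         paste(low, collapse = ", "))
  rules$classes_list <- lapply(rules$classes, parse_ratio_classes)
  structure(list(assays = assays, targets = targets, target_matrix = M,
                 rules = rules, carriage = carriage, coverage = cov),
            class = "kir_assays")
}

#' @rdname load_assay_definitions
#' @export
kir_assays <- function() {
  if (is.null(.kirhap_cache$assays))
    .kirhap_cache$assays <- load_assay_definitions()
  .kirhap_cache$assays
}

parse_ratio_classes <- function(s) {
  if (identical(s, "any")) return(NULL)  # any reduced integer ratio
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  m <- do.call(rbind, lapply(parts, function(p)
    as.integer(strsplit(p, ":", fixed = TRUE)[[1L]])))
  colnames(m) <- c("n1", "n2")
  m
}

## all reduced integer ratios a:b with 1 <= a,b <= cap
extended_ratio_classes <- function(cap = 8L) {
  g <- expand.grid(n1 = seq_len(cap), n2 = seq_len(cap))
  keep <- mapply(function(a, b) {
    r <- function(x, y) if (y == 0) x else r(y, x %% y)
    r(a, b) == 1L
  }, g$n1, g$n2)
  as.matrix(g[keep, ])
}

#' Expand a diplotype copy vector for the forward model
#'
#' Maps a catalog-level vector (merged 2DS35 locus) onto the assay-level
#' column layout, assigning merged 2DS35 copies to one of the 2DS3/2DS5
#' allele sets (the catalog does not distinguish them).
#'
#' @param counts Named integer vector (may contain `2DS35` and/or
#'   `2DS3`/`2DS5` entries).
#' @param s35_allele Which gene the merged 2DS35 copies carry
#'   (`"2DS3"` default, or `"2DS5"`).
#' @return Named integer vector over the assay-level columns.
#' @export
expand_fwd_vector <- function(counts, s35_allele = c("2DS3", "2DS5")) {
  s35_allele <- match.arg(s35_allele)
  v <- stats::setNames(integer(length(FWD_COLS)), FWD_COLS)
  for (nm in names(counts)) {
    tgt <- if (nm == "2DS35") s35_allele else nm
    if (tgt %in% names(v)) v[tgt] <- v[tgt] + as.integer(counts[[nm]])
  }
  v
}

#' Noiseless expected peak heights
#'
#' For every scored target of every assay, the expected height of base b
#' at position p is `gain` times the summed copy number of the amplified
#' loci carrying (p, b), with hybrid loci contributing the parental
#' allele of the segment their amplicon lies in.
#'
#' @param diplotype Named diploid copy vector (catalog-level or
#'   assay-level columns).
#' @param assay_defs A `kir_assays` bundle (default packaged).
#' @param gain Positive scalar or named per-assay vector of gains.
#' @param s35_allele See [expand_fwd_vector()].
#' @return data.frame (assay, position, base, height).
#' @export
expected_peaks <- function(diplotype, assay_defs = kir_assays(), gain = 1000,
                           s35_allele = "2DS3") {
  x <- expand_fwd_vector(diplotype, s35_allele)
  tg <- assay_defs$targets
  copies <- as.numeric(assay_defs$target_matrix %*% x)
  g <- if (length(gain) == 1L && is.null(names(gain)))
    rep(gain, nrow(tg)) else unname(gain[tg$assay])
  data.frame(assay = tg$assay, position = tg$position, base = tg$base,
             height = g * copies, stringsAsFactors = FALSE)
}

#' Classify a peak-height pair into an integer copy ratio
#'
#' Returns the allowed ratio class minimising the log-space distance
#' `|ln(h1/h2) - ln(n1/n2)|` when both heights clear the detection
#' floor; `absent-numerator`/`absent-denominator` when one side is below
#' floor; `unclassifiable` when the nearest class exceeds `tolerance`.
#'
#' @param heights Numeric length 2: numerator and denominator heights.
#' @param classes Integer matrix of allowed classes (columns n1, n2), a
#'   class string such as `"1:1,2:1"`, or NULL for any reduced integer
#'   ratio up to 8.
#' @param tolerance Maximum log-ratio distance (default 0.2, half the
#'   gap between the 1:1 and 3:2 classes).
#' @param detection_floor A side is absent when its height falls below
#'   this fraction of the larger height (default 0.05).
#' @return List with `status` (`"ok"`, `"absent-numerator"`,
#'   `"absent-denominator"`, `"unclassifiable"`), `class` (string
#'   `"n1:n2"` or NA) and `distance`.
#' @examples
#' classify_ratio(c(1500, 1000), "1:1,2:1,3:1,3:2,4:1")$class  # "3:2"
#' @export
classify_ratio <- function(heights, classes = NULL, tolerance = 0.2,
                           detection_floor = 0.05) {
  stopifnot(length(heights) == 2L, all(heights >= 0))
  if (is.character(classes)) classes <- parse_ratio_classes(classes)
  if (is.null(classes)) classes <- extended_ratio_classes()
  hmax <- max(heights)
  if (hmax <= 0)
    stop("no signal: both peak heights are zero (assay should always ",
         "yield product)")
  lo <- heights < detection_floor * hmax
  if (lo[1L]) return(list(status = "absent-numerator", class = NA_character_,
                          distance = NA_real_))
  if (lo[2L]) return(list(status = "absent-denominator", class = NA_character_,
                          distance = NA_real_))
  keep <- classes[, 1L] > 0L & classes[, 2L] > 0L
  classes <- classes[keep, , drop = FALSE]
  d <- abs(log(heights[1L] / heights[2L]) -
           log(classes[, 1L] / classes[, 2L]))
  i <- which.min(d)
  if (d[i] > tolerance)
    return(list(status = "unclassifiable", class = NA_character_,
                distance = unname(d[i])))
  list(status = "ok",
       class = paste0(classes[i, 1L], ":", classes[i, 2L]),
       distance = unname(d[i]))
}
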