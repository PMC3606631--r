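#' @keywords internal
"_PACKAGE"

## Canonical KIR locus set, chromosome order, and motif/submotif grammar.
## The KIR region is a tandem cluster on chromosome 19q13.4; gene order is
## invariant and haplotypes are combinations of one centromeric and one
## telomeric motif, optionally altered by recurrent block deletions,
## insertions (duplications) and gene hybridisations ("submotifs").

#' Canonical KIR loci
#'
#' The 16 canonical KIR genes in chromosome order (3DL3 first, 3DL2 last),
#' the hybrid (fusion) pseudo-loci, and the column layout used by copy
#' vectors throughout the package.
#'
#' @format Character vectors of locus names.
#' @name kir_loci
NULL

#' @rdname kir_loci
#' @export
KIR_LOCI <- c("3DL3", "2DS2", "2DL2", "2DL3", "2DL5", "2DS3", "2DS5",
              "2DP1", "2DL1", "3DP1", "2DL4", "3DL1", "3DS1", "2DS1",
              "2DS4", "3DL2")

#' @rdname kir_loci
#' @export
KIR_HYBRIDS <- c("2DS2/S3", "2DP1/L1", "2DL1/S1", "3DL1/L2")

## Catalog-level copy vectors collapse 2DS3 + 2DS5 into the merged 2DS35
## locus (the two are treated as allele sets of one gene, not as
## distinguishing haplotype content).
#' @rdname kir_loci
#' @export
KIR_LOCI_COLLAPSED <- c("3DL3", "2DS2", "2DL2", "2DL3", "2DL5", "2DS35",
                        "2DP1", "2DL1", "3DP1", "2DL4", "3DL1", "3DS1",
                        "2DS1", "2DS4", "3DL2")

#' @rdname kir_loci
#' @export
KIR_VECTOR_COLS <- c(KIR_LOCI_COLLAPSED, KIR_HYBRIDS)

## Region assignment used for LD ordering and rule checks.
KIR_CEN <- c("3DL3", "2DS2", "2DL2", "2DL3", "2DL5", "2DS3", "2DS5",
             "2DS35", "2DP1", "2DL1", "3DP1")
KIR_TEL <- c("2DL4", "3DL1", "3DS1", "2DS1", "2DS4", "3DL2")

## Framework genes: present on (nearly) every haplotype.
KIR_FRAMEWORK <- c("3DL3", "2DL4", "3DL2")

#' KIR motif definitions
#'
#' Ordered gene lists of the four centromeric (cA01, cB01, cB02, cB03) and
#' two telomeric (tA01, tB01) motifs.  cB03 is the rare centromeric motif
#' equal to cA01 with the 2DL5-2DS35 block inserted between 2DL3 and 2DP1;
#' it is also expressible as a submotif edit of cA01.
#'
#' @return Named list of character vectors (gene order along the
#'   chromosome).
#' @export
kir_motifs <- function() {
  list(
    cA01 = c("3DL3", "2DL3", "2DP1", "2DL1", "3DP1"),
    cB01 = c("3DL3", "2DS2", "2DL2", "2DL5", "2DS35", "2DP1", "2DL1", "3DP1"),
    cB02 = c("3DL3", "2DS2", "2DL2", "3DP1"),
    cB03 = c("3DL3", "2DL3", "2DL5", "2DS35", "2DP1", "2DL1", "3DP1"),
    tA01 = c("2DL4", "3DL1", "2DS4", "3DL2"),
    tB01 = c("2DL4", "3DS1", "2DL5", "2DS35", "2DS1", "3DL2")
  )
}

## Submotif rule table.  Each rule records the operation type, the copy
## deltas it applies to a haploid vector (on the collapsed column set),
## any hybrid locus it creates, and the motif combinations it may occur
## on ("associated region").  `cens`/`tels` of NULL mean "any"; `combos`
## restricts to full cen|tel combinations.
kir_submotif_rules <- function() {
  rule <- function(op, minus = character(), plus = character(),
                   cens = NULL, tels = NULL, combos = NULL) {
    list(op = op, minus = minus, plus = plus,
         cens = cens, tels = tels, combos = combos)
  }
  list(
    cB03 = rule("insert-block", plus = c("2DL5", "2DS35"), cens = "cA01"),
    del3 = rule("delete-block", minus = "2DS2", cens = c("cB01", "cB02")),
    del4 = rule("delete-block", minus = "2DL2", cens = "cB01"),
    del9 = rule("delete-block", minus = c("2DL5", "2DS35", "2DP1"),
                cens = "cB01"),
    del10 = rule("hybridize",
                 minus = c("2DS2", "2DL2", "2DL5", "2DS35"),
                 plus = "2DS2/S3", cens = "cB01"),
    hybd1 = rule("hybridize", minus = c("3DL1", "2DS4", "3DL2"),
                 plus = "3DL1/L2", tels = "tA01"),
    del5 = rule("delete-block", minus = c("3DP1", "2DL4", "3DL1"),
                combos = c("cA01|tA01", "cB01|tA01")),
    del6 = rule("delete-block", minus = c("3DP1", "2DL4", "3DS1"),
                combos = c("cA01|tB01", "cB02|tB01")),
    del7 = rule("hybridize",
                minus = c("2DL1", "3DP1", "2DL4", "3DS1", "2DL5",
                          "2DS35", "2DS1"),
                plus = "2DL1/S1", combos = c("cA01|tB01", "cB01|tB01")),
    del8 = rule("hybridize",
                minus = c("2DL1", "3DP1", "2DL4", "3DS1", "2DL5",
                          "2DS35", "2DS1"),
                plus = "2DL1/S1", combos = c("cA01|tB01", "cB01|tB01")),
    ins3 = rule("insert-block", plus = c("3DP1", "2DL4", "3DL1"),
                combos = c("cA01|tA01", "cB01|tA01", "cB02|tA01",
                           "cA01|tB01", "cB01|tB01")),
    ins4 = rule("insert-block", plus = c("3DP1", "2DL4", "3DS1"),
                combos = c("cA01|tA01", "cB01|tA01", "cB02|tA01",
                           "cA01|tB01", "cB01|tB01")),
    ins5 = rule("insert-block",
                plus = c("3DP1", "2DL4", "3DS1", "2DL5", "2DS35",
                         "2DP1/L1"),
                combos = c("cA01|tA01", "cB01|tA01", "cB02|tA01",
                           "cB03|tA01", "cB01|tB01"))
  )
}

#' Hybrid gene segment boundaries
#'
#' Each hybrid (fusion) KIR gene carries its 5' parent's sequence up to a
#' boundary intron and its 3' parent's sequence beyond it.  The boundary
#' determines which parental allele an amplicon assay observes.
#'
#' @return data.frame with columns `hybrid`, `parent5`, `parent3`,
#'   `boundary` (last 5'-parent exon).
#' @export
kir_hybrid_boundaries <- function() {
  data.frame(
    hybrid   = c("2DS2/S3", "2DP1/L1", "2DL1/S1", "3DL1/L2"),
    parent5  = c("2DS2", "2DP1", "2DL1", "3DL1"),
    parent3  = c("2DS3", "2DL1", "2DS1", "3DL2"),
    boundary = c(6L, 3L, 3L, 5L),  # intron after this exon
    stringsAsFactors = FALSE
  )
}

empty_copy_vector <- function() {
  stats::setNames(integer(length(KIR_VECTOR_COLS)), KIR_VECTOR_COLS)
}

#' Parse a haplotype name
#'
#' Haplotype names follow the `cen|tel[-submotif...]` nomenclature, e.g.
#' `"cB02|tB01-del6"` or `"cB01|tA01-del3-ins4"`.
#'
#' @param name Haplotype name string.
#' @return List with `cen`, `tel`, `submotifs` (character vector, possibly
#'   empty).
#' @export
parse_hap_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  halves <- strsplit(name, "|", fixed = TRUE)[[1L]]
  if (length(halves) != 2L)
    stop("malformed haplotype name (expected 'cen|tel...'): ", name)
  cen <- halves[1L]
  rest <- strsplit(halves[2L], "-", fixed = TRUE)[[1L]]
  tel <- rest[1L]
  motifs <- kir_motifs()
  if (!cen %in% c("cA01", "cB01", "cB02", "cB03"))
    stop("unknown centromeric motif in name: ", name)
  if (!tel %in% c("tA01", "tB01"))
    stop("unknown telomeric motif in name: ", name)
  list(cen = cen, tel = tel,
       submotifs = if (length(rest) > 1L) rest[-1L] else character())
}

submotif_applicable <- function(rule, cen, tel) {
  if (!is.null(rule$combos)) return(paste0(cen, "|", tel) %in% rule$combos)
  ok <- TRUE
  if (!is.null(rule$cens)) ok <- ok && cen %in% rule$cens
  if (!is.null(rule$tels)) ok <- ok && tel %in% rule$tels
  ok
}

#' Build a haplotype from the motif/submotif grammar
#'
#' Applies submotif block operations (deletion, insertion/duplication,
#' hybridisation) to the gene lists of a centromeric and telomeric motif
#' pair, producing the haploid gene copy vector.
#'
#' @param cen Centromeric motif name (`cA01`, `cB01`, `cB02`, `cB03`).
#' @param tel Telomeric motif name (`tA01`, `tB01`).
#' @param submotifs Character vector of submotif rule names (possibly
#'   empty).
#' @param name Optional haplotype name to attach (defaults to the
#'   canonical `cen|tel[-submotif]` spelling).
#' @return Object of class `kir_haplotype`: list with `name`, `cen`,
#'   `tel`, `submotifs` and `content` (named integer copy vector over
#'   [KIR_VECTOR_COLS]).
#' @examples
#' h <- build_haplotype("cA01", "tA01")
#' h$content[c("3DL3", "2DL3", "3DL1")]
#' @export
build_haplotype <- function(cen, tel, submotifs = character(), name = NULL) {
  motifs <- kir_motifs()
  rules <- kir_submotif_rules()
  if (!cen %in% c("cA01", "cB01", "cB02", "cB03"))
    stop("unknown centromeric motif: ", cen)
  if (!tel %in% c("tA01", "tB01"))
    stop("unknown telomeric motif: ", tel)
  v <- empty_copy_vector()
  for (g in c(motifs[[cen]], motifs[[tel]])) v[g] <- v[g] + 1L
  for (s in submotifs) {
    r <- rules[[s]]
    if (is.null(r)) stop("unknown submotif rule: ", s)
    if (!submotif_applicable(r, cen, tel))
      stop("submotif ", s, " is not applicable to parent ", cen, "|", tel)
    for (g in r$minus) v[g] <- v[g] - 1L
    for (g in r$plus) v[g] <- v[g] + 1L
    if (any(v < 0L))
      stop("submotif ", s, " removes a gene absent from ", cen, "|", tel)
  }
  if (is.null(name))
    name <- paste0(cen, "|", tel,
                   if (length(submotifs)) paste0("-", paste(submotifs, collapse = "-")) else "")
  structure(list(name = name, cen = cen, tel = tel,
                 submotifs = submotifs, content = v),
            class = "kir_haplotype")
}

#' Validate a haploid copy vector against the haplotype grammar
#'
#' Checks the framework-gene constraint (3DL3 present; 3DL2 present either
#' free-standing or as the 3' half of a 3DL1/L2 hybrid), the
#' 2DP1-connection rule (2DP1 never joins 2DS2-2DL2 directly: a haplotype
#' carrying 2DS2 and 2DP1 must carry 2DL3 or 2DL5), and copy bounds
#' (0-2 per haplotype).
#'
#' @param content Named integer vector over [KIR_VECTOR_COLS].
#' @return Invisibly TRUE; stops with a descriptive error on violation.
#' @export
validate_haploid_vector <- function(content) {
  stopifnot(all(KIR_VECTOR_COLS %in% names(content)))
  v <- content[KIR_VECTOR_COLS]
  ## the 2DL5-2DS35 block can reside on both halves AND be duplicated by
  ## ins5 (cB01|tB01-ins5 carries three copies); all other loci cap at 2
  cap <- ifelse(names(v) %in% c("2DL5", "2DS35"), 3L, 2L)
  if (any(v < 0L) || any(v > cap))
    stop("haploid copy counts out of range (0..2, 2DL5/2DS35 0..3)")
  if (v[["3DL3"]] < 1L)
    stop("framework violation: 3DL3 absent")
  if (v[["3DL2"]] + v[["3DL1/L2"]] < 1L)
    stop("framework violation: 3DL2 absent (and no 3DL1/L2 hybrid)")
  if (v[["2DS2"]] >= 1L && v[["2DP1"]] >= 1L &&
      v[["2DL3"]] == 0L && v[["2DL5"]] == 0L)
    stop("rule-(v) violation: 2DP1-2DL1 block joined directly to 2DS2-2DL2")
  invisible(TRUE)
}

#' Collapse 2DS3/2DS5 counts into the merged 2DS35 locus
#'
#' Assay-level genotypes distinguish 2DS3 from 2DS5; catalog matching does
#' not.  Adds any `2DS3`/`2DS5` counts into `2DS35` and drops the split
#' columns.
#'
#' @param counts Named integer vector containing `2DS3`/`2DS5` and/or
#'   `2DS35` entries.
#' @return Named integer vector over [KIR_VECTOR_COLS].
#' @export
collapse_2DS35 <- function(counts) {
  v <- empty_copy_vector()
  for (nm in names(counts)) {
    tgt <- if (nm %in% c("2DS3", "2DS5")) "2DS35" else nm
    if (tgt %in% names(v)) v[tgt] <- v[tgt] + as.integer(counts[[nm]])
  }
  v
}

#' Diplotype copy vector
#'
#' Component-wise sum of two haploid copy vectors (commutative).
#'
#' @param h1,h2 `kir_haplotype` objects or named haploid copy vectors.
#' @return Named integer vector over [KIR_VECTOR_COLS] at diploid level.
#' @export
diplotype_vector <- function(h1, h2) {
  c1 <- if (inherits(h1, "kir_haplotype")) h1$content else h1
  c2 <- if (inherits(h2, "kir_haplotype")) h2$content else h2
  c1[KIR_VECTOR_COLS] + c2[KIR_VECTOR_COLS]
}

#' @export
print.kir_haplotype <- function(x, ...) {
  cat("KIR haplotype", x$name, "\n")
  present <- x$content[x$content > 0L]
  cat(" ", paste(sprintf("%s:%d", names(present), present), collapse = " "), "\n")
  invisible(x)
}
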