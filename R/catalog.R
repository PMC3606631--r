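## Catalog loading and validation.

.kirhap_cache <- new.env(parent = emptyenv())

#' Load the gene-content haplotype catalog
#'
#' Reads a catalog table (by default the packaged 37-haplotype reference
#' catalog) and validates every record against the motif/submotif
#' grammar: each stored copy vector is recomputed from the record's
#' motif + submotif decomposition and must match exactly, and every
#' vector must satisfy the framework-gene and 2DP1-connection
#' constraints.
#'
#' @param source Path to a tab-separated catalog table.  Default: the
#'   table shipped with the package.
#' @return Object of class `kir_catalog`: a data.frame with one row per
#'   haplotype (name, cen_motif, tel_motif, submotifs, partial_3DL2,
#'   per-locus copy columns, frequency).
#' @examples
#' cat37 <- load_catalog()
#' nrow(cat37)  # 37
#' @export
load_catalog <- function(source = system.file("extdata", "kir_catalog.tsv",
                                              package = "kirhap")) {
  if (!nzchar(source) || !file.exists(source))
    stop("catalog table not found: ", source)
  df <- utils::read.delim(source, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- sub(".", "/", names(df), fixed = TRUE)
  needed <- c("name", "cen_motif", "tel_motif", "submotifs", "frequency",
              KIR_VECTOR_COLS)
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("catalog table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("grammar violation: duplicated haplotype name '",
         df$name[duplicated(df$name)][1L], "'")
  for (i in seq_len(nrow(df))) {
    nm <- df$name[i]
    parsed <- parse_hap_name(nm)
    subs <- if (df$submotifs[i] %in% c(".", "", NA)) character() else
      strsplit(df$submotifs[i], ",", fixed = TRUE)[[1L]]
    if (!identical(sort(subs), sort(parsed$submotifs)) ||
        parsed$cen != df$cen_motif[i] || parsed$tel != df$tel_motif[i])
      stop("grammar violation: name '", nm,
           "' disagrees with its motif/submotif columns")
    rebuilt <- build_haplotype(parsed$cen, parsed$tel, parsed$submotifs)
    stored <- as.integer(df[i, KIR_VECTOR_COLS])
    names(stored) <- KIR_VECTOR_COLS
    if (!identical(stored, rebuilt$content))
      stop("grammar violation: stored copy vector of '", nm,
           "' does not equal its motif/submotif reconstruction")
    validate_haploid_vector(stored)
  }
  if (abs(sum(df$frequency) - 1) > 1e-9)
    stop("catalog frequencies do not sum to 1")
  class(df) <- c("kir_catalog", "data.frame")
  df
}

#' Packaged reference catalog (cached)
#'
#' @return The validated 37-haplotype `kir_catalog`.
#' @export
kir_catalog <- function() {
  if (is.null(.kirhap_cache$catalog))
    .kirhap_cache$catalog <- load_catalog()
  .kirhap_cache$catalog
}

#' Extract a haplotype record from a catalog
#'
#' @param catalog A `kir_catalog`.
#' @param name Haplotype name.
#' @return `kir_haplotype` object (with `frequency` and `partial_3DL2`
#'   attached).
#' @export
catalog_haplotype <- function(catalog, name) {
  i <- match(name, catalog$name)
  if (is.na(i)) stop("haplotype not in catalog: ", name)
  v <- as.integer(catalog[i, KIR_VECTOR_COLS])
  names(v) <- KIR_VECTOR_COLS
  parsed <- parse_hap_name(name)
  structure(list(name = name, cen = parsed$cen, tel = parsed$tel,
                 submotifs = parsed$submotifs, content = v,
                 frequency = catalog$frequency[i],
                 partial_3DL2 = isTRUE(catalog$partial_3DL2[i] == 1L)),
            class = "kir_haplotype")
}

#' Copy-vector matrix of a catalog
#'
#' @param catalog A `kir_catalog`.
#' @return Integer matrix, rows = haplotypes (named), columns =
#'   [KIR_VECTOR_COLS].
#' @export
catalog_matrix <- function(catalog = kir_catalog()) {
  m <- as.matrix(catalog[, KIR_VECTOR_COLS])
  mode(m) <- "integer"
  rownames(m) <- catalog$name
  m
}

#' Export a catalog as JSON
#'
#' @param catalog A `kir_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(catalog, path) {
  recs <- lapply(seq_len(nrow(catalog)), function(i) {
    v <- as.integer(catalog[i, KIR_VECTOR_COLS])
    names(v) <- KIR_VECTOR_COLS
    list(name = catalog$name[i], cen_motif = catalog$cen_motif[i],
         tel_motif = catalog$tel_motif[i],
         submotifs = if (catalog$submotifs[i] == ".") character() else
           strsplit(catalog$submotifs[i], ",")[[1L]],
         content = as.list(v), frequency = catalog$frequency[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
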