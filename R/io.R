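## Tabular and JSON input/output for the pipeline artefacts.  Every
## writer prefixes a metadata header (# key: value lines) recording the
## tool version, seed and parameters of the run.

meta_header <- function(meta = list()) {
  meta <- c(list(tool = paste0("kirhap ",
                               as.character(utils::packageVersion("kirhap"))),
                 date = format(Sys.time(), "%Y-%m-%d")), meta)
  sprintf("# %s: %s", names(meta), vapply(meta, as.character, ""))
}

write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read peak observations from TSV
#'
#' Expected columns: sample_id, assay, position, base, height.  Lines
#' starting with `#` are metadata.
#'
#' @param path File path.
#' @return data.frame of peak observations.
#' @export
read_peaks_tsv <- function(path) {
  df <- read_tsv_meta(path)
  need <- c("sample_id", "assay", "position", "base", "height")
  if (!all(need %in% names(df)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write peak observations to TSV
#' @param peaks data.frame of peak observations.
#' @param path Output path.
#' @param meta Named list added to the metadata header.
#' @return `path`, invisibly.
#' @export
write_peaks_tsv <- function(peaks, path, meta = list())
  write_tsv_meta(peaks, path, meta)

#' Write genotype calls
#'
#' TSV (one row per sample, one column per locus) and, optionally, JSON
#' with evidence and discordances.
#'
#' @param genotypes List of `kir_genotype` objects.
#' @param path Output TSV path.
#' @param json_path Optional JSON path.
#' @param meta Metadata header entries.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, json_path = NULL,
                            meta = list()) {
  rows <- lapply(genotypes, function(g) {
    v <- if (is.null(g$copies)) stats::setNames(
      rep(NA_integer_, length(KIR_VECTOR_COLS)), KIR_VECTOR_COLS) else g$copies
    cbind(data.frame(sample_id = g$sample_id, status = g$status,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  write_tsv_meta(do.call(rbind, rows), path, meta)
  if (!is.null(json_path)) {
    jsonlite::write_json(lapply(genotypes, function(g)
      list(sample_id = g$sample_id, status = g$status,
           copies = as.list(g$copies), evidence = as.list(g$evidence),
           provisional = g$provisional, discordances = g$discordances)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write diplotype resolutions
#'
#' Flat TSV summary (sample_id, hap1, hap2, status) plus JSON-lines with
#' the full pair sets and rule traces.
#'
#' @param resolutions List of `kir_resolution` objects.
#' @param path Output TSV path.
#' @param jsonl_path Optional JSON-lines path.
#' @param meta Metadata header entries.
#' @return `path`, invisibly.
#' @export
write_resolutions <- function(resolutions, path, jsonl_path = NULL,
                              meta = list()) {
  rows <- lapply(resolutions, function(r) data.frame(
    sample_id = r$sample_id,
    hap1 = if (nrow(r$pairs)) r$pairs$hap1[1L] else NA_character_,
    hap2 = if (nrow(r$pairs)) r$pairs$hap2[1L] else NA_character_,
    status = r$status, stringsAsFactors = FALSE))
  write_tsv_meta(do.call(rbind, rows), path, meta)
  if (!is.null(jsonl_path)) {
    con <- file(jsonl_path, "w")
    on.exit(close(con))
    for (r in resolutions)
      writeLines(jsonlite::toJSON(list(
        sample_id = r$sample_id, status = r$status,
        pairs = r$pairs, rule_trace = r$rule_trace),
        auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write a frequency estimate
#'
#' TSV (haplotype, frequency, chromosome count) and optional JSON with
#' the log-likelihood trace.
#'
#' @param estimate `kir_freq_estimate`.
#' @param path Output TSV path.
#' @param json_path Optional JSON path.
#' @param meta Metadata header entries.
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(estimate, path, json_path = NULL,
                              meta = list()) {
  df <- data.frame(haplotype = names(estimate$frequencies),
                   frequency = unname(estimate$frequencies),
                   count = unname(estimate$frequencies) *
                     estimate$n_chromosomes,
                   stringsAsFactors = FALSE)
  write_tsv_meta(df, path, c(meta, list(
    n_chromosomes = estimate$n_chromosomes,
    n_excluded = estimate$n_excluded,
    converged = estimate$converged)))
  if (!is.null(json_path))
    jsonlite::write_json(list(frequencies = as.list(estimate$frequencies),
                              loglik_trace = estimate$loglik_trace,
                              n_chromosomes = estimate$n_chromosomes,
                              n_excluded = estimate$n_excluded,
                              converged = estimate$converged),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write LD matrices
#'
#' @param ld `kir_ld`.
#' @param dprime_path,rsq_path Output TSV paths.
#' @param meta Metadata header entries.
#' @return `dprime_path`, invisibly.
#' @export
write_ld <- function(ld, dprime_path, rsq_path, meta = list()) {
  meta <- c(meta, list(weighted = ld$weighted, note = ld$note))
  write_tsv_meta(cbind(gene = rownames(ld$dprime),
                       as.data.frame(ld$dprime, check.names = FALSE)),
                 dprime_path, meta)
  write_tsv_meta(cbind(gene = rownames(ld$rsq),
                       as.data.frame(ld$rsq, check.names = FALSE)),
                 rsq_path, meta)
  invisible(dprime_path)
}

#' Write breakpoint calls
#'
#' @param calls data.frame from [scan_triplet()].
#' @param path Output TSV path.
#' @param meta Metadata header entries.
#' @return `path`, invisibly.
#' @export
write_breakpoints <- function(calls, path, meta = list())
  write_tsv_meta(calls, path, meta)
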