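#!/usr/bin/env Rscript
## Generates the packaged reference tables under inst/extdata/.
## Content vectors here are written out record-by-record from explicit
## gene lists (independent of the package's grammar code, which is used
## at load time to cross-validate this transcription).

cols <- c("3DL3", "2DS2", "2DL2", "2DL3", "2DL5", "2DS35", "2DP1", "2DL1",
          "3DP1", "2DL4", "3DL1", "3DS1", "2DS1", "2DS4", "3DL2",
          "2DS2/S3", "2DP1/L1", "2DL1/S1", "3DL1/L2")

vec <- function(...) {
  genes <- c(...)
  v <- setNames(integer(length(cols)), cols)
  for (g in genes) v[g] <- v[g] + 1L
  v
}

cA01 <- c("3DL3", "2DL3", "2DP1", "2DL1", "3DP1")
cB01 <- c("3DL3", "2DS2", "2DL2", "2DL5", "2DS35", "2DP1", "2DL1", "3DP1")
cB02 <- c("3DL3", "2DS2", "2DL2", "3DP1")
cB03 <- c("3DL3", "2DL3", "2DL5", "2DS35", "2DP1", "2DL1", "3DP1")
tA01 <- c("2DL4", "3DL1", "2DS4", "3DL2")
tB01 <- c("2DL4", "3DS1", "2DL5", "2DS35", "2DS1", "3DL2")

drop1 <- function(genes, remove) {
  for (r in remove) {
    i <- match(r, genes)
    stopifnot(!is.na(i))
    genes <- genes[-i]
  }
  genes
}

recs <- list()
add <- function(name, genes, partial_3DL2 = 0L) {
  recs[[length(recs) + 1L]] <<- list(name = name, v = vec(genes),
                                     partial_3DL2 = partial_3DL2)
}

## -- majors ---------------------------------------------------------------
add("cA01|tA01", c(cA01, tA01))
add("cA01|tB01", c(cA01, tB01))
add("cB01|tA01", c(cB01, tA01))
add("cB01|tB01", c(cB01, tB01))
add("cB02|tA01", c(cB02, tA01))
add("cB02|tB01", c(cB02, tB01))
## -- centromeric submotifs ------------------------------------------------
add("cB03|tA01", c(cB03, tA01))
add("cB01|tA01-del3", c(drop1(cB01, "2DS2"), tA01))
add("cB02|tA01-del3", c(drop1(cB02, "2DS2"), tA01))
add("cB01|tA01-del4", c(drop1(cB01, "2DL2"), tA01))
add("cB01|tA01-del9", c(drop1(cB01, c("2DL5", "2DS35", "2DP1")), tA01))
add("cB01|tA01-del10",
    c(drop1(cB01, c("2DS2", "2DL2", "2DL5", "2DS35")), "2DS2/S3", tA01))
## -- telomeric hybridisation ---------------------------------------------
add("cA01|tA01-hybd1",
    c(cA01, drop1(tA01, c("3DL1", "2DS4", "3DL2")), "3DL1/L2"))
## -- boundary-spanning deletions ------------------------------------------
add("cA01|tA01-del5", c(drop1(c(cA01, tA01), c("3DP1", "2DL4", "3DL1"))))
add("cB01|tA01-del5", c(drop1(c(cB01, tA01), c("3DP1", "2DL4", "3DL1"))))
add("cA01|tB01-del6", c(drop1(c(cA01, tB01), c("3DP1", "2DL4", "3DS1"))))
add("cB02|tB01-del6", c(drop1(c(cB02, tB01), c("3DP1", "2DL4", "3DS1"))))
del7block <- c("2DL1", "3DP1", "2DL4", "3DS1", "2DL5", "2DS35", "2DS1")
add("cA01|tB01-del7", c(drop1(c(cA01, tB01), del7block), "2DL1/S1"),
    partial_3DL2 = 1L)
add("cB01|tB01-del7", c(drop1(c(cB01, tB01), del7block), "2DL1/S1"))
add("cA01|tB01-del8", c(drop1(c(cA01, tB01), del7block), "2DL1/S1"))
## -- insertions / duplications --------------------------------------------
i3 <- c("3DP1", "2DL4", "3DL1")
i4 <- c("3DP1", "2DL4", "3DS1")
i5 <- c("3DP1", "2DL4", "3DS1", "2DL5", "2DS35", "2DP1/L1")
add("cA01|tA01-ins3", c(cA01, tA01, i3))
add("cB01|tA01-ins3", c(cB01, tA01, i3))
add("cB02|tA01-ins3", c(cB02, tA01, i3))
add("cA01|tB01-ins3", c(cA01, tB01, i3))
add("cB01|tB01-ins3", c(cB01, tB01, i3))
add("cA01|tA01-ins4", c(cA01, tA01, i4))
add("cB01|tA01-ins4", c(cB01, tA01, i4))
add("cB02|tA01-ins4", c(cB02, tA01, i4))
add("cA01|tB01-ins4", c(cA01, tB01, i4))
add("cB01|tB01-ins4", c(cB01, tB01, i4))
add("cA01|tA01-ins5", c(cA01, tA01, i5))
add("cB01|tA01-ins5", c(cB01, tA01, i5))
add("cB02|tA01-ins5", c(cB02, tA01, i5))
add("cB03|tA01-ins5", c(cB03, tA01, i5))
add("cB01|tB01-ins5", c(cB01, tB01, i5))
## -- combined submotifs ---------------------------------------------------
add("cB01|tA01-del3-ins4", c(drop1(cB01, "2DS2"), tA01, i4))
add("cB02|tB01-del3-del6",
    c(drop1(cB02, c("2DS2", "3DP1")), drop1(tB01, c("2DL4", "3DS1"))))

names(recs) <- vapply(recs, function(r) r$name, "")
stopifnot(length(recs) == 37L, !anyDuplicated(names(recs)))

## -- frequencies ----------------------------------------------------------
## Submotif rows (printed percentages) split equally among their records.
sub_rows <- list(
  cB03  = list(f = 0.24, recs = "cB03|tA01"),
  del3  = list(f = 0.27, recs = c("cB01|tA01-del3", "cB02|tA01-del3")),
  del4  = list(f = 0.02, recs = "cB01|tA01-del4"),
  del9  = list(f = 0.02, recs = "cB01|tA01-del9"),
  del10 = list(f = 0.19, recs = "cB01|tA01-del10"),
  hybd1 = list(f = 0.39, recs = "cA01|tA01-hybd1"),
  del5  = list(f = 0.11, recs = c("cA01|tA01-del5", "cB01|tA01-del5")),
  del6  = list(f = 2.37, recs = c("cA01|tB01-del6", "cB02|tB01-del6")),
  del78 = list(f = 0.61, recs = c("cA01|tB01-del7", "cB01|tB01-del7",
                                  "cA01|tB01-del8")),
  ins3  = list(f = 0.16, recs = c("cA01|tA01-ins3", "cB01|tA01-ins3",
                                  "cB02|tA01-ins3", "cA01|tB01-ins3",
                                  "cB01|tB01-ins3")),
  ins4  = list(f = 1.01, recs = c("cA01|tA01-ins4", "cB01|tA01-ins4",
                                  "cB02|tA01-ins4", "cA01|tB01-ins4",
                                  "cB01|tB01-ins4")),
  ins5  = list(f = 1.05, recs = c("cA01|tA01-ins5", "cB01|tA01-ins5",
                                  "cB02|tA01-ins5", "cB03|tA01-ins5",
                                  "cB01|tB01-ins5")),
  comb  = list(f = 0.16, recs = c("cB01|tA01-del3-ins4",
                                  "cB02|tB01-del3-del6"))
)
freq <- setNames(numeric(37), names(recs))
for (row in sub_rows) freq[row$recs] <- (row$f / 100) / length(row$recs)
sub_mass <- sum(vapply(sub_rows, function(r) r$f, 0)) / 100   # 0.0660
stopifnot(abs(sub_mass - 0.0660) < 1e-12)

## Major mass split under cen x tel independence.  Printed centromeric
## major percentages exclude every submotif-bearing chromosome; printed
## telomeric percentages include chromosomes whose cen half bears a
## cen-only submotif (their tel half is intact), so subtract that mass
## from the printed tA01 figure before normalising.
R <- 1 - sub_mass
cen_printed <- c(cA01 = 66.93, cB01 = 11.55, cB02 = 14.86) / 100
cen_only_telA <- sum(freq[c("cB03|tA01", "cB01|tA01-del3", "cB02|tA01-del3",
                            "cB01|tA01-del4", "cB01|tA01-del9",
                            "cB01|tA01-del10")])
tel_adj <- c(tA01 = 0.7461 - cen_only_telA, tB01 = 0.1963)
r_c <- cen_printed / sum(cen_printed) * R
t_t <- tel_adj / sum(tel_adj) * R
for (c in names(r_c)) for (t in names(t_t))
  freq[paste0(c, "|", t)] <- r_c[[c]] * t_t[[t]] / R
freq <- freq / sum(freq)
stopifnot(abs(sum(freq) - 1) < 1e-12)

## sanity: reconstructed printed-style marginals match Table-3 within
## rounding slack
major <- names(freq)[!grepl("-", names(freq)) ]  # no submotif suffix
major <- setdiff(major, "cB03|tA01")
printed_cen <- sapply(c("cA01", "cB01", "cB02"), function(c)
  sum(freq[major[startsWith(major, c)]]))
stopifnot(max(abs(printed_cen * 100 - c(66.93, 11.55, 14.86))) < 0.2)
printed_tA <- sum(freq[major[grepl("tA01", major)]]) + cen_only_telA
stopifnot(abs(printed_tA * 100 - 74.61) < 0.2)

cat <- data.frame(
  name = names(recs),
  cen_motif = sub("\\|.*", "", names(recs)),
  tel_motif = sub("-.*", "", sub(".*\\|", "", names(recs))),
  submotifs = vapply(names(recs), function(n) {
    parts <- strsplit(sub(".*\\|", "", n), "-", fixed = TRUE)[[1]]
    if (length(parts) > 1) paste(parts[-1], collapse = ",") else "."
  }, ""),
  partial_3DL2 = vapply(recs, function(r) r$partial_3DL2, 0L),
  stringsAsFactors = FALSE
)
m <- t(vapply(recs, function(r) r$v, recs[[1]]$v))
colnames(m) <- sub("/", ".", cols, fixed = TRUE)
cat <- base::cbind(cat, as.data.frame(m), frequency = sprintf("%.12f", freq))
rownames(cat) <- NULL

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(cat, "inst/extdata/kir_catalog.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## ------------------------------------------------------------------------
## Assay definitions: amplicons, scored SNP targets, ratio rules, hybrid
## base carriage.  Diagnostic bases are the printed ones; counterpart
## bases of the other amplified genes are a consistent transcription
## choice (they are unprinted).
assays <- "assay\texon\tgenes_amplified
2DL2-001\t5\t2DL2,2DL3,2DS2,2DP1,(3DL2)
2DL3-006\t7/8\t2DL3,2DS3,2DS5
2DL5\t3\t2DL1,2DL4,2DL5,3DP1
2DP1-002\t3\t2DP1
2DS2-002\t4\t2DL1,2DL2,2DL3,2DS2,3DP1
2DS35-005\t4\t2DS1,2DS3,2DS5,3DP1,(2DL1)
3DL1-002\t4\t3DL1,3DS1
3DL1-005\t4\t3DL1,3DS1
KIR-2DL2-N1\t4\t2DL2,2DL3,2DS2,2DP1
KIR-2DS2-N1\t5\t2DL2,2DL3,2DP1,2DS2
2DS1-4-002\t4\t2DS1,2DL1,2DS4,(2DS3),(2DS5)
2DS1-004\t4\t2DS1,2DL1,(2DS4)
3DL1-3DS1-01\t4\t3DL1,3DS1,3DL2
3DL1-3DS1-05\t4\t3DL1,3DS1,3DL2
"
writeLines(assays, "inst/extdata/kir_assays.tsv", sep = "")

targets <- "assay\tposition\tbase\tgenes\ttier
2DL2-001\t93\tT\t2DL2\tprimary
2DL2-001\t93\tC\t2DL3,2DS2,2DP1\tshared
2DL2-001\t137\tC\t2DS2,2DL2,2DL3\tshared
2DL2-001\t137\tT\t2DP1\tsecondary
2DL2-001\t206\tA\t2DL2,2DL3\tshared
2DL2-001\t206\tC\t2DP1\tshared
2DL2-001\t206\tG\t2DS2\tshared
2DL2-001\t209\tT\t2DS2\tsecondary
2DL2-001\t209\tC\t2DL2,2DL3,2DP1\tshared
2DL3-006\t136\tG\t2DL3\tprimary
2DL3-006\t136\tT\t2DS3,2DS5\tshared
2DL3-006\t616\tT\t2DL3\tprimary
2DL3-006\t616\tC\t2DS3,2DS5\tshared
2DL3-006\t59\tA\t2DS3,2DS5\tsecondary
2DL3-006\t59\tG\t2DL3\tshared
2DL5\t170\tG\t2DL5\tprimary
2DL5\t170\tC\t2DL4,3DP1\tshared
2DL5\t170\tT\t2DL1\tshared
2DL5\t174\tA\t2DL5\tprimary
2DL5\t174\tC\t2DL4,3DP1\tshared
2DL5\t58\tG\t2DL5\tsecondary
2DL5\t58\tA\t2DL4,3DP1\tshared
2DL5\t79\tT\t2DL5\tsecondary
2DL5\t79\tC\t2DL4,3DP1\tshared
2DL5\t103\tC\t2DL5\tsecondary
2DL5\t103\tT\t2DL4,3DP1\tshared
2DL5\t157\tA\t2DL5\tsecondary
2DL5\t157\tG\t2DL4,3DP1\tshared
2DP1-002\t128\tG\t2DP1\tprimary
2DP1-002\t130\tA\t2DP1\tprimary
2DS2-002\t89\tA\t2DS2\tprimary
2DS2-002\t89\tG\t2DL1,2DL2,2DL3\tshared
2DS2-002\t60\tA\t2DL1\tsecondary
2DS2-002\t60\tG\t2DL2,2DL3,2DS2\tshared
2DS2-002\t117\tA\t2DL1\tsecondary
2DS2-002\t117\tC\t2DL2,2DL3,2DS2\tshared
2DS2-002\t154\tA\t2DL1\tsecondary
2DS2-002\t154\tT\t2DL2,2DL3,2DS2\tshared
2DS35-005\t247\tT\t2DS3,2DS5\tprimary
2DS35-005\t247\tC\t2DS1\tshared
2DS35-005\t251\tG\t2DS3,2DS5\tprimary
2DS35-005\t251\tA\t2DS1\tshared
2DS35-005\t403\tA\t2DS3,2DS5\tprimary
2DS35-005\t403\tG\t2DS1\tshared
2DS35-005\t404\tT\t2DS3,2DS5\tprimary
2DS35-005\t404\tC\t2DS1\tshared
2DS35-005\t446\tG\t2DS3\tprimary
2DS35-005\t446\tA\t2DS1\tsecondary
2DS35-005\t446\tT\t2DS5\tshared
2DS35-005\t507\tT\t2DS3\tprimary
2DS35-005\t507\tC\t2DS1,2DS5\tshared
2DS35-005\t376\tC\t2DS5\tprimary
2DS35-005\t376\tT\t2DS1,2DS3\tshared
2DS35-005\t447\tA\t2DS5\tprimary
2DS35-005\t447\tG\t2DS1,2DS3\tshared
3DL1-002\t85\tT\t3DL1\tprimary
3DL1-002\t85\tG\t3DS1\tprimary
3DL1-005\t157\tC\t3DL1\tprimary
3DL1-005\t157\tT\t3DS1\tprimary
3DL1-005\t167\tT\t3DL1\tprimary
3DL1-005\t167\tG\t3DS1\tprimary
KIR-2DL2-N1\t126\tG\t2DL2\tprimary
KIR-2DL2-N1\t126\tA\t2DL3,2DS2,2DP1\tshared
KIR-2DL2-N1\t213\tA\t2DS2\tsecondary
KIR-2DL2-N1\t213\tG\t2DL2,2DL3,2DP1\tshared
KIR-2DL2-N1\t217\tC\t2DP1\tsecondary
KIR-2DL2-N1\t217\tT\t2DL2,2DL3,2DS2\tshared
KIR-2DS2-N1\t92\tT\t2DS2\tprimary
KIR-2DS2-N1\t92\tC\t2DL2,2DL3,2DP1\tshared
KIR-2DS2-N1\t179\tT\t2DL2\tsecondary
KIR-2DS2-N1\t179\tC\t2DL3,2DS2,2DP1\tshared
2DS1-4-002\t257\tA\t2DS1\tprimary
2DS1-4-002\t257\tC\t2DL1\tprimary
2DS1-4-002\t257\tT\t2DS4\tprimary
2DS1-4-002\t86\tT\t2DS4\tprimary
2DS1-4-002\t86\tC\t2DS1,2DL1\tshared
2DS1-4-002\t95\tA\t2DS4\tprimary
2DS1-4-002\t95\tG\t2DS1,2DL1\tshared
2DS1-4-002\t76\tT\t2DS4\tsecondary
2DS1-4-002\t76\tA\t2DS1,2DL1\tshared
2DS1-4-002\t138\tG\t2DS4\tsecondary
2DS1-4-002\t138\tA\t2DS1,2DL1\tshared
2DS1-004\t80\tA\t2DS1\tprimary
2DS1-004\t80\tC\t2DL1\tprimary
2DS1-004\t139\tG\t2DL1\tsecondary
2DS1-004\t139\tT\t2DS1\tsecondary
3DL1-3DS1-01\t300\tA\t3DL1,3DS1\tshared
3DL1-3DS1-01\t300\tG\t3DL2\tsecondary
3DL1-3DS1-05\t310\tC\t3DL1,3DS1\tshared
3DL1-3DS1-05\t310\tT\t3DL2\tsecondary
"
writeLines(targets, "inst/extdata/kir_assay_targets.tsv", sep = "")

rules <- "assay\tnum_genes\tden_genes\tnum_position\tnum_base\tden_position\tden_base\tclasses
2DL2-001\t2DS2,2DL2,2DL3\t2DP1\t137\tC\t137\tT\t1:1,2:1,3:1,3:2,4:1
2DL2-001\t2DL2,2DL3\t2DP1\t206\tA\t206\tC\t1:1,2:1
2DL2-001\t2DL2,2DL3\t2DS2\t206\tA\t209\tT\t1:1,2:1
2DL3-006\t2DL3\t2DS3,2DS5\t136\tG\t136\tT\t1:1,2:1,1:2
2DL5\t2DL5\t2DL4,3DP1\t170\tG\t170\tC\tany
2DS35-005\t2DS1\t2DS3\t446\tA\t446\tG\t1:1,1:2
2DS35-005\t2DS3\t2DS5\t446\tG\t447\tA\t1:1,2:1,1:2
3DL1-005\t3DL1\t3DS1\t167\tT\t167\tG\t1:1
KIR-2DL2-N1\t2DS2\t2DP1\t213\tA\t217\tC\t1:1,1:2
3DL1-3DS1-01\t3DL1,3DS1\t3DL2\t300\tA\t300\tG\t1:1,0:2,1:2,3:2
3DL1-3DS1-05\t3DL1,3DS1\t3DL2\t310\tC\t310\tT\t1:1,0:2,1:2,3:2
"
writeLines(rules, "inst/extdata/kir_ratio_rules.tsv", sep = "")

carriage <- "hybrid\tassay\tpresents_as
2DS2/S3\t2DL2-001\t2DS2
2DS2/S3\t2DS2-002\t2DS2
2DS2/S3\tKIR-2DL2-N1\t2DS2
2DS2/S3\tKIR-2DS2-N1\t2DS2
2DS2/S3\t2DL3-006\t2DS3
2DP1/L1\t2DP1-002\t2DP1
2DP1/L1\t2DS2-002\t2DL1
2DP1/L1\t2DS1-4-002\t2DL1
2DP1/L1\t2DS1-004\t2DL1
2DL1/S1\t2DL5\t2DL1
2DL1/S1\t2DS35-005\t2DS1
2DL1/S1\t2DS1-4-002\t2DS1
2DL1/S1\t2DS1-004\t2DS1
3DL1/L2\t3DL1-002\t3DL1
3DL1/L2\t3DL1-005\t3DL1
3DL1/L2\t3DL1-3DS1-01\t3DL1
3DL1/L2\t3DL1-3DS1-05\t3DL1
"
writeLines(carriage, "inst/extdata/kir_hybrid_carriage.tsv", sep = "")

message("wrote inst/extdata tables: 37 catalog records, ",
        length(readLines("inst/extdata/kir_assay_targets.tsv")) - 1L,
        " scored targets")
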