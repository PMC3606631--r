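## Recombination breakpoint detection in aligned triplets
## (query + two candidate parents) and pairwise identity profiles.

as_triplet <- function(x) {
  if (inherits(x, "kir_triplet")) return(x)
  stop("expected a kir_triplet (see simulate_triplet() or read_triplet_fasta())")
}

#' Read an aligned FASTA into a triplet
#'
#' The first record is taken as the query and the next two as the
#' candidate parents unless names are given.
#'
#' @param path Aligned FASTA file (equal-length records).
#' @param query,parent_a,parent_b Optional record names overriding the
#'   positional default.
#' @return `kir_triplet`.
#' @export
read_triplet_fasta <- function(path, query = NULL, parent_a = NULL,
                               parent_b = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 3L) stop("need at least 3 aligned records")
  nms <- names(seqs)
  pick <- function(want, default) {
    if (is.null(want)) return(default)
    i <- match(want, nms)
    if (is.na(i)) stop("record not found in FASTA: ", want)
    i
  }
  qi <- pick(query, 1L); ai <- pick(parent_a, 2L); bi <- pick(parent_b, 3L)
  lens <- Biostrings::width(seqs)[c(qi, ai, bi)]
  if (length(unique(lens)) != 1L)
    stop("aligned records have unequal lengths")
  split1 <- function(i) strsplit(toupper(as.character(seqs[[i]])), "")[[1L]]
  structure(list(query = split1(qi), parent_a = split1(ai),
                 parent_b = split1(bi),
                 names = nms[c(qi, ai, bi)], length = lens[1L],
                 truth = NULL),
            class = "kir_triplet")
}

#' Write a triplet as aligned FASTA
#'
#' @param triplet `kir_triplet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triplet_fasta <- function(triplet, path) {
  seqs <- Biostrings::DNAStringSet(c(paste(triplet$query, collapse = ""),
                                     paste(triplet$parent_a, collapse = ""),
                                     paste(triplet$parent_b, collapse = "")))
  names(seqs) <- triplet$names
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Informative sites of an aligned triplet
#'
#' Alignment columns where the two parents differ and the query matches
#' exactly one of them; columns containing gaps or N in any sequence,
#' and columns where the query matches neither parent, are excluded (the
#' latter are counted in the diagnostics attribute).
#'
#' @param triplet `kir_triplet`.
#' @return data.frame with columns `column` (0-based) and `supports`
#'   (`"A"`/`"B"`), ascending; attribute `"n_unresolved"` counts
#'   three-way-mismatch columns.
#' @export
informative_sites <- function(triplet) {
  tr <- as_triplet(triplet)
  good <- !(tr$query %in% c("-", "N") | tr$parent_a %in% c("-", "N") |
            tr$parent_b %in% c("-", "N"))
  differ <- tr$parent_a != tr$parent_b & good
  ma <- differ & tr$query == tr$parent_a
  mb <- differ & tr$query == tr$parent_b
  unresolved <- differ & !ma & !mb
  cols <- which(ma | mb)
  out <- data.frame(column = cols - 1L,
                    supports = ifelse(ma[cols], "A", "B"),
                    stringsAsFactors = FALSE)
  attr(out, "n_unresolved") <- sum(unresolved)
  if (!nrow(out))
    attr(out, "diagnostic") <- "no informative sites (parents identical or query diverged)"
  out
}

chisq_2x2 <- function(a, b, c, d) {
  ## chi-square on [[a, b], [c, d]] with continuity correction when any
  ## expected cell is small
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(0)
  e <- outer(c(r1, r2), c(c1, c2)) / n
  yates <- any(e < 5)
  num <- abs(a * d - b * c) - if (yates) n / 2 else 0
  num <- max(num, 0)
  n * num^2 / (r1 * r2 * c1 * c2)
}

#' Scan an aligned triplet for recombination breakpoints
#'
#' At each boundary between consecutive informative sites, the parental
#' support of the flanking windows is tested in a 2x2 chi-square
#' (left/right x supports-A/supports-B, continuity-corrected when
#' counts are small); p-values are Bonferroni-corrected by the number of
#' boundaries tested and significant maximal non-overlapping calls are
#' returned.
#'
#' @param triplet `kir_triplet`.
#' @param window Flank size (default 20).
#' @param alpha Significance threshold after correction (default 0.001).
#' @param window_unit `"sites"` (default): each flank holds up to
#'   `window` informative sites; `"columns"`: each flank holds the
#'   informative sites within `window` alignment columns.
#' @return data.frame of calls: `start`, `end` (0-based half-open column
#'   interval between the flanking informative sites), `statistic`,
#'   `p_adjusted`, `left_support`, `right_support` (counts as
#'   `"A/B"` strings), sorted and non-overlapping.
#' @export
scan_triplet <- function(triplet, window = 20L, alpha = 0.001,
                         window_unit = c("sites", "columns")) {
  tr <- as_triplet(triplet)
  window_unit <- match.arg(window_unit)
  if (2L * window > tr$length)
    stop("window larger than the alignment permits")
  sites <- informative_sites(tr)
  k <- nrow(sites)
  empty <- data.frame(start = integer(), end = integer(),
                      statistic = numeric(), p_adjusted = numeric(),
                      left_support = character(),
                      right_support = character(),
                      stringsAsFactors = FALSE)
  if (k < 2L) return(empty)
  isB <- sites$supports == "B"
  bnd <- seq_len(k - 1L)  # boundary after site i
  stat <- numeric(length(bnd))
  la <- lb <- ra <- rb <- integer(length(bnd))
  for (i in bnd) {
    if (window_unit == "sites") {
      L <- max(1L, i - window + 1L):i
      R <- (i + 1L):min(k, i + window)
    } else {
      cutL <- sites$column[i] - window
      cutR <- sites$column[i + 1L] + window
      L <- which(sites$column <= sites$column[i] & sites$column > cutL)
      R <- which(sites$column >= sites$column[i + 1L] & sites$column < cutR)
    }
    lb[i] <- sum(isB[L]); la[i] <- length(L) - lb[i]
    rb[i] <- sum(isB[R]); ra[i] <- length(R) - rb[i]
    stat[i] <- chisq_2x2(la[i], lb[i], ra[i], rb[i])
  }
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  p_adj <- pmin(1, p * length(bnd))
  sig <- which(p_adj <= alpha)
  if (!length(sig)) return(empty)
  ## greedy selection of maximal non-overlapping calls: strongest
  ## boundary first, suppressing boundaries whose flanks overlap it
  chosen <- integer()
  remaining <- sig[order(-stat[sig])]
  while (length(remaining)) {
    b <- remaining[1L]
    chosen <- c(chosen, b)
    remaining <- remaining[abs(remaining - b) > window]
  }
  chosen <- sort(chosen)
  out <- data.frame(start = sites$column[chosen] + 1L,
                    end = sites$column[chosen + 1L],
                    statistic = stat[chosen], p_adjusted = p_adj[chosen],
                    left_support = sprintf("%d/%d", la[chosen], lb[chosen]),
                    right_support = sprintf("%d/%d", ra[chosen], rb[chosen]),
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Convert alignment columns to ungapped query coordinates
#'
#' @param triplet `kir_triplet`.
#' @param columns 0-based alignment columns.
#' @return 0-based positions in the ungapped query (NA at gap columns).
#' @export
alignment_to_query_coord <- function(triplet, columns) {
  tr <- as_triplet(triplet)
  notgap <- tr$query != "-"
  pos <- cumsum(notgap) - 1L
  ifelse(notgap[columns + 1L], pos[columns + 1L], NA_integer_)
}

#' Sliding-window pairwise identity profile
#'
#' Percent identity of the query to each reference in half-open 0-based
#' windows, excluding columns where either sequence has a gap or N.
#'
#' @param query Character vector of aligned bases (or `kir_triplet`,
#'   whose parents become the references).
#' @param references List (named) of aligned character vectors.
#' @param window Window width in columns (default 400).
#' @param step Step between window starts (default 100).
#' @return data.frame: `start`, `end`, then one percent-identity column
#'   per reference (NA when a window has no comparable columns).
#' @export
identity_profile <- function(query, references = NULL, window = 400L,
                             step = 100L) {
  if (inherits(query, "kir_triplet")) {
    tr <- query
    query <- tr$query
    references <- list(parentA = tr$parent_a, parentB = tr$parent_b)
  }
  len <- length(query)
  stopifnot(all(vapply(references, length, 0L) == len), window <= len)
  starts <- seq(0L, len - window, by = step)
  out <- data.frame(start = starts, end = starts + window)
  for (nm in names(references)) {
    ref <- references[[nm]]
    usable <- !(query %in% c("-", "N") | ref %in% c("-", "N"))
    match_ <- usable & query == ref
    cum_u <- c(0L, cumsum(usable))
    cum_m <- c(0L, cumsum(match_))
    nu <- cum_u[starts + window + 1L] - cum_u[starts + 1L]
    nmatch <- cum_m[starts + window + 1L] - cum_m[starts + 1L]
    out[[nm]] <- ifelse(nu > 0L, 100 * nmatch / nu, NA_real_)
  }
  out
}
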