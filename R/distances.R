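#' Site-pattern counts for a sequence pair
#'
#' Compares two aligned sequences column by column. Only columns where both
#' symbols are unambiguous bases (A, C, G, T) are comparable (pairwise
#' deletion); gaps, N and IUPAC ambiguity codes are skipped. Transitions are
#' A<->G and C<->T; every other mismatch is a transversion.
#'
#' @param a,b aligned DNA strings of equal length.
#' @return A list with `n` (comparable sites), `P` (transition proportion)
#'   and `Q` (transversion proportion).
#' @export
count_site_patterns <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  bases <- c("A", "C", "G", "T")
  ok <- a %in% bases & b %in% bases
  n <- sum(ok)
  if (n == 0L) stop("zero comparable sites")
  a <- a[ok]; b <- b[ok]
  mism <- a != b
  # purine (A,G) vs pyrimidine (C,T) class; same-class mismatch = transition
  cls <- function(x) x == "A" | x == "G"
  ts <- mism & (cls(a) == cls(b))
  list(n = n, P = sum(ts) / n, Q = sum(mism & !ts) / n)
}

#' Kimura 2-parameter distance from site-pattern proportions
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, in expected substitutions
#' per site. When either factor is non-positive the distance is saturated
#' and `NA_real_` is returned (recorded, not raised), so callers can track
#' undefined pairs.
#'
#' @param counts a list with elements `P` and `Q` (as from
#'   [count_site_patterns]), or a numeric `P` when `Q` is given separately.
#' @param Q transversion proportion when `counts` is numeric.
#' @return Distance in substitutions/site, or `NA_real_` if undefined.
#' @export
k2p <- function(counts, Q = NULL) {
  if (is.list(counts)) {
    P <- counts$P; Q <- counts$Q
  } else {
    P <- counts
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

# Integer encoding of an aligned record set: rows = records, cols = sites,
# A=1, C=2, G=3, T=4, anything else 0. Purine class precomputed alongside.
.encode_alignment <- function(sequences) {
  key <- integer(256)
  key[utf8ToInt("A")] <- 1L; key[utf8ToInt("C")] <- 2L
  key[utf8ToInt("G")] <- 3L; key[utf8ToInt("T")] <- 4L
  n <- length(sequences)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences are not aligned")
  m <- matrix(0L, n, L)
  for (i in seq_len(n))
    m[i, ] <- key[utf8ToInt(toupper(sequences[i]))]
  m
}

# K2P machinery on the integer encoding; shared by distance_matrix and the
# bootstrap resampler.
.pair_k2p <- function(x, y) {
  ok <- x > 0L & y > 0L
  n <- sum(ok)
  if (n == 0L) return(c(n = 0, P = NA_real_, Q = NA_real_, d = NA_real_))
  x <- x[ok]; y <- y[ok]
  mism <- x != y
  pur_x <- x == 1L | x == 3L
  pur_y <- y == 1L | y == 3L
  ts <- sum(mism & (pur_x == pur_y))
  tv <- sum(mism) - ts
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  c(n = n, P = P, Q = Q, d = d)
}

.k2p_matrices <- function(enc, labels) {
  n <- nrow(enc)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  ns <- matrix(0L, n, n, dimnames = list(labels, labels))
  diag(ns) <- rowSums(enc > 0L)
  undef <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- .pair_k2p(enc[i, ], enc[j, ])
    ns[i, j] <- ns[j, i] <- as.integer(r[["n"]])
    d[i, j] <- d[j, i] <- r[["d"]]
    if (is.na(r[["d"]]))
      undef <- c(undef, paste(labels[i], labels[j], sep = "\r"))
  }
  list(d = d, n_sites = ns, undefined = undef)
}

#' Pairwise K2P distance matrix
#'
#' Computes Kimura 2-parameter distances between all record pairs of an
#' aligned set. Under `deletion = "pairwise"` each pair uses every column
#' where both members carry an unambiguous base; under `"complete"` every
#' column containing any gap/ambiguity in any record is removed first.
#' Saturated pairs (no finite K2P estimate) and pairs with zero comparable
#' sites are listed in `undefined_pairs` with a warning rather than
#' aborting.
#'
#' @param records aligned [barcode_records] (>= 2 rows).
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return An object of class `k2p_dist`: list with `labels`, symmetric
#'   matrices `d` (substitutions/site; `NA` where undefined) and `n_sites`,
#'   `undefined_pairs` (two-column character matrix), and `deletion`.
#' @export
distance_matrix <- function(records, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (nrow(records) < 2L) stop("need >= 2 records")
  aligned_length(records)
  enc <- .encode_alignment(records$sequence)
  if (deletion == "complete") {
    keep <- colSums(enc == 0L) == 0L
    if (!any(keep)) stop("complete deletion removed every column")
    enc <- enc[, keep, drop = FALSE]
  }
  res <- .k2p_matrices(enc, records$accession)
  undef <- if (length(res$undefined)) {
    do.call(rbind, strsplit(res$undefined, "\r", fixed = TRUE))
  } else {
    matrix(character(0), 0, 2)
  }
  if (nrow(undef))
    warning(nrow(undef), " pair(s) with undefined K2P distance")
  structure(list(labels = records$accession, d = res$d,
                 n_sites = res$n_sites, undefined_pairs = undef,
                 deletion = deletion),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("K2P distance matrix over", length(x$labels), "records (",
      x$deletion, "deletion );",
      nrow(x$undefined_pairs), "undefined pair(s)\n")
  invisible(x)
}

#' Export a distance matrix as labelled TSV
#'
#' Writes the square distance matrix (3 decimal places, the precision used
#' in reports; `NA` for undefined pairs) to a tab-separated file.
#'
#' @param dm a `k2p_dist` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  m <- format(round(dm$d, 3), nsmall = 3, trim = TRUE)
  m[is.na(dm$d)] <- "NA"
  df <- data.frame(accession = dm$labels, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("accession", dm$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
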