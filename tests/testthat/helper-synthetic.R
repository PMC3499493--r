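# Shared fixture builders. Everything is generated in code; no binary data.

# Random record table with valid labels (not necessarily aligned).
random_records <- function(n, len = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  barcode_records(
    accession = sprintf("ACC%03d", seq_len(n)),
    species = sample(c("Rita rita", "Mystus vittatus", "Wallago attu"),
                     n, replace = TRUE),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), ""))
}

# Records built from explicit (accession, species, sequence) triples.
records_from <- function(...) {
  rows <- list(...)
  barcode_records(accession = vapply(rows, `[[`, "", 1L),
                  species = vapply(rows, `[[`, "", 2L),
                  sequence = vapply(rows, `[[`, "", 3L))
}

# Full delineation analysis used by several test files.
analyse_dataset <- function(records, trim = "none") {
  dm <- suppressWarnings(distance_matrix(records))
  tree <- nj_tree(dm)
  partition <- partition_pairs(dm, records)
  cohesion <- vapply(unique(records$species), function(s)
    is_cohesive(tree, s, records), logical(1))
  thresholds <- compute_thresholds(partition, cohesion, trim = trim)
  list(dm = dm, tree = tree, partition = partition,
       cohesion = cohesion, thresholds = thresholds,
       flags = flag_anomalies(partition, thresholds),
       delineation = delineate(records, dm, tree, thresholds))
}

# Independent brute-force K2P for a sequence pair: recounts site patterns
# symbol by symbol with explicit case analysis, then evaluates the closed
# form. Used as the oracle against the matrix implementation.
brute_k2p <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    x <- a[i]; y <- b[i]
    if (!(x %in% c("A", "C", "G", "T"))) next
    if (!(y %in% c("A", "C", "G", "T"))) next
    n <- n + 1L
    if (x == y) next
    pair <- paste(sort(c(x, y)), collapse = "")
    if (pair == "AG" || pair == "CT") ts <- ts + 1L else tv <- tv + 1L
  }
  if (n == 0L) return(NULL)
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Bipartition set of a phylo tree as canonical strings (test-local copy,
# independent of the package internals).
split_set <- function(phy) {
  tips <- phy$tip.label
  ref <- sort(tips)[1L]
  parts <- ape::prop.part(phy)
  out <- character(0)
  for (p in parts) {
    side <- tips[p]
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  sort(unique(out))
}
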