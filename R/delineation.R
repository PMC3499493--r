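#' Partition defined distance pairs by taxonomic relation
#'
#' Every defined pair of the distance matrix is classified from the two
#' records' labels: `conspecific` (same species), `congeneric` (same genus,
#' different species) or `other` (different genera). The three classes
#' partition the defined pairs.
#'
#' @param dm a `k2p_dist` object.
#' @param records [barcode_records] covering every matrix label.
#' @return A `data.frame` of class `pair_partition` with columns `acc_a`,
#'   `acc_b`, `species_a`, `species_b`, `genus_a`, `genus_b`, `distance`,
#'   `type`.
#' @export
partition_pairs <- function(dm, records) {
  idx <- match(dm$labels, records$accession)
  if (anyNA(idx))
    stop("labels without species metadata: ",
         paste(dm$labels[is.na(idx)], collapse = ", "))
  sp <- records$species[idx]
  gen <- records$genus[idx]
  n <- length(dm$labels)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  d <- dm$d[cbind(i, j)]
  keep <- !is.na(d)
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  type <- ifelse(sp[i] == sp[j], "conspecific",
                 ifelse(gen[i] == gen[j], "congeneric", "other"))
  out <- data.frame(acc_a = dm$labels[i], acc_b = dm$labels[j],
                    species_a = sp[i], species_b = sp[j],
                    genus_a = gen[i], genus_b = gen[j],
                    distance = d, type = type,
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_partition", "data.frame")
  out
}

#' Delineation thresholds and the fold-ratio barcoding gap
#'
#' The conspecific threshold is the maximum K2P divergence over conspecific
#' pairs of species judged cohesive on the NJ tree; the congeneric
#' threshold is the minimum divergence over congeneric pairs whose two
#' species are each cohesive. The barcoding gap is their fold ratio
#' `min_congeneric / max_conspecific` (reported to 2 decimals; full
#' precision retained).
#'
#' `trim = "midgap"` additionally screens the eligible conspecific pairs
#' for gap-dwelling records before taking the maximum: a record whose
#' *every* conspecific divergence exceeds the geometric midpoint between
#' the typical conspecific divergence (the pool median) and the congeneric
#' floor (`sqrt(median * min_congeneric)` — the natural boundary on the
#' fold scale the barcoding gap is defined on) has its pairs set aside. A
#' deep intraspecific lineage elevates all of its record's conspecific
#' distances at once and would otherwise *define* the conspecific maximum,
#' masking itself from anomaly flagging; an ordinary noisy pair elevates
#' only itself and is never set aside. Off by default: with the trim
#' disabled the thresholds are a deterministic single pass and clean data
#' can never produce a deep-divergence flag. Trimmed pairs are returned in
#' `$trimmed` and surface downstream as deep-divergence flags.
#'
#' @param partition a `pair_partition` from [partition_pairs].
#' @param cohesion named logical vector, species -> cohesive on the tree
#'   (see [is_cohesive]). Species absent from the vector are treated as not
#'   cohesive. `NULL` treats every species as cohesive.
#' @param trim `"none"` (default) or `"midgap"`.
#' @return An object of class `delineation_thresholds`: list with
#'   `max_conspecific`, `min_congeneric`, `gap_fold`, the defining pairs,
#'   and `trimmed` (possibly empty data frame of set-aside pairs).
#' @export
compute_thresholds <- function(partition, cohesion = NULL,
                               trim = c("none", "midgap")) {
  trim <- match.arg(trim)
  coh <- function(sp) {
    if (is.null(cohesion)) rep(TRUE, length(sp))
    else !is.na(cohesion[sp]) & cohesion[sp]
  }
  cons <- partition[partition$type == "conspecific" &
                      coh(partition$species_a), , drop = FALSE]
  cong <- partition[partition$type == "congeneric" &
                      coh(partition$species_a) &
                      coh(partition$species_b), , drop = FALSE]
  if (nrow(cong) == 0L)
    stop("thresholds undefined: no eligible congeneric pairs")
  if (nrow(cons) == 0L)
    stop("thresholds undefined: no eligible conspecific pairs ",
         "(all species singletons?)")
  min_congeneric <- min(cong$distance)
  trimmed <- cons[0, , drop = FALSE]
  if (trim == "midgap") {
    med <- stats::median(cons$distance)
    if (med > 0) {
      cut <- sqrt(med * min_congeneric)
      accs <- unique(c(cons$acc_a, cons$acc_b))
      gap_dwelling <- vapply(accs, function(a) {
        d <- cons$distance[cons$acc_a == a | cons$acc_b == a]
        min(d) > cut
      }, logical(1))
      set_aside <- cons$acc_a %in% accs[gap_dwelling] |
        cons$acc_b %in% accs[gap_dwelling]
      if (all(set_aside))
        stop("midgap trim removed every conspecific pair; ",
             "no barcoding gap in these data")
      trimmed <- cons[set_aside, , drop = FALSE]
      cons <- cons[!set_aside, , drop = FALSE]
    }
  }
  max_conspecific <- max(cons$distance)
  structure(list(max_conspecific = max_conspecific,
                 min_congeneric = min_congeneric,
                 gap_fold = min_congeneric / max_conspecific,
                 max_pair = cons[which.max(cons$distance),
                                 c("acc_a", "acc_b", "species_a")],
                 min_pair = cong[which.min(cong$distance),
                                 c("acc_a", "acc_b", "species_a",
                                   "species_b")],
                 trimmed = trimmed, trim = trim),
            class = "delineation_thresholds")
}

#' @export
print.delineation_thresholds <- function(x, ...) {
  cat(sprintf(paste0("Delineation thresholds: max conspecific %.3f, ",
                     "min congeneric %.3f, barcoding gap %.2f-fold\n"),
              x$max_conspecific, x$min_congeneric, x$gap_fold))
  if (nrow(x$trimmed))
    cat("  (", nrow(x$trimmed),
        "deep conspecific pair(s) set aside by midgap trim )\n")
  invisible(x)
}

#' Flag distance pairs that violate the barcoding-gap thresholds
#'
#' Three anomaly kinds, relative to computed thresholds:
#' \describe{
#'   \item{conspecific_merge}{a heterospecific pair at or below the maximum
#'     conspecific divergence — a mislabel or synonymy candidate (equality
#'     counts as a merge: conservative flagging).}
#'   \item{deep_conspecific_divergence}{a conspecific pair above the
#'     maximum conspecific divergence — a deep intraspecific lineage or a
#'     mislabelled same-named record. The more divergent member of the pair
#'     (larger mean distance to its labelled conspecifics) is reported in
#'     `acc_b`.}
#'   \item{subthreshold_congeneric}{a congeneric pair strictly between the
#'     two thresholds — congeners closer than the gap admits.}
#' }
#'
#' @param partition a `pair_partition`.
#' @param thresholds a `delineation_thresholds` object.
#' @return A `data.frame` (possibly 0-row) with columns `kind`, `acc_a`,
#'   `acc_b`, `species_a`, `species_b`, `distance`.
#' @export
flag_anomalies <- function(partition, thresholds) {
  hi <- thresholds$max_conspecific
  lo <- thresholds$min_congeneric
  hetero <- partition$type != "conspecific"
  merge <- hetero & partition$distance <= hi
  deep <- partition$type == "conspecific" & partition$distance > hi
  sub <- partition$type == "congeneric" &
    partition$distance > hi & partition$distance < lo
  rows <- function(mask, kind) {
    if (!any(mask)) return(NULL)
    p <- partition[mask, c("acc_a", "acc_b", "species_a", "species_b",
                           "distance"), drop = FALSE]
    cbind(kind = kind, p, stringsAsFactors = FALSE)
  }
  deep_rows <- rows(deep, "deep_conspecific_divergence")
  if (!is.null(deep_rows)) {
    # orient each deep pair so acc_b is the more aberrant record
    cons <- partition[partition$type == "conspecific", , drop = FALSE]
    mean_d <- function(acc) {
      d <- cons$distance[cons$acc_a == acc | cons$acc_b == acc]
      if (length(d)) mean(d) else 0
    }
    for (r in seq_len(nrow(deep_rows))) {
      if (mean_d(deep_rows$acc_a[r]) > mean_d(deep_rows$acc_b[r])) {
        tmp <- deep_rows$acc_a[r]
        deep_rows$acc_a[r] <- deep_rows$acc_b[r]
        deep_rows$acc_b[r] <- tmp
      }
    }
  }
  out <- rbind(rows(merge, "conspecific_merge"), deep_rows,
               rows(sub, "subthreshold_congeneric"))
  if (is.null(out))
    out <- data.frame(kind = character(0), acc_a = character(0),
                      acc_b = character(0), species_a = character(0),
                      species_b = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Delineate species from tree cohesion and threshold flags
#'
#' A species is `delineated` when its records form an exclusive cluster on
#' the NJ tree and none of its records appear in any anomaly flag;
#' otherwise it is `ambiguous` and its flags are attached. Singleton
#' species are cohesive by convention, so a singleton whose nearest
#' neighbour lies beyond the congeneric minimum is delineated.
#'
#' @param records [barcode_records].
#' @param dm a `k2p_dist` over those records.
#' @param tree a `phylo` tree over the same accessions.
#' @param thresholds a `delineation_thresholds` object.
#' @return A `data.frame` with columns `species`, `n_records`, `cohesive`,
#'   `status`, `n_flags`; the full flag table is attached as attribute
#'   `"flags"`.
#' @export
delineate <- function(records, dm, tree, thresholds) {
  partition <- partition_pairs(dm, records)
  flags <- flag_anomalies(partition, thresholds)
  flagged_accs <- unique(c(flags$acc_a, flags$acc_b))
  species <- unique(records$species)
  cohesive <- vapply(species, function(s)
    is_cohesive(tree, s, records), logical(1))
  touched <- vapply(species, function(s)
    any(records$accession[records$species == s] %in% flagged_accs),
    logical(1))
  out <- data.frame(species = species,
                    n_records = as.integer(table(records$species)[species]),
                    cohesive = cohesive,
                    status = ifelse(cohesive & !touched,
                                    "delineated", "ambiguous"),
                    n_flags = vapply(species, function(s)
                      sum(flags$species_a == s | flags$species_b == s),
                      integer(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "flags") <- flags
  out
}
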