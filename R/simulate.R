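#' Simulation configuration for synthetic barcode datasets
#'
#' Defaults mirror the divergence structure the delineation analysis
#' assumes for COI barcodes: small conspecific divergence (expected
#' pairwise divergence uniform on (0, 0.02) substitutions/site), congeneric
#' divergence at least four-fold larger (uniform on (0.10, 0.15)), 655
#' aligned sites, and transition-biased substitution (kappa = 3, a typical
#' fish mitochondrial bias).
#'
#' @param n_genera number of genera (default 5; with the other defaults
#'   this gives a 30-record, 10-species set — a runtime-scaled emulation of
#'   a multi-genus barcode survey with a handful of individuals per
#'   species).
#' @param species_per_genus species per genus.
#' @param individuals_per_species individuals per species (1 = singleton).
#' @param sequence_length aligned sites (default 655).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param intra_divergence_range `(lo, hi)` expected substitutions/site
#'   between conspecific individuals.
#' @param inter_divergence_range `(lo, hi)` expected substitutions/site
#'   between congeneric species; `lo` must exceed `hi` of the intra range
#'   for a clean scenario.
#' @param mislabel_count records to relabel into a congeneric species.
#' @param deep_lineage_count records to evolve down an extra branch whose
#'   expected divergence falls strictly inside the barcoding gap.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genera = 5, species_per_genus = 2,
                       individuals_per_species = 3,
                       sequence_length = 655, kappa = 3,
                       intra_divergence_range = c(0, 0.02),
                       inter_divergence_range = c(0.10, 0.15),
                       mislabel_count = 0, deep_lineage_count = 0,
                       seed = NULL) {
  stopifnot(n_genera >= 1, species_per_genus >= 1,
            individuals_per_species >= 1, sequence_length >= 1,
            kappa > 0,
            length(intra_divergence_range) == 2,
            length(inter_divergence_range) == 2)
  if (any(intra_divergence_range < 0) || any(inter_divergence_range < 0) ||
      diff(intra_divergence_range) < 0 || diff(inter_divergence_range) < 0)
    stop("divergence ranges must be non-negative with lo <= hi")
  structure(list(n_genera = n_genera,
                 species_per_genus = species_per_genus,
                 individuals_per_species = individuals_per_species,
                 sequence_length = sequence_length, kappa = kappa,
                 intra_divergence_range = intra_divergence_range,
                 inter_divergence_range = inter_divergence_range,
                 mislabel_count = mislabel_count,
                 deep_lineage_count = deep_lineage_count,
                 seed = seed),
            class = "sim_config")
}

#' Expected K2P site-pattern proportions after a branch
#'
#' Closed-form transition (`P`) and transversion (`Q`) proportions expected
#' between the two ends of a branch of length `d` expected substitutions
#' per site under the Kimura 2-parameter process with
#' transition/transversion rate ratio `kappa` (rates normalised so the
#' total substitution rate is 1). [k2p] applied to the result returns `d`
#' (round-trip identity).
#'
#' @param branch_length expected substitutions/site (>= 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @return A list with `P` and `Q`.
#' @export
expected_k2p <- function(branch_length, kappa) {
  stopifnot(branch_length >= 0, kappa > 0)
  beta <- 1 / (kappa + 2)          # each of the two transversion rates
  alpha <- kappa * beta            # transition rate; alpha + 2 beta = 1
  d <- branch_length
  Q <- 0.5 - 0.5 * exp(-4 * beta * d)
  P <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  list(P = P, Q = Q)
}

# Evolve integer-encoded sequences (1..4 = A,C,G,T) down a branch of
# expected length d under K2P with ratio kappa. Vectorised per site.
.evolve <- function(seq_int, d, kappa) {
  if (d == 0) return(seq_int)
  pq <- expected_k2p(d, kappa)
  ts_prob <- pq$P
  tv_prob <- pq$Q / 2              # per transversion target
  # transition partner: A<->G (1<->3), C<->T (2<->4)
  ts_partner <- c(3L, 4L, 1L, 2L)
  # the two transversion partners of each base
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  u <- stats::runif(length(seq_int))
  out <- seq_int
  sel <- u < ts_prob
  out[sel] <- ts_partner[seq_int[sel]]
  sel <- u >= ts_prob & u < ts_prob + tv_prob
  out[sel] <- tv1[seq_int[sel]]
  sel <- u >= ts_prob + tv_prob & u < ts_prob + 2 * tv_prob
  out[sel] <- tv2[seq_int[sel]]
  out
}

.decode <- function(seq_int) {
  paste(c("A", "C", "G", "T")[seq_int], collapse = "")
}

#' Simulate a synthetic barcode dataset with a truth table
#'
#' Draws a uniform ancestral sequence and evolves it down a
#' star-of-stars genealogy under the K2P substitution process: genus
#' ancestors diverge deeply from the root, species ancestors diverge from
#' their genus ancestor so that congeneric pairwise expectations fall in
#' the configured inter range, and individuals diverge from their species
#' ancestor so that conspecific pairwise expectations fall in the intra
#' range. Mislabels are injected by relabelling a record into a congeneric
#' species; deep lineages by evolving one individual down an extra branch
#' equal to the midpoint of (intra hi, inter lo), so its expected
#' conspecific divergence falls strictly inside the barcoding gap.
#'
#' Record labels follow the `SYNTH0001|Genus species` dialect, so simulated
#' FASTA feeds the analysis pipeline unchanged.
#'
#' @param config a [sim_config].
#' @return A list with `records` (aligned [barcode_records], labelled with
#'   *assigned* species) and `truth` (`data.frame`: `accession`,
#'   `true_species`, `assigned_species`, `role` in
#'   normal/mislabeled/deep_lineage, and per-record branch lengths
#'   `g`, `b`, `v` from root to tip).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  intra <- config$intra_divergence_range
  inter <- config$inter_divergence_range
  n_sp_total <- config$n_genera * config$species_per_genus
  if (config$mislabel_count > 0 && config$species_per_genus < 2)
    stop("mislabels need >= 2 species in some genus")
  if (config$mislabel_count > 0 || config$deep_lineage_count > 0) {
    if (inter[1] <= intra[2])
      stop("injection scenarios need inter lo > intra hi")
  }
  deep_extra <- (intra[2] + inter[1]) / 2
  L <- config$sequence_length
  kappa <- config$kappa
  root <- sample.int(4L, L, replace = TRUE)

  genus_names <- paste0("Genus", LETTERS[seq_len(config$n_genera)])
  acc_i <- 0L
  rows <- list()
  for (gi in seq_len(config$n_genera)) {
    # deep genus stem keeps cross-genus pairs clear of the congeneric range
    g_branch <- inter[2]
    g_anc <- .evolve(root, g_branch, kappa)
    for (si in seq_len(config$species_per_genus)) {
      sp_name <- paste(genus_names[gi], sprintf("species%d", si))
      b_branch <- stats::runif(1, inter[1], inter[2]) / 2
      s_anc <- .evolve(g_anc, b_branch, kappa)
      for (ii in seq_len(config$individuals_per_species)) {
        v_branch <- stats::runif(1, intra[1], intra[2]) / 2
        tip <- .evolve(s_anc, v_branch, kappa)
        acc_i <- acc_i + 1L
        rows[[acc_i]] <- list(accession = sprintf("SYNTH%04d", acc_i),
                              genus = genus_names[gi],
                              species = sp_name,
                              g = g_branch, b = b_branch, v = v_branch,
                              seq_int = tip)
      }
    }
  }
  truth <- data.frame(
    accession = vapply(rows, `[[`, "", "accession"),
    true_species = vapply(rows, `[[`, "", "species"),
    assigned_species = vapply(rows, `[[`, "", "species"),
    role = "normal",
    g = vapply(rows, `[[`, 0, "g"),
    b = vapply(rows, `[[`, 0, "b"),
    v = vapply(rows, `[[`, 0, "v"),
    stringsAsFactors = FALSE)
  genus_of <- vapply(rows, `[[`, "", "genus")

  # deep lineages first (on records left alone by mislabelling)
  pool <- seq_len(nrow(truth))
  if (config$deep_lineage_count > 0) {
    # a deep lineage is only observable against conspecifics
    eligible <- pool[table(truth$true_species)[truth$true_species] >= 2L]
    if (length(eligible) < config$deep_lineage_count)
      stop("not enough multi-individual species for deep lineages")
    picks <- sample(eligible, config$deep_lineage_count)
    for (p in picks) {
      rows[[p]]$seq_int <- .evolve(rows[[p]]$seq_int, deep_extra, kappa)
      truth$v[p] <- truth$v[p] + deep_extra
      truth$role[p] <- "deep_lineage"
    }
    pool <- setdiff(pool, picks)
  }
  if (config$mislabel_count > 0) {
    candidates <- pool[vapply(pool, function(p) {
      sum(genus_of == genus_of[p]) > sum(truth$true_species ==
                                           truth$true_species[p])
    }, logical(1))]
    if (length(candidates) < config$mislabel_count)
      stop("not enough congeneric records to mislabel")
    picks <- sample(candidates, config$mislabel_count)
    for (p in picks) {
      others <- setdiff(unique(truth$true_species[genus_of ==
                                                    genus_of[p]]),
                        truth$true_species[p])
      truth$assigned_species[p] <- if (length(others) == 1L) others
        else sample(others, 1L)
      truth$role[p] <- "mislabeled"
    }
  }

  records <- barcode_records(
    accession = truth$accession,
    species = truth$assigned_species,
    sequence = vapply(rows, function(r) .decode(r$seq_int), ""))
  list(records = records, truth = truth)
}

#' Expected pairwise divergence implied by a truth table
#'
#' Sums the generating branch lengths below each pair's most recent common
#' ancestor (true taxonomy, not assigned labels): conspecific pairs
#' `v_i + v_j`, congeneric pairs additionally the two species stems, and
#' cross-genus pairs the genus stems as well.
#'
#' @param truth the `truth` data frame from [simulate_dataset].
#' @return A symmetric matrix of expected substitutions/site with
#'   accession dimnames.
#' @export
truth_expected_divergence <- function(truth) {
  n <- nrow(truth)
  gen <- vapply(strsplit(truth$true_species, " "), `[[`, "", 1L)
  m <- matrix(0, n, n, dimnames = list(truth$accession, truth$accession))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- truth$v[i] + truth$v[j]
    if (truth$true_species[i] != truth$true_species[j])
      d <- d + truth$b[i] + truth$b[j]
    if (gen[i] != gen[j])
      d <- d + truth$g[i] + truth$g[j]
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Write a simulated dataset to disk
#'
#' @param sim output of [simulate_dataset].
#' @param out_dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_simulated <- function(sim, out_dir, prefix = "synthetic") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(out_dir, paste0(prefix, ".fasta"))
  tsv <- file.path(out_dir, paste0(prefix, "_truth.tsv"))
  write_fasta(sim$records, fasta)
  utils::write.table(sim$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta, truth = tsv))
}
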