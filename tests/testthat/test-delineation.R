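test_that("partition_pairs classifies by species and genus labels", {
  r <- records_from(list("r1", "Rita rita", "AAAA"),
                    list("r2", "Rita rita", "AAAT"),
                    list("mv", "Mystus vittatus", "TTTT"),
                    list("mh", "Mystus horai", "TTTA"),
                    list("wa", "Wallago attu", "GAAA"))
  dm <- suppressWarnings(distance_matrix(r))
  p <- partition_pairs(dm, r)
  get <- function(a, b) p$type[(p$acc_a == a & p$acc_b == b) |
                                 (p$acc_a == b & p$acc_b == a)]
  expect_equal(get("r1", "r2"), "conspecific")
  expect_equal(get("mv", "mh"), "congeneric")
  expect_equal(get("r1", "wa"), "other")
  # the three classes partition the defined pairs
  n_def <- sum(!is.na(dm$d[upper.tri(dm$d)]))
  expect_equal(nrow(p), n_def)
  expect_equal(sum(table(p$type)), n_def)
})

test_that("thresholds reproduce the fold-gap arithmetic", {
  # partition carrying exactly the printed extremes 0.024 / 0.104
  p <- data.frame(acc_a = c("a1", "b1"), acc_b = c("a2", "b2"),
                  species_a = c("Rita rita", "Mystus vittatus"),
                  species_b = c("Rita rita", "Mystus horai"),
                  genus_a = c("Rita", "Mystus"),
                  genus_b = c("Rita", "Mystus"),
                  distance = c(0.024, 0.104),
                  type = c("conspecific", "congeneric"),
                  stringsAsFactors = FALSE)
  th <- compute_thresholds(p)
  expect_equal(th$max_conspecific, 0.024)
  expect_equal(th$min_congeneric, 0.104)
  expect_equal(round(th$gap_fold, 2), 4.33)
})

test_that("thresholds error out without eligible conspecific pairs", {
  p <- data.frame(acc_a = "b1", acc_b = "b2",
                  species_a = "Mystus vittatus",
                  species_b = "Mystus horai",
                  genus_a = "Mystus", genus_b = "Mystus",
                  distance = 0.1, type = "congeneric",
                  stringsAsFactors = FALSE)
  expect_error(compute_thresholds(p), "conspecific")
})

test_that("thresholds respect cohesion gating", {
  p <- data.frame(acc_a = c("a1", "c1", "b1"),
                  acc_b = c("a2", "c2", "b2"),
                  species_a = c("Rita rita", "Mystus horai",
                                "Mystus vittatus"),
                  species_b = c("Rita rita", "Mystus horai",
                                "Mystus horai"),
                  genus_a = c("Rita", "Mystus", "Mystus"),
                  genus_b = c("Rita", "Mystus", "Mystus"),
                  distance = c(0.01, 0.05, 0.12),
                  type = c("conspecific", "conspecific", "congeneric"),
                  stringsAsFactors = FALSE)
  # with M. horai non-cohesive its deep pair and its congeneric pair drop
  coh <- c("Rita rita" = TRUE, "Mystus horai" = FALSE,
           "Mystus vittatus" = TRUE)
  expect_error(compute_thresholds(p, coh), "congeneric")
  coh2 <- c("Rita rita" = TRUE, "Mystus horai" = TRUE,
            "Mystus vittatus" = TRUE)
  th <- compute_thresholds(p, coh2)
  expect_equal(th$max_conspecific, 0.05)
})

test_that("gap_fold is invariant under uniform distance scaling", {
  set.seed(23)
  sim <- simulate_dataset(sim_config(n_genera = 3, seed = 23))
  dm <- distance_matrix(sim$records)
  part <- partition_pairs(dm, sim$records)
  th1 <- compute_thresholds(part)
  part2 <- part
  part2$distance <- part2$distance * 7.5
  th2 <- compute_thresholds(part2)
  expect_equal(th2$gap_fold, th1$gap_fold)
  expect_gt(th1$gap_fold, 1)
})

test_that("flag boundary conventions are respected", {
  p <- data.frame(
    acc_a = c("a1", "m1", "m2", "g1", "a3"),
    acc_b = c("a2", "x1", "x2", "g2", "a4"),
    species_a = c("Sp a", "Sp m", "Sp m", "Sp g", "Sp a"),
    species_b = c("Sp a", "Sp x", "Sp x", "Sp g", "Sp a"),
    genus_a = rep("Sp", 5), genus_b = rep("Sp", 5),
    distance = c(0.024, 0.024, 0.05, 0.08, 0.01),
    type = c("conspecific", "congeneric", "congeneric",
             "conspecific", "conspecific"),
    stringsAsFactors = FALSE)
  th <- list(max_conspecific = 0.024, min_congeneric = 0.104)
  fl <- flag_anomalies(p, th)
  kind_of <- function(a) fl$kind[fl$acc_a == a | fl$acc_b == a]
  # equality with the conspecific maximum counts as a merge
  expect_equal(kind_of("x1"), "conspecific_merge")
  # strictly between the thresholds: subthreshold congeneric
  expect_equal(kind_of("x2"), "subthreshold_congeneric")
  # conspecific pair above the maximum: deep divergence
  expect_equal(kind_of("g1"), "deep_conspecific_divergence")
  # pairs respecting both thresholds are untouched
  expect_false("a4" %in% c(fl$acc_a, fl$acc_b))
  expect_equal(nrow(fl), 3L)
})

test_that("clean synthetic datasets delineate every species", {
  for (s in c(101, 202)) {
    sim <- simulate_dataset(sim_config(seed = s))
    a <- analyse_dataset(sim$records)
    expect_equal(nrow(a$flags), 0L)
    expect_true(all(a$delineation$status == "delineated"))
  }
})

test_that("one injected mislabel makes exactly the two species ambiguous", {
  sim <- simulate_dataset(sim_config(mislabel_count = 1, seed = 77))
  a <- analyse_dataset(sim$records, trim = "midgap")
  tr <- sim$truth
  mis <- tr[tr$role == "mislabeled", ]
  affected <- sort(unique(c(mis$true_species, mis$assigned_species)))
  amb <- sort(a$delineation$species[a$delineation$status == "ambiguous"])
  expect_equal(amb, affected)
})

test_that("relabelling a record into a sister species yields a merge flag", {
  set.seed(55)
  for (s in 1:5) {
    sim <- simulate_dataset(sim_config(seed = 300 + s))
    rec <- sim$records
    # move one record of a two-species genus into its congener
    sp <- rec$species[1]
    genus <- rec$genus[1]
    sister <- setdiff(unique(rec$species[rec$genus == genus]), sp)[1]
    victim <- which(rec$species == sp)[1]
    rec$species[victim] <- sister
    rec <- barcode_records(rec$accession, rec$species, rec$sequence)
    a <- analyse_dataset(rec, trim = "midgap")
    merges <- a$flags[a$flags$kind == "conspecific_merge", ]
    expect_gt(nrow(merges), 0)
    expect_true(rec$accession[victim] %in%
                  c(merges$acc_a, merges$acc_b))
  }
})

test_that("singleton species beyond the congeneric floor are delineated", {
  sim <- simulate_dataset(sim_config(n_genera = 3, seed = 90))
  rec <- sim$records
  # thin the first species down to a single record
  sp <- rec$species[1]
  rec <- rec[rec$species != sp | rec$accession == rec$accession[1], ]
  rec <- barcode_records(rec$accession, rec$species, rec$sequence)
  a <- analyse_dataset(rec)
  st <- a$delineation
  expect_equal(st$n_records[st$species == sp], 1L)
  expect_equal(st$status[st$species == sp], "delineated")
})
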