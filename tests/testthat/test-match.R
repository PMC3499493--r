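fixture_path <- function(name) {
  system.file("extdata", name, package = "barcodeGap", mustWork = TRUE)
}

row_of <- function(q, db, m, s = NA_real_) {
  data.frame(query_species = q, database = db, match_species = m,
             similarity = s, stringsAsFactors = FALSE)
}

test_that("band partitions [0,100] with edges exactly at 97 and 92", {
  expect_equal(band(c(99, 100, 97)), rep("significant", 3))
  expect_equal(band(c(93, 96.9, 92)), rep("moderate", 3))
  expect_equal(band(c(91, 91.99, 0)), rep("insignificant", 3))
  # total and single-valued across a fine grid
  g <- seq(0, 100, by = 0.25)
  expect_true(all(band(g) %in% c("significant", "moderate",
                                 "insignificant")))
  expect_error(band(101), "0, 100")
  expect_error(band(-1), "0, 100")
})

test_that("classify_species reproduces the category exemplars", {
  # all same-named significant matches across both databases
  rita <- rbind(row_of("Rita rita", "genbank", "Rita rita", 99),
                row_of("Rita rita", "bold", "Rita rita", 100))
  expect_equal(classify_species(rita)$outcome, "definitive")

  # a no-match database never blocks definitive status
  hf <- rbind(row_of("Heteropneustes fossilis", "genbank",
                     "Heteropneustes fossilis", 100),
              row_of("Heteropneustes fossilis", "bold", "NO_MATCH"))
  expect_equal(classify_species(hf)$outcome, "definitive")

  # significant specific + significant non-specific: cat1
  mv <- rbind(row_of("Mystus vittatus", "genbank", "Mystus vittatus", 99),
              row_of("Mystus vittatus", "bold", "Mystus vittatus", 99.83),
              row_of("Mystus vittatus", "genbank", "Mystus horai", 99),
              row_of("Mystus vittatus", "bold", "Mystus horai", 99.64))
  expect_equal(classify_species(mv)$categories, "cat1")

  # same-named significant + same-named insignificant: cat2 (not cat4)
  cb <- rbind(row_of("Clarias batrachus", "genbank",
                     "Clarias batrachus", 98),
              row_of("Clarias batrachus", "bold",
                     "Clarias batrachus", 98.64),
              row_of("Clarias batrachus", "genbank",
                     "Clarias batrachus", 90))
  expect_equal(classify_species(cb)$categories, "cat2")

  # best same-named match moderate + same-named insignificant: cat3 + cat4
  aa <- rbind(row_of("Amblyceps apangi", "genbank",
                     "Amblyceps apangi", 95),
              row_of("Amblyceps apangi", "genbank",
                     "Amblyceps apangi", 88),
              row_of("Amblyceps apangi", "bold", "NO_MATCH"))
  expect_setequal(classify_species(aa)$categories, c("cat3", "cat4"))

  # only a non-specific insignificant hit: cat5
  mb <- rbind(row_of("Mystus bleekeri", "genbank", "Mystus bocourti", 88),
              row_of("Mystus bleekeri", "bold", "NO_MATCH"))
  expect_equal(classify_species(mb)$categories, "cat5")

  # an extra insignificant non-specific row never dilutes cat1
  bb <- rbind(row_of("Bagarius bagarius", "genbank",
                     "Bagarius bagarius", 100),
              row_of("Bagarius bagarius", "genbank",
                     "Bagarius yarrelli", 100),
              row_of("Bagarius bagarius", "genbank",
                     "Bagarius yarrelli", 91))
  expect_equal(classify_species(bb)$categories, "cat1")
})

test_that("classify_species is invariant to row order", {
  rows <- rbind(row_of("Amblyceps apangi", "genbank",
                       "Amblyceps apangi", 95),
                row_of("Amblyceps apangi", "genbank",
                       "Amblyceps apangi", 88),
                row_of("Amblyceps apangi", "bold", "NO_MATCH"))
  base <- classify_species(rows)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    p <- classify_species(rows[perm, ])
    expect_equal(p$outcome, base$outcome)
    expect_setequal(p$categories, base$categories)
  }
})

test_that("classify_species validates its input", {
  expect_error(classify_species(row_of("X y", "genbank", "NO_MATCH")),
               "no returned match")
  expect_error(classify_species(rbind(row_of("X y", "genbank", "A b", 99),
                                      row_of("Z w", "bold", "A b", 99))),
               "several")
})

test_that("the catfish survey table reproduces the published tallies", {
  tab <- read_match_table(fixture_path("catfish_matches.tsv"))
  s <- summarize_matches(tab)
  expect_equal(s$n_species, 25L)
  expect_equal(s$definitive, 11L)
  expect_equal(s$cat5_only, 7L)
  expect_equal(s$ambiguous_total, 14L)
})

test_that("flag resolution promotes mislabel-explained species", {
  tab <- read_match_table(fixture_path("catfish_matches.tsv"))
  cl <- classify_matches(tab)
  flags <- utils::read.delim(fixture_path("catfish_anomalies.tsv"),
                             stringsAsFactors = FALSE)
  res <- resolve_with_flags(cl, flags)
  get <- function(sp) res$final_status[res$query_species == sp]
  expect_equal(get("Mystus vittatus"), "identified_mislabel")
  expect_equal(get("Bagarius bagarius"), "identified_mislabel")
  expect_equal(get("Clarias batrachus"), "identified_mislabel")
  expect_equal(get("Amblyceps apangi"), "inconclusive")
  expect_equal(get("Glyptothorax telchitta"), "inconclusive")
  expect_equal(get("Mystus bleekeri"), "identified")  # cat5, unflagged
  expect_equal(get("Rita rita"), "identified")
  ids <- identification_summary(res)
  expect_equal(ids$identified, 21L)
  expect_equal(ids$inconclusive, 4L)
  expect_equal(ids$identified_pct, 84)
})

test_that("a flagged cat5 species is not waved through", {
  cl <- data.frame(query_species = "X y", outcome = "ambiguous",
                   categories = "cat5", stringsAsFactors = FALSE)
  fl <- data.frame(kind = "conspecific_merge", acc_a = "q1", acc_b = "d1",
                   species_a = "X y", species_b = "Z w",
                   distance = 0.01, stringsAsFactors = FALSE)
  expect_equal(resolve_with_flags(cl, fl)$final_status, "inconclusive")
  none <- fl[0, ]
  expect_equal(resolve_with_flags(cl, none)$final_status, "identified")
})
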