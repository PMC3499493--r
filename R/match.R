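#' Similarity band of a database match
#'
#' Percent-similarity bands used to grade database hits: `significant`
#' (>= 97), `moderate` (>= 92 and < 97), `insignificant` (< 92). The bands
#' partition [0, 100]; fractional similarities are banded on their exact
#' value.
#'
#' @param similarity numeric vector of percentages in [0, 100].
#' @return Character vector of band names.
#' @export
band <- function(similarity) {
  if (any(is.na(similarity)) || any(similarity < 0 | similarity > 100))
    stop("similarity must lie in [0, 100]")
  ifelse(similarity >= 97, "significant",
         ifelse(similarity >= 92, "moderate", "insignificant"))
}

#' Read a database-similarity table
#'
#' TSV schema: `query_species`, `database` (`genbank` or `bold`),
#' `match_species` (a binomial, or the literal `NO_MATCH`), `similarity`
#' (percent; empty for no-match rows).
#'
#' @param path path to the TSV file.
#' @return A validated `data.frame` of match rows.
#' @export
read_match_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_species", "database", "match_species", "similarity")
  if (!all(need %in% names(df)))
    stop("match table must have columns: ", paste(need, collapse = ", "))
  df$database <- tolower(df$database)
  if (!all(df$database %in% c("genbank", "bold")))
    stop("database must be 'genbank' or 'bold'")
  no_match <- df$match_species == "NO_MATCH"
  if (any(no_match & !is.na(df$similarity)))
    stop("NO_MATCH rows must have empty similarity")
  if (any(!no_match & is.na(df$similarity)))
    stop("matched rows must carry a similarity")
  df
}

#' Classify one query species' database matches
#'
#' Outcomes follow the definitive-identity rule and five ambiguity
#' categories:
#' \describe{
#'   \item{definitive}{every returned match (across databases) bears the
#'     query's own name and is significant; databases returning no match
#'     are ignored.}
#'   \item{cat1}{significant matches to both the same and a different
#'     name — conflicting significant evidence.}
#'   \item{cat2}{same-named matches both significant and insignificant.}
#'   \item{cat3}{the best same-named match is only moderate.}
#'   \item{cat4}{a same-named match is insignificant and no same-named
#'     match is significant.}
#'   \item{cat5}{only different-named matches, none significant — no
#'     usable reference data for the species.}
#' }
#' Categories are assigned per match and unioned per species, so a species
#' can carry several (e.g. cat3 and cat4 from two database records).
#' Insignificant different-named extras never add a category when specific
#' evidence exists: a significant conflict dominates.
#'
#' @param rows match-table rows for a single query species (>= 1 row;
#'   no-match rows allowed).
#' @return A list with `query_species`, `outcome` (`"definitive"` or
#'   `"ambiguous"`), and `categories` (character vector, empty when
#'   definitive).
#' @export
classify_species <- function(rows) {
  if (nrow(rows) == 0L) stop("no rows for species")
  qs <- unique(rows$query_species)
  if (length(qs) != 1L)
    stop("rows span several query species: ", paste(qs, collapse = ", "))
  hits <- rows[rows$match_species != "NO_MATCH", , drop = FALSE]
  if (nrow(hits) == 0L)
    stop("species has no returned match in any database: ", qs)
  b <- band(hits$similarity)
  same <- hits$match_species == qs
  s_sig <- any(same & b == "significant")
  s_mod <- any(same & b == "moderate")
  s_ins <- any(same & b == "insignificant")
  d_sig <- any(!same & b == "significant")
  if (all(same) && all(b == "significant"))
    return(list(query_species = qs, outcome = "definitive",
                categories = character(0)))
  cats <- character(0)
  if (d_sig && s_sig) cats <- c(cats, "cat1")
  if (s_sig && s_ins) cats <- c(cats, "cat2")
  if (any(same) && !s_sig && s_mod) cats <- c(cats, "cat3")
  if (s_ins && !s_sig) cats <- c(cats, "cat4")
  if (!any(same) && !d_sig) cats <- c(cats, "cat5")
  if (length(cats) == 0L) {
    # remaining patterns outside the five printed exemplars: conflicting
    # non-same-named significant evidence, or specific evidence diluted by
    # non-specific extras -- graded by the dominant conflict
    cats <- if (any(!same)) "cat1" else "cat2"
  }
  list(query_species = qs, outcome = "ambiguous", categories = cats)
}

#' Classify every species of a match table
#'
#' @param table a match table (see [read_match_table]).
#' @return A `data.frame` with one row per query species (input order):
#'   `query_species`, `outcome`, `categories` (comma-separated string).
#' @export
classify_matches <- function(table) {
  species <- unique(table$query_species)
  res <- lapply(species, function(s)
    classify_species(table[table$query_species == s, , drop = FALSE]))
  data.frame(query_species = species,
             outcome = vapply(res, `[[`, "", "outcome"),
             categories = vapply(res, function(r)
               paste(r$categories, collapse = ","), ""),
             stringsAsFactors = FALSE)
}

#' Headline counts over a classified match table
#'
#' @param table a match table (see [read_match_table]).
#' @return A list: `n_species`, `definitive`, `cat5_only` (species whose
#'   only category is cat5 — no reference data), `ambiguous_total`
#'   (everything not definitive; includes the cat5-only species).
#' @export
summarize_matches <- function(table) {
  cl <- classify_matches(table)
  list(n_species = nrow(cl),
       definitive = sum(cl$outcome == "definitive"),
       cat5_only = sum(cl$categories == "cat5"),
       ambiguous_total = sum(cl$outcome == "ambiguous"))
}

#' Resolve ambiguous match categories against distance-based anomaly flags
#'
#' Combines the database-match classification with the anomaly flags from
#' the divergence analysis:
#' \itemize{
#'   \item definitive species are `identified`;
#'   \item cat5-only species untouched by any flag are `identified` (their
#'     own records cluster cleanly; the databases simply lack references);
#'   \item a cat1 species whose conflict traces to a record flagged
#'     `conspecific_merge` is `identified_mislabel` (the different-named
#'     database record is treated as mislabelled or a synonym);
#'   \item a cat2 species with a merge flag, or with exactly one deviant
#'     same-named record carrying `deep_conspecific_divergence` flags, is
#'     `identified_mislabel`;
#'   \item cat3/cat4 species with deep-divergence flags, and anything else,
#'     remain `inconclusive`.
#' }
#'
#' @param classification output of [classify_matches].
#' @param flags a flag `data.frame` as produced by [flag_anomalies]
#'   (columns `kind`, `acc_a`, `acc_b`, `species_a`, `species_b`; distances
#'   optional). `species_a`/`species_b` are matched against query species;
#'   for deep flags, `acc_b` names the deviant record.
#' @return `classification` with a `final_status` column added
#'   (`identified`, `identified_mislabel`, `inconclusive`).
#' @export
resolve_with_flags <- function(classification, flags) {
  status <- character(nrow(classification))
  for (i in seq_len(nrow(classification))) {
    sp <- classification$query_species[i]
    cats <- strsplit(classification$categories[i], ",")[[1]]
    f <- flags[flags$species_a == sp | flags$species_b == sp, ,
               drop = FALSE]
    has_merge <- any(f$kind == "conspecific_merge")
    deep <- f[f$kind == "deep_conspecific_divergence", , drop = FALSE]
    lone_deviant <- length(unique(deep$acc_b)) == 1L && nrow(deep) >= 1L
    status[i] <-
      if (classification$outcome[i] == "definitive") "identified"
      else if (identical(cats, "cat5") && nrow(f) == 0L) "identified"
      else if (any(cats %in% c("cat3", "cat4")) && nrow(deep) > 0L)
        "inconclusive"
      else if ("cat1" %in% cats && has_merge) "identified_mislabel"
      else if ("cat2" %in% cats && (has_merge || lone_deviant))
        "identified_mislabel"
      else "inconclusive"
  }
  classification$final_status <- status
  classification
}

#' Identification summary after flag resolution
#'
#' @param resolved output of [resolve_with_flags].
#' @return A list: `identified` (count, mislabel-resolved included),
#'   `inconclusive`, `identified_pct` (percentage of species identified).
#' @export
identification_summary <- function(resolved) {
  ok <- resolved$final_status %in% c("identified", "identified_mislabel")
  list(identified = sum(ok),
       inconclusive = sum(!ok),
       identified_pct = 100 * sum(ok) / nrow(resolved))
}
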