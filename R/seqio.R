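#' Barcode record tables
#'
#' A barcode record set is a plain `data.frame` with one row per sequence and
#' columns `accession`, `species`, `genus`, `sequence`, `provenance`
#' (`"novel"` or `"database"`). The `genus` column is always the first
#' whitespace-separated token of `species`. Accessions are unique within a
#' set.
#'
#' @param accession character vector of unique, non-empty identifiers.
#' @param species character vector of binomials ("Genus species"); at least
#'   two whitespace-separated tokens each.
#' @param sequence character vector of DNA strings over A,C,G,T,N, gap `-`
#'   and IUPAC ambiguity codes; stored uppercased.
#' @param provenance `"novel"` (generated in-study) or `"database"`
#'   (retrieved reference), recycled as needed.
#' @return A `data.frame` of class `barcode_records`.
#' @export
barcode_records <- function(accession, species, sequence,
                            provenance = "novel") {
  accession <- as.character(accession)
  species <- as.character(species)
  sequence <- toupper(as.character(sequence))
  if (length(accession) != length(species) ||
      length(accession) != length(sequence))
    stop("accession, species and sequence must have equal length")
  if (any(!nzchar(accession)))
    stop("empty accession")
  if (anyDuplicated(accession))
    stop("duplicate accession: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for: ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  toks <- strsplit(trimws(species), "[[:space:]]+")
  bad <- vapply(toks, length, 1L) < 2L
  if (any(bad))
    stop("species name needs >= 2 tokens ('Genus species'): ",
         paste(sprintf("'%s' (%s)", species[bad], accession[bad]),
               collapse = ", "))
  provenance <- rep_len(match.arg(provenance, c("novel", "database"),
                                  several.ok = FALSE), length(accession))
  out <- data.frame(accession = accession,
                    species = trimws(gsub("[[:space:]]+", " ", species)),
                    genus = vapply(toks, `[[`, "", 1L),
                    sequence = sequence,
                    provenance = provenance,
                    stringsAsFactors = FALSE)
  class(out) <- c("barcode_records", "data.frame")
  out
}

#' Read labelled barcode FASTA
#'
#' Parses a (possibly line-wrapped) FASTA file whose headers follow the
#' `accession|Genus species` convention; underscores in the species part are
#' normalised to spaces. Sequences are uppercased; record order is preserved.
#'
#' @param path path to a FASTA file.
#' @param provenance provenance assigned to all records read
#'   (`"novel"` or `"database"`).
#' @return A [barcode_records] data frame (zero rows for an empty file).
#' @export
read_fasta <- function(path, provenance = "novel") {
  if (!file.exists(path)) stop("no such file: ", path)
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(dna) || length(dna) == 0L) {
    return(barcode_records(character(0), character(0), character(0))[0, ])
  }
  headers <- names(dna)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  parts <- regmatches(headers, regexpr("|", headers, fixed = TRUE),
                      invert = TRUE)
  acc <- vapply(parts, `[`, "", 1L)
  sp <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "",
               character(1))
  no_pipe <- !grepl("|", headers, fixed = TRUE)
  sp <- gsub("_", " ", sp)
  bad <- no_pipe | !nzchar(trimws(sp)) | !nzchar(trimws(acc))
  if (any(bad))
    stop("malformed FASTA header (expected 'accession|Genus species'): ",
         paste(sQuote(headers[bad]), collapse = ", "))
  barcode_records(trimws(acc), sp, seqs, provenance = provenance)
}

#' Write labelled barcode FASTA
#'
#' Inverse of [read_fasta]: headers are `accession|Genus species`, one
#' sequence line per record. Round-trips losslessly on (accession, species,
#' sequence).
#'
#' @param records a [barcode_records] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(c(paste0(">", records$accession[i], "|", records$species[i]),
                 records$sequence[i]), con)
  }
  invisible(path)
}

.ungapped_length <- function(sequence) {
  nchar(gsub("-", "", sequence, fixed = TRUE))
}

#' Reading-frame check under the vertebrate mitochondrial code
#'
#' A sequence passes if at least one of the three forward reading frames
#' contains no internal stop codon (TAA, TAG, AGA, AGG under the vertebrate
#' mitochondrial code). "Internal" means any complete codon other than the
#' last complete codon of the frame; codons containing ambiguity codes or N
#' translate to unknown and never count as stops. Gaps are removed before
#' framing. Barcode orientation is fixed by the amplification primers, so
#' reverse frames are not examined.
#'
#' @param sequence a DNA string.
#' @return `TRUE` if some forward frame is free of internal stops.
#' @export
translate_ok <- function(sequence) {
  s <- gsub("-", "", toupper(sequence), fixed = TRUE)
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  stops <- c("TAA", "TAG", "AGA", "AGG")
  for (frame in 0:2) {
    n_codon <- (nchar(s) - frame) %/% 3L
    if (n_codon < 1L) next
    starts <- frame + 1L + 3L * (seq_len(n_codon) - 1L)
    codons <- substring(s, starts, starts + 2L)
    internal <- codons[-n_codon]   # terminal codon may legitimately be a stop
    if (!any(internal %in% stops)) return(TRUE)
  }
  FALSE
}

#' Sequence quality-control filter
#'
#' Applies the barcode QC rules: the ungapped length must strictly exceed
#' `min_length` sites, and [translate_ok] must pass. Failures are reported,
#' not raised; the report partitions the input accessions into `kept` and
#' `rejected` (reason one of `too_short`, `internal_stop`, `empty`).
#'
#' @param records a [barcode_records] data frame.
#' @param min_length minimum ungapped length in sites (strict `>`;
#'   default 600).
#' @param check_frame apply the [translate_ok] reading-frame check
#'   (default `TRUE`). Disable for sequences that are not codon-structured,
#'   e.g. simulator output.
#' @return An object of class `qc_report`: list with `kept` (character
#'   vector) and `rejected` (named character vector, accession -> reason).
#' @export
qc_filter <- function(records, min_length = 600, check_frame = TRUE) {
  kept <- character(0)
  rejected <- character(0)
  for (i in seq_len(nrow(records))) {
    acc <- records$accession[i]
    s <- records$sequence[i]
    len <- .ungapped_length(s)
    if (len == 0L) {
      rejected[acc] <- "empty"
    } else if (len <= min_length) {
      rejected[acc] <- "too_short"
    } else if (check_frame && len >= 3L && !translate_ok(s)) {
      rejected[acc] <- "internal_stop"
    } else {
      kept <- c(kept, acc)
    }
  }
  structure(list(kept = kept, rejected = rejected,
                 min_length = min_length),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Barcode QC report: ", length(x$kept), " kept, ",
      length(x$rejected), " rejected (min ungapped length > ",
      x$min_length, ")\n", sep = "")
  if (length(x$rejected))
    print(x$rejected)
  invisible(x)
}

#' Subset records to those kept by a QC report
#'
#' @param records a [barcode_records] data frame.
#' @param report a `qc_report` from [qc_filter].
#' @return The kept rows, original order preserved.
#' @export
qc_keep <- function(records, report) {
  records[records$accession %in% report$kept, , drop = FALSE]
}

.IUPAC_OF <- c("A" = "A", "C" = "C", "G" = "G", "T" = "T",
               "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S",
               "CT" = "Y", "GT" = "K", "ACG" = "V", "ACT" = "H",
               "AGT" = "D", "CGT" = "B", "ACGT" = "N")

#' Species consensus sequence
#'
#' Per-column strict-majority base over an aligned conspecific record set.
#' Columns with a tie among the most frequent unambiguous bases emit the
#' IUPAC code covering the tied bases; columns with no unambiguous base emit
#' `N` (or `-` if every symbol is a gap). All records must belong to one
#' species and share one alignment length.
#'
#' @param records aligned [barcode_records], all of the same species.
#' @return A single DNA string of the common alignment length.
#' @export
consensus_sequence <- function(records) {
  if (nrow(records) < 1L) stop("need >= 1 record")
  if (length(unique(records$species)) != 1L)
    stop("consensus requires a single species, got: ",
         paste(unique(records$species), collapse = ", "))
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1L)
    stop("records are not aligned (unequal lengths)")
  if (nrow(records) == 1L) return(records$sequence)
  m <- do.call(rbind, strsplit(records$sequence, ""))
  apply_col <- function(col) {
    tab <- table(factor(col[col %in% c("A", "C", "G", "T")],
                        levels = c("A", "C", "G", "T")))
    if (sum(tab) == 0L) {
      if (all(col == "-")) return("-")
      return("N")
    }
    top <- names(tab)[tab == max(tab)]
    .IUPAC_OF[[paste(sort(top), collapse = "")]]
  }
  paste(apply(m, 2L, apply_col), collapse = "")
}

#' Check that records form an aligned set
#'
#' @param records a [barcode_records] data frame with >= 1 row.
#' @return The common alignment length, invisibly; errors if lengths differ.
#' @export
aligned_length <- function(records) {
  lens <- unique(nchar(records$sequence))
  if (length(lens) != 1L)
    stop("sequences are not aligned: lengths ",
         paste(lens, collapse = ", "))
  invisible(lens)
}
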