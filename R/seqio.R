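# IUPAC nucleotide handling, FASTA and reference-table input, and the
# elementary sequence transforms everything else builds on.

IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

# complement table over the full IUPAC alphabet (after U -> T normalization)
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Normalize nucleotide residues
#'
#' Uppercases, maps `U` to `T`, strips leading and trailing `N` runs, and
#' validates that only IUPAC nucleotide symbols remain. This is the single
#' canonical representation used throughout the package; every reader applies
#' it on the way in.
#'
#' @param x Character vector of nucleotide sequences.
#' @param strip_n Strip leading/trailing `N` codes (default `TRUE`). Terminal
#'   `N`s carry no information for context extraction and are removed the way
#'   curated barcode datasets conventionally trim them.
#' @return Character vector of normalized sequences.
#' @examples
#' normalize_residues("nnacgUn")  # "ACGT"
#' @export
normalize_residues <- function(x, strip_n = TRUE) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- regexpr(paste0("[^", paste(IUPAC_NT, collapse = ""), "]"), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort(sprintf(
      "invalid residue symbol '%s' at position %d of sequence %d",
      substr(x[i], bad[i], bad[i]), bad[i], i
    ), class = "bronx_alphabet_error")
  }
  if (strip_n) {
    x <- gsub("^N+", "", x)
    x <- gsub("N+$", "", x)
  }
  x
}

#' Construct a tibble of sequence records
#'
#' The package's working unit is a tibble with one row per marker sequence of
#' one specimen. All readers and the simulator return this shape, and all
#' downstream functions (database building, identification, evaluation)
#' accept it.
#'
#' @param specimen_id Character, opaque specimen identifier.
#' @param genus,epithet Character, taxonomic labels; the species binomial is
#'   `genus epithet`.
#' @param marker Character, marker name (e.g. `"matK"`, `"rbcL"`,
#'   `"combined"`).
#' @param residues Character, nucleotide sequence (normalized on entry).
#' @param accession Optional character accession.
#' @param is_reference Logical, whether the record may enter a reference set.
#' @return A tibble with columns `specimen_id`, `genus`, `epithet`, `species`,
#'   `marker`, `accession`, `residues`, `is_reference`.
#' @export
sequence_records <- function(specimen_id, genus, epithet, marker, residues,
                             accession = NA_character_, is_reference = TRUE) {
  residues <- normalize_residues(residues)
  if (any(!nzchar(residues))) {
    abort("empty residues after terminal-N stripping",
          class = "bronx_empty_sequence")
  }
  out <- tibble::tibble(
    specimen_id = as.character(specimen_id),
    genus = as.character(genus),
    epithet = as.character(epithet),
    species = paste(genus, epithet),
    marker = as.character(marker),
    accession = as.character(accession),
    residues = residues,
    is_reference = as.logical(is_reference)
  )
  dup <- duplicated(out[c("specimen_id", "marker")])
  if (any(dup)) {
    abort(sprintf("duplicate specimen_id/marker pair: %s/%s",
                  out$specimen_id[dup][1L], out$marker[dup][1L]),
          class = "bronx_duplicate_record")
  }
  out
}

#' Reverse complement of IUPAC nucleotide sequences
#'
#' Complements every symbol over the full IUPAC alphabet (`R` with `Y`, `K`
#' with `M`, `B` with `V`, `D` with `H`; `S`, `W` and `N` are their own
#' complements) and reverses the sequence. Applying it twice is the identity.
#'
#' @param x Character vector of IUPAC nucleotide sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAGN")  # "NCTT"
#' @export
reverse_complement <- function(x) {
  x <- toupper(gsub("U", "T", x, fixed = TRUE))
  bad <- regexpr(paste0("[^", paste(IUPAC_NT, collapse = ""), "]"), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort(sprintf("invalid residue symbol '%s' at position %d",
                  substr(x[i], bad[i], bad[i]), bad[i]),
          class = "bronx_alphabet_error")
  }
  comp <- chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                 paste(IUPAC_COMPLEMENT, collapse = ""), x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Concatenate marker sequences with an N spacer
#'
#' Joins an ordered set of marker sequences into a single combined sequence
#' with a run of `spacer` `N` codes between consecutive markers. Because
#' context windows containing any non-ACGT symbol are never stored, no window
#' can span the junction: the markers stay informationally separate inside
#' one sequence.
#'
#' @param seqs Character vector of sequences, in marker order.
#' @param spacer Integer, number of `N` codes between markers (default 15).
#' @return Single concatenated sequence.
#' @examples
#' concatenate_markers(c("ACGT", "GGCC"), spacer = 15)
#' @export
concatenate_markers <- function(seqs, spacer = 15L) {
  if (length(seqs) == 0L) {
    abort("no sequences to concatenate", class = "bronx_empty_input")
  }
  paste(seqs, collapse = strrep("N", spacer))
}

#' Combine per-marker records into combined-marker records
#'
#' For each specimen holding every requested marker, concatenates the marker
#' sequences (in the order given) with [concatenate_markers()] and returns
#' one `combined` record per specimen. Specimens missing a marker are dropped
#' with a warning.
#'
#' @param records Sequence-record tibble (see [sequence_records()]).
#' @param markers Character vector of marker names, in concatenation order.
#' @param spacer Spacer length passed to [concatenate_markers()].
#' @return Sequence-record tibble with `marker = "combined"`.
#' @export
combine_marker_records <- function(records, markers = c("matK", "rbcL"),
                                   spacer = 15L) {
  sub <- dplyr::filter(records, .data$marker %in% markers)
  wide <- tidyr::pivot_wider(
    dplyr::select(sub, "specimen_id", "genus", "epithet", "species",
                  "marker", "residues", "is_reference"),
    names_from = "marker", values_from = "residues"
  )
  missing <- !stats::complete.cases(wide[markers])
  if (any(missing)) {
    warn(sprintf("%d specimen(s) lack at least one of the markers and were dropped",
                 sum(missing)))
    wide <- wide[!missing, , drop = FALSE]
  }
  joined <- vapply(seq_len(nrow(wide)), function(i) {
    concatenate_markers(unlist(wide[i, markers], use.names = FALSE), spacer)
  }, character(1))
  tibble::tibble(
    specimen_id = wide$specimen_id,
    genus = wide$genus,
    epithet = wide$epithet,
    species = wide$species,
    marker = "combined",
    accession = NA_character_,
    residues = joined,
    is_reference = wide$is_reference
  )
}

#' Read sequence records from FASTA
#'
#' Headers follow the pipe-delimited convention
#' `specimen|genus|epithet|marker`; residues are normalized (uppercased,
#' `U` to `T`, terminal `N`s stripped).
#'
#' @param path Path to a FASTA file.
#' @param is_reference Logical flag applied to all records read.
#' @return Sequence-record tibble.
#' @export
read_fasta <- function(path, is_reference = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) {
    warn(sprintf("empty FASTA file: %s", path))
    return(sequence_records(character(), character(), character(),
                            character(), character())[0, ])
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  n_ok <- lengths(parts) == 4L
  if (any(!n_ok)) {
    abort(sprintf("FASTA header not of the form specimen|genus|epithet|marker: '%s'",
                  headers[!n_ok][1L]), class = "bronx_header_error")
  }
  m <- do.call(rbind, parts)
  if (anyDuplicated(paste(m[, 1], m[, 4]))) {
    abort("duplicate specimen/marker identifiers in FASTA",
          class = "bronx_duplicate_record")
  }
  sequence_records(m[, 1], m[, 2], m[, 3], m[, 4],
                   unname(as.character(set)), is_reference = is_reference)
}

#' Write sequence records to FASTA
#'
#' Emits 70-column FASTA with `specimen|genus|epithet|marker` headers,
#' the inverse of [read_fasta()].
#'
#' @param records Sequence-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- paste(records$specimen_id, records$genus, records$epithet,
                      records$marker, sep = "|")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# fixed column order of the two-marker reference table dialect
REFTABLE_COLUMNS <- c("genus", "epithet", "specimen_id",
                      "matK_accession", "matK_sequence", "matK_mini",
                      "rbcL_accession", "rbcL_sequence", "rbcL_mini",
                      "reference_flag")

#' Read a two-marker barcode reference table
#'
#' Reads the CSV dialect used for curated two-marker plant barcode data: one
#' row per specimen with columns, in order, genus, specific epithet, specimen
#' id, matK accession, matK sequence, matK mini-barcode, rbcL accession, rbcL
#' sequence, rbcL mini-barcode, and a reference-use flag. Columns are matched
#' by position; extra trailing columns are ignored with a warning.
#'
#' Each row yields one full-length record per marker plus, when present, one
#' auxiliary record per stored mini-barcode with marker suffix `"_mini"`.
#'
#' @param path Path to the CSV file (header row present).
#' @return Sequence-record tibble.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < length(REFTABLE_COLUMNS)) {
    abort(sprintf("reference table has %d columns; %d required",
                  ncol(raw), length(REFTABLE_COLUMNS)),
          class = "bronx_table_error")
  }
  if (ncol(raw) > length(REFTABLE_COLUMNS)) {
    warn(sprintf("ignoring %d extra column(s) beyond the %d expected",
                 ncol(raw) - length(REFTABLE_COLUMNS),
                 length(REFTABLE_COLUMNS)))
  }
  raw <- raw[, seq_along(REFTABLE_COLUMNS)]
  names(raw) <- REFTABLE_COLUMNS

  needed <- c("genus", "epithet", "specimen_id",
              "matK_sequence", "rbcL_sequence")
  bad_row <- which(!stats::complete.cases(raw[needed]) |
                     rowSums(raw[needed] == "") > 0L)
  if (length(bad_row) > 0L) {
    abort(sprintf("malformed reference table row %d (missing required field)",
                  bad_row[1L]), class = "bronx_table_error")
  }

  is_ref <- tolower(raw$reference_flag) %in% c("yes", "y", "true", "1")
  one_marker <- function(marker, seq_col, acc_col) {
    sequence_records(raw$specimen_id, raw$genus, raw$epithet, marker,
                     raw[[seq_col]], accession = raw[[acc_col]],
                     is_reference = is_ref)
  }
  full <- dplyr::bind_rows(
    one_marker("matK", "matK_sequence", "matK_accession"),
    one_marker("rbcL", "rbcL_sequence", "rbcL_accession")
  )
  minis <- list()
  for (mk in c("matK", "rbcL")) {
    col <- paste0(mk, "_mini")
    keep <- !is.na(raw[[col]]) & nzchar(raw[[col]])
    if (any(keep)) {
      minis[[mk]] <- sequence_records(
        raw$specimen_id[keep], raw$genus[keep], raw$epithet[keep],
        paste0(mk, "_mini"), raw[[col]][keep],
        accession = NA_character_, is_reference = FALSE
      )
    }
  }
  dplyr::bind_rows(full, dplyr::bind_rows(minis))
}
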