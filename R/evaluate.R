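# Benchmarking framework: restricted reference-set selection, weak/strong
# test classification, mini-barcode generation, and the severity rule
# turning per-query identifications into per-species success rates.

#' Select the restricted reference set
#'
#' Keeps one specimen per species: the one whose primary-marker sequence has
#' the highest length/completeness score, defined here as the count of
#' unambiguous `A`/`C`/`G`/`T` symbols. Ties are resolved deterministically
#' by lexicographically smallest specimen id. All markers of the chosen
#' specimen are retained.
#'
#' @param records Sequence-record tibble.
#' @param marker Marker whose completeness drives the choice
#'   (default `"matK"`).
#' @return Sequence-record tibble restricted to the chosen specimens, with
#'   `is_reference = TRUE`.
#' @export
select_reference_set <- function(records, marker = "matK") {
  mk <- records[records$marker == marker, , drop = FALSE]
  if (nrow(mk) == 0L) {
    abort(sprintf("no records for marker '%s'", marker),
          class = "bronx_empty_input")
  }
  mk$completeness <- completeness_score(mk$residues)
  chosen <- dplyr::slice_head(
    dplyr::arrange(dplyr::group_by(mk, .data$species),
                   dplyr::desc(.data$completeness), .data$specimen_id,
                   .by_group = TRUE),
    n = 1L
  )
  out <- records[records$specimen_id %in% chosen$specimen_id &
                   !grepl("_mini$", records$marker), , drop = FALSE]
  out$is_reference <- TRUE
  out
}

# length/completeness score: unambiguous nucleotide count
completeness_score <- function(x) {
  nchar(gsub("[^ACGT]", "", x))
}

#' Classify species-level tests as weak or strong
#'
#' A species-level identification test is *weak* when the reference set
#' holds no congener of the test species (the query merely has to land in
#' the right genus-neighbourhood) and *strong* when at least one congeneric
#' species is present to confuse it with.
#'
#' @param reference_species A data frame with columns `species` and `genus`
#'   (one row per reference species), or a sequence-record tibble (reduced
#'   to distinct species first).
#' @return A tibble with columns `species`, `genus`, `class`
#'   (`"weak"`/`"strong"`), of class `bronx_classification`.
#' @export
classify_tests <- function(reference_species) {
  sp <- dplyr::distinct(reference_species[, c("species", "genus")])
  counts <- dplyr::add_count(sp, .data$genus, name = "n_in_genus")
  out <- tibble::tibble(
    species = counts$species,
    genus = counts$genus,
    class = ifelse(counts$n_in_genus > 1L, "strong", "weak")
  )
  class(out) <- c("bronx_classification", class(out))
  out
}

#' Excise a random mini-barcode fragment
#'
#' Draws a contiguous fragment whose size is uniform on 100-200 bases and
#' whose position is uniform within the sequence, emulating the patchy
#' sequence recovery typical of degraded-DNA amplicons. Sequences of at
#' most 100 bases are returned whole; for sequences shorter than 200 the
#' size is clamped to the sequence length.
#'
#' @param seq Nucleotide sequence.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   in isolation, otherwise the current RNG stream is used.
#' @param min_size,max_size Fragment size bounds (defaults 100 and 200).
#' @return A contiguous substring of `seq`.
#' @export
make_minibarcode <- function(seq, seed = NULL, min_size = 100L,
                             max_size = 200L) {
  draw <- function() {
    L <- nchar(seq)
    if (L <= min_size) return(seq)
    size <- sample(min_size:min(max_size, L), 1L)
    start <- sample(0:(L - size), 1L)  # 0-based offset
    substr(seq, start + 1L, start + size)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a mini-barcode query set
#'
#' Applies [make_minibarcode()] to every record under a single seeded RNG
#' stream, so the whole set is reproducible from one seed. Taxonomic labels
#' are inherited from the source records; markers gain a `"_mini"` suffix.
#'
#' @param records Sequence-record tibble.
#' @param seed Integer seed (mandatory: fragments are random by design).
#' @param min_size,max_size Passed to [make_minibarcode()].
#' @return Sequence-record tibble of fragments with `is_reference = FALSE`.
#' @export
generate_minibarcode_set <- function(records, seed, min_size = 100L,
                                     max_size = 200L) {
  frags <- withr::with_seed(seed, vapply(records$residues, function(s) {
    make_minibarcode(s, min_size = min_size, max_size = max_size)
  }, character(1), USE.NAMES = FALSE))
  out <- records
  out$residues <- frags
  out$marker <- paste0(out$marker, "_mini")
  out$accession <- NA_character_
  out$is_reference <- FALSE
  out
}

#' Score an identification engine under the severity rule
#'
#' Converts per-query identifications into per-species success and
#' sensitivity. A species succeeds at a level only when *all* of its query
#' sequences are identified correctly and unambiguously at that level —
#' ambiguous and unidentified results count as incorrect. Sensitivity is
#' successes over species-tests, with a 95% Wilson interval; at species
#' level the summary is also broken out by weak/strong test class when a
#' classification is given.
#'
#' @param results Identification tibble with columns `query_id`, `level`,
#'   `winners` (list-column), `ambiguous`, `unidentified`
#'   ([bronx_identify()] or [identify_by_distance()] output).
#' @param truth A data frame with columns `specimen_id`, `genus`, `species`
#'   giving the true labels of each query.
#' @param level Level to evaluate (`"species"` or `"genus"`).
#' @param classification Optional [classify_tests()] tibble; adds weak/strong
#'   breakdown rows at species level.
#' @param conf Confidence level of the Wilson interval.
#' @return A tibble of class `bronx_eval` with one row per test class
#'   (`overall` and, when applicable, `weak`/`strong`): `level`, `class`,
#'   `k`, `n`, `sensitivity`, `ci_low`, `ci_high`; the per-species outcome
#'   table is attached as attribute `"species_success"`.
#' @export
score_side <- function(results, truth, level,
                       classification = NULL, conf = 0.95) {
  res <- results[results$level == level, , drop = FALSE]
  if (nrow(res) == 0L) {
    abort(sprintf("no results at level '%s'", level),
          class = "bronx_level_error")
  }
  truth <- tibble::as_tibble(truth)
  truth$truth_label <- if (level == "genus") truth$genus else truth$species
  res <- dplyr::inner_join(res, truth[, c("specimen_id", "truth_label")],
                           by = c(query_id = "specimen_id"))
  if (nrow(res) == 0L) {
    abort("no query ids in common between results and truth",
          class = "bronx_empty_input")
  }
  res$correct <- !res$ambiguous & !res$unidentified &
    mapply(function(w, t) length(w) == 1L && w == t,
           res$winners, res$truth_label)
  # severity rule: every query of the species must be correct
  sp_truth <- truth[match(res$query_id, truth$specimen_id), ]
  per_species <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(species = sp_truth$species,
                                   genus = sp_truth$genus,
                                   correct = res$correct),
                    .data$species, .data$genus),
    success = all(.data$correct), .groups = "drop"
  )
  summarize_class <- function(tbl, cls) {
    ci <- wilson_ci(sum(tbl$success), nrow(tbl), conf = conf)
    tibble::tibble(level = level, class = cls, k = ci$k, n = ci$n,
                   sensitivity = ci$estimate,
                   ci_low = ci$ci_low, ci_high = ci$ci_high)
  }
  rows <- list(summarize_class(per_species, "overall"))
  if (!is.null(classification) && level == "species") {
    cl <- dplyr::inner_join(per_species,
                            classification[, c("species", "class")],
                            by = "species")
    for (cls in c("weak", "strong")) {
      sub <- cl[cl$class == cls, , drop = FALSE]
      if (nrow(sub) > 0L) {
        rows[[length(rows) + 1L]] <- summarize_class(sub, cls)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "species_success") <- per_species
  class(out) <- c("bronx_eval", class(out))
  out
}

#' Build a ratings matrix across identification engines
#'
#' Arranges per-species outcomes of several engines into the
#' items-by-categories count matrix consumed by [fleiss_kappa()]: each
#' species-test is an item, each engine a rater, and the categories are
#' correct/incorrect.
#'
#' @param ... Named `bronx_eval` objects (their `"species_success"`
#'   attribute supplies the per-species outcomes), or named logical vectors
#'   indexed by species.
#' @return Integer matrix with one row per species shared by all engines
#'   and columns `correct`, `incorrect`.
#' @export
ratings_matrix <- function(...) {
  raters <- list(...)
  if (length(raters) < 2L) {
    abort("need at least two engines to compare",
          class = "bronx_param_error")
  }
  as_outcome <- function(x) {
    if (inherits(x, "bronx_eval")) {
      ss <- attr(x, "species_success")
      setNames(ss$success, ss$species)
    } else {
      x
    }
  }
  outcomes <- lapply(raters, as_outcome)
  shared <- Reduce(intersect, lapply(outcomes, names))
  m <- vapply(outcomes, function(o) as.integer(o[shared]),
              integer(length(shared)))
  cbind(correct = rowSums(m), incorrect = length(outcomes) - rowSums(m))
}
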