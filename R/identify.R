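# Query scoring and identification against a reference database.

#' Nearest-postext fallback lookup
#'
#' When a query window's (pretext, postext) pair is absent from a terminal's
#' expose but the pretext itself is known there, the engine falls back to the
#' stored postext that lies physically nearest downstream of that pretext —
#' the stored combination with the shortest text, ties broken
#' lexicographically by postext then text. The fallback awards a match when
#' the stored text and the query text agree on their first
#' `min(|stored text|, x)` symbols.
#'
#' This function exposes the rule in isolation for inspection; scoring uses
#' the same logic vectorized.
#'
#' @param db A `bronx_db`.
#' @param level Taxonomic level of the expose.
#' @param terminal Terminal name.
#' @param pretext Query window pretext.
#' @param query_text Query window text (length `x`).
#' @return A one-row tibble with the selected `fb_text`, `fb_postext` and
#'   logical `match`, or a zero-row tibble when the pretext is unknown to
#'   the terminal (no fallback fires).
#' @export
nearest_fallback <- function(db, level, terminal, pretext, query_text) {
  cand <- dplyr::filter(db$nearest, .data$level == !!level,
                        .data$terminal == !!terminal,
                        .data$pretext == !!pretext)
  if (nrow(cand) == 0L) {
    return(tibble::tibble(fb_text = character(), fb_postext = character(),
                          match = logical()))
  }
  m <- pmin(nchar(cand$fb_text), nchar(query_text))
  tibble::tibble(
    fb_text = cand$fb_text,
    fb_postext = cand$fb_postext,
    match = substr(cand$fb_text, 1L, m) == substr(query_text, 1L, m)
  )
}

level_slice <- function(db, level) {
  if (!level %in% db$levels) {
    abort(sprintf("level '%s' not present in database (has: %s)",
                  level, paste(db$levels, collapse = ", ")),
          class = "bronx_level_error")
  }
  list(
    combos = dplyr::filter(db$combos, .data$level == !!level),
    pairs = dplyr::filter(db$pairs, .data$level == !!level),
    nearest = dplyr::filter(db$nearest, .data$level == !!level),
    terminals = unique(db$membership$terminal[db$membership$level == level])
  )
}

#' Score a query against every terminal of a level
#'
#' Extracts query windows (both strands, fixed text length `x`) and scores
#' each terminal: a window awards +1 to every terminal whose expose contains
#' the exact (pretext, text, postext) combination; for terminals where that
#' (pretext, postext) pair is absent but the pretext is present, the
#' nearest-postext fallback (see [nearest_fallback()]) may award +1 instead.
#' A window never contributes more than +1 to any given terminal, so every
#' score is bounded by the number of query windows.
#'
#' @param db A `bronx_db`.
#' @param seq Query sequence (normalized on entry).
#' @param level Taxonomic level to score.
#' @param fallback Use the nearest-postext fallback (default `TRUE`).
#' @return A tibble of class `bronx_scores` with columns `terminal`, `score`
#'   (all terminals of the level, zero scores included), ordered by
#'   decreasing score; attributes `level` and `n_query_windows`.
#' @export
score_query <- function(db, seq, level, fallback = TRUE) {
  if (db$params$x > db$params$y) {
    abort("query text length x exceeds stored maximum y",
          class = "bronx_param_error")
  }
  seq <- normalize_residues(seq)
  ls <- level_slice(db, level)
  qw <- scan_query(seq, db$params)
  qw$w <- seq_len(nrow(qw))

  if (nrow(qw) == 0L) {
    hits <- tibble::tibble(w = integer(), terminal = character())
  } else {
    exact <- dplyr::distinct(
      dplyr::inner_join(qw, ls$combos,
                        by = c("pretext", "text", "postext"),
                        relationship = "many-to-many")[c("w", "terminal")]
    )
    if (fallback) {
      pair_present <- dplyr::distinct(
        dplyr::inner_join(qw, ls$pairs, by = c("pretext", "postext"),
                          relationship = "many-to-many")[c("w", "terminal")]
      )
      fb <- dplyr::inner_join(qw, ls$nearest, by = "pretext",
                              relationship = "many-to-many")
      fb <- dplyr::anti_join(fb, pair_present, by = c("w", "terminal"))
      m <- pmin(nchar(fb$fb_text), nchar(fb$text))
      fb <- fb[substr(fb$fb_text, 1L, m) == substr(fb$text, 1L, m),
               c("w", "terminal")]
      hits <- dplyr::distinct(dplyr::bind_rows(exact, fb))
    } else {
      hits <- exact
    }
  }
  scores <- dplyr::count(hits, .data$terminal, name = "score")
  out <- dplyr::left_join(tibble::tibble(terminal = ls$terminals), scores,
                          by = "terminal")
  out$score <- ifelse(is.na(out$score), 0L, out$score)
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$terminal)
  structure(out, level = level, n_query_windows = nrow(qw),
            class = c("bronx_scores", class(out)))
}

result_row <- function(query_id, level, scores) {
  n_win <- attr(scores, "n_query_windows")
  top <- if (nrow(scores) == 0L) 0L else max(scores$score)
  if (top == 0L) {
    winners <- character()
  } else {
    winners <- sort(scores$terminal[scores$score == top])
  }
  n_winners <- length(winners)
  tibble::tibble(
    query_id = query_id,
    level = level,
    winners = list(winners),
    top_score = as.integer(top),
    n_windows = as.integer(n_win),
    ambiguous = n_winners > 1L,
    unidentified = top == 0L
  )
}

#' Identify query sequences
#'
#' Scores each query at each requested level and reports the set of
#' top-scoring terminals. The winner set is returned whole: ties are real
#' ambiguity (typically shared haplotypes) and are never broken arbitrarily.
#' A query matching nothing (top score zero) is reported as unidentified.
#'
#' @param db A `bronx_db`.
#' @param queries Either a sequence-record tibble (see [sequence_records()])
#'   or a named character vector of sequences.
#' @param levels Levels to report (default: all levels in the database).
#' @param fallback Use the nearest-postext fallback (default `TRUE`).
#' @return A tibble of class `bronx_id` with one row per query per level:
#'   `query_id`, `level`, `winners` (list-column of character vectors),
#'   `top_score`, `n_windows`, `ambiguous`, `unidentified`.
#' @export
bronx_identify <- function(db, queries, levels = db$levels,
                           fallback = TRUE) {
  if (is.data.frame(queries)) {
    ids <- queries$specimen_id
    seqs <- queries$residues
  } else {
    seqs <- unname(queries)
    ids <- names(queries) %||% paste0("query", seq_along(seqs))
  }
  rows <- list()
  for (i in seq_along(seqs)) {
    for (lv in levels) {
      rows[[length(rows) + 1L]] <-
        result_row(ids[i], lv, score_query(db, seqs[i], lv,
                                           fallback = fallback))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bronx_id", class(out))
  out
}

#' Flatten identification results for export
#'
#' Collapses the `winners` list-column to a semicolon-joined string, the
#' shape written by the command-line interface.
#'
#' @param results A `bronx_id` tibble from [bronx_identify()].
#' @return A plain tibble with `winners` as character.
#' @export
flatten_identifications <- function(results) {
  out <- tibble::as_tibble(results)
  out$winners <- vapply(out$winners, paste, character(1), collapse = ";")
  out
}
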