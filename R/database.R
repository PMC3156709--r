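# Reference database construction: context-window extraction and the
# composite per-terminal exposes with their derived lookup tables.

#' Database construction parameters
#'
#' The engine's tunable constants. `n` is the length of the invariant
#' flanking context (pretext and postext) in nucleotides; `y` the maximum
#' stored text length on the reference side (texts of every length `1..y`
#' are stored); `x` the fixed text length extracted from queries; `spacer`
#' the number of `N` codes inserted between concatenated markers.
#'
#' @param n Pretext/postext length (default 6).
#' @param y Maximum reference text length (default 8).
#' @param x Query text length (default 3); must satisfy `1 <= x <= y`.
#' @param spacer Marker-join N count (default 15).
#' @return An object of class `bronx_params`.
#' @export
bronx_params <- function(n = 6L, y = 8L, x = 3L, spacer = 15L) {
  n <- as.integer(n); y <- as.integer(y)
  x <- as.integer(x); spacer <- as.integer(spacer)
  if (n < 1L) abort("n must be >= 1", class = "bronx_param_error")
  if (x < 1L || x > y) {
    abort("query text length x must satisfy 1 <= x <= y",
          class = "bronx_param_error")
  }
  if (spacer < 0L) abort("spacer must be >= 0", class = "bronx_param_error")
  structure(list(n = n, y = y, x = x, spacer = spacer),
            class = "bronx_params")
}

#' @export
print.bronx_params <- function(x, ...) {
  cat(sprintf("<bronx_params> n=%d y=%d x=%d spacer=%d\n",
              x$n, x$y, x$x, x$spacer))
  invisible(x)
}

# Vectorized window extraction at fixed text length. Positions are 0-based
# offsets of the pretext start. Windows containing any non-ACGT symbol
# anywhere in pretext, text or postext are dropped: ambiguity codes are
# never stored and never scored.
windows_at_x <- function(seq, n, x, strand) {
  L <- nchar(seq)
  n_win <- L - 2L * n - x + 1L
  if (n_win <= 0L) {
    return(tibble::tibble(position = integer(), strand = character(),
                          pretext = character(), text = character(),
                          postext = character()))
  }
  p <- 0:(n_win - 1L)
  out <- tibble::tibble(
    position = p,
    strand = strand,
    pretext = substring(seq, p + 1L, p + n),
    text = substring(seq, p + n + 1L, p + n + x),
    postext = substring(seq, p + n + x + 1L, p + 2L * n + x)
  )
  clean <- !grepl("[^ACGT]", paste0(out$pretext, out$text, out$postext))
  out[clean, , drop = FALSE]
}

#' Extract reference context windows
#'
#' For every position `p` and every text length `x` in `1..y` such that the
#' window fits, extracts the (pretext, text, postext) triple: `n` pretext
#' nucleotides starting at `p`, `x` text nucleotides, then `n` postext
#' nucleotides. Windows containing any IUPAC ambiguity symbol are omitted.
#' References are indexed on the given strand only; strand handling lives on
#' the query side.
#'
#' @param seq Normalized nucleotide sequence.
#' @param params A [bronx_params()] object.
#' @return Tibble with columns `position` (0-based pretext start), `strand`,
#'   `pretext`, `text`, `postext`. Empty for sequences shorter than
#'   `2n + 1`.
#' @export
extract_reference_windows <- function(seq, params = bronx_params()) {
  dplyr::bind_rows(lapply(seq_len(params$y), function(x) {
    windows_at_x(seq, params$n, x, "forward")
  }))
}

#' Extract query context windows
#'
#' Extracts windows exactly as on the reference side but with the text
#' length fixed at `x`, from both the query and its reverse complement.
#' Windows containing ambiguity symbols are omitted, mirroring the
#' reference side.
#'
#' @inheritParams extract_reference_windows
#' @return Tibble as for [extract_reference_windows()], with `strand` either
#'   `"forward"` or `"reverse"` (positions on the reverse strand are offsets
#'   into the reverse complement).
#' @export
scan_query <- function(seq, params = bronx_params()) {
  dplyr::bind_rows(
    windows_at_x(seq, params$n, params$x, "forward"),
    windows_at_x(reverse_complement(seq), params$n, params$x, "reverse")
  )
}

# Expand records into one row per (level, terminal) membership.
terminal_map <- function(records, levels, custom = NULL) {
  maps <- list()
  if ("species" %in% levels) {
    maps$species <- tibble::tibble(level = "species",
                                   terminal = records$species,
                                   row = seq_len(nrow(records)))
  }
  if ("genus" %in% levels) {
    maps$genus <- tibble::tibble(level = "genus",
                                 terminal = records$genus,
                                 row = seq_len(nrow(records)))
  }
  if ("custom" %in% levels) {
    if (is.null(custom) || length(custom) == 0L) {
      abort("custom level requested but no custom terminals supplied",
            class = "bronx_param_error")
    }
    maps$custom <- dplyr::bind_rows(lapply(names(custom), function(nm) {
      rows <- which(records$species %in% custom[[nm]])
      tibble::tibble(level = "custom", terminal = nm, row = rows)
    }))
  }
  dplyr::bind_rows(maps)
}

#' Build a reference database of composite exposes
#'
#' Extracts all context windows from every reference record and pools them
#' into one composite expose per terminal at each requested level: a species
#' expose is the union of combinations over all sequences of that species, a
#' genus expose the union over all member species, and a custom terminal
#' the union over a user-listed set of species. Combinations are set-valued:
#' a combination counts once per terminal no matter how many specimens show
#' it, which is what lets shared haplotypes surface as ambiguity instead of
#' arbitrary winners.
#'
#' @param records Sequence-record tibble; all rows are indexed, so filter to
#'   the intended reference set (e.g. with [select_reference_set()]) and a
#'   single marker (or `combined`) first.
#' @param params A [bronx_params()] object.
#' @param levels Character subset of `c("species", "genus", "custom")`.
#' @param custom Named list mapping custom terminal names to character
#'   vectors of member species binomials (required iff `"custom"` is in
#'   `levels`).
#' @return An object of class `bronx_db`.
#' @export
bronx_build <- function(records, params = bronx_params(),
                        levels = c("species", "genus"), custom = NULL) {
  if (nrow(records) == 0L) {
    abort("empty reference set", class = "bronx_empty_input")
  }
  bad <- !levels %in% c("species", "genus", "custom")
  if (any(bad)) {
    abort(sprintf("unknown level '%s'", levels[bad][1L]),
          class = "bronx_param_error")
  }
  win <- lapply(records$residues, extract_reference_windows, params = params)
  n_raw <- sum(vapply(win, nrow, integer(1)))
  per_rec <- dplyr::bind_rows(
    lapply(seq_along(win), function(i) {
      w <- win[[i]]
      if (nrow(w) == 0L) return(NULL)
      tibble::tibble(row = i, pretext = w$pretext, text = w$text,
                     postext = w$postext)
    })
  )
  tm <- terminal_map(records, levels, custom)
  combos <- dplyr::distinct(
    dplyr::select(dplyr::inner_join(tm, per_rec, by = "row",
                                    relationship = "many-to-many"),
                  "level", "terminal", "pretext", "text", "postext")
  )
  combos <- dplyr::arrange(combos, .data$level, .data$terminal,
                           .data$pretext, .data$text, .data$postext)
  membership <- dplyr::distinct(
    tibble::tibble(level = tm$level, terminal = tm$terminal,
                   species = records$species[tm$row])
  )
  db <- structure(list(
    params = params,
    levels = unique(tm$level),
    combos = combos,
    membership = membership,
    n_records = nrow(records),
    n_windows = n_raw
  ), class = "bronx_db")
  db$pairs <- db_pairs(db)
  db$nearest <- db_nearest(db)
  db
}

# distinct (level, terminal, pretext, postext) pairs: the "pair exists"
# test that decides whether the fallback is blocked for a terminal
db_pairs <- function(db) {
  dplyr::distinct(dplyr::select(db$combos, "level", "terminal",
                                "pretext", "postext"))
}

# per (level, terminal, pretext): the stored combination whose text is
# shortest, i.e. whose postext begins physically nearest downstream of the
# pretext in the source sequence; ties broken lexicographically by postext
# then text for determinism
db_nearest <- function(db) {
  dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(db$combos, .data$level, .data$terminal, .data$pretext),
      nchar(.data$text), .data$postext, .data$text, .by_group = TRUE
    ),
    n = 1L
  ) |> dplyr::ungroup() |>
    dplyr::rename(fb_text = "text", fb_postext = "postext")
}

#' @export
print.bronx_db <- function(x, ...) {
  nt <- dplyr::count(dplyr::distinct(x$combos, .data$level, .data$terminal),
                     .data$level)
  cat(sprintf("<bronx_db> %d reference sequence(s); n=%d y=%d x=%d\n",
              x$n_records, x$params$n, x$params$y, x$params$x))
  for (i in seq_len(nrow(nt))) {
    cat(sprintf("  level %-8s %4d terminal(s)\n", nt$level[i], nt$n[i]))
  }
  cat(sprintf("  %d stored combination(s) across levels\n", nrow(x$combos)))
  invisible(x)
}

#' @describeIn bronx_build Tidy view of a database: one row per stored
#'   (level, terminal, pretext, text, postext) combination.
#' @param x A `bronx_db` object.
#' @param ... Unused.
#' @export
tidy.bronx_db <- function(x, ...) {
  x$combos
}

#' @describeIn bronx_build One-row summary of a database (terminal and
#'   combination counts, parameters).
#' @export
glance.bronx_db <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    n_terminals = nrow(dplyr::distinct(x$combos, .data$level,
                                       .data$terminal)),
    n_combinations = nrow(x$combos),
    n = x$params$n, y = x$params$y, x_query = x$params$x,
    spacer = x$params$spacer
  )
}

BRONX_DB_FORMAT <- "bronx-db"
BRONX_DB_VERSION <- 1L

#' Save and load reference databases
#'
#' Persists a database to a single self-describing JSON file with canonical
#' key ordering, replacing a server-side store with a zero-dependency flat
#' file. A loaded database produces identical identifications to the one
#' saved.
#'
#' @param db A `bronx_db` object.
#' @param path File path.
#' @return `save_bronx_db` returns `path` invisibly; `read_bronx_db` returns
#'   a `bronx_db`.
#' @export
save_bronx_db <- function(db, path) {
  payload <- list(
    format = BRONX_DB_FORMAT,
    version = BRONX_DB_VERSION,
    params = unclass(db$params),
    levels = db$levels,
    n_records = db$n_records,
    n_windows = db$n_windows,
    membership = as.list(db$membership),
    combos = as.list(dplyr::arrange(db$combos, .data$level, .data$terminal,
                                    .data$pretext, .data$text,
                                    .data$postext))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_bronx_db
#' @export
read_bronx_db <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        abort(sprintf("cannot parse database file %s: %s",
                                      path, conditionMessage(e)),
                              class = "bronx_db_format_error")
                      })
  if (!identical(payload$format, BRONX_DB_FORMAT)) {
    abort(sprintf("not a bronx database file: %s", path),
          class = "bronx_db_format_error")
  }
  if (!identical(as.integer(payload$version), BRONX_DB_VERSION)) {
    abort(sprintf("database version %s unsupported (reader version %d)",
                  payload$version, BRONX_DB_VERSION),
          class = "bronx_db_version_error")
  }
  db <- structure(list(
    params = do.call(bronx_params, payload$params),
    levels = payload$levels,
    combos = tibble::as_tibble(payload$combos),
    membership = tibble::as_tibble(payload$membership),
    n_records = payload$n_records,
    n_windows = payload$n_windows
  ), class = "bronx_db")
  db$pairs <- db_pairs(db)
  db$nearest <- db_nearest(db)
  db
}
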