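# Seeded simulator for two-marker plastid barcode datasets: hierarchical
# divergence (root -> genus -> species -> specimen), indels on species
# branches, optional shared haplotypes between congeneric species.

#' Simulation configuration
#'
#' Defines a hierarchical two-marker barcode simulation. One random root
#' sequence is drawn per marker; genus ancestors diverge from the root,
#' species ancestors from their genus, and specimen haplotypes from their
#' species, each by independent per-site substitutions (uniform over the
#' three alternative bases). Indels with geometric lengths are applied on
#' species branches, making the markers alignment-hostile the way plant
#' barcodes are. Marker lengths default to a matK-like 1300 bp and an
#' rbcL-like 620 bp.
#'
#' @param n_genera Number of genera (default 5).
#' @param species_per_genus Species per genus (default 3).
#' @param specimens_per_species Specimens (haplotypes) per species
#'   (default 2).
#' @param marker_length Named integer vector of marker lengths
#'   (default `c(matK = 1300, rbcL = 620)`).
#' @param genus_divergence Substitutions per site on root-to-genus branches
#'   (default 0.05).
#' @param species_divergence Substitutions per site on genus-to-species
#'   branches (default 0.02).
#' @param within_divergence Substitutions per site on species-to-specimen
#'   branches (default 0.002).
#' @param indel_prob Probability of one indel event on each species branch
#'   per marker (default 0.1).
#' @param indel_mean_length Mean of the geometric indel length distribution
#'   (default 3).
#' @param shared_haplotype_pairs List of length-2 character vectors of
#'   species binomials forced to share identical haplotypes (must be
#'   congeneric).
#' @param ambiguity_rate Per-site probability of replacing a base with `N`
#'   in specimen sequences (default 0, giving ACGT-only data).
#' @param seed Integer seed (mandatory).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_genera = 5L, species_per_genus = 3L,
                         specimens_per_species = 2L,
                         marker_length = c(matK = 1300L, rbcL = 620L),
                         genus_divergence = 0.05,
                         species_divergence = 0.02,
                         within_divergence = 0.002,
                         indel_prob = 0.1, indel_mean_length = 3,
                         shared_haplotype_pairs = NULL,
                         ambiguity_rate = 0, seed) {
  if (missing(seed)) abort("seed is mandatory", class = "bronx_param_error")
  rates <- c(genus_divergence, species_divergence, within_divergence,
             indel_prob, ambiguity_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("rates must lie in [0, 1]", class = "bronx_param_error")
  }
  if (is.null(names(marker_length))) {
    names(marker_length) <- paste0("marker", seq_along(marker_length))
  }
  structure(list(
    n_genera = as.integer(n_genera),
    species_per_genus = as.integer(species_per_genus),
    specimens_per_species = as.integer(specimens_per_species),
    marker_length = marker_length,
    genus_divergence = genus_divergence,
    species_divergence = species_divergence,
    within_divergence = within_divergence,
    indel_prob = indel_prob,
    indel_mean_length = indel_mean_length,
    shared_haplotype_pairs = shared_haplotype_pairs,
    ambiguity_rate = ambiguity_rate,
    seed = as.integer(seed)
  ), class = "synth_config")
}

BASES <- c("A", "C", "G", "T")

random_seq <- function(length) {
  paste(sample(BASES, length, replace = TRUE), collapse = "")
}

# per-site substitution, uniform over the three alternative bases
mutate_seq <- function(seq, rate) {
  if (rate == 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(s)) < rate
  if (any(hit)) {
    s[hit] <- vapply(s[hit], function(b) sample(setdiff(BASES, b), 1L),
                     character(1))
  }
  paste(s, collapse = "")
}

# at most one indel event per call: a deletion or insertion of geometric
# length at a uniform position
apply_indel <- function(seq, prob, mean_length) {
  if (runif(1) >= prob) return(seq)
  len <- 1L + stats::rgeom(1L, 1 / max(mean_length, 1))
  L <- nchar(seq)
  if (runif(1) < 0.5 && L > len + 1L) {  # deletion
    start <- sample(seq_len(L - len), 1L)
    paste0(substr(seq, 1L, start - 1L), substr(seq, start + len, L))
  } else {  # insertion
    pos <- sample(0:L, 1L)
    paste0(substr(seq, 1L, pos), random_seq(len),
           substr(seq, pos + 1L, L))
  }
}

inject_ambiguity <- function(seq, rate) {
  if (rate == 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  s[runif(length(s)) < rate] <- "N"
  paste(s, collapse = "")
}

#' Generate a synthetic two-marker barcode dataset
#'
#' Simulates the full hierarchy described in [synth_config()] and returns
#' the specimen records together with a truth table. Shared-haplotype pairs
#' are produced by copying the first species' specimen sequences verbatim
#' onto the second species, so the pair is genuinely indistinguishable at
#' the sequence level while remaining congeneric (and hence resolvable at
#' genus level).
#'
#' @param config A [synth_config()] object.
#' @return A list with elements `records` (sequence-record tibble, one row
#'   per specimen per marker) and `truth` (tibble `specimen_id`, `genus`,
#'   `species`).
#' @export
generate_dataset <- function(config) {
  pairs <- config$shared_haplotype_pairs
  sp_name <- function(g, s) sprintf("Genus%02d species%02d", g, s)
  all_species <- as.vector(outer(seq_len(config$n_genera),
                                 seq_len(config$species_per_genus),
                                 sp_name))
  if (!is.null(pairs)) {
    for (pr in pairs) {
      if (length(pr) != 2L || !all(pr %in% all_species)) {
        abort(sprintf("shared-haplotype pair (%s) names unknown species",
                      paste(pr, collapse = ", ")),
              class = "bronx_param_error")
      }
      g1 <- sub(" .*$", "", pr[1]); g2 <- sub(" .*$", "", pr[2])
      if (!identical(g1, g2)) {
        abort("shared-haplotype pairs must be congeneric: a haplotype shared across genera would make genus-level truth incoherent",
              class = "bronx_param_error")
      }
    }
  }
  withr::with_seed(config$seed, {
    rows <- list()
    for (mk in names(config$marker_length)) {
      root <- random_seq(config$marker_length[[mk]])
      for (g in seq_len(config$n_genera)) {
        genus_anc <- mutate_seq(root, config$genus_divergence)
        genus_lab <- sprintf("Genus%02d", g)
        for (s in seq_len(config$species_per_genus)) {
          sp_anc <- mutate_seq(genus_anc, config$species_divergence)
          sp_anc <- apply_indel(sp_anc, config$indel_prob,
                                config$indel_mean_length)
          for (i in seq_len(config$specimens_per_species)) {
            hap <- mutate_seq(sp_anc, config$within_divergence)
            hap <- inject_ambiguity(hap, config$ambiguity_rate)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              specimen_id = sprintf("G%02dS%02dI%02d", g, s, i),
              genus = genus_lab,
              epithet = sprintf("species%02d", s),
              marker = mk,
              residues = hap
            )
          }
        }
      }
    }
    recs <- dplyr::bind_rows(rows)
    recs$species <- paste(recs$genus, recs$epithet)
    if (!is.null(pairs)) {
      for (pr in pairs) {
        src <- recs[recs$species == pr[1], , drop = FALSE]
        for (mk in names(config$marker_length)) {
          src_mk <- src[src$marker == mk, , drop = FALSE]
          tgt_idx <- which(recs$species == pr[2] & recs$marker == mk)
          recs$residues[tgt_idx] <-
            rep_len(src_mk$residues, length(tgt_idx))
        }
      }
    }
    records <- sequence_records(recs$specimen_id, recs$genus, recs$epithet,
                                recs$marker, recs$residues,
                                is_reference = TRUE)
    truth <- dplyr::distinct(records[, c("specimen_id", "genus", "species")])
    list(records = records, truth = truth)
  })
}
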