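# Independent brute-force oracles used to check the vectorized/indexed
# implementations. These deliberately share no code with the package:
# plain loops over definitions.

# enumerate every (p, x) reference window by scanning character by character
oracle_windows <- function(seq, n = 6L, y = 8L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- list()
  for (p in 0:max(L - 1, 0)) {
    for (x in 1:y) {
      if (p + 2 * n + x > L) next
      pre <- paste(chars[(p + 1):(p + n)], collapse = "")
      txt <- paste(chars[(p + n + 1):(p + n + x)], collapse = "")
      post <- paste(chars[(p + n + x + 1):(p + 2 * n + x)], collapse = "")
      if (grepl("[^ACGT]", paste0(pre, txt, post))) next
      out[[length(out) + 1]] <- data.frame(
        position = p, x = x, pretext = pre, text = txt, postext = post,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, list(data.frame(position = integer(), x = integer(),
                                        pretext = character(),
                                        text = character(),
                                        postext = character()))))
}

# quadratic reference scorer: per query window, loop over terminals and
# stored combinations, applying exact match then the nearest-postext
# fallback rule
oracle_score <- function(records, query, level = "species",
                         n = 6L, y = 8L, x = 3L, fallback = TRUE) {
  terminal_of <- if (level == "genus") records$genus else records$species
  terminals <- sort(unique(terminal_of))
  expose <- lapply(terminals, function(t) {
    seqs <- records$residues[terminal_of == t]
    do.call(rbind, lapply(seqs, oracle_windows, n = n, y = y))
  })
  names(expose) <- terminals

  revcomp <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
             W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
             N = "N")
    paste(rev(map[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }
  qwin <- rbind(
    oracle_windows(query, n = n, y = x)[
      oracle_windows(query, n = n, y = x)$x == x, ],
    oracle_windows(revcomp(query), n = n, y = x)[
      oracle_windows(revcomp(query), n = n, y = x)$x == x, ]
  )
  scores <- setNames(rep(0L, length(terminals)), terminals)
  if (nrow(qwin) == 0) return(scores)
  for (i in seq_len(nrow(qwin))) {
    pre <- qwin$pretext[i]; txt <- qwin$text[i]; post <- qwin$postext[i]
    for (t in terminals) {
      ex <- expose[[t]]
      if (is.null(ex) || nrow(ex) == 0) next
      exact <- any(ex$pretext == pre & ex$text == txt & ex$postext == post)
      if (exact) {
        scores[t] <- scores[t] + 1L
        next
      }
      if (!fallback) next
      pair_present <- any(ex$pretext == pre & ex$postext == post)
      if (pair_present) next
      cand <- ex[ex$pretext == pre, , drop = FALSE]
      if (nrow(cand) == 0) next
      cand <- cand[order(nchar(cand$text), cand$postext, cand$text), ,
                   drop = FALSE]
      stored <- cand$text[1]
      m <- min(nchar(stored), nchar(txt))
      if (substr(stored, 1, m) == substr(txt, 1, m)) {
        scores[t] <- scores[t] + 1L
      }
    }
  }
  scores
}

# exhaustive alignment enumerator: recursively generate every gapped
# alignment, score complete alignments (gap run of length L costs
# open + extend * (L - 1)), return the optimum
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 5, gap_extend = 2,
                               mode = "global") {
  score_alignment <- function(ra, rb) {
    s <- 0
    run_a <- 0L; run_b <- 0L
    for (i in seq_along(ra)) {
      if (ra[i] == "-") {
        run_a <- run_a + 1L; run_b <- 0L
        s <- s - (if (run_a == 1L) gap_open else gap_extend)
      } else if (rb[i] == "-") {
        run_b <- run_b + 1L; run_a <- 0L
        s <- s - (if (run_b == 1L) gap_open else gap_extend)
      } else {
        run_a <- 0L; run_b <- 0L
        s <- s + (if (ra[i] == rb[i]) match else mismatch)
      }
    }
    s
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- -Inf
  recurse <- function(i, j, ra, rb) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score_alignment(ra, rb))
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      recurse(i + 1, j + 1, c(ra, ca[i]), c(rb, cb[j]))
    }
    if (i <= length(ca)) recurse(i + 1, j, c(ra, ca[i]), c(rb, "-"))
    if (j <= length(cb)) recurse(i, j + 1, c(ra, "-"), c(rb, cb[j]))
  }
  if (mode == "global") {
    recurse(1, 1, character(), character())
    return(best)
  }
  # local: optimum over all substring pairs (empty alignment scores 0)
  best_local <- 0
  for (i1 in seq_along(ca)) for (i2 in i1:length(ca)) {
    for (j1 in seq_along(cb)) for (j2 in j1:length(cb)) {
      best <<- -Inf
      ca_sub <- ca[i1:i2]; cb_sub <- cb[j1:j2]
      sub_rec <- function(i, j, ra, rb) {
        if (i > length(ca_sub) && j > length(cb_sub)) {
          best <<- max(best, score_alignment(ra, rb))
          return(invisible())
        }
        if (i <= length(ca_sub) && j <= length(cb_sub)) {
          sub_rec(i + 1, j + 1, c(ra, ca_sub[i]), c(rb, cb_sub[j]))
        }
        if (i <= length(ca_sub)) sub_rec(i + 1, j, c(ra, ca_sub[i]), c(rb, "-"))
        if (j <= length(cb_sub)) sub_rec(i, j + 1, c(ra, "-"), c(rb, cb_sub[j]))
      }
      sub_rec(1, 1, character(), character())
      best_local <- max(best_local, best)
    }
  }
  best_local
}

# site-scan p-distance oracle
oracle_p_distance <- function(a, b) {
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  diff <- 0L; comp <- 0L
  for (i in seq_along(sa)) {
    if (sa[i] %in% c("A", "C", "G", "T") && sb[i] %in% c("A", "C", "G", "T")) {
      comp <- comp + 1L
      if (sa[i] != sb[i]) diff <- diff + 1L
    }
  }
  c(differences = diff, compared = comp)
}

# closed-form Wilson interval
oracle_wilson <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(low = centre - half, high = centre + half)
}

# random ACGT (or IUPAC) string
random_dna <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# small divergent four-species fixture: two genera x two species, clearly
# separated sequences
toy_records <- function(seed = 11, L = 80) {
  withr::with_seed(seed, {
    base <- random_dna(L)
    mut <- function(s, k) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      idx <- sample(length(ch), k)
      ch[idx] <- vapply(ch[idx],
                        function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                        character(1))
      paste(ch, collapse = "")
    }
    sequence_records(
      specimen_id = c("A1", "A2", "B1", "C1"),
      genus = c("Aus", "Aus", "Aus", "Dus"),
      epithet = c("bus", "bus", "cus", "eus"),
      marker = "matK",
      residues = c(base, mut(base, 2), mut(base, 8), mut(base, 20))
    )
  })
}
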