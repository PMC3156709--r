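test_that("query scanning extracts fixed-length texts from both strands", {
  p <- bronx_params()
  q <- scan_query("ACGTACGGTTTGCAA", p)  # L = 15: one window per strand
  expect_equal(nrow(q), 2L)
  fwd <- q[q$strand == "forward", ]
  rev <- q[q$strand == "reverse", ]
  expect_equal(unname(unlist(fwd[c("pretext", "text", "postext")])),
               c("ACGTAC", "GGT", "TTGCAA"))
  expect_equal(unname(unlist(rev[c("pretext", "text", "postext")])),
               c("TTGCAA", "ACC", "GTACGT"))
  # too short for any window
  expect_equal(nrow(scan_query(strrep("A", 14), p)), 0L)
  # ambiguity in the text kills windows on both strands
  expect_equal(nrow(scan_query("ACGTACNGTTTGCAA", p)), 0L)
})

test_that("nearest-postext fallback picks the shortest stored text and prefix-matches", {
  # expose holding two combinations downstream of the same pretext
  recs <- sequence_records("R1", "Aus", "bus", "matK",
                           "ACGTACGGTTTGCAAGG")
  db <- bronx_build(recs, levels = "species")
  # stored for pretext ACGTAC: texts "G" (postext GTTTGC) ... "GGTTT"
  fb <- nearest_fallback(db, "species", "Aus bus", "ACGTAC", "GTT")
  expect_equal(nrow(fb), 1L)
  expect_equal(fb$fb_text, "G")
  expect_equal(fb$fb_postext, "GTTTGC")
  expect_true(fb$match)  # min(1, 3) = 1 symbol: "G" vs "G"
  # non-matching query text at the compared prefix
  fb2 <- nearest_fallback(db, "species", "Aus bus", "ACGTAC", "TTT")
  expect_false(fb2$match)
  # unknown pretext: no fallback fires
  fb3 <- nearest_fallback(db, "species", "Aus bus", "TTTTTT", "GTT")
  expect_equal(nrow(fb3), 0L)
})

test_that("indexed scoring equals the quadratic brute-force matcher", {
  p <- bronx_params()
  withr::with_seed(31, {
    for (rep in 1:8) {
      # small random instances: up to 5 terminals, sequences up to 60 bp
      n_sp <- sample(2:5, 1)
      recs <- sequence_records(
        specimen_id = paste0("S", seq_len(n_sp)),
        genus = sample(c("Aus", "Bus"), n_sp, replace = TRUE),
        epithet = paste0("sp", seq_len(n_sp)),
        marker = "matK",
        residues = vapply(seq_len(n_sp), function(i)
          random_dna(sample(20:60, 1)), character(1))
      )
      db <- bronx_build(recs, levels = "species")
      # queries: a mutated copy of a reference and pure noise
      base <- recs$residues[1]
      queries <- c(
        paste0(substr(base, 1, nchar(base) - 2), "AA"),
        random_dna(40)
      )
      for (q in queries) {
        got <- score_query(db, q, "species")
        want <- oracle_score(recs, q, "species")
        expect_equal(setNames(got$score, got$terminal)[names(want)], want)
        # fallback-free route too
        got0 <- score_query(db, q, "species", fallback = FALSE)
        want0 <- oracle_score(recs, q, "species", fallback = FALSE)
        expect_equal(setNames(got0$score, got0$terminal)[names(want0)],
                     want0)
      }
    }
  })
})

test_that("self-query score equals the forward window count on a clean reference", {
  ref <- "ACGTACGGTTTGCAAGGATC"  # L = 20
  recs <- sequence_records("R1", "Aus", "bus", "matK", ref)
  db <- bronx_build(recs, levels = "species")
  st <- score_query(db, ref, "species")
  # frozen from the brute-force oracle: all 6 forward windows
  # (L - (2n + x) + 1) match exactly and no reverse-strand window scores
  expect_equal(st$score, 6L)
  expect_equal(oracle_score(recs, ref, "species")[["Aus bus"]], 6L)
})

test_that("scores are bounded by the query window count", {
  recs <- toy_records()
  db <- bronx_build(recs)
  withr::with_seed(17, {
    for (i in 1:10) {
      q <- random_dna(sample(20:120, 1))
      st <- score_query(db, q, "species")
      expect_true(all(st$score >= 0))
      expect_true(all(st$score <= attr(st, "n_query_windows")))
    }
  })
})

test_that("identification is strand-symmetric at every level", {
  recs <- toy_records()
  db <- bronx_build(recs)
  withr::with_seed(23, {
    queries <- c(recs$residues[1],
                 vapply(1:5, function(i) random_dna(60), character(1)))
  })
  for (q in queries) {
    a <- bronx_identify(db, c(q = q))
    b <- bronx_identify(db, c(q = reverse_complement(q)))
    expect_equal(a[c("level", "winners", "top_score", "n_windows",
                     "ambiguous", "unidentified")],
                 b[c("level", "winners", "top_score", "n_windows",
                     "ambiguous", "unidentified")])
  }
})

test_that("exact-match scoring is monotone in the expose", {
  # adding a sequence to a terminal never lowers its exact-match score
  withr::with_seed(41, {
    for (rep in 1:5) {
      s1 <- random_dna(50)
      s2 <- random_dna(50)
      q <- random_dna(50)
      one <- sequence_records("A1", "Aus", "bus", "matK", s1)
      two <- sequence_records(c("A1", "A2"), "Aus", "bus", "matK",
                              c(s1, s2))
      db1 <- bronx_build(one, levels = "species")
      db2 <- bronx_build(two, levels = "species")
      sc1 <- score_query(db1, q, "species", fallback = FALSE)
      sc2 <- score_query(db2, q, "species", fallback = FALSE)
      expect_true(sc2$score >= sc1$score)
    }
  })
})

test_that("per-level identification reports winners, ambiguity and failures", {
  recs <- toy_records()
  db <- bronx_build(recs)
  # exact copy of a reference: unambiguous at both levels
  res <- bronx_identify(db, c(q1 = recs$residues[1]))
  sp <- res[res$level == "species", ]
  gn <- res[res$level == "genus", ]
  expect_equal(sp$winners[[1]], "Aus bus")
  expect_equal(gn$winners[[1]], "Aus")
  expect_false(any(res$ambiguous))
  expect_false(any(res$unidentified))
  # unknown level is refused
  expect_error(bronx_identify(db, c(q = recs$residues[1]),
                              levels = "family"),
               class = "bronx_level_error")
})

test_that("a shared haplotype is ambiguous at species level, resolved at genus level", {
  hap <- withr::with_seed(5, random_dna(90))
  other <- withr::with_seed(6, random_dna(90))
  recs <- sequence_records(
    specimen_id = c("A1", "B1", "C1"),
    genus = c("Aus", "Aus", "Dus"),
    epithet = c("bus", "cus", "eus"),
    marker = "matK",
    residues = c(hap, hap, other)  # bus and cus share the haplotype
  )
  db <- bronx_build(recs)
  res <- bronx_identify(db, c(q = hap))
  sp <- res[res$level == "species", ]
  gn <- res[res$level == "genus", ]
  expect_true(sp$ambiguous)
  expect_setequal(sp$winners[[1]], c("Aus bus", "Aus cus"))
  expect_false(gn$ambiguous)
  expect_equal(gn$winners[[1]], "Aus")
})

test_that("terminals indexed from identical sequences always tie", {
  hap <- withr::with_seed(8, random_dna(70))
  recs <- sequence_records(c("A1", "B1"), c("Aus", "Aus"),
                           c("bus", "cus"), "matK", c(hap, hap))
  db <- bronx_build(recs, levels = "species")
  withr::with_seed(9, {
    for (i in 1:5) {
      st <- score_query(db, random_dna(50), "species")
      expect_equal(st$score[1], st$score[2])
    }
  })
})

test_that("random queries never beat a self-match, and may be unidentified", {
  recs <- toy_records()
  db <- bronx_build(recs)
  self <- score_query(db, recs$residues[1], "species")
  self_top <- max(self$score)
  withr::with_seed(77, {
    tops <- vapply(1:50, function(i) {
      st <- score_query(db, random_dna(200), "species")
      max(st$score)
    }, numeric(1))
  })
  expect_true(all(tops < self_top))
})

test_that("identification results flatten and summarise tidily", {
  recs <- toy_records()
  db <- bronx_build(recs)
  res <- bronx_identify(db, recs[1:2, ])
  flat <- flatten_identifications(res)
  expect_type(flat$winners, "character")
  g <- glance(res)
  expect_equal(sort(g$level), c("genus", "species"))
  expect_equal(g$n_queries, c(2L, 2L))
})
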