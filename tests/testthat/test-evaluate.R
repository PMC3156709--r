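test_that("reference selection keeps the most complete specimen per species", {
  recs <- sequence_records(
    specimen_id = c("A1", "A2", "B1"),
    genus = "Aus", epithet = c("bus", "bus", "cus"),
    marker = "matK",
    residues = c(paste0(strrep("ACGT", 160), strrep("N", 9), "A"),  # 641 ACGT
                 strrep("ACGT", 165),                               # 660 ACGT
                 strrep("ACGT", 20))
  )
  refs <- select_reference_set(recs)
  expect_equal(sort(unique(refs$specimen_id)), c("A2", "B1"))
  expect_true(all(refs$is_reference))
  # ties resolved by lexicographically smallest specimen id
  tie <- sequence_records(
    specimen_id = c("Z9", "A1"), genus = "Aus", epithet = "bus",
    marker = "matK", residues = c(strrep("ACGT", 10), strrep("TGCA", 10))
  )
  expect_equal(unique(select_reference_set(tie)$specimen_id), "A1")
  # all markers of the chosen specimen are retained, minis are not
  two <- dplyr::bind_rows(
    sequence_records("A1", "Aus", "bus", "matK", strrep("ACGT", 10)),
    sequence_records("A1", "Aus", "bus", "rbcL", strrep("GGCC", 10)),
    sequence_records("A1", "Aus", "bus", "matK_mini", "ACGTACGTACGT")
  )
  kept <- select_reference_set(two)
  expect_setequal(kept$marker, c("matK", "rbcL"))
  expect_error(select_reference_set(recs, marker = "rbcL"),
               class = "bronx_empty_input")
})

test_that("weak/strong classification partitions species by congeners", {
  sp <- tibble::tibble(
    species = c("Aus bus", "Aus cus", "Dus eus"),
    genus = c("Aus", "Aus", "Dus")
  )
  cl <- classify_tests(sp)
  expect_equal(cl$class[cl$species == "Aus bus"], "strong")
  expect_equal(cl$class[cl$species == "Aus cus"], "strong")
  expect_equal(cl$class[cl$species == "Dus eus"], "weak")
  # all-distinct genera: everything weak; classes always partition
  lonely <- tibble::tibble(species = paste("G", 1:4), genus = paste0("g", 1:4))
  cl2 <- classify_tests(lonely)
  expect_true(all(cl2$class == "weak"))
  expect_equal(nrow(cl) , 3L)
  expect_equal(sum(cl$class == "weak") + sum(cl$class == "strong"), 3L)
})

test_that("mini-barcode fragments obey size bounds and are true substrings", {
  withr::with_seed(55, long <- random_dna(300))
  for (seed in c(1, 42, 99)) {
    frag <- make_minibarcode(long, seed = seed)
    expect_gte(nchar(frag), 100L)
    expect_lte(nchar(frag), 200L)
    expect_true(grepl(frag, long, fixed = TRUE))
    # determinism under the seed
    expect_equal(make_minibarcode(long, seed = seed), frag)
  }
  # short sequences are returned whole
  withr::with_seed(56, shorty <- random_dna(100))
  expect_equal(make_minibarcode(shorty, seed = 1), shorty)
  # between 100 and 200: size clamped to the sequence length
  withr::with_seed(57, mid <- random_dna(150))
  frag <- make_minibarcode(mid, seed = 7)
  expect_lte(nchar(frag), 150L)
  expect_gte(nchar(frag), 100L)
})

test_that("mini-barcode sets are seed-reproducible and inherit taxonomy", {
  recs <- toy_records(L = 300)
  a <- generate_minibarcode_set(recs, seed = 11)
  b <- generate_minibarcode_set(recs, seed = 11)
  c <- generate_minibarcode_set(recs, seed = 12)
  expect_equal(a, b)
  expect_false(identical(a$residues, c$residues))
  expect_equal(a$species, recs$species)
  expect_equal(a$marker, paste0(recs$marker, "_mini"))
  expect_false(any(a$is_reference))
  for (i in seq_len(nrow(a))) {
    expect_true(grepl(a$residues[i], recs$residues[i], fixed = TRUE))
  }
})

test_that("the severity rule demands every query correct and unambiguous", {
  truth <- tibble::tibble(
    specimen_id = c("q1", "q2", "q3"),
    genus = c("Aus", "Aus", "Dus"),
    species = c("Aus bus", "Aus bus", "Dus eus")
  )
  res <- tibble::tibble(
    query_id = c("q1", "q2", "q3"),
    level = "species",
    winners = list("Aus bus", c("Aus bus", "Aus cus"), "Dus eus"),
    top_score = c(10L, 8L, 9L),
    n_windows = 20L,
    ambiguous = c(FALSE, TRUE, FALSE),
    unidentified = FALSE
  )
  cl <- tibble::tibble(species = c("Aus bus", "Dus eus"),
                       genus = c("Aus", "Dus"),
                       class = c("strong", "weak"))
  ev <- score_side(res, truth, "species", classification = cl)
  overall <- ev[ev$class == "overall", ]
  # Aus bus fails (one ambiguous query), Dus eus succeeds
  expect_equal(overall$k, 1L)
  expect_equal(overall$n, 2L)
  expect_equal(overall$sensitivity, 0.5)
  ss <- attr(ev, "species_success")
  expect_false(ss$success[ss$species == "Aus bus"])
  expect_true(ss$success[ss$species == "Dus eus"])
  # all-correct results give sensitivity 1 with a proper Wilson interval
  res_ok <- res
  res_ok$winners <- list("Aus bus", "Aus bus", "Dus eus")
  res_ok$ambiguous <- FALSE
  ev_ok <- score_side(res_ok, truth, "species", classification = cl)
  expect_true(all(ev_ok$sensitivity == 1))
  expect_true(all(ev_ok$ci_low <= 1 & ev_ok$ci_high == 1))
})

test_that("levels are judged independently", {
  truth <- tibble::tibble(specimen_id = "q1", genus = "Aus",
                          species = "Aus bus")
  res <- tibble::tibble(
    query_id = "q1",
    level = c("species", "genus"),
    winners = list("Aus cus", "Aus"),  # wrong species, right genus
    top_score = 5L, n_windows = 10L,
    ambiguous = FALSE, unidentified = FALSE
  )
  sp <- score_side(res, truth, "species")
  gn <- score_side(res, truth, "genus")
  expect_equal(sp$sensitivity[sp$class == "overall"], 0)
  expect_equal(gn$sensitivity[gn$class == "overall"], 1)
})

test_that("severity scoring is monotone in per-query correctness", {
  withr::with_seed(66, {
    truth <- tibble::tibble(
      specimen_id = paste0("q", 1:12),
      genus = rep(c("Aus", "Bus", "Cus"), each = 4),
      species = rep(c("Aus a", "Aus b", "Bus a", "Bus b", "Cus a", "Cus b"),
                    each = 2)
    )
    base_correct <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    mk_res <- function(correct) {
      tibble::tibble(
        query_id = truth$specimen_id,
        level = "species",
        winners = lapply(seq_along(correct), function(i)
          if (correct[i]) truth$species[i] else "Zus zus"),
        top_score = 1L, n_windows = 2L,
        ambiguous = FALSE, unidentified = FALSE
      )
    }
    ev0 <- score_side(mk_res(base_correct), truth, "species")
    for (i in which(!base_correct)) {
      flipped <- base_correct
      flipped[i] <- TRUE
      ev1 <- score_side(mk_res(flipped), truth, "species")
      expect_gte(ev1$sensitivity[ev1$class == "overall"],
                 ev0$sensitivity[ev0$class == "overall"])
    }
  })
})

test_that("ratings matrices line engines up for agreement analysis", {
  truth <- tibble::tibble(
    specimen_id = paste0("q", 1:4), genus = "Aus",
    species = paste("Aus", c("a", "b", "c", "d"))
  )
  mk_res <- function(correct) {
    tibble::tibble(
      query_id = truth$specimen_id, level = "species",
      winners = lapply(seq_along(correct), function(i)
        if (correct[i]) truth$species[i] else "Zus z"),
      top_score = 1L, n_windows = 2L,
      ambiguous = FALSE, unidentified = FALSE
    )
  }
  ev_a <- score_side(mk_res(c(TRUE, TRUE, FALSE, FALSE)), truth, "species")
  ev_b <- score_side(mk_res(c(TRUE, FALSE, TRUE, FALSE)), truth, "species")
  m <- ratings_matrix(a = ev_a, b = ev_b)
  expect_equal(dim(m), c(4L, 2L))
  expect_true(all(rowSums(m) == 2L))
  # both engines agree on items 1 (both correct) and 4 (both incorrect)
  expect_equal(sort(m[, "correct"]), c(0L, 1L, 1L, 2L))
  expect_error(ratings_matrix(a = ev_a), class = "bronx_param_error")
})
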