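test_that("Matthews correlation has the textbook fixed points", {
  expect_equal(mcc(confusion_matrix(1, 0, 1, 0)), 1)
  expect_equal(mcc(confusion_matrix(0, 1, 0, 1)), -1)
  expect_equal(mcc(confusion_matrix(0, 0, 5, 0)), 0)  # degenerate -> 0
  expect_equal(mcc(confusion_matrix(0, 0, 0, 0)), 0)
  m <- rates(confusion_matrix(0, 0, 0, 0))
  expect_equal(c(m$tpr, m$tnr, m$mcc), c(0, 0, 0))
})

test_that("mcc agrees with the brute-force binary-vector correlation", {
  set.seed(42)
  for (i in 1:300) {
    cm <- confusion_matrix(sample(0:40, 1), sample(0:40, 1),
                           sample(0:40, 1), sample(0:40, 1))
    ours <- mcc(cm)
    oracle <- mcc_bruteforce(cm)
    if (!is.na(oracle)) expect_equal(ours, oracle, tolerance = 1e-12)
    expect_gte(ours, -1)
    expect_lte(ours, 1)
    # symmetry under swapping the positive/negative labelling
    swapped <- confusion_matrix(cm$tn, cm$fn, cm$tp, cm$fp)
    expect_equal(mcc(swapped), ours, tolerance = 1e-12)
  }
})

test_that("rates computes TPR and TNR from the count definitions", {
  m <- rates(confusion_matrix(tp = 9, fp = 1, tn = 80, fn = 3))
  expect_equal(m$tpr, 9 / 12)
  expect_equal(m$tnr, 80 / 81)
  expect_equal(m$mcc, mcc(confusion_matrix(9, 1, 80, 3)))
})

test_that("scoring against gold distinguishes TP, FP, FN and keyless exclusions", {
  preds <- tibble::tibble(
    record_id = rep(c("g1", "g2", "g3", "g4", "g5"), each = 4),
    trait = rep(c("length", "mass", "sex", "life stage"), 5),
    present = FALSE, value = NA_character_
  )
  set <- function(preds, id, trait, value) {
    i <- preds$record_id == id & preds$trait == trait
    preds$present[i] <- TRUE
    preds$value[i] <- value
    preds
  }
  preds <- set(preds, "g1", "mass", "71.9")   # TP (value match)
  preds <- set(preds, "g2", "mass", "70")     # FP (value mismatch)
  preds <- set(preds, "g3", "sex", "male")    # FP (gold absent)
  # g4: FN (gold has mass, nothing predicted)
  # g5: keyless life stage in gold, not predicted -> excluded, not FN
  gold <- tibble::tibble(
    record_id = c("g1", "g2", "g4", "g5"),
    trait = c("mass", "mass", "mass", "life stage"),
    present = TRUE,
    value = c("71.9", "71.9", "5", "adult"),
    units = c("g", "g", "g", NA),
    keyless_implied = c(FALSE, FALSE, FALSE, TRUE)
  )
  cm <- score_against_gold(preds, gold, "mass")
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(1, 1, 2, 1))

  cm_stage <- score_against_gold(preds, gold, "life stage")
  expect_equal(attr(cm_stage, "keyless_excluded"), 1)
  expect_equal(cm_stage$fn, 0)
  expect_equal(cm_stage$tn, 4)

  cm_sex <- score_against_gold(preds, gold, "sex")
  expect_equal(cm_sex$fp, 1)

  # gold value in other units is harmonized before comparison
  gold_kg <- tibble::tibble(record_id = "g1", trait = "mass", present = TRUE,
                            value = "0.0719", units = "kg",
                            keyless_implied = FALSE)
  expect_equal(score_against_gold(preds, gold_kg, "mass")$tp, 1)

  bad_gold <- tibble::tibble(record_id = "nope", trait = "mass",
                             present = TRUE, value = "1", units = "g",
                             keyless_implied = FALSE)
  expect_error(score_against_gold(preds, bad_gold, "mass"), "absent")
})

test_that("gold label files round-trip through the CSV layer", {
  gold <- generate_corpus(50, style_mix(), seed = 8)$gold
  f <- tempfile(fileext = ".csv")
  write_gold(gold, f)
  back <- read_gold(f)
  expect_equal(back$record_id, gold$record_id)
  expect_equal(back$trait, gold$trait)
  expect_equal(back$present, gold$present)
  expect_equal(back$value, as.character(gold$value))
  expect_equal(back$units, gold$units)
  expect_equal(back$keyless_implied, gold$keyless_implied)
})

test_that("validation sampling is a seeded random-key sort", {
  recs <- ten_record_fixture()
  s1 <- sample_validation_set(recs, 4, seed = 7)
  s2 <- sample_validation_set(recs, 4, seed = 7)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 4)
  # n = N returns a permutation of everything
  all_rows <- sample_validation_set(recs, 10, seed = 1)
  expect_setequal(all_rows$record_id, recs$record_id)
  expect_error(sample_validation_set(recs, 11, seed = 1), "cannot sample")
  # different seeds give different draws (with overwhelming probability)
  s3 <- sample_validation_set(recs, 4, seed = 8)
  expect_false(identical(s1$record_id, s3$record_id))
})
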