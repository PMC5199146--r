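test_that("length conversions use exact factors and flag inferred units", {
  expect_equal(convert_length(10, "in"), tibble::tibble(mm = 254, inferred = FALSE))
  expect_equal(convert_length(235, "inferred")$mm, 235)
  expect_true(convert_length(235, "inferred")$inferred)
  expect_equal(convert_length(2, "ft")$mm, 609.6)
  expect_equal(convert_length(12.3, "cm")$mm, 123)
  # over-precise inputs are truncated, not rounded
  expect_equal(convert_length(44.123456, "mm")$mm, 44.12)
  expect_equal(convert_length(44.999, "mm")$mm, 44.99)
})

test_that("mass conversions cover metric, Imperial and the compound form", {
  expect_equal(convert_mass(20, "kg")$g, 20000)
  expect_false(convert_mass(20, "kg")$inferred)
  expect_equal(convert_mass(71.9, "inferred")$g, 71.9)
  expect_true(convert_mass(71.9, "inferred")$inferred)
  expect_equal(convert_mass(1, "lb")$g, 453.59)
  expect_equal(convert_mass(1, "oz")$g, 28.34)
  # 2 lb 3 oz = 907.18474 + 85.048569375, truncated
  expect_equal(convert_mass(2, "lb+oz", value2 = 3)$g, 992.23)
})

test_that("non-positive values and unknown units are rejected, not converted", {
  expect_true(is.na(suppressMessages(convert_length(-5, "mm"))$mm))
  expect_true(is.na(suppressMessages(convert_length(0, "mm"))$mm))
  expect_true(is.na(suppressMessages(convert_length(10, "furlong"))$mm))
  expect_true(is.na(suppressMessages(convert_mass(10, "stone"))$g))
  # a rejected conversion drops the trait from the harmonized record
  recs <- occurrence_records("z1", dynamic_properties = "total length: 0 mm")
  h <- suppressMessages(harmonize_traits(recs, extract_traits(recs)))
  expect_false(h$hasLength)
})

test_that("unit conversions compose: metres agree with centimetres x100", {
  set.seed(5)
  x <- exp(runif(30, log(0.01), log(10)))
  expect_equal(convert_length(x, rep("m", 30))$mm,
               convert_length(100 * x, rep("cm", 30))$mm)
})

test_that("derived sex and life stage prefer the Darwin Core field", {
  recs <- occurrence_records(
    c("h1", "h2", "h3"),
    sex_field = c("Female", "", ""),
    life_stage_field = c("", "Adult", ""),
    dynamic_properties = c("sex: male", "sex: male; age: juvenile",
                           "no trait text here")
  )
  h <- harmonize_traits(recs, extract_traits(recs))
  expect_equal(h$derivedSex, c("Female", "male", ""))
  expect_equal(h$derivedLifeStage, c("", "Adult", ""))
  expect_equal(h$hasSex, c(TRUE, TRUE, FALSE))
  expect_equal(h$hasLifeStage, c(FALSE, TRUE, FALSE))
})

test_that("range extractions set hasLength with a range lengthType and no value", {
  recs <- occurrence_records("r1",
    dynamic_properties = "standard length: 20-35 mm")
  h <- harmonize_traits(recs, extract_traits(recs))
  expect_true(h$hasLength)
  expect_equal(h$lengthType, "standard length range")
  expect_true(is.na(h$lengthInMM))
  expect_false(h$wereLengthUnitsInferred)
})

test_that("harmonized invariants hold across a mixed synthetic corpus", {
  corpus <- generate_corpus(400, style_mix(), seed = 21)
  recs <- filter_candidates(corpus$records)
  h <- harmonize_traits(recs, extract_traits(recs))
  expect_true(all(h$hasLength[!is.na(h$lengthInMM)]))
  expect_true(all(h$hasMass[!is.na(h$massInG)]))
  expect_true(all(h$hasSex[nzchar(h$derivedSex)]))
  expect_true(all(h$hasLifeStage[nzchar(h$derivedLifeStage)]))
  is_rng <- !is.na(h$lengthType) & grepl(" range$", h$lengthType)
  expect_true(all(is.na(h$lengthInMM[is_rng])))
  expect_true(all(h$hasLength[is_rng]))
  expect_true(all(h$lengthInMM >= 0, na.rm = TRUE))
  expect_true(all(h$massInG >= 0, na.rm = TRUE))
})

test_that("harmonization is idempotent through its serialized output", {
  corpus <- generate_corpus(80, clean_mix(), seed = 31)
  recs <- filter_candidates(corpus$records)
  h <- harmonize_traits(recs, extract_traits(recs))
  f <- tempfile(fileext = ".csv")
  write_harmonized(recs, h, f)
  back <- read_harmonized(f)
  h2 <- harmonize_traits(back$records, extract_traits(back$records))
  expect_equal(h2, h)
})
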