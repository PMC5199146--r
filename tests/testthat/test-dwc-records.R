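test_that("CSV/TSV readers map Darwin Core headers and keep passthrough columns", {
  path <- write_fixture_csv(c(
    "occurrenceID,dynamicProperties,catalogNumber",
    "a1,\"total length: 10 mm\",CN-1",
    "a2,,CN-2"
  ))
  recs <- read_occurrences(path)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$record_id, c("a1", "a2"))
  expect_equal(recs$dynamic_properties[1], "total length: 10 mm")
  expect_equal(recs$catalogNumber, c("CN-1", "CN-2"))

  # header-only file -> zero records, not an error
  empty <- read_occurrences(write_fixture_csv("occurrenceID,sex"))
  expect_equal(nrow(empty), 0)

  tsv <- write_fixture_csv(c("occurrenceID\tfieldNotes", "t1\twt 5 g"),
                           ext = "tsv")
  expect_equal(read_occurrences(tsv)$field_notes, "wt 5 g")
})

test_that("header matching is case-insensitive and prefix-tolerant", {
  path <- write_fixture_csv(c(
    "dwc:OccurrenceID,DYNAMICPROPERTIES,ScientificName",
    "x1,sex=male,Tamias minimus"
  ))
  recs <- read_occurrences(path)
  expect_equal(recs$record_id, "x1")
  expect_equal(recs$dynamic_properties, "sex=male")
  expect_equal(recs$scientific_name, "Tamias minimus")
})

test_that("files without any Darwin Core term are rejected by name", {
  path <- write_fixture_csv(c("foo,bar", "1,2"))
  expect_error(read_occurrences(path), "Darwin Core")
  expect_error(read_occurrences(tempfile()), "cannot read")
})

test_that("filter_candidates keeps exactly the records with free-text content", {
  recs <- ten_record_fixture()
  kept <- filter_candidates(recs)
  # hand enumeration: r01 (dynamicProperties), r06, r08 (fieldNotes), r09
  expect_equal(kept$record_id, c("r01", "r06", "r08", "r09"))
  # NULL/NA/whitespace sentinels count as empty
  expect_false("r03" %in% kept$record_id)
  expect_false("r04" %in% kept$record_id)
  expect_false("r05" %in% kept$record_id)
})

test_that("filter_candidates is idempotent and never grows the set", {
  for (seed in 1:3) {
    corpus <- generate_corpus(60, style_mix(), seed = seed)
    once <- filter_candidates(corpus$records)
    twice <- filter_candidates(once)
    expect_identical(once, twice)
    expect_lte(nrow(once), nrow(corpus$records))
  }
})

test_that("harmonized CSV write -> read -> write is the identity", {
  recs <- occurrence_records(
    record_id = c("w1", "w2"),
    sex_field = c("Female", ""),
    dynamic_properties = c("total length: 235 mm; weight: 20 kg",
                           "standard length: 20-35 mm")
  )
  traits <- harmonize_traits(recs, extract_traits(recs))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_harmonized(recs, traits, f1)
  back <- read_harmonized(f1)
  write_harmonized(back$records, back$traits, f2)
  expect_identical(readLines(f1), readLines(f2))

  # field values survive the round trip
  expect_equal(back$records$dynamic_properties, recs$dynamic_properties)
  expect_equal(back$traits$lengthInMM, traits$lengthInMM)

  # a 235 mm total length serializes as the bare cell "235"
  tab <- readr::read_csv(f1, show_col_types = FALSE)
  expect_equal(as.character(tab$lengthInMM[1]), "235")
  expect_equal(tab$hasLength, c(TRUE, TRUE))
})

test_that("records with no traits serialize as all-false flags and empty numerics", {
  recs <- occurrence_records("n1", occurrence_remarks = "seen at dusk")
  traits <- harmonize_traits(recs, extract_traits(recs))
  f <- tempfile(fileext = ".csv")
  write_harmonized(recs, traits, f)
  row <- readr::read_csv(f, col_types = readr::cols(.default = "c"),
                         na = character())
  expect_equal(row$hasLength, "false")
  expect_equal(row$hasMass, "false")
  expect_equal(row$lengthInMM, "")
  expect_equal(row$massInG, "")
})

test_that("Darwin Core Archive occurrence cores are read, extensions ignored", {
  recs <- read_occurrences(dwca_fixture_dir(), dialect = "dwca-core")
  expect_equal(recs$record_id, c("occ-1", "occ-2"))
  expect_equal(recs$taxon_class, c("Mammalia", "Aves"))
  expect_equal(recs$dynamic_properties[1], "total length: 120 mm")

  expect_warning(
    read_occurrences(dwca_fixture_dir(with_extension = TRUE),
                     dialect = "dwca-core"),
    "extensions"
  )
})
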