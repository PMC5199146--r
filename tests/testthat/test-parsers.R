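test_that("length parsing follows the precedence table", {
  cases <- list(
    list(text = "total length: 230 mm", type = "total length",
         value = "230", units = "mm", tier = 1),
    list(text = "total length 230", type = "total length",
         value = "230", units = "inferred", tier = 2),
    list(text = "SVL 44", type = "snout-vent length",
         value = "44", units = "inferred", tier = 3),
    list(text = "ToL=235mm", type = "total length",
         value = "235", units = "mm", tier = 3),
    list(text = "totalLengthInMM=182;", type = "total length",
         value = "182", units = "inferred", tier = 2),
    list(text = "fork length: 88 cm", type = "fork length",
         value = "88", units = "cm", tier = 1),
    list(text = "head-body length: 91", type = "head-body length",
         value = "91", units = "inferred", tier = 2),
    list(text = "length: 102 mm", type = "total length",
         value = "102", units = "mm", tier = 1),
    list(text = "Length 3 in", type = "total length",
         value = "3", units = "in", tier = 1)
  )
  for (cs in cases) {
    got <- parse_length(cs$text)
    expect_equal(nrow(got), 1, info = cs$text)
    expect_equal(got$trait_type, cs$type, info = cs$text)
    expect_equal(got$value, cs$value, info = cs$text)
    expect_equal(got$units, cs$units, info = cs$text)
    expect_equal(got$tier, cs$tier, info = cs$text)
  }
  expect_equal(nrow(parse_length("")), 0)
  # a specific key never also fires the generic bare-"length" synonym,
  # and unrelated measurements never map to a body-length subtype
  expect_equal(nrow(parse_length("standard length: 20 mm")), 1)
  expect_equal(nrow(parse_length("tail length: 30 mm")), 0)
  expect_equal(nrow(parse_length("wing length: 55 mm")), 0)
})

test_that("length ranges are captured with both endpoints", {
  got <- parse_length("standard length: 20-35 mm")
  expect_equal(got$trait_type, "standard length")
  expect_true(got$is_range)
  expect_equal(c(got$value, got$value2), c("20", "35"))
  expect_equal(got$units, "mm")

  endash <- parse_length("total length: 20–35")
  expect_true(endash$is_range)
  expect_equal(endash$units, "inferred")
})

test_that("mass parsing requires a key and recognizes the unit family", {
  cases <- list(
    list(text = "weight=71.9 g", value = "71.9", units = "g"),
    list(text = "body mass: 20 kg", value = "20", units = "kg"),
    list(text = "wt 12.5", value = "12.5", units = "inferred"),
    list(text = "weight: 2 lbs", value = "2", units = "lb"),
    list(text = "weight: 3.5 oz", value = "3.5", units = "oz"),
    list(text = "weight: 71,9 g", value = "71.9", units = "g"),
    list(text = "weight: 1,250 g", value = "1250", units = "g")
  )
  for (cs in cases) {
    got <- parse_mass(cs$text)
    expect_equal(nrow(got), 1, info = cs$text)
    expect_equal(got$value, cs$value, info = cs$text)
    expect_equal(got$units, cs$units, info = cs$text)
  }
  comp <- parse_mass("weight: 2 lbs 3 oz")
  expect_equal(comp$units, "lb+oz")
  expect_equal(c(comp$value, comp$value2), c("2", "3"))

  expect_equal(nrow(parse_mass("mass not recorded")), 0)
  expect_equal(nrow(parse_mass("")), 0)
  # key-less numbers are never mass; keyed mass ranges denote lots
  expect_equal(nrow(parse_mass("measured 71.9 g of bait")), 0)
  expect_equal(nrow(parse_mass("weight: 20-30 g")), 0)
})

test_that("mammal shorthand yields total length and mass, middle values discarded", {
  got <- parse_shorthand("235-97-31-25 = 71.9")
  expect_equal(got$trait_type, c("total length", "body mass"))
  expect_equal(got$value, c("235", "71.9"))
  expect_equal(got$units, c("inferred", "inferred"))
  expect_false(any(got$is_range))

  # explicit gram token on the mass part
  g <- parse_shorthand("152-63-20-15=9.8g")
  expect_equal(g$units, c("inferred", "g"))

  # three-number form without mass still gives the total length
  expect_equal(parse_shorthand("235-97-31")$value, "235")

  # date-like tokens are rejected
  expect_equal(nrow(parse_shorthand("12-05-2003")), 0)
  expect_equal(nrow(parse_shorthand("2-3-1999")), 0)
  expect_equal(nrow(parse_shorthand("")), 0)
})

test_that("sex extraction is keyed or unambiguous, never multi-individual", {
  expect_equal(parse_sex("sex=male;")$value, "male")
  expect_equal(parse_sex("sex: F")$value, "female")
  expect_equal(parse_sex("adult female, worn plumage")$value, "female")
  expect_equal(nrow(parse_sex("males and females in lot")), 0)
  expect_equal(nrow(parse_sex("one male and two female in lot")), 0)
  # single letters only count when keyed
  expect_equal(nrow(parse_sex("f wing 55mm")), 0)
  expect_equal(nrow(parse_sex("")), 0)
})

test_that("life stage requires a key by default; aggressive mode flags bare words", {
  expect_equal(parse_lifestage("age class: adult")$value, "adult")
  expect_equal(parse_lifestage("lifestage=juvenile")$value, "juvenile")
  expect_equal(parse_lifestage("age: 2 years")$value, "2 years")
  expect_equal(nrow(parse_lifestage("adult")), 0)

  agg <- parse_lifestage("adult", aggressive = TRUE)
  expect_equal(agg$value, "adult")
  expect_true(agg$flagged)
  expect_false(parse_lifestage("age: adult", aggressive = TRUE)$flagged)
})

test_that("extract_record applies field priority per trait type", {
  rec <- occurrence_records(
    "p1",
    dynamic_properties = "total length: 100 mm",
    field_notes = "total length: 200 mm"
  )
  got <- extract_record(rec)
  expect_equal(nrow(got), 1)
  expect_equal(got$value, "100")
  expect_equal(got$source_field, "dynamicProperties")

  # a later field still contributes traits the earlier fields lack
  rec2 <- occurrence_records(
    "p2",
    dynamic_properties = "sex: male",
    field_notes = "235-97-31-25 = 71.9"
  )
  got2 <- extract_record(rec2)
  expect_setequal(got2$trait_type, c("sex", "total length", "body mass"))
  expect_equal(
    got2$source_field[got2$trait_type == "body mass"], "fieldNotes")

  expect_equal(nrow(extract_record(occurrence_records("p3"))), 0)
})

test_that("parsing is deterministic and stable under appended text", {
  texts <- c("total length: 230 mm; weight: 5 g", "SVL 44; sex=f",
             "235-97-31-25 = 71.9", "standard length: 20-35 mm")
  for (tx in texts) {
    a <- parse_length(tx); b <- parse_length(tx)
    expect_identical(a, b)
    # appending content after the match never changes the captured value
    suffixed <- parse_length(paste0(tx, "; collector notes follow"))
    if (nrow(a)) expect_equal(suffixed$value[1], a$value[1])
  }
})

test_that("every extraction reports a substring actually present at its span", {
  corpus <- generate_corpus(150, clean_mix(), seed = 99)
  ex <- extract_traits(corpus$records)
  expect_gt(nrow(ex), 0)
  cols <- c(dynamicProperties = "dynamic_properties",
            occurrenceRemarks = "occurrence_remarks",
            fieldNotes = "field_notes")
  for (i in seq_len(nrow(ex))) {
    field <- corpus$records[[cols[[ex$source_field[i]]]]][
      match(ex$record_id[i], corpus$records$record_id)]
    expect_identical(substr(field, ex$start[i], ex$end[i]),
                     ex$verbatim_match[i])
    expect_lte(ex$end[i], nchar(field))
  }
  # ranges only ever occur for length subtypes
  rng <- ex[ex$is_range, , drop = FALSE]
  expect_true(all(rng$trait_type %in% c(
    "total length", "head-body length", "snout-vent length",
    "standard length", "fork length")))
})
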