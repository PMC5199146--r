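# Rule-based extraction engine.
#
# Patterns are matched in a strict precedence order, reflecting how trait
# content is written on specimen labels:
#   tier 1  explicit key with units        "total length: 230 mm"
#   tier 2  explicit key, units optional   "total length 230"
#   tier 3  abbreviation + adjacent value  "TL 230", "SVL=44"
#   tier 4  positional mammal shorthand    "235-97-31-25 = 71.9"
# Earlier tiers mask overlapping later matches within the same trait class;
# for ties the longer (more specific) match wins, so "standard length: 20"
# is never also read as a bare "length" hit.

DWC_FIELD_NAMES <- c(
  dynamic_properties = "dynamicProperties",
  occurrence_remarks = "occurrenceRemarks",
  field_notes = "fieldNotes"
)

# numeric token: plain, thousands-grouped ("1,250"), or decimal-comma ("71,9")
NUM_RE <- paste0(
  "((?:[0-9]{1,3}(?:,[0-9]{3})+|[0-9]+)(?:\\.[0-9]+)?",
  "|[0-9]+,[0-9]{1,2}(?![0-9]))"
)
RANGE_RE <- paste0(
  "(?:\\s*(?:–|—|-|\\bto\\b)\\s*", NUM_RE,
  "(?![0-9.–—-]))?"
)
LEN_UNIT_RE <- paste0(
  "(millimeters?|millimetres?|centimeters?|centimetres?|meters?|metres?",
  "|inches|inch|feet|foot|mm|cm|ft|in|m)"
)
MASS_UNIT_RE <- "(kilograms?|kgs?|grams?|gms?|pounds?|lbs?|ounces?|oz|g)"
SEP_EXPLICIT <- "\\s*[:=]?\\s*"
SEP_ABBREV <- "[.:=]?\\s{0,3}"   # abbreviations need the value close by

unit_group <- function(unit_re, required = FALSE) {
  g <- paste0("\\s*", unit_re, "\\.?(?![A-Za-z])")
  if (required) g else paste0("(?:", g, ")?")
}

# Turn one lexicon synonym into a key regex. Word separators in the synonym
# (space, hyphen, underscore) match any run of separators, so "snout-vent
# length" also hits "snout vent length" and "snoutventlength". `guarded`
# keys additionally refuse to match right after another word ("tail length"
# must not fire the bare "length" key).
key_regex <- function(synonym, guarded = FALSE) {
  tokens <- strsplit(synonym, "[ _-]+")[[1]]
  esc <- vapply(tokens, function(tk) {
    gsub("([^A-Za-z0-9])", "\\\\\\1", tk)
  }, "")
  body <- paste(esc, collapse = "[\\s_.-]*")
  guard <- if (guarded) {
    "(?<![A-Za-z][\\s_.-])(?<![A-Za-z0-9])"
  } else {
    "(?<![A-Za-z0-9])"
  }
  paste0(guard, "(?:", body, ")(?![A-Za-z])")
}

key_alternation <- function(lex_rows) {
  pats <- mapply(key_regex, lex_rows$synonym, lex_rows$guarded,
                 USE.NAMES = FALSE)
  paste0("(?:", paste(pats, collapse = "|"), ")")
}

# Pattern table for the measurement traits, derived from a lexicon.
build_patterns <- function(lexicon = default_lexicon()) {
  row_for <- function(trait_type, tier, pattern, kind = "value") {
    tibble::tibble(trait_type = trait_type, tier = tier,
                   pattern = pattern, kind = kind)
  }
  out <- list()
  for (sub in LENGTH_SUBTYPES) {
    expl <- lexicon[lexicon$canonical == sub &
                    lexicon$match_kind == "explicit_key", , drop = FALSE]
    abbr <- lexicon[lexicon$canonical == sub &
                    lexicon$match_kind == "abbreviation", , drop = FALSE]
    if (nrow(expl)) {
      keys <- key_alternation(expl)
      out[[length(out) + 1L]] <- row_for(sub, 1L, paste0(
        keys, SEP_EXPLICIT, NUM_RE, RANGE_RE, unit_group(LEN_UNIT_RE, TRUE)))
      out[[length(out) + 1L]] <- row_for(sub, 2L, paste0(
        keys, SEP_EXPLICIT, NUM_RE, RANGE_RE, unit_group(LEN_UNIT_RE)))
    }
    if (nrow(abbr)) {
      out[[length(out) + 1L]] <- row_for(sub, 3L, paste0(
        key_alternation(abbr), SEP_ABBREV, NUM_RE, RANGE_RE,
        unit_group(LEN_UNIT_RE)))
    }
  }
  mass <- lexicon[lexicon$trait_class == "body_mass", , drop = FALSE]
  m_expl <- mass[mass$match_kind == "explicit_key", , drop = FALSE]
  m_abbr <- mass[mass$match_kind == "abbreviation", , drop = FALSE]
  mout <- list()
  if (nrow(m_expl)) {
    mkeys <- key_alternation(m_expl)
    mout[[length(mout) + 1L]] <- row_for("body mass", 1L, paste0(
      mkeys, SEP_EXPLICIT, NUM_RE, "\\s*(?:pounds?|lbs?)\\.?\\s*(?:and\\s*)?",
      NUM_RE, "\\s*(?:ounces?|oz)\\.?(?![A-Za-z])"), kind = "compound")
    mout[[length(mout) + 1L]] <- row_for("body mass", 1L, paste0(
      mkeys, SEP_EXPLICIT, NUM_RE, RANGE_RE, unit_group(MASS_UNIT_RE, TRUE)))
    mout[[length(mout) + 1L]] <- row_for("body mass", 2L, paste0(
      mkeys, SEP_EXPLICIT, NUM_RE, RANGE_RE, unit_group(MASS_UNIT_RE)))
  }
  if (nrow(m_abbr)) {
    mout[[length(mout) + 1L]] <- row_for("body mass", 3L, paste0(
      key_alternation(m_abbr), SEP_ABBREV, NUM_RE, RANGE_RE,
      unit_group(MASS_UNIT_RE)))
  }
  list(length = dplyr::bind_rows(out), mass = dplyr::bind_rows(mout))
}

# Normalize a captured numeric token to a decimal-point string.
normalize_number <- function(x) {
  thousands <- grepl("^[0-9]{1,3}(,[0-9]{3})+(\\.[0-9]+)?$", x)
  x[thousands] <- gsub(",", "", x[thousands], fixed = TRUE)
  sub(",", ".", x, fixed = TRUE)
}

canonical_length_unit <- function(token) {
  token <- sub("\\.$", "", tolower(token))
  map <- c(mm = "mm", millimeter = "mm", millimeters = "mm",
           millimetre = "mm", millimetres = "mm",
           cm = "cm", centimeter = "cm", centimeters = "cm",
           centimetre = "cm", centimetres = "cm",
           m = "m", meter = "m", meters = "m", metre = "m", metres = "m",
           "in" = "in", inch = "in", inches = "in",
           ft = "ft", foot = "ft", feet = "ft")
  out <- unname(map[token])
  out[is.na(token) | !nzchar(token)] <- "inferred"
  out
}

canonical_mass_unit <- function(token) {
  token <- sub("\\.$", "", tolower(token))
  map <- c(g = "g", gm = "g", gms = "g", gram = "g", grams = "g",
           kg = "kg", kgs = "kg", kilogram = "kg", kilograms = "kg",
           lb = "lb", lbs = "lb", pound = "lb", pounds = "lb",
           oz = "oz", ounce = "oz", ounces = "oz")
  out <- unname(map[token])
  out[is.na(token) | !nzchar(token)] <- "inferred"
  out
}

empty_extractions <- function() {
  tibble::tibble(
    source_field = character(), trait_type = character(),
    verbatim_match = character(), value = character(),
    value2 = character(), units = character(),
    start = integer(), end = integer(), is_range = logical(),
    tier = integer(), flagged = logical()
  )
}

# First match of one pattern over a text vector -> candidate rows.
match_one <- function(texts, row) {
  re <- stringr::regex(row$pattern, ignore_case = TRUE)
  loc <- stringr::str_locate(texts, re)
  hit <- which(!is.na(loc[, 1]))
  if (!length(hit)) return(NULL)
  m <- stringr::str_match(texts[hit], re)
  tibble::tibble(
    idx = hit, trait_type = row$trait_type, tier = row$tier,
    kind = row$kind, start = loc[hit, 1], end = loc[hit, 2],
    verbatim_match = m[, 1], value = m[, 2],
    value2 = if (ncol(m) >= 3) m[, 3] else NA_character_,
    units_token = if (ncol(m) >= 4) m[, 4] else NA_character_
  )
}

gather_candidates <- function(texts, pattern_tbl) {
  rows <- lapply(seq_len(nrow(pattern_tbl)), function(i) {
    match_one(texts, pattern_tbl[i, , drop = FALSE])
  })
  dplyr::bind_rows(rows)
}

# Precedence resolution within one trait class: keep the best candidate per
# (text, subtype), then mask overlaps across subtypes (lower tier first,
# longer match first).
resolve_candidates <- function(cands) {
  if (is.null(cands) || !nrow(cands)) return(cands)
  cands$span <- cands$end - cands$start
  cands <- dplyr::arrange(cands, .data$idx, .data$trait_type, .data$tier,
                          .data$start, dplyr::desc(.data$span))
  cands <- dplyr::distinct(cands, .data$idx, .data$trait_type,
                           .keep_all = TRUE)
  multi <- unique(cands$idx[duplicated(cands$idx)])
  if (length(multi)) {
    drop <- logical(nrow(cands))
    for (i in multi) {
      rows <- which(cands$idx == i)
      ord <- rows[order(cands$tier[rows], -cands$span[rows],
                        cands$start[rows])]
      kept_s <- integer(0); kept_e <- integer(0)
      for (r in ord) {
        if (any(cands$start[r] <= kept_e & cands$end[r] >= kept_s)) {
          drop[r] <- TRUE
        } else {
          kept_s <- c(kept_s, cands$start[r])
          kept_e <- c(kept_e, cands$end[r])
        }
      }
    }
    cands <- cands[!drop, , drop = FALSE]
  }
  cands
}

SHORTHAND_RE <- paste0(
  "(?<![0-9A-Za-z=./–—-])",
  "([0-9]+(?:\\.[0-9]+)?)\\s*-\\s*([0-9]+(?:\\.[0-9]+)?)",
  "\\s*-\\s*([0-9]+(?:\\.[0-9]+)?)",
  "(?:\\s*-\\s*([0-9]+(?:\\.[0-9]+)?))?",
  "(?:\\s*-\\s*([0-9]+(?:\\.[0-9]+)?))?",
  "(?:\\s*=\\s*([0-9]+(?:\\.[0-9]+)?)\\s*(grams?|gms?|g)?(?![A-Za-z]))?",
  "(?![0-9=./-])"
)

shorthand_candidates <- function(texts) {
  re <- stringr::regex(SHORTHAND_RE, ignore_case = TRUE)
  loc <- stringr::str_locate(texts, re)
  hit <- which(!is.na(loc[, 1]))
  if (!length(hit)) return(NULL)
  m <- stringr::str_match(texts[hit], re)
  nums <- matrix(suppressWarnings(as.numeric(m[, 2:6])), ncol = 5)
  n_nums <- rowSums(!is.na(nums))
  mass_val <- m[, 7]
  mass_unit <- m[, 8]
  # date guard: a bare triple like "12-05-2003" (or all components <= 31)
  # is calendar shorthand, not a measurement series
  datelike <- n_nums == 3 & is.na(mass_val) &
    ((!is.na(nums[, 3]) & nums[, 3] >= 1000 & nums[, 3] < 3000) |
       (nums[, 1] <= 31 & nums[, 2] <= 31 & nums[, 3] <= 31))
  keep <- which(!datelike)
  if (!length(keep)) return(NULL)
  tibble::tibble(
    idx = hit[keep], start = loc[hit[keep], 1], end = loc[hit[keep], 2],
    verbatim_match = m[keep, 1],
    tl_value = m[keep, 2],
    mass_value = mass_val[keep],
    mass_units = ifelse(is.na(mass_unit[keep]), "inferred", "g")
  )
}

finalize_length <- function(cands, sh) {
  out <- list()
  if (!is.null(cands) && nrow(cands)) {
    out[[1]] <- tibble::tibble(
      idx = cands$idx, trait_type = cands$trait_type,
      verbatim_match = cands$verbatim_match,
      value = normalize_number(cands$value),
      value2 = ifelse(is.na(cands$value2), NA_character_,
                      normalize_number(cands$value2)),
      units = canonical_length_unit(cands$units_token),
      start = cands$start, end = cands$end,
      is_range = !is.na(cands$value2), tier = cands$tier, flagged = FALSE
    )
  }
  if (!is.null(sh) && nrow(sh)) {
    out[[length(out) + 1L]] <- tibble::tibble(
      idx = sh$idx, trait_type = "total length",
      verbatim_match = sh$verbatim_match, value = sh$tl_value,
      value2 = NA_character_, units = "inferred",
      start = sh$start, end = sh$end, is_range = FALSE, tier = 4L,
      flagged = FALSE
    )
  }
  if (!length(out)) return(NULL)
  dplyr::bind_rows(out)
}

finalize_mass <- function(cands, sh) {
  out <- list()
  if (!is.null(cands) && nrow(cands)) {
    compound <- cands$kind == "compound"
    # keyed mass ranges denote multi-specimen lots and are not emitted
    keep <- compound | is.na(cands$value2)
    cands <- cands[keep, , drop = FALSE]
    compound <- compound[keep]
    if (nrow(cands)) {
      out[[1]] <- tibble::tibble(
        idx = cands$idx, trait_type = "body mass",
        verbatim_match = cands$verbatim_match,
        value = normalize_number(cands$value),
        value2 = ifelse(compound, normalize_number(cands$value2),
                        NA_character_),
        units = ifelse(compound, "lb+oz",
                       canonical_mass_unit(cands$units_token)),
        start = cands$start, end = cands$end, is_range = FALSE,
        tier = cands$tier, flagged = FALSE
      )
    }
  }
  if (!is.null(sh) && nrow(sh)) {
    has_mass <- !is.na(sh$mass_value)
    if (any(has_mass)) {
      shm <- sh[has_mass, , drop = FALSE]
      out[[length(out) + 1L]] <- tibble::tibble(
        idx = shm$idx, trait_type = "body mass",
        verbatim_match = shm$verbatim_match, value = shm$mass_value,
        value2 = NA_character_, units = shm$mass_units,
        start = shm$start, end = shm$end, is_range = FALSE, tier = 4L,
        flagged = FALSE
      )
    }
  }
  if (!length(out)) return(NULL)
  dplyr::bind_rows(out)
}

SEX_KEYED_RE <- "(?<![A-Za-z])sex\\s*[:=]?\\s*(males?|females?|m|f)(?![A-Za-z])"
SEX_TOKEN_RE <- "(?<![A-Za-z])(males?|females?)(?![A-Za-z])"
SEX_SINGULAR_RE <- "(?<![A-Za-z])(male|female)(?![A-Za-z])"

normalize_sex <- function(x) {
  x <- tolower(x)
  x[x %in% c("m", "male", "males")] <- "male"
  x[x %in% c("f", "female", "females")] <- "female"
  x
}

sex_extractions <- function(texts) {
  keyed_re <- stringr::regex(SEX_KEYED_RE, ignore_case = TRUE)
  token_re <- stringr::regex(SEX_TOKEN_RE, ignore_case = TRUE)
  sing_re <- stringr::regex(SEX_SINGULAR_RE, ignore_case = TRUE)

  keyed_loc <- stringr::str_locate(texts, keyed_re)
  keyed_hit <- !is.na(keyed_loc[, 1])
  sing_loc <- stringr::str_locate(texts, sing_re)
  sing_hit <- !is.na(sing_loc[, 1])
  scan <- which(keyed_hit | sing_hit)
  if (!length(scan)) return(NULL)

  keyed_val <- rep(NA_character_, length(texts))
  if (any(keyed_hit)) {
    keyed_val[keyed_hit] <-
      stringr::str_match(texts[keyed_hit], keyed_re)[, 2]
  }
  rows <- lapply(scan, function(i) {
    tokens <- normalize_sex(stringr::str_match_all(texts[i], token_re)[[1]][, 2])
    if (!is.na(keyed_val[i])) tokens <- c(tokens, normalize_sex(keyed_val[i]))
    if (length(unique(tokens)) > 1) return(NULL)  # multi-individual remark
    if (!is.na(keyed_val[i])) {
      s <- keyed_loc[i, 1]; e <- keyed_loc[i, 2]
      val <- normalize_sex(keyed_val[i])
    } else {
      s <- sing_loc[i, 1]; e <- sing_loc[i, 2]
      val <- normalize_sex(substr(texts[i], s, e))
    }
    tibble::tibble(idx = i, trait_type = "sex",
                   verbatim_match = substr(texts[i], s, e),
                   value = val, value2 = NA_character_,
                   units = NA_character_, start = s, end = e,
                   is_range = FALSE, tier = 1L, flagged = FALSE)
  })
  dplyr::bind_rows(rows)
}

LIFESTAGE_KEYED_RE <- paste0(
  "(?<![A-Za-z])(?:life\\s*[_-]?\\s*stage|age\\s*[_-]?\\s*class|age)",
  "\\s*[:=]\\s*([^;,.:=]{1,40}?)\\s*(?=[;,.:=\\n\\r]|$)"
)
LIFESTAGE_BARE_RE <- paste0(
  "(?<![A-Za-z])(adults?|juveniles?|subadults?|sub-adults?|immatures?",
  "|hatchlings?|fledglings?|nestlings?|neonates?|yearlings?|larvae?",
  "|larval|tadpoles?|embryos?|fetus(?:es)?)(?![A-Za-z])"
)

lifestage_extractions <- function(texts, aggressive = FALSE) {
  keyed_re <- stringr::regex(LIFESTAGE_KEYED_RE, ignore_case = TRUE)
  loc <- stringr::str_locate(texts, keyed_re)
  hit <- which(!is.na(loc[, 1]))
  out <- list()
  if (length(hit)) {
    m <- stringr::str_match(texts[hit], keyed_re)
    val <- trimws(m[, 2])
    ok <- nzchar(val)
    if (any(ok)) {
      out[[1]] <- tibble::tibble(
        idx = hit[ok], trait_type = "life stage",
        verbatim_match = m[ok, 1], value = val[ok],
        value2 = NA_character_, units = NA_character_,
        start = loc[hit[ok], 1], end = loc[hit[ok], 2],
        is_range = FALSE, tier = 1L, flagged = FALSE
      )
    }
  }
  if (aggressive) {
    rest <- setdiff(seq_along(texts), hit)
    bare_re <- stringr::regex(LIFESTAGE_BARE_RE, ignore_case = TRUE)
    bloc <- stringr::str_locate(texts[rest], bare_re)
    bhit <- which(!is.na(bloc[, 1]))
    if (length(bhit)) {
      bm <- stringr::str_match(texts[rest][bhit], bare_re)
      out[[length(out) + 1L]] <- tibble::tibble(
        idx = rest[bhit], trait_type = "life stage",
        verbatim_match = bm[, 1], value = tolower(bm[, 2]),
        value2 = NA_character_, units = NA_character_,
        start = bloc[bhit, 1], end = bloc[bhit, 2],
        is_range = FALSE, tier = 2L, flagged = TRUE
      )
    }
  }
  if (!length(out)) return(NULL)
  dplyr::bind_rows(out)
}

# Run every parser over a vector of field texts.
parse_field_texts <- function(texts, patterns, aggressive_lifestage = FALSE) {
  sh <- shorthand_candidates(texts)
  len <- resolve_candidates(gather_candidates(texts, patterns$length))
  mass <- resolve_candidates(gather_candidates(texts, patterns$mass))
  res <- dplyr::bind_rows(
    finalize_length(len, sh),
    finalize_mass(mass, sh),
    sex_extractions(texts),
    lifestage_extractions(texts, aggressive_lifestage)
  )
  if (!nrow(res)) return(res)
  dplyr::arrange(res, .data$idx, .data$start)
}

single_text_parse <- function(text, f, ...) {
  stopifnot(length(text) == 1)
  res <- f(as.character(text), ...)
  if (is.null(res) || !nrow(res)) return(empty_extractions())
  res$source_field <- NA_character_
  res[, names(empty_extractions()), drop = FALSE]
}

#' Parse body-length measurements out of one free-text field
#'
#' Finds at most one extraction per length subtype, by precedence: explicit
#' key with units, explicit key without units, abbreviation with an adjacent
#' value, positional shorthand. Values capture decimals and ranges
#' ("20-35 mm"); units are reported verbatim-canonical (`mm`, `cm`, `m`,
#' `in`, `ft`) or `"inferred"` when none were written.
#'
#' @param text A single string (may be empty).
#' @param lexicon A trait lexicon tibble.
#' @return A tibble of raw extractions (possibly empty) with columns
#'   `source_field`, `trait_type`, `verbatim_match`, `value`, `value2`,
#'   `units`, `start`, `end`, `is_range`, `tier`, `flagged`.
#' @export
#' @examples
#' parse_length("total length: 230 mm")
#' parse_length("SVL 44")
parse_length <- function(text, lexicon = default_lexicon()) {
  pats <- build_patterns(lexicon)
  single_text_parse(text, function(t) {
    finalize_length(resolve_candidates(gather_candidates(t, pats$length)),
                    shorthand_candidates(t))
  })
}

#' Parse a body-mass measurement out of one free-text field
#'
#' At most one mass extraction per field. Recognized units: g, gm, grams,
#' kg, lb/lbs, oz, and the compound "X lbs Y oz" (reported as units
#' `"lb+oz"` with the two components in `value`/`value2`). Key-less numbers
#' are never read as mass except through the positional shorthand.
#'
#' @inheritParams parse_length
#' @return A raw-extraction tibble (see [parse_length()]).
#' @export
#' @examples
#' parse_mass("weight=71.9 g")
parse_mass <- function(text, lexicon = default_lexicon()) {
  pats <- build_patterns(lexicon)
  single_text_parse(text, function(t) {
    finalize_mass(resolve_candidates(gather_candidates(t, pats$mass)),
                  shorthand_candidates(t))
  })
}

#' Parse the positional mammalogy shorthand
#'
#' Detects the collector convention of 3-5 dash-separated numbers,
#' optionally followed by `= mass`: "235-97-31-25 = 71.9" records total
#' length 235 (customarily mm), then tail, hind foot and ear lengths, then
#' body mass 71.9 (customarily g). Only the total length and the mass are
#' emitted, both with units `"inferred"` unless a gram token was written;
#' the middle values are matched but discarded. Bare date-like triples
#' ("12-05-2003") are rejected.
#'
#' @param text A single string.
#' @return A raw-extraction tibble with up to one total-length and one
#'   body-mass row.
#' @export
#' @examples
#' parse_shorthand("235-97-31-25 = 71.9")
parse_shorthand <- function(text) {
  single_text_parse(text, function(t) {
    sh <- shorthand_candidates(t)
    dplyr::bind_rows(finalize_length(NULL, sh), finalize_mass(NULL, sh))
  })
}

#' Parse sex out of one free-text field
#'
#' Sex is extracted when keyed ("sex: male", "sex=F") or present as an
#' isolated unambiguous token; single letters only count when keyed. A field
#' mentioning more than one sex (a multi-individual remark) yields nothing,
#' trading false negatives for false-positive control.
#'
#' @param text A single string.
#' @return A raw-extraction tibble with at most one row; `value` is
#'   normalized to `"male"`/`"female"`.
#' @export
#' @examples
#' parse_sex("sex=male;")
#' parse_sex("one male and two female in lot")   # ambiguous: empty
parse_sex <- function(text) {
  single_text_parse(text, sex_extractions)
}

#' Parse life stage out of one free-text field
#'
#' Default behaviour extracts keyed forms only ("life stage: adult",
#' "age class: adult", "age=juvenile"); a bare "adult" with no key is left
#' alone. With `aggressive = TRUE` bare stage words are extracted too and
#' flagged (`flagged = TRUE`).
#'
#' @param text A single string.
#' @param aggressive Also match keyless stage words.
#' @return A raw-extraction tibble with at most one row.
#' @export
#' @examples
#' parse_lifestage("age class: adult")
#' parse_lifestage("adult")                      # default: empty
parse_lifestage <- function(text, aggressive = FALSE) {
  single_text_parse(text, lifestage_extractions, aggressive = aggressive)
}

#' Extract all four traits from a set of occurrence records
#'
#' Runs the length, mass, shorthand, sex and life-stage parsers over
#' `dynamicProperties`, then `occurrenceRemarks`, then `fieldNotes`. For
#' each trait type the first field (in that priority order) yielding a
#' match wins; every retained extraction carries its source field.
#'
#' @param records Occurrence-record tibble.
#' @param lexicon Trait lexicon tibble.
#' @param aggressive_lifestage Extract keyless life-stage words (flagged).
#' @return A tibble of raw extractions with a `record_id` column.
#' @export
extract_traits <- function(records, lexicon = default_lexicon(),
                           aggressive_lifestage = FALSE) {
  patterns <- build_patterns(lexicon)
  per_field <- lapply(seq_along(FREE_TEXT_COLS), function(k) {
    col <- names(DWC_FIELD_NAMES)[k]
    res <- parse_field_texts(records[[col]], patterns, aggressive_lifestage)
    if (!nrow(res)) return(NULL)
    res$source_field <- DWC_FIELD_NAMES[[col]]
    res$field_rank <- k
    res
  })
  all <- dplyr::bind_rows(per_field)
  if (!nrow(all)) {
    out <- empty_extractions()
    out$record_id <- character()
    return(out[, c("record_id", names(empty_extractions()))])
  }
  all <- dplyr::arrange(all, .data$idx, .data$trait_type, .data$field_rank)
  all <- dplyr::distinct(all, .data$idx, .data$trait_type, .keep_all = TRUE)
  all$record_id <- records$record_id[all$idx]
  all <- dplyr::arrange(all, .data$idx, .data$field_rank, .data$start)
  all[, c("record_id", names(empty_extractions()))]
}

#' Extract traits from a single occurrence record
#'
#' @param record A one-row occurrence-record tibble.
#' @inheritParams extract_traits
#' @return A raw-extraction tibble (see [extract_traits()]).
#' @export
extract_record <- function(record, lexicon = default_lexicon(),
                           aggressive_lifestage = FALSE) {
  stopifnot(nrow(record) == 1)
  extract_traits(record, lexicon, aggressive_lifestage)
}
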