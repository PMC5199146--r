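#' Canonical trait vocabulary
#'
#' The five body-length measurement conventions recognized across vertebrate
#' collections, plus the single mass/sex/life-stage types.
#'
#' @format Character vectors of canonical trait type names.
#' @name trait-types
NULL

LENGTH_SUBTYPES <- c(
  "total length", "head-body length", "snout-vent length",
  "standard length", "fork length"
)
TRAIT_TYPES <- c(LENGTH_SUBTYPES, "body mass", "sex", "life stage")
TRAIT_CLASSES <- c("body_length", "body_mass", "sex", "life_stage")

# Ontology identifiers recorded as fixed metadata for the two measured traits.
VTO_IDS <- c(
  `body length` = "http://purl.obolibrary.org/obo/VT_0001256",
  `body mass`   = "http://purl.obolibrary.org/obo/VT_0001259"
)

lex_entry <- function(canonical, trait_class, match_kind, synonyms,
                      guarded = FALSE) {
  tibble::tibble(
    canonical = canonical, trait_class = trait_class,
    match_kind = match_kind, synonym = synonyms, guarded = guarded
  )
}

#' Built-in trait synonym lexicon
#'
#' Canonical trait terms with the verbatim keys and abbreviations under which
#' they appear in digitized specimen records. `explicit_key` synonyms are
#' full words or concatenated field names ("total length", "totallengthinmm");
#' `abbreviation` synonyms are short forms ("TL", "SVL") that only match when
#' immediately followed by a numeric value. Generic synonyms such as bare
#' "length" carry a guard so they do not fire inside more specific keys
#' ("tail length", "standard length").
#'
#' @return A tibble with columns `canonical`, `trait_class`, `match_kind`,
#'   `synonym`, `guarded`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' lex[lex$synonym == "SVL", "canonical"]
default_lexicon <- function() {
  lex <- dplyr::bind_rows(
    lex_entry("total length", "body_length", "explicit_key", c(
      "total length", "totallength", "total length in mm",
      "totallengthinmm", "totallengthinmillimeters", "body length"
    )),
    lex_entry("total length", "body_length", "explicit_key",
              c("length", "lengthinmm", "lengthinmillimeters"),
              guarded = TRUE),
    lex_entry("total length", "body_length", "abbreviation",
              c("TL", "ToL", "t.l.")),
    lex_entry("head-body length", "body_length", "explicit_key", c(
      "head-body length", "headbodylength", "headbodylengthinmm",
      "head and body length", "head-body"
    )),
    lex_entry("head-body length", "body_length", "abbreviation",
              c("HB", "HBL")),
    lex_entry("snout-vent length", "body_length", "explicit_key", c(
      "snout-vent length", "snoutventlength", "snoutventlengthinmm",
      "snout-vent", "snout vent"
    )),
    lex_entry("snout-vent length", "body_length", "abbreviation",
              c("SVL", "s.v.l.")),
    lex_entry("standard length", "body_length", "explicit_key",
              c("standard length", "standardlength", "standardlengthinmm")),
    lex_entry("standard length", "body_length", "abbreviation", "SL"),
    lex_entry("fork length", "body_length", "explicit_key",
              c("fork length", "forklength", "forklengthinmm")),
    lex_entry("fork length", "body_length", "abbreviation", "FL"),
    lex_entry("body mass", "body_mass", "explicit_key", c(
      "body mass", "bodymass", "mass", "weight", "body weight",
      "bodyweight", "weight in grams", "weightingrams", "observedweight",
      "weight in lbs", "weightinlbs"
    )),
    lex_entry("body mass", "body_mass", "abbreviation",
              c("wt", "w.t.", "wgt")),
    lex_entry("sex", "sex", "explicit_key", "sex"),
    lex_entry("life stage", "life_stage", "explicit_key", c(
      "life stage", "lifestage", "life-stage", "age class", "ageclass", "age"
    ))
  )
  validate_lexicon(lex)
}

validate_lexicon <- function(lex) {
  req <- c("canonical", "trait_class", "match_kind", "synonym")
  if (!all(req %in% names(lex))) {
    stop("lexicon is missing columns: ",
         paste(setdiff(req, names(lex)), collapse = ", "), call. = FALSE)
  }
  if (!"guarded" %in% names(lex)) lex$guarded <- FALSE
  bad_class <- setdiff(unique(lex$trait_class), TRAIT_CLASSES)
  if (length(bad_class)) {
    stop("unknown trait_class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  bad_len <- setdiff(
    unique(lex$canonical[lex$trait_class == "body_length"]), LENGTH_SUBTYPES
  )
  if (length(bad_len)) {
    stop("body_length canonical must be one of the five subtypes; got: ",
         paste(bad_len, collapse = ", "), call. = FALSE)
  }
  # a synonym may not point at two canonicals within one trait class
  key <- paste(lex$trait_class, tolower(lex$synonym))
  per_canon <- !duplicated(paste(key, lex$canonical))
  dup <- key[per_canon][duplicated(key[per_canon])]
  if (length(dup)) {
    stop("duplicate synonym within a trait class: ",
         paste(unique(dup), collapse = "; "), call. = FALSE)
  }
  lex[!duplicated(paste(key, lex$match_kind)), , drop = FALSE]
}

#' Load a trait lexicon from a YAML config (or the built-in default)
#'
#' The config is a YAML map of trait classes (`body_length`, `body_mass`,
#' `sex`, `life_stage`) to canonical terms, each with optional `explicit`
#' and `abbreviation` synonym lists:
#'
#' ```yaml
#' body_length:
#'   total length:
#'     explicit: ["total length", "totallength"]
#'     abbreviation: ["TL", "ToL"]
#' ```
#'
#' A trait class that is absent or empty in the config falls back to the
#' built-in entries for that class, so partial configs only override what
#' they mention.
#'
#' @param config Path to a YAML file, or `NULL` for the built-in default.
#' @return A validated lexicon tibble (see [default_lexicon()]).
#' @export
load_lexicon <- function(config = NULL) {
  if (is.null(config)) return(default_lexicon())
  if (!file.exists(config)) stop("lexicon config not found: ", config,
                                 call. = FALSE)
  raw <- yaml::read_yaml(config)
  default <- default_lexicon()
  parts <- lapply(TRAIT_CLASSES, function(cls) {
    section <- raw[[cls]]
    if (is.null(section) || !length(section)) {
      return(default[default$trait_class == cls, , drop = FALSE])
    }
    dplyr::bind_rows(lapply(names(section), function(canon) {
      spec <- section[[canon]]
      dplyr::bind_rows(
        if (length(spec$explicit))
          lex_entry(canon, cls, "explicit_key", unlist(spec$explicit)),
        if (length(spec$abbreviation))
          lex_entry(canon, cls, "abbreviation", unlist(spec$abbreviation))
      )
    }))
  })
  validate_lexicon(dplyr::bind_rows(parts))
}

#' Built-in descriptor taxonomy
#'
#' A representative classification of verbatim trait descriptors into body
#' regions and measurement-versus-qualitative modes, as used when profiling
#' the descriptor diversity of a corpus. The inventory in real corpora is
#' far larger (on the order of a thousand distinct descriptors); this table
#' is a seed meant to be extended through [categorize_descriptors()]'s
#' `taxonomy` argument.
#'
#' @return A tibble with columns `descriptor`, `region`, `mode`.
#' @export
default_descriptor_taxonomy <- function() {
  d <- function(region, mode, descriptors) {
    tibble::tibble(descriptor = descriptors, region = region, mode = mode)
  }
  dplyr::bind_rows(
    d("head", "measurement", c(
      "head length", "skull length", "bill length", "culmen length",
      "beak length", "snout length", "head width", "eye diameter",
      "bill depth", "gape width", "ear length"
    )),
    d("head", "qualitative", c(
      "beak color", "bill color", "eye color", "iris color", "crest"
    )),
    d("neck", "measurement", "neck length"),
    d("neck", "qualitative", "neck coloration"),
    d("appendage", "measurement", c(
      "tarsus length", "wing length", "wing chord", "forearm length",
      "hind foot length", "hindfoot length", "foot length", "flipper length",
      "fin length", "toe length", "claw length", "hand length"
    )),
    d("appendage", "qualitative", c(
      "wing condition", "fin shape", "webbing", "claw condition"
    )),
    d("tail", "measurement", c("tail length", "tail width")),
    d("tail", "qualitative", c("tail condition", "tail shape")),
    d("trunk", "measurement", c(
      "girth", "chest circumference", "body width", "gonad length",
      "gonad width", "testis length", "testes size", "ovary length"
    )),
    d("trunk", "qualitative", c(
      "fat deposits", "reproductive condition", "gonad condition",
      "mammae condition", "pelage color", "plumage", "molt", "skin texture"
    )),
    d("wholeOrg", "measurement", c(
      "total length", "standard length", "fork length", "body mass",
      "weight", "total body weight", "wingspan", "clutch size"
    )),
    d("wholeOrg", "qualitative", c("coloration", "overall condition")),
    d("orgPartsComplex", "measurement", c(
      "head-body length", "snout-vent length", "crown-rump length"
    )),
    d("nonOrg", "measurement", c("nest height", "egg length", "elevation")),
    d("nonOrg", "qualitative", c("nest material", "habitat"))
  )
}

DESCRIPTOR_REGIONS <- c("head", "neck", "appendage", "tail", "trunk",
                        "wholeOrg", "orgPartsComplex", "nonOrg", "other")
DESCRIPTOR_MODES <- c("measurement", "qualitative")

#' Tally distinct trait descriptors by body region and mode
#'
#' Counts how many *distinct* descriptors (case-insensitive, after whitespace
#' trimming) fall into each body-region x mode cell of a descriptor taxonomy.
#' Duplicated occurrences of the same descriptor count once, so the matrix
#' total equals the number of distinct classified descriptors. Descriptors
#' absent from the taxonomy are not counted; they are returned in the
#' `unmatched` attribute and reported via a message.
#'
#' @param descriptors Character vector of verbatim descriptors (repeats
#'   allowed).
#' @param taxonomy A descriptor taxonomy tibble
#'   (see [default_descriptor_taxonomy()]); each descriptor must map to
#'   exactly one (region, mode) pair.
#' @return An integer matrix, regions x modes, with attribute `unmatched`.
#' @export
#' @examples
#' categorize_descriptors(c("tarsus length", "tarsus length", "beak color"))
categorize_descriptors <- function(descriptors,
                                   taxonomy = default_descriptor_taxonomy()) {
  tax_key <- tolower(trimws(taxonomy$descriptor))
  if (anyDuplicated(tax_key)) {
    stop("taxonomy maps a descriptor to more than one (region, mode) pair: ",
         paste(unique(tax_key[duplicated(tax_key)]), collapse = ", "),
         call. = FALSE)
  }
  out <- matrix(0L, nrow = length(DESCRIPTOR_REGIONS),
                ncol = length(DESCRIPTOR_MODES),
                dimnames = list(DESCRIPTOR_REGIONS, DESCRIPTOR_MODES))
  keys <- unique(tolower(trimws(descriptors)))
  keys <- keys[nzchar(keys)]
  idx <- match(keys, tax_key)
  unmatched <- keys[is.na(idx)]
  hit <- idx[!is.na(idx)]
  for (i in hit) {
    out[taxonomy$region[i], taxonomy$mode[i]] <-
      out[taxonomy$region[i], taxonomy$mode[i]] + 1L
  }
  if (length(unmatched)) {
    message("categorize_descriptors: ", length(unmatched),
            " descriptor(s) not in taxonomy: ",
            paste(utils::head(unmatched, 10), collapse = ", "))
  }
  attr(out, "unmatched") <- unmatched
  out
}
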