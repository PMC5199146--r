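GEN_STYLES <- c("explicit_keyed", "abbreviated", "shorthand", "range",
                "imperial_units", "unitless", "verbose_multi_individual",
                "empty")

# styles whose rendering is unambiguous: the pipeline is expected to recover
# the generated ground truth exactly on these
CLEAN_STYLES <- c("explicit_keyed", "abbreviated", "shorthand", "range",
                  "imperial_units")

#' Define a mix of text-rendering styles for the synthetic corpus
#'
#' Weights are non-negative and are normalized to sum to 1; at least one
#' must be positive. The styles emulate how trait content shows up in
#' digitized records: explicit "key: value" pairs, abbreviated keys,
#' positional mammal shorthand, length ranges, Imperial units, unitless
#' values, verbose multi-individual remarks, and fully empty fields.
#'
#' @param ... Named weights over a subset of the styles; omitted styles get
#'   weight 0. With no arguments, all eight styles are weighted equally.
#' @return A named numeric vector of class `style_mix` summing to 1.
#' @export
#' @examples
#' style_mix(explicit_keyed = 2, shorthand = 1)
style_mix <- function(...) {
  w <- c(...)
  if (!length(w)) w <- stats::setNames(rep(1, length(GEN_STYLES)), GEN_STYLES)
  bad <- setdiff(names(w), GEN_STYLES)
  if (length(bad) || is.null(names(w))) {
    stop("unknown style(s): ", paste(bad, collapse = ", "),
         "; valid styles are: ", paste(GEN_STYLES, collapse = ", "),
         call. = FALSE)
  }
  if (any(w < 0) || sum(w) <= 0) {
    stop("style weights must be non-negative with a positive sum",
         call. = FALSE)
  }
  full <- stats::setNames(numeric(length(GEN_STYLES)), GEN_STYLES)
  full[names(w)] <- w
  structure(full / sum(full), class = c("style_mix", "numeric"))
}

SYNTH_SPECIES <- list(
  Mammalia = list(class = "Mammalia", species = c(
    "Tamias minimus", "Peromyscus maniculatus", "Sorex cinereus",
    "Microtus pennsylvanicus", "Sciurus carolinensis")),
  Aves = list(class = "Aves", species = c(
    "Turdus migratorius", "Zonotrichia leucophrys", "Passer domesticus",
    "Corvus brachyrhynchos")),
  Reptilia = list(class = "Reptilia", species = c(
    "Sceloporus undulatus", "Thamnophis sirtalis", "Anolis carolinensis")),
  Amphibia = list(class = "Amphibia", species = c(
    "Lithobates pipiens", "Ambystoma maculatum", "Plethodon cinereus")),
  Fish = list(class = "Actinopterygii", species = c(
    "Lepomis macrochirus", "Notropis hudsonius", "Catostomus commersonii",
    "Perca flavescens"))
)

CLADE_CONTEXT <- c(Mammalia = "mammalogy", Aves = "ornithology",
                   Fish = "ichthyology", Reptilia = "", Amphibia = "")

subtype_for_clade <- function(clade) {
  switch(clade,
    Mammalia = sample(c("total length", "head-body length"), 1,
                      prob = c(0.7, 0.3)),
    Aves = "total length",
    Reptilia = ,
    Amphibia = "snout-vent length",
    Fish = sample(c("standard length", "fork length", "total length"), 1,
                  prob = c(0.5, 0.3, 0.2)),
    "total length"
  )
}

SUBTYPE_ABBREV <- c(
  "total length" = "TL", "head-body length" = "HB",
  "snout-vent length" = "SVL", "standard length" = "SL", "fork length" = "FL"
)

# log-uniform draws: body sizes span orders of magnitude
rlog_unif <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))

rnd_val <- function(x, max_digits = 1) {
  d <- sample(0:max_digits, 1)
  max(round(x, d), 10^-d)  # keep strictly positive after rounding
}

fmt_val <- function(x) {
  s <- sprintf("%.2f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Generate a synthetic occurrence corpus with known ground truth
#'
#' Creates `n` specimen records whose free-text fields are rendered in
#' styles sampled from `mix`, from true trait values drawn log-uniformly
#' (lengths 5-2000 mm, masses 0.5-25000 g, sex in male/female, stage in
#' adult/juvenile/subadult). The returned gold labels hold the true values
#' with the units as written (`"inferred"` when the style omits them) and
#' flag styles that a key-based extractor is *expected* to miss
#' (`keyless_implied`, e.g. verbose multi-individual sex remarks).
#' Deterministic for a fixed seed.
#'
#' @param n Number of records.
#' @param mix A [style_mix()].
#' @param seed Integer seed.
#' @return A list with `records` (occurrence tibble), `gold` (label tibble
#'   with the [read_gold()] columns plus `is_range` and `subtype`) and
#'   `styles` (tibble `record_id`, `style`).
#' @export
#' @examples
#' corpus <- generate_corpus(5, style_mix(shorthand = 1), seed = 42)
#' corpus$records$dynamic_properties
generate_corpus <- function(n, mix = style_mix(), seed = 1) {
  if (!inherits(mix, "style_mix")) mix <- do.call(style_mix, as.list(mix))
  stopifnot(n >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  recs <- vector("list", n)
  golds <- vector("list", n)
  styles <- character(n)
  for (i in seq_len(n)) {
    id <- sprintf("synth-%06d", i)
    style <- sample(GEN_STYLES, 1, prob = unclass(mix))
    styles[i] <- style
    clade <- sample(names(SYNTH_SPECIES), 1,
                    prob = c(0.3, 0.25, 0.15, 0.1, 0.2))
    pool <- SYNTH_SPECIES[[clade]]
    sp <- strsplit(sample(pool$species, 1), " ")[[1]]
    subtype <- subtype_for_clade(clade)

    has <- c(length = FALSE, mass = FALSE, sex = FALSE, stage = FALSE)
    if (style %in% c("explicit_keyed", "abbreviated", "imperial_units",
                     "unitless")) {
      has[] <- stats::runif(4) < c(0.9, 0.7, 0.6, 0.5)
      if (!any(has)) has["length"] <- TRUE
    } else if (style == "shorthand") {
      has[c("length", "mass")] <- TRUE
      has[c("sex", "stage")] <- stats::runif(2) < c(0.4, 0.3)
    } else if (style == "range") {
      has["length"] <- TRUE
      has["sex"] <- stats::runif(1) < 0.3
    } else if (style == "verbose_multi_individual") {
      has["sex"] <- TRUE
    }

    sex_val <- sample(c("male", "female"), 1)
    stage_val <- sample(c("adult", "juvenile", "subadult"), 1)
    parts <- character(0)
    gold <- list()
    g_row <- function(trait, value, units, keyless = FALSE,
                      is_range = FALSE, sub = NA_character_) {
      tibble::tibble(record_id = id, trait = trait, present = TRUE,
                     value = value, units = units,
                     keyless_implied = keyless, is_range = is_range,
                     subtype = sub)
    }

    if (style == "shorthand") {
      tl <- round(rlog_unif(60, 2000))
      tail_v <- round(tl * stats::runif(1, 0.25, 0.6))
      hf <- round(tail_v * stats::runif(1, 0.2, 0.5))
      ear <- max(round(hf * stats::runif(1, 0.3, 0.9)), 2)
      mass_v <- round(rlog_unif(2, 5000), 1)
      spaced <- sample(c(TRUE, FALSE), 1)
      glue <- if (spaced) " = " else "="
      parts <- c(parts, paste0(tl, "-", tail_v, "-", hf, "-", ear,
                               glue, fmt_val(mass_v)))
      gold$len <- g_row("length", as.character(tl), "inferred",
                        sub = "total length")
      gold$mass <- g_row("mass", fmt_val(mass_v), "inferred")
      if (has["sex"]) {
        parts <- c(parts, paste0("sex=", sex_val))
        gold$sex <- g_row("sex", sex_val, NA_character_)
      }
      if (has["stage"]) {
        parts <- c(parts, paste0("age: ", stage_val))
        gold$stage <- g_row("life stage", stage_val, NA_character_)
      }
    } else if (style == "verbose_multi_individual") {
      tmpl <- sample(c(
        "lot of %d specimens: one male and two female, collected together",
        "mixed series with male and female individuals",
        "both male and female present in this lot"
      ), 1)
      n_lot <- sample(3:12, 1)
      parts <- c(parts,
                 if (grepl("%d", tmpl, fixed = TRUE)) sprintf(tmpl, n_lot)
                 else tmpl)
      gold$sex <- g_row("sex", NA_character_, NA_character_, keyless = TRUE)
    } else if (style != "empty") {
      if (has["length"]) {
        key <- if (style == "abbreviated") SUBTYPE_ABBREV[[subtype]] else subtype
        if (style == "range") {
          lo <- rnd_val(rlog_unif(5, 500), 0)
          hi <- lo + sample(5:40, 1)
          with_units <- stats::runif(1) < 0.7
          u <- if (with_units) "mm" else "inferred"
          parts <- c(parts, paste0(
            subtype, ": ", fmt_val(lo), "-", fmt_val(hi),
            if (with_units) " mm" else ""))
          gold$len <- g_row("length", NA_character_, u, is_range = TRUE,
                            sub = subtype)
        } else if (style == "imperial_units") {
          u <- sample(c("in", "ft"), 1, prob = c(0.8, 0.2))
          v <- if (u == "ft") max(round(rlog_unif(0.5, 6.5), 1), 0.5)
               else max(round(rlog_unif(0.2, 78), sample(1:2, 1)), 0.2)
          parts <- c(parts, paste0(subtype, ": ", fmt_val(v), " ", u))
          gold$len <- g_row("length", fmt_val(v), u, sub = subtype)
        } else {
          with_units <- style == "explicit_keyed" ||
            (style == "abbreviated" && stats::runif(1) < 0.5)
          if (style == "unitless") with_units <- FALSE
          u <- if (!with_units) "inferred"
               else sample(c("mm", "cm"), 1, prob = c(0.8, 0.2))
          v <- if (identical(u, "cm")) rnd_val(rlog_unif(0.5, 200), 1)
               else rnd_val(rlog_unif(5, 2000), 1)
          sep <- if (style == "abbreviated") sample(c(" ", "="), 1) else ": "
          parts <- c(parts, paste0(
            key, sep, fmt_val(v),
            if (with_units) paste0(sample(c(" ", ""), 1), u) else ""))
          gold$len <- g_row("length", fmt_val(v), u, sub = subtype)
        }
      }
      if (has["mass"]) {
        key <- if (style == "abbreviated") "wt"
               else sample(c("weight", "body mass", "mass"), 1)
        if (style == "imperial_units") {
          compound <- stats::runif(1) < 0.3
          if (compound) {
            lb <- sample(1:40, 1)
            oz <- sample(1:15, 1)
            parts <- c(parts, paste0(key, ": ", lb, " lbs ", oz, " oz"))
            # oz/16 lb is exact under the conversion table
            # (453.59237 / 16 = 28.349523125), so the gold value can be
            # expressed in decimal pounds
            gold$mass <- g_row("mass", as.character(lb + oz / 16), "lb")
          } else {
            v <- max(round(rlog_unif(0.1, 55), sample(1:2, 1)), 0.1)
            u <- sample(c("lb", "oz"), 1, prob = c(0.7, 0.3))
            tok <- if (u == "lb") sample(c("lb", "lbs"), 1) else "oz"
            parts <- c(parts, paste0(key, ": ", fmt_val(v), " ", tok))
            gold$mass <- g_row("mass", fmt_val(v), u)
          }
        } else {
          with_units <- style == "explicit_keyed" ||
            (style == "abbreviated" && stats::runif(1) < 0.5)
          if (style == "unitless") with_units <- FALSE
          u <- if (!with_units) "inferred"
               else sample(c("g", "kg"), 1, prob = c(0.85, 0.15))
          v <- if (identical(u, "kg")) rnd_val(rlog_unif(0.5, 25), 1)
               else rnd_val(rlog_unif(0.5, 25000), 1)
          sep <- if (style == "abbreviated") sample(c(" ", "="), 1) else ": "
          parts <- c(parts, paste0(
            key, sep, fmt_val(v),
            if (with_units) paste0(sample(c(" ", ""), 1), u) else ""))
          gold$mass <- g_row("mass", fmt_val(v), u)
        }
      }
      if (has["sex"]) {
        sep <- sample(c(": ", "="), 1)
        parts <- c(parts, paste0("sex", sep, sex_val))
        gold$sex <- g_row("sex", sex_val, NA_character_)
      }
      if (has["stage"]) {
        key <- sample(c("life stage", "age class", "age"), 1)
        parts <- c(parts, paste0(key, ": ", stage_val))
        gold$stage <- g_row("life stage", stage_val, NA_character_)
      }
    }

    text <- paste(parts, collapse = "; ")
    field <- sample(FREE_TEXT_COLS, 1, prob = c(0.7, 0.2, 0.1))
    blank_class <- stats::runif(1) < 0.05
    use_binomial <- stats::runif(1) < 0.9
    rec <- tibble::tibble(
      record_id = id,
      taxon_class = if (blank_class) "" else pool$class,
      genus = if (use_binomial) sp[1] else "",
      specific_epithet = if (use_binomial) sp[2] else "",
      scientific_name = if (use_binomial && stats::runif(1) < 0.5) ""
                        else paste(sp, collapse = " "),
      sex_field = if (has["sex"] && style != "verbose_multi_individual" &&
                      stats::runif(1) < 0.3) sex_val else "",
      life_stage_field = if (has["stage"] && stats::runif(1) < 0.3)
                           stage_val else "",
      dynamic_properties = "", occurrence_remarks = "", field_notes = "",
      collection_context = if (blank_class)
                             CLADE_CONTEXT[[clade]] else ""
    )
    rec[[field]] <- text
    recs[[i]] <- rec
    golds[[i]] <- dplyr::bind_rows(gold)
  }
  records <- validate_records(dplyr::bind_rows(recs))
  gold <- dplyr::bind_rows(golds)
  if (!nrow(gold)) {
    gold <- tibble::tibble(record_id = character(), trait = character(),
                           present = logical(), value = character(),
                           units = character(), keyless_implied = logical(),
                           is_range = logical(), subtype = character())
  }
  list(records = records, gold = gold,
       styles = tibble::tibble(record_id = records$record_id, style = styles))
}
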