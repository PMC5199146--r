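VALIDATION_TRAITS <- c("length", "mass", "sex", "life stage")

#' Confusion matrix for one trait's extraction decisions
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return An object of class `confusion_matrix`.
#' @export
#' @examples
#' confusion_matrix(tp = 271, fp = 7, tn = 1705, fn = 10)
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (n = %d)\n", x$tp + x$fp + x$tn + x$fn))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  m <- rates(x)
  cat(sprintf("  TPR %.3f  TNR %.3f  MCC %.3f\n", m$tpr, m$tnr, m$mcc))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. When any factor
#' of the denominator is zero the coefficient is undefined and 0 is
#' returned by convention.
#'
#' @param cm A [confusion_matrix()].
#' @return A number in \[-1, 1\] (full precision; round to 3 decimals for
#'   reporting).
#' @export
#' @examples
#' mcc(confusion_matrix(271, 7, 1705, 10))  # ~0.965
mcc <- function(cm) {
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Sensitivity, specificity and Matthews correlation for a confusion matrix
#'
#' `tpr = tp/(tp+fn)`, `tnr = tn/(tn+fp)` (0 when a denominator vanishes),
#' plus [mcc()].
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`, `tpr`,
#'   `tnr`, `mcc` (full precision).
#' @export
rates <- function(cm) {
  tpr <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else 0
  tnr <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else 0
  tibble::tibble(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
                 tpr = tpr, tnr = tnr, mcc = mcc(cm))
}

#' Per-record trait predictions from raw extractions
#'
#' Reduces extractions to the per-record presence/value form used for
#' scoring against a gold standard: harmonized numeric values (mm/g) for
#' the measured traits (`NA` value for range extractions, which still count
#' as present), the extracted token for sex and life stage. Unlike
#' [harmonize_traits()] this never falls back to the `dwc:sex` /
#' `dwc:lifeStage` fields — validation scores what the code extracted.
#'
#' @param records Occurrence-record tibble (defines the id universe).
#' @param extractions Raw extractions for these records.
#' @return A tibble with one row per record and trait class:
#'   `record_id`, `trait`, `present`, `value` (character).
#' @export
harmonized_predictions <- function(records, extractions) {
  n <- nrow(records)
  grid <- tibble::tibble(
    record_id = rep(records$record_id, each = length(VALIDATION_TRAITS)),
    trait = rep(VALIDATION_TRAITS, n),
    present = FALSE, value = NA_character_
  )
  set_pred <- function(grid, trait, ids, values) {
    i <- match(paste(ids, trait), paste(grid$record_id, grid$trait))
    grid$present[i] <- TRUE
    grid$value[i] <- values
    grid
  }
  if (!is.null(extractions) && nrow(extractions)) {
    ex <- extractions
    ex$field_rank <- match(ex$source_field, unname(DWC_FIELD_NAMES))
    ex$field_rank[is.na(ex$field_rank)] <- 1L

    len <- ex[ex$trait_type %in% LENGTH_SUBTYPES, , drop = FALSE]
    if (nrow(len)) {
      len$subtype_rank <- SUBTYPE_PRIORITY[len$trait_type]
      len <- dplyr::arrange(len, .data$record_id, .data$field_rank,
                            .data$tier, .data$start, .data$subtype_rank)
      len <- dplyr::distinct(len, .data$record_id, .keep_all = TRUE)
      conv <- convert_length(as.numeric(len$value), len$units)
      ok <- len$is_range | !is.na(conv$mm)
      grid <- set_pred(grid, "length", len$record_id[ok],
                       ifelse(len$is_range[ok], NA_character_,
                              as.character(conv$mm[ok])))
    }
    mass <- ex[ex$trait_type == "body mass", , drop = FALSE]
    if (nrow(mass)) {
      mass <- dplyr::arrange(mass, .data$record_id, .data$field_rank,
                             .data$tier, .data$start)
      mass <- dplyr::distinct(mass, .data$record_id, .keep_all = TRUE)
      conv <- convert_mass(as.numeric(mass$value), mass$units,
                           suppressWarnings(as.numeric(mass$value2)))
      ok <- !is.na(conv$g)
      grid <- set_pred(grid, "mass", mass$record_id[ok],
                       as.character(conv$g[ok]))
    }
    for (tt in c(sex = "sex", `life stage` = "life stage")) {
      sub <- ex[ex$trait_type == tt, , drop = FALSE]
      if (nrow(sub)) {
        sub <- dplyr::arrange(sub, .data$record_id, .data$field_rank,
                              .data$start)
        sub <- dplyr::distinct(sub, .data$record_id, .keep_all = TRUE)
        grid <- set_pred(grid, tt, sub$record_id, sub$value)
      }
    }
  }
  grid
}

harmonize_gold_value <- function(gold) {
  val <- rep(NA_character_, nrow(gold))
  num <- suppressWarnings(as.numeric(gold$value))
  is_len <- gold$trait == "length"
  is_mass <- gold$trait == "mass"
  if (any(is_len)) {
    conv <- convert_length(num[is_len], ifelse(
      is.na(gold$units[is_len]) | !nzchar(gold$units[is_len]),
      "inferred", gold$units[is_len]))
    val[is_len] <- as.character(conv$mm)
  }
  if (any(is_mass)) {
    conv <- convert_mass(num[is_mass], ifelse(
      is.na(gold$units[is_mass]) | !nzchar(gold$units[is_mass]),
      "inferred", gold$units[is_mass]))
    val[is_mass] <- as.character(conv$g)
  }
  other <- !(is_len | is_mass)
  val[other] <- gold$value[other]
  # a gold range has no single value: presence-only comparison
  val[is.na(gold$value) | !nzchar(gold$value)] <- NA_character_
  val
}

value_matches <- function(trait, pred, gold) {
  both_absent <- is.na(pred) & is.na(gold)
  if (trait %in% c("length", "mass")) {
    p <- suppressWarnings(as.numeric(pred))
    g <- suppressWarnings(as.numeric(gold))
    both_absent | (!is.na(p) & !is.na(g) & abs(p - g) < 1e-9)
  } else {
    both_absent |
      (!is.na(pred) & !is.na(gold) &
         tolower(trimws(pred)) == tolower(trimws(gold)))
  }
}

#' Score predictions against a hand-labelled gold standard
#'
#' A record counts TP when the gold standard has the trait and the
#' prediction agrees (presence and, for measurements, exact equality of the
#' harmonized value after truncation); FP when predicted but absent in gold
#' (or with a non-matching value); FN when present in gold but not
#' predicted; TN otherwise. Gold entries flagged `keyless_implied` — values
#' a human can infer but that carry no explicit key in the text — are
#' tallied separately and excluded from the matrix.
#'
#' @param predictions Tibble from [harmonized_predictions()] (or with the
#'   same columns) covering every assessed record.
#' @param gold Gold-label tibble with columns `record_id`, `trait`,
#'   `present`, `value`, `units`, `keyless_implied` (see [read_gold()]).
#' @param trait One of `"length"`, `"mass"`, `"sex"`, `"life stage"`.
#' @return A [confusion_matrix()] with attribute `keyless_excluded`.
#' @export
score_against_gold <- function(predictions, gold, trait) {
  trait <- match.arg(trait, VALIDATION_TRAITS)
  pred <- predictions[predictions$trait == trait, , drop = FALSE]
  gld <- gold[gold$trait == trait & gold$present, , drop = FALSE]
  stray <- setdiff(gld$record_id, pred$record_id)
  if (length(stray)) {
    stop("gold labels refer to records absent from predictions: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(pred$record_id)) {
    stop("duplicate record_id in predictions", call. = FALSE)
  }
  i <- match(pred$record_id, gld$record_id)
  gold_present <- !is.na(i)
  gold_value <- harmonize_gold_value(gld)[i]
  keyless <- gold_present & gld$keyless_implied[i]

  use <- !keyless
  p <- pred$present[use]
  g <- gold_present[use]
  match_ok <- value_matches(trait, pred$value[use], gold_value[use])
  tp <- sum(p & g & match_ok)
  fp <- sum(p & !(g & match_ok))
  fn <- sum(!p & g)
  tn <- sum(!p & !g)
  out <- confusion_matrix(tp, fp, tn, fn)
  attr(out, "keyless_excluded") <- sum(keyless)
  out
}

#' Validation metrics for every trait at once
#'
#' @inheritParams score_against_gold
#' @return A tibble with one row per trait: counts, TPR, TNR, MCC and the
#'   keyless-implied exclusion tally.
#' @export
validation_report <- function(predictions, gold) {
  dplyr::bind_rows(lapply(VALIDATION_TRAITS, function(tt) {
    cm <- score_against_gold(predictions, gold, tt)
    cbind(tibble::tibble(trait = tt), rates(cm),
          tibble::tibble(keyless_excluded = attr(cm, "keyless_excluded")))
  }))
}

#' Draw a reproducible random validation sample
#'
#' Implemented the way hand-validation sets are customarily drawn from a
#' spreadsheet: attach a column of random numbers, sort on it, take the
#' first `n` rows. Uniform without replacement and reproducible for a fixed
#' seed.
#'
#' @param records A tibble (any rows).
#' @param n Sample size; must not exceed `nrow(records)`.
#' @param seed Integer seed.
#' @return `n` rows of `records`.
#' @export
sample_validation_set <- function(records, n, seed) {
  if (n > nrow(records)) {
    stop("cannot sample ", n, " from ", nrow(records), " records",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  key <- stats::runif(nrow(records))
  out <- records[order(key)[seq_len(n)], , drop = FALSE]
  attr(out, "col_map") <- attr(records, "col_map")
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read / write gold-standard label files
#'
#' CSV with columns `record_id`, `trait` (`length`, `mass`, `sex`,
#' `life stage`), `present` (`true`/`false`), `value` (harmonizable number
#' for measurements, token for sex/life stage, empty for ranges), `units`
#' (unit token, `inferred`, or empty) and `keyless_implied` (`true` when
#' the text implies the trait without an explicit key; such rows are
#' excluded from error calculation).
#'
#' @param path CSV path.
#' @return `read_gold`: a gold tibble. `write_gold`: `path`, invisibly.
#' @export
read_gold <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  req <- c("record_id", "trait", "present", "value", "units",
           "keyless_implied")
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    stop("gold file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    record_id = raw$record_id, trait = raw$trait,
    present = tolower(raw$present) == "true",
    value = ifelse(nzchar(raw$value), raw$value, NA_character_),
    units = ifelse(nzchar(raw$units), raw$units, NA_character_),
    keyless_implied = tolower(raw$keyless_implied) == "true"
  )
}

#' @rdname read_gold
#' @param gold A gold tibble.
#' @export
write_gold <- function(gold, path) {
  out <- tibble::tibble(
    record_id = gold$record_id, trait = gold$trait,
    present = fmt_bool(gold$present),
    value = ifelse(is.na(gold$value), "", as.character(gold$value)),
    units = ifelse(is.na(gold$units), "", gold$units),
    keyless_implied = fmt_bool(gold$keyless_implied)
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
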