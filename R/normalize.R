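# Exact conversion factors to the community-standard units (mm, g).
LENGTH_FACTORS <- c(mm = 1, cm = 10, m = 1000, "in" = 25.4, ft = 304.8,
                    inferred = 1)
MASS_FACTORS <- c(g = 1, kg = 1000, lb = 453.59237, oz = 28.349523125,
                  inferred = 1)

# Truncation (not rounding) to two decimal places; values reported at lower
# precision pass through unchanged. The epsilon guards against binary
# floating-point representations just under the true product.
truncate2 <- function(x) trunc(x * 100 + 1e-7) / 100

#' Convert a body-length value to millimetres
#'
#' Exact factor conversion (cm x10, m x1000, in x25.4, ft x304.8). Units
#' `"inferred"` means none were written: the value is assumed to already be
#' in millimetres and flagged. Results are truncated to two decimal places.
#' Non-positive values and unknown unit tokens are rejected (`mm = NA`), so
#' the extraction is dropped downstream.
#'
#' @param value Numeric vector of reported values.
#' @param units Character vector of unit tokens (`mm`, `cm`, `m`, `in`,
#'   `ft`, or `"inferred"`), recycled against `value`.
#' @return A tibble with columns `mm` (numeric, `NA` on rejection) and
#'   `inferred` (logical).
#' @export
#' @examples
#' convert_length(10, "in")        # 254 mm
#' convert_length(235, "inferred") # assumed mm, flagged
convert_length <- function(value, units) {
  n <- max(length(value), length(units))
  value <- rep_len(as.numeric(value), n)
  units <- rep_len(as.character(units), n)
  factor <- LENGTH_FACTORS[units]
  bad <- is.na(factor) | is.na(value) | value <= 0
  report <- !is.na(value) & (is.na(factor) | value <= 0)
  if (any(report)) {
    message("convert_length: dropped ", sum(report), " value(s) with ",
            "unknown units or non-positive magnitude")
  }
  mm <- truncate2(value * unname(factor))
  mm[bad] <- NA_real_
  tibble::tibble(mm = mm, inferred = unname(!bad & units == "inferred"))
}

#' Convert a body-mass value to grams
#'
#' kg x1000, lb x453.59237, oz x28.349523125; the compound Imperial form
#' ("2 lbs 3 oz") passes the pound part in `value` and the ounce part in
#' `value2` with `units = "lb+oz"`, and the two components are summed.
#' Inferred units assume grams. Truncation and rejection rules are the same
#' as [convert_length()].
#'
#' @param value Numeric vector of reported values (pound part for `lb+oz`).
#' @param units Character vector of unit tokens (`g`, `kg`, `lb`, `oz`,
#'   `lb+oz`, `"inferred"`).
#' @param value2 Ounce component for the compound form (ignored otherwise).
#' @return A tibble with columns `g` and `inferred`.
#' @export
#' @examples
#' convert_mass(20, "kg")     # 20000 g
#' convert_mass(2, "lb+oz", value2 = 3)
convert_mass <- function(value, units, value2 = NA_real_) {
  n <- max(length(value), length(units))
  value <- rep_len(as.numeric(value), n)
  units <- rep_len(as.character(units), n)
  value2 <- rep_len(as.numeric(value2), n)
  compound <- !is.na(units) & units == "lb+oz"
  factor <- MASS_FACTORS[units]
  factor[compound] <- MASS_FACTORS[["lb"]]
  bad <- is.na(factor) | is.na(value) | value <= 0 |
    (compound & (is.na(value2) | value2 < 0))
  g <- value * unname(factor)
  g[compound] <- g[compound] + value2[compound] * MASS_FACTORS[["oz"]]
  g <- truncate2(g)
  g[bad] <- NA_real_
  report <- !is.na(value) & bad
  if (any(report)) {
    message("convert_mass: dropped ", sum(report), " value(s) with ",
            "unknown units or non-positive magnitude")
  }
  tibble::tibble(g = unname(g), inferred = unname(!bad & units == "inferred"))
}

empty_harmonized <- function(n) {
  tibble::tibble(
    hasLength = rep(FALSE, n), hasMass = FALSE, hasSex = FALSE,
    hasLifeStage = FALSE, lengthInMM = NA_real_, massInG = NA_real_,
    wereLengthUnitsInferred = FALSE, wereMassUnitsInferred = FALSE,
    derivedSex = "", derivedLifeStage = "", lengthType = NA_character_
  )
}

# order used to break ties when several length subtypes were extracted
SUBTYPE_PRIORITY <- stats::setNames(seq_along(LENGTH_SUBTYPES),
                                    LENGTH_SUBTYPES)

#' Assemble the harmonized trait fields for a set of records
#'
#' Applies the unit conversions and derives the portal output schema:
#' the four `has*` presence flags, `lengthInMM`/`massInG`, the
#' inferred-units flags, `derivedSex`/`derivedLifeStage` (the Darwin Core
#' field value when non-empty, else the extracted value, else empty), and
#' `lengthType` (the length subtype, suffixed `" range"` for range
#' extractions, which keep `hasLength = TRUE` but no indexable value).
#' When several length subtypes were extracted for one record, the one from
#' the highest-priority field, then lowest precedence tier, then leftmost
#' span is kept. Conversion rejections leave the trait unset.
#'
#' @param records Occurrence-record tibble.
#' @param extractions Raw extractions from [extract_traits()] for these
#'   records.
#' @return A harmonized-trait tibble, one row per record, aligned with
#'   `records`.
#' @export
harmonize_traits <- function(records, extractions) {
  n <- nrow(records)
  out <- empty_harmonized(n)
  if (!is.null(extractions) && nrow(extractions)) {
    unknown <- setdiff(unique(extractions$record_id), records$record_id)
    if (length(unknown)) {
      stop("extractions refer to unknown record_id: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(extractions) || !nrow(extractions)) {
    out$derivedSex <- records$sex_field
    out$derivedLifeStage <- records$life_stage_field
    out$hasSex <- nzchar(out$derivedSex)
    out$hasLifeStage <- nzchar(out$derivedLifeStage)
    return(out)
  }
  ex <- extractions
  ex$row <- match(ex$record_id, records$record_id)
  ex$field_rank <- match(ex$source_field, unname(DWC_FIELD_NAMES))
  ex$field_rank[is.na(ex$field_rank)] <- 1L

  len <- ex[ex$trait_type %in% LENGTH_SUBTYPES, , drop = FALSE]
  if (nrow(len)) {
    len$subtype_rank <- SUBTYPE_PRIORITY[len$trait_type]
    len <- dplyr::arrange(len, .data$row, .data$field_rank, .data$tier,
                          .data$start, .data$subtype_rank)
    len <- dplyr::distinct(len, .data$row, .keep_all = TRUE)
    conv <- convert_length(as.numeric(len$value), len$units)
    is_range <- len$is_range
    ok <- is_range | !is.na(conv$mm)
    r <- len$row[ok]
    out$hasLength[r] <- TRUE
    out$lengthInMM[r] <- ifelse(is_range[ok], NA_real_, conv$mm[ok])
    out$wereLengthUnitsInferred[r] <- len$units[ok] == "inferred"
    out$lengthType[r] <- ifelse(is_range[ok],
                                paste0(len$trait_type[ok], " range"),
                                len$trait_type[ok])
  }

  mass <- ex[ex$trait_type == "body mass", , drop = FALSE]
  if (nrow(mass)) {
    mass <- dplyr::arrange(mass, .data$row, .data$field_rank, .data$tier,
                           .data$start)
    mass <- dplyr::distinct(mass, .data$row, .keep_all = TRUE)
    conv <- convert_mass(as.numeric(mass$value), mass$units,
                         suppressWarnings(as.numeric(mass$value2)))
    ok <- !is.na(conv$g)
    r <- mass$row[ok]
    out$hasMass[r] <- TRUE
    out$massInG[r] <- conv$g[ok]
    out$wereMassUnitsInferred[r] <- conv$inferred[ok]
  }

  pick_value <- function(trait) {
    sub <- ex[ex$trait_type == trait, , drop = FALSE]
    v <- rep("", n)
    if (nrow(sub)) {
      sub <- dplyr::arrange(sub, .data$row, .data$field_rank, .data$start)
      sub <- dplyr::distinct(sub, .data$row, .keep_all = TRUE)
      v[sub$row] <- sub$value
    }
    v
  }
  ex_sex <- pick_value("sex")
  ex_stage <- pick_value("life stage")
  out$derivedSex <- ifelse(nzchar(records$sex_field), records$sex_field,
                           ex_sex)
  out$derivedLifeStage <- ifelse(nzchar(records$life_stage_field),
                                 records$life_stage_field, ex_stage)
  out$hasSex <- nzchar(out$derivedSex)
  out$hasLifeStage <- nzchar(out$derivedLifeStage)
  out
}
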