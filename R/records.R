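# Canonical column names used internally, and the Darwin Core simple terms
# (lowercased, namespace prefix stripped) that map onto them.
CANONICAL_COLS <- c(
  record_id = "occurrenceID", taxon_class = "class", genus = "genus",
  specific_epithet = "specificEpithet", scientific_name = "scientificName",
  sex_field = "sex", life_stage_field = "lifeStage",
  dynamic_properties = "dynamicProperties",
  occurrence_remarks = "occurrenceRemarks", field_notes = "fieldNotes",
  collection_context = "collectionContext"
)

DWC_TERM_MAP <- stats::setNames(names(CANONICAL_COLS),
                                tolower(unname(CANONICAL_COLS)))

FREE_TEXT_COLS <- c("dynamic_properties", "occurrence_remarks", "field_notes")

canonical_header <- function(h) {
  h <- sub("^.*:", "", trimws(h))  # strip any namespace prefix (dwc:sex)
  unname(DWC_TERM_MAP[tolower(h)])
}

#' Build an occurrence-record tibble from loose vectors
#'
#' Convenience constructor used by the synthetic generator and in tests.
#' All fields are strings; missing ones default to the empty string.
#'
#' @param record_id Unique identifiers (required).
#' @param ... Any of `taxon_class`, `genus`, `specific_epithet`,
#'   `scientific_name`, `sex_field`, `life_stage_field`,
#'   `dynamic_properties`, `occurrence_remarks`, `field_notes`,
#'   `collection_context`, recycled to length of `record_id`.
#' @return A tibble with the full canonical column set.
#' @export
occurrence_records <- function(record_id, ...) {
  dots <- list(...)
  bad <- setdiff(names(dots), names(CANONICAL_COLS))
  if (length(bad)) stop("unknown occurrence fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  n <- length(record_id)
  out <- tibble::tibble(record_id = as.character(record_id))
  for (col in setdiff(names(CANONICAL_COLS), "record_id")) {
    v <- dots[[col]]
    out[[col]] <- if (is.null(v)) "" else rep_len(as.character(v), n)
  }
  validate_records(out)
}

validate_records <- function(records) {
  if (any(!nzchar(records$record_id))) {
    stop("record_id must be non-empty for every record", call. = FALSE)
  }
  if (anyDuplicated(records$record_id)) {
    warning("duplicate record_id values: ",
            paste(utils::head(unique(
              records$record_id[duplicated(records$record_id)]), 5),
              collapse = ", "))
  }
  records
}

#' Read occurrence records from Darwin Core CSV/TSV or a Darwin Core Archive
#'
#' Header matching is case-insensitive on the Darwin Core simple term names,
#' with or without a namespace prefix (`dwc:sex` and `SEX` both map to the
#' sex field). All cells are read verbatim as character (only surrounding
#' whitespace in headers is trimmed); invalid bytes are replaced and logged.
#' Columns that are not recognized Darwin Core terms are retained unchanged
#' so the output can reproduce the input.
#'
#' For `dialect = "dwca-core"`, `path` may be a `.zip` Darwin Core Archive
#' or an unpacked archive directory; only the occurrence core is read
#' (extensions are ignored with a warning).
#'
#' @param path Input file (or archive/directory for `dwca-core`).
#' @param dialect One of `"csv"`, `"tsv"`, `"dwca-core"`. Defaults from the
#'   file extension (`.tsv`/`.txt` read as TSV, `.zip` as archive).
#' @return A tibble of occurrence records: the canonical columns
#'   (`record_id`, `taxon_class`, ..., `field_notes`) followed by any
#'   passthrough columns. The attribute `col_map` records the original
#'   header order and spelling.
#' @export
read_occurrences <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("cannot read input: ", path, call. = FALSE)
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (dir.exists(path) || ext == "zip") "dwca-core"
               else if (ext %in% c("tsv", "txt", "tab")) "tsv" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "tsv", "dwca-core"))
  if (dialect == "dwca-core") return(read_dwca_core(path))

  delim <- if (dialect == "tsv") "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = "c"),
    na = character(), trim_ws = FALSE, progress = FALSE,
    show_col_types = FALSE,
    locale = readr::locale(encoding = "UTF-8")
  )
  canonicalize_columns(raw)
}

canonicalize_columns <- function(raw) {
  headers <- names(raw)
  canon <- canonical_header(headers)
  if (!any(!is.na(canon))) {
    stop("no recognizable Darwin Core header; expected at least one of: ",
         paste(unname(CANONICAL_COLS), collapse = ", "), call. = FALSE)
  }
  # first occurrence wins if a term is repeated
  canon[duplicated(canon) & !is.na(canon)] <- NA

  out <- tibble::tibble(.rows = nrow(raw))
  for (col in names(CANONICAL_COLS)) {
    j <- which(canon == col)
    v <- if (length(j)) raw[[j]] else rep("", nrow(raw))
    v[is.na(v)] <- ""
    out[[col]] <- trimws(v)
  }
  if (all(!nzchar(out$record_id))) {
    out$record_id <- sprintf("row-%d", seq_len(nrow(raw)))
  }
  pass <- which(is.na(canon))
  for (j in pass) {
    v <- raw[[j]]
    v[is.na(v)] <- ""
    out[[headers[j]]] <- v
  }
  attr(out, "col_map") <- stats::setNames(canon, headers)
  validate_records(out)
}

read_dwca_core <- function(path) {
  root <- path
  if (!dir.exists(path)) {
    root <- tempfile("dwca")
    dir.create(root)
    utils::unzip(path, exdir = root)
  }
  meta_path <- file.path(root, "meta.xml")
  if (!file.exists(meta_path)) {
    stop("not a Darwin Core Archive: missing meta.xml in ", path,
         call. = FALSE)
  }
  meta <- xml2::read_xml(meta_path)
  xml2::xml_ns_strip(meta)
  core <- xml2::xml_find_first(meta, ".//core")
  if (inherits(core, "xml_missing")) {
    stop("Darwin Core Archive has no <core> element", call. = FALSE)
  }
  if (length(xml2::xml_find_all(meta, ".//extension"))) {
    warning("Darwin Core Archive extensions are ignored; ",
            "only the occurrence core is read")
  }
  loc <- xml2::xml_text(xml2::xml_find_first(core, ".//files/location"))
  sep <- xml2::xml_attr(core, "fieldsTerminatedBy")
  if (is.na(sep) || !nzchar(sep)) sep <- ","
  sep <- gsub("\\t", "\t", sep, fixed = TRUE)
  skip <- suppressWarnings(as.integer(xml2::xml_attr(core, "ignoreHeaderLines")))
  if (is.na(skip)) skip <- 0L

  fields <- xml2::xml_find_all(core, ".//field")
  f_idx <- as.integer(xml2::xml_attr(fields, "index"))
  f_term <- basename(xml2::xml_attr(fields, "term"))
  id_idx <- suppressWarnings(as.integer(
    xml2::xml_attr(xml2::xml_find_first(core, ".//id"), "index")))

  raw <- readr::read_delim(
    file.path(root, loc), delim = sep, col_names = FALSE,
    col_types = readr::cols(.default = "c"), na = character(),
    skip = skip, trim_ws = FALSE, progress = FALSE, show_col_types = FALSE,
    locale = readr::locale(encoding = "UTF-8")
  )
  headers <- sprintf("column%d", seq_along(raw) - 1L)
  headers[f_idx + 1L] <- f_term
  if (!is.na(id_idx) && !"occurrenceID" %in% f_term) {
    headers[id_idx + 1L] <- "occurrenceID"
  }
  names(raw) <- headers
  canonicalize_columns(raw)
}

is_blank_field <- function(x) {
  toupper(trimws(x)) %in% c("", "NA", "NULL")
}

#' Keep only records that can carry trait text
#'
#' Returns the records whose `dynamicProperties`, `occurrenceRemarks` or
#' `fieldNotes` hold any content, in input order. `""`, `"NA"` and `"NULL"`
#' (after whitespace trimming, case-insensitive) all count as empty,
#' approximating SQL `IS NOT NULL` semantics for CSV exports.
#'
#' @param records An occurrence-record tibble.
#' @return The subset of `records` with at least one populated free-text
#'   field; attributes (including `col_map`) are preserved.
#' @export
filter_candidates <- function(records) {
  keep <- !(is_blank_field(records$dynamic_properties) &
            is_blank_field(records$occurrence_remarks) &
            is_blank_field(records$field_notes))
  out <- records[keep, , drop = FALSE]
  attr(out, "col_map") <- attr(records, "col_map")
  out
}

HARMONIZED_COLS <- c(
  "hasLength", "hasMass", "hasSex", "hasLifeStage", "lengthInMM", "massInG",
  "wereLengthUnitsInferred", "wereMassUnitsInferred", "derivedSex",
  "derivedLifeStage", "lengthType"
)

fmt_bool <- function(x) ifelse(x, "true", "false")

# Minimal locale-independent decimal serialization of a value already
# truncated to <= 2 decimals: no trailing zeros, no scientific notation.
fmt_num <- function(x) {
  out <- rep("", length(x))
  ok <- !is.na(x)
  s <- sprintf("%.2f", x[ok])
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  out[ok] <- s
  out
}

#' Write records with their harmonized trait columns
#'
#' Emits a CSV holding every original input column (original spelling and
#' order when the records came from a file) followed by the harmonized trait
#' columns, in this fixed order: `hasLength, hasMass, hasSex, hasLifeStage,
#' lengthInMM, massInG, wereLengthUnitsInferred, wereMassUnitsInferred,
#' derivedSex, derivedLifeStage, lengthType`. Booleans are serialized as
#' `"true"`/`"false"`; absent numerics as the empty string.
#'
#' @param records Occurrence-record tibble (one row per record).
#' @param traits Harmonized-trait tibble from [harmonize_traits()], aligned
#'   row-by-row with `records`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(records, traits, path) {
  stopifnot(nrow(records) == nrow(traits))
  col_map <- attr(records, "col_map")
  out <- tibble::tibble(.rows = nrow(records))
  if (!is.null(col_map)) {
    for (h in names(col_map)) {
      src <- if (is.na(col_map[[h]])) h else col_map[[h]]
      out[[h]] <- records[[src]]
    }
  } else {
    for (col in names(CANONICAL_COLS)) {
      out[[CANONICAL_COLS[[col]]]] <- records[[col]]
    }
    for (extra in setdiff(names(records), names(CANONICAL_COLS))) {
      out[[extra]] <- records[[extra]]
    }
  }
  out$hasLength <- fmt_bool(traits$hasLength)
  out$hasMass <- fmt_bool(traits$hasMass)
  out$hasSex <- fmt_bool(traits$hasSex)
  out$hasLifeStage <- fmt_bool(traits$hasLifeStage)
  out$lengthInMM <- fmt_num(traits$lengthInMM)
  out$massInG <- fmt_num(traits$massInG)
  out$wereLengthUnitsInferred <- fmt_bool(traits$wereLengthUnitsInferred)
  out$wereMassUnitsInferred <- fmt_bool(traits$wereMassUnitsInferred)
  out$derivedSex <- traits$derivedSex
  out$derivedLifeStage <- traits$derivedLifeStage
  out$lengthType <- ifelse(is.na(traits$lengthType), "", traits$lengthType)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a harmonized CSV back into records + traits
#'
#' Inverse of [write_harmonized()]: splits off the harmonized trait columns
#' (parsing booleans and numerics) and returns the remaining columns as an
#' occurrence-record tibble. `read_harmonized` then `write_harmonized` is
#' the identity on the file.
#'
#' @param path CSV written by [write_harmonized()].
#' @return A list with elements `records` and `traits`.
#' @export
read_harmonized <- function(path) {
  all <- read_occurrences(path, dialect = "csv")
  missing <- setdiff(HARMONIZED_COLS, names(all))
  if (length(missing)) {
    stop("not a harmonized CSV; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_or_na <- function(x) suppressWarnings(
    ifelse(nzchar(x), as.numeric(x), NA_real_))
  traits <- tibble::tibble(
    hasLength = all$hasLength == "true",
    hasMass = all$hasMass == "true",
    hasSex = all$hasSex == "true",
    hasLifeStage = all$hasLifeStage == "true",
    lengthInMM = num_or_na(all$lengthInMM),
    massInG = num_or_na(all$massInG),
    wereLengthUnitsInferred = all$wereLengthUnitsInferred == "true",
    wereMassUnitsInferred = all$wereMassUnitsInferred == "true",
    derivedSex = all$derivedSex,
    derivedLifeStage = all$derivedLifeStage,
    lengthType = ifelse(nzchar(all$lengthType), all$lengthType, NA_character_)
  )
  records <- all[, setdiff(names(all), HARMONIZED_COLS), drop = FALSE]
  col_map <- attr(all, "col_map")
  attr(records, "col_map") <- col_map[!names(col_map) %in% HARMONIZED_COLS]
  list(records = records, traits = traits)
}
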