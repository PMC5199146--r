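CLADES <- c("Fish", "Amphibia", "Reptilia", "Aves", "Mammalia",
            "Non_vertebrates", "Unknown")

# dwc:class values folded into the Fish bucket
FISH_CLASSES <- c(
  "actinopterygii", "cephalaspidomorphi", "chondrichthyes", "elasmobranchii",
  "holocephali", "leptocardii", "myxini", "petromyzonti", "sarcopterygii"
)

# illustrative, config-extensible: recognizable non-vertebrate classes
NONVERT_CLASSES <- c(
  "insecta", "arachnida", "malacostraca", "gastropoda", "bivalvia",
  "cephalopoda", "diplopoda", "chilopoda", "branchiopoda", "anthozoa",
  "polychaeta", "clitellata", "demospongiae", "echinoidea", "asteroidea",
  "holothuroidea", "ophiuroidea", "crinoidea", "hydrozoa", "scyphozoa"
)

# collection metadata tags that determine a clade when dwc:class is empty;
# herpetology is deliberately absent (it cannot separate Reptilia from
# Amphibia)
CONTEXT_CLADES <- c(
  ornithology = "Aves", birds = "Aves", bird = "Aves",
  mammalogy = "Mammalia", mammals = "Mammalia", mammal = "Mammalia",
  ichthyology = "Fish", fish = "Fish", fishes = "Fish"
)

#' Assign each record to a vertebrate clade bucket
#'
#' Maps `dwc:class` onto Fish (Actinopterygii, Cephalaspidomorphi,
#' Chondrichthyes, Elasmobranchii, Holocephali, Leptocardii, Myxini,
#' Petromyzonti, Sarcopterygii), Amphibia, Reptilia, Aves or Mammalia
#' (case-insensitive exact match). An empty class falls back to the
#' collection context tag (e.g. a record from an ornithology collection is
#' assigned to Aves); recognizable non-vertebrate classes map to
#' `Non_vertebrates`; anything else is `Unknown` (unrecognized non-empty
#' values are additionally reported via a message).
#'
#' @param records Occurrence-record tibble (or a one-row record).
#' @param nonvert_classes Extra class names (case-insensitive) to treat as
#'   non-vertebrate, beyond the built-in list.
#' @return Character vector of clade buckets, one per record.
#' @export
assign_clade <- function(records, nonvert_classes = character()) {
  cls <- tolower(trimws(records$taxon_class))
  ctx <- tolower(trimws(records$collection_context))
  out <- rep("Unknown", nrow(records))
  vert <- c(amphibia = "Amphibia", reptilia = "Reptilia", aves = "Aves",
            mammalia = "Mammalia")
  out[cls %in% FISH_CLASSES] <- "Fish"
  known <- cls %in% names(vert)
  out[known] <- vert[cls[known]]
  nonvert <- c(NONVERT_CLASSES, tolower(nonvert_classes))
  out[cls %in% nonvert] <- "Non_vertebrates"
  blank <- !nzchar(cls)
  ctx_known <- blank & ctx %in% names(CONTEXT_CLADES)
  out[ctx_known] <- CONTEXT_CLADES[ctx[ctx_known]]
  unrecognized <- unique(cls[!blank & out == "Unknown"])
  if (length(unrecognized)) {
    message("assign_clade: unrecognized class value(s): ",
            paste(utils::head(unrecognized, 10), collapse = ", "))
  }
  out
}

#' Derive a binomial species name from a record
#'
#' Rule (i): concatenate `dwc:genus` and `dwc:specificEpithet` when both are
#' non-empty; else rule (ii): the first two whitespace-separated words of
#' `dwc:scientificName` (punctuation retained); else absent (`NA`).
#'
#' @param records Occurrence-record tibble.
#' @return Character vector of species names (`NA` where underivable).
#' @export
#' @examples
#' recs <- occurrence_records("r1", genus = "Tamias",
#'                            specific_epithet = "minimus")
#' derive_species_name(recs)
derive_species_name <- function(records) {
  g <- trimws(records$genus)
  e <- trimws(records$specific_epithet)
  sn <- trimws(records$scientific_name)
  out <- rep(NA_character_, nrow(records))
  rule1 <- nzchar(g) & nzchar(e)
  out[rule1] <- paste(g[rule1], e[rule1])
  words <- stringr::str_split(sn, "\\s+")
  rule2 <- !rule1 & vapply(words, length, 0L) >= 2 & nzchar(sn)
  out[rule2] <- vapply(words[rule2],
                       function(w) paste(w[1:2], collapse = " "), "")
  out
}

#' Trait coverage by clade: species counts at record-count thresholds
#'
#' For each trait and clade, counts the distinct species names whose number
#' of records carrying that trait reaches each threshold: at least 1, more
#' than 10, more than 100 records. Records without a derivable species name
#' are ignored; a species split across clades (a data error upstream) is
#' counted in each clade independently. A `Total` row per trait sums the
#' clade counts.
#'
#' @param records Occurrence-record tibble.
#' @param traits Harmonized traits aligned with `records`.
#' @return A tibble with columns `clade`, `trait`, `n_species_min1`,
#'   `n_species_gt10`, `n_species_gt100`.
#' @export
summarize_coverage <- function(records, traits) {
  stopifnot(nrow(records) == nrow(traits))
  base <- tibble::tibble(
    clade = assign_clade(records),
    species = derive_species_name(records),
    length = traits$hasLength, mass = traits$hasMass,
    sex = traits$hasSex, `life stage` = traits$hasLifeStage
  )
  base <- base[!is.na(base$species), , drop = FALSE]
  out <- list()
  for (tt in VALIDATION_TRAITS) {
    tallies <- dplyr::count(base[base[[tt]], , drop = FALSE],
                            .data$clade, .data$species)
    per_clade <- dplyr::summarise(
      dplyr::group_by(tallies, .data$clade),
      n_species_min1 = sum(.data$n >= 1),
      n_species_gt10 = sum(.data$n > 10),
      n_species_gt100 = sum(.data$n > 100),
      .groups = "drop"
    )
    full <- tibble::tibble(clade = CLADES)
    full <- dplyr::left_join(full, per_clade, by = "clade")
    for (cc in c("n_species_min1", "n_species_gt10", "n_species_gt100")) {
      full[[cc]][is.na(full[[cc]])] <- 0L
    }
    total <- tibble::tibble(
      clade = "Total",
      n_species_min1 = sum(full$n_species_min1),
      n_species_gt10 = sum(full$n_species_gt10),
      n_species_gt100 = sum(full$n_species_gt100)
    )
    block <- dplyr::bind_rows(full, total)
    block$trait <- tt
    out[[tt]] <- block[, c("clade", "trait", "n_species_min1",
                           "n_species_gt10", "n_species_gt100")]
  }
  dplyr::bind_rows(out)
}
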