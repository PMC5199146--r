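# Small in-code fixtures shared across test files.

write_fixture_csv <- function(lines, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

# ten records, four of which carry free-text content (one of the empties
# uses "NULL", one "NA", one whitespace-only)
ten_record_fixture <- function() {
  occurrence_records(
    record_id = sprintf("r%02d", 1:10),
    dynamic_properties = c("total length: 100 mm", "", "NULL", "", "",
                           "weight: 5 g", "", "", "sex: male", ""),
    occurrence_remarks = c("", "", "", "NA", "", "", "", "", "", ""),
    field_notes = c("", "", "", "", "   ", "", "", "wt 5 g", "", "")
  )
}

# an unpacked Darwin Core Archive (meta.xml + occurrence core), written to
# a temp directory; returns the directory path
dwca_fixture_dir <- function(with_extension = FALSE) {
  dir <- tempfile("dwca_fix")
  dir.create(dir)
  ext_node <- if (with_extension) paste0(
    "<extension rowType=\"http://rs.gbif.org/terms/1.0/Multimedia\">",
    "<files><location>media.txt</location></files>",
    "<coreid index=\"0\"/></extension>") else ""
  writeLines(c(
    "<archive xmlns=\"http://rs.tdwg.org/dwc/text/\">",
    paste0("<core encoding=\"UTF-8\" fieldsTerminatedBy=\"\\t\" ",
           "linesTerminatedBy=\"\\n\" ignoreHeaderLines=\"1\" ",
           "rowType=\"http://rs.tdwg.org/dwc/terms/Occurrence\">"),
    "<files><location>occurrence.txt</location></files>",
    "<id index=\"0\"/>",
    "<field index=\"0\" term=\"http://rs.tdwg.org/dwc/terms/occurrenceID\"/>",
    "<field index=\"1\" term=\"http://rs.tdwg.org/dwc/terms/class\"/>",
    "<field index=\"2\" term=\"http://rs.tdwg.org/dwc/terms/dynamicProperties\"/>",
    "</core>", ext_node, "</archive>"
  ), file.path(dir, "meta.xml"))
  writeLines(c(
    "occurrenceID\tclass\tdynamicProperties",
    "occ-1\tMammalia\ttotal length: 120 mm",
    "occ-2\tAves\tsex: female"
  ), file.path(dir, "occurrence.txt"))
  if (with_extension) writeLines("occ-1\thttp://x", file.path(dir, "media.txt"))
  dir
}

clean_mix <- function() {
  style_mix(explicit_keyed = 1, abbreviated = 1, shorthand = 1, range = 1,
            imperial_units = 1)
}

# brute-force Matthews correlation: Pearson correlation of the two binary
# vectors the confusion matrix summarizes
mcc_bruteforce <- function(cm) {
  truth <- c(rep(1, cm$tp), rep(0, cm$fp), rep(1, cm$fn), rep(0, cm$tn))
  pred <- c(rep(1, cm$tp), rep(1, cm$fp), rep(0, cm$fn), rep(0, cm$tn))
  suppressWarnings(stats::cor(truth, pred))
}
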