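#' Zone label from sampling depth
#'
#' Samples at or below the boundary depth belong to the mesopelagic zone,
#' shallower samples to the productive zone. The operational boundary is
#' 200 m.
#'
#' @param depth depth in metres, positive downward; vectorised.
#' @param boundary zone boundary (m), default 200.
#' @return character vector, `"productive"` or `"mesopelagic"`.
#' @export
assign_zone <- function(depth, boundary = 200) {
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be >= 0")
  ifelse(depth >= boundary, "mesopelagic", "productive")
}

#' File and column layout of a cruise directory
#'
#' The deposited accession documents its column headers only in its
#' `README.txt`, so the reader is driven by a schema map instead of
#' hard-coded names: `files` maps table keys to CSV file names and
#' `columns` maps, per table, canonical column names to the names found in
#' the files. The defaults describe the layout written by [write_cruise()];
#' a map for the accession's own headers can be supplied without touching
#' the reader.
#'
#' @param files,columns named lists overriding individual entries of the
#'   default map.
#' @return a `poc_schema` list with `files` and `columns`.
#' @export
cruise_schema <- function(files = list(), columns = list()) {
  def_files <- list(
    standards = "Standards.csv",
    capsules = "Capsules.csv",
    nonacidified = "NonAcidifiedFilters.csv",
    acidified = "AcidifiedFilters.csv",
    upoc = "uPOCFilters.csv",
    adoc = "aDOCFilters.csv",
    dup_upoc = "DuplicateuPOC.csv",
    dup_adoc = "DuplicateaDOC.csv"
  )
  identity_map <- function(cols) stats::setNames(as.list(cols), cols)
  def_cols <- list(
    standards = identity_map(c("run", "type", "standard_id", "known_mass",
                               "response")),
    capsules = identity_map(c("run", "capsule_id", "response")),
    nonacidified = identity_map(c("run", "blank_id", "response")),
    acidified = identity_map(c("run", "desiccator", "blank_id", "response")),
    upoc = identity_map(c("sample_id", "station", "depth", "latitude",
                          "longitude", "datetime", "province", "cast", "run",
                          "desiccator", "volume", "n_bottles", "is_duplicate",
                          "response")),
    adoc = identity_map(c("sample_id", "station", "depth", "run",
                          "desiccator", "is_duplicate", "response"))
  )
  def_cols$dup_upoc <- def_cols$upoc
  def_cols$dup_adoc <- def_cols$adoc
  def_files[names(files)] <- files
  for (tab in names(columns)) {
    def_cols[[tab]][names(columns[[tab]])] <- columns[[tab]]
  }
  structure(list(files = def_files, columns = def_cols),
            class = "poc_schema")
}

#' Write a cruise dataset as a directory of CSV files
#'
#' Emits the same file layout as the deposited accession (standards,
#' capsules, blank filters, paired uPOC/aDOC filters, duplicates), plus --
#' for synthetic cruises -- `ground_truth.csv` and `ground_truth_runs.csv`,
#' which have no counterpart in real data. All files are RFC 4180 CSV with a
#' header row.
#'
#' @param cruise a cruise as returned by [generate_cruise()], or a bare list
#'   of tables.
#' @param dir output directory (created if needed).
#' @param schema a [cruise_schema()] supplying the file names.
#' @return `dir`, invisibly.
#' @export
write_cruise <- function(cruise, dir, schema = cruise_schema()) {
  tables <- if (!is.null(cruise$tables)) cruise$tables else cruise
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(schema$files)) {
    if (is.null(tables[[key]])) next
    utils::write.csv(tables[[key]], file.path(dir, schema$files[[key]]),
                     row.names = FALSE)
  }
  if (!is.null(cruise$truth)) {
    utils::write.csv(cruise$truth$samples, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(cruise$truth$runs,
                     file.path(dir, "ground_truth_runs.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read and link a cruise dataset from a directory of CSV files
#'
#' Loads the eight measurement tables, renames columns through the schema
#' map, checks that every uPOC record pairs with exactly one aDOC record
#' (and vice versa) sharing its run and desiccator, and links duplicate
#' records to their partner sample by station and depth.
#'
#' @param dir directory containing the CSV files.
#' @param schema a [cruise_schema()].
#' @return list of validated tables (same keys as the schema).
#' @export
read_cruise <- function(dir, schema = cruise_schema()) {
  tables <- lapply(names(schema$files), function(key) {
    path <- file.path(dir, schema$files[[key]])
    if (!file.exists(path)) {
      stop("required cruise file missing: ", schema$files[[key]])
    }
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    cmap <- schema$columns[[key]]
    missing_cols <- setdiff(unlist(cmap), names(raw))
    if (length(missing_cols)) {
      stop(schema$files[[key]], " lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    out <- raw[unlist(cmap)]
    names(out) <- names(cmap)
    out
  })
  names(tables) <- names(schema$files)

  for (key in c("standards", "capsules", "nonacidified", "acidified",
                "upoc", "adoc", "dup_upoc", "dup_adoc")) {
    bad <- !is.finite(tables[[key]]$response)
    if (any(bad)) {
      stop(schema$files[[key]], ": non-numeric response in row(s) ",
           paste(utils::head(which(bad), 10), collapse = ", "))
    }
  }
  for (key in c("upoc", "dup_upoc")) {
    bad <- !is.finite(tables[[key]]$volume) | tables[[key]]$volume <= 0
    if (any(bad)) {
      stop(schema$files[[key]], ": invalid volume in row(s) ",
           paste(utils::head(which(bad), 10), collapse = ", "))
    }
  }

  check_pairing(tables$upoc, tables$adoc, "uPOC/aDOC")
  check_pairing(tables$dup_upoc, tables$dup_adoc, "duplicate uPOC/aDOC")

  # every duplicate must trace to a partner sample at the same station/depth
  key_main <- paste(tables$upoc$station, tables$upoc$depth)
  key_dup <- paste(tables$dup_upoc$station, tables$dup_upoc$depth)
  orphan <- !(key_dup %in% key_main)
  if (any(orphan)) {
    stop("duplicate sample(s) without a partner at the same station/depth: ",
         paste(utils::head(tables$dup_upoc$sample_id[orphan], 10),
               collapse = ", "))
  }
  tables
}

check_pairing <- function(upoc, adoc, what) {
  if (nrow(upoc) != nrow(adoc)) {
    stop(what, ": ", nrow(upoc), " upper vs ", nrow(adoc), " lower filters")
  }
  idx <- match(upoc$sample_id, adoc$sample_id)
  if (anyNA(idx) || anyDuplicated(adoc$sample_id)) {
    missing_ids <- upoc$sample_id[is.na(idx)]
    stop(what, ": unpairable records: ",
         paste(utils::head(c(missing_ids,
                             adoc$sample_id[duplicated(adoc$sample_id)]), 10),
               collapse = ", "))
  }
  mismatch <- upoc$run != adoc$run[idx] |
    upoc$desiccator != adoc$desiccator[idx]
  if (any(mismatch)) {
    stop(what, ": paired filters with different run/desiccator: ",
         paste(utils::head(upoc$sample_id[mismatch], 10), collapse = ", "))
  }
  invisible(TRUE)
}
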