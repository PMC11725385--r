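# Readers and writers.  Everything tabular is TSV (tab-delimited, UTF-8,
# Unix newlines), samples as rows and variants as columns; the registry
# is JSON.  All writers emit a deterministic column order so identical
# inputs give byte-identical files.

.writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a variant count table from TSV
#'
#' Expected layout: first column `sample_id`, remaining columns one per
#' sequence variant, cells non-negative integers.  Non-integer cells,
#' duplicate sample or variant ids and ragged rows are rejected with a
#' message naming the offending row/column.
#'
#' @param path TSV file path.
#' @param metadataPath optional metadata TSV (see
#'   [readSampleMetadata()]) attached as `colData`.
#' @return A [VariantCountTable-class].
#' @export
readCountTable <- function(path, metadataPath = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id")
    .stopf("first column of '%s' must be 'sample_id'", path)
  ids <- df$sample_id
  if (anyDuplicated(ids))
    .stopf("duplicate sample id(s): %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vars <- names(df)[-1L]
  if (length(vars) == 0L) .stopf("no variant columns in '%s'", path)
  if (anyDuplicated(vars))
    .stopf("duplicate variant id(s): %s",
           paste(unique(vars[duplicated(vars)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), length(vars),
              dimnames = list(ids, vars))
  for (j in seq_along(vars)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | !is.finite(v) | v < 0 | abs(v - round(v)) > 0)
    if (length(bad))
      .stopf("non-integer count '%s' at row '%s', column '%s'",
             df[[j + 1L]][bad[1L]], ids[bad[1L]], vars[j])
    m[, j] <- v
  }
  md <- if (!is.null(metadataPath)) readSampleMetadata(metadataPath) else NULL
  VariantCountTable(m, sampleData = md)
}

#' Write a count table to TSV
#'
#' @param table a [VariantCountTable-class] or
#'   [CollapsedCountTable-class].
#' @param path output path.
#' @export
writeCountTable <- function(table, path) {
  m <- .asSampleMatrix(table)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

#' Read/write sample metadata
#'
#' Columns: `sample_id`, `stage`, `treatment`, `family`, `timepoint`.
#'
#' @param path TSV file path.
#' @return data.frame of metadata.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "treatment", "family")
  if (!all(need %in% names(df)))
    .stopf("metadata must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) .stopf("duplicate sample ids in metadata")
  df
}

#' @rdname readSampleMetadata
#' @param table a count table whose `colData` holds the metadata.
#' @export
writeSampleMetadata <- function(table, path) {
  cd <- as.data.frame(colData(table))
  df <- data.frame(sample_id = sampleIds(table), cd, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

#' Read a profile registry from JSON
#'
#' Schema:
#' `{"profiles":[{"name":"C15-C15dq","members":["C15","C15dq"]}],
#'   "background_read_threshold":200,"low_depth_threshold":1000}`.
#' Each profile's name must equal its members joined by `-`.
#'
#' @param path JSON file path.
#' @return A [ProfileRegistry-class].
#' @export
readRegistry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$profiles)) .stopf("registry JSON is missing 'profiles'")
  profiles <- lapply(j$profiles, function(p) {
    if (is.null(p$name) || is.null(p$members))
      .stopf("registry profile entries need 'name' and 'members'")
    members <- unlist(p$members)
    if (!identical(p$name, paste(members, collapse = "-")))
      .stopf("profile name '%s' does not match members [%s]",
             p$name, paste(members, collapse = ", "))
    DIVProfile(members)
  })
  ProfileRegistry(
    profiles,
    backgroundReadThreshold =
      if (is.null(j$background_read_threshold)) 200
      else j$background_read_threshold,
    lowDepthThreshold =
      if (is.null(j$low_depth_threshold)) 1000 else j$low_depth_threshold)
}

#' @rdname readRegistry
#' @param registry a [ProfileRegistry-class].
#' @export
writeRegistry <- function(registry, path) {
  x <- list(
    profiles = lapply(registry@profiles, function(p)
      list(name = p@name, members = as.list(p@members))),
    background_read_threshold = registry@backgroundReadThreshold,
    low_depth_threshold = registry@lowDepthThreshold)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read/write survival records
#'
#' Columns: `individual_id`, `stage`, `treatment`, `family`,
#' `time_days`, `event` (0/1).
#'
#' @param path TSV file path.
#' @return data.frame of survival records.
#' @export
readSurvivalRecords <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("individual_id", "stage", "treatment", "family", "time_days",
            "event")
  if (!all(need %in% names(df)))
    .stopf("survival records need columns %s", paste(need, collapse = ", "))
  if (!all(df$event %in% c(0L, 1L))) .stopf("event must be 0/1")
  if (any(df$time_days < 0)) .stopf("time_days must be >= 0")
  df
}

#' @rdname readSurvivalRecords
#' @param records survival records data.frame.
#' @export
writeSurvivalRecords <- function(records, path) .writeTsv(records, path)

#' Write a square distance matrix as TSV
#'
#' Header row and first column carry the sample ids.
#'
#' @param d a `dist` or symmetric matrix.
#' @param path output path.
#' @export
writeDistanceMatrix <- function(d, path) {
  D <- as.matrix(d)
  df <- data.frame(sample_id = rownames(D), D, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  D <- as.matrix(df[, -1L, drop = FALSE])
  rownames(D) <- df$sample_id
  if (!identical(rownames(D), colnames(D)))
    .stopf("distance matrix row/column ids disagree")
  stats::as.dist(D)
}

#' Write a Kaplan-Meier curve as TSV
#'
#' Columns: `time`, `n_risk`, `n_event`, `survival`.
#'
#' @param curve a [KMCurve-class].
#' @param path output path.
#' @export
writeKMCurve <- function(curve, path) {
  .writeTsv(data.frame(time = curve@time, n_risk = curve@nRisk,
                       n_event = curve@nEvent, survival = curve@surv),
            path)
}
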