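#' Read MS scan metadata from an mzML/mzXML file
#'
#' Extracts per-spectrum metadata — retention time, MS level, total ion
#' current and precursor charge — from an open-format raw file into a
#' [ScanTable-class]. All MS levels are kept; downstream filtering selects
#' the MS/MS scans. Retention times are converted to minutes on ingest
#' whatever unit the file records (the parsing layer resolves the unit
#' annotation). When a spectrum carries no total-ion-current attribute its
#' TIC is computed as the sum of its peak intensities; when it does carry
#' one, the instrument's recorded value wins. For chimeric spectra with
#' several precursors the first listed (selected) precursor's charge is used.
#' Vendor RAW files are not read; convert to mzML first.
#'
#' @param path path to an mzML or mzXML file.
#' @param runId run identifier; defaults to the file name without extension.
#' @return A [ScanTable-class] sorted by retention time.
#' @seealso [readScanTable()] for the canonical TSV interchange format.
#' @export
readMzML <- function(path, runId = sub("\\.(mzML|mzXML)$", "", basename(path),
                                       ignore.case = TRUE)) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("cannot parse '", path,
                                          "' as mzML/mzXML: ",
                                          conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(ms), add = TRUE)
  h <- tryCatch(mzR::header(ms),
                error = function(e) stop("cannot read spectra from '", path,
                                         "': ", conditionMessage(e),
                                         call. = FALSE))
  if (is.null(h) || nrow(h) == 0L)
    stop("'", path, "' contains no spectra", call. = FALSE)

  tic <- as.numeric(h$totIonCurrent)
  needs_sum <- which((is.na(tic) | tic <= 0) & h$peaksCount > 0L)
  for (j in needs_sum) {
    pk <- mzR::peaks(ms, j)
    tic[j] <- sum(pk[, 2L])
  }
  tic[is.na(tic)] <- 0

  charge <- as.integer(h$precursorCharge)
  charge[!is.na(charge) & charge < 1L] <- NA_integer_
  charge[h$msLevel < 2L] <- NA_integer_

  scan_id <- as.character(h$spectrumId)
  if (!length(scan_id) || anyNA(scan_id) || !any(nzchar(scan_id)))
    scan_id <- sprintf("scan=%d", h$acquisitionNum)

  ScanTable(data.frame(scan_id = scan_id,
                       rt = as.numeric(h$retentionTime) / 60,
                       ms_level = as.integer(h$msLevel),
                       tic = tic,
                       precursor_charge = charge,
                       stringsAsFactors = FALSE),
            runId = runId)
}

.scan_table_header <- c("scan_id", "rt_min", "ms_level", "tic",
                        "precursor_charge")

#' Read and write the canonical scan-table format
#'
#' The canonical interchange format for scan metadata is a UTF-8
#' tab-separated file with header
#' `scan_id<TAB>rt_min<TAB>ms_level<TAB>tic<TAB>precursor_charge`, one row per
#' scan, an empty `precursor_charge` field meaning unknown. It makes every
#' pipeline stage testable without an mzML file, and `readMzML()` followed by
#' `writeScanTable()` exports any run into it. Writing then reading a table
#' restores it field-for-field (retention times to well below 1e-9 min); rows
#' are re-sorted by retention time on read.
#'
#' @param path path to a scan-table TSV.
#' @param runId run identifier; defaults to the file name without extension.
#' @return `readScanTable()` returns a [ScanTable-class]; `writeScanTable()`
#'   invisibly returns `path`.
#' @export
readScanTable <- function(path, runId = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  cls <- if ("precursor_charge" %in% hdr)
    c(precursor_charge = "character") else NA
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = cls)
  missing_cols <- setdiff(.scan_table_header, names(df))
  if (length(missing_cols))
    stop("scan table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(is.na(df$rt_min) | df$rt_min < 0 | is.na(df$tic) | df$tic < 0)
  if (length(bad))
    stop("scan table ", path, " has negative or missing rt/tic at row ",
         bad[1L], call. = FALSE)
  charge <- suppressWarnings(as.integer(df$precursor_charge))
  charge[!nzchar(trimws(df$precursor_charge))] <- NA_integer_
  ScanTable(data.frame(scan_id = as.character(df$scan_id),
                       rt = df$rt_min,
                       ms_level = df$ms_level,
                       tic = df$tic,
                       precursor_charge = charge,
                       stringsAsFactors = FALSE),
            runId = runId)
}

#' @rdname readScanTable
#' @param table a [ScanTable-class].
#' @export
writeScanTable <- function(table, path) {
  stopifnot(is(table, "ScanTable"))
  sc <- scans(table)
  out <- data.frame(scan_id = sc$scan_id,
                    rt_min = sprintf("%.15g", sc$rt),
                    ms_level = sc$ms_level,
                    tic = sprintf("%.15g", sc$tic),
                    precursor_charge = ifelse(is.na(sc$precursor_charge), "",
                                              as.character(sc$precursor_charge)),
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.scan_table_header, collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}
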