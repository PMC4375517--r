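#' Describe a synthetic LC-MS/MS run
#'
#' Builds a [SyntheticRunSpec-class] emulating the scan-level structure the
#' optimizer consumes: retention times with a controllable skew (fractionated
#' samples often elute predominantly early or late because peptide-level
#' pre-fractionation is not orthogonal to reversed-phase separation), TICs
#' from a two-component lognormal mixture in which an "identifiable"
#' high-TIC component sits well above a low-TIC noise component, and a
#' realistic tryptic precursor charge mix, drawn independently of retention
#' time and TIC.
#'
#' Retention-time presets: `"uniform"`; `"early"` (beta(2, 5) over the run,
#' a hydrophilic-biased fraction); `"late"` (beta(5, 2), hydrophobic-biased);
#' `"bimodal"` (equal mixture of beta(8, 2) and beta(2, 8)).
#'
#' @param nScans number of MS/MS scans.
#' @param runLength run duration in minutes. Default 60, a common analytical
#'   gradient length.
#' @param rtPreset one of `"uniform"`, `"early"`, `"late"`, `"bimodal"`;
#'   ignored when `rtDistribution` is given.
#' @param rtDistribution explicit distribution list, see
#'   [SyntheticRunSpec-class].
#' @param ticModel list overriding any of `pId`, `meanlogHigh`, `sdlogHigh`,
#'   `meanlogLow`, `sdlogLow`. Defaults: half the scans identifiable
#'   (`pId = 0.5`), high component lognormal(log 1e7, 0.6), low component
#'   lognormal(log 1e5, 0.6) — two orders of magnitude apart, so the TIC
#'   filter recovers the identifiable component almost perfectly.
#' @param chargeProbs named probabilities over `c("1","2","3","4","unknown")`.
#'   Default `c(0.15, 0.50, 0.25, 0.05, 0.05)`, a typical tryptic mix.
#' @param nMs1 number of evenly spaced MS1 survey scans to interleave
#'   (default 0).
#' @param seed RNG seed.
#' @return A [SyntheticRunSpec-class].
#' @export
syntheticRunSpec <- function(nScans = 1000L, runLength = 60,
                             rtPreset = c("uniform", "early", "late",
                                          "bimodal"),
                             rtDistribution = NULL, ticModel = list(),
                             chargeProbs = c("1" = 0.15, "2" = 0.50,
                                             "3" = 0.25, "4" = 0.05,
                                             "unknown" = 0.05),
                             nMs1 = 0L, seed = 1L) {
  if (is.null(rtDistribution)) {
    rtDistribution <- switch(match.arg(rtPreset),
      uniform = list(kind = "uniform"),
      early = list(kind = "beta", shape1 = 2, shape2 = 5),
      late = list(kind = "beta", shape1 = 5, shape2 = 2),
      bimodal = list(kind = "mixture", shape1 = 8, shape2 = 2,
                     shape3 = 2, shape4 = 8, p = 0.5))
  }
  tm <- utils::modifyList(list(pId = 0.5, meanlogHigh = log(1e7),
                               sdlogHigh = 0.6, meanlogLow = log(1e5),
                               sdlogLow = 0.6), ticModel)
  new("SyntheticRunSpec", nScans = as.integer(nScans),
      runLength = as.numeric(runLength), rtDistribution = rtDistribution,
      ticModel = tm, chargeProbs = chargeProbs, nMs1 = as.integer(nMs1),
      seed = as.integer(seed))
}

#' Generate a synthetic run
#'
#' Deterministic given the seed in the run specification (the caller's RNG
#' state is left
#' untouched). The generated table's `metadata$ticComponent` records, per
#' scan id, whether each MS/MS scan's TIC was drawn from the `"high"`
#' (identifiable) or `"low"` (noise) component, so tests can check what the
#' TIC filter recovered.
#'
#' @param spec a [SyntheticRunSpec-class].
#' @return A [ScanTable-class].
#' @export
generateRun <- function(spec) {
  stopifnot(is(spec, "SyntheticRunSpec"))
  validObject(spec)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec@seed)
  n <- spec@nScans
  rd <- spec@rtDistribution
  u <- switch(rd$kind,
    uniform = stats::runif(n),
    beta = stats::rbeta(n, rd$shape1, rd$shape2),
    mixture = {
      pick <- stats::runif(n) < rd$p
      ifelse(pick, stats::rbeta(n, rd$shape1, rd$shape2),
             stats::rbeta(n, rd$shape3, rd$shape4))
    })
  rt <- u * spec@runLength

  tm <- spec@ticModel
  high <- stats::runif(n) < tm$pId
  tic <- ifelse(high,
                stats::rlnorm(n, tm$meanlogHigh, tm$sdlogHigh),
                stats::rlnorm(n, tm$meanlogLow, tm$sdlogLow))

  lv <- c("1", "2", "3", "4", "unknown")
  ch_lab <- sample(lv, n, replace = TRUE, prob = spec@chargeProbs[lv])
  charge <- suppressWarnings(as.integer(ch_lab))

  df <- data.frame(rt = rt, ms_level = 2L, tic = tic,
                   precursor_charge = charge, component = ifelse(high, "high", "low"),
                   stringsAsFactors = FALSE)
  if (spec@nMs1 > 0L) {
    ms1_rt <- seq(0, spec@runLength, length.out = spec@nMs1 + 2L)
    ms1_rt <- ms1_rt[-c(1L, length(ms1_rt))]
    df <- rbind(df, data.frame(rt = ms1_rt, ms_level = 1L,
                               tic = stats::rlnorm(spec@nMs1,
                                                   tm$meanlogHigh + 1, 0.3),
                               precursor_charge = NA_integer_,
                               component = "ms1",
                               stringsAsFactors = FALSE))
  }
  df <- df[order(df$rt), , drop = FALSE]
  df$scan_id <- sprintf("scan=%d", seq_len(nrow(df)))
  comp <- stats::setNames(df$component, df$scan_id)
  ScanTable(df[.scan_cols], runId = sprintf("synthetic-seed%d", spec@seed),
            runLength = spec@runLength,
            metadata = list(ticComponent = comp, spec = spec))
}

## ---- minimal mzML fixture writer ----

.b64_doubles <- function(x)
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))

.mzml_binary_array <- function(x, accession, name, unit) {
  enc <- .b64_doubles(x)
  sprintf(paste0(
    '<binaryDataArray encodedLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="MS" accession="%s" name="%s" %s/>',
    '<binary>%s</binary></binaryDataArray>'),
    nchar(enc), accession, name, unit, enc)
}

.mzml_spectrum <- function(idx, id, rt_sec, ms_level, tic, charge, mz, inten) {
  tic_param <- if (!is.na(tic))
    sprintf('<cvParam cvRef="MS" accession="MS:1000285" name="total ion current" value="%.12g"/>', tic)
  else ""
  prec <- ""
  if (ms_level >= 2L) {
    ch <- if (!is.na(charge))
      sprintf('<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>', charge)
    else ""
    prec <- paste0(
      '<precursorList count="1"><precursor><selectedIonList count="1">',
      '<selectedIon><cvParam cvRef="MS" accession="MS:1000744" ',
      'name="selected ion m/z" value="500.25" unitCvRef="MS" ',
      'unitAccession="MS:1000040" unitName="m/z"/>', ch,
      '</selectedIon></selectedIonList><activation>',
      '<cvParam cvRef="MS" accession="MS:1000422" ',
      'name="beam-type collision-induced dissociation"/>',
      '</activation></precursor></precursorList>')
  }
  level_param <- if (ms_level == 1L)
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum"/>'
  paste0(
    sprintf('<spectrum index="%d" id="%s" defaultArrayLength="%d">',
            idx, id, length(mz)),
    sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
            ms_level),
    level_param,
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
    tic_param,
    '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination"/><scan>',
    sprintf('<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.12g" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>',
            rt_sec),
    '</scan></scanList>', prec,
    '<binaryDataArrayList count="2">',
    .mzml_binary_array(mz, "MS:1000514", "m/z array",
                       'unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"'),
    .mzml_binary_array(inten, "MS:1000515", "intensity array",
                       'unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"'),
    '</binaryDataArrayList></spectrum>')
}

#' Write a minimal mzML fixture for a scan table
#'
#' Serializes a [ScanTable-class] as a small, standards-conformant mzML 1.1
#' file carrying, per spectrum: scan start time (written in seconds, with the
#' unit annotation, so readers must perform the seconds-to-minutes
#' conversion), MS level, total ion current, and — for MS/MS scans with known
#' charge — a precursor record with the charge state. Unknown charges omit
#' the charge element; MS1 scans omit the precursor list. Reading the file
#' back with [readMzML()] reproduces the table.
#'
#' Scans listed in `omitTic` are written without the total-ion-current
#' attribute; instead they carry a small synthetic peak list whose
#' intensities sum to the scan's TIC, exercising readers' sum-of-peaks
#' fallback. `peakData` overrides the peak list of any scan.
#'
#' @param table a [ScanTable-class].
#' @param path output path.
#' @param omitTic character vector of `scan_id`s to write without a TIC
#'   attribute.
#' @param peakData named list (by `scan_id`) of two-column matrices
#'   (m/z, intensity).
#' @return Invisibly, `path`.
#' @export
writeFixtureMzML <- function(table, path, omitTic = character(),
                             peakData = list()) {
  stopifnot(is(table, "ScanTable"))
  sc <- scans(table)
  if (!nrow(sc)) stop("cannot write an empty scan table as mzML", call. = FALSE)
  unknown_ids <- setdiff(omitTic, sc$scan_id)
  if (length(unknown_ids))
    stop("omitTic names unknown scan_id(s): ",
         paste(unknown_ids, collapse = ", "), call. = FALSE)
  specs <- character(nrow(sc))
  for (j in seq_len(nrow(sc))) {
    id <- sc$scan_id[j]
    pk <- peakData[[id]]
    omit <- id %in% omitTic
    if (omit && is.null(pk)) {
      # fabricate a 3-peak list summing to the recorded TIC so the
      # sum-of-peaks fallback reproduces it
      inten <- sc$tic[j] * c(0.25, 0.25, 0.5)
      pk <- cbind(c(400.1, 500.2, 600.3), inten)
    }
    if (is.null(pk)) pk <- cbind(numeric(0), numeric(0))
    specs[j] <- .mzml_spectrum(j - 1L, id, sc$rt[j] * 60, sc$ms_level[j],
                               if (omit) NA_real_ else sc$tic[j],
                               sc$precursor_charge[j], pk[, 1L], pk[, 2L])
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="',
    runId(table), '">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" version="09:04:2014" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum"/></fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="msgrad fixture writer"/></software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model"/></instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/></processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="', runId(table), '" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="', nrow(sc), '" defaultDataProcessingRef="dp">\n',
    paste(specs, collapse = "\n"),
    '\n</spectrumList>\n</run>\n</mzML>\n')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(doc, con, eos = NULL)
  invisible(path)
}
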