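# Format readers and writers.
#
# Spectra enter either as standard mzXML (read through mzR) or as the
# simplified peak-list TSV dialect used for fixtures: UTF-8,
# tab-separated, '.' decimal, mandatory header row with columns
# scan_id, rt_s, mz, intensity. Retention times are seconds everywhere.

#' MS1 spectra container
#'
#' @param scans list of scans, each a list with `rt_s` (seconds), `mz`
#'   and `intensity` (parallel numeric vectors of centroid peaks). Scans
#'   are sorted by retention time.
#' @return An `ms1_spectra` object.
#' @export
ms1_spectra <- function(scans) {
  rts <- vapply(scans, function(s) s$rt_s, numeric(1))
  structure(list(scans = scans[order(rts)]), class = "ms1_spectra")
}

#' @export
print.ms1_spectra <- function(x, ...) {
  rts <- vapply(x$scans, function(s) s$rt_s, numeric(1))
  npk <- sum(vapply(x$scans, function(s) length(s$mz), numeric(1)))
  cat(
    "<MS1 spectra> ", length(x$scans), " scans, ", npk, " peaks, rt ",
    min(rts), "-", max(rts), " s\n", sep = ""
  )
  invisible(x)
}

#' Read a peak-list TSV into MS1 spectra
#'
#' @param path TSV file with columns `scan_id`, `rt_s`, `mz`, `intensity`.
#' @return An `ms1_spectra` object.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("peak-list file not found: ", path)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("scan_id", "rt_s", "mz", "intensity")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("peak list lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  scans <- lapply(split(d, d$scan_id), function(s) {
    o <- order(s$mz)
    list(rt_s = s$rt_s[1L], mz = s$mz[o], intensity = s$intensity[o])
  })
  ms1_spectra(unname(scans))
}

#' Write MS1 spectra as a peak-list TSV
#'
#' @param spectra an `ms1_spectra` object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_peaklist <- function(spectra, path) {
  stopifnot(inherits(spectra, "ms1_spectra"))
  rows <- lapply(seq_along(spectra$scans), function(i) {
    s <- spectra$scans[[i]]
    if (!length(s$mz)) {
      return(NULL)
    }
    data.frame(
      scan_id = i, rt_s = s$rt_s, mz = s$mz, intensity = s$intensity
    )
  })
  d <- do.call(rbind, rows)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read MS1 scans from an mzXML file
#'
#' Uses mzR to parse the file; MS2 (and higher-level) scans are skipped
#' with a message reporting the count. Retention times are normalized to
#' seconds.
#'
#' @param path mzXML file.
#' @return An `ms1_spectra` object.
#' @export
read_mzxml <- function(path) {
  if (!file.exists(path)) stop("mzXML file not found: ", path)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (!nrow(hdr)) stop("no scans found in ", path)
  is_ms1 <- hdr$msLevel == 1L
  n_skipped <- sum(!is_ms1)
  if (n_skipped > 0) {
    message("read_mzxml: skipped ", n_skipped, " non-MS1 scan(s)")
  }
  idx <- which(is_ms1)
  scans <- lapply(idx, function(i) {
    pk <- mzR::peaks(handle, i)
    list(
      rt_s = hdr$retentionTime[i],
      mz = pk[, 1L],
      intensity = pk[, 2L]
    )
  })
  ms1_spectra(scans)
}

#' Write MS1 spectra as mzXML
#'
#' Minimal mzXML 3.2 serializer (centroided MS1 scans; peaks encoded as
#' base64 network-order 64-bit m/z-intensity pairs), sufficient for the
#' standard reader path and round-trip tested against mzR.
#'
#' @param spectra an `ms1_spectra` object. Scans may carry an optional
#'   `ms_level` field (default 1).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_mzxml <- function(spectra, path) {
  stopifnot(inherits(spectra, "ms1_spectra"))
  con <- file(path, "w")
  on.exit(close(con))
  scans <- spectra$scans
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"ISO-8859-1\"?>",
    "<mzXML xmlns=\"http://sashimi.sourceforge.net/schema_revision/mzXML_3.2\">",
    sprintf(" <msRun scanCount=\"%d\">", length(scans))
  ), con)
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    lvl <- if (!is.null(s$ms_level)) s$ms_level else 1L
    n <- length(s$mz)
    b64 <- if (n) {
      jsonlite::base64_enc(writeBin(
        as.numeric(as.vector(rbind(s$mz, s$intensity))),
        raw(), size = 8, endian = "big"
      ))
    } else {
      ""
    }
    writeLines(sprintf(
      paste0(
        "  <scan num=\"%d\" msLevel=\"%d\" peaksCount=\"%d\"",
        " retentionTime=\"PT%.4fS\" lowMz=\"%.4f\" highMz=\"%.4f\">"
      ),
      i, lvl, n,
      s$rt_s,
      if (n) min(s$mz) else 0,
      if (n) max(s$mz) else 0
    ), con)
    writeLines(sprintf(
      paste0(
        "   <peaks precision=\"64\" byteOrder=\"network\"",
        " contentType=\"m/z-int\" compressionType=\"none\"",
        " compressedLen=\"0\">%s</peaks>"
      ), b64
    ), con)
    writeLines("  </scan>", con)
  }
  writeLines(c(" </msRun>", "</mzXML>"), con)
  invisible(path)
}

#' Read and validate a peptide identification table
#'
#' TSV with columns `protein_id`, `sequence`, `charge`, `mono_mz`, `rt_s`,
#' `time_point_h`. Each record's observed monoisotopic m/z is
#' cross-checked against the sequence-derived value; records off by more
#' than `mz_tol` are excluded (never silently repaired) and reported.
#'
#' @param path TSV file.
#' @param mz_tol maximum allowed |observed - computed| m/z (default 0.05).
#' @param const constants from [isotope_constants()].
#' @return data.frame of accepted records; excluded records (with a
#'   `reason` column) are attached as `attr(, "excluded")`.
#' @export
read_peptide_ids <- function(path, mz_tol = 0.05,
                             const = isotope_constants()) {
  if (!file.exists(path)) stop("peptide ID file not found: ", path)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("protein_id", "sequence", "charge", "mono_mz", "rt_s", "time_point_h")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("peptide ID table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(d)) {
    warning("peptide ID table is empty")
    attr(d, "excluded") <- d
    return(d)
  }
  reason <- character(nrow(d))
  for (i in seq_len(nrow(d))) {
    expected <- tryCatch(
      mz_for_charge(
        composition_from_sequence(d$sequence[i], const),
        d$charge[i], const
      ),
      error = function(e) NA_real_
    )
    if (is.na(expected)) {
      reason[i] <- "invalid_sequence_or_charge"
    } else if (abs(d$mono_mz[i] - expected) > mz_tol) {
      reason[i] <- sprintf(
        "mz_mismatch: observed %.4f vs computed %.4f",
        d$mono_mz[i], expected
      )
    }
  }
  bad <- nzchar(reason)
  if (any(bad)) {
    for (i in which(bad)) {
      message(
        "read_peptide_ids: excluded ", d$sequence[i], " (", reason[i], ")"
      )
    }
  }
  excluded <- d[bad, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[bad]
  out <- d[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Read a GC-MS mass-isotopomer abundance table
#'
#' CSV with columns `analyte`, `fragment_formula`, `n_labeled`, `time_h`,
#' `replicate`, and fractional abundance columns `m0`, `m1`, ...
#'
#' @param path CSV file.
#' @return data.frame suitable for [aa_turnover()].
#' @export
read_gcms_table <- function(path) {
  if (!file.exists(path)) stop("GC-MS table not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("analyte", "fragment_formula", "n_labeled", "time_h")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("GC-MS table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!any(grepl("^m[0-9]+$", names(d)))) {
    stop("GC-MS table has no abundance columns (m0, m1, ...)")
  }
  d
}

#' Write a result table with a provenance header
#'
#' Prepends comment lines recording the package version, the RNG seed and
#' a hash of the run configuration, then the TSV body.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed RNG seed used for the run (recorded in the header).
#' @param params named list of run parameters (hashed into the header).
#' @return The path, invisibly.
#' @export
write_result_tsv <- function(df, path, seed = NA, params = list()) {
  cfg <- paste(names(params), unlist(params), sep = "=", collapse = ";")
  tmp <- tempfile()
  writeLines(cfg, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# isochase ", as.character(utils::packageVersion("isochase"))),
    paste0("# seed: ", seed),
    paste0("# config: ", cfg),
    paste0("# config_md5: ", cfg_hash)
  ), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
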