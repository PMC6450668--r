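## On-disk dialects (plain text, diffable):
##  - photon table: TSV `timestamp_ticks  detector{D,A}  excitation{Dex,Aex}`
##    preceded by `# key value` header lines (tick_seconds,
##    alternation_period_us, duration_s).
##  - traces: CSV `molecule_id,bin_index,donor_counts,acceptor_counts` with a
##    `# bin_width_ms` header line.
##  - instrument config: flat YAML.

#' Read a photon stream from a TSV photon table
#'
#' The table has one row per photon (columns \code{timestamp_ticks},
#' \code{detector}, \code{excitation}) and \verb{#}-prefixed header lines
#' carrying \code{tick_seconds}, \code{alternation_period_us} and
#' \code{duration_s}. The excitation column may be omitted, in which case
#' labels are assigned from the alternation schedule.
#'
#' @param path file path.
#' @return a [PhotonStream-class].
#' @seealso [writePhotonStream()]
#' @export
readPhotonStream <- function(path) {
  if (!file.exists(path)) stop("photon table not found: ", path)
  hdr <- readHeaderKeys(path)
  for (key in c("tick_seconds", "alternation_period_us", "duration_s"))
    if (is.null(hdr[[key]]))
      stop("photon table header missing key '", key, "' in ", path)
  dat <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      colClasses = "character"),
    error = function(e) stop("malformed photon table ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dat) == 0L) {
    return(PhotonStream(numeric(0), character(0), character(0),
                        tickSeconds = as.numeric(hdr$tick_seconds),
                        alternationPeriodUs = as.numeric(hdr$alternation_period_us),
                        durationS = as.numeric(hdr$duration_s)))
  }
  if (!all(c("timestamp_ticks", "detector") %in% names(dat)))
    stop("photon table ", path,
         " must have columns timestamp_ticks and detector")
  ts <- suppressWarnings(as.numeric(dat$timestamp_ticks))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("non-numeric timestamp at data row ", bad, " of ", path)
  }
  if (is.unsorted(ts))
    stop("decreasing timestamps in ", path, " (first at data row ",
         which(diff(ts) < 0)[1] + 1, ")")
  det <- dat$detector
  if (!all(det %in% c("D", "A"))) {
    bad <- which(!det %in% c("D", "A"))[1]
    stop("invalid detector label '", det[bad], "' at data row ", bad,
         " of ", path)
  }
  exc <- if ("excitation" %in% names(dat)) dat$excitation else NULL
  PhotonStream(ts, det, exc,
               tickSeconds = as.numeric(hdr$tick_seconds),
               alternationPeriodUs = as.numeric(hdr$alternation_period_us),
               durationS = as.numeric(hdr$duration_s))
}

#' Write a photon stream as a TSV photon table
#'
#' Round-trips exactly: \code{readPhotonStream(writePhotonStream(s, f))}
#' reproduces \code{s} bit for bit (timestamps are integer ticks).
#'
#' @param stream a [PhotonStream-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePhotonStream <- function(stream, path) {
  stopifnot(is(stream, "PhotonStream"))
  validObject(stream)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    sprintf("# tick_seconds %.17g", stream@tickSeconds),
    sprintf("# alternation_period_us %.17g", stream@alternationPeriodUs),
    sprintf("# duration_s %.17g", stream@durationS),
    "timestamp_ticks\tdetector\texcitation"), con)
  if (length(stream@timestamps)) {
    writeLines(paste(format(stream@timestamps, scientific = FALSE, trim = TRUE),
                     stream@detector, stream@excitation, sep = "\t"), con)
  }
  invisible(path)
}

#' Read binned two-color traces from a trace CSV
#'
#' Rows carry \code{molecule_id,bin_index,donor_counts,acceptor_counts}; a
#' \verb{# bin_width_ms} header line gives the bin width. Rows are grouped by
#' \code{molecule_id} (bin order taken from \code{bin_index}) into one
#' [FretTrace-class] per molecule.
#'
#' @param path file path.
#' @return a list of [FretTrace-class] objects, named by molecule id.
#' @seealso [writeTraces()]
#' @export
readTraces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  hdr <- readHeaderKeys(path)
  if (is.null(hdr$bin_width_ms))
    stop("trace file header missing key 'bin_width_ms' in ", path)
  binMs <- as.numeric(hdr$bin_width_ms)
  dat <- tryCatch(
    utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
                      colClasses = c("character", "numeric", "numeric", "numeric")),
    error = function(e) stop("malformed trace file ", path, ": ",
                             conditionMessage(e)))
  need <- c("molecule_id", "bin_index", "donor_counts", "acceptor_counts")
  if (!all(need %in% names(dat)))
    stop("trace file ", path, " must have columns ",
         paste(need, collapse = ", "))
  if (any(dat$donor_counts < 0) || any(dat$acceptor_counts < 0))
    stop("negative count at data row ",
         which(dat$donor_counts < 0 | dat$acceptor_counts < 0)[1],
         " of ", path)
  ids <- unique(dat$molecule_id)
  out <- lapply(ids, function(id) {
    sub <- dat[dat$molecule_id == id, , drop = FALSE]
    sub <- sub[order(sub$bin_index), , drop = FALSE]
    if (!identical(as.numeric(sub$bin_index), as.numeric(seq_len(nrow(sub)) - 1)))
      stop("molecule '", id, "' in ", path,
           " has missing or duplicated bin indices")
    FretTrace(sub$donor_counts, sub$acceptor_counts, binWidthMs = binMs,
              moleculeId = id)
  })
  names(out) <- ids
  out
}

#' Write traces to a trace CSV
#'
#' @param traces list of [FretTrace-class] (equal bin widths).
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTraces <- function(traces, path) {
  stopifnot(length(traces) > 0, all(vapply(traces, is, TRUE, "FretTrace")))
  binMs <- unique(vapply(traces, binWidth, 0))
  if (length(binMs) != 1L)
    stop("all traces in one file must share a bin width")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(sprintf("# bin_width_ms %.17g", binMs),
               "molecule_id,bin_index,donor_counts,acceptor_counts"), con)
  for (tr in traces) {
    n <- nBins(tr)
    writeLines(paste(tr@moleculeId, seq_len(n) - 1,
                     format(tr@donorCounts, scientific = FALSE, trim = TRUE),
                     format(tr@acceptorCounts, scientific = FALSE, trim = TRUE),
                     sep = ","), con)
  }
  invisible(path)
}

#' Read / write an InstrumentConfig as flat YAML
#'
#' Keys: \code{alternation_period_us}, \code{bg_dd_khz}, \code{bg_da_khz},
#' \code{bg_aa_khz}, \code{leakage}, \code{direct_excitation}, \code{gamma},
#' \code{r0_nm}.
#'
#' @param path file path.
#' @return [readInstrumentConfig()]: an [InstrumentConfig-class];
#'   [writeInstrumentConfig()]: invisibly, \code{path}.
#' @export
readInstrumentConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("alternation_period_us", "bg_dd_khz", "bg_da_khz", "bg_aa_khz",
            "leakage", "direct_excitation", "gamma", "r0_nm")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop("config ", path, " missing keys: ", paste(missing, collapse = ", "))
  instrumentConfig(
    alternationPeriodUs = y$alternation_period_us,
    bgDD = y$bg_dd_khz, bgDA = y$bg_da_khz, bgAA = y$bg_aa_khz,
    leakage = y$leakage, directExcitation = y$direct_excitation,
    gamma = y$gamma, r0Nm = y$r0_nm)
}

#' @rdname readInstrumentConfig
#' @param cfg an [InstrumentConfig-class].
#' @export
writeInstrumentConfig <- function(cfg, path) {
  stopifnot(is(cfg, "InstrumentConfig"))
  validObject(cfg)
  yaml::write_yaml(list(
    alternation_period_us = cfg@alternationPeriodUs,
    bg_dd_khz = cfg@bgDD, bg_da_khz = cfg@bgDA, bg_aa_khz = cfg@bgAA,
    leakage = cfg@leakage, direct_excitation = cfg@directExcitation,
    gamma = cfg@gamma, r0_nm = cfg@r0Nm), path)
  invisible(path)
}

# `# key value` header lines at the top of a text file
readHeaderKeys <- function(path) {
  out <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    parts <- strsplit(sub("^#\\s*", "", line), "\\s+")[[1]]
    if (length(parts) >= 2L) out[[parts[1]]] <- parts[2]
  }
  out
}
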