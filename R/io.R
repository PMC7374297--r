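#' Read and write recordings
#'
#' Two on-disk forms are supported. The CSV dialect is a plain-text file
#' with header `ch1,ch2,ch3,ch4` and one sample per line (microvolts),
#' accompanied by a `<base>.fqrs.txt` file listing the 0-based fetal R-peak
#' sample indices one per line. The WFDB form covers the subset used by
#' PhysioNet non-invasive fECG records: a `.hea` header plus a format-16
#' (little-endian 16-bit) `.dat` signal file; annotations are read from the
#' same `<base>.fqrs.txt` sidecar.
#'
#' @name recording_io
NULL

ann_path_for <- function(base) paste0(base, ".fqrs.txt")

read_annotations <- function(path) {
  if (!file.exists(path)) return(integer())
  v <- scan(path, what = integer(), quiet = TRUE)
  sort(unique(as.integer(v)))
}

#' @rdname recording_io
#' @param rec An [recording()].
#' @param path Output path base; extensions are added per format.
#' @param format `"csv"` or `"wfdb"`.
#' @param gain Integer ADC units per microvolt for the WFDB form (format 16
#'   stores integers; larger gains keep more precision).
#' @return `write_recording` returns the paths written, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "wfdb"), gain = 10L) {
  stopifnot(inherits(rec, "octqrs_recording"))
  format <- match.arg(format)
  base <- sub("\\.(csv|hea|dat)$", "", path)
  if (format == "csv") {
    sig_path <- paste0(base, ".csv")
    df <- as.data.frame(rec$signals)
    names(df) <- paste0("ch", seq_len(ncol(df)))
    utils::write.csv(df, sig_path, row.names = FALSE)
    paths <- sig_path
  } else {
    hea_path <- paste0(base, ".hea")
    dat_path <- paste0(base, ".dat")
    nsig <- ncol(rec$signals)
    dat_name <- basename(dat_path)
    hdr <- c(
      sprintf("%s %d %d %d", basename(base), nsig, rec$sampling_rate,
              nrow(rec$signals)),
      vapply(seq_len(nsig), function(i)
        sprintf("%s 16 %d(0)/uV 16 0 0 0 0 ch%d", dat_name, gain, i),
        character(1)))
    writeLines(hdr, hea_path)
    dig <- round(rec$signals * gain)
    if (any(abs(dig) > 32767))
      abort("signal exceeds the 16-bit range at this gain; lower `gain`")
    con <- file(dat_path, "wb")
    on.exit(close(con))
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
    paths <- c(hea_path, dat_path)
  }
  ann <- ann_path_for(base)
  writeLines(as.character(rec$fqrs), ann)
  invisible(c(paths, ann))
}

#' @rdname recording_io
#' @param require_channels,require_rate Expected channel count and sampling
#'   rate; mismatches raise descriptive errors (`NULL` skips the check).
#' @export
read_recording_csv <- function(path, require_channels = 4L,
                               require_rate = 1000L) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  check_channels(ncol(df), require_channels, path)
  base <- sub("\\.csv$", "", path)
  recording(as.matrix(df), read_annotations(ann_path_for(base)),
            record_id = basename(base),
            sampling_rate = require_rate %||% 1000L)
}

check_channels <- function(got, want, path) {
  if (!is.null(want) && got != want)
    abort(sprintf("%s has %d channels but the detector requires %d abdominal channels",
                  path, got, want))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname recording_io
#' @export
read_wfdb_record <- function(path, require_channels = 4L,
                             require_rate = 1000L) {
  base <- sub("\\.hea$", "", path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) abort(sprintf("missing WFDB header: %s", hea_path))
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec_line <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec_line[2])
  fs <- if (length(rec_line) >= 3) as.numeric(sub("/.*", "", rec_line[3])) else 250
  nsamp <- if (length(rec_line) >= 4) as.integer(rec_line[4]) else NA_integer_
  check_channels(nsig, require_channels, hea_path)
  if (!is.null(require_rate) && fs != require_rate)
    abort(sprintf("%s is sampled at %g Hz but the detector requires %d Hz",
                  hea_path, fs, require_rate))
  sig_lines <- lapply(lines[1 + seq_len(nsig)],
                      function(l) strsplit(trimws(l), "\\s+")[[1]])
  fmts <- vapply(sig_lines, `[`, character(1), 2)
  if (!all(sub("x.*|:.*|\\+.*", "", fmts) == "16"))
    abort("only WFDB signal format 16 is supported")
  dat_file <- file.path(dirname(hea_path), sig_lines[[1]][1])
  if (!file.exists(dat_file)) abort(sprintf("missing WFDB signal file: %s", dat_file))
  parse_gain <- function(tok) {
    # gain token: gain(baseline)/units, all parts optional
    g <- sub("\\(.*", "", sub("/.*", "", tok))
    b <- if (grepl("\\(", tok)) sub(".*\\((-?[0-9]+)\\).*", "\\1", tok) else "0"
    u <- if (grepl("/", tok)) sub(".*/", "", tok) else "adu"
    gain <- as.numeric(g)
    list(gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = as.numeric(b), units = u)
  }
  cal <- lapply(sig_lines, function(sl) parse_gain(sl[3]))
  raw <- readBin(dat_file, "integer", n = file.size(dat_file) / 2L,
                 size = 2L, endian = "little")
  if (!is.na(nsamp) && length(raw) >= nsig * nsamp) raw <- raw[seq_len(nsig * nsamp)]
  mat <- matrix(as.numeric(raw), ncol = nsig, byrow = TRUE)
  for (i in seq_len(nsig)) {
    phys <- (mat[, i] - cal[[i]]$baseline) / cal[[i]]$gain
    if (identical(cal[[i]]$units, "mV")) phys <- phys * 1000
    mat[, i] <- phys
  }
  recording(mat, read_annotations(ann_path_for(base)),
            record_id = basename(base), sampling_rate = as.integer(fs))
}
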