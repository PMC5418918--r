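#' @title Trace and annotation I/O
#' @name ecg_io
#' @description
#' Two interchange formats: WFDB (the PhysioNet header/signal/annotation
#' layout the clinical records ship in; a minimal format-16 reader/writer
#' is built in since no WFDB package exists for R) and plain CSV for
#' synthetic fixtures. All readers convert to microvolts on load — WFDB
#' gains are ADC units per millivolt — so downstream amplitudes are
#' directly comparable across sources. Annotation sample indices are taken
#' as exact R-peak positions (reference markers are expert-verified; no
#' re-centering), converted to this package's 1-based indexing.
NULL

# ---- CSV ----

#' Read a single-column CSV as a Trace
#'
#' @param path CSV file; one header row, one or more numeric columns,
#'   values in microvolts.
#' @param fs sampling rate in Hz (CSV carries no rate).
#' @param column column name or index (default 1).
#' @return `Trace`.
#' @export
read_csv_trace <- function(path, fs, column = 1L) {
  if (!file.exists(path)) stop("read_csv_trace: no such file: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("read_csv_trace: cannot parse ", path,
                                          ": ", conditionMessage(e)))
  if (!nrow(df)) stop("read_csv_trace: ", path, " has no data rows")
  if (is.character(column) && !column %in% names(df))
    stop("read_csv_trace: no column '", column, "' in ", path)
  v <- df[[column]]
  if (is.null(v)) stop("read_csv_trace: no column ", column, " in ", path)
  num <- suppressWarnings(as.numeric(v))
  if (anyNA(num)) {
    bad <- which(is.na(num))[1L]
    stop("read_csv_trace: non-numeric value '", v[bad], "' at data row ", bad,
         " of ", path)
  }
  lab <- if (is.character(column)) column else names(df)[column]
  trace(num, fs, label = lab)
}

#' Write a Trace as a single-column CSV
#'
#' @param tr `Trace`; the column header is the trace label (or `"uv"`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_csv_trace <- function(tr, path) {
  stopifnot_trace(tr)
  lab <- if (nzchar(tr$label)) make.names(tr$label) else "uv"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lab, con)
  writeLines(sprintf("%.9f", tr$samples), con)
  invisible(path)
}

#' Write a decomposition as CSV components + JSON sidecar
#'
#' One CSV per component and a `decomposition.json` sidecar recording the
#' sampling rate, component names and lengths, and whether the components
#' still sum to the stored input within 1e-6 uV.
#'
#' @param decomp a `fecg_direct_decomp` or `fecg_abdominal_decomp`.
#' @param path output directory (created if needed).
#' @return named character vector of written files, invisibly.
#' @export
write_decomposition <- function(decomp, path) {
  if (inherits(decomp, "fecg_direct_decomp")) {
    comps <- c("input", "dfecg", "dn")
    recon <- decomp$dfecg$samples + decomp$dn$samples
  } else if (inherits(decomp, "fecg_abdominal_decomp")) {
    comps <- c("input", "mecg", "ifecg_noisy", "ifecg", "in_noise")
    recon <- decomp$mecg$samples + decomp$ifecg$samples + decomp$in_noise$samples
  } else stop("write_decomposition: not a decomposition object")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("write_decomposition: cannot create ", path)
  files <- character()
  for (nm in comps) {
    f <- file.path(path, paste0(nm, ".csv"))
    write_csv_trace(decomp[[nm]], f)
    files[nm] <- f
  }
  sidecar <- list(
    fs = decomp$input$fs,
    components = as.list(stats::setNames(
      vapply(comps, function(nm) length(decomp[[nm]]$samples), 0L), comps)),
    n = length(decomp$input$samples),
    conserved = max(abs(recon - decomp$input$samples)) <= 1e-6
  )
  jf <- file.path(path, "decomposition.json")
  jsonlite::write_json(sidecar, jf, auto_unbox = TRUE, digits = NA)
  files["sidecar"] <- jf
  invisible(files)
}

# ---- WFDB (minimal: format 16, one .dat per record, MIT annotations) ----

.parse_gain <- function(spec) {
  # "gain(baseline)/units", each part optional; defaults gain 200, baseline 0
  gain <- 200; baseline <- 0; units <- "mV"
  if (nzchar(spec)) {
    m <- regmatches(spec, regexec("^([-0-9.]+)?(\\(([-0-9]+)\\))?(/(\\S+))?$", spec))[[1]]
    if (length(m)) {
      if (nzchar(m[2])) gain <- as.numeric(m[2])
      if (nzchar(m[4])) baseline <- as.integer(m[4])
      if (nzchar(m[6])) units <- m[6]
    }
  }
  if (!is.finite(gain) || gain == 0) gain <- 200
  list(gain = gain, baseline = baseline, units = units)
}

#' Read a WFDB record (format 16) as a record set
#'
#' Reads `<path>.hea` and its signal file, converts every channel to
#' microvolts using the per-signal gain (ADC units per millivolt) and
#' baseline, and optionally reads an MIT-format annotation file whose
#' sample indices become the fetal R-peak series
#' (`source = "reference"`).
#'
#' @param path record path without extension.
#' @param annotation_extension annotation file extension (e.g. `"qrs"`),
#'   or `NULL` for none.
#' @param direct_channel index of the direct (scalp) channel among the
#'   signals, or `NA` if the record is abdominal-only. Default 1, the
#'   layout of the clinical database.
#' @return list with `direct` (`Trace` or `NULL`), `abdominal` (list of
#'   `Trace`s in source order), `fetal_rpeaks` (`RPeakSeries` or `NULL`),
#'   `metadata`.
#' @export
read_wfdb_record <- function(path, annotation_extension = NULL,
                             direct_channel = 1L) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("read_wfdb_record: missing header file ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_f <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  nsig <- as.integer(head_f[2L])
  fs <- if (length(head_f) >= 3L) as.numeric(head_f[3L]) else 250
  nsamp <- if (length(head_f) >= 4L) as.integer(head_f[4L]) else NA_integer_
  if (length(lines) < 1L + nsig)
    stop("read_wfdb_record: header ", hea, " declares ", nsig,
         " signals but lists fewer")
  sig <- lapply(lines[1L + seq_len(nsig)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  datf <- vapply(sig, `[`, "", 1L)
  if (length(unique(datf)) != 1L)
    stop("read_wfdb_record: multi-file records are not supported (", hea, ")")
  fmt <- vapply(sig, `[`, "", 2L)
  if (!all(fmt == "16"))
    stop("read_wfdb_record: only format 16 is supported, got ", paste(unique(fmt), collapse = ","))
  datpath <- file.path(dirname(path), datf[1L])
  if (!file.exists(datpath)) stop("read_wfdb_record: missing signal file ", datpath)
  raw <- readBin(datpath, "integer", n = file.size(datpath) %/% 2L,
                 size = 2L, signed = TRUE, endian = "little")
  if (length(raw) %% nsig != 0L)
    stop("read_wfdb_record: signal file ", datpath,
         " is not a whole number of ", nsig, "-sample frames")
  n <- length(raw) %/% nsig
  if (!is.na(nsamp) && nsamp != n)
    stop("read_wfdb_record: header declares ", nsamp, " samples but ",
         datpath, " holds ", n)
  mat <- matrix(raw, nrow = nsig)
  traces <- lapply(seq_len(nsig), function(j) {
    g <- .parse_gain(if (length(sig[[j]]) >= 3L) sig[[j]][3L] else "")
    desc <- if (length(sig[[j]]) >= 9L)
      paste(sig[[j]][9:length(sig[[j]])], collapse = " ") else sprintf("sig%d", j)
    uv_per_unit <- if (tolower(g$units) == "uv") 1 else 1000  # mV default
    trace((mat[j, ] - g$baseline) * (uv_per_unit / g$gain), fs, label = desc)
  })
  ann <- NULL
  if (!is.null(annotation_extension)) {
    af <- paste0(path, ".", annotation_extension)
    if (!file.exists(af)) stop("read_wfdb_record: missing annotation file ", af)
    idx0 <- read_wfdb_annotation(af)
    ann <- rpeak_series(idx0 + 1L, fs, source = "reference", n_samples = n)
  }
  direct <- NULL
  abdominal <- traces
  if (!is.na(direct_channel) && nsig >= 1L) {
    if (direct_channel < 1L || direct_channel > nsig)
      stop("read_wfdb_record: direct_channel out of range")
    direct <- traces[[direct_channel]]
    abdominal <- traces[-direct_channel]
  }
  list(direct = direct, abdominal = abdominal, fetal_rpeaks = ann,
       metadata = list(record = basename(path), fs = fs, n = n, nsig = nsig))
}

#' Write traces as a WFDB format-16 record
#'
#' @param traces list of `Trace`s sharing fs and length (microvolts).
#' @param path record path without extension; writes `<path>.hea` and
#'   `<path>.dat`.
#' @param gain ADC units per millivolt (default 200).
#' @return `path`, invisibly.
#' @export
write_wfdb_record <- function(traces, path, gain = 200) {
  if (is_trace(traces)) traces <- list(traces)
  do.call(.check_same_grid, c(traces, list(what = "write_wfdb_record")))
  fs <- traces[[1L]]$fs
  n <- length(traces[[1L]]$samples)
  nsig <- length(traces)
  dig <- vapply(traces, function(tr) {
    d <- as.integer(round(tr$samples / 1000 * gain))
    if (any(d > 32767L | d < -32768L))
      stop("write_wfdb_record: sample overflows 16-bit range at gain ", gain)
    d
  }, integer(n))
  interleaved <- as.integer(t(dig))
  rec <- basename(path)
  writeBin(interleaved, paste0(path, ".dat"), size = 2L, endian = "little")
  checksum <- vapply(seq_len(nsig), function(j) {
    s <- sum(dig[, j]) %% 65536
    if (s >= 32768) s - 65536 else s
  }, 0)
  hea <- c(sprintf("%s %d %g %d", rec, nsig, fs, n),
           vapply(seq_len(nsig), function(j)
             sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s",
                     rec, gain, dig[1L, j], as.integer(checksum[j]),
                     if (nzchar(traces[[j]]$label)) gsub("\\s+", "_", traces[[j]]$label)
                     else sprintf("sig%d", j)),
             ""))
  writeLines(hea, paste0(path, ".hea"))
  invisible(path)
}

# MIT annotation words: code in the top 6 bits, time increment in the low
# 10; code 59 (SKIP) escapes a 32-bit interval in the following two words.
.ANN_NORMAL <- 1L
.ANN_SKIP <- 59L

#' Read an MIT-format annotation file
#'
#' @param path annotation file.
#' @return 0-based annotation sample numbers (callers convert to 1-based).
#' @export
read_wfdb_annotation <- function(path) {
  if (!file.exists(path)) stop("read_wfdb_annotation: no such file: ", path)
  words <- readBin(path, "integer", n = file.size(path) %/% 2L,
                   size = 2L, signed = FALSE, endian = "little")
  t <- 0; out <- numeric(); i <- 1L
  while (i <= length(words)) {
    w <- words[i]
    code <- w %/% 1024L
    dt <- w %% 1024L
    if (code == 0L && dt == 0L) break
    if (code == .ANN_SKIP) {
      if (i + 2L > length(words)) stop("read_wfdb_annotation: truncated SKIP in ", path)
      high <- words[i + 1L]; low <- words[i + 2L]
      iv <- high * 65536 + low
      if (iv >= 2^31) iv <- iv - 2^32
      t <- t + iv
      i <- i + 3L
      next
    }
    t <- t + dt
    if (code %in% c(60L, 61L, 62L, 63L)) {  # NUM/SUB/CHN/AUX carry no time
      if (code == 63L) i <- i + ceiling(dt / 2)  # AUX payload
      i <- i + 1L
      next
    }
    out <- c(out, t)
    i <- i + 1L
  }
  out
}

#' Write annotation sample indices in MIT format
#'
#' @param indices 1-based, strictly increasing sample indices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wfdb_annotation <- function(indices, path) {
  indices <- as.integer(round(indices))
  if (length(indices) && any(diff(indices) <= 0L))
    stop("write_wfdb_annotation: indices must be strictly increasing")
  t0 <- c(indices[1L] - 1L, diff(indices))  # to 0-based increments
  words <- integer()
  for (dt in t0) {
    if (dt < 1024L) {
      words <- c(words, .ANN_NORMAL * 1024L + dt)
    } else {
      words <- c(words, .ANN_SKIP * 1024L,
                 dt %/% 65536L, dt %% 65536L,
                 .ANN_NORMAL * 1024L)
    }
  }
  words <- c(words, 0L)
  bytes <- as.raw(c(rbind(words %% 256L, words %/% 256L)))
  writeBin(bytes, path)
  invisible(path)
}
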