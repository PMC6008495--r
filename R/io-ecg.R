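#' ECG record container
#'
#' @param samples Numeric vector of samples (mV).
#' @param fs Sampling rate in Hz.
#' @param record_id Record identifier.
#' @param lead Lead name or `NULL`.
#' @return An `ecg_record` object.
#' @export
ecg_record <- function(samples, fs, record_id = "record", lead = NULL) {
  if (!is.numeric(samples) || length(samples) < 1 || !all(is.finite(samples)))
    abort("`samples` must be a non-empty finite numeric vector.",
          class = "tfarr_format_error")
  if (!is.numeric(fs) || fs <= 0)
    abort("`fs` must be positive.", class = "tfarr_format_error")
  structure(list(samples = as.numeric(samples), fs = fs,
                 record_id = record_id, lead = lead),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$lead)) "" else paste0(", lead ", x$lead)))
  invisible(x)
}

#' Read an ECG record from disk
#'
#' `format = "csv"` reads a plain text file with one sample per line (mV);
#' the sampling rate must be supplied. `format = "wfdb"` reads a
#' PhysioNet-style record: `path` names the header (`.hea`) file or the
#' record path without extension; signal formats 16 (16-bit little-endian)
#' and 212 (packed 12-bit) are supported and samples are converted to
#' physical units via the header gain and baseline. Multi-lead records
#' return channel 0 only.
#'
#' @param path File path (for wfdb: header path or record stem).
#' @param format `"csv"` or `"wfdb"`.
#' @param fs Sampling rate in Hz, required for csv, ignored for wfdb.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"), fs = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path))
      abort(paste0("File not found: ", path), class = "tfarr_io_error")
    if (is.null(fs))
      abort("`fs` is required for csv records.", class = "tfarr_format_error")
    x <- tryCatch(scan(path, what = double(), quiet = TRUE,
                       comment.char = "#"),
                  error = function(e)
                    abort(paste0("Cannot parse ", path, ": ",
                                 conditionMessage(e)),
                          class = "tfarr_format_error"))
    if (length(x) == 0)
      abort(paste0("Empty record file: ", path), class = "tfarr_format_error")
    ecg_record(x, fs,
               record_id = sub("\\.[^.]*$", "", basename(path)))
  } else {
    read_wfdb_record(path)
  }
}

## ---- minimal WFDB support (header + signal formats 16 and 212) ----

.parse_hea <- function(hea_path) {
  if (!file.exists(hea_path))
    abort(paste0("File not found: ", hea_path), class = "tfarr_io_error")
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2)
    abort("Unreadable WFDB header.", class = "tfarr_format_error")
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3)
    abort("Unreadable WFDB header line.", class = "tfarr_format_error")
  record_id <- sub("/.*$", "", top[1])
  n_sig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*$", "", top[3]))
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- purrr::map(lines[1 + seq_len(n_sig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- as.integer(sub("x.*$", "", f[2]))
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_field)))
    baseline <- if (grepl("\\(", gain_field))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field)) else NA_real_
    adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
            else NA_character_
    list(file = f[1], format = fmt,
         gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = if (is.na(baseline)) adc_zero else baseline,
         desc = desc)
  })
  list(record_id = record_id, n_sig = n_sig, fs = fs, n_samp = n_samp,
       signals = sig)
}

.read_dat <- function(dat_path, n_sig, fmt, n_samp) {
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  if (fmt == 16) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                 signed = TRUE, endian = "little")
    matrix(v, ncol = n_sig, byrow = TRUE)
  } else if (fmt == 212) {
    ## 2 samples packed in 3 bytes
    n_tri <- length(raw) %/% 3
    b <- matrix(as.integer(raw[seq_len(3 * n_tri)]), nrow = 3)
    s1 <- b[1, ] + bitwShiftL(bitwAnd(b[2, ], 0x0F), 8)
    s2 <- b[3, ] + bitwShiftL(bitwAnd(bitwShiftR(b[2, ], 4), 0x0F), 8)
    s1 <- ifelse(s1 > 2047, s1 - 4096, s1)
    s2 <- ifelse(s2 > 2047, s2 - 4096, s2)
    v <- as.vector(rbind(s1, s2))
    matrix(v[seq_len((length(v) %/% n_sig) * n_sig)], ncol = n_sig,
           byrow = TRUE)
  } else {
    abort(paste0("Unsupported WFDB signal format: ", fmt),
          class = "tfarr_format_error")
  }
}

#' Read a WFDB-style record (header + binary signal file)
#'
#' @param path Path to the `.hea` file or the record stem.
#' @return An [ecg_record()] holding channel 0 in physical units.
#' @export
read_wfdb_record <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  h <- .parse_hea(hea)
  s0 <- h$signals[[1]]
  fmts <- unique(purrr::map_int(h$signals, ~ as.integer(.x$format)))
  if (length(fmts) != 1)
    abort("Mixed signal formats are not supported.",
          class = "tfarr_format_error")
  dat <- file.path(dirname(hea), s0$file)
  if (!file.exists(dat))
    abort(paste0("Signal file not found: ", dat), class = "tfarr_io_error")
  m <- .read_dat(dat, h$n_sig, fmts, h$n_samp)
  if (!is.na(h$n_samp) && nrow(m) > h$n_samp) m <- m[seq_len(h$n_samp), ,
                                                     drop = FALSE]
  x <- (m[, 1] - s0$baseline) / s0$gain
  ecg_record(x, h$fs, record_id = h$record_id, lead = s0$desc)
}

## ---- rhythm annotations ----

.rhythm_map <- c(VF = "VF", VFIB = "VF", VT = "VT", VFL = "VFL",
                 FLUT = "VFL", N = "NSR", NSR = "NSR", SR = "NSR",
                 NOISE = "NOISE", NOIS = "NOISE")

#' Map a rhythm annotation string to a canonical rhythm code
#'
#' Strips a leading `(` (the WFDB rhythm-change convention) and maps to one
#' of `NSR`, `VT`, `VF`, `VFL`, `NOISE`; unrecognized strings map to
#' `OTHER`. The table can be extended via `extra`.
#'
#' @param x Character vector of rhythm strings, e.g. `"(VFL"`.
#' @param extra Named character vector of additional mappings
#'   (name = cleaned string, value = rhythm code).
#' @return Character vector of rhythm codes.
#' @export
#' @examples
#' map_rhythm_string(c("(VF", "(AFIB", "N"))
map_rhythm_string <- function(x, extra = NULL) {
  map <- c(.rhythm_map, extra)
  key <- toupper(sub("^\\(", "", trimws(x)))
  out <- unname(map[key])
  out[is.na(out)] <- "OTHER"
  out
}

#' Read rhythm annotations from the internal text format
#'
#' Each line is `sample_index,rhythm_string`; indices are 0-based and must
#' be non-negative and sorted non-decreasingly. Rhythm strings pass through
#' [map_rhythm_string()].
#'
#' @param path File path.
#' @param extra Extra mappings forwarded to [map_rhythm_string()].
#' @return Tibble with columns `sample` (integer) and `rhythm` (code).
#' @export
read_annotations <- function(path, extra = NULL) {
  if (!file.exists(path))
    abort(paste0("File not found: ", path), class = "tfarr_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    abort("Empty annotation file.", class = "tfarr_format_error")
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(parts) < 2))
    abort("Malformed annotation line.", class = "tfarr_format_error")
  idx <- suppressWarnings(as.numeric(trimws(purrr::map_chr(parts, 1))))
  code <- map_rhythm_string(purrr::map_chr(parts, 2), extra = extra)
  if (any(is.na(idx)) || any(idx < 0))
    abort("Annotation indices must be non-negative numbers.",
          class = "tfarr_format_error")
  if (is.unsorted(idx))
    abort("Annotation indices must be sorted.", class = "tfarr_format_error")
  tibble::tibble(sample = as.integer(idx), rhythm = code)
}

#' Write rhythm annotations in the internal text format
#'
#' @param events Tibble/data frame with columns `sample` and `rhythm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  writeLines(paste0(events$sample, ",", events$rhythm), path)
  invisible(path)
}

#' Read rhythm annotations from a WFDB (MIT-format) annotation file
#'
#' Parses the binary MIT annotation format and keeps rhythm-change events
#' (annotation code 28, `+`) whose aux strings name the rhythm, mapped via
#' [map_rhythm_string()].
#'
#' @param path Path to the annotation file (e.g. `.atr`).
#' @param extra Extra mappings forwarded to [map_rhythm_string()].
#' @return Tibble with columns `sample` and `rhythm`.
#' @export
read_wfdb_annotations <- function(path, extra = NULL) {
  if (!file.exists(path))
    abort(paste0("File not found: ", path), class = "tfarr_io_error")
  raw <- readBin(path, "raw", n = file.info(path)$size)
  words <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                   signed = FALSE, endian = "little")
  t_cur <- 0
  i <- 1
  samples <- integer(0)
  rhythms <- character(0)
  while (i <= length(words)) {
    w <- words[i]
    code <- bitwShiftR(w, 10)
    tfield <- bitwAnd(w, 1023)
    if (code == 0 && tfield == 0) break          # EOF
    if (code == 59) {                            # SKIP: 4-byte interval
      hi <- words[i + 1]
      lo <- words[i + 2]
      dt <- hi * 65536 + lo
      if (dt > 2^31) dt <- dt - 2^32
      t_cur <- t_cur + dt
      i <- i + 3
      next
    }
    if (code %in% c(60, 61, 62)) {               # NUM / SUB / CHN
      i <- i + 1
      next
    }
    if (code == 63) {                            # AUX string
      n_aux <- tfield
      n_words <- (n_aux + (n_aux %% 2)) %/% 2
      aux_raw <- raw[(2 * i + 1):(2 * i + n_aux)]
      aux <- rawToChar(aux_raw[aux_raw != as.raw(0)])
      if (grepl("^\\(", aux)) {
        samples <- c(samples, t_cur)
        rhythms <- c(rhythms, aux)
      }
      i <- i + 1 + n_words
      next
    }
    t_cur <- t_cur + tfield
    i <- i + 1
  }
  tibble::tibble(sample = as.integer(samples),
                 rhythm = map_rhythm_string(rhythms, extra = extra))
}

#' Convert an annotation event stream into rhythm episodes
#'
#' Each event opens an episode that is closed by the next event (or the
#' record end); episodes are 0-based half-open sample intervals that tile
#' `[first event, record_length)`. When several events share an index the
#' last one wins (later annotator correction).
#'
#' @param events Tibble with columns `sample` and `rhythm`, sorted.
#' @param record_length Total number of samples in the record.
#' @return Tibble with columns `start_sample`, `end_sample`, `rhythm`.
#' @export
#' @examples
#' ev <- tibble::tibble(sample = c(0L, 5000L), rhythm = c("NSR", "VF"))
#' episodes_from_annotations(ev, 10000)
episodes_from_annotations <- function(events, record_length) {
  if (is.null(events) || nrow(events) == 0)
    abort("Empty event list.", class = "tfarr_invalid_input")
  if (is.unsorted(events$sample))
    abort("Events must be sorted by sample index.",
          class = "tfarr_format_error")
  if (record_length <= max(events$sample))
    abort("`record_length` must exceed the last event index.",
          class = "tfarr_invalid_input")
  ## last event at a duplicated index wins
  ev <- events[!duplicated(events$sample, fromLast = TRUE), , drop = FALSE]
  starts <- ev$sample
  ends <- c(ev$sample[-1], as.integer(record_length))
  tibble::tibble(start_sample = as.integer(starts),
                 end_sample = as.integer(ends),
                 rhythm = ev$rhythm)
}
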