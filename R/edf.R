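# Minimal EDF / EDF+ (16-bit) codec for single-channel work.
#
# EDF is a fixed-layout format: a 256-byte ASCII header, 256 bytes of ASCII
# per signal, then data records of little-endian int16 samples scaled
# linearly between a digital and a physical range. EDF+ stores event
# markers in a dedicated "EDF Annotations" signal whose bytes are
# time-stamped annotation lists (TALs): "+onset\x14label\x14\x00".

edf_fmt <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field overflow: ", s, call. = FALSE)
  formatC(s, width = -width, flag = " ")
}

# numeric -> at most `width` ASCII chars
edf_fmt_num <- function(x, width = 8L) {
  for (d in seq(10L, 1L)) {
    s <- formatC(x, digits = d, format = "g", width = -1)
    if (nchar(s) <= width) return(edf_fmt(s, width))
  }
  stop("cannot format ", x, " in ", width, " chars", call. = FALSE)
}

#' Write a recording to an EDF/EDF+ file
#'
#' Encodes a single-channel recording as 16-bit EDF. When the recording
#' carries annotations an EDF+ "EDF Annotations" signal is added and the
#' file is marked EDF+C. The physical range is set symmetrically to the
#' recording's peak amplitude, so round-tripping preserves samples within
#' one quantization step of that range. Data are stored in 1-s records; a
#' trace that is not a whole number of seconds is zero-padded to the next
#' record boundary (with a warning), which keeps the stored sampling rate
#' exact.
#'
#' @param rec An [eeg_recording()] (voltages in microvolts).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  if (!inherits(rec, "eeg_recording"))
    rec <- do.call(eeg_recording, rec)  # validates
  x <- rec$samples
  n <- length(x)
  fs <- rec$fs
  # 1-s records; the record duration field is 8 ASCII chars, so the only
  # way to keep fs exact for awkward lengths is to zero-pad the final
  # partial second rather than store a rounded duration
  if (fs != round(fs))
    stop("write_edf requires an integer sampling rate", call. = FALSE)
  rec_dur <- 1
  spr <- as.integer(fs)
  nrec <- as.integer(ceiling(n / spr))

  # symmetric physical range just above the peak, representable in the
  # 8-char header field including the minus sign
  phys_hi <- max(abs(x))
  if (phys_hi == 0) phys_hi <- 1
  for (dgt in 6:1) {
    cand <- as.numeric(formatC(phys_hi * 1.001, digits = dgt, format = "g"))
    if (nchar(edf_num_str(-cand)) <= 8 && cand >= phys_hi) {
      phys_hi <- cand
      break
    }
  }
  phys_lo <- -phys_hi
  dmin <- -32768L; dmax <- 32767L
  gain <- (phys_hi - phys_lo) / (dmax - dmin)
  dig <- as.integer(pmin(pmax(round((x - phys_lo) / gain) + dmin, dmin), dmax))
  if (n %% spr != 0) {
    warning("trace zero-padded to a whole number of 1-s records",
            call. = FALSE)
    dig <- c(dig, as.integer(round(-phys_lo / gain) + dmin) +
               integer(nrec * spr - n))
  }

  has_ann <- nrow(rec$annotations) > 0L
  ann_payload <- NULL
  if (has_ann) {
    ann_payload <- vector("list", nrec)
    for (r in seq_len(nrec)) {
      # R strings cannot hold NUL, so TALs are assembled as raw bytes
      pay <- c(charToRaw(sprintf("+%s\x14\x14",
                                 edf_num_str((r - 1) * rec_dur))), as.raw(0))
      if (r == 1L) {
        a <- rec$annotations
        tals <- sprintf("+%s\x14%s\x14", vapply(a$onset, edf_num_str, ""),
                        a$label)
        for (tl in tals) pay <- c(pay, charToRaw(tl), as.raw(0))
      }
      ann_payload[[r]] <- pay
    }
    ann_bytes <- max(vapply(ann_payload, length, integer(1)))
    if (ann_bytes %% 2L == 1L) ann_bytes <- ann_bytes + 1L
    spr_ann <- ann_bytes %/% 2L
  }

  ns <- if (has_ann) 2L else 1L
  hdr <- paste0(
    edf_fmt("0", 8), edf_fmt("X", 80), edf_fmt("Startdate X", 80),
    edf_fmt("01.01.26", 8), edf_fmt("00.00.00", 8),
    edf_fmt(256L * (ns + 1L), 8),
    edf_fmt(if (has_ann) "EDF+C" else "", 44),
    edf_fmt(nrec, 8), edf_fmt_num(rec_dur, 8), edf_fmt(ns, 4))

  sig <- function(main, ann) if (has_ann) c(main, ann) else main
  hdr <- paste0(hdr,
    paste0(vapply(sig(rec$channel_label, "EDF Annotations"),
                  edf_fmt, "", width = 16), collapse = ""),
    paste0(vapply(sig("", ""), edf_fmt, "", width = 80), collapse = ""),
    paste0(vapply(sig("uV", ""), edf_fmt, "", width = 8), collapse = ""),
    paste0(vapply(sig(edf_num_str(phys_lo), "-1"), edf_fmt, "", width = 8),
           collapse = ""),
    paste0(vapply(sig(edf_num_str(phys_hi), "1"), edf_fmt, "", width = 8),
           collapse = ""),
    paste0(vapply(sig("-32768", "-32768"), edf_fmt, "", width = 8),
           collapse = ""),
    paste0(vapply(sig("32767", "32767"), edf_fmt, "", width = 8),
           collapse = ""),
    paste0(vapply(sig("", ""), edf_fmt, "", width = 80), collapse = ""),
    paste0(vapply(sig(as.character(spr),
                      if (has_ann) as.character(spr_ann) else ""),
                  edf_fmt, "", width = 8), collapse = ""),
    paste0(vapply(sig("", ""), edf_fmt, "", width = 32), collapse = ""))

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(dig[idx], con, size = 2L, endian = "little")
    if (has_ann) {
      pay <- ann_payload[[r]]
      writeBin(c(pay, raw(2L * spr_ann - length(pay))), con)
    }
  }
  invisible(path)
}

# plain decimal string (EDF+ TAL onsets must not use scientific notation)
edf_num_str <- function(x) {
  s <- formatC(x, format = "f", digits = 6)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Read one channel from an EDF/EDF+ file
#'
#' Parses the fixed-layout EDF header, extracts the named channel's trace
#' scaled to physical units (converted to microvolts if the file declares
#' mV or V), and collects any EDF+ annotations.
#'
#' @param path Path to an EDF or EDF+ file.
#' @param channel Channel label to extract; `NULL` takes the first
#'   ordinary signal.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channel = NULL) {
  if (!file.exists(path))
    stop("EDF file not found: '", path, "'", call. = FALSE)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 256) stop("unreadable EDF file (truncated header)", call. = FALSE)
  h <- readBin(con, "raw", 256L)
  # headers are ASCII by spec; decode via latin1 so corrupt bytes never
  # produce invalid strings (they fail the version check instead)
  fld <- function(raw, from, len)
    trimws(iconv(rawToChar(raw[from:(from + len - 1L)]), "latin1", "UTF-8"))
  if (fld(h, 1, 8) != "0")
    stop("unreadable EDF file (bad version field)", call. = FALSE)
  nrec <- as.integer(fld(h, 237, 8))
  rec_dur <- as.numeric(fld(h, 245, 8))
  ns <- as.integer(fld(h, 253, 4))
  if (is.na(ns) || ns < 1 || sz < 256 * (ns + 1))
    stop("unreadable EDF file (corrupt signal header)", call. = FALSE)
  sh <- readBin(con, "raw", 256L * ns)
  sfld <- function(from0, len) vapply(seq_len(ns) - 1L, function(i)
    fld(sh, from0 + i * len, len), "")
  labels <- sfld(1, 16)
  phys_dim <- sfld(ns * 96 + 1, 8)
  phys_min <- as.numeric(sfld(ns * 104 + 1, 8))
  phys_max <- as.numeric(sfld(ns * 112 + 1, 8))
  dig_min <- as.numeric(sfld(ns * 120 + 1, 8))
  dig_max <- as.numeric(sfld(ns * 128 + 1, 8))
  spr <- as.integer(sfld(ns * 216 + 1, 8))
  if (any(is.na(spr)) || any(spr < 1))
    stop("unreadable EDF file (corrupt samples-per-record)", call. = FALSE)

  is_ann <- labels == "EDF Annotations"
  if (is.na(nrec) || nrec < 0)
    nrec <- as.integer((sz - 256 * (ns + 1)) %/% (2 * sum(spr)))
  if (is.null(channel)) {
    ch <- which(!is_ann)[1L]
    if (is.na(ch)) stop("no data channel in EDF file", call. = FALSE)
  } else {
    ch <- which(labels == channel & !is_ann)[1L]
    if (is.na(ch))
      stop("channel '", channel, "' not found (file holds: ",
           paste(labels[!is_ann], collapse = ", "), ")", call. = FALSE)
  }

  words <- readBin(con, "integer", nrec * sum(spr), size = 2L,
                   endian = "little")
  if (length(words) < nrec * sum(spr))
    stop("unreadable EDF file (truncated data records)", call. = FALSE)
  offs <- c(0L, cumsum(spr))
  tot <- sum(spr)
  take <- function(j) {
    idx <- as.vector(outer((offs[j] + 1L):offs[j + 1L],
                           (seq_len(nrec) - 1L) * tot, `+`))
    words[idx]
  }
  dig <- take(ch)
  gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
  x <- (dig - dig_min[ch]) * gain + phys_min[ch]
  unit <- switch(tolower(phys_dim[ch]), "mv" = 1e3, "v" = 1e6, 1)
  x <- x * unit

  ann <- data.frame(onset = numeric(0), label = character(0),
                    stringsAsFactors = FALSE)
  for (j in which(is_ann)) {
    bytes <- writeBin(take(j), raw(), size = 2L, endian = "little")
    ann <- rbind(ann, parse_tals(bytes))
  }
  fs <- spr[ch] / rec_dur
  eeg_recording(x, fs = fs, channel_label = labels[ch], annotations = ann)
}

# Split raw TAL bytes into (onset, label) rows; timekeeping TALs (empty
# label) are dropped.
parse_tals <- function(bytes) {
  out <- data.frame(onset = numeric(0), label = character(0),
                    stringsAsFactors = FALSE)
  chunks <- split(bytes, cumsum(bytes == as.raw(0)))
  for (ck in chunks) {
    ck <- ck[ck != as.raw(0)]
    if (length(ck) == 0) next
    parts <- strsplit(rawToChar(ck), "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    onset <- as.numeric(sub("\x15.*$", "", parts[1]))
    labs <- parts[-1]
    labs <- labs[nzchar(labs)]
    if (length(labs) == 0 || is.na(onset)) next
    out <- rbind(out, data.frame(onset = onset, label = labs,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Read trial annotations from CSV
#'
#' Alternative annotation source: a CSV with columns
#' `onset_seconds,label`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `onset`, `label`.
#' @export
read_annotations_csv <- function(path) {
  if (!file.exists(path))
    stop("annotation CSV not found: '", path, "'", call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_seconds", "label") %in% names(d)))
    stop("annotation CSV needs columns onset_seconds,label", call. = FALSE)
  data.frame(onset = as.numeric(d$onset_seconds),
             label = as.character(d$label), stringsAsFactors = FALSE)
}

#' Write trial annotations to CSV
#' @param annotations Data frame with columns `onset`, `label`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(annotations, path) {
  utils::write.csv(data.frame(onset_seconds = annotations$onset,
                              label = annotations$label),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
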