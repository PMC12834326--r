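# Bit-exact reader/writer for the rig's hourly binary files. Layout:
#   file   = 4096-byte header | stream of 63-byte packets
#   packet = counter(3, BE) | status AFE1(3) | 8 x 3-byte AFE1 channel codes
#            | status AFE2(3) | 8 x 3-byte AFE2 channel codes
#            | 3 x 2-byte acceleration codes
# Channel codes are big-endian two's complement (the AFE's native output
# order); acceleration codes little-endian two's complement (the
# accelerometer's native order). Status words are carried opaquely.

PACKET_BYTES <- 63L
HEADER_BYTES <- 4096L
HEADER_MAGIC <- "EMUHDR"

#' Construct a raw telemetry packet
#'
#' One 63-byte telemetry sample: a 3-byte wrapping counter, two opaque
#' 3-byte AFE status words, 16 signed 24-bit biopotential channel codes and
#' 3 signed 16-bit acceleration codes.
#'
#' @param counter unsigned counter in `[0, 2^24 - 1]`; wraps modulo `2^24`.
#' @param chan_codes_afe1,chan_codes_afe2 8 signed integers each in
#'   `[-2^23, 2^23 - 1]`.
#' @param accel_codes 3 signed integers (x, y, z) in `[-2^15, 2^15 - 1]`.
#' @param status_afe1,status_afe2 3-byte raw vectors, carried opaquely.
#' @return an object of class `emu_packet`.
#' @export
emu_packet <- function(counter = 0,
                       chan_codes_afe1 = rep(0, 8),
                       chan_codes_afe2 = rep(0, 8),
                       accel_codes = rep(0, 3),
                       status_afe1 = as.raw(c(0, 0, 0)),
                       status_afe2 = as.raw(c(0, 0, 0))) {
  p <- structure(
    list(counter = as.numeric(counter),
         status_afe1 = as.raw(status_afe1),
         chan_codes_afe1 = as.numeric(chan_codes_afe1),
         status_afe2 = as.raw(status_afe2),
         chan_codes_afe2 = as.numeric(chan_codes_afe2),
         accel_codes = as.numeric(accel_codes)),
    class = "emu_packet")
  validate_packet(p)
  p
}

validate_packet <- function(p) {
  chk <- function(x, lo, hi, name) {
    if (any(x != round(x)) || any(x < lo) || any(x > hi))
      stop("field '", name, "' out of range [", lo, ", ", hi, "]")
  }
  chk(p$counter, 0, 2^24 - 1, "counter")
  if (length(p$chan_codes_afe1) != 8) stop("chan_codes_afe1 must have 8 codes")
  if (length(p$chan_codes_afe2) != 8) stop("chan_codes_afe2 must have 8 codes")
  if (length(p$accel_codes) != 3) stop("accel_codes must have 3 codes")
  chk(p$chan_codes_afe1, -2^23, 2^23 - 1, "chan_codes_afe1")
  chk(p$chan_codes_afe2, -2^23, 2^23 - 1, "chan_codes_afe2")
  chk(p$accel_codes, -2^15, 2^15 - 1, "accel_codes")
  if (length(p$status_afe1) != 3) stop("status_afe1 must be 3 bytes")
  if (length(p$status_afe2) != 3) stop("status_afe2 must be 3 bytes")
  invisible(p)
}

# vectorised signed-24 <-> 3 big-endian bytes
int24_to_be <- function(codes) {
  v <- codes %% 2^24                       # two's complement
  rbind(v %/% 65536, (v %/% 256) %% 256, v %% 256)
}
be_to_int24 <- function(b1, b2, b3) {
  v <- b1 * 65536 + b2 * 256 + b3
  ifelse(v >= 2^23, v - 2^24, v)
}
# matrix form: codes (nch x N) -> bytes (3*nch x N), per-channel interleaved
int24_to_be_mat <- function(m) {
  v <- m %% 2^24
  out <- matrix(0, nrow = 3 * nrow(m), ncol = ncol(m))
  out[seq(1, nrow(out), 3), ] <- v %/% 65536
  out[seq(2, nrow(out), 3), ] <- (v %/% 256) %% 256
  out[seq(3, nrow(out), 3), ] <- v %% 256
  out
}
# signed-16 <-> 2 little-endian bytes
int16_to_le <- function(codes) {
  v <- codes %% 2^16
  rbind(v %% 256, v %/% 256)
}
# matrix form: codes (nax x N) -> bytes (2*nax x N), per-axis interleaved
int16_to_le_mat <- function(m) {
  v <- m %% 2^16
  out <- matrix(0, nrow = 2 * nrow(m), ncol = ncol(m))
  out[seq(1, nrow(out), 2), ] <- v %% 256
  out[seq(2, nrow(out), 2), ] <- v %/% 256
  out
}
le_to_int16 <- function(lo, hi) {
  v <- hi * 256 + lo
  ifelse(v >= 2^15, v - 2^16, v)
}

#' Encode a packet to its 63-byte wire form
#'
#' @param p an [emu_packet()].
#' @return raw vector of length 63.
#' @export
encode_packet <- function(p) {
  validate_packet(p)
  as.raw(c(
    int24_to_be(p$counter),
    as.integer(p$status_afe1),
    int24_to_be(p$chan_codes_afe1),
    as.integer(p$status_afe2),
    int24_to_be(p$chan_codes_afe2),
    int16_to_le(p$accel_codes)))
}

#' Decode a 63-byte wire packet
#'
#' Exact inverse of [encode_packet()]: yields the counter, two opaque status
#' words, 16 biopotential channel codes and 3 acceleration codes.
#'
#' @param b raw vector of length exactly 63.
#' @return an [emu_packet()].
#' @export
decode_packet <- function(b) {
  if (length(b) != PACKET_BYTES)
    stop("expected exactly ", PACKET_BYTES, " bytes, got ", length(b))
  v <- as.integer(as.raw(b))
  m <- decode_packet_matrix(matrix(v, nrow = PACKET_BYTES))
  emu_packet(counter = m$counter[1],
             chan_codes_afe1 = m$chan1[1, ],
             chan_codes_afe2 = m$chan2[1, ],
             accel_codes = m$accel[1, ],
             status_afe1 = as.raw(v[4:6]),
             status_afe2 = as.raw(v[31:33]))
}

# Bulk decode: `bytes` is a 63 x N integer matrix (one packet per column).
decode_packet_matrix <- function(bytes) {
  list(
    counter = be_to_int24(bytes[1, ], bytes[2, ], bytes[3, ]) %% 2^24,
    chan1 = t(be_to_int24(bytes[7 + 3 * (0:7), , drop = FALSE],
                          bytes[8 + 3 * (0:7), , drop = FALSE],
                          bytes[9 + 3 * (0:7), , drop = FALSE])),
    chan2 = t(be_to_int24(bytes[34 + 3 * (0:7), , drop = FALSE],
                          bytes[35 + 3 * (0:7), , drop = FALSE],
                          bytes[36 + 3 * (0:7), , drop = FALSE])),
    accel = t(le_to_int16(bytes[58 + 2 * (0:2), , drop = FALSE],
                          bytes[59 + 2 * (0:2), , drop = FALSE])))
}

# counter comes back unsigned; be_to_int24 maps >= 2^23 negative, undo above.

#' Recording-file header
#'
#' Device configuration occupying the first 4096 bytes of an hourly file,
#' serialised as UTF-8 `key=value` lines zero-padded to 4096 bytes; the first
#' line is a magic string with the format version.
#'
#' @param format_version small integer format version.
#' @param start_time_utc start time, seconds since epoch (fractional allowed).
#' @param sample_rate_hz sampling rate in Hz (device default 1000, max 16000).
#' @param afe_gain two programmable-gain values, one per AFE.
#' @param vref_volts ADC reference voltage (default 4.5).
#' @param accel_full_scale_g accelerometer full scale in g.
#' @param channel_labels 16 unique short labels (e.g. HPL, HAL, EPR).
#' @param rig_id short rig identifier used in file names.
#' @param dac_waveform optional [waveform_spec()] driving the function
#'   generator, or `NULL`.
#' @return an object of class `emu_header`.
#' @export
emu_header <- function(format_version = 1L,
                       start_time_utc = 0,
                       sample_rate_hz = 1000,
                       afe_gain = c(1, 1),
                       vref_volts = 4.5,
                       accel_full_scale_g = 2,
                       channel_labels = sprintf("CH%02d", 1:16),
                       rig_id = "rig0",
                       dac_waveform = NULL) {
  stopifnot(sample_rate_hz > 0, length(afe_gain) == 2, all(afe_gain > 0),
            vref_volts > 0, accel_full_scale_g > 0,
            length(channel_labels) == 16)
  if (anyDuplicated(channel_labels))
    stop("all 16 channel labels must be unique")
  structure(
    list(format_version = as.integer(format_version),
         start_time_utc = as.numeric(start_time_utc),
         sample_rate_hz = as.numeric(sample_rate_hz),
         afe_gain = as.numeric(afe_gain),
         vref_volts = as.numeric(vref_volts),
         accel_full_scale_g = as.numeric(accel_full_scale_g),
         channel_labels = as.character(channel_labels),
         rig_id = as.character(rig_id),
         dac_waveform = dac_waveform),
    class = "emu_header")
}

fmt_num <- function(x) sprintf("%.17g", x)

serialize_header <- function(h) {
  stopifnot(inherits(h, "emu_header"))
  lines <- c(
    paste0(HEADER_MAGIC, " v", h$format_version),
    paste0("start_time_utc=", fmt_num(h$start_time_utc)),
    paste0("sample_rate_hz=", fmt_num(h$sample_rate_hz)),
    paste0("afe_gain=", paste(fmt_num(h$afe_gain), collapse = ",")),
    paste0("vref_volts=", fmt_num(h$vref_volts)),
    paste0("accel_full_scale_g=", fmt_num(h$accel_full_scale_g)),
    paste0("channel_labels=", paste(h$channel_labels, collapse = ",")),
    paste0("rig_id=", h$rig_id))
  if (!is.null(h$dac_waveform)) {
    w <- h$dac_waveform
    kv <- paste(names(w$params), vapply(w$params, fmt_num, ""),
                sep = ":", collapse = ";")
    lines <- c(lines, paste0(
      "dac_waveform=", w$kind, ";", kv,
      ";duration_s:", fmt_num(w$duration_s),
      ";update_rate_hz:", fmt_num(w$update_rate_hz)))
  }
  payload <- charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
  if (length(payload) > HEADER_BYTES)
    stop("header exceeds ", HEADER_BYTES, " bytes")
  c(payload, raw(HEADER_BYTES - length(payload)))
}

parse_header <- function(bytes) {
  if (length(bytes) < HEADER_BYTES)
    stop("short header: expected ", HEADER_BYTES, " bytes, got ", length(bytes))
  bytes <- bytes[seq_len(HEADER_BYTES)]
  txt <- rawToChar(bytes[bytes != as.raw(0)])
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (!startsWith(lines[1], HEADER_MAGIC))
    stop("not a recognised recording header (missing magic string)")
  ver <- as.integer(sub(paste0("^", HEADER_MAGIC, " v"), "", lines[1]))
  kv <- strsplit(lines[-1], "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
    vapply(kv, `[[`, "", 1))
  wf <- NULL
  if (!is.na(vals["dac_waveform"])) {
    parts <- strsplit(vals[["dac_waveform"]], ";", fixed = TRUE)[[1]]
    pk <- strsplit(parts[-1], ":", fixed = TRUE)
    pv <- stats::setNames(
      lapply(pk, function(x) as.numeric(x[2])),
      vapply(pk, `[[`, "", 1))
    wf <- waveform_spec(
      kind = parts[1],
      params = pv[setdiff(names(pv), c("duration_s", "update_rate_hz"))],
      duration_s = pv[["duration_s"]],
      update_rate_hz = pv[["update_rate_hz"]])
  }
  emu_header(
    format_version = ver,
    start_time_utc = as.numeric(vals[["start_time_utc"]]),
    sample_rate_hz = as.numeric(vals[["sample_rate_hz"]]),
    afe_gain = as.numeric(strsplit(vals[["afe_gain"]], ",")[[1]]),
    vref_volts = as.numeric(vals[["vref_volts"]]),
    accel_full_scale_g = as.numeric(vals[["accel_full_scale_g"]]),
    channel_labels = strsplit(vals[["channel_labels"]], ",")[[1]],
    rig_id = vals[["rig_id"]],
    dac_waveform = wf)
}

#' Write an hourly recording file
#'
#' File = 4096 header bytes, then packets at 63 bytes each; the first packet
#' begins at byte offset 4096 (0-based). When the header carries a sampling
#' rate, at most `fs * 3600` packets (one hour) are accepted per file.
#'
#' @param header an [emu_header()].
#' @param packets list of [emu_packet()], or a pre-encoded raw vector whose
#'   length is a multiple of 63.
#' @param path output file path.
#' @return invisibly, the number of bytes written.
#' @export
write_hourly_file <- function(header, packets, path) {
  hb <- serialize_header(header)
  pb <- if (is.raw(packets)) {
    if (length(packets) %% PACKET_BYTES != 0)
      stop("raw packet payload length must be a multiple of ", PACKET_BYTES)
    packets
  } else {
    do.call(c, c(list(raw(0)), lapply(packets, encode_packet)))
  }
  n <- length(pb) / PACKET_BYTES
  if (n > header$sample_rate_hz * 3600)
    stop("more than one hour of packets (", n, " > fs*3600); rotate files")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hb, con)
  if (length(pb)) writeBin(pb, con)
  invisible(HEADER_BYTES + length(pb))
}

#' Read an hourly recording file
#'
#' @param path input file path.
#' @param as_packets if `TRUE` (default) decode packets into a list of
#'   [emu_packet()]; if `FALSE` return bulk-decoded numeric matrices
#'   (`counter`, `chan1`, `chan2`, `accel`, `status1`, `status2`), which is
#'   much faster for long files.
#' @return list with `header`, `packets` (or bulk matrices in `$data`),
#'   `n_packets`, and `fragment_bytes` (length of any trailing partial
#'   packet; a warning is raised, nothing is silently dropped).
#' @export
read_hourly_file <- function(path, as_packets = TRUE) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0) stop("empty or unreadable source: ", path)
  if (sz < HEADER_BYTES)
    stop("short header: file has ", sz, " bytes, need ", HEADER_BYTES)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- parse_header(readBin(con, "raw", HEADER_BYTES))
  body <- readBin(con, "raw", sz - HEADER_BYTES)
  n <- length(body) %/% PACKET_BYTES
  frag <- length(body) - n * PACKET_BYTES
  if (frag > 0)
    warning("trailing partial packet of ", frag, " bytes (power loss?)")
  out <- list(header = header, n_packets = n, fragment_bytes = frag)
  if (n > 0) {
    bytes <- matrix(as.integer(body[seq_len(n * PACKET_BYTES)]),
                    nrow = PACKET_BYTES)
    m <- decode_packet_matrix(bytes)
    if (as_packets) {
      out$packets <- lapply(seq_len(n), function(k) emu_packet(
        counter = m$counter[k],
        chan_codes_afe1 = m$chan1[k, ],
        chan_codes_afe2 = m$chan2[k, ],
        accel_codes = m$accel[k, ],
        status_afe1 = as.raw(bytes[4:6, k]),
        status_afe2 = as.raw(bytes[31:33, k])))
    } else {
      out$data <- m
      out$data$status1 <- t(bytes[4:6, , drop = FALSE])
      out$data$status2 <- t(bytes[31:33, , drop = FALSE])
    }
  } else {
    if (as_packets) out$packets <- list() else out$data <- NULL
  }
  out
}

#' Hourly file name for a rig and start time
#'
#' `<rig_id>_<ISO8601 start>.emu`; the starting time of the data in each file
#' is reflected in the file name.
#'
#' @param rig_id rig identifier.
#' @param start_time_utc start time in seconds since epoch.
#' @return file name string.
#' @export
hourly_file_name <- function(rig_id, start_time_utc) {
  stamp <- format(as.POSIXct(start_time_utc, origin = "1970-01-01",
                             tz = "UTC"), "%Y%m%dT%H%M%SZ")
  paste0(rig_id, "_", stamp, ".emu")
}

#' Convert an ADC channel code to volts
#'
#' `volts = code * (vref / gain) / 2^23`; at gain 1 and vref 4.5 V the
#' representable range is the rig's +/-4.5 V dynamic range.
#'
#' @param code signed 24-bit code(s).
#' @param gain programmable gain (> 0).
#' @param vref_volts reference voltage (> 0), default 4.5.
#' @return volts (numeric, vectorised).
#' @export
code_to_volts <- function(code, gain = 1, vref_volts = 4.5) {
  if (gain <= 0 || vref_volts <= 0) stop("gain and vref must be positive")
  code * (vref_volts / gain) / 2^23
}

#' Convert volts to the nearest ADC channel code
#'
#' Inverse of [code_to_volts()] with rounding and saturation at the signed
#' 24-bit range; used when exporting simulated sessions to the wire format.
#'
#' @inheritParams code_to_volts
#' @param volts voltage value(s).
#' @return list with `code` and `n_saturated` (count of clipped samples).
#' @export
volts_to_code <- function(volts, gain = 1, vref_volts = 4.5) {
  if (gain <= 0 || vref_volts <= 0) stop("gain and vref must be positive")
  code <- round(volts * 2^23 * gain / vref_volts)
  n_sat <- sum(code < -2^23 | code > 2^23 - 1)
  list(code = pmin(pmax(code, -2^23), 2^23 - 1), n_saturated = n_sat)
}

#' Convert an accelerometer code to g
#'
#' `g = code * full_scale_g / 2^15`; odd-symmetric in the code.
#'
#' @param code signed 16-bit code(s).
#' @param full_scale_g full-scale acceleration in g (> 0).
#' @return acceleration in g.
#' @export
accel_code_to_g <- function(code, full_scale_g = 2) {
  if (full_scale_g <= 0) stop("full scale must be positive")
  code * full_scale_g / 2^15
}

#' Convert acceleration in g to the nearest accelerometer code
#'
#' @inheritParams accel_code_to_g
#' @param g acceleration value(s) in g.
#' @return list with `code` and `n_saturated`.
#' @export
g_to_accel_code <- function(g, full_scale_g = 2) {
  if (full_scale_g <= 0) stop("full scale must be positive")
  code <- round(g * 2^15 / full_scale_g)
  n_sat <- sum(code < -2^15 | code > 2^15 - 1)
  list(code = pmin(pmax(code, -2^15), 2^15 - 1), n_saturated = n_sat)
}

#' Audit packet-counter continuity
#'
#' The 3-byte counter must advance by 1 modulo `2^24` through a contiguous
#' stream; the wrap `2^24 - 1 -> 0` is not a gap. Used to audit dropouts.
#'
#' @param counters numeric vector of packet counters (or a list of
#'   [emu_packet()]).
#' @return data.frame with one row per gap: `position` (index of the packet
#'   after the gap) and `missing` (number of missing packets). Zero rows if
#'   the stream is contiguous.
#' @export
check_counter_continuity <- function(counters) {
  if (is.list(counters))
    counters <- vapply(counters, function(p) p$counter, numeric(1))
  if (length(counters) < 2)
    return(data.frame(position = integer(0), missing = numeric(0)))
  d <- (diff(counters) - 1) %% 2^24
  idx <- which(d != 0)
  data.frame(position = idx + 1L, missing = d[idx])
}
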