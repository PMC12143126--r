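#' Write a recording as a BrainVision triplet
#'
#' Writes `<basename>.vhdr` (header), `<basename>.vmrk` (markers) and
#' `<basename>.eeg` (binary data, multiplexed channel order). Two binary
#' dialects are supported: `IEEE_FLOAT_32` (values stored in microvolt,
#' resolution 1) and `INT_16` (values divided by the per-channel resolution
#' and rounded).
#'
#' @param raw a [raw_recording()].
#' @param basename path without extension.
#' @param binary_format `"IEEE_FLOAT_32"` or `"INT_16"`.
#' @param resolution per-channel resolution in microvolt per LSB (recycled);
#'   used only for `INT_16`.
#' @return `basename`, invisibly.
#' @export
write_brainvision <- function(raw, basename,
                              binary_format = c("IEEE_FLOAT_32", "INT_16"),
                              resolution = 0.1) {
  stopifnot(inherits(raw, "raw_recording"))
  binary_format <- match.arg(binary_format)
  nch <- nrow(raw$data)
  res <- rep_len(if (binary_format == "IEEE_FLOAT_32") 1 else resolution, nch)
  base <- basename(basename)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "", "[Common Infos]", "Codepage=UTF-8",
           sprintf("DataFile=%s.eeg", base),
           sprintf("MarkerFile=%s.vmrk", base),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           sprintf("NumberOfChannels=%d", nch),
           sprintf("SamplingInterval=%.10g", 1e6 / raw$fs),
           "", "[Binary Infos]",
           sprintf("BinaryFormat=%s", binary_format),
           "", "[Channel Infos]",
           sprintf("Ch%d=%s,,%.10g,µV", seq_len(nch), raw$channel_names, res))
  writeLines(hdr, paste0(basename, ".vhdr"), useBytes = TRUE)

  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]", "Codepage=UTF-8",
          sprintf("DataFile=%s.eeg", base),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,0")
  if (nrow(raw$events) > 0)
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(raw$events)) + 1L,
                        raw$events$code, raw$events$sample))
  writeLines(mk, paste0(basename, ".vmrk"), useBytes = TRUE)

  con <- file(paste0(basename, ".eeg"), "wb")
  on.exit(close(con))
  interleaved <- as.vector(raw$data)       # column-major = multiplexed
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    scaled <- round(sweep(raw$data, 1L, res, "/"))
    if (any(abs(scaled) > 32767))
      stop_config("INT_16 overflow: increase `resolution`")
    writeBin(as.integer(as.vector(scaled)), con, size = 2, endian = "little")
  }
  invisible(basename)
}

# minimal INI-section parser for .vhdr/.vmrk files
parse_bv_ini <- function(lines) {
  sec <- NULL; out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    if (grepl("^\\s*\\[", ln)) {
      sec <- gsub("^\\s*\\[|\\]\\s*$", "", ln)
      out[[sec]] <- character()
    } else if (!is.null(sec) && grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      out[[sec]][trimws(key)] <- val
    }
  }
  out
}

#' Read a BrainVision triplet
#'
#' Reads the `.vhdr` header, resolves the companion `.vmrk` and `.eeg` files,
#' and returns data in microvolt regardless of the on-disk resolution.
#' Supports binary `IEEE_FLOAT_32` and `INT_16` in both `MULTIPLEXED` and
#' `VECTORIZED` orientations.
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @return a [raw_recording()].
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop_config("header file not found: %s", vhdr_path)
  ini <- parse_bv_ini(readLines(vhdr_path, encoding = "UTF-8", warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  chi <- ini[["Channel Infos"]]
  dir <- dirname(vhdr_path)
  need <- function(tbl, key, where) {
    if (is.null(tbl) || is.na(tbl[key]))
      stop_config("header field missing: %s (%s)", key, where)
    unname(tbl[key])
  }
  eeg_path <- file.path(dir, need(ci, "DataFile", "Common Infos"))
  vmrk_path <- file.path(dir, need(ci, "MarkerFile", "Common Infos"))
  if (!file.exists(eeg_path)) stop_config("missing companion file: %s", eeg_path)
  nch <- as.integer(need(ci, "NumberOfChannels", "Common Infos"))
  fs <- 1e6 / as.numeric(need(ci, "SamplingInterval", "Common Infos"))
  orientation <- toupper(need(ci, "DataOrientation", "Common Infos"))
  fmt <- toupper(need(bi, "BinaryFormat", "Binary Infos"))
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    stop_config("unknown BinaryFormat '%s'", fmt)

  ch <- lapply(seq_len(nch), function(i) {
    val <- chi[sprintf("Ch%d", i)]
    if (is.na(val)) stop_config("channel-count mismatch: Ch%d missing", i)
    strsplit(val, ",")[[1]]
  })
  channel_names <- vapply(ch, `[`, character(1), 1L)
  res <- vapply(ch, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))

  sz <- file.size(eeg_path)
  bytes <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  n_vals <- sz %/% bytes
  if (n_vals %% nch != 0)
    stop_config("channel-count mismatch: %d values not divisible by %d channels",
                n_vals, nch)
  con <- file(eeg_path, "rb")
  vals <- if (fmt == "IEEE_FLOAT_32")
    readBin(con, "numeric", n_vals, size = 4, endian = "little")
  else
    readBin(con, "integer", n_vals, size = 2, endian = "little")
  close(con)
  n_samp <- n_vals %/% nch
  data <- if (orientation == "MULTIPLEXED") matrix(vals, nrow = nch)
          else t(matrix(vals, nrow = n_samp))
  if (fmt == "INT_16") data <- sweep(data, 1L, res, "*")

  events <- data.frame(sample = integer(), code = character())
  if (file.exists(vmrk_path)) {
    mki <- parse_bv_ini(readLines(vmrk_path, encoding = "UTF-8", warn = FALSE))
    mk <- mki[["Marker Infos"]]
    if (!is.null(mk)) {
      parts <- lapply(mk, function(v) strsplit(v, ",")[[1]])
      keep <- vapply(parts, function(p) length(p) >= 3 && p[1] != "New Segment",
                     logical(1))
      if (any(keep))
        events <- data.frame(
          sample = vapply(parts[keep], function(p) as.integer(p[3]), integer(1)),
          code = vapply(parts[keep], function(p) p[2], character(1)))
    }
  }
  raw_recording(data, fs = fs, channel_names = channel_names, events = events)
}
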