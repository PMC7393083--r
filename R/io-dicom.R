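# Compact DICOM series reader.
#
# Scope: uncompressed little-endian CT slices (explicit or implicit VR),
# single frame per file, one series per directory. This covers standard CT
# exports and everything the package's own tooling produces; compressed
# transfer syntaxes are rejected with a clear error.

DCM_TAGS <- list(
  transfer_syntax  = c(0x0002, 0x0010),
  ipp              = c(0x0020, 0x0032),
  rows             = c(0x0028, 0x0010),
  cols             = c(0x0028, 0x0011),
  pixel_spacing    = c(0x0028, 0x0030),
  bits_allocated   = c(0x0028, 0x0100),
  pixel_rep        = c(0x0028, 0x0103),
  window_center    = c(0x0028, 0x1050),
  window_width     = c(0x0028, 0x1051),
  rescale_intercept = c(0x0028, 0x1052),
  rescale_slope    = c(0x0028, 0x1053),
  pixel_data       = c(0x7FE0, 0x0010)
)

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
dcm_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

# parse one file's data elements into a named list of raw values
dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 136L ||
      rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  out <- list()
  pos <- 133L
  explicit <- TRUE      # file meta group is always explicit VR
  ts <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  n <- length(raw)
  while (pos + 7L <= n) {
    grp <- dcm_u16(raw, pos); ele <- dcm_u16(raw, pos + 2L)
    pos <- pos + 4L
    if (!is.null(ts) && grp > 0x0002 && ts == "1.2.840.10008.1.2") {
      explicit <- FALSE
    }
    if (explicit || grp == 0x0002) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% long_vrs) {
        len <- dcm_u32(raw, pos + 4L); pos <- pos + 8L
      } else {
        len <- dcm_u16(raw, pos + 2L); pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(raw, pos); pos <- pos + 4L
    }
    if (len == 4294967295) {  # undefined length: scan for sequence delimiter
      del <- as.raw(c(0xFE, 0xFF, 0xDD, 0xE0))
      j <- pos
      while (j + 3L <= n && !(raw[j] == del[1] && raw[j + 1L] == del[2] &&
                              raw[j + 2L] == del[3] && raw[j + 3L] == del[4])) {
        j <- j + 1L
      }
      pos <- j + 8L
      next
    }
    val_end <- pos + len - 1L
    key <- NULL
    for (nm in names(DCM_TAGS)) {
      tg <- DCM_TAGS[[nm]]
      if (grp == tg[1] && ele == tg[2]) { key <- nm; break }
    }
    if (!is.null(key) && len > 0) {
      out[[key]] <- raw[pos:val_end]
      if (key == "transfer_syntax") {
        ts <- sub("\\0+$", "", rawToChar(out[[key]]))
        out$transfer_syntax_uid <- ts
        if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
          stop("unsupported (compressed?) DICOM transfer syntax: ", ts,
               call. = FALSE)
        }
      }
    }
    pos <- val_end + 1L
  }
  out
}

dcm_numeric <- function(rawval) {
  if (is.null(rawval)) return(NULL)
  txt <- sub("\\0+$", "", rawToChar(rawval))
  as.numeric(strsplit(trimws(txt), "\\\\")[[1]])
}
dcm_us <- function(rawval) {
  if (is.null(rawval)) return(NULL)
  dcm_u16(rawval, 1L)
}

dcm_slice <- function(path) {
  el <- dcm_parse_file(path)
  rows <- dcm_us(el$rows); cols <- dcm_us(el$cols)
  if (is.null(rows) || is.null(cols) || is.null(el$pixel_data)) {
    stop("DICOM file lacks image data: ", path, call. = FALSE)
  }
  bits <- dcm_us(el$bits_allocated) %||% 16L
  signed <- (dcm_us(el$pixel_rep) %||% 1L) == 1L
  vals <- if (bits == 16L) {
    readBin(el$pixel_data, "integer", n = rows * cols, size = 2L,
            signed = signed, endian = "little")
  } else if (bits == 8L) {
    as.integer(el$pixel_data)
  } else {
    stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  }
  slope <- dcm_numeric(el$rescale_slope) %||% 1
  inter <- dcm_numeric(el$rescale_intercept) %||% 0
  ps <- dcm_numeric(el$pixel_spacing) %||% c(1, 1)   # (row=y, col=x)
  ipp <- dcm_numeric(el$ipp) %||% c(0, 0, NA)
  wc <- dcm_numeric(el$window_center)
  ww <- dcm_numeric(el$window_width)
  # pixel data is row-major (x fastest): matrix(nrow=cols) is (x, y)
  img <- t(matrix(vals * slope + inter, nrow = cols, ncol = rows))  # (y, x)
  list(img = img, z = ipp[3], spacing_yx = ps,
       wc = wc[1], ww = ww[1], origin_xy = ipp[1:2])
}

#' Read a DICOM series directory into a CT volume
#'
#' Slices are sorted by the z-component of ImagePositionPatient; the slice
#' spacing is the median inter-slice gap and must be consistent across the
#' stack (see `gap_tol`).
#'
#' @inheritParams read_volume
#' @return a [ct_volume()] in HU (RescaleSlope/Intercept applied).
#' @export
read_dicom_series <- function(path, default_window = c(-600, 1500),
                              gap_tol = 0.01) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  assert_that(length(files) >= 2L, "DICOM directory needs at least two slices")
  slices <- lapply(files, dcm_slice)
  zs <- vapply(slices, function(s) s$z, numeric(1))
  assert_that(all(is.finite(zs)), "missing ImagePositionPatient in series")
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  gaps <- diff(zs)
  sz <- stats::median(gaps)
  assert_that(sz > 0, "degenerate slice positions (zero gap)")
  bad <- which(abs(gaps - sz) > gap_tol * sz)
  if (length(bad)) {
    stop(sprintf(
      "inconsistent slice spacing: gap %g mm between slices %d and %d (median %g mm)",
      gaps[bad[1]], bad[1], bad[1] + 1L, sz), call. = FALSE)
  }
  shp <- dim(slices[[1]]$img)
  data <- array(0, c(length(slices), shp[1], shp[2]))
  for (i in seq_along(slices)) {
    assert_that(identical(dim(slices[[i]]$img), shp),
                "slice dimensions differ within the series")
    data[i, , ] <- slices[[i]]$img
  }
  ps <- slices[[1]]$spacing_yx
  wc <- slices[[1]]$wc; ww <- slices[[1]]$ww
  if (is.null(wc) || is.null(ww) || !is.finite(wc) || !is.finite(ww)) {
    wc <- default_window[1]; ww <- default_window[2]
    message(sprintf("no window tags in series; using default WC=%g WW=%g", wc, ww))
  }
  ct_volume(data, spacing = c(sz, ps[1], ps[2]),
            origin = c(zs[1], slices[[1]]$origin_xy[2], slices[[1]]$origin_xy[1]),
            window_center = wc, window_width = ww)
}
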