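#' Construct a multichannel image
#'
#' The container for raw detector data: an `H x W x n` array of nonnegative
#' per-channel intensities on a photon-count scale, channels ordered by
#' ascending center wavelength (channel axis last). Channel metadata is
#' carried as labels only and never enters any computation.
#'
#' @param intensities Numeric `H x W x n` array (or `H x W` matrix for a
#'   single channel, rejected since n >= 2 is required).
#' @param channel_centers Optional per-channel center wavelengths (nm).
#' @param channel_bandwidths Optional per-channel filter bandwidths (nm).
#' @param channel_names Optional per-channel names.
#' @return Object of class `"multichannel_image"` (an array subclass).
#' @export
multichannel_image <- function(intensities, channel_centers = NULL,
                               channel_bandwidths = NULL, channel_names = NULL) {
  a <- intensities
  if (length(dim(a)) != 3L)
    stop("intensities must be an H x W x n array with n >= 2 channels")
  if (dim(a)[3L] < 2L)
    stop("a multichannel image needs at least 2 channels")
  if (anyNA(a) || any(a < 0))
    stop("intensities must be nonnegative and finite")
  for (meta in list(channel_centers, channel_bandwidths, channel_names))
    if (!is.null(meta) && length(meta) != dim(a)[3L])
      stop("channel metadata length must equal the number of channels")
  structure(unclass(a), class = "multichannel_image",
            channel_centers = channel_centers,
            channel_bandwidths = channel_bandwidths,
            channel_names = channel_names)
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x)
  cat("<multichannel_image>", d[1L], "x", d[2L], "pixels,", d[3L], "channels\n")
  cn <- attr(x, "channel_names")
  cc <- attr(x, "channel_centers")
  if (!is.null(cn) || !is.null(cc))
    cat("  channels:", paste(if (is.null(cn)) sprintf("%g nm", cc) else cn,
                             collapse = ", "), "\n")
  cat("  intensity range: [", signif(min(x), 4), ",", signif(max(x), 4), "]\n")
  invisible(x)
}

#' Default two-photon detection filter set
#'
#' Center wavelength and bandwidth labels of a seven-filter PMT detection
#' cascade commonly used for blue-to-near-infrared multiplexing
#' (466/40, 525/50, 562/40, 593/40, 617/70, 655/40, 710/40 nm). Used purely
#' as channel labels; no computation reads these numbers.
#'
#' @param n Number of channels (1..7).
#' @return Data frame with columns `center` and `bandwidth` (nm).
#' @export
default_filter_set <- function(n) {
  centers <- c(466, 525, 562, 593, 617, 655, 710)
  halfwidths <- c(20, 25, 20, 20, 35, 20, 20)
  if (n < 1L || n > length(centers))
    stop("default filter set supports 1..7 channels")
  data.frame(center = centers[seq_len(n)], bandwidth = 2 * halfwidths[seq_len(n)])
}

## ---- minimal baseline TIFF writer -----------------------------------------
## The installed TIFF reader handles IEEE-float and 16-bit files; writing
## float32 samples and ImageDescription tags is done here directly
## (little-endian, one strip per page, no compression).

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

tiff_entry <- function(tag, type, count, value_raw) {
  # value_raw: exactly 4 bytes (inline value, left-justified) or an offset
  c(u16le(tag), u16le(type), u32le(count), value_raw)
}

inline4 <- function(bytes) c(bytes, raw(4L - length(bytes)))

page_payload <- function(page, format) {
  # row-major, channel-interleaved sample stream
  if (length(dim(page)) == 3L) {
    vals <- aperm(page, c(3L, 2L, 1L))  # channel fastest, then column, then row
  } else {
    vals <- t(page)
  }
  v <- as.vector(vals)
  if (format == "float32") {
    writeBin(as.numeric(v), raw(), size = 4, endian = "little")
  } else {
    if (any(v < 0) || any(v > 65535))
      stop("uint16 TIFF values must lie in [0, 65535]")
    writeBin(as.integer(round(v)), raw(), size = 2, endian = "little")
  }
}

write_tiff_pages <- function(pages, path, format = c("float32", "uint16"),
                             description = NULL) {
  format <- match.arg(format)
  bps <- if (format == "float32") 32L else 16L
  sfmt <- if (format == "float32") 3L else 1L
  npages <- length(pages)
  stopifnot(npages >= 1L)

  payloads <- lapply(pages, page_payload, format = format)
  dims <- lapply(pages, function(p) {
    d <- dim(p)
    list(h = d[1L], w = d[2L], spp = if (length(d) == 3L) d[3L] else 1L)
  })
  desc_raw <- if (!is.null(description)) c(charToRaw(description), as.raw(0L))

  # pass 1: layout offsets (everything kept word-aligned)
  pad2 <- function(k) k + (k %% 2L)
  cur <- 8L
  data_off <- ifd_off <- extra_off <- integer(npages)
  ntags <- integer(npages)
  extra_bytes <- vector("list", npages)
  for (p in seq_len(npages)) {
    d <- dims[[p]]
    tags <- 10L                                 # fixed tag set
    extra <- raw(0)
    extra_slots <- list()
    if (d$spp > 2L) {                           # BitsPerSample / SampleFormat arrays
      extra_slots$bits <- length(extra); extra <- c(extra, u16le(rep(bps, d$spp)))
      extra_slots$sfmt <- length(extra); extra <- c(extra, u16le(rep(sfmt, d$spp)))
    }
    if (d$spp > 1L) {                           # ExtraSamples: unspecified channels
      tags <- tags + 1L
      if (d$spp - 1L > 2L) {
        extra_slots$exs <- length(extra); extra <- c(extra, u16le(rep(0L, d$spp - 1L)))
      }
    }
    if (p == 1L && !is.null(desc_raw)) {
      tags <- tags + 1L
      if (length(desc_raw) > 4L) {
        extra_slots$desc <- length(extra); extra <- c(extra, desc_raw)
        if (length(extra) %% 2L) extra <- c(extra, raw(1))
      }
    }
    data_off[p] <- cur; cur <- cur + pad2(length(payloads[[p]]))
    ifd_off[p] <- cur; cur <- cur + 2L + 12L * tags + 4L
    extra_off[p] <- cur; cur <- cur + pad2(length(extra))
    ntags[p] <- tags
    extra_bytes[[p]] <- list(bytes = extra, slots = extra_slots)
  }

  # pass 2: emit
  out <- c(charToRaw("II"), u16le(42L), u32le(ifd_off[1L]))
  for (p in seq_len(npages)) {
    d <- dims[[p]]
    ex <- extra_bytes[[p]]
    pay <- payloads[[p]]
    if (length(pay) %% 2L) pay <- c(pay, raw(1))
    entries <- list(
      tiff_entry(256L, 4L, 1L, u32le(d$w)),
      tiff_entry(257L, 4L, 1L, u32le(d$h)),
      if (d$spp > 2L)
        tiff_entry(258L, 3L, d$spp, u32le(extra_off[p] + ex$slots$bits))
      else
        tiff_entry(258L, 3L, d$spp, inline4(u16le(rep(bps, d$spp)))),
      tiff_entry(259L, 3L, 1L, inline4(u16le(1L))),
      tiff_entry(262L, 3L, 1L, inline4(u16le(1L)))
    )
    if (p == 1L && !is.null(desc_raw)) {
      val <- if (length(desc_raw) > 4L) u32le(extra_off[p] + ex$slots$desc)
             else inline4(desc_raw)
      entries <- c(entries, list(tiff_entry(270L, 2L, length(desc_raw), val)))
    }
    entries <- c(entries, list(
      tiff_entry(273L, 4L, 1L, u32le(data_off[p])),
      tiff_entry(277L, 3L, 1L, inline4(u16le(d$spp))),
      tiff_entry(278L, 4L, 1L, u32le(d$h)),
      tiff_entry(279L, 4L, 1L, u32le(length(payloads[[p]]))),
      if (d$spp > 1L) {
        if (d$spp - 1L > 2L)
          tiff_entry(338L, 3L, d$spp - 1L, u32le(extra_off[p] + ex$slots$exs))
        else
          tiff_entry(338L, 3L, d$spp - 1L, inline4(u16le(rep(0L, d$spp - 1L))))
      },
      if (d$spp > 2L)
        tiff_entry(339L, 3L, d$spp, u32le(extra_off[p] + ex$slots$sfmt))
      else
        tiff_entry(339L, 3L, d$spp, inline4(u16le(rep(sfmt, d$spp))))
    ))
    next_ifd <- if (p < npages) ifd_off[p + 1L] else 0L
    exb <- ex$bytes
    if (length(exb) %% 2L) exb <- c(exb, raw(1))
    out <- c(out, pay,
             u16le(ntags[p]), unlist(entries), u32le(next_ifd), exb)
  }
  writeBin(out, path)
  invisible(path)
}

ome_description <- function(n, names = NULL, centers = NULL) {
  chans <- vapply(seq_len(n), function(j) {
    attrs <- sprintf(' ID="Channel:%d"', j - 1L)
    if (!is.null(names)) attrs <- paste0(attrs, sprintf(' Name="%s"', names[j]))
    if (!is.null(centers))
      attrs <- paste0(attrs, sprintf(' EmissionWavelength="%g" EmissionWavelengthUnit="nm"',
                                     centers[j]))
    sprintf("<Channel%s/>", attrs)
  }, "")
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
         '<Image ID="Image:0"><Pixels ID="Pixels:0" SizeC="', n, '">',
         paste(chans, collapse = ""), "</Pixels></Image></OME>")
}

parse_ome_channels <- function(description) {
  doc <- tryCatch(xml2::read_xml(description), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  ch <- xml2::xml_find_all(doc, "//*[local-name()='Channel']")
  if (!length(ch)) return(NULL)
  nm <- xml2::xml_attr(ch, "Name")
  wl <- suppressWarnings(as.numeric(xml2::xml_attr(ch, "EmissionWavelength")))
  list(names = if (!all(is.na(nm))) nm,
       centers = if (!all(is.na(wl))) wl)
}

#' Write a multichannel image as TIFF
#'
#' Intensities are stored as 32-bit IEEE floats, lossless at single
#' precision. Layouts: `"pages"` writes one grayscale page per channel,
#' `"samples"` one page with channel-interleaved samples, `"ome"` is the
#' pages layout plus an OME-XML ImageDescription carrying channel names and
#' emission wavelengths.
#'
#' @param image A [multichannel_image()].
#' @param path Output file path.
#' @param layout One of `"pages"`, `"samples"`, `"ome"`.
#' @return `path`, invisibly.
#' @export
write_multichannel_tiff <- function(image, path,
                                    layout = c("pages", "samples", "ome")) {
  layout <- match.arg(layout)
  stopifnot(inherits(image, "multichannel_image"))
  n <- dim(image)[3L]
  a <- unclass(image)
  if (layout == "samples") {
    write_tiff_pages(list(a), path, "float32")
  } else {
    pages <- lapply(seq_len(n), function(j) a[, , j])
    desc <- if (layout == "ome")
      ome_description(n, attr(image, "channel_names"), attr(image, "channel_centers"))
    write_tiff_pages(pages, path, "float32", description = desc)
  }
  invisible(path)
}

#' Read a multichannel TIFF
#'
#' Normalizes the channel axis to last. Integer data are promoted to float
#' counts without rescaling; float data are read as stored. With
#' `layout = "ome"` (or when an OME-XML ImageDescription is present in a
#' multipage file) channel names and emission wavelengths are attached as
#' metadata. A file whose layout cannot be inferred (multiple pages each
#' carrying multiple samples) is rejected unless `layout` is given.
#'
#' @param path TIFF file path.
#' @param layout `NULL` to infer, or one of `"pages"` (pages are channels),
#'   `"samples"` (samples within one page are channels), `"ome"`.
#' @return A [multichannel_image()].
#' @export
read_multichannel_tiff <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!is.null(layout))
    layout <- match.arg(layout, c("pages", "samples", "ome"))
  probe <- tiff::readTIFF(path, info = TRUE, payload = FALSE)
  is_float <- identical(probe$sample.format[1L], "float")
  pages <- if (is_float) tiff::readTIFF(path, all = TRUE, info = TRUE)
           else lapply(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
                       function(p) { storage.mode(p) <- "double"; p })
  if (!is.list(pages)) pages <- list(pages)
  spp <- dim(pages[[1L]])
  spp <- if (length(spp) == 3L) spp[3L] else 1L
  if (is.null(layout)) {
    if (length(pages) > 1L && spp > 1L)
      stop("ambiguous TIFF layout (multiple pages and multiple samples); ",
           "pass layout = \"pages\" or \"samples\" explicitly")
    layout <- if (spp > 1L) "samples" else "pages"
  }
  desc <- attr(pages[[1L]], "description")
  if (is.null(desc) && "description" %in% names(probe))
    desc <- probe$description[1L]
  if (layout == "samples") {
    if (length(pages) != 1L) stop("samples-as-channels expects a single page")
    a <- pages[[1L]]
    if (length(dim(a)) != 3L || dim(a)[3L] < 2L)
      stop("samples-as-channels needs >= 2 samples per pixel")
  } else {
    if (length(pages) < 2L)
      stop("pages-as-channels needs >= 2 pages (channels)")
    if (spp != 1L) stop("pages-as-channels expects single-sample pages")
    a <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  }
  meta <- if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE))
    parse_ome_channels(desc)
  multichannel_image(a,
                     channel_centers = meta$centers,
                     channel_names = meta$names)
}

#' Write a label image as 16-bit TIFF
#'
#' @param labels Integer matrix (0 = background, 1..m = class labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  if (!is.matrix(labels) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be a matrix of nonnegative integers")
  write_tiff_pages(list(labels), path, "uint16")
}

#' Read a 16-bit label TIFF
#'
#' @param path Path written by [write_label_tiff()].
#' @return Integer matrix of labels.
#' @export
read_label_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(m) || length(dim(m)) != 2L)
    stop("expected a single-page single-sample label image")
  storage.mode(m) <- "integer"
  m
}
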