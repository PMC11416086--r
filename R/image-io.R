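# Image input/output and physical scale handling for scanned WSP cards.

#' 8-bit grayscale image
#'
#' Container for the working representation of a scanned water-sensitive
#' paper card: an integer matrix of gray levels in \[0, 255\] plus the scan
#' resolution in dots per inch, which converts pixel counts to physical
#' area.
#'
#' @param pixels Numeric matrix of gray levels; values must be whole numbers
#'   in \[0, 255\]. Rows are image rows (height), columns are image columns
#'   (width).
#' @param dpi Positive scan resolution in dots per inch. Default 96, the
#'   resolution of a typical flatbed WSP scan.
#' @return An object of class `gray_image`: a list with elements `pixels`
#'   (integer matrix), `height_px`, `width_px` and `dpi`.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16), dpi = 96)
#' dim(img)
#' @export
gray_image <- function(pixels, dpi = 96) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one pixel", call. = FALSE)
  }
  if (anyNA(pixels)) stop("`pixels` contains NA", call. = FALSE)
  if (any(pixels < 0 | pixels > 255) || any(pixels != round(pixels))) {
    stop("gray levels must be integers in [0, 255]", call. = FALSE)
  }
  check_scalar_number(dpi, "dpi", lower = .Machine$double.eps)
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, height_px = nrow(pixels), width_px = ncol(pixels),
         dpi = as.numeric(dpi)),
    class = "gray_image"
  )
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px @ %.4g DPI, gray range [%d, %d]\n",
              x$height_px, x$width_px, x$dpi,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

#' Physical scale of a scan
#'
#' Maps pixel units to millimetres via the scan resolution. The card
#' dimensions default to the standard 76 mm x 26 mm WSP format.
#'
#' @param dpi Positive dots per inch (default 96).
#' @param paper_width_mm,paper_height_mm Nominal card dimensions in mm.
#' @return An object of class `physical_scale` with elements `mm_per_px`
#'   (= 25.4 / dpi), `dpi`, `paper_width_mm`, `paper_height_mm`.
#' @examples
#' physical_scale(96)$mm_per_px    # 0.2646 mm per pixel
#' @export
physical_scale <- function(dpi = 96, paper_width_mm = 76,
                           paper_height_mm = 26) {
  check_scalar_number(dpi, "dpi", lower = .Machine$double.eps)
  check_scalar_number(paper_width_mm, "paper_width_mm",
                      lower = .Machine$double.eps)
  check_scalar_number(paper_height_mm, "paper_height_mm",
                      lower = .Machine$double.eps)
  structure(
    list(mm_per_px = 25.4 / dpi, dpi = as.numeric(dpi),
         paper_width_mm = paper_width_mm, paper_height_mm = paper_height_mm),
    class = "physical_scale"
  )
}

#' Scanned area of an image in square centimetres
#'
#' Physical area of the raster, the denominator A of the droplet-density
#' statistic D = N / A.
#'
#' @param img A [gray_image()].
#' @param scale A [physical_scale()]; defaults to one built from the image's
#'   own DPI.
#' @return Positive scalar, area in cm^2:
#'   `width_px * height_px * mm_per_px^2 / 100`.
#' @examples
#' img <- gray_image(matrix(255L, 96, 96), dpi = 96)
#' physical_area_cm2(img)   # one square inch = 6.4516 cm^2
#' @export
physical_area_cm2 <- function(img, scale = physical_scale(img$dpi)) {
  stopifnot(inherits(img, "gray_image"), inherits(scale, "physical_scale"))
  img$width_px * img$height_px * scale$mm_per_px^2 / 100
}

#' Read a scanned WSP image
#'
#' Reads a PNG, JPEG or plain PNM (PGM/PPM) raster and converts it to the
#' 8-bit grayscale working representation. RGB scans are reduced to a single
#' channel; the default is the red channel, which carries the strongest
#' contrast on WSP (yellow paper is bright in red, blue stains are dark).
#' `channel = "luma"` uses the ITU-R BT.601 weighting
#' 0.299 R + 0.587 G + 0.114 B.
#'
#' Resolution is taken from file metadata when present (PNG), else from
#' `dpi_override`, else falls back to 96 DPI with a warning. Note PNG stores
#' resolution in pixels per metre, so a nominal 96 DPI reads back as
#' approximately 95.99.
#'
#' @param path Path to a `.png`, `.jpg`/`.jpeg`, `.pgm`/`.ppm`/`.pnm` file.
#'   TIFF is not supported (no TIFF decoder is available).
#' @param channel One of `"red"`, `"luma"`, `"green"`, `"blue"`; ignored for
#'   single-channel inputs.
#' @param dpi_override Optional positive DPI used when the file has no
#'   resolution metadata.
#' @return A [gray_image()].
#' @examples
#' f <- tempfile(fileext = ".pgm")
#' write_pnm(matrix(c(0L, 255L), 2, 2), f)
#' load_image(f, dpi_override = 96)
#' @export
load_image <- function(path, channel = c("red", "luma", "green", "blue"),
                       dpi_override = NULL) {
  channel <- match.arg(channel)
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file not found: %s", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  dpi <- NULL
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    if (!is.null(info$dpi) && all(is.finite(info$dpi)) &&
        all(info$dpi > 0)) {
      dpi <- mean(info$dpi)
    }
    px <- channel_to_gray(arr, channel)
  } else if (ext %in% c("jpg", "jpeg")) {
    arr <- jpeg::readJPEG(path)
    px <- channel_to_gray(arr, channel)
  } else if (ext %in% c("pgm", "ppm", "pnm")) {
    arr <- read_pnm(path)
    px <- if (is.matrix(arr)) arr else channel_to_gray(arr / 255, channel)
  } else if (ext %in% c("tif", "tiff")) {
    stop(sprintf("unsupported format for %s: no TIFF decoder available; ",
                 path), "convert to PNG first", call. = FALSE)
  } else {
    stop(sprintf("unsupported image format: %s", path), call. = FALSE)
  }
  if (length(px) == 0L || nrow(px) < 1L || ncol(px) < 1L) {
    stop(sprintf("zero-sized image: %s", path), call. = FALSE)
  }
  if (is.null(dpi)) {
    if (!is.null(dpi_override)) {
      check_scalar_number(dpi_override, "dpi_override",
                          lower = .Machine$double.eps)
      dpi <- dpi_override
    } else {
      warning(sprintf("no resolution metadata in %s; assuming 96 DPI", path),
              call. = FALSE)
      dpi <- 96
    }
  }
  gray_image(px, dpi = dpi)
}

# [0,1] float array (matrix, or H x W x {2,3,4}) -> integer gray matrix.
channel_to_gray <- function(arr, channel) {
  if (is.matrix(arr)) {
    px <- arr
  } else if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch == 2L) {           # gray + alpha
      px <- arr[, , 1]
    } else {
      px <- switch(channel,
        red   = arr[, , 1],
        green = arr[, , 2],
        blue  = arr[, , 3],
        luma  = 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
      )
    }
  } else {
    stop("unsupported image array layout", call. = FALSE)
  }
  matrix(as.integer(round(pmin(pmax(px, 0), 1) * 255)),
         nrow(px), ncol(px))
}

#' Read a plain or raw PNM image (PGM/PPM)
#'
#' Minimal reader for the text-friendly Netpbm formats: P2/P5 grayscale and
#' P3/P6 RGB, maxval at most 255. Values are rescaled to \[0, 255\] when
#' maxval differs.
#'
#' @param path Path to the PNM file.
#' @return An integer matrix (grayscale) or an H x W x 3 integer array (RGB).
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop(sprintf("not a supported PNM file: %s", path), call. = FALSE)
  }
  if (magic %in% c("P2", "P3")) {
    close(con)
    on.exit()
    return(read_pnm_plain(path, magic))
  }
  # Tokenized header: width, height, maxval; '#' starts a comment.
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (length(ch) == 0L || ch == "") stop("truncated PNM header")
      if (ch == "#") {
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1L))
          if (ch == "\n" || ch == "") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok) > 0L) break
      } else {
        tok <- c(tok, ch)
      }
    }
    as.integer(paste(tok, collapse = ""))
  }
  w <- read_token()
  h <- read_token()
  maxval <- read_token()
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) {
    stop("invalid PNM dimensions", call. = FALSE)
  }
  if (is.na(maxval) || maxval < 1L || maxval > 255L) {
    stop("PNM maxval must be in [1, 255]", call. = FALSE)
  }
  nch <- if (magic == "P6") 3L else 1L
  n <- w * h * nch
  vals <- as.integer(readBin(con, "raw", n))
  pnm_assemble(vals, w, h, nch, maxval)
}

read_pnm_plain <- function(path, magic) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- unlist(strsplit(paste(lines, collapse = " "), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.integer(toks[-1]))   # drop magic token
  if (anyNA(vals) || length(vals) < 3L) {
    stop(sprintf("malformed plain PNM file: %s", path), call. = FALSE)
  }
  w <- vals[1]; h <- vals[2]; maxval <- vals[3]
  if (w < 1L || h < 1L) stop("invalid PNM dimensions", call. = FALSE)
  if (maxval < 1L || maxval > 255L) {
    stop("PNM maxval must be in [1, 255]", call. = FALSE)
  }
  nch <- if (magic == "P3") 3L else 1L
  pnm_assemble(vals[-(1:3)], w, h, nch, maxval)
}

pnm_assemble <- function(vals, w, h, nch, maxval) {
  n <- w * h * nch
  if (length(vals) != n) stop("truncated PNM pixel data", call. = FALSE)
  if (maxval != 255L) vals <- as.integer(round(vals * 255 / maxval))
  if (nch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    arr <- array(0L, c(h, w, 3L))          # interleaved RGB, row-major
    for (ch in 1:3) {
      arr[, , ch] <- matrix(vals[seq(ch, n, by = 3L)], h, w, byrow = TRUE)
    }
    arr
  }
}

#' Write a plain-text PNM image (P2/P3)
#'
#' Writes grayscale matrices as plain PGM (P2) and H x W x 3 arrays as plain
#' PPM (P3); values must be integers in \[0, 255\]. Plain formats are used so
#' fixtures stay human-readable text.
#'
#' @param pixels Integer matrix or H x W x 3 array in \[0, 255\].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pnm <- function(pixels, path) {
  if (any(pixels < 0 | pixels > 255) || any(pixels != round(pixels))) {
    stop("pixel values must be integers in [0, 255]", call. = FALSE)
  }
  if (is.matrix(pixels)) {
    header <- c("P2", paste(ncol(pixels), nrow(pixels)), "255")
    body <- apply(pixels, 1L, paste, collapse = " ")
  } else if (length(dim(pixels)) == 3L && dim(pixels)[3] == 3L) {
    header <- c("P3", paste(dim(pixels)[2], dim(pixels)[1]), "255")
    body <- vapply(seq_len(dim(pixels)[1]), function(r) {
      paste(as.vector(t(pixels[r, , ])), collapse = " ")
    }, character(1))
  } else {
    stop("`pixels` must be a matrix or an H x W x 3 array", call. = FALSE)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a droplet mask as PNG
#'
#' Serialises a binary droplet mask with droplet pixels at 255 and
#' background at 0. Note this polarity is chosen so droplets are visible
#' (white on black); it is the inverse of the thresholding rule's raw
#' output, which maps bright paper to 255.
#'
#' @param mask A [droplet_mask] (see [apply_threshold()]).
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "droplet_mask"))
  png::writePNG(ifelse(mask$pixels, 1, 0), path)
  invisible(path)
}
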