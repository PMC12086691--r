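# Images are held in memory as h x w x 3 arrays of 8-bit intensities
# (0..255, stored as doubles). Readers: PNG (via the png package) and the
# plain-text PPM dialects P3/P6. TIFF is not supported by this build: no
# TIFF reader is available in the dependency set; convert to PNG first.

#' Read an RGB image
#'
#' Supports 8-bit RGB PNG and PPM (ASCII `P3` or binary `P6`). Grayscale
#' input is replicated to three channels with a warning; an alpha channel is
#' dropped.
#'
#' @param path image file (`.png`, `.ppm`).
#' @return h x w x 3 array of intensities in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) {
      warning("grayscale image; replicating channel to RGB")
      a <- array(rep(a, 3L), c(dim(a), 3L))
    }
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
    if (dim(a)[3] == 1L) {
      warning("grayscale image; replicating channel to RGB")
      a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
    }
    return(round(a * 255))
  }
  if (ext %in% c("ppm", "pnm")) return(read_ppm(path))
  stop("unsupported image format '.", ext, "'; use PNG or PPM ",
       "(TIFF is not supported -- convert to PNG first)")
}

#' Write an RGB image
#'
#' Writes PNG or ASCII PPM (`P3`) depending on the file extension.
#'
#' @param img h x w x 3 array of intensities in \[0, 255\].
#' @param path output path (`.png` or `.ppm`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  img <- pmin(pmax(round(img), 0), 255)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext %in% c("ppm", "pnm")) {
    write_ppm(img, path)
  } else stop("unsupported image format '.", ext, "'")
  invisible(path)
}

read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P3", "P6")) stop("corrupted PPM header in ", path,
                                      ": expected P3 or P6, got '", magic, "'")
  # header tokens: width height maxval, with '#' comments allowed
  tokens <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L) stop("truncated PPM header in ", path)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || !grepl("[0-9]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (anyNA(c(w, h, maxval)) || w < 1 || h < 1)
    stop("corrupted PPM header in ", path)
  npx <- as.double(w) * h * 3
  if (magic == "P6") {
    raw <- readBin(con, "integer", n = npx, size = 1L, signed = FALSE)
  } else {
    raw <- scan(con, what = integer(), n = npx, quiet = TRUE)
  }
  if (length(raw) < npx) stop("truncated PPM pixel data in ", path)
  # PPM stores pixels row-major, channels interleaved
  arr <- aperm(array(raw, c(3L, w, h)), c(3L, 2L, 1L))
  arr * (255 / maxval)
}

write_ppm <- function(img, path) {
  h <- dim(img)[1]; w <- dim(img)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0("P3\n", w, " ", h, "\n255\n"), con, eos = NULL)
  flat <- as.integer(aperm(img, c(3L, 2L, 1L)))  # interleave channels
  writeChar(paste0(paste(flat, collapse = "\n"), "\n"), con, eos = NULL)
  invisible(path)
}

#' Feature extraction configuration
#'
#' @param scales patch side lengths as multiples of the spot diameter;
#'   default `c(0.5, 1, 2)` (sub-spot, at-spot and context scales within
#'   the supported 0.1-3.0 range).
#' @param n_bins histogram bins per colour channel, default 10.
#' @param intensity_range intensity span of the input, default `c(0, 255)`
#'   for 8-bit images.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(scales = c(0.5, 1, 2), n_bins = 10L,
                           intensity_range = c(0, 255)) {
  if (any(scales <= 0)) stop("scales must be positive")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  structure(list(scales = scales, n_bins = n_bins, channels = 3L,
                 intensity_range = as.numeric(intensity_range)),
            class = "feature_config")
}

# Odd patch side so the centre pixel is well defined; at least 1 px.
patch_side <- function(scale, spot_diameter_px) {
  side <- max(1L, as.integer(round(scale * spot_diameter_px)))
  if (side %% 2L == 0L) side <- side + 1L
  side
}

#' Extract a square patch around a spot centre
#'
#' Returns the `side_px x side_px x 3` block centred at `centre_px`
#' (0-based `(row, col)` pixel coordinates). At image borders the patch is
#' clipped to the valid region, so the returned block may be smaller;
#' downstream histogram counts are conserved against the actual pixel
#' count.
#'
#' @param image h x w x 3 array.
#' @param centre_px numeric length-2, 0-based (row, col).
#' @param side_px odd positive patch side in pixels.
#' @param barcode optional spot name used in error messages.
#' @return Array block (possibly clipped).
#' @export
extract_patch <- function(image, centre_px, side_px, barcode = NULL) {
  h <- dim(image)[1]; w <- dim(image)[2]
  r <- round(centre_px[1]); c <- round(centre_px[2])
  if (r < 0 || r >= h || c < 0 || c >= w)
    stop("spot centre ", if (!is.null(barcode)) paste0("'", barcode, "' "),
         "(", r, ", ", c, ") lies outside the ", h, " x ", w, " image")
  half <- (side_px - 1) %/% 2
  rows <- max(0, r - half):min(h - 1, r + half)
  cols <- max(0, c - half):min(w - 1, c + half)
  image[rows + 1L, cols + 1L, , drop = FALSE]
}

#' Per-channel histogram bin counts of a patch
#'
#' Divides the intensity range of each channel into `n_bins` equal-width
#' bins and counts the pixels falling in each (the last bin is closed on
#' the right). Channel profiles are concatenated channel-major, so the
#' result has length `channels * n_bins` and per-channel sums equal the
#' patch pixel count.
#'
#' @param block patch array from [extract_patch()].
#' @param n_bins bins per channel.
#' @param intensity_range numeric length-2 bin span, default `c(0, 255)`.
#' @return Integer vector of length `3 * n_bins`.
#' @export
histogram_features <- function(block, n_bins = 10L,
                               intensity_range = c(0, 255)) {
  if (is.null(dim(block)) || any(dim(block)[1:2] == 0L) ||
      length(block) == 0L)
    stop("empty patch: cannot compute histogram features")
  lo <- intensity_range[1]; hi <- intensity_range[2]
  width <- (hi - lo) / n_bins
  nch <- dim(block)[3]
  out <- integer(0)
  for (ch in seq_len(nch)) {
    v <- as.numeric(block[, , ch])
    idx <- floor((v - lo) / width) + 1
    idx[v >= hi] <- n_bins   # right-closed last bin
    idx[idx < 1] <- 1L
    out <- c(out, tabulate(idx, nbins = n_bins))
  }
  out
}

#' Build the spot x feature matrix from an H&E image
#'
#' For every spot, extracts square patches at each configured scale
#' (multiples of the spot diameter) centred on the spot's full-resolution
#' pixel coordinates and concatenates per-channel histogram bin counts into
#' one row. Columns are ordered scale-major, then channel, then bin, and
#' named `s<scale>_<channel>_bin<i>`.
#'
#' @param image h x w x 3 array (see [read_image()]).
#' @param spot_table data.frame with columns `barcode`, `pixel_row`,
#'   `pixel_col` (0-based full-resolution coordinates), e.g. from
#'   [read_positions()].
#' @param config a [feature_config()].
#' @param spot_diameter_px spot diameter in pixels at the image's
#'   resolution.
#' @return A [spot_image_features()] with
#'   `length(scales) * 3 * n_bins` columns, rows in `spot_table` order.
#' @export
build_feature_matrix <- function(image, spot_table,
                                 config = feature_config(),
                                 spot_diameter_px) {
  stopifnot(is.data.frame(spot_table),
            all(c("barcode", "pixel_row", "pixel_col") %in%
                  names(spot_table)))
  if (missing(spot_diameter_px) || !is.numeric(spot_diameter_px))
    stop("spot_diameter_px is required (from the scale-factor descriptor ",
         "or an explicit argument)")
  h <- dim(image)[1]; w <- dim(image)[2]
  bad <- spot_table$pixel_row < 0 | spot_table$pixel_row >= h |
    spot_table$pixel_col < 0 | spot_table$pixel_col >= w
  if (any(bad))
    stop("spot centre(s) outside the image: ",
         paste(utils::head(spot_table$barcode[bad], 10L), collapse = ", "),
         if (sum(bad) > 10L) " ..." else "")
  sides <- vapply(config$scales, patch_side, integer(1),
                  spot_diameter_px = spot_diameter_px)
  f <- length(config$scales) * config$channels * config$n_bins
  M <- matrix(0, nrow(spot_table), f)
  cn <- unlist(lapply(config$scales, function(s)
    paste0("s", s, "_", rep(c("R", "G", "B"), each = config$n_bins),
           "_bin", rep(seq_len(config$n_bins), times = 3L))))
  for (i in seq_len(nrow(spot_table))) {
    row <- integer(0)
    for (sc in seq_along(sides)) {
      blk <- extract_patch(image,
                           c(spot_table$pixel_row[i], spot_table$pixel_col[i]),
                           sides[sc], barcode = spot_table$barcode[i])
      row <- c(row, histogram_features(blk, config$n_bins,
                                       config$intensity_range))
    }
    M[i, ] <- row
  }
  spot_image_features(M, barcodes = spot_table$barcode, feature_names = cn)
}

#' Load user-supplied spot features
#'
#' Reads a delimited table (first column barcode, remaining columns
#' non-negative features), validates it and re-orders the rows to the
#' barcode order of the paired expression object.
#'
#' @param path delimited text file (separator auto-detected among tab,
#'   comma, whitespace); a header row is expected.
#' @param barcodes character vector giving the required barcode order
#'   (e.g. `expr$barcodes`).
#' @return A [spot_image_features()] aligned to `barcodes`.
#' @export
load_user_features <- function(path, barcodes) {
  df <- read_delim_auto(path, header = TRUE)
  bc <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  if (anyNA(M)) stop("user feature table contains non-numeric or missing ",
                     "values")
  neg <- which(M < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop("negative feature value at barcode '", bc[neg[1, 1]],
         "', column '", colnames(M)[neg[1, 2]], "'")
  missing_bc <- setdiff(barcodes, bc)
  if (length(missing_bc) > 0L)
    stop("feature table is missing ", length(missing_bc), " barcode(s): ",
         paste(utils::head(missing_bc, 10L), collapse = ", "),
         if (length(missing_bc) > 10L) " ..." else "")
  M <- M[match(barcodes, bc), , drop = FALSE]
  spot_image_features(M, barcodes = barcodes,
                      feature_names = colnames(M))
}

#' Write spot features to delimited text
#'
#' @param features a [spot_image_features()].
#' @param path output path (tab-separated, barcode first column).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  df <- data.frame(barcode = features$barcodes,
                   features$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Sniff the field separator from the first line.
read_delim_auto <- function(path, header = TRUE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.table(path, header = header, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}
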