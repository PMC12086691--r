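#' Read a spot expression bundle
#'
#' Accepts either a directory holding a Matrix Market triplet matrix
#' (`matrix.mtx`, optionally gzipped) with `barcodes.tsv` and
#' `features.tsv`/`genes.tsv` lists (plain or gzipped), or a single dense
#' delimited table (first column barcodes, header row of gene
#' identifiers). On-disk orientation (spots x genes vs genes x spots) is
#' auto-detected from the list lengths; duplicate gene symbols are
#' disambiguated by suffixing.
#'
#' @param path bundle directory or dense table file.
#' @param orientation `"auto"` (detect from list lengths), or force
#'   `"spots_x_genes"` / `"genes_x_spots"` for ambiguous square matrices.
#' @return A [spot_expression()].
#' @export
read_expression_bundle <- function(path,
                                   orientation = c("auto", "spots_x_genes",
                                                   "genes_x_spots")) {
  orientation <- match.arg(orientation)
  if (dir.exists(path)) {
    mtx <- first_existing(path, c("matrix.mtx", "matrix.mtx.gz"))
    bcf <- first_existing(path, c("barcodes.tsv", "barcodes.tsv.gz"))
    gnf <- first_existing(path, c("features.tsv", "features.tsv.gz",
                                  "genes.tsv", "genes.tsv.gz"))
    M <- as.matrix(Matrix::readMM(mtx))
    barcodes <- read_first_column(bcf)
    genes <- read_first_column(gnf, prefer_second = TRUE)
    if (orientation == "auto") {
      if (nrow(M) == length(barcodes) && ncol(M) == length(genes)) {
        # already spots x genes
      } else if (nrow(M) == length(genes) && ncol(M) == length(barcodes)) {
        M <- t(M)
      } else {
        stop("matrix is ", nrow(M), " x ", ncol(M), " but the bundle lists ",
             length(barcodes), " barcodes and ", length(genes), " features")
      }
    } else if (orientation == "genes_x_spots") M <- t(M)
    if (nrow(M) != length(barcodes) || ncol(M) != length(genes))
      stop("matrix is ", nrow(M), " x ", ncol(M), " but the bundle lists ",
           length(barcodes), " barcodes and ", length(genes), " features")
  } else if (file.exists(path)) {
    df <- read_delim_auto(path, header = TRUE)
    barcodes <- as.character(df[[1]])
    M <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(M) <- "double"
    genes <- colnames(M)
  } else stop("no such bundle: ", path)
  if (min(M) < 0) stop("expression bundle contains negative entries")
  if (anyDuplicated(genes)) genes <- make.unique(genes, sep = "-dup")
  spot_expression(M, barcodes = barcodes, gene_ids = genes)
}

first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  stop("none of ", paste(names, collapse = ", "), " found in ", dir)
}

# Barcode/feature lists: one id per line, possibly tab-delimited with the
# symbol in the second column (CellRanger features.tsv).
read_first_column <- function(path, prefer_second = FALSE) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vapply(parts, function(p) {
    if (prefer_second && length(p) >= 2L) p[2] else p[1]
  }, character(1))
}

#' Read a spot positions table
#'
#' Parses the tissue-positions dialects: headered CSV
#' (`barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres`)
#' or the older headerless 6-column file. Pixel coordinates are returned
#' 0-based at full resolution; when a scale-factor descriptor is supplied
#' (for a down-sampled image) coordinates and the spot diameter are
#' multiplied by its factor.
#'
#' @param path delimited positions file.
#' @param scalefactors optional path to a `scalefactors_json.json` (or an
#'   already-parsed list); fields used: `tissue_hires_scalef` (or
#'   `scalef`), `spot_diameter_fullres`.
#' @param barcodes optional expression barcode vector; positions for
#'   unknown barcodes are dropped with a warning, and expression barcodes
#'   missing from the table raise an error.
#' @return data.frame with columns `barcode`, `in_tissue`, `array_row`,
#'   `array_col`, `pixel_row`, `pixel_col` and attribute
#'   `spot_diameter_px` (NA when no descriptor was given).
#' @export
read_positions <- function(path, scalefactors = NULL, barcodes = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- read_delim_auto2(path, header = has_header)
  if (ncol(df) < 6L)
    stop("positions table must have 6 columns (barcode, in_tissue, ",
         "array_row, array_col, pixel row, pixel col); found ", ncol(df))
  df <- df[, 1:6]
  names(df) <- c("barcode", "in_tissue", "array_row", "array_col",
                 "pixel_row", "pixel_col")
  df$barcode <- as.character(df$barcode)
  sf <- 1.0
  diam <- NA_real_
  if (!is.null(scalefactors)) {
    sfl <- if (is.character(scalefactors))
      jsonlite::read_json(scalefactors) else scalefactors
    if (!is.null(sfl$tissue_hires_scalef)) sf <- sfl$tissue_hires_scalef
    else if (!is.null(sfl$scalef)) sf <- sfl$scalef
    if (!is.null(sfl$spot_diameter_fullres))
      diam <- sfl$spot_diameter_fullres * sf
  }
  df$pixel_row <- df$pixel_row * sf
  df$pixel_col <- df$pixel_col * sf
  if (!is.null(barcodes)) {
    unknown <- setdiff(df$barcode, barcodes)
    if (length(unknown) > 0L) {
      warning("dropping ", length(unknown), " position row(s) with ",
              "barcodes absent from the expression matrix")
      df <- df[df$barcode %in% barcodes, , drop = FALSE]
    }
    absent <- setdiff(barcodes, df$barcode)
    if (length(absent) > 0L)
      stop(length(absent), " expression barcode(s) have no position: ",
           paste(utils::head(absent, 10L), collapse = ", "),
           if (length(absent) > 10L) " ..." else "")
    df <- df[match(barcodes, df$barcode), , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "spot_diameter_px") <- diam
  df
}

# Like read_delim_auto but must also cope with headerless numeric files.
read_delim_auto2 <- function(path, header) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.table(path, header = header, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Serialize a fitted model to a directory
#'
#' Writes `W.csv`, `H_rna.csv`, `H_img.csv` (delimited, with identifier
#' header rows) and `metadata.json` (alpha, k, seed, rescale scalars,
#' objective trace, convergence flag).
#'
#' @param model a [jnmf_fit()] model.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "joint_factor_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(barcode = rownames(model$W), model$W,
                              check.names = FALSE),
                   file.path(dir, "W.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(factor = rownames(model$H_rna), model$H_rna,
                              check.names = FALSE),
                   file.path(dir, "H_rna.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(model$H_img))
    utils::write.csv(data.frame(factor = rownames(model$H_img), model$H_img,
                                check.names = FALSE),
                     file.path(dir, "H_img.csv"), row.names = FALSE,
                     quote = FALSE)
  meta <- list(alpha = model$alpha, k = model$k, seed = model$seed,
               rescale = as.list(model$rescale),
               objective_trace = model$objective_trace,
               converged = model$converged,
               unweighted_blocks = model$unweighted_blocks,
               init = model$config$init)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a serialized model
#'
#' @param dir directory written by [write_model()].
#' @return A `joint_factor_model` (without the full fit configuration).
#' @export
read_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  Wdf <- utils::read.csv(file.path(dir, "W.csv"), check.names = FALSE)
  W <- as.matrix(Wdf[, -1, drop = FALSE])
  rownames(W) <- Wdf[[1]]
  Hdf <- utils::read.csv(file.path(dir, "H_rna.csv"), check.names = FALSE)
  H_rna <- as.matrix(Hdf[, -1, drop = FALSE])
  rownames(H_rna) <- Hdf[[1]]
  H_img <- NULL
  if (file.exists(file.path(dir, "H_img.csv"))) {
    Hidf <- utils::read.csv(file.path(dir, "H_img.csv"), check.names = FALSE)
    H_img <- as.matrix(Hidf[, -1, drop = FALSE])
    rownames(H_img) <- Hidf[[1]]
  }
  structure(list(W = W, H_rna = H_rna, H_img = H_img, alpha = meta$alpha,
                 k = meta$k, objective_trace = meta$objective_trace,
                 converged = meta$converged, seed = meta$seed,
                 rescale = c(rna = meta$rescale$rna, img = meta$rescale$img),
                 unweighted_blocks = meta$unweighted_blocks,
                 config = list(init = meta$init)),
            class = "joint_factor_model")
}
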