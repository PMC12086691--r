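# Synthetic paired expression / image-feature data with planted shared
# factors. Stands in for annotated tissues: k spatial regions on a grid of
# spots drive both modalities, so every downstream module (features, joint
# fit, rank selection, clustering evaluation) is testable without any
# download. Purely a stated world: rectangular regions, half-normal
# factors, additive Gaussian noise clipped at zero (or Poisson counts on
# request); no histology texture and no spatial autocorrelation beyond the
# region blocks.

#' Simulate paired spot expression and image features
#'
#' Spots sit on a near-square grid partitioned into `k` contiguous
#' rectangular regions. The shared score matrix `W_true` is half-normal
#' with a dominant column for each spot's own region (block structure);
#' loadings are i.i.d. half-normal. Data are `Y = W H + noise` with
#' Gaussian noise scaled to the requested signal-to-noise ratio
#' (`var(signal) / sigma^2`) and clipped at zero; `noise_model = "poisson"`
#' instead draws `Y ~ Poisson(W H)` for count realism.
#'
#' @param m,n,f,k spots, genes, image features, true rank (= number of
#'   regions); `k <= min(m, n, f)`.
#' @param snr_rna,snr_img per-modality signal-to-noise ratios (variance
#'   ratio before clipping); defaults 5, a realistic mid-noise regime for
#'   normalized spot data.
#' @param seed integer seed; the generator is a pure function of it.
#' @param noise_model `"gaussian"` (default, analytic SNR control) or
#'   `"poisson"`.
#' @param spot_diameter_px,gap_px spot geometry used for the coordinate
#'   grid, in pixels (defaults 11 and 5).
#' @return list with `expression` ([spot_expression()]), `features`
#'   ([spot_image_features()]) and `truth` (class `synthetic_truth`:
#'   `W_true`, `H_rna_true`, `H_img_true`, `region_labels`, `coords`,
#'   `signal_rna`, `signal_img`, `sigma_rna`, `sigma_img`, `snr`, `seed`).
#' @examples
#' sim <- simulate_joint_data(m = 30, n = 40, f = 9, k = 3, seed = 7)
#' table(sim$truth$region_labels)
#' @export
simulate_joint_data <- function(m = 150L, n = 200L, f = 90L, k = 4L,
                                snr_rna = 5, snr_img = 5, seed = 1L,
                                noise_model = c("gaussian", "poisson"),
                                spot_diameter_px = 11L, gap_px = 5L) {
  noise_model <- match.arg(noise_model)
  if (k > min(m, n, f))
    stop("k = ", k, " exceeds min(m, n, f) = ", min(m, n, f))
  out <- with_seed(as.integer(seed), {
    grid <- spot_grid(m, spot_diameter_px, gap_px)
    region <- grid_regions(grid, k)
    # block-structured half-normal scores: dominant loading on own region
    W <- matrix(abs(stats::rnorm(m * k)) * 0.15, m, k)
    W[cbind(seq_len(m), region)] <- W[cbind(seq_len(m), region)] +
      abs(stats::rnorm(m)) + 0.5
    Hr <- matrix(abs(stats::rnorm(k * n)), k, n)
    Hi <- matrix(abs(stats::rnorm(k * f)), k, f)
    Sr <- W %*% Hr
    Si <- W %*% Hi
    if (noise_model == "gaussian") {
      sig_r <- stats::sd(Sr) / sqrt(snr_rna)
      sig_i <- stats::sd(Si) / sqrt(snr_img)
      Yr <- pmax(Sr + matrix(stats::rnorm(m * n, sd = sig_r), m, n), 0)
      Yi <- pmax(Si + matrix(stats::rnorm(m * f, sd = sig_i), m, f), 0)
    } else {
      sig_r <- sig_i <- NA_real_
      Yr <- matrix(stats::rpois(m * n, lambda = Sr), m, n)
      Yi <- matrix(stats::rpois(m * f, lambda = Si), m, f)
    }
    barcodes <- sprintf("spot%04d", seq_len(m))
    list(
      expression = spot_expression(Yr, barcodes,
                                   sprintf("gene%04d", seq_len(n))),
      features = spot_image_features(Yi, barcodes,
                                     sprintf("feat%03d", seq_len(f))),
      truth = structure(list(W_true = W, H_rna_true = Hr, H_img_true = Hi,
                             region_labels = region, coords = grid,
                             signal_rna = Sr, signal_img = Si,
                             sigma_rna = sig_r, sigma_img = sig_i,
                             snr = c(rna = snr_rna, img = snr_img),
                             spot_diameter_px = spot_diameter_px,
                             seed = as.integer(seed)),
                        class = "synthetic_truth"))
  })
  out
}

# Near-square grid of spot centres in 0-based full-resolution pixels.
spot_grid <- function(m, spot_diameter_px, gap_px) {
  ncols <- ceiling(sqrt(m))
  nrows <- ceiling(m / ncols)
  pitch <- spot_diameter_px + gap_px
  margin <- spot_diameter_px  # keep full patches at scale 1 inside the canvas
  idx <- seq_len(m) - 1L
  data.frame(
    barcode = sprintf("spot%04d", seq_len(m)),
    array_row = idx %/% ncols,
    array_col = idx %% ncols,
    pixel_row = margin + (idx %/% ncols) * pitch,
    pixel_col = margin + (idx %% ncols) * pitch)
}

# k contiguous rectangular regions: vertical strips of grid columns.
grid_regions <- function(grid, k) {
  ncols <- max(grid$array_col) + 1L
  strip <- pmin(k, 1L + (grid$array_col * k) %/% ncols)
  as.integer(strip)
}

#' Paint a synthetic tissue image
#'
#' Renders an 8-bit RGB canvas in which each region is painted a distinct
#' base colour with small per-pixel jitter, so spot-centred patches from
#' different regions separate cleanly by their colour histograms. Each
#' spot's tile (one grid pitch) takes its region's colour.
#'
#' @param coords data.frame from the generator's `truth$coords` (columns
#'   `pixel_row`, `pixel_col`).
#' @param region_labels integer region per spot.
#' @param spot_diameter_px spot diameter in pixels.
#' @param gap_px gap between spot edges in pixels.
#' @param palette_seed seed for the region palette and the pixel jitter.
#' @param jitter_sd per-pixel Gaussian colour jitter, default 4.
#' @return h x w x 3 array of intensities in \[0, 255\].
#' @export
simulate_tissue_image <- function(coords, region_labels,
                                  spot_diameter_px = 11L, gap_px = 5L,
                                  palette_seed = 1L, jitter_sd = 4) {
  pitch <- spot_diameter_px + gap_px
  h <- max(coords$pixel_row) + spot_diameter_px + 1L
  w <- max(coords$pixel_col) + spot_diameter_px + 1L
  if (any(coords$pixel_row < 0 | coords$pixel_col < 0))
    stop("coordinates must be non-negative")
  K <- max(region_labels)
  with_seed(as.integer(palette_seed), {
    # well-separated base colours: spaced hues at full saturation
    hues <- (seq_len(K) - 1) / K + stats::runif(1) / K
    base <- t(grDevices::col2rgb(grDevices::hsv(hues %% 1, s = 0.85,
                                                v = 0.9)))
    img <- array(235, c(h, w, 3L))  # near-white background
    half <- pitch %/% 2
    for (i in seq_along(region_labels)) {
      r0 <- max(0L, coords$pixel_row[i] - half)
      r1 <- min(h - 1L, coords$pixel_row[i] + half)
      c0 <- max(0L, coords$pixel_col[i] - half)
      c1 <- min(w - 1L, coords$pixel_col[i] + half)
      for (ch in 1:3)
        img[(r0:r1) + 1L, (c0:c1) + 1L, ch] <- base[region_labels[i], ch]
    }
    img <- img + array(stats::rnorm(length(img), sd = jitter_sd), dim(img))
    pmin(pmax(round(img), 0), 255)
  })
}

#' Write a Visium-like bundle
#'
#' Emits the on-disk dialect the readers consume: a Matrix Market triplet
#' matrix (genes x spots, as emitted by the common pipelines) with
#' `barcodes.tsv` and `features.tsv`, a headered
#' `tissue_positions.csv`, a `scalefactors_json.json` carrying the spot
#' diameter, and the H&E image (PNG, or text PPM when `image_format =
#' "ppm"`).
#'
#' @param dir output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param expression a [spot_expression()].
#' @param image h x w x 3 array or NULL to skip the image.
#' @param coords data.frame with `barcode`, `array_row`, `array_col`,
#'   `pixel_row`, `pixel_col`.
#' @param spot_diameter_px written into the scale-factor descriptor.
#' @param image_format `"png"` or `"ppm"`.
#' @param overwrite allow writing into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_visium_like_bundle <- function(dir, expression, image, coords,
                                     spot_diameter_px = 11,
                                     image_format = c("png", "ppm"),
                                     overwrite = FALSE) {
  image_format <- match.arg(image_format)
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite)
    stop("directory ", dir, " is not empty; pass overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # genes x spots on disk, the orientation CellRanger-style bundles use
  M <- Matrix::Matrix(t(expression$values), sparse = TRUE)
  Matrix::writeMM(M, file.path(dir, "matrix.mtx"))
  writeLines(expression$barcodes, file.path(dir, "barcodes.tsv"))
  writeLines(paste(expression$gene_ids, expression$gene_ids,
                   "Gene Expression", sep = "\t"),
             file.path(dir, "features.tsv"))
  pos <- data.frame(barcode = coords$barcode, in_tissue = 1L,
                    array_row = coords$array_row,
                    array_col = coords$array_col,
                    pxl_row_in_fullres = coords$pixel_row,
                    pxl_col_in_fullres = coords$pixel_col)
  utils::write.csv(pos, file.path(dir, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(spot_diameter_fullres = spot_diameter_px,
                            tissue_hires_scalef = 1.0),
                       file.path(dir, "scalefactors_json.json"),
                       auto_unbox = TRUE)
  if (!is.null(image))
    write_image(image, file.path(dir, paste0("image.", image_format)))
  invisible(dir)
}

#' Match recovered factors to planted ones
#'
#' Hungarian assignment maximizing the column-wise Pearson correlation
#' between recovered and true score matrices; used to judge parameter
#' recovery up to the factorization's permutation/scale ambiguity.
#'
#' @param W_hat,W_true m x k score matrices.
#' @return list with `assignment` (for each true column, the matched
#'   recovered column) and `correlations` (the matched correlations).
#' @export
match_factors <- function(W_hat, W_true) {
  k <- ncol(W_true)
  C <- suppressWarnings(stats::cor(W_true, W_hat))
  C[!is.finite(C)] <- 0
  sol <- clue::solve_LSAP(pmax(C, 0) + 1, maximum = TRUE)
  idx <- as.integer(sol)
  list(assignment = idx, correlations = C[cbind(seq_len(k), idx)])
}
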