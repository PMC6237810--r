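#' Two-channel gel image container
#'
#' @param stain,cy5 non-negative intensity matrices of equal shape
#'   (rows = `y` dimension-1, columns = `x` dimension-2; the well sits at
#'   pixel `[1, 1]`, coordinate `(0, 0)`).
#' @param px_per_mm nominal pixel pitch.
#' @param metadata run-configuration echo.
#' @return an object of class `nla_gel`.
#' @export
gel_image <- function(stain, cy5, px_per_mm = 10, metadata = list()) {
  assert_that(all(dim(stain) == dim(cy5)), "channels must share one shape")
  assert_that(all(is.finite(stain)) && all(is.finite(cy5)),
              "intensities must be finite")
  assert_that(min(stain) >= 0 && min(cy5) >= 0,
              "intensities must be non-negative")
  structure(list(stain = stain, cy5 = cy5, px_per_mm = px_per_mm,
                 well_origin = c(y = 0, x = 0), metadata = metadata),
            class = "nla_gel")
}

#' @export
print.nla_gel <- function(x, ...) {
  cat(sprintf("<nla_gel> %d x %d px, stain sum %.4g, cy5 sum %.4g\n",
              nrow(x$stain), ncol(x$stain), sum(x$stain), sum(x$cy5)))
  invisible(x)
}

# Accumulate Gaussian spots into a matrix. Spots are aggregated on a
# 0.25 px grid first (apoptotic ladders collapse thousands of identical
# fragments onto a handful of spots). Each spot integrates to
# `gain * mass` up to truncation at 4 sigma (< 0.02% loss).
draw_spots <- function(mat, xs, ys, masses, sigma, gain) {
  if (length(xs) == 0L) return(mat)
  key <- paste(round(xs * 4), round(ys * 4), sep = ",")
  agg <- rowsum(masses, key)
  uk <- strsplit(rownames(agg), ",", fixed = TRUE)
  ux <- vapply(uk, function(k) as.numeric(k[1]) / 4, 0)
  uy <- vapply(uk, function(k) as.numeric(k[2]) / 4, 0)
  um <- agg[, 1]
  nr <- nrow(mat); nc <- ncol(mat)
  r4 <- ceiling(4 * sigma)
  for (i in seq_along(ux)) {
    # pixel (r, c) covers coordinate (r-1, c-1)
    c0 <- ux[i] + 1; r0 <- uy[i] + 1
    c_lo <- max(1L, floor(c0 - r4)); c_hi <- min(nc, ceiling(c0 + r4))
    r_lo <- max(1L, floor(r0 - r4)); r_hi <- min(nr, ceiling(r0 + r4))
    if (c_lo > c_hi || r_lo > r_hi) next  # spot clipped off the raster
    cc <- c_lo:c_hi; rr <- r_lo:r_hi
    gx <- stats::dnorm(cc, mean = c0, sd = sigma)
    gy <- stats::dnorm(rr, mean = r0, sd = sigma)
    mat[rr, cc] <- mat[rr, cc] + (gain * um[i]) * outer(gy, gx)
  }
  mat
}

#' Render migration spots into a two-channel gel raster
#'
#' Each spot is drawn as an isotropic Gaussian of sd `psf_sigma_px`
#' integrating to `gain * mass`; the Cy5 ladder is projected through the
#' same mobility model into the second channel. Additive background and
#' seeded Gaussian noise are applied and intensities clipped at 0. With
#' `noise_sd = 0` the background-subtracted integral is proportional to
#' total mass within 1% (PSF truncation at image edges excepted).
#'
#' @param spots `data.frame` from [project_population()].
#' @param ladder an [ladder_spec()] (or `NULL` to leave the Cy5 channel
#'   blank).
#' @param model an [mobility_model()].
#' @param image_shape `c(rows, cols)` in px.
#' @param seed RNG seed for the noise field.
#' @return an [gel_image()].
#' @export
render_gel <- function(spots, ladder = ladder_spec(), model = mobility_model(),
                       image_shape = c(1024L, 1024L), seed = 1L) {
  assert_that(all(image_shape >= 1), "non-positive image shape")
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  if (!is.null(ladder)) {
    lpop <- denature(ladder_population(ladder))
    lspots <- project_population(lpop, model)
    spots <- rbind(spots[, c("x_px", "y_px", "mass", "channel",
                             "source_class")],
                   lspots)
  }
  chan <- function(name) {
    m <- matrix(0, nr, nc)
    sel <- spots$channel == name
    m <- draw_spots(m, spots$x_px[sel], spots$y_px[sel], spots$mass[sel],
                    model$psf_sigma_px, model$gain)
    m + model$background_level
  }
  stain <- chan("stain"); cy5 <- chan("cy5")
  if (model$noise_sd > 0) {
    with_op_seed(seed, {
      stain <- stain + matrix(stats::rnorm(nr * nc, 0, model$noise_sd), nr, nc)
      cy5 <- cy5 + matrix(stats::rnorm(nr * nc, 0, model$noise_sd), nr, nc)
    })
  }
  gel_image(pmax(stain, 0), pmax(cy5, 0),
            metadata = list(model = unclass(model), seed = seed,
                            shape = c(nr, nc)))
}

# ---- image file I/O ------------------------------------------------------
# No TIFF library is available in this R stack; 16-bit gel rasters are
# stored as binary PGM (P5, maxval 65535, big-endian) with a JSON
# metadata sidecar. PNG previews are 8-bit via the png package.

write_pgm16 <- function(mat, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c("P5", sprintf("%d %d", ncol(mat), nrow(mat)), "65535"), con)
  vals <- as.integer(round(clamp(t(mat), 0, 65535)))
  writeBin(vals, con, size = 2L, endian = "big")
  invisible(path)
}

read_pgm16 <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readLines(con, 1L)
  assert_that(identical(magic, "P5"), "not a binary PGM file: %s", path)
  hdr <- character()
  while (length(hdr) < 3L) {
    ln <- readLines(con, 1L)
    ln <- sub("#.*", "", ln)
    hdr <- c(hdr, strsplit(trimws(ln), "\\s+")[[1]])
  }
  nc <- as.integer(hdr[1]); nr <- as.integer(hdr[2]); mx <- as.integer(hdr[3])
  assert_that(mx == 65535, "expected 16-bit PGM")
  vals <- readBin(con, "integer", n = nr * nc, size = 2L, signed = FALSE,
                  endian = "big")
  assert_that(length(vals) == nr * nc, "truncated PGM payload")
  matrix(as.double(vals), nr, nc, byrow = TRUE)
}

#' Write / read a two-channel gel image
#'
#' Writes `<prefix>_stain.pgm`, `<prefix>_cy5.pgm` (16-bit binary PGM) and
#' `<prefix>_meta.json`, plus an 8-bit `<prefix>_preview.png`.
#'
#' @param image an [gel_image()].
#' @param prefix output path prefix.
#' @param preview also write a PNG preview (default `TRUE`).
#' @return the prefix, invisibly.
#' @export
write_gel_image <- function(image, prefix, preview = TRUE) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  write_pgm16(image$stain, paste0(prefix, "_stain.pgm"))
  write_pgm16(image$cy5, paste0(prefix, "_cy5.pgm"))
  jsonlite::write_json(image$metadata, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (preview) {
    rng <- max(image$stain, image$cy5, 1)
    rgb <- array(0, c(nrow(image$stain), ncol(image$stain), 3L))
    rgb[, , 2] <- clamp(image$stain / rng, 0, 1)  # stain in green
    rgb[, , 1] <- clamp(image$cy5 / rng, 0, 1)    # ladder in red
    png::writePNG(rgb, paste0(prefix, "_preview.png"))
  }
  invisible(prefix)
}

#' @rdname write_gel_image
#' @export
read_gel_image <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::fromJSON(meta_path, simplifyVector = TRUE) else list()
  gel_image(read_pgm16(paste0(prefix, "_stain.pgm")),
            read_pgm16(paste0(prefix, "_cy5.pgm")),
            metadata = meta)
}
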