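#' @include render.R mobility.R
NULL

REGION_NAMES <- c("undigested", "dsDNA", "behind", "front", "ssb_streak")

box_blur3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  # replicate borders
  p[1, ] <- p[2, ]; p[nr + 2L, ] <- p[nr + 1L, ]
  p[, 1] <- p[, 2]; p[, nc + 2L] <- p[, nc + 1L]
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  acc / 9
}

local_maxima <- function(m, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  ok <- m > threshold
  for (dr in 0:2) for (dc in 0:2) {
    if (dr == 1L && dc == 1L) next
    ok <- ok & (m >= p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)])
  }
  which(ok, arr.ind = TRUE)
}

half_max_edges <- function(ch, r0, c0, bg) {
  peak <- ch[r0, c0]
  half <- bg + (peak - bg) / 2
  scan <- function(vals, start, dir) {
    i <- start
    repeat {
      j <- i + dir
      if (j < 1L || j > length(vals)) return(i)
      if (vals[j] < half) {
        # linear interpolation of the crossing
        frac <- (vals[i] - half) / (vals[i] - vals[j])
        return(i + dir * frac)
      }
      i <- j
    }
  }
  r0 <- unname(r0); c0 <- unname(c0)
  row_prof <- ch[r0, ]; col_prof <- ch[, c0]
  c(left = scan(row_prof, c0, -1L), right = scan(row_prof, c0, 1L),
    top = scan(col_prof, r0, -1L), bottom = scan(col_prof, r0, 1L))
}

#' Detect Cy5 ladder bands
#'
#' Finds local maxima in the Cy5 channel, merges maxima closer than
#' `min_separation`, and matches candidates to the nominal ladder sizes by
#' x-order (larger fragments migrate less in dimension 2). Band edges are
#' placed on the half-maximum contour; centroids are intensity-weighted
#' within the edge box. The bands required for region construction
#' (100, 1000, 2000, 3000 bp) must all be matched.
#'
#' @param image an [gel_image()].
#' @param ladder an [ladder_spec()].
#' @param min_separation minimum peak separation in px.
#' @return a `data.frame` of class `nla_bands`: `size`, centroid `x`/`y`
#'   (0-based pixel coordinates), half-max `left`/`right`/`top`/`bottom`
#'   edges, `intensity`.
#' @export
detect_ladder_bands <- function(image, ladder = ladder_spec(),
                                min_separation = 8) {
  ch <- image$cy5
  bg <- stats::median(ch)
  noise <- stats::mad(ch)
  assert_that(max(ch) > bg + 5 * noise, "no ladder signal in the Cy5 channel")
  sm <- box_blur3(ch)
  cand <- local_maxima(sm, bg + 5 * noise)
  assert_that(nrow(cand) > 0L, "no ladder signal in the Cy5 channel")
  heights <- sm[cand]
  ord <- order(heights, decreasing = TRUE)
  keep <- integer()
  for (i in ord) {
    if (length(keep) == 0L ||
        all((cand[i, 1] - cand[keep, 1])^2 +
            (cand[i, 2] - cand[keep, 2])^2 >= min_separation^2))
      keep <- c(keep, i)
    if (length(keep) == length(ladder$band_sizes)) break
  }
  assert_that(length(keep) == length(ladder$band_sizes),
              "ladder band unmatched: found %d candidate bands, expected %d",
              length(keep), length(ladder$band_sizes))
  cand <- cand[keep, , drop = FALSE]
  # ascending x <-> descending size
  cand <- cand[order(cand[, 2]), , drop = FALSE]
  sizes <- rev(ladder$band_sizes)
  bands <- lapply(seq_along(sizes), function(i) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    e <- half_max_edges(ch, r0, c0, bg)
    rr <- max(1L, floor(e["top"])):min(nrow(ch), ceiling(e["bottom"]))
    cc <- max(1L, floor(e["left"])):min(ncol(ch), ceiling(e["right"]))
    w <- pmax(ch[rr, cc, drop = FALSE] - bg, 0)
    tot <- sum(w)
    cx <- sum(t(t(w) * (cc - 1))) / tot
    cy <- sum(w * (rr - 1)) / tot
    data.frame(size = sizes[i], x = cx, y = cy,
               left = e["left"] - 1, right = e["right"] - 1,
               top = e["top"] - 1, bottom = e["bottom"] - 1,
               intensity = tot, row.names = NULL)
  })
  out <- do.call(rbind, bands)
  out <- out[order(out$size), , drop = FALSE]
  rownames(out) <- NULL
  assert_that(all(diff(out$x) < 0),
              "detected band centroids not x-ordered with size")
  class(out) <- c("nla_bands", class(out))
  out
}

band_row <- function(bands, size) {
  i <- which(bands$size == size)
  assert_that(length(i) == 1L, "required ladder band (%d bp) missing", size)
  bands[i, , drop = FALSE]
}

# linear interpolation with end-slope extrapolation
lin_map <- function(xs, ys) {
  ord <- order(xs); xs <- xs[ord]; ys <- ys[ord]
  n <- length(xs)
  function(v) {
    out <- stats::approx(xs, ys, xout = v, rule = 1)$y
    lo <- v < xs[1]; hi <- v > xs[n]
    out[lo] <- ys[1] + (v[lo] - xs[1]) * (ys[2] - ys[1]) / (xs[2] - xs[1])
    out[hi] <- ys[n] + (v[hi] - xs[n]) *
      (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
    out
  }
}

#' Fit a monotone size calibration from detected ladder bands
#'
#' Piecewise-linear interpolation of log size against each gel coordinate,
#' "drawing a line through the ladder": because single strands sit directly
#' above double strands of the same size, the x-map transfers fragment
#' sizes to any part of the gel. Queries outside the fitted band range are
#' linearly extrapolated and flagged.
#'
#' @param bands an `nla_bands` data frame (>= 4 bands).
#' @return an object of class `nla_calibration` with monotone maps
#'   `x_from_size`, `y_from_size`, `size_from_x`, `size_from_y`, the
#'   validity `range`, and `is_extrapolated(size)`.
#' @export
fit_size_calibration <- function(bands) {
  assert_that(nrow(bands) >= 4L, "need >= 4 ladder bands to calibrate")
  bands <- bands[order(bands$size), , drop = FALSE]
  assert_that(all(diff(bands$x) < 0) && all(diff(bands$y) < 0),
              "non-monotone ladder coordinates")
  ls <- log(bands$size)
  cal <- list(
    x_from_size = function(size) lin_map(ls, bands$x)(log(size)),
    y_from_size = function(size) lin_map(ls, bands$y)(log(size)),
    size_from_x = function(x) exp(lin_map(bands$x, ls)(x)),
    size_from_y = function(y) exp(lin_map(bands$y, ls)(y)),
    range = range(bands$size),
    knots = bands[, c("size", "x", "y")]
  )
  cal$is_extrapolated <- function(size)
    size < cal$range[1] | size > cal$range[2]
  structure(cal, class = "nla_calibration")
}

#' Construct the five diagnostic gel regions
#'
#' Pure function of the detected ladder bands (same bands, same polygons):
#' \describe{
#'   \item{undigested}{well rows down to the upper edge of the 3000 bp
#'     band, bounded right by that band's right edge (unmigrated
#'     high-molecular-weight DNA).}
#'   \item{dsDNA}{arc-following corridor between the 1000 bp upper edge and
#'     the 100 bp lower edge; the centerline interpolates the band
#'     centroids and the half-width is `margin_scale` times the half-max
#'     band half-width.}
#'   \item{behind}{the dsDNA corridor displaced left by the ladder-derived
#'     size-doubling offset (covalently joined strands are at least twice
#'     the single-strand length), widened by one corridor width —
#'     interstrand crosslinks.}
#'   \item{front}{everything right of the corridor from the horizontal
#'     through the 2000 bp band down to the 100 bp lower edge, capped at
#'     the 100 bp band's right edge — bent molecules, ssDNA and released
#'     short strands.}
#'   \item{ssb_streak}{the undigested rows right of the 3000 bp band,
#'     extending to vertically over the 100 bp band — the horizontal
#'     single-strand-break streak.}
#' }
#' Regions are clipped to be mutually disjoint in the priority order
#' undigested > dsDNA > behind > front > ssb_streak, and a background box
#' is auto-placed on the lowest-intensity margin unless supplied.
#'
#' @param bands an `nla_bands` data frame; 100, 1000, 2000 and 3000 bp
#'   bands are required.
#' @param image an [gel_image()] (shape and background placement).
#' @param margin_scale region half-width in units of the half-max band
#'   half-width (default 2: a half-max contour holds ~76% of a Gaussian
#'   band's marginal mass, twice that ~98%).
#' @param background_box optional `c(row0, row1, col0, col1)` override.
#' @return an object of class `nla_regions`: logical `masks` per region,
#'   the `background_box`, and construction parameters.
#' @export
build_regions <- function(bands, image, margin_scale = 2,
                          background_box = NULL) {
  nr <- nrow(image$stain); nc <- ncol(image$stain)
  b100 <- band_row(bands, 100L); b1000 <- band_row(bands, 1000L)
  b2000 <- band_row(bands, 2000L); b3000 <- band_row(bands, 3000L)
  half_w <- (bands$right - bands$left) / 2
  half_h <- (bands$bottom - bands$top) / 2
  W <- margin_scale * stats::median(half_w)
  edge <- function(b, which) {
    h <- switch(which,
      top = -(b$y - b$top), bottom = b$bottom - b$y,
      left = -(b$x - b$left), right = b$right - b$x)
    (if (which %in% c("top", "bottom")) b$y else b$x) + margin_scale * h
  }
  ord <- order(bands$y)
  arc_x <- lin_map(bands$y[ord], bands$x[ord])
  # size-doubling offset, from the 100 and 1000 bp centroids assuming the
  # semi-log mobility the calibration itself relies on
  delta <- (b100$x - b1000$x) * log(2) / log(10)

  rows_px <- function(y0, y1) max(1L, round(y0) + 1L):min(nr, round(y1) + 1L)
  cols_px <- function(x0, x1) {
    c0 <- max(1L, round(x0) + 1L); c1 <- min(nc, round(x1) + 1L)
    if (c0 > c1) integer() else c0:c1
  }
  mk <- function() matrix(FALSE, nr, nc)

  und <- mk()
  und_rows <- rows_px(0, edge(b3000, "top"))
  und[und_rows, cols_px(0, edge(b3000, "right"))] <- TRUE

  streak <- mk()
  streak[und_rows, cols_px(edge(b3000, "right") + 1, edge(b100, "right"))] <- TRUE

  # The corridor follows a diagonal arc: a band of perpendicular
  # half-width W cut horizontally is wider by sec(arc angle), i.e.
  # sqrt(1 + (dx/dy)^2) with the slope taken from the ladder itself.
  w_row <- function(y) {
    dxdy <- (arc_x(y + 2) - arc_x(y - 2)) / 4
    W * sqrt(1 + dxdy^2)
  }

  ds <- mk(); behind <- mk()
  ds_rows <- rows_px(edge(b1000, "top"), edge(b100, "bottom"))
  for (r in ds_rows) {
    xc <- arc_x(r - 1); Wr <- w_row(r - 1)
    ds[r, cols_px(xc - Wr, xc + Wr)] <- TRUE
    behind[r, cols_px(xc - Wr - delta - W, xc - Wr - 1)] <- TRUE
  }

  front <- mk()
  front_rows <- rows_px(edge(b2000, "top"), edge(b100, "bottom"))
  for (r in front_rows) {
    xc <- arc_x(r - 1); Wr <- w_row(r - 1)
    front[r, cols_px(xc + Wr + 1, edge(b100, "right"))] <- TRUE
  }

  masks <- list(undigested = und, dsDNA = ds, behind = behind,
                front = front, ssb_streak = streak)
  taken <- mk()
  for (nm in REGION_NAMES) {
    masks[[nm]] <- masks[[nm]] & !taken
    taken <- taken | masks[[nm]]
  }

  if (is.null(background_box))
    background_box <- auto_background_box(image$stain, taken)
  bb <- background_box
  bb_mask <- mk(); bb_mask[bb[1]:bb[2], bb[3]:bb[4]] <- TRUE
  assert_that(!any(bb_mask & taken),
              "background box overlaps a diagnostic region")

  structure(list(masks = masks, background_box = bb,
                 background_mask = bb_mask, bands = bands,
                 margin_scale = margin_scale, delta = delta, W = W),
            class = "nla_regions")
}

# DNA-free 64x64 window over the image margins, avoiding the regions.
# The window with the *median* mean among candidates is chosen: most
# margin windows are signal-free, so the median is robust to the few that
# contain signal, while a minimum-mean choice would select a downward
# noise fluctuation and bias the background low.
auto_background_box <- function(ch, taken, box = 64L, step = 32L) {
  nr <- nrow(ch); nc <- ncol(ch)
  margin <- 192L
  starts_r <- unique(pmin(pmax(seq(1L, nr - box + 1L, by = step), 1L),
                          nr - box + 1L))
  starts_c <- unique(pmin(pmax(seq(1L, nc - box + 1L, by = step), 1L),
                          nc - box + 1L))
  cand <- list(); means <- numeric()
  for (r0 in starts_r) for (c0 in starts_c) {
    on_margin <- r0 <= margin || c0 <= margin ||
      (r0 + box - 1L) >= nr - margin || (c0 + box - 1L) >= nc - margin
    if (!on_margin) next
    rr <- r0:(r0 + box - 1L); cc <- c0:(c0 + box - 1L)
    if (any(taken[rr, cc])) next
    cand[[length(cand) + 1L]] <- c(r0, r0 + box - 1L, c0, c0 + box - 1L)
    means <- c(means, mean(ch[rr, cc]))
  }
  assert_that(length(cand) > 0L, "no DNA-free margin found for background box")
  cand[[which.min(abs(means - stats::median(means)))]]
}

#' Background-corrected fraction percentages
#'
#' Per region: corrected density = integrated intensity minus the
#' background-box mean intensity times the region area, clipped at 0;
#' percentages normalise the corrected densities to 100 — quantification
#' is a relative measurement of density within each gel area.
#'
#' @param image an [gel_image()].
#' @param regions an `nla_regions` from [build_regions()].
#' @param background_box optional override `c(row0, row1, col0, col1)`.
#' @param channel `"stain"` (default) or `"cy5"`.
#' @return a `data.frame` of class `nla_fractions`: `region`,
#'   `raw_density`, `area_px`, `corrected_density`, `percentage` (sums to
#'   100); background mean as attribute `background_per_px`.
#' @export
quantify_fractions <- function(image, regions, background_box = NULL,
                               channel = c("stain", "cy5")) {
  channel <- match.arg(channel)
  ch <- image[[channel]]
  bb <- background_box %||% regions$background_box
  bg <- mean(ch[bb[1]:bb[2], bb[3]:bb[4]])
  rows <- lapply(REGION_NAMES, function(nm) {
    mask <- regions$masks[[nm]]
    raw <- sum(ch[mask]); area <- sum(mask)
    data.frame(region = nm, raw_density = raw, area_px = area,
               corrected_density = max(raw - bg * area, 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot <- sum(out$corrected_density)
  assert_that(tot > 0, "no signal above background")
  out$percentage <- 100 * out$corrected_density / tot
  attr(out, "background_per_px") <- bg
  class(out) <- c("nla_fractions", class(out))
  out
}

#' Size distribution of a gel region
#'
#' Column-wise background-corrected intensity mapped to fragment size
#' through the x-calibration (single strands sit directly above double
#' strands of equal size). The unresolved `undigested` fraction contains
#' large molecules of various sizes and refuses size estimation.
#'
#' @param image an [gel_image()].
#' @param regions an `nla_regions`.
#' @param region region name (not `"undigested"`).
#' @param cal an `nla_calibration`.
#' @param channel `"stain"` or `"cy5"`.
#' @return a `data.frame` of class `nla_sizedist`, ascending in `size`,
#'   with per-column `intensity`; attributes `mode`, `quantiles`,
#'   `extrapolated`, `region`.
#' @export
estimate_size_distribution <- function(image, regions, region = "dsDNA",
                                       cal, channel = c("stain", "cy5")) {
  channel <- match.arg(channel)
  assert_that(region %in% REGION_NAMES, "unknown region '%s'", region)
  assert_that(region != "undigested",
              "size estimation is not supported for the unresolved undigested fraction")
  ch <- image[[channel]]
  mask <- regions$masks[[region]]
  bb <- regions$background_box
  bg <- mean(ch[bb[1]:bb[2], bb[3]:bb[4]])
  cols <- which(colSums(mask) > 0L)
  if (length(cols) == 0L) {
    out <- data.frame(size = numeric(), intensity = numeric())
  } else {
    intensity <- vapply(cols, function(cc) {
      rows <- mask[, cc]
      max(sum(ch[rows, cc]) - bg * sum(rows), 0)
    }, 0)
    size <- cal$size_from_x(cols - 1)
    out <- data.frame(size = size, intensity = intensity)
    out <- out[order(out$size), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "region") <- region
  attr(out, "extrapolated") <- any(cal$is_extrapolated(out$size))
  if (nrow(out) > 0L && sum(out$intensity) > 0) {
    attr(out, "mode") <- out$size[which.max(out$intensity)]
    cw <- cumsum(out$intensity) / sum(out$intensity)
    attr(out, "quantiles") <- vapply(c(q25 = 0.25, q50 = 0.5, q75 = 0.75),
      function(q) out$size[which(cw >= q)[1]], 0)
  }
  class(out) <- c("nla_sizedist", class(out))
  out
}

running_mean <- function(v, k = 5L) {
  if (length(v) < k) return(v)
  stats::filter(v, rep(1 / k, k), sides = 2) |>
    (\(f) { f[is.na(f)] <- v[is.na(f)]; as.numeric(f) })()
}

#' Call peaks on a size distribution
#'
#' Prominence-based peak calling on the (smoothed) intensity-versus-size
#' series; used to read apoptosis ladders (mono-, di-nucleosome bands at
#' multiples of the nucleosome repeat).
#'
#' @param dist an `nla_sizedist`.
#' @param min_prominence minimum peak prominence in intensity units;
#'   default 10% of the maximum smoothed intensity.
#' @param min_separation minimum relative size separation between reported
#'   peaks (default 0.1: peaks closer than 10% in size merge into the
#'   higher one).
#' @return numeric vector of peak sizes in nt, increasing; empty for a
#'   featureless profile.
#' @export
detect_ladder_peaks <- function(dist, min_prominence = NULL,
                                min_separation = 0.1) {
  if (nrow(dist) == 0L || sum(dist$intensity) == 0) return(numeric())
  v <- running_mean(dist$intensity, 5L)
  if (is.null(min_prominence)) min_prominence <- 0.1 * max(v)
  n <- length(v)
  is_max <- which(v > c(-Inf, v[-n]) & v >= c(v[-1], -Inf))
  prom <- vapply(is_max, function(j) {
    h <- v[j]
    left <- if (any(v[seq_len(j - 1)] > h)) {
      k <- max(which(v[seq_len(j - 1)] > h)); min(v[k:j])
    } else min(v[1:j])
    right <- if (j < n && any(v[(j + 1):n] > h)) {
      k <- j + min(which(v[(j + 1):n] > h)); min(v[j:k])
    } else min(v[j:n])
    h - max(left, right)
  }, 0)
  keep <- is_max[prom >= min_prominence]
  if (length(keep) == 0L) return(numeric())
  # merge peaks closer than min_separation in relative size
  keep <- keep[order(v[keep], decreasing = TRUE)]
  sel <- integer()
  for (j in keep) {
    if (all(abs(log(dist$size[j] / dist$size[sel])) > min_separation))
      sel <- c(sel, j)
  }
  sort(dist$size[sel])
}

#' One-call quantification pipeline
#'
#' Ladder detection, size calibration, region construction and
#' background-corrected fraction percentages for one gel image.
#'
#' @param image an [gel_image()].
#' @param ladder an [ladder_spec()].
#' @param margin_scale see [build_regions()].
#' @param background_box optional background override.
#' @return list with `bands`, `calibration`, `regions`, `report`.
#' @export
quantify_gel <- function(image, ladder = ladder_spec(), margin_scale = 2,
                         background_box = NULL) {
  bands <- detect_ladder_bands(image, ladder)
  cal <- fit_size_calibration(bands)
  regions <- build_regions(bands, image, margin_scale = margin_scale,
                           background_box = background_box)
  report <- quantify_fractions(image, regions)
  list(bands = bands, calibration = cal, regions = regions, report = report)
}

REGION_COLORS <- c(undigested = "#9b59b6", dsDNA = "#2ecc71",
                   behind = "#3498db", front = "#e74c3c",
                   ssb_streak = "#8d6e3f")

#' Write a region-overlay PNG for visual QC
#'
#' @param image an [gel_image()].
#' @param regions an `nla_regions`.
#' @param path output PNG path.
#' @export
write_region_overlay <- function(image, regions, path) {
  ch <- image$stain
  base <- clamp(ch / stats::quantile(ch, 0.999), 0, 1)
  rgb <- array(0, c(nrow(ch), ncol(ch), 3L))
  for (k in 1:3) rgb[, , k] <- base * 0.8
  for (nm in REGION_NAMES) {
    m <- regions$masks[[nm]]
    edge <- m & !(shift_mask(m, 1, 0) & shift_mask(m, -1, 0) &
                  shift_mask(m, 0, 1) & shift_mask(m, 0, -1))
    col <- grDevices::col2rgb(REGION_COLORS[[nm]]) / 255
    for (k in 1:3) { p <- rgb[, , k]; p[edge] <- col[k]; rgb[, , k] <- p }
  }
  bb <- regions$background_box
  for (k in 1:3) rgb[c(bb[1], bb[2]), bb[3]:bb[4], k] <- 1
  for (k in 1:3) rgb[bb[1]:bb[2], c(bb[3], bb[4]), k] <- 1
  png::writePNG(rgb, path)
  invisible(path)
}

shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Serialize a region set as JSON
#'
#' Emits, per region, the per-row x-intervals as a polygon-style list.
#'
#' @param regions an `nla_regions`.
#' @param path output JSON path.
#' @export
write_regions_json <- function(regions, path) {
  desc <- lapply(REGION_NAMES, function(nm) {
    m <- regions$masks[[nm]]
    rows <- which(rowSums(m) > 0L)
    list(name = nm,
         rows = lapply(rows, function(r) {
           cc <- range(which(m[r, ]))
           list(row = r, col_min = cc[1], col_max = cc[2])
         }))
  })
  jsonlite::write_json(list(regions = desc,
                            background_box = regions$background_box),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
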