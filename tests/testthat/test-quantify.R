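test_that("ladder bands are recovered at their projected coordinates", {
  m <- fixture_noiseless_model()
  img <- render_gel(data.frame(x_px = numeric(), y_px = numeric(),
                               mass = numeric(), channel = character(),
                               source_class = character()),
                    ladder_spec(), m)
  bands <- detect_ladder_bands(img, ladder_spec())
  expect_identical(bands$size, sort(ladder_spec()$band_sizes))
  for (i in seq_len(nrow(bands))) {
    seg <- strand_segment(bands$size[i],
                          parent_duplex_length = bands$size[i])
    expect_lt(abs(bands$x[i] - d2_migration(seg, m)), 1)
    expect_lt(abs(bands$y[i] - d1_migration(seg, m)), 1)
  }
  # half-max edges bracket the centroid
  expect_true(all(bands$left < bands$x & bands$x < bands$right))
})

test_that("band detection works at default noise and errors when blank", {
  q <- fixture_clean_quant()
  expect_identical(q$bands$size, sort(ladder_spec()$band_sizes))
  blank <- gel_image(matrix(100, 64, 64), matrix(100, 64, 64))
  expect_error(detect_ladder_bands(blank), "no ladder signal")
})

test_that("size calibration interpolates exactly at knots", {
  q <- fixture_clean_quant()
  cal <- q$calibration
  for (i in seq_len(nrow(q$bands))) {
    expect_equal(cal$size_from_x(q$bands$x[i]), q$bands$size[i],
                 tolerance = 1e-9)
    expect_equal(cal$size_from_y(q$bands$y[i]), q$bands$size[i],
                 tolerance = 1e-9)
    expect_equal(cal$x_from_size(q$bands$size[i]), q$bands$x[i],
                 tolerance = 1e-9)
  }
  expect_false(cal$is_extrapolated(500))
  expect_true(cal$is_extrapolated(5000))
})

test_that("leave-one-out calibration recovers the 500 bp band within 5%", {
  q <- fixture_clean_quant()
  bands <- q$bands
  drop <- which(bands$size == 500L)
  cal <- fit_size_calibration(bands[-drop, ])
  est <- cal$size_from_x(bands$x[drop])
  expect_lt(abs(est - 500) / 500, 0.05)
})

test_that("calibration rejects shuffled or sparse ladders", {
  q <- fixture_clean_quant()
  shuffled <- q$bands
  shuffled$x <- sample(shuffled$x)
  expect_error(fit_size_calibration(shuffled), "non-monotone")
  expect_error(fit_size_calibration(q$bands[1:3, ]), ">= 4")
})

test_that("regions are anchored on the required band edges", {
  q <- fixture_clean_quant()
  rg <- q$regions; bands <- q$bands
  ms <- rg$margin_scale
  b3000 <- bands[bands$size == 3000, ]
  b1000 <- bands[bands$size == 1000, ]
  b100 <- bands[bands$size == 100, ]
  und_rows <- which(rowSums(rg$masks$undigested) > 0)
  expect_equal(max(und_rows) - 1,
               round(b3000$y - ms * (b3000$y - b3000$top)), tolerance = 1)
  ds_rows <- which(rowSums(rg$masks$dsDNA) > 0)
  expect_equal(min(ds_rows) - 1,
               round(b1000$y - ms * (b1000$y - b1000$top)), tolerance = 1)
  expect_equal(max(ds_rows) - 1,
               round(b100$y + ms * (b100$bottom - b100$y)), tolerance = 1)
  # missing required band -> error
  expect_error(build_regions(bands[bands$size != 3000, ],
                             fixture_clean()$digested), "3000")
  # mutual disjointness incl. background box
  acc <- rg$background_mask * 1
  for (nm in names(rg$masks)) acc <- acc + rg$masks[[nm]]
  expect_lte(max(acc), 1)
})

test_that("region construction is a pure function of the band set", {
  q <- fixture_clean_quant()
  r1 <- build_regions(q$bands, fixture_clean()$digested)
  r2 <- build_regions(q$bands, fixture_clean()$digested)
  expect_identical(r1$masks, r2$masks)
})

test_that("fraction quantification matches the pixel-sum oracle", {
  q <- fixture_clean_quant()
  rg <- q$regions
  m <- fixture_noiseless_model()
  shape <- dim(fixture_clean()$digested$stain)
  # known masses: one spot on the arc at 300 bp, one a size-doubling to
  # its left (the canonical interstrand position, centered in `behind`)
  seg <- strand_segment(300, parent_duplex_length = 300)
  x0 <- d2_migration(seg, m); y0 <- d1_migration(seg, m)
  sp <- data.frame(
    x_px = c(x0, x0 - rg$delta),
    y_px = c(y0, y0),
    mass = c(7000, 3000), channel = "stain",
    source_class = c("ds_arc", "behind"))
  img <- render_gel(sp, ladder_spec(), m, shape)
  rep <- quantify_fractions(img, rg)
  expect_equal(rep$percentage[rep$region == "dsDNA"], 70, tolerance = 0.8)
  expect_equal(rep$percentage[rep$region == "behind"], 30, tolerance = 0.8)
  expect_equal(sum(rep$percentage), 100, tolerance = 1e-6)
  # all signal strictly inside one region -> 100% / 0%
  ds_idx <- which(rg$masks$dsDNA, arr.ind = TRUE)
  r_mid <- round(stats::median(ds_idx[, 1]))
  c_mid <- round(stats::median(ds_idx[ds_idx[, 1] == r_mid, 2]))
  flat1 <- matrix(m$background_level, shape[1], shape[2])
  flat1[(r_mid - 1):(r_mid + 1), (c_mid - 1):(c_mid + 1)] <- 5000
  stopifnot(all(rg$masks$dsDNA[(r_mid - 1):(r_mid + 1),
                               (c_mid - 1):(c_mid + 1)]))
  img1 <- gel_image(flat1, flat1 * 0)
  rep1 <- quantify_fractions(img1, rg)
  expect_equal(rep1$percentage[rep1$region == "dsDNA"], 100)
  expect_true(all(rep1$percentage[rep1$region != "dsDNA"] == 0))
  # flat background-only image
  flat <- gel_image(matrix(m$background_level, shape[1], shape[2]),
                    matrix(m$background_level, shape[1], shape[2]))
  expect_error(quantify_fractions(flat, rg), "no signal above background")
})

test_that("percentages sum to 100 whenever any signal exists", {
  for (sc in c("clean", "nicking")) {
    sim <- if (sc == "clean") fixture_clean()
           else cached("nick_sim", simulate_experiment("nicking", seed = 7L))
    for (member in c("undigested", "digested")) {
      rep <- quantify_gel(sim[[member]])$report
      expect_equal(sum(rep$percentage), 100, tolerance = 1e-6)
      expect_true(all(rep$percentage >= 0))
    }
  }
})

test_that("size distribution recovers a programmed column and refuses the well", {
  q <- fixture_clean_quant()
  m <- fixture_noiseless_model()
  shape <- dim(fixture_clean()$digested$stain)
  seg <- strand_segment(180, parent_duplex_length = 180)
  sp <- data.frame(x_px = d2_migration(seg, m), y_px = d1_migration(seg, m),
                   mass = 1e5, channel = "stain", source_class = "ds_arc")
  img <- render_gel(sp, ladder_spec(), m, shape)
  dist <- estimate_size_distribution(img, q$regions, "dsDNA",
                                     q$calibration)
  expect_lt(abs(attr(dist, "mode") - 180) / 180, 0.1)
  expect_error(estimate_size_distribution(img, q$regions, "undigested",
                                          q$calibration), "undigested")
  # empty region -> empty distribution
  blank <- gel_image(matrix(m$background_level, shape[1], shape[2]),
                     img$cy5)
  d0 <- estimate_size_distribution(blank, q$regions, "behind",
                                   q$calibration)
  expect_true(nrow(d0) == 0 || sum(d0$intensity) == 0)
})

test_that("peak calling finds exactly the synthetic bands", {
  # three synthetic bands at 150/300/450 on a hand-built histogram
  sizes <- seq(100, 600, by = 2)
  intens <- 50 +
    2000 * exp(-(sizes - 150)^2 / 50) +
    1500 * exp(-(sizes - 300)^2 / 50) +
    1000 * exp(-(sizes - 450)^2 / 50)
  dist <- structure(data.frame(size = sizes, intensity = intens),
                    class = c("nla_sizedist", "data.frame"))
  peaks <- detect_ladder_peaks(dist)
  expect_length(peaks, 3L)
  expect_equal(peaks, c(150, 300, 450), tolerance = 0.02)
  # a smooth featureless smear yields no peaks
  smear <- structure(data.frame(size = sizes,
                                intensity = 3000 - 2 * sizes + 500),
                     class = c("nla_sizedist", "data.frame"))
  expect_length(detect_ladder_peaks(smear), 0L)
  empty <- structure(data.frame(size = numeric(), intensity = numeric()),
                     class = c("nla_sizedist", "data.frame"))
  expect_length(detect_ladder_peaks(empty), 0L)
})
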