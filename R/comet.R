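#' Simulate an alkaline comet image
#'
#' Head: isotropic Gaussian disc. Tail: exponential intensity profile
#' extending in the migration direction (+x). Interstrand crosslinks
#' retard migration of the broken fragments, so the tail carries
#' `fraction_in_tail * (1 - crosslink_retardation)` of the total mass over
#' an effective extent `tail_length * (1 - crosslink_retardation)`: the
#' programmed (ground-truth) tail moment decreases strictly with
#' crosslink retardation.
#'
#' @param fraction_in_tail programmed DNA fraction in the tail, in [0, 1].
#' @param tail_length programmed tail extent in px (from the head center).
#' @param crosslink_retardation in [0, 1); 0 = no crosslinks.
#' @param seed RNG seed for the noise field.
#' @param shape image shape `c(rows, cols)`.
#' @param head_sigma head Gaussian sd in px.
#' @param total_mass integrated signal in intensity units.
#' @param background,noise_sd additive background and noise.
#' @return an object of class `nla_comet`: intensity matrix `img`, head
#'   center, and the programmed ground truth (including the effective
#'   tail fraction/length after crosslink retardation).
#' @export
simulate_comet <- function(fraction_in_tail, tail_length,
                           crosslink_retardation = 0, seed = 1L,
                           shape = c(200L, 320L), head_sigma = 7,
                           total_mass = 3e6, background = 200,
                           noise_sd = 15) {
  assert_that(fraction_in_tail >= 0 && fraction_in_tail <= 1,
              "fraction_in_tail must lie in [0, 1]")
  assert_that(tail_length >= 0, "tail_length must be >= 0")
  assert_that(crosslink_retardation >= 0 && crosslink_retardation < 1,
              "crosslink_retardation must lie in [0, 1)")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  cy <- (nr + 1) / 2; cx <- round(nc * 0.28)
  f_eff <- fraction_in_tail * (1 - crosslink_retardation)
  l_eff <- tail_length * (1 - crosslink_retardation)
  img <- matrix(0, nr, nc)
  gy <- stats::dnorm(seq_len(nr), cy, head_sigma)
  gx <- stats::dnorm(seq_len(nc), cx, head_sigma)
  img <- img + (total_mass * (1 - f_eff)) * outer(gy, gx)
  if (f_eff > 0 && l_eff >= 1) {
    # truncated exponential linear density over (cx, cx + l_eff]
    d <- seq_len(nc) - cx
    lam <- 2 / l_eff
    dens <- ifelse(d > 0 & d <= l_eff, exp(-lam * d), 0)
    dens <- dens / sum(dens)
    img <- img + (total_mass * f_eff) * outer(gy / sum(gy), dens)
  }
  img <- img + background
  if (noise_sd > 0)
    img <- img + with_op_seed(seed,
      matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc))
  structure(list(img = pmax(img, 0), head_center = c(x = cx, y = cy),
                 truth = list(fraction_in_tail = fraction_in_tail,
                              tail_length = tail_length,
                              crosslink_retardation = crosslink_retardation,
                              effective_fraction = f_eff,
                              effective_length = l_eff)),
            class = "nla_comet")
}

#' Score a comet image for tail moment
#'
#' The head is segmented by mirror symmetry: columns on the non-migration
#' side of the head centroid estimate the symmetric head profile, and the
#' residual signal on the migration side is the tail. The tail length is
#' the distance from the head centroid to the last tail column above the
#' threshold (background mean + 3 sd). The tail moment is the product
#' fraction-of-DNA-in-tail x tail-length.
#'
#' @param comet an `nla_comet` or a plain intensity matrix.
#' @return an object of class `nla_comet_score`: `percent_dna_in_tail`,
#'   `tail_length` (px), `tail_moment` (= fraction x length, exactly).
#' @export
score_comet <- function(comet) {
  img <- if (inherits(comet, "nla_comet")) comet$img else comet
  border <- img[c(1:5, (nrow(img) - 4):nrow(img)), ]
  bg <- mean(border); bg_sd <- stats::sd(as.vector(border))
  thr <- bg + 3 * bg_sd
  peak <- which(img == max(img), arr.ind = TRUE)[1, ]
  assert_that(img[peak[1], peak[2]] > thr, "no head found above background")
  # The head center must not be estimated from an intensity centroid: the
  # tail drags it toward the migration side and the mirror subtraction
  # then cancels genuine tail signal. Instead use tail-free information:
  # the left (non-migration) half-maximum crossing plus the head FWHM
  # measured vertically, where head and tail share the same profile.
  half_cross <- function(vals, start, dir, level) {
    i <- start
    repeat {
      j <- i + dir
      if (j < 1L || j > length(vals)) return(i)
      if (vals[j] < level) {
        frac <- (vals[i] - level) / (vals[i] - vals[j])
        return(i + dir * frac)
      }
      i <- j
    }
  }
  r_p <- unname(peak[1]); c_p <- unname(peak[2])
  col_prof <- img[, c_p]
  lev_y <- bg + (col_prof[r_p] - bg) / 2
  top <- half_cross(col_prof, r_p, -1L, lev_y)
  bot <- half_cross(col_prof, r_p, 1L, lev_y)
  cy <- (top + bot) / 2
  sigma <- (bot - top) / 2.355
  # log-linear fit of the Gaussian flank: ln v(c) = const - (c-cx)^2/(2 s^2)
  # is linear in c once c^2/(2 s^2) is added back, so cx = s^2 * slope.
  row_prof <- img[round(cy), ]
  amp <- row_prof[c_p] - bg
  lc <- max(1L, floor(c_p - 4 * sigma)):max(1L, c_p - 3L)
  v <- row_prof[lc] - bg
  keep_c <- v > max(0.15 * amp, 5 * bg_sd)
  assert_that(sum(keep_c) >= 2L, "no head flank found")
  lc <- lc[keep_c]; v <- v[keep_c]
  z <- log(v) + lc^2 / (2 * sigma^2)
  cx <- sigma^2 * stats::cov(lc, z) / stats::var(lc)
  c0 <- round(cx)
  head_rows <- which(img[, c0] > thr)
  # total signal restricted to above-threshold pixels so that clipped
  # noise does not inflate the denominator
  mask <- img > thr
  total <- sum(img[mask] - bg)
  # mirror the left (non-migration) side onto the right: the residual on
  # the migration side is tail signal
  tail_sum <- 0
  last_col <- c0
  max_d <- min(c0 - 1L, ncol(img) - c0)
  for (d in seq_len(max_d)) {
    right <- img[, c0 + d]; left <- img[, c0 - d]
    sel <- right > thr
    tail_sum <- tail_sum + sum(pmax(right[sel] - pmax(left[sel], bg), 0))
    if (length(head_rows) > 0) {
      resid_hr <- right[head_rows] - left[head_rows]
      if (sum(resid_hr > 5 * bg_sd + 1e-12) >= 2L) last_col <- c0 + d
    }
  }
  frac <- if (total > 0) min(tail_sum / total, 1) else 0
  len <- max(last_col - cx, 0)
  if (frac == 0) len <- 0
  structure(list(percent_dna_in_tail = 100 * frac, tail_length = len,
                 tail_moment = frac * len),
            class = "nla_comet_score")
}

#' @export
print.nla_comet_score <- function(x, ...) {
  cat(sprintf("comet: %.1f%% DNA in tail, tail length %.1f px, tail moment %.2f\n",
              x$percent_dna_in_tail, x$tail_length, x$tail_moment))
  invisible(x)
}

#' Simulate and score a batch of comets
#'
#' One row per comet, mirroring the "100 comets scored in triplicate"
#' design.
#'
#' @param n number of comets.
#' @param fraction_in_tail,tail_length,crosslink_retardation programmed
#'   parameters (recycled).
#' @param seed master seed; per-comet seeds are derived.
#' @param ... passed to [simulate_comet()].
#' @return `data.frame` with programmed truth and scored values.
#' @export
comet_batch <- function(n, fraction_in_tail, tail_length,
                        crosslink_retardation = 0, seed = 1L, ...) {
  f <- rep_len(fraction_in_tail, n)
  l <- rep_len(tail_length, n)
  cr <- rep_len(crosslink_retardation, n)
  rows <- lapply(seq_len(n), function(i) {
    cm <- simulate_comet(f[i], l[i], cr[i], seed = derive_seed(seed, i), ...)
    sc <- score_comet(cm)
    data.frame(comet = i, programmed_fraction = f[i],
               programmed_tail_length = l[i],
               crosslink_retardation = cr[i],
               percent_dna_in_tail = sc$percent_dna_in_tail,
               tail_length = sc$tail_length, tail_moment = sc$tail_moment)
  })
  do.call(rbind, rows)
}
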