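#' Phenomenological 2D-SDE mobility model
#'
#' Migration distance follows a semi-log law between a resolving floor
#' `L_min` and the limiting-mobility size `L_sat`:
#' `d = d_lim + (d_max - d_lim) * clamp(log(L_sat/L) / log(L_sat/L_min), 0, 1)`.
#' Dimension 1 (native, downward `y`) additionally retards strands that are
#' single-stranded (`ss_d1_factor`) and duplexes bent by adducts
#' (`1 / (1 + bend_kappa * n_bend)`); dimension 2 (denatured, rightward
#' `x`) separates by single-strand length only.
#'
#' @param d1_lim,d1_max,d2_lim,d2_max migration distances in px; molecules
#'   at or above `L_sat` stop at the limiting distance `d*_lim`, molecules
#'   at or below `L_min` reach `d*_max`.
#' @param L_min,L_sat resolving range bounds in nt.
#' @param ss_d1_factor dimension-1 retardation of single strands, in (0, 1].
#' @param bend_kappa per-bend dimension-1 retardation (>= 0).
#' @param psf_sigma_px isotropic Gaussian point-spread sigma used by the
#'   renderer.
#' @param noise_sd additive Gaussian noise sd in intensity units (default
#'   0.5% of the 16-bit dynamic range).
#' @param background_level additive background in intensity units.
#' @param gain intensity units per unit mass.
#' @return an object of class `nla_mobility`.
#' @export
mobility_model <- function(d1_lim = 80, d1_max = 950,
                           d2_lim = 80, d2_max = 950,
                           L_min = 50L, L_sat = 20000L,
                           ss_d1_factor = 0.85, bend_kappa = 0.15,
                           psf_sigma_px = 4, noise_sd = 0.005 * 65535,
                           background_level = 1500, gain = 1) {
  assert_that(d1_lim < d1_max && d2_lim < d2_max, "need d*_lim < d*_max")
  assert_that(L_min < L_sat, "need L_min < L_sat")
  assert_that(ss_d1_factor > 0 && ss_d1_factor <= 1,
              "ss_d1_factor must lie in (0, 1]")
  assert_that(bend_kappa >= 0 && psf_sigma_px > 0 && noise_sd >= 0 &&
              background_level >= 0 && gain > 0, "invalid model parameter")
  structure(list(d1_lim = d1_lim, d1_max = d1_max, d2_lim = d2_lim,
                 d2_max = d2_max, L_min = as.integer(L_min),
                 L_sat = as.integer(L_sat), ss_d1_factor = ss_d1_factor,
                 bend_kappa = bend_kappa, psf_sigma_px = psf_sigma_px,
                 noise_sd = noise_sd, background_level = background_level,
                 gain = gain),
            class = "nla_mobility")
}

semilog_distance <- function(L, lim, dmax, L_min, L_sat) {
  lim + (dmax - lim) * clamp(log(L_sat / L) / log(L_sat / L_min), 0, 1)
}

#' Dimension-1 (native) migration distance
#'
#' Uses the native-phase species: duplex-derived strands and renatured
#' crosslink networks migrate by their parent duplex length, with the bend
#' retardation `1/(1 + bend_kappa * n_bend)`; strands single-stranded in
#' dimension 1 migrate by their own length scaled by `ss_d1_factor`.
#' Monotone non-increasing in length.
#'
#' @param entry a post-denaturation molecule (`nla_segment`,
#'   `nla_network`) or a native `nla_duplex`.
#' @param model an [mobility_model()].
#' @return migration distance `y` in px (downward from the well).
#' @export
d1_migration <- function(entry, model) {
  if (inherits(entry, "nla_duplex")) {
    L <- entry$length
    bends <- sum(entry$lesions$kind %in% BEND_KINDS)
    ss <- entry$locally_denatured
  } else {
    L <- entry$parent_duplex_length
    bends <- entry$parent_bend_count
    ss <- isTRUE(entry$is_ss_in_d1)
  }
  assert_that(L > 0, "dimension-1 length must be positive")
  y <- semilog_distance(L, model$d1_lim, model$d1_max, model$L_min,
                        model$L_sat)
  if (ss) y <- y * model$ss_d1_factor
  y / (1 + model$bend_kappa * bends)
}

#' Dimension-2 (denatured) migration distance
#'
#' The same semi-log law applied to the effective single-strand length:
#' a segment's own length, or the summed member length of a crosslink
#' network (which therefore trails behind single strands of the original
#' duplex size). No bend or strandness modifiers apply after in-gel
#' denaturation.
#'
#' @param entry an `nla_segment` or `nla_network`.
#' @param model an [mobility_model()].
#' @return migration distance `x` in px (rightward from the well).
#' @export
d2_migration <- function(entry, model) {
  L <- if (inherits(entry, "nla_network")) entry$effective_length
       else entry$length
  assert_that(L > 0, "effective length must be positive")
  semilog_distance(L, model$d2_lim, model$d2_max, model$L_min, model$L_sat)
}

#' Cy5 ladder specification
#'
#' Default sizes follow the GeneRuler 100 bp Plus ladder, 100-3000 bp.
#'
#' @param band_sizes strictly increasing fragment sizes in bp.
#' @param band_masses positive per-band masses (intensity units are
#'   arbitrary; the default renders bands well above the noise floor).
#' @return an object of class `nla_ladder`.
#' @export
ladder_spec <- function(band_sizes = c(seq(100L, 1000L, 100L), 1200L,
                                       1500L, 2000L, 3000L),
                        band_masses = rep(2e6, length(band_sizes))) {
  band_sizes <- as.integer(band_sizes)
  assert_that(all(diff(band_sizes) > 0), "band sizes must strictly increase")
  assert_that(length(band_masses) == length(band_sizes) &&
              all(band_masses > 0), "one positive mass per band required")
  structure(list(band_sizes = band_sizes, band_masses = band_masses),
            class = "nla_ladder")
}

ladder_population <- function(ladder) {
  molecule_population(
    lapply(ladder$band_sizes, function(s)
      duplex_molecule(s, origin_label = sprintf("ladder-%d", s))),
    mass_weights = ladder$band_masses,
    seed_provenance = "ladder")
}

is_ladder_label <- function(lbl) startsWith(lbl %||% "", "ladder")

classify_entry <- function(mol, model) {
  if (is_ladder_label(mol$origin_label)) return("ladder")
  if (inherits(mol, "nla_network")) return("behind")
  if (isTRUE(mol$is_ss_in_d1)) return("front_ss")
  if (mol$parent_duplex_length >= model$L_sat) {
    if (mol$length < mol$parent_duplex_length) return("ssb_streak")
    return("unmigrated")
  }
  if (mol$parent_bend_count > 0L) return("front_bent")
  if (mol$length < mol$parent_duplex_length) return("front_ss")
  "ds_arc"
}

#' Project a denatured population onto gel coordinates
#'
#' Every post-denaturation species receives `x = d2_migration` of itself
#' and `y = d1_migration` of its native-phase parent, its mass weight, and
#' a diagnostic class derived from provenance:
#' `unmigrated` (limiting-mobility parent, no strand released), `ssb_streak`
#' (short strand released from a limiting-mobility parent; these fall along
#' the limiting-mobility row with `x` set by their own length),
#' `behind` (crosslink networks), `front_bent` / `front_ss` (bent parents,
#' strands single-stranded in dimension 1, or strands released short of
#' their parent), `ds_arc` (intact duplex-derived strands) and `ladder`.
#' Total spot mass equals total population mass exactly.
#'
#' @param pop a denatured `nla_population` (see [denature()]).
#' @param model an [mobility_model()].
#' @param digested logical flag recorded with the spots (metadata only).
#' @return a `data.frame` of migration spots: `x_px`, `y_px`, `mass`,
#'   `channel` (`stain` or `cy5`), `source_class`.
#' @export
project_population <- function(pop, model, digested = FALSE) {
  assert_that(length(pop$entries) > 0L, "empty population")
  n <- length(pop$entries)
  x <- y <- mass <- numeric(n)
  cls <- character(n)
  for (i in seq_len(n)) {
    mol <- pop$entries[[i]]$mol
    if (inherits(mol, "nla_duplex"))
      stop_nla("population must be denatured before projection")
    x[i] <- d2_migration(mol, model)
    y[i] <- d1_migration(mol, model)
    mass[i] <- pop$entries[[i]]$mass
    cls[i] <- classify_entry(mol, model)
  }
  data.frame(x_px = x, y_px = y, mass = mass,
             channel = ifelse(cls == "ladder", "cy5", "stain"),
             source_class = cls, stringsAsFactors = FALSE)
}

SOURCE_CLASSES <- c("unmigrated", "ds_arc", "behind", "front_bent",
                    "front_ss", "ssb_streak")

#' Ground-truth mass fractions by diagnostic class
#'
#' @param spots output of [project_population()].
#' @return named vector of stain-channel mass fractions over the six
#'   source classes (ladder excluded).
#' @export
spot_class_fractions <- function(spots) {
  s <- spots[spots$channel == "stain", , drop = FALSE]
  tot <- sum(s$mass)
  out <- vapply(SOURCE_CLASSES, function(k)
    sum(s$mass[s$source_class == k]) / tot, 0)
  names(out) <- SOURCE_CLASSES
  out
}
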