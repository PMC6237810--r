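#' @include mobility.R render.R damage.R
NULL

SCENARIOS <- c("clean", "cisplatin-dose", "nicking", "dsb", "apoptosis",
               "parp-inhibitor", "heat-denatured", "interstrand-fraction")

# Genomic DNA stand-in: a whole genome cannot be enumerated in tests, so
# the undigested sample is a set of length-only duplexes above the
# limiting-mobility size; total mass is normalised to `stain_mass`
# intensity units.
genomic_population <- function(n_molecules = 40L, molecule_length = 30000L,
                               stain_mass = 3e7) {
  mols <- lapply(seq_len(n_molecules), function(i)
    duplex_molecule(molecule_length, origin_label = "genomic"))
  molecule_population(mols,
    mass_weights = rep(stain_mass / n_molecules, n_molecules),
    seed_provenance = "genomic-standin")
}

chromatin_population <- function(n_substrates = 40L, n_repeats = 250L,
                                 repeat_length = 180L, stain_mass = 3e7) {
  L <- as.integer(n_repeats * repeat_length)
  mols <- lapply(seq_len(n_substrates), function(i)
    duplex_molecule(L, origin_label = "chromatin"))
  molecule_population(mols,
    mass_weights = rep(stain_mass / n_substrates, n_substrates),
    seed_provenance = "chromatin-standin")
}

# Assign one interstrand crosslink to a Bernoulli(f) subset of molecules;
# used for ground-truth parameter-recovery sweeps.
mark_interstrand_fraction <- function(pop, fraction, seed = NULL) {
  assert_that(fraction >= 0 && fraction <= 1, "fraction must lie in [0,1]")
  if (fraction == 0) return(pop)
  with_op_seed(seed, map_population(pop, function(mol) {
    if (!inherits(mol, "nla_duplex") || stats::runif(1) >= fraction)
      return(list(mol))
    pos <- sample.int(mol$length, 1L) - 1L
    list(duplex_molecule(mol$length, sequence = mol$sequence,
      nicks_top = mol$nicks_top, nicks_bottom = mol$nicks_bottom,
      lesions = lesion_table(c(mol$lesions$kind, "interstrand_crosslink"),
                             c(mol$lesions$position, pos),
                             c(mol$lesions$strand, "both")),
      origin_label = mol$origin_label,
      locally_denatured = mol$locally_denatured))
  }))
}

#' Simulate a full NLA experiment
#'
#' Runs the assay's paired design: one aliquot left undigested (detects
#' strand breaks and unmigrated high-molecular-weight DNA) and one
#' digested with Mbo I (detects crosslinks and denaturation), each taken
#' through damage induction, in-gel heat denaturation, projection onto gel
#' coordinates and rendering, together with the Cy5-labeled ladder.
#'
#' Scenarios (parameters via `params`):
#' \describe{
#'   \item{clean}{no damage.}
#'   \item{cisplatin-dose}{`dose` (uM), plus any [induce_crosslink_damage()]
#'     arguments; digestion precedes treatment, as in the bench protocol.}
#'   \item{nicking}{`nick_rate` per nt (site-specific nicking enzyme
#'     emulation).}
#'   \item{dsb}{`dsb_rate` per nt.}
#'   \item{apoptosis}{`p_linker_cleave`, `ssb_in_linker_rate`,
#'     `n_repeats`, `repeat_length`, `core_length`: internucleosomal
#'     fragmentation of a chromatin substrate (the apoptosis ladder is read
#'     from the undigested member).}
#'   \item{parp-inhibitor}{`nick_rate` and `dsb_rate` combined (olaparib
#'     break patterns).}
#'   \item{heat-denatured}{`dose` as cisplatin, then the sample is heated
#'     before loading: crosslink-free DNA becomes single-stranded while
#'     crosslinked molecules renature and keep their native mobility.}
#'   \item{interstrand-fraction}{`fraction`: a Bernoulli share of digested
#'     molecules receives exactly one interstrand crosslink (ground-truth
#'     recovery sweeps).}
#' }
#'
#' @param scenario scenario name.
#' @param params named list of scenario parameters.
#' @param model an [mobility_model()].
#' @param ladder an [ladder_spec()].
#' @param image_shape raster shape in px.
#' @param seed master seed; stage seeds are derived from it.
#' @param n_molecules,molecule_length,stain_mass genomic stand-in geometry.
#' @return a list with elements `undigested` and `digested`
#'   ([gel_image()]s), `spots` (projection data frames), `populations`
#'   (post-denaturation populations), and `truth` (per-member mass
#'   fractions by source class, plus scenario extras).
#' @export
simulate_experiment <- function(scenario = "clean", params = list(),
                                model = mobility_model(),
                                ladder = ladder_spec(),
                                image_shape = c(1024L, 1024L),
                                seed = 1L,
                                n_molecules = 40L,
                                molecule_length = 30000L,
                                stain_mass = 3e7) {
  assert_that(scenario %in% SCENARIOS,
              "unknown scenario '%s' (one of: %s)", scenario,
              paste(SCENARIOS, collapse = ", "))
  p <- params
  s <- function(k) derive_seed(seed, k)
  extras <- list()

  if (scenario == "apoptosis") {
    rep_len <- as.integer(p$repeat_length %||% 180L)
    base <- chromatin_population(
      n_substrates = p$n_substrates %||% 40L,
      n_repeats = p$n_repeats %||% 250L,
      repeat_length = rep_len, stain_mass = stain_mass)
    base <- apoptotic_fragmentation(base, repeat_length = rep_len,
      core_length = as.integer(p$core_length %||% 147L),
      p_linker_cleave = p$p_linker_cleave %||% 0.5,
      ssb_in_linker_rate = p$ssb_in_linker_rate %||% 0.3, seed = s(1))
    undig <- base
    dig <- mbo1_digest(base, length_only = "geometric", seed = s(2))
  } else {
    base <- genomic_population(n_molecules, molecule_length, stain_mass)
    dig <- mbo1_digest(base, length_only = "geometric", seed = s(2))
    undig <- base
    if (scenario == "cisplatin-dose" || scenario == "heat-denatured") {
      dmg <- function(pop, k) induce_crosslink_damage(pop,
        dose = p$dose %||% 8,
        lesion_rate_per_nt_per_dose = p$lesion_rate_per_nt_per_dose %||% 2.5e-4,
        mix = p$mix %||% c(interstrand_crosslink = 0.05,
                           intrastrand_crosslink = 0.75, monoadduct = 0.20),
        denaturation_density_threshold =
          p$denaturation_density_threshold %||% (1 / 200),
        seed = s(k))
      undig <- dmg(undig, 3); dig <- dmg(dig, 4)
      if (scenario == "heat-denatured") {
        undig <- denature(undig, context = "pre_load")
        dig <- denature(dig, context = "pre_load")
      }
    } else if (scenario == "nicking") {
      undig <- induce_nicks(undig, rate = p$nick_rate %||% 1e-3, seed = s(3))
      dig <- induce_nicks(dig, rate = p$nick_rate %||% 1e-3, seed = s(4))
    } else if (scenario == "dsb") {
      undig <- induce_dsbs(undig, rate = p$dsb_rate %||% 2e-4, seed = s(3))
      dig <- induce_dsbs(dig, rate = p$dsb_rate %||% 2e-4, seed = s(4))
    } else if (scenario == "parp-inhibitor") {
      undig <- induce_nicks(undig, rate = p$nick_rate %||% 3e-4, seed = s(3))
      undig <- induce_dsbs(undig, rate = p$dsb_rate %||% 1e-4, seed = s(5))
      dig <- induce_nicks(dig, rate = p$nick_rate %||% 3e-4, seed = s(4))
      dig <- induce_dsbs(dig, rate = p$dsb_rate %||% 1e-4, seed = s(6))
    } else if (scenario == "interstrand-fraction") {
      dig <- mark_interstrand_fraction(dig, p$fraction %||% 0.1, seed = s(3))
      extras$realized_interstrand_fraction <- nonamplifiable_mass_fraction(dig)
    }
  }

  den_undig <- denature(undig, context = "between_dimensions")
  den_dig <- denature(dig, context = "between_dimensions")
  spots_undig <- project_population(den_undig, model, digested = FALSE)
  spots_dig <- project_population(den_dig, model, digested = TRUE)
  list(
    undigested = render_gel(spots_undig, ladder, model, image_shape,
                            seed = s(7)),
    digested = render_gel(spots_dig, ladder, model, image_shape,
                          seed = s(8)),
    spots = list(undigested = spots_undig, digested = spots_dig),
    populations = list(undigested = den_undig, digested = den_dig),
    truth = c(list(undigested = spot_class_fractions(spots_undig),
                   digested = spot_class_fractions(spots_dig),
                   scenario = scenario, seed = seed), extras))
}
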