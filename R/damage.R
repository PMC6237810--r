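#' @include molecules.R
NULL

# Split one duplex at sorted cut offsets (0-based, strictly inside).
# Fragments inherit nicks and lesions with coordinates shifted by the
# fragment start; a nick coinciding with a cut becomes a fragment end.
split_duplex_at <- function(d, cuts) {
  cuts <- sort(unique(as.integer(cuts)))
  cuts <- cuts[cuts > 0L & cuts < d$length]
  if (length(cuts) == 0L) return(list(d))
  bounds <- c(0L, cuts, d$length)
  lapply(seq_len(length(bounds) - 1L), function(i) {
    a <- bounds[i]; b <- bounds[i + 1L]
    les <- d$lesions[d$lesions$position >= a & d$lesions$position < b, ,
                     drop = FALSE]
    les$position <- les$position - a
    duplex_molecule(b - a,
      sequence = if (is.null(d$sequence)) NULL else substr(d$sequence, a + 1L, b),
      nicks_top = shift_nicks(d$nicks_top, a, b),
      nicks_bottom = shift_nicks(d$nicks_bottom, a, b),
      lesions = les, origin_label = d$origin_label,
      locally_denatured = d$locally_denatured)
  })
}

shift_nicks <- function(nicks, a, b) nicks[nicks > a & nicks < b] - a

split_segment_at <- function(s, cuts) {
  cuts <- sort(unique(as.integer(cuts)))
  cuts <- cuts[cuts > 0L & cuts < s$length]
  if (length(cuts) == 0L) return(list(s))
  bounds <- c(0L, cuts, s$length)
  lapply(seq_len(length(bounds) - 1L), function(i) {
    a <- bounds[i]; b <- bounds[i + 1L]
    strand_segment(b - a, parent_duplex_length = b - a,
      parent_bend_count = 0L, is_ss_in_d1 = s$is_ss_in_d1,
      sequence = if (is.null(s$sequence)) NULL else substr(s$sequence, a + 1L, b),
      origin_label = s$origin_label)
  })
}

# Map an operation over population entries; `f(mol)` returns a list of
# product molecules. Mass is distributed proportionally to nucleotide
# count, so total mass and total nucleotides are conserved exactly.
map_population <- function(pop, f, provenance = pop$seed_provenance) {
  out <- vector("list", 0L)
  for (e in pop$entries) {
    prods <- f(e$mol)
    parent_nt <- as.double(nt_count(e$mol))
    shares <- vapply(prods, function(p) as.double(nt_count(p)), 0) / parent_nt
    out <- c(out, Map(function(p, s) list(mol = p, mass = e$mass * s),
                      prods, shares))
  }
  pop_from_entries(out, provenance)
}

find_site_cuts <- function(sequence, site) {
  # cut 5' of the recognition site (Mbo I ^GATC chemistry): the cut offset
  # equals the 0-based start of each occurrence.
  starts <- gregexpr(site, sequence, fixed = TRUE)[[1]]
  if (starts[1] == -1L) return(integer())
  as.integer(starts) - 1L
}

#' Mbo I restriction digestion
#'
#' Converts every occurrence of the recognition site (default `GATC`) into
#' a double-strand cut, 5' of the site. Mbo I digests both double- and
#' single-stranded DNA, so sequence-carrying strand segments are cut at the
#' same occurrences. A cut is blocked when any lesion lies within
#' `lesion_block_window` nucleotides of the site (adducts sterically block
#' restriction). Fragments inherit nicks and lesions with shifted
#' coordinates; the total nucleotide count is conserved.
#'
#' Populations in length-only mode (no sequences) require
#' `length_only = "geometric"`: fragment lengths are then sampled from a
#' geometric law with mean `4^nchar(site)` (256 nt for a 4-cutter), the
#' expected spacing of a random site.
#'
#' @param pop an `nla_population`.
#' @param site recognition sequence over A/C/G/T.
#' @param lesion_block_window cut-blocking half-window in nt (default 4).
#' @param length_only `"error"` (default) or `"geometric"`.
#' @param seed RNG seed, used only in length-only mode.
#' @return the digested population.
#' @export
mbo1_digest <- function(pop, site = "GATC", lesion_block_window = 4L,
                        length_only = c("error", "geometric"), seed = NULL) {
  length_only <- match.arg(length_only)
  site <- toupper(site)
  assert_that(!grepl("[^ACGT]", site) && nchar(site) >= 1L,
              "site not over alphabet {A,C,G,T}")
  w <- as.integer(lesion_block_window)
  mean_frag <- 4^nchar(site)
  with_op_seed(seed, map_population(pop, function(mol) {
    if (inherits(mol, "nla_network")) return(list(mol))
    if (is.null(mol$sequence)) {
      if (length_only == "error")
        stop_nla("molecule lacks a sequence and length-only digestion is not enabled")
      cuts <- sample_geometric_cuts(mol$length, mean_frag)
    } else {
      cuts <- find_site_cuts(mol$sequence, site)
      if (inherits(mol, "nla_duplex") && nrow(mol$lesions) > 0L && length(cuts)) {
        blocked <- vapply(cuts, function(cc) {
          any(mol$lesions$position >= cc - w &
              mol$lesions$position <= cc + nchar(site) - 1L + w)
        }, TRUE)
        cuts <- cuts[!blocked]
      }
    }
    if (inherits(mol, "nla_duplex")) split_duplex_at(mol, cuts)
    else split_segment_at(mol, cuts)
  }))
}

sample_geometric_cuts <- function(L, mean_frag) {
  # successive fragment lengths ~ 1 + Geom(1/mean): mean = mean_frag
  cuts <- integer(); pos <- 0L
  repeat {
    pos <- pos + 1L + stats::rgeom(1L, 1 / mean_frag)
    if (pos >= L) break
    cuts <- c(cuts, pos)
  }
  cuts
}

#' Induce single-strand nicks
#'
#' Either site-specific (a nicking endonuclease recognition sequence, e.g.
#' the 5 bp site of Nt.BstNB I) or random at `rate` nicks per nucleotide
#' (Poisson). In `strand_mode = "both"` random nicks are assigned to a
#' uniformly chosen strand, keeping the expected total at `rate * length`.
#' Molecule count and total length are unchanged.
#'
#' @param pop an `nla_population`.
#' @param recognition optional recognition sequence (requires sequences).
#' @param rate nicks per nucleotide (>= 0); ignored when `recognition`
#'   is given.
#' @param strand_mode `"top_only"` or `"both"`.
#' @param seed RNG seed.
#' @return population with nicks appended; only duplexes are nicked.
#' @export
induce_nicks <- function(pop, recognition = NULL, rate = NULL,
                         strand_mode = c("both", "top_only"), seed = NULL) {
  strand_mode <- match.arg(strand_mode)
  if (is.null(recognition)) {
    assert_that(is.numeric(rate) && rate >= 0, "negative nick rate")
    if (rate == 0) return(pop)
  } else {
    recognition <- toupper(recognition)
    assert_that(!grepl("[^ACGT]", recognition), "invalid recognition sequence")
  }
  with_op_seed(seed, map_population(pop, function(mol) {
    if (!inherits(mol, "nla_duplex")) return(list(mol))
    L <- mol$length
    if (is.null(recognition)) {
      n <- stats::rpois(1L, rate * L)
      if (n == 0L || L < 2L) return(list(mol))
      positions <- sample.int(L - 1L, min(n, L - 1L), replace = FALSE)
      on_top <- if (strand_mode == "top_only") rep(TRUE, length(positions))
                else sample(c(TRUE, FALSE), length(positions), replace = TRUE)
    } else {
      assert_that(!is.null(mol$sequence),
                  "recognition-site nicking requires sequences")
      pos_top <- find_site_cuts(mol$sequence, recognition)
      pos_top <- pos_top[pos_top > 0L & pos_top < L]
      if (strand_mode == "both") {
        rc <- revcomp(mol$sequence)
        pos_bot <- find_site_cuts(rc, recognition)
        pos_bot <- L - pos_bot - nchar(recognition)
        pos_bot <- pos_bot[pos_bot > 0L & pos_bot < L]
      } else pos_bot <- integer()
      positions <- c(pos_top, pos_bot)
      on_top <- c(rep(TRUE, length(pos_top)), rep(FALSE, length(pos_bot)))
      if (length(positions) == 0L) return(list(mol))
    }
    list(duplex_molecule(L, sequence = mol$sequence,
      nicks_top = c(mol$nicks_top, positions[on_top]),
      nicks_bottom = c(mol$nicks_bottom, positions[!on_top]),
      lesions = mol$lesions, origin_label = mol$origin_label,
      locally_denatured = mol$locally_denatured))
  }))
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Induce double-strand breaks
#'
#' Breaks are placed at Poisson-distributed positions (`rate` per
#' nucleotide); each molecule splits into independent fragments that
#' inherit re-homed nicks and lesions. Total length is conserved.
#'
#' @param pop an `nla_population`.
#' @param rate breaks per nucleotide (>= 0).
#' @param seed RNG seed.
#' @return the fragmented population.
#' @export
induce_dsbs <- function(pop, rate, seed = NULL) {
  assert_that(is.numeric(rate) && rate >= 0, "negative DSB rate")
  if (rate == 0) return(pop)
  with_op_seed(seed, map_population(pop, function(mol) {
    if (inherits(mol, "nla_network")) return(list(mol))
    L <- mol$length
    n <- stats::rpois(1L, rate * L)
    if (n == 0L || L < 2L) return(list(mol))
    cuts <- sample.int(L - 1L, min(n, L - 1L), replace = FALSE)
    if (inherits(mol, "nla_duplex")) split_duplex_at(mol, cuts)
    else split_segment_at(mol, cuts)
  }))
}

#' Induce crosslinking damage (cisplatin / mitomycin C model)
#'
#' Lesion count per duplex is Poisson with mean
#' `dose * lesion_rate_per_nt_per_dose * length`; lesion kinds follow the
#' `mix` proportions (interstrand crosslinks join both strands; intrastrand
#' crosslinks and monoadducts bend the duplex and sit on one strand).
#' Duplexes whose density of non-interstrand lesions exceeds
#' `denaturation_density_threshold` lose base pairing and are flagged
#' locally denatured: their strands enter dimension 1 single-stranded.
#'
#' @param pop an `nla_population`.
#' @param dose treatment dose (arbitrary units, e.g. uM; >= 0).
#' @param lesion_rate_per_nt_per_dose lesions per nucleotide per dose unit.
#' @param mix named proportions over `interstrand_crosslink`,
#'   `intrastrand_crosslink`, `monoadduct`; must sum to 1.
#' @param denaturation_density_threshold bending lesions per nt above which
#'   the duplex denatures locally (default 1 per 200 nt).
#' @param seed RNG seed.
#' @return the damaged population.
#' @export
induce_crosslink_damage <- function(pop, dose,
    lesion_rate_per_nt_per_dose = 2.5e-4,
    mix = c(interstrand_crosslink = 0.05, intrastrand_crosslink = 0.75,
            monoadduct = 0.20),
    denaturation_density_threshold = 1 / 200, seed = NULL) {
  assert_that(is.numeric(dose) && dose >= 0, "negative dose")
  assert_that(all(names(mix) %in% LESION_KINDS) && length(mix) > 0,
              "mix must be named over the lesion kinds")
  assert_that(abs(sum(mix) - 1) <= 1e-9, "mix proportions must sum to 1")
  if (dose == 0) return(pop)
  with_op_seed(seed, map_population(pop, function(mol) {
    if (!inherits(mol, "nla_duplex")) return(list(mol))
    L <- mol$length
    n <- stats::rpois(1L, dose * lesion_rate_per_nt_per_dose * L)
    if (n == 0L) return(list(mol))
    n <- min(n, L)
    kinds <- sample(names(mix), n, replace = TRUE, prob = mix)
    positions <- sample.int(L, n, replace = FALSE) - 1L
    strands <- ifelse(kinds == "interstrand_crosslink", "both",
                      sample(c("top", "bottom"), n, replace = TRUE))
    new_les <- lesion_table(c(mol$lesions$kind, kinds),
                            c(mol$lesions$position, positions),
                            c(mol$lesions$strand, strands))
    bend_density <- sum(new_les$kind %in% BEND_KINDS) / L
    list(duplex_molecule(L, sequence = mol$sequence,
      nicks_top = mol$nicks_top, nicks_bottom = mol$nicks_bottom,
      lesions = new_les, origin_label = mol$origin_label,
      locally_denatured = mol$locally_denatured ||
        bend_density > denaturation_density_threshold))
  }))
}

#' Apoptotic internucleosomal fragmentation
#'
#' Chromatin substrates are cut only in linker DNA: the midpoint of the
#' linker following nucleosome k sits at `(k-1)*repeat_length +
#' (core_length + repeat_length) %/% 2` and is cleaved with probability
#' `p_linker_cleave`, so fragment lengths are multiples of the nucleosome
#' repeat (boundary fragments excepted). Uncleaved linkers additionally
#' receive a single-strand nick with probability `ssb_in_linker_rate`
#' (incomplete fragmentation intermediates), which produces the vertical
#' columns and the horizontal streak seen alongside real apoptotic ladders.
#'
#' @param pop an `nla_population` of chromatin-sized duplexes.
#' @param repeat_length nucleosome repeat in nt (default 180, human).
#' @param core_length core particle in nt (default 147).
#' @param p_linker_cleave per-linker cleavage probability in `[0, 1]`.
#' @param ssb_in_linker_rate per-linker nick probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return the fragmented population.
#' @export
apoptotic_fragmentation <- function(pop, repeat_length = 180L,
                                    core_length = 147L,
                                    p_linker_cleave = 0.5,
                                    ssb_in_linker_rate = 0.3,
                                    seed = NULL) {
  repeat_length <- as.integer(repeat_length)
  core_length <- as.integer(core_length)
  assert_that(repeat_length > core_length && core_length >= 0L,
              "need repeat_length > core_length >= 0")
  assert_that(p_linker_cleave >= 0 && p_linker_cleave <= 1 &&
              ssb_in_linker_rate >= 0 && ssb_in_linker_rate <= 1,
              "probabilities must lie in [0, 1]")
  if (p_linker_cleave == 0 && ssb_in_linker_rate == 0) return(pop)
  offset <- (core_length + repeat_length) %/% 2L
  with_op_seed(seed, map_population(pop, function(mol) {
    if (!inherits(mol, "nla_duplex")) return(list(mol))
    L <- mol$length
    k_max <- (L - offset - 1L) %/% repeat_length
    if (k_max < 0L) return(list(mol))
    mids <- offset + repeat_length * (0L:k_max)
    cut <- stats::runif(length(mids)) < p_linker_cleave
    nick <- !cut & stats::runif(length(mids)) < ssb_in_linker_rate
    nick_top <- nick & sample(c(TRUE, FALSE), length(mids), replace = TRUE)
    d <- duplex_molecule(L, sequence = mol$sequence,
      nicks_top = c(mol$nicks_top, mids[nick_top]),
      nicks_bottom = c(mol$nicks_bottom, mids[nick & !nick_top]),
      lesions = mol$lesions, origin_label = mol$origin_label,
      locally_denatured = mol$locally_denatured)
    split_duplex_at(d, mids[cut])
  }))
}

#' Heat denaturation
#'
#' Each duplex separates into single strands split at its nick positions.
#' Strands joined by at least one interstrand crosslink remain covalently
#' attached and merge into one [crosslink_network()]. The `context`
#' distinguishes the two uses of heat in the assay:
#'
#' * `between_dimensions` (in-gel, before dimension 2): strands remember
#'   the duplex they belonged to during dimension-1 migration.
#' * `pre_load` (sample heated before loading): crosslink-free duplexes
#'   permanently become single strands and run dimension 1 by their own
#'   length; crosslinked molecules renature in solution and re-adopt the
#'   dimension-1 mobility of their parent duplex, which is why the
#'   interstrand arc is resistant to heat denaturation.
#'
#' Locally denatured duplexes (high adduct density) behave like `pre_load`
#' crosslink-free duplexes. Total nucleotides are conserved; the operation
#' is idempotent on segments and networks.
#'
#' @param pop an `nla_population`.
#' @param context `"between_dimensions"` or `"pre_load"`.
#' @return the denatured population.
#' @export
denature <- function(pop, context = c("between_dimensions", "pre_load")) {
  context <- match.arg(context)
  map_population(pop, function(mol) denature_mol(mol, context))
}

denature_mol <- function(mol, context) {
  if (!inherits(mol, "nla_duplex")) return(list(mol))
  L <- mol$length
  top_bounds <- c(0L, mol$nicks_top, L)
  bot_bounds <- c(0L, mol$nicks_bottom, L)
  n_top <- length(top_bounds) - 1L
  n_bot <- length(bot_bounds) - 1L
  icl <- mol$lesions[mol$lesions$kind == "interstrand_crosslink", ,
                     drop = FALSE]
  bends <- sum(mol$lesions$kind %in% BEND_KINDS)
  seg_of <- function(p, bounds) findInterval(p, bounds,
                                             rightmost.closed = FALSE)
  # union-find over strand segments: nodes 1..n_top are top segments,
  # n_top+1..n_top+n_bot bottom segments
  parent <- seq_len(n_top + n_bot)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(icl) > 0L) {
    for (p in icl$position) {
      a <- find(seg_of(p, top_bounds))
      b <- find(n_top + seg_of(p, bot_bounds))
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_along(parent), find, 0L)
  linked_nodes <- if (nrow(icl) > 0L)
    unique(c(vapply(icl$position, function(p) find(seg_of(p, top_bounds)), 0L)))
  else integer()
  seg_len <- c(diff(top_bounds), diff(bot_bounds))
  make_seg <- function(len, free) {
    # `free`: strand not attached to a network; under pre_load (or a
    # locally denatured duplex) free strands run dimension 1 by themselves
    ss <- free && (context == "pre_load" || mol$locally_denatured)
    strand_segment(len,
      parent_duplex_length = if (ss) len else L,
      parent_bend_count = if (ss) 0L else bends,
      is_ss_in_d1 = ss, origin_label = mol$origin_label)
  }
  out <- list()
  for (root in unique(roots)) {
    nodes <- which(roots == root)
    if (root %in% linked_nodes && length(nodes) >= 2L) {
      members <- lapply(seg_len[nodes], function(len)
        strand_segment(len, parent_duplex_length = L,
                       parent_bend_count = bends,
                       origin_label = mol$origin_label))
      out <- c(out, list(crosslink_network(members, L, bends,
                                           mol$origin_label)))
    } else {
      out <- c(out, lapply(seg_len[nodes], make_seg, free = TRUE))
    }
  }
  out
}
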