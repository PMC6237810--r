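test_that("Mbo I digestion matches the linear-scan oracle", {
  # no site: one fragment
  p <- seq_pop(strrep("ACGT", 10))
  expect_identical(entry_lengths(mbo1_digest(p)), 40L)
  # GATC at 0-based offsets 10 and 30 -> cuts 5' of the site: 10/20/20
  s <- paste0(strrep("A", 10), "GATC", strrep("C", 16), "GATC",
              strrep("T", 16))
  expect_identical(nchar(s), 50L)
  expect_identical(entry_lengths(mbo1_digest(seq_pop(s))),
                   c(10L, 20L, 20L))
  expect_conserved(seq_pop(s), mbo1_digest(seq_pop(s)))
  # oracle cross-check on a random sequence: fragment lengths equal the
  # diffs of an independent regex scan
  set.seed(42)
  rs <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
              collapse = "")
  got <- entry_lengths(mbo1_digest(seq_pop(rs)))
  starts <- gregexpr("GATC", rs, fixed = TRUE)[[1]]
  starts <- if (starts[1] == -1) integer() else as.integer(starts) - 1L
  expect_identical(got, as.integer(diff(c(0L, starts, 3000L))))
})

test_that("Mbo I digests single strands and respects lesion blocking", {
  # a single strand segment carrying one GATC -> 2 segments
  seg <- strand_segment(30, sequence = paste0(strrep("A", 13), "GATC",
                                              strrep("C", 13)),
                        is_ss_in_d1 = TRUE)
  pop <- molecule_population(list(seg))
  cut <- mbo1_digest(pop)
  expect_identical(entry_lengths(cut), c(13L, 17L))
  expect_true(all(vapply(cut$entries, function(e) e$mol$is_ss_in_d1, TRUE)))
  # a lesion within the blocking window protects the site
  s <- paste0(strrep("A", 13), "GATC", strrep("C", 13))
  blocked <- seq_pop(s)
  blocked$entries[[1]]$mol$lesions <-
    lesion_table("monoadduct", 15, "top")
  expect_identical(entry_lengths(mbo1_digest(blocked)), 30L)
  # same lesion outside the window does not block
  far <- seq_pop(s)
  far$entries[[1]]$mol$lesions <- lesion_table("monoadduct", 25, "top")
  expect_identical(entry_lengths(mbo1_digest(far)), c(13L, 17L))
  # invalid site
  expect_error(mbo1_digest(seq_pop(s), site = "GAXC"), "alphabet")
  # length-only mode must be requested explicitly
  expect_error(mbo1_digest(molecule_population(list(duplex_molecule(100)))),
               "sequence")
})

test_that("length-only digestion samples geometric fragments with mean 4^k", {
  pop <- molecule_population(list(duplex_molecule(200000L)))
  dig <- mbo1_digest(pop, length_only = "geometric", seed = 7)
  expect_conserved(pop, dig)
  lens <- entry_lengths(dig)
  # mean fragment length within 3 SE of 256 (sd ~ mean for a geometric law)
  se <- 256 / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 256), 3 * se)
  # determinism
  dig2 <- mbo1_digest(pop, length_only = "geometric", seed = 7)
  expect_identical(entry_lengths(dig2), lens)
})

test_that("nick induction is Poisson with conserved molecules", {
  pop <- molecule_population(lapply(1:20, function(i) duplex_molecule(1000)))
  expect_identical(induce_nicks(pop, rate = 0), pop)
  expect_error(induce_nicks(pop, rate = -1), "negative")
  nicked <- induce_nicks(pop, rate = 1e-3, seed = 1)
  expect_length(nicked$entries, 20L)
  expect_conserved(pop, nicked)
  # Monte-Carlo oracle: mean nick count ~ rate * L over seeds
  rate <- 2e-3; L <- 20 * 1000
  counts <- vapply(1:200, function(sd) {
    np <- induce_nicks(pop, rate = rate, seed = sd)
    sum(vapply(np$entries, function(e)
      length(e$mol$nicks_top) + length(e$mol$nicks_bottom), 0L))
  }, 0)
  se <- sqrt(rate * L / 200)  # Poisson sd of the mean
  expect_lt(abs(mean(counts) - rate * L), 3 * se)
})

test_that("recognition-site nicking marks only matching sites", {
  s <- paste0("ACGT", "GAGTC", strrep("T", 20), "GAGTC", "ACGTA")
  pop <- seq_pop(s)
  top <- induce_nicks(pop, recognition = "GAGTC", strand_mode = "top_only")
  d <- top$entries[[1]]$mol
  expect_identical(d$nicks_top, c(4L, 29L))
  expect_identical(d$nicks_bottom, integer())
  both <- induce_nicks(pop, recognition = "GAGTC", strand_mode = "both")
  expect_identical(both$entries[[1]]$mol$nicks_top, c(4L, 29L))
})

test_that("DSB induction splits molecules and conserves totals", {
  pop <- molecule_population(list(duplex_molecule(1000)))
  expect_identical(induce_dsbs(pop, 0), pop)
  expect_error(induce_dsbs(pop, -0.1), "negative")
  # forced single cut arithmetic via split helper
  frags <- northernlights:::split_duplex_at(duplex_molecule(1000), 100L)
  expect_identical(vapply(frags, function(f) f$length, 0L), c(100L, 900L))
  # Monte-Carlo oracle: fragment count = 1 + Poisson(rate*L)
  rate <- 5e-3; L <- 1000
  n_frag <- vapply(1:200, function(sd)
    length(induce_dsbs(pop, rate, seed = sd)$entries), 0)
  se <- sqrt(rate * L / 200)
  expect_lt(abs(mean(n_frag) - (1 + rate * L)), 3 * se)
  for (sd in 1:5)
    expect_conserved(pop, induce_dsbs(pop, rate, seed = sd))
})

test_that("crosslink damage follows the dose model", {
  pop <- molecule_population(lapply(1:10, function(i) duplex_molecule(2000)))
  expect_identical(induce_crosslink_damage(pop, dose = 0), pop)
  expect_error(induce_crosslink_damage(pop, dose = 1,
    mix = c(interstrand_crosslink = 0.6, intrastrand_crosslink = 0.6)),
    "sum to 1")
  # Monte-Carlo oracle for the lesion count
  dose <- 4; rate <- 2.5e-4; L <- 10 * 2000
  counts <- vapply(1:200, function(sd) {
    dp <- induce_crosslink_damage(pop, dose, rate, seed = sd)
    sum(vapply(dp$entries, function(e) nrow(e$mol$lesions), 0L))
  }, 0)
  lambda <- dose * rate * L
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
  # expected interstrand count strictly increases with dose
  icl_mean <- vapply(c(2, 8, 20), function(d) {
    mean(vapply(1:60, function(sd) {
      dp <- induce_crosslink_damage(pop, d, rate, seed = sd)
      sum(vapply(dp$entries, function(e)
        sum(e$mol$lesions$kind == "interstrand_crosslink"), 0L))
    }, 0))
  }, 0)
  expect_true(all(diff(icl_mean) > 0))
  # high adduct density flags local denaturation
  dense <- induce_crosslink_damage(pop, dose = 200, rate, seed = 1)
  expect_true(any(vapply(dense$entries, function(e)
    e$mol$locally_denatured, TRUE)))
})

test_that("apoptotic fragmentation cuts only linker midpoints", {
  pop <- molecule_population(list(duplex_molecule(100L * 180L,
                                                  origin_label = "chromatin")))
  expect_identical(apoptotic_fragmentation(pop, p_linker_cleave = 0,
                                           ssb_in_linker_rate = 0), pop)
  expect_error(apoptotic_fragmentation(pop, p_linker_cleave = 1.5),
               "\\[0, 1\\]")
  expect_error(apoptotic_fragmentation(pop, repeat_length = 100,
                                       core_length = 150), "core_length")
  # complete cleavage: all internal fragments exactly one repeat
  full <- apoptotic_fragmentation(pop, p_linker_cleave = 1,
                                  ssb_in_linker_rate = 0, seed = 1)
  lens <- entry_lengths(full)
  expect_true(all(lens[2:(length(lens) - 1)] == 180L))
  expect_conserved(pop, full)
  # partial cleavage: geometric fragment sizes, mean ~ 2 repeats at p=0.5
  sizes <- unlist(lapply(1:30, function(sd) {
    f <- apoptotic_fragmentation(pop, p_linker_cleave = 0.5,
                                 ssb_in_linker_rate = 0, seed = sd)
    lens <- entry_lengths(f)
    lens[2:(length(lens) - 1)] / 180
  }))
  expect_true(all(abs(sizes - round(sizes)) < 1e-9))
  se <- sqrt(2) / sqrt(length(sizes))  # geometric(1/2) sd ~ sqrt(2)
  expect_lt(abs(mean(sizes) - 2), 3 * se)
})

test_that("denaturation splits strands at nicks and builds networks", {
  # intact duplex -> two equal strands
  den <- denature(molecule_population(list(duplex_molecule(500))))
  expect_identical(entry_lengths(den), c(500L, 500L))
  # one top nick at 200 -> 200 + 300 + 500
  den2 <- denature(molecule_population(list(
    duplex_molecule(500, nicks_top = 200L))))
  expect_setequal(entry_lengths(den2), c(200L, 300L, 500L))
  # interstrand crosslink -> one network of both strands, 1000 nt
  icl <- duplex_molecule(500,
    lesions = lesion_table("interstrand_crosslink", 250, "both"))
  den3 <- denature(molecule_population(list(icl)))
  expect_length(den3$entries, 1L)
  expect_s3_class(den3$entries[[1]]$mol, "nla_network")
  expect_identical(den3$entries[[1]]$mol$effective_length, 1000L)
  # a nick-detached segment outside the crosslink leaves the network
  icl_nick <- duplex_molecule(500, nicks_top = 400L,
    lesions = lesion_table("interstrand_crosslink", 100, "both"))
  den4 <- denature(molecule_population(list(icl_nick)))
  cls <- vapply(den4$entries, function(e) class(e$mol)[1], "")
  expect_identical(sort(cls), c("nla_network", "nla_segment"))
  net <- den4$entries[[which(cls == "nla_network")]]$mol
  expect_identical(net$effective_length, 900L)  # 400 (top) + 500 (bottom)
  expect_conserved(molecule_population(list(icl_nick)), den4)
})

test_that("denaturation is idempotent and pre_load frees single strands", {
  pop <- molecule_population(list(
    duplex_molecule(400, nicks_top = 100L),
    duplex_molecule(300,
      lesions = lesion_table("interstrand_crosslink", 50, "both"))))
  once <- denature(pop)
  twice <- denature(once)
  expect_identical(entry_lengths(once), entry_lengths(twice))
  expect_identical(vapply(once$entries, function(e) class(e$mol)[1], ""),
                   vapply(twice$entries, function(e) class(e$mol)[1], ""))
  # pre_load: crosslink-free strands run dimension 1 by themselves,
  # crosslinked molecules renature with the parent's native mobility
  pre <- denature(pop, context = "pre_load")
  segs <- Filter(function(e) inherits(e$mol, "nla_segment"), pre$entries)
  expect_true(all(vapply(segs, function(e) e$mol$is_ss_in_d1, TRUE)))
  expect_true(all(vapply(segs, function(e)
    e$mol$parent_duplex_length == e$mol$length, TRUE)))
  nets <- Filter(function(e) inherits(e$mol, "nla_network"), pre$entries)
  expect_identical(nets[[1]]$mol$parent_duplex_length, 300L)
})

test_that("damage operations are seed-deterministic and conservative", {
  base <- molecule_population(lapply(1:10, function(i)
    duplex_molecule(5000)))
  ops <- list(
    function(p, sd) induce_nicks(p, rate = 5e-4, seed = sd),
    function(p, sd) induce_dsbs(p, rate = 2e-4, seed = sd),
    function(p, sd) induce_crosslink_damage(p, dose = 8, seed = sd),
    function(p, sd) mbo1_digest(p, length_only = "geometric", seed = sd),
    function(p, sd) apoptotic_fragmentation(p, seed = sd))
  for (op in ops) {
    for (sd in c(1, 99)) {
      a <- op(base, sd); b <- op(base, sd)
      expect_identical(a, b)
      expect_conserved(base, a)
      expect_conserved(a, denature(a))
    }
  }
})
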