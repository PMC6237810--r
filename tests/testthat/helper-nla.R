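# Shared fixtures, memoized: several tests reuse the same simulated gels.
.nla_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .nla_cache)) {
    assign(key, force(expr), envir = .nla_cache)
  }
  get(key, envir = .nla_cache)
}

fixture_clean <- function() {
  cached("clean", simulate_experiment("clean", seed = 101L))
}

fixture_clean_quant <- function() {
  cached("clean_quant", quantify_gel(fixture_clean()$digested))
}

fixture_noiseless_model <- function() mobility_model(noise_sd = 0)

# a small sequence-carrying duplex population for digestion tests
seq_pop <- function(seqs, ...) {
  molecule_population(lapply(seqs, function(s)
    duplex_molecule(nchar(s), sequence = s, ...)))
}

entry_lengths <- function(pop) {
  vapply(pop$entries, function(e)
    if (is.null(e$mol$length)) NA_integer_ else e$mol$length, 0L)
}

expect_conserved <- function(before, after) {
  expect_equal(total_nt(after), total_nt(before))
  expect_equal(total_mass(after), total_mass(before))
}
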