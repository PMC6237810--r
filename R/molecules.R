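#' DNA molecule and lesion containers
#'
#' The molecule model represents the species resolved by 2D
#' strandness-dependent electrophoresis (2D-SDE): native duplexes with
#' per-strand nicks and covalent lesions, single strands produced by
#' denaturation, and the covalent networks formed when interstrand
#' crosslinks keep complementary strands attached after heat denaturation.
#'
#' Coordinates are 0-based: nick offsets are cut points strictly inside
#' `(0, length)` (between nucleotides), lesion positions are nucleotide
#' offsets in `[0, length)`.
#'
#' @name molecule-model
NULL

LESION_KINDS <- c("interstrand_crosslink", "intrastrand_crosslink", "monoadduct")
BEND_KINDS <- c("intrastrand_crosslink", "monoadduct")

#' Create a lesion table
#'
#' @param kind character vector over
#'   `interstrand_crosslink`, `intrastrand_crosslink`, `monoadduct`.
#' @param position integer nucleotide offsets (0-based).
#' @param strand `"top"`, `"bottom"` or `"both"`; interstrand crosslinks
#'   always join both strands, other kinds never do.
#' @return a `data.frame` with columns `kind`, `position`, `strand`.
#' @export
lesion_table <- function(kind = character(), position = integer(),
                         strand = character()) {
  kind <- as.character(kind); strand <- as.character(strand)
  position <- as.integer(position)
  assert_that(all(kind %in% LESION_KINDS), "unknown lesion kind")
  assert_that(length(kind) == length(position) && length(kind) == length(strand),
              "lesion fields must have equal length")
  inter <- kind == "interstrand_crosslink"
  assert_that(all(strand[inter] == "both"),
              "interstrand_crosslink lesions must have strand='both'")
  assert_that(all(strand[!inter] %in% c("top", "bottom")),
              "non-interstrand lesions must sit on one strand")
  df <- data.frame(kind = kind, position = position, strand = strand,
                   stringsAsFactors = FALSE)
  df[order(df$position), , drop = FALSE]
}

empty_lesions <- function() lesion_table()

#' Construct a duplex DNA molecule
#'
#' @param length duplex length in base pairs (>= 1).
#' @param sequence optional top-strand nucleotide string (A/C/G/T) of
#'   `length` characters; `NULL` enables length-only mode.
#' @param nicks_top,nicks_bottom sorted unique strand-break offsets,
#'   strictly inside `(0, length)`.
#' @param lesions a [lesion_table()].
#' @param origin_label free-text provenance (e.g. `"genomic"`,
#'   `"ladder-600"`).
#' @param locally_denatured if `TRUE` the duplex has lost base pairing
#'   (e.g. high adduct density) and its strands run the first dimension as
#'   single strands.
#' @return an object of class `nla_duplex`.
#' @export
duplex_molecule <- function(length, sequence = NULL,
                            nicks_top = integer(), nicks_bottom = integer(),
                            lesions = empty_lesions(),
                            origin_label = "genomic",
                            locally_denatured = FALSE) {
  length <- as.integer(length)
  assert_that(length >= 1L, "duplex length must be >= 1")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    assert_that(nchar(sequence) == length,
                "sequence length (%d) != declared length (%d)",
                nchar(sequence), length)
    assert_that(!grepl("[^ACGT]", sequence), "sequence not over {A,C,G,T}")
  }
  nicks_top <- check_nicks(nicks_top, length)
  nicks_bottom <- check_nicks(nicks_bottom, length)
  assert_that(all(lesions$position >= 0L & lesions$position < length),
              "lesion positions must lie in [0, length)")
  structure(list(length = length, sequence = sequence,
                 nicks_top = nicks_top, nicks_bottom = nicks_bottom,
                 lesions = lesions, origin_label = origin_label,
                 locally_denatured = isTRUE(locally_denatured)),
            class = "nla_duplex")
}

check_nicks <- function(nicks, length) {
  nicks <- sort(unique(as.integer(nicks)))
  assert_that(all(nicks > 0L & nicks < length),
              "nick positions must be strictly inside (0, length)")
  nicks
}

#' Construct a single-stranded segment
#'
#' Segments are the second-dimension species: after in-gel heat denaturation
#' every molecule without interstrand crosslinks becomes single strands.
#' Each segment remembers the duplex it belonged to during dimension-1
#' migration.
#'
#' @param length segment length in nucleotides.
#' @param parent_duplex_length length of the native-phase parent; must be
#'   >= `length`.
#' @param parent_bend_count number of bending lesions (intrastrand
#'   crosslinks + monoadducts) carried by the parent during dimension 1.
#' @param is_ss_in_d1 `TRUE` if the strand was already single-stranded in
#'   dimension 1 (heat-denatured sample or locally denatured duplex); such
#'   strands migrate dimension 1 by their own length with the
#'   single-strand retardation factor.
#' @param sequence optional nucleotide string.
#' @param network_id optional identifier of a crosslink network.
#' @param origin_label provenance text.
#' @return an object of class `nla_segment`.
#' @export
strand_segment <- function(length, parent_duplex_length = length,
                           parent_bend_count = 0L, is_ss_in_d1 = FALSE,
                           sequence = NULL, network_id = NULL,
                           origin_label = "genomic") {
  length <- as.integer(length)
  parent_duplex_length <- as.integer(parent_duplex_length)
  assert_that(length >= 1L, "segment length must be >= 1")
  assert_that(length <= parent_duplex_length,
              "segment longer than its parent duplex")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    assert_that(nchar(sequence) == length, "segment sequence length mismatch")
  }
  structure(list(length = length,
                 parent_duplex_length = parent_duplex_length,
                 parent_bend_count = as.integer(parent_bend_count),
                 is_ss_in_d1 = isTRUE(is_ss_in_d1),
                 sequence = sequence, network_id = network_id,
                 origin_label = origin_label),
            class = "nla_segment")
}

#' Construct a crosslink network
#'
#' Strands joined by at least one interstrand crosslink remain covalently
#' attached when denatured; the joined species migrates dimension 2 by the
#' summed length of its members.
#'
#' @param members list of [strand_segment()] objects (>= 2).
#' @param parent_duplex_length,parent_bend_count native-phase properties of
#'   the parent duplex (used for the dimension-1 coordinate).
#' @param origin_label provenance text.
#' @return an object of class `nla_network`.
#' @export
crosslink_network <- function(members, parent_duplex_length,
                              parent_bend_count = 0L,
                              origin_label = "genomic") {
  assert_that(length(members) >= 2L, "a crosslink network needs >= 2 members")
  assert_that(all(vapply(members, inherits, TRUE, "nla_segment")),
              "network members must be strand segments")
  eff <- sum(vapply(members, function(m) m$length, 0L))
  structure(list(members = members, effective_length = as.integer(eff),
                 parent_duplex_length = as.integer(parent_duplex_length),
                 parent_bend_count = as.integer(parent_bend_count),
                 origin_label = origin_label),
            class = "nla_network")
}

#' Total nucleotide count of a molecule
#'
#' Duplexes count both strands (`2 * length`); segments and networks count
#' single-stranded nucleotides. Every operation in the molecule model
#' conserves the population total exactly.
#'
#' @param mol a molecule object.
#' @return integer nucleotide count.
#' @export
nt_count <- function(mol) UseMethod("nt_count")
#' @export
nt_count.nla_duplex <- function(mol) 2L * mol$length
#' @export
nt_count.nla_segment <- function(mol) mol$length
#' @export
nt_count.nla_network <- function(mol) mol$effective_length

#' Construct a molecule population
#'
#' @param molecules list of molecule objects.
#' @param mass_weights non-negative masses (arbitrary units); default is the
#'   nucleotide count of each molecule, i.e. mass proportional to the amount
#'   of DNA.
#' @param seed_provenance free text recording how the population was made.
#' @return an object of class `nla_population` with an `entries` list of
#'   `list(mol=, mass=)` pairs.
#' @export
molecule_population <- function(molecules, mass_weights = NULL,
                                seed_provenance = "") {
  if (is.null(mass_weights))
    mass_weights <- vapply(molecules, nt_count, 0L)
  assert_that(length(mass_weights) == length(molecules),
              "one mass per molecule required")
  assert_that(all(mass_weights >= 0), "mass weights must be non-negative")
  assert_that(length(molecules) == 0L || sum(mass_weights) > 0,
              "total population mass must be > 0")
  entries <- Map(function(m, w) list(mol = m, mass = as.double(w)),
                 molecules, mass_weights)
  structure(list(entries = unname(entries),
                 seed_provenance = seed_provenance),
            class = "nla_population")
}

pop_from_entries <- function(entries, provenance = "") {
  structure(list(entries = unname(entries), seed_provenance = provenance),
            class = "nla_population")
}

#' Population totals
#'
#' @param pop an `nla_population`.
#' @return `total_nt()`: summed nucleotide count; `total_mass()`: summed
#'   mass weight.
#' @export
total_nt <- function(pop) {
  sum(vapply(pop$entries, function(e) as.double(nt_count(e$mol)), 0))
}

#' @rdname total_nt
#' @export
total_mass <- function(pop) sum(vapply(pop$entries, function(e) e$mass, 0))

#' @export
print.nla_population <- function(x, ...) {
  cls <- vapply(x$entries, function(e) class(e$mol)[1], "")
  cat(sprintf("<nla_population> %d entries (%s), %.4g nt, mass %.4g\n",
              length(x$entries),
              paste(sprintf("%s:%d", names(table(cls)), table(cls)),
                    collapse = ", "),
              total_nt(x), total_mass(x)))
  invisible(x)
}

#' Template amplifiability oracle
#'
#' A molecule can serve as a PCR template unless it carries an interstrand
#' crosslink: neither strand of a crosslinked duplex can be separated for
#' priming, and a crosslink network is by construction held together by at
#' least one interstrand crosslink. Nicks and monoadducts alone do not
#' block amplification (at least one intact template strand is assumed
#' recoverable).
#'
#' @param entry a molecule object, or a population entry `list(mol=, mass=)`.
#' @return `TRUE` if amplifiable.
#' @export
is_amplifiable <- function(entry) {
  mol <- if (is.list(entry) && !is.null(entry$mol)) entry$mol else entry
  if (inherits(mol, "nla_network")) return(FALSE)
  if (inherits(mol, "nla_segment")) return(TRUE)
  if (inherits(mol, "nla_duplex"))
    return(!any(mol$lesions$kind == "interstrand_crosslink"))
  stop_nla("not a molecule object")
}

#' Mass fraction of a population blocked from amplification
#'
#' @param pop an `nla_population`.
#' @return mass-weighted fraction for which [is_amplifiable()] is `FALSE`.
#' @export
nonamplifiable_mass_fraction <- function(pop) {
  m <- vapply(pop$entries, function(e) e$mass, 0)
  bad <- !vapply(pop$entries, is_amplifiable, TRUE)
  if (sum(m) == 0) return(0)
  sum(m[bad]) / sum(m)
}

# ---- external interfaces -------------------------------------------------

#' Read a FASTA file into a duplex population
#'
#' Each record becomes one sequence-carrying duplex; mass defaults to the
#' nucleotide count. Uses Biostrings when available, otherwise a minimal
#' built-in reader.
#'
#' @param path FASTA file.
#' @param origin_label provenance label applied to all records.
#' @return an `nla_population`.
#' @export
population_from_fasta <- function(path, origin_label = "fasta") {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    seqs <- as.character(ss)
  } else {
    lines <- readLines(path)
    idx <- cumsum(grepl("^>", lines))
    body <- split(lines[!grepl("^>", lines)], idx[!grepl("^>", lines)])
    seqs <- vapply(body, paste0, "", collapse = "")
  }
  mols <- lapply(unname(seqs), function(s)
    duplex_molecule(nchar(s), sequence = s, origin_label = origin_label))
  molecule_population(mols, seed_provenance = sprintf("fasta:%s", basename(path)))
}

mol_to_record <- function(e) {
  m <- e$mol
  if (inherits(m, "nla_duplex")) {
    list(type = "duplex", length = m$length, sequence = m$sequence,
         nicks_top = I(m$nicks_top), nicks_bottom = I(m$nicks_bottom),
         lesions = m$lesions, origin_label = m$origin_label,
         locally_denatured = m$locally_denatured, mass_weight = e$mass)
  } else if (inherits(m, "nla_segment")) {
    list(type = "segment", length = m$length,
         parent_duplex_length = m$parent_duplex_length,
         parent_bend_count = m$parent_bend_count,
         is_ss_in_d1 = m$is_ss_in_d1, origin_label = m$origin_label,
         mass_weight = e$mass)
  } else {
    list(type = "network",
         member_lengths = I(vapply(m$members, function(s) s$length, 0L)),
         parent_duplex_length = m$parent_duplex_length,
         parent_bend_count = m$parent_bend_count,
         origin_label = m$origin_label, mass_weight = e$mass)
  }
}

#' Serialize a population as JSON-lines
#'
#' One JSON object per molecule: type, length(s), nicks, lesions, mass.
#'
#' @param pop an `nla_population`.
#' @param path output file.
#' @export
write_population_jsonl <- function(pop, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (e in pop$entries)
    writeLines(jsonlite::toJSON(mol_to_record(e), auto_unbox = TRUE,
                                null = "null", digits = NA), con)
  invisible(path)
}

#' Read a JSON-lines population
#'
#' @param path file written by [write_population_jsonl()].
#' @return an `nla_population`.
#' @export
read_population_jsonl <- function(path) {
  lines <- readLines(path)
  entries <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l)
    mol <- switch(r$type,
      duplex = duplex_molecule(r$length, sequence = r$sequence,
        nicks_top = r$nicks_top %||% integer(),
        nicks_bottom = r$nicks_bottom %||% integer(),
        lesions = if (length(r$lesions)) lesion_table(r$lesions$kind,
          r$lesions$position, r$lesions$strand) else empty_lesions(),
        origin_label = r$origin_label,
        locally_denatured = isTRUE(r$locally_denatured)),
      segment = strand_segment(r$length, r$parent_duplex_length,
        r$parent_bend_count, r$is_ss_in_d1, origin_label = r$origin_label),
      network = crosslink_network(
        lapply(r$member_lengths, strand_segment,
               parent_duplex_length = r$parent_duplex_length,
               origin_label = r$origin_label),
        r$parent_duplex_length, r$parent_bend_count, r$origin_label),
      stop_nla("unknown record type '%s'", r$type))
    list(mol = mol, mass = r$mass_weight)
  })
  pop_from_entries(entries, provenance = sprintf("jsonl:%s", basename(path)))
}
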