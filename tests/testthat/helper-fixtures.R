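# Small fixtures built in code; nothing is read from disk except the
# packaged reference tables.

# single-chromosome map with evenly spaced markers
toy_map <- function(n = 3, spacing = 10, chrom = "1") {
  genetic_map(sprintf("M%02d", seq_len(n)), rep(chrom, n), spacing * (seq_len(n) - 1))
}

# compact breeding program for generic property tests
small_program <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_founders = 20, n_markers = 120, n_chrom = 6, founder_year = 1900,
         cp_year = 1950, end_year = 2000, crosses_per_year = 2,
         progeny_per_cross = 3, seed = seed),
    list(...))
  cfg <- do.call(sim_config, args)
  map <- sim_genetic_map(cfg$n_markers, cfg$n_chrom, seed = cfg$seed)
  fo <- simulate_founders(cfg, map)
  arch <- sim_trait_architecture(map, effect_sd = 2, founder_freq = fo$founder_freq,
                                 rare_favorable = 1, freq_alpha = -1, n_qtl = 20,
                                 seed = cfg$seed)
  prog <- simulate_breeding_program(fo, cfg, arch)
  c(prog, list(map = map, founders = fo))
}

# pedigree used in several relationship-matrix tests:
# A, B founders; C, D full sibs (A x B); E = C x D; S = selfed child of A
nuclear_pedigree <- function() {
  pedigree(data.frame(
    id = c("A", "B", "C", "D", "E", "S"),
    sire = c(NA, NA, "A", "A", "C", "A"),
    dam = c(NA, NA, "B", "B", "D", "A"),
    birth_year = c(1, 1, 2, 2, 3, 2)))
}

extdata <- function(f) system.file("extdata", f, package = "breedgain")
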