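# Synthetic breeding-program generator: genetic map, phased founder
# haplotypes, gene-dropping through a pedigree with a mid-history switch from
# random mating to truncation selection, and replicated clonal-trial
# phenotypes. All downstream modules are exercised against this truth.

#' Construct a genetic map
#'
#' @param marker character vector of unique marker ids.
#' @param chrom chromosome label per marker.
#' @param pos map position in centimorgans, strictly increasing within each
#'   chromosome.
#' @return A `genetic_map` data frame with columns `marker`, `chrom`, `pos`.
#' @export
genetic_map <- function(marker, chrom, pos) {
  assert(length(marker) > 0, "genetic map is empty", class = "breedgain_config_error")
  assert(!anyDuplicated(marker), "duplicated marker ids in map")
  assert(all(pos >= 0), "map positions must be non-negative")
  df <- data.frame(marker = as.character(marker), chrom = as.character(chrom),
                   pos = as.numeric(pos), stringsAsFactors = FALSE)
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    assert(all(diff(p) > 0), "map positions not strictly increasing on chromosome ", ch)
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Simulate a genetic map with evenly scattered markers
#'
#' Marker positions are drawn uniformly along each chromosome and sorted;
#' ties are separated by a minimal offset so within-chromosome positions are
#' strictly increasing.
#'
#' @param n_markers total number of markers.
#' @param n_chrom number of chromosomes (default 28, the chromosome number of
#'   octoploid strawberry).
#' @param chrom_length_cM genetic length per chromosome.
#' @param seed integer seed.
#' @export
sim_genetic_map <- function(n_markers, n_chrom = 28, chrom_length_cM = 100, seed = 1) {
  assert(n_markers >= n_chrom, "need at least one marker per chromosome")
  with_substream(seed, "genetic_map", {
    chrom <- sort(rep_len(seq_len(n_chrom), n_markers))
    pos <- unlist(lapply(split(chrom, chrom), function(ix) {
      p <- sort(runif(length(ix), 0, chrom_length_cM))
      p + seq_along(p) * 1e-6  # enforce strict increase
    }), use.names = FALSE)
    genetic_map(sprintf("M%05d", seq_len(n_markers)),
                sprintf("chr%02d", chrom), pos)
  })
}

#' Simulation configuration for a synthetic breeding program
#'
#' Defaults emulate a long-lived clonal program: founders in 1775, random
#' mating until truncation selection begins at `cp_year` (1953), and a final
#' cohort in 2015.
#'
#' @param n_founders number of founder individuals (>= 2).
#' @param n_markers,n_chrom marker panel dimensions for [sim_genetic_map()].
#' @param founder_year,cp_year,end_year calendar years with
#'   `founder_year < cp_year < end_year`.
#' @param crosses_per_year,progeny_per_cross family structure per year.
#' @param selection_fraction proportion of the parent pool retained by
#'   truncation selection on true breeding value once selection is fully
#'   established.
#' @param selection_ramp years over which selection intensity phases in
#'   linearly from none (at `cp_year`) to full; models the gradual build-up
#'   of a breeding program rather than an instantaneous switch, which would
#'   put a discontinuous jump in the breeding-value trajectory.
#' @param genotyped_fraction proportion of individuals flagged genotyped when
#'   exporting marker data.
#' @param missing_rate proportion of dosages masked as missing on export.
#' @param parent_window parents are drawn from individuals born within this
#'   many years before the cross.
#' @param migration_rate probability per year that one cross uses a fresh
#'   exotic accession drawn from the base-population allele frequencies
#'   (germplasm exchange/introgression). Migration stops `migration_window`
#'   years after `cp_year`, emulating the closure of a breeding population
#'   once an elite pool is established.
#' @param migration_window years after `cp_year` during which migration
#'   continues.
#' @param seed integer seed; all stochastic operations consume named
#'   substreams derived from it.
#' @export
sim_config <- function(n_founders = 40, n_markers = 500, n_chrom = 28,
                       founder_year = 1775, cp_year = 1953, end_year = 2015,
                       crosses_per_year = 3, progeny_per_cross = 4,
                       selection_fraction = 0.5, selection_ramp = 10,
                       genotyped_fraction = 0.25, missing_rate = 0.02,
                       parent_window = 15, migration_rate = 0.5,
                       migration_window = 35, seed = 1) {
  assert(n_founders >= 2, "n_founders must be >= 2", class = "breedgain_config_error")
  assert(founder_year < cp_year && cp_year < end_year,
         "need founder_year < cp_year < end_year", class = "breedgain_config_error")
  for (p in c(selection_fraction, genotyped_fraction, missing_rate))
    assert(p >= 0 && p <= 1, "proportions must lie in [0,1]", class = "breedgain_config_error")
  assert(selection_fraction > 0, "selection_fraction must be positive", class = "breedgain_config_error")
  assert(selection_ramp >= 1, "selection_ramp must be >= 1 year", class = "breedgain_config_error")
  structure(list(n_founders = n_founders, n_markers = n_markers, n_chrom = n_chrom,
                 founder_year = founder_year, cp_year = cp_year, end_year = end_year,
                 crosses_per_year = crosses_per_year, progeny_per_cross = progeny_per_cross,
                 selection_fraction = selection_fraction, selection_ramp = selection_ramp,
                 genotyped_fraction = genotyped_fraction, missing_rate = missing_rate,
                 parent_window = parent_window, migration_rate = migration_rate,
                 migration_window = migration_window, seed = seed),
            class = "sim_config")
}

#' Trait architecture for the simulator
#'
#' Per-marker additive effects are drawn from a multivariate normal across
#' traits so that shared markers induce a controllable genetic correlation.
#' One designated marker acts as a dominant flowering locus (PF): carriers
#' (dosage >= 1) receive an extra genetic-value bonus on `pf_trait`.
#'
#' @param map a [genetic_map()].
#' @param n_traits number of traits.
#' @param trait_correlation target genetic correlation matrix (symmetric,
#'   unit diagonal, positive semidefinite).
#' @param effect_sd per-marker effect standard deviation (scaled by
#'   `1/sqrt(n_markers)` so additive variance is O(`effect_sd^2`)).
#' @param pf_locus marker index of the dominant flowering locus.
#' @param pf_effect genetic-value bonus for carriers.
#' @param pf_trait which trait the dominant locus affects.
#' @param intercepts per-trait baseline.
#' @param founder_freq optional per-marker founder allele frequencies used to
#'   orient effect signs (see `rare_favorable`).
#' @param rare_favorable probability that the minor founder allele is the
#'   trait-increasing one for the focal (first) trait. At 0.5 (default)
#'   effect signs are independent of frequency; above 0.5 favorable alleles
#'   start rare, so directional selection first drives them towards
#'   intermediate frequency and additive variance grows before it erodes —
#'   the standing-variation structure behind sustained long-term response
#'   and transgressive segregation.
#' @param n_qtl number of markers carrying non-zero effects (default: all).
#'   Trait loci are a random subset of the panel; the remaining markers act
#'   as neutral markers in linkage with them, as on a real SNP array.
#' @param freq_alpha exponent of the effect-size/frequency relationship:
#'   per-marker effects are scaled by `(2 p (1-p))^(freq_alpha/2)` using the
#'   founder frequencies. 0 (default) means no relationship; negative values
#'   give rare alleles larger effects, the pattern typical of fitness-related
#'   quantitative traits. Requires `founder_freq`.
#' @param seed integer seed.
#' @export
sim_trait_architecture <- function(map, n_traits = 1, trait_correlation = diag(n_traits),
                                   effect_sd = 1, pf_locus = 1L, pf_effect = 0,
                                   pf_trait = 1L, intercepts = rep(0, n_traits),
                                   founder_freq = NULL, rare_favorable = 0.5,
                                   n_qtl = NULL, freq_alpha = 0, seed = 1) {
  m <- nrow(map)
  C <- as.matrix(trait_correlation)
  assert(nrow(C) == n_traits && ncol(C) == n_traits, "correlation matrix dimension mismatch")
  assert(max(abs(C - t(C))) < 1e-8 && all(abs(diag(C) - 1) < 1e-8),
         "trait correlation must be symmetric with unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  assert(min(ev) > -1e-8, "trait correlation must be positive semidefinite")
  assert(pf_locus >= 1 && pf_locus <= m, "pf_locus outside marker panel")
  with_substream(seed, "trait_architecture", {
    L <- chol(C + diag(1e-10, n_traits))
    B <- matrix(rnorm(m * n_traits, sd = effect_sd / sqrt(m)), m, n_traits) %*% L
    if (!is.null(n_qtl) && n_qtl < m) {
      B[sample.int(m, m - n_qtl), ] <- 0
      B <- B * sqrt(m / n_qtl)  # keep total additive variance comparable
    }
    if (!is.null(founder_freq)) {
      p <- rep_len(founder_freq, m)
      if (freq_alpha != 0) {
        w <- (2 * p * (1 - p))^(freq_alpha / 2)
        B <- B * (w / sqrt(mean(w^2)))  # rescale to keep total variance comparable
      }
      if (rare_favorable != 0.5) {
        want_pos <- (p < 0.5) == (runif(m) < rare_favorable)
        flip <- want_pos != (B[, 1] > 0)
        B[flip, ] <- -B[flip, , drop = FALSE]
      }
    }
    rownames(B) <- map$marker
    colnames(B) <- sprintf("trait%d", seq_len(n_traits))
    structure(list(marker_effects = B, trait_correlation = C,
                   pf_locus = as.integer(pf_locus), pf_effect = pf_effect,
                   pf_trait = as.integer(pf_trait), intercepts = intercepts,
                   map = map),
              class = "trait_architecture")
  })
}

# ---- haplotypes and meiosis -------------------------------------------------

new_haplotype_set <- function(h1, h2, map) {
  stopifnot(identical(dim(h1), dim(h2)), ncol(h1) == nrow(map))
  structure(list(h1 = h1, h2 = h2, map = map), class = "haplotype_set")
}

#' Dosage matrix from a phased haplotype set
#' @param hap a `haplotype_set`.
#' @return integer matrix of 0/1/2 allele dosages (individuals x markers).
#' @export
dosages <- function(hap) {
  stopifnot(inherits(hap, "haplotype_set"))
  d <- hap$h1 + hap$h2
  colnames(d) <- hap$map$marker
  d
}

# Recombination fraction from map distance in cM (Haldane, no interference).
haldane_c <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# Per-chromosome marker indices and adjacent recombination fractions,
# precomputed once per map.
map_meiosis_layout <- function(map) {
  idx <- split(seq_len(nrow(map)), map$chrom)
  list(idx = idx,
       rec = lapply(idx, function(i) haldane_c(diff(map$pos[i]))))
}

# One recombinant gamete from a phased parent. h1/h2 are 0/1 allele vectors.
# Consumes the current RNG stream.
meiosis_gamete <- function(h1, h2, layout) {
  out <- numeric(length(h1))
  for (k in seq_along(layout$idx)) {
    ix <- layout$idx[[k]]
    start <- sample.int(2L, 1L) - 1L
    if (length(ix) > 1L) {
      sw <- runif(length(ix) - 1L) < layout$rec[[k]]
      phase <- (start + cumsum(c(0L, as.integer(sw)))) %% 2L
    } else phase <- start
    out[ix] <- ifelse(phase == 0L, h1[ix], h2[ix])
  }
  out
}

# ---- founders ---------------------------------------------------------------

#' Simulate founder haplotypes and a founder-only pedigree
#'
#' Founder allele frequencies are drawn uniformly on \[0.05, 0.95\] per
#' marker (site-wise independent, no founder linkage disequilibrium) and
#' haplotype alleles are Bernoulli draws at those frequencies.
#'
#' @param config a [sim_config()].
#' @param map a [genetic_map()]; must be non-empty.
#' @param freq optional vector of founder allele frequencies overriding the
#'   uniform draw (recycled across markers).
#' @return list with `haplotypes` (a `haplotype_set`) and `pedigree`.
#' @export
simulate_founders <- function(config, map, freq = NULL) {
  assert(inherits(map, "genetic_map") && nrow(map) > 0, "map is empty",
         class = "breedgain_config_error")
  n <- config$n_founders
  m <- nrow(map)
  with_substream(config$seed, "founders", {
    p <- if (is.null(freq)) runif(m, 0.05, 0.95) else rep_len(freq, m)
    h1 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
    h2 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
    ids <- sprintf("I%05d", seq_len(n))
    rownames(h1) <- rownames(h2) <- ids
    ped <- pedigree(data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                               birth_year = config$founder_year))
    list(haplotypes = new_haplotype_set(h1, h2, map), pedigree = ped,
         founder_freq = p)
  })
}

# ---- breeding program -------------------------------------------------------

#' Simulate a multi-generation breeding program
#'
#' Gene-drops phased haplotypes through a growing pedigree. Each year,
#' `crosses_per_year` biparental crosses each produce `progeny_per_cross`
#' offspring. Before `cp_year` parents are drawn at random from the recent
#' cohort pool; from `cp_year` onward the pool is truncated to the top
#' `selection_fraction` by true breeding value of the focal trait before
#' drawing, producing the directional trend the change-point machinery is
#' designed to recover. Meiosis uses the Haldane map function per chromosome.
#'
#' @param founders output of [simulate_founders()].
#' @param config a [sim_config()].
#' @param arch a [sim_trait_architecture()].
#' @param focal_trait trait column used for truncation selection.
#' @return list with `pedigree`, `haplotypes`, `tbv` (true additive breeding
#'   values, individuals x traits), and `genetic_values` (tbv plus the
#'   dominant-locus deviation).
#' @export
simulate_breeding_program <- function(founders, config, arch, focal_trait = 1L) {
  map <- founders$haplotypes$map
  assert(identical(arch$map$marker, map$marker), "architecture and map disagree")
  layout <- map_meiosis_layout(map)
  B <- arch$marker_effects
  nf <- config$n_founders
  years <- seq(config$founder_year + 1L, config$end_year)
  mig_end <- config$cp_year + config$migration_window
  n_mig_max <- if (config$migration_rate > 0) sum(years <= mig_end) else 0L
  n_total <- nf + length(years) * config$crosses_per_year * config$progeny_per_cross +
    n_mig_max
  m <- nrow(map)

  h1 <- matrix(0L, n_total, m); h2 <- matrix(0L, n_total, m)
  h1[1:nf, ] <- founders$haplotypes$h1
  h2[1:nf, ] <- founders$haplotypes$h2
  ids <- sprintf("I%05d", seq_len(n_total))
  sire <- dam <- rep(NA_character_, n_total)
  byear <- rep(NA_integer_, n_total)
  byear[1:nf] <- config$founder_year
  tbv <- matrix(0, n_total, ncol(B))
  tbv[1:nf, ] <- (h1[1:nf, , drop = FALSE] + h2[1:nf, , drop = FALSE]) %*% B

  with_substream(config$seed, "breeding_program", {
    nxt <- nf + 1L
    for (y in years) {
      pool <- which(byear >= y - config$parent_window & byear <= y - 1L)
      if (length(pool) < 2L) pool <- which(byear <= y - 1L)
      if (y >= config$cp_year) {
        # intensity phases in over selection_ramp years
        w <- min(1, (y - config$cp_year + 1L) / config$selection_ramp)
        frac <- 1 - (1 - config$selection_fraction) * w
        keep <- ceiling(frac * length(pool))
        if (keep < 2L)
          stop_bg("truncation selection leaves fewer than 2 parents in year ", y,
                  class = "breedgain_degenerate_selection")
        pool <- pool[order(tbv[pool, focal_trait], decreasing = TRUE)][seq_len(keep)]
      }
      migrant <- NA_integer_
      if (config$migration_rate > 0 && y <= mig_end &&
          runif(1) < config$migration_rate) {
        # exotic accession sampled from the base-population frequencies
        migrant <- nxt
        h1[migrant, ] <- rbinom(m, 1L, founders$founder_freq)
        h2[migrant, ] <- rbinom(m, 1L, founders$founder_freq)
        byear[migrant] <- y - 1L
        tbv[migrant, ] <- (h1[migrant, ] + h2[migrant, ]) %*% B
        nxt <- nxt + 1L
      }
      for (cx in seq_len(config$crosses_per_year)) {
        par <- if (cx == 1L && !is.na(migrant)) {
          c(migrant, if (length(pool) == 1L) pool else sample(pool, 1L))
        } else if (length(pool) == 2L) pool else sample(pool, 2L)
        for (k in seq_len(config$progeny_per_cross)) {
          h1[nxt, ] <- meiosis_gamete(h1[par[1L], ], h2[par[1L], ], layout)
          h2[nxt, ] <- meiosis_gamete(h1[par[2L], ], h2[par[2L], ], layout)
          sire[nxt] <- ids[par[1L]]; dam[nxt] <- ids[par[2L]]
          byear[nxt] <- y
          tbv[nxt, ] <- (h1[nxt, ] + h2[nxt, ]) %*% B
          nxt <- nxt + 1L
        }
      }
    }
  })

  used <- seq_len(max(which(!is.na(byear))))
  h1 <- h1[used, , drop = FALSE]; h2 <- h2[used, , drop = FALSE]
  tbv <- tbv[used, , drop = FALSE]
  ids <- ids[used]; sire <- sire[used]; dam <- dam[used]; byear <- byear[used]
  rownames(h1) <- rownames(h2) <- ids
  rownames(tbv) <- ids
  colnames(tbv) <- colnames(B)
  gv <- sweep(tbv, 2, arch$intercepts, "+")
  carrier <- (h1[, arch$pf_locus] + h2[, arch$pf_locus]) >= 1
  gv[, arch$pf_trait] <- gv[, arch$pf_trait] + arch$pf_effect * carrier
  ped <- pedigree(data.frame(id = ids, sire = sire, dam = dam, birth_year = byear))
  list(pedigree = ped, haplotypes = new_haplotype_set(h1, h2, map),
       tbv = tbv, genetic_values = gv, config = config, arch = arch)
}

# ---- trial phenotypes -------------------------------------------------------

#' Trial design for the phenotype simulator
#'
#' Variance components are in squared trait units. `sigma2_gy`, `sigma2_gl`
#' and `sigma2_gyl` are the hybrid-by-year, hybrid-by-location and three-way
#' interaction variances of the clone-mean heritability denominator;
#' `sigma2_e` is the plot residual.
#'
#' @param n_blocks,n_years,n_locations design dimensions (all >= 1).
#' @param sigma2_block,sigma2_year,sigma2_loc main-effect variances.
#' @param sigma2_gy,sigma2_gl,sigma2_gyl,sigma2_e interaction and residual
#'   variances (>= 0).
#' @export
trial_design <- function(n_blocks = 4, n_years = 2, n_locations = 1,
                         sigma2_block = 0.5, sigma2_year = 1, sigma2_loc = 1,
                         sigma2_gy = 0, sigma2_gl = 0, sigma2_gyl = 0,
                         sigma2_e = 1) {
  assert(n_blocks >= 1 && n_years >= 1 && n_locations >= 1,
         "design counts must be >= 1", class = "breedgain_config_error")
  v <- c(sigma2_block, sigma2_year, sigma2_loc, sigma2_gy, sigma2_gl, sigma2_gyl, sigma2_e)
  assert(all(v >= 0), "variance components must be non-negative",
         class = "breedgain_config_error")
  structure(list(n_blocks = n_blocks, n_years = n_years, n_locations = n_locations,
                 sigma2_block = sigma2_block, sigma2_year = sigma2_year,
                 sigma2_loc = sigma2_loc, sigma2_gy = sigma2_gy,
                 sigma2_gl = sigma2_gl, sigma2_gyl = sigma2_gyl,
                 sigma2_e = sigma2_e), class = "trial_design")
}

#' Simulate replicated clonal-trial phenotypes
#'
#' Balanced randomized-complete-block observations:
#' value = intercept + genetic value + block + year + location + G x Y +
#' G x L + G x Y x L + residual, with every effect drawn from a centered
#' normal at the design's variance. Block, year and location effects are
#' indexed by label so the generating process matches the mixed model fitted
#' downstream.
#'
#' @param genetic_values named numeric vector (one entry per hybrid).
#' @param design a [trial_design()].
#' @param intercept grand mean in trait units.
#' @param trait trait label written to the output.
#' @param seed integer seed.
#' @return data frame with columns hybrid, block, year, location, trait,
#'   value.
#' @export
simulate_trials <- function(genetic_values, design, intercept = 0,
                            trait = "trait1", seed = 1) {
  assert(inherits(design, "trial_design"), "design must be a trial_design")
  ids <- names(genetic_values)
  assert(!is.null(ids) && all(nzchar(ids)), "genetic_values must be named by hybrid")
  with_substream(seed, paste0("trials_", trait), {
    grid <- expand.grid(hybrid = ids,
                        block = sprintf("B%d", seq_len(design$n_blocks)),
                        year = sprintf("Y%d", seq_len(design$n_years)),
                        location = sprintf("L%d", seq_len(design$n_locations)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    nh <- length(ids)
    eff <- function(n, s2) if (s2 > 0) rnorm(n, sd = sqrt(s2)) else numeric(n)
    # single-level factors are confounded with the intercept: no effect drawn
    meff <- function(n, s2) if (n > 1) eff(n, s2) else 0
    b <- setNames(rep_len(meff(design$n_blocks, design$sigma2_block), design$n_blocks),
                  unique(grid$block))
    yr <- setNames(rep_len(meff(design$n_years, design$sigma2_year), design$n_years),
                   unique(grid$year))
    lc <- setNames(rep_len(meff(design$n_locations, design$sigma2_loc), design$n_locations),
                   unique(grid$location))
    gy <- matrix(eff(nh * design$n_years, design$sigma2_gy), nh,
                 dimnames = list(ids, unique(grid$year)))
    gl <- matrix(eff(nh * design$n_locations, design$sigma2_gl), nh,
                 dimnames = list(ids, unique(grid$location)))
    gyl <- array(eff(nh * design$n_years * design$n_locations, design$sigma2_gyl),
                 dim = c(nh, design$n_years, design$n_locations),
                 dimnames = list(ids, unique(grid$year), unique(grid$location)))
    val <- intercept + genetic_values[grid$hybrid] + b[grid$block] + yr[grid$year] +
      lc[grid$location] + gy[cbind(grid$hybrid, grid$year)] +
      gl[cbind(grid$hybrid, grid$location)] +
      gyl[cbind(grid$hybrid, grid$year, grid$location)] +
      eff(nrow(grid), design$sigma2_e)
    data.frame(grid, trait = trait, value = as.numeric(val),
               stringsAsFactors = FALSE)
  })
}

# ---- dominant flowering locus ----------------------------------------------

#' Classify individuals at a dominant locus
#'
#' Individuals with dosage >= 1 at the designated marker carry the dominant
#' allele (e.g. day-neutral flowering at the PERPETUAL FLOWERING locus);
#' dosage 0 is homozygous recessive; missing dosage is unclassified.
#'
#' @param dosage matrix (individuals x markers) or vector of dosages at the
#'   locus.
#' @param pf_locus marker index or name when `dosage` is a matrix.
#' @return factor with levels carrier / homozygous-recessive (NA when the
#'   dosage is missing).
#' @export
classify_pf <- function(dosage, pf_locus = NULL) {
  d <- if (is.matrix(dosage)) {
    assert(!is.null(pf_locus), "pf_locus required for a dosage matrix")
    dosage[, pf_locus]
  } else dosage
  factor(ifelse(is.na(d), NA, ifelse(d >= 1, "carrier", "homozygous-recessive")),
         levels = c("carrier", "homozygous-recessive"))
}

#' Expected segregation at a dominant locus for a biparental cross
#'
#' A parent with dosage d transmits the dominant allele with probability
#' d/2; the carrier proportion among progeny is 1 - (1 - d1/2)(1 - d2/2).
#'
#' @param dosage1,dosage2 parental dosages at the locus (0, 1 or 2).
#' @return list with `prop_carrier` and a conventional `ratio` string
#'   (carriers : non-carriers).
#' @export
pf_segregation <- function(dosage1, dosage2) {
  assert(all(c(dosage1, dosage2) %in% 0:2), "parental dosages must be 0, 1 or 2")
  p <- 1 - (1 - dosage1 / 2) * (1 - dosage2 / 2)
  ratio <- if (p == 1) "all carriers" else if (p == 0) "no carriers" else {
    q <- p / (1 - p)
    if (abs(q - round(q)) < 1e-9) sprintf("%d:1", as.integer(round(q)))
    else if (abs(1 / q - round(1 / q)) < 1e-9) sprintf("1:%d", as.integer(round(1 / q)))
    else sprintf("%.3g:1", q)
  }
  list(prop_carrier = p, ratio = ratio)
}
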