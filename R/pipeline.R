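# End-to-end demo pipeline on the synthetic program:
# simulate -> QC/relationship matrices -> trials -> EMMs -> single-step BLUP
# -> change-point analyses -> cross prediction, with every artifact written
# to disk and hashed into a manifest for reproducibility checks.

#' Run the full analysis pipeline on a synthetic breeding program
#'
#' Generates a breeding program, phenotypes a recent training population in
#' replicated clonal trials, builds A/G/H, estimates breeding values for
#' every pedigree individual by single-step BLUP, locates the selection
#' onset by change-point regression of GEBVs on birth year (plus the
#' transformed-residual variance trend), predicts cross means/variances for
#' pre- and post-era parents, and writes all artifacts with an md5 manifest.
#' Identical configuration and seed give byte-identical artifacts.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()]; its `seed` drives every substream.
#' @param design a [trial_design()] for the training-population trials.
#' @param arch optional [sim_trait_architecture()]; by default a single
#'   trait with heritable additive architecture and a dominant flowering
#'   locus is built from the simulated map.
#' @param training_window phenotype individuals born within this many years
#'   of the end year (default 20).
#' @param maf_min,miss_max QC thresholds for [qc_genotypes()].
#' @param blend_weight,tune H-matrix constants for [hmatrix()].
#' @param guard change-point guard margin.
#' @param era_threshold era boundary year for [compare_eras()].
#' @param n_crosses_per_era,n_progeny cross-prediction effort.
#' @return invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         design = trial_design(sigma2_gy = 0.1, sigma2_e = 1),
                         arch = NULL, training_window = 20,
                         maf_min = 0.05, miss_max = 0.10,
                         blend_weight = 0.05, tune = TRUE, guard = 5,
                         era_threshold = 1953, n_crosses_per_era = 25,
                         n_progeny = 200) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_bg("[", name, "] ", conditionMessage(e), class = "breedgain_stage_error"))
  }

  # -- simulate ---------------------------------------------------------------
  sim <- stage("simulate", {
    map <- sim_genetic_map(config$n_markers, config$n_chrom, seed = seed)
    fo <- simulate_founders(config, map)
    if (is.null(arch))
      arch <- sim_trait_architecture(map, n_traits = 1, effect_sd = 2,
                                     pf_locus = max(1L, config$n_markers %/% 2L),
                                     pf_effect = 1,
                                     founder_freq = fo$founder_freq,
                                     rare_favorable = 1, freq_alpha = -1,
                                     n_qtl = max(20L, config$n_markers %/% 12L),
                                     seed = seed)
    prog <- simulate_breeding_program(fo, config, arch)
    list(map = map, arch = arch, program = prog)
  })
  ped <- sim$program$pedigree
  ids <- ped$id
  byear <- setNames(ped$birth_year, ped$id)

  # -- genotyped subset with missingness --------------------------------------
  # genotyped_fraction = 0 means no marker data at all (pedigree-only run)
  train_ids <- ids[byear[ids] >= config$end_year - training_window]
  geno_ids <- if (config$genotyped_fraction == 0) character(0) else
    with_substream(seed, "genotyped_subset", {
      extra <- setdiff(ids, train_ids)
      n_extra <- round(config$genotyped_fraction * length(ids))
      sort(unique(c(train_ids, if (n_extra > 0) sample(extra, min(n_extra, length(extra))))))
    })
  raw <- NULL
  if (length(geno_ids) > 0) {
    raw <- dosages(sim$program$haplotypes)[geno_ids, , drop = FALSE]
    raw <- with_substream(seed, "missingness", {
      mask <- matrix(runif(length(raw)) < config$missing_rate, nrow(raw))
      raw[mask] <- NA
      raw
    })
  }

  # -- relationship matrices --------------------------------------------------
  rel <- stage("relmat", {
    A <- amatrix(ped)
    if (length(geno_ids) > 0) {
      geno <- qc_genotypes(raw, maf_min = maf_min, miss_max = miss_max)
      G <- gmatrix(geno)
      H <- hmatrix(A, G, blend_weight, tune)
    } else {
      geno <- NULL; G <- NULL
      H <- new_relmatrix(unclass(A), "H", meta = list(n_genotyped = 0L))
    }
    list(A = A, G = G, H = H, geno = geno)
  })

  # -- trials and EMMs --------------------------------------------------------
  trial <- stage("trial", {
    gvals <- setNames(sim$program$genetic_values[train_ids, 1], train_ids)
    pheno <- simulate_trials(gvals, design, seed = seed)
    fx <- fit_trial_lmm(pheno, "fixed")
    rd <- fit_trial_lmm(pheno, "random")
    list(pheno = pheno, emms = fx$emms, varcomps = rd$varcomps,
         h2 = heritability_clone_mean(rd$varcomps))
  })

  # -- single-step BLUP -------------------------------------------------------
  ss <- stage("ssblup", {
    fit_ssblup(setNames(trial$emms$emm, trial$emms$hybrid), rel$H,
               birth_year = byear, genotyped = geno_ids,
               max_ids = max(5000, nrow(rel$H)))
  })

  # -- change-point analyses --------------------------------------------------
  cp <- stage("changepoint", {
    g <- ss$gebv[!is.na(ss$gebv$birth_year), ]
    fit <- fit_changepoint(g$birth_year, g$gebv, guard = guard)
    list(fit = fit,
         pct = percent_change_summary(fit, min(g$birth_year), max(g$birth_year)),
         var_trend = variance_trend(fit))
  })

  # -- cross prediction (needs marker data) -----------------------------------
  cross <- if (length(geno_ids) == 0) NULL else stage("crosspredict", {
    eff <- estimate_marker_effects(rel$geno, setNames(trial$emms$emm, trial$emms$hybrid))
    pre_pool <- ids[!is.na(byear[ids]) & byear[ids] <= era_threshold]
    post_pool <- ids[!is.na(byear[ids]) & byear[ids] > era_threshold]
    pick <- function(pool, n, label) with_substream(seed, paste0("cross_pairs_", label), {
      t(vapply(seq_len(n), function(k) sample(pool, 2), character(2)))
    })
    pairs <- rbind(pick(pre_pool, n_crosses_per_era, "pre"),
                   pick(post_pool, n_crosses_per_era, "post"))
    crosses <- lapply(seq_len(nrow(pairs)), function(k) {
      predict_cross(parent_phase(sim$program$haplotypes, pairs[k, 1]),
                    parent_phase(sim$program$haplotypes, pairs[k, 2]),
                    eff, sim$map, n_progeny = n_progeny,
                    seed = substream_seed(seed, paste0("cross_", k)),
                    parent_ids = pairs[k, ],
                    parent_birth_years = byear[pairs[k, ]])
    })
    list(effects = eff, crosses = crosses,
         eras = compare_eras(crosses, era_threshold))
  })

  # -- artifacts + manifest ---------------------------------------------------
  path <- function(f) file.path(out_dir, f)
  write_pedigree(ped, path("pedigree.csv"))
  write_map(sim$map, path("map.tsv"))
  if (!is.null(raw)) write_genotypes(raw, path("genotypes.tsv"))
  write_phenotypes(trial$pheno, path("phenotypes.csv"))
  write.csv(trial$emms, path("emms.csv"), row.names = FALSE, quote = FALSE)
  write_gebv(ss$gebv, path("gebv.csv"))
  cp_sum <- data.frame(cp_year = cp$fit$cp_year, pre_slope = cp$fit$pre_slope,
                       post_slope = cp$fit$post_slope,
                       pre_pct = cp$pct$pre_pct, post_pct = cp$pct$post_pct,
                       resid_cp_year = cp$var_trend$cp_year,
                       resid_post_slope = cp$var_trend$post_slope)
  write.csv(cp_sum, path("changepoint.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(cross)) {
    cross_df <- do.call(rbind, lapply(cross$crosses, function(x)
      data.frame(parent1 = x$parent_ids[1], parent2 = x$parent_ids[2],
                 mu = x$mu, va = x$va, n_progeny = x$n_progeny)))
    write.csv(cross_df, path("cross_predictions.csv"), row.names = FALSE, quote = FALSE)
    write.csv(cross$eras, path("eras.csv"), row.names = FALSE, quote = FALSE)
  }
  files <- c("pedigree.csv", "map.tsv", "phenotypes.csv",
             "emms.csv", "gebv.csv", "changepoint.csv",
             if (!is.null(raw)) "genotypes.tsv",
             if (!is.null(cross)) c("cross_predictions.csv", "eras.csv"))
  manifest <- list(
    version = as.character(utils::packageVersion("breedgain")),
    seed = seed,
    config = unclass(config),
    constants = list(maf_min = maf_min, miss_max = miss_max,
                     blend_weight = blend_weight, tune = tune, guard = guard,
                     era_threshold = era_threshold,
                     n_crosses_per_era = n_crosses_per_era, n_progeny = n_progeny),
    h2 = trial$h2,
    varcomps = unclass(trial$varcomps),
    ssblup = list(mu = ss$mu, sigma2_g = ss$sigma2_g, sigma2_e = ss$sigma2_e),
    cp_year = cp$fit$cp_year,
    hashes = as.list(setNames(unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(sim = sim, rel = rel, trial = trial, ssblup = ss,
                 changepoint = cp, cross = cross, manifest = manifest,
                 out_dir = out_dir))
}
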