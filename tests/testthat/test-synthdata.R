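# Generator: founder sampling, meiosis, selection trend, trial phenotypes,
# dominant-locus classification.

test_that("founder haplotypes are valid 0/1/2 dosages and reproducible under a seed", {
  map <- sim_genetic_map(50, 5, seed = 2)
  cfg <- sim_config(n_founders = 20, n_markers = 50, n_chrom = 5, seed = 2)
  f1 <- simulate_founders(cfg, map)
  f2 <- simulate_founders(cfg, map)
  expect_identical(f1$haplotypes$h1, f2$haplotypes$h1)
  expect_identical(f1$haplotypes$h2, f2$haplotypes$h2)
  d <- dosages(f1$haplotypes)
  expect_true(all(d %in% 0:2))
  expect_true(all(is.na(f1$pedigree$sire)))
  expect_true(all(f1$pedigree$birth_year == cfg$founder_year))
  # forced p = 0.5 at a single marker still yields legal dosages
  f3 <- simulate_founders(sim_config(n_founders = 2, n_markers = 1, n_chrom = 1, seed = 1),
                          toy_map(1), freq = 0.5)
  expect_true(all(dosages(f3$haplotypes) %in% 0:2))
  expect_error(simulate_founders(cfg, genetic_map(character(0), character(0), numeric(0))),
               class = "breedgain_config_error")
})

test_that("realized founder MAF matches the U(0.05, 0.95) sampling distribution", {
  # oracle: moments of min(p, 1-p) for p ~ U(0.05, 0.95) by dense quadrature
  pg <- seq(0.05, 0.95, length.out = 20001)
  mu <- mean(pmin(pg, 1 - pg))
  se <- sd(pmin(pg, 1 - pg)) / sqrt(500)
  cfg <- sim_config(n_founders = 200, n_markers = 500, seed = 5)
  fo <- simulate_founders(cfg, sim_genetic_map(500, 28, seed = 5))
  p <- colMeans(dosages(fo$haplotypes)) / 2
  expect_lt(abs(mean(pmin(p, 1 - p)) - mu), 3 * se)
})

test_that("without selection the breeding-value trend is flat (seed batch)", {
  slopes <- vapply(1:6, function(s) {
    pr <- small_program(seed = s, selection_fraction = 1)
    unname(coef(lm(pr$tbv[, 1] ~ pr$pedigree$birth_year))[2])
  }, 0)
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(length(slopes)) + 1e-3)
})

test_that("truncation selection produces rising decade means after the onset", {
  # averaged over a 20-seed batch the post-onset decade means increase strictly
  decades <- seq(1950, 1990, 10)
  mat <- vapply(1:20, function(s) {
    pr <- small_program(seed = s)
    by <- pr$pedigree$birth_year
    vapply(decades, function(d) mean(pr$tbv[by >= d & by < d + 10, 1]), 0)
  }, numeric(length(decades)))
  expect_true(all(diff(rowMeans(mat)) > 0))
})

test_that("breeding-program pedigrees are acyclic with parents born earlier", {
  pr <- small_program(seed = 3)
  ped <- pr$pedigree
  expect_s3_class(ped, "pedigree")  # constructor runs the topological check
  by <- setNames(ped$birth_year, ped$id)
  known <- !is.na(ped$sire)
  expect_true(all(by[ped$sire[known]] < by[ped$id[known]]))
  expect_true(all(by[ped$dam[known]] < by[ped$id[known]]))
})

test_that("gene dropping conserves allele frequency without selection", {
  changes <- vapply(1:10, function(s) {
    pr <- small_program(seed = s, selection_fraction = 1, migration_rate = 0)
    by <- pr$pedigree$birth_year
    final <- colMeans(dosages(pr$haplotypes)[by >= 1990, , drop = FALSE]) / 2
    founder <- colMeans(dosages(pr$haplotypes)[by == 1900, , drop = FALSE]) / 2
    mean(final - founder)
  }, 0)
  expect_lt(abs(mean(changes)), 4 * sd(changes) / sqrt(length(changes)))
})

test_that("single-marker cross segregates 1:1 within binomial bounds", {
  map <- toy_map(1)
  p1 <- list(h1 = 1L, h2 = 0L)
  p2 <- list(h1 = 0L, h2 = 0L)
  d <- simulate_cross(p1, p2, map, n_progeny = 400, seed = 9)
  expect_true(all(d %in% 0:1))
  bounds <- qbinom(c(0.005, 0.995), 400, 0.5)
  expect_gte(sum(d), bounds[1])
  expect_lte(sum(d), bounds[2])
})

test_that("adjacent-marker recombination matches the Haldane map function", {
  map <- toy_map(2, spacing = 10)
  c_exp <- 0.5 * (1 - exp(-2 * 10 / 100))
  p1 <- list(h1 = c(1L, 1L), h2 = c(0L, 0L))   # coupling phase
  p2 <- list(h1 = c(0L, 0L), h2 = c(0L, 0L))   # tester
  n <- 10000
  d <- simulate_cross(p1, p2, map, n_progeny = n, seed = 4)
  rec <- sum(d[, 1] != d[, 2])
  bounds <- qbinom(c(0.005, 0.995), n, c_exp)
  expect_gte(rec, bounds[1])
  expect_lte(rec, bounds[2])
})

test_that("noiseless trials return genetic value plus intercept exactly", {
  g <- c(a = 1.5, b = -0.5, c = 0)
  des <- trial_design(n_blocks = 2, n_years = 2, sigma2_block = 0, sigma2_year = 0,
                      sigma2_gy = 0, sigma2_e = 0)
  ph <- simulate_trials(g, des, intercept = 10, seed = 1)
  expect_equal(ph$value, unname(10 + g[ph$hybrid]))
  expect_identical(ph, simulate_trials(g, des, intercept = 10, seed = 1))
  expect_error(trial_design(n_blocks = 0), class = "breedgain_config_error")
})

test_that("trial noise follows the configured variance structure", {
  g <- setNames(rep(0, 200), sprintf("h%03d", 1:200))
  des <- trial_design(n_blocks = 4, n_years = 2, sigma2_block = 0, sigma2_year = 0,
                      sigma2_gy = 0, sigma2_e = 4)
  ph <- simulate_trials(g, des, seed = 3)
  expect_equal(var(ph$value), 4, tolerance = 0.15)
})

test_that("dominant-locus classification and segregation ratios are Mendelian", {
  expect_equal(as.character(classify_pf(c(0, 1, 2, NA))),
               c("homozygous-recessive", "carrier", "carrier", NA))
  expect_equal(pf_segregation(1, 1)$ratio, "3:1")
  expect_equal(pf_segregation(1, 0)$ratio, "1:1")
  expect_equal(pf_segregation(2, 0)$ratio, "all carriers")
  expect_equal(pf_segregation(1, 1)$prop_carrier, 0.75)
  m <- matrix(c(2, 0), 2, 1, dimnames = list(c("x", "y"), "M01"))
  expect_equal(as.character(classify_pf(m, "M01")[1]), "carrier")
})

test_that("impossibly strong truncation raises a degenerate-selection error", {
  expect_error(
    small_program(seed = 1, n_founders = 2, crosses_per_year = 1,
                  progeny_per_cross = 1, parent_window = 2,
                  selection_fraction = 0.01, selection_ramp = 1,
                  migration_rate = 0),
    class = "breedgain_degenerate_selection")
})
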