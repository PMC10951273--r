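# Cross prediction: ridge marker effects, meiosis, predicted progeny means
# and additive variances, era summaries.

test_that("ridge effects recover a single causal marker as shrinkage vanishes", {
  set.seed(1)
  n <- 60
  W0 <- matrix(rbinom(n * 5, 2, 0.5), n, dimnames = list(sprintf("i%02d", 1:n),
                                                         paste0("m", 1:5)))
  y <- setNames(3 + 2 * (W0[, 3] - mean(W0[, 3])), rownames(W0))
  eff <- estimate_marker_effects(qc_genotypes(W0, 0, 1), y, lambda = 1e-8)
  expect_equal(unname(eff$effects["m3"]), 2, tolerance = 1e-3)
  expect_lt(max(abs(eff$effects[-3])), 0.05)
})

test_that("duplicated marker columns split the effect mass equally", {
  set.seed(2)
  n <- 50
  x <- rbinom(n, 2, 0.5)
  W0 <- cbind(m1 = x, m2 = x, m3 = rbinom(n, 2, 0.4))
  rownames(W0) <- sprintf("i%02d", 1:n)
  y <- setNames(1.5 * (x - mean(x)) + rnorm(n, sd = 0.1), rownames(W0))
  eff <- estimate_marker_effects(qc_genotypes(W0, 0, 1), y, lambda = 0.5)
  expect_equal(unname(eff$effects["m1"]), unname(eff$effects["m2"]), tolerance = 1e-10)
})

test_that("REML-derived shrinkage correlates estimated with true effects", {
  pr <- small_program(seed = 9)
  by <- setNames(pr$pedigree$birth_year, pr$pedigree$id)
  train <- pr$pedigree$id[by >= 1980]
  set.seed(9)
  y <- setNames(pr$tbv[train, 1] + rnorm(length(train), sd = 0.5), train)
  eff <- estimate_marker_effects(qc_genotypes(dosages(pr$haplotypes)[train, ], 0.05, 1), y)
  a <- pr$arch$marker_effects[names(eff$effects), 1]
  expect_gt(cor(eff$effects, a), 0.2)
  # and the implied GEBVs track true breeding values
  W <- sweep(dosages(pr$haplotypes)[train, names(eff$effects)], 2, eff$center)
  expect_gt(cor(as.numeric(W %*% eff$effects), pr$tbv[train, 1]), 0.6)
})

test_that("crosses of identical fully inbred parents show zero variance", {
  map <- toy_map(6, spacing = 5)
  hom <- list(h1 = rep(1L, 6), h2 = rep(1L, 6))
  eff <- structure(list(effects = setNames(rnorm(6), map$marker), intercept = 2,
                        lambda = 1, center = rep(1, 6)), class = "marker_effects")
  cp <- predict_cross(hom, hom, eff, map, n_progeny = 100, seed = 1)
  expect_equal(cp$va, 0)
  expect_equal(cp$mu, 2 + sum((2 - 1) * eff$effects))
})

test_that("a single heterozygous marker gives variance a^2/4 (enumeration)", {
  map <- toy_map(1)
  het <- list(h1 = 1L, h2 = 0L); hom <- list(h1 = 0L, h2 = 0L)
  a <- 1.8
  eff <- structure(list(effects = c(M01 = a), intercept = 0, lambda = 1,
                        center = 0.5), class = "marker_effects")
  # exact oracle: two progeny classes (dosage 0 or 1), probability 1/2 each,
  # so the value is a scaled Bernoulli(1/2): mean 0, variance a^2/4
  mu_exact <- mean(c(0 - 0.5, 1 - 0.5) * a)
  va_exact <- a^2 / 4
  cp <- predict_cross(het, hom, eff, map, n_progeny = 600, seed = 2)
  expect_equal(cp$mu, mu_exact, tolerance = 3 * (a / 2) / sqrt(600))
  # sampling distribution of the variance of a scaled Bernoulli(1/2)
  expect_equal(cp$va, va_exact, tolerance = 3 * va_exact * sqrt(2 / 599))
})

test_that("predicted mean and variance match exhaustive gamete enumeration", {
  # three unlinked segregating markers: enumerate all 8 x 2 gamete combos
  map <- genetic_map(paste0("m", 1:3), c("1", "2", "3"), c(0, 0, 0))
  p1 <- list(h1 = c(1L, 0L, 1L), h2 = c(0L, 1L, 1L))  # het, het, hom
  p2 <- list(h1 = c(1L, 0L, 0L), h2 = c(0L, 0L, 0L))  # het, hom, hom
  beta <- c(m1 = 1.2, m2 = -0.7, m3 = 0.4)
  ctr <- c(m1 = 1, m2 = 0.5, m3 = 1.5)
  eff <- structure(list(effects = beta, intercept = 5, lambda = 1, center = ctr),
                   class = "marker_effects")
  # oracle: enumerate gametes of each parent with equal probability
  gam <- function(p) expand.grid(lapply(1:3, function(j) unique(c(p$h1[j], p$h2[j]))))
  g1 <- gam(p1); g2 <- gam(p2)
  combos <- merge(g1, g2, by = NULL)
  dose <- as.matrix(combos[, 1:3]) + as.matrix(combos[, 4:6])
  vals <- 5 + as.numeric(sweep(dose, 2, ctr) %*% beta)
  mu_exact <- mean(vals)
  va_exact <- mean(vals^2) - mu_exact^2
  cp <- predict_cross(p1, p2, eff, map, n_progeny = 2000, seed = 7)
  expect_equal(cp$mu, mu_exact, tolerance = 3 * sd(vals) / sqrt(2000))
  expect_equal(cp$va, va_exact, tolerance = 3 * va_exact * sqrt(2 / 1999))
})

test_that("variance is invariant to the intercept; doubling effects quadruples it", {
  map <- toy_map(4, spacing = 20)
  p1 <- list(h1 = c(1L, 0L, 1L, 0L), h2 = c(0L, 1L, 1L, 0L))
  p2 <- list(h1 = c(1L, 1L, 0L, 0L), h2 = c(0L, 0L, 0L, 1L))
  base <- structure(list(effects = setNames(c(0.5, -0.3, 0.8, 0.2), map$marker),
                         intercept = 0, lambda = 1, center = rep(1, 4)),
                    class = "marker_effects")
  shifted <- base; shifted$intercept <- 42
  doubled <- base; doubled$effects <- 2 * base$effects
  c0 <- predict_cross(p1, p2, base, map, n_progeny = 300, seed = 3)
  c1 <- predict_cross(p1, p2, shifted, map, n_progeny = 300, seed = 3)
  c2 <- predict_cross(p1, p2, doubled, map, n_progeny = 300, seed = 3)
  expect_equal(c1$va, c0$va, tolerance = 1e-12)
  expect_equal(c1$mu, c0$mu + 42, tolerance = 1e-12)
  expect_equal(c2$va, 4 * c0$va, tolerance = 1e-10)
  expect_equal(c2$mu, 2 * c0$mu, tolerance = 1e-10)
})

test_that("the random-phase heuristic respects dosages and is flagged", {
  ph <- parent_phase(c(0, 1, 2, 1), seed = 1)
  expect_true(ph$heuristic)
  expect_equal(ph$h1 + ph$h2, c(0, 1, 2, 1))
  expect_true(all(c(ph$h1, ph$h2) %in% 0:1))
})

test_that("era summaries split, count and warn as specified", {
  mk <- function(mu, va, by) structure(list(mu = mu, va = va, n_progeny = 10,
                                            parent_ids = c("a", "b"),
                                            parent_birth_years = by),
                                       class = "cross_prediction")
  crosses <- list(mk(1, 0.5, c(1950, 1940)), mk(2, 0.9, c(1960, 1950)),
                  mk(3, 1.1, c(1990, 2000)))
  e <- compare_eras(crosses, 1953)
  expect_equal(e$n[e$era == "pre"], 1)
  expect_equal(e$n[e$era == "post"], 2)
  expect_equal(e$mean_va[e$era == "post"], 1.0)
  # threshold beyond all birth years: single (pre) era
  e2 <- compare_eras(crosses, 2050)
  expect_equal(e2$n[e2$era == "post"], 0)
  expect_warning(compare_eras(c(crosses, list(mk(0, 0, c(NA, 1990)))), 1953),
                 "excluded")
})
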