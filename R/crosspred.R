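# Genomic prediction of cross outcomes: ridge-regression BLUP marker
# effects from training data, meiosis simulation from phased parents over a
# genetic map, and per-cross predicted progeny means and additive genetic
# variances, with a pre/post breeding-era comparison.

#' Estimate additive marker effects by ridge-regression BLUP
#'
#' Solves `effects = W'(W W' + lambda I)^-1 (y - mu)` with `W` the centered
#' dosage matrix (equivalent to `(W'W + lambda I)^-1 W'(y - mu)`), where the
#' shrinkage `lambda = sigma2_e / sigma2_u` is estimated by REML on the
#' equivalent kinship model unless supplied.
#'
#' @param geno a `genotype_matrix` (training individuals, post-QC) or a
#'   plain dosage matrix.
#' @param y named vector (or data frame id/emm) of training phenotypes;
#'   names must match genotype rows.
#' @param lambda optional fixed ridge parameter (> 0).
#' @return a `marker_effects` object: per-marker `effects`, `intercept`,
#'   `lambda`, and the dosage `center` (2p) used for W.
#' @export
estimate_marker_effects <- function(geno, y, lambda = NULL) {
  if (!inherits(geno, "genotype_matrix")) geno <- qc_genotypes(geno, 0, 1)
  if (is.data.frame(y)) y <- setNames(y$emm, y$id)
  ids <- intersect(names(y), rownames(geno$dosage))
  assert(length(ids) >= 3, "need >= 3 individuals both genotyped and phenotyped")
  assert(ncol(geno$dosage) >= 1, "empty marker panel", class = "breedgain_empty_panel")
  center <- 2 * geno$p
  W <- sweep(geno$imputed[ids, , drop = FALSE], 2, center)
  yv <- as.numeric(y[ids])
  n <- length(yv)

  if (is.null(lambda)) {
    K <- tcrossprod(W)
    fit <- fit_ssblup(setNames(yv, ids), new_relmatrix(K, "G"))
    lambda <- fit$theta
    mu <- fit$mu
  } else {
    assert(lambda > 0, "lambda must be positive")
    mu <- mean(yv)
  }
  eff <- as.numeric(crossprod(W, solve(tcrossprod(W) + diag(lambda, n), yv - mu)))
  structure(list(effects = setNames(eff, colnames(geno$dosage)),
                 intercept = mu, lambda = lambda, center = center),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  cat(sprintf("marker effects: %d markers, intercept = %.4g, lambda = %.4g\n",
              length(x$effects), x$intercept, x$lambda))
  invisible(x)
}

#' Simulate progeny of a biparental cross
#'
#' Each progeny receives one recombinant gamete from each phased parent;
#' gametes are generated per chromosome with Haldane recombination fractions
#' from the map's centimorgan distances. Deterministic under `seed`.
#'
#' @param p1,p2 parent haplotype pairs: a list with 0/1 vectors `h1`, `h2`
#'   over the map's markers (see [parent_phase()]).
#' @param map a [genetic_map()].
#' @param n_progeny progeny per cross (default 200).
#' @param seed integer seed.
#' @return progeny dosage matrix (n_progeny x markers).
#' @export
simulate_cross <- function(p1, p2, map, n_progeny = 200, seed = 1) {
  for (p in list(p1, p2))
    assert(is.list(p) && all(c("h1", "h2") %in% names(p)) &&
             length(p$h1) == nrow(map) && length(p$h2) == nrow(map),
           "parents must be phased over the marker panel; see parent_phase()")
  layout <- map_meiosis_layout(map)
  with_substream(seed, "cross", {
    D <- matrix(0L, n_progeny, nrow(map), dimnames = list(NULL, map$marker))
    for (k in seq_len(n_progeny)) {
      D[k, ] <- meiosis_gamete(p1$h1, p1$h2, layout) +
        meiosis_gamete(p2$h1, p2$h2, layout)
    }
    D
  })
}

#' Extract (or heuristically construct) a parent's phased haplotypes
#'
#' From a `haplotype_set` the simulation-true phase is returned. From an
#' unphased dosage vector a random phase consistent with the dosages is
#' drawn (heterozygous sites assigned independently) and flagged
#' `heuristic = TRUE`; linkage between heterozygous sites is then not
#' preserved, which inflates apparent recombination.
#'
#' @param x a `haplotype_set` or a dosage vector (0/1/2 over the map).
#' @param id individual id when `x` is a `haplotype_set`.
#' @param seed seed for the random-phase heuristic.
#' @export
parent_phase <- function(x, id = NULL, seed = 1) {
  if (inherits(x, "haplotype_set")) {
    i <- match(id, rownames(x$h1))
    assert(!is.na(i), "id not found in haplotype set")
    return(list(h1 = x$h1[i, ], h2 = x$h2[i, ], heuristic = FALSE))
  }
  d <- as.numeric(x)
  assert(all(d %in% 0:2), "dosages must be 0/1/2 to phase heuristically")
  with_substream(seed, "phase_heuristic", {
    h1 <- as.integer(d == 2)
    het <- which(d == 1)
    pick <- runif(length(het)) < 0.5
    h1[het] <- as.integer(pick)
    list(h1 = h1, h2 = as.integer(d) - h1, heuristic = TRUE)
  })
}

#' Predict progeny mean and additive variance for one cross
#'
#' Simulates `n_progeny` offspring, scores each as
#' `gebv = intercept + sum_j (dosage_j - center_j) * effect_j`, and reports
#' the progeny mean and the additive variance (n-1 denominator).
#'
#' @param p1,p2 phased parents (see [simulate_cross()]).
#' @param effects a `marker_effects` object.
#' @param map a [genetic_map()].
#' @param n_progeny simulated progeny per cross (default 200).
#' @param seed integer seed.
#' @param parent_ids,parent_birth_years optional labels carried to the
#'   output for era assignment.
#' @return a `cross_prediction`: list with `mu`, `va`, `n_progeny`, parents
#'   and birth years.
#' @export
predict_cross <- function(p1, p2, effects, map, n_progeny = 200, seed = 1,
                          parent_ids = c(NA, NA), parent_birth_years = c(NA, NA)) {
  stopifnot(inherits(effects, "marker_effects"))
  D <- simulate_cross(p1, p2, map, n_progeny, seed)
  use <- intersect(colnames(D), names(effects$effects))
  assert(length(use) == length(effects$effects),
         "effect markers missing from the simulated panel")
  D <- D[, use, drop = FALSE]
  ctr <- effects$center
  if (is.null(names(ctr))) names(ctr) <- names(effects$effects)
  W <- sweep(D, 2, ctr[use])
  g <- effects$intercept + as.numeric(W %*% effects$effects[use])
  structure(list(mu = mean(g), va = var(g), n_progeny = n_progeny,
                 parent_ids = parent_ids, parent_birth_years = parent_birth_years),
            class = "cross_prediction")
}

#' Summarize predicted crosses by parental era
#'
#' A cross belongs to the pre-era iff both parents were born in or before
#' `threshold_year` (default 1953, the conventional break between the
#' random-mating and directional-selection phases of the program); all other
#' crosses with known birth years are post-era. Crosses with a missing
#' parental birth year are excluded and counted.
#'
#' @param crosses list of `cross_prediction` objects.
#' @param threshold_year era boundary.
#' @return data frame with one row per era: counts, mean predicted progeny
#'   mean, and mean predicted additive variance; excluded-cross count as an
#'   attribute.
#' @export
compare_eras <- function(crosses, threshold_year = 1953) {
  by <- t(vapply(crosses, function(x) as.numeric(x$parent_birth_years), numeric(2)))
  mu <- vapply(crosses, function(x) x$mu, 0)
  va <- vapply(crosses, function(x) x$va, 0)
  known <- !is.na(by[, 1]) & !is.na(by[, 2])
  n_excluded <- sum(!known)
  if (n_excluded > 0)
    warning(n_excluded, " cross(es) excluded for missing parental birth years")
  era <- ifelse(by[known, 1] <= threshold_year & by[known, 2] <= threshold_year,
                "pre", "post")
  out <- do.call(rbind, lapply(c("pre", "post"), function(e) {
    i <- era == e
    data.frame(era = e, n = sum(i),
               mean_mu = if (any(i)) mean(mu[known][i]) else NA_real_,
               mean_va = if (any(i)) mean(va[known][i]) else NA_real_)
  }))
  attr(out, "n_excluded") <- n_excluded
  out
}
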