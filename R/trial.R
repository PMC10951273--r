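# Replicated clonal-trial analysis: REML variance components and estimated
# marginal means via lme4/emmeans, clone-mean heritability, genetic-gain
# contrasts between extreme hybrids, and AUDPS disease scoring.

#' Fit the clonal-trial linear mixed model
#'
#' With `hybrid_as = "fixed"` the model is
#' `value ~ hybrid + (1|block) + (1|year) + (1|hybrid:year) + ...` and the
#' hybrid estimated marginal means (least-squares means over the factor
#' grid) are returned. With `hybrid_as = "random"` hybrids enter as a random
#' effect and the REML variance components needed for clone-mean
#' heritability are returned. Terms whose factor has a single level in the
#' data (e.g. location in a one-location trial) are dropped automatically.
#'
#' @param data data frame with columns hybrid, block, year, value and
#'   optionally location and trait.
#' @param hybrid_as `"fixed"` (EMMs) or `"random"` (variance components).
#' @param trait restrict to one trait label when a `trait` column is present.
#' @param df degrees-of-freedom method for the EMMs: `"satterthwaite"`,
#'   `"asymptotic"`, or `"auto"` (Satterthwaite up to 60 hybrids, above
#'   which its per-mean cost becomes prohibitive and the asymptotic
#'   normal reference is used).
#' @return list with `fit` (the merMod/lm object), `emms` (data frame
#'   hybrid/emm/se/df; fixed-hybrid fits only), and `varcomps` (a `varcomps`
#'   object; random-hybrid fits only).
#' @export
fit_trial_lmm <- function(data, hybrid_as = c("fixed", "random"), trait = NULL,
                          df = c("auto", "satterthwaite", "asymptotic")) {
  hybrid_as <- match.arg(hybrid_as)
  df_method <- match.arg(df)
  df <- as.data.frame(data)
  if (!is.null(trait) && "trait" %in% names(df)) df <- df[df$trait == trait, ]
  assert(all(c("hybrid", "block", "year", "value") %in% names(df)),
         "data needs columns hybrid, block, year, value")
  if (!"location" %in% names(df)) df$location <- "L1"
  assert(all(is.finite(df$value)), "phenotype values must be finite")
  key <- if ("rep" %in% names(df))
    interaction(df$hybrid, df$block, df$year, df$location, df$rep, drop = TRUE)
  else interaction(df$hybrid, df$block, df$year, df$location, drop = TRUE)
  assert(!anyDuplicated(key), "duplicated (hybrid, block, year, location) cells")
  for (v in c("hybrid", "block", "year", "location")) df[[v]] <- factor(df[[v]])
  assert(nlevels(df$hybrid) >= 2, "need at least 2 hybrids")
  assert(nrow(df) > nlevels(df$hybrid), "need replication beyond one record per hybrid",
         class = "breedgain_inestimable")

  nlev <- vapply(df[c("block", "year", "location")], nlevels, 1L)
  rand <- character(0)
  if (nlev["block"] > 1) rand <- c(rand, "(1 | block)")
  if (nlev["year"] > 1) rand <- c(rand, "(1 | year)", "(1 | hybrid:year)")
  if (nlev["location"] > 1) {
    rand <- c(rand, "(1 | location)", "(1 | hybrid:location)")
    if (nlev["year"] > 1) rand <- c(rand, "(1 | year:location)", "(1 | hybrid:year:location)")
  }
  fixed <- if (hybrid_as == "fixed") "value ~ hybrid" else "value ~ 1"
  if (hybrid_as == "random") rand <- c("(1 | hybrid)", rand)
  use_lmer <- length(rand) > 0
  form <- as.formula(paste(c(fixed, rand), collapse = " + "))

  fit <- if (use_lmer) {
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  } else {
    assert(hybrid_as == "fixed", "unreplicated design cannot estimate a hybrid variance",
           class = "breedgain_inestimable")
    lm(as.formula(fixed), data = df)
  }

  out <- list(fit = fit, data = df, hybrid_as = hybrid_as)
  if (hybrid_as == "fixed") {
    if (df_method == "auto")
      df_method <- if (nlevels(droplevels(df$hybrid)) <= 60) "satterthwaite" else "asymptotic"
    em <- emmeans::emmeans(fit, "hybrid", lmer.df = df_method)
    es <- as.data.frame(summary(em))
    out$emms <- data.frame(hybrid = as.character(es$hybrid), emm = es$emmean,
                           se = es$SE, df = es$df, stringsAsFactors = FALSE)
  } else {
    vc <- as.data.frame(lme4::VarCorr(fit))
    grab <- function(g) { i <- match(g, vc$grp); if (is.na(i)) 0 else max(vc$vcov[i], 0) }
    reps <- table(df$hybrid) / (nlev["year"] * nlev["location"])
    out$varcomps <- varcomps(
      sigma2_g = grab("hybrid"), sigma2_gy = grab("hybrid:year"),
      sigma2_gl = grab("hybrid:location"), sigma2_gyl = grab("hybrid:year:location"),
      sigma2_e = grab("Residual"),
      y = unname(nlev["year"]), l = unname(nlev["location"]),
      r = harmonic_mean(as.numeric(reps)))
  }
  out
}

#' Variance-component bundle for clone-mean heritability
#'
#' @param sigma2_g among-hybrid (total genetic) variance.
#' @param sigma2_gy,sigma2_gl,sigma2_gyl hybrid-by-year, hybrid-by-location
#'   and three-way interaction variances.
#' @param sigma2_e residual variance.
#' @param y,l number of years and locations in the design.
#' @param r harmonic-mean number of replicates per hybrid per environment.
#' @export
varcomps <- function(sigma2_g, sigma2_gy = 0, sigma2_gl = 0, sigma2_gyl = 0,
                     sigma2_e = 0, y = 1, l = 1, r = 1) {
  v <- c(sigma2_g, sigma2_gy, sigma2_gl, sigma2_gyl, sigma2_e)
  assert(all(v >= 0), "variance components must be non-negative")
  assert(y >= 1 && l >= 1 && r > 0, "need y, l >= 1 and r > 0")
  structure(list(sigma2_g = sigma2_g, sigma2_gy = sigma2_gy, sigma2_gl = sigma2_gl,
                 sigma2_gyl = sigma2_gyl, sigma2_e = sigma2_e, y = y, l = l, r = r),
            class = "varcomps")
}

#' Broad-sense heritability on a clone-mean basis
#'
#' `H2 = s2_G / (s2_G + s2_GxY/y + s2_GxL/l + s2_GxYxL/(l y) + s2_E/(r l y))`.
#' With a single location the location terms vanish and the expression
#' reduces to the one-location form.
#'
#' @param vc a [varcomps()] object.
#' @return heritability in `[0, 1]`.
#' @export
heritability_clone_mean <- function(vc) {
  stopifnot(inherits(vc, "varcomps"))
  denom <- vc$sigma2_g + vc$sigma2_gy / vc$y + vc$sigma2_gl / vc$l +
    vc$sigma2_gyl / (vc$l * vc$y) + vc$sigma2_e / (vc$r * vc$l * vc$y)
  assert(denom > 0, "all variance components are zero; heritability undefined")
  vc$sigma2_g / denom
}

#' Genetic gain (or loss) contrast between two hybrids
#'
#' Computes `dG = EMM_1 - EMM_2`, the percent gain
#' `dG_pct = dG / EMM_2 * 100`, a t-statistic `dG / SE(dG)` with
#' Satterthwaite degrees of freedom, and a Bonferroni-adjusted p-value over
#' `n_tests` tests per trait (default 2: one per low-benchmark).
#'
#' @param emms data frame with columns hybrid, emm and optionally se, df.
#' @param high,low hybrid ids of the high and low (benchmark) entries.
#' @param n_tests number of tests per trait for the Bonferroni adjustment.
#' @return list with emm_high, emm_low, dG, dG_pct, se, t, df, p, p_adj and
#'   `pct_reliable` (FALSE when the benchmark EMM is not strictly positive).
#' @export
genetic_gain_contrast <- function(emms, high, low, n_tests = 2) {
  emms <- as.data.frame(emms)
  i <- match(high, emms$hybrid); j <- match(low, emms$hybrid)
  assert(!is.na(i) && !is.na(j), "high/low hybrid not found in the EMM table")
  e1 <- emms$emm[i]; e2 <- emms$emm[j]
  dG <- e1 - e2
  pct_ok <- is.finite(e2) && e2 > 0
  dG_pct <- if (e2 != 0) dG / e2 * 100 else NA_real_
  se <- t <- dfree <- p <- p_adj <- NA_real_
  if (all(c("se", "df") %in% names(emms))) {
    s1 <- emms$se[i]; s2 <- emms$se[j]
    se <- sqrt(s1^2 + s2^2)
    if (se > 0) {
      t <- dG / se
      dfree <- se^4 / (s1^4 / emms$df[i] + s2^4 / emms$df[j])  # Satterthwaite
      p <- 2 * pt(-abs(t), df = dfree)
      p_adj <- min(1, p * n_tests)
    } else { t <- 0; p <- p_adj <- 1 }
  }
  list(emm_high = e1, emm_low = e2, dG = dG, dG_pct = dG_pct,
       se = se, t = t, df = dfree, p = p, p_adj = p_adj, pct_reliable = pct_ok)
}

#' Area under the disease progress stairs (AUDPS)
#'
#' `AUDPS = AUDPC + (y_1 + y_n)/2 * D/(n - 1)` where AUDPC is the trapezoid
#' area under the rating curve and `D = t_n - t_1`. For equally spaced
#' observation times this equals `spacing * sum(y)`.
#'
#' @param scores ordered disease ratings.
#' @param times strictly increasing observation times.
#' @return list with `audpc` and `audps` (rating x time units).
#' @export
audps <- function(scores, times) {
  assert(length(scores) == length(times), "scores and times differ in length")
  assert(length(scores) >= 2, "need at least two time points")
  assert(all(diff(times) > 0), "times must be strictly increasing")
  n <- length(scores)
  audpc <- sum(diff(times) * (scores[-n] + scores[-1]) / 2)
  D <- times[n] - times[1]
  list(audpc = audpc, audps = audpc + (scores[1] + scores[n]) / 2 * D / (n - 1))
}
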