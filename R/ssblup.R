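# Single-step BLUP of breeding values from hybrid-mean phenotypes and a
# relationship matrix. The model is y = 1*mu + Z g + e with
# g ~ N(0, H * sigma2_g) and e ~ N(0, I * sigma2_e). Variance components are
# estimated by REML, profiled over the ratio theta = sigma2_e / sigma2_g on
# the eigenbasis of the phenotyped block of H (the transformation that makes
# the restricted likelihood a cheap one-dimensional function of theta).

#' Fit single-step BLUP breeding values
#'
#' Solves the animal-model mixed equations for every individual in the
#' relationship matrix, phenotyped or not. Unphenotyped individuals receive
#' predictions through their relationships alone and shrink towards 0 (the
#' centered population mean) as their information content vanishes.
#'
#' @param y phenotypes: a named numeric vector, or a data frame with columns
#'   `id` and `emm` (one hybrid-mean record per id).
#' @param H a `relmatrix` (kind "A", "G" or "H") whose ids cover all
#'   phenotyped individuals.
#' @param varcomp optional `c(sigma2_g, sigma2_e)` to skip REML.
#' @param birth_year optional named vector of birth years copied into the
#'   output table.
#' @param genotyped optional character vector of genotyped ids (flag only).
#' @param max_ids guard on the dense solve (default 5000 individuals);
#'   larger problems are refused rather than approximated.
#' @param jitter diagonal jitter used in the positive-definiteness check.
#' @return list with `mu`, `sigma2_g`, `sigma2_e`, `theta`, `loglik`,
#'   `converged`, and `gebv`: a data frame (id, birth_year, gebv, pev,
#'   accuracy, genotyped, phenotyped).
#' @export
fit_ssblup <- function(y, H, varcomp = NULL, birth_year = NULL,
                       genotyped = NULL, max_ids = 5000, jitter = 1e-8) {
  if (is.data.frame(y)) {
    assert(all(c("id", "emm") %in% names(y)), "y data frame needs columns id, emm")
    y <- setNames(y$emm, y$id)
  }
  assert(length(y) >= 1 && !is.null(names(y)), "no phenotyped individuals",
         class = "breedgain_no_phenotypes")
  ids <- rownames(H)
  q <- length(ids)
  assert(q <= max_ids, "relationship matrix has ", q, " individuals; the dense ",
         "solve is limited to max_ids = ", max_ids,
         " (subset the pedigree or raise max_ids explicitly)")
  miss <- setdiff(names(y), ids)
  assert(length(miss) == 0, "phenotyped ids absent from H: ",
         paste(utils::head(miss, 5), collapse = ", "))
  Hm <- unclass(H)
  chk <- tryCatch(chol(Hm + diag(jitter * mean(diag(Hm)), q)), error = function(e) NULL)
  if (is.null(chk)) {
    ev <- range(eigen(Hm, symmetric = TRUE, only.values = TRUE)$values)
    stop_bg("H is not positive semidefinite beyond jitter (eigenvalue range ",
            format(ev[1]), " .. ", format(ev[2]), ")")
  }

  zi <- match(names(y), ids)
  n <- length(y)
  K <- Hm[zi, zi, drop = FALSE]
  yv <- as.numeric(y)

  converged <- TRUE
  if (is.null(varcomp)) {
    assert(n >= 3, "need >= 3 phenotyped individuals to estimate variances")
    Q2 <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
    em <- eigen(crossprod(Q2, K %*% Q2), symmetric = TRUE)
    xi <- pmax(em$values, 0)
    eta <- as.numeric(crossprod(Q2 %*% em$vectors, yv))
    nr <- n - 1
    reml <- function(lt) {
      th <- exp(lt)
      s2g <- sum(eta^2 / (xi + th)) / nr
      -0.5 * (nr * (log(2 * pi) + log(s2g) + 1) + sum(log(xi + th)))
    }
    grid <- seq(log(1e-6), log(1e6), length.out = 41)
    lls <- vapply(grid, reml, 0)
    i0 <- which.max(lls)
    lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
    opt <- optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-10)
    theta <- exp(opt$maximum)
    sigma2_g <- sum(eta^2 / (xi + theta)) / nr
    sigma2_e <- theta * sigma2_g
    loglik <- opt$objective
    converged <- i0 > 1 && i0 < length(grid)
  } else {
    sigma2_g <- varcomp[1]; sigma2_e <- varcomp[2]
    assert(sigma2_g > 0 && sigma2_e >= 0, "variances must be positive")
    theta <- sigma2_e / sigma2_g
    loglik <- NA_real_
  }

  V <- sigma2_g * K + diag(sigma2_e, n)
  Vi <- solve(V)
  one <- rep(1, n)
  xvx <- sum(Vi)                      # 1' Vi 1
  mu <- sum(Vi %*% yv) / xvx
  P <- Vi - (Vi %*% one) %*% (t(one) %*% Vi) / xvx
  Tm <- Hm[, zi, drop = FALSE]
  gebv <- as.numeric(sigma2_g * (Tm %*% (P %*% yv)))
  TP <- Tm %*% P
  pev <- sigma2_g * diag(Hm) - sigma2_g^2 * rowSums(TP * Tm)
  pev <- pmax(pev, 0)
  acc <- gebv_accuracy(pev, sigma2_g)

  by <- rep(NA_integer_, q)
  if (!is.null(birth_year)) by <- unname(birth_year[ids])
  tab <- data.frame(id = ids, birth_year = by, gebv = gebv, pev = pev,
                    accuracy = as.numeric(acc),
                    genotyped = ids %in% (genotyped %||% character(0)),
                    phenotyped = ids %in% names(y),
                    stringsAsFactors = FALSE)
  structure(list(mu = mu, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 theta = theta, loglik = loglik, converged = converged,
                 gebv = tab), class = "ssblup_fit")
}

#' @export
print.ssblup_fit <- function(x, ...) {
  cat(sprintf("single-step BLUP: %d individuals (%d phenotyped)\n",
              nrow(x$gebv), sum(x$gebv$phenotyped)))
  cat(sprintf("mu = %.4g, sigma2_g = %.4g, sigma2_e = %.4g\n",
              x$mu, x$sigma2_g, x$sigma2_e))
  invisible(x)
}

#' Breeding-value prediction accuracy from PEV
#'
#' `accuracy = 1 - sqrt(PEV / sigma2_A)`, clipped to \[0, 1\]. A `clipped`
#' attribute flags entries where the raw value fell outside the interval.
#'
#' @param pev prediction error variance(s), >= 0.
#' @param sigma2_a additive genetic variance, > 0.
#' @export
gebv_accuracy <- function(pev, sigma2_a) {
  assert(length(sigma2_a) == 1 && sigma2_a > 0, "sigma2_a must be a single positive value")
  assert(all(pev >= 0), "PEV must be non-negative")
  raw <- 1 - sqrt(pev / sigma2_a)
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "clipped") <- raw < 0 | raw > 1
  out
}

#' Genetic correlations among traits from breeding values
#'
#' Pairwise Pearson correlations among per-trait GEBV vectors on the ids
#' shared by all traits.
#'
#' @param gebvs named list; each element a GEBV data frame (columns id,
#'   gebv) or a named numeric vector.
#' @param ids optional id subset.
#' @return trait x trait correlation matrix with unit diagonal; pairs with a
#'   zero-variance vector are `NA` (with a warning).
#' @export
genetic_correlations <- function(gebvs, ids = NULL) {
  vecs <- lapply(gebvs, function(g) {
    if (is.data.frame(g)) setNames(g$gebv, g$id) else g
  })
  shared <- Reduce(intersect, lapply(vecs, names))
  if (!is.null(ids)) shared <- intersect(shared, ids)
  assert(length(shared) >= 3, "need >= 3 shared ids across traits")
  M <- vapply(vecs, function(v) v[shared], numeric(length(shared)))
  sds <- apply(M, 2, sd)
  R <- suppressWarnings(cor(M))
  diag(R) <- 1
  if (any(sds == 0)) {
    warning("zero-variance GEBV vector(s): ",
            paste(names(vecs)[sds == 0], collapse = ", "))
  }
  R
}
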