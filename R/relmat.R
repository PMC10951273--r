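# Additive relationship matrices: pedigree numerator matrix A by the tabular
# method, genomic matrix G (VanRaden method 1), and the unified single-step
# matrix H that updates A's genotyped block and cross-terms with G.

new_relmatrix <- function(M, kind, meta = list()) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  structure(M, kind = kind, meta = meta, class = c("relmatrix", class(M)))
}

#' @export
print.relmatrix <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d individuals\n", attr(x, "kind"), nrow(x)))
  meta <- attr(x, "meta")
  if (length(meta)) cat("meta:", paste(names(meta), unlist(lapply(meta, format)),
                                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# ---- genotype QC ------------------------------------------------------------

#' Quality-control a dosage matrix
#'
#' Drops markers by minor allele frequency and missingness, then mean-imputes
#' (2p) the surviving missing entries for genomic-relationship construction.
#' The raw post-filter matrix (missing preserved) is retained alongside.
#'
#' @param raw individuals x markers matrix of 0/1/2 dosages with `NA` for
#'   missing calls.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param miss_max maximum per-marker missingness (default 0.10).
#' @return a `genotype_matrix`: list with `dosage` (raw, post-filter),
#'   `imputed`, per-marker allele frequency `p`, and `qc_meta`.
#' @export
qc_genotypes <- function(raw, maf_min = 0.05, miss_max = 0.10) {
  raw <- as.matrix(raw)
  vals <- raw[!is.na(raw)]
  assert(all(vals %in% 0:2), "dosages must be 0, 1, 2 or NA")
  miss <- colMeans(is.na(raw))
  p <- colMeans(raw, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing marker
  keep <- maf >= maf_min & miss <= miss_max
  if (!any(keep))
    stop_bg("no markers pass QC (maf_min=", maf_min, ", miss_max=", miss_max, ")",
            class = "breedgain_empty_panel")
  kept <- raw[, keep, drop = FALSE]
  p <- colMeans(kept, na.rm = TRUE) / 2
  imputed <- kept
  for (j in which(colSums(is.na(kept)) > 0))
    imputed[is.na(kept[, j]), j] <- 2 * p[j]
  structure(list(dosage = kept, imputed = imputed, p = p,
                 qc_meta = list(maf_min = maf_min, miss_max = miss_max,
                                n_markers_in = ncol(raw), n_markers_out = ncol(kept))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype matrix: %d individuals x %d markers (from %d pre-QC)\n",
              nrow(x$dosage), ncol(x$dosage), x$qc_meta$n_markers_in))
  invisible(x)
}

# ---- A matrix ---------------------------------------------------------------

#' Pedigree numerator relationship matrix (A)
#'
#' Tabular-method recursion over a topologically sorted pedigree:
#' `a(i,i) = 1 + a(s,d)/2` (0 when a parent is unknown) and
#' `a(i,j) = (a(j,s) + a(j,d))/2` for previously processed j. Inbreeding is
#' `F_i = a(i,i) - 1`.
#'
#' @param ped a [pedigree()] (or data frame coercible to one).
#' @return a `relmatrix` of kind `"A"` with individual ids as dimnames.
#' @export
amatrix <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      row_s <- if (is.na(s)) 0 else A[s, prev]
      row_d <- if (is.na(d)) 0 else A[d, prev]
      a <- 0.5 * (row_s + row_d)
      A[i, prev] <- a; A[prev, i] <- a
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  new_relmatrix(A, "A")
}

#' Inbreeding coefficients from a relationship matrix
#' @param A a kind-"A" (or "H") `relmatrix`.
#' @export
inbreeding <- function(A) diag(A) - 1

# ---- G matrix ---------------------------------------------------------------

#' Genomic relationship matrix (G), VanRaden method 1
#'
#' `W = dosage - 2p` per marker (mean-imputed dosages) and
#' `G = W W' / (2 * sum p_j (1 - p_j))`.
#'
#' @param geno a `genotype_matrix` from [qc_genotypes()], or a plain dosage
#'   matrix (passed through QC with filters disabled).
#' @return a `relmatrix` of kind `"G"`.
#' @export
gmatrix <- function(geno) {
  if (!inherits(geno, "genotype_matrix")) geno <- qc_genotypes(geno, 0, 1)
  p <- geno$p
  poly <- p > 0 & p < 1
  assert(sum(poly) >= 2, "need >= 2 polymorphic markers",
         class = "breedgain_empty_panel")
  denom <- 2 * sum(p * (1 - p))
  assert(denom > 0, "all markers fixed; genomic relationships undefined",
         class = "breedgain_empty_panel")
  W <- sweep(geno$imputed, 2, 2 * p)
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(geno$dosage), rownames(geno$dosage))
  new_relmatrix(G, "G", meta = list(n_markers = ncol(geno$dosage), denom = denom))
}

# ---- H matrix ---------------------------------------------------------------

#' Unified single-step relationship matrix (H)
#'
#' Combines the pedigree matrix A (all individuals) with the genomic matrix
#' G (genotyped subset). Optionally G is first tuned to the genotyped block
#' A22 by solving `mean(diag(a + b G)) = mean(diag(A22))` and
#' `mean(offdiag(a + b G)) = mean(offdiag(A22))`, then blended as
#' `Gb = (1 - w) G* + w A22`. The standard block identity updates A:
#' `H22 = Gb`, `H12 = A12 A22^-1 Gb`, and
#' `H11 = A11 + A12 A22^-1 (Gb - A22) A22^-1 A21`.
#'
#' @param A kind-"A" `relmatrix` covering all individuals.
#' @param G kind-"G" `relmatrix`; its ids must be a subset of A's.
#' @param blend_weight blend weight w on A22 (default 0.05).
#' @param tune rescale G to A22 means before blending (default TRUE).
#' @return a `relmatrix` of kind `"H"` with the constants in its metadata.
#' @export
hmatrix <- function(A, G, blend_weight = 0.05, tune = TRUE) {
  ids <- rownames(A)
  gids <- rownames(G)
  assert(all(gids %in% ids), "G contains ids absent from A")
  w <- blend_weight
  assert(w >= 0 && w <= 1, "blend_weight must lie in [0,1]")
  meta <- list(blend_weight = w, tune = tune, n_genotyped = length(gids))
  if (length(gids) == 0L) return(new_relmatrix(unclass(A), "H", meta))

  gi <- match(gids, ids); ni <- setdiff(seq_along(ids), gi)
  A22 <- A[gi, gi, drop = FALSE]
  Gm <- unclass(G)[gids, gids, drop = FALSE]
  if (tune) {
    md_A <- mean(diag(A22)); md_G <- mean(diag(Gm))
    off <- function(M) if (nrow(M) > 1) mean(M[lower.tri(M)]) else 0
    mo_A <- off(A22); mo_G <- off(Gm)
    beta <- if (abs(md_G - mo_G) > 1e-12) (md_A - mo_A) / (md_G - mo_G) else 1
    alpha <- md_A - beta * md_G
    Gm <- alpha + beta * Gm
    meta$tune_alpha <- alpha; meta$tune_beta <- beta
  }
  Gb <- (1 - w) * Gm + w * A22

  if (length(ni) == 0L) {
    H <- Gb
    dimnames(H) <- list(ids[gi], ids[gi])
    return(new_relmatrix(H[ids, ids, drop = FALSE], "H", meta))
  }

  A22i_ok <- tryCatch(solve(A22), error = function(e) NULL)
  if (is.null(A22i_ok))
    stop_bg("A22 is singular; use blend_weight > 0 or prune duplicated genotyped lines")
  A12 <- A[ni, gi, drop = FALSE]
  T12 <- A12 %*% A22i_ok                       # A12 A22^-1
  H <- unclass(A)
  H[ni, gi] <- T12 %*% Gb
  H[gi, ni] <- t(H[ni, gi, drop = FALSE])
  H[ni, ni] <- A[ni, ni, drop = FALSE] + T12 %*% (Gb - A22) %*% t(T12)
  H[gi, gi] <- Gb
  H <- (H + t(H)) / 2
  new_relmatrix(H, "H", meta)
}
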