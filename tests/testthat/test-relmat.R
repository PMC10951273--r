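# Relationship matrices: QC filters, tabular-method A, VanRaden G, and the
# single-step H with its degenerate limits.

test_that("genotype QC drops monomorphic, low-MAF and high-missingness markers", {
  raw <- cbind(m1 = c(0, 0, 0, 0, 0),    # monomorphic
               m2 = c(2, NA, NA, 0, 1),  # 40% missing
               m3 = c(0, 1, 0, 0, 0),    # MAF 0.10
               m4 = c(2, 1, 0, 1, 2))    # MAF 0.40, clean
  rownames(raw) <- letters[1:5]
  g <- qc_genotypes(raw, maf_min = 0.05, miss_max = 0.10)
  expect_identical(colnames(g$dosage), c("m3", "m4"))  # hand count
  g2 <- qc_genotypes(raw, maf_min = 0.15, miss_max = 0.10)
  expect_identical(colnames(g2$dosage), "m4")
  expect_error(qc_genotypes(raw[, 1, drop = FALSE]), class = "breedgain_empty_panel")
  # mean imputation at 2p, raw retained
  gi <- qc_genotypes(raw, maf_min = 0.05, miss_max = 0.5)
  expect_true(anyNA(gi$dosage))
  expect_false(anyNA(gi$imputed))
  expect_equal(unname(gi$imputed[2, "m2"]), 2 * mean(c(2, 0, 1)) / 2)
})

test_that("A matrix reproduces textbook relationship values", {
  A0 <- amatrix(pedigree(data.frame(id = c("X", "Y"), sire = NA, dam = NA,
                                    birth_year = 1)))
  expect_equal(unclass(A0), diag(2), ignore_attr = TRUE)

  A <- amatrix(nuclear_pedigree())
  expect_equal(A["A", "C"], 0.5)       # parent-offspring
  expect_equal(A["C", "D"], 0.5)       # full sibs
  expect_equal(A["S", "S"], 1.5)       # selfed offspring, F = 0.5
  expect_equal(A["E", "E"], 1.25)      # full-sib mating, F = 0.25
  expect_equal(unclass(A), t(unclass(A)))
  ev <- eigen(unclass(A), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
})

test_that("non-inbred pedigrees have unit A diagonal", {
  # two generations from disjoint founder pairs: nobody can be inbred
  ped <- pedigree(data.frame(
    id = c(paste0("F", 1:6), "o1", "o2", "o3", "g1"),
    sire = c(rep(NA, 6), "F1", "F3", "F5", "o1"),
    dam = c(rep(NA, 6), "F2", "F4", "F6", "o2"),
    birth_year = c(rep(1, 6), 2, 2, 2, 3)))
  A <- amatrix(ped)
  expect_true(all(diag(A) == 1))
  expect_equal(A["g1", "o1"], 0.5)
  expect_equal(A["g1", "F1"], 0.25)  # grandparent
})

test_that("cyclic pedigrees are rejected naming the cycle", {
  df <- data.frame(id = c("a", "b"), sire = c("b", "a"), dam = NA, birth_year = 1)
  err <- tryCatch(pedigree(df), error = identity)
  expect_s3_class(err, "breedgain_cycle_error")
  expect_match(conditionMessage(err), "a")
})

test_that("G matrix centering and scaling behave as VanRaden method 1", {
  raw <- rbind(i1 = c(0, 1, 2, 1), i2 = c(0, 1, 2, 1), i3 = c(2, 1, 0, 1))
  colnames(raw) <- paste0("m", 1:4)
  G <- gmatrix(qc_genotypes(raw, 0, 1))
  # identical rows: equal diagonals and off-diagonal equal to that diagonal
  expect_equal(G["i1", "i1"], G["i2", "i2"])
  expect_equal(G["i1", "i2"], G["i1", "i1"])
  # an individual whose dosages equal 2p everywhere has zero relationships
  raw2 <- rbind(a = c(0, 2), b = c(2, 0), c = c(1, 1))
  G2 <- gmatrix(qc_genotypes(raw2, 0, 1))
  expect_equal(unname(G2["c", ]), rep(0, 3))
  # fixed panel is refused
  expect_error(gmatrix(qc_genotypes(rbind(c(2, 2), c(2, 2)), 0, 1)),
               class = "breedgain_empty_panel")
})

test_that("simulated full sibs average a genomic relationship near 0.5", {
  # 20 independent 3-progeny families against a 160-founder reference panel,
  # so family members barely perturb the allele-frequency estimates
  m <- 400
  map <- toy_map(m, spacing = 0.5)
  cfg <- sim_config(n_founders = 160, n_markers = m, n_chrom = 1, seed = 6)
  fo <- simulate_founders(cfg, map)
  sibs <- list()
  for (fam in 1:20) {
    p1 <- parent_phase(fo$haplotypes, sprintf("I%05d", 2 * fam - 1))
    p2 <- parent_phase(fo$haplotypes, sprintf("I%05d", 2 * fam))
    pr <- simulate_cross(p1, p2, map, n_progeny = 3, seed = fam)
    rownames(pr) <- sprintf("fam%02d_s%d", fam, 1:3)
    sibs[[fam]] <- pr
  }
  panel <- rbind(dosages(fo$haplotypes), do.call(rbind, sibs))
  G <- gmatrix(qc_genotypes(panel, 0.01, 1))
  vals <- unlist(lapply(sibs, function(pr) {
    g <- G[rownames(pr), rownames(pr)]
    g[upper.tri(g)]
  }))
  expect_lt(abs(mean(vals) - 0.5), 3 * sd(vals) / sqrt(length(vals)) + 0.05)
})

test_that("H collapses to A with no genotypes and to G with all genotyped", {
  ped <- nuclear_pedigree()
  A <- amatrix(ped)
  raw <- matrix(rbinom(6 * 40, 2, 0.4), 6, dimnames = list(ped$id, paste0("m", 1:40)))
  G <- gmatrix(qc_genotypes(raw, 0, 1))
  H_all <- hmatrix(A, G, blend_weight = 0, tune = FALSE)
  expect_equal(unclass(H_all)[ped$id, ped$id], unclass(G)[ped$id, ped$id],
               tolerance = 1e-12)
  H_none <- hmatrix(A, G[integer(0), integer(0)], blend_weight = 0.05)
  expect_equal(unclass(H_none), unclass(A), ignore_attr = TRUE)
  expect_identical(attr(H_all, "kind"), "H")
})

test_that("H matches the long-hand single-step block formula", {
  ped <- nuclear_pedigree()
  A <- amatrix(ped)
  gids <- c("C", "D")
  Gm <- matrix(c(1.12, 0.43, 0.43, 0.97), 2, dimnames = list(gids, gids))
  G <- structure(Gm, class = c("relmatrix", "matrix"), kind = "G")
  H <- hmatrix(A, G, blend_weight = 0.05, tune = FALSE)
  # independent evaluation from the joint-distribution form
  gi <- match(gids, rownames(A)); ni <- setdiff(seq_len(6), gi)
  A22 <- unclass(A)[gi, gi]; A12 <- unclass(A)[ni, gi]; A11 <- unclass(A)[ni, ni]
  Gb <- 0.95 * Gm + 0.05 * A22
  A22i <- solve(A22)
  T12 <- A12 %*% A22i
  H11 <- A11 - T12 %*% t(A12) + T12 %*% Gb %*% t(T12)
  H12 <- T12 %*% Gb
  expect_equal(unclass(H)[ni, ni], H11, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(H)[ni, gi], H12, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(H)[gi, gi], Gb, tolerance = 1e-10, ignore_attr = TRUE)
  # w = 1 restores A22 in the genotyped block
  H1 <- hmatrix(A, structure(Gm, class = c("relmatrix", "matrix"), kind = "G"),
                blend_weight = 1, tune = FALSE)
  expect_equal(unclass(H1)[gi, gi], A22, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("tuning matches G's mean diagonal and off-diagonal to A22", {
  pr <- small_program(seed = 4)
  ped <- pr$pedigree
  A <- amatrix(ped)
  gids <- ped$id[ped$birth_year >= 1990][1:40]
  G <- gmatrix(qc_genotypes(dosages(pr$haplotypes)[gids, ], 0.05, 1))
  H <- hmatrix(A, G, blend_weight = 0, tune = TRUE)
  A22 <- unclass(A)[gids, gids]
  H22 <- unclass(H)[gids, gids]
  off <- function(M) mean(M[lower.tri(M)])
  expect_equal(mean(diag(H22)), mean(diag(A22)), tolerance = 1e-8)
  expect_equal(off(H22), off(A22), tolerance = 1e-8)
})
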