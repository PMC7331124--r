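test_that("pedigree A reproduces textbook relationships", {
  # two founders
  A0 <- build_pedigree_A(pedigree(c("f1", "f2"), c(NA, NA), c(NA, NA)))
  expect_equal(unclass(A0), diag(2), ignore_attr = TRUE)

  # sire-offspring with unknown dam
  A1 <- build_pedigree_A(pedigree(c("s", "o"), c(NA, "s"), c(NA, NA)))
  expect_equal(A1["s", "o"], 0.5)
  expect_equal(A1["o", "o"], 1.0)

  # offspring of half sibs is inbred: diagonal 1.125
  ped <- pedigree(c("s", "d1", "d2", "h1", "h2", "o"),
                  c(NA, NA, NA, "s", "s", "h1"),
                  c(NA, NA, NA, "d1", "d2", "h2"))
  A <- build_pedigree_A(ped)
  expect_equal(A["o", "o"], 1.125)

  expect_error(pedigree(c("a", "b"), c("b", "a"), c(NA, NA)), "cycle")
})

test_that("tabular A equals the recursive coancestry oracle", {
  set.seed(40)
  for (rep in 1:3) {
    n <- 25
    sire <- dam <- rep(NA_character_, n)
    for (i in 6:n) {
      sire[i] <- as.character(sample(max(1, i - 10):(i - 1), 1))
      dam[i] <- as.character(sample(max(1, i - 10):(i - 1), 1))
      if (dam[i] == sire[i]) dam[i] <- NA
    }
    ped <- pedigree(as.character(1:n), sire, dam)
    A <- build_pedigree_A(ped)
    expect_equal(unclass(A), kinship_oracle(ped), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("the genomic relationship matrix follows its defining formula", {
  # all animals sharing one genotype vector
  g0 <- matrix(rep(c(0L, 1L, 2L, 1L, 0L), each = 4), 4)
  # make one SNP differ so not everything is monomorphic
  g0[1, 1] <- 2L
  G <- suppressMessages(build_grm(genotype_matrix(g0)))
  p <- colMeans(g0) / 2
  poly <- p > 0 & p < 1
  Z <- sweep(g0[, poly, drop = FALSE], 2, 2 * p[poly])
  expect_equal(unclass(G), tcrossprod(Z) / (2 * sum(p[poly] * (1 - p[poly]))),
               ignore_attr = TRUE, tolerance = 1e-12)

  # simulated unrelated HWE genotypes: mean diagonal near 1
  set.seed(41)
  gm <- genotype_matrix(matrix(rbinom(200 * 5000, 2, runif(5000, 0.1, 0.9)),
                               200, byrow = TRUE))
  G2 <- build_grm(gm)
  expect_lt(abs(mean(diag(G2)) - 1), 0.05)
  # PSD within roundoff
  expect_gt(min(eigen(unclass(G2), symmetric = TRUE,
                      only.values = TRUE)$values), -1e-8)

  expect_error(build_grm(genotype_matrix(matrix(2L, 5, 4))), "monomorphic")
})

test_that("design matrices follow the treatment-constraint scheme", {
  df <- data.frame(animal_id = sprintf("a%d", 1:8),
                   HY = rep(c("h1", "h2"), 4),
                   BM = rep(c("b1", "b2"), each = 4),
                   PN = "p1", LW = seq(100, 135, 5))
  dsg <- build_design(df, trait_model_spec())
  # first factor keeps both levels; single-level PN contributes nothing
  expect_true(all(c("HY:h1", "HY:h2", "BM:b2", "LW") %in% colnames(dsg$X)))
  expect_false("BM:b1" %in% colnames(dsg$X))
  expect_false(any(grepl("^PN:", colnames(dsg$X))))
  # covariate column is untouched (no silent standardization)
  expect_equal(dsg$X[, "LW"], df$LW, ignore_attr = TRUE)
  # single level per factor reduces to intercept + covariate
  df1 <- df; df1$HY <- "h"; df1$BM <- "b"
  dsg1 <- build_design(df1)
  expect_equal(ncol(dsg1$X), 2L)
  expect_equal(unname(dsg1$X[, 1]), rep(1, 8))

  df2 <- df; df2$BM <- df2$HY   # fully confounded factors
  expect_error(build_design(df2), "confounded")
  df3 <- df; df3$LW[2] <- NA
  expect_error(build_design(df3), "missing")
})

test_that("solve_mme matches the GLS oracle and its limits", {
  set.seed(42)
  n <- 15
  ped <- pedigree(as.character(1:n),
                  c(rep(NA, 5), as.character(sample(1:3, n - 5, TRUE))),
                  c(rep(NA, 5), as.character(sample(4:5, n - 5, TRUE))))
  K <- build_pedigree_A(ped)
  df <- data.frame(animal_id = ped$animal,
                   HY = sample(c("x", "y"), n, TRUE),
                   BM = sample(c("m", "n"), n, TRUE),
                   PN = sample(c("1", "2"), n, TRUE),
                   LW = rnorm(n, 120, 5))
  dsg <- build_design(df)
  y <- rnorm(n)
  s2a <- 0.4; s2e <- 0.6
  fit <- solve_mme(y, dsg, K, s2a, s2e)
  expect_lt(fit$mme_relative_residual, 1e-10)

  ids <- ped$animal
  Km <- unclass(K)[ids, ids]
  V <- s2a * Km + s2e * diag(n)
  Vi <- solve(V)
  X <- dsg$X
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2a * Km %*% Vi %*% (y - X %*% b)
  expect_lt(max(abs(fit$b - b)), 1e-6)
  expect_lt(max(abs(fit$u[ids] - u)), 1e-6)

  # vanishing genetic variance shrinks every EBV to zero
  fit0 <- solve_mme(y, dsg, K, 1e-10, 1)
  expect_lt(max(abs(fit0$u)), 1e-6)

  # K = I, intercept-only: EBV equals the univariate shrinkage formula
  KI <- relationship_matrix(diag(n))
  rownames(KI) <- colnames(KI) <- df$animal_id
  dfi <- df; dfi$HY <- "h"; dfi$BM <- "b"; dfi$PN <- "p"; dfi$LW <- 0
  dsgi <- build_design(dfi, trait_model_spec(covariate = NULL))
  fitI <- solve_mme(y, dsgi, KI, 0.5, 0.5)
  lambda <- 0.5 / 0.5
  expect_lt(max(abs(fitI$u[df$animal_id] -
                    (y - fitI$b[1]) / (1 + lambda))), 1e-8)
})

test_that("masked animals receive predictions through relationships only", {
  set.seed(43)
  cfg <- small_cfg(seed = 5)
  sim <- simulate_pedigree_genotypes(cfg)
  ids <- sim$phenotyped[1:60]
  A <- build_pedigree_A(sim$pedigree)
  Ks <- relationship_matrix(unclass(A)[ids, ids])
  y <- rnorm(60)
  y[1:10] <- NA
  df <- data.frame(animal_id = ids, HY = "h", BM = "b", PN = "p",
                   LW = rnorm(60, 120, 5))
  dsg <- build_design(df)
  fit <- solve_mme(y, dsg, Ks, 0.5, 0.5)
  expect_all_finite(fit$u)
  # masked full siblings of recorded animals get non-trivial GEBV
  expect_gt(max(abs(fit$u[ids[1:10]])), 0)
})

test_that("REML finds the truth on average and flags null signal", {
  set.seed(44)
  cfg <- sim_config(seed = 50, n_animals = 300, n_snps = 10,
                    n_founders = 60, n_gen = 2, n_sires = 8, n_dams = 25)
  sim <- simulate_pedigree_genotypes(cfg)
  ids <- sim$phenotyped
  A <- build_pedigree_A(sim$pedigree)
  Ks <- relationship_matrix(unclass(A)[ids, ids])
  L <- chol(unclass(Ks) + diag(1e-9, length(ids)))
  X <- matrix(1, length(ids), 1)
  est <- replicate(12, {
    a <- as.numeric(t(L) %*% rnorm(length(ids))) * sqrt(0.5)
    y <- 3 + a + rnorm(length(ids), 0, sqrt(0.5))
    reml_estimate(y, X, Ks)$h2
  })
  expect_lt(abs(mean(est) - 0.5), 0.08)

  # no genetic signal: boundary estimate, flagged
  y0 <- rnorm(length(ids))
  vc0 <- reml_estimate(y0, X, Ks)
  expect_lt(vc0$h2, 0.15)

  # estimates invariant to animal reordering
  a <- as.numeric(t(L) %*% rnorm(length(ids))) * sqrt(0.5)
  y <- a + rnorm(length(ids), 0, sqrt(0.5))
  vc1 <- reml_estimate(y, X, Ks)
  perm <- sample(length(ids))
  Kp <- relationship_matrix(unclass(Ks)[perm, perm])
  vc2 <- reml_estimate(y[perm], X, Kp)
  expect_equal(vc1$h2, vc2$h2, tolerance = 1e-6)
  expect_true(is.finite(vc1$h2_se) && vc1$h2_se > 0)
})

test_that("pairwise multi-trait REML agrees with univariate on diagonal truth", {
  set.seed(45)
  n <- 250
  gm <- genotype_matrix(matrix(rbinom(n * 2000, 2, 0.4), n,
                               dimnames = list(sprintf("i%03d", 1:n), NULL)))
  K <- build_grm(gm)
  L <- chol(unclass(K) + diag(1e-6, n))
  Y <- sapply(c(0.3, 0.7), function(h2) {
    a <- as.numeric(t(L) %*% rnorm(n)) * sqrt(h2)
    a + rnorm(n, 0, sqrt(1 - h2))
  })
  X <- matrix(1, n, 1)
  vc <- reml_estimate(Y, X, K)
  u1 <- reml_estimate(Y[, 1], X, K)
  u2 <- reml_estimate(Y[, 2], X, K)
  expect_equal(vc$h2, c(u1$h2, u2$h2), tolerance = 1e-8)
  # independent traits: estimated genetic correlation near zero
  rg <- vc$G_cov[1, 2] / sqrt(vc$G_cov[1, 1] * vc$G_cov[2, 2])
  expect_lt(abs(rg), 0.5)
  expect_equal(vc$P_cov, vc$G_cov + vc$R_cov)
})

test_that("GP^-1 eigenanalysis handles canonical cases", {
  set.seed(46)
  P <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  ge <- genetic_eigen(0.3 * P, P)
  expect_equal(ge$values, rep(0.3, 5), tolerance = 1e-10)

  G <- diag(c(0.7, 0.2, 0.5))
  ge2 <- genetic_eigen(G, diag(3))
  expect_equal(ge2$values, c(0.7, 0.5, 0.2))
  # eigenvectors are coordinate axes with the +1 normalization
  expect_equal(abs(ge2$vectors), diag(3)[, c(1, 3, 2)], tolerance = 1e-12)
  expect_equal(max(ge2$vectors), 1)

  # G "below" P gives eigenvalues in [0, 1]
  for (r in 1:5) {
    B <- matrix(rnorm(16), 4)
    E <- crossprod(matrix(rnorm(16), 4)) + 0.5 * diag(4)
    Gc <- crossprod(B)
    ge3 <- genetic_eigen(Gc, Gc + E)
    expect_true(all(ge3$values > -1e-10 & ge3$values < 1 + 1e-10))
  }
  expect_error(genetic_eigen(diag(2), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("aggregate heritability is the explained-variance-weighted sum", {
  expect_equal(aggregate_heritability(c(0.5, 0.3), c(0, 0)), 0)
  expect_equal(aggregate_heritability(c(0.5, 0.3), c(1, 1)), 0.8)
  expect_error(aggregate_heritability(1:3 / 10, 1:2 / 10), "length")
})

test_that("pedigree CSV round-trips with 0 for unknown parents", {
  ped <- pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
  f <- tempfile(fileext = ".csv")
  write_pedigree(ped, f)
  p2 <- read_pedigree(f)
  expect_equal(as.data.frame(p2), as.data.frame(ped))
})

test_that("genotype readers parse raw, VCF and CSV formats identically", {
  counts <- matrix(c(0L, 1L, 2L, 1L, 2L, 0L), 2,
                   dimnames = list(c("id1", "id2"), NULL))
  # PLINK .raw-style
  fr <- tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE snp1_A snp2_A snp3_A",
               "f1 id1 0 0 1 -9 0 2 2",
               "f2 id2 0 0 1 -9 1 1 0"), fr)
  g1 <- read_genotypes(fr)
  expect_equal(unclass(g1), counts, ignore_attr = TRUE)
  expect_equal(rownames(g1), c("id1", "id2"))

  # VCF with GT field; counts are of the reference allele
  fv <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="G">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "id1", "id2", sep = "\t"),
               paste("1", "100", "snp1", "A", "G", ".", ".", ".", "GT",
                     "1/1", "0/1", sep = "\t"),
               paste("1", "200", "snp2", "C", "T", ".", ".", ".", "GT",
                     "0/0", "0|1", sep = "\t"),
               paste("1", "300", "snp3", "G", "A", ".", ".", ".", "GT",
                     "0/0", "1/1", sep = "\t")), fv)
  g2 <- read_genotypes(fv)
  expect_equal(unclass(g2), counts, ignore_attr = TRUE)

  # CSV allele-count table
  fc <- tempfile(fileext = ".csv")
  writeLines(c("animal_id,snp1,snp2,snp3", "id1,0,2,2", "id2,1,1,0"), fc)
  expect_equal(unclass(read_genotypes(fc)), counts, ignore_attr = TRUE)
})

test_that("variance-component and MME solution files are complete", {
  set.seed(47)
  n <- 60
  gm <- genotype_matrix(matrix(rbinom(n * 500, 2, 0.4), n,
                               dimnames = list(sprintf("w%02d", 1:n), NULL)))
  K <- build_grm(gm)
  df <- data.frame(animal_id = rownames(gm),
                   HY = sample(c("h1", "h2"), n, TRUE),
                   BM = sample(c("b1", "b2"), n, TRUE),
                   PN = "p", LW = rnorm(n, 120, 5))
  dsg <- build_design(df)
  L <- chol(unclass(K) + diag(1e-6, n))
  y <- as.numeric(t(L) %*% rnorm(n)) * sqrt(0.5) + rnorm(n, 0, sqrt(0.5))
  vc <- reml_estimate(y, dsg, K)
  ge <- genetic_eigen(vc$G_cov, vc$P_cov)
  pre <- tempfile()
  write_variance_components(vc, pre, eigen = ge)
  cv <- read.csv(paste0(pre, "_covariances.csv"))
  expect_setequal(unique(cv$component), c("genetic", "residual",
                                          "phenotypic"))
  h2f <- read.csv(paste0(pre, "_h2.csv"))
  expect_equal(h2f$h2, vc$h2, tolerance = 1e-12)
  expect_true(file.exists(paste0(pre, "_eigen.csv")))

  fit <- solve_mme(y, dsg, K, vc$G_cov[1, 1], vc$R_cov[1, 1])
  write_mme_fit(fit, pre)
  fx <- read.csv(paste0(pre, "_fixed.csv"))
  expect_equal(nrow(fx), length(fit$b))
  expect_true(all(fx$n_obs[!is.na(fx$level)] >= 1))
  ebv <- read.csv(paste0(pre, "_ebv.csv"))
  expect_equal(nrow(ebv), n)
})
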