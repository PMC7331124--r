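# shared miniature genetic-prediction setup built in code
pred_setup <- function(seed = 60, n = 80) {
  set.seed(seed)
  gm <- genotype_matrix(matrix(rbinom(n * 800, 2, 0.4), n,
                               dimnames = list(sprintf("v%03d", 1:n), NULL)))
  K <- build_grm(gm)
  df <- data.frame(animal_id = rownames(gm),
                   HY = sample(c("h1", "h2", "h3"), n, TRUE),
                   BM = sample(c("b1", "b2"), n, TRUE),
                   PN = sample(c("p1", "p2"), n, TRUE),
                   LW = rnorm(n, 122.8, 5.2))
  dsg <- build_design(df)
  L <- chol(unclass(K) + diag(1e-6, n))
  a <- as.numeric(t(L) %*% rnorm(n)) * sqrt(0.6)
  y <- 2 + 0.3 * (df$LW - mean(df$LW)) + a + rnorm(n, 0, sqrt(0.4))
  list(K = K, df = df, dsg = dsg, y = y)
}

test_that("the validation filter enforces minimum level support", {
  s <- pred_setup()
  # make one herd-year level rare among training records
  rec <- s$dsg$record_levels
  training <- rep(TRUE, nrow(s$df))
  rare_lv <- rec$HY[1]
  training[rec$HY == rare_lv] <- FALSE
  training[which(rec$HY == rare_lv)[1:3]] <- TRUE  # 3 training obs only
  vid <- s$df$animal_id[which(rec$HY == rare_lv)[4]]
  training[s$df$animal_id == vid] <- FALSE

  filt <- filter_validation(s$dsg, training, vid, min_obs = 4)
  expect_equal(filt$excluded, vid)
  expect_match(filt$reasons[[vid]], "HY")

  # well-supported animals are retained; min_obs = 0 retains everyone
  ok_id <- s$df$animal_id[which(rec$HY != rare_lv)[1]]
  expect_equal(filter_validation(s$dsg, training, ok_id, 4)$retained, ok_id)
  expect_equal(filter_validation(s$dsg, training, vid, 0)$retained, vid)
})

test_that("score predictions add GEBV to fixed-effect solutions", {
  s <- pred_setup()
  y <- s$y
  vids <- s$df$animal_id[1:8]
  y[1:8] <- NA
  fit <- solve_mme(y, s$dsg, s$K, 0.6, 0.4)
  ps <- predict_scores(list(fit), s$dsg, vids, include_gebv = TRUE)
  ps_fe <- predict_scores(list(fit), s$dsg, vids, include_gebv = FALSE)
  expect_equal(ps - ps_fe, matrix(fit$u[vids], ncol = 1),
               ignore_attr = TRUE)
  # fixed-effects-only prediction is the design row times the BLUE
  expect_equal(as.numeric(ps_fe),
               as.numeric(s$dsg$X[1:8, ] %*% fit$b))
  # linear in LW with slope beta-hat
  expect_equal(ps_fe[2] - ps_fe[1],
               sum((s$dsg$X[2, ] - s$dsg$X[1, ]) * fit$b))
  expect_error(predict_scores(list(fit), s$dsg, "nope"), "no design record")
})

test_that("a validation clone of a training animal predicts its fitted value", {
  set.seed(61)
  n <- 12
  gm <- matrix(rbinom(n * 600, 2, 0.4), n)
  gm <- rbind(gm, gm[1, ])   # animal 13 is a genotypic clone of animal 1
  rownames(gm) <- sprintf("c%02d", 1:(n + 1))
  K <- build_grm(genotype_matrix(gm))
  df <- data.frame(animal_id = rownames(gm),
                   HY = c(rep(c("h1", "h2"), 6), "h1"),
                   BM = "b", PN = "p", LW = c(rnorm(n, 120, 5), 0))
  df$LW[n + 1] <- df$LW[1]   # identical covariate too
  dsg <- build_design(df, trait_model_spec(fixed = "HY"))
  y <- c(rnorm(n), NA)       # clone is masked
  fit <- solve_mme(y, dsg, K, 0.6, 0.4)
  pred <- predict_scores(list(fit), dsg, "c13")
  fitted1 <- sum(dsg$X[1, ] * fit$b) + fit$u["c01"]
  expect_equal(as.numeric(pred), as.numeric(fitted1), tolerance = 1e-6)
})

test_that("mean error curves behave at their limits", {
  ms_seed <- 62
  set.seed(ms_seed)
  K <- 15
  W <- qr.Q(qr(matrix(rnorm(3 * K * 3), 3 * K, 3)))
  s <- matrix(rnorm(20 * 3), 20) %*% diag(c(6, 3, 1))
  X <- matrix(rnorm(3 * K, sd = 4), 20, 3 * K, byrow = TRUE) + s %*% t(W)
  sm <- shape_matrix(X, sprintf("m%02d", 1:20))
  pca <- fit_pca(sm)
  npc <- ncol(pca$loadings)

  # perfect scores: error 0 at full k, non-increasing in k
  mec <- mean_error_curve(sm, pca, pca$scores, k_max = npc)
  expect_lt(mec$mean[npc + 1], 1e-8)
  expect_true(all(diff(mec$mean) <= 1e-10))

  # k = 0 equals the mean distance to the training mean shape
  d0 <- scapmorph:::node_mean_error(X, matrix(pca$mean, 20, 3 * K,
                                              byrow = TRUE))
  expect_equal(unname(mec$per_animal[, 1]), unname(d0))
})

test_that("spatial reliability is calibrated and matches a per-node loop", {
  set.seed(63)
  K <- 12; M <- 9
  X <- matrix(rnorm(M * 3 * K, sd = 2), M)
  mu <- colMeans(X) + rnorm(3 * K, 0, 0.5)
  # perfect prediction
  expect_equal(spatial_reliability(X, X, mu), rep(1, K))
  # mean-shape prediction
  Xmu <- matrix(mu, M, 3 * K, byrow = TRUE)
  expect_equal(spatial_reliability(X, Xmu, mu), rep(0, K),
               tolerance = 1e-12)
  # anti-correlated predictions are worse than the mean: R2 < 0
  Xanti <- Xmu + (Xmu - X)
  expect_true(all(spatial_reliability(X, Xanti, mu) < 0))

  # independent per-node loop oracle
  Xhat <- X + matrix(rnorm(M * 3 * K, 0, 1), M)
  r2 <- spatial_reliability(X, Xhat, mu)
  oracle <- numeric(K)
  for (k in seq_len(K)) {
    cols <- (3 * (k - 1) + 1):(3 * k)
    num <- mean(rowSums((X[, cols] - Xhat[, cols])^2))
    den <- mean(rowSums((X[, cols] - matrix(mu[cols], M, 3,
                                            byrow = TRUE))^2))
    oracle[k] <- 1 - num / den
  }
  expect_equal(r2, oracle, tolerance = 1e-10)

  # zero denominator reported as NA with a warning
  Xc <- matrix(rep(mu, each = 2), 2)
  expect_warning(r2c <- spatial_reliability(Xc, Xc + 0.1, mu), "undefined")
  expect_true(all(is.na(r2c)))
})

test_that("isonormals point outward with unit length", {
  # voxelized ball: node normals should be near-radial
  cl <- threshold_bone(ball_volume(6))
  sm <- extract_surface(prune_long_edges(delaunay_tets(cl, "generic"), 5))
  nn <- isonormal_field(sm)
  expect_equal(rowSums(nn^2), rep(1, nrow(nn)), tolerance = 1e-8)
  ctr <- colMeans(sm$nodes)
  rad <- sweep(sm$nodes, 2, ctr)
  rad <- rad / sqrt(rowSums(rad^2))
  ang <- acos(pmin(pmax(rowSums(nn * rad), -1), 1)) * 180 / pi
  expect_lt(stats::quantile(ang, 0.95), 25)
  expect_lt(median(ang), 5)

  # flat plate: normals along +-z
  plate <- surface_mesh(cbind(expand.grid(x = 0:2, y = 0:2), z = 0),
                        rbind(c(1, 2, 4), c(2, 5, 4), c(2, 3, 5),
                              c(3, 6, 5), c(4, 5, 7), c(5, 8, 7),
                              c(5, 6, 8), c(6, 9, 8)))
  nnp <- isonormal_field(plate)
  expect_equal(abs(nnp[, 3]), rep(1, 9), tolerance = 1e-12)
})

test_that("loading heatmaps are the normal-projected mode field", {
  set.seed(64)
  cl <- threshold_bone(ball_volume(5))
  sm <- extract_surface(prune_long_edges(delaunay_tets(cl, "generic"), 5))
  nn <- isonormal_field(sm)
  K <- nrow(nn)
  # loading equal to the normal field: scalar 1 everywhere
  f1 <- loading_heatmap(as.vector(t(nn)), nn)
  expect_equal(f1$values, rep(1, K), tolerance = 1e-10)
  # orthogonal loading: 0 everywhere
  tang <- cbind(-nn[, 2], nn[, 1], 0)
  f0 <- loading_heatmap(as.vector(t(tang)), nn)
  expect_lt(max(abs(f0$values)), 1e-10)
  # linearity under negation
  w <- rnorm(3 * K)
  expect_equal(loading_heatmap(-w, nn)$values,
               -loading_heatmap(w, nn)$values)
  expect_error(loading_heatmap(w[-1], nn), "3 x node count")
})

test_that("prediction reports are written completely", {
  set.seed(65)
  K <- 6; M <- 4
  X <- matrix(rnorm(M * 3 * K), M, dimnames = list(sprintf("r%d", 1:M), NULL))
  sm <- shape_matrix(X)
  pca <- fit_pca(sm)
  mec <- mean_error_curve(sm, pca, pca$scores, k_max = 2)
  r2 <- rep(0.5, K)
  pre <- tempfile()
  write_prediction_report(mec, r2, pre)
  err <- read.csv(paste0(pre, "_errors.csv"))
  expect_equal(nrow(err), M * 3)
  rel <- read.csv(paste0(pre, "_reliability.csv"))
  expect_equal(rel$r2, r2)
})
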