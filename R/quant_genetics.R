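#' Pedigree constructor
#'
#' @param animal,sire,dam character/integer vectors; `"0"`, `""` or `NA`
#'   denote an unknown parent. Every parent that appears must either have its
#'   own record or is added as a founder.
#' @return A data frame of class `pedigree` with character columns
#'   `animal`, `sire`, `dam`, topologically sorted (parents before
#'   offspring). A cycle raises an error naming the animals involved.
#' @export
pedigree <- function(animal, sire, dam) {
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0" | x == ""] <- NA_character_
    x
  }
  animal <- norm(animal); sire <- norm(sire); dam <- norm(dam)
  if (anyDuplicated(animal)) stop("duplicated animal ids in pedigree")
  parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(parents) > 0) {
    animal <- c(parents, animal)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  n <- length(animal)
  si <- match(sire, animal); di <- match(dam, animal)
  # Kahn topological sort
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) for (p in c(si[i], di[i])) if (!is.na(p)) {
    indeg[i] <- indeg[i] + 1L
    kids[[p]] <- c(kids[[p]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) != n)
    stop("pedigree contains a cycle involving: ",
         paste(animal[setdiff(seq_len(n), ord)], collapse = ", "))
  out <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A by the standard
#' tabular recursion over a topologically sorted pedigree: diagonal
#' `1 + 0.5 * A[sire, dam]` (inbreeding included), off-diagonal
#' `0.5 * (A[j, sire] + A[j, dam])`. Unknown parents are unrelated founders.
#'
#' @param ped a [pedigree()].
#' @return A `relationship_matrix` of kind `"pedigree_A"` with animal ids as
#'   dimnames.
#' @export
build_pedigree_A <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped$animal, ped$sire, ped$dam)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal); di <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[prev, s] else 0
      ad_ <- if (!is.na(d)) A[prev, d] else 0
      A[prev, i] <- A[i, prev] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  relationship_matrix(A, kind = "pedigree_A")
}

#' Relationship matrix container
#' @param mat square symmetric matrix with animal-id dimnames.
#' @param kind `"pedigree_A"` or `"genomic_G"`.
#' @return An object of class `relationship_matrix` (a matrix).
#' @export
relationship_matrix <- function(mat, kind = c("pedigree_A", "genomic_G")) {
  kind <- match.arg(kind)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("matrix must be square")
  if (max(abs(mat - t(mat))) > 1e-10) stop("matrix must be symmetric")
  if (is.null(rownames(mat)))
    dimnames(mat) <- list(as.character(seq_len(nrow(mat))),
                          as.character(seq_len(nrow(mat))))
  structure(mat, class = c("relationship_matrix", "matrix"), kind = kind)
}

#' Genotype matrix container
#' @param counts animals x SNPs matrix of first-allele counts in `{0, 1, 2}`,
#'   with animal-id rownames.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(counts %in% c(0L, 1L, 2L))) stop("allele counts must be 0, 1 or 2")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- as.character(seq_len(nrow(counts)))
  structure(counts, class = c("genotype_matrix", "matrix"))
}

#' Genomic relationship matrix (VanRaden)
#'
#' `G = Z Z' / (2 * sum p_j (1 - p_j))` with `Z_ij = I_ij - 2 p_j`, where
#' `I_ij` is animal i's count of the first allele at SNP j and `p_j` the
#' frequency of that allele computed from all supplied animals. Monomorphic
#' SNPs carry no relationship information and are dropped (count reported via
#' a message).
#'
#' @param g a [genotype_matrix()].
#' @return A `relationship_matrix` of kind `"genomic_G"` (positive
#'   semi-definite by construction).
#' @export
build_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic")
  if (any(!poly))
    message(sum(!poly), " monomorphic SNP(s) dropped")
  Z <- sweep(g[, poly, drop = FALSE], 2, 2 * p[poly])
  G <- tcrossprod(Z) / (2 * sum(p[poly] * (1 - p[poly])))
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(g), rownames(g))
  relationship_matrix(G, kind = "genomic_G")
}

#' Fixed-effect structure of the animal model
#'
#' The score of animal m for trait n is modelled as
#' `s = HY + BM + PN + beta * LW + a + e`: herd-year of birth, birth month
#' and parity number of the dam as categorical fixed effects, live weight at
#' scanning as a fixed covariate, an additive genetic animal effect with a
#' pedigree or genomic relationship matrix, and a residual.
#'
#' @param fixed character vector of factor column names (first factor keeps
#'   all its levels, later factors drop their first level: treatment
#'   constraints).
#' @param covariate name of the numeric covariate column (or `NULL`).
#' @return An object of class `trait_model_spec`.
#' @export
trait_model_spec <- function(fixed = c("HY", "BM", "PN"), covariate = "LW") {
  structure(list(fixed = fixed, covariate = covariate),
            class = "trait_model_spec")
}

#' Build design structures for the animal model
#'
#' Returns the fixed-effect incidence matrix (identifiability by treatment
#' constraints: the first factor keeps all levels, every later factor drops
#' its first level), the covariate column unscaled, the animal-to-record map
#' and per-level observation counts (used by the validation filter).
#'
#' @param phenotypes data frame with one row per record: `animal_id`, the
#'   factor columns and the covariate named in `spec`.
#' @param spec a [trait_model_spec()].
#' @return A list of class `model_design`: `X`, `animal_id`, `levels` (list
#'   of level vectors per factor), `level_counts`, `term_map` (data frame
#'   mapping X columns to factor/level), `spec`.
#' @export
build_design <- function(phenotypes, spec = trait_model_spec()) {
  stopifnot(is.data.frame(phenotypes), inherits(spec, "trait_model_spec"))
  if (!"animal_id" %in% names(phenotypes)) stop("phenotypes needs animal_id")
  for (f in spec$fixed)
    if (!f %in% names(phenotypes)) stop("missing fixed-effect column ", f)
  if (anyNA(phenotypes[, c(spec$fixed, spec$covariate)]))
    stop("missing fixed-effect levels or covariate values")
  n <- nrow(phenotypes)
  Xs <- list(); term_map <- list(); levels_list <- list(); counts <- list()
  for (k in seq_along(spec$fixed)) {
    f <- spec$fixed[k]
    v <- factor(as.character(phenotypes[[f]]))
    levs <- levels(v)
    levels_list[[f]] <- levs
    counts[[f]] <- table(v)
    keep <- if (k == 1L) levs else levs[-1]
    if (length(keep) == 0L) next   # single-level later factor: no columns
    M <- matrix(0, n, length(keep),
                dimnames = list(NULL, paste0(f, ":", keep)))
    hit <- as.character(v) %in% keep
    M[cbind(which(hit), match(as.character(v)[hit], keep))] <- 1
    Xs[[f]] <- M
    term_map[[f]] <- data.frame(term = f, level = keep)
  }
  X <- do.call(cbind, Xs)
  if (!is.null(spec$covariate)) {
    cv <- as.numeric(phenotypes[[spec$covariate]])
    X <- cbind(X, cv)
    colnames(X)[ncol(X)] <- spec$covariate
    term_map[[spec$covariate]] <-
      data.frame(term = spec$covariate, level = NA_character_)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed effects; confounded columns: ",
         paste(drop, collapse = ", "))
  }
  rec_levels <- as.data.frame(lapply(phenotypes[spec$fixed], as.character),
                              stringsAsFactors = FALSE)
  names(rec_levels) <- spec$fixed
  structure(list(X = X, animal_id = as.character(phenotypes$animal_id),
                 levels = levels_list, level_counts = counts,
                 record_levels = rec_levels,
                 term_map = do.call(rbind, term_map), spec = spec),
            class = "model_design")
}

#' Solve Henderson's mixed-model equations
#'
#' Best linear unbiased estimates of the fixed effects and best linear
#' unbiased predictions of the additive genetic effects for a single trait,
#' given variance components. Animals present in the relationship matrix but
#' without records (e.g. masked validation animals, non-phenotyped ancestors)
#' receive predictions through their relationships alone.
#'
#' @param y numeric response, one value per design row; `NA` rows are
#'   dropped (masked records).
#' @param design a [build_design()] result.
#' @param K a [relationship_matrix()] covering at least all recorded animals.
#' @param sigma2_a,sigma2_e additive genetic and residual variances.
#' @return An object of class `mme_fit`: `b` (named BLUE vector), `u` (named
#'   BLUP/(G)EBV vector over all animals in `K`), `level_counts`,
#'   `sigma2_a`, `sigma2_e` and the `design` spec needed for prediction.
#' @export
solve_mme <- function(y, design, K, sigma2_a, sigma2_e) {
  stopifnot(inherits(design, "model_design"),
            inherits(K, "relationship_matrix"))
  if (sigma2_a < 0 || sigma2_e <= 0) stop("invalid variance components")
  obs <- which(!is.na(y))
  X <- design$X[obs, , drop = FALSE]
  yy <- y[obs]
  ids <- rownames(K)
  ai <- match(design$animal_id[obs], ids)
  if (anyNA(ai)) stop("recorded animal missing from relationship matrix")
  nK <- nrow(K)
  Z <- matrix(0, length(obs), nK)
  Z[cbind(seq_along(obs), ai)] <- 1
  # Henderson's equations premultiplied by K in the random block:
  # [X'X  X'Z; K Z'X  K Z'Z + alpha I] [b; u] = [X'y; K Z'y].
  # Equivalent to the classical K^-1 form for invertible K, but needs no
  # inverse and remains exact for the singular G of sample-frequency GRMs
  # (the solution u lies in the range of K, pinning the GEBV sum).
  Km <- unclass(K)
  alpha <- sigma2_e / max(sigma2_a, 1e-12)
  KZt <- Km %*% t(Z)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(KZt %*% X, KZt %*% Z + diag(alpha, nK)))
  rhs <- c(crossprod(X, yy), KZt %*% yy)
  sol <- solve(C, rhs)
  p <- ncol(X)
  b <- sol[seq_len(p)]; names(b) <- colnames(design$X)
  u <- sol[-seq_len(p)]; names(u) <- ids
  res <- C %*% sol - rhs
  structure(list(b = b, u = u, level_counts = design$level_counts,
                 sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 design = design, K_ids = ids,
                 mme_relative_residual =
                   sqrt(sum(res^2)) / max(sqrt(sum(rhs^2)), 1e-300)),
            class = "mme_fit")
}

#' @export
print.mme_fit <- function(x, ...) {
  cat(sprintf("<mme_fit> %d fixed effects, %d animals, h2 used %.3f\n",
              length(x$b), length(x$u),
              x$sigma2_a / (x$sigma2_a + x$sigma2_e)))
  invisible(x)
}

#' Multi-trait BLUP as per-trait univariate solves
#'
#' Solves the mixed-model equations trait by trait with each trait's own
#' variance components. With every trait recorded on the same animals and
#' the modest genetic correlations typical of principal-component traits,
#' per-trait solves give the multi-trait predictions up to the (small)
#' information exchange through genetic covariances.
#'
#' @param Y records x traits matrix (NA = masked).
#' @param design a [build_design()] result.
#' @param K a [relationship_matrix()].
#' @param vc a `variance_components` object from [reml_estimate()].
#' @return List of [solve_mme()] fits, one per trait.
#' @export
solve_mme_multi <- function(Y, design, K, vc) {
  Y <- as.matrix(Y)
  lapply(seq_len(ncol(Y)), function(tr)
    solve_mme(Y[, tr], design, K, sigma2_a = vc$G_cov[tr, tr],
              sigma2_e = vc$R_cov[tr, tr]))
}

# Rotated univariate REML machinery: with K = U D U' and at most one record
# per animal, V = sigma2_a * D + sigma2_e * I is diagonal after rotation,
# and the residual variance profiles out in closed form given the ratio
# gamma = sigma2_a / sigma2_e.
reml_profile_loglik <- function(log_gamma, d, yt, Xt, h2_penalty = 0) {
  gamma <- exp(log_gamma)
  wv <- 1 / (gamma * d + 1)
  XtW <- Xt * wv
  XWX <- crossprod(XtW, Xt)
  XWy <- crossprod(XtW, yt)
  ch <- tryCatch(chol(XWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  b <- backsolve(ch, forwardsolve(t(ch), XWy))
  r <- yt - Xt %*% b
  n <- length(yt); p <- ncol(Xt)
  s2e <- sum(wv * r^2) / (n - p)
  ll <- -0.5 * (sum(log(gamma * d + 1)) + (n - p) * log(s2e) +
                2 * sum(log(diag(ch))) + (n - p))
  if (h2_penalty > 0) {
    h2 <- gamma / (1 + gamma)
    ll <- ll + h2_penalty * (log(h2) + log(1 - h2))
  }
  ll
}

reml_univariate <- function(y, X, K, h2_penalty = 0) {
  obs <- which(!is.na(y))
  if (length(obs) < ncol(X) + 2) stop("too few records for REML")
  Ko <- K[obs, obs, drop = FALSE]
  e <- eigen(Ko, symmetric = TRUE)
  d <- pmax(e$values, 0)
  yt <- as.numeric(crossprod(e$vectors, y[obs]))
  Xt <- crossprod(e$vectors, X[obs, , drop = FALSE])
  opt <- optimize(reml_profile_loglik, interval = c(-14, 14), d = d,
                  yt = yt, Xt = Xt, h2_penalty = h2_penalty,
                  maximum = TRUE, tol = 1e-10)
  gamma <- exp(opt$maximum)
  boundary <- opt$maximum < -13 || opt$maximum > 13
  wv <- 1 / (gamma * d + 1)
  XtW <- Xt * wv
  XWX <- crossprod(XtW, Xt)
  b <- solve(XWX, crossprod(XtW, yt))
  r <- as.numeric(yt - Xt %*% b)
  n <- length(yt); p <- ncol(Xt)
  s2e <- sum(wv * r^2) / (n - p)
  s2a <- max(gamma * s2e, 1e-10)
  # average-information matrix on (sigma2_a, sigma2_e) at the optimum
  v <- s2a * d + s2e
  Py <- {
    Vy <- yt / v; VX <- Xt / v
    Vy - VX %*% solve(crossprod(Xt, VX), crossprod(VX, yt))
  }
  Pfun <- function(x) {
    Vx <- x / v; VX <- Xt / v
    Vx - VX %*% solve(crossprod(Xt, VX), crossprod(VX, x))
  }
  PdPy <- Pfun(d * Py)
  PPy <- Pfun(as.numeric(Py))
  AI <- 0.5 * matrix(c(sum((d * Py) * PdPy), sum((d * Py) * PPy),
                       sum((d * Py) * PPy), sum(Py * PPy)), 2, 2)
  cov_theta <- tryCatch(solve(AI), error = function(e) matrix(NA, 2, 2))
  h2 <- s2a / (s2a + s2e)
  gr <- c(s2e, -s2a) / (s2a + s2e)^2
  h2_se <- sqrt(max(as.numeric(t(gr) %*% cov_theta %*% gr), 0))
  list(sigma2_a = s2a, sigma2_e = s2e, h2 = h2, h2_se = h2_se,
       beta = as.numeric(b), loglik = opt$objective, boundary = boundary,
       cov_theta = cov_theta)
}

# Bivariate REML log-likelihood for a trait pair with variances fixed;
# parameters are the genetic and residual correlations (Fisher-z scale).
bireml_loglik <- function(par, d, Y2, Xt, va, ve) {
  ra <- tanh(par[1]); re <- tanh(par[2])
  ca <- ra * sqrt(va[1] * va[2]); ce <- re * sqrt(ve[1] * ve[2])
  a11 <- va[1] * d + ve[1]; a22 <- va[2] * d + ve[2]
  a12 <- ca * d + ce
  det_i <- a11 * a22 - a12^2
  if (any(det_i <= 0)) return(-Inf)
  w11 <- a22 / det_i; w22 <- a11 / det_i; w12 <- -a12 / det_i
  y1 <- Y2[, 1]; y2 <- Y2[, 2]
  S11 <- crossprod(Xt * w11, Xt); S22 <- crossprod(Xt * w22, Xt)
  S12 <- crossprod(Xt * w12, Xt)
  S <- rbind(cbind(S11, S12), cbind(S12, S22))
  rhs <- c(crossprod(Xt, w11 * y1 + w12 * y2),
           crossprod(Xt, w12 * y1 + w22 * y2))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  b <- backsolve(ch, forwardsolve(t(ch), rhs))
  quad <- sum(w11 * y1^2 + 2 * w12 * y1 * y2 + w22 * y2^2) - sum(b * rhs)
  -0.5 * (sum(log(det_i)) + 2 * sum(log(diag(ch))) + quad)
}

#' REML variance components for principal-component traits
#'
#' Single-trait components are estimated by restricted maximum likelihood
#' using an exact one-dimensional profile over the variance ratio after
#' eigen-rotation of the relationship matrix (the residual variance has a
#' closed form given the ratio, so the profile search is globally robust);
#' standard errors come from the inverse average-information matrix at the
#' optimum and heritability SEs by the delta method. For multiple traits the
#' genetic and residual covariances are estimated pairwise by bivariate REML
#' with the variances held at their univariate estimates.
#'
#' @param Y numeric vector or records x traits matrix (NA = masked record).
#' @param design a [build_design()] result (or a plain design matrix).
#' @param K a [relationship_matrix()] covering the recorded animals.
#' @param h2_penalty weight of an optional weakly-informative Beta-type
#'   penalty `h2_penalty * (log h2 + log(1 - h2))` added to the restricted
#'   likelihood. The default 0 is plain REML; a value of 1 (a Beta(2, 2)
#'   prior on heritability) pulls boundary estimates off 0 and 1 and is
#'   recommended when training sets are small enough for REML to hit the
#'   boundary spuriously, where unpenalized components produce overdispersed
#'   breeding values.
#' @return An object of class `variance_components`: `G_cov`, `R_cov`,
#'   `P_cov` (= `G_cov + R_cov`), `h2`, `h2_se`, `beta` (per-trait BLUE at
#'   the optimum), `boundary` flags and per-trait log-likelihoods.
#' @export
reml_estimate <- function(Y, design, K, h2_penalty = 0) {
  stopifnot(inherits(K, "relationship_matrix"))
  X <- if (inherits(design, "model_design")) design$X else as.matrix(design)
  ids <- if (inherits(design, "model_design")) design$animal_id else NULL
  Y <- as.matrix(Y)
  Tn <- ncol(Y)
  # records must map 1:1 onto K rows for the rotation trick
  Kuse <- if (!is.null(ids)) {
    ai <- match(ids, rownames(K))
    if (anyNA(ai)) stop("recorded animal missing from relationship matrix")
    if (anyDuplicated(ai[!is.na(Y[, 1])]))
      stop("repeated records per animal are not supported")
    unclass(K)[ai, ai, drop = FALSE]
  } else unclass(K)
  uni <- lapply(seq_len(Tn), function(tr)
    reml_univariate(Y[, tr], X, Kuse, h2_penalty = h2_penalty))
  G <- diag(vapply(uni, `[[`, 0, "sigma2_a"), Tn)
  R <- diag(vapply(uni, `[[`, 0, "sigma2_e"), Tn)
  if (Tn > 1) {
    obs <- which(stats::complete.cases(Y))
    Ko <- Kuse[obs, obs, drop = FALSE]
    e <- eigen(Ko, symmetric = TRUE)
    d <- pmax(e$values, 0)
    Xt <- crossprod(e$vectors, X[obs, , drop = FALSE])
    Yt <- crossprod(e$vectors, Y[obs, , drop = FALSE])
    for (s in seq_len(Tn - 1)) for (t in (s + 1):Tn) {
      opt <- optim(c(0, 0), bireml_loglik, d = d,
                   Y2 = Yt[, c(s, t)], Xt = Xt,
                   va = c(G[s, s], G[t, t]), ve = c(R[s, s], R[t, t]),
                   control = list(fnscale = -1, reltol = 1e-10))
      G[s, t] <- G[t, s] <- tanh(opt$par[1]) * sqrt(G[s, s] * G[t, t])
      R[s, t] <- R[t, s] <- tanh(opt$par[2]) * sqrt(R[s, s] * R[t, t])
    }
  }
  h2 <- vapply(uni, `[[`, 0, "h2")
  structure(list(G_cov = G, R_cov = R, P_cov = G + R, h2 = h2,
                 h2_se = vapply(uni, `[[`, 0, "h2_se"),
                 beta = lapply(uni, function(u) {
                   b <- u$beta; names(b) <- colnames(X); b
                 }),
                 boundary = vapply(uni, `[[`, TRUE, "boundary"),
                 loglik = vapply(uni, `[[`, 0, "loglik")),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> %d trait(s); h2: %s\n",
              length(x$h2), paste(sprintf("%.3f", x$h2), collapse = " ")))
  invisible(x)
}

#' Genetically uncorrelated trait combinations (GP^-1 eigenanalysis)
#'
#' Eigen-decomposition of `G %*% solve(P)` computed through the symmetric
#' similarity `L^-1 G L^-T` with `L` the lower Cholesky factor of `P`, which
#' guarantees real eigenvalues. The eigenvalue attached to each combination
#' acts as its heritability; the leading eigenvector is the direction of
#' trait space with the strongest genetic determination.
#'
#' @param G_cov genetic covariance matrix (T x T).
#' @param P_cov phenotypic covariance matrix, positive definite.
#' @return List with `values` (descending) and `vectors` (columns, in
#'   PC-trait coordinates, each scaled so its largest-magnitude entry is +1).
#' @export
genetic_eigen <- function(G_cov, P_cov) {
  G_cov <- as.matrix(G_cov); P_cov <- as.matrix(P_cov)
  ch <- tryCatch(chol(P_cov), error = function(e)
    stop("P_cov must be positive definite"))
  L <- t(ch)
  Msym <- forwardsolve(L, t(forwardsolve(L, t(G_cov))))
  Msym <- (Msym + t(Msym)) / 2
  e <- eigen(Msym, symmetric = TRUE)
  V <- backsolve(ch, e$vectors)
  for (j in seq_len(ncol(V)))
    V[, j] <- V[, j] / V[which.max(abs(V[, j])), j]
  list(values = e$values, vectors = V)
}

#' Aggregate heritability of the observed shape
#'
#' The explained-variance-weighted sum of per-component heritabilities,
#' `sum_n explained_n * h2_n`: a lower-bound summary of how heritable the
#' whole observed shape is, since variance beyond the retained components may
#' also have a genetic component.
#'
#' @param explained per-component explained-variance fractions.
#' @param h2 per-component heritabilities, same length.
#' @return Scalar aggregate heritability.
#' @export
aggregate_heritability <- function(explained, h2) {
  if (length(explained) != length(h2))
    stop("explained and h2 must have equal length")
  sum(explained * h2)
}

#' Published genetic parameters of the ten PC scapula-shape traits
#'
#' The reference table of explained-variance fractions, heritabilities (with
#' SE) and live-weight regression coefficients reported for the first ten
#' principal components of pig scapula shape; used by the worked example of
#' [aggregate_heritability()].
#'
#' @return Data frame with columns `pc`, `exp_var`, `h2`, `se`, `beta`.
#' @export
pc_genetic_parameters <- function() {
  read.csv(system.file("extdata", "pc_genetic_parameters.csv",
                       package = "scapmorph"))
}

#' Pedigree CSV IO (`animal,sire,dam`, "0" = unknown)
#' @param path CSV path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- read.csv(path, colClasses = "character")
  pedigree(df$animal, df$sire, df$dam)
}

#' @rdname read_pedigree
#' @param ped a [pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- "0"
  df$dam[is.na(df$dam)] <- "0"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
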