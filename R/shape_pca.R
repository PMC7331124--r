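#' Shape matrix: flattened landmark coordinates per animal
#'
#' Rows are animals, columns the 3K flattened coordinates (x1, y1, z1, x2,
#' ...) of K corresponded landmarks in mm. Column order is the atlas order
#' and defines phenotype identity.
#'
#' @param values M x 3K numeric matrix, no missing values.
#' @param animals character vector of M animal ids.
#' @return An object of class `shape_matrix`.
#' @export
shape_matrix <- function(values, animals = rownames(values)) {
  values <- as.matrix(values); storage.mode(values) <- "double"
  if (is.null(animals)) animals <- as.character(seq_len(nrow(values)))
  animals <- as.character(animals)
  if (length(animals) != nrow(values)) stop("one id per row required")
  if (anyDuplicated(animals)) stop("animal ids must be unique")
  if (ncol(values) %% 3L != 0L) stop("column count must be a multiple of 3")
  if (any(!is.finite(values))) stop("shape matrix must be complete and finite")
  rownames(values) <- animals
  structure(list(animals = animals, values = values), class = "shape_matrix")
}

#' Assemble a shape matrix from landmark sets
#' @param sets list of [landmark_set()] objects sharing the atlas ordering.
#' @return A [shape_matrix()] (coordinates flattened x1,y1,z1,x2,...).
#' @export
shape_matrix_from_sets <- function(sets) {
  vals <- t(vapply(sets, function(s) as.vector(t(s$coords)),
                   numeric(3L * nrow(sets[[1]]$coords))))
  shape_matrix(vals, animals = vapply(sets, `[[`, "", "animal_id"))
}

#' @export
print.shape_matrix <- function(x, ...) {
  cat(sprintf("<shape_matrix> %d animals x %d coordinates (%d landmarks)\n",
              nrow(x$values), ncol(x$values), ncol(x$values) %/% 3L))
  invisible(x)
}

#' Flag whole-animal outliers by the interquartile-range rule
#'
#' For each animal the absolute deviations from the population column means
#' are summed over all 3K coordinates; animals whose sum falls more than 1.5
#' interquartile ranges below the first quartile or above the third quartile
#' of that distribution are flagged. Registration failures (wrong-side
#' correspondences, collapsed landmarks) inflate the sum and are caught here
#' before any model sees the data.
#'
#' @param data a [shape_matrix()] with at least 4 animals.
#' @param k fence multiplier (1.5 by convention).
#' @return Character vector of flagged animal ids.
#' @export
flag_outliers <- function(data, k = 1.5) {
  stopifnot(inherits(data, "shape_matrix"))
  X <- data$values
  if (nrow(X) < 4L) stop("need at least 4 animals")
  S <- rowSums(abs(sweep(X, 2, colMeans(X))))
  q <- quantile(S, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  data$animals[S < q[1] - k * iqr | S > q[2] + k * iqr]
}

#' Principal-component shape model
#'
#' Covariance PCA of the flattened landmark coordinates: the mean shape and
#' the loadings are computed from the training animals only (any ids in
#' `mask` are held out as a validation set and merely projected), so masked
#' animals provably do not influence the model. Coordinates share units (mm),
#' so variables are not standardized. Each loading's sign is fixed so its
#' largest-magnitude entry is positive, making scores reproducible across
#' linear-algebra backends.
#'
#' Every shape decomposes as `X_m = mean + sum_n w_n s_nm`; truncating the
#' sum at the first few components gives the scalar phenotypes used in the
#' genetic analysis.
#'
#' @param data a [shape_matrix()].
#' @param mask character vector of validation animal ids excluded from
#'   fitting (default none).
#' @param n_components components to retain; default all available
#'   (`min(M_train - 1, 3K)`).
#' @return An object of class `shape_pca`: `mean` (3K), `loadings`
#'   (3K x n), `scores` (M x n, all animals), `explained` (fractions of the
#'   training variance), `animals`, `training` (logical per animal).
#' @export
fit_pca <- function(data, mask = character(0), n_components = NULL) {
  stopifnot(inherits(data, "shape_matrix"))
  X <- data$values
  training <- !(data$animals %in% mask)
  if (sum(training) < 2L) stop("need at least 2 training animals")
  Xt <- X[training, , drop = FALSE]
  mu <- colMeans(Xt)
  Xc <- sweep(Xt, 2, mu)
  total_var <- sum(Xc^2) / (nrow(Xc) - 1)
  if (total_var <= 0) stop("zero-variance data")
  sv <- svd(Xc)
  navail <- sum(sv$d > sv$d[1] * 1e-12)
  n <- if (is.null(n_components)) navail else min(n_components, navail)
  W <- sv$v[, seq_len(n), drop = FALSE]
  # sign canonicalization: largest-|entry| of each loading positive
  for (j in seq_len(n)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  ev <- sv$d[seq_len(n)]^2 / (nrow(Xc) - 1)
  scores <- sweep(X, 2, mu) %*% W
  colnames(scores) <- paste0("pc", seq_len(n))
  structure(list(mean = mu, loadings = W, scores = scores,
                 explained = ev / total_var, animals = data$animals,
                 training = training),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("<shape_pca> %d components, %d/%d training animals\n",
              ncol(x$loadings), sum(x$training), length(x$animals)))
  cat("  explained (first 5):",
      paste(sprintf("%.3f", head(x$explained, 5)), collapse = " "), "\n")
  invisible(x)
}

#' Reconstruct shapes from component scores
#'
#' `mean + sum_{n <= n_components} w_n s_n`; zero components returns the mean
#' shape, all components a full reconstruction.
#'
#' @param model a [fit_pca()] model.
#' @param scores numeric vector (one animal) or matrix (animals x
#'   components).
#' @param n_components number of leading components to use.
#' @return Matrix of reconstructed flattened coordinates (animals x 3K).
#' @export
reconstruct <- function(model, scores, n_components = ncol(model$loadings)) {
  stopifnot(inherits(model, "shape_pca"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (n_components > ncol(model$loadings))
    stop("n_components exceeds available components")
  if (ncol(scores) < n_components)
    stop("score length mismatch: need at least n_components values")
  out <- matrix(model$mean, nrow(scores), length(model$mean), byrow = TRUE)
  if (n_components > 0)
    out <- out + scores[, seq_len(n_components), drop = FALSE] %*%
      t(model$loadings[, seq_len(n_components), drop = FALSE])
  out
}

#' Landmark-space truncation error of the shape model
#'
#' For each animal, the mean over landmarks of the Euclidean distance between
#' the true 3D landmark positions and their reconstruction from the first
#' `k` component scores; quantifies the information lost by summarizing 3K
#' coordinates with k scalar phenotypes.
#'
#' @param model a [fit_pca()] model.
#' @param data the [shape_matrix()] the model was fitted to.
#' @param k number of components used in the reconstruction.
#' @return List with `per_animal` (named numeric, mm) and `grand_mean` (mm).
#' @export
truncation_error <- function(model, data, k) {
  stopifnot(inherits(model, "shape_pca"), inherits(data, "shape_matrix"))
  if (k < 0) stop("k must be >= 0")
  sc <- model$scores[match(data$animals, model$animals), , drop = FALSE]
  rec <- reconstruct(model, sc, n_components = k)
  per <- node_mean_error(data$values, rec)
  names(per) <- data$animals
  list(per_animal = per, grand_mean = mean(per))
}

# mean over landmarks of point-wise 3D Euclidean distance between two
# flattened coordinate matrices
node_mean_error <- function(true, pred) {
  d2 <- (true - pred)^2
  K <- ncol(true) %/% 3L
  i1 <- seq(1L, 3L * K, by = 3L)
  rowMeans(sqrt(d2[, i1, drop = FALSE] + d2[, i1 + 1L, drop = FALSE] +
                d2[, i1 + 2L, drop = FALSE]))
}

#' Save / load a PCA shape model as CSV files
#'
#' Writes `<prefix>_mean.csv`, `<prefix>_loadings.csv` (3K x n),
#' `<prefix>_scores.csv` (`animal_id,pc1..pcn`) and
#' `<prefix>_explained.csv`, all round-tripping at 17 significant digits.
#'
#' @param model a [fit_pca()] model.
#' @param prefix file-path prefix.
#' @export
write_pca_model <- function(model, prefix) {
  stopifnot(inherits(model, "shape_pca"))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(c("mean", fmt(model$mean)), paste0(prefix, "_mean.csv"))
  ld <- as.data.frame(model$loadings)
  names(ld) <- paste0("pc", seq_len(ncol(ld)))
  write.csv(data.frame(lapply(ld, fmt)), paste0(prefix, "_loadings.csv"),
            row.names = FALSE, quote = FALSE)
  sc <- data.frame(animal_id = model$animals,
                   training = model$training,
                   data.frame(lapply(as.data.frame(model$scores), fmt)))
  write.csv(sc, paste0(prefix, "_scores.csv"), row.names = FALSE,
            quote = FALSE)
  writeLines(c("explained", fmt(model$explained)),
             paste0(prefix, "_explained.csv"))
  invisible(prefix)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(prefix) {
  mu <- as.numeric(readLines(paste0(prefix, "_mean.csv"))[-1])
  W <- as.matrix(read.csv(paste0(prefix, "_loadings.csv")))
  sc <- read.csv(paste0(prefix, "_scores.csv"))
  expl <- as.numeric(readLines(paste0(prefix, "_explained.csv"))[-1])
  scores <- as.matrix(sc[, grep("^pc", names(sc)), drop = FALSE])
  structure(list(mean = mu, loadings = unname(W), scores = unname(scores),
                 explained = expl, animals = as.character(sc$animal_id),
                 training = as.logical(sc$training)),
            class = "shape_pca")
}
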