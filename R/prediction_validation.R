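#' Filter validation animals by fixed-effect support
#'
#' A validation animal's score prediction borrows the BLUE of each of its
#' fixed-effect levels; levels estimated from very few training records make
#' those predictions unreliable. Animals for which any fixed-effect level has
#' fewer than `min_obs` training observations are excluded.
#'
#' @param design a [build_design()] result covering all records.
#' @param training logical vector (per design row): which records carried a
#'   phenotype during training.
#' @param validation_ids animal ids to screen.
#' @param min_obs minimum training observations per level (default 4).
#' @return List with `retained`, `excluded` and `reasons` (named character).
#' @export
filter_validation <- function(design, training, validation_ids, min_obs = 4) {
  stopifnot(inherits(design, "model_design"))
  if (length(training) != nrow(design$X))
    stop("training must have one entry per design row")
  rows <- which(training)
  rec_levels <- design$record_levels
  if (is.null(rec_levels))
    stop("design lacks record_levels; rebuild with build_design()")
  reasons <- character(0)
  retained <- character(0)
  for (id in validation_ids) {
    r <- which(design$animal_id == id)[1]
    if (is.na(r)) {
      reasons[id] <- "no record"
      next
    }
    bad <- NULL
    for (f in design$spec$fixed) {
      lev <- rec_levels[r, f]
      nobs <- sum(rec_levels[rows, f] == lev)
      if (nobs < min_obs)
        bad <- c(bad, sprintf("%s=%s (%d obs)", f, lev, nobs))
    }
    if (is.null(bad)) retained <- c(retained, id)
    else reasons[id] <- paste(bad, collapse = "; ")
  }
  list(retained = retained, excluded = names(reasons), reasons = reasons)
}

#' Predict principal-component scores for validation animals
#'
#' The genomic estimated breeding value of each validation animal is added to
#' the solutions of its fixed-effect levels,
#' `s_hat = HY + BM + PN + beta * LW + GEBV`, per trait. The
#' fixed-effects-only variant (no GEBV) is the environmental baseline against
#' which the genomic contribution is judged.
#'
#' @param fits list of [solve_mme()] fits, one per trait (e.g. from
#'   [solve_mme_multi()]).
#' @param design the [build_design()] result the fits were computed from.
#' @param animal_ids animals to predict (must appear in the design rows and
#'   in the relationship matrix).
#' @param include_gebv add the GEBV (default) or predict from fixed effects
#'   only.
#' @return Matrix of predicted scores, animals x traits.
#' @export
predict_scores <- function(fits, design, animal_ids, include_gebv = TRUE) {
  stopifnot(inherits(design, "model_design"))
  rows <- match(animal_ids, design$animal_id)
  if (anyNA(rows))
    stop("no design record for animal(s): ",
         paste(animal_ids[is.na(rows)], collapse = ", "))
  X <- design$X[rows, , drop = FALSE]
  out <- vapply(fits, function(fit) {
    fe <- as.numeric(X %*% fit$b)
    if (include_gebv) {
      ui <- match(animal_ids, fit$K_ids)
      if (anyNA(ui))
        stop("animal(s) missing from relationship matrix: ",
             paste(animal_ids[is.na(ui)], collapse = ", "))
      fe <- fe + fit$u[ui]
    }
    fe
  }, numeric(length(animal_ids)))
  out <- matrix(out, nrow = length(animal_ids))
  dimnames(out) <- list(animal_ids, paste0("pc", seq_along(fits)))
  out
}

#' Mean Euclidean node error of genomic shape predictions
#'
#' For `k = 0..k_max`, the validation shapes are reconstructed from the first
#' `k` predicted component scores (`k = 0` is the training mean shape) and
#' compared with the true landmark coordinates; the error for one animal is
#' the mean over landmarks of the 3D point-wise Euclidean distance.
#'
#' @param true_shapes [shape_matrix()] (or plain matrix) of the validation
#'   animals' true flattened coordinates, rows in `animal_ids` order.
#' @param model a [fit_pca()] model.
#' @param s_hat matrix of predicted scores (animals x >= k_max components).
#' @param k_max largest component count to evaluate.
#' @return List with `per_animal` (animals x (k_max + 1) matrix, columns
#'   `k0..k<k_max>`) and `mean` (length k_max + 1).
#' @export
mean_error_curve <- function(true_shapes, model, s_hat, k_max = 10) {
  X <- if (inherits(true_shapes, "shape_matrix")) true_shapes$values
       else as.matrix(true_shapes)
  s_hat <- as.matrix(s_hat)
  if (k_max > ncol(model$loadings))
    stop("k_max exceeds available components")
  if (ncol(s_hat) < k_max) stop("s_hat has fewer than k_max columns")
  per <- sapply(0:k_max, function(k) {
    rec <- reconstruct(model, s_hat, n_components = k)
    node_mean_error(X, rec)
  })
  per <- matrix(per, nrow = nrow(X),
                dimnames = list(rownames(X), paste0("k", 0:k_max)))
  list(per_animal = per, mean = colMeans(per))
}

#' Spatial prediction reliability per landmark
#'
#' For each landmark node,
#' `R2 = 1 - mean_m d(x_m, x_hat_m)^2 / mean_m d(x_m, x_bar)^2`
#' over the validation animals, where `x_bar` is the training mean shape at
#' that node. Perfect prediction gives 1, predicting the mean shape gives 0,
#' and predictions worse than the mean go negative (the ratio is not
#' floored). A node where all validation animals coincide with the mean
#' shape has an undefined ratio and is reported as `NA` with a warning.
#'
#' @param true_shapes,predicted_shapes matrices (animals x 3K) of flattened
#'   coordinates.
#' @param mean_shape length-3K training mean shape.
#' @return Numeric vector of per-node reliabilities (length K).
#' @export
spatial_reliability <- function(true_shapes, predicted_shapes, mean_shape) {
  X <- if (inherits(true_shapes, "shape_matrix")) true_shapes$values
       else as.matrix(true_shapes)
  Xh <- as.matrix(predicted_shapes)
  if (nrow(X) < 2) stop("need at least 2 validation animals")
  if (!all(dim(X) == dim(Xh)) || ncol(X) != length(mean_shape))
    stop("dimension mismatch")
  K <- ncol(X) %/% 3L
  i1 <- seq(1L, 3L * K, by = 3L)
  sq3 <- function(D) D[, i1, drop = FALSE]^2 + D[, i1 + 1L, drop = FALSE]^2 +
    D[, i1 + 2L, drop = FALSE]^2
  num <- colMeans(sq3(X - Xh))
  den <- colMeans(sq3(sweep(X, 2, mean_shape)))
  r2 <- 1 - num / den
  if (any(den == 0)) {
    warning(sum(den == 0), " node(s) with zero denominator; R2 undefined")
    r2[den == 0] <- NA_real_
  }
  r2
}

#' Outward unit normals at the nodes of a surface mesh
#'
#' Face normals are oriented outward by testing them against the vector from
#' the mesh centroid to the face centre; each node normal is the mean of its
#' adjacent face normals, renormalized to unit length.
#'
#' @param mesh a [surface_mesh()].
#' @return K x 3 matrix of unit normals (one row per node).
#' @export
isonormal_field <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  V <- mesh$nodes; F <- mesh$faces
  if (nrow(F) == 0L) stop("mesh has no faces")
  ctr <- colMeans(V)
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(fn^2))
  if (any(nrm == 0)) stop("degenerate face with zero area")
  fn <- fn / nrm
  fc <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
  flip <- rowSums(fn * sweep(fc, 2, ctr)) < 0
  fn[flip, ] <- -fn[flip, ]
  nn <- matrix(0, nrow(V), 3)
  cnt <- integer(nrow(V))
  for (j in 1:3) {
    for (r in seq_len(nrow(F))) {
      v <- F[r, j]
      nn[v, ] <- nn[v, ] + fn[r, ]
      cnt[v] <- cnt[v] + 1L
    }
  }
  if (any(cnt == 0)) stop("node without any adjacent face")
  len <- sqrt(rowSums(nn^2))
  if (any(len == 0)) stop("cancelled node normal (non-orientable spot)")
  nn / len
}

#' Scalar surface field of a shape mode
#'
#' The 3K loading vector of one principal component, reshaped to a per-node
#' 3-vector field and projected on the node isonormals: positive values mean
#' the component pushes the surface outward (growth perpendicular to the
#' surface), negative values inward shrinkage. This is the heatmap field
#' used to visualize what each shape mode does.
#'
#' @param loading length-3K loading vector (atlas flattening order).
#' @param normals K x 3 matrix of unit node normals from
#'   [isonormal_field()].
#' @return An object of class `scalar_surface_field`: list with `values`
#'   (length K) and `normals`.
#' @export
loading_heatmap <- function(loading, normals) {
  normals <- as.matrix(normals)
  K <- nrow(normals)
  if (length(loading) != 3L * K)
    stop("loading length must be 3 x node count")
  L <- matrix(loading, ncol = 3, byrow = TRUE)
  structure(list(values = rowSums(L * normals), normals = normals),
            class = "scalar_surface_field")
}

#' @export
print.scalar_surface_field <- function(x, ...) {
  cat(sprintf("<scalar_surface_field> %d nodes, range [%.3g, %.3g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Write a prediction report
#'
#' Emits `<prefix>_errors.csv` (`animal_id,k,error_mm`),
#' `<prefix>_reliability.csv` (`landmark_id,r2`) and, when a mesh is given,
#' `<prefix>_reliability.ply` with the reliability as a per-vertex quality
#' channel for external viewers.
#'
#' @param curve a [mean_error_curve()] result.
#' @param r2 per-node reliabilities from [spatial_reliability()].
#' @param prefix output path prefix.
#' @param mesh optional [surface_mesh()] over the same nodes.
#' @export
write_prediction_report <- function(curve, r2, prefix, mesh = NULL) {
  pa <- curve$per_animal
  df <- data.frame(animal_id = rep(rownames(pa), ncol(pa)),
                   k = rep(0:(ncol(pa) - 1), each = nrow(pa)),
                   error_mm = as.vector(pa))
  write.csv(df, paste0(prefix, "_errors.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(landmark_id = seq_along(r2), r2 = r2),
            paste0(prefix, "_reliability.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(mesh))
    write_ply(mesh, paste0(prefix, "_reliability.ply"), quality = r2)
  invisible(prefix)
}
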