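#' Coherent point drift parameters
#'
#' Defaults: no outlier mass (`w = 0`), relative objective tolerance `1e-5`,
#' at most 100 EM iterations; for the non-rigid mode a Gaussian kernel width
#' `beta = 2` and regularization `lambda = 2` (both in the normalized units
#' CPD works in internally).
#'
#' @param w outlier weight in `[0, 1)`.
#' @param tol relative change of the negative log-likelihood that stops EM.
#' @param max_iter iteration cap.
#' @param beta non-rigid Gaussian kernel width.
#' @param lambda non-rigid regularization weight.
#' @return A list of class `cpd_params`.
#' @export
cpd_params <- function(w = 0, tol = 1e-5, max_iter = 100, beta = 2,
                       lambda = 2) {
  stopifnot(w >= 0, w < 1, tol > 0, max_iter >= 1, beta > 0, lambda > 0)
  structure(list(w = w, tol = tol, max_iter = max_iter, beta = beta,
                 lambda = lambda), class = "cpd_params")
}

#' Register a point set onto another with coherent point drift
#'
#' The moving cloud `Y` is treated as the centroids of a Gaussian mixture
#' fitted to the data points `X` by expectation-maximization; at the optimum
#' the posterior matrix `P` holds, for every data point of `X` (columns), the
#' probability that each point of `Y` (rows) generated it. In the atlas
#' pipeline `X` is the sparse semi-landmark atlas and `Y` the dense surface
#' cloud of one individual, so the argmax of each column picks the surface
#' point corresponding to each atlas landmark.
#'
#' Three deformation families are supported: `rigid`
#' (rotation + isotropic scale + translation), `affine` (general linear map
#' + translation) and `nonrigid` (Gaussian-kernel displacement field with
#' motion-coherence regularization). Both clouds are standardized internally;
#' reported transforms are mapped back to the input units.
#'
#' @param X data [point_cloud()] (or an `atlas`).
#' @param Y moving [point_cloud()]; its points become GMM centroids.
#' @param mode `"affine"`, `"rigid"` or `"nonrigid"`.
#' @param params a [cpd_params()] list.
#' @return An object of class `cpd_result` with elements `mode`, `transform`
#'   (mode-specific, input units), `TY` (transformed `Y`, input units), `P`
#'   (|Y| x |X| posterior matrix), `sigma2`, `n_iter`, `converged`, `flag`
#'   and `objective_trace` (non-increasing negative log-likelihood).
#' @export
cpd_register <- function(X, Y, mode = c("affine", "rigid", "nonrigid"),
                         params = cpd_params()) {
  mode <- match.arg(mode)
  if (inherits(X, "atlas")) X <- atlas_cloud(X)
  stopifnot(inherits(X, "point_cloud"), inherits(Y, "point_cloud"))
  X0 <- X$coords; Y0 <- Y$coords
  N <- nrow(X0); M <- nrow(Y0)
  if (N < 4L) stop("X needs at least 4 points")
  if (M < 4L) stop("Y needs at least 4 points")

  # standardize both clouds (restored on output)
  mux <- colMeans(X0); muy <- colMeans(Y0)
  sx <- sqrt(mean(rowSums(sweep(X0, 2, mux)^2)))
  sy <- sqrt(mean(rowSums(sweep(Y0, 2, muy)^2)))
  if (sx == 0 || sy == 0) stop("degenerate cloud with zero spread")
  Xn <- sweep(X0, 2, mux) / sx
  Yn <- sweep(Y0, 2, muy) / sy

  D <- 3
  w <- params$w
  TY <- Yn
  sigma2 <- (N * sum(TY^2) + M * sum(Xn^2) -
             2 * sum(colSums(TY) * colSums(Xn))) / (D * M * N)

  G <- NULL; W <- NULL
  if (mode == "nonrigid") {
    d2 <- outer(rowSums(Yn^2), rep(1, M)) + outer(rep(1, M), rowSums(Yn^2)) -
      2 * Yn %*% t(Yn)
    G <- exp(-d2 / (2 * params$beta^2))
    W <- matrix(0, M, D)
  }
  B <- diag(D); s <- 1; R <- diag(D); tvec <- rep(0, D)

  trace <- numeric(0)
  E_old <- Inf
  converged <- FALSE
  flag <- NA_character_
  P <- NULL
  Xn2 <- rowSums(Xn^2)

  for (it in seq_len(params$max_iter)) {
    # E-step (length-M vector recycles down columns)
    D2 <- TY %*% (-2 * t(Xn)) + rowSums(TY^2)
    D2 <- sweep(D2, 2, Xn2, `+`)
    D2[D2 < 0] <- 0
    K <- exp(-D2 / (2 * sigma2))
    cs <- colSums(K)
    cden <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N
    denom <- cs + cden
    denom[denom < .Machine$double.xmin] <- .Machine$double.xmin
    P <- sweep(K, 2, denom, `/`)
    E <- -sum(log(denom)) + D * N * log(sigma2) / 2
    if (mode == "nonrigid")
      E <- E + params$lambda / 2 * sum(W * (G %*% W))
    trace <- c(trace, E)
    if (!is.finite(sigma2) || !is.finite(E))
      stop("numeric degeneracy in CPD (non-finite objective)")
    if (is.finite(E_old) &&
        abs(E_old - E) < params$tol * abs(E_old)) { converged <- TRUE; break }
    E_old <- E

    # M-step
    P1 <- rowSums(P)       # length M
    Pt1 <- colSums(P)      # length N
    Np <- sum(P1)
    mu_x <- colSums(Pt1 * Xn) / Np
    mu_y <- colSums(P1 * Yn) / Np
    Xh <- sweep(Xn, 2, mu_x); Yh <- sweep(Yn, 2, mu_y)
    A <- t(Xh) %*% (t(P) %*% Yh)    # D x D
    if (mode == "affine") {
      YPY <- t(Yh) %*% (P1 * Yh)
      B <- A %*% solve(YPY)
      tvec <- mu_x - B %*% mu_y
      TY <- Yn %*% t(B) + matrix(tvec, M, D, byrow = TRUE)
      sigma2 <- (sum(Pt1 * rowSums(Xh^2)) - sum(A * B)) / (Np * D)
    } else if (mode == "rigid") {
      sv <- svd(A)
      C <- diag(c(1, 1, det(sv$u %*% t(sv$v))))
      R <- sv$u %*% C %*% t(sv$v)
      s <- sum(diag(C) * sv$d) / sum(P1 * rowSums(Yh^2))
      tvec <- mu_x - s * R %*% mu_y
      TY <- s * Yn %*% t(R) + matrix(tvec, M, D, byrow = TRUE)
      sigma2 <- (sum(Pt1 * rowSums(Xh^2)) - s * sum(diag(C) * sv$d)) /
        (Np * D)
    } else {
      rhs <- P %*% Xn - P1 * Yn
      W <- solve(P1 * G + params$lambda * sigma2 * diag(M), rhs)
      TY <- Yn + G %*% W
      sigma2 <- (sum(Pt1 * Xn2) - 2 * sum((P %*% Xn) * TY) +
                 sum(P1 * rowSums(TY^2))) / (Np * D)
    }
    if (sigma2 < 1e-10) {
      sigma2 <- 1e-10
      converged <- TRUE
      flag <- "sigma2_floor"
      # final E-step so P reflects the converged transform
      D2 <- TY %*% (-2 * t(Xn)) + rowSums(TY^2)
      D2 <- sweep(D2, 2, Xn2, `+`)
      D2[D2 < 0] <- 0
      K <- exp(-D2 / (2 * sigma2))
      cs <- colSums(K)
      denom <- cs + (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N
      denom[denom < .Machine$double.xmin] <- .Machine$double.xmin
      P <- sweep(K, 2, denom, `/`)
      break
    }
  }
  if (!converged) flag <- "max_iter"

  # map transform and TY back to input units
  TY0 <- sx * TY + matrix(mux, M, D, byrow = TRUE)
  transform <- switch(mode,
    affine = {
      B0 <- (sx / sy) * B
      t0 <- sx * as.numeric(tvec) + mux - as.numeric(B0 %*% muy)
      list(A = B0, t = t0)
    },
    rigid = {
      s0 <- s * sx / sy
      t0 <- sx * as.numeric(tvec) + mux - s0 * as.numeric(R %*% muy)
      list(s = s0, R = R, t = t0)
    },
    nonrigid = list(W = W, beta = params$beta, lambda = params$lambda,
                    displacement = TY0 - Y0))

  structure(list(mode = mode, transform = transform, TY = TY0, P = P,
                 sigma2 = sigma2, n_iter = length(trace),
                 converged = converged, flag = flag,
                 objective_trace = trace,
                 params = params),
            class = "cpd_result")
}

#' @export
print.cpd_result <- function(x, ...) {
  cat(sprintf("<cpd_result> mode %s, %d iterations, sigma2 %.3g%s\n",
              x$mode, x$n_iter, x$sigma2,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Ordered landmark set for one animal
#' @param coords K x 3 matrix, ordering identical to the atlas.
#' @param animal_id identifier.
#' @param units coordinate units.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(coords, animal_id = NA_character_, units = "mm") {
  coords <- as.matrix(coords); storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  structure(list(animal_id = as.character(animal_id), coords = coords,
                 units = units),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %s: %d landmarks [%s]\n", x$animal_id,
              nrow(x$coords), x$units))
  invisible(x)
}

#' Hard (or soft) correspondence extraction from a CPD posterior
#'
#' For each atlas point (column of `P`) the most probable generating point of
#' `Y` is selected and its original, untransformed coordinate emitted, so the
#' landmark set is a subset (possibly with repeats) of the individual's
#' surface points. Ties go to the lowest `Y` index. The soft variant returns
#' the `P`-weighted average of `Y` coordinates instead.
#'
#' @param result a [cpd_register()] result.
#' @param Y the original moving [point_cloud()] used in the registration.
#' @param animal_id identifier stored in the output.
#' @param soft if `TRUE`, posterior-weighted coordinates instead of argmax.
#' @return A [landmark_set()] with one row per atlas point, plus an attribute
#'   `n_duplicates`: the number of atlas points sharing their matched surface
#'   point with another (a multi-correspondence diagnostic).
#' @export
extract_correspondence <- function(result, Y, animal_id = NA_character_,
                                   soft = FALSE) {
  stopifnot(inherits(result, "cpd_result"), inherits(Y, "point_cloud"))
  P <- result$P
  if (any(!is.finite(P))) stop("P contains non-finite entries")
  if (nrow(P) != n_points(Y))
    stop("P row count does not match Y")
  if (soft) {
    cw <- colSums(P)
    bad <- which(cw <= 0)
    if (length(bad) > 0)
      stop("correspondence failure: zero posterior mass in columns ",
           paste(head(bad, 10), collapse = ", "))
    coords <- t(t(Y$coords) %*% P) / cw
    return(landmark_set(coords, animal_id, units = Y$units))
  }
  cmax <- apply(P, 2, max)
  bad <- which(cmax <= 0)
  if (length(bad) > 0)
    stop("correspondence failure: zero posterior mass in columns ",
         paste(head(bad, 10), collapse = ", "))
  rows <- apply(P, 2, which.max)   # ties: lowest index
  out <- landmark_set(Y$coords[rows, , drop = FALSE], animal_id,
                      units = Y$units)
  attr(out, "matched_rows") <- rows
  attr(out, "n_duplicates") <- sum(duplicated(rows))
  out
}

#' Re-align landmark sets into a shared millimetre frame
#'
#' Each set is pose-normalized (centred, principal axes aligned, sign
#' convention applied) and then mapped back to millimetres by undoing the
#' scaling only, so all animals share orientation and centre while keeping
#' their individual size -- size itself is a breeding-relevant phenotype and
#' must survive into the shape matrix.
#'
#' Because all sets share the atlas point ordering, axis signs are resolved
#' against the first set's normalized configuration rather than by shape
#' moments: correspondence pins the orientation even when a shape is nearly
#' symmetric about an axis, so no animal can end up mirrored.
#'
#' @param sets list of [landmark_set()] objects with equal landmark counts.
#' @return List of re-aligned [landmark_set()] objects (mm, centred).
#' @export
realign_landmarks <- function(sets) {
  stopifnot(length(sets) > 0)
  K <- nrow(sets[[1]]$coords)
  reference <- NULL
  out <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    stopifnot(inherits(s, "landmark_set"))
    if (nrow(s$coords) != K)
      stop("landmark count mismatch for animal ", s$animal_id)
    np <- tryCatch(normalize_pose(point_cloud(s$coords, units = "mm"),
                                  reference = reference),
                   error = function(e)
                     stop("degenerate landmark set for animal ", s$animal_id,
                          ": ", conditionMessage(e)))
    if (is.null(reference)) reference <- np$cloud$coords
    out[[i]] <- landmark_set(np$cloud$coords / np$transform$scale,
                             s$animal_id, units = "mm")
  }
  out
}

#' Signed paired-distance quality control for thin bone regions
#'
#' Where the bone is thin (the scapular spine, the fossae), CPD can match an
#' atlas point to the wrong side of the surface. Given pairs of landmarks
#' that sit on opposite sides of the bone with similar coordinates along the
#' other two axes, the signed coordinate difference along the crossing axis
#' is positive for a correct match and negative when sides were swapped.
#'
#' @param set a [landmark_set()].
#' @param pairs data frame with columns `id_a`, `id_b` (landmark indices) and
#'   `axis` (`"x"`, `"y"` or `"z"`).
#' @return The input `pairs` with columns `distance` (signed, mm) and
#'   `flag_swapped`.
#' @export
paired_distance_qc <- function(set, pairs) {
  stopifnot(inherits(set, "landmark_set"), is.data.frame(pairs))
  need <- c("id_a", "id_b", "axis")
  if (!all(need %in% names(pairs))) stop("pairs needs id_a, id_b, axis")
  ax <- match(pairs$axis, c("x", "y", "z"))
  if (any(is.na(ax))) stop("axis must be x, y or z")
  K <- nrow(set$coords)
  if (any(pairs$id_a < 1 | pairs$id_a > K | pairs$id_b < 1 | pairs$id_b > K))
    stop("pair indices out of range")
  d <- set$coords[cbind(pairs$id_a, ax)] - set$coords[cbind(pairs$id_b, ax)]
  pairs$distance <- d
  pairs$flag_swapped <- d < 0
  pairs
}

#' Empirical cumulative distribution table
#'
#' Sorted `(value, fraction <= value)` pairs; the fraction at the maximum is
#' exactly 1. Used to display the distribution of paired QC distances across
#' animals.
#'
#' @param values numeric vector, non-empty.
#' @return Data frame with columns `value` and `fraction`.
#' @export
qc_ecdf <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("values must be non-empty")
  v <- sort(unique(values))
  data.frame(value = v, fraction = ecdf(values)(v))
}

#' Write a QC report as TSV (pair id, distance, flag)
#' @param qc output of [paired_distance_qc()].
#' @param path TSV path.
#' @export
write_qc_report <- function(qc, path) {
  df <- data.frame(pair_id = seq_len(nrow(qc)), distance_mm = qc$distance,
                   flag_swapped = qc$flag_swapped)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
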