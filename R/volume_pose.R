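#' Voxel volume container
#'
#' A 3D grid of CT intensities in Hounsfield units (HU) on a regular,
#' possibly anisotropic grid. World coordinates follow the voxel-centre
#' convention: the centre of voxel `(i, j, k)` (1-based) lies at
#' `origin + (c(i, j, k) - 1) * spacing` millimetres.
#'
#' @param intensities 3D numeric array of Hounsfield units.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (any(dim(intensities) < 1L))
    stop("grid dimensions must be >= 1")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers")
  structure(list(intensities = intensities, spacing = spacing,
                 origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Ordered 3D point cloud
#'
#' @param coords numeric matrix with 3 columns (x, y, z); row order is
#'   meaningful and preserved by all operations.
#' @param units `"mm"` or `"normalized"`.
#' @param grid_index optional integer matrix of voxel indices (same row count)
#'   carried along for clouds extracted from a voxel grid; enables the exact
#'   lattice triangulation path in [delaunay_tets()].
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(coords, units = c("mm", "normalized"),
                        grid_index = NULL) {
  units <- match.arg(units)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  storage.mode(coords) <- "double"
  if (nrow(coords) > 0L && any(!is.finite(coords)))
    stop("coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  obj <- structure(list(coords = coords, units = units),
                   class = "point_cloud")
  if (!is.null(grid_index)) {
    grid_index <- as.matrix(grid_index)
    storage.mode(grid_index) <- "integer"
    if (nrow(grid_index) != nrow(coords) || ncol(grid_index) != 3L)
      stop("grid_index must be an n x 3 integer matrix")
    obj$grid_index <- grid_index
  }
  obj
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points [%s]%s\n", nrow(x$coords), x$units,
              if (!is.null(x$grid_index)) " +grid" else ""))
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$coords)

#' Extract bone voxels by Hounsfield thresholding
#'
#' Returns the world-coordinate centres (mm) of all voxels whose intensity is
#' greater than or equal to `threshold`. 200 HU is the conventional cutoff
#' separating bone from soft tissue in porcine CT.
#'
#' The comparison is inclusive (`>=`). An empty result is legal (returned with
#' a warning and an `empty` attribute), e.g. for a soft-tissue-only volume.
#'
#' @param volume a [voxel_volume()].
#' @param threshold HU cutoff, default 200.
#' @return A [point_cloud()] in mm, with the voxel `grid_index` attached.
#' @export
threshold_bone <- function(volume, threshold = 200) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (any(!is.finite(volume$intensities)))
    stop("intensities contain non-finite values")
  idx <- which(volume$intensities >= threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("no voxel reaches the threshold; returning an empty cloud")
    cl <- point_cloud(matrix(numeric(0), 0, 3), units = "mm",
                      grid_index = matrix(integer(0), 0, 3))
    attr(cl, "empty") <- TRUE
    return(cl)
  }
  coords <- sweep(sweep((idx - 1), 2, volume$spacing, `*`),
                  2, volume$origin, `+`)
  point_cloud(coords, units = "mm", grid_index = idx)
}

#' Rigid-plus-scale pose transform
#'
#' Forward map (mm -> normalized): `y = scale * (x - translation) %*% rotation`,
#' where the columns of `rotation` are the principal axes. The inverse map is
#' exact, so normalization round-trips to machine precision.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector (mm): the cloud centroid.
#' @param scale positive scalar.
#' @return An object of class `pose_transform`.
#' @export
pose_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be 3x3 orthonormal")
  if (det(rotation) <= 0) stop("rotation must have determinant +1")
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 scale = as.numeric(scale)),
            class = "pose_transform")
}

#' @export
print.pose_transform <- function(x, ...) {
  cat(sprintf("<pose_transform> scale %.6g, translation (%.3g, %.3g, %.3g)\n",
              x$scale, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Normalize the pose of a point cloud
#'
#' Centres the cloud on its centroid, rotates the principal axes of its
#' covariance onto the coordinate axes (largest variance along x, second
#' along y, third along z), and rescales so that the second principal axis
#' has unit standard deviation ("second invariant" scaling: on scapula CT
#' the width axis is the best-measured dimension, so it anchors the scale).
#'
#' Axis signs are fixed deterministically: each axis is oriented so that the
#' third central moment of the projections is non-negative (falling back to a
#' non-negative first-point coordinate for symmetric clouds); if the
#' resulting frame is left-handed, the z-axis is flipped to restore
#' determinant +1.
#'
#' @param cloud a [point_cloud()] in mm with at least 4 non-coplanar points.
#' @param invariant `"eigenvalue2"` (default) scales by the inverse square
#'   root of the second covariance eigenvalue; `"inertia_I2"` scales by the
#'   fourth root of the second invariant of the covariance tensor
#'   (`l1*l2 + l1*l3 + l2*l3`).
#' @param reference optional K x 3 matrix of corresponded coordinates in an
#'   already-normalized frame (same point order as `cloud`). When given,
#'   axis signs are chosen to agree with the reference instead of the
#'   skewness rule: point-for-point correspondence pins the orientation far
#'   more reliably than third moments on near-symmetric shapes.
#' @return A list with `cloud` (normalized units) and `transform`
#'   (a [pose_transform()]).
#' @export
normalize_pose <- function(cloud, invariant = c("eigenvalue2", "inertia_I2"),
                           reference = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  invariant <- match.arg(invariant)
  if (cloud$units != "mm") stop("normalize_pose expects a cloud in mm")
  X <- cloud$coords
  if (nrow(X) < 4L) stop("need at least 4 points")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  S <- crossprod(Xc) / nrow(Xc)
  ev <- eigen(S, symmetric = TRUE)
  lambda <- ev$values
  if (lambda[3] <= max(lambda[1], 0) * 1e-10)
    stop("degenerate geometry: points are (nearly) coplanar or collinear")
  R <- ev$vectors   # columns: principal axes, eigen() sorts decreasing
  proj <- Xc %*% R
  g <- numeric(3)   # per-axis sign evidence
  for (k in 1:3) {
    g[k] <- if (is.null(reference)) mean(proj[, k]^3) / lambda[k]^1.5
            else sum(proj[, k] * reference[, k]) /
              sqrt(sum(proj[, k]^2) * max(sum(reference[, k]^2),
                                          .Machine$double.eps))
    s <- if (abs(g[k]) > 1e-12) sign(g[k])
         else if (abs(proj[1, k]) > 0) sign(proj[1, k]) else 1
    if (s < 0) R[, k] <- -R[, k]
  }
  # restore right-handedness by flipping the axis whose sign evidence is
  # weakest, so well-determined axes keep a stable orientation across
  # individuals
  if (det(R) < 0) {
    k <- which.min(abs(g))
    R[, k] <- -R[, k]
  }
  scale <- switch(invariant,
                  eigenvalue2 = 1 / sqrt(lambda[2]),
                  inertia_I2 = (lambda[1] * lambda[2] + lambda[1] * lambda[3] +
                                lambda[2] * lambda[3])^(-0.25))
  tr <- pose_transform(rotation = R, translation = ctr, scale = scale)
  out <- point_cloud(scale * (Xc %*% R), units = "normalized",
                     grid_index = cloud$grid_index)
  list(cloud = out, transform = tr)
}

#' Apply a pose transform (mm -> normalized)
#' @param cloud a [point_cloud()] in mm.
#' @param transform a [pose_transform()].
#' @return The normalized [point_cloud()].
#' @export
apply_pose <- function(cloud, transform) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(transform, "pose_transform"))
  if (cloud$units != "mm") stop("unit mismatch: expected a cloud in mm")
  Y <- transform$scale *
    (sweep(cloud$coords, 2, transform$translation) %*% transform$rotation)
  point_cloud(Y, units = "normalized", grid_index = cloud$grid_index)
}

#' Invert a pose transform (normalized -> mm)
#'
#' Maps normalized coordinates back to millimetres in the original Eulerian
#' frame, exactly undoing [normalize_pose()].
#'
#' @param cloud a [point_cloud()] in normalized units.
#' @param transform the [pose_transform()] recorded at normalization.
#' @return A [point_cloud()] in mm.
#' @export
apply_inverse <- function(cloud, transform) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(transform, "pose_transform"))
  if (cloud$units != "normalized")
    stop("unit mismatch: expected a cloud in normalized units")
  X <- sweep((cloud$coords / transform$scale) %*% t(transform$rotation),
             2, transform$translation, `+`)
  point_cloud(X, units = "mm", grid_index = cloud$grid_index)
}

#' Serialize a pose transform to a 12-number text record
#'
#' Layout: 9 rotation entries (row-major), 3 translation entries, then the
#' scale, one number per line at full precision.
#' @param transform a [pose_transform()].
#' @param path output file.
#' @export
write_pose_transform <- function(transform, path) {
  stopifnot(inherits(transform, "pose_transform"))
  vals <- c(t(transform$rotation), transform$translation, transform$scale)
  writeLines(formatC(vals, format = "g", digits = 17), path)
  invisible(path)
}

#' @rdname write_pose_transform
#' @export
read_pose_transform <- function(path) {
  vals <- as.numeric(readLines(path))
  if (length(vals) != 13L) stop("expected 13 numbers (R row-major, t, s)")
  pose_transform(rotation = matrix(vals[1:9], 3, 3, byrow = TRUE),
                 translation = vals[10:12], scale = vals[13])
}

#' Read a volume from NIfTI or plain NRRD
#'
#' NIfTI (`.nii`, `.nii.gz`) is read through RNifti; spacing comes from the
#' pixel dimensions and the origin from the stored transform's translation
#' (axis-aligned volumes assumed). NRRD support covers the plain raw/ascii
#' encodings of the detached-header-free format.
#'
#' @param path file path.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    hdr <- RNifti::niftiHeader(img)
    spacing <- abs(hdr$pixdim[2:4])
    spacing[spacing == 0] <- 1
    xf <- try(RNifti::xform(img), silent = TRUE)
    origin <- if (!inherits(xf, "try-error")) xf[1:3, 4] else c(0, 0, 0)
    voxel_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                 spacing = spacing, origin = origin)
  } else if (grepl("\\.nrrd$", path)) {
    read_nrrd(path)
  } else stop("unsupported volume format: ", path)
}

#' Write a volume as plain NRRD
#'
#' @param volume a [voxel_volume()].
#' @param path output `.nrrd` file.
#' @param encoding `"ascii"` (text, default) or `"raw"` (little-endian
#'   doubles).
#' @export
write_nrrd <- function(volume, path, encoding = c("ascii", "raw")) {
  stopifnot(inherits(volume, "voxel_volume"))
  encoding <- match.arg(encoding)
  d <- dim(volume$intensities)
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           paste("sizes:", paste(d, collapse = " ")),
           paste("spacings:", paste(volume$spacing, collapse = " ")),
           paste("axis mins:", paste(volume$origin, collapse = " ")),
           "endian: little",
           paste("encoding:", encoding),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (encoding == "ascii")
    writeLines(paste(formatC(as.vector(volume$intensities), format = "g",
                             digits = 17), collapse = " "), con)
  else
    writeBin(as.vector(volume$intensities), con, endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ": ?")[[1]]
    fields[[tolower(kv[1])]] <- kv[2]
  }
  sizes <- as.integer(strsplit(fields$sizes, " +")[[1]])
  spacing <- if (!is.null(fields$spacings))
    as.numeric(strsplit(fields$spacings, " +")[[1]]) else rep(1, 3)
  origin <- if (!is.null(fields[["axis mins"]]))
    as.numeric(strsplit(fields[["axis mins"]], " +")[[1]]) else rep(0, 3)
  enc <- fields$encoding
  n <- prod(sizes)
  vals <- if (identical(enc, "ascii")) {
    as.numeric(strsplit(paste(readLines(con), collapse = " "), "[ \t\n]+")[[1]])
  } else if (identical(enc, "raw")) {
    if (!identical(fields$type, "double"))
      stop("raw NRRD support is limited to type double")
    readBin(con, "double", n = n, endian = "little")
  } else stop("unsupported NRRD encoding: ", enc)
  vals <- vals[!is.na(vals)]
  if (length(vals) < n) stop("truncated NRRD data")
  voxel_volume(array(vals[seq_len(n)], dim = sizes), spacing = spacing,
               origin = origin)
}

#' Point-cloud CSV IO (`point_id,x_mm,y_mm,z_mm`)
#' @param cloud a [point_cloud()] in mm.
#' @param path CSV path.
#' @export
write_point_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  df <- data.frame(point_id = seq_len(n_points(cloud)),
                   x_mm = cloud$coords[, 1], y_mm = cloud$coords[, 2],
                   z_mm = cloud$coords[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  df <- read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) stop("expected columns point_id,x_mm,y_mm,z_mm")
  df <- df[order(df$point_id), , drop = FALSE]
  point_cloud(as.matrix(df[, need]), units = "mm")
}
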