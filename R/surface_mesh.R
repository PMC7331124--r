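#' Tetrahedral mesh
#' @param nodes n x 3 coordinate matrix.
#' @param tets t x 4 integer matrix of node indices (1-based); every
#'   tetrahedron is stored with positive orientation.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns")
  if (ncol(tets) != 4L) stop("tets must have 4 columns")
  if (nrow(tets) > 0L) {
    if (min(tets) < 1L || max(tets) > nrow(nodes))
      stop("tet indices out of range")
    vol <- cpp_tet_volumes(nodes, tets)
    neg <- vol < 0
    if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  }
  structure(list(nodes = nodes, tets = tets), class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tetrahedra\n",
              nrow(x$nodes), nrow(x$tets)))
  invisible(x)
}

#' Triangulated surface mesh
#' @param nodes n x 3 coordinate matrix.
#' @param faces m x 3 integer matrix of node indices (1-based).
#' @param node_map optional integer vector mapping surface nodes back to the
#'   node indices of the originating tetrahedral mesh.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(nodes, faces, node_map = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(nodes))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
      stop("degenerate face with repeated node")
  }
  structure(list(nodes = nodes, faces = faces, node_map = node_map),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d nodes, %d faces\n",
              nrow(x$nodes), nrow(x$faces)))
  invisible(x)
}

#' Delaunay tetrahedralization of a point cloud
#'
#' For clouds carrying a voxel `grid_index` (from [threshold_bone()]) the
#' triangulation is the Kuhn split of every complete 2x2x2 cell of the
#' lattice, which for a regular grid is a Delaunay triangulation of the
#' occupied region and is exact (no cospherical ambiguity). For general
#' clouds an incremental Bowyer-Watson triangulation of the convex hull is
#' computed after a deterministic relative joggle of `1e-8` that breaks
#' near-degenerate configurations; zero-volume tetrahedra are discarded.
#'
#' @param cloud a [point_cloud()] with at least 4 points.
#' @param engine `"auto"` (lattice when a grid index is present), `"lattice"`
#'   or `"generic"`.
#' @return A [tet_mesh()] over the cloud's points (node order preserved).
#' @export
delaunay_tets <- function(cloud, engine = c("auto", "lattice", "generic")) {
  stopifnot(inherits(cloud, "point_cloud"))
  engine <- match.arg(engine)
  X <- cloud$coords
  if (nrow(X) < 4L) stop("need at least 4 points")
  if (engine == "auto")
    engine <- if (!is.null(cloud$grid_index)) "lattice" else "generic"
  if (engine == "lattice") {
    if (is.null(cloud$grid_index))
      stop("lattice engine requires a grid_index")
    tets <- cpp_lattice_tets(cloud$grid_index)
    return(tet_mesh(X, tets))
  }
  # coplanarity guard
  sv <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = 0)$d
  if (sv[3] < 1e-10 * max(sv[1], .Machine$double.eps))
    stop("degenerate geometry: points are (nearly) coplanar")
  # The deterministic joggle acts as a symbolic perturbation: the
  # triangulation is that of the (imperceptibly) perturbed points, so no
  # zero-volume tetrahedra arise there and face multiplicities stay
  # consistent even for exactly cospherical inputs like voxel grids.
  tet_mesh(X, cpp_delaunay(X, 1e-8))
}

#' Remove tetrahedra with long edges (alpha-shape-style pruning)
#'
#' Retains exactly the tetrahedra whose six edges are all `<= max_edge`;
#' a tetrahedron with one or more edge strictly longer than the threshold is
#' removed. The node list is unchanged. Pruning lets the convex Delaunay
#' volume shed tetrahedra spanning concave regions of the bone.
#'
#' @param mesh a [tet_mesh()].
#' @param max_edge edge-length threshold, same units as the nodes
#'   (default 5 mm).
#' @return A [tet_mesh()] with the retained tetrahedra.
#' @export
prune_long_edges <- function(mesh, max_edge = 5) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (!is.numeric(max_edge) || length(max_edge) != 1L || is.na(max_edge) ||
      max_edge <= 0)
    stop("max_edge must be a positive number")
  if (nrow(mesh$tets) == 0L) return(mesh)
  keep <- cpp_max_edge(mesh$nodes, mesh$tets) <= max_edge
  if (!any(keep))
    warning("all tetrahedra removed by edge pruning")
  tet_mesh(mesh$nodes, mesh$tets[keep, , drop = FALSE])
}

#' Extract the boundary surface of a tetrahedral mesh
#'
#' Faces belonging to exactly one tetrahedron are the surface; interior faces
#' (shared by two) are dropped, and only nodes incident to a surface face are
#' retained. The returned mesh's `node_map` gives, for each surface node, its
#' index in the input mesh.
#'
#' @param mesh a [tet_mesh()].
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (nrow(mesh$tets) == 0L)
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                        node_map = integer(0)))
  fm <- cpp_face_multiplicity(mesh$tets)
  if (fm$max_multiplicity > 2L)
    stop("topology error: a face is shared by more than two tetrahedra")
  faces <- fm$surface_faces
  keep <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$nodes))
  remap[keep] <- seq_along(keep)
  faces <- matrix(remap[faces], ncol = 3)
  surface_mesh(mesh$nodes[keep, , drop = FALSE], faces, node_map = keep)
}

# one-ring neighbours of a node: all nodes sharing a face with it
one_ring <- function(mesh, node, node_faces = NULL) {
  f <- if (is.null(node_faces)) {
    which(mesh$faces[, 1] == node | mesh$faces[, 2] == node |
          mesh$faces[, 3] == node)
  } else node_faces[[node]]
  setdiff(unique(as.vector(mesh$faces[f, , drop = FALSE])), node)
}

# convex-hull volume of a small point set (rank < 3 -> 0)
hull_volume <- function(pts) {
  if (nrow(pts) < 4L) return(0)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], .Machine$double.eps)) return(0)
  tets <- cpp_delaunay(pts, 1e-9)
  sum(abs(cpp_tet_volumes(pts, tets)))
}

#' Local volume of a surface node
#'
#' Volume of the convex hull of a node together with its one-ring (the nodes
#' sharing a face with it). Flat neighbourhoods give volume 0; nodes in
#' highly curved regions give large volumes, so ranking nodes by local volume
#' identifies the geometrically least informative ones.
#'
#' @param node_index node index into `mesh`.
#' @param mesh a [surface_mesh()].
#' @return Volume in cubic input units (mm^3 for a mm mesh).
#' @export
local_volume <- function(node_index, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ring <- one_ring(mesh, node_index)
  if (length(ring) == 0L) stop("isolated node has no one-ring")
  if (length(ring) < 3L) stop("node has fewer than 3 one-ring neighbours")
  hull_volume(mesh$nodes[c(node_index, ring), , drop = FALSE])
}

# ordered cycle of the one-ring boundary, or NULL if not a single simple cycle
ring_cycle <- function(faces_v, node) {
  edges <- t(apply(faces_v, 1, function(f) f[f != node]))
  if (ncol(edges) != 2L) return(NULL)
  verts <- unique(as.vector(edges))
  cnt <- table(factor(as.vector(edges), levels = verts))
  if (any(cnt != 2L)) return(NULL)   # boundary or non-manifold
  adj <- lapply(verts, function(v) {
    r <- edges[, 1] == v | edges[, 2] == v
    setdiff(unique(as.vector(edges[r, , drop = FALSE])), v)
  })
  names(adj) <- as.character(verts)
  start <- verts[1]
  cyc <- c(start, adj[[as.character(start)]][1])
  while (TRUE) {
    nxt <- setdiff(adj[[as.character(cyc[length(cyc)])]],
                   cyc[length(cyc) - 1])
    if (length(nxt) != 1L) return(NULL)
    if (nxt == start) break
    cyc <- c(cyc, nxt)
    if (length(cyc) > length(verts)) return(NULL)
  }
  if (length(cyc) != length(verts)) return(NULL)  # disconnected cycles
  cyc
}

#' Sparsify a surface mesh into a semi-landmark atlas
#'
#' Greedy decimation: the node with the smallest local volume is removed, its
#' one-ring hole is re-triangulated by a fan from the hole's least-index
#' vertex, affected local volumes are recomputed, and the loop repeats until
#' no local volume is below the threshold (`mode = "volume_threshold"`) or
#' exactly `value` nodes remain (`mode = "target_count"`). Ties in the
#' minimal volume are broken by the lowest node index. Nodes whose one-ring
#' is not a single simple cycle (mesh boundary, non-manifold spots) are never
#' removed.
#'
#' The surviving nodes, in lexicographic coordinate order, constitute the
#' atlas: the ordered semi-landmark set that defines phenotype identity for
#' every animal registered against it.
#'
#' @param mesh a [surface_mesh()].
#' @param mode `"target_count"` (default) or `"volume_threshold"`.
#' @param value target landmark count, or the local-volume threshold
#'   (cubic units).
#' @return An object of class `atlas` with fields `landmarks` (K x 3 matrix,
#'   lexicographic order), `node_ids` (indices into the input mesh) and
#'   `params`.
#' @export
sparsify <- function(mesh, mode = c("target_count", "volume_threshold"),
                     value) {
  stopifnot(inherits(mesh, "surface_mesh"))
  mode <- match.arg(mode)
  if (!is.numeric(value) || length(value) != 1L || value <= 0)
    stop("value must be a positive number")
  n <- nrow(mesh$nodes)
  if (mode == "target_count") {
    value <- as.integer(value)
    if (value > n) stop("target_count exceeds node count")
  }

  faces <- mesh$faces
  alive_face <- rep(TRUE, nrow(faces))
  alive_node <- rep(TRUE, n)
  node_faces <- vector("list", n)
  for (i in seq_len(nrow(faces)))
    for (v in faces[i, ]) node_faces[[v]] <- c(node_faces[[v]], i)

  lv <- function(v) {
    fids <- node_faces[[v]]
    fids <- fids[alive_face[fids]]
    if (length(fids) == 0L) return(Inf)
    fv <- faces[fids, , drop = FALSE]
    ring <- setdiff(unique(as.vector(fv)), v)
    if (length(ring) < 3L) return(Inf)
    if (is.null(ring_cycle(fv, v))) return(Inf)
    hull_volume(mesh$nodes[c(v, ring), , drop = FALSE])
  }
  vols <- vapply(seq_len(n), lv, numeric(1))

  remaining <- n
  repeat {
    if (mode == "target_count" && remaining <= value) break
    cand <- which(alive_node & is.finite(vols))
    if (length(cand) == 0L) {
      if (mode == "target_count")
        stop("ran out of removable nodes before reaching target_count")
      break
    }
    vmin <- min(vols[cand])
    if (mode == "volume_threshold" && vmin >= value) break
    v <- cand[which(vols[cand] == vmin)][1]   # ties: lowest index

    fids <- node_faces[[v]]; fids <- fids[alive_face[fids]]
    fv <- faces[fids, , drop = FALSE]
    cyc <- ring_cycle(fv, v)
    if (is.null(cyc)) { vols[v] <- Inf; next }
    # fan from the least-index hole vertex
    r0 <- min(cyc)
    p <- which(cyc == r0)
    cyc <- c(cyc[p:length(cyc)], cyc[seq_len(p - 1)])
    newf <- cbind(r0, cyc[2:(length(cyc) - 1)], cyc[3:length(cyc)])
    alive_face[fids] <- FALSE
    fstart <- nrow(faces)
    faces <- rbind(faces, newf)
    alive_face <- c(alive_face, rep(TRUE, nrow(newf)))
    for (i in seq_len(nrow(newf)))
      for (w in newf[i, ]) node_faces[[w]] <- c(node_faces[[w]], fstart + i)
    alive_node[v] <- FALSE
    vols[v] <- Inf
    remaining <- remaining - 1L
    for (w in unique(as.vector(fv[fv != v]))) if (alive_node[w])
      vols[w] <- lv(w)
  }

  ids <- which(alive_node)
  lm <- mesh$nodes[ids, , drop = FALSE]
  ord <- order(lm[, 1], lm[, 2], lm[, 3])
  structure(list(landmarks = lm[ord, , drop = FALSE],
                 node_ids = ids[ord],
                 params = list(mode = mode, value = value)),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("<atlas> %d semi-landmarks (%s = %g)\n",
              nrow(x$landmarks), x$params$mode, x$params$value))
  invisible(x)
}

#' Coerce an atlas to a point cloud
#' @param atlas an [sparsify()] result.
#' @param units coordinate units of the atlas frame.
#' @return A [point_cloud()].
#' @export
atlas_cloud <- function(atlas, units = "normalized") {
  point_cloud(atlas$landmarks, units = units)
}

#' Landmark-to-surface fit quality
#'
#' For every dense surface point, the Euclidean distance to its nearest
#' landmark; the median and maximum summarize how well a sparse landmark set
#' represents the full surface (used to compare CPD deformation modes).
#'
#' @param landmarks a [point_cloud()] (or atlas coordinates).
#' @param dense a [point_cloud()] of the dense surface, same units.
#' @return Named numeric vector `c(median, max)` in input units.
#' @export
fit_quality <- function(landmarks, dense) {
  lm <- if (inherits(landmarks, "point_cloud")) landmarks$coords
        else as.matrix(landmarks)
  dn <- if (inherits(dense, "point_cloud")) dense$coords else as.matrix(dense)
  if (inherits(landmarks, "point_cloud") && inherits(dense, "point_cloud") &&
      landmarks$units != dense$units)
    stop("unit mismatch between landmark and dense clouds")
  if (nrow(lm) == 0L || nrow(dn) == 0L) stop("clouds must be non-empty")
  d <- RANN::nn2(lm, dn, k = 1)$nn.dists[, 1]
  c(median = median(d), max = max(d))
}

#' Write/read a surface mesh as ascii PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path `.ply` file path.
#' @param quality optional per-vertex scalar written as a `quality` property
#'   (e.g. a reliability field for external viewers).
#' @export
write_ply <- function(mesh, path, quality = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$nodes)
  if (!is.null(quality) && length(quality) != nv)
    stop("quality must have one value per vertex")
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nv),
           "property double x", "property double y", "property double z",
           if (!is.null(quality)) "property double quality",
           paste("element face", nrow(mesh$faces)),
           "property list uchar int vertex_indices",
           "end_header")
  vt <- apply(mesh$nodes, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  if (!is.null(quality))
    vt <- paste(vt, sprintf("%.17g", quality))
  fc <- apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(hdr, vt, fc), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file")
  endh <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vlines <- trimws(lines[(endh + 1):(endh + nv)])
  vm <- do.call(rbind, lapply(strsplit(vlines, " +"), as.numeric))
  flines <- if (nf > 0) lines[(endh + nv + 1):(endh + nv + nf)] else character(0)
  fm <- if (nf > 0)
    do.call(rbind, lapply(strsplit(flines, " +"),
                          function(v) as.integer(v[2:4]) + 1L))
  else matrix(integer(0), 0, 3)
  mesh <- surface_mesh(vm[, 1:3, drop = FALSE], fm)
  if (ncol(vm) >= 4) attr(mesh, "quality") <- vm[, 4]
  mesh
}

#' Write/read a surface mesh as Wavefront OBJ
#' @param mesh a [surface_mesh()].
#' @param path `.obj` file path.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- apply(mesh$nodes, 1, function(r)
    paste("v", paste(sprintf("%.17g", r), collapse = " ")))
  f <- apply(mesh$faces, 1, function(r) paste("f", paste(r, collapse = " ")))
  writeLines(c(v, f), path)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  v <- lines[startsWith(lines, "v ")]
  f <- lines[startsWith(lines, "f ")]
  vm <- do.call(rbind, lapply(strsplit(v, " +"),
                              function(x) as.numeric(x[2:4])))
  fm <- if (length(f) > 0)
    do.call(rbind, lapply(strsplit(f, " +"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
  else matrix(integer(0), 0, 3)
  surface_mesh(vm, fm)
}

#' Save an atlas as CSV plus a JSON sidecar
#'
#' The CSV has columns `landmark_id,x,y,z`; the sidecar records the pose
#' transform of the reference individual, the edge-pruning threshold and the
#' sparsification parameters so a registration run is fully reproducible.
#'
#' @param atlas an atlas from [sparsify()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param transform optional [pose_transform()] of the reference individual.
#' @param max_edge edge threshold used for the dense mesh, if known.
#' @export
write_atlas <- function(atlas, path, transform = NULL, max_edge = NULL) {
  stopifnot(inherits(atlas, "atlas"))
  df <- data.frame(landmark_id = seq_len(nrow(atlas$landmarks)),
                   x = atlas$landmarks[, 1], y = atlas$landmarks[, 2],
                   z = atlas$landmarks[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(sparsify = atlas$params, max_edge = max_edge)
  if (!is.null(transform))
    meta$pose_transform <- list(rotation = as.vector(t(transform$rotation)),
                                translation = transform$translation,
                                scale = transform$scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  df <- read.csv(path)
  df <- df[order(df$landmark_id), , drop = FALSE]
  lm <- as.matrix(df[, c("x", "y", "z")])
  params <- list(mode = "target_count", value = nrow(lm))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$sparsify)) params <- meta$sparsify
  }
  structure(list(landmarks = lm, node_ids = seq_len(nrow(lm)),
                 params = params),
            class = "atlas")
}
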