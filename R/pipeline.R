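#' Build a semi-landmark atlas from one reference individual
#'
#' The reference bone is thresholded at 200 HU, pose-normalized (centred,
#' principal axes aligned, width-axis standard deviation scaled to 1), its
#' dense surface extracted by Delaunay tetrahedralization with long-edge
#' pruning, and the surface sparsified into the ordered semi-landmark atlas.
#' The edge threshold is given in mm and converted into the normalized frame
#' through the recorded scale.
#'
#' @param volume the reference individual's [voxel_volume()].
#' @param n_landmarks atlas size (target-count sparsification).
#' @param threshold_hu bone threshold (200 HU).
#' @param max_edge_mm edge-pruning threshold in mm (5 mm).
#' @return List of class `atlas_build`: `atlas`, `dense_mesh`, `transform`,
#'   `cloud` (normalized bone cloud) and the parameters used.
#' @export
build_reference_atlas <- function(volume, n_landmarks = 1234,
                                  threshold_hu = 200, max_edge_mm = 5) {
  cloud_mm <- threshold_bone(volume, threshold_hu)
  np <- normalize_pose(cloud_mm)
  max_edge <- max_edge_mm * np$transform$scale
  tm <- prune_long_edges(delaunay_tets(np$cloud), max_edge)
  sm <- extract_surface(tm)
  atl <- sparsify(sm, mode = "target_count",
                  value = min(n_landmarks, nrow(sm$nodes)))
  structure(list(atlas = atl, dense_mesh = sm, transform = np$transform,
                 cloud = np$cloud,
                 params = list(threshold_hu = threshold_hu,
                               max_edge_mm = max_edge_mm,
                               n_landmarks = n_landmarks)),
            class = "atlas_build")
}

#' Register one individual against the atlas
#'
#' The individual's bone voxels are thresholded and pose-normalized like the
#' atlas individual, its dense surface mesh is built, the atlas is put in
#' correspondence with the surface nodes by CPD, the most probable surface
#' point is taken for every atlas landmark, and the landmark set is mapped
#' back to millimetres through the individual's inverse pose transform.
#'
#' @param volume the individual's [voxel_volume()].
#' @param ref an [build_reference_atlas()] result.
#' @param animal_id id stored in the landmark set.
#' @param mode CPD deformation mode (affine by default, as the
#'   best-performing mode for scapula surfaces).
#' @param params a [cpd_params()] list.
#' @param soft use posterior-weighted surface coordinates instead of the
#'   most probable point. Hard argmax is the default; the soft variant
#'   suppresses the coordinate quantization that coarse voxel grids imprint
#'   on argmax correspondences.
#' @return A [landmark_set()] in mm with attributes `fit_quality`
#'   (median/max landmark-to-surface distance, normalized units) and
#'   `n_duplicates`.
#' @export
register_animal <- function(volume, ref, animal_id = NA_character_,
                            mode = "affine", params = cpd_params(),
                            soft = FALSE) {
  stopifnot(inherits(ref, "atlas_build"))
  cloud_mm <- threshold_bone(volume)
  np <- normalize_pose(cloud_mm)
  tm <- prune_long_edges(delaunay_tets(np$cloud),
                         ref$params$max_edge_mm * np$transform$scale)
  sm <- extract_surface(tm)
  Y <- point_cloud(sm$nodes, units = "normalized")
  res <- cpd_register(ref$atlas, Y, mode = mode, params = params)
  lms_norm <- extract_correspondence(res, Y, animal_id = animal_id,
                                     soft = soft)
  fq <- fit_quality(point_cloud(lms_norm$coords, units = "normalized"), Y)
  mm <- apply_inverse(point_cloud(lms_norm$coords, units = "normalized"),
                      np$transform)
  out <- landmark_set(mm$coords, animal_id, units = "mm")
  attr(out, "fit_quality") <- fq
  attr(out, "n_duplicates") <- attr(lms_norm, "n_duplicates")
  attr(out, "cpd_flag") <- res$flag
  out
}

#' Run the full synthetic study: voxels to spatial reliability
#'
#' Generates a pedigree, gene-dropped genotypes and latent shape scores,
#' voxelizes one scapuloid per animal (geometry driven by the first latent
#' modes), builds the atlas from the zero-score reference solid, registers
#' every animal by CPD, filters outliers by the IQR rule, fits the masked
#' PCA, estimates REML variance components of the PC scores with the genomic
#' relationship matrix, predicts validation scores with and without GEBV,
#' and scores both predictions by mean node error and spatial reliability.
#'
#' @param cfg a [sim_config()]; pick small sizes for interactive use.
#' @param n_landmarks atlas size.
#' @param n_validation animals masked before the PCA as the validation set.
#' @param n_pc principal components carried into the genetic analysis.
#' @param min_obs validation filter: minimum training records per
#'   fixed-effect level.
#' @param soft posterior-weighted correspondence (see [register_animal()]);
#'   recommended for coarse scaled-down voxel grids.
#' @return A list of class `synthetic_study` with the intermediate objects
#'   (`atlas_build`, `landmarks`, `shapes`, `pca`, `vc`, `fits`) and the
#'   validation report (`validation_ids`, `error_curve`, `error_curve_fe`,
#'   `r2`, `r2_fe`, `excluded`).
#' @export
run_synthetic_study <- function(cfg, n_landmarks = 150, n_validation = 5,
                                n_pc = 10, min_obs = 4, soft = FALSE) {
  sim <- simulate_pedigree_genotypes(cfg)
  base <- scapuloid_params()
  ref_vol <- make_scapuloid_volume(base, spacing = cfg$spacing)
  ref <- build_reference_atlas(ref_vol, n_landmarks = n_landmarks)
  K <- nrow(ref$atlas$landmarks)

  shp <- simulate_shapes(cfg, sim, base_landmarks = ref$atlas$landmarks)
  ids <- sim$phenotyped
  zscores <- sweep(shp$scores, 2, sqrt(shp$mode_var), `/`)

  sets <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    par_i <- scapuloid_from_scores(zscores[i, ], base)
    vol_i <- make_scapuloid_volume(par_i, spacing = cfg$spacing)
    sets[[i]] <- register_animal(vol_i, ref, animal_id = ids[i],
                                 soft = soft)
  }
  sets <- realign_landmarks(sets)
  shapes <- shape_matrix_from_sets(sets)

  out_ids <- flag_outliers(shapes)
  keep <- setdiff(shapes$animals, out_ids)
  shapes <- shape_matrix(shapes$values[keep, , drop = FALSE], keep)

  set.seed(cfg$seed + 3L)
  validation_ids <- sample(shapes$animals, min(n_validation,
                                               length(shapes$animals) - 2))
  pca <- fit_pca(shapes, mask = validation_ids,
                 n_components = min(n_pc, length(keep) - 2))
  npc <- ncol(pca$loadings)

  covar <- shp$covariates[match(shapes$animals, shp$covariates$animal_id), ]
  design <- build_design(covar)
  training <- !(shapes$animals %in% validation_ids)
  Y <- pca$scores[match(shapes$animals, pca$animals), , drop = FALSE]
  Ymask <- Y
  Ymask[!training, ] <- NA

  G <- build_grm(genotype_matrix(
    unclass(sim$genotypes)[shapes$animals, , drop = FALSE]))
  vc <- reml_estimate(Ymask, design, G, h2_penalty = 1)
  fits <- solve_mme_multi(Ymask, design, G, vc)

  filt <- filter_validation(design, training, validation_ids,
                            min_obs = min_obs)
  vids <- filt$retained
  if (length(vids) < 2)
    stop("fewer than 2 validation animals survive the fixed-effect filter")
  s_hat <- predict_scores(fits, design, vids, include_gebv = TRUE)
  s_fe <- predict_scores(fits, design, vids, include_gebv = FALSE)

  truth <- shapes$values[vids, , drop = FALSE]
  curve <- mean_error_curve(truth, pca, s_hat, k_max = npc)
  curve_fe <- mean_error_curve(truth, pca, s_fe, k_max = npc)
  pred <- reconstruct(pca, s_hat, n_components = npc)
  pred_fe <- reconstruct(pca, s_fe, n_components = npc)
  r2 <- spatial_reliability(truth, pred, pca$mean)
  r2_fe <- spatial_reliability(truth, pred_fe, pca$mean)

  structure(list(config = cfg, atlas_build = ref, landmarks = sets,
                 shapes = shapes, outliers = out_ids, pca = pca,
                 design = design, grm = G, vc = vc, fits = fits,
                 truth = shp, validation_ids = vids,
                 excluded = filt$excluded,
                 s_hat = s_hat, s_fe = s_fe,
                 error_curve = curve, error_curve_fe = curve_fe,
                 r2 = r2, r2_fe = r2_fe),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  npc <- ncol(x$pca$loadings)
  cat(sprintf("<synthetic_study> %d animals, %d landmarks, %d PCs\n",
              length(x$shapes$animals), nrow(x$atlas_build$atlas$landmarks),
              npc))
  cat(sprintf("  h2 (PC1..%d): %s\n", min(3, npc),
              paste(sprintf("%.2f", head(x$vc$h2, 3)), collapse = " ")))
  cat(sprintf("  mean node error k=0: %.2f mm -> k=%d: %.2f mm\n",
              x$error_curve$mean[1], npc,
              x$error_curve$mean[npc + 1]))
  cat(sprintf("  mean spatial R2: %.3f (GEBV) vs %.3f (fixed only)\n",
              mean(x$r2), mean(x$r2_fe)))
  invisible(x)
}
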