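test_that("icospheres are closed orientable manifolds with Euler characteristic 2", {
  for (s in 0:2) {
    ic <- icosphere(s)
    V <- nrow(ic$vertices); F <- nrow(ic$faces); E <- 3 * F / 2
    expect_equal(V, 10 * 4^s + 2)
    expect_equal(V - E + F, 2)
    expect_true(growmap:::sg_mesh_closed(ic$faces, V))
    # consistent outward orientation: positive signed volume
    a <- ic$vertices[ic$faces[, 1], ]; b <- ic$vertices[ic$faces[, 2], ]
    c3 <- ic$vertices[ic$faces[, 3], ]
    vol <- sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
                 a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
                 a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
    expect_gt(vol, 0)
  }
})

test_that("vertex areas conserve total area and recover the sphere", {
  # single triangle of area 3: one third to each vertex
  v <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0))
  expect_equal(vertex_local_area(v, rbind(1:3)), rep(1, 3))
  ic <- icosphere(3)
  va <- vertex_local_area(ic$vertices, ic$faces)
  tot <- sum(growmap:::sg_triangle_areas(ic$vertices, ic$faces))
  expect_lt(abs(sum(va) - tot) / tot, 1e-10)
  expect_lt(abs(tot - 4 * pi) / (4 * pi), 0.01)
  ic2 <- icosphere(2)
  tot2 <- sum(vertex_local_area(ic2$vertices, ic2$faces))
  expect_lt(abs(tot2 - 4 * pi) / (4 * pi), 0.02)
})

test_that("areas are invariant to rigid motion and quadratic under scaling", {
  ic <- icosphere(1)
  va <- vertex_local_area(ic$vertices, ic$faces)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ic$vertices %*% R + matrix(c(10, -4, 2), nrow(ic$vertices), 3,
                                      byrow = TRUE)
  expect_lt(max(abs(vertex_local_area(moved, ic$faces) - va)), 1e-9)
  expect_equal(vertex_local_area(ic$vertices * 2.5, ic$faces), va * 2.5^2,
               tolerance = 1e-12)
})

test_that("degenerate and non-manifold meshes are rejected by triangle index", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
  expect_error(vertex_local_area(v, rbind(c(1, 2, 3), c(1, 2, 4))),
               "degenerate .* triangle 2")
  v2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  f3 <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(vertex_local_area(v2, f3), "non-manifold")
})

test_that("uniform growth scales every vertex area by the same ratio", {
  g <- small_cohort(71, n = 20)
  gm <- generate_meshes(g$records, n_vertices = 42, patch_frac = 0,
                        noise_sd = 0, subject_scale_sd = 0, seed = 1)
  s <- gm$series
  sub <- names(which(table(s$meta$subject_id) >= 2))[1]
  i <- which(s$meta$subject_id == sub)
  i <- i[order(s$meta$age_days[i])][1:2]
  a1 <- vertex_local_area(s$coords[[i[1]]], s$faces)
  a2 <- vertex_local_area(s$coords[[i[2]]], s$faces)
  ratio <- a2 / a1
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
})

test_that("a planted patch expands faster than the background", {
  g <- small_cohort(72, n = 20)
  gm <- generate_meshes(g$records, n_vertices = 42, noise_sd = 0,
                        subject_scale_sd = 0, seed = 2)
  s <- gm$series; tr <- gm$mesh_truth
  sub <- names(which(table(s$meta$subject_id) >= 2))[1]
  i <- which(s$meta$subject_id == sub)
  i <- i[order(s$meta$age_days[i])][c(1, 2)]
  ratio <- vertex_local_area(s$coords[[i[2]]], s$faces) /
    vertex_local_area(s$coords[[i[1]]], s$faces)
  bg <- setdiff(seq_len(42), c(tr$high, tr$low))
  expect_gt(min(ratio[tr$high]), median(ratio[bg]))
  expect_gt(median(ratio[tr$high]), max(ratio[bg]))
  expect_lt(median(ratio[tr$low]), min(ratio[bg]))
})

test_that("mesh generation is deterministic and validates its inputs", {
  g <- small_cohort(73, n = 10)
  m1 <- generate_meshes(g$records, n_vertices = 12, seed = 9)
  m2 <- generate_meshes(g$records, n_vertices = 12, seed = 9)
  expect_identical(m1$series$coords, m2$series$coords)
  expect_error(generate_meshes(g$records, n_vertices = 6), "at least 12")
})

test_that("PLY round trip is lossless and the reader validates the series", {
  g <- small_cohort(74, n = 10)
  gm <- generate_meshes(g$records, n_vertices = 12, seed = 4)
  d <- tmpdir()
  write_mesh_series(gm$series, d)
  s2 <- read_mesh_series(d, g$records)
  j <- match(gm$series$meta$scan_id, s2$meta$scan_id)
  for (i in seq_along(j)) {
    expect_lt(max(abs(s2$coords[[j[i]]] - gm$series$coords[[i]])), 1e-6)
  }
  expect_identical(s2$faces, gm$series$faces)
  # scalar properties survive a round trip
  f1 <- file.path(d, "scalar.ply")
  write_ply(gm$series$coords[[1]], gm$series$faces, f1,
            scalars = list(rate = seq_len(12) / 7))
  back <- read_mesh(f1)
  expect_equal(back$scalars$rate, seq_len(12) / 7, tolerance = 1e-12)
  # permuted triangle list is rejected
  first <- list.files(d, pattern = "^S.*\\.ply$", full.names = TRUE)[1]
  m1 <- read_mesh(first)
  write_ply(m1$vertices, m1$faces[rev(seq_len(nrow(m1$faces))), ], first)
  expect_error(read_mesh_series(d, g$records), "does not match")
})

test_that("OFF meshes are read and unknown scans are rejected", {
  g <- small_cohort(75, n = 5)
  gm <- generate_meshes(g$records, n_vertices = 12, seed = 4)
  d <- tmpdir()
  v <- gm$series$coords[[1]]; f <- gm$series$faces
  off <- file.path(d, paste0(gm$series$meta$scan_id[1], ".off"))
  writeLines(c("OFF", paste(nrow(v), nrow(f), 0),
               apply(format(v, digits = 17), 1, paste, collapse = " "),
               paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1)), off)
  s <- read_mesh_series(d, g$records)
  expect_lt(max(abs(s$coords[[1]] - v)), 1e-9)
  # a mesh with no cohort record is rejected by file name
  write_ply(v, f, file.path(d, "UNKNOWN_0001.ply"))
  expect_error(read_mesh_series(d, g$records), "UNKNOWN_0001")
})
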