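# Surface targeting: peak detection, geodesic spheres, sphere means,
# overlap rates.

test_that("find_peaks returns argmax/argmin with low-index tie-breaking", {
  mesh <- surface_mesh(cbind(0:7, 0, 0), cbind(1, 2, 3))
  m <- fc_map(c(0.1, 0.9, -0.7, 0, 0, 0, 0, 0), mesh, scale = "z")
  p <- find_peaks(m)
  expect_equal(p$positive$vertex, 2L)
  expect_equal(p$negative$vertex, 3L)
  expect_equal(p$negative$xyz, c(2, 0, 0))
  # tie at the max between vertices 5 and 8 -> vertex 5
  m2 <- fc_map(c(0, 0, -1, 0, 2, 0, 0, 2), mesh, scale = "z")
  expect_equal(find_peaks(m2)$positive$vertex, 5L)
  # exclusion flags are honoured; all-excluded errors
  p3 <- find_peaks(m, exclude = c(FALSE, TRUE, rep(FALSE, 6)))
  expect_equal(p3$positive$vertex, 1L)
  expect_error(find_peaks(m, exclude = rep(TRUE, 8)),
               class = "fctarget_arg_error")
  const <- fc_map(rep(1, 8), mesh, scale = "z")
  expect_error(find_peaks(const), class = "fctarget_data_error")
})

test_that("geodesic spheres follow graph distance on a path graph", {
  mesh <- path_mesh(6)  # vertices 1..6 at unit spacing along x
  expect_identical(geodesic_sphere(mesh, 1, 0)$members, 1L)
  roi <- geodesic_sphere(mesh, 1, 2.5)
  # oracle: brute-force shortest paths; helper vertices sit sqrt(0.5^2+0.8^2)
  # = 0.943 off the path, so radius 2.5 reaches path vertices <= 2 hops and
  # the first two off-path vertices
  d <- oracle_dijkstra(mesh$vertices, fctarget:::mesh_edges(mesh), 1)
  expect_identical(roi$members, which(d <= 2.5))
  expect_true(all(c(1L, 2L, 3L) %in% roi$members))
  expect_false(4L %in% roi$members)
  expect_equal(roi$distances, d[roi$members])
  expect_error(geodesic_sphere(mesh, 1, -1), class = "fctarget_arg_error")
  expect_error(geodesic_sphere(mesh, 99, 1), class = "fctarget_arg_error")
})

test_that("geodesic spheres equal the exhaustive oracle on a real mesh", {
  mesh <- small_mesh()  # 162 vertices
  edges <- fctarget:::mesh_edges(mesh)
  for (center in c(1L, 60L, 162L)) {
    d <- oracle_dijkstra(mesh$vertices, edges, center)
    for (radius in c(6, 15, 40)) {
      roi <- geodesic_sphere(mesh, center, radius)
      expect_identical(roi$members, which(d <= radius))
    }
  }
})

test_that("sphere membership is monotone in the radius", {
  mesh <- small_mesh()
  radii <- c(0, 3, 6, 12, 24, 48)
  rois <- lapply(radii, function(r) geodesic_sphere(mesh, 42L, r)$members)
  for (k in seq_len(length(radii) - 1))
    expect_true(all(rois[[k]] %in% rois[[k + 1]]))
})

test_that("sphere_mean averages members; full mesh gives the global mean", {
  mesh <- path_mesh(4)
  nv <- nrow(mesh$vertices)
  vals <- seq_len(nv)
  m <- fc_map(vals, mesh, scale = "z")
  expect_equal(sphere_mean(m, list(members = 2L)), 2)
  expect_equal(sphere_mean(m, list(members = c(1L, 2L, 3L))), 2)
  const <- fc_map(rep(7, nv), mesh, scale = "z")
  expect_equal(sphere_mean(const, geodesic_sphere(mesh, 1, 2)), 7)
  full <- list(members = seq_len(nv))
  expect_identical(sphere_mean(m, full), mean(vals))
  expect_error(sphere_mean(m, list(members = integer(0))),
               class = "fctarget_arg_error")
})

test_that("overlap_rate counts maximal vertex coverage", {
  mesh <- path_mesh(8)
  roi <- function(members) list(members = as.integer(members))
  # identical ROIs -> 1
  expect_equal(overlap_rate(list(roi(1:3), roi(1:3), roi(1:3)), mesh), 1)
  # pairwise disjoint ROIs among n subjects -> 1/n
  expect_equal(overlap_rate(list(roi(1), roi(2), roi(3), roi(4)), mesh), 1 / 4)
  # constructed 3-subject case: vertex 2 covered by subjects 1 and 2 -> 2/3
  rois <- list(roi(c(1, 2)), roi(c(2, 3)), roi(5))
  counts <- tabulate(unlist(lapply(rois, `[[`, "members")),
                     nbins = nrow(mesh$vertices))
  expect_equal(max(counts) / 3, 2 / 3)  # exhaustive per-vertex count
  expect_equal(overlap_rate(rois, mesh), 2 / 3)
  expect_error(overlap_rate(list(roi(1)), mesh), class = "fctarget_arg_error")
  # mean pairwise Jaccard variant
  expect_equal(overlap_rate(list(roi(1:2), roi(2:3)), mesh,
                            statistic = "mean_pairwise"), 1 / 3)
})
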