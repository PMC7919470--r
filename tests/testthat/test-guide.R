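test_that("geodesic patches on a sphere match the spherical-cap area", {
  R <- 50; r <- 30
  sph <- mesh_icosphere(R, subdiv = 4)
  patch <- select_contact_region(sph, c(0, 0, R), r)
  cap <- 2 * pi * R^2 * (1 - cos(r / R))
  expect_lt(abs(mesh_area(patch) - cap) / cap, 0.05)
  # patch is connected and open
  expect_gt(nrow(boundary_edges(patch)), 0)
  # saturation: radius beyond the geodesic diameter returns the whole surface
  whole <- select_contact_region(sph, c(0, 0, R), pi * R * 1.2)
  expect_equal(nrow(whole$faces), nrow(sph$faces))
  expect_error(select_contact_region(sph, c(0, 0, R + 10), 20), "seed")
})

test_that("mid-shaft patches on a cylinder are connected and contain the seed", {
  cyl <- mesh_tube(15, 120, segments = 36, rings = 24)
  seed <- c(15, 0, 0)
  patch <- select_contact_region(cyl, seed, 20)
  expect_lt(mesh_closest_points(patch, seed)$distance, 0.5)
  g <- igraph::graph_from_edgelist(rbind(patch$faces[, 1:2], patch$faces[, 2:3],
                                         patch$faces[, c(3, 1)]),
                                   directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)
})

test_that("guide bodies are watertight negatives of the bone patch", {
  expect_error(build_guide(flat_plate(), 0), "> 0")
  # planar 20 x 20 patch, 3 mm thickness: prism of 1200 mm^3
  g <- build_guide(flat_plate(10, 11), 3)
  expect_true(is_watertight(g$body))
  expect_lt(abs(mesh_volume(g$body) - 1200) / 1200, 0.10)
  # spherical patch: inner surface coincides with the bone
  sph <- mesh_icosphere(40, subdiv = 3)
  patch <- select_contact_region(sph, c(0, 0, 40), 18)
  gs <- build_guide(patch, 3)
  expect_true(is_watertight(gs$body))
  d <- mesh_closest_points(sph, gs$contact_patch$vertices)$distance
  expect_lt(mean(d), 0.2)
  expect_lt(max(d), 0.2)   # Hausdorff bound on the analytic shape
})

test_that("screw holes remove cylinder-sized volume and keep the body closed", {
  g <- build_guide(flat_plate(10, 11), 3)
  expect_identical(add_screw_holes(g, list()), g)
  gh <- add_screw_holes(g, list(
    list(point = c(-5, 0, 5), direction = c(0, 0, -1)),
    list(point = c(5, 0, 5), direction = c(0, 0, -1))))
  expect_true(is_watertight(gh$body))
  removed <- mesh_volume(g$body) - mesh_volume(gh$body)
  expect_lt(abs(removed - 2 * pi * 2.5^2 * 3) / (2 * pi * 2.5^2 * 3), 0.15)
  expect_equal(length(gh$screw_axes), 2L)
  expect_equal(gh$screw_axes[[1]]$diameter, 5)
  # an axis missing the body is a no-op on the volume
  gn <- add_screw_holes(g, list(list(point = c(500, 500, 0),
                                     direction = c(0, 0, 1))))
  expect_equal(mesh_volume(gn$body), mesh_volume(g$body), tolerance = 1e-9)
})

test_that("the marker holder stores its pose exactly and clears the cube", {
  g <- build_guide(flat_plate(15, 13), 3)
  set.seed(61)
  pose <- rigid_transform(random_rotation(), c(0, 0, 60), "guide", "marker")
  gm <- add_marker_holder(g, pose)
  expect_identical(gm$holder_pose, pose)            # bit-exact storage
  # a 30 mm cube at the holder pose does not intersect the socket walls
  cube <- transform_mesh(pose, mesh_box(c(30, 30, 30)))
  sock <- transform_mesh(pose, socket_mesh())
  set.seed(62)
  cube_pts <- sample_surface_points(cube, 400)
  expect_false(any(points_in_mesh(sock, cube_pts)))
  sock_pts <- sample_surface_points(sock, 400)
  expect_false(any(points_in_mesh(cube, sock_pts)))
  # identity pose: socket frame coincides with the guide frame
  gi <- add_marker_holder(build_guide(flat_plate(15, 13), 3),
                          transform_identity("guide", "marker"))
  expect_equal(as.matrix(gi$holder_pose), diag(4))
  # a pose whose socket walls pass through the contact patch errors
  bad <- rigid_transform(diag(3), c(0, 0, 2), "guide", "marker")
  expect_error(add_marker_holder(build_guide(flat_plate(25, 15), 3), bad),
               "collides")
})

test_that("conical fiducials carve to depth with the apex on the normal", {
  plate <- mesh_box(c(30, 30, 6))
  out <- add_cone_fiducials(plate, matrix(c(0, 0, 3), 1))
  m <- out$mesh
  expect_true(is_watertight(m))
  apex <- c(0, 0, 3) - 3 * c(0, 0, 1)
  expect_lt(min(sqrt(rowSums(sweep(m$vertices, 2, apex)^2))), 0.1)
  foot <- m$vertices[abs(m$vertices[, 1]) < 2 & abs(m$vertices[, 2]) < 2 &
                       m$vertices[, 3] > -3, , drop = FALSE]
  expect_equal(3 - min(foot[, 3]), 3, tolerance = 0.1)   # depth 3 +/- 0.1
  expect_equal(length(out$cones), 1L)
  expect_equal(out$cones[[1]]$diameter, 4)
  # zero points: unchanged; off-surface points: error naming offenders
  expect_identical(add_cone_fiducials(plate, matrix(numeric(0), 0, 3))$mesh,
                   plate)
  expect_error(add_cone_fiducials(plate, rbind(c(0, 0, 3), c(0, 0, 30))),
               "off the surface.*2")
})

test_that("bone fragments contain the patch and stay inside the bone", {
  sph <- mesh_icosphere(30, subdiv = 3)
  patch <- select_contact_region(sph, c(0, 0, 30), 12)
  frag <- extract_bone_fragment(sph, patch, margin = 6)
  expect_true(is_watertight(frag))
  bb_f <- mesh_bbox(frag); bb_b <- mesh_bbox(sph)
  expect_true(all(bb_f[1, ] >= bb_b[1, ] - 1.1) && all(bb_f[2, ] <= bb_b[2, ] + 1.1))
  expect_lt(mesh_volume(frag), mesh_volume(sph))
  # every patch vertex lies in (or within a voxel of) the fragment
  inside <- points_in_mesh(frag, patch$vertices)
  near <- mesh_closest_points(frag, patch$vertices)$distance < 1.1
  expect_true(all(inside | near))
  # saturating margin returns the whole bone (up to voxelization)
  whole <- extract_bone_fragment(sph, patch, margin = 1000)
  expect_equal(mesh_volume(whole), mesh_volume(sph), tolerance = 0.1)
})

test_that("cutting planes carry a unit normal and mesh to a thin slab", {
  pl <- cutting_plane(c(10, 0, 5), c(0, 0, 2), extents = c(20, 15))
  expect_equal(pl$normal, c(0, 0, 1))
  expect_error(cutting_plane(c(0, 0, 0), c(0, 0, 0)), "non-zero")
  m <- cutting_plane_mesh(pl, thickness = 0.4)
  expect_true(is_watertight(m))
  expect_equal(mesh_volume(m), 40 * 30 * 0.4, tolerance = 1e-9)
  expect_lt(abs(mean(m$vertices[, 3]) - 5), 1e-9)
})

test_that("guide seating is recovered by ICP from a perturbed start", {
  ph <- test_phantom(7L)
  fit0 <- fit_guide(ph$guide, ph$bone)
  expect_true(fit0$converged)
  expect_lt(fit0$rms, 1e-6)
  expect_lt(sqrt(sum(fit0$transform$translation^2)), 0.05)
  # displaced by a known small rigid motion, init near truth: recovers it
  set.seed(63)
  for (i in 1:5) {
    init <- perturb_transform(transform_identity("anatomy", "guide"), 0.5, 0.5)
    fit <- fit_guide(ph$guide, ph$bone, init)
    expect_lt(sqrt(sum(fit$transform$translation^2)), 0.1)
    expect_lt(rotation_angle(fit$transform$rotation), 0.1)
  }
})
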