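test_that("a pixel at a triangle's projected centroid gets (1/3,1/3,1/3) weights", {
  # one triangle facing the front camera (normal along +y), centroid at origin
  V <- rbind(c(-30, 0, -30), c(30, 0, -30), c(0, 0, 60))
  m <- registered_mesh(V, rbind(c(1, 2, 3)), "tri")
  vs <- view_spec("front", 31, 31, window = list(u = c(-31, 31), v = c(-31, 31)))
  atlas <- build_atlas(m, list(vs))
  vw <- atlas$views[[1]]
  # centroid (0,0) lies at pixel center (16,16) of the 31x31 window
  expect_equal(vw$tri[16, 16], 1L)
  w <- c(vw$w[[1]][16, 16], vw$w[[2]][16, 16], vw$w[[3]][16, 16])
  expect_equal(w, rep(1 / 3, 3), tolerance = 1e-9)
  # foreground + background partition the image
  expect_equal(sum(vw$mask) + sum(!vw$mask), 31L * 31L)
})

test_that("occlusion assigns the nearer of two stacked triangles", {
  # two parallel triangles; the front camera looks along -y, so larger y wins
  V <- rbind(c(-50, 10, -50), c(50, 10, -50), c(0, 10, 80),    # near (y = 10)
             c(-50, -10, -50), c(50, -10, -50), c(0, -10, 80)) # far (y = -10)
  m <- registered_mesh(V, rbind(c(4, 5, 6), c(1, 2, 3)), "occl")
  vs <- view_spec("front", 32, 32, window = list(u = c(-60, 60), v = c(-60, 90)))
  atlas <- build_atlas(m, list(vs))
  tri <- atlas$views[[1]]$tri
  expect_true(all(tri[tri > 0] == 2L))  # triangle 2 is the near one
})

test_that("rendering is linear and G reproduces rendered foreground values", {
  bp <- small_bodies(2)
  template <- mean_mesh(bp$meshes)
  atlas <- build_atlas(template, default_body_views(template, 64))
  reg <- build_G(atlas)
  expect_equal(nrow(reg$G),
               sum(vapply(atlas$views, function(v) sum(v$mask), 0L)))
  expect_equal(range(Matrix::rowSums(reg$G)), c(1, 1), tolerance = 1e-9)
  imgs <- render_scan(template, atlas)
  P <- pixel_observations(imgs, atlas)
  expect_lt(max(abs(as.matrix(reg$G %*% template$vertices) - P)), 1e-9)
  # global offset shifts every foreground pixel by exactly the offset
  moved <- transform_mesh(bp$meshes[[1]], diag(3), c(10, 0, 0))
  i0 <- render_scan(bp$meshes[[1]], atlas)
  i1 <- render_scan(moved, atlas)
  fg <- atlas$views[[1]]$mask
  expect_equal(max(abs((i1$front$pixels[, , 1] - i0$front$pixels[, , 1])[fg] - 10)),
               0, tolerance = 1e-9)
  expect_lt(max(abs((i1$front$pixels[, , 2] - i0$front$pixels[, , 2])[fg])), 1e-9)
})

test_that("atlas construction is deterministic", {
  bp <- small_bodies(1)
  a1 <- build_atlas(bp$meshes[[1]], default_body_views(bp$meshes[[1]], 48))
  a2 <- build_atlas(bp$meshes[[1]], default_body_views(bp$meshes[[1]], 48))
  expect_identical(a1$views$front$tri, a2$views$front$tri)
  expect_identical(a1$views$bottom$w, a2$views$bottom$w)
})

test_that("visibility covers almost all vertices with three views, fewer with one", {
  bp <- small_bodies(2)
  template <- mean_mesh(bp$meshes)
  reg3 <- build_G(build_atlas(template, default_body_views(template, 128)))
  vis3 <- visibility_report(reg3)
  expect_gte(vis3$visible_fraction, 0.95)
  # single front view of a closed body leaves back-facing vertices invisible
  front <- build_atlas(template, default_body_views(template, 128)[1])
  vis1 <- visibility_report(build_G(front))
  expect_lt(vis1$visible_fraction, 1)
  # empty registration
  e <- structure(list(G = Matrix::sparseMatrix(i = integer(), j = integer(),
                                               x = numeric(), dims = c(0, 10)),
                      n_vertices = 10L), class = "sparse_registration")
  expect_equal(visibility_report(e)$visible_fraction, 0)
})

test_that("visible fraction is monotone in view resolution", {
  bp <- small_bodies(1)
  template <- bp$meshes[[1]]
  fr <- vapply(c(64, 128, 256), function(res)
    visibility_report(build_G(build_atlas(template,
      default_body_views(template, res))))$visible_fraction, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("pack/unpack views invert and meshes outside the window error", {
  bp <- small_bodies(1)
  template <- bp$meshes[[1]]
  atlas <- build_atlas(template, default_body_views(template, 48))
  imgs <- render_scan(template, atlas)
  packed <- pack_views(imgs)
  expect_equal(dim(packed$pixels)[3], 9)
  un <- unpack_views(packed, atlas)
  expect_equal(un$back$pixels, imgs$back$pixels)
  bad <- view_spec("front", 32, 32,
                   window = list(u = c(5000, 6000), v = c(5000, 6000)))
  expect_error(build_atlas(template, list(bad)), "outside")
})
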