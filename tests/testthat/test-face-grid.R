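test_that("face_to_image places vertices at mapped pixels and inverts exactly", {
  grid <- face_template_grid(2, 2)
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  m <- registered_mesh(V, grid$faces, grid$template_id)
  img <- face_to_image(m, grid)
  # vertex_index_of[r, c] = (r-1)*W + c (row-major): pixel (1,2) holds vertex 2
  expect_equal(img$pixels[1, 2, ], V[2, ])
  expect_equal(img$pixels[2, 1, ], V[3, ])
  expect_true(all(img$mask))
  m2 <- image_to_face(img, grid)
  expect_identical(m2$vertices, m$vertices)
})

test_that("conversion is invariant to vertex storage order given a matching map", {
  set.seed(10)
  H <- 4; W <- 4
  grid <- face_template_grid(H, W)
  V <- matrix(rnorm(H * W * 3), H * W, 3)
  m <- registered_mesh(V, grid$faces, grid$template_id)
  # permuted storage: vertex i moves to position perm[i]
  perm <- sample(H * W)
  Vp <- matrix(0, H * W, 3)
  Vp[perm, ] <- V
  grid_p <- face_template_grid(H, W, matrix(perm[grid$vertex_index_of], H, W))
  mp <- registered_mesh(Vp, grid_p$faces, grid_p$template_id)
  expect_equal(face_to_image(mp, grid_p)$pixels, face_to_image(m, grid)$pixels)
})

test_that("round-trips through images are exact on generated faces", {
  pop <- small_faces(6)
  for (m in pop$meshes) {
    img <- face_to_image(m, pop$grid)
    expect_identical(image_to_face(img, pop$grid)$vertices, m$vertices)
  }
})

test_that("fit_ranges computes per-pixel extrema and is idempotent over duplication", {
  g1 <- geometric_image(array(1, c(2, 2, 1)))
  g3 <- geometric_image(array(3, c(2, 2, 1)))
  r1 <- fit_ranges(list(g1))
  expect_equal(r1$min, r1$max)
  r <- fit_ranges(list(g1, g3))
  expect_equal(as.vector(r$min), rep(1, 4))
  expect_equal(as.vector(r$max), rep(3, 4))
  rdup <- fit_ranges(list(g1, g3, g1, g3))
  expect_identical(r, rdup)
  expect_error(fit_ranges(list()), "empty")
})

test_that("normalization maps endpoints, clamps, and round-trips", {
  pop <- small_faces(5)
  imgs <- lapply(pop$meshes, face_to_image, grid = pop$grid)
  rg <- fit_ranges(imgs)
  n1 <- normalize_image(imgs[[1]], rg)
  expect_true(all(n1$pixels >= 0 & n1$pixels <= 1))
  d1 <- denormalize_image(n1, rg)
  expect_lt(max(abs(d1$pixels - imgs[[1]]$pixels)), 1e-6)
  # endpoints: a pixel at its min maps to 0, at its max to 1
  span <- rg$max - rg$min
  j <- which(span > 0)[1]
  at_min <- imgs[[1]]$pixels
  at_min[j] <- rg$min[j]
  n_min <- normalize_image(geometric_image(at_min), rg)
  expect_equal(n_min$pixels[j], 0)
  at_max <- imgs[[1]]$pixels
  at_max[j] <- rg$max[j]
  expect_equal(normalize_image(geometric_image(at_max), rg)$pixels[j], 1)
  # below-range synthetic value clamps to 0
  at_min[j] <- rg$min[j] - 5
  expect_equal(normalize_image(geometric_image(at_min), rg)$pixels[j], 0)
  # degenerate (max == min) pixels normalize to 0 and denormalize to min
  k <- which(span == 0)[1]
  expect_equal(n1$pixels[k], 0)
  expect_equal(d1$pixels[k], rg$min[k])
})

test_that("normalized meshes cannot be converted without denormalization", {
  pop <- small_faces(2)
  imgs <- lapply(pop$meshes, face_to_image, grid = pop$grid)
  rg <- fit_ranges(imgs)
  expect_error(image_to_face(normalize_image(imgs[[1]], rg), pop$grid),
               "denormalize")
})

test_that("mirror augmentation is an involution and respects symmetry", {
  pop <- small_faces(4)
  m <- pop$meshes[[2]]
  mm <- mirror_augment(mirror_augment(m, pop$grid), pop$grid)
  expect_identical(mm$vertices, m$vertices)
  # bilaterally symmetric base face is its own mirror
  base <- make_face_population(population_spec(1, "face_grid", factor_sd = 0,
                                               noise_sd = 0, seed = 1), 16, 16)
  b <- base$meshes[[1]]
  expect_lt(max(abs(mirror_augment(b, base$grid)$vertices - b$vertices)), 1e-9)
  # generated faces carry asymmetric modes: mirror differs
  expect_gt(weighted_rmse(m, mirror_augment(m, pop$grid)), 0)
  # mirroring is an isometry: pairwise diversity is unchanged, so augmenting
  # a population leaves its diversity distribution symmetric
  m2 <- pop$meshes[[3]]
  expect_equal(weighted_rmse(mirror_augment(m, pop$grid),
                             mirror_augment(m2, pop$grid)),
               weighted_rmse(m, m2), tolerance = 1e-12)
})
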