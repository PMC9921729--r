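test_that("the umbrella Laplacian has the hand-derived single-triangle form", {
  L <- as.matrix(build_laplacian(rbind(c(1, 2, 3)), 3))
  for (i in 1:3) {
    expect_equal(L[i, i], 1)
    expect_equal(sort(L[i, -i]), c(-0.5, -0.5))
  }
  # zero on constant meshes
  V <- matrix(5, 3, 3)
  expect_lt(max(abs(as.matrix(L %*% V))), 1e-12)
})

test_that("the Laplacian annihilates affine fields on a regular grid interior", {
  grid <- face_template_grid(8, 8)
  L <- build_laplacian(grid$faces, 64)
  # linear function of grid position
  r <- (grid$vertex_index_of - 1) %/% 8
  c <- (grid$vertex_index_of - 1) %% 8
  f <- numeric(64)
  f[as.vector(grid$vertex_index_of)] <- as.vector(2 * r - 3 * c + 1)
  res <- as.numeric(L %*% f)
  # interior vertices of the symmetric stencil: rows/cols 2..7 minus the
  # diagonal-neighbour asymmetry of the split quads is still affine-exact
  interior <- as.vector(grid$vertex_index_of[3:6, 3:6])
  expect_lt(max(abs(res[interior])), 1e-9)
  expect_lt(max(abs(Matrix::rowSums(L))), 1e-9)
  expect_warning(build_laplacian(rbind(c(1, 2, 3)), 5), "isolated")
})

test_that("solve_vertices handles identity, pure-prior and oracle cases", {
  set.seed(20)
  # identity G, alpha = 0: exact fit
  n <- 12
  grid <- face_template_grid(3, 4)
  L <- build_laplacian(grid$faces, n)
  P <- matrix(rnorm(n * 3), n, 3)
  G <- Matrix::Diagonal(n)
  V <- solve_vertices(reconstruction_problem(G, P, L, matrix(0, n, 3), alpha = 0))
  expect_lt(max(abs(V - P)), 1e-10)
  # no observations, alpha > 0: the prior is returned
  G0 <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                             dims = c(0, n))
  V0 <- matrix(rnorm(n * 3), n, 3)
  V <- solve_vertices(reconstruction_problem(G0, matrix(0, 0, 3), L, V0, 0.5))
  expect_lt(max(abs(V - V0)), 1e-8)
  # without regularization an unobserved mesh is an error naming components
  expect_error(solve_vertices(reconstruction_problem(G0, matrix(0, 0, 3), L,
                                                     V0, 0)),
               "no observed vertex")
})

test_that("sparse solutions match a dense normal-equation oracle", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    # ring plus long chords: connected, no isolated vertices
    faces <- cbind(seq_len(n), c(seq_len(n - 1) + 1, 1),
                   ((seq_len(n) + n %/% 2 - 1) %% n) + 1)
    L <- build_laplacian(faces, n)
    n_obs <- sample(5:(2 * n), 1)
    ji <- t(vapply(seq_len(n_obs), function(i) sample(n, 3), integer(3)))
    wts <- matrix(stats::rexp(n_obs * 3), n_obs)
    wts <- wts / rowSums(wts)
    G <- Matrix::sparseMatrix(i = rep(seq_len(n_obs), 3), j = as.vector(ji),
                              x = as.vector(wts), dims = c(n_obs, n))
    P <- matrix(rnorm(n_obs * 3, sd = 10), n_obs, 3)
    V0 <- matrix(rnorm(n * 3, sd = 10), n, 3)
    alpha <- stats::runif(1, 1e-4, 1)
    V <- solve_vertices(reconstruction_problem(G, P, L, V0, alpha))
    Ad <- as.matrix(Matrix::crossprod(G) + alpha * Matrix::crossprod(L))
    rhs <- as.matrix(Matrix::crossprod(G, P) +
                       alpha * Matrix::crossprod(L) %*% V0)
    Vd <- solve(Ad, rhs)
    expect_lt(max(abs(V - Vd)), 1e-8)
  }
})

test_that("the returned solution is the objective's minimizer", {
  set.seed(22)
  bp <- small_bodies(2, resolution = 24)
  template <- mean_mesh(bp$meshes)
  atlas <- build_atlas(template, default_body_views(template, 48))
  reg <- build_G(atlas)
  L <- build_laplacian(template$faces, nrow(template$vertices))
  P <- as.matrix(reg$G %*% bp$meshes[[1]]$vertices)
  pb <- reconstruction_problem(reg, P, L, template$vertices, 0.001)
  V <- solve_vertices(pb)
  obj <- reconstruction_objective(pb, V)
  expect_lte(obj, reconstruction_objective(pb, template$vertices))
  for (i in 1:100) {
    Vp <- V + matrix(rnorm(length(V), sd = 0.01), nrow(V))
    expect_lte(obj, reconstruction_objective(pb, Vp))
  }
})

test_that("growing alpha drives L V toward L V0 monotonically", {
  set.seed(23)
  bp <- small_bodies(2, resolution = 24)
  template <- mean_mesh(bp$meshes)
  atlas <- build_atlas(template, default_body_views(template, 48))
  reg <- build_G(atlas)
  L <- build_laplacian(template$faces, nrow(template$vertices))
  mesh <- bp$meshes[[2]]
  P <- as.matrix(reg$G %*% mesh$vertices) +
    matrix(rnorm(3 * nrow(reg$G)), ncol = 3)  # noisy observations
  V0 <- template$vertices
  lap_res <- vapply(c(1e-3, 1, 1e3), function(a) {
    V <- solve_vertices(reconstruction_problem(reg, P, L, V0, a))
    sqrt(sum(as.matrix(L %*% (V - V0))^2))
  }, 0)
  expect_true(all(diff(lap_res) < 0))
})

test_that("the solution is translation-equivariant", {
  set.seed(24)
  bp <- small_bodies(1, resolution = 24)
  m <- bp$meshes[[1]]
  atlas <- build_atlas(m, default_body_views(m, 48))
  reg <- build_G(atlas)
  L <- build_laplacian(m$faces, nrow(m$vertices))
  P <- as.matrix(reg$G %*% m$vertices)
  V0 <- m$vertices
  V1 <- solve_vertices(reconstruction_problem(reg, P, L, V0, 0.001))
  sh <- c(12, -7, 3)
  P2 <- sweep(P, 2, sh, `+`)
  V02 <- sweep(V0, 2, sh, `+`)
  V2 <- solve_vertices(reconstruction_problem(reg, P2, L, V02, 0.001))
  expect_lt(max(abs(V2 - sweep(V1, 2, sh, `+`))), 1e-8)
})

test_that("round trips are near-exact at the template and tight elsewhere", {
  bp <- small_bodies(3, resolution = 32)
  template <- mean_mesh(bp$meshes)
  atlas <- build_atlas(template, default_body_views(template, 128))
  reg <- build_G(atlas)
  L <- build_laplacian(template$faces, nrow(template$vertices))
  # observations and prior agree at the template itself
  rt0 <- roundtrip_error(template, atlas, reg = reg, L = L)
  expect_lt(rt0$mean_error, 1e-6)
  rt <- roundtrip_error(bp$meshes[[1]], atlas, reg = reg, L = L)
  expect_lt(rt$mean_error, 0.14)
})

test_that("invisible vertices reconstruct worse than visible ones on average", {
  bp <- small_bodies(2, resolution = 32)
  template <- mean_mesh(bp$meshes)
  # a single front view leaves the back of the body unobserved
  atlas <- build_atlas(template, default_body_views(template, 96)[1])
  reg <- build_G(atlas)
  vis <- visibility_report(reg)$visible
  expect_true(any(!vis))
  L <- build_laplacian(template$faces, nrow(template$vertices))
  rt <- roundtrip_error(bp$meshes[[1]], atlas, reg = reg, L = L)
  expect_gte(mean(rt$per_vertex[!vis]), mean(rt$per_vertex[vis]))
})
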