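test_that("PCA is exact on low-rank populations and standard invariants hold", {
  set.seed(30)
  # population in an exact 3-dim affine subspace
  n <- 20; nv <- 30
  basis <- qr.Q(qr(matrix(rnorm(3 * nv * 3), 3 * nv, 3)))
  mu <- rnorm(3 * nv)
  faces <- rbind(c(1, 2, 3))
  meshes <- lapply(1:n, function(i)
    registered_mesh(matrix(mu + basis %*% rnorm(3, sd = 5), ncol = 3), faces, "lr"))
  model <- fit_pca(meshes, 3)
  for (m in meshes[1:5]) {
    rec <- pca_decode(model, pca_encode(model, m))
    expect_lt(max(abs(rec$vertices - m$vertices)), 1e-6)
  }
  expect_lt(max(abs(colMeans(model$scores))), 1e-8)
  vs <- apply(model$scores, 2, var)
  expect_true(all(diff(vs) <= 1e-8))
  expect_lt(max(abs(tcrossprod(model$components) - diag(3))), 1e-8)
  expect_error(fit_pca(meshes, 25), "exceeds")
})

test_that("encode/decode are mutually consistent and affine", {
  pop <- small_faces(15)
  model <- fit_pca(pop$meshes, 5)
  # mean shape encodes to zero; zero decodes to the mean
  mean_m <- mean_mesh(pop$meshes)
  expect_lt(max(abs(pca_encode(model, mean_m))), 1e-8)
  expect_lt(max(abs(pca_decode(model, rep(0, 5))$vertices - mean_m$vertices)), 1e-8)
  # decode is affine in the scores
  s1 <- rnorm(5); s2 <- rnorm(5); a <- 0.3
  lhs <- pca_decode(model, a * s1 + (1 - a) * s2)$vertices
  rhs <- a * pca_decode(model, s1)$vertices + (1 - a) * pca_decode(model, s2)$vertices
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("round-trip error equals the rank-k residual from a dense SVD oracle", {
  pop <- small_faces(12, seed = 31)
  k <- 4
  model <- fit_pca(pop$meshes, k)
  X <- t(sapply(pop$meshes, function(m) as.vector(m$vertices)))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  proj <- sv$u[, 1:k] %*% diag(sv$d[1:k]) %*% t(sv$v[, 1:k])
  for (i in c(1, 5, 9)) {
    rec <- pca_decode(model, pca_encode(model, pop$meshes[[i]]))
    oracle_res <- sqrt(sum((Xc[i, ] - proj[i, ])^2))
    got_res <- sqrt(sum((as.vector(rec$vertices) - X[i, ])^2))
    expect_equal(got_res, oracle_res, tolerance = 1e-6)
  }
})

test_that("eCDF score sampling respects degenerate columns, bounds and marginals", {
  pop <- small_faces(40, seed = 32)
  model <- fit_pca(pop$meshes, 6)
  # degenerate eCDF: constant training scores reproduce the constant
  model2 <- model
  model2$scores[, 3] <- 1.25
  S <- sample_scores(model2, 50, seed = 1)
  expect_true(all(S[, 3] == 1.25))
  # bounds per component
  S <- sample_scores(model, 400, seed = 2)
  expect_true(all(S >= matrix(apply(model$scores, 2, min), 400, 6, byrow = TRUE) - 1e-9))
  expect_true(all(S <= matrix(apply(model$scores, 2, max), 400, 6, byrow = TRUE) + 1e-9))
  # step sampling draws only training values
  Ss <- sample_scores(model, 100, seed = 3, method = "step")
  expect_true(all(Ss[, 1] %in% model$scores[, 1]))
  # marginal recovery: two-sample KS against training scores
  S2 <- sample_scores(model, 2000, seed = 4)
  pv <- vapply(1:6, function(j)
    suppressWarnings(stats::ks.test(S2[, j], model$scores[, j]))$p.value, 0)
  expect_gte(mean(pv > 0.01), 0.95)
})

test_that("independent sampling destroys engineered cross-component dependence", {
  set.seed(33)
  # population with s2 deterministically dependent on s1 (curved manifold)
  n <- 300; nv <- 40
  basis <- qr.Q(qr(matrix(rnorm(3 * nv * 2), 3 * nv, 2)))
  s1 <- rnorm(n, sd = 4)
  s2 <- (s1^2 - 16) / 8
  X <- cbind(s1, s2) %*% t(basis)
  meshes <- lapply(1:n, function(i)
    registered_mesh(matrix(X[i, ], ncol = 3), rbind(c(1, 2, 3)), "dep"))
  model <- fit_pca(meshes, 2)
  tr_dep <- abs(cor(model$scores[, 1]^2, model$scores[, 2]))
  expect_gt(tr_dep, 0.9)
  S <- sample_scores(model, 2000, seed = 5)
  expect_lt(abs(cor(S[, 1]^2, S[, 2])), 0.1)
  expect_lt(abs(cor(S[, 1], S[, 2])), 0.1)
})

test_that("sampled meshes are reproducible, valid, and centred on the mean", {
  pop <- small_faces(30, 8, 8, seed = 34)
  model <- fit_pca(pop$meshes, 4)
  a <- sample_meshes(model, 5, seed = 6)
  b <- sample_meshes(model, 5, seed = 6)
  expect_identical(a[[3]]$vertices, b[[3]]$vertices)
  expect_identical(a[[1]]$faces, pop$meshes[[1]]$faces)
  big <- sample_meshes(model, 1000, seed = 7)
  avg <- Reduce(`+`, lapply(big, function(m) m$vertices)) / 1000
  mean_v <- mean_mesh(pop$meshes)$vertices
  expect_lt(max(abs(avg - mean_v)), 2)
})
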