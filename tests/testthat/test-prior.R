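test_that("the prior memorizes identical code maps and argmax-samples them back", {
  set.seed(60)
  K <- 16
  map <- matrix(sample.int(K, 36, replace = TRUE), 6, 6)
  codes <- const_codes(map, 30)
  cfg <- prior_config(K, epochs = 25, batch_size = 8, seed = 2)
  top <- train_prior(codes, "top", cfg)
  expect_gte(utils::tail(top$history$val_accuracy, 1), 0.99)
  # convergence beats chance 1/K by >= 10x
  expect_gte(utils::tail(top$history$val_accuracy, 1), 10 / K)
  bottom <- train_prior(codes, "bottom", cfg)
  expect_gte(utils::tail(bottom$history$val_accuracy, 1), 0.99)
  # temperature -> 0 reproduces the memorized map
  s <- sample_codes(top, bottom, 2, temperature = 1e-6, seed = 5)
  expect_identical(s[[1]]$top, map)
  expect_identical(s[[1]]$bottom, map)
  expect_identical(s[[2]]$bottom, map)
})

test_that("predictions are strictly causal in raster order", {
  set.seed(61)
  K <- 6
  map <- matrix(sample.int(K, 25, replace = TRUE), 5, 5)
  codes <- const_codes(map, 10)
  cfg <- prior_config(K, epochs = 3, batch_size = 4, seed = 1)
  top <- train_prior(codes, "top", cfg)
  base <- prior_logit_map(top, codes[[1]])
  for (t in c(8, 15, 25)) {
    pert <- map
    r <- (t - 1) %/% 5 + 1; c <- (t - 1) %% 5 + 1
    pert[r, c] <- (pert[r, c] %% K) + 1L
    lg <- prior_logit_map(top, structure(list(top = pert, bottom = pert),
                                         class = "latent_codes"))
    expect_equal(lg[seq_len(t - 1), , drop = FALSE],
                 base[seq_len(t - 1), , drop = FALSE])
  }
})

test_that("uniform random codes keep validation accuracy at chance level", {
  set.seed(62)
  K <- 4
  mk <- function() {
    m <- matrix(sample.int(K, 36, replace = TRUE), 6, 6)
    structure(list(top = m, bottom = m), class = "latent_codes")
  }
  train <- replicate(300, mk(), simplify = FALSE)
  val <- replicate(100, mk(), simplify = FALSE)
  cfg <- prior_config(K, epochs = 8, batch_size = 32, seed = 3)
  model <- train_prior(train, "top", cfg, val_codes = val)
  acc <- utils::tail(model$history$val_accuracy, 1)
  expect_gt(acc, 0.25 - 0.05)
  expect_lt(acc, 0.25 + 0.05)
})

test_that("sampling is seeded-deterministic and hotter temperatures raise entropy", {
  set.seed(63)
  K <- 6
  # structured but stochastic maps: strong row pattern plus noise
  mk <- function() {
    base <- matrix(rep(rep(1:3, each = 2), 6), 6, 6, byrow = TRUE)
    noise <- matrix(sample.int(K, 36, TRUE), 6, 6)
    pick <- matrix(runif(36) < 0.25, 6, 6)
    m <- base; m[pick] <- noise[pick]
    structure(list(top = m, bottom = m), class = "latent_codes")
  }
  codes <- replicate(60, mk(), simplify = FALSE)
  cfg <- prior_config(K, epochs = 15, batch_size = 16, seed = 4)
  top <- train_prior(codes, "top", cfg)
  bottom <- train_prior(codes, "bottom", cfg)
  s1 <- sample_codes(top, bottom, 3, temperature = 1, seed = 9)
  s2 <- sample_codes(top, bottom, 3, temperature = 1, seed = 9)
  expect_identical(s1, s2)
  expect_error(sample_codes(top, bottom, 2, temperature = 0), "temperature")
  entropy_at <- function(temp) {
    s <- sample_codes(top, bottom, 100, temperature = temp, seed = 10)
    tops <- t(sapply(s, function(x) as.vector(x$top)))
    mean(apply(tops, 2, function(col) {
      p <- tabulate(col, K) / length(col)
      -sum(p[p > 0] * log(p[p > 0]))
    }))
  }
  expect_gt(entropy_at(3), entropy_at(1))
})

test_that("a bottom-level prior without a top map is rejected", {
  set.seed(64)
  map <- matrix(sample.int(4, 16, TRUE), 4, 4)
  codes <- const_codes(map, 8)
  cfg <- prior_config(4, epochs = 2, batch_size = 4, seed = 1)
  bottom <- train_prior(codes, "bottom", cfg)
  Cm <- matrix(as.vector(t(map)), 1)
  expect_error(
    shapesynth:::prior_forward(bottom$params, bottom$config, bottom$geom, Cm, NULL),
    "top"
  )
})

test_that("end-to-end generation yields valid, distinct meshes with IoU report", {
  pop <- small_faces(24, 16, 16, seed = 65)
  imgs <- lapply(pop$meshes, face_to_image, grid = pop$grid)
  rg <- fit_ranges(imgs)
  nimgs <- lapply(imgs, normalize_image, ranges = rg)
  vcfg <- vq_config(16, 16, 3, K = 16, D = 2, epochs = 8, batch_size = 8, seed = 5)
  vq <- train_vqvae(nimgs, vcfg)
  codes <- lapply(nimgs, encode_to_codes, model = vq)
  pcfg <- prior_config(16, epochs = 10, batch_size = 8, seed = 6)
  top <- train_prior(codes, "top", pcfg)
  bottom <- train_prior(codes, "bottom", pcfg)
  gen <- generate_shapes(vq, top, bottom, rg, 5, kind = "face", grid = pop$grid,
                         seed = 11)
  expect_length(gen$meshes, 5)
  for (m in gen$meshes) {
    expect_s3_class(m, "registered_mesh")
    expect_identical(m$faces, pop$meshes[[1]]$faces)
  }
  # all outputs differ pairwise
  for (i in 1:4) for (j in (i + 1):5)
    expect_gt(weighted_rmse(gen$meshes[[i]], gen$meshes[[j]]), 0)
  expect_length(gen$iou, 5)
  expect_true(all(gen$iou >= 0 & gen$iou <= 1))
})
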