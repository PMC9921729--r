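test_that("diversity matches hand values and absorbs rigid motion when aligned", {
  m1 <- tiny_mesh()
  expect_identical(diversity(m1, m1, align = FALSE), 0)
  # the weighted hand case (no alignment)
  V1 <- rbind(c(0, 0, 0), c(1, 0, 0))
  V2 <- rbind(c(0, 0, 0), c(3, 0, 0))
  f <- rbind(c(1, 2, 1))
  a <- registered_mesh(V1, f, "pair")
  b <- registered_mesh(V2, f, "pair")
  expect_equal(diversity(a, b, vertex_weights(c(1, 3)), align = FALSE), sqrt(3),
               tolerance = 1e-10)
  # rigid motion of a mesh has zero aligned diversity
  set.seed(40)
  m <- random_mesh(12)
  moved <- transform_mesh(m, random_rotation_fx(), rnorm(3, sd = 20))
  expect_lt(diversity(m, moved, align = TRUE), 1e-8)
})

test_that("specificity is the minimum distance to the training set", {
  set.seed(41)
  m <- random_mesh(8, "s")
  t1 <- registered_mesh(m$vertices + cbind(rep(1, 8), 0, 0), m$faces, "s")
  t2 <- registered_mesh(m$vertices + cbind(rep(2, 8), 0, 0), m$faces, "s")
  expect_equal(specificity(m, list(t1, t2), align = FALSE), 1, tolerance = 1e-10)
  expect_identical(specificity(m, list(t1, m), align = FALSE), 0)
  # bounded above by the diversity to every training scan
  for (t in list(t1, t2))
    expect_lte(specificity(m, list(t1, t2), align = FALSE),
               diversity(m, t, align = FALSE))
  expect_error(specificity(m, list()), "empty")
})

test_that("both metrics reduce to plain RMSE under uniform weights", {
  set.seed(42)
  pop <- small_faces(10, 8, 8)
  plain_rmse <- function(V1, V2) sqrt(mean(rowSums((V1 - V2)^2)))
  for (i in 1:20) {
    p <- sample(10, 2)
    a <- pop$meshes[[p[1]]]; b <- pop$meshes[[p[2]]]
    expect_equal(diversity(a, b, align = FALSE),
                 plain_rmse(a$vertices, b$vertices), tolerance = 1e-10)
  }
})

test_that("diversity distributions draw distinct seeded pairs", {
  pop <- small_faces(10, 8, 8)
  d <- diversity_distribution(pop$meshes, 20, align = FALSE, seed = 3)
  expect_equal(d$n, 20)
  expect_true(all(d$values > 0))
  d2 <- diversity_distribution(pop$meshes, 20, align = FALSE, seed = 3)
  expect_identical(d$values, d2$values)
  expect_error(diversity_distribution(pop$meshes, 46, align = FALSE), "pairs")
  # all-identical population
  same <- rep(pop$meshes[1], 5)
  expect_true(all(diversity_distribution(same, 8, align = FALSE)$values == 0))
})

test_that("specificity distributions give one value per sample", {
  pop <- small_faces(8, 8, 8)
  sd1 <- specificity_distribution(pop$meshes[1:4], pop$meshes, align = FALSE)
  expect_equal(sd1$n, 4)
  expect_true(all(sd1$values == 0))  # samples are training members
  sd2 <- specificity_distribution(pop$meshes[5:8], pop$meshes[1:4], align = FALSE)
  expect_true(all(sd2$values >= 0))
})

test_that("distribution comparison returns KS extremes and a summary", {
  a <- shapesynth:::metric_distribution("diversity", c(1, 2, 3, 4), "test")
  self <- compare_distributions(a, a)
  expect_equal(self$ks_statistic, 0)
  b <- shapesynth:::metric_distribution("diversity", c(10, 11, 12), "pca")
  disj <- compare_distributions(a, b)
  expect_equal(disj$ks_statistic, 1)
  expect_s3_class(disj$summary, "data.frame")
  c_ <- shapesynth:::metric_distribution("specificity", 1:3, "x")
  expect_error(compare_distributions(a, c_), "compare")
  # null calibration: two seeded draws from one generator population
  pop <- small_faces(40, 8, 8, seed = 43)
  d1 <- diversity_distribution(pop$meshes[1:20], 60, align = FALSE, seed = 1)
  d2 <- diversity_distribution(pop$meshes[21:40], 60, align = FALSE, seed = 2)
  expect_gt(compare_distributions(d1, d2)$p_value, 0.01)
})

test_that("failure detection IoU matches hand-set arithmetic", {
  H <- 10; W <- 10
  template_fg <- matrix(TRUE, H, W)
  template_fg[1:5, 1:10] <- FALSE           # 50 background pixels
  mk <- function(bg) {
    px <- array(0.5, c(H, W, 3))
    for (ch in 1:3) { sl <- px[, , ch]; sl[bg] <- 0; px[, , ch] <- sl }
    geometric_image(px, space = "normalized")
  }
  # sample background identical to template: IoU 1, not failed
  r <- detect_failed_sample(mk(!template_fg), template_fg)
  expect_equal(r$iou, 1)
  expect_false(r$failed)
  # disjoint: sample bg where template is fg
  bg2 <- matrix(FALSE, H, W); bg2[6:10, 1:10] <- TRUE
  r2 <- detect_failed_sample(mk(bg2), template_fg)
  expect_equal(r2$iou, 0)
  expect_true(r2$failed)
  # half overlap: sample bg = 25 of the 50 template bg pixels
  bg3 <- matrix(FALSE, H, W); bg3[1:5, 1:5] <- TRUE
  expect_equal(detect_failed_sample(mk(bg3), template_fg)$iou, 0.5)
  # both masks empty
  all_fg <- matrix(TRUE, H, W)
  expect_equal(detect_failed_sample(mk(matrix(FALSE, H, W)), all_fg)$iou, 1)
})

test_that("metric CSV export is tidy", {
  a <- shapesynth:::metric_distribution("diversity", c(1, 2), "test")
  b <- shapesynth:::metric_distribution("specificity", c(3), "vq")
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- write_metric_csv(list(a, b), f)
  got <- read.csv(f)
  expect_equal(nrow(got), 3)
  expect_equal(got$provenance, c("test", "test", "vq"))
})
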