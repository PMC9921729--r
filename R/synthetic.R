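#' Specification of a synthetic shape population
#'
#' Describes a seeded population of registered synthetic shapes with known
#' low-rank latent structure, used to exercise the full pipeline without
#' proprietary scan data. Latent factors are drawn i.i.d. Gaussian with
#' standard deviation `factor_sd` (mm); `noise_sd` adds per-vertex
#' displacement noise.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param kind `"face_grid"` or `"body"`.
#' @param n_latent_factors Number of latent shape factors.
#' @param factor_sd Standard deviation of each latent factor, mm.
#' @param noise_sd Per-vertex noise standard deviation, mm.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_subjects, kind = c("face_grid", "body"),
                            n_latent_factors = NULL, factor_sd = NULL,
                            noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(factor_sd)) factor_sd <- if (kind == "face_grid") 3 else 50
  if (is.null(n_latent_factors)) n_latent_factors <- if (kind == "face_grid") 6L else 4L
  if (n_subjects < 1) stop_arg("n_subjects must be >= 1")
  if (factor_sd < 0 || noise_sd < 0) stop_arg("factor_sd and noise_sd must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), kind = kind,
                 n_latent_factors = as.integer(n_latent_factors),
                 factor_sd = factor_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# Smooth unit-peak Gaussian bump on normalized grid coordinates.
grid_bump <- function(u, v, cu, cv, su, sv) {
  exp(-((u - cu)^2 / (2 * su^2) + (v - cv)^2 / (2 * sv^2)))
}

# Deterministic library of smooth face deformation modes (unit peak, mm per
# mm of latent factor). Mode 2 is deliberately asymmetric (left cheek).
face_modes <- function(u, v, k) {
  protos <- list(
    function() grid_bump(u, v, 0.5, 0.30, 0.35, 0.25),          # forehead dome
    function() grid_bump(u, v, 0.25, 0.62, 0.12, 0.12),         # left cheek (asymmetric)
    function() grid_bump(u, v, 0.5, 0.55, 0.08, 0.22),          # nose ridge length
    function() grid_bump(u, v, 0.5, 0.9, 0.4, 0.12),            # jaw width
    function() cos(2 * pi * u) * sin(pi * v) * 0.5 + 0.5 * grid_bump(u, v, 0.5, 0.5, 0.3, 0.3),
    function() grid_bump(u, v, 0.8, 0.35, 0.15, 0.2)            # right brow (asymmetric)
  )
  m <- protos[[(k - 1L) %% length(protos) + 1L]]()
  m / max(abs(m))
}

#' Generate a registered synthetic face population
#'
#' Faces are smooth height fields over a fixed regular grid: `x` and `y` are
#' the grid coordinates (identical across subjects, spanning roughly a
#' 160 x 200 mm facial patch) and only `z` varies, as
#' `z = base profile + sum_k factor_k * mode_k + noise`.
#'
#' Latent factors start as i.i.d. Gaussians but pass through an
#' energy-regulation nonlinearity: each subject's factor vector is rescaled
#' toward the shell of radius `sqrt(k) * factor_sd` (with a small lognormal
#' jitter), so the total deformation magnitude is tightly regulated while
#' its direction varies freely. Per-factor marginals keep variance
#' `factor_sd^2`, but the joint distribution lives on a curved shell that
#' independent per-score resampling cannot reproduce — the PCA-sampling
#' weakness the evaluation metrics expose. All meshes share one
#' triangulation.
#'
#' @param spec A [population_spec()] with `kind = "face_grid"`.
#' @param grid_h,grid_w Grid dimensions (>= 8 each).
#' @param nonlinear_strength Exponent in `(target_radius / ||g||)^strength`
#'   blending raw Gaussian factors (0) into full energy regulation (1, the
#'   default).
#' @param radius_jitter Lognormal sd of the shell radius (default 0.04).
#' @return List with `meshes` (list of [registered_mesh()]), `factors`
#'   (`n x k` matrix, mm), `grid` (a [face_template_grid()]), and
#'   `subject_ids`.
#' @export
make_face_population <- function(spec, grid_h = 128L, grid_w = 128L,
                                 nonlinear_strength = 1, radius_jitter = 0.04) {
  stopifnot(inherits(spec, "population_spec"), spec$kind == "face_grid")
  if (grid_h < 8 || grid_w < 8) stop_arg("grid must be at least 8 x 8")
  H <- as.integer(grid_h); W <- as.integer(grid_w)
  grid <- face_template_grid(H, W)

  # Fixed grid coordinates: columns span x (subject's right at column 1),
  # rows span y (forehead at row 1). Face patch approx 160 x 200 mm.
  u <- (col(matrix(0, H, W)) - 1) / (W - 1)    # 0..1 left-right
  v <- (row(matrix(0, H, W)) - 1) / (H - 1)    # 0..1 top-bottom
  x <- (u - 0.5) * 160
  y <- (0.5 - v) * 200
  # Bilaterally symmetric base profile: dome + nose ridge + brow + chin.
  base_z <- 40 * grid_bump(u, v, 0.5, 0.5, 0.45, 0.55) +
    18 * grid_bump(u, v, 0.5, 0.55, 0.07, 0.18) +
    6 * grid_bump(u, v, 0.5, 0.32, 0.3, 0.08) +
    5 * grid_bump(u, v, 0.5, 0.95, 0.2, 0.1)

  k <- spec$n_latent_factors
  # Orthonormalize the smooth mode stack and scale to unit RMS so a factor
  # of 1 mm produces 1 mm RMS vertex displacement, independent of overlap
  # between the raw bumps. Modes are first projected off the rigid-motion
  # tangent space of the height field (constant and tilt z-fields), so
  # per-pair rigid alignment is a first-order no-op on this population.
  M <- vapply(seq_len(max(k, 1L)), function(j) as.vector(face_modes(u, v, j)),
              numeric(H * W))
  B <- cbind(1, as.vector(x), as.vector(y))
  M <- M - B %*% solve(crossprod(B), crossprod(B, M))
  Q <- qr.Q(qr(M)) * sqrt(H * W)
  modes <- lapply(seq_len(max(k, 1L)), function(j) matrix(Q[, j], H, W))

  with_seed(spec$seed, {
    factors <- matrix(stats::rnorm(spec$n_subjects * k, 0, spec$factor_sd),
                      spec$n_subjects, k)
    if (nonlinear_strength > 0 && spec$factor_sd > 0 && k >= 2) {
      # Energy regulation: pull each factor vector toward the shell of
      # radius sqrt(k) * factor_sd (small lognormal jitter).
      norms <- sqrt(rowSums(factors^2))
      target <- sqrt(k) * spec$factor_sd *
        exp(stats::rnorm(spec$n_subjects, 0, radius_jitter))
      scale <- ifelse(norms > 0, (target / norms)^nonlinear_strength, 1)
      factors <- factors * scale
    }
    meshes <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      z <- base_z
      for (j in seq_len(k)) z <- z + factors[i, j] * modes[[j]]
      if (spec$noise_sd > 0)
        z <- z + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
      V <- matrix(0, H * W, 3)
      # vertex_index_of[r, c] = (r-1)*W + c  (row-major)
      V[as.vector(grid$vertex_index_of), 1] <- as.vector(x)
      V[as.vector(grid$vertex_index_of), 2] <- as.vector(y)
      V[as.vector(grid$vertex_index_of), 3] <- as.vector(z)
      meshes[[i]] <- registered_mesh(V, grid$faces, grid$template_id)
    }
    list(meshes = meshes, factors = factors, grid = grid,
         subject_ids = sprintf("face%05d", seq_len(spec$n_subjects)))
  })
}

# ---- synthetic bodies -------------------------------------------------------

# Polar cross-section radius r(theta, z_frac) of the base body, mm.
# Soft p-norm union of primitive lobes: torso/head/neck ellipses on the axis,
# offset arm and leg circles, and a thin bridge keeping the section
# star-shaped between the legs.
body_radius <- function(theta, zf, girth = 1, arm = 1, leg = 1) {
  ct <- cos(theta); st <- sin(theta)
  r_ellipse <- function(a, b) {
    ok <- a > 0 & b > 0
    r <- numeric(length(a))
    r[ok] <- 1 / sqrt((ct[ok] / a[ok])^2 + (st[ok] / b[ok])^2)
    r
  }
  # Far ray-circle intersection for circle centred (cx, 0), radius R (0 if missed).
  r_offset_circle <- function(cx, R) {
    disc <- R^2 - (cx * st)^2
    ok <- disc > 0 & R > 0
    t <- numeric(length(disc))
    t[ok] <- cx[ok] * ct[ok] + sqrt(disc[ok])
    pmax(t, 0)
  }

  torso_a <- profile_fun(c(0.44, 0.52, 0.60, 0.70, 0.815, 0.86),
                         c(150, 168, 148, 166, 182, 60))(zf) * girth
  torso_b <- profile_fun(c(0.44, 0.52, 0.60, 0.70, 0.815, 0.86),
                         c(105, 118, 102, 114, 106, 55))(zf) * girth
  neck_r  <- profile_fun(c(0.835, 0.86, 0.885), c(0, 52, 58))(zf) * girth
  head_a  <- profile_fun(c(0.865, 0.90, 0.935, 0.97, 0.995, 1.0),
                         c(40, 72, 80, 62, 28, 2))(zf) * girth
  head_b  <- profile_fun(c(0.865, 0.90, 0.935, 0.97, 0.995, 1.0),
                         c(45, 85, 98, 75, 32, 2))(zf) * girth

  arm_x <- profile_fun(c(0.50, 0.55, 0.62, 0.72, 0.80, 0.835),
                       c(190, 196, 200, 200, 194, 182))(zf) * girth
  arm_r <- profile_fun(c(0.50, 0.53, 0.60, 0.70, 0.78, 0.815, 0.835),
                       c(0, 24, 32, 37, 42, 40, 12))(zf) * arm

  leg_x <- profile_fun(c(0.0, 0.04, 0.28, 0.44, 0.52, 0.56),
                       c(88, 88, 92, 96, 88, 70))(zf) * girth
  leg_r <- profile_fun(c(0.0, 0.04, 0.28, 0.44, 0.52, 0.56),
                       c(58, 44, 56, 80, 92, 0))(zf) * leg
  bridge_on <- smoothstep(zf, -0.01, 0.0) * (1 - smoothstep(zf, 0.50, 0.56))

  p <- 10
  acc <- r_ellipse(torso_a, torso_b)^p +
    r_ellipse(neck_r, neck_r)^p +
    r_ellipse(head_a, head_b)^p +
    r_offset_circle(arm_x, arm_r)^p + r_offset_circle(-arm_x, arm_r)^p +
    r_offset_circle(leg_x, leg_r)^p + r_offset_circle(-leg_x, leg_r)^p +
    (bridge_on * r_ellipse(leg_x + 0.3 * leg_r, rep(20, length(zf))))^p
  acc^(1 / p)
}

#' Generate a registered synthetic body population
#'
#' Bodies are closed, watertight, genus-0 meshes built as a single
#' star-shaped tube: `n_z` horizontal rings of `n_theta` vertices whose polar
#' radius field is a smooth soft-max union of primitive lobes (torso, head,
#' neck, two arms hanging down, two legs joined by a thin bridge), capped by
#' pole vertices at the soles and crown. Standing height of the base body is
#' 1700 mm. The first four latent factors modulate stature, girth, arm
#' thickness and leg thickness; girth additionally couples nonlinearly with
#' stature (`(height/1700)^0.4`), so the population is not an exact linear
#' subspace. All meshes share one topology (full correspondence).
#'
#' Coordinate convention: z up, y from back to front, x to the subject's
#' left; units mm.
#'
#' @param spec A [population_spec()] with `kind = "body"`.
#' @param resolution Ring count `n_z` (also used for `n_theta`); must give at
#'   least 500 vertices (`resolution >= 23`). The default (48) yields 2306
#'   vertices.
#' @return List with `meshes`, `factors` (`n x k`, mm), `subject_ids`.
#' @export
make_body_population <- function(spec, resolution = 48L) {
  stopifnot(inherits(spec, "population_spec"), spec$kind == "body")
  n_z <- as.integer(resolution)
  n_theta <- as.integer(resolution)
  if (n_z * n_theta + 2L < 500L) stop_arg("resolution too small: need >= 500 vertices")

  theta <- 2 * pi * (seq_len(n_theta) - 0.5) / n_theta
  zf <- seq_len(n_z) / (n_z + 1)              # ring heights as fraction of stature
  faces <- tube_faces(n_z, n_theta)
  k <- spec$n_latent_factors
  H0 <- 1700

  with_seed(spec$seed, {
    factors <- matrix(stats::rnorm(spec$n_subjects * k, 0, spec$factor_sd),
                      spec$n_subjects, k)
    meshes <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      f <- c(factors[i, ], rep(0, 4))[1:4]
      height <- H0 + f[1]
      girth <- (1 + f[2] / 500) * (height / H0)^0.4
      arm <- 1 + f[3] / 250
      leg <- 1 + f[4] / 250
      V <- matrix(0, n_z * n_theta + 2L, 3)
      for (iz in seq_len(n_z)) {
        r <- body_radius(theta, rep(zf[iz], n_theta), girth, arm, leg)
        if (spec$noise_sd > 0) r <- pmax(r + stats::rnorm(n_theta, 0, spec$noise_sd), 1)
        rows <- (iz - 1L) * n_theta + seq_len(n_theta)
        V[rows, 1] <- r * cos(theta)
        V[rows, 2] <- r * sin(theta)
        V[rows, 3] <- zf[iz] * height
      }
      V[n_z * n_theta + 1L, ] <- c(0, 0, 0)        # bottom pole (soles)
      V[n_z * n_theta + 2L, ] <- c(0, 0, height)   # top pole (crown)
      meshes[[i]] <- registered_mesh(V, faces, sprintf("body-tube-%dx%d", n_z, n_theta))
    }
    list(meshes = meshes, factors = factors,
         subject_ids = sprintf("body%05d", seq_len(spec$n_subjects)))
  })
}

# Triangulation of the ring tube plus the two pole fans (watertight).
tube_faces <- function(n_z, n_theta) {
  vid <- function(iz, j) (iz - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  quads <- vector("list", n_z - 1L)
  for (iz in seq_len(n_z - 1L)) {
    j <- seq_len(n_theta)
    quads[[iz]] <- rbind(
      cbind(vid(iz, j), vid(iz, j + 1L), vid(iz + 1L, j)),
      cbind(vid(iz, j + 1L), vid(iz + 1L, j + 1L), vid(iz + 1L, j))
    )
  }
  pb <- n_z * n_theta + 1L
  pt <- n_z * n_theta + 2L
  j <- seq_len(n_theta)
  bottom <- cbind(rep(pb, n_theta), vid(1L, j + 1L), vid(1L, j))
  top <- cbind(rep(pt, n_theta), vid(n_z, j), vid(n_z, j + 1L))
  do.call(rbind, c(quads, list(bottom, top)))
}

#' Mean shape of a registered population
#'
#' @param meshes Non-empty list of comparable [registered_mesh()] objects.
#' @return A [registered_mesh()] with the vertex-wise mean coordinates.
#' @export
mean_mesh <- function(meshes) {
  if (!length(meshes)) stop_arg("empty mesh list")
  V <- Reduce(`+`, lapply(meshes, function(m) m$vertices)) / length(meshes)
  registered_mesh(V, meshes[[1]]$faces, meshes[[1]]$template_id)
}

#' Subject-stratified train/validation/test split
#'
#' All meshes belonging to one subject id land in the same split (so
#' augmented copies never leak across splits). Split sizes in subjects match
#' the requested fractions to within one subject (largest-remainder
#' rounding); assignment is a seeded permutation of the unique subject ids.
#'
#' @param subject_ids Character vector, one id per mesh.
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1.
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `val`, `test` into the
#'   original mesh order.
#' @export
split_dataset <- function(subject_ids, fractions = c(0.9, 0.05, 0.05), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop_arg("fractions must be three values summing to 1")
  subjects <- unique(subject_ids)
  if (length(subjects) < 3L) stop_arg("need at least 3 subjects to form 3 splits")
  with_seed(seed, {
    subjects <- sample(subjects)
    n <- length(subjects)
    raw <- fractions * n
    counts <- floor(raw)
    rem <- n - sum(counts)
    if (rem > 0) {
      order_rem <- order(raw - counts, decreasing = TRUE)
      counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1L
    }
    groups <- rep(c("train", "val", "test"), counts)
    assign_of <- stats::setNames(groups, subjects)
    lapply(stats::setNames(c("train", "val", "test"), c("train", "val", "test")),
           function(g) which(assign_of[subject_ids] == g))
  })
}

#' Save a population as PLY files plus a sidecar CSV
#'
#' @param population Result of [make_face_population()] or
#'   [make_body_population()].
#' @param dir Output directory (created if needed).
#' @param binary Write binary PLY.
#' @return `dir`, invisibly.
#' @export
save_population <- function(population, dir, binary = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- population$subject_ids
  for (i in seq_along(population$meshes))
    write_mesh(population$meshes[[i]], file.path(dir, paste0(ids[i], ".ply")),
               format = "ply", binary = binary)
  tab <- data.frame(subject_id = ids, file = paste0(ids, ".ply"),
                    population$factors)
  names(tab)[-(1:2)] <- paste0("factor", seq_len(ncol(population$factors)))
  utils::write.csv(tab, file.path(dir, "population.csv"), row.names = FALSE)
  invisible(dir)
}
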