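# Shared fixtures built in code at test time.

tiny_mesh <- function(template_id = "tiny") {
  registered_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 3, 4)),
                  template_id)
}

random_mesh <- function(n = 10, template_id = "rnd") {
  registered_mesh(matrix(stats::rnorm(n * 3, sd = 10), n, 3),
                  rbind(c(1, 2, 3)), template_id)
}

random_rotation_fx <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Small face population shared by several tests.
small_faces <- function(n = 12, h = 16, w = 16, seed = 42) {
  make_face_population(population_spec(n, "face_grid", seed = seed), h, w)
}

small_bodies <- function(n = 3, resolution = 24, seed = 5) {
  make_body_population(population_spec(n, "body", seed = seed), resolution)
}

# Identical latent-code maps (memorizable prior dataset).
const_codes <- function(map, n) {
  rep(list(structure(list(top = map, bottom = map), class = "latent_codes")), n)
}

# Brute-force rigid alignment oracle: dense grid over Euler angles plus
# local refinement; independent of the Kabsch path.
brute_force_align_residual <- function(Vs, Vt, w) {
  rot_euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) {
    R <- rot_euler(a)
    Va <- Vs %*% t(R)
    # optimal translation matches weighted centroids
    tv <- colSums((Vt - Va) * w) / sum(w)
    Va <- sweep(Va, 2, tv, `+`)
    sqrt(sum(w * rowSums((Va - Vt)^2)) / sum(w))
  }
  grid <- seq(-pi, pi, length.out = 9)
  best <- NULL; best_val <- Inf
  for (a1 in grid) for (a2 in seq(-pi / 2, pi / 2, length.out = 5)) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_val) { best_val <- v; best <- c(a1, a2, a3) }
  }
  res <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  res <- stats::optim(res$par, obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  res$value
}
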