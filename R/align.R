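#' Weighted rigid alignment of two registered meshes
#'
#' Finds the rotation (determinant +1, no reflection or scaling) and
#' translation minimizing the weighted RMSE between corresponding vertices,
#' via the weighted Kabsch algorithm: SVD of the weighted cross-covariance of
#' centred vertex sets, with the sign of the smallest singular direction
#' corrected to exclude reflections. Weighted centroids of the aligned source
#' and the target coincide exactly.
#'
#' @param source,target Comparable [registered_mesh()] objects.
#' @param w Optional [vertex_weights()]; uniform if omitted.
#' @return List with `aligned` (the transformed source mesh), `transform`
#'   (list of 3x3 `rotation` and length-3 `translation` in mm), and
#'   `residual`, the minimized weighted RMSE in mm.
#' @export
rigid_align <- function(source, target, w = NULL) {
  check_comparable(source, target)
  Vs <- source$vertices
  Vt <- target$vertices
  n <- nrow(Vs)
  if (is.null(w)) w <- rep(1, n)
  w <- as.numeric(w)
  if (length(w) != n) stop_arg("weight length %d != %d vertices", length(w), n)
  sw <- sum(w)
  if (sw <= 0) stop_arg("all-zero vertex weights")

  mus <- colSums(Vs * w) / sw
  mut <- colSums(Vt * w) / sw
  Cs <- sweep(Vs, 2, mus)
  Ct <- sweep(Vt, 2, mut)
  H <- crossprod(Cs * w, Ct)                 # 3x3 weighted cross-covariance
  sv <- svd(H)
  # Degeneracy: all weighted vertices collinear (rank of spread <= 1).
  spread <- svd(Cs * sqrt(w), nu = 0, nv = 0)$d
  if (spread[2] <= 1e-9 * max(spread[1], 1))
    stop_arg("degenerate alignment: source vertices are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(mut - R %*% mus)
  Va <- Vs %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE)
  aligned <- registered_mesh(Va, source$faces, source$template_id)
  list(
    aligned = aligned,
    transform = list(rotation = R, translation = t_vec),
    residual = weighted_rmse(Va, Vt, w)
  )
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh A [registered_mesh()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation (mm).
#' @return The transformed mesh.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  V <- mesh$vertices %*% t(rotation) +
    matrix(translation, nrow(mesh$vertices), 3, byrow = TRUE)
  registered_mesh(V, mesh$faces, mesh$template_id)
}

# Random rotation matrix (uniform via QR of Gaussian, det corrected to +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
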