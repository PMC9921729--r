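#' Registered triangle mesh
#'
#' A triangle mesh in full vertex correspondence with a template: vertex `i`
#' denotes the same anatomical location on every subject sharing the template,
#' so vertex-wise arithmetic (distances, averages, PCA) is meaningful.
#' Coordinates are millimetres throughout the package.
#'
#' @param vertices Numeric `N x 3` matrix of vertex coordinates (mm).
#' @param faces Integer `M x 3` matrix of 1-based vertex indices.
#' @param template_id Character label naming the template; two meshes are
#'   comparable iff their `template_id` and vertex count match.
#' @return An object of class `registered_mesh` with fields `vertices`,
#'   `faces`, `template_id`.
#' @export
registered_mesh <- function(vertices, faces, template_id = "template") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L || nrow(vertices) < 1L)
    stop_arg("vertices must be a non-empty N x 3 matrix")
  if (!all(is.finite(vertices)))
    stop_arg("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (length(faces) && ncol(faces) != 3L)
    stop_arg("faces must be an M x 3 matrix of vertex indices")
  if (length(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_arg("face indices out of range [1, %d]", nrow(vertices))
  structure(
    list(vertices = vertices, faces = faces, template_id = as.character(template_id)),
    class = "registered_mesh"
  )
}

#' @export
print.registered_mesh <- function(x, ...) {
  cat(sprintf("registered_mesh: %d vertices, %d triangles, template '%s'\n",
              nrow(x$vertices), nrow(x$faces), x$template_id))
  invisible(x)
}

#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

is_mesh <- function(x) inherits(x, "registered_mesh")

# Check that two meshes may be compared vertex-wise.
check_comparable <- function(m1, m2) {
  if (!is_mesh(m1) || !is_mesh(m2)) stop_arg("expected registered_mesh objects")
  if (m1$template_id != m2$template_id)
    stop_arg("meshes are not comparable: template ids differ ('%s' vs '%s')",
             m1$template_id, m2$template_id)
  if (nrow(m1$vertices) != nrow(m2$vertices))
    stop_arg("meshes are not comparable: vertex counts differ (%d vs %d)",
             nrow(m1$vertices), nrow(m2$vertices))
  invisible(TRUE)
}

#' Per-vertex weights for shape distances
#'
#' Nonnegative weights, one per vertex, used by [weighted_rmse()] and
#' [rigid_align()]. The default is uniform weighting.
#'
#' @param w Numeric vector of nonnegative weights, or a single count `n`
#'   to create uniform weights of length `n`.
#' @return Numeric weight vector of class `vertex_weights`.
#' @export
vertex_weights <- function(w) {
  if (length(w) == 1L && w == round(w) && w >= 1) w <- rep(1, w)
  w <- as.numeric(w)
  if (any(!is.finite(w)) || any(w < 0)) stop_arg("weights must be finite and nonnegative")
  if (sum(w) <= 0) stop_arg("at least one vertex weight must be positive")
  structure(w, class = "vertex_weights")
}

as_vertex_matrix <- function(x) {
  if (is_mesh(x)) x$vertices else as.matrix(x)
}

#' Weighted RMSE distance between corresponding vertices
#'
#' The root of the weighted mean squared Euclidean distance between vertex
#' pairs: `sqrt(sum_i w_i ||v1_i - v2_i||^2 / sum_i w_i)`. This is the base
#' distance underlying the diversity and specificity metrics.
#'
#' @param v1,v2 `N x 3` vertex matrices or `registered_mesh` objects with
#'   equal vertex counts.
#' @param w Optional [vertex_weights()]; uniform if omitted.
#' @return Distance in mm (nonnegative scalar).
#' @export
weighted_rmse <- function(v1, v2, w = NULL) {
  V1 <- as_vertex_matrix(v1)
  V2 <- as_vertex_matrix(v2)
  if (is_mesh(v1) && is_mesh(v2)) check_comparable(v1, v2)
  if (nrow(V1) != nrow(V2)) stop_arg("vertex counts differ (%d vs %d)", nrow(V1), nrow(V2))
  if (is.null(w)) w <- rep(1, nrow(V1))
  w <- as.numeric(w)
  if (length(w) != nrow(V1)) stop_arg("weight length %d != %d vertices", length(w), nrow(V1))
  if (sum(w) <= 0) stop_arg("all-zero vertex weights")
  d2 <- rowSums((V1 - V2)^2)
  sqrt(sum(w * d2) / sum(w))
}
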