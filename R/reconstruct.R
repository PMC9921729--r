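# Closed-form 2D -> 3D inversion: Laplacian-regularized sparse least squares
# recovering all template vertices (including ones invisible in every view)
# from multiview pixel observations.

#' Uniform (umbrella) mesh Laplacian
#'
#' Row `i` is `e_i - mean of e_j over edge-neighbours j`: zero on constant
#' fields, it measures each vertex's offset from the average of its
#' neighbours and is used to fill unobserved vertices smoothly. Topology-only
#' (scan-independent). Isolated vertices get a zero row and a warning.
#'
#' @param faces `M x 3` triangle matrix (1-based).
#' @param n_vertices Vertex count.
#' @return Sparse `N x N` [Matrix::sparseMatrix()] with attribute
#'   `flavor = "uniform"`.
#' @export
build_laplacian <- function(faces, n_vertices) {
  faces <- as.matrix(faces)
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))              # directed unique edges
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(n_vertices, n_vertices))
  deg <- Matrix::rowSums(A)
  iso <- which(deg == 0)
  if (length(iso))
    warning(sprintf("%d isolated vertices have zero Laplacian rows", length(iso)))
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  L <- Matrix::Diagonal(n_vertices, x = as.numeric(deg > 0)) -
    Matrix::Diagonal(n_vertices, inv_deg) %*% A
  attr(L, "flavor") <- "uniform"
  L
}

#' Reconstruction problem
#'
#' Bundles the sparse registration matrix, observed pixel positions, the
#' mesh Laplacian, the prior (mean-template) vertices and the regularization
#' weight of the quadratic cost
#' `||G V - P||^2 + alpha ||L V - L V0||^2` (mm units).
#'
#' @param reg A [build_G()] result (or a bare sparse matrix G).
#' @param P `n_obs x 3` observed xyz values (mm).
#' @param L Laplacian from [build_laplacian()].
#' @param V0 `N x 3` prior vertices (mm).
#' @param alpha Regularization weight (>= 0); default 0.001 for mm inputs.
#' @return A `reconstruction_problem` list.
#' @export
reconstruction_problem <- function(reg, P, L, V0, alpha = 0.001) {
  G <- if (inherits(reg, "sparse_registration")) reg$G else reg
  P <- as.matrix(P)
  V0 <- as.matrix(V0)
  if (alpha < 0) stop_arg("alpha must be >= 0")
  if (nrow(P) != nrow(G)) stop_arg("P has %d rows; G has %d", nrow(P), nrow(G))
  if (ncol(G) != nrow(V0)) stop_arg("V0 has %d vertices; G has %d columns",
                                    nrow(V0), ncol(G))
  if (!identical(dim(L), c(nrow(V0), nrow(V0)))) stop_arg("L dimensions mismatch")
  structure(list(G = G, P = P, L = L, V0 = V0, alpha = alpha),
            class = "reconstruction_problem")
}

#' Solve for vertex positions (closed form)
#'
#' Unique minimizer of the quadratic cost via the SPD normal equations
#' `(G'G + alpha L'L) V = G'P + alpha L'L V0`, solved by sparse Cholesky
#' with one factorization shared by the x, y, z right-hand sides.
#'
#' A connected component with no observed vertex leaves its translation
#' undetermined by the Laplacian term alone; with `alpha > 0` such
#' components are anchored to the prior `V0` (an entirely unobserved mesh
#' reconstructs exactly as `V0`). With `alpha = 0` the singular system is an
#' error naming the unobserved components.
#'
#' @param problem A [reconstruction_problem()].
#' @return `N x 3` vertex matrix (mm).
#' @export
solve_vertices <- function(problem) {
  G <- problem$G; L <- problem$L; alpha <- problem$alpha
  n <- ncol(G)
  A <- Matrix::crossprod(G) + alpha * Matrix::crossprod(L)
  rhs <- as.matrix(Matrix::crossprod(G, problem$P) +
                     alpha * Matrix::crossprod(L) %*% problem$V0)
  obs <- Matrix::colSums(G != 0) > 0
  if (!all(obs)) {
    bad <- unobserved_components(G, L)
    if (length(bad)) {
      if (alpha <= 0)
        stop_arg("singular reconstruction system: %d connected component(s) have no observed vertex (e.g. vertices %s) and alpha = 0 provides no prior",
                 length(bad), paste(utils::head(unlist(bad), 5), collapse = ", "))
      # Anchor unobserved components softly to the prior; exact V0 there.
      anchor <- unlist(bad)
      d <- numeric(n); d[anchor] <- alpha
      A <- A + Matrix::Diagonal(n, d)
      rhs <- rhs + problem$V0 * d
    }
  }
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  fact <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE),
                   error = function(e) NULL)
  if (is.null(fact))
    stop_arg("singular reconstruction system: the normal matrix is not positive definite")
  V <- as.matrix(Matrix::solve(fact, rhs))
  dimnames(V) <- NULL
  V
}

# Connected components of the Laplacian adjacency with zero observation mass.
# The umbrella Laplacian's nonzero pattern is symmetric, so column access of
# the CsparseMatrix gives each vertex's neighbourhood directly.
unobserved_components <- function(G, L) {
  n <- ncol(G)
  obs <- Matrix::colSums(G != 0) > 0
  adj <- methods::as(methods::as(L, "CsparseMatrix") != 0, "CsparseMatrix")
  p <- adj@p; iidx <- adj@i
  nbrs <- function(v) iidx[(p[v] + 1L):p[v + 1L]] + 1L
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s
    seen[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, function(v)
        if (p[v + 1L] > p[v]) nbrs(v) else integer())))
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    if (!any(obs[comp])) comps[[length(comps) + 1L]] <- comp
  }
  comps
}

#' Quadratic reconstruction objective
#'
#' @param problem A [reconstruction_problem()].
#' @param V `N x 3` candidate vertices.
#' @return Scalar objective value.
#' @export
reconstruction_objective <- function(problem, V) {
  r1 <- problem$G %*% V - problem$P
  r2 <- problem$L %*% (V - problem$V0)
  sum(r1^2) + problem$alpha * sum(r2^2)
}

#' Render-then-reconstruct round-trip error
#'
#' Renders a scan through the atlas, solves the regularized inverse with the
#' template mean as prior, and returns the per-vertex Euclidean errors
#' between the reconstruction and the original scan.
#'
#' @param mesh A [registered_mesh()] matching the atlas.
#' @param atlas A [build_atlas()] result.
#' @param alpha Regularization weight (default 0.001).
#' @param V0 Prior vertices (default: the atlas template).
#' @param reg Optional precomputed [build_G()]; rebuilt if omitted.
#' @param L Optional precomputed Laplacian.
#' @return List with `mean_error` (mm) and `per_vertex` errors.
#' @export
roundtrip_error <- function(mesh, atlas, alpha = 0.001, V0 = NULL,
                            reg = NULL, L = NULL) {
  if (is.null(reg)) reg <- build_G(atlas)
  if (is.null(L)) L <- build_laplacian(mesh$faces, nrow(mesh$vertices))
  if (is.null(V0)) V0 <- atlas$template_vertices
  P <- as.matrix(reg$G %*% mesh$vertices)      # exact forward rendering
  V <- solve_vertices(reconstruction_problem(reg, P, L, V0, alpha))
  err <- sqrt(rowSums((V - mesh$vertices)^2))
  list(mean_error = mean(err), per_vertex = err)
}
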