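# PCA baseline shape model: linear components over flattened vertex vectors
# plus per-component empirical-CDF score sampling.

#' Fit a PCA shape model
#'
#' Standard PCA on flattened `3N`-vectors of vertex coordinates (via SVD of
#' the centred data matrix). Stores the training scores and a sorted score
#' array (empirical CDF) per component for [sample_scores()].
#'
#' @param meshes List of >= 2 comparable [registered_mesh()]es.
#' @param k Number of components, at most `min(n_train - 1, 3N)`.
#' @return A `pca_shape_model` with fields `mean` (3N), `components`
#'   (`k x 3N`, orthonormal rows), `scores` (`n_train x k`), `sdev`,
#'   `faces`, `template_id`.
#' @export
fit_pca <- function(meshes, k) {
  n <- length(meshes)
  if (n < 2L) stop_arg("need at least 2 training meshes")
  X <- t(vapply(meshes, function(m) as.vector(m$vertices), numeric(3L * nrow(meshes[[1]]$vertices))))
  kmax <- min(n - 1L, ncol(X))
  if (k > kmax) stop_arg("k = %d exceeds max %d for %d training meshes", k, kmax, n)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = k, nv = k)
  components <- t(sv$v[, seq_len(k), drop = FALSE])    # k x 3N
  scores <- Xc %*% t(components)                        # n x k
  structure(list(mean = mu, components = components, scores = scores,
                 sdev = sv$d[seq_len(k)] / sqrt(max(n - 1L, 1L)),
                 faces = meshes[[1]]$faces,
                 template_id = meshes[[1]]$template_id,
                 n_vertices = nrow(meshes[[1]]$vertices)),
            class = "pca_shape_model")
}

#' @export
print.pca_shape_model <- function(x, ...) {
  cat(sprintf("pca_shape_model: %d components over %d vertices (%d training shapes)\n",
              nrow(x$components), x$n_vertices, nrow(x$scores)))
  invisible(x)
}

#' Encode a mesh to PCA scores
#'
#' @param model A [fit_pca()] model.
#' @param mesh A comparable [registered_mesh()].
#' @return Length-`k` score vector.
#' @export
pca_encode <- function(model, mesh) {
  x <- as.vector(mesh$vertices)
  if (length(x) != length(model$mean)) stop_arg("mesh size does not match model")
  as.numeric(model$components %*% (x - model$mean))
}

#' Decode PCA scores to a mesh
#'
#' Affine in the scores; `decode(encode(m))` is the rank-k projection of `m`.
#'
#' @param model A [fit_pca()] model.
#' @param scores Length-`k` score vector.
#' @return A [registered_mesh()].
#' @export
pca_decode <- function(model, scores) {
  if (length(scores) != nrow(model$components)) stop_arg("expected %d scores",
                                                         nrow(model$components))
  x <- model$mean + as.numeric(crossprod(model$components, scores))
  registered_mesh(matrix(x, ncol = 3), model$faces, model$template_id)
}

#' Sample PCA scores from per-component empirical CDFs
#'
#' Each column is drawn i.i.d. by inverse-eCDF: `u ~ Uniform(0, 1)` mapped
#' through the order statistics of the training scores, either with linear
#' interpolation between adjacent order statistics (default) or as a step
#' function (exact resampling of training values). Columns are sampled
#' independently, which preserves marginals but deliberately destroys any
#' cross-component dependence present in the training scores — the known
#' weakness of independent PCA-score sampling this package's metrics expose.
#' Samples never leave the `[min, max]` range of the training scores.
#'
#' @param model A [fit_pca()] model.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param method `"linear"` or `"step"`.
#' @return `n x k` score matrix.
#' @export
sample_scores <- function(model, n, seed = 1L, method = c("linear", "step")) {
  method <- match.arg(method)
  k <- nrow(model$components)
  m <- nrow(model$scores)
  with_seed(seed, {
    out <- matrix(0, n, k)
    for (j in seq_len(k)) {
      s <- sort(model$scores[, j])
      u <- stats::runif(n)
      out[, j] <- if (m == 1L) rep(s, n)
      else if (method == "linear") {
        pos <- 1 + u * (m - 1)
        lo <- pmin(floor(pos), m - 1)
        s[lo] + (pos - lo) * (s[lo + 1] - s[lo])
      } else s[pmax(ceiling(u * m), 1L)]
    }
    out
  })
}

#' Sample novel meshes from the PCA-eCDF model
#'
#' Composition of [sample_scores()] and [pca_decode()].
#'
#' @inheritParams sample_scores
#' @return List of [registered_mesh()]es.
#' @export
sample_meshes <- function(model, n, seed = 1L, method = c("linear", "step")) {
  S <- sample_scores(model, n, seed, method)
  lapply(seq_len(n), function(i) pca_decode(model, S[i, ]))
}
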