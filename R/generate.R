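#' Generate novel registered meshes from the trained VQ stack
#'
#' End-to-end sampling: latent codes are drawn from the autoregressive
#' priors (top then bottom), decoded to normalized geometric images,
#' denormalized with the training ranges, and inverted to 3D — bijectively
#' through the face grid, or through the Laplacian-regularized multiview
#' solve for bodies. Every sample is screened by the background-mask IoU
#' failure detector; failed samples are flagged in the result, never
#' silently dropped.
#'
#' @param vqvae A trained [train_vqvae()] model.
#' @param top_prior,bottom_prior Trained [train_prior()] models.
#' @param ranges [fit_ranges()] of the training images.
#' @param n Number of samples.
#' @param kind `"face"` (requires `grid`) or `"body"` (requires `atlas`).
#' @param grid A [face_template_grid()] (face kind).
#' @param atlas A [build_atlas()] result (body kind).
#' @param reg,L,V0 Optional precomputed registration matrix, Laplacian and
#'   prior vertices for the body solve (derived from the atlas if omitted;
#'   `V0` defaults to the atlas template).
#' @param faces Triangle topology for body meshes (defaults to none needed —
#'   taken from `template_mesh` when given).
#' @param template_mesh Optional [registered_mesh()] supplying body topology
#'   and the Laplacian.
#' @param alpha Regularization weight of the body solve.
#' @param temperature,seed Passed to [sample_codes()].
#' @param eps,iou_threshold Passed to [detect_failed_sample()].
#' @return List with `meshes`, `images` (normalized), `failed`, `iou`,
#'   `codes`.
#' @export
generate_shapes <- function(vqvae, top_prior, bottom_prior, ranges, n,
                            kind = c("face", "body"), grid = NULL,
                            atlas = NULL, reg = NULL, L = NULL, V0 = NULL,
                            template_mesh = NULL, alpha = 0.001,
                            temperature = 1, seed = 1L, eps = 1 / 255,
                            iou_threshold = 0.95) {
  kind <- match.arg(kind)
  if (kind == "face" && is.null(grid)) stop_arg("face generation requires a grid")
  if (kind == "body") {
    if (is.null(atlas)) stop_arg("body generation requires an atlas")
    if (is.null(reg)) reg <- build_G(atlas)
    if (is.null(template_mesh) && is.null(L))
      stop_arg("body generation requires template_mesh or a precomputed Laplacian")
    if (is.null(L)) L <- build_laplacian(template_mesh$faces, atlas$n_vertices)
    if (is.null(V0)) V0 <- atlas$template_vertices
  }
  codes <- sample_codes(top_prior, bottom_prior, n, temperature, seed)
  meshes <- vector("list", n)
  images <- vector("list", n)
  failed <- logical(n)
  iou <- numeric(n)
  template_mask <- vqvae$mask
  for (i in seq_len(n)) {
    img <- decode_codes(vqvae, codes[[i]])
    images[[i]] <- img
    # The background check is vacuous for an all-foreground (face) template.
    chk <- if (any(!template_mask))
      detect_failed_sample(img, template_mask, eps, iou_threshold)
    else list(failed = FALSE, iou = 1)
    failed[i] <- chk$failed
    iou[i] <- chk$iou
    raw <- denormalize_image(img, ranges)
    meshes[[i]] <- if (kind == "face") image_to_face(raw, grid) else {
      views <- unpack_views(raw, atlas)
      P <- pixel_observations(views, atlas)
      V <- solve_vertices(reconstruction_problem(reg, P, L, V0, alpha))
      registered_mesh(V,
                      if (!is.null(template_mesh)) template_mesh$faces
                      else matrix(integer(), 0, 3),
                      atlas$template_id)
    }
  }
  list(meshes = meshes, images = images, failed = failed, iou = iou,
       codes = codes)
}
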