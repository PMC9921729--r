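# Two-level vector-quantized autoencoder over geometric images.
#
# Architecture (desk-scale CPU design): per-patch affine/ReLU maps play the
# role of strided convolutions. The bottom level embeds 4x4 pixel patches
# (latent map at 1/4 resolution); the top level embeds 2x2 blocks of bottom
# features (1/8 resolution). Both latent maps are vector-quantized with
# EMA-learned codebooks and a commitment cost; gradients pass the quantizer
# via the straight-through estimator; the decoder sees quantized vectors
# exactly. The bottom quantizer input is conditioned on the decoded top
# level, as in the two-level hierarchy it implements.

# --- layout helpers ---------------------------------------------------------
# Feature matrices hold one row per (cell, image): row = (cell - 1) * n + m,
# cells in raster order k = (i - 1) * W + j.

vq_geom <- function(config) {
  p <- 4L
  Hb <- config$input_h %/% p; Wb <- config$input_w %/% p
  Ht <- Hb %/% 2L; Wt <- Wb %/% 2L
  list(p = p, Hb = Hb, Wb = Wb, Ht = Ht, Wt = Wt,
       pdim = p * p * config$channels)
}

img_stack <- function(images) {
  if (is.array(images) && length(dim(images)) == 4L) return(images)
  px <- lapply(images, function(im) if (inherits(im, "geometric_image")) im$pixels else im)
  d <- dim(px[[1]])
  A <- array(0, c(length(px), d))
  for (i in seq_along(px)) A[i, , , ] <- px[[i]]
  A
}

# n x H x W x C array -> (Hb*Wb*n) x (p*p*C) patch matrix (cell-major rows).
patches_extract <- function(A, p) {
  d <- dim(A); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Hb <- H %/% p; Wb <- W %/% p
  out <- matrix(0, Hb * Wb * n, p * p * C)
  for (i in seq_len(Hb)) for (j in seq_len(Wb)) {
    k <- (i - 1L) * Wb + j
    blk <- A[, ((i - 1L) * p + 1L):(i * p), ((j - 1L) * p + 1L):(j * p), , drop = FALSE]
    out[(k - 1L) * n + seq_len(n), ] <- matrix(blk, n)
  }
  out
}

patches_assemble <- function(Pm, n, H, W, C, p) {
  Hb <- H %/% p; Wb <- W %/% p
  A <- array(0, c(n, H, W, C))
  for (i in seq_len(Hb)) for (j in seq_len(Wb)) {
    k <- (i - 1L) * Wb + j
    blk <- array(Pm[(k - 1L) * n + seq_len(n), ], c(n, p, p, C))
    A[, ((i - 1L) * p + 1L):(i * p), ((j - 1L) * p + 1L):(j * p), ] <- blk
  }
  A
}

# Row indices mapping each top cell's 2x2 bottom block (quadrant q in 1..4).
gather_idx <- function(Ht, Wt, Wb, n) {
  lapply(1:4, function(q) {
    di <- (q - 1L) %/% 2L; dj <- (q - 1L) %% 2L
    idx <- integer(Ht * Wt * n)
    for (ti in seq_len(Ht)) for (tj in seq_len(Wt)) {
      kt <- (ti - 1L) * Wt + tj
      kb <- (2L * ti - 2L + di) * Wb + (2L * tj - 1L + dj)
      idx[(kt - 1L) * n + seq_len(n)] <- (kb - 1L) * n + seq_len(n)
    }
    idx
  })
}

vq_init_params <- function(config) {
  g <- vq_geom(config)
  F <- config$n_feat; H1 <- config$hidden; D <- config$D
  list(
    W1 = glorot(g$pdim, H1), b1 = rep(0, H1),
    W2 = glorot(H1, F), b2 = rep(0, F),
    W3 = glorot(4L * F, H1), b3 = rep(0, H1),
    W4 = glorot(H1, D), b4 = rep(0, D),
    W5 = glorot(D, H1), b5 = rep(0, H1),
    W6 = glorot(H1, 4L * F), b6 = rep(0, 4L * F),
    W7 = glorot(F + F, D), b7 = rep(0, D),
    W8 = glorot(D + F, H1), b8 = rep(0, H1),
    W9 = glorot(H1, g$pdim), b9 = rep(0, g$pdim)
  )
}

addb <- function(M, b) sweep(M, 2, b, `+`)

# Forward pass over a patch matrix for n images; returns intermediates.
vq_forward <- function(params, cb_t, cb_b, P0, n, g, Fdim) {
  idx <- gather_idx(g$Ht, g$Wt, g$Wb, n)
  h1p <- addb(P0 %*% params$W1, params$b1); h1 <- relu(h1p)
  f_b <- addb(h1 %*% params$W2, params$b2)
  Bt <- cbind(f_b[idx[[1]], , drop = FALSE], f_b[idx[[2]], , drop = FALSE],
              f_b[idx[[3]], , drop = FALSE], f_b[idx[[4]], , drop = FALSE])
  h3p <- addb(Bt %*% params$W3, params$b3); h3 <- relu(h3p)
  z_t <- addb(h3 %*% params$W4, params$b4)
  qt <- quantize(z_t, cb_t$embed)
  h5p <- addb(qt$quantized %*% params$W5, params$b5); h5 <- relu(h5p)
  Ut <- addb(h5 %*% params$W6, params$b6)
  U <- matrix(0, nrow(f_b), Fdim)
  for (q in 1:4) U[idx[[q]], ] <- Ut[, ((q - 1L) * Fdim + 1L):(q * Fdim)]
  z_b <- addb(cbind(f_b, U) %*% params$W7, params$b7)
  qb <- quantize(z_b, cb_b$embed)
  Dc <- cbind(qb$quantized, U)
  h8p <- addb(Dc %*% params$W8, params$b8); h8 <- relu(h8p)
  Xhat <- addb(h8 %*% params$W9, params$b9)
  list(h1p = h1p, h1 = h1, f_b = f_b, Bt = Bt, h3p = h3p, h3 = h3, z_t = z_t,
       qt = qt, h5p = h5p, h5 = h5, Ut = Ut, U = U, z_b = z_b, qb = qb,
       Dc = Dc, h8p = h8p, h8 = h8, Xhat = Xhat, idx = idx)
}

vq_backward <- function(params, fw, P0, beta, Fdim, D) {
  dXhat <- 2 * (fw$Xhat - P0) / length(P0)
  gr <- list()
  gr$W9 <- crossprod(fw$h8, dXhat); gr$b9 <- colSums(dXhat)
  dh8 <- (dXhat %*% t(params$W9)) * (fw$h8p > 0)
  gr$W8 <- crossprod(fw$Dc, dh8); gr$b8 <- colSums(dh8)
  dDc <- dh8 %*% t(params$W8)
  dqb <- dDc[, seq_len(D), drop = FALSE]
  dU <- dDc[, D + seq_len(Fdim), drop = FALSE]
  dz_b <- dqb + 2 * beta * (fw$z_b - fw$qb$quantized) / length(fw$z_b)
  gr$W7 <- crossprod(cbind(fw$f_b, fw$U), dz_b); gr$b7 <- colSums(dz_b)
  dcat <- dz_b %*% t(params$W7)
  df_b <- dcat[, seq_len(Fdim), drop = FALSE]
  dU <- dU + dcat[, Fdim + seq_len(Fdim), drop = FALSE]
  dUt <- matrix(0, nrow(fw$Ut), 4L * Fdim)
  for (q in 1:4) dUt[, ((q - 1L) * Fdim + 1L):(q * Fdim)] <- dU[fw$idx[[q]], , drop = FALSE]
  gr$W6 <- crossprod(fw$h5, dUt); gr$b6 <- colSums(dUt)
  dh5 <- (dUt %*% t(params$W6)) * (fw$h5p > 0)
  gr$W5 <- crossprod(fw$qt$quantized, dh5); gr$b5 <- colSums(dh5)
  dqt <- dh5 %*% t(params$W5)
  dz_t <- dqt + 2 * beta * (fw$z_t - fw$qt$quantized) / length(fw$z_t)
  gr$W4 <- crossprod(fw$h3, dz_t); gr$b4 <- colSums(dz_t)
  dh3 <- (dz_t %*% t(params$W4)) * (fw$h3p > 0)
  gr$W3 <- crossprod(fw$Bt, dh3); gr$b3 <- colSums(dh3)
  dBt <- dh3 %*% t(params$W3)
  for (q in 1:4)
    df_b[fw$idx[[q]], ] <- df_b[fw$idx[[q]], , drop = FALSE] +
      dBt[, ((q - 1L) * Fdim + 1L):(q * Fdim), drop = FALSE]
  gr$W2 <- crossprod(fw$h1, df_b); gr$b2 <- colSums(df_b)
  dh1 <- (df_b %*% t(params$W2)) * (fw$h1p > 0)
  gr$W1 <- crossprod(P0, dh1); gr$b1 <- colSums(dh1)
  gr
}

#' Train the two-level VQ autoencoder
#'
#' Minibatch Adam on reconstruction MSE plus commitment losses; codebooks
#' learned by exponential moving averages (initialized from encoder outputs
#' of the first batch). Training is deterministic given `config$seed`.
#'
#' @param images Training images: list of normalized [geometric_image()]s
#'   (values in `[0, 1]`) or an `n x H x W x C` array.
#' @param config A [vq_config()] matching the image dimensions.
#' @param val_images Optional held-out images for the per-epoch validation
#'   reconstruction MSE (training images are used if omitted).
#' @return A `vqvae` model (parameters, codebooks, config, `history`
#'   data.frame of per-epoch train/validation MSE).
#' @export
train_vqvae <- function(images, config, val_images = NULL) {
  A <- img_stack(images)
  d <- dim(A)
  if (d[2] != config$input_h || d[3] != config$input_w || d[4] != config$channels)
    stop_arg("images are %dx%dx%d; config expects %dx%dx%d", d[2], d[3], d[4],
             config$input_h, config$input_w, config$channels)
  n_all <- d[1]
  if (n_all < config$batch_size)
    stop_arg("dataset (%d) smaller than batch size (%d)", n_all, config$batch_size)
  g <- vq_geom(config)
  Fdim <- config$n_feat; D <- config$D
  mask <- if (is.list(images) && inherits(images[[1]], "geometric_image"))
    images[[1]]$mask else matrix(TRUE, d[2], d[3])
  Aval <- if (is.null(val_images)) A else img_stack(val_images)

  with_seed(config$seed, {
    params <- vq_init_params(config)
    cb_t <- new_codebook(config$K, D)
    cb_b <- new_codebook(config$K, D)
    opt <- adam_init(params)
    history <- data.frame()
    first_batch <- TRUE
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_all)
      tr_mse <- 0; nb <- 0L
      for (start in seq(1L, n_all, by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1L, n_all)]
        nB <- length(ids)
        P0 <- patches_extract(A[ids, , , , drop = FALSE], g$p)
        if (first_batch) {
          # Seed both codebooks from actual encoder outputs for healthy usage.
          fw0 <- vq_forward(params, cb_t, cb_b, P0, nB, g, Fdim)
          pick_t <- sample.int(nrow(fw0$z_t), config$K, replace = TRUE)
          pick_b <- sample.int(nrow(fw0$z_b), config$K, replace = TRUE)
          cb_t <- new_codebook(config$K, D, fw0$z_t[pick_t, , drop = FALSE] +
                                 matrix(stats::rnorm(config$K * D, 0, 1e-3), config$K, D))
          cb_b <- new_codebook(config$K, D, fw0$z_b[pick_b, , drop = FALSE] +
                                 matrix(stats::rnorm(config$K * D, 0, 1e-3), config$K, D))
          first_batch <- FALSE
        }
        fw <- vq_forward(params, cb_t, cb_b, P0, nB, g, Fdim)
        gr <- vq_backward(params, fw, P0, config$beta, Fdim, D)
        st <- adam_step(opt, params, gr, config$lr)
        opt <- st$state; params <- st$params
        cb_t <- ema_update(cb_t, fw$z_t, fw$qt$codes, config$ema_decay)
        cb_b <- ema_update(cb_b, fw$z_b, fw$qb$codes, config$ema_decay)
        tr_mse <- tr_mse + mean((fw$Xhat - P0)^2); nb <- nb + 1L
      }
      model_now <- list(params = params, cb_t = cb_t, cb_b = cb_b,
                        config = config, geom = g, mask = mask)
      val_mse <- vq_reconstruction_mse(model_now, Aval)
      history <- rbind(history, data.frame(epoch = epoch, train_mse = tr_mse / nb,
                                           val_mse = val_mse))
    }
    structure(list(params = params, cb_t = cb_t, cb_b = cb_b, config = config,
                   geom = g, mask = mask, history = history, trained = TRUE),
              class = "vqvae")
  })
}

#' @export
print.vqvae <- function(x, ...) {
  cat(sprintf("vqvae: %dx%dx%d input, K = %d, D = %d, latent maps %dx%d (bottom) / %dx%d (top)\n",
              x$config$input_h, x$config$input_w, x$config$channels,
              x$config$K, x$config$D, x$geom$Hb, x$geom$Wb, x$geom$Ht, x$geom$Wt))
  if (nrow(x$history))
    cat(sprintf("  final validation MSE: %.3g\n", utils::tail(x$history$val_mse, 1)))
  invisible(x)
}

# Mean reconstruction MSE of an image stack (normalized units).
vq_reconstruction_mse <- function(model, A) {
  n <- dim(A)[1]
  P0 <- patches_extract(A, model$geom$p)
  fw <- vq_forward(model$params, model$cb_t, model$cb_b, P0, n, model$geom,
                   model$config$n_feat)
  mean((fw$Xhat - P0)^2)
}

check_trained <- function(model) {
  if (!inherits(model, "vqvae") || !isTRUE(model$trained))
    stop_arg("model is not a trained vqvae")
}

#' Encode an image to discrete latent codes
#'
#' @param model A trained [train_vqvae()] model.
#' @param image A normalized [geometric_image()] (or bare array).
#' @return A `latent_codes` list with integer matrices `top`
#'   (`H/8 x W/8`) and `bottom` (`H/4 x W/4`), values in `1..K`.
#' @export
encode_to_codes <- function(model, image) {
  check_trained(model)
  px <- if (inherits(image, "geometric_image")) image$pixels else image
  A <- array(px, c(1L, dim(px)))
  g <- model$geom
  P0 <- patches_extract(A, g$p)
  fw <- vq_forward(model$params, model$cb_t, model$cb_b, P0, 1L, g,
                   model$config$n_feat)
  structure(list(
    top = matrix(fw$qt$codes, g$Ht, g$Wt, byrow = TRUE),
    bottom = matrix(fw$qb$codes, g$Hb, g$Wb, byrow = TRUE)
  ), class = "latent_codes")
}

#' Decode latent codes to an image
#'
#' Runs the top-level upsampler and the decoder on codebook vectors only;
#' `decode_codes(encode_to_codes(x))` equals the model's reconstruction of
#' `x` exactly.
#'
#' @param model A trained [train_vqvae()] model.
#' @param codes A `latent_codes` object (fields `top`, `bottom`).
#' @return A normalized [geometric_image()] (model's template mask).
#' @export
decode_codes <- function(model, codes) {
  check_trained(model)
  g <- model$geom
  Fdim <- model$config$n_feat
  p <- model$params
  q_t <- model$cb_t$embed[as.vector(t(codes$top)), , drop = FALSE]
  q_b <- model$cb_b$embed[as.vector(t(codes$bottom)), , drop = FALSE]
  h5 <- relu(addb(q_t %*% p$W5, p$b5))
  Ut <- addb(h5 %*% p$W6, p$b6)
  idx <- gather_idx(g$Ht, g$Wt, g$Wb, 1L)
  U <- matrix(0, g$Hb * g$Wb, Fdim)
  for (q in 1:4) U[idx[[q]], ] <- Ut[, ((q - 1L) * Fdim + 1L):(q * Fdim)]
  h8 <- relu(addb(cbind(q_b, U) %*% p$W8, p$b8))
  Xhat <- addb(h8 %*% p$W9, p$b9)
  A <- patches_assemble(Xhat, 1L, model$config$input_h, model$config$input_w,
                        model$config$channels, g$p)
  geometric_image(array(A[1, , , ], dim(A)[2:4]), model$mask, "normalized")
}

#' Model reconstruction of an image (encode, quantize, decode)
#'
#' @param model A trained [train_vqvae()] model.
#' @param image A normalized [geometric_image()] or array.
#' @return A normalized [geometric_image()].
#' @export
vq_reconstruct <- function(model, image) {
  decode_codes(model, encode_to_codes(model, image))
}
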