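# Vector quantization primitives shared by the two-level autoencoder.

#' VQ autoencoder configuration
#'
#' Desk-scale defaults (64x64 inputs, K = 64) train in minutes on one CPU;
#' `full_scale_config()` returns the published-scale setting (256x256,
#' K = 512, D = 2, batch 32, 420 epochs), which is only practical with GPU
#' training. Latent maps sit at 1/4 (bottom) and 1/8 (top) of the input
#' resolution.
#'
#' @param input_h,input_w Input resolution, divisible by 8.
#' @param channels Input channels (3 for faces, 9 for channel-packed bodies).
#' @param K Codebook size (>= 2).
#' @param D Code dimension (>= 1).
#' @param n_feat Width of the bottom feature maps.
#' @param hidden Hidden width of the per-patch encoder/decoder layers.
#' @param epochs,batch_size,lr Training schedule.
#' @param beta Commitment cost (0.25, the published VQ-VAE-2 default).
#' @param ema_decay Codebook exponential-moving-average decay.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A `vq_config` list.
#' @export
vq_config <- function(input_h = 64L, input_w = 64L, channels = 3L, K = 64L,
                      D = 2L, n_feat = 16L, hidden = 64L, epochs = 30L,
                      batch_size = 32L, lr = 3e-3, beta = 0.25,
                      ema_decay = 0.99, seed = 1L) {
  if (K < 2) stop_arg("K must be >= 2")
  if (D < 1) stop_arg("D must be >= 1")
  if (input_h %% 8 != 0 || input_w %% 8 != 0)
    stop_arg("input resolution must be divisible by 8")
  structure(as.list(environment()), class = "vq_config")
}

#' Full-scale VQ configuration
#'
#' The full-scale setting (256x256 inputs, K = 512, D = 2, batch 32,
#' 420 epochs). GPU-recommended; far beyond desk-scale CPU budgets.
#'
#' @param channels Input channels.
#' @return A `vq_config`.
#' @export
full_scale_config <- function(channels = 9L) {
  vq_config(input_h = 256L, input_w = 256L, channels = channels, K = 512L,
            D = 2L, n_feat = 64L, hidden = 256L, epochs = 420L,
            batch_size = 32L)
}

#' Nearest-codebook quantization
#'
#' Assigns each row of `z` the index of the nearest codebook prototype in
#' Euclidean distance (ties broken toward the lowest index) and returns the
#' quantized vectors.
#'
#' @param z `n x D` matrix of latent vectors.
#' @param codebook `K x D` matrix of prototypes.
#' @return List with integer `codes` (in `1..K`) and `quantized` (`n x D`).
#' @export
quantize <- function(z, codebook) {
  z <- as.matrix(z)
  codebook <- as.matrix(codebook)
  if (!nrow(codebook)) stop_arg("empty codebook")
  if (ncol(z) != ncol(codebook)) stop_arg("dimension mismatch: z is %d-d, codebook %d-d",
                                          ncol(z), ncol(codebook))
  # Squared distance up to the per-row constant ||z||^2.
  part <- -2 * z %*% t(codebook) +
    matrix(rowSums(codebook^2), nrow(z), nrow(codebook), byrow = TRUE)
  codes <- max.col(-part, ties.method = "first")
  list(codes = codes, quantized = codebook[codes, , drop = FALSE])
}

# ---- small optimizer --------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

relu <- function(x) x * (x > 0)

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
}

# EMA codebook update with Laplace count smoothing.
ema_update <- function(cb, z, codes, decay = 0.99, eps = 1e-5) {
  K <- nrow(cb$embed)
  counts <- tabulate(codes, K)
  sums <- matrix(0, K, ncol(cb$embed))
  rs <- rowsum(z, group = codes)
  sums[as.integer(rownames(rs)), ] <- rs
  cb$cluster_size <- decay * cb$cluster_size + (1 - decay) * counts
  cb$ema_w <- decay * cb$ema_w + (1 - decay) * sums
  ntot <- sum(cb$cluster_size)
  smoothed <- (cb$cluster_size + eps) / (ntot + K * eps) * ntot
  cb$embed <- cb$ema_w / smoothed
  cb
}

new_codebook <- function(K, D, init = NULL) {
  embed <- init %||% matrix(stats::rnorm(K * D, 0, 0.1), K, D)
  list(embed = embed, cluster_size = rep(1, K), ema_w = embed)
}
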