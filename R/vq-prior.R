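# Causal autoregressive prior over discrete latent code maps: codes are
# ordered top-left to bottom-right and code t is predicted from codes < t
# through a masked causal context kernel plus a strictly-causal single-head
# self-attention block; the bottom-level prior is additionally conditioned
# on the (upsampled) top code map. Sampling is ancestral in raster order
# with a temperature on the logits.

#' Autoregressive prior configuration
#'
#' @param K Codebook size the codes are drawn from.
#' @param embed_dim Code embedding dimension.
#' @param hidden Hidden feature width.
#' @param context_rows,context_cols Causal kernel extent: offsets up to
#'   `context_rows` rows above and `context_cols` columns around (strictly
#'   left on the current row).
#' @param attention Include the causal self-attention block.
#' @param attn_dim Attention head dimension.
#' @param epochs,batch_size,lr Training schedule.
#' @param seed Integer seed.
#' @return A `prior_config` list.
#' @export
prior_config <- function(K, embed_dim = 16L, hidden = 48L, context_rows = 2L,
                         context_cols = 2L, attention = TRUE, attn_dim = 8L,
                         epochs = 40L, batch_size = 16L, lr = 5e-3, seed = 1L) {
  if (K < 2) stop_arg("K must be >= 2")
  structure(as.list(environment()), class = "prior_config")
}

# Strictly causal kernel offsets (dr, dc).
causal_offsets <- function(rows, cols) {
  out <- list()
  for (dr in -rows:0) for (dc in -cols:cols) {
    if (dr > 0 || (dr == 0 && dc >= 0)) next
    out[[length(out) + 1L]] <- c(dr, dc)
  }
  out
}

# src[t]: raster index of (r + dr, c + dc), or 0 outside the map.
offset_sources <- function(Hc, Wc, off) {
  t <- seq_len(Hc * Wc)
  r <- (t - 1L) %/% Wc + 1L
  c <- (t - 1L) %% Wc + 1L
  rs <- r + off[1]; cs <- c + off[2]
  ok <- rs >= 1L & rs <= Hc & cs >= 1L & cs <= Wc
  ifelse(ok, (rs - 1L) * Wc + cs, 0L)
}

prior_init_params <- function(cfg, n_off, Tpos, conditioned) {
  E <- cfg$embed_dim; Hd <- cfg$hidden
  p <- list(Emb = matrix(stats::rnorm(cfg$K * E, 0, 0.1), cfg$K, E),
            Pos = matrix(stats::rnorm(Tpos * Hd, 0, 0.1), Tpos, Hd),
            b = rep(0, Hd),
            Wout = glorot(Hd, cfg$K), bout = rep(0, cfg$K))
  for (o in seq_len(n_off)) p[[paste0("Wo", o)]] <- glorot(E, Hd)
  if (conditioned) {
    p$CEmb <- matrix(stats::rnorm(cfg$K * E, 0, 0.1), cfg$K, E)
    p$Wcond <- glorot(E, Hd)
  }
  if (cfg$attention) {
    da <- cfg$attn_dim
    p$Wq <- glorot(Hd, da); p$Wk <- glorot(Hd, da); p$Wv <- glorot(Hd, da)
    p$Wa <- glorot(da, Hd)
  }
  p
}

# Forward pass. codes: B x T integer matrix (1..K); top: B x Tt or NULL.
# Rows of all feature matrices are position-major: row = (t - 1) * B + b.
prior_forward <- function(params, cfg, geom, codes, top = NULL, need_grad = FALSE) {
  B <- nrow(codes); T <- geom$T
  Hd <- cfg$hidden
  Hpre <- params$Pos[rep(seq_len(T), each = B), , drop = FALSE] +
    matrix(params$b, B * T, Hd, byrow = TRUE)
  ctx <- list()
  for (o in seq_along(geom$src)) {
    ts <- geom$ts[[o]]
    if (!length(ts)) { ctx[[o]] <- NULL; next }
    cv <- as.vector(codes[, geom$src[[o]][ts], drop = FALSE])
    rows <- rep((ts - 1L) * B, each = B) + seq_len(B)
    Memb <- params$Emb[cv, , drop = FALSE]
    Hpre[rows, ] <- Hpre[rows, , drop = FALSE] + Memb %*% params[[paste0("Wo", o)]]
    ctx[[o]] <- list(cv = cv, rows = rows, Memb = Memb)
  }
  cond <- NULL
  if (!is.null(geom$top_of)) {
    if (is.null(top)) stop_arg("bottom-level prior requires the top code map")
    cvt <- as.vector(top[, geom$top_of, drop = FALSE])
    CM <- params$CEmb[cvt, , drop = FALSE]
    Hpre <- Hpre + CM %*% params$Wcond
    cond <- list(cvt = cvt, CM = CM)
  }
  H <- relu(Hpre)
  att <- NULL
  G <- H
  if (cfg$attention) {
    da <- cfg$attn_dim
    G <- H * 0
    att <- vector("list", B)
    for (b in seq_len(B)) {
      rows_b <- seq(b, by = B, length.out = T)
      Hb <- H[rows_b, , drop = FALSE]
      Q <- Hb %*% params$Wq; Kk <- Hb %*% params$Wk; Vv <- Hb %*% params$Wv
      S <- Q %*% t(Kk) / sqrt(da)
      # Strictly causal: position t attends to positions < t only.
      S[upper.tri(S, diag = TRUE)] <- -Inf
      W <- exp(S - apply(S, 1, max))
      W[!is.finite(W)] <- 0
      rs <- rowSums(W)
      W <- W / ifelse(rs > 0, rs, 1)
      A <- W %*% Vv
      G[rows_b, ] <- Hb + A %*% params$Wa
      if (need_grad) att[[b]] <- list(rows_b = rows_b, Q = Q, K = Kk, V = Vv,
                                      W = W, A = A)
    }
  }
  logits <- addb(G %*% params$Wout, params$bout)
  out <- list(logits = logits, B = B, T = T)
  if (need_grad) out <- c(out, list(Hpre = Hpre, H = H, G = G, ctx = ctx,
                                    cond = cond, att = att))
  out
}

prior_backward <- function(params, cfg, geom, fw, targets) {
  B <- fw$B; T <- fw$T
  n <- B * T
  P <- exp(fw$logits - apply(fw$logits, 1, max))
  P <- P / rowSums(P)
  dlogits <- P
  dlogits[cbind(seq_len(n), targets)] <- dlogits[cbind(seq_len(n), targets)] - 1
  dlogits <- dlogits / n
  gr <- list(Wout = crossprod(fw$G, dlogits), bout = colSums(dlogits))
  dG <- dlogits %*% t(params$Wout)
  dH <- dG * 0
  if (cfg$attention) {
    da <- cfg$attn_dim
    gr$Wq <- params$Wq * 0; gr$Wk <- params$Wk * 0
    gr$Wv <- params$Wv * 0; gr$Wa <- params$Wa * 0
    for (b in seq_len(B)) {
      at <- fw$att[[b]]
      rows_b <- at$rows_b
      dGb <- dG[rows_b, , drop = FALSE]
      Hb <- fw$H[rows_b, , drop = FALSE]
      dHb <- dGb
      gr$Wa <- gr$Wa + crossprod(at$A, dGb)
      dA <- dGb %*% t(params$Wa)
      dV <- crossprod(at$W, dA)
      dW <- dA %*% t(at$V)
      # softmax rows backward (zero rows stay zero).
      dS <- at$W * (dW - rowSums(dW * at$W))
      dQ <- dS %*% at$K / sqrt(da)
      dK <- crossprod(dS, at$Q) / sqrt(da)
      gr$Wq <- gr$Wq + crossprod(Hb, dQ)
      gr$Wk <- gr$Wk + crossprod(Hb, dK)
      gr$Wv <- gr$Wv + crossprod(Hb, dV)
      dHb <- dHb + dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
      dH[rows_b, ] <- dHb
    }
  } else dH <- dG
  dHpre <- dH * (fw$Hpre > 0)
  gr$b <- colSums(dHpre)
  gr$Pos <- rowsum(dHpre, group = rep(seq_len(T), each = B))
  dimnames(gr$Pos) <- NULL
  gr$Emb <- params$Emb * 0
  for (o in seq_along(geom$src)) {
    ct <- fw$ctx[[o]]
    if (is.null(ct)) { gr[[paste0("Wo", o)]] <- params[[paste0("Wo", o)]] * 0; next }
    dcon <- dHpre[ct$rows, , drop = FALSE]
    gr[[paste0("Wo", o)]] <- crossprod(ct$Memb, dcon)
    dMemb <- dcon %*% t(params[[paste0("Wo", o)]])
    rs <- rowsum(dMemb, group = ct$cv)
    ids <- as.integer(rownames(rs))
    gr$Emb[ids, ] <- gr$Emb[ids, , drop = FALSE] + rs
  }
  if (!is.null(fw$cond)) {
    gr$Wcond <- crossprod(fw$cond$CM, dHpre)
    dCM <- dHpre %*% t(params$Wcond)
    gr$CEmb <- params$CEmb * 0
    rs <- rowsum(dCM, group = fw$cond$cvt)
    ids <- as.integer(rownames(rs))
    gr$CEmb[ids, ] <- rs
  }
  loss <- -mean(log(pmax(P[cbind(seq_len(n), targets)], 1e-12)))
  list(grads = gr, loss = loss)
}

prior_geom <- function(Hc, Wc, cfg, conditioned, Wt = NULL) {
  offs <- causal_offsets(cfg$context_rows, cfg$context_cols)
  src <- lapply(offs, function(o) offset_sources(Hc, Wc, o))
  ts <- lapply(src, function(s) which(s > 0L))
  top_of <- NULL
  if (conditioned) {
    t <- seq_len(Hc * Wc)
    r <- (t - 1L) %/% Wc + 1L
    c <- (t - 1L) %% Wc + 1L
    top_of <- (ceiling(r / 2) - 1L) * Wt + ceiling(c / 2)
  }
  list(Hc = Hc, Wc = Wc, T = Hc * Wc, src = src, ts = ts, top_of = top_of)
}

codes_to_matrix <- function(codes_list, field) {
  len <- length(codes_list[[1]][[field]])
  t(vapply(codes_list, function(cd) as.integer(as.vector(t(cd[[field]]))),
           integer(len)))
}

#' Train an autoregressive prior over latent code maps
#'
#' Cross-entropy training (Adam, minibatches) of the causal model; reports
#' per-epoch validation accuracy, the fraction of held-out codes whose
#' argmax prediction is correct.
#'
#' @param codes List of [encode_to_codes()] results from one fixed VQ model.
#' @param level `"top"` (unconditional) or `"bottom"` (conditioned on the
#'   top map).
#' @param config A [prior_config()].
#' @param val_codes Optional held-out list for validation accuracy (training
#'   codes are used if omitted).
#' @return An `ar_prior` model with a `history` data.frame (per-epoch loss
#'   and validation accuracy).
#' @export
train_prior <- function(codes, level = c("top", "bottom"), config,
                        val_codes = NULL) {
  level <- match.arg(level)
  if (!length(codes)) stop_arg("empty code list")
  conditioned <- level == "bottom"
  Cm <- codes_to_matrix(codes, if (conditioned) "bottom" else "top")
  Hc <- nrow(codes[[1]][[if (conditioned) "bottom" else "top"]])
  Wc <- ncol(codes[[1]][[if (conditioned) "bottom" else "top"]])
  Tm <- NULL; Wt <- NULL
  if (conditioned) {
    Tm <- codes_to_matrix(codes, "top")
    Wt <- ncol(codes[[1]]$top)
  }
  geom <- prior_geom(Hc, Wc, config, conditioned, Wt)
  if (is.null(val_codes)) val_codes <- codes
  Cv <- codes_to_matrix(val_codes, if (conditioned) "bottom" else "top")
  Tv <- if (conditioned) codes_to_matrix(val_codes, "top") else NULL
  n_all <- nrow(Cm)

  with_seed(config$seed, {
    params <- prior_init_params(config, length(geom$src), geom$T, conditioned)
    opt <- adam_init(params)
    history <- data.frame()
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_all)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n_all, by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1L, n_all)]
        fw <- prior_forward(params, config, geom, Cm[ids, , drop = FALSE],
                            if (conditioned) Tm[ids, , drop = FALSE] else NULL,
                            need_grad = TRUE)
        targets <- as.vector(Cm[ids, , drop = FALSE])
        bw <- prior_backward(params, config, geom, fw, targets)
        st <- adam_step(opt, params, bw$grads, config$lr)
        opt <- st$state; params <- st$params
        ep_loss <- ep_loss + bw$loss; nb <- nb + 1L
      }
      model_now <- list(params = params, config = config, geom = geom,
                        level = level)
      acc <- prior_accuracy_mat(model_now, Cv, Tv)
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / nb,
                                           val_accuracy = acc))
    }
    structure(list(params = params, config = config, geom = geom,
                   level = level, history = history),
              class = "ar_prior")
  })
}

#' @export
print.ar_prior <- function(x, ...) {
  cat(sprintf("ar_prior (%s level): %dx%d maps, K = %d%s\n", x$level,
              x$geom$Hc, x$geom$Wc, x$config$K,
              if (nrow(x$history))
                sprintf(", validation accuracy %.3f", utils::tail(x$history$val_accuracy, 1))
              else ""))
  invisible(x)
}

prior_accuracy_mat <- function(model, Cm, Tm = NULL) {
  fw <- prior_forward(model$params, model$config, model$geom, Cm, Tm)
  pred <- max.col(fw$logits, ties.method = "first")
  mean(pred == as.vector(Cm))
}

#' Per-code prediction accuracy of a prior on a code set
#'
#' @param model A trained [train_prior()] model.
#' @param codes List of `latent_codes`.
#' @return Fraction of codes whose argmax prediction is correct.
#' @export
prior_accuracy <- function(model, codes) {
  conditioned <- model$level == "bottom"
  Cm <- codes_to_matrix(codes, if (conditioned) "bottom" else "top")
  Tm <- if (conditioned) codes_to_matrix(codes, "top") else NULL
  prior_accuracy_mat(model, Cm, Tm)
}

#' Logits of a prior at every position of given code maps
#'
#' Exposes the causal predictions (used for probes and diagnostics): the
#' logits at raster position t depend only on codes at positions before t.
#'
#' @param model A trained [train_prior()] model.
#' @param codes A single `latent_codes` object.
#' @return `T x K` logit matrix in raster order.
#' @export
prior_logit_map <- function(model, codes) {
  conditioned <- model$level == "bottom"
  Cm <- matrix(as.vector(t(codes[[if (conditioned) "bottom" else "top"]])), 1)
  Tm <- if (conditioned) matrix(as.vector(t(codes$top)), 1) else NULL
  prior_forward(model$params, model$config, model$geom, Cm, Tm)$logits
}

# Ancestral raster-order sampling of one level for B maps at once.
sample_level <- function(model, B, temperature, top_mat = NULL) {
  geom <- model$geom
  T <- geom$T
  codes <- matrix(1L, B, T)
  for (t in seq_len(T)) {
    fw <- prior_forward(model$params, model$config, geom, codes, top_mat)
    lg <- fw$logits[(t - 1L) * B + seq_len(B), , drop = FALSE] / temperature
    lg <- lg - apply(lg, 1, max)
    pr <- exp(lg); pr <- pr / rowSums(pr)
    u <- stats::runif(B)
    cum <- t(apply(pr, 1, cumsum))
    codes[, t] <- max.col(cum >= u, ties.method = "first")
  }
  codes
}

#' Sample latent code maps from trained priors
#'
#' Ancestral sampling in raster order: the top map is sampled
#' unconditionally, then the bottom map conditioned on it. Codes are drawn
#' from `softmax(logits / temperature)`; higher temperatures flatten the
#' distribution and raise sample entropy/diversity.
#'
#' @param top_model,bottom_model Trained [train_prior()] models.
#' @param n Number of samples.
#' @param temperature Positive sampling temperature (default 1).
#' @param seed Integer seed (sampling is deterministic given it).
#' @return List of `latent_codes` objects.
#' @export
sample_codes <- function(top_model, bottom_model, n, temperature = 1,
                         seed = 1L) {
  if (temperature <= 0) stop_arg("temperature must be > 0")
  with_seed(seed, {
    Ct <- sample_level(top_model, n, temperature)
    Cb <- sample_level(bottom_model, n, temperature, Ct)
    gt <- top_model$geom; gb <- bottom_model$geom
    lapply(seq_len(n), function(i) structure(list(
      top = matrix(Ct[i, ], gt$Hc, gt$Wc, byrow = TRUE),
      bottom = matrix(Cb[i, ], gb$Hc, gb$Wc, byrow = TRUE)
    ), class = "latent_codes"))
  })
}
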