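# Non-bijective multiview representation of closed body meshes: orthographic
# rasterization of the template into a fixed pixel -> (triangle, barycentric)
# atlas, forward rendering of any registered scan through that atlas, and the
# sparse registration matrix G used by the closed-form 3D reconstruction.
#
# Coordinate convention: z up, y back-to-front, x subject's left (mm).
# Views: front projects along -y, back along +y, bottom along +z.

#' Orthographic view specification
#'
#' @param axis `"front"`, `"back"` or `"bottom"`.
#' @param image_h,image_w Image resolution in pixels (>= 16).
#' @param window List with `u` and `v` ranges (mm) of the in-plane world
#'   window, or `NULL` to fit the template bounding box with a margin when
#'   the atlas is built.
#' @param name View label (defaults to the axis).
#' @return A `view_spec` object.
#' @export
view_spec <- function(axis = c("front", "back", "bottom"), image_h = 256L,
                      image_w = 256L, window = NULL, name = NULL) {
  axis <- match.arg(axis)
  if (image_h < 16 || image_w < 16) stop_arg("view resolution must be >= 16")
  if (!is.null(window)) {
    stopifnot(is.list(window), length(window$u) == 2L, length(window$v) == 2L)
    if (diff(window$u) <= 0 || diff(window$v) <= 0)
      stop_arg("view window must have positive extent")
  }
  structure(list(name = name %||% axis, axis = axis,
                 image_h = as.integer(image_h), image_w = as.integer(image_w),
                 window = window),
            class = "view_spec")
}

#' Default front/back/bottom views for a body template
#'
#' @param template The template [registered_mesh()] (used to size windows).
#' @param resolution Per-view square resolution in pixels.
#' @param margin Fractional margin added around the template bounding box.
#' @return List of three [view_spec()]s.
#' @export
default_body_views <- function(template, resolution = 256L, margin = 0.05) {
  lapply(c("front", "back", "bottom"), function(ax) {
    vs <- view_spec(ax, resolution, resolution)
    vs$window <- auto_window(template$vertices, ax, margin)
    vs
  })
}

# In-plane axes (u, v) and depth per view; depth grows away from the camera.
view_frame <- function(axis) {
  switch(axis,
    front = list(u = c(1, 0, 0), v = c(0, 0, 1), d = c(0, -1, 0)),
    back = list(u = c(-1, 0, 0), v = c(0, 0, 1), d = c(0, 1, 0)),
    bottom = list(u = c(1, 0, 0), v = c(0, 1, 0), d = c(0, 0, 1)),
    stop_arg("unknown view axis '%s'", axis))
}

auto_window <- function(V, axis, margin = 0.05) {
  fr <- view_frame(axis)
  u <- V %*% fr$u
  v <- V %*% fr$v
  pad <- function(r) r + c(-1, 1) * margin * max(diff(r), 1)
  list(u = pad(range(u)), v = pad(range(v)))
}

#' Build the template atlas for a set of orthographic views
#'
#' Rasterizes the template into each view: every pixel center is tested
#' against all projected triangles and assigned the front-most covering
#' triangle together with its barycentric weights. Pixel centers sit at
#' `(col - 0.5, row - 0.5)` in pixel units scaled into the world window;
#' row 1 is the top of the image. Depth ties within 1e-6 mm are broken by
#' the lower triangle index. Uncovered pixels are background.
#'
#' The atlas is built once from the (mean) template and reused for every
#' scan in correspondence: the pixel semantics are fixed by the template,
#' not re-rasterized per scan.
#'
#' @param template A [registered_mesh()].
#' @param views List of [view_spec()]s (default: [default_body_views()]).
#' @return A `template_atlas` object.
#' @export
build_atlas <- function(template, views = NULL) {
  if (is.null(views)) views <- default_body_views(template)
  V <- template$vertices
  F <- template$faces
  out_views <- lapply(views, function(vs) {
    if (is.null(vs$window)) vs$window <- auto_window(V, vs$axis)
    fr <- view_frame(vs$axis)
    u <- as.numeric(V %*% fr$u)
    v <- as.numeric(V %*% fr$v)
    d <- as.numeric(V %*% fr$d)
    H <- vs$image_h; W <- vs$image_w
    du <- diff(vs$window$u) / W
    dv <- diff(vs$window$v) / H
    # Pixel (r, c) center sits at world (u, v) = (umin + (c - 0.5) du,
    # vmax - (r - 0.5) dv); r = 1 at the top of the image. In continuous
    # pixel coordinates that center is the integer point (c, r).
    px <- (u - vs$window$u[1]) / du + 0.5
    py <- (vs$window$v[2] - v) / dv + 0.5
    if (max(px) < 0.5 || min(px) > W + 0.5 || max(py) < 0.5 || min(py) > H + 0.5)
      stop_arg("template lies outside the window of view '%s'", vs$name)

    tri_of <- matrix(0L, H, W)
    depth <- matrix(Inf, H, W)
    w1 <- matrix(0, H, W); w2 <- matrix(0, H, W); w3 <- matrix(0, H, W)

    ax <- px[F[, 1]]; ay <- py[F[, 1]]
    bx <- px[F[, 2]]; by <- py[F[, 2]]
    cx <- px[F[, 3]]; cy <- py[F[, 3]]
    area2 <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
    d1 <- d[F[, 1]]; d2 <- d[F[, 2]]; d3 <- d[F[, 3]]
    # Pixel (r, c) center sits at (c, r) in continuous pixel coordinates.
    cmin <- pmax(ceiling(pmin(ax, bx, cx)), 1L)
    cmax <- pmin(floor(pmax(ax, bx, cx)), W)
    rmin <- pmax(ceiling(pmin(ay, by, cy)), 1L)
    rmax <- pmin(floor(pmax(ay, by, cy)), H)

    for (t in seq_len(nrow(F))) {
      if (abs(area2[t]) < 1e-12) next        # degenerate in this projection
      if (cmin[t] > cmax[t] || rmin[t] > rmax[t]) next
      cc <- cmin[t]:cmax[t]
      rr <- rmin[t]:rmax[t]
      pxs <- as.numeric(cc)
      pys <- as.numeric(rr)
      X <- matrix(pxs, length(rr), length(cc), byrow = TRUE)
      Y <- matrix(pys, length(rr), length(cc))
      l1 <- ((by[t] - cy[t]) * (X - cx[t]) + (cx[t] - bx[t]) * (Y - cy[t])) / area2[t]
      l2 <- ((cy[t] - ay[t]) * (X - ax[t]) + (ax[t] - cx[t]) * (Y - ay[t])) / area2[t]
      l3 <- 1 - l1 - l2
      inside <- l1 >= 0 & l2 >= 0 & l3 >= 0
      if (!any(inside)) next
      dep <- l1 * d1[t] + l2 * d2[t] + l3 * d3[t]
      sub_d <- depth[rr, cc, drop = FALSE]
      upd <- inside & (dep < sub_d - 1e-6)   # strict improvement: ties keep lower index
      if (!any(upd)) next
      idx <- which(upd)
      ridx <- rr[(idx - 1L) %% length(rr) + 1L]
      cidx <- cc[(idx - 1L) %/% length(rr) + 1L]
      lin <- cbind(ridx, cidx)
      depth[lin] <- dep[idx]
      tri_of[lin] <- t
      w1[lin] <- l1[idx]; w2[lin] <- l2[idx]; w3[lin] <- l3[idx]
    }
    list(spec = vs, tri = tri_of, depth = depth,
         w = list(w1, w2, w3),
         vid = list(matrix(F[pmax(tri_of, 1L), 1], H, W) * (tri_of > 0),
                    matrix(F[pmax(tri_of, 1L), 2], H, W) * (tri_of > 0),
                    matrix(F[pmax(tri_of, 1L), 3], H, W) * (tri_of > 0)),
         mask = tri_of > 0L)
  })
  names(out_views) <- vapply(out_views, function(x) x$spec$name, "")
  structure(list(views = out_views, n_vertices = nrow(V),
                 template_id = template$template_id,
                 template_vertices = V),
            class = "template_atlas")
}

#' @export
print.template_atlas <- function(x, ...) {
  cat(sprintf("template_atlas: %d views, template '%s' (%d vertices)\n",
              length(x$views), x$template_id, x$n_vertices))
  for (v in x$views)
    cat(sprintf("  %-7s %dx%d, %d foreground pixels\n", v$spec$name,
                v$spec$image_h, v$spec$image_w, sum(v$mask)))
  invisible(x)
}

#' Render a registered scan through a template atlas
#'
#' Each foreground pixel value is the barycentric combination of the SCAN's
#' vertex coordinates under the atlas's fixed template assignment, so
#' rendering is exactly linear in the scan vertices. Background pixels hold
#' 0 mm (never used; the mask marks them).
#'
#' @param mesh A [registered_mesh()] in correspondence with the atlas.
#' @param atlas A [build_atlas()] result.
#' @return Named list of raw-mm [geometric_image()]s, one per view (C = 3).
#' @export
render_scan <- function(mesh, atlas) {
  if (nrow(mesh$vertices) != atlas$n_vertices)
    stop_arg("mesh has %d vertices; atlas expects %d",
             nrow(mesh$vertices), atlas$n_vertices)
  V <- mesh$vertices
  lapply(atlas$views, function(vw) {
    H <- vw$spec$image_h; W <- vw$spec$image_w
    px <- array(0, c(H, W, 3))
    fg <- which(vw$mask)
    for (ch in 1:3) {
      sl <- matrix(0, H, W)
      sl[fg] <- vw$w[[1]][fg] * V[vw$vid[[1]][fg], ch] +
        vw$w[[2]][fg] * V[vw$vid[[2]][fg], ch] +
        vw$w[[3]][fg] * V[vw$vid[[3]][fg], ch]
      px[, , ch] <- sl
    }
    geometric_image(px, vw$mask, "raw_mm")
  })
}

#' Build the sparse registration matrix G
#'
#' Rows are the foreground pixels across all views (view-major, column-major
#' within a view); columns are template vertices. Each row holds the three
#' barycentric weights of its assigned triangle, so `G %*% V` reproduces the
#' rendered foreground pixel values exactly.
#'
#' @param atlas A [build_atlas()] result.
#' @return A `sparse_registration` object with fields `G` (dgCMatrix),
#'   `pixel_index` (data.frame mapping rows to view/pixel), `n_vertices`.
#' @export
build_G <- function(atlas) {
  rows_i <- integer(); cols_j <- integer(); vals <- numeric()
  view_tab <- list()
  offset <- 0L
  for (vn in names(atlas$views)) {
    vw <- atlas$views[[vn]]
    fg <- which(vw$mask)                       # column-major pixel order
    nfg <- length(fg)
    if (nfg) {
      r <- offset + seq_len(nfg)
      rows_i <- c(rows_i, rep(r, 3L))
      cols_j <- c(cols_j, vw$vid[[1]][fg], vw$vid[[2]][fg], vw$vid[[3]][fg])
      vals <- c(vals, vw$w[[1]][fg], vw$w[[2]][fg], vw$w[[3]][fg])
      view_tab[[vn]] <- data.frame(view = vn, pixel = fg, row = r)
    }
    offset <- offset + nfg
  }
  G <- Matrix::sparseMatrix(i = rows_i, j = cols_j, x = vals,
                            dims = c(offset, atlas$n_vertices))
  structure(list(G = G, pixel_index = do.call(rbind, view_tab),
                 n_vertices = atlas$n_vertices),
            class = "sparse_registration")
}

#' Assemble the observation matrix P from rendered view images
#'
#' Extracts foreground pixel xyz values in the row order of [build_G()].
#'
#' @param images Named list of raw-mm view images (as from [render_scan()]).
#' @param atlas The atlas the images were rendered through.
#' @return Numeric `n_fg x 3` matrix (mm).
#' @export
pixel_observations <- function(images, atlas) {
  P <- lapply(names(atlas$views), function(vn) {
    vw <- atlas$views[[vn]]
    fg <- which(vw$mask)
    im <- images[[vn]]
    cbind(im$pixels[, , 1][fg], im$pixels[, , 2][fg], im$pixels[, , 3][fg])
  })
  do.call(rbind, P)
}

#' Vertex visibility report
#'
#' A vertex is visible iff it receives nonzero weight in at least one view
#' (its column of G has a nonzero entry).
#'
#' @param reg A [build_G()] result.
#' @return List with `visible_fraction` and the logical per-vertex `visible`
#'   flag.
#' @export
visibility_report <- function(reg) {
  if (nrow(reg$G) == 0L)
    return(list(visible_fraction = 0, visible = rep(FALSE, reg$n_vertices)))
  nnz <- diff(reg$G@p)                         # nonzeros per column
  visible <- nnz > 0L
  list(visible_fraction = mean(visible), visible = visible)
}

#' Pack per-view images into one channel-stacked array
#'
#' Stacks the three view canvases channel-wise into a single
#' `H x W x (3 * n_views)` array for network input; [unpack_views()] inverts
#' it.
#'
#' @param images Named list of same-size [geometric_image()]s.
#' @return A [geometric_image()] with the union mask and stacked channels.
#' @export
pack_views <- function(images) {
  d <- dim(images[[1]]$pixels)
  px <- array(0, c(d[1], d[2], 3L * length(images)))
  for (i in seq_along(images)) px[, , (3L * i - 2L):(3L * i)] <- images[[i]]$pixels
  mask <- Reduce(`|`, lapply(images, function(x) x$mask))
  geometric_image(px, mask, images[[1]]$space)
}

#' Unpack a channel-stacked image into per-view images
#'
#' @param image A packed [geometric_image()] (channels a multiple of 3).
#' @param atlas Atlas supplying per-view masks and names.
#' @return Named list of [geometric_image()]s.
#' @export
unpack_views <- function(image, atlas) {
  n <- length(atlas$views)
  out <- lapply(seq_len(n), function(i) {
    geometric_image(image$pixels[, , (3L * i - 2L):(3L * i), drop = FALSE],
                    atlas$views[[i]]$mask, image$space)
  })
  names(out) <- names(atlas$views)
  out
}
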