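#' Face template grid
#'
#' Bijective map between a regular `grid_h x grid_w` pixel grid and the mesh
#' vertex order: `vertex_index_of[r, c]` is the (1-based) vertex index stored
#' at pixel `(r, c)`. Row 1 is the top of the face and column 1 the subject's
#' right, so mirror augmentation is well defined. Includes the shared
#' triangulation (two triangles per grid quad).
#'
#' @param grid_h,grid_w Grid dimensions.
#' @param vertex_index_of Optional custom bijection; defaults to row-major.
#' @return A `face_template_grid` object.
#' @export
face_template_grid <- function(grid_h, grid_w, vertex_index_of = NULL) {
  H <- as.integer(grid_h); W <- as.integer(grid_w)
  if (is.null(vertex_index_of))
    vertex_index_of <- matrix(seq_len(H * W), H, W, byrow = TRUE)
  vertex_index_of <- matrix(as.integer(vertex_index_of), H, W)
  if (!identical(sort(as.vector(vertex_index_of)), seq_len(H * W)))
    stop_arg("vertex_index_of must be a bijection onto 1..%d", H * W)
  # Triangulate quads consistently.
  r <- rep(seq_len(H - 1L), each = W - 1L)
  c <- rep(seq_len(W - 1L), times = H - 1L)
  v00 <- vertex_index_of[cbind(r, c)]
  v01 <- vertex_index_of[cbind(r, c + 1L)]
  v10 <- vertex_index_of[cbind(r + 1L, c)]
  v11 <- vertex_index_of[cbind(r + 1L, c + 1L)]
  faces <- rbind(cbind(v00, v01, v10), cbind(v01, v11, v10))
  structure(list(grid_h = H, grid_w = W, vertex_index_of = vertex_index_of,
                 faces = faces, template_id = sprintf("face-grid-%dx%d", H, W)),
            class = "face_template_grid")
}

#' Geometric image
#'
#' An `H x W x C` array whose pixel channels store 3D surface coordinates
#' (raw mm) or their per-pixel range-normalized values in `[0, 1]`, plus a
#' boolean foreground mask. Background pixels hold the background constant
#' (0).
#'
#' @param pixels `H x W x C` numeric array.
#' @param mask `H x W` logical foreground mask (default all foreground).
#' @param space `"raw_mm"` or `"normalized"`.
#' @return A `geometric_image` object.
#' @export
geometric_image <- function(pixels, mask = NULL, space = c("raw_mm", "normalized")) {
  space <- match.arg(space)
  pixels <- as.array(pixels)
  if (length(dim(pixels)) != 3L) stop_arg("pixels must be an H x W x C array")
  if (is.null(mask)) mask <- matrix(TRUE, dim(pixels)[1], dim(pixels)[2])
  if (!identical(dim(mask), dim(pixels)[1:2])) stop_arg("mask dims must match pixels")
  structure(list(pixels = pixels, mask = mask, space = space),
            class = "geometric_image")
}

#' @export
print.geometric_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("geometric_image: %d x %d x %d (%s), %d foreground pixels\n",
              d[1], d[2], d[3], x$space, sum(x$mask)))
  invisible(x)
}

check_gi_dims <- function(a, b) {
  if (!identical(dim(a$pixels)[1:2], dim(b$pixels)[1:2]))
    stop_arg("geometric image dimensions differ")
}

#' Convert a grid-structured face mesh to a geometric image
#'
#' Pixel `(r, c)` receives the xyz coordinates of vertex
#' `vertex_index_of[r, c]`; the mask is all-foreground (the face map is
#' bijective).
#'
#' @param mesh A [registered_mesh()] whose vertex count equals the grid size.
#' @param grid A [face_template_grid()].
#' @return A raw-mm [geometric_image()] with `C = 3`.
#' @export
face_to_image <- function(mesh, grid) {
  H <- grid$grid_h; W <- grid$grid_w
  if (nrow(mesh$vertices) != H * W)
    stop_arg("mesh has %d vertices; grid expects %d", nrow(mesh$vertices), H * W)
  px <- array(0, c(H, W, 3))
  idx <- as.vector(grid$vertex_index_of)          # column-major traversal of (r, c)
  for (ch in 1:3) px[, , ch] <- matrix(mesh$vertices[idx, ch], H, W)
  geometric_image(px, space = "raw_mm")
}

#' Convert a geometric image back to a grid-structured face mesh
#'
#' Exact inverse of [face_to_image()] for raw-mm images.
#'
#' @param image A raw-mm [geometric_image()] with `C = 3`.
#' @param grid A [face_template_grid()] of matching dimensions.
#' @return A [registered_mesh()].
#' @export
image_to_face <- function(image, grid) {
  if (image$space != "raw_mm")
    stop_arg("image is in normalized space; denormalize before converting to a mesh")
  H <- grid$grid_h; W <- grid$grid_w
  d <- dim(image$pixels)
  if (d[1] != H || d[2] != W || d[3] != 3L)
    stop_arg("image dims %dx%dx%d do not match grid %dx%dx3", d[1], d[2], d[3], H, W)
  V <- matrix(0, H * W, 3)
  idx <- as.vector(grid$vertex_index_of)
  for (ch in 1:3) V[idx, ch] <- as.vector(image$pixels[, , ch])
  registered_mesh(V, grid$faces, grid$template_id)
}

#' Fit per-pixel normalization ranges
#'
#' Computes, for every pixel and channel, the min and max over a training
#' list of raw-mm geometric images. The ranges are retained to denormalize
#' synthetic images back into mm.
#'
#' @param images Non-empty list of raw-mm [geometric_image()]s with
#'   identical dimensions.
#' @return A `normalization_ranges` object with `min` and `max` arrays.
#' @export
fit_ranges <- function(images) {
  if (!length(images)) stop_arg("empty image list")
  d <- dim(images[[1]]$pixels)
  mn <- images[[1]]$pixels
  mx <- images[[1]]$pixels
  for (im in images[-1]) {
    if (!identical(dim(im$pixels), d)) stop_arg("images have mismatched dimensions")
    mn <- pmin(mn, im$pixels)
    mx <- pmax(mx, im$pixels)
  }
  structure(list(min = mn, max = mx), class = "normalization_ranges")
}

#' Normalize a raw-mm geometric image to the unit interval
#'
#' Foreground values map as `(v - min) / (max - min)`, clamped to `[0, 1]`
#' (synthetic values can exceed the training range). Degenerate pixels with
#' `max == min` map to 0. Background pixels are set to the background
#' constant 0.
#'
#' @param image A raw-mm [geometric_image()].
#' @param ranges A [fit_ranges()] result of matching dimensions.
#' @return A normalized [geometric_image()].
#' @export
normalize_image <- function(image, ranges) {
  if (!identical(dim(image$pixels), dim(ranges$min)))
    stop_arg("image and ranges dimensions differ")
  span <- ranges$max - ranges$min
  out <- (image$pixels - ranges$min) / ifelse(span > 0, span, 1)
  out[span <= 0] <- 0
  out <- pmin(pmax(out, 0), 1)
  bg <- !image$mask
  if (any(bg)) for (ch in seq_len(dim(out)[3])) {
    sl <- out[, , ch]; sl[bg] <- 0; out[, , ch] <- sl
  }
  geometric_image(out, image$mask, "normalized")
}

#' Denormalize a unit-interval geometric image back to mm
#'
#' Inverts [normalize_image()] on the foreground (values are clamped to
#' `[0, 1]` first); degenerate pixels recover their `min` value.
#'
#' @param image A normalized [geometric_image()].
#' @param ranges A [fit_ranges()] result of matching dimensions.
#' @return A raw-mm [geometric_image()].
#' @export
denormalize_image <- function(image, ranges) {
  if (!identical(dim(image$pixels), dim(ranges$min)))
    stop_arg("image and ranges dimensions differ")
  v <- pmin(pmax(image$pixels, 0), 1)
  span <- ranges$max - ranges$min
  out <- ranges$min + v * ifelse(span > 0, span, 0)
  bg <- !image$mask
  if (any(bg)) for (ch in seq_len(dim(out)[3])) {
    sl <- out[, , ch]; sl[bg] <- 0; out[, , ch] <- sl
  }
  geometric_image(out, image$mask, "raw_mm")
}

#' Mirror augmentation of a grid-structured face
#'
#' Reflects the face across the sagittal plane: x coordinates are negated
#' and grid columns reversed, so the result is again in template
#' correspondence with left and right swapped. An involution.
#'
#' @param mesh A grid-structured [registered_mesh()].
#' @param grid Its [face_template_grid()].
#' @return The mirrored [registered_mesh()].
#' @export
mirror_augment <- function(mesh, grid) {
  H <- grid$grid_h; W <- grid$grid_w
  if (nrow(mesh$vertices) != H * W)
    stop_arg("mesh has %d vertices; grid expects %d", nrow(mesh$vertices), H * W)
  img <- face_to_image(mesh, grid)
  px <- img$pixels[, W:1, , drop = FALSE]
  px[, , 1] <- -px[, , 1]
  image_to_face(geometric_image(px, space = "raw_mm"), grid)
}
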