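# OBJ and PLY mesh readers/writers (ASCII OBJ; ASCII and binary_little_endian
# PLY). Only triangle meshes are accepted; OBJ faces may carry v/vt/vn slashes.

#' Read a triangle mesh from OBJ or PLY
#'
#' @param path File path; format detected from the `.obj`/`.ply` extension.
#' @param template_id Template label attached to the mesh.
#' @return A [registered_mesh()].
#' @export
read_mesh <- function(path, template_id = "template") {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") read_obj(path, template_id)
  else if (ext == "ply") read_ply(path, template_id)
  else stop_arg("unsupported mesh format '.%s' (expected .obj or .ply)", ext)
}

#' Write a triangle mesh to OBJ or PLY
#'
#' @param mesh A [registered_mesh()].
#' @param path Output file path.
#' @param format `"obj"` or `"ply"`; default inferred from the extension.
#' @param binary For PLY, write `binary_little_endian` instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  if (!is_mesh(mesh)) stop_arg("expected a registered_mesh")
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "ply"))
  if (format == "obj") write_obj(mesh, path) else write_ply(mesh, path, binary)
  invisible(path)
}

read_obj <- function(path, template_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines)) stop_arg("OBJ file has no vertices: %s", path)
  V <- do.call(rbind, lapply(strsplit(sub("^v\\s+", "", vlines), "\\s+"), function(p) {
    xyz <- suppressWarnings(as.numeric(p[1:3]))
    if (any(is.na(xyz))) stop_arg("malformed OBJ vertex line")
    xyz
  }))
  F <- do.call(rbind, lapply(strsplit(sub("^f\\s+", "", flines), "\\s+"), function(p) {
    if (length(p) != 3L) stop_arg("non-triangular OBJ face (%d vertices)", length(p))
    idx <- suppressWarnings(as.integer(sub("/.*$", "", p)))
    if (any(is.na(idx))) stop_arg("malformed OBJ face line")
    idx
  }))
  if (is.null(F)) F <- matrix(integer(), 0, 3)
  if (length(F) && (min(F) < 1L || max(F) > nrow(V)))
    stop_arg("OBJ face references vertex %d of %d", max(F), nrow(V))
  registered_mesh(V, F, template_id)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# shapesynth OBJ export", con)
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$faces))
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

write_ply <- function(mesh, path, binary = FALSE) {
  n <- nrow(mesh$vertices)
  m <- nrow(mesh$faces)
  hdr <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment shapesynth PLY export",
    sprintf("element vertex %d", n),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", m),
    "property list uchar int vertex_indices",
    "end_header"
  )
  if (!binary) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.9g %.9g %.9g",
                       mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
    if (m) writeLines(sprintf("3 %d %d %d",
                              mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    if (m) {
      for (i in seq_len(m)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
      }
    }
  }
}

read_ply <- function(path, template_id) {
  con <- file(path, "rb")
  on.exit(close(con))
  # Header is always ASCII lines.
  hdr <- character()
  repeat {
    line <- readBinLine(con)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 200) stop_arg("PLY header not terminated: %s", path)
  }
  fmt_line <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt_line)) stop_arg("PLY file missing format line")
  binary <- grepl("binary_little_endian", fmt_line[1])
  if (!binary && !grepl("ascii", fmt_line[1]))
    stop_arg("unsupported PLY format: %s", fmt_line[1])

  # Parse element declarations in order, with their property lists.
  elems <- list()
  cur <- NULL
  for (line in hdr) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(toks)) next
    if (toks[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = toks[2], count = as.integer(toks[3]), props = list())
    } else if (toks[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1L]] <-
        if (toks[2] == "list") list(kind = "list", count_type = toks[3],
                                    item_type = toks[4], name = toks[5])
        else list(kind = "scalar", type = toks[2], name = toks[3])
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex)) stop_arg("PLY file has no vertex element")

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
                 int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  is_float <- function(t) t %in% c("float", "float32", "double", "float64")
  read_scalar <- function(t) {
    sz <- type_size[[t]]
    if (is_float(t)) readBin(con, "double", 1, size = sz, endian = "little")
    else readBin(con, "integer", 1, size = sz, signed = !(sz < 4 && grepl("^u", t)),
                 endian = "little")
  }

  V <- NULL; F <- NULL
  if (binary) {
    for (el in elems) {
      if (el$name == "vertex") {
        scalar_types <- vapply(el$props, function(p) p$type, "")
        names(scalar_types) <- vapply(el$props, function(p) p$name, "")
        # Fast path: homogeneous float/double properties.
        if (length(unique(scalar_types)) == 1L) {
          t <- scalar_types[[1]]
          vals <- readBin(con, if (is_float(t)) "double" else "integer",
                          el$count * length(scalar_types), size = type_size[[t]],
                          endian = "little")
          M <- matrix(vals, ncol = length(scalar_types), byrow = TRUE)
          colnames(M) <- names(scalar_types)
          V <- M[, c("x", "y", "z"), drop = FALSE]
        } else {
          V <- matrix(0, el$count, 3)
          for (i in seq_len(el$count)) {
            row <- vapply(el$props, function(p) read_scalar(p$type), 0)
            names(row) <- names(scalar_types)
            V[i, ] <- row[c("x", "y", "z")]
          }
        }
      } else if (el$name == "face") {
        lp <- el$props[[1]]
        F <- matrix(0L, el$count, 3)
        for (i in seq_len(el$count)) {
          k <- read_scalar(lp$count_type)
          if (k != 3L) stop_arg("non-triangular PLY face (%d vertices)", k)
          F[i, ] <- readBin(con, "integer", 3, size = type_size[[lp$item_type]],
                            endian = "little")
        }
      } else {
        # Skip unknown fixed-size elements.
        for (i in seq_len(el$count))
          for (p in el$props)
            if (p$kind == "scalar") read_scalar(p$type) else {
              k <- read_scalar(p$count_type)
              for (j in seq_len(k)) read_scalar(p$item_type)
            }
      }
    }
  } else {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    pos <- 1L
    for (el in elems) {
      take <- body[pos:(pos + el$count - 1L)]
      pos <- pos + el$count
      if (el$name == "vertex") {
        pn <- vapply(el$props, function(p) p$name, "")
        M <- do.call(rbind, lapply(strsplit(trimws(take), "\\s+"), as.numeric))
        colnames(M) <- pn
        V <- M[, c("x", "y", "z"), drop = FALSE]
      } else if (el$name == "face") {
        F <- do.call(rbind, lapply(strsplit(trimws(take), "\\s+"), function(p) {
          p <- as.integer(p)
          if (p[1] != 3L) stop_arg("non-triangular PLY face (%d vertices)", p[1])
          p[2:4]
        }))
      }
    }
  }
  if (is.null(F)) F <- matrix(integer(), 0, 3)
  if (length(F) && (min(F) < 0L || max(F) >= nrow(V)))
    stop_arg("PLY face index out of range")
  registered_mesh(V, F + 1L, template_id)
}

# Read one newline-terminated ASCII line from a binary connection.
readBinLine <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", 1)
    if (!length(b) || b == as.raw(10L)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}
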