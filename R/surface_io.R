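#' Read and write head surfaces (PLY / OBJ with a JSON fiducial sidecar)
#'
#' `read_surface` accepts ascii PLY, binary little-endian PLY, or Wavefront
#' OBJ triangle meshes. Fiducials are looked for in a JSON sidecar (same
#' path with extension `.json`, or given explicitly) holding
#' `{"nasion": [x,y,z], "lpa": [...], "rpa": [...]}` in mm, MRI frame. A
#' missing sidecar yields a surface without fiducials; operations that need
#' them then fail explicitly. Non-triangular faces are an error in either
#' format.
#'
#' `write_surface` writes PLY (ascii or binary little-endian with
#' double-precision coordinates, so binary round-trips are bit-exact) and
#' writes the sidecar whenever the surface carries fiducials.
#'
#' @param path mesh file path (`.ply` or `.obj`).
#' @param fiducials_path optional sidecar path; defaults to `path` with a
#'   `.json` extension.
#' @param check_fiducials passed to [head_surface()].
#' @return `read_surface` returns a `head_surface`; `write_surface` returns
#'   `path` invisibly.
#' @export
read_surface <- function(path, fiducials_path = NULL, check_fiducials = TRUE) {
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
                 ply = read_ply(path),
                 obj = read_obj(path),
                 stop("unsupported mesh format: .", ext))
  if (is.null(fiducials_path)) {
    fiducials_path <- paste0(tools::file_path_sans_ext(path), ".json")
  }
  fiducials <- if (file.exists(fiducials_path)) {
    read_fiducials(fiducials_path)
  } else NULL
  head_surface(mesh$vertices, mesh$triangles, fiducials,
               check_fiducials = check_fiducials)
}

#' @rdname read_surface
#' @param surface a `head_surface`.
#' @param binary write binary little-endian PLY instead of ascii.
#' @export
write_surface <- function(surface, path, fiducials_path = NULL,
                          binary = FALSE) {
  stopifnot(inherits(surface, "head_surface"))
  ext <- tolower(tools::file_ext(path))
  if (ext != "ply") stop("write_surface writes PLY only")
  write_ply(surface$vertices, surface$triangles, path, binary = binary)
  if (!is.null(surface$fiducials)) {
    if (is.null(fiducials_path)) {
      fiducials_path <- paste0(tools::file_path_sans_ext(path), ".json")
    }
    write_fiducials(surface$fiducials, fiducials_path)
  }
  invisible(path)
}

#' @rdname read_surface
#' @export
read_fiducials <- function(path) {
  validate_fiducials(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_surface
#' @param fiducials named list with `nasion`, `lpa`, `rpa` (mm).
#' @export
write_fiducials <- function(fiducials, path) {
  jsonlite::write_json(validate_fiducials(fiducials), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# ---- PLY ------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file")
  fmt <- NULL
  elements <- list()  # list of list(name, count, props=data.frame(type,name,list_count_type,list_item_type))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("unterminated PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt %||% "missing")
  }
  if (!all(c("vertex", "face") %in% names(elements))) {
    stop("PLY must define vertex and face elements")
  }
  if (fmt == "ascii") read_ply_ascii(con, elements)
  else read_ply_binary(con, elements)
}

ply_type_info <- function(type) {
  switch(type,
         char = , int8 = list(what = integer(), size = 1, signed = TRUE),
         uchar = , uint8 = list(what = integer(), size = 1, signed = FALSE),
         short = , int16 = list(what = integer(), size = 2, signed = TRUE),
         ushort = , uint16 = list(what = integer(), size = 2, signed = FALSE),
         int = , int32 = list(what = integer(), size = 4, signed = TRUE),
         uint = , uint32 = list(what = integer(), size = 4, signed = TRUE),
         float = , float32 = list(what = numeric(), size = 4, signed = TRUE),
         double = , float64 = list(what = numeric(), size = 8, signed = TRUE),
         stop("unsupported PLY property type: ", type))
}

read_ply_ascii <- function(con, elements) {
  vertices <- NULL
  triangles <- NULL
  for (el in elements) {
    if (el$count == 0) stop("PLY element ", el$name, " is empty")
    rows <- readLines(con, n = el$count)
    toks <- strsplit(trimws(rows), "\\s+")
    if (el$name == "vertex") {
      names_ <- vapply(el$props, `[[`, "", "name")
      xyz <- match(c("x", "y", "z"), names_)
      if (any(is.na(xyz))) stop("PLY vertex element lacks x/y/z")
      vals <- t(vapply(toks, function(tk) as.numeric(tk[xyz]), numeric(3)))
      vertices <- vals
    } else if (el$name == "face") {
      tri <- lapply(toks, function(tk) {
        n <- as.integer(tk[1])
        if (n != 3) stop("non-triangular face (", n, " vertices) in PLY")
        as.integer(tk[2:4])
      })
      triangles <- do.call(rbind, tri) + 1L
    }
  }
  list(vertices = vertices, triangles = triangles)
}

read_ply_binary <- function(con, elements) {
  vertices <- NULL
  triangles <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      names_ <- vapply(el$props, `[[`, "", "name")
      if (any(vapply(el$props, `[[`, TRUE, "list"))) {
        stop("list property in PLY vertex element unsupported")
      }
      # uniform type fast path, otherwise per-row
      vals <- matrix(NA_real_, el$count, length(el$props))
      infos <- lapply(el$props, function(p) ply_type_info(p$type))
      for (i in seq_len(el$count)) {
        for (j in seq_along(infos)) {
          vals[i, j] <- readBin(con, infos[[j]]$what, n = 1,
                                size = infos[[j]]$size, endian = "little",
                                signed = infos[[j]]$signed)
        }
      }
      xyz <- match(c("x", "y", "z"), names_)
      if (any(is.na(xyz))) stop("PLY vertex element lacks x/y/z")
      vertices <- vals[, xyz, drop = FALSE]
    } else if (el$name == "face") {
      p <- el$props[[1]]
      if (!p$list) stop("PLY face element must carry a vertex index list")
      cinfo <- ply_type_info(p$count_type)
      iinfo <- ply_type_info(p$type)
      tri <- matrix(NA_integer_, el$count, 3)
      for (i in seq_len(el$count)) {
        n <- readBin(con, cinfo$what, n = 1, size = cinfo$size,
                     endian = "little", signed = cinfo$signed)
        if (n != 3) stop("non-triangular face (", n, " vertices) in PLY")
        tri[i, ] <- readBin(con, iinfo$what, n = 3, size = iinfo$size,
                            endian = "little", signed = iinfo$signed)
      }
      triangles <- tri + 1L
    }
  }
  list(vertices = vertices, triangles = triangles)
}

write_ply <- function(vertices, triangles, path, binary = FALSE) {
  nv <- nrow(vertices)
  nf <- nrow(triangles)
  vtype <- "double"
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", nv),
    sprintf("property %s x", vtype),
    sprintf("property %s y", vtype),
    sprintf("property %s z", vtype),
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    # interleave x,y,z per vertex
    writeBin(as.vector(t(vertices)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(triangles[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    vrows <- apply(vertices, 1,
                   function(r) paste(sprintf("%.17g", r), collapse = " "))
    frows <- apply(triangles - 1L, 1,
                   function(r) paste(c(3L, r), collapse = " "))
    writeLines(c(header, vrows, frows), path)
  }
  invisible(path)
}

# ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0 || length(flines) == 0) {
    stop("OBJ file lacks vertices or faces")
  }
  vertices <- t(vapply(strsplit(vlines, "\\s+"),
                       function(tk) as.numeric(tk[2:4]), numeric(3)))
  tri <- lapply(strsplit(flines, "\\s+"), function(tk) {
    idx <- tk[-1]
    if (length(idx) != 3) {
      stop("non-triangular face (", length(idx), " vertices) in OBJ")
    }
    # "f v", "f v/vt", "f v/vt/vn", "f v//vn" all start with the vertex index
    as.integer(vapply(strsplit(idx, "/"), `[[`, "", 1))
  })
  list(vertices = vertices, triangles = do.call(rbind, tri))
}

# ---- headshape text format ------------------------------------------------

#' Read and write digitized headshape files
#'
#' Plain-text format, one point per row: `x y z role` with coordinates in mm
#' (head frame) and role one of `fiducial:nasion`, `fiducial:lpa`,
#' `fiducial:rpa`, `hpi`, `headshape`. Comment lines start with `#`.
#'
#' @param path file path.
#' @return `read_headshape` returns a `headshape_set`; `write_headshape`
#'   returns `path` invisibly.
#' @export
read_headshape <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  tok <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(tok) != 4)) stop("each headshape row must be 'x y z role'")
  pts <- t(vapply(tok, function(tk) as.numeric(tk[1:3]), numeric(3)))
  raw_roles <- vapply(tok, `[[`, "", 4)
  roles <- ifelse(startsWith(raw_roles, "fiducial"), "fiducial", raw_roles)
  labels <- sub("^fiducial:", "", raw_roles[roles == "fiducial"])
  headshape_set(pts, roles, fiducial_labels = labels)
}

#' @rdname read_headshape
#' @param hs a `headshape_set`.
#' @export
write_headshape <- function(hs, path) {
  stopifnot(inherits(hs, "headshape_set"))
  roles <- hs$roles
  fi <- which(roles == "fiducial")
  roles[fi] <- paste0("fiducial:", hs$fiducial_labels)
  rows <- vapply(seq_len(nrow(hs$points)), function(i) {
    paste(c(sprintf("%.17g", hs$points[i, ]), roles[i]), collapse = " ")
  }, "")
  writeLines(c("# x y z role (mm, head frame)", rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
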