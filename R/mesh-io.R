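#' Read and write triangle meshes
#'
#' PLY is the canonical on-disk format (ascii and binary little-endian read;
#' ascii written); OBJ is read-only.  Round trips are stable: vertices within
#' 1e-6 mm and identical faces.  Malformed headers, out-of-range face indices
#' and unsupported element types raise distinct classed errors
#' (`morphoatlas_error_ply_header`, `morphoatlas_error_index_range`,
#' `morphoatlas_error_unsupported`).
#'
#' @param path File path; format chosen by extension (.ply or .obj).
#' @param mesh A [mesh3t()].
#' @return `read_mesh()` returns a [mesh3t()]; `write_mesh()` returns `path`
#'   invisibly.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stop_morpho(paste0("unsupported mesh format: .", ext), "unsupported"))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext != "ply")
    stop_morpho("only PLY output is supported", "unsupported")
  write_ply(mesh, path)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)
ply_type_float <- c("float", "float32", "double", "float64")

#' @rdname read_mesh
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply"))
    stop_morpho("not a PLY file (missing 'ply' magic)", "ply_header")
  fmt <- NULL
  elements <- list()   # each: list(name, count, props = list(name,type,list_count_type))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop_morpho("unterminated PLY header", "ply_header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      if (!tok[2] %in% c("ascii", "binary_little_endian"))
        stop_morpho(paste("unsupported PLY format:", tok[2]), "unsupported")
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      elements[[length(elements) + 1L]] <-
        list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (length(elements) == 0L)
        stop_morpho("property before element in PLY header", "ply_header")
      i <- length(elements)
      if (tok[2] == "list") {
        p <- list(name = tok[5], type = tok[4], list_count_type = tok[3])
      } else {
        p <- list(name = tok[3], type = tok[2], list_count_type = NA)
      }
      if (!p$type %in% names(ply_type_size))
        stop_morpho(paste("unsupported PLY property type:", p$type),
                    "unsupported")
      elements[[i]]$props <- c(elements[[i]]$props, list(p))
    } else if (tok[1] == "end_header") {
      break
    } else {
      stop_morpho(paste("unrecognised PLY header line:", line), "ply_header")
    }
  }
  if (is.null(fmt)) stop_morpho("PLY header lacks a format line", "ply_header")
  names(elements) <- vapply(elements, `[[`, "", "name")
  if (!all(c("vertex", "face") %in% names(elements)))
    stop_morpho("PLY must declare vertex and face elements", "ply_header")

  parsed <- if (fmt == "ascii") read_ply_ascii(con, elements)
            else read_ply_binary(con, elements)
  v <- parsed$vertex[, c("x", "y", "z"), drop = FALSE]
  f <- parsed$face
  if (nrow(f) > 0 && (min(f) < 0L || max(f) >= nrow(v)))
    stop_morpho("PLY face index out of range", "index_range")
  mesh3t(v, f + 1L, specimen_id = sub("\\.[^.]*$", "", basename(path)))
}

read_ply_ascii <- function(con, elements) {
  txt <- readLines(con)
  txt <- txt[nzchar(trimws(txt))]
  pos <- 1L
  out <- list()
  for (el in elements) {
    rows <- txt[pos:(pos + el$count - 1L)]
    pos <- pos + el$count
    toks <- strsplit(trimws(rows), "\\s+")
    is_list <- vapply(el$props, function(p) !is.na(p$list_count_type), TRUE)
    if (any(is_list)) {
      if (length(el$props) != 1L)
        stop_morpho("mixed list/scalar PLY properties unsupported",
                    "unsupported")
      counts <- vapply(toks, function(t) as.integer(t[1]), 1L)
      if (any(counts != 3L))
        stop_morpho("non-triangular PLY faces unsupported", "unsupported")
      m <- t(vapply(toks, function(t) as.integer(t[2:4]), integer(3)))
      out[[el$name]] <- m
    } else {
      m <- t(vapply(toks, function(t) as.numeric(t), numeric(length(el$props))))
      colnames(m) <- vapply(el$props, `[[`, "", "name")
      out[[el$name]] <- m
    }
  }
  out
}

read_ply_binary <- function(con, elements) {
  out <- list()
  read_scalar <- function(type, n) {
    sz <- ply_type_size[[type]]
    if (type %in% ply_type_float)
      readBin(con, "double", n = n, size = sz, endian = "little")
    else
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }
  for (el in elements) {
    is_list <- vapply(el$props, function(p) !is.na(p$list_count_type), TRUE)
    if (any(is_list)) {
      if (length(el$props) != 1L)
        stop_morpho("mixed list/scalar PLY properties unsupported",
                    "unsupported")
      p <- el$props[[1]]
      m <- matrix(0L, el$count, 3)
      for (i in seq_len(el$count)) {
        cnt <- read_scalar(p$list_count_type, 1L)
        if (cnt != 3L)
          stop_morpho("non-triangular PLY faces unsupported", "unsupported")
        m[i, ] <- as.integer(read_scalar(p$type, 3L))
      }
      out[[el$name]] <- m
    } else {
      np <- length(el$props)
      types <- vapply(el$props, `[[`, "", "type")
      if (length(unique(types)) == 1L) {
        vals <- read_scalar(types[1], el$count * np)
        m <- matrix(vals, el$count, np, byrow = TRUE)
      } else {
        m <- matrix(0, el$count, np)
        for (i in seq_len(el$count))
          for (j in seq_len(np)) m[i, j] <- read_scalar(types[j], 1L)
      }
      colnames(m) <- vapply(el$props, `[[`, "", "name")
      out[[el$name]] <- m
    }
  }
  out
}

#' @rdname read_mesh
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nrow(v)),
              "property double x", "property double y", "property double z",
              paste("element face", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3])
  fl <- sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
  writeLines(c(header, vl, fl), path)
  invisible(path)
}

#' @rdname read_mesh
#' @export
read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vt <- txt[startsWith(txt, "v ")]
  ft <- txt[startsWith(txt, "f ")]
  if (length(vt) == 0L) stop_morpho("OBJ file has no vertices", "ply_header")
  v <- t(vapply(strsplit(trimws(vt), "\\s+"),
                function(t) as.numeric(t[2:4]), numeric(3)))
  f <- t(vapply(strsplit(trimws(ft), "\\s+"), function(t) {
    if (length(t) != 4L)
      stop_morpho("non-triangular OBJ faces unsupported", "unsupported")
    as.integer(vapply(strsplit(t[2:4], "/"), `[[`, "", 1L))
  }, integer(3)))
  if (nrow(f) > 0 && (min(f) < 1L || max(f) > nrow(v)))
    stop_morpho("OBJ face index out of range", "index_range")
  mesh3t(v, f, specimen_id = sub("\\.[^.]*$", "", basename(path)))
}
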