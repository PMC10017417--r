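#' Read a point cloud from PLY, PCD or XYZ
#'
#' Supports ascii and binary_little_endian PLY, ascii PCD, and plain
#' whitespace-delimited XYZ (one point per line, optional 4th column read as
#' the label). Vertex positions are returned in `points`; any other scalar
#' vertex properties (color, normals, ...) are kept in `attrs` so that a
#' write/read round trip preserves them. A vertex property named `label` is
#' mapped to the cloud's labels.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"ply"`, `"pcd"`, `"xyz"`; `"auto"` picks by
#'   file extension (defaulting to xyz).
#' @return a [point_cloud()].
#' @export
read_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("ply", "pcd")) ext else "xyz"
  }
  switch(format,
         ply = .read_ply(path),
         pcd = .read_pcd(path),
         xyz = .read_xyz(path))
}

#' Write a point cloud to PLY, PCD or XYZ
#'
#' The PLY writer emits double-precision coordinates (so coordinates round
#' trip bit-for-bit), the label as an extra integer vertex property `label`,
#' and any extra attributes as double properties.
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format one of `"auto"`, `"ply"`, `"pcd"`, `"xyz"`.
#' @param binary write binary_little_endian PLY instead of ascii.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyz"),
                        binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("ply", "pcd")) ext else "xyz"
  }
  switch(format,
         ply = .write_ply(cloud, path, binary = binary),
         pcd = .write_pcd(cloud, path),
         xyz = .write_xyz(cloud, path))
  invisible(path)
}

## ---- PLY ----------------------------------------------------------------

# rows of a numeric matrix as "%.17g"-formatted whitespace-joined strings
# (17 significant digits round-trip doubles exactly)
.num_rows <- function(m) {
  if (nrow(m) == 0) return(character(0))
  cols <- lapply(seq_len(ncol(m)), function(j) sprintf("%.17g", m[, j]))
  do.call(paste, cols)
}

.ply_type_info <- function(type) {
  # returns list(size, what, signed) for readBin
  switch(type,
         char = , int8 = list(size = 1, what = "integer", signed = TRUE),
         uchar = , uint8 = list(size = 1, what = "integer", signed = FALSE),
         short = , int16 = list(size = 2, what = "integer", signed = TRUE),
         ushort = , uint16 = list(size = 2, what = "integer", signed = FALSE),
         int = , int32 = list(size = 4, what = "integer", signed = TRUE),
         uint = , uint32 = list(size = 4, what = "integer", signed = TRUE),
         float = , float32 = list(size = 4, what = "double", signed = TRUE),
         double = , float64 = list(size = 8, what = "double", signed = TRUE),
         stop("unsupported PLY property type: ", type))
}

.read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  # locate end_header line boundary in the raw buffer
  nl <- which(raw == as.raw(10L))
  hdr_end_byte <- NULL
  prev <- 0L
  for (pos in nl) {
    line <- rawToChar(raw[seq.int(prev + 1L, pos - 1L)])
    if (grepl("^\\s*end_header\\s*$", line)) { hdr_end_byte <- pos; break }
    prev <- pos
  }
  if (is.null(hdr_end_byte)) stop("PLY header ended before end_header: ", path)
  hdr_lines <- strsplit(rawToChar(raw[seq_len(hdr_end_byte - 1L)]), "\r?\n")[[1]]
  if (length(hdr_lines) == 0 || !identical(trimws(hdr_lines[1]), "ply"))
    stop("not a PLY file (missing 'ply' magic line): ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = list(name, type))
  cur <- NULL
  for (line in hdr_lines[-1]) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format '", fmt, "' in ", path)
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[length(elements) + 1]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property before any element: ", line)
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], type = "list", count_type = tok[3],
               item_type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1]] <- list(name = tok[3], type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      break
    } else stop("unrecognized PLY header line: '", line, "'")
  }
  if (!is.null(cur)) elements[[length(elements) + 1]] <- cur
  if (is.null(fmt)) stop("PLY header has no format line: ", path)
  body_raw <- raw[seq.int(hdr_end_byte + 1L, length.out = length(raw) - hdr_end_byte)]
  body_lines <- NULL
  if (fmt == "ascii") {
    body_lines <- strsplit(rawToChar(body_raw), "\r?\n")[[1]]
    body_lines <- body_lines[nzchar(trimws(body_lines))]
  }
  line_off <- 0L
  byte_off <- 0L
  vert <- NULL
  for (el in elements) {
    is_vertex <- identical(el$name, "vertex")
    if (is_vertex && any(vapply(el$props, function(p) p$type == "list", TRUE)))
      stop("list properties on the vertex element are not supported")
    if (fmt == "ascii") {
      if (length(body_lines) < line_off + el$count)
        stop("PLY element '", el$name, "' truncated: expected ", el$count,
             " records, got ", length(body_lines) - line_off)
      lines <- body_lines[seq.int(line_off + 1L, length.out = el$count)]
      line_off <- line_off + el$count
      if (is_vertex) {
        nums <- strsplit(trimws(lines), "\\s+")
        npr <- length(el$props)
        bad <- which(lengths(nums) != npr)
        if (length(bad))
          stop("PLY vertex record ", bad[1], " has ", lengths(nums)[bad[1]],
               " fields, expected ", npr)
        m <- matrix(as.numeric(unlist(nums)), ncol = npr, byrow = TRUE)
        colnames(m) <- vapply(el$props, `[[`, "", "name")
        vert <- m
      }
    } else {
      if (is_vertex) {
        npr <- length(el$props)
        m <- matrix(0, el$count, npr)
        colnames(m) <- vapply(el$props, `[[`, "", "name")
        infos <- lapply(el$props, function(p) .ply_type_info(p$type))
        rec_size <- sum(vapply(infos, `[[`, 0, "size"))
        if (length(body_raw) < byte_off + rec_size * el$count)
          stop("PLY binary vertex data truncated in ", path)
        rawv <- body_raw[seq.int(byte_off + 1L,
                                 length.out = rec_size * el$count)]
        byte_off <- byte_off + rec_size * el$count
        off <- 0
        for (j in seq_len(npr)) {
          ii <- infos[[j]]
          sel <- as.vector(outer(seq_len(ii$size) + off,
                                 (seq_len(el$count) - 1) * rec_size, "+"))
          m[, j] <- readBin(rawv[sel], ii$what, n = el$count, size = ii$size,
                            signed = ii$signed, endian = "little")
          off <- off + ii$size
        }
        vert <- m
      } else {
        # cannot size-skip unknown binary elements that follow; vertex data,
        # if already read, is complete at this point
        if (is.null(vert))
          stop("binary PLY with non-vertex element before vertex is not supported")
        break
      }
    }
  }
  if (is.null(vert)) {
    vcount <- vapply(elements, function(e) identical(e$name, "vertex"), TRUE)
    if (!any(vcount)) stop("PLY file has no vertex element: ", path)
    vert <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  }
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(vert)))
    stop("PLY vertex element lacks x/y/z properties")
  pts <- vert[, need, drop = FALSE]
  labels <- if ("label" %in% colnames(vert)) as.integer(vert[, "label"])
  extra <- setdiff(colnames(vert), c(need, "label"))
  attrs <- if (length(extra))
    as.data.frame(vert[, extra, drop = FALSE])
  point_cloud(pts, labels = labels, attrs = attrs)
}

.write_ply <- function(cloud, path, binary = FALSE) {
  p <- cloud$points
  attrs <- cloud$attrs
  header <- c("ply",
              paste("format", if (binary) "binary_little_endian" else "ascii",
                    "1.0"),
              "comment written by podscan",
              paste("element vertex", nrow(p)),
              "property double x", "property double y", "property double z")
  if (!is.null(attrs))
    header <- c(header, paste("property double", names(attrs)))
  if (!is.null(cloud$labels))
    header <- c(header, "property int label")
  header <- c(header, "end_header")
  cols <- cbind(p, if (!is.null(attrs)) as.matrix(attrs))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    nlab <- if (is.null(cloud$labels)) 0L else 1L
    for (i in seq_len(nrow(p))) {
      writeBin(as.double(cols[i, ]), con, size = 8, endian = "little")
      if (nlab) writeBin(as.integer(cloud$labels[i]), con, size = 4,
                         endian = "little")
    }
  } else {
    body <- .num_rows(cols)
    if (!is.null(cloud$labels) && length(body))
      body <- paste(body, cloud$labels)
    writeLines(c(header, body), path)
  }
  invisible(path)
}

## ---- PCD ----------------------------------------------------------------

.read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_keys <- c("FIELDS", "SIZE", "TYPE", "COUNT", "WIDTH", "HEIGHT",
                "VIEWPOINT", "POINTS", "DATA", "VERSION", "#")
  is_hdr <- grepl(paste0("^(", paste(hdr_keys, collapse = "|"), ")"), lines)
  hdr_end <- grep("^DATA", lines)
  if (length(hdr_end) == 0) stop("PCD file has no DATA line: ", path)
  hdr_end <- hdr_end[1]
  hdr <- lines[seq_len(hdr_end)]
  data_mode <- strsplit(trimws(hdr[hdr_end]), "\\s+")[[1]][2]
  if (!identical(data_mode, "ascii"))
    stop("only ascii PCD files are supported (got DATA ", data_mode, ")")
  fields_line <- grep("^FIELDS", hdr, value = TRUE)
  if (length(fields_line) == 0) stop("PCD file has no FIELDS line: ", path)
  fields <- strsplit(trimws(fields_line[1]), "\\s+")[[1]][-1]
  pts_line <- grep("^POINTS", hdr, value = TRUE)
  npts <- if (length(pts_line)) as.integer(strsplit(trimws(pts_line[1]),
                                                    "\\s+")[[1]][2]) else NA
  body <- lines[seq.int(hdr_end + 1, length.out = length(lines) - hdr_end)]
  body <- body[nzchar(trimws(body))]
  if (!is.na(npts) && length(body) < npts)
    stop("PCD data truncated: expected ", npts, " points, got ", length(body))
  if (length(body) == 0) {
    m <- matrix(numeric(0), 0, length(fields))
  } else {
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(toks) != length(fields))
    if (length(bad))
      stop("PCD record ", bad[1], " has ", lengths(toks)[bad[1]],
           " fields, expected ", length(fields))
    m <- matrix(as.numeric(unlist(toks)), ncol = length(fields), byrow = TRUE)
  }
  colnames(m) <- fields
  if (!all(c("x", "y", "z") %in% fields))
    stop("PCD file lacks x/y/z fields")
  labels <- if ("label" %in% fields) as.integer(m[, "label"])
  extra <- setdiff(fields, c("x", "y", "z", "label"))
  point_cloud(m[, c("x", "y", "z"), drop = FALSE], labels = labels,
              attrs = if (length(extra)) as.data.frame(m[, extra, drop = FALSE]))
}

.write_pcd <- function(cloud, path) {
  p <- cloud$points
  fields <- c("x", "y", "z", if (!is.null(cloud$labels)) "label")
  n <- nrow(p)
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", paste(fields, collapse = " ")),
           paste("SIZE", paste(rep(ifelse(fields == "label", 4, 8),
                                   length.out = length(fields)), collapse = " ")),
           paste("TYPE", paste(ifelse(fields == "label", "I", "F"),
                               collapse = " ")),
           paste("COUNT", paste(rep(1, length(fields)), collapse = " ")),
           paste("WIDTH", n), "HEIGHT 1", "VIEWPOINT 0 0 0 1 0 0 0",
           paste("POINTS", n), "DATA ascii")
  body <- .num_rows(p)
  if (!is.null(cloud$labels) && length(body)) body <- paste(body, cloud$labels)
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- XYZ ----------------------------------------------------------------

.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(point_cloud(matrix(numeric(0), 0, 3)))
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 3))
    stop("XYZ line ", which(nf < 3)[1], " has fewer than 3 fields")
  if (length(unique(nf)) > 1)
    stop("XYZ file has inconsistent field counts (line ",
         which(nf != nf[1])[1], ")")
  m <- matrix(as.numeric(unlist(toks)), ncol = nf[1], byrow = TRUE)
  if (anyNA(m))
    stop("XYZ file has a non-numeric field (line ",
         which(rowSums(is.na(m)) > 0)[1], ")")
  labels <- if (ncol(m) >= 4) as.integer(m[, 4])
  point_cloud(m[, 1:3, drop = FALSE], labels = labels)
}

.write_xyz <- function(cloud, path) {
  body <- .num_rows(cloud$points)
  if (!is.null(cloud$labels) && length(body)) body <- paste(body, cloud$labels)
  writeLines(body, path)
  invisible(path)
}
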