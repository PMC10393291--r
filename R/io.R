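# Surface-format I/O. Two interchange routes:
#   * GIFTI (.surf.gii / .func.gii / .shape.gii / .label.gii): XML per the
#     format specification; writing uses ASCII data encoding, reading also
#     accepts Base64Binary and GZipBase64Binary. Triangle indices are
#     0-based on disk (the format's convention) and 1-based in memory.
#   * the gradparc container: a plain-text, versioned, header + row-major
#     values format that round-trips doubles bit-exactly ("%.17g").

## ---- gradparc container ----------------------------------------------

#' Write matrices to a gradparc container file
#'
#' A versioned plain-text format: a magic line, optional metadata lines,
#' and named blocks of row-major numeric values written with full
#' precision, so write-then-read reproduces every value bit-exactly.
#'
#' @param blocks named list of numeric matrices/vectors.
#' @param path output path.
#' @param meta named character vector of metadata.
#' @export
write_container <- function(blocks, path, meta = character()) {
  stopifnot(is.list(blocks), !is.null(names(blocks)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gradparc-container 1", con)
  for (key in names(meta))
    writeLines(paste0("meta ", key, "\t", meta[[key]]), con)
  for (name in names(blocks)) {
    b <- blocks[[name]]
    if (is.null(dim(b))) b <- matrix(b, ncol = 1L)
    writeLines(sprintf("@block %s %d %d %s", name, nrow(b), ncol(b),
                       if (is.integer(b)) "int" else "double"), con)
    if (is.integer(b)) {
      writeLines(apply(b, 1L, paste, collapse = " "), con)
    } else {
      txt <- matrix(sprintf("%.17g", b), nrow(b), ncol(b))
      writeLines(apply(txt, 1L, paste, collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a gradparc container file
#'
#' @param path path written by \code{\link{write_container}}.
#' @return list with \code{blocks} (named matrices) and \code{meta}.
#' @export
read_container <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[[1L]], "#gradparc-container"))
    stop("not a gradparc container: missing magic line in ", path)
  meta <- character()
  blocks <- list()
  i <- 2L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, "meta ")) {
      kv <- strsplit(sub("^meta ", "", ln), "\t", fixed = TRUE)[[1L]]
      meta[kv[[1L]]] <- if (length(kv) > 1L) kv[[2L]] else ""
      i <- i + 1L
    } else if (startsWith(ln, "@block ")) {
      hdr <- strsplit(ln, " ", fixed = TRUE)[[1L]]
      if (length(hdr) != 5L) stop("malformed @block header: ", ln)
      nr <- as.integer(hdr[[3L]])
      nc <- as.integer(hdr[[4L]])
      rows <- lines[(i + 1L):(i + nr)]
      vals <- scan(text = rows, quiet = TRUE,
                   what = if (hdr[[5L]] == "int") integer() else double())
      if (length(vals) != nr * nc)
        stop("block '", hdr[[2L]], "' has ", length(vals),
             " values, expected ", nr * nc)
      blocks[[hdr[[2L]]]] <- matrix(vals, nr, nc, byrow = TRUE)
      i <- i + 1L + nr
    } else if (!nzchar(trimws(ln))) {
      i <- i + 1L
    } else {
      stop("unexpected line ", i, " in container: ", ln)
    }
  }
  list(blocks = blocks, meta = meta)
}

#' Write a cortical mesh to a container file
#' @param mesh a \code{cortical_mesh}.
#' @param path output path.
#' @export
write_mesh_container <- function(mesh, path) {
  write_container(
    list(vertices = mesh$vertices, triangles = mesh$triangles,
         sphere = mesh$sphere,
         medial_wall = matrix(as.integer(mesh$medial_wall), ncol = 1L)),
    path,
    meta = c(type = "mesh", hemisphere = mesh$hemisphere,
             radius = sprintf("%.17g", mesh$radius)))
}

#' Read a cortical mesh from a container file
#' @param path container path written by \code{\link{write_mesh_container}}.
#' @return a \code{cortical_mesh}.
#' @export
read_mesh_container <- function(path) {
  x <- read_container(path)
  if (!identical(unname(x$meta["type"]), "mesh"))
    stop("container is not of type 'mesh'")
  cortical_mesh(x$blocks$vertices, x$blocks$triangles,
                sphere = x$blocks$sphere,
                radius = as.numeric(x$meta["radius"]),
                medial_wall = x$blocks$medial_wall[, 1L] == 1L,
                hemisphere = unname(x$meta["hemisphere"]))
}

## ---- GIFTI ------------------------------------------------------------

gifti_type_info <- function(dtype) {
  switch(dtype,
         NIFTI_TYPE_FLOAT32 = list(what = "double", size = 4L),
         NIFTI_TYPE_FLOAT64 = list(what = "double", size = 8L),
         NIFTI_TYPE_INT32 = list(what = "integer", size = 4L),
         NIFTI_TYPE_UINT8 = list(what = "integer", size = 1L),
         stop("unsupported GIFTI DataType: ", dtype))
}

gifti_read_data <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  endian <- xml2::xml_attr(node, "Endian")
  dims <- as.integer(c(xml2::xml_attr(node, "Dim0"),
                       xml2::xml_attr(node, "Dim1")))
  dims <- dims[!is.na(dims)]
  order_rm <- !identical(xml2::xml_attr(node, "ArrayIndexingOrder"),
                         "ColumnMajorOrder")
  data_node <- xml2::xml_find_first(node, ".//Data")
  if (inherits(data_node, "xml_missing"))
    stop("malformed GIFTI DataArray: missing Data element")
  txt <- xml2::xml_text(data_node)
  info <- gifti_type_info(dtype)
  vals <- switch(enc,
    ASCII = scan(text = txt, what = double(), quiet = TRUE, na.strings = c("NA", "NaN", "nan")),
    Base64Binary = {
      raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
      readBin(raw, info$what, n = length(raw) / info$size, size = info$size,
              endian = if (identical(endian, "BigEndian")) "big" else "little")
    },
    GZipBase64Binary = {
      raw <- memDecompress(jsonlite::base64_dec(gsub("\\s", "", txt)),
                           type = "gzip")
      readBin(raw, info$what, n = length(raw) / info$size, size = info$size,
              endian = if (identical(endian, "BigEndian")) "big" else "little")
    },
    stop("unsupported GIFTI Encoding: ", enc))
  if (length(dims) == 2L) {
    matrix(vals, dims[[1L]], dims[[2L]], byrow = order_rm)
  } else {
    vals
  }
}

gifti_data_array <- function(values, intent, dtype) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  dimattr <- if (ncol(values) > 1L)
    sprintf(' Dimensionality="2" Dim0="%d" Dim1="%d"', nrow(values),
            ncol(values))
  else sprintf(' Dimensionality="1" Dim0="%d"', nrow(values))
  fmt_num <- function(v) {
    out <- sprintf("%.9g", v)
    out[is.na(v)] <- "NaN"
    out
  }
  body <- if (intent == "NIFTI_INTENT_TRIANGLE" || dtype == "NIFTI_TYPE_INT32") {
    apply(matrix(as.integer(values), nrow(values)), 1L, paste, collapse = " ")
  } else {
    apply(matrix(fmt_num(values), nrow(values)), 1L, paste, collapse = " ")
  }
  paste0('<DataArray Intent="', intent, '" DataType="', dtype,
         '" ArrayIndexingOrder="RowMajorOrder"', dimattr,
         ' Encoding="ASCII" Endian="LittleEndian"',
         ' ExternalFileName="" ExternalFileOffset="">\n<Data>',
         paste(body, collapse = "\n"), "</Data>\n</DataArray>")
}

gifti_document <- function(arrays, label_table = NULL) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<!DOCTYPE GIFTI SYSTEM "http://www.nitrc.org/frs/download.php/115/gifti.dtd">\n',
         '<GIFTI Version="1.0" NumberOfDataArrays="', length(arrays), '">\n',
         if (!is.null(label_table)) label_table else "",
         paste(arrays, collapse = "\n"), "\n</GIFTI>\n")
}

#' Write a mesh as a GIFTI surface file
#'
#' Two data arrays: the vertex coordinates (pointset) and the 0-based
#' triangle indices. Coordinates are written as float values in ASCII
#' encoding; round trips reproduce them within float precision.
#'
#' @param mesh a \code{cortical_mesh}.
#' @param path output path (conventionally \code{*.surf.gii}).
#' @param sphere write the spherical coordinates instead of the anatomical
#'   ones.
#' @export
write_surface_gifti <- function(mesh, path, sphere = FALSE) {
  coords <- if (sphere) mesh$sphere else mesh$vertices
  arrays <- c(
    gifti_data_array(coords, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32"),
    gifti_data_array(mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                     "NIFTI_TYPE_INT32"))
  writeLines(gifti_document(arrays), path)
  invisible(path)
}

#' Write per-vertex maps as a GIFTI metric file
#'
#' @param values per-vertex vector or V x n matrix (one data array per
#'   column); \code{NA} is written as NaN.
#' @param path output path (\code{*.func.gii} / \code{*.shape.gii}).
#' @export
write_metric_gifti <- function(values, path) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  arrays <- vapply(seq_len(ncol(values)), function(j)
    gifti_data_array(values[, j], "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32"),
    character(1))
  writeLines(gifti_document(arrays), path)
  invisible(path)
}

#' Write a parcellation as a GIFTI label file
#'
#' Label 0 is reserved for the border/medial wall and named \code{???} by
#' convention; parcel labels get a deterministic colortable.
#'
#' @param parc a \code{parcellation} (or integer label vector).
#' @param path output path (\code{*.label.gii}).
#' @export
write_label_gifti <- function(parc, path) {
  labels <- if (inherits(parc, "parcellation")) parc$labels else as.integer(parc)
  ids <- sort(unique(labels))
  set_cols <- function(id) {
    # deterministic colortable: golden-ratio hue walk
    h <- (id * 0.618033988749895) %% 1
    c(h, (0.35 + 0.5 * ((id * 7L) %% 2L)), 0.85)
  }
  rows <- vapply(ids, function(id) {
    if (id == 0L)
      return('<Label Key="0" Red="0.66" Green="0.66" Blue="0.66" Alpha="1">???</Label>')
    col <- set_cols(id)
    sprintf('<Label Key="%d" Red="%.4f" Green="%.4f" Blue="%.4f" Alpha="1">parcel_%03d</Label>',
            id, col[1L], col[2L], col[3L], id)
  }, character(1))
  lt <- paste0("<LabelTable>\n", paste(rows, collapse = "\n"),
               "\n</LabelTable>\n")
  arrays <- gifti_data_array(matrix(labels, ncol = 1L),
                             "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32")
  writeLines(gifti_document(arrays, label_table = lt), path)
  invisible(path)
}

#' Read a GIFTI file
#'
#' Dispatches on the intents found: a pointset + triangle pair yields a
#' \code{cortical_mesh}, label arrays yield an integer label vector with a
#' \code{label_table} attribute, and metric arrays yield a per-vertex
#' vector or matrix (NaN read back as \code{NA}).
#'
#' @param path GIFTI file path.
#' @param radius sphere radius assumed when the file holds a spherical
#'   surface.
#' @return mesh, labels or metric values, by content.
#' @export
read_gifti <- function(path, radius = 100) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed GIFTI file ", path, ": ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0L)
    stop("malformed GIFTI file ", path, ": no DataArray element")
  intents <- xml2::xml_attr(arrays, "Intent")
  data <- lapply(arrays, gifti_read_data)
  if ("NIFTI_INTENT_POINTSET" %in% intents &&
      "NIFTI_INTENT_TRIANGLE" %in% intents) {
    pts <- data[[which(intents == "NIFTI_INTENT_POINTSET")[1L]]]
    tri <- data[[which(intents == "NIFTI_INTENT_TRIANGLE")[1L]]] + 1L
    storage.mode(tri) <- "integer"
    nrm <- sqrt(rowSums(pts^2))
    on_sphere <- max(abs(nrm - mean(nrm))) < 1e-3 * mean(nrm)
    return(cortical_mesh(pts, tri,
                         sphere = if (on_sphere) pts * (radius / nrm),
                         radius = radius))
  }
  if (all(intents == "NIFTI_INTENT_LABEL")) {
    labels <- as.integer(data[[1L]])
    lt_nodes <- xml2::xml_find_all(doc, ".//LabelTable/Label")
    lt <- setNames(xml2::xml_text(lt_nodes),
                   xml2::xml_attr(lt_nodes, "Key"))
    attr(labels, "label_table") <- lt
    return(labels)
  }
  out <- do.call(cbind, data)
  out[is.nan(out)] <- NA_real_
  if (ncol(out) == 1L) out <- out[, 1L]
  out
}
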