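## Domain containers and cryo-EM file formats (MRC2014 images/volumes,
## STAR-style metadata tables, plain-text pick coordinate files).

#' 2D image with a physical pixel size
#'
#' The basic unit of all 2D processing: a real-valued pixel matrix (indexed
#' `[x, y]`, 0-based coordinates in the documented convention) plus the pixel
#' size in Angstrom per pixel.
#'
#' @param pixels numeric matrix of finite values.
#' @param pixel_size pixel size in Angstrom/pixel, > 0.
#' @return an object of class `image2d`: a list with elements `pixels` and
#'   `pixel_size`.
#' @export
image2d <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), length(pixel_size) == 1, pixel_size > 0)
  if (!all(is.finite(pixels))) stop("image2d: non-finite pixel values")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %d x %d, %.4g A/px, range [%.4g, %.4g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_image2d <- function(x, pixel_size = 1) {
  if (inherits(x, "image2d")) x else image2d(x, pixel_size)
}

#' Stack of equally-sized 2D images with per-image metadata
#'
#' @param data 3D numeric array `nx x ny x n_images` (or a list of `image2d`).
#' @param pixel_size Angstrom/pixel shared by all images.
#' @param metadata data frame with one row per image; when omitted a minimal
#'   table with a `segment_id` column is created.
#' @return object of class `image_stack` with elements `data`, `pixel_size`,
#'   `metadata`.
#' @export
image_stack <- function(data, pixel_size, metadata = NULL) {
  if (is.list(data) && !is.array(data)) {
    ps <- unique(vapply(data, function(im) im$pixel_size, numeric(1)))
    if (length(ps) != 1) stop("image_stack: inconsistent pixel sizes")
    if (missing(pixel_size)) pixel_size <- ps
    data <- simplify2array(lapply(data, function(im) im$pixels))
  }
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3, pixel_size > 0)
  if (!all(is.finite(data))) stop("image_stack: non-finite pixel values")
  n <- dim(data)[3]
  if (is.null(metadata)) {
    metadata <- data.frame(segment_id = seq_len(n))
  }
  if (nrow(metadata) != n)
    stop("image_stack: metadata rows (", nrow(metadata),
         ") != number of images (", n, ")")
  structure(list(data = data, pixel_size = as.numeric(pixel_size),
                 metadata = metadata),
            class = "image_stack")
}

#' Number of images in a stack
#' @param stack an `image_stack`.
#' @export
n_images <- function(stack) dim(stack$data)[3]

#' Extract one image of a stack as an `image2d`
#' @param stack an `image_stack`.
#' @param i image index (1-based).
#' @export
get_image <- function(stack, i) {
  image2d(stack$data[, , i], stack$pixel_size)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack: %d images of %d x %d, %.4g A/px, %d metadata cols>\n",
              d[3], d[1], d[2], x$pixel_size, ncol(x$metadata)))
  invisible(x)
}

#' Cubic 3D density volume
#'
#' Houses the azimuthal average; the tube axis runs along the third (z)
#' array dimension.
#'
#' @param voxels cubic numeric 3D array.
#' @param voxel_size Angstrom/voxel, > 0.
#' @export
volume3d <- function(voxels, voxel_size) {
  d <- dim(voxels)
  stopifnot(length(d) == 3, voxel_size > 0)
  if (d[1] != d[2] || d[2] != d[3])
    stop("volume3d: volume must be cubic, got ", paste(d, collapse = "x"))
  if (!all(is.finite(voxels))) stop("volume3d: non-finite voxel values")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d %d^3, %.4g A/voxel>\n", dim(x$voxels)[1], x$voxel_size))
  invisible(x)
}

## ---------------------------------------------------------------------------
## MRC2014 reader/writer (mode 2, 32-bit float, little-endian).

mrc_write_header <- function(con, nx, ny, nz, pixel_size, d, is_volume) {
  writeBin(as.integer(c(nx, ny, nz, 2L)), con, size = 4, endian = "little")
  writeBin(as.integer(c(0, 0, 0)), con, size = 4, endian = "little")   # nstart
  writeBin(as.integer(c(nx, ny, nz)), con, size = 4, endian = "little") # mx my mz
  writeBin(as.numeric(c(nx, ny, nz) * pixel_size), con, size = 4,
           endian = "little")                                           # cella
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little") # cellb
  writeBin(as.integer(c(1, 2, 3)), con, size = 4, endian = "little")    # map order
  writeBin(as.numeric(c(min(d), max(d), mean(d))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(if (is_volume) 1L else 0L, 0L)), con, size = 4,
           endian = "little")                                           # ispg, nsymbt
  writeBin(raw(100), con)                                               # extra
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")    # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                      # machst
  writeBin(as.numeric(stats::sd(d)), con, size = 4, endian = "little")  # rms
  writeBin(0L, con, size = 4, endian = "little")                        # nlabl
  writeBin(raw(800), con)                                               # labels
}

mrc_read_header <- function(con, path) {
  ints1 <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  maps  <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstat <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  isp   <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  seek(con, 208)
  map_id <- readChar(con, 4, useBytes = TRUE)
  nx <- ints1[1]; ny <- ints1[2]; nz <- ints1[3]; mode <- ints1[4]
  mx <- ints1[8]
  if (!identical(map_id, "MAP ") && !identical(substr(map_id, 1, 3), "MAP"))
    stop("not an MRC2014 file (missing MAP id): ", path)
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e5 || ny > 1e5 || nz > 1e6)
    stop("corrupt MRC header dimensions in ", path)
  if (mode != 2)
    stop("unsupported MRC mode ", mode, " (only mode 2 float32): ", path)
  pixel_size <- if (mx > 0 && cella[1] > 0) cella[1] / mx else 1
  list(nx = nx, ny = ny, nz = nz, mode = mode, pixel_size = pixel_size,
       ispg = isp[1])
}

mrc_read_data <- function(con, h, path) {
  seek(con, 1024)
  n <- h$nx * h$ny * h$nz
  d <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(d) != n)
    stop("MRC data truncated: header promises ", n, " values, file has ",
         length(d), ": ", path)
  array(d, dim = c(h$nx, h$ny, h$nz))
}

## ---------------------------------------------------------------------------
## STAR-style metadata tables.

## internal column name -> RELION-style STAR label
star_label_map <- c(
  segment_id      = "rlnImageId",
  micrograph_id   = "rlnMicrographName",
  origin_x        = "rlnCoordinateX",
  origin_y        = "rlnCoordinateY",
  psi_deg         = "rlnAnglePsi",
  theta_deg       = "rlnAngleTilt",
  phi_deg         = "rlnAngleRot",
  shift_x_px      = "rlnOriginX",
  shift_y_px      = "rlnOriginY",
  defocus_A       = "rlnDefocusU",
  amp_contrast    = "rlnAmplitudeContrast",
  alignment_score = "rastrAlignmentScore",
  edge_left_px    = "rastrEdgeLeft",
  edge_right_px   = "rastrEdgeRight",
  align_ok        = "rastrAlignOk",
  scale_alpha     = "rastrScaleAlpha",
  residual_rms    = "rastrResidualRms"
)

#' Write a metadata table as a STAR file
#'
#' Columns with a standard RELION name are written under that label
#' (`rlnAnglePsi`, `rlnOriginX`, ...); package-specific columns are prefixed
#' `rastr`. Numeric values keep at least 7 significant digits.
#'
#' @param df data frame, one row per image/particle.
#' @param path output path.
#' @param block STAR data block name (default "particles").
#' @export
write_star <- function(df, path, block = "particles") {
  labels <- vapply(names(df), function(nm) {
    if (nm %in% names(star_label_map)) star_label_map[[nm]]
    else if (grepl("^(rln|rastr)", nm)) nm
    else paste0("rastr", toupper(substring(nm, 1, 1)), substring(nm, 2))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", paste0("data_", block), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", labels, seq_along(labels)), con)
  fmt_cell <- function(v) {
    if (is.numeric(v)) formatC(v, format = "g", digits = 8)
    else as.character(v)
  }
  cols <- lapply(df, fmt_cell)
  if (nrow(df) > 0)
    writeLines(do.call(paste, cols), con)
  invisible(path)
}

#' Read a STAR file into a data frame
#'
#' Parses the first `loop_` block; RELION-style labels that have a package
#' equivalent are mapped back to internal column names.
#'
#' @param path STAR file path.
#' @return data frame.
#' @export
read_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (length(loop_at) == 0) stop("no loop_ block in STAR file: ", path)
  i <- loop_at[1] + 1
  labels <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    lab <- sub("^_", "", strsplit(lines[i], "[ \t#]+")[[1]][1])
    labels <- c(labels, lab)
    i <- i + 1
  }
  rows <- lines[i:length(lines)]
  rows <- rows[nzchar(rows) & !startsWith(rows, "data_")]
  if (length(rows) == 0) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(labels)))
  } else {
    parts <- strsplit(rows, "[ \t]+")
    bad <- vapply(parts, length, integer(1)) != length(labels)
    if (any(bad)) stop("malformed STAR row(s) in ", path)
    df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  }
  names(df) <- labels
  rev_map <- stats::setNames(names(star_label_map), star_label_map)
  names(df) <- ifelse(names(df) %in% names(rev_map), rev_map[names(df)],
                      names(df))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (nrow(df) == 0 || !anyNA(v)) df[[j]] <- v
  }
  df
}

## ---------------------------------------------------------------------------
## High-level stack / volume I/O.

star_sidecar <- function(path) sub("\\.mrcs?$", ".star", path)

#' Write an image stack to disk (MRC + STAR sidecar)
#'
#' Writes a mode-2 (32-bit float) MRC2014 image stack with the pixel size
#' recorded in the header, and the metadata table as a STAR file next to it
#' (same basename, `.star` extension).
#'
#' @param stack an `image_stack` with at least one image.
#' @param path output `.mrc`/`.mrcs` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (n_images(stack) == 0) stop("write_stack: empty stack")
  d <- dim(stack$data)
  con <- file(path, "wb")
  on.exit(close(con))
  mrc_write_header(con, d[1], d[2], d[3], stack$pixel_size, stack$data,
                   is_volume = FALSE)
  writeBin(as.numeric(stack$data), con, size = 4, endian = "little")
  close(con); on.exit(NULL)
  write_star(stack$metadata, star_sidecar(path))
  invisible(path)
}

#' Read an image stack from disk
#'
#' Reads a mode-2 MRC2014 stack; if a STAR sidecar (same basename) exists its
#' rows become the stack metadata, otherwise a minimal table with
#' `segment_id` is created.
#'
#' @param path `.mrc`/`.mrcs` file.
#' @return an `image_stack`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  expected <- file.size(path) - 1024
  con <- file(path, "rb")
  on.exit(close(con))
  h <- mrc_read_header(con, path)
  if (h$nx * h$ny * h$nz * 4 > expected)
    stop("MRC data truncated: header promises more images than the file holds: ",
         path)
  data <- mrc_read_data(con, h, path)
  meta_path <- star_sidecar(path)
  metadata <- if (file.exists(meta_path)) read_star(meta_path) else NULL
  image_stack(data, h$pixel_size, metadata)
}

#' Write a cubic volume as an MRC2014 file
#' @param vol a `volume3d`.
#' @param path output path.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  d <- dim(vol$voxels)
  con <- file(path, "wb")
  on.exit(close(con))
  mrc_write_header(con, d[1], d[2], d[3], vol$voxel_size, vol$voxels,
                   is_volume = TRUE)
  writeBin(as.numeric(vol$voxels), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a cubic volume from an MRC2014 file
#' @param path MRC file; must contain a cubic grid.
#' @return a `volume3d`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- mrc_read_header(con, path)
  if (h$nx != h$ny || h$ny != h$nz)
    stop("read_volume: non-cubic volume ",
         paste(c(h$nx, h$ny, h$nz), collapse = "x"), ": ", path)
  data <- mrc_read_data(con, h, path)
  volume3d(data, h$pixel_size)
}

#' Write picks as a plain-text coordinate file
#'
#' Tab-separated columns: micrograph_id, global_x, global_y (0-based pixel
#' coordinates in the parent micrograph frame), score, plus the
#' segment-local bookkeeping columns (segment_id, local_x, local_y).
#'
#' @param picks data frame of picks (see [pick_by_template()]).
#' @param path output path.
#' @export
write_picks <- function(picks, path) {
  cols <- intersect(c("micrograph_id", "global_x", "global_y", "score",
                      "segment_id", "local_x", "local_y"), names(picks))
  df <- picks[, cols, drop = FALSE]
  utils::write.table(format(df, digits = 8, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pick coordinate file written by [write_picks()]
#' @param path coordinate file.
#' @export
read_picks <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
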