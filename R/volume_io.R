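#' Gray-level 3-D volume
#'
#' Container for a reconstructed (or synthetic) gray-level voxel grid with an
#' isotropic voxel size in micrometres.
#'
#' @param voxels 3-D integer or numeric array of gray levels.
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @param provenance Free-form list recording where the volume came from
#'   (source path, phantom seed/spec, ...).
#' @return A `volume3d` object.
#' @export
volume3d <- function(voxels, voxel_size, provenance = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    stop_olive("voxels must be a 3-D array")
  }
  if (any(dim(voxels) < 8)) stop_olive("all volume dimensions must be >= 8")
  check_number(voxel_size, "voxel_size", lower = 1e-9)
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 provenance = provenance),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume3d> %d x %d x %d voxels @ %.1f um (range %d..%d)\n",
              d[1], d[2], d[3], x$voxel_size,
              as.integer(min(x$voxels)), as.integer(max(x$voxels))))
  invisible(x)
}

#' Write / read a volume as a multi-page TIFF stack
#'
#' Slices are stored along z (page order = z). A JSON sidecar
#' (`<path>.json`) records the voxel size and provenance so the volume
#' round-trips losslessly.
#'
#' @param volume A [volume3d()].
#' @param path Output `.tif` path.
#' @param bits 8 or 16 bits per sample.
#' @return `write_volume_tiff()` returns `path` invisibly;
#'   `read_volume_tiff()` returns a [volume3d()].
#' @export
write_volume_tiff <- function(volume, path, bits = 8L) {
  stopifnot(inherits(volume, "volume3d"), bits %in% c(8L, 16L))
  maxval <- 2^bits - 1
  v <- volume$voxels
  v[] <- pmin(maxval, pmax(0, round(v)))
  slices <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / maxval)
  tiff::writeTIFF(slices, path, bits.per.sample = bits)
  sidecar <- list(voxel_size_um = volume$voxel_size,
                  dims = dim(v), bits = bits,
                  provenance = volume$provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  d <- dim(slices[[1]])
  vox <- array(0L, c(d[2], d[1], length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- t(slices[[k]])
  meta_path <- paste0(path, ".json")
  voxel_size <- 1
  provenance <- list(source = path)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    voxel_size <- meta$voxel_size_um %||% 1
    provenance <- c(provenance, meta["provenance"])
  }
  volume3d(vox, voxel_size = voxel_size, provenance = provenance)
}

#' Write / read a volume in NRRD format
#'
#' Minimal NRRD support (raw little-endian encoding, 8- or 16-bit unsigned),
#' sufficient to exchange single-drupe volumes with common micro-CT viewers.
#'
#' @inheritParams write_volume_tiff
#' @param path Output `.nrrd` path.
#' @export
write_volume_nrrd <- function(volume, path, bits = 8L) {
  stopifnot(inherits(volume, "volume3d"), bits %in% c(8L, 16L))
  v <- volume$voxels
  spacing <- volume$voxel_size / 1000  # mm
  header <- c(
    "NRRD0004",
    "# olivemorph volume",
    paste0("type: ", if (bits == 8L) "unsigned char" else "unsigned short"),
    "dimension: 3",
    paste0("sizes: ", paste(dim(v), collapse = " ")),
    paste0("spacings: ", paste(rep(spacing, 3), collapse = " ")),
    "encoding: raw",
    "endian: little",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  vals <- as.integer(pmin(2^bits - 1, pmax(0, round(v))))
  writeBin(vals, con, size = bits / 8, endian = "little")
  invisible(path)
}

#' @rdname write_volume_nrrd
#' @export
read_volume_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0 || line == "") break
    header <- c(header, line)
  }
  field <- function(key) {
    hit <- grep(paste0("^", key, ":"), header, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  type <- field("type") %||% "unsigned char"
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  spacings <- suppressWarnings(as.numeric(strsplit(field("spacings") %||% "1 1 1",
                                                   "\\s+")[[1]]))
  enc <- field("encoding") %||% "raw"
  if (enc != "raw") stop_olive("only raw NRRD encoding is supported")
  size <- if (grepl("short|int16|uint16", type)) 2L else 1L
  n <- prod(sizes)
  vals <- readBin(con, "integer", n = n, size = size, signed = FALSE,
                  endian = "little")
  volume3d(array(vals, sizes), voxel_size = spacings[1] * 1000,
           provenance = list(source = path))
}
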