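# Point-cloud file IO: binary little-endian PLY and PCD v0.7. Coordinates
# are written as 32-bit floats (the formats' conventional precision) and
# colors as uchar, so a write-read round trip reproduces coordinates at
# float32 precision exactly.

#' Write a point cloud to PLY or PCD
#'
#' PLY is written `format binary_little_endian 1.0` with float `x y z`
#' and, when the cloud is colored, `uchar red green blue`. PCD is written
#' v0.7 binary with fields `x y z` (+ packed float `rgb` when colored).
#'
#' @param cloud A finite [point_cloud()].
#' @param path Output path.
#' @param format `"ply"` or `"pcd"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cloud$count > 0 && !all(is.finite(cloud$points)))
    stop("cloud contains non-finite points; run remove_invalid() first")
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "pcd"))
  if (format == "ply") write_ply(cloud, path) else write_pcd(cloud, path)
}

#' Read a point cloud from PLY or PCD
#' @param path Input path.
#' @param format `"ply"` or `"pcd"` (default from the file extension).
#' @return A [point_cloud()].
#' @export
read_cloud <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "pcd"))
  if (format == "ply") read_ply(path) else read_pcd(path)
}

#' @rdname write_cloud
#' @export
write_ply <- function(cloud, path) {
  n <- cloud$count
  colored <- !is.null(cloud$colors)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z")
  if (colored)
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con, sep = "\n")
  if (n > 0) {
    xyz <- t(cloud$points)
    if (colored) {
      rgb <- t(pmin(pmax(round(cloud$colors * 255), 0), 255))
      for (i in seq_len(n)) {
        writeBin(as.numeric(xyz[, i]), con, size = 4, endian = "little")
        writeBin(as.integer(rgb[, i]), con, size = 1, endian = "little")
      }
    } else {
      writeBin(as.numeric(xyz), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname read_cloud
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    hdr <- c(hdr, line)
    if (line == "end_header") break
    if (length(hdr) > 200) stop("not a PLY file: ", path)
  }
  if (hdr[1] != "ply" || !any(grepl("binary_little_endian", hdr)))
    stop("only binary little-endian PLY is supported")
  n <- as.integer(sub("element vertex ", "",
                      grep("^element vertex", hdr, value = TRUE)))
  props <- sub("^property ", "", grep("^property", hdr, value = TRUE))
  colored <- any(grepl("uchar red", props))
  if (n == 0) return(point_cloud(matrix(numeric(), 0, 3)))
  if (colored) {
    raw <- readBin(con, "raw", n * 15L)
    m <- matrix(raw, nrow = 15L)
    xyz <- matrix(readBin(as.vector(m[1:12, ]), "numeric", n * 3L,
                          size = 4, endian = "little"), ncol = 3,
                  byrow = TRUE)
    rgb <- matrix(as.integer(m[13:15, ]), ncol = 3, byrow = TRUE) / 255
    point_cloud(xyz, rgb)
  } else {
    xyz <- matrix(readBin(con, "numeric", n * 3L, size = 4,
                          endian = "little"), ncol = 3, byrow = TRUE)
    point_cloud(xyz)
  }
}

pack_rgb_float <- function(colors) {
  rgb <- pmin(pmax(round(colors * 255), 0), 255)
  ints <- as.integer(rgb[, 1]) * 65536L + as.integer(rgb[, 2]) * 256L +
    as.integer(rgb[, 3])
  readBin(writeBin(ints, raw(), size = 4, endian = "little"),
          "numeric", length(ints), size = 4, endian = "little")
}

unpack_rgb_float <- function(f) {
  ints <- readBin(writeBin(f, raw(), size = 4, endian = "little"),
                  "integer", length(f), size = 4, endian = "little")
  cbind(bitwAnd(bitwShiftR(ints, 16L), 255L),
        bitwAnd(bitwShiftR(ints, 8L), 255L),
        bitwAnd(ints, 255L)) / 255
}

#' @rdname write_cloud
#' @export
write_pcd <- function(cloud, path) {
  n <- cloud$count
  colored <- !is.null(cloud$colors)
  fields <- if (colored) "x y z rgb" else "x y z"
  nf <- if (colored) 4L else 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("# .PCD v0.7 - Point Cloud Data file format",
               "VERSION 0.7",
               paste("FIELDS", fields),
               paste("SIZE", paste(rep(4, nf), collapse = " ")),
               paste("TYPE", paste(rep("F", nf), collapse = " ")),
               paste("COUNT", paste(rep(1, nf), collapse = " ")),
               sprintf("WIDTH %d", n), "HEIGHT 1",
               "VIEWPOINT 0 0 0 1 0 0 0",
               sprintf("POINTS %d", n), "DATA binary"), con, sep = "\n")
  if (n > 0) {
    dat <- t(cloud$points)
    if (colored) dat <- rbind(dat, pack_rgb_float(cloud$colors))
    writeBin(as.numeric(dat), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname read_cloud
#' @export
read_pcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    hdr <- c(hdr, line)
    if (grepl("^DATA", line)) break
    if (length(hdr) > 50) stop("not a PCD file: ", path)
  }
  if (!grepl("binary", hdr[length(hdr)]))
    stop("only binary PCD is supported")
  n <- as.integer(sub("POINTS ", "", grep("^POINTS", hdr, value = TRUE)))
  fields <- strsplit(sub("FIELDS ", "",
                         grep("^FIELDS", hdr, value = TRUE)), " ")[[1]]
  nf <- length(fields)
  if (n == 0) return(point_cloud(matrix(numeric(), 0, 3)))
  dat <- matrix(readBin(con, "numeric", n * nf, size = 4,
                        endian = "little"), nrow = nf)
  cols <- if ("rgb" %in% fields)
    unpack_rgb_float(dat[which(fields == "rgb"), ]) else NULL
  point_cloud(t(dat[1:3, , drop = FALSE]), cols)
}
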