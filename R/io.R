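# Volume containers and file formats: MetaImage-style volumes (text header
# + raw, round-trips bit-exactly), JSON configs/sidecars, CSV reports.

#' Create a gridded volume
#'
#' The shared lattice container: a 3-D array with a world origin (mm, at the
#' corner of the first voxel) and per-axis spacing (mm). Voxel centers sit at
#' `origin + (index - 0.5) * spacing` (1-based indices). Axis convention:
#' x = left-right, y = anterior->posterior (the AP beam direction),
#' z = superior-inferior (the gantry rotation axis).
#'
#' @param data 3-D numeric or integer array.
#' @param origin numeric length-3, mm.
#' @param spacing numeric length-3, mm (all > 0).
#' @param meta optional named list of provenance fields.
#' @return object of class `tte_volume`.
#' @export
tte_volume <- function(data, origin, spacing, meta = list()) {
  stopifnot(length(dim(data)) == 3L, length(origin) == 3L,
            length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), meta = meta),
            class = "tte_volume")
}

#' @export
print.tte_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tte_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Voxel-center coordinates of a volume axis
#' @param vol a `tte_volume` (or any object with origin/spacing/data).
#' @param axis 1, 2 or 3 (or "x","y","z").
#' @return numeric vector of world coordinates (mm).
#' @export
voxel_centers <- function(vol, axis) {
  a <- if (is.character(axis)) match(axis, c("x", "y", "z")) else axis
  n <- dim(vol$data)[a]
  vol$origin[a] + (seq_len(n) - 0.5) * vol$spacing[a]
}

#' Write / read MetaImage-style volumes
#'
#' A minimal MetaImage (.mhd + .raw) dialect: text header with NDims,
#' DimSize, ElementSpacing, Offset, ElementType (MET_DOUBLE, MET_FLOAT or
#' MET_SHORT), ElementByteOrderMSB = False (little endian),
#' ElementDataFile. Extra provenance fields are written as comment lines
#' and restored on read. Round trip is bit-exact for MET_DOUBLE and
#' MET_SHORT.
#'
#' @param vol a [tte_volume()].
#' @param path path to the `.mhd` header; the `.raw` file is written next
#'   to it.
#' @param type element type.
#' @return `write_mhd`: the path, invisibly. `read_mhd`: a [tte_volume()].
#' @export
write_mhd <- function(vol, path, type = c("MET_DOUBLE", "MET_FLOAT", "MET_SHORT")) {
  type <- match.arg(type)
  stopifnot(inherits(vol, "tte_volume"))
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  if (identical(raw_name, basename(path))) raw_name <- paste0(basename(path), ".raw")
  d <- dim(vol$data)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "ElementByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(sprintf("%.17g", vol$spacing), collapse = " ")),
           paste("Offset =", paste(sprintf("%.17g", vol$origin), collapse = " ")),
           paste("ElementType =", type))
  if (length(vol$meta)) {
    flat <- vapply(vol$meta, function(v) paste(as.character(v), collapse = ","), "")
    hdr <- c(hdr, paste0("# meta ", names(flat), " = ", flat))
  }
  hdr <- c(hdr, paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  vals <- as.vector(vol$data)
  switch(type,
    MET_DOUBLE = writeBin(as.double(vals), con, size = 8, endian = "little"),
    MET_FLOAT  = writeBin(as.double(vals), con, size = 4, endian = "little"),
    MET_SHORT  = writeBin(as.integer(vals), con, size = 2, endian = "little"))
  invisible(path)
}

#' @rdname write_mhd
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# meta ", lines, value = TRUE)
  lines2 <- grep("^#", lines, invert = TRUE, value = TRUE)
  kv <- strsplit(lines2, " = ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1); vals <- vapply(kv, `[`, "", 2)
  get <- function(k) vals[match(k, keys)]
  d <- as.integer(strsplit(get("DimSize"), " ")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), " ")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), " ")[[1]])
  type <- get("ElementType")
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(d)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  data <- switch(type,
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    MET_FLOAT  = readBin(con, "double", n, size = 4, endian = "little"),
    MET_SHORT  = readBin(con, "integer", n, size = 2, signed = TRUE,
                         endian = "little"),
    stop("unsupported ElementType ", type))
  meta <- list()
  if (length(meta_lines)) {
    mm <- sub("^# meta ", "", meta_lines)
    mkv <- strsplit(mm, " = ", fixed = TRUE)
    meta <- stats::setNames(lapply(mkv, function(p) {
      v <- strsplit(p[2], ",", fixed = TRUE)[[1]]
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num)) num else v
    }), vapply(mkv, `[`, "", 1))
  }
  tte_volume(array(data, d), origin, spacing, meta)
}

#' Write a config / provenance JSON file
#'
#' Serializes a named list with [jsonlite::write_json()]; `read_config`
#' reads it back with simplification. Every pipeline output carries such a
#' sidecar with the seed, engine settings and a config hash.
#'
#' @param x named list.
#' @param path output path.
#' @export
write_config <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Stable hash of a configuration list
#'
#' MD5 of the canonical JSON serialization; recorded in output sidecars so
#' runs can be matched to their exact configuration.
#' @param x named list.
#' @return hex string.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Write a CSV report with provenance header comments
#'
#' RFC-4180 body preceded by `#`-prefixed metadata lines.
#' @param df data.frame.
#' @param path output path.
#' @param meta named list written as `# key = value` lines.
#' @export
write_report_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", names(meta), " = ",
                      vapply(meta, function(v) paste(v, collapse = ","), "")),
               con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
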