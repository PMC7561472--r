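RECORD_SCHEMA <- "blastomorph-records-1"
VOLUME_SCALE <- 65535

#' Write a 3D volume to disk
#'
#' Multi-page TIFF (`.tif` / `.tiff`; page k is z-slice k, 16-bit) or
#' raw-encoded NRRD (`.nrrd`). A sidecar JSON (`<path>.json`) records axis
#' order (`zyx`), voxel spacing and the integer scale, so a volume round
#' trips exactly for integer data in `[0, 65535]`; values are clipped and
#' rounded to that range.
#'
#' @param vol 3D numeric/integer array, `dim = (nz, ny, nx)`.
#' @param path output path ending in `.tif`, `.tiff` or `.nrrd`.
#' @param spacing voxel spacing `(z, y, x)` in µm.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  v <- pmin(pmax(round(vol), 0), VOLUME_SCALE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(dim(v)[1]), function(k) v[k, , ] / VOLUME_SCALE)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else if (ext == "nrrd") {
    write_nrrd(v, path, spacing)
  } else {
    stop("unsupported volume extension: .", ext)
  }
  jsonlite::write_json(
    list(axis_order = "zyx", spacing = spacing, scale = VOLUME_SCALE,
         dims = dim(v)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 3D volume written by [write_volume()]
#'
#' @param path `.tif` / `.tiff` / `.nrrd` path.
#' @return list with `vol` (integer array, `dim = (nz, ny, nx)`) and
#'   `spacing` (from the sidecar or NRRD header; `NULL` for a bare TIFF).
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nz <- length(pages)
    d <- dim(pages[[1]])
    vol <- array(0L, c(nz, d[1], d[2]))
    for (k in seq_len(nz)) vol[k, , ] <- as.integer(round(pages[[k]] * VOLUME_SCALE))
    spacing <- if (!is.null(meta)) as.numeric(unlist(meta$spacing)) else NULL
  } else if (ext == "nrrd") {
    nr <- read_nrrd(path)
    vol <- nr$vol
    spacing <- nr$spacing %||%
      (if (!is.null(meta)) as.numeric(unlist(meta$spacing)) else NULL)
  } else {
    stop("unsupported volume extension: .", ext)
  }
  list(vol = vol, spacing = spacing)
}

# Minimal NRRD writer: raw little-endian uint16, detached header not used.
# Sizes are listed fastest axis first (our dim 1 = z is fastest in memory).
write_nrrd <- function(v, path, spacing) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# blastomorph volume",
           "type: unsigned short",
           "dimension: 3",
           sprintf("sizes: %d %d %d", dim(v)[1], dim(v)[2], dim(v)[3]),
           sprintf("spacings: %.10g %.10g %.10g",
                   spacing[1], spacing[2], spacing[3]),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.integer(v), con, size = 2L, endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L || line == "") break
    hdr <- c(hdr, line)
  }
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  if (!identical(get_field("encoding"), "raw")) {
    stop("only raw-encoded NRRD is supported")
  }
  sizes <- as.integer(strsplit(get_field("sizes"), " +")[[1]])
  spacing <- if (!is.null(get_field("spacings"))) {
    as.numeric(strsplit(get_field("spacings"), " +")[[1]])
  }
  n <- prod(sizes)
  raw <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                 endian = "little")
  list(vol = array(as.integer(raw), sizes), spacing = spacing)
}

#' Write blastomere records to CSV
#'
#' The first line is a schema comment (`# schema: blastomorph-records-1`)
#' checked on read, guarding the pipeline against column drift.
#'
#' @param records data.frame of blastomere records.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema: ", RECORD_SCHEMA), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read a blastomere record CSV
#'
#' @param path CSV written by [write_records()].
#' @return data.frame of records.
#' @export
read_records <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, paste0("# schema: ", RECORD_SCHEMA))) {
    stop("not a blastomorph record CSV (schema header missing or mismatched)")
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(record_columns, names(df))
  if (length(missing) > 0) {
    stop("record CSV missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Serialise a synthetic config to JSON
#' @param config a [synthetic_config()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$coupling$type != "affine") {
    stop("only affine couplings are JSON-serialisable")
  }
  x <- unclass(config)
  x$coupling <- unclass(x$coupling)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a synthetic config from JSON
#' @param path JSON written by [write_config()].
#' @return a [synthetic_config()].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_config(
    n_cells = x$n_cells, envelope = x$envelope,
    envelope_radius = x$envelope_radius, channel_radius = x$channel_radius,
    slab_fraction = x$slab_fraction, compaction = x$compaction,
    nucleus_radius_fraction = x$nucleus_radius_fraction,
    coupling = coupling_affine(x$coupling$intercept, x$coupling$slope),
    noise_sd = x$noise_sd, perm_polarity = x$perm_polarity,
    apical_perm_gain = x$apical_perm_gain,
    voxel_spacing = x$voxel_spacing, seed = x$seed)
}

#' Write a classified surface mesh as ASCII PLY
#'
#' Vertices are deduplicated; each face carries an integer `domain` tag
#' (0 = exposed, 1 = junctional, 2 = contact).
#'
#' @param domain_cell one element of a `domain_map` (a single cell).
#' @param path output `.ply` path.
#' @return the path, invisibly.
#' @export
write_ply <- function(domain_cell, path) {
  stopifnot(!is.null(domain_cell$tags))
  tri <- soupify(domain_cell)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(tri$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(tri$faces)),
               "property list uchar int vertex_indices",
               "property int domain",
               "end_header"), con)
  utils::write.table(format(tri$vertices, trim = TRUE), con, sep = " ",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, tri$faces - 1L, tri$domain), con, sep = " ",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Deduplicate a triangle soup into vertices + 0-based face indices with a
# per-face domain code.
soupify <- function(domain_cell) {
  tr <- domain_cell$triangles
  if (is.null(tr)) stop("domain cell carries no triangles")
  v <- rbind(tr[, 1:3, drop = FALSE], tr[, 4:6, drop = FALSE],
             tr[, 7:9, drop = FALSE])
  key <- apply(round(v, 6), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  id <- match(key, key[uk])
  n <- nrow(tr)
  faces <- cbind(id[seq_len(n)], id[n + seq_len(n)], id[2 * n + seq_len(n)])
  list(vertices = v[uk, , drop = FALSE], faces = faces,
       domain = as.integer(domain_cell$tags) - 1L)
}
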