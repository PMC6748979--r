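## Volume and table IO.
##
## Volumes travel as multi-page grayscale TIFF (pages = z-planes, axis
## order (x, y, z)); binary volumes are stored as 0/255 8-bit, intensity
## and thickness volumes as 32-bit float rescaled to [0, 1] with the scale
## factor recorded in a JSON sidecar (`<file>.json`) together with the
## voxel spacing, type tag and connectivity, since baseline TIFF tags
## cannot carry them portably.  Feature tables are plain CSV.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stopf("cannot read '%s' as TIFF: %s",
                                              path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stopf("'%s' has %d plane(s); a z-stack needs at least 2",
                               path, length(pages))
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    di <- dim(pages[[i]])
    if (length(di) != 2)
      stopf("plane %d of '%s' is not grayscale (dims [%s])", i, path,
            paste(di, collapse = ", "))
    if (!identical(di, d1))
      stopf("plane %d of '%s' has shape %dx%d, expected %dx%d", i, path,
            di[1], di[2], d1[1], d1[2])
  }
  # page rows are y, columns are x; volume axis order is (x, y, z)
  arr <- array(0, c(d1[2], d1[1], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- t(pages[[i]])
  arr
}

#' Read a z-stack from a multi-page grayscale TIFF
#'
#' @param path TIFF file; a JSON sidecar written by [write_volume()] is
#'   used for spacing and intensity scale when present.
#' @param spacing fallback voxel spacing when no sidecar is found
#'   (default voxel units `c(1, 1, 1)`).
#' @return a [zstack()].
#' @export
read_zstack <- function(path, spacing = c(1, 1, 1)) {
  arr <- read_tiff_pages(path)
  sc <- read_sidecar(path)
  if (!is.null(sc)) {
    spacing <- sc$spacing %||% spacing
    arr <- arr * (sc$scale %||% 1)
  }
  zstack(arr, spacing = spacing, meta = list(path = path))
}

#' Read any volume written by [write_volume()]
#'
#' Uses the sidecar's type tag to reconstruct a [zstack()],
#' [binary_volume()] or [thickness_map()] (thickness maps are returned as
#' the diameters annotating their own foreground).
#'
#' @param path TIFF file.
#' @return a volume object.
#' @export
read_volume <- function(path) {
  sc <- read_sidecar(path)
  type <- sc$type %||% "zstack"
  if (type == "zstack") return(read_zstack(path))
  arr <- read_tiff_pages(path)
  spacing <- sc$spacing %||% c(1, 1, 1)
  if (type == "binary") {
    return(binary_volume(array(arr > 0.5, dim(arr)), spacing = spacing,
                         connectivity = sc$connectivity %||% "26-6"))
  }
  if (type == "thickness") {
    di <- arr * (sc$scale %||% 1)
    src <- binary_volume(array(di > 0, dim(di)), spacing = spacing)
    return(thickness_map(di, src))
  }
  stopf("unknown volume type '%s' in sidecar of '%s'", type, path)
}

#' Write a volume as multi-page TIFF (+ JSON sidecar)
#'
#' Binary volumes are written as 8-bit 0/255; z-stacks and thickness maps
#' as 32-bit float rescaled to `[0, 1]`, the scale going to the sidecar.
#'
#' @param vol a [zstack()], [binary_volume()] or [thickness_map()].
#' @param path output file; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stopf("cannot write '%s': directory '%s' does not exist", path, dirname(path))
  if (inherits(vol, "binary_volume")) {
    pages <- volume_pages(array(as.numeric(vol$occupancy), dim(vol$occupancy)))
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 8L),
                   error = function(e) stopf("cannot write '%s': %s", path,
                                             conditionMessage(e)))
    write_sidecar(path, list(type = "binary", spacing = vol$spacing,
                             connectivity = vol$connectivity))
  } else if (inherits(vol, "zstack") || inherits(vol, "thickness_map")) {
    a <- if (inherits(vol, "zstack")) vol$voxels else vol$diameters
    scale <- max(a)
    if (scale <= 0) scale <- 1
    pages <- volume_pages(a / scale)
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 32L),
                   error = function(e) stopf("cannot write '%s': %s", path,
                                             conditionMessage(e)))
    sp <- if (inherits(vol, "zstack")) vol$spacing else vol$source$spacing
    write_sidecar(path, list(type = if (inherits(vol, "zstack")) "zstack" else "thickness",
                             spacing = sp, scale = scale))
  } else stopf("write_volume: unsupported object of class %s", class(vol)[1])
  invisible(path)
}

volume_pages <- function(arr) {
  lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]))
}

#' Read / write a sample feature table as CSV
#'
#' The CSV has one row per sample and columns `sample_id`, `age`,
#' optionally `group`, plus the 40 canonical feature columns; the schema
#' is validated on read (missing or extra feature columns are an error
#' listing the offending names).
#'
#' @param path CSV file.
#' @return a [sample_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_table(df)
}

#' @rdname read_feature_table
#' @param t a [sample_table()].
#' @export
write_feature_table <- function(t, path) {
  stopifnot(inherits(t, "sample_table"))
  if (!dir.exists(dirname(path)))
    stopf("cannot write '%s': directory '%s' does not exist", path, dirname(path))
  utils::write.csv(as.data.frame(t), path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' JSON (by extension `.json`) or plain-text `key=value` lines; values
#' that parse as numbers become numeric, comma-separated values become
#' vectors.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("cannot read config '%s'", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopf("bad config line: '%s'", ln)
    key <- trimws(kv[1])
    vals <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (anyNA(num)) vals else num
  }
  out
}
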