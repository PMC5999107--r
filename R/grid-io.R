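#' Read a labeled voxel grid from disk
#'
#' Supported formats: MetaImage (`.mhd` text header + `.raw` 8-bit payload,
#' voxel size taken from `ElementSpacing`), multi-page TIFF stacks (one page
#' per k-slice; TIFF carries no spacing, so `voxel_size` must be supplied),
#' and the native serialized container written by [write_grid()] (`.rds`).
#' Stored values outside `{0, 1, 2}` are an error, never remapped.
#'
#' @param path File to read.
#' @param format One of `"auto"`, `"mhd"`, `"tiff"`, `"rds"`.  `"auto"`
#'   dispatches on the file extension.
#' @param voxel_size Voxel edge length in mm; required for TIFF, optional
#'   override elsewhere.
#' @return A [voxel_grid()].
#' @export
#' @examples
#' g <- fixture_grid("digital_ball", shape = c(16, 16, 16), radius = 5)
#' f <- tempfile(fileext = ".mhd")
#' write_grid(g, f)
#' identical(read_grid(f)$labels, g$labels)
read_grid <- function(path, format = c("auto", "mhd", "tiff", "rds"),
                      voxel_size = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  g <- switch(format,
    mhd = read_mhd(path),
    tiff = read_tiff_stack(path, voxel_size),
    rds = readRDS(path)
  )
  if (!inherits(g, "voxel_grid")) stop("file did not contain a voxel grid", call. = FALSE)
  if (!is.null(voxel_size)) g$voxel_size <- voxel_size
  # revalidate (catches out-of-range stored labels and bad metadata)
  voxel_grid(g$labels, g$voxel_size, g$origin)
}

#' Write a labeled voxel grid to disk
#'
#' Labels are stored bit-faithfully.  MetaImage stores the voxel size as
#' `ElementSpacing` and the origin as `Offset`; the native `.rds` container
#' stores the full object; TIFF stores labels only.
#'
#' @inheritParams read_grid
#' @param grid A [voxel_grid()].
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("auto", "mhd", "tiff", "rds")) {
  stopifnot(inherits(grid, "voxel_grid"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    mhd = write_mhd(grid, path),
    tiff = write_tiff_stack(grid, path),
    rds = saveRDS(grid, path)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    mhd = "mhd",
    tif = ,
    tiff = "tiff",
    rds = "rds",
    stop("cannot infer format from extension '.", ext,
         "'; pass `format` explicitly", call. = FALSE)
  )
}

# --- MetaImage -------------------------------------------------------------

write_mhd <- function(grid, path) {
  raw_path <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
  if (identical(raw_path, path)) raw_path <- paste0(path, ".raw")
  d <- dim(grid)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            grid$voxel_size, grid$voxel_size, grid$voxel_size),
    sprintf("Offset = %.10g %.10g %.10g",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    "ElementType = MET_UCHAR",
    sprintf("ElementDataFile = %s", basename(raw_path))
  )
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  # column-major with i fastest matches the MetaImage x-fastest convention
  writeBin(as.raw(grid$labels), con)
}

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  meta <- setNames(vals, keys)
  need <- function(key) {
    if (!key %in% names(meta)) stop("MetaImage header missing ", key, call. = FALSE)
    meta[[key]]
  }
  if (need("ElementType") != "MET_UCHAR") {
    stop("unsupported ElementType: ", meta[["ElementType"]], call. = FALSE)
  }
  d <- as.integer(strsplit(need("DimSize"), "\\s+")[[1L]])
  sp <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1L]])
  org <- if ("Offset" %in% names(meta)) {
    as.numeric(strsplit(meta[["Offset"]], "\\s+")[[1L]])
  } else {
    c(0, 0, 0)
  }
  raw_path <- file.path(dirname(path), need("ElementDataFile"))
  if (!file.exists(raw_path)) stop("raw payload not found: ", raw_path, call. = FALSE)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = prod(d))
  if (length(bytes) != prod(d)) {
    stop("raw payload has ", length(bytes), " bytes, expected ", prod(d), call. = FALSE)
  }
  labels <- array(as.integer(bytes), dim = d)
  voxel_grid(labels, sp, org)
}

# --- TIFF stack ------------------------------------------------------------

write_tiff_stack <- function(grid, path) {
  d <- dim(grid)
  # one page per k-slice; 8-bit samples, stored as label/255
  pages <- lapply(seq_len(d[3]), function(k) grid$labels[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
}

read_tiff_stack <- function(path, voxel_size) {
  if (is.null(voxel_size)) {
    stop("TIFF stores no voxel size; supply `voxel_size`", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate grey-stored-as-RGB
    round(p * 255)
  })
  labels <- array(as.integer(unlist(slices)),
                  dim = c(dim(slices[[1L]]), length(slices)))
  voxel_grid(labels, voxel_size)
}
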