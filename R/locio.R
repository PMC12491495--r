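#' Localization table
#'
#' The pipeline's interchange object: one row per localization with the
#' columns of the common SMLM localization-list dialect. `frame` is
#' 0-based; `x` and `y` are in pixels (origin at the top-left corner,
#' 1 pixel = `pixel_size` nm); `z` is in nm; `lpx`/`lpy` are per-localization
#' precisions in pixels. Metadata records the acquisition geometry.
#'
#' @param locs Data frame with at least `frame`, `x`, `y`. Missing optional
#'   columns (`z`, `photons`) are filled with 0; unknown extra columns are
#'   kept untouched.
#' @param n_frames,width,height,pixel_size Acquisition metadata: frame
#'   count, FOV width/height in pixels, pixel size in nm.
#' @param exposure Seconds per frame (optional, NA if unknown).
#' @param round_label Free-form label of the imaging round (optional).
#' @param extra Named list of additional metadata to carry along.
#'
#' @return An object of class `loc_table`: a list with elements `locs`
#'   (tibble) and `meta` (named list).
#' @export
loc_table <- function(locs, n_frames, width, height, pixel_size,
                      exposure = NA_real_, round_label = NA_character_,
                      extra = list()) {
  locs <- tibble::as_tibble(locs)
  if (!"z" %in% names(locs)) locs$z <- rep(0, nrow(locs))
  if (!"photons" %in% names(locs)) locs$photons <- rep(0, nrow(locs))
  meta <- c(list(n_frames = as.integer(n_frames),
                 width = as.integer(width),
                 height = as.integer(height),
                 pixel_size = as.numeric(pixel_size),
                 exposure = as.numeric(exposure),
                 round_label = round_label),
            extra)
  out <- list(locs = locs, meta = meta)
  class(out) <- "loc_table"
  validate_loc_table(out)
  out
}

#' Validate a localization table
#'
#' Checks the mandatory columns and the record/metadata invariants:
#' frames in `[0, n_frames)`, coordinates inside the field of view,
#' positive pixel size.
#'
#' @param table A `loc_table`.
#' @return The table, invisibly; errors describe the first violation found.
#' @export
validate_loc_table <- function(table) {
  if (!inherits(table, "loc_table")) {
    stop("expected a `loc_table` object", call. = FALSE)
  }
  locs <- table$locs; meta <- table$meta
  missing_cols <- setdiff(c("frame", "x", "y"), names(locs))
  if (length(missing_cols) > 0) {
    stop("loc_table: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (nm in c("n_frames", "width", "height", "pixel_size")) {
    if (is.null(meta[[nm]]) || is.na(meta[[nm]])) {
      stop("loc_table: metadata field `", nm, "` is required", call. = FALSE)
    }
  }
  if (meta$pixel_size <= 0) {
    stop("loc_table: `pixel_size` must be positive", call. = FALSE)
  }
  if (nrow(locs) > 0) {
    if (any(locs$frame < 0) || any(locs$frame >= meta$n_frames)) {
      stop("loc_table: frame indices must lie in [0, n_frames); found ",
           "range [", min(locs$frame), ", ", max(locs$frame), "] with ",
           "n_frames = ", meta$n_frames, call. = FALSE)
    }
    if (any(!is.finite(locs$x)) || any(!is.finite(locs$y))) {
      stop("loc_table: non-finite coordinates", call. = FALSE)
    }
  }
  invisible(table)
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf(
    "<loc_table> %d localizations, %d frames, %dx%d px @ %g nm/px%s\n",
    nrow(x$locs), x$meta$n_frames, x$meta$width, x$meta$height,
    x$meta$pixel_size,
    if (!is.na(x$meta$round_label)) paste0(" [", x$meta$round_label, "]")
    else ""))
  invisible(x)
}

loc_columns <- c("frame", "x", "y", "z", "photons", "lpx", "lpy")

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".yaml")
}

meta_to_sidecar <- function(meta) {
  out <- list(Width = meta$width, Height = meta$height,
              Frames = meta$n_frames, Pixelsize = meta$pixel_size)
  if (!is.na(meta$exposure)) out$Exposure <- meta$exposure
  if (!is.null(meta$round_label) && !is.na(meta$round_label)) {
    out$Round <- meta$round_label
  }
  out
}

sidecar_to_meta <- function(sc) {
  list(n_frames = sc$Frames, width = sc$Width, height = sc$Height,
       pixel_size = sc$Pixelsize,
       exposure = if (is.null(sc$Exposure)) NA_real_ else sc$Exposure,
       round_label = if (is.null(sc$Round)) NA_character_ else sc$Round)
}

#' Write a localization table
#'
#' Writes the records plus a YAML metadata sidecar (`<stem>.yaml` with keys
#' `Width`, `Height`, `Frames`, `Pixelsize`). HDF5 output stores the
#' records as a compound dataset named `"locs"` (the common localization
#' list dialect, readable by standard SMLM tools); CSV output uses a
#' comma-separated header-row file with identical column names. Records
#' are sorted by frame before writing. Coordinates are stored as 64-bit
#' floats in both formats, so round-trips are lossless.
#'
#' @param table A `loc_table`.
#' @param path Output file path.
#' @param format `"hdf5"` or `"csv"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_locs <- function(table, path, format = NULL) {
  validate_loc_table(table)
  if (is.null(format)) {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
              else "csv"
  }
  format <- match.arg(format, c("hdf5", "csv"))
  locs <- table$locs[order(table$locs$frame), , drop = FALSE]
  keep <- c(intersect(loc_columns, names(locs)),
            setdiff(names(locs), loc_columns))
  locs <- locs[, keep, drop = FALSE]
  if (format == "hdf5") {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("write_locs: HDF5 output requires the `rhdf5` package",
           call. = FALSE)
    }
    if (file.exists(path)) file.remove(path)
    ok <- rhdf5::h5createFile(path)
    if (!isTRUE(ok)) stop("write_locs: cannot create ", path, call. = FALSE)
    if (nrow(locs) > 0) {
      rhdf5::h5write(as.data.frame(locs), path, "locs")
    } else {
      # HDF5 compound datasets cannot be zero-length; record the schema so
      # the reader can reconstruct an empty table.
      rhdf5::h5write(names(locs), path, "locs_schema")
    }
    rhdf5::h5closeAll()
  } else {
    utils::write.csv(as.data.frame(locs), path, row.names = FALSE)
  }
  yaml::write_yaml(meta_to_sidecar(table$meta), sidecar_path(path))
  invisible(path)
}

#' Read a localization table
#'
#' Reads the HDF5 localization-list dialect (compound dataset `"locs"`
#' plus YAML sidecar) or a header-row CSV. Missing optional columns are
#' filled with defaults (`z = 0`, `photons = 0`); unknown extra columns
#' are kept. Metadata comes from the YAML sidecar when present and is
#' otherwise inferred from the records (with a warning).
#'
#' @param path Input file path.
#' @param format `"hdf5"` or `"csv"` (default guessed from the extension).
#' @return A validated `loc_table`.
#' @export
read_locs <- function(path, format = NULL) {
  if (!file.exists(path)) stop("read_locs: no such file: ", path,
                               call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
              else "csv"
  }
  format <- match.arg(format, c("hdf5", "csv"))
  if (format == "hdf5") {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("read_locs: HDF5 input requires the `rhdf5` package",
           call. = FALSE)
    }
    contents <- rhdf5::h5ls(path)
    if ("locs" %in% contents$name) {
      locs <- rhdf5::h5read(path, "locs")
      rhdf5::h5closeAll()
      # rhdf5 returns 1-d arrays; strip dims so columns are plain vectors.
      locs <- as.data.frame(lapply(locs, as.vector),
                            stringsAsFactors = FALSE)
    } else if ("locs_schema" %in% contents$name) {
      cols <- as.vector(rhdf5::h5read(path, "locs_schema"))
      rhdf5::h5closeAll()
      locs <- as.data.frame(stats::setNames(
        rep(list(numeric(0)), length(cols)), cols))
      locs$frame <- integer(0)
    } else {
      rhdf5::h5closeAll()
      stop("read_locs: ", path, " has no `locs` dataset ",
           "(not a localization-list file?)", call. = FALSE)
    }
  } else {
    locs <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(c("frame", "x", "y"), names(locs))
  if (length(missing_cols) > 0) {
    stop("read_locs: ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- sidecar_to_meta(yaml::read_yaml(sp))
  } else {
    warning("read_locs: no metadata sidecar found for ", path,
            "; inferring geometry from the records")
    meta <- list(
      n_frames = if (nrow(locs)) max(locs$frame) + 1L else 1L,
      width = if (nrow(locs)) as.integer(ceiling(max(locs$x))) else 1L,
      height = if (nrow(locs)) as.integer(ceiling(max(locs$y))) else 1L,
      pixel_size = 130, exposure = NA_real_, round_label = NA_character_)
  }
  loc_table(locs, n_frames = meta$n_frames, width = meta$width,
            height = meta$height, pixel_size = meta$pixel_size,
            exposure = meta$exposure, round_label = meta$round_label)
}
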