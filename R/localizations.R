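#' @name localizations
#' @title Localization tables
#'
#' @description
#' All functions in lapfc operate on a *localization table*: a tibble with one
#' row per fitted emitter observation and the columns
#'
#' \describe{
#'   \item{id}{integer record index, unique within the table}
#'   \item{frame}{integer camera frame, 1-based}
#'   \item{x, y}{fitted position, pixels}
#'   \item{sigma_x, sigma_y}{per-axis localization standard error, pixels}
#'   \item{photons}{expected photon count for the observation}
#'   \item{background}{background level, photons/pixel/frame}
#'   \item{emitter_id}{ground-truth emitter index, or -1 when unknown}
#' }
#'
#' Positions are continuous pixel coordinates with the origin at the ROI
#' corner.  The same schema is used on disk (native CSV, columns in the order
#' above).
NULL

loc_columns <- c("id", "frame", "x", "y", "sigma_x", "sigma_y",
                 "photons", "background", "emitter_id")

empty_localizations <- function() {
  tibble::tibble(
    id = integer(), frame = integer(), x = numeric(), y = numeric(),
    sigma_x = numeric(), sigma_y = numeric(), photons = numeric(),
    background = numeric(), emitter_id = integer()
  )
}

#' Coerce and validate a localization table
#'
#' Checks the schema and the per-record invariants (positive precisions,
#' frames >= 1, finite positions, unique ids) and returns the table as a
#' tibble with columns in canonical order.
#'
#' @param locs A data frame carrying at least the columns listed in
#'   [localizations]; `id`, `background` and `emitter_id` are filled with
#'   defaults (row number, 0, -1) when absent.
#' @return A validated localization tibble.
#' @export
as_localizations <- function(locs) {
  locs <- tibble::as_tibble(locs)
  if (!"id" %in% names(locs)) locs$id <- seq_len(nrow(locs))
  if (!"background" %in% names(locs)) locs$background <- 0
  if (!"emitter_id" %in% names(locs)) locs$emitter_id <- -1L
  missing <- setdiff(loc_columns, names(locs))
  if (length(missing) > 0) {
    abort(paste0("localization table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "lapfc_schema_error")
  }
  locs <- locs[loc_columns]
  locs$id <- as.integer(locs$id)
  locs$frame <- as.integer(locs$frame)
  locs$emitter_id <- as.integer(locs$emitter_id)
  validate_localizations(locs)
  locs
}

validate_localizations <- function(locs) {
  if (nrow(locs) == 0) return(invisible(locs))
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      abort(sprintf("invalid localization(s): %s (row%s %s)", what,
                    if (length(rows) > 1) "s" else "",
                    paste(head(rows, 10), collapse = ", ")),
            class = "lapfc_validation_error")
    }
  }
  bad(is.na(locs$frame) | locs$frame < 1L, "frame must be >= 1")
  bad(!is.finite(locs$x) | !is.finite(locs$y), "x, y must be finite")
  bad(!is.finite(locs$sigma_x) | locs$sigma_x <= 0, "sigma_x must be > 0")
  bad(!is.finite(locs$sigma_y) | locs$sigma_y <= 0, "sigma_y must be > 0")
  bad(is.na(locs$photons) | locs$photons < 0, "photons must be >= 0")
  if (anyDuplicated(locs$id) > 0) {
    abort("localization ids must be unique", class = "lapfc_validation_error")
  }
  invisible(locs)
}

#' Read a localization table from CSV
#'
#' @param path Path to a CSV file.
#' @param dialect `"native"` for the lapfc schema (see [localizations]), or
#'   `"thunderstorm"` for ThunderSTORM-style export columns (`"frame"`,
#'   `"x [nm]"`, `"y [nm]"`, `"sigma [nm]"`, `"intensity [photon]"`), which
#'   are converted from nanometers to pixels.
#' @param pixel_size_nm Camera pixel size in nm; required for the
#'   thunderstorm dialect, ignored otherwise.
#' @return A validated localization tibble.
#' @export
read_localizations <- function(path, dialect = c("native", "thunderstorm"),
                               pixel_size_nm = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("localization file not found: ", path),
          class = "lapfc_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "native") {
    return(as_localizations(raw))
  }
  if (is.null(pixel_size_nm)) {
    abort("thunderstorm dialect requires `pixel_size_nm` to convert nm to px",
          class = "lapfc_schema_error")
  }
  ts_cols <- c("frame", "x [nm]", "y [nm]", "sigma [nm]", "intensity [photon]")
  missing <- setdiff(ts_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("thunderstorm file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "lapfc_schema_error")
  }
  sigma_px <- raw[["sigma [nm]"]] / pixel_size_nm
  as_localizations(tibble::tibble(
    frame = raw[["frame"]],
    x = raw[["x [nm]"]] / pixel_size_nm,
    y = raw[["y [nm]"]] / pixel_size_nm,
    sigma_x = sigma_px,
    sigma_y = sigma_px,
    photons = raw[["intensity [photon]"]]
  ))
}

#' Write a localization table to CSV
#'
#' The round trip `read_localizations(write_localizations(locs))` reproduces
#' every field at full double precision.
#'
#' @param locs A localization tibble.
#' @param path Output path.
#' @return `locs`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  locs <- as_localizations(locs)
  readr::write_csv(locs, path, progress = FALSE)
  invisible(locs)
}

#' Render a Gaussian reconstruction image
#'
#' Each localization contributes a pixel-integrated 2-D Gaussian of its own
#' precision, normalized to unit integral, so the rendered grid sums to the
#' number of localizations (up to truncation at the ROI edge).
#'
#' @param locs A localization tibble.
#' @param roi ROI rectangle `c(x_min, x_max, y_min, y_max)` in pixels;
#'   defaults to the bounding box of the data padded by 3 input pixels.
#' @param zoom Output pixels per input pixel (>= 1).
#' @return A numeric matrix (rows = y, columns = x) of intensities.
#' @export
render_gaussian_image <- function(locs, roi = NULL, zoom = 10) {
  stopifnot(zoom >= 1)
  locs <- as_localizations(locs)
  if (is.null(roi)) {
    if (nrow(locs) == 0) roi <- c(0, 1, 0, 1)
    else roi <- c(floor(min(locs$x)) - 3, ceiling(max(locs$x)) + 3,
                  floor(min(locs$y)) - 3, ceiling(max(locs$y)) + 3)
  }
  nx <- max(1L, as.integer(ceiling((roi[2] - roi[1]) * zoom)))
  ny <- max(1L, as.integer(ceiling((roi[4] - roi[3]) * zoom)))
  img <- matrix(0, nrow = ny, ncol = nx)
  if (nrow(locs) == 0) return(img)
  # output pixel edges in input-pixel units
  xe <- roi[1] + seq(0, nx) / zoom
  ye <- roi[3] + seq(0, ny) / zoom
  for (i in seq_len(nrow(locs))) {
    # restrict to a +/- 5 sigma window for speed
    sx <- locs$sigma_x[i]; sy <- locs$sigma_y[i]
    jx <- which(xe[-1] >= locs$x[i] - 5 * sx & xe[-(nx + 1)] <= locs$x[i] + 5 * sx)
    jy <- which(ye[-1] >= locs$y[i] - 5 * sy & ye[-(ny + 1)] <= locs$y[i] + 5 * sy)
    if (length(jx) == 0 || length(jy) == 0) next
    px <- diff(pnorm(xe[c(jx, jx[length(jx)] + 1)], locs$x[i], sx))
    py <- diff(pnorm(ye[c(jy, jy[length(jy)] + 1)], locs$y[i], sy))
    img[jy, jx] <- img[jy, jx] + outer(py, px)
  }
  img
}
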