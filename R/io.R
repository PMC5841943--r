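# Reading user cell contours and writing metrics tables.

#' Read cell contours from CSV or JSON
#'
#' Two plain-text layouts are supported:
#' \itemize{
#'   \item CSV with columns `x`, `y` (optionally `z` and `cell_id`), one row
#'     per contour point, points of each cell contiguous and in order;
#'   \item JSON of the form
#'     `{"cells": [{"id": ..., "points": [[x, y(, z)], ...]}, ...]}`.
#' }
#' 3D contours (a `z` column) can be flattened per cell with
#' [pca_project()] before computing metrics.
#'
#' @param path File path; format inferred from the `.csv` / `.json`
#'   extension.
#' @return A tibble with columns `cell_id`, `x`, `y` and, if present, `z`.
#' @export
read_contours <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(doc$cells)) stop("JSON contour file needs a `cells` array", call. = FALSE)
    cells <- doc$cells
    out <- purrr::map2_dfr(cells$id, cells$points, function(id, pts) {
      m <- matrix(as.double(pts), ncol = ncol(pts))
      d <- tibble::tibble(cell_id = id, x = m[, 1], y = m[, 2])
      if (ncol(m) >= 3) d$z <- m[, 3]
      d
    })
    return(out)
  }
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x", "y") %in% names(d))) {
    stop("contour CSV needs `x` and `y` columns", call. = FALSE)
  }
  if (!"cell_id" %in% names(d)) d$cell_id <- 1L
  dplyr::relocate(d, "cell_id")
}

#' Write a metrics table as CSV
#'
#' Deterministic full-precision CSV (identical runs give byte-identical
#' files), with the canonical column order.
#'
#' @param records A metrics tibble (from [measure_tissue()],
#'   [contour_metrics()] or `tidy()` on a run).
#' @param path Output file.
#' @return `records`, invisibly.
#' @export
write_metrics_csv <- function(records, path) {
  first <- intersect(c("step", "cell_id", "interior", "area", "perimeter",
                       "lobeyness", "circularity", "hull_solidity",
                       "lec_radius", "lec_area", "aspect_ratio",
                       "stress_proxy", "active_springs"), names(records))
  out <- dplyr::relocate(records, dplyr::all_of(first))
  readr::write_csv(out, path)
  invisible(records)
}
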