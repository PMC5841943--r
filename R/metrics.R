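# Contour-based shape statistics for pavement cells. All scalar metrics are
# invariant under rigid motion and uniform scaling; lobeyness is the
# perimeter-based convexity deviation used throughout the package.

#' Lobeyness of a cell contour
#'
#' Perimeter of the cell divided by the perimeter of its convex hull. Equals 1
#' for convex shapes and grows with contour complexity; unlike circularity it
#' is insensitive to elongation, which makes it the preferred readout for how
#' lobed a pavement cell is.
#'
#' @inheritParams normalize_contour
#' @return Dimensionless scalar `>= 1`.
#' @examples
#' plus <- data.frame(x = c(1, 2, 2, 3, 3, 2, 2, 1, 1, 0, 0, 1),
#'                    y = c(0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 1, 1))
#' lobeyness(plus) # 12 / (4 + 4 * sqrt(2))
#' @export
lobeyness <- function(points) {
  m <- .ctr(points)
  .perim(m) / .perim(.ctr(convex_hull(m)))
}

#' Circularity of a cell contour
#'
#' Perimeter divided by the square root of area; minimal (`2 * sqrt(pi)`) for
#' a disc. Both elongated and lobed cells score high, so circularity cannot
#' separate those two shape families -- it is provided for comparison with
#' [lobeyness()], which can.
#'
#' @inheritParams normalize_contour
#' @return Dimensionless scalar `>= 2 * sqrt(pi)` (up to discretization).
#' @export
circularity <- function(points) {
  m <- .ctr(points)
  a <- abs(.signed_area(m))
  if (a <= 0) stop("zero-area contour", call. = FALSE)
  .perim(m) / sqrt(a)
}

#' Convex-hull solidity of a cell contour
#'
#' Area of the convex hull divided by the area of the cell, `>= 1`. Thin bent
#' shapes (worms, boomerangs) score high even without lobes, which is why the
#' perimeter ratio ([lobeyness()]) is the primary lobedness measure.
#'
#' @inheritParams normalize_contour
#' @return Dimensionless scalar `>= 1`.
#' @export
hull_solidity <- function(points) {
  m <- .ctr(points)
  a <- abs(.signed_area(m))
  if (a <= 0) stop("zero-area contour", call. = FALSE)
  polygon_area(convex_hull(m)) / a
}

#' Growth anisotropy between two tracked contours
#'
#' Fits the least-squares linear map taking the centered points of the earlier
#' contour to the centered points of the later one (points must correspond row
#' by row) and returns the ratio of its singular values: the expansion rate in
#' the direction of maximal growth divided by the rate in the direction of
#' minimal growth. 1 means isotropic expansion.
#'
#' @param before,after Corresponding contours (data frames with `x`, `y` or
#'   two-column matrices) with equal row counts; row i of `before` is the same
#'   material point as row i of `after`.
#' @return Dimensionless scalar `>= 1`.
#' @examples
#' sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' stretched <- data.frame(x = sq$x * 1.2, y = sq$y)
#' growth_anisotropy(sq, stretched) # 1.2
#' @export
growth_anisotropy <- function(before, after) {
  m0 <- .xy(before); m1 <- .xy(after)
  if (nrow(m0) != nrow(m1)) {
    stop("`before` and `after` must have the same number of points", call. = FALSE)
  }
  if (nrow(m0) < 3) stop("need at least 3 corresponded points", call. = FALSE)
  x0 <- scale(m0, scale = FALSE); x1 <- scale(m1, scale = FALSE)
  g <- crossprod(x0)
  if (abs(det(g)) < 1e-300 * max(1, sum(diag(g)))^2) {
    stop("rank-deficient correspondence set", call. = FALSE)
  }
  a <- crossprod(x1, x0) %*% solve(g)
  s <- svd(a)$d
  if (s[2] < 1e-300) stop("degenerate deformation (zero minimal growth)", call. = FALSE)
  s[1] / s[2]
}

#' Thin-wall hoop-stress proxy from LEC radius
#'
#' Pressure-induced wall stress estimated as the hoop stress of a thin-walled
#' cylinder, `P * r / t`, evaluated with the largest-empty-circle radius in
#' place of the cylinder radius. For long thin cells the LEC radius is half
#' the cell diameter, for which this closed form is the classical predictor;
#' for lobed cells it extends the idea that the large open area of the cell
#' sets the stress scale. A documented proxy, not a finite-element result.
#'
#' @param lec_radius LEC radius (micrometres).
#' @param pressure Turgor pressure (MPa); 0.5 MPa = 5 bar.
#' @param thickness Wall thickness (micrometres).
#' @return Stress in MPa.
#' @examples
#' stress_proxy(10, pressure = 0.5, thickness = 1) # 5 MPa
#' @export
stress_proxy <- function(lec_radius, pressure = 0.5, thickness = 1) {
  stopifnot(all(lec_radius >= 0), pressure > 0, thickness > 0)
  pressure * lec_radius / thickness
}

#' Aspect ratio of a contour
#'
#' Square root of the ratio of the eigenvalues of the contour-point covariance
#' matrix: 1 for isotropic point clouds, larger for elongated cells.
#'
#' @inheritParams normalize_contour
#' @return Dimensionless scalar `>= 1`.
#' @export
aspect_ratio <- function(points) {
  m <- .ctr(points)
  ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-300) return(Inf)
  sqrt(ev[1] / ev[2])
}

#' Full per-cell shape metrics
#'
#' Computes the package's standard metric set for one or many cell contours.
#' With a `cell_id` column (and optionally `step`) in `data`, metrics are
#' computed per group, so a long table of contour points for a whole tissue
#' tidies into one row per cell.
#'
#' @param data Contour points: data frame with `x`, `y` and optional `cell_id`
#'   and `step` columns.
#' @param lec Compute the largest empty circle (the most expensive metric)?
#' @param spacing Contour resampling interval passed to
#'   [largest_empty_circle()]; `NULL` for the per-cell default.
#' @param pressure,thickness Passed to [stress_proxy()]; set `pressure = NA`
#'   to skip the stress column.
#' @return A tibble with one row per cell: `area`, `perimeter`, `lobeyness`,
#'   `circularity`, `hull_solidity`, `lec_radius`, `lec_area`, `aspect_ratio`
#'   and `stress_proxy` (NA where not computed), preceded by any grouping
#'   columns.
#' @export
contour_metrics <- function(data, lec = TRUE, spacing = NULL,
                            pressure = 0.5, thickness = 1) {
  stopifnot(is.data.frame(data))
  keys <- intersect(c("step", "time", "cell_id"), names(data))
  one <- function(df) {
    m <- .ctr(df)
    lr <- NA_real_
    if (lec) lr <- largest_empty_circle(m, spacing = spacing)$radius
    tibble::tibble(
      area = polygon_area(m),
      perimeter = .perim(m),
      lobeyness = lobeyness(m),
      circularity = circularity(m),
      hull_solidity = hull_solidity(m),
      lec_radius = lr,
      lec_area = pi * lr^2,
      aspect_ratio = aspect_ratio(m),
      stress_proxy = if (is.na(pressure) || is.na(lr)) NA_real_ else
        stress_proxy(lr, pressure, thickness)
    )
  }
  if (length(keys) == 0) return(one(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Mean LEC area versus mean cell area over the largest cells
#'
#' For each time group, restricts to the largest `top_fraction` of cells by
#' area (excluding the small cells of the stomatal lineage is the motivation
#' for the default 20 percent) and reports mean cell area and mean LEC area,
#' together with the perfectly-circular reference where LEC area equals cell
#' area. Cells below the reference keep their open area -- and hence the
#' stress proxy -- small relative to their size.
#'
#' @param records A metrics table with columns `area` and `lec_area` (or
#'   `lec_radius`), plus a grouping column `step` or `time` if present.
#' @param top_fraction Fraction of largest cells retained per group, in
#'   `(0, 1]`. Default 0.2.
#' @return A tibble with one row per group: `n_cells`, `mean_cell_area`,
#'   `mean_lec_area` and `circular_reference` (equal to `mean_cell_area`).
#' @export
lec_vs_area_summary <- function(records, top_fraction = 0.2) {
  stopifnot(is.data.frame(records), top_fraction > 0, top_fraction <= 1)
  if (!"lec_area" %in% names(records)) {
    if (!"lec_radius" %in% names(records)) {
      stop("records need a `lec_area` or `lec_radius` column", call. = FALSE)
    }
    records$lec_area <- pi * records$lec_radius^2
  }
  if (!"area" %in% names(records)) stop("records need an `area` column", call. = FALSE)
  keys <- intersect(c("step", "time"), names(records))
  grouped <- records |>
    dplyr::filter(!is.na(.data$area), !is.na(.data$lec_area)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)))
  if (any(dplyr::group_size(grouped) == 0) || nrow(records) == 0) {
    stop("empty group in records", call. = FALSE)
  }
  grouped |>
    dplyr::group_modify(function(df, key) {
      k <- max(1L, ceiling(top_fraction * nrow(df)))
      top <- df |> dplyr::slice_max(.data$area, n = k, with_ties = FALSE)
      tibble::tibble(
        n_cells = nrow(top),
        mean_cell_area = mean(top$area),
        mean_lec_area = mean(top$lec_area),
        circular_reference = mean(top$area)
      )
    }) |>
    dplyr::ungroup()
}
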