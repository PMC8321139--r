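#' Sector grids for lattice retinal thickness data
#'
#' The ETDRS grid partitions the macula into nine subfields: the central
#' subfield (CS), four inner-ring sectors (superior/temporal/inferior/nasal
#' inner: SI, TI, II, NI) and four outer-ring sectors (SO, TO, IO, NO).
#' Spatial correlation kernels act on Euclidean distances between sector
#' centroids, so each grid carries centroid coordinates (in millimetres),
#' the pairwise distance matrix and a canonical sector ordering used to
#' define the lag of the autoregressive kernel.
#'
#' Centroids are placed at the mid-radius of each annulus: with the ETDRS
#' ring radii of 0.5, 1.5 and 3.0 mm the inner-ring centroids sit at
#' (0.5 + 1.5)/2 = 1.0 mm and the outer-ring centroids at
#' (1.5 + 3.0)/2 = 2.25 mm from the foveal centre; CS sits at the origin.
#' Superior is at 90 degrees and inferior at 270 degrees; for a right eye
#' nasal is at 0 degrees and temporal at 180 degrees, mirrored for a left
#' eye. Distances are reflection-invariant, so both lateralities share the
#' same distance matrix; laterality matters only when mapping sectors to
#' anatomical positions.
#'
#' @param laterality `"right"` or `"left"`.
#' @param inner_radius_mm Centroid radius of the inner ring (mm).
#' @param outer_radius_mm Centroid radius of the outer ring (mm); must
#'   exceed `inner_radius_mm`.
#' @param lag_order Character vector: permutation of the nine sector ids
#'   giving the ordering under which the autoregressive kernel measures
#'   lag. Default is ring-then-angle: CS first, then the inner ring, then
#'   the outer ring.
#'
#' @return An object of class `sector_grid`: a list with elements
#'   `sector_ids`, `centroids` (9 x 2 matrix, mm), `distance_matrix`
#'   (9 x 9, mm), `lag_order` and `laterality`.
#' @examples
#' g <- etdrs_grid()
#' g$distance_matrix["CS", "SI"]   # 1 mm
#' sector_lag(g, "CS", "NI")       # 2
#' @export
etdrs_grid <- function(laterality = c("right", "left"),
                       inner_radius_mm = 1.0,
                       outer_radius_mm = 2.25,
                       lag_order = c("CS", "SI", "NI", "II", "TI",
                                     "SO", "NO", "IO", "TO")) {
  laterality <- match.arg(laterality)
  if (!is.numeric(inner_radius_mm) || !is.numeric(outer_radius_mm) ||
      inner_radius_mm <= 0 || outer_radius_mm <= inner_radius_mm)
    stop("radii must satisfy 0 < inner_radius_mm < outer_radius_mm")
  ids <- c("CS", "SI", "TI", "II", "NI", "SO", "TO", "IO", "NO")
  if (!setequal(lag_order, ids) || anyDuplicated(lag_order))
    stop("'lag_order' must be a permutation of the nine sector ids")

  # angles: superior 90, inferior 270; nasal 0 for right eye, 180 for left
  nasal <- if (laterality == "right") 0 else 180
  temporal <- (nasal + 180) %% 360
  ang <- c(SI = 90, TI = temporal, II = 270, NI = nasal,
           SO = 90, TO = temporal, IO = 270, NO = nasal)
  rad <- c(SI = inner_radius_mm, TI = inner_radius_mm,
           II = inner_radius_mm, NI = inner_radius_mm,
           SO = outer_radius_mm, TO = outer_radius_mm,
           IO = outer_radius_mm, NO = outer_radius_mm)
  cent <- rbind(CS = c(0, 0),
                t(vapply(names(ang), function(s) {
                  a <- ang[[s]] * pi / 180
                  rad[[s]] * c(cos(a), sin(a))
                }, numeric(2))))
  cent <- cent[ids, , drop = FALSE]
  colnames(cent) <- c("x_mm", "y_mm")
  dm <- as.matrix(stats::dist(cent))
  dimnames(dm) <- list(ids, ids)
  structure(list(sector_ids = ids, centroids = cent, distance_matrix = dm,
                 lag_order = lag_order, laterality = laterality),
            class = "sector_grid")
}

#' Build a sector grid from arbitrary centroid coordinates
#'
#' Supports lattices other than the ETDRS grid (for instance other imaging
#' grids). Sector ids are taken in the given order, which also becomes the
#' default lag ordering.
#'
#' @param sector_ids Character vector of unique sector labels.
#' @param x_mm,y_mm Numeric centroid coordinates in millimetres.
#' @param lag_order Optional permutation of `sector_ids`.
#' @param laterality Label stored on the grid (`"right"` by default).
#' @return A `sector_grid`.
#' @export
sector_grid <- function(sector_ids, x_mm, y_mm, lag_order = sector_ids,
                        laterality = "right") {
  sector_ids <- as.character(sector_ids)
  if (anyDuplicated(sector_ids)) stop("duplicate sector ids")
  if (length(x_mm) != length(sector_ids) || length(y_mm) != length(sector_ids))
    stop("coordinate lengths must match 'sector_ids'")
  if (!setequal(lag_order, sector_ids) || anyDuplicated(lag_order))
    stop("'lag_order' must be a permutation of 'sector_ids'")
  cent <- cbind(x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm))
  rownames(cent) <- sector_ids
  dm <- as.matrix(stats::dist(cent))
  dimnames(dm) <- list(sector_ids, sector_ids)
  structure(list(sector_ids = sector_ids, centroids = cent,
                 distance_matrix = dm, lag_order = as.character(lag_order),
                 laterality = laterality),
            class = "sector_grid")
}

#' @export
print.sector_grid <- function(x, ...) {
  cat("Sector grid (", x$laterality, " eye), ", length(x$sector_ids),
      " sectors: ", paste(x$sector_ids, collapse = " "), "\n", sep = "")
  cat("Max pairwise centroid distance:",
      format(max(x$distance_matrix), digits = 4), "mm\n")
  invisible(x)
}

#' Lag between two sectors under the grid's autoregressive ordering
#'
#' @param grid A `sector_grid`.
#' @param sector_a,sector_b Sector ids present in the grid.
#' @return Nonnegative integer `|position(a) - position(b)|` under
#'   `grid$lag_order`; zero iff the sectors coincide.
#' @export
sector_lag <- function(grid, sector_a, sector_b) {
  stopifnot(inherits(grid, "sector_grid"))
  pa <- match(sector_a, grid$lag_order)
  pb <- match(sector_b, grid$lag_order)
  if (anyNA(pa) || anyNA(pb)) stop("sector not in grid")
  abs(pa - pb)
}

#' Full lag matrix of a grid, in `sector_ids` order
#' @param grid A `sector_grid`.
#' @return Integer matrix of pairwise lags.
#' @export
lag_matrix <- function(grid) {
  pos <- match(grid$sector_ids, grid$lag_order)
  m <- abs(outer(pos, pos, "-"))
  dimnames(m) <- list(grid$sector_ids, grid$sector_ids)
  m
}

#' Read / write a sector grid as CSV
#'
#' The CSV has columns `sector_id`, `x_mm`, `y_mm` (ordered; the row order
#' defines the default lag ordering).
#'
#' @param grid A `sector_grid`.
#' @param path File path.
#' @return `read_sector_grid` returns a `sector_grid`;
#'   `write_sector_grid` returns `path` invisibly.
#' @export
write_sector_grid <- function(grid, path) {
  stopifnot(inherits(grid, "sector_grid"))
  df <- data.frame(sector_id = grid$sector_ids,
                   x_mm = grid$centroids[, "x_mm"],
                   y_mm = grid$centroids[, "y_mm"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sector_grid
#' @export
read_sector_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sector_id", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("grid CSV must have columns: ", paste(need, collapse = ", "))
  sector_grid(df$sector_id, df$x_mm, df$y_mm)
}
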