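# Screen geometry, left/middle/right region assignment, hexagonal binning
# and the per-cell count table that feeds the Poisson models.

#' Screen geometry and region boundaries
#'
#' Describes the text display: pixel dimensions and the two x-coordinates
#' splitting the width into left / middle / right regions. The defaults match
#' a 1024 x 768 display split into equal thirds; the boundaries are
#' configurable because a thirds split of the screen and a split of the text
#' extent differ for texts with a ragged right margin.
#'
#' @param width_px,height_px Screen size in pixels.
#' @param region_bounds Two increasing x-coordinates strictly inside
#'   `(0, width_px)`. Defaults to thirds of the width.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1024, height_px = 768,
                            region_bounds = c(width_px / 3,
                                              2 * width_px / 3)) {
  stopifnot(width_px > 0, height_px > 0, length(region_bounds) == 2L)
  if (!(0 < region_bounds[1] && region_bounds[1] < region_bounds[2] &&
        region_bounds[2] < width_px)) {
    stop("region bounds must satisfy 0 < bound1 < bound2 < width")
  }
  structure(list(width_px = width_px, height_px = height_px,
                 region_bounds = as.numeric(region_bounds)),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat("screen ", x$width_px, " x ", x$height_px, " px; region bounds at x = ",
      paste(round(x$region_bounds, 1), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Position of a binocular fixation
#'
#' A binocular fixation's screen position is the right eye's mean coordinates
#' during the fixation (the choice of eye is a convention without analytic
#' consequence for the spatial summaries).
#'
#' @param pairs A binocular-pair data frame from [pair_fixations()].
#' @return A data frame with columns `x_px`, `y_px`.
#' @export
pair_position <- function(pairs) {
  data.frame(x_px = pairs$right_x_px, y_px = pairs$right_y_px)
}

#' Assign fixations to left / middle / right screen regions
#'
#' Regions partition the horizontal axis only: `left` is `x < bound1`,
#' `middle` is `bound1 <= x < bound2`, `right` is `x >= bound2`.
#'
#' @param x_px Horizontal positions in pixels; must lie in
#'   `[0, width_px]`.
#' @param geometry A [screen_geometry()].
#' @return A factor with levels `left`, `middle`, `right`.
#' @export
#' @examples
#' assign_region(c(100, 512, 1000), screen_geometry())
assign_region <- function(x_px, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (anyNA(x_px) || any(x_px < 0 | x_px > geometry$width_px)) {
    stop("x positions outside the screen [0, ", geometry$width_px, "]")
  }
  b <- geometry$region_bounds
  idx <- 1L + (x_px >= b[1]) + (x_px >= b[2])
  factor(c("left", "middle", "right")[idx],
         levels = c("left", "middle", "right"))
}

#' Hexagonal binning of fixation positions
#'
#' Bins points on a pointy-top hexagonal tessellation: each point is assigned
#' to the nearest hexagon centre (via axial coordinates and cube rounding),
#' so cell counts always sum to the number of points.
#'
#' @param x_px,y_px Point coordinates in pixels.
#' @param hex_radius_px Centre-to-vertex hexagon radius in pixels; the
#'   default 25 px is roughly one character of large print text.
#' @param origin Length-2 numeric, the centre of hexagon `(0, 0)`.
#' @return An object of class `hexbin_grid`: a data frame of occupied cells
#'   with axial indices `q`, `r`, centre coordinates `cx`, `cy` and `count`,
#'   plus attributes `hex_radius_px`, `origin` and `n`.
#' @export
hexbin_counts <- function(x_px, y_px, hex_radius_px = 25,
                          origin = c(0, 0)) {
  if (length(x_px) == 0L) stop("no points to bin")
  stopifnot(length(x_px) == length(y_px))
  if (length(hex_radius_px) != 1L || is.na(hex_radius_px) ||
      hex_radius_px <= 0) {
    stop("hex radius must be a single positive number")
  }
  x <- (x_px - origin[1]) / hex_radius_px
  y <- (y_px - origin[2]) / hex_radius_px
  qf <- (sqrt(3) / 3) * x - (1 / 3) * y
  rf <- (2 / 3) * y
  rounded <- .cube_round(qf, rf)
  key <- paste(rounded$q, rounded$r)
  tab <- table(key)
  first <- !duplicated(key)
  km <- data.frame(key = key[first], q = rounded$q[first],
                   r = rounded$r[first], stringsAsFactors = FALSE)
  km <- km[order(km$q, km$r), , drop = FALSE]
  counts <- as.integer(tab[km$key])
  grid <- data.frame(
    q = km$q, r = km$r,
    cx = origin[1] + hex_radius_px * sqrt(3) * (km$q + km$r / 2),
    cy = origin[2] + hex_radius_px * (3 / 2) * km$r,
    count = counts
  )
  rownames(grid) <- NULL
  structure(grid, hex_radius_px = hex_radius_px, origin = origin,
            n = length(x_px), class = c("hexbin_grid", "data.frame"))
}

# Cube rounding of fractional axial coordinates: yields the hexagon whose
# centre is nearest to the point.
.cube_round <- function(qf, rf) {
  xf <- qf
  zf <- rf
  yf <- -xf - zf
  rx <- round(xf)
  ry <- round(yf)
  rz <- round(zf)
  dx <- abs(rx - xf)
  dy <- abs(ry - yf)
  dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  list(q = as.integer(rx), r = as.integer(rz))
}

#' Count fixation pairs per modelling cell
#'
#' Aggregates classified, region-annotated binocular fixations into one count
#' per (participant, group, article, page, region, type) cell — the unit of
#' observation for the Poisson count models.
#'
#' @param pairs Binocular pairs carrying `type` (see [classify_pairs()]) and
#'   `region` columns.
#' @param complete_zeros If `TRUE`, zero cells are added so every observed
#'   (participant, article, page) combination has a row for each region and
#'   each type in `types`. Modelling region effects requires the zeros;
#'   the default `FALSE` returns only occupied cells.
#' @param types Type labels to keep (and to complete over); default all nine.
#' @return A data frame with columns `participant_id`, `group`, `article_id`,
#'   `page_id`, `region`, `type`, `count`.
#' @export
count_table <- function(pairs, complete_zeros = FALSE, types = ASYNC_LABELS) {
  stopifnot(is.data.frame(pairs))
  if (is.null(pairs$type) || anyNA(pairs$type)) {
    stop("pairs must all carry a `type` (run classify_pairs() first)")
  }
  if (is.null(pairs$region) || anyNA(pairs$region)) {
    stop("pairs must all carry a `region` (run assign_region() first)")
  }
  keep <- pairs$type %in% types
  pairs <- pairs[keep, , drop = FALSE]
  agg <- aggregate(
    list(count = rep(1L, nrow(pairs))),
    by = list(participant_id = pairs$participant_id, group = pairs$group,
              article_id = pairs$article_id, page_id = pairs$page_id,
              region = factor(pairs$region,
                              levels = c("left", "middle", "right")),
              type = factor(as.character(pairs$type), levels = types)),
    FUN = sum
  )
  if (complete_zeros) {
    sess <- unique(agg[c("participant_id", "group", "article_id", "page_id")])
    full <- merge(
      merge(sess, expand.grid(region = levels(agg$region),
                              type = levels(agg$type))),
      agg, all.x = TRUE
    )
    full$count[is.na(full$count)] <- 0L
    agg <- full
  }
  agg <- agg[order(agg$participant_id, agg$article_id, agg$page_id,
                   agg$region, agg$type), , drop = FALSE]
  rownames(agg) <- NULL
  agg[c("participant_id", "group", "article_id", "page_id",
        "region", "type", "count")]
}
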