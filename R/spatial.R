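# Channel geometry: source-detector distance filtering, ROI membership
# (Talairach box or Brodmann-area label sets), and a simple
# inverse-distance-weighted cortical surface projection for maps.

#' Construct a channel-geometry table
#'
#' One row per channel, holding the 3-D source and detector positions in
#' a declared head frame (mm), the derived source-detector distance, a
#' representative channel location (source-detector midpoint, the
#' standard shallow "banana-path" heuristic), mapped Talairach (X, Y)
#' coordinates, and an optional Brodmann-area label.  The Talairach
#' mapping of a montage is an affine placement declared when the
#' geometry is built; no MRI co-registration is performed, and box
#' membership ignores depth (only X and Y are used).
#'
#' @param df data.frame with columns `channel_id`, `sx`, `sy`, `sz`,
#'   `dx`, `dy`, `dz` (mm) and optionally `tal_x`, `tal_y`,
#'   `region_label`.  Missing `tal_x`/`tal_y` default to the midpoint x/y.
#' @return A `channel_geometry` data.frame with derived columns
#'   `sd_distance_cm`, `x_mm`, `y_mm`, `tal_x`, `tal_y`, `region_label`.
#' @export
channel_geometry <- function(df) {
  req <- c("channel_id", "sx", "sy", "sz", "dx", "dy", "dz")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("geometry is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$channel_id)) stop("duplicate channel_id in geometry")
  df$sd_distance_cm <- sqrt((df$sx - df$dx)^2 + (df$sy - df$dy)^2 +
                              (df$sz - df$dz)^2) / 10
  if (any(df$sd_distance_cm <= 0)) {
    stop("source and detector coincide for some channel")
  }
  df$x_mm <- (df$sx + df$dx) / 2
  df$y_mm <- (df$sy + df$dy) / 2
  if (is.null(df$tal_x)) df$tal_x <- df$x_mm
  if (is.null(df$tal_y)) df$tal_y <- df$y_mm
  if (is.null(df$region_label)) {
    df$region_label <- rep(NA_character_, nrow(df))
  }
  class(df) <- c("channel_geometry", "data.frame")
  df
}

#' Filter channels by source-detector distance
#'
#' Retains exactly the channels whose source-detector separation lies in
#' the closed interval \[`min_cm`, `max_cm`\] (default 2--6 cm, the range
#' interrogating cortical depth: shorter pairs see mostly scalp, longer
#' pairs too little light).  Boundary values are retained.
#'
#' @param geom A `channel_geometry`.
#' @param min_cm,max_cm Distance bounds in cm.
#' @return The retained `channel_geometry`, with attribute `exclusions`
#'   (data.frame `channel_id`, `sd_distance_cm`, `reason`).  Warns if no
#'   channel survives.
#' @export
filter_channels <- function(geom, min_cm = 2, max_cm = 6) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (nrow(geom) == 0) {
    warning("empty geometry: nothing to filter")
    attr(geom, "exclusions") <- data.frame(channel_id = character(0),
                                           sd_distance_cm = numeric(0),
                                           reason = character(0))
    return(geom)
  }
  ok <- geom$sd_distance_cm >= min_cm & geom$sd_distance_cm <= max_cm
  excl <- data.frame(channel_id = geom$channel_id[!ok],
                     sd_distance_cm = geom$sd_distance_cm[!ok],
                     reason = ifelse(geom$sd_distance_cm[!ok] < min_cm,
                                     "too_short", "too_long"),
                     stringsAsFactors = FALSE)
  out <- geom[ok, , drop = FALSE]
  if (nrow(out) == 0) warning("no channel inside the distance band")
  attr(out, "exclusions") <- excl
  out
}

#' Define a region of interest
#'
#' Either a Talairach box (closed on all edges, depth ignored) or a set
#' of Brodmann-area labels.
#'
#' @param name ROI name.
#' @param kind `"box"` or `"labels"`.
#' @param box Numeric `c(x_min, x_max, y_min, y_max)` for box ROIs.
#' @param labels Character vector of area labels for label ROIs.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, kind = c("box", "labels"), box = NULL,
                     labels = NULL) {
  kind <- match.arg(kind)
  if (kind == "box") {
    if (is.null(box) || length(box) != 4 || box[1] >= box[2] ||
        box[3] >= box[4]) {
      stop("box must be c(x_min, x_max, y_min, y_max) with min < max")
    }
  } else if (is.null(labels) || !length(labels)) {
    stop("label ROI needs a non-empty label set")
  }
  structure(list(name = name, kind = kind, box = box, labels = labels),
            class = "roi_spec")
}

#' The global cortical-surface ROI
#'
#' Talairach box X in \[-45, 45\], Y in \[-80, 50\], covering most of the
#' axial cortical surface.
#' @export
roi_global <- function() {
  roi_spec("global", "box", box = c(-45, 45, -80, 50))
}

#' Frontoparietal ROI (Brodmann areas 9 and 7)
#' @export
roi_frontoparietal <- function() {
  roi_spec("frontoparietal", "labels", labels = c("BA9", "BA7"))
}

#' Visual-cortex ROI (Brodmann areas 17 and 18)
#' @export
roi_visual <- function() {
  roi_spec("visual", "labels", labels = c("BA17", "BA18"))
}

#' Read ROI definitions from a YAML file
#'
#' The file holds a list of entries with fields `name`, `kind`
#' (`box`/`labels`) and either `box: [x_min, x_max, y_min, y_max]` or
#' `labels: [...]`.
#'
#' @param path YAML file path.
#' @return Named list of `roi_spec` objects.
#' @export
read_roi_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(r) {
    roi_spec(r$name, r$kind, box = unlist(r$box),
             labels = unlist(r$labels))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' ROI membership of channels/units
#'
#' Deterministic membership test: box ROIs compare the unit's Talairach
#' (X, Y) against the closed box; label ROIs compare the unit's
#' `region_label` against the label set.  A unit may belong to multiple
#' ROIs (membership is evaluated per ROI).
#'
#' @param geom A `channel_geometry`.
#' @param roi A `roi_spec`.
#' @return Logical vector along `geom` rows with attribute `n_members`.
#'   An ROI resolving to zero units raises an error of class
#'   `cerepulse_empty_roi`.
#' @export
assign_units <- function(geom, roi) {
  stopifnot(inherits(geom, "channel_geometry"), inherits(roi, "roi_spec"))
  member <- if (roi$kind == "box") {
    geom$tal_x >= roi$box[1] & geom$tal_x <= roi$box[2] &
      geom$tal_y >= roi$box[3] & geom$tal_y <= roi$box[4]
  } else {
    geom$region_label %in% roi$labels
  }
  member[is.na(member)] <- FALSE
  if (!any(member)) {
    stop(structure(class = c("cerepulse_empty_roi", "error", "condition"),
                   list(message = paste0("ROI '", roi$name,
                                         "' resolves to zero units"),
                        call = NULL)))
  }
  attr(member, "n_members") <- sum(member)
  member
}

#' Project per-unit values onto a regular 2-D surface grid
#'
#' Inverse-distance-weighted interpolation of unit values (e.g. arterial
#' compliance) at the units' Talairach (X, Y) locations onto a regular
#' grid, for rendering surface maps.  Grid cells farther than
#' `radius_mm` from every unit are masked `NA`.  This is a rendering
#' convenience, not a tomographic reconstruction.
#'
#' @param values Numeric per-unit values, aligned with `geom` rows.
#' @param geom A `channel_geometry`.
#' @param extent `c(x_min, x_max, y_min, y_max)`; default the unit
#'   bounding box padded by `radius_mm`.
#' @param n_grid Grid points per axis (default 60).
#' @param power IDW exponent (default 2).
#' @param radius_mm Influence radius for masking (default 30).
#' @return A list of class `surface_map`: `z` (matrix, rows = y),
#'   `x`, `y` grid coordinates, `extent`.
#' @export
project_to_surface_map <- function(values, geom, extent = NULL, n_grid = 60,
                                   power = 2, radius_mm = 30) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (length(values) != nrow(geom)) stop("values must align with geometry rows")
  ok <- is.finite(values)
  if (!any(ok)) stop("no finite unit value to project")
  px <- geom$tal_x[ok]; py <- geom$tal_y[ok]; pv <- values[ok]
  if (diff(range(px)) == 0 && diff(range(py)) == 0 && length(pv) > 1) {
    warning("all units co-located: interpolation is degenerate")
  }
  if (is.null(extent)) {
    extent <- c(min(px) - radius_mm, max(px) + radius_mm,
                min(py) - radius_mm, max(py) + radius_mm)
  }
  gx <- seq(extent[1], extent[2], length.out = n_grid)
  gy <- seq(extent[3], extent[4], length.out = n_grid)
  z <- matrix(NA_real_, n_grid, n_grid)
  eps <- 1e-9
  for (iy in seq_len(n_grid)) {
    dx <- outer(gx, px, "-"); dy2 <- (gy[iy] - py)^2
    d <- sqrt(sweep(dx^2, 2, dy2, "+"))
    wmat <- 1 / (d^power + eps)
    zi <- as.numeric(wmat %*% pv) / rowSums(wmat)
    near <- apply(d, 1, min) <= radius_mm
    # exact hit: take the unit value
    hit <- which(d < 1e-6, arr.ind = TRUE)
    if (nrow(hit)) zi[hit[, 1]] <- pv[hit[, 2]]
    zi[!near] <- NA_real_
    z[iy, ] <- zi
  }
  structure(list(z = z, x = gx, y = gy, extent = extent),
            class = "surface_map")
}

#' Write a surface map as a CSV grid
#'
#' Long format (`x`, `y`, `value`) with the extent recorded in a header
#' comment-free first row set, so the map can be regenerated and compared
#' byte-for-byte.
#'
#' @param map A `surface_map`.
#' @param path Output CSV path.
#' @export
write_surface_map <- function(map, path) {
  stopifnot(inherits(map, "surface_map"))
  grid <- expand.grid(x = map$x, y = map$y, KEEP.OUT.ATTRS = FALSE)
  grid$value <- as.numeric(t(map$z))
  write.csv(grid, path, row.names = FALSE)
  invisible(path)
}
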