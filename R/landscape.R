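#' Delaunay connectivity network among sampling localities
#'
#' Builds the genetic-landscape connectivity network: Delaunay triangulation
#' of the locality coordinates, with each edge carrying (i) the mean pairwise
#' genetic distance between individuals of its two endpoint localities and
#' (ii) the great-circle (haversine) distance in km between the localities,
#' plus the great-circle midpoint where residuals will be attached.
#'
#' @param meta metadata tibble (`id, locality, lat, lon`; see
#'   [read_metadata()]).
#' @param d individual-level distance matrix from [pairwise_distance()]
#'   (raw differences by default in the pipeline; any model is accepted).
#' @return An object of class `connectivity_network`: list with `localities`
#'   (tibble `locality, lat, lon, n`) and `edges` (tibble `locality_a,
#'   locality_b, genetic_distance, geographic_km, mid_lat, mid_lon`).
#' @export
build_connectivity <- function(meta, d) {
  meta <- validate_metadata(meta)
  locs <- meta %>%
    group_by(.data$locality) %>%
    summarise(lat = .data$lat[1], lon = .data$lon[1], n = dplyr::n(),
              .groups = "drop")
  if (nrow(locs) < 3) {
    abort(paste0("need >= 3 localities for a Delaunay network ",
                 "(consider a complete-graph connectivity fallback)"))
  }
  tris <- delaunay_triangulate(locs$lon, locs$lat)
  ed <- delaunay_edges(tris)

  members <- split(meta$id, meta$locality)
  edge_tbl <- purrr::map_dfr(seq_len(nrow(ed)), function(k) {
    a <- ed[k, 1]; b <- ed[k, 2]
    ids_a <- members[[locs$locality[a]]]
    ids_b <- members[[locs$locality[b]]]
    p1 <- c(locs$lon[a], locs$lat[a])
    p2 <- c(locs$lon[b], locs$lat[b])
    mid <- geosphere::midPoint(p1, p2)
    tibble(
      locality_a = locs$locality[a],
      locality_b = locs$locality[b],
      genetic_distance = mean_group_distance(d, ids_a, ids_b),
      geographic_km = geosphere::distHaversine(p1, p2) / 1000,
      mid_lat = mid[2], mid_lon = mid[1]
    )
  })
  structure(list(localities = locs, edges = edge_tbl),
            class = "connectivity_network")
}

#' @export
print.connectivity_network <- function(x, ...) {
  cat(sprintf("<connectivity_network> %d localities, %d Delaunay edges\n",
              nrow(x$localities), nrow(x$edges)))
  invisible(x)
}

#' Residual genetic distances
#'
#' Ordinary least squares of the per-edge genetic distance on the per-edge
#' geographic distance; the residual (observed minus fitted) is attached to
#' the edge midpoint. Regressing out geography is recommended when geographic
#' distances between connected localities vary substantially; what remains is
#' the geography-free component of genetic structure.
#'
#' @param net a `connectivity_network` from [build_connectivity()].
#' @return A tibble `locality_a, locality_b, mid_lat, mid_lon, residual`,
#'   with the fitted model attached as attribute `fit`.
#' @export
residual_distances <- function(net) {
  stopifnot(inherits(net, "connectivity_network"))
  e <- net$edges
  if (nrow(e) < 3) abort("need >= 3 edges for the regression")
  if (var(e$geographic_km) == 0) {
    abort("zero variance in geographic distances; regression undefined")
  }
  fit <- lm(genetic_distance ~ geographic_km, data = e)
  out <- tibble(
    locality_a = e$locality_a, locality_b = e$locality_b,
    mid_lat = e$mid_lat, mid_lon = e$mid_lon,
    residual = as.numeric(residuals(fit))
  )
  attr(out, "fit") <- fit
  out
}

#' Inverse-distance-weighted landscape surface
#'
#' Interpolates midpoint residuals onto a regular latitude/longitude grid:
#' `Z(g) = sum(z_i * w_i) / sum(w_i)` with `w_i = 1/dist(g, midpoint_i)^alpha`
#' (great-circle distances); a grid node coinciding with a midpoint takes that
#' midpoint's value. The grid is anchored at the minimum latitude/longitude of
#' the localities; cells outside the convex hull of the localities are masked
#' by default.
#'
#' @param resid tibble from [residual_distances()] (needs `mid_lat`,
#'   `mid_lon`, `residual`).
#' @param localities tibble with `lat`, `lon` of the sampling localities
#'   (defines grid extent and mask); defaults to the midpoints themselves.
#' @param cell grid cell size in degrees (default 0.05).
#' @param alpha distance-weighting exponent (> 0; default 1).
#' @param mask_hull mask grid nodes outside the convex hull of `localities`.
#' @return An object of class `landscape_surface`: tibble `lat, lon, value,
#'   masked` with attributes `cell` and `alpha`.
#' @export
interpolate_surface <- function(resid, localities = NULL, cell = 0.05,
                                alpha = 1, mask_hull = TRUE) {
  if (alpha <= 0) abort("`alpha` must be > 0")
  if (cell <= 0) abort("`cell` must be > 0")
  if (nrow(resid) < 1) abort("need >= 1 midpoint")
  if (is.null(localities)) {
    localities <- tibble(lat = resid$mid_lat, lon = resid$mid_lon)
    mask_hull <- FALSE
  }
  lat0 <- min(localities$lat); lon0 <- min(localities$lon)
  lats <- seq(lat0, max(localities$lat) + cell / 2, by = cell)
  lons <- seq(lon0, max(localities$lon) + cell / 2, by = cell)
  grid <- tidyr::expand_grid(lat = lats, lon = lons)

  masked <- rep(FALSE, nrow(grid))
  if (mask_hull && nrow(localities) >= 3) {
    hull <- localities[grDevices::chull(localities$lon, localities$lat), ]
    masked <- !point_in_polygon(grid$lon, grid$lat, hull$lon, hull$lat)
  }

  vals <- rep(NA_real_, nrow(grid))
  open <- which(!masked)
  if (length(open)) {
    dm <- geosphere::distm(cbind(grid$lon[open], grid$lat[open]),
                           cbind(resid$mid_lon, resid$mid_lat),
                           fun = geosphere::distHaversine)
    z <- resid$residual
    vals[open] <- vapply(seq_along(open), function(i) {
      di <- dm[i, ]
      hit <- which(di < 1e-6)       # metres: node coincides with a midpoint
      if (length(hit)) return(z[hit[1]])
      w <- 1 / di^alpha
      sum(z * w) / sum(w)
    }, numeric(1))
  }
  structure(tibble(lat = grid$lat, lon = grid$lon, value = vals,
                   masked = masked),
            class = c("landscape_surface", class(tibble())),
            cell = cell, alpha = alpha)
}

# ray-casting point-in-polygon (closed polygon, vertices in order)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Write a landscape surface as long-form CSV
#' @param surface a `landscape_surface`.
#' @param path output CSV path (`lat,lon,value`; masked cells omitted).
#' @export
write_surface <- function(surface, path) {
  write.csv(surface[!surface$masked, c("lat", "lon", "value")],
            path, row.names = FALSE)
  invisible(surface)
}
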