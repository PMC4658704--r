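make_meta <- function(localities, per = 2) {
  tidyr::uncount(localities, per) %>%
    dplyr::group_by(locality) %>%
    dplyr::mutate(id = paste0(locality, "_", dplyr::row_number())) %>%
    dplyr::ungroup() %>%
    dplyr::select(id, locality, lat, lon)
}

fake_distance <- function(ids, fun) {
  d <- outer(seq_along(ids), seq_along(ids), function(i, j) fun(i, j))
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(d, model = "raw_differences", units = "sites")
}

test_that("Delaunay edge counts match the forced small cases", {
  tri <- tibble::tibble(locality = c("a", "b", "c"),
                        lat = c(43, 44, 43.5), lon = c(14, 14.5, 15.5))
  meta <- make_meta(tri)
  d <- fake_distance(meta$id, function(i, j) abs(i - j))
  net <- build_connectivity(meta, d)
  expect_equal(nrow(net$edges), 3)

  quad <- tibble::tibble(locality = c("a", "b", "c", "d"),
                         lat = c(43, 43.2, 44.1, 44), lon = c(14, 15.6, 15.5, 14.1))
  net4 <- build_connectivity(make_meta(quad), fake_distance(make_meta(quad)$id,
                                                            function(i, j) 1 + 0 * i))
  expect_equal(nrow(net4$edges), 5)

  expect_error(build_connectivity(make_meta(tri[1:2, ]), d), ">= 3")
  coll <- tibble::tibble(locality = c("a", "b", "c"),
                         lat = c(43, 44, 45), lon = c(14, 15, 16))
  expect_error(build_connectivity(make_meta(coll),
                                  fake_distance(make_meta(coll)$id,
                                                function(i, j) 1 + 0 * i)),
               "collinear")
})

test_that("triangulations satisfy the empty-circumcircle property", {
  set.seed(81)
  for (rep in 1:3) {
    x <- runif(10, 13, 17); y <- runif(10, 42, 45)
    tris <- tideclock:::delaunay_triangulate(x, y)
    expect_gte(nrow(tris), 1)
    for (t in seq_len(nrow(tris))) {
      expect_true(circumcircle_empty(tris[t, ], x, y))
    }
    # triangulation tiles the convex hull: areas add up
    area <- function(ix) {
      abs((x[ix[2]] - x[ix[1]]) * (y[ix[3]] - y[ix[1]]) -
            (x[ix[3]] - x[ix[1]]) * (y[ix[2]] - y[ix[1]])) / 2
    }
    hull <- grDevices::chull(x, y)
    hull_area <- sum(vapply(2:(length(hull) - 1), function(i)
      area(c(hull[1], hull[i], hull[i + 1])), numeric(1)))
    expect_equal(sum(apply(tris, 1, area)), hull_area, tolerance = 1e-9)
  }
})

test_that("residuals vanish for perfectly linear genetic-geographic data", {
  locs <- tibble::tibble(locality = c("a", "b", "c", "d"),
                         lat = c(43, 43.3, 44.0, 43.9), lon = c(14, 15.5, 15.3, 14.2))
  meta <- make_meta(locs)
  net <- build_connectivity(meta, fake_distance(meta$id, function(i, j) 1 + 0 * i))
  # rebuild edge genetic distances as an exact line in geography
  net$edges$genetic_distance <- 2 + 0.03 * net$edges$geographic_km
  res <- residual_distances(net)
  expect_equal(res$residual, rep(0, nrow(res)), tolerance = 1e-10)
})

test_that("residuals sum to zero and match the normal equations", {
  locs <- tibble::tibble(locality = c("a", "b", "c", "d"),
                         lat = c(43, 43.4, 44.1, 43.8), lon = c(14, 15.6, 15.2, 14.3))
  meta <- make_meta(locs)
  set.seed(83)
  net <- build_connectivity(meta, fake_distance(meta$id,
                                                function(i, j) (i + j) %% 5))
  res <- residual_distances(net)
  expect_equal(sum(res$residual), 0, tolerance = 1e-10)
  # closed-form OLS on the edge table
  xx <- net$edges$geographic_km; yy <- net$edges$genetic_distance
  b <- sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
  a <- mean(yy) - b * mean(xx)
  expect_equal(res$residual, yy - (a + b * xx), tolerance = 1e-10)
})

test_that("IDW surface is a convex combination with exact-node interpolation", {
  res <- tibble::tibble(mid_lat = c(43.1, 43.6, 44.2),
                        mid_lon = c(14.2, 15.1, 14.7),
                        residual = c(5, 5, 5))
  surf <- interpolate_surface(res, cell = 0.2)
  expect_true(all(abs(surf$value[!surf$masked] - 5) < 1e-9))

  res$residual <- c(1, 7, 4)
  surf2 <- interpolate_surface(res, cell = 0.2)
  v <- surf2$value[!surf2$masked]
  expect_true(all(v >= 1 - 1e-9 & v <= 7 + 1e-9))
  # grid node sitting on a midpoint takes its value
  exact <- interpolate_surface(res[1, ], cell = 0.05)
  expect_true(all(abs(exact$value[!exact$masked] - 1) < 1e-9))

  # alpha -> infinity approaches nearest-neighbour assignment
  surf_nn <- interpolate_surface(res, cell = 0.2, alpha = 50)
  open <- which(!surf_nn$masked)
  nn <- vapply(open, function(i) {
    di <- geosphere::distHaversine(
      cbind(surf_nn$lon[i], surf_nn$lat[i]),
      cbind(res$mid_lon, res$mid_lat))
    res$residual[which.min(di)]
  }, numeric(1))
  expect_equal(surf_nn$value[open], nn, tolerance = 0.05)
  expect_error(interpolate_surface(res, alpha = 0), "alpha")
})

test_that("surfaces at alpha 0.3 and 3 agree in rank (qualitative stability)", {
  rho <- vapply(84:88, function(seed) {
    ds <- generate_dataset(sim_config(seed = seed))
    d <- pairwise_distance(ds$alignment, "raw_differences")
    net <- build_connectivity(ds$metadata, d)
    res <- residual_distances(net)
    s1 <- interpolate_surface(res, net$localities, cell = 0.05, alpha = 0.3)
    s2 <- interpolate_surface(res, net$localities, cell = 0.05, alpha = 3)
    keep <- !s1$masked
    stats::cor(s1$value[keep], s2$value[keep], method = "spearman")
  }, numeric(1))
  expect_gte(median(rho), 0.8)
})

test_that("the surface is invariant under locality relabelling", {
  set.seed(85)
  ds <- generate_dataset(sim_config(n = 30, L = 200, seed = 85))
  d <- pairwise_distance(ds$alignment, "raw_differences")
  net <- build_connectivity(ds$metadata, d)
  surf <- interpolate_surface(residual_distances(net), net$localities,
                              cell = 0.3)
  relab <- ds$metadata
  map <- setNames(paste0("Z", 1:10), sprintf("L%02d", 1:10))
  relab$locality <- unname(map[relab$locality])
  net2 <- build_connectivity(relab, d)
  surf2 <- interpolate_surface(residual_distances(net2), net2$localities,
                               cell = 0.3)
  expect_equal(sort(surf$value[!surf$masked]), sort(surf2$value[!surf2$masked]),
               tolerance = 1e-9)
})
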