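# Structural pipeline: normalization, CHM, treetops, watershed, density,
# categories.

grid_cloud <- function(xs, ys, z_fun, classification = "ground",
                       return_number = 1L) {
  g <- expand.grid(x = xs, y = ys)
  data.frame(x = g$x, y = g$y, z = z_fun(g$x, g$y),
             return_number = return_number, classification = classification)
}

test_that("heights are measured against flat and sloped ground planes", {
  ground <- grid_cloud(0:60, 0:20, function(x, y) 100 + 0 * x)
  veg <- data.frame(x = 30.2, y = 10.3, z = 105, return_number = 1L,
                    classification = "vegetation")
  norm <- normalize_heights(rbind(ground, veg))
  expect_equal(norm$z[norm$classification == "vegetation"], 5, tolerance = 1e-6)
  # ground points themselves sit at height zero
  expect_lt(max(abs(norm$z[norm$classification == "ground"])), 1e-6)

  sloped <- grid_cloud(0:60, 0:20, function(x, y) 100 + 0.1 * x)
  veg2 <- data.frame(x = 50, y = 9.7, z = 110, return_number = 1L,
                     classification = "vegetation")
  norm2 <- normalize_heights(rbind(sloped, veg2))
  expect_equal(norm2$z[norm2$classification == "vegetation"], 5,
               tolerance = 1e-6)
})

test_that("degenerate ground configurations are rejected by name", {
  veg <- data.frame(x = 1, y = 1, z = 5, return_number = 1L,
                    classification = "vegetation")
  two <- data.frame(x = c(0, 1), y = c(0, 0), z = c(0, 0),
                    return_number = 1L, classification = "ground")
  expect_error(normalize_heights(rbind(two, veg)), "at least 3 ground points")
  line <- data.frame(x = 0:10, y = rep(2, 11), z = 0, return_number = 1L,
                     classification = "ground")
  expect_error(normalize_heights(rbind(line, veg)), "collinear")
})

test_that("noise points are dropped before any processing", {
  ground <- grid_cloud(0:10, 0:10, function(x, y) 0 * x)
  noise <- data.frame(x = 5, y = 5, z = 500, return_number = 1L,
                      classification = "noise")
  norm <- normalize_heights(rbind(ground, noise))
  expect_false(any(norm$classification == "noise"))
})

test_that("the CHM keeps the per-cell maximum of first returns only", {
  ground <- grid_cloud(seq(0, 4, 0.5), seq(0, 4, 0.5), function(x, y) 0 * x)
  veg <- data.frame(
    x = c(1.1, 2.6, 2.7, 3.6), y = c(1.1, 2.6, 2.7, 1.1),
    z = c(7.2, 3.0, 8.0, 9.0),
    return_number = c(1L, 1L, 1L, 2L),
    classification = "vegetation"
  )
  cloud <- rbind(ground, veg)
  attr(cloud, "normalized") <- TRUE
  chm <- rasterize_chm(cloud, 0.5)
  cell <- thermascape:::xy_to_cell(chm, veg$x, veg$y)
  # single first return fills its own cell, neighbours stay empty
  expect_equal(chm$values[cell$row[1], cell$col[1]], 7.2)
  expect_true(all(is.na(chm$values[cell$row[1] + c(-1, 1), cell$col[1]])))
  # two first returns in one cell: the maximum wins
  expect_equal(chm$values[cell$row[2], cell$col[2]], 8.0)
  # a lone second return does not rasterize
  expect_true(is.na(chm$values[cell$row[4], cell$col[4]]))
  expect_error(rasterize_chm(cloud[0, ]), "empty")
})

test_that("a single paraboloid crown yields exactly one treetop at its apex", {
  chm <- chm_paraboloid(h = 10, r = 2.5)
  tops <- detect_treetops(chm)
  expect_equal(nrow(tops), 1L)
  apex_cell <- which(chm$values == max(chm$values, na.rm = TRUE),
                     arr.ind = TRUE)
  expect_equal(unname(c(tops$row, tops$col)), unname(as.vector(apex_cell)))
  expect_equal(tops$height_m, 10)
})

test_that("a perfectly flat CHM contains no treetops", {
  chm <- canopy_raster(matrix(5, 20, 20), 0.5, origin = c(0, 10))
  expect_equal(nrow(detect_treetops(chm)), 0L)
})

test_that("a flat-topped crown is reported once, at the plateau centroid", {
  chm <- chm_paraboloid(h = 8, r = 2.5)
  # flatten the top 3x3 cells to an exact plateau
  apex <- which(chm$values == max(chm$values, na.rm = TRUE), arr.ind = TRUE)
  rows <- apex[1] + (-1:1); cols <- apex[2] + (-1:1)
  chm$values[rows, cols] <- 8
  tops <- detect_treetops(chm)
  expect_equal(nrow(tops), 1L)
  expect_equal(unname(c(tops$row, tops$col)), unname(as.vector(apex)))
})

test_that("well-separated synthetic trees are recovered one-for-one", {
  spec <- separated_stand(50, seed = 21)
  st <- generate_stand(spec)
  seg <- segment_trees(st$cloud)
  expect_equal(nrow(seg$apexes), 50L)
  # match each detection to the nearest planted tree
  idx <- vapply(seq_len(nrow(seg$apexes)), function(i) {
    which.min((st$trees$apex_x - seg$apexes$x[i])^2 +
                (st$trees$apex_y - seg$apexes$y[i])^2)
  }, integer(1))
  expect_equal(sort(idx), 1:50)  # a bijection
  expect_true(all(abs(seg$apexes$height_m - st$trees$height_m[idx]) <= 0.5))
  # CHM never exceeds the true apex height beyond ground-model noise:
  # crown returns are capped at the apex, so any excess is the (small)
  # error of the fitted ground surface
  expect_true(all(seg$apexes$height_m <= st$trees$height_m[idx] + 0.05))
})

test_that("an isolated crown's segmented area matches its 2-m footprint", {
  h <- 10; r <- 2.5; res <- 0.5
  chm <- chm_paraboloid(h, r, res)
  tops <- detect_treetops(chm)
  crowns <- segment_crowns(chm, tops)
  r_cut <- r * sqrt(1 - 2 / h)  # crown radius at the 2-m cut plane
  expect_equal(crowns$crown_area_m2, pi * r_cut^2,
               tolerance = (2 * pi * r_cut * res + 4 * res^2) / (pi * r_cut^2))
})

test_that("two equal touching crowns split along the equidistant line", {
  res <- 0.5; h <- 8; r <- 3
  ext <- c(20, 12)
  n_r <- ext[2] / res; n_c <- ext[1] / res
  xs <- res * (seq_len(n_c) - 0.5); ys <- ext[2] - res * (seq_len(n_r) - 0.5)
  a1 <- c(7, 6); a2 <- c(13, 6)  # 6 m apart, crowns overlap
  s1 <- outer(ys, xs, function(y, x) h * (1 - ((x - a1[1])^2 + (y - a1[2])^2) / r^2))
  s2 <- outer(ys, xs, function(y, x) h * (1 - ((x - a2[1])^2 + (y - a2[2])^2) / r^2))
  v <- pmax(s1, s2)
  v[v <= 0] <- NA
  chm <- canopy_raster(v, res, origin = c(0, ext[2]))
  tops <- detect_treetops(chm)
  expect_equal(nrow(tops), 2L)
  crowns <- segment_crowns(chm, tops)
  lab <- attr(crowns, "labels")
  cells <- which(lab > 0L, arr.ind = TRUE)
  x <- res * (cells[, 2] - 0.5); y <- ext[2] - res * (cells[, 1] - 0.5)
  d1 <- sqrt((x - a1[1])^2 + (y - a1[2])^2)
  d2 <- sqrt((x - a2[1])^2 + (y - a2[2])^2)
  lab_at <- lab[cells]
  i1 <- which(tops$x < 10)  # the apex belonging to the left crown
  lab_a1 <- lab[tops$row[i1], tops$col[i1]]
  nearer1 <- d1 < d2 - res  # strictly nearer by more than one cell
  nearer2 <- d2 < d1 - res
  expect_true(all(lab_at[nearer1] == lab_a1))
  expect_true(all(lab_at[nearer2] != lab_a1))
})

test_that("a marker on sub-threshold cells produces no crown", {
  chm <- chm_paraboloid(h = 10, r = 2)
  tops <- detect_treetops(chm)
  spurious <- data.frame(tree_id = 2L, row = 2L, col = 2L, x = NA, y = NA,
                         height_m = NA)  # corner cell: below 2 m / NA
  crowns <- segment_crowns(chm, rbind(tops, spurious))
  expect_equal(nrow(crowns), 1L)
  expect_error(segment_crowns(chm, data.frame(row = 1e4, col = 1L)),
               "outside")
})

test_that("crowns partition the canopy cells with one apex each", {
  spec <- separated_stand(12, seed = 31)
  st <- generate_stand(spec)
  seg <- segment_trees(st$cloud)
  lab <- attr(seg$crowns, "labels")
  H <- seg$chm$values
  expect_true(all(H[lab > 0L] > 2))
  # one apex per crown, sitting inside its own mask
  apex_lab <- lab[cbind(seg$crowns$apex_row, seg$crowns$apex_col)]
  expect_equal(apex_lab, seg$crowns$tree_id)
  expect_lte(sum(seg$crowns$n_cells), sum(H > 2, na.rm = TRUE))
})

test_that("density ratio arithmetic follows the upper-canopy definition", {
  lab <- matrix(1L, 10, 10)
  crowns <- manual_crown_set(apex_height = 10, labels = lab)
  mk <- function(n, z) data.frame(x = runif(n, 0.2, 4.8), y = runif(n, 0.2, 4.8),
                                  z = z, return_number = 1L,
                                  classification = "vegetation")
  set.seed(1)
  all_up <- mk(50, 8)
  expect_equal(canopy_density(all_up, crowns), 1.0)
  mixed <- rbind(mk(30, 8), mk(70, 3))
  expect_equal(canopy_density(mixed, crowns), 0.30)
  empty <- mk(5, 8); empty$x <- empty$x + 100  # outside the footprint
  expect_error(canopy_density(empty, crowns), "no vegetation return")
})

test_that("true density ratios are recovered within 0.05 by the pipeline", {
  for (p in c(0.2, 0.6, 0.8)) {
    spec <- stand_spec(
      extent_m = c(30, 30), n_trees = 1,
      height_law = list(breaks = c(8, 8.0001), weights = 1),
      density_law = list(mean = p, sd = 0),
      crown_radius_law = list(a = 1.5, b = 0, sd = 0),
      crown_point_density_per_m3 = 30, seed = 41
    )
    st <- generate_stand(spec)
    seg <- segment_trees(st$cloud)
    expect_lt(abs(seg$crowns$density_ratio - p), 0.05)
  }
})

test_that("density ratio is invariant under uniform thinning (binomial test)", {
  spec <- stand_spec(
    extent_m = c(30, 30), n_trees = 1,
    height_law = list(breaks = c(8, 8.0001), weights = 1),
    density_law = list(mean = 0.6, sd = 0),
    crown_radius_law = list(a = 1.5, b = 0, sd = 0),
    crown_point_density_per_m3 = 60, seed = 43
  )
  st <- generate_stand(spec)
  seg <- segment_trees(st$cloud)
  p_full <- seg$crowns$density_ratio
  set.seed(7)
  veg <- st$cloud$classification == "vegetation"
  thin <- st$cloud[!veg | runif(nrow(st$cloud)) < 0.5, ]
  seg2 <- segment_trees(thin)
  n_thin <- sum(thin$classification == "vegetation")
  x_up <- round(seg2$crowns$density_ratio * n_thin)
  expect_gt(stats::binom.test(x_up, n_thin, p = p_full)$p.value, 0.01)
})

test_that("category bins are half-open with a closed top and 100 cells", {
  grid <- category_grid()
  expect_equal(grid$n_categories, 100L)
  expect_equal(assign_category(3.0, 0.5)$height_label, "3-4m")
  got <- assign_category(5.5, 0.55)
  expect_equal(got$height_label, "4-6m")
  expect_equal(got$density_label, "0.5-0.6")
  expect_equal(assign_category(5, 1.0)$density_label, "0.9-1.0")
  expect_equal(assign_category(20, 0)$height_label, "18-20m")
  expect_equal(assign_category(5, 0)$density_label, "0.0-0.1")
  expect_error(assign_category(2, 0.5), "outside")
  expect_error(assign_category(20.5, 0.5), "outside")
  expect_error(assign_category(5, 1.2), "density")
  # enumerate representative points of all cells: exactly 100 categories
  hb <- grid$height_breaks_m; db <- grid$density_breaks
  reps <- expand.grid(h = (hb[-11] + hb[-1]) / 2, d = (db[-11] + db[-1]) / 2)
  cats <- assign_category(reps$h, reps$d)$category
  expect_equal(sort(cats), 1:100)
})

test_that("crown tables and label rasters export to text formats", {
  spec <- separated_stand(4, seed = 51)
  st <- generate_stand(spec)
  seg <- segment_trees(st$cloud)
  csv <- tempfile(fileext = ".csv")
  write_crowns_csv(seg$crowns, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(seg$crowns))
  asc <- tempfile(fileext = ".asc")
  write_esri_ascii(seg$chm, asc)
  chm2 <- read_esri_ascii(asc)
  expect_equal(chm2$values, seg$chm$values, tolerance = 1e-4)
  expect_equal(chm2$resolution, seg$chm$resolution)
})
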