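#' Normalize point heights against a fitted ground surface
#'
#' Replaces absolute elevations by height above ground. The ground surface
#' is estimated from the classified ground returns with a moving-window
#' least-squares plane fit evaluated on a coarse grid (each node takes the
#' plane fitted to the ground points of its 3x3 cell neighbourhood), then
#' evaluated at every point by bilinear interpolation between nodes. The
#' estimator is exact for planar terrain and tracks smooth low-frequency
#' relief. Noise-classified points are dropped; ground points end up at
#' height ~0 and small negative heights (interpolation noise) are clamped
#' to zero.
#'
#' @param cloud point-cloud data.frame (`x`, `y`, `z`, `return_number`,
#'   `classification`).
#' @param grid_res node spacing of the ground model in metres.
#' @return The cloud with `z` replaced by height above ground (m) and
#'   attribute `normalized = TRUE`.
#' @export
normalize_heights <- function(cloud, grid_res = 2) {
  cloud <- cloud[cloud$classification != "noise", , drop = FALSE]
  g <- cloud[cloud$classification == "ground", , drop = FALSE]
  if (nrow(g) < 3L) {
    stop("ground model needs at least 3 ground points, got ", nrow(g))
  }
  xy <- cbind(g$x, g$y)
  sv <- svd(sweep(xy, 2, colMeans(xy)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("ground points are collinear; cannot triangulate a ground surface")
  }

  x0 <- min(cloud$x); y0 <- min(cloud$y)
  nc <- max(1L, ceiling((max(cloud$x) - x0) / grid_res))
  nr <- max(1L, ceiling((max(cloud$y) - y0) / grid_res))

  col <- pmin(nc, pmax(1L, floor((g$x - x0) / grid_res) + 1L))
  row <- pmin(nr, pmax(1L, floor((g$y - y0) / grid_res) + 1L))
  idx <- (col - 1L) * nr + row

  # centre coordinates on each cell's node to keep the normal equations
  # well conditioned
  xc_node <- x0 + grid_res * (col - 0.5)
  yc_node <- y0 + grid_res * (row - 0.5)
  u <- g$x - xc_node; v <- g$y - yc_node

  cellsum <- function(val) {
    out <- numeric(nr * nc)
    s <- rowsum(val, idx)
    out[as.integer(rownames(s))] <- s
    matrix(out, nr, nc)
  }
  S1 <- cellsum(rep(1, nrow(g)))
  Su <- cellsum(u); Sv <- cellsum(v); Sz <- cellsum(g$z)
  Suu <- cellsum(u * u); Suv <- cellsum(u * v); Svv <- cellsum(v * v)
  Suz <- cellsum(u * g$z); Svz <- cellsum(v * g$z)

  # aggregate sums over the 3x3 node neighbourhood; for a neighbour cell at
  # offset (di, dj) the point coordinate relative to the centre node is
  # u + dj*res (x offset by column) and v + di*res (y offset by row; grid
  # rows increase with y here)
  N1 <- matrix(0, nr, nc); Nu <- Nv <- Nz <- N1
  Nuu <- Nuv <- Nvv <- Nuz <- Nvz <- N1
  for (di in -1:1) for (dj in -1:1) {
    src_r <- max(1L, 1L + di):min(nr, nr + di)
    src_c <- max(1L, 1L + dj):min(nc, nc + dj)
    dst_r <- src_r - di; dst_c <- src_c - dj
    ou <- dj * grid_res; ov <- di * grid_res
    N1[dst_r, dst_c] <- N1[dst_r, dst_c] + S1[src_r, src_c]
    Nz[dst_r, dst_c] <- Nz[dst_r, dst_c] + Sz[src_r, src_c]
    Nu[dst_r, dst_c] <- Nu[dst_r, dst_c] + Su[src_r, src_c] + ou * S1[src_r, src_c]
    Nv[dst_r, dst_c] <- Nv[dst_r, dst_c] + Sv[src_r, src_c] + ov * S1[src_r, src_c]
    Nuu[dst_r, dst_c] <- Nuu[dst_r, dst_c] + Suu[src_r, src_c] +
      2 * ou * Su[src_r, src_c] + ou^2 * S1[src_r, src_c]
    Nvv[dst_r, dst_c] <- Nvv[dst_r, dst_c] + Svv[src_r, src_c] +
      2 * ov * Sv[src_r, src_c] + ov^2 * S1[src_r, src_c]
    Nuv[dst_r, dst_c] <- Nuv[dst_r, dst_c] + Suv[src_r, src_c] +
      ou * Sv[src_r, src_c] + ov * Su[src_r, src_c] + ou * ov * S1[src_r, src_c]
    Nuz[dst_r, dst_c] <- Nuz[dst_r, dst_c] + Suz[src_r, src_c] + ou * Sz[src_r, src_c]
    Nvz[dst_r, dst_c] <- Nvz[dst_r, dst_c] + Svz[src_r, src_c] + ov * Sz[src_r, src_c]
  }

  # solve the 3x3 normal equations [N1 Nu Nv; Nu Nuu Nuv; Nv Nuv Nvv] beta =
  # [Nz; Nuz; Nvz] per node by Cramer's rule; the intercept is the ground
  # elevation at the node
  det3 <- N1 * (Nuu * Nvv - Nuv^2) - Nu * (Nu * Nvv - Nuv * Nv) +
    Nv * (Nu * Nuv - Nuu * Nv)
  detA <- Nz * (Nuu * Nvv - Nuv^2) - Nu * (Nuz * Nvv - Nuv * Nvz) +
    Nv * (Nuz * Nuv - Nuu * Nvz)
  node <- detA / det3
  # degenerate nodes (too few / collinear local points): global plane fallback
  bad <- !is.finite(node) | N1 < 3 | abs(det3) < 1e-8
  if (any(bad)) {
    fit <- stats::lm.fit(cbind(1, g$x, g$y), g$z)$coefficients
    rr <- ((seq_len(nr * nc) - 1L) %% nr) + 1L
    cc <- ((seq_len(nr * nc) - 1L) %/% nr) + 1L
    nx <- x0 + grid_res * (cc - 0.5); ny <- y0 + grid_res * (rr - 0.5)
    glob <- matrix(fit[1] + fit[2] * nx + fit[3] * ny, nr, nc)
    node[bad] <- glob[bad]
  }

  # bilinear interpolation between node centres, clamped at the hull edge
  fx <- clamp((cloud$x - x0) / grid_res - 0.5, 0, nc - 1)
  fy <- clamp((cloud$y - y0) / grid_res - 0.5, 0, nr - 1)
  c1 <- pmin(floor(fx) + 1L, nc - 1L); c1 <- pmax(c1, 1L)
  r1 <- pmin(floor(fy) + 1L, nr - 1L); r1 <- pmax(r1, 1L)
  tx <- fx - (c1 - 1L); ty <- fy - (r1 - 1L)
  if (nc == 1L) { c1 <- 1L; tx <- 0 }
  if (nr == 1L) { r1 <- 1L; ty <- 0 }
  c2 <- pmin(c1 + 1L, nc); r2 <- pmin(r1 + 1L, nr)
  zg <- (1 - tx) * (1 - ty) * node[cbind(r1, c1)] +
    tx * (1 - ty) * node[cbind(r1, c2)] +
    (1 - tx) * ty * node[cbind(r2, c1)] +
    tx * ty * node[cbind(r2, c2)]

  out <- cloud
  out$z <- pmax(cloud$z - zg, 0)
  attr(out, "normalized") <- TRUE
  out
}

#' Rasterize a canopy height model from first returns
#'
#' Grids the maximum height among *first-return vegetation* points per
#' cell; cells containing no first-return vegetation point are `NA`
#' (no-canopy). Expects a height-normalized cloud.
#'
#' @param cloud a [normalize_heights()]-processed point cloud.
#' @param resolution_m cell size in metres (default 0.5).
#' @return A [canopy_raster] of canopy heights (m).
#' @export
rasterize_chm <- function(cloud, resolution_m = 0.5) {
  if (nrow(cloud) == 0L) stop("cannot rasterize an empty point cloud")
  if (!isTRUE(attr(cloud, "normalized"))) {
    warning("cloud does not look height-normalized; call normalize_heights() first")
  }
  res <- resolution_m
  x0 <- floor(min(cloud$x) / res) * res
  ytop <- ceiling(max(cloud$y) / res) * res
  nc <- max(1L, ceiling((max(cloud$x) - x0) / res))
  nr <- max(1L, ceiling((ytop - min(cloud$y)) / res))
  r <- canopy_raster(matrix(NA_real_, nr, nc), res, origin = c(x0, ytop),
                     layer = "chm")
  v <- cloud[cloud$classification == "vegetation" & cloud$return_number == 1L, ,
             drop = FALSE]
  if (nrow(v)) {
    cell <- xy_to_cell(r, v$x, v$y)
    ok <- !is.na(cell$row)
    idx <- (cell$col[ok] - 1L) * nr + cell$row[ok]
    mx <- tapply(v$z[ok], idx, max)
    r$values[as.integer(names(mx))] <- as.numeric(mx)
  }
  r
}

#' Variable-window specification for treetop detection
#'
#' The search radius grows linearly with canopy height,
#' `r(h) = a + b h` metres, floored at `min_radius_m`: taller trees have
#' wider crowns, so their apex must dominate a wider neighbourhood.
#'
#' @param a,b intercept (m) and slope (m per m of height) of the window
#'   radius rule.
#' @param min_radius_m smallest allowed radius (m).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(a = 1, b = 0.05, min_radius_m = 1) {
  stopifnot_scalar_number(a, "a", 0)
  stopifnot_scalar_number(b, "b", 0)
  stopifnot_scalar_number(min_radius_m, "min_radius_m", lo = 1e-9)
  structure(list(a = a, b = b, min_radius_m = min_radius_m),
            class = "window_spec")
}

# Neighbourhood maximum over a circular window of radius `rad_cells`
# (in cell units, cell-centre metric), excluding the centre cell.
# NA cells are ignored; cells whose whole window is NA get -Inf.
neighbourhood_max <- function(H, rad_cells) {
  nr <- nrow(H); nc <- ncol(H)
  out <- matrix(-Inf, nr, nc)
  Hf <- H; Hf[is.na(Hf)] <- -Inf
  r <- ceiling(rad_cells)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0L && dj == 0L) next
    if (di * di + dj * dj > rad_cells^2 + 1e-9) next
    src_r <- max(1L, 1L + di):min(nr, nr + di)
    src_c <- max(1L, 1L + dj):min(nc, nc + dj)
    dst_r <- src_r - di; dst_c <- src_c - dj
    out[dst_r, dst_c] <- pmax(out[dst_r, dst_c], Hf[src_r, src_c])
  }
  out
}

#' Detect treetops as variable-window local maxima
#'
#' Scans the CHM for cells higher than `min_height` that strictly dominate
#' every other cell within their height-dependent circular window.
#' Flat-topped crowns (plateaus of tied cells that jointly dominate their
#' windows) are collapsed to the plateau member nearest its centroid and
#' reported once; a perfectly flat CHM therefore yields no treetops.
#'
#' @param chm a [canopy_raster] canopy height model.
#' @param window a [window_spec].
#' @param min_height minimum apex height (m); trees at or below are ignored.
#' @return data.frame of apexes ordered by height (descending):
#'   `tree_id`, `row`, `col`, `x`, `y`, `height_m`.
#' @export
detect_treetops <- function(chm, window = window_spec(), min_height = 2) {
  H <- chm$values
  res <- chm$resolution
  cand <- which(!is.na(H) & H > min_height)
  empty <- data.frame(tree_id = integer(0), row = integer(0), col = integer(0),
                      x = numeric(0), y = numeric(0), height_m = numeric(0))
  if (!length(cand)) return(empty)

  r_m <- pmax(window$min_radius_m, window$a + window$b * H[cand])
  rad_cells <- r_m / res
  grp <- ceiling(rad_cells - 1e-9)   # group candidates by integer cell radius

  keep_strict <- integer(0)
  tie_cells <- integer(0)
  tie_rad <- numeric(0)
  for (g in sort(unique(grp))) {
    nm <- neighbourhood_max(H, g)
    in_g <- cand[grp == g]
    hv <- H[in_g]; mv <- nm[in_g]
    keep_strict <- c(keep_strict, in_g[hv > mv])
    ties <- hv == mv
    tie_cells <- c(tie_cells, in_g[ties])
    tie_rad <- c(tie_rad, rep(g, sum(ties)))
  }

  nr <- nrow(H); nc <- ncol(H)
  apex_rows <- ((keep_strict - 1L) %% nr) + 1L
  apex_cols <- ((keep_strict - 1L) %/% nr) + 1L
  apex_h <- H[keep_strict]

  # plateau handling: connected components (8-adjacency) of tied candidate
  # cells with equal height; a component is a treetop if some window
  # neighbour outside it exists (it is then strictly lower or NA)
  if (length(tie_cells)) {
    tset <- new.env(hash = TRUE)
    for (k in seq_along(tie_cells)) {
      assign(as.character(tie_cells[k]), tie_rad[k], envir = tset)
    }
    visited <- new.env(hash = TRUE)
    for (start in tie_cells) {
      skey <- as.character(start)
      if (!is.null(visited[[skey]])) next
      h0 <- H[start]
      comp <- integer(0)
      queue <- start
      visited[[skey]] <- TRUE
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        comp <- c(comp, cur)
        cr <- ((cur - 1L) %% nr) + 1L; cc <- ((cur - 1L) %/% nr) + 1L
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0L && dj == 0L) next
          rr <- cr + di; ccj <- cc + dj
          if (rr < 1L || rr > nr || ccj < 1L || ccj > nc) next
          nxt <- (ccj - 1L) * nr + rr
          nkey <- as.character(nxt)
          if (!is.null(visited[[nkey]])) next
          if (is.null(tset[[nkey]])) next
          if (!identical(H[nxt], h0)) next
          visited[[nkey]] <- TRUE
          queue <- c(queue, nxt)
        }
      }
      # any in-grid window neighbour outside the component?
      g <- tset[[skey]]
      rint <- ceiling(g)
      comp_r <- ((comp - 1L) %% nr) + 1L
      comp_c <- ((comp - 1L) %/% nr) + 1L
      compset <- new.env(hash = TRUE)
      for (cc2 in comp) assign(as.character(cc2), TRUE, envir = compset)
      has_outside <- FALSE
      for (k in seq_along(comp)) {
        for (di in -rint:rint) for (dj in -rint:rint) {
          if (di == 0L && dj == 0L) next
          if (di * di + dj * dj > g^2 + 1e-9) next
          rr <- comp_r[k] + di; ccj <- comp_c[k] + dj
          if (rr < 1L || rr > nr || ccj < 1L || ccj > nc) next
          if (is.null(compset[[as.character((ccj - 1L) * nr + rr)]])) {
            has_outside <- TRUE
            break
          }
        }
        if (has_outside) break
      }
      if (has_outside) {
        cen_r <- mean(comp_r); cen_c <- mean(comp_c)
        pick <- which.min((comp_r - cen_r)^2 + (comp_c - cen_c)^2)
        apex_rows <- c(apex_rows, comp_r[pick])
        apex_cols <- c(apex_cols, comp_c[pick])
        apex_h <- c(apex_h, h0)
      }
    }
  }

  if (!length(apex_h)) return(empty)
  ord <- order(apex_h, decreasing = TRUE)
  xy <- cell_to_xy(chm, apex_rows[ord], apex_cols[ord])
  data.frame(tree_id = seq_along(ord), row = apex_rows[ord],
             col = apex_cols[ord], x = xy$x, y = xy$y,
             height_m = apex_h[ord])
}

#' Delineate tree crowns by marker-based watershed
#'
#' Floods the inverted CHM from the treetop markers: cells above
#' `min_height` are processed in order of decreasing height and each is
#' attached to the crown of its highest already-labelled 8-neighbour, so
#' basins grow downhill from each apex and meet along valleys (the
#' equidistant ridge for symmetric neighbouring crowns). Cells not
#' reachable from any marker stay unlabelled; markers whose crown would
#' contain no cell above `min_height` are dropped.
#'
#' @param chm a [canopy_raster] canopy height model.
#' @param apexes data.frame from [detect_treetops()] (needs `row`, `col`).
#' @param min_height crowns are restricted to cells above this height (m).
#' @return A `crown_set`: data.frame with one row per crown (`tree_id`,
#'   `apex_row`, `apex_col`, `apex_x`, `apex_y`, `apex_height_m`,
#'   `n_cells`, `crown_area_m2`, and placeholders `density_ratio`,
#'   `height_bin`, `density_bin` filled by [add_crown_density()]), with the
#'   crown-label matrix in `attr(, "labels")` and the CHM geometry in
#'   `attr(, "geometry")`.
#' @export
segment_crowns <- function(chm, apexes, min_height = 2) {
  if (is.null(apexes) || nrow(apexes) == 0L) stop("need at least one apex")
  H <- chm$values
  nr <- nrow(H); nc <- ncol(H)
  if (any(apexes$row < 1L | apexes$row > nr | apexes$col < 1L | apexes$col > nc)) {
    stop("apex outside the CHM grid")
  }
  veg <- !is.na(H) & H > min_height
  lab <- matrix(0L, nr, nc)
  acell <- (apexes$col - 1L) * nr + apexes$row
  if (anyDuplicated(acell)) stop("duplicate apex cells")
  lab[acell] <- seq_len(nrow(apexes))
  lab[!veg] <- 0L  # spurious markers on sub-threshold cells are dropped

  cells <- which(veg)
  ord <- cells[order(H[cells], decreasing = TRUE)]
  Hf <- H; Hf[is.na(Hf)] <- -Inf
  repeat {
    changed <- FALSE
    for (cell in ord) {
      if (lab[cell] != 0L) next
      cr <- ((cell - 1L) %% nr) + 1L
      cc <- ((cell - 1L) %/% nr) + 1L
      best_lab <- 0L; best_h <- -Inf
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        rr <- cr + di; ccj <- cc + dj
        if (rr < 1L || rr > nr || ccj < 1L || ccj > nc) next
        ncell <- (ccj - 1L) * nr + rr
        l <- lab[ncell]
        if (l > 0L && Hf[ncell] > best_h) {
          best_h <- Hf[ncell]; best_lab <- l
        }
      }
      if (best_lab > 0L) {
        lab[cell] <- best_lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  keep <- which(tabulate(lab[lab > 0L], nbins = nrow(apexes)) > 0L)
  # relabel consecutively, preserving apex order
  new_id <- integer(nrow(apexes))
  new_id[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nr, nc)
  nz <- lab > 0L
  lab2[nz] <- new_id[lab[nz]]

  res <- chm$resolution
  n_cells <- tabulate(lab2[lab2 > 0L], nbins = length(keep))
  xy <- cell_to_xy(chm, apexes$row[keep], apexes$col[keep])
  crowns <- data.frame(
    tree_id = seq_along(keep),
    apex_row = apexes$row[keep], apex_col = apexes$col[keep],
    apex_x = xy$x, apex_y = xy$y,
    apex_height_m = H[(apexes$col[keep] - 1L) * nr + apexes$row[keep]],
    n_cells = n_cells,
    crown_area_m2 = n_cells * res^2,
    density_ratio = NA_real_,
    height_bin = NA_integer_, density_bin = NA_integer_,
    height_label = NA_character_, density_label = NA_character_
  )
  structure(crowns,
            labels = lab2,
            geometry = list(resolution = res, origin = chm$origin),
            min_height = min_height,
            class = c("crown_set", "data.frame"))
}

#' @export
print.crown_set <- function(x, ...) {
  cat(sprintf("<crown_set> %d crowns, area %.1f-%.1f m2, apex height %.1f-%.1f m\n",
              nrow(x), min(x$crown_area_m2), max(x$crown_area_m2),
              min(x$apex_height_m), max(x$apex_height_m)))
  if (!all(is.na(x$density_ratio))) {
    cat(sprintf("  density ratio %.2f-%.2f\n",
                min(x$density_ratio, na.rm = TRUE),
                max(x$density_ratio, na.rm = TRUE)))
  }
  NextMethod()
}

# Label raster of a crown set, as a canopy_raster (0 = background).
crown_label_raster <- function(crowns) {
  geom <- attr(crowns, "geometry")
  lab <- attr(crowns, "labels")
  lab_na <- lab
  lab_na[lab_na == 0L] <- NA_integer_
  canopy_raster(lab_na, geom$resolution, geom$origin, layer = "crown_labels")
}

#' Canopy density ratio of segmented crowns
#'
#' The foliage density metric: the ratio of vegetation returns in the
#' upper canopy (height above `upper_fraction` of the apex height) to all
#' vegetation returns inside the crown footprint,
#' `density = N_upper / (N_upper + N_lower)`, in `[0, 1]`. All return
#' numbers contribute with unit weight by default; `weight_by_height`
#' weights each return by its relative height instead, which is recorded
#' in the result metadata either way.
#'
#' @param cloud height-normalized point cloud.
#' @param crowns a [segment_crowns()] `crown_set` (all crowns measured).
#' @param upper_fraction fraction of apex height dividing upper from lower
#'   canopy (default 0.5).
#' @param weight_by_height logical; weight returns by relative height.
#' @return Numeric vector of density ratios, one per crown; crowns whose
#'   footprint contains no vegetation return raise an error.
#' @export
canopy_density <- function(cloud, crowns, upper_fraction = 0.5,
                           weight_by_height = FALSE) {
  stopifnot_scalar_number(upper_fraction, "upper_fraction", 1e-6, 1 - 1e-6)
  geom <- attr(crowns, "geometry")
  lab <- attr(crowns, "labels")
  ras <- canopy_raster(lab * 1.0, geom$resolution, geom$origin)
  v <- cloud[cloud$classification == "vegetation", , drop = FALSE]
  cell <- xy_to_cell(ras, v$x, v$y)
  ok <- !is.na(cell$row)
  lb <- lab[cbind(cell$row[ok], cell$col[ok])]
  z <- v$z[ok]
  inside <- lb > 0L
  lb <- lb[inside]; z <- z[inside]

  out <- numeric(nrow(crowns))
  for (i in seq_len(nrow(crowns))) {
    zi <- z[lb == crowns$tree_id[i]]
    if (!length(zi)) {
      stop(sprintf("crown %d contains no vegetation return", crowns$tree_id[i]))
    }
    cut <- upper_fraction * crowns$apex_height_m[i]
    w <- if (weight_by_height) zi / crowns$apex_height_m[i] else rep(1, length(zi))
    out[i] <- sum(w[zi > cut]) / sum(w)
  }
  out
}

#' Measure density and assign categories on a crown set
#'
#' Convenience step combining [canopy_density()] and [assign_category()];
#' crowns taller than the category grid's range keep `NA` bins.
#'
#' @inheritParams canopy_density
#' @param grid a [category_grid()].
#' @return The crown set with `density_ratio`, bins and labels filled and
#'   the density-metric definition recorded in `attr(, "density_meta")`.
#' @export
add_crown_density <- function(cloud, crowns, upper_fraction = 0.5,
                              weight_by_height = FALSE, grid = category_grid()) {
  crowns$density_ratio <- canopy_density(cloud, crowns, upper_fraction,
                                         weight_by_height)
  in_range <- crowns$apex_height_m > min(grid$height_breaks_m) &
    crowns$apex_height_m <= max(grid$height_breaks_m)
  if (any(in_range)) {
    cat_df <- assign_category(crowns$apex_height_m[in_range],
                              crowns$density_ratio[in_range], grid)
    crowns$height_bin[in_range] <- cat_df$height_bin
    crowns$density_bin[in_range] <- cat_df$density_bin
    crowns$height_label[in_range] <- cat_df$height_label
    crowns$density_label[in_range] <- cat_df$density_label
  }
  attr(crowns, "density_meta") <- list(upper_fraction = upper_fraction,
                                       weight_by_height = weight_by_height)
  crowns
}

#' The 100-category canopy height x density grid
#'
#' Ten height bins (2-3, 3-4, 4-6, 6-8, 8-10, 10-12, 12-14, 14-16, 16-18,
#' 18-20 m) crossed with ten density bins (0-0.1 through 0.9-1.0) give 100
#' canopy classes; every tree in the modelled range maps to exactly one.
#'
#' @return List of class `category_grid` with `height_breaks_m`,
#'   `density_breaks`, labels and `n_categories` (100).
#' @export
category_grid <- function() {
  hb <- c(2, 3, 4, 6, 8, 10, 12, 14, 16, 18, 20)
  db <- seq(0, 1, by = 0.1)
  structure(list(
    height_breaks_m = hb,
    density_breaks = db,
    height_labels = paste0(hb[-length(hb)], "-", hb[-1], "m"),
    density_labels = sprintf("%.1f-%.1f", db[-length(db)], db[-1]),
    n_categories = (length(hb) - 1L) * (length(db) - 1L)
  ), class = "category_grid")
}

#' Assign trees to height x density categories
#'
#' Bins are half-open `[lo, hi)` with the last bin closed on the right, so
#' a height of exactly 3 m falls in the 3-4 m bin and a density of exactly
#' 1 falls in the 0.9-1.0 bin. Heights at or below 2 m or above 20 m are
#' outside the modelled range and raise an error.
#'
#' @param height_m apex heights (m), vectorized.
#' @param density_ratio density ratios in `[0, 1]`, vectorized.
#' @param grid a [category_grid()].
#' @return data.frame with `height_bin`, `density_bin` (1-based indices),
#'   `height_label`, `density_label`, and `category` (1..100).
#' @export
assign_category <- function(height_m, density_ratio, grid = category_grid()) {
  hb <- grid$height_breaks_m; db <- grid$density_breaks
  if (any(!is.finite(height_m)) || any(height_m <= hb[1] | height_m > hb[length(hb)])) {
    stop(sprintf("height outside the modelled range (%g, %g]", hb[1], hb[length(hb)]))
  }
  if (any(!is.finite(density_ratio)) || any(density_ratio < 0 | density_ratio > 1)) {
    stop("density ratio must be in [0, 1]")
  }
  h_bin <- findInterval(height_m, hb, rightmost.closed = TRUE)
  d_bin <- findInterval(density_ratio, db, rightmost.closed = TRUE)
  d_bin[density_ratio == 0] <- 1L
  data.frame(
    height_bin = h_bin, density_bin = d_bin,
    height_label = grid$height_labels[h_bin],
    density_label = grid$density_labels[d_bin],
    category = (h_bin - 1L) * (length(db) - 1L) + d_bin
  )
}

#' Segment trees from a classified point cloud (full structural pipeline)
#'
#' One-call wrapper: drop noise, normalize heights, rasterize the CHM at
#' `resolution_m`, detect treetops, delineate crowns by watershed, measure
#' the density ratio and assign each tree to a height x density category.
#'
#' @param cloud classified point cloud (`x,y,z,return_number,classification`).
#' @param resolution_m CHM cell size (m).
#' @param min_height minimum tree height (m); vegetation at or below is
#'   excluded.
#' @param window a [window_spec] for treetop detection.
#' @param ground_res ground-model node spacing (m), see [normalize_heights()].
#' @return List with `cloud` (normalized), `chm`, `apexes`, `crowns`.
#' @export
segment_trees <- function(cloud, resolution_m = 0.5, min_height = 2,
                          window = window_spec(), ground_res = 2) {
  norm <- normalize_heights(cloud, grid_res = ground_res)
  chm <- rasterize_chm(norm, resolution_m)
  apexes <- detect_treetops(chm, window, min_height)
  if (nrow(apexes) == 0L) {
    stop("no treetops above ", min_height, " m detected")
  }
  crowns <- segment_crowns(chm, apexes, min_height)
  crowns <- add_crown_density(norm, crowns)
  list(cloud = norm, chm = chm, apexes = apexes, crowns = crowns)
}

#' Write a crown table as CSV
#'
#' @param crowns a `crown_set`.
#' @param path CSV file path.
#' @export
write_crowns_csv <- function(crowns, path) {
  cols <- c("tree_id", "apex_x", "apex_y", "apex_height_m", "crown_area_m2",
            "density_ratio", "height_bin", "density_bin",
            "height_label", "density_label")
  utils::write.csv(as.data.frame(crowns)[, cols], path, row.names = FALSE)
  invisible(path)
}
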