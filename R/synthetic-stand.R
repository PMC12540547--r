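#' Specification of a synthetic savanna stand
#'
#' Bundles the parameters from which [generate_stand()] draws a classified
#' point cloud with known per-tree ground truth. The defaults emulate a
#' semi-arid savanna dominated by 2-6 m trees: tree heights are drawn from
#' a mixture over the height classes 2-3, 3-4, 4-6, 6-8, 8-16 and 16-20 m
#' with weights 0.372, 0.282, 0.21, 0.089, 0.045 and 0.002, and crown
#' density ratios from a clamped normal centred on 0.58 so that most trees
#' fall in the 0.5-0.7 range.
#'
#' @param extent_m width and height of the stand in metres.
#' @param n_trees number of trees to place (>= 0).
#' @param height_law list with `breaks` (class edges, m) and `weights`
#'   (mixture weights, summing to 1); heights are uniform within a class.
#' @param density_law list with `mean` and `sd` of the true crown density
#'   ratio; draws are clamped to `[0.05, 0.95]`.
#' @param crown_radius_law list with `a`, `b`, `sd`: crown radius is
#'   `a + b * height` plus normal jitter, clamped to `[0.6, 3.5]` m.
#' @param min_tree_spacing_m minimum distance between tree apexes (m).
#' @param ground_point_density_per_m2 ground returns per square metre.
#' @param crown_point_density_per_m3 crown returns per cubic metre of
#'   crown volume (each crown gets at least 40 points).
#' @param terrain list with plane coefficients `z0`, `sx`, `sy` and an
#'   optional low-frequency relief `relief_amp` (m) and `relief_wavelength`
#'   (m); the default is a flat plane at 100 m elevation.
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @return A list of class `stand_spec`.
#' @seealso [generate_stand()]
#' @export
stand_spec <- function(extent_m = c(120, 120),
                       n_trees = 40,
                       height_law = list(
                         breaks = c(2, 3, 4, 6, 8, 16, 20),
                         weights = c(0.372, 0.282, 0.21, 0.089, 0.045, 0.002)
                       ),
                       density_law = list(mean = 0.58, sd = 0.12),
                       crown_radius_law = list(a = 0.5, b = 0.18, sd = 0.15),
                       min_tree_spacing_m = 4,
                       ground_point_density_per_m2 = 2,
                       crown_point_density_per_m3 = 30,
                       terrain = list(z0 = 100, sx = 0, sy = 0,
                                      relief_amp = 0, relief_wavelength = 60),
                       seed = 1L) {
  if (length(extent_m) != 2L || any(!is.finite(extent_m)) || any(extent_m <= 0)) {
    stop("`extent_m` must be two positive numbers")
  }
  stopifnot_scalar_number(n_trees, "n_trees", lo = 0)
  stopifnot_scalar_number(min_tree_spacing_m, "min_tree_spacing_m", lo = 0)
  stopifnot_scalar_number(ground_point_density_per_m2,
                          "ground_point_density_per_m2", lo = 0)
  stopifnot_scalar_number(crown_point_density_per_m3,
                          "crown_point_density_per_m3", lo = 0)
  w <- height_law$weights
  if (length(w) != length(height_law$breaks) - 1L || any(w < 0) ||
      abs(sum(w) - 1) > 1e-6) {
    stop("`height_law$weights` must be nonnegative, one per class, and sum to 1")
  }
  structure(
    list(extent_m = as.numeric(extent_m), n_trees = as.integer(n_trees),
         height_law = height_law, density_law = density_law,
         crown_radius_law = crown_radius_law,
         min_tree_spacing_m = min_tree_spacing_m,
         ground_point_density_per_m2 = ground_point_density_per_m2,
         crown_point_density_per_m3 = crown_point_density_per_m3,
         terrain = terrain, seed = as.integer(seed)),
    class = "stand_spec"
  )
}

# Terrain elevation (m a.s.l.) under a stand spec.
terrain_elevation <- function(spec, x, y) {
  tr <- spec$terrain
  z <- tr$z0 + tr$sx * x + tr$sy * y
  if ((tr$relief_amp %||% 0) != 0) {
    wl <- tr$relief_wavelength %||% 60
    z <- z + tr$relief_amp * sin(2 * pi * x / wl) * sin(2 * pi * y / wl)
  }
  z
}

# Dart-throwing apex placement honouring the minimum spacing.
place_apexes <- function(n, extent, spacing, margin) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  # quick infeasibility screen: disc packing cannot beat ~0.9 (hex) density
  if (n > 1L && spacing > 0) {
    usable <- prod(pmax(extent - 2 * margin, 0))
    if (n * pi * (spacing / 2)^2 > 0.9 * usable) {
      stop(sprintf("cannot place %d trees with %.1f m spacing in a %g x %g m extent",
                   n, spacing, extent[1], extent[2]), call. = FALSE)
    }
  }
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L; max_attempts <- 400L * n
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf("cannot place %d trees with %.1f m spacing in a %g x %g m extent",
                   n, spacing, extent[1], extent[2]), call. = FALSE)
    }
    px <- stats::runif(1, margin, extent[1] - margin)
    py <- stats::runif(1, margin, extent[2] - margin)
    if (length(xs) == 0L ||
        min((xs - px)^2 + (ys - py)^2) >= spacing^2) {
      xs <- c(xs, px); ys <- c(ys, py)
    }
  }
  cbind(xs, ys)
}

# Sample n points inside/on a paraboloid crown: apex at height h, radius r at
# the crown base plane. The crown surface is z(d) = h (1 - (d/r)^2). A
# Bernoulli(p) split fixes the fraction of points above h/2 so the density
# ratio of the sample is binomially centred on `p`. Roughly `surface_frac`
# of points sit on the surface (the laser's first returns); the rest fill
# the solid (later returns).
sample_crown_points <- function(n, h, r, p, z_min, surface_frac = 0.4,
                                surface_noise_sd = 0.03) {
  upper <- stats::runif(n) < p
  on_surface <- stats::runif(n) < surface_frac
  t_up <- 0.5 * sqrt(stats::runif(n))          # t = 1 - z/h in [0, 0.5]
  t0 <- 0.5; t1 <- max(0.5, 1 - z_min / h)
  t_low <- sqrt(t0^2 + stats::runif(n) * (t1^2 - t0^2))
  t <- ifelse(upper, t_up, pmin(t_low, 1 - 1e-6))
  z <- h * (1 - t)
  # radial position: on the surface d = r sqrt(t); interior uniform in disc
  d_surf <- r * sqrt(t)
  d_int <- r * sqrt(t) * sqrt(stats::runif(n))
  d <- ifelse(on_surface, d_surf, d_int)
  z <- ifelse(on_surface,
              pmin(h, z + stats::rnorm(n, 0, surface_noise_sd)),
              z)
  z <- pmax(z, z_min)
  ang <- stats::runif(n, 0, 2 * pi)
  data.frame(dx = d * cos(ang), dy = d * sin(ang), z = z,
             return_number = ifelse(on_surface, 1L, 2L))
}

#' Generate a classified savanna point cloud with known ground truth
#'
#' Simulates a discrete-return LiDAR acquisition over a synthetic stand:
#' ground returns on a smooth (optionally sloped or gently undulating)
#' terrain, plus one paraboloid crown per tree whose returns are sampled so
#' that the fraction of points in the upper half of the crown matches the
#' tree's true density ratio. Every point carries a return number and a
#' `ground`/`vegetation` classification. An explicit first return is always
#' placed at each tree apex (the treetop reflects the pulse), so the
#' canopy height model recovers apex heights exactly at cell resolution,
#' and no crown return ever exceeds the apex height.
#'
#' @param spec a [stand_spec].
#' @return A list with `cloud` (data.frame: `x`, `y`, `z`,
#'   `return_number`, `classification`) and `trees` (data.frame of ground
#'   truth: `tree_id`, `apex_x`, `apex_y`, `height_m`, `crown_radius_m`,
#'   `crown_shape`, `true_density_ratio`).
#' @export
generate_stand <- function(spec) {
  if (!inherits(spec, "stand_spec")) stop("`spec` must be a stand_spec")
  with_seed(spec$seed, {
    extent <- spec$extent_m
    # ground returns
    n_ground <- round(spec$ground_point_density_per_m2 * prod(extent))
    gx <- stats::runif(n_ground, 0, extent[1])
    gy <- stats::runif(n_ground, 0, extent[2])
    gz <- terrain_elevation(spec, gx, gy) + stats::rnorm(n_ground, 0, 0.02)
    ground <- data.frame(x = gx, y = gy, z = gz,
                         return_number = sample(c(1L, 2L), n_ground,
                                                replace = TRUE, prob = c(0.8, 0.2)),
                         classification = "ground")

    n <- spec$n_trees
    if (n == 0L) {
      trees <- data.frame(tree_id = integer(0), apex_x = numeric(0),
                          apex_y = numeric(0), height_m = numeric(0),
                          crown_radius_m = numeric(0),
                          crown_shape = character(0),
                          true_density_ratio = numeric(0))
      cloud <- ground
      rownames(cloud) <- NULL
      return(list(cloud = cloud, trees = trees))
    }

    hl <- spec$height_law
    cls <- sample.int(length(hl$weights), n, replace = TRUE, prob = hl$weights)
    heights <- stats::runif(n, hl$breaks[cls], hl$breaks[cls + 1L])
    crl <- spec$crown_radius_law
    radii <- clamp(crl$a + crl$b * heights + stats::rnorm(n, 0, crl$sd), 0.6, 3.5)
    dl <- spec$density_law
    dens <- clamp(stats::rnorm(n, dl$mean, dl$sd), 0.05, 0.95)

    apexes <- place_apexes(n, extent, spec$min_tree_spacing_m,
                           margin = min(extent) * 0.02 + max(radii))

    veg <- vector("list", n)
    for (i in seq_len(n)) {
      h <- heights[i]; r <- radii[i]
      z_min <- max(0.5, 0.12 * h)
      vol <- pi * r^2 * h / 2  # paraboloid solid volume
      npts <- max(40L, round(spec$crown_point_density_per_m3 * vol))
      pts <- sample_crown_points(npts, h, r, dens[i], z_min)
      base_z <- terrain_elevation(spec, apexes[i, 1], apexes[i, 2])
      veg[[i]] <- data.frame(
        x = apexes[i, 1] + c(0, pts$dx),
        y = apexes[i, 2] + c(0, pts$dy),
        z = base_z + c(h, pts$z),
        return_number = c(1L, pts$return_number),
        classification = "vegetation"
      )
    }
    cloud <- rbind(ground, do.call(rbind, veg))
    rownames(cloud) <- NULL
    trees <- data.frame(tree_id = seq_len(n), apex_x = apexes[, 1],
                        apex_y = apexes[, 2], height_m = heights,
                        crown_radius_m = radii, crown_shape = "paraboloid",
                        true_density_ratio = dens)
    list(cloud = cloud, trees = trees)
  })
}

#' Write / read a point cloud as XYZ CSV
#'
#' Columns `x,y,z,return_number,classification`; classification is one of
#' `ground`, `vegetation`, `noise`.
#'
#' @param cloud point-cloud data.frame.
#' @param path CSV file path.
#' @export
write_point_cloud <- function(cloud, path) {
  utils::write.csv(cloud, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  cloud <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "return_number", "classification")
  if (!all(need %in% names(cloud))) {
    stop("point-cloud CSV must have columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(cloud$classification), c("ground", "vegetation", "noise"))
  if (length(bad)) stop("unknown classification value(s): ", paste(bad, collapse = ", "))
  cloud
}
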