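#' Persistence-image configuration
#'
#' The descriptor is a pair of fixed-size rasters (one for H0, one for H1)
#' on the (birth, persistence) plane. Defaults follow the elemental
#' persistence-image protocol used for the surrogate: a 55 x 55 grid spanning
#' -0.10 to 3.5 Angstrom on both axes with a Gaussian spread of 3.0.
#'
#' @param resolution Pixels per axis (default 55).
#' @param spread Standard deviation of the Gaussian kernel (default 3.0),
#'   interpreted in `spread_units`.
#' @param spread_units Either `"pixel"` (default; the spread is measured in
#'   pixel widths, so 3.0 pixels of a 3.6-Angstrom window is about 0.196
#'   Angstrom) or `"angstrom"`.
#' @param lower,upper Window bounds in Angstrom on both axes (defaults -0.10
#'   and 3.5).
#' @param weighting Per-feature weight: `"persistence"` (default; weight =
#'   death - birth) or `"uniform"`.
#' @param lambda Electronegativity modulation coefficient (>= 0, default
#'   0.25): the spread of a feature whose defining edge joins elements with
#'   Pauling electronegativities chi_a, chi_b is
#'   `sigma * (1 + lambda * |chi_a - chi_b|)`.
#' @param truncated Policy for bars still alive at `r_max`: `"clip"`
#'   (default; death clipped to the window upper bound) or `"drop"`.
#' @return A list of class `image_config`.
#' @export
image_config <- function(resolution = 55, spread = 3.0,
                         spread_units = c("pixel", "angstrom"),
                         lower = -0.10, upper = 3.5,
                         weighting = c("persistence", "uniform"),
                         lambda = 0.25,
                         truncated = c("clip", "drop")) {
  spread_units <- match.arg(spread_units)
  weighting <- match.arg(weighting)
  truncated <- match.arg(truncated)
  stopifnot(resolution >= 1, upper > lower, spread > 0, lambda >= 0)
  structure(list(resolution = as.integer(resolution), spread = spread,
                 spread_units = spread_units, lower = lower, upper = upper,
                 weighting = weighting, lambda = lambda,
                 truncated = truncated),
            class = "image_config")
}

#' Gaussian spread in Angstrom implied by an image configuration
#'
#' @param config An [image_config()].
#' @return Base spread sigma in Angstrom.
#' @export
base_spread <- function(config) {
  if (config$spread_units == "pixel") {
    config$spread * (config$upper - config$lower) / config$resolution
  } else {
    config$spread
  }
}

#' Effective Gaussian spread of one feature
#'
#' The spread is widened multiplicatively by the electronegativity contrast
#' of the feature's defining edge: `sigma_eff = sigma * (1 + lambda *
#' |chi_a - chi_b|)`. Edges between identical elements keep the base spread.
#'
#' @param element_pair Character vector of two element symbols.
#' @param config An [image_config()].
#' @param table Element table.
#' @return Effective spread in Angstrom.
#' @export
effective_spread <- function(element_pair, config = image_config(),
                             table = element_table()) {
  chi <- electronegativity(element_pair, table)
  base_spread(config) * (1 + config$lambda * abs(chi[1] - chi[2]))
}

#' Convert a diagram to weighted (birth, persistence) points
#'
#' Applies the truncated-bar policy, drops any infinite bars, and maps each
#' remaining bar (b, d) to the point (b, d - b) with weight d - b (or 1 under
#' uniform weighting).
#'
#' @param diagram A `persistence_diagram`.
#' @param config An [image_config()].
#' @return data.frame with columns `order`, `birth`, `persistence`, `weight`,
#'   `elem_a`, `elem_b`.
#' @export
to_birth_persistence <- function(diagram, config = image_config()) {
  f <- diagram$features
  f <- f[is.finite(f$death), , drop = FALSE]
  if (config$truncated == "drop") {
    f <- f[!f$truncated, , drop = FALSE]
  } else if (any(f$truncated)) {
    f$death[f$truncated] <- pmin(f$death[f$truncated], config$upper)
  }
  pers <- pmax(f$death - f$birth, 0)
  data.frame(order = f$order, birth = f$birth, persistence = pers,
             weight = if (config$weighting == "persistence") pers else
               rep(1, nrow(f)),
             elem_a = f$elem_a, elem_b = f$elem_b, stringsAsFactors = FALSE)
}

#' Rasterize weighted persistence points into per-order pixel grids
#'
#' Each point deposits an isotropic Gaussian of standard deviation
#' [effective_spread()] centered at (birth, persistence); pixel values are
#' the weighted density at the pixel center times the pixel area, summed over
#' features of the same homological order.
#'
#' @param points data.frame from [to_birth_persistence()].
#' @param config An [image_config()].
#' @param table Element table.
#' @param structure_id Identifier stored on the image.
#' @return A list of class `persistence_image` with fields `structure_id`,
#'   `h0`, `h1` (resolution x resolution matrices) and `config`.
#' @export
rasterize <- function(points, config = image_config(),
                      table = element_table(), structure_id = "") {
  res <- config$resolution
  delta <- (config$upper - config$lower) / res
  centers <- config$lower + (seq_len(res) - 0.5) * delta
  grid_for <- function(ord) {
    g <- matrix(0, res, res)
    sel <- points[points$order == ord, , drop = FALSE]
    for (k in seq_len(nrow(sel))) {
      sig <- effective_spread(c(sel$elem_a[k], sel$elem_b[k]), config, table)
      gx <- stats::dnorm(centers, mean = sel$birth[k], sd = sig)
      gy <- stats::dnorm(centers, mean = sel$persistence[k], sd = sig)
      g <- g + sel$weight[k] * delta^2 * outer(gx, gy)
    }
    g
  }
  structure(list(structure_id = structure_id, h0 = grid_for(0L),
                 h1 = grid_for(1L), config = config),
            class = "persistence_image")
}

#' @export
print.persistence_image <- function(x, ...) {
  cat("<persistence_image>", x$structure_id, "-",
      x$config$resolution, "x", x$config$resolution,
      "per order; total mass", format(sum(x$h0) + sum(x$h1), digits = 4), "\n")
  invisible(x)
}

#' Featurize a point cloud as a flat elemental persistence-image vector
#'
#' Pipeline: Vietoris-Rips diagram, truncation policy, electronegativity-
#' weighted Gaussian rasterization, then concatenation of the H0 grid
#' followed by the H1 grid in row-major order. With the default 55 x 55
#' configuration the descriptor has length 6050. The vector is invariant
#' under translation, rotation and atom reordering of the cloud.
#'
#' @param cloud A [molecule_cloud()].
#' @param topo A [topo_config()].
#' @param image An [image_config()].
#' @return Numeric vector of length `2 * resolution^2`.
#' @export
featurize <- function(cloud, topo = topo_config(), image = image_config()) {
  diagram <- compute_diagram(cloud, topo)
  pts <- to_birth_persistence(diagram, image)
  img <- rasterize(pts, image, structure_id = cloud$id)
  c(as.vector(t(img$h0)), as.vector(t(img$h1)))
}

#' Featurize many clouds into a descriptor matrix
#'
#' @param clouds List of [molecule_cloud()] objects.
#' @param topo A [topo_config()].
#' @param image An [image_config()].
#' @return Matrix with one descriptor row per cloud, rownames = cloud ids.
#' @export
featurize_all <- function(clouds, topo = topo_config(),
                          image = image_config()) {
  X <- t(vapply(clouds, featurize, numeric(2 * image_config_len(image)),
                topo = topo, image = image))
  rownames(X) <- vapply(clouds, function(cl) cl$id, character(1))
  X
}

image_config_len <- function(config) config$resolution^2

#' Stable hash of an image configuration
#'
#' Used to detect train/predict featurization mismatches. A polynomial
#' rolling hash over the canonical key=value serialization of the
#' configuration.
#'
#' @param config An [image_config()].
#' @return Hexadecimal hash string.
#' @export
image_config_hash <- function(config) {
  keys <- sort(names(config))
  txt <- paste(sprintf("%s=%s", keys,
                       vapply(config[keys], function(v)
                         format(v, digits = 15), character(1))),
               collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
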