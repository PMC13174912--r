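#' Regular polygon point cloud
#'
#' `n` carbon atoms at the vertices of a planar regular n-gon with
#' nearest-neighbor distance `side`. The standard oracle input for ring
#' (H1) persistence: a hexagon of side s has exactly one H1 bar born at s.
#'
#' @param n Number of vertices (>= 3).
#' @param side Edge length in Angstrom.
#' @param id Structure id.
#' @return A [molecule_cloud()].
#' @export
regular_polygon_cloud <- function(n, side, id = sprintf("polygon%d", n)) {
  stopifnot(n >= 3, side > 0)
  radius <- side / (2 * sin(pi / n))
  theta <- 2 * pi * (seq_len(n) - 1) / n
  molecule_cloud(id, rep("C", n),
                 cbind(radius * cos(theta), radius * sin(theta), 0))
}

#' Synthetic calix[4]arene-like structure
#'
#' Idealized geometry exercising every pipeline stage: four planar
#' 6-membered carbon rings (bond length 1.40 Angstrom) arranged around a
#' square of bridge atoms, each ring tilted out of the bridge plane with a
#' sign pattern set by the conformation (cone `++++`, partial cone `+++-`,
#' 1,2-alternate `++--`, 1,3-alternate `+-+-`). One hydroxyl-like oxygen per
#' ring provides heteroatom edges for the elemental descriptor; optional
#' linear carbon chains of `substituent_len` atoms extend from the para
#' position. Gaussian coordinate noise is added with the given seed. The
#' returned atom map feeds [classify_conformation()].
#'
#' @param conformation One of `"cone"`, `"partial_cone"`, `"alt12"`,
#'   `"alt13"`.
#' @param family Scaffold family; sets the bridge element (calix C, aza N,
#'   oxa O, thia S).
#' @param substituent_len Number of chain atoms on each para position
#'   (default 0).
#' @param noise Coordinate noise standard deviation in Angstrom (default 0).
#' @param seed RNG seed for the noise.
#' @param id Structure id.
#' @return List with `cloud` ([molecule_cloud()]), `atom_map` (fields
#'   `rings`, `bridges`), `family` and `conformation`.
#' @export
synthetic_calixarene <- function(conformation = c("cone", "partial_cone",
                                                  "alt12", "alt13"),
                                 family = c("calix", "aza", "oxa", "thia"),
                                 substituent_len = 0, noise = 0, seed = 1,
                                 id = NULL) {
  conformation <- match.arg(conformation)
  family <- match.arg(family)
  signs <- switch(conformation,
                  cone = c(1, 1, 1, 1),
                  partial_cone = c(1, 1, 1, -1),
                  alt12 = c(1, 1, -1, -1),
                  alt13 = c(1, -1, 1, -1))
  bridge_elem <- c(calix = "C", aza = "N", oxa = "O", thia = "S")[[family]]
  if (is.null(id)) id <- paste(family, conformation, sep = "_")
  bond <- 1.40
  ring_radius <- 3.5      # macrocycle radius of the ring centers
  bridge_radius <- 3.0
  tilt <- 40 * pi / 180   # ring tilt out of the bridge plane

  elements <- character(0)
  coords <- NULL
  rings <- vector("list", 4)
  for (i in 1:4) {
    phi <- (i - 1) * pi / 2
    r_hat <- c(cos(phi), sin(phi), 0)
    t_hat <- c(-sin(phi), cos(phi), 0)
    normal <- cos(tilt) * r_hat + signs[i] * sin(tilt) * c(0, 0, 1)
    e1 <- t_hat
    e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
            normal[3] * e1[1] - normal[1] * e1[3],
            normal[1] * e1[2] - normal[2] * e1[1])
    center <- ring_radius * r_hat
    ang <- 2 * pi * (0:5) / 6
    ring_pts <- t(vapply(ang, function(a) {
      center + bond * (cos(a) * e1 + sin(a) * e2)
    }, numeric(3)))
    rings[[i]] <- nrow(coords %||% matrix(0, 0, 3)) + 1:6
    coords <- rbind(coords, ring_pts)
    elements <- c(elements, rep("C", 6))
    # hydroxyl-like oxygen on the innermost ring atom, pointing inward
    inner <- ring_pts[which.min(rowSums(ring_pts[, 1:2]^2)), ]
    coords <- rbind(coords, inner - 1.36 * r_hat)
    elements <- c(elements, "O")
    if (substituent_len > 0) {
      outer_idx <- which.max(rowSums(ring_pts[, 1:2]^2))
      dir <- ring_pts[outer_idx, ] - center
      dir <- dir / sqrt(sum(dir^2))
      for (k in seq_len(substituent_len)) {
        coords <- rbind(coords, ring_pts[outer_idx, ] + 1.5 * k * dir)
        elements <- c(elements, "C")
      }
    }
  }
  bridges <- integer(4)
  for (i in 1:4) {
    phi <- (i - 0.5) * pi / 2
    coords <- rbind(coords, bridge_radius * c(cos(phi), sin(phi), 0))
    elements <- c(elements, bridge_elem)
    bridges[i] <- nrow(coords)
  }
  if (noise > 0) {
    coords <- coords + with_local_seed(seed,
      matrix(stats::rnorm(length(coords), 0, noise), nrow(coords), 3))
  }
  list(cloud = molecule_cloud(id, elements, coords),
       atom_map = list(rings = rings, bridges = bridges),
       family = family, conformation = conformation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic study set of calixarene-like structures
#'
#' Families are drawn uniformly; conformations are drawn with weights
#' (0.60, 0.04, 0.01, 0.35) for cone / partial cone / 1,2-alternate /
#' 1,3-alternate, mirroring the strong dominance of cone and 1,3-alternate
#' geometries among relaxed calix[4]arenes. Substituent chain lengths vary
#' from 0 to 3 atoms and every structure carries 0.05 Angstrom coordinate
#' noise so descriptors vary continuously.
#'
#' @param n Number of structures.
#' @param seed RNG seed.
#' @param noise Coordinate noise sd in Angstrom (default 0.05).
#' @param prefix Structure-id prefix (default `"syn"`); use distinct
#'   prefixes for disjoint sets (e.g. training vs. screening pool).
#' @return List with `structures` (list of [synthetic_calixarene()]
#'   results) and `manifest` (data.frame of id, family, site, substituent,
#'   conformation).
#' @export
synthetic_study_set <- function(n, seed = 1, noise = 0.05, prefix = "syn") {
  draws <- with_local_seed(seed, {
    data.frame(
      family = sample(.families, n, replace = TRUE),
      conformation = sample(c("cone", "partial_cone", "alt12", "alt13"), n,
                            replace = TRUE,
                            prob = c(0.60, 0.04, 0.01, 0.35)),
      sub_len = sample(0:3, n, replace = TRUE),
      sub_seed = sample.int(2^30, n)
    )
  })
  structures <- lapply(seq_len(n), function(i) {
    synthetic_calixarene(draws$conformation[i], draws$family[i],
                         substituent_len = draws$sub_len[i],
                         noise = noise, seed = draws$sub_seed[i],
                         id = sprintf("%s%04d", prefix, i))
  })
  manifest <- data.frame(
    structure_id = vapply(structures, function(s) s$cloud$id, character(1)),
    family = draws$family,
    site = ifelse(draws$sub_len > 0, "para", "none"),
    substituent = ifelse(draws$sub_len > 0,
                         strrep("C", draws$sub_len), ""),
    conformation = draws$conformation,
    stringsAsFactors = FALSE)
  list(structures = structures, manifest = manifest)
}

#' Synthetic adsorption-enthalpy labels linear in descriptor pixels
#'
#' Labels are `y_i = w . PI(x_i) + b + eps_i` with `eps ~ N(0, noise_sd)`
#' and `w` sparse over a declared pixel subset (the `n_active` pixels with
#' the highest descriptor variance across the set). Weights are scaled so
#' the noise-free signal has standard deviation `signal_sd`, giving labels
#' in a realistic adsorption-enthalpy range around `intercept`. The ground
#' truth (active pixels, weights, intercept) is returned so recovery tests
#' can verify against it.
#'
#' @param X Descriptor matrix (rows = structures), e.g. from
#'   [featurize_all()].
#' @param noise_sd Label noise sd in kcal/mol (default 0.3).
#' @param seed RNG seed.
#' @param n_active Number of active pixels (default 40).
#' @param signal_sd Noise-free signal sd in kcal/mol (default 2).
#' @param intercept Mean enthalpy level in kcal/mol (default -5).
#' @return List with `y`, `active` (pixel indices), `w` (weights on those
#'   pixels), `b` (intercept) and `noise_sd`.
#' @export
synthetic_labels <- function(X, noise_sd = 0.3, seed = 1, n_active = 40,
                             signal_sd = 2, intercept = -5) {
  X <- as.matrix(X)
  v <- apply(X, 2, stats::var)
  active <- order(v, decreasing = TRUE)[seq_len(min(n_active, ncol(X)))]
  out <- with_local_seed(seed, {
    w <- stats::rnorm(length(active))
    signal <- as.numeric(X[, active, drop = FALSE] %*% w)
    s <- stats::sd(signal)
    if (is.finite(s) && s > 0) {
      w <- w * signal_sd / s
      signal <- signal * signal_sd / s
    } else {
      w <- rep(0, length(active))
      signal <- rep(0, nrow(X))
    }
    y <- intercept + signal - mean(signal) +
      stats::rnorm(nrow(X), 0, noise_sd)
    list(y = y, w = w)
  })
  list(y = out$y, active = active, w = out$w, b = intercept,
       noise_sd = noise_sd)
}

#' Write a fixture set to disk
#'
#' XYZ files, a manifest CSV and (when labels are supplied) a ground-truth
#' JSON sidecar.
#'
#' @param set Result of [synthetic_study_set()].
#' @param dir Output directory (created if needed).
#' @param labels Optional result of [synthetic_labels()].
#' @return Invisibly, `dir`.
#' @export
write_fixture_set <- function(set, dir, labels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in set$structures) {
    write_xyz(s$cloud, file.path(dir, paste0(s$cloud$id, ".xyz")))
  }
  manifest <- set$manifest
  manifest$delta_h <- if (is.null(labels)) "" else labels$y
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(labels) && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(active = labels$active, w = labels$w, b = labels$b,
           noise_sd = labels$noise_sd),
      file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}
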