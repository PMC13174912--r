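#' CO2 adsorption enthalpy from component enthalpies
#'
#' `dH = H_complex - H_host - H_guest` at 298.15 K; negative values mean
#' favorable binding.
#'
#' @param h_complex Enthalpy of the host + CO2 complex (kcal/mol).
#' @param h_host Enthalpy of the empty host (kcal/mol).
#' @param h_guest Enthalpy of free CO2 (kcal/mol).
#' @return Adsorption enthalpy in kcal/mol.
#' @export
adsorption_enthalpy <- function(h_complex, h_host, h_guest) {
  stopifnot(all(is.finite(c(h_complex, h_host, h_guest))))
  h_complex - h_host - h_guest
}

#' Rank a candidate pool by predicted adsorption enthalpy
#'
#' Most favorable (most negative) predictions first; ties broken by
#' candidate id so the ranking is a stable total order. The pool must have
#' been featurized under the model's image configuration.
#'
#' @param model A `surrogate_model`.
#' @param X Pool descriptor matrix.
#' @param ids Candidate identifiers, one per row of `X`.
#' @param config_hash Hash of the configuration used to featurize `X`;
#'   checked against the model's.
#' @return data.frame with columns `candidate_id`, `predicted_dh`, `rank`,
#'   ordered by rank.
#' @export
rank_candidates <- function(model, X, ids, config_hash = model$config_hash) {
  X <- as.matrix(X)
  stopifnot(length(ids) == nrow(X))
  pred <- stats::predict(model, X, config_hash = config_hash)
  ord <- order(pred, ids)
  data.frame(candidate_id = as.character(ids)[ord],
             predicted_dh = pred[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Biased stratified validation sample
#'
#' Splits ranked candidates into enthalpy strata by signed boundaries
#' (default -5 and -7 kcal/mol: weakest stratum predicted dH > -5, middle
#' -7 < dH <= -5, strongest dH <= -7) and draws a seeded uniform sample
#' without replacement within each stratum. The default counts (3, 3, 5)
#' bias the 11-structure draw toward strong binders.
#'
#' @param ranked data.frame from [rank_candidates()].
#' @param boundaries Two decreasing signed boundaries in kcal/mol.
#' @param counts Draws per stratum, weakest first.
#' @param seed Sampling seed.
#' @param families Optional family filter applied before sampling; requires
#'   a `family` column in `ranked`.
#' @return Subset of `ranked` with a `stratum` column, ordered by rank.
#' @export
stratified_validation_sample <- function(ranked, boundaries = c(-5, -7),
                                         counts = c(3, 3, 5), seed = 1,
                                         families = NULL) {
  stopifnot(length(boundaries) == 2, boundaries[1] > boundaries[2],
            length(counts) == 3)
  if (!is.null(families)) {
    if (is.null(ranked$family)) stop("family filter requires a family column")
    ranked <- ranked[ranked$family %in% families, , drop = FALSE]
  }
  stratum <- ifelse(ranked$predicted_dh > boundaries[1], 1L,
                    ifelse(ranked$predicted_dh > boundaries[2], 2L, 3L))
  picks <- with_local_seed(seed, {
    unlist(lapply(1:3, function(s) {
      avail <- which(stratum == s)
      if (length(avail) < counts[s]) {
        stop("stratum ", s, " (", c("dH > ", "dH <= ", "dH <= ")[s],
             c(boundaries[1], boundaries[1], boundaries[2])[s],
             " kcal/mol) has only ", length(avail), " candidates; need ",
             counts[s])
      }
      sample(avail, counts[s])
    }))
  })
  out <- ranked[picks, , drop = FALSE]
  out$stratum <- stratum[picks]
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Augment the training set and retrain with a fresh grid search
#'
#' Appends newly labeled records to the training data (duplicate ids are an
#' error), reruns the full grid search with the one-standard-error rule on
#' the union, and refits. Provenance tags are preserved so each row's origin
#' (initial set vs. augmentation round) stays auditable.
#'
#' @param data List with `X` (descriptors), `y` (labels), `ids`,
#'   `provenance` (character tags), `config_hash`.
#' @param new_X,new_y,new_ids New labeled records (may be empty).
#' @param provenance Tag for the new records (e.g. `"augmentation_1"`).
#' @param alpha_grid,gamma_grid,k,seed Passed to [grid_search_one_se()].
#' @return List with the merged `data`, the fitted `model` and the grid
#'   `search` result.
#' @export
augment_and_retrain <- function(data, new_X = NULL, new_y = numeric(0),
                                new_ids = character(0),
                                provenance = "augmentation_1",
                                alpha_grid = default_grids()$alpha,
                                gamma_grid = default_grids()$gamma,
                                k = 3, seed = 1) {
  if (length(new_ids) > 0) {
    if (any(new_ids %in% data$ids)) {
      stop("duplicate structure ids in augmentation: ",
           paste(intersect(new_ids, data$ids), collapse = ", "))
    }
    stopifnot(nrow(new_X) == length(new_y), length(new_y) == length(new_ids))
    data$X <- rbind(data$X, new_X)
    data$y <- c(data$y, new_y)
    data$ids <- c(data$ids, new_ids)
    data$provenance <- c(data$provenance, rep(provenance, length(new_ids)))
  }
  search <- grid_search_one_se(data$X, data$y, alpha_grid, gamma_grid,
                               k = k, seed = seed)
  model <- fit_surrogate(data$X, data$y, search$alpha, search$gamma,
                         config_hash = data$config_hash)
  list(data = data, model = model, search = search)
}

# Best-fit unit normal of a set of points (smallest principal direction).
plane_normal <- function(pts) {
  centered <- sweep(pts, 2, colMeans(pts))
  v <- svd(centered)$v[, 3]
  v / sqrt(sum(v^2))
}

#' Classify the conformation of a calix[4]arene-like host
#'
#' Fits a least-squares plane to the four bridge atoms, orients each aryl
#' ring's best-fit normal so that its in-plane component points outward from
#' the macrocycle center, and reads the cyclic pattern of the normals'
#' signs along the bridge-plane normal: all four alike is `cone`, a 3-1
#' split `partial_cone`, adjacent pairs `alt12` and alternating signs
#' `alt13`. A ring whose normal is nearly parallel to the bridge plane
#' (|cos| below `threshold`) makes the geometry `undetermined`.
#'
#' @param cloud A [molecule_cloud()].
#' @param atom_map List with `rings` (list of four integer vectors of ring
#'   member indices, in cyclic order around the macrocycle) and `bridges`
#'   (integer vector of the four bridge atoms).
#' @param threshold Minimum |cosine| between ring normal and bridge-plane
#'   normal (default 0.1).
#' @return One of `"cone"`, `"partial_cone"`, `"alt12"`, `"alt13"`,
#'   `"undetermined"`.
#' @export
classify_conformation <- function(cloud, atom_map, threshold = 0.1) {
  stopifnot(inherits(cloud, "molecule_cloud"))
  if (length(atom_map$rings) != 4 || length(atom_map$bridges) != 4) {
    stop("atom map must identify 4 rings and 4 bridge atoms")
  }
  idx <- c(unlist(atom_map$rings), atom_map$bridges)
  if (any(idx < 1 | idx > nrow(cloud$coords))) {
    stop("atom map refers to atoms outside the cloud")
  }
  bridge_pts <- cloud$coords[atom_map$bridges, , drop = FALSE]
  u <- plane_normal(bridge_pts)
  center <- colMeans(bridge_pts)
  signs <- vapply(atom_map$rings, function(ring) {
    pts <- cloud$coords[ring, , drop = FALSE]
    n <- plane_normal(pts)
    radial <- colMeans(pts) - center
    radial_in_plane <- radial - sum(radial * u) * u
    rn <- sqrt(sum(radial_in_plane^2))
    if (rn < 1e-8) return(NA_real_)
    align <- sum(n * radial_in_plane) / rn
    # the outward reference itself is unreliable when the ring normal is
    # (anti)parallel to the bridge-plane normal
    if (abs(align) < threshold) return(NA_real_)
    if (align < 0) n <- -n
    sum(n * u)
  }, numeric(1))
  if (any(is.na(signs)) || any(abs(signs) < threshold)) {
    return("undetermined")
  }
  s <- signs > 0
  n_up <- sum(s)
  if (n_up %in% c(0, 4)) return("cone")
  if (n_up %in% c(1, 3)) return("partial_cone")
  if (s[1] == s[2] || s[2] == s[3]) "alt12" else "alt13"
}

#' Box-plot style summaries of enthalpies by family and conformation
#'
#' Quartiles use linear interpolation (quantile type 7); whiskers extend to
#' the most extreme data within 1.5 interquartile ranges of the box, and
#' points beyond are listed as outliers. Empty groups are omitted.
#'
#' @param records data.frame with columns `family`, `conformation`,
#'   `delta_h` and optionally `structure_id` (used to name outliers).
#' @return data.frame with one row per nonempty (family, conformation)
#'   group: `n`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `n_outliers`, `outlier_ids` (comma-separated).
#' @export
summarize_by_group <- function(records) {
  stopifnot(all(c("family", "conformation", "delta_h") %in% names(records)))
  records <- records[is.finite(records$delta_h), , drop = FALSE]
  key <- interaction(records$family, records$conformation, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    x <- g$delta_h
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- x >= lo_fence & x <= hi_fence
    ids <- if (!is.null(g$structure_id)) g$structure_id else
      as.character(seq_along(x))
    data.frame(family = g$family[1], conformation = g$conformation[1],
               n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
               n_outliers = sum(!inside),
               outlier_ids = paste(ids[!inside], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$family, out$conformation), , drop = FALSE]
}

#' Write a deterministic screening report
#'
#' Fixed six-decimal formatting so identical inputs produce byte-identical
#' files.
#'
#' @param ranked data.frame from [rank_candidates()].
#' @param selected Optional data.frame from
#'   [stratified_validation_sample()]; marks selected rows and their strata.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_screening_report <- function(ranked, selected = NULL, path) {
  stratum <- rep("", nrow(ranked))
  sel <- rep("FALSE", nrow(ranked))
  if (!is.null(selected)) {
    m <- match(selected$candidate_id, ranked$candidate_id)
    stratum[m] <- as.character(selected$stratum)
    sel[m] <- "TRUE"
  }
  lines <- c("candidate_id,predicted_dh,rank,stratum,selected",
             sprintf("%s,%.6f,%d,%s,%s", ranked$candidate_id,
                     ranked$predicted_dh, ranked$rank, stratum, sel))
  writeLines(lines, path)
  invisible(path)
}
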