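#' Topology configuration
#'
#' @param r_max Maximum Vietoris-Rips filtration radius in Angstrom. The
#'   default, 7 Angstrom, is twice the persistence-image upper bound so that
#'   ring features dying beyond the plotted window still register before
#'   clipping.
#' @param drop_infinite Drop the single infinite connected-component bar from
#'   diagrams (default `TRUE`).
#' @param include_hydrogens Keep hydrogen atoms in the point cloud (default
#'   `TRUE`).
#' @return A list of class `topo_config`.
#' @export
topo_config <- function(r_max = 7.0, drop_infinite = TRUE,
                        include_hydrogens = TRUE) {
  stopifnot(r_max > 0)
  structure(list(r_max = r_max, drop_infinite = drop_infinite,
                 include_hydrogens = include_hydrogens),
            class = "topo_config")
}

#' Euclidean pairwise distance matrix of a point cloud
#'
#' @param cloud A [molecule_cloud()].
#' @return Symmetric matrix of Euclidean distances in Angstrom.
#' @export
pairwise_distances <- function(cloud) {
  stopifnot(inherits(cloud, "molecule_cloud"))
  n <- length(cloud$elements)
  if (n == 0) stop("empty cloud has no distance matrix")
  as.matrix(stats::dist(cloud$coords))
}

#' Zeroth-order (connected-component) persistence
#'
#' All components are born at radius 0 and merge at the single-linkage
#' heights, i.e. the edge weights of a minimum spanning tree of the distance
#' matrix. Chemically these merge heights track interatomic (bond) distances.
#' Returns the N-1 finite bars plus one infinite bar; each finite bar carries
#' the element pair of its merging edge.
#'
#' @param distances Symmetric distance matrix.
#' @param elements Element symbols, one per matrix row.
#' @return data.frame with columns `order`, `birth`, `death`, `elem_a`,
#'   `elem_b`, `truncated` (`death = Inf` for the essential bar).
#' @export
h0_persistence <- function(distances, elements) {
  n <- nrow(distances)
  stopifnot(length(elements) == n)
  if (n == 1) {
    return(data.frame(order = 0L, birth = 0, death = Inf,
                      elem_a = elements[1], elem_b = elements[1],
                      truncated = FALSE, stringsAsFactors = FALSE))
  }
  mst <- cpp_h0_persistence(distances)
  data.frame(order = 0L,
             birth = 0,
             death = c(mst$death, Inf),
             elem_a = c(elements[mst$i], elements[n]),
             elem_b = c(elements[mst$j], elements[n]),
             truncated = FALSE, stringsAsFactors = FALSE)
}

#' First-order (ring) persistence of the Vietoris-Rips clique complex
#'
#' Edges up to `r_max` and their clique triangles form the filtered complex;
#' bars come from Z/2 boundary-matrix column reduction with simplices ordered
#' by (filtration value, dimension, lexicographic vertex tuple). Each bar
#' carries the element pair of its birth edge. Bars still alive at `r_max`
#' are reported with `death = r_max` and `truncated = TRUE`.
#'
#' @param distances Symmetric distance matrix.
#' @param elements Element symbols, one per matrix row.
#' @param r_max Maximum filtration radius (> 0).
#' @return data.frame with columns `order`, `birth`, `death`, `elem_a`,
#'   `elem_b`, `truncated`.
#' @export
h1_persistence <- function(distances, elements, r_max = topo_config()$r_max) {
  if (r_max <= 0) stop("r_max must be positive")
  n <- nrow(distances)
  stopifnot(length(elements) == n)
  if (n < 3) {
    return(empty_features())
  }
  bars <- cpp_h1_persistence(distances, r_max)
  if (nrow(bars) == 0) return(empty_features())
  out <- data.frame(order = 1L, birth = bars$birth, death = bars$death,
                    elem_a = elements[bars$i], elem_b = elements[bars$j],
                    truncated = bars$truncated, stringsAsFactors = FALSE)
  out[order(out$birth, out$death, out$elem_a, out$elem_b), , drop = FALSE]
}

empty_features <- function() {
  data.frame(order = integer(0), birth = numeric(0), death = numeric(0),
             elem_a = character(0), elem_b = character(0),
             truncated = logical(0), stringsAsFactors = FALSE)
}

#' Persistence diagram of a molecular point cloud
#'
#' Concatenates the H0 (connectivity) and H1 (ring) features of the cloud's
#' Vietoris-Rips filtration. The infinite H0 bar is dropped by default.
#'
#' @param cloud A [molecule_cloud()].
#' @param config A [topo_config()].
#' @return A list of class `persistence_diagram` with fields `structure_id`,
#'   `features` (data.frame) and `r_max`.
#' @export
compute_diagram <- function(cloud, config = topo_config()) {
  stopifnot(inherits(cloud, "molecule_cloud"))
  if (!config$include_hydrogens) {
    keep <- cloud$elements != "H"
    cloud <- molecule_cloud(cloud$id, cloud$elements[keep],
                            cloud$coords[keep, , drop = FALSE])
  }
  d <- pairwise_distances(cloud)
  h0 <- h0_persistence(d, cloud$elements)
  h1 <- h1_persistence(d, cloud$elements, config$r_max)
  if (config$drop_infinite) h0 <- h0[is.finite(h0$death), , drop = FALSE]
  feats <- rbind(h0, h1)
  rownames(feats) <- NULL
  structure(list(structure_id = cloud$id, features = feats,
                 r_max = config$r_max),
            class = "persistence_diagram")
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat("<persistence_diagram>", x$structure_id, "-",
      sum(x$features$order == 0), "H0 bars,",
      sum(x$features$order == 1), "H1 bars (r_max =", x$r_max, "A)\n")
  invisible(x)
}

#' Write persistence diagrams to CSV
#'
#' Columns: `structure_id, order, birth, death, elem_a, elem_b, truncated`.
#'
#' @param diagrams A `persistence_diagram` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_diagrams <- function(diagrams, path) {
  if (inherits(diagrams, "persistence_diagram")) diagrams <- list(diagrams)
  rows <- lapply(diagrams, function(d) {
    cbind(structure_id = d$structure_id, d$features)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
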