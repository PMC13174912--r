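# Independent oracles used across the suite.
#
# vr_oracle: exhaustive persistence of the Vietoris-Rips clique complex up
# to dimension 2 by reduction of the FULL boundary matrix (vertices, edges
# and triangles in one global (filtration, dimension, lexicographic) order),
# deliberately different from the package's triangle-only reduction path.

vr_oracle <- function(dist, rmax) {
  n <- nrow(dist)
  simplices <- list()
  for (v in seq_len(n)) {
    simplices[[length(simplices) + 1]] <- list(verts = v, filt = 0, dim = 0)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (dist[i, j] <= rmax) {
        simplices[[length(simplices) + 1]] <-
          list(verts = c(i, j), filt = dist[i, j], dim = 1)
      }
    }
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        if (dist[i, j] > rmax) next
        for (k in (j + 1):n) {
          if (dist[i, k] <= rmax && dist[j, k] <= rmax) {
            simplices[[length(simplices) + 1]] <-
              list(verts = c(i, j, k),
                   filt = max(dist[i, j], dist[i, k], dist[j, k]), dim = 2)
          }
        }
      }
    }
  }
  key <- sapply(simplices, function(s) {
    sprintf("%.12f|%d|%s", s$filt, s$dim,
            paste(sprintf("%03d", s$verts), collapse = ","))
  })
  simplices <- simplices[order(key)]
  m <- length(simplices)
  index_of <- new.env(hash = TRUE)
  for (s in seq_len(m)) {
    assign(paste(simplices[[s]]$verts, collapse = ","), s, envir = index_of)
  }
  boundary <- function(s) {
    v <- simplices[[s]]$verts
    if (length(v) == 1) return(integer(0))
    faces <- lapply(seq_along(v), function(drop) v[-drop])
    sort(vapply(faces, function(f)
      get(paste(f, collapse = ","), envir = index_of), integer(1)))
  }
  cols <- lapply(seq_len(m), boundary)
  pivot <- rep(NA_integer_, m)   # row -> owning column
  for (jcol in seq_len(m)) {
    col <- cols[[jcol]]
    while (length(col) > 0) {
      low <- col[length(col)]
      if (is.na(pivot[low])) break
      other <- cols[[pivot[low]]]
      col <- sort(setdiff(union(col, other), intersect(col, other)))
    }
    cols[[jcol]] <- col
    if (length(col) > 0) pivot[col[length(col)]] <- jcol
  }
  h0_death <- numeric(0)
  h1 <- data.frame(birth = numeric(0), death = numeric(0),
                   truncated = logical(0))
  paired_row <- which(!is.na(pivot))
  for (row in paired_row) {
    jcol <- pivot[row]
    b <- simplices[[row]]$filt
    d <- simplices[[jcol]]$filt
    if (simplices[[row]]$dim == 0) {
      h0_death <- c(h0_death, d)
    } else if (simplices[[row]]$dim == 1 && d > b) {
      h1 <- rbind(h1, data.frame(birth = b, death = d, truncated = FALSE))
    }
  }
  # essential (unpaired positive) simplices within the truncated filtration
  is_positive <- vapply(seq_len(m), function(s) length(cols[[s]]) == 0,
                        logical(1))
  for (s in seq_len(m)) {
    if (is_positive[s] && is.na(pivot[s]) && simplices[[s]]$dim == 1 &&
        rmax > simplices[[s]]$filt) {
      h1 <- rbind(h1, data.frame(birth = simplices[[s]]$filt, death = rmax,
                                 truncated = TRUE))
    }
  }
  list(h0_deaths = sort(h0_death), h1 = h1[order(h1$birth, h1$death), ])
}

random_cloud <- function(n, seed, scale = 3) {
  set.seed(seed)
  molecule_cloud(sprintf("rnd%d_%d", n, seed),
                 sample(c("C", "N", "O", "H"), n, replace = TRUE),
                 matrix(runif(3 * n, 0, scale), n, 3))
}

expect_oracle_match <- function(cloud, rmax) {
  d <- pairwise_distances(cloud)
  oracle <- vr_oracle(d, rmax)
  h0 <- h0_persistence(d, cloud$elements)
  expect_equal(sort(h0$death[is.finite(h0$death)]), oracle$h0_deaths,
               tolerance = 1e-12)
  h1 <- h1_persistence(d, cloud$elements, rmax)
  got <- h1[order(h1$birth, h1$death), c("birth", "death", "truncated")]
  want <- oracle$h1
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want, tolerance = 1e-12)
}
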