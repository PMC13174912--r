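toy_model <- function(n = 40, p = 6, seed = 20) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  y <- as.numeric(X %*% seq(-3, 2, length.out = p)) - 5
  list(X = X, y = y,
       model = fit_surrogate(X, y, alpha = 0.01, gamma = 0.5,
                             config_hash = "cfg"))
}

test_that("adsorption enthalpy is the component difference", {
  expect_equal(adsorption_enthalpy(-100, -90, -10), 0)
  expect_equal(adsorption_enthalpy(-108.37, -90, -10), -8.37)
  set.seed(21)
  for (k in 1:20) {
    h <- rnorm(3, -50, 30)
    expect_equal(adsorption_enthalpy(h[1], h[2], h[3]), h[1] - h[2] - h[3])
  }
  expect_error(adsorption_enthalpy(NaN, 0, 0))
})

test_that("candidate ranking is ascending with stable id tie-breaks", {
  tm <- toy_model()
  ids <- sprintf("cand%02d", seq_len(nrow(tm$X)))
  ranked <- rank_candidates(tm$model, tm$X, ids)
  expect_equal(ranked$rank, seq_len(nrow(tm$X)))
  expect_true(all(diff(ranked$predicted_dh) >= 0))

  one <- rank_candidates(tm$model, tm$X[5, , drop = FALSE], "only")
  expect_equal(one$candidate_id, "only")

  # equal predictions fall back to id order
  dup <- rbind(tm$X[1, ], tm$X[1, ])
  r2 <- rank_candidates(tm$model, dup, c("zzz", "aaa"))
  expect_equal(r2$candidate_id, c("aaa", "zzz"))

  expect_error(rank_candidates(tm$model, tm$X, ids, config_hash = "other"),
               "mismatch")
})

test_that("a planted strong binder is ranked first", {
  set.seed(22)
  X <- matrix(runif(200), 40, 5)
  y <- -2 - 6 * X[, 1]        # known label function of the descriptor
  model <- fit_surrogate(X, y, alpha = 1e-8, gamma = 1, config_hash = "cfg")
  # pool drawn from the training design, with the strongest binder planted
  pool <- X[c(11:25, which.min(y)), ]
  ranked <- rank_candidates(model, pool, sprintf("p%02d", 1:16))
  expect_equal(ranked$candidate_id[1], "p16")
})

test_that("stratified sampling draws the configured counts per stratum", {
  ranked <- data.frame(candidate_id = sprintf("c%03d", 1:60),
                       predicted_dh = seq(-9.5, -2, length.out = 60),
                       rank = 1:60, stringsAsFactors = FALSE)
  sel <- stratified_validation_sample(ranked, seed = 7)
  expect_equal(nrow(sel), 11)
  expect_equal(as.vector(table(sel$stratum)), c(3L, 3L, 5L))
  expect_true(all(sel$predicted_dh[sel$stratum == 1] > -5))
  expect_true(all(sel$predicted_dh[sel$stratum == 2] <= -5 &
                    sel$predicted_dh[sel$stratum == 2] > -7))
  expect_true(all(sel$predicted_dh[sel$stratum == 3] <= -7))
  expect_false(anyDuplicated(sel$candidate_id) > 0)
  expect_identical(stratified_validation_sample(ranked, seed = 7), sel)

  single <- stratified_validation_sample(ranked, counts = c(0, 0, 1), seed = 1)
  expect_equal(nrow(single), 1)
  expect_lte(single$predicted_dh, -7)

  weakless <- ranked[ranked$predicted_dh <= -7, ]
  expect_error(stratified_validation_sample(weakless, seed = 1),
               "stratum 1")
})

test_that("augmentation grows the dataset and refuses duplicate ids", {
  set.seed(23)
  data <- list(X = matrix(runif(345 * 4), 345, 4), y = rnorm(345, -5, 2),
               ids = sprintf("s%03d", 1:345),
               provenance = rep("initial", 345), config_hash = "cfg")
  grids <- list(a = c(0.1, 1), g = c(0.2))
  fit1 <- augment_and_retrain(data, matrix(runif(44), 11, 4), rnorm(11, -8, 1),
                              sprintf("v%02d", 1:11), "augmentation_1",
                              grids$a, grids$g, seed = 2)
  expect_equal(nrow(fit1$data$X), 356)
  expect_equal(sum(fit1$data$provenance == "augmentation_1"), 11)
  fit2 <- augment_and_retrain(fit1$data, matrix(runif(20), 5, 4),
                              rnorm(5, -9, 1), sprintf("w%02d", 1:5),
                              "augmentation_2", grids$a, grids$g, seed = 2)
  expect_equal(nrow(fit2$data$X), 361)
  expect_error(
    augment_and_retrain(fit2$data, matrix(runif(4), 1, 4), -9, "v01",
                        alpha_grid = grids$a, gamma_grid = grids$g),
    "duplicate")

  # empty augmentation: identical data, identical metrics under one seed
  same <- augment_and_retrain(data, alpha_grid = grids$a, gamma_grid = grids$g,
                              seed = 5)
  same2 <- augment_and_retrain(data, alpha_grid = grids$a, gamma_grid = grids$g,
                               seed = 5)
  expect_identical(same$search$metrics$mean, same2$search$metrics$mean)
  expect_equal(nrow(same$data$X), 345)
})

test_that("conformation classification handles all labels and rigid motion", {
  for (cf in c("cone", "partial_cone", "alt12", "alt13")) {
    fix <- synthetic_calixarene(cf)
    expect_equal(classify_conformation(fix$cloud, fix$atom_map), cf)
  }
  # arbitrary rotation + translation leaves the label unchanged
  fix <- synthetic_calixarene("cone")
  ang <- c(0.4, 1.1, 2.3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -cos(ang[3] - pi / 2),
                 cos(ang[3]), 0, 0, 0, 1), 3, 3)
  moved <- molecule_cloud("m", fix$cloud$elements,
                          sweep(fix$cloud$coords %*% Rx %*% Rz, 2,
                                c(10, -4, 3), `+`))
  expect_equal(classify_conformation(moved, fix$atom_map), "cone")

  # atom reordering with a consistent map
  n <- length(fix$cloud$elements)
  set.seed(24)
  perm <- sample(n)
  inv <- order(perm)
  permuted <- molecule_cloud("p", fix$cloud$elements[perm],
                             fix$cloud$coords[perm, ])
  map2 <- list(rings = lapply(fix$atom_map$rings, function(r) inv[r]),
               bridges = inv[fix$atom_map$bridges])
  expect_equal(classify_conformation(permuted, map2), "cone")

  # coplanar degenerate geometry is undetermined
  flat <- synthetic_calixarene("cone")
  flat_coords <- flat$cloud$coords
  flat_coords[, 3] <- 0
  flat_cloud <- molecule_cloud("flat", flat$cloud$elements, flat_coords)
  expect_equal(classify_conformation(flat_cloud, flat$atom_map),
               "undetermined")

  expect_error(classify_conformation(fix$cloud,
                                     list(rings = fix$atom_map$rings[1:3],
                                          bridges = fix$atom_map$bridges)),
               "4 rings")
})

test_that("group summaries reproduce box-plot statistics", {
  g1 <- data.frame(family = "calix", conformation = "cone", delta_h = -4.2)
  s1 <- summarize_by_group(g1)
  expect_equal(s1$median, -4.2)
  expect_equal(s1$q1, -4.2)
  expect_equal(s1$q3, -4.2)
  expect_equal(s1$n_outliers, 0)

  g2 <- data.frame(structure_id = sprintf("x%d", 1:5), family = "thia",
                   conformation = "cone", delta_h = c(1, 2, 3, 4, 100))
  s2 <- summarize_by_group(g2)
  q <- quantile(c(1, 2, 3, 4, 100), c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(s2$q1, q[1])
  expect_equal(s2$q3, q[2])
  expect_equal(s2$n_outliers, 1)
  expect_equal(s2$outlier_ids, "x5")
  expect_equal(s2$whisker_hi, 4)

  set.seed(25)
  many <- data.frame(
    structure_id = sprintf("m%03d", 1:80),
    family = sample(c("calix", "aza", "oxa", "thia"), 80, replace = TRUE),
    conformation = sample(c("cone", "alt13"), 80, replace = TRUE),
    delta_h = rnorm(80, -5, 2))
  sm <- summarize_by_group(many)
  expect_equal(sum(sm$n), 80)  # groups partition the dataset
  expect_true(all(sm$q1 <= sm$median & sm$median <= sm$q3))
  expect_true(all(sm$whisker_lo >= sm$q1 - 1.5 * (sm$q3 - sm$q1) - 1e-12))
  expect_true(all(sm$whisker_hi <= sm$q3 + 1.5 * (sm$q3 - sm$q1) + 1e-12))
})
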