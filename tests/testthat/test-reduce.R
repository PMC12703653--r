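# E3 alignment, inertia-tensor orientation features, k selection, k-means
# and representative selection.

test_that("E3 alignment leaves the anchor fixed and registers copies", {
  ts <- make_toy_system(2, seed = 1)
  lib <- torsion_library(fallback = three_peak_rule())
  ens <- enumerate_conformers(ts$degrader, ts$constraints, lib, prune = NULL)
  models <- assemble_ensemble(ens, ts$poi_complex, ts$e3_complex)
  al <- align_on_e3(models)
  cl <- vapply(models, `[[`, numeric(1), "clash_score")
  rk <- vapply(models, `[[`, integer(1), "rank")
  expect_equal(al$anchor, order(cl, rk)[1])
  expect_identical(al$models[[al$anchor]]$e3$atoms,
                   models[[al$anchor]]$e3$atoms)
  # a rigidly moved copy of the anchor aligns back exactly
  moved <- models[[al$anchor]]
  tr <- with_seed_rotation(55)
  moved$e3 <- transform_complex(moved$e3, tr)
  moved$poi <- transform_complex(moved$poi, tr)
  moved$rank <- max(rk) + 1L
  al2 <- align_on_e3(c(models, list(moved)))
  last <- al2$models[[length(al2$models)]]
  expect_equal(protaconf:::.all_calpha(last$e3),
               protaconf:::.all_calpha(al2$models[[al2$anchor]]$e3),
               tolerance = 1e-6)
})

test_that("inertia features recover box axes and are equivariant", {
  # axis-aligned 2 x 4 x 8 box of unit masses: principal axes must be the
  # coordinate axes; smallest moment about the longest (z) extent
  g <- as.matrix(expand.grid(x = c(-1, 1), y = c(-2, 2), z = c(-4, 4)))
  f <- inertia_features(g)
  expect_equal(abs(matrix(f, 3, 3)), diag(3)[, 3:1], tolerance = 1e-9)
  expect_false(attr(f, "degenerate"))
  # rotation equivariance after sign fixing
  set.seed(8)
  R <- random_rotation()
  f2 <- inertia_features(g %*% t(R))
  for (k in 1:3) {
    v <- as.numeric(R %*% matrix(f, 3, 3)[, k])
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(f2[(3 * k - 2):(3 * k)], v, tolerance = 1e-9)
  }
  # translation invariance
  expect_equal(as.numeric(inertia_features(sweep(g, 2, c(3, -7, 2), `+`))),
               as.numeric(f), tolerance = 1e-9)
  # near-spherical cloud flags degeneracy
  cube <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  expect_true(attr(inertia_features(cube), "degenerate"))
  expect_error(inertia_features(cbind(1:5, 0, 0)), "collinear")
})

test_that("silhouette-based k selection finds planted blob counts", {
  set.seed(21)
  blob <- function(center, n = 15, sd = 0.01)
    sweep(matrix(rnorm(n * length(center), sd = sd), n), 2, center, `+`)
  x3 <- rbind(blob(c(0, 0)), blob(c(3, 0)), blob(c(0, 3)))
  expect_equal(as.integer(choose_k(x3, 2:6, seed = 5)), 3L)
  x2 <- rbind(blob(c(0, 0)), blob(c(4, 4)))
  expect_equal(as.integer(choose_k(x2, 2:5, seed = 5)), 2L)
  # tiny input: any valid deterministic answer
  x4 <- matrix(c(0, 0, 0, 0.1, 5, 5, 5, 5.1), 4, 2, byrow = TRUE)
  k1 <- choose_k(x4, 2:3, seed = 7)
  k2 <- choose_k(x4, 2:3, seed = 7)
  expect_identical(as.integer(k1), as.integer(k2))
  expect_true(as.integer(k1) %in% 2:3)
})

test_that("seeded k-means recovers planted labels exactly", {
  set.seed(33)
  centers <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(0, 0, 5))
  truth <- rep(1:4, each = 12)
  x <- centers[truth, ] + matrix(rnorm(48 * 3, sd = 0.05), 48, 3)
  cm <- cluster_models(x, 4, seed = 2)
  # adjusted-Rand-style check: identical partitions up to label names
  tab <- table(cm$assignments, truth)
  expect_equal(sum(tab > 0), 4L)
  expect_true(all(colSums(tab > 0) == 1))
  # permuting rows gives the same partition as a set
  perm <- sample(nrow(x))
  cm2 <- cluster_models(x[perm, ], 4, seed = 2)
  key1 <- unname(split(seq_len(nrow(x)), cm$assignments))
  key2 <- unname(split(perm, cm2$assignments))
  expect_setequal(lapply(key1, sort), lapply(key2, sort))
  # k = n puts every point in its own cluster
  cm_n <- cluster_models(x[1:6, ], 6, seed = 1)
  expect_equal(sort(cm_n$assignments), 1:6)
})

test_that("representatives maximise the compromise score per cluster", {
  mk <- function(cl, su, rank, raw) {
    m <- list(clash_score = cl, surface_score = su, rank = rank,
              raw_clash = raw, raw_surface = raw)
    class(m) <- "ternary_model"; m
  }
  models <- list(mk(1, 10, 1L, 0), mk(10, 1, 2L, 9),  # cluster 1
                 mk(2, 9, 3L, 1), mk(2, 2, 4L, 1))    # cluster 2
  sel <- select_representatives(models, c(1L, 1L, 2L, 2L),
                                compromise_weights(0.62, 0.38))
  expect_equal(sel$k, 2L)
  expect_equal(sel$representatives, c(1L, 3L))
  # singleton cluster selects its only member; ties break by raw clash
  sel2 <- select_representatives(models[c(1, 1, 2)], c(1L, 2L, 2L),
                                 compromise_weights())
  expect_equal(sel2$representatives[1], 1L)
})

test_that("end-to-end reduction recovers planted POI orientations", {
  # five distinct POI orientations, each jittered 20 times
  ts <- make_toy_system(2, seed = 4)
  base <- assemble_ternary(ts$degrader, ts$poi_complex, ts$e3_complex)
  set.seed(19)
  rots <- replicate(5, random_rotation(), simplify = FALSE)
  models <- list(); truth <- integer()
  rank <- 1L
  for (g in seq_along(rots)) {
    for (j in 1:20) {
      m <- base
      ctr <- colMeans(protaconf:::.all_calpha(base$poi))
      jitter <- protaconf:::.rotation_about_axis(
        c(1, 0, 0) / 1, rnorm(1, sd = 0.002))
      R <- rots[[g]] %*% jitter
      shift <- ctr - as.numeric(R %*% ctr)
      m$poi <- transform_complex(base$poi, rigid_transform(R, shift))
      m$rank <- rank; rank <- rank + 1L
      m$raw_clash <- 0L; m$raw_surface <- 20L
      m$clash_score <- 1.0; m$surface_score <- 1.0
      models[[length(models) + 1L]] <- m
      truth <- c(truth, g)
    }
  }
  red <- reduce_ensemble(models, window = plausibility_window(),
                         k_range = 2:8, seed = 3)
  expect_equal(red$k, 5L)
  tab <- table(red$selection$assignments, truth)
  expect_true(all(colSums(tab > 0) == 1))
  expect_equal(sum(tab > 0), 5L)
  expect_length(red$selection$representatives, 5L)
  # representatives all lie inside the plausibility window
  for (i in red$selection$representatives) {
    expect_lte(red$models[[i]]$clash_score, 1.1)
    expect_lte(red$models[[i]]$surface_score, 1.2)
  }
})
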