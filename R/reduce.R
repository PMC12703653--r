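# Ensemble reduction: align every model's E3 onto the lowest-clash model,
# describe each POI orientation by the concatenated principal axes of its
# inertia tensor (9-vector), select k by silhouette (elbow tie-break), run
# seeded k-means++ with restarts, and pick one representative per cluster by
# compromise-score.

#' Align all models on the E3 of the lowest-clash anchor
#'
#' The anchor is the model with the lowest clash-score (ties broken by lower
#' rank) and is left untouched; every other model is rigidly transformed so
#' its E3 Calpha set superposes the anchor's. Model lists must share a
#' common E3 definition (same residues), as produced by
#' \code{\link{assemble_ensemble}}.
#'
#' @param models list of \code{ternary_model} with scores set.
#' @return list: \code{models} (transformed), \code{anchor} (index).
#' @export
align_on_e3 <- function(models) {
  stopifnot(length(models) >= 1L)
  cl <- vapply(models, `[[`, numeric(1), "clash_score")
  rk <- vapply(models, `[[`, integer(1), "rank")
  anchor <- order(cl, rk)[1]
  ref <- .all_calpha(models[[anchor]]$e3)
  out <- lapply(seq_along(models), function(i) {
    if (i == anchor) return(models[[i]])
    m <- models[[i]]
    mob <- .all_calpha(m$e3)
    sup <- kabsch_superpose(mob, ref)
    m$e3 <- transform_complex(m$e3, sup$transform)
    m$poi <- transform_complex(m$poi, sup$transform)
    m$degrader <- set_coords(m$degrader,
                             transform_coords(m$degrader$coords,
                                              sup$transform))
    m
  })
  list(models = out, anchor = anchor)
}

.all_calpha <- function(px) {
  a <- px$atoms[px$atoms$atom == "CA", ]
  a <- a[order(a$chain, a$resno), ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Inertia-tensor orientation feature of a POI
#'
#' Inertia tensor of the heavy atoms (standard atomic masses) about the
#' centroid; the three unit eigenvectors, sorted by ascending eigenvalue,
#' are sign-fixed (largest-magnitude component positive) and concatenated
#' into a 9-vector. Translation-invariant and rotation-equivariant. A
#' near-degenerate spectrum (two eigenvalues within 1e-6 relative) sets
#' attribute \code{"degenerate"}; the feature is still returned.
#'
#' @param coords n x 3 heavy-atom coordinates (n >= 3, non-collinear).
#' @param masses atomic masses, recycled (default: unit masses; pass
#'   \code{atomic_mass(elements)} for physical weighting).
#' @return numeric length-9 vector with attribute \code{"degenerate"}.
#' @export
inertia_features <- function(coords, masses = 1) {
  x <- as.matrix(coords)
  stopifnot(ncol(x) == 3L)
  if (nrow(x) < 3L) stop("need at least 3 atoms")
  m <- rep_len(as.numeric(masses), nrow(x))
  ctr <- colSums(x * m) / sum(m)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) stop("atoms are collinear")
  r2 <- rowSums(xc^2)
  I <- diag(sum(m * r2), 3) - crossprod(xc * sqrt(m))  # sum m (r^2 I - r r^T)
  # crossprod(xc * sqrt(m)) = sum_i m_i r_i r_i^T
  eig <- eigen(I, symmetric = TRUE)
  ord <- order(eig$values)            # ascending
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  degenerate <- any(abs(diff(vals)) < 1e-6 * pmax(abs(vals[-1]), 1))
  feat <- numeric(9)
  for (k in 1:3) {
    v <- vecs[, k]
    v <- v / sqrt(sum(v^2))
    top <- which.max(abs(v))
    if (v[top] < 0) v <- -v
    feat[(3 * k - 2):(3 * k)] <- v
  }
  attr(feat, "degenerate") <- degenerate
  feat
}

#' Orientation feature matrix of a model list
#' @param models list of \code{ternary_model}
#' @return n x 9 matrix (one row per model), attribute "degenerate" flags
#' @export
model_orientation_features <- function(models) {
  rows <- lapply(models, function(m) {
    xyz <- protein_heavy_coords(m$poi)
    elem <- m$poi$atoms$elem[m$poi$atoms$elem != "H"]
    inertia_features(xyz, atomic_mass(elem))
  })
  out <- do.call(rbind, rows)
  attr(out, "degenerate") <- vapply(rows, attr, logical(1), "degenerate")
  out
}

# seeded k-means++ initialisation + stats::kmeans polish
.kmeanspp <- function(x, k, seed) {
  with_local_seed(seed, {
    n <- nrow(x)
    centers <- matrix(NA_real_, k, ncol(x))
    idx <- sample.int(n, 1)
    centers[1, ] <- x[idx, ]
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in seq_len(k - 1L) + 1L) {
      p <- d2 / sum(d2)
      idx <- sample.int(n, 1, prob = p)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
    centers
  })
}

#' Seeded k-means clustering of orientation features
#'
#' k-means++ initialisation, \code{restarts} independent seeded restarts,
#' Lloyd polish via \code{stats::kmeans}, best within-cluster inertia kept.
#' Deterministic for a fixed seed and independent of input row order (up to
#' label permutation).
#'
#' @param features n x d feature matrix.
#' @param k number of clusters (k <= n).
#' @param seed RNG seed (default 1).
#' @param restarts number of k-means++ restarts (default 10).
#' @return list: \code{assignments} (integer labels), \code{centers},
#'   \code{inertia}.
#' @export
cluster_models <- function(features, k, seed = 1L, restarts = 10L) {
  x <- as.matrix(features)
  stopifnot(k >= 1L, k <= nrow(x))
  if (k == nrow(x)) {
    return(list(assignments = seq_len(nrow(x)), centers = x,
                inertia = 0))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    ctr <- .kmeanspp(x, k, seed = as.integer(seed) * 131L + r)
    if (anyDuplicated(ctr)) ctr <- ctr + (r - 1) * 1e-9
    km <- suppressWarnings(stats::kmeans(x, centers = ctr, iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(assignments = as.integer(best$cluster), centers = best$centers,
       inertia = best$tot.withinss)
}

#' Select the number of clusters
#'
#' Scans \code{k_range}, clustering at each k, and picks the k with the
#' highest mean silhouette width; near-ties (within \code{tie_tol}) are
#' broken toward the elbow of the within-cluster inertia curve (largest
#' second difference). Deterministic under the seed.
#'
#' @param features n x d feature matrix (n >= 4).
#' @param k_range candidate k values within [2, n-1] (default 2:min(50, n-1)).
#' @param seed RNG seed.
#' @param tie_tol silhouette tie tolerance (default 1e-6).
#' @return chosen k, with attribute \code{"diagnostics"} (k, silhouette,
#'   inertia table).
#' @export
choose_k <- function(features, k_range = NULL, seed = 1L, tie_tol = 1e-6) {
  x <- as.matrix(features)
  n <- nrow(x)
  stopifnot(n >= 4L)
  if (is.null(k_range)) k_range <- 2:min(50L, n - 1L)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 2L), all(k_range <= n - 1L))
  dmat <- stats::dist(x)
  sil <- numeric(length(k_range)); inert <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    cm <- cluster_models(x, k_range[i], seed = seed)
    inert[i] <- cm$inertia
    s <- cluster::silhouette(cm$assignments, dmat)
    sil[i] <- mean(s[, "sil_width"])
  }
  best_sil <- max(sil)
  tied <- which(sil >= best_sil - tie_tol)
  if (length(tied) > 1L && length(k_range) >= 3L) {
    # elbow: largest second difference of inertia (interior points only)
    d2 <- rep(-Inf, length(k_range))
    for (i in 2:(length(k_range) - 1L))
      d2[i] <- inert[i - 1] - 2 * inert[i] + inert[i + 1]
    tied <- tied[order(d2[tied], decreasing = TRUE)]
  }
  k <- k_range[tied[1]]
  attr(k, "diagnostics") <- data.frame(k = k_range, silhouette = sil,
                                       inertia = inert)
  k
}

#' Pick one representative model per cluster
#'
#' Per cluster, the model maximising the compromise-score under the given
#' weights; ties broken by lower raw clash count, then lower rank.
#'
#' @param models list of \code{ternary_model} with normalised scores.
#' @param assignments integer cluster label per model.
#' @param weights a \code{\link{compromise_weights}}.
#' @return a \code{cluster_selection}: \code{k}, \code{assignments},
#'   \code{representatives} (model indices, one per cluster, ordered by
#'   cluster label), \code{compromise} (score per model), \code{weights}.
#' @export
select_representatives <- function(models, assignments,
                                   weights = compromise_weights()) {
  stopifnot(length(models) == length(assignments))
  us <- unit_scores(models)
  sc <- compromise_score(us$clash, us$surface, weights)
  raw_cl <- vapply(models, `[[`, numeric(1), "raw_clash")
  rk <- vapply(models, `[[`, integer(1), "rank")
  labs <- sort(unique(assignments))
  reps <- vapply(labs, function(lb) {
    idx <- which(assignments == lb)
    cand <- idx[sc[idx] == max(sc[idx])]
    if (length(cand) > 1L) cand <- cand[order(raw_cl[cand], rk[cand])]
    cand[1]
  }, integer(1))
  structure(list(k = length(labs), assignments = as.integer(assignments),
                 representatives = reps, compromise = sc, weights = weights),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("<cluster_selection> k = %d, weights (clash %.2f, surface %.2f)\n",
              x$k, x$weights$w_clash, x$weights$w_surface))
  cat("  representatives (model indices):",
      paste(x$representatives, collapse = ", "), "\n")
  invisible(x)
}

#' Full ensemble-reduction pipeline
#'
#' Mirrors the published order of operations: plausibility-window filter,
#' E3 alignment on the lowest-clash anchor, inertia-tensor orientation
#' features, silhouette/elbow k-selection, seeded k-means, compromise-weight
#' optimisation against a reference score density, and representative
#' selection.
#'
#' @param models list of scored \code{ternary_model}.
#' @param window a \code{\link{plausibility_window}}.
#' @param k_range candidate cluster counts (see \code{\link{choose_k}});
#'   a single value skips selection.
#' @param reference_scores data.frame with [0,1] columns \code{clash},
#'   \code{surface} used for the KDE reference; defaults to the unit scores
#'   of the window-passing models themselves (prospective mode).
#' @param alpha regularisation strength (default 0.1).
#' @param seed RNG seed for clustering.
#' @return list: \code{selection} (a \code{cluster_selection}),
#'   \code{models} (window-passing, E3-aligned), \code{k}, \code{weights},
#'   \code{anchor}.
#' @export
reduce_ensemble <- function(models, window = plausibility_window(),
                            k_range = NULL, reference_scores = NULL,
                            alpha = 0.1, seed = 1L) {
  passing <- filter_plausible(models, window)
  if (length(passing) < 4L)
    stop("too few window-passing models to reduce (", length(passing), ")")
  al <- align_on_e3(passing)
  feats <- model_orientation_features(al$models)
  k <- if (!is.null(k_range) && length(k_range) == 1L) as.integer(k_range)
       else choose_k(feats, k_range, seed = seed)
  cm <- cluster_models(feats, as.integer(k), seed = seed)
  if (is.null(reference_scores)) {
    us <- unit_scores(al$models)
    reference_scores <- data.frame(clash = us$clash, surface = us$surface)
  }
  dens <- fit_score_density(reference_scores)
  weights <- if (length(unique(cm$assignments)) >= 2L)
    optimize_weights(al$models, cm$assignments, dens, alpha)
  else compromise_weights(0.5, 0.5, alpha)
  sel <- select_representatives(al$models, cm$assignments, weights)
  list(selection = sel, models = al$models, k = as.integer(k),
       weights = weights, anchor = al$anchor)
}
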