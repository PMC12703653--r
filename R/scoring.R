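# Ensemble-level score handling: min-max normalisation to the 1-10 scale,
# the plausibility window, [0,1] rescaling, the compromise-score, reflected
# Gaussian KDE reference densities and regularised weight optimisation.

#' Normalise raw scores within an ensemble to the 1-10 scale
#'
#' Linear map with the ensemble minimum at 1 and maximum at 10. A constant
#' input maps every value to 1 (the best end), so an ensemble of uniformly
#' clash-free models is not penalised.
#' @param values numeric vector of raw scores (length >= 1)
#' @export
normalize_ensemble <- function(values) {
  stopifnot(length(values) >= 1L)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1.0, length(values)))
  1 + 9 * (values - rng[1]) / (rng[2] - rng[1])
}

#' Rescale 1-10 scores onto [0, 1]
#'
#' Min-max onto the unit interval; constant input maps to 0. Composing
#' \code{\link{normalize_ensemble}} with this equals a direct min-max of the
#' raw values onto [0, 1].
#' @param values numeric vector on the 1-10 scale
#' @export
rescale_to_unit <- function(values) {
  stopifnot(length(values) >= 1L)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0.0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' The plausibility window
#'
#' Normalised-score region enriched in experiment-like ternary models:
#' clash-score at most \code{clash_max} and surface-score at most
#' \code{surface_max} on the 1-10 scale. The defaults follow the range
#' observed for experimental ternary complexes (clash within 1.0-1.1,
#' surface within 1.0-1.2).
#' @param clash_max default 1.1
#' @param surface_max default 1.2
#' @export
plausibility_window <- function(clash_max = 1.1, surface_max = 1.2) {
  stopifnot(clash_max >= 1, surface_max >= 1)
  structure(list(clash_max = clash_max, surface_max = surface_max),
            class = "plausibility_window")
}

#' Filter models through the plausibility window
#' @param models list of \code{ternary_model} with normalised scores set
#' @param window a \code{\link{plausibility_window}}
#' @return the passing subset, rank order preserved
#' @export
filter_plausible <- function(models, window = plausibility_window()) {
  keep <- vapply(models, function(m)
    m$clash_score <= window$clash_max &&
    m$surface_score <= window$surface_max, logical(1))
  models[keep]
}

#' Compromise weights
#' @param w_clash,w_surface non-negative, summing to 1
#' @param alpha regularisation strength used when optimising (default 0.1)
#' @export
compromise_weights <- function(w_clash = 0.5, w_surface = 1 - w_clash,
                               alpha = 0.1) {
  stopifnot(w_clash >= 0, w_surface >= 0,
            abs(w_clash + w_surface - 1) < 1e-9, alpha >= 0)
  structure(list(w_clash = w_clash, w_surface = w_surface, alpha = alpha),
            class = "compromise_weights")
}

#' The compromise-score
#'
#' S = 1 - (w_clash * S_clash + w_surface * (1 - S_surface)) on
#' [0,1]-rescaled scores: higher is better, rewarding low clash and high
#' surface contact simultaneously.
#' @param s_clash,s_surface scores on the [0, 1] scale
#' @param weights a \code{\link{compromise_weights}}
#' @export
compromise_score <- function(s_clash, s_surface,
                             weights = compromise_weights()) {
  1 - (weights$w_clash * s_clash + weights$w_surface * (1 - s_surface))
}

#' Reference score densities by reflected Gaussian KDE
#'
#' Independent univariate densities for the clash and surface scores on
#' [0, 1], each a Gaussian KDE with mass reflected at both boundaries so the
#' density integrates to 1 on the unit interval. Evaluated on a fixed grid;
#' lookups interpolate linearly.
#'
#' @param reference data.frame/list with components \code{clash} and
#'   \code{surface}, both on [0, 1], at least 2 rows.
#' @param bandwidth kernel standard deviation (default 0.05).
#' @return a \code{score_density}.
#' @export
fit_score_density <- function(reference, bandwidth = 0.05) {
  cl <- reference$clash; su <- reference$surface
  stopifnot(length(cl) >= 2L, length(su) == length(cl),
            all(cl >= 0 & cl <= 1), all(su >= 0 & su <= 1), bandwidth > 0)
  grid <- seq(0, 1, length.out = 401L)
  one <- function(x) {
    d <- vapply(grid, function(g)
      mean(stats::dnorm(g - x, sd = bandwidth) +
           stats::dnorm(g + x, sd = bandwidth) +          # reflect at 0
           stats::dnorm(g - (2 - x), sd = bandwidth)),    # reflect at 1
      numeric(1))
    # trapezoid normalisation on [0,1]
    h <- grid[2] - grid[1]
    z <- sum(d) * h - (d[1] + d[length(d)]) * h / 2
    d / z
  }
  structure(list(grid = grid, clash = one(cl), surface = one(su),
                 bandwidth = bandwidth), class = "score_density")
}

#' Evaluate a fitted score density
#' @param density a \code{score_density}
#' @param x values on [0, 1]
#' @param which "clash" or "surface"
#' @param floor smallest returned density (keeps logs finite)
#' @export
eval_score_density <- function(density, x, which = c("clash", "surface"),
                               floor = 1e-12) {
  which <- match.arg(which)
  y <- stats::approx(density$grid, density[[which]], xout = pmin(pmax(x, 0), 1),
                     rule = 2)$y
  pmax(y, floor)
}

#' Optimise compromise weights against reference densities
#'
#' Chooses the simplex weights (w, 1-w) maximising
#' \deqn{J(w) = mean_k [log f_c(S_clash of rep_k(w)) +
#'              log f_s(S_surface of rep_k(w))] - alpha (w^2 + (1-w)^2)}
#' where rep_k(w) is the model each cluster selects under weights w (highest
#' compromise-score; ties by lower raw clash then lower rank), and f_c, f_s
#' are the reference densities. Deterministic 101-point grid search over
#' w_clash followed by golden-section refinement in the best grid cell.
#'
#' @param models list of \code{ternary_model} with [0,1] scores attached via
#'   \code{\link{unit_scores}}.
#' @param clusters integer cluster label per model.
#' @param density a \code{score_density}.
#' @param alpha regularisation strength (default 0.1).
#' @return a \code{\link{compromise_weights}} with attribute
#'   \code{"objective"}.
#' @export
optimize_weights <- function(models, clusters, density, alpha = 0.1) {
  stopifnot(length(models) == length(clusters), length(models) >= 1L)
  labs <- unique(clusters)
  if (length(labs) < 2L) stop("need at least 2 clusters to optimise weights")
  us <- unit_scores(models)
  raw_cl <- vapply(models, `[[`, numeric(1), "raw_clash")
  rank <- vapply(models, `[[`, integer(1), "rank")
  pick <- function(w) {
    vapply(labs, function(lb) {
      idx <- which(clusters == lb)
      s <- compromise_score(us$clash[idx], us$surface[idx],
                            compromise_weights(w, 1 - w, alpha))
      cand <- idx[s == max(s)]
      if (length(cand) > 1L) cand <- cand[order(raw_cl[cand], rank[cand])]
      cand[1]
    }, integer(1))
  }
  J <- function(w) {
    rep_idx <- pick(w)
    mean(log(eval_score_density(density, us$clash[rep_idx], "clash")) +
         log(eval_score_density(density, us$surface[rep_idx], "surface"))) -
      alpha * (w^2 + (1 - w)^2)
  }
  grid <- seq(0, 1, by = 0.01)
  vals <- vapply(grid, J, numeric(1))
  best <- which.max(vals)
  lo <- grid[max(1L, best - 1L)]; hi <- grid[min(length(grid), best + 1L)]
  opt <- stats::optimize(J, c(lo, hi), maximum = TRUE, tol = 1e-6)
  w <- if (opt$objective > vals[best]) opt$maximum else grid[best]
  out <- compromise_weights(w, 1 - w, alpha)
  attr(out, "objective") <- max(opt$objective, vals[best])
  out
}

#' [0,1]-rescaled clash and surface scores of a model list
#' @param models list of \code{ternary_model} with 1-10 scores set
#' @return list: \code{clash}, \code{surface} vectors on [0,1]
#' @export
unit_scores <- function(models) {
  list(clash = rescale_to_unit(vapply(models, `[[`, numeric(1), "clash_score")),
       surface = rescale_to_unit(vapply(models, `[[`, numeric(1),
                                        "surface_score")))
}
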