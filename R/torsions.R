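# Torsion-angle knowledge: wrapped-Gaussian kernel density estimation of
# dihedral observations, representative-angle extraction with basin
# probabilities, rule assignment to rotatable bonds, and a line-oriented
# plain-text library format.

#' Construct a torsion observation set
#' @param pattern dihedral SMARTS (four atoms; atom maps 1-4 optional).
#' @param angles observed dihedrals in degrees, each in (-180, 180].
#' @export
torsion_observations <- function(pattern, angles) {
  angles <- as.numeric(angles)
  if (!length(angles)) stop("invalid input: need at least one observation")
  if (any(!is.finite(angles)) || any(angles <= -180 | angles > 180))
    stop("angles must lie in (-180, 180]")
  if (pattern != "*") {
    q <- parse_smarts(pattern)
    if (nrow(q$atoms) != 4L)
      stop("a dihedral pattern must have exactly four atoms")
  }
  structure(list(pattern = pattern, angles = angles),
            class = "torsion_observations")
}

#' Construct a torsion rule
#' @param pattern dihedral SMARTS, or "*" for the fallback rule.
#' @param peaks data.frame with columns \code{angle} (degrees) and
#'   \code{probability} (positive, summing to 1 within 1e-9).
#' @param bandwidth fitting bandwidth in degrees; peak angles must be
#'   pairwise separated by more than it on the circle.
#' @export
torsion_rule <- function(pattern, peaks, bandwidth = 10) {
  peaks <- as.data.frame(peaks)[, c("angle", "probability")]
  if (nrow(peaks) < 1L) stop("a torsion rule needs at least one peak")
  if (any(peaks$probability <= 0))
    stop("peak probabilities must be strictly positive")
  if (abs(sum(peaks$probability) - 1) > 1e-9)
    stop("peak probabilities must sum to 1 (got ",
         format(sum(peaks$probability), digits = 12), ")")
  if (any(peaks$angle <= -180 | peaks$angle > 180))
    stop("peak angles must lie in (-180, 180]")
  if (nrow(peaks) > 1L) {
    dmat <- .circ_dist(peaks$angle, peaks$angle)
    if (min(dmat[upper.tri(dmat)]) <= bandwidth)
      stop("peak angles must be separated by more than the bandwidth")
  }
  structure(list(pattern = pattern, peaks = peaks, bandwidth = bandwidth),
            class = "torsion_rule")
}

#' @export
print.torsion_rule <- function(x, ...) {
  cat(sprintf("<torsion_rule> %s (bw %g deg): %s\n", x$pattern, x$bandwidth,
              paste(sprintf("%g deg (p=%.3f)", x$peaks$angle,
                            x$peaks$probability), collapse = ", ")))
  invisible(x)
}

.circ_dist <- function(a, b) {
  d <- abs(outer(a, b, `-`)) %% 360
  pmin(d, 360 - d)
}

#' Wrapped-Gaussian kernel density of dihedral observations
#'
#' Density on a 1-degree grid over (-180, 180], each observation smoothed by
#' a Gaussian kernel wrapped around the circle; normalised so the trapezoid
#' integral over the full circle is 1.
#' @param angles observations in degrees
#' @param bandwidth kernel standard deviation in degrees
#' @return list: \code{grid} (degrees), \code{density} (per degree)
#' @export
wrapped_kde <- function(angles, bandwidth = 10) {
  stopifnot(length(angles) >= 1L, bandwidth > 0)
  grid <- seq(-179, 180, by = 1)
  dens <- numeric(length(grid))
  for (k in -2:2) {
    for (g in seq_along(grid)) {
      dens[g] <- dens[g] +
        sum(stats::dnorm(grid[g] - angles + 360 * k, sd = bandwidth))
    }
  }
  dens <- dens / length(angles)
  dens <- dens / (sum(dens) * 1)   # grid spacing 1 degree, circular sum
  list(grid = grid, density = dens)
}

#' Fit a torsion rule from observed dihedrals
#'
#' Estimates a periodic density by wrapped-Gaussian KDE, takes its local
#' maxima as representative angles (capped at \code{max_peaks} by descending
#' density), and assigns each peak the density mass of its basin of
#' attraction, the arc between the adjacent local minima on the circle.
#' Peaks closer than the bandwidth to a stronger peak are merged into it;
#' the mass of any dropped peak's basin is reassigned to the circularly
#' nearest retained peak. Probabilities are renormalised to sum to 1.
#'
#' @param obs a \code{torsion_observations} (or bare numeric vector, with
#'   \code{pattern} then taken as "*").
#' @param bandwidth kernel bandwidth in degrees (default 10).
#' @param max_peaks cap on the number of representative angles (default 10).
#' @return a \code{torsion_rule}.
#' @export
fit_torsion_rule <- function(obs, bandwidth = 10, max_peaks = 10L) {
  if (is.numeric(obs)) obs <- torsion_observations("*", obs)
  stopifnot(inherits(obs, "torsion_observations"),
            bandwidth > 0, max_peaks >= 1L)
  kde <- wrapped_kde(obs$angles, bandwidth)
  d <- kde$density; m <- length(d)
  nxt <- c(2:m, 1); prv <- c(m, 1:(m - 1))
  is_max <- d > d[prv] & d >= d[nxt]
  if (!any(is_max)) is_max[which.max(d)] <- TRUE
  peak_idx <- which(is_max)
  # basin boundaries: local minima (same convention, inverted)
  is_min <- d < d[prv] & d <= d[nxt]
  basin <- .assign_basins(d, peak_idx, which(is_min))
  mass <- vapply(seq_along(peak_idx), function(p) sum(d[basin == p]), numeric(1))
  ord <- order(d[peak_idx], decreasing = TRUE)
  # retain by descending density, enforcing circular separation > bandwidth
  retained <- integer()
  for (p in ord) {
    if (length(retained) >= max_peaks) break
    if (!length(retained) ||
        min(.circ_dist(kde$grid[peak_idx[p]], kde$grid[peak_idx[retained]])) >
          bandwidth)
      retained <- c(retained, p)
  }
  dropped <- setdiff(seq_along(peak_idx), retained)
  for (p in dropped) {
    near <- retained[which.min(.circ_dist(kde$grid[peak_idx[p]],
                                          kde$grid[peak_idx[retained]]))]
    mass[near] <- mass[near] + mass[p]
  }
  probs <- mass[retained] / sum(mass[retained])
  peaks <- data.frame(angle = kde$grid[peak_idx[retained]],
                      probability = probs)
  peaks <- peaks[order(peaks$probability, abs(peaks$angle),
                       -sign(peaks$angle), decreasing = c(TRUE, FALSE, FALSE),
                       method = "radix"), ]
  rownames(peaks) <- NULL
  torsion_rule(obs$pattern, peaks, bandwidth)
}

# watershed: walk uphill from every grid point to its peak
.assign_basins <- function(d, peak_idx, min_idx) {
  m <- length(d)
  basin <- integer(m)
  peak_of <- integer(m)
  peak_of[peak_idx] <- seq_along(peak_idx)
  uphill <- function(i) {
    steps <- 0L
    while (peak_of[i] == 0L && steps <= m) {
      lo <- if (i == 1L) m else i - 1L
      hi <- if (i == m) 1L else i + 1L
      i <- if (d[lo] > d[hi]) lo else hi
      steps <- steps + 1L
    }
    peak_of[i]
  }
  for (i in seq_len(m)) basin[i] <- uphill(i)
  basin
}

# --- library -----------------------------------------------------------------

#' Construct a torsion library
#'
#' An ordered rule list (first matching pattern wins) plus a mandatory
#' fallback rule (pattern "*") applied when nothing matches.
#' @param rules list of \code{torsion_rule} (may be empty).
#' @param fallback a \code{torsion_rule} with pattern "*".
#' @export
torsion_library <- function(rules = list(), fallback = default_fallback_rule()) {
  stopifnot(inherits(fallback, "torsion_rule"))
  if (fallback$pattern != "*") stop("fallback rule must have pattern '*'")
  pats <- vapply(rules, function(r) r$pattern, character(1))
  if (anyDuplicated(pats)) stop("duplicate patterns in torsion library")
  structure(list(rules = rules, fallback = fallback),
            class = "torsion_library")
}

#' @export
print.torsion_library <- function(x, ...) {
  cat(sprintf("<torsion_library> %d rule(s) + fallback\n", length(x$rules)))
  invisible(x)
}

#' Generic single/gauche fallback torsion rule
#'
#' Used when no library pattern matches a rotatable bond: anti (180 degrees)
#' preferred over the two gauche wells, the classic alkane-like preference.
#' @export
default_fallback_rule <- function() {
  torsion_rule("*", data.frame(angle = c(180, 60, -60),
                               probability = c(0.5, 0.25, 0.25)),
               bandwidth = 10)
}

#' Assign torsion rules to the rotatable bonds of a molecule
#'
#' For each rotatable bond the first library rule whose 4-atom dihedral
#' pattern matches with its central (2nd-3rd) atoms on that bond wins;
#' otherwise the fallback applies, so assignment is total.
#'
#' @param mol a \code{mol_structure}
#' @param library a \code{torsion_library}
#' @param bonds optional data.frame of bonds (as from
#'   \code{\link{rotatable_bonds}}); defaults to all rotatable bonds.
#' @return data.frame: columns \code{a}, \code{b} plus list-column
#'   \code{rule}.
#' @export
assign_rules <- function(mol, library, bonds = rotatable_bonds(mol)) {
  stopifnot(inherits(library, "torsion_library"))
  if (!nrow(bonds)) {
    out <- data.frame(a = integer(), b = integer())
    out$rule <- list()
    return(out)
  }
  # precompute matches per rule once
  rule_bonds <- lapply(library$rules, function(r) {
    hits <- match_substructure(mol, r$pattern, unique_sets = FALSE)
    if (!length(hits)) return(character())
    unique(vapply(hits, function(h) {
      ctr <- .dihedral_center_atoms(r$pattern, h)
      paste(min(ctr), max(ctr))
    }, character(1)))
  })
  rules <- vector("list", nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    key <- paste(bonds$a[i], bonds$b[i])
    hit <- which(vapply(rule_bonds, function(v) key %in% v, logical(1)))
    rules[[i]] <- if (length(hit)) library$rules[[hit[1]]] else library$fallback
  }
  out <- bonds[, c("a", "b")]
  out$rule <- rules
  out
}

.dihedral_center_atoms <- function(pattern, hit) {
  q <- parse_smarts(pattern)
  maps <- q$atoms$map
  if (all(!is.na(maps)) && setequal(maps, 1:4)) {
    c(hit[which(maps == 2L)], hit[which(maps == 3L)])
  } else {
    c(hit[2L], hit[3L])
  }
}

#' Read a torsion library file
#'
#' Plain-text, line-oriented: one rule per block, blocks separated by blank
#' lines or simply starting at each \code{PATTERN} line:
#' \preformatted{
#' PATTERN [C:1][C:2][O:3][C:4]
#' BANDWIDTH 10
#' PEAK 180 0.5
#' PEAK 75 0.25
#' PEAK -75 0.25
#' }
#' The fallback rule is keyed \code{PATTERN *} and must be present.
#' @param path file path
#' @return a \code{torsion_library}
#' @export
read_torsion_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rules <- list(); fallback <- NULL
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return()
    if (is.null(cur$bandwidth)) cur$bandwidth <- 10
    if (!nrow(cur$peaks))
      stop("malformed torsion library: rule '", cur$pattern, "' has no peaks")
    r <- tryCatch(torsion_rule(cur$pattern, cur$peaks, cur$bandwidth),
                  error = function(e) stop("malformed torsion library: rule '",
                                           cur$pattern, "': ",
                                           conditionMessage(e), call. = FALSE))
    if (r$pattern == "*") fallback <<- r else rules[[length(rules) + 1L]] <<- r
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    parts <- strsplit(line, "[[:space:]]+")[[1]]
    kw <- toupper(parts[1])
    if (kw == "PATTERN") {
      flush(cur)
      if (length(parts) != 2L)
        stop("malformed torsion library at line ", ln, ": ", line)
      cur <- list(pattern = parts[2], bandwidth = NULL,
                  peaks = data.frame(angle = numeric(), probability = numeric()))
    } else if (kw == "BANDWIDTH") {
      if (is.null(cur)) stop("BANDWIDTH before PATTERN at line ", ln)
      cur$bandwidth <- as.numeric(parts[2])
    } else if (kw == "PEAK") {
      if (is.null(cur)) stop("PEAK before PATTERN at line ", ln)
      if (length(parts) != 3L)
        stop("malformed PEAK record at line ", ln, ": ", line)
      cur$peaks <- rbind(cur$peaks,
                         data.frame(angle = as.numeric(parts[2]),
                                    probability = as.numeric(parts[3])))
    } else {
      stop("unknown torsion-library keyword '", parts[1], "' at line ", ln)
    }
  }
  flush(cur)
  if (is.null(fallback))
    stop("torsion library has no fallback rule (PATTERN *)")
  torsion_library(rules, fallback)
}

#' Write a torsion library file
#' @param library a \code{torsion_library}
#' @param path output file path
#' @export
write_torsion_library <- function(library, path) {
  stopifnot(inherits(library, "torsion_library"))
  fmt_rule <- function(r) {
    c(paste("PATTERN", r$pattern),
      paste("BANDWIDTH", format(r$bandwidth, digits = 17)),
      sprintf("PEAK %s %s", format(r$peaks$angle, digits = 17),
              format(r$peaks$probability, digits = 17)),
      "")
  }
  out <- unlist(c(lapply(library$rules, fmt_rule),
                  list(fmt_rule(library$fallback))))
  writeLines(out, path)
  invisible(path)
}

#' Read a torsion observation file
#'
#' Plain text: a \code{PATTERN <smarts>} line followed by one observed
#' dihedral (degrees) per line; \code{#} comments allowed.
#' @param path file path
#' @return a \code{torsion_observations}
#' @export
read_torsion_observations <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || !startsWith(toupper(lines[1]), "PATTERN "))
    stop("observation file must start with a PATTERN line: ", path)
  pattern <- strsplit(lines[1], "[[:space:]]+")[[1]][2]
  angles <- suppressWarnings(as.numeric(lines[-1]))
  if (anyNA(angles))
    stop("non-numeric observation in ", path, " at record ",
         which(is.na(angles))[1])
  torsion_observations(pattern, angles)
}

#' The bundled default torsion library
#'
#' Rules fitted with \code{\link{fit_torsion_rule}} from bundled synthetic
#' dihedral observations emulating common linker chemotypes (ether, alkyl,
#' amide-adjacent, aryl-alkyl). These are stand-ins generated in code, not
#' crystallographic survey data; supply your own library for production use.
#' @return a \code{torsion_library}
#' @export
default_torsion_library <- function() {
  path <- system.file("extdata", "default_torsions.txt", package = "protaconf")
  if (!nzchar(path)) stop("bundled torsion library not found")
  read_torsion_library(path)
}
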