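# Deterministic 3D embedding from SMILES: a small distance-geometry scheme
# (seeded random initialisation, then stress minimisation over bond-length,
# 1-3 angle and non-bonded repulsion terms). Adequate for linker-sized
# molecules with simple rings; it makes no claim to conformational realism,
# which is the job of the knowledge-based torsion sampling downstream.

# run expr with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.BOND_SCALE <- c("1" = 1.00, "1.5" = 0.93, "2" = 0.87, "3" = 0.78)

#' Embed a molecule in 3D from a SMILES string
#'
#' Parses the supported SMILES subset (see \code{\link{parse_smarts}}),
#' builds target distances (bond lengths from covalent-radius sums scaled by
#' bond order; 1-3 distances from ideal angles: tetrahedral, trigonal for
#' unsaturated or aromatic centres, ring-interior angles inside small
#' rings), and minimises a stress function from a seeded random start. The
#' result is deterministic for a given (smiles, seed) pair. Hydrogens are
#' added afterwards from standard valences.
#'
#' @param smiles the SMILES string.
#' @param seed RNG seed for the initial coordinates (default 1).
#' @param add_hydrogens fill hydrogens after embedding (default TRUE).
#' @return a \code{mol_structure} with one 3D conformation.
#' @export
embed_from_smiles <- function(smiles, seed = 1L, add_hydrogens = TRUE) {
  q <- parse_smarts(smiles)
  if (any(q$atoms$wildcard))
    stop("invalid SMILES: wildcard atoms cannot be embedded")
  if (any(q$bonds$type == "any"))
    stop("invalid SMILES: '~' bonds cannot be embedded")
  n <- nrow(q$atoms)
  order <- vapply(seq_len(nrow(q$bonds)), function(k) {
    ty <- q$bonds$type[k]
    arom <- q$atoms$aromatic[q$bonds$a[k]] && q$atoms$aromatic[q$bonds$b[k]]
    switch(ty, single = 1, double = 2, triple = 3, aromatic = 1.5,
           default = if (arom) 1.5 else 1)
  }, numeric(1))
  bonds <- data.frame(a = q$bonds$a, b = q$bonds$b, order = order)
  elems <- q$atoms$elem
  if (n == 1L) {
    mol <- mol_structure(elems, matrix(0, 1, 3), NULL, q$atoms$charge,
                         name = smiles)
    return(if (add_hydrogens) add_missing_hydrogens(mol) else mol)
  }

  r <- covalent_radius(elems)
  d0 <- vapply(seq_len(nrow(bonds)), function(k)
    (r[bonds$a[k]] + r[bonds$b[k]]) *
      .BOND_SCALE[[as.character(bonds$order[k])]], numeric(1))

  # ring membership for interior-angle targets
  gi <- igraph::graph_from_data_frame(
    data.frame(from = bonds$a, to = bonds$b), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  ring_sizes <- .smallest_ring_sizes(gi, n)

  # 1-3 targets
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a[k]]] <- c(adj[[bonds$a[k]]], bonds$b[k])
    adj[[bonds$b[k]]] <- c(adj[[bonds$b[k]]], bonds$a[k])
  }
  blen <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(bonds)))
    blen[[paste(min(bonds$a[k], bonds$b[k]),
                max(bonds$a[k], bonds$b[k]))]] <- d0[k]
  has_multiple <- function(i) any(
    bonds$order[bonds$a == i | bonds$b == i] >= 1.5)
  has_triple <- function(i) any(
    bonds$order[bonds$a == i | bonds$b == i] == 3)
  t13 <- NULL
  bonded_key <- vapply(seq_len(nrow(bonds)), function(k)
    paste(min(bonds$a[k], bonds$b[k]), max(bonds$a[k], bonds$b[k])),
    character(1))
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    ang <- if (has_triple(j)) 180
           else if (!is.na(ring_sizes[j]) && ring_sizes[j] <= 6)
             (ring_sizes[j] - 2) * 180 / ring_sizes[j]
           else if (has_multiple(j) || q$atoms$aromatic[j]) 120
           else 109.47
    for (p in seq_len(length(nb) - 1L)) for (qq in (p + 1L):length(nb)) {
      i <- nb[p]; k <- nb[qq]
      if (paste(min(i, k), max(i, k)) %in% bonded_key) next
      di <- blen[[paste(min(i, j), max(i, j))]]
      dk <- blen[[paste(min(j, k), max(j, k))]]
      d <- sqrt(di^2 + dk^2 - 2 * di * dk * cos(ang * pi / 180))
      t13 <- rbind(t13, c(i, k, d))
    }
  }

  # non-bonded lower bounds (not bonded, not 1-3)
  excl <- c(bonded_key, if (!is.null(t13))
    paste(pmin(t13[, 1], t13[, 2]), pmax(t13[, 1], t13[, 2])))
  lower <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!(paste(i, j) %in% excl)) lower <- rbind(lower, c(i, j, 2.0))
  }

  # stacked constraint table: i, j, target, weight, one-sided flag
  con_i <- bonds$a; con_j <- bonds$b; con_t <- d0
  con_w <- rep(10, nrow(bonds)); con_lb <- rep(FALSE, nrow(bonds))
  if (!is.null(t13)) {
    con_i <- c(con_i, t13[, 1]); con_j <- c(con_j, t13[, 2])
    con_t <- c(con_t, t13[, 3]); con_w <- c(con_w, rep(3, nrow(t13)))
    con_lb <- c(con_lb, rep(FALSE, nrow(t13)))
  }
  if (!is.null(lower)) {
    con_i <- c(con_i, lower[, 1]); con_j <- c(con_j, lower[, 2])
    con_t <- c(con_t, lower[, 3]); con_w <- c(con_w, rep(1, nrow(lower)))
    con_lb <- c(con_lb, rep(TRUE, nrow(lower)))
  }
  pair_geom <- function(x) {
    xyz <- matrix(x, n, 3)
    dv <- xyz[con_i, , drop = FALSE] - xyz[con_j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    list(xyz = xyz, dv = dv, d = pmax(d, 1e-9))
  }
  active <- function(g) !con_lb | g$d < con_t
  stress <- function(x) {
    g <- pair_geom(x)
    act <- active(g)
    sum(con_w[act] * (g$d[act] - con_t[act])^2)
  }
  stress_grad <- function(x) {
    g <- pair_geom(x)
    act <- active(g)
    coef <- numeric(length(con_t))
    coef[act] <- 2 * con_w[act] * (g$d[act] - con_t[act]) / g$d[act]
    contrib <- g$dv * coef
    acc <- rowsum(rbind(contrib, -contrib), group = c(con_i, con_j))
    gmat <- matrix(0, n, 3)
    gmat[as.integer(rownames(acc)), ] <- acc
    as.numeric(gmat)
  }

  xyz0 <- with_local_seed(seed, {
    # BFS layout as a sane start, plus small random jitter to break symmetry
    pos <- matrix(0, n, 3)
    placed <- rep(FALSE, n); placed[1] <- TRUE
    queue <- 1L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb2 in adj[[cur]]) {
        if (!placed[nb2]) {
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          key <- paste(min(cur, nb2), max(cur, nb2))
          pos[nb2, ] <- pos[cur, ] + dir * blen[[key]]
          placed[nb2] <- TRUE; queue <- c(queue, nb2)
        }
      }
    }
    pos + matrix(stats::rnorm(3 * n, sd = 0.05), n, 3)
  })
  fit <- stats::optim(as.numeric(xyz0), stress, gr = stress_grad,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  xyz <- matrix(fit$par, n, 3)
  mol <- mol_structure(elems, xyz, bonds, q$atoms$charge, name = smiles)
  # sanity: every bond within 40% of the covalent target
  dd <- vapply(seq_len(nrow(bonds)), function(k)
    sqrt(sum((xyz[bonds$a[k], ] - xyz[bonds$b[k], ])^2)), numeric(1))
  if (any(abs(dd - d0) / d0 > 0.4))
    stop("embedding failed: bond lengths outside tolerance; try another seed")
  if (add_hydrogens) mol <- add_missing_hydrogens(mol)
  mol
}

.smallest_ring_sizes <- function(g, n) {
  out <- rep(NA_real_, n)
  girth_of <- function(v) {
    # smallest cycle through v: BFS-based
    nbrs <- as.integer(igraph::neighbors(g, v))
    best <- Inf
    for (u in nbrs) {
      g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(v, u)))
      d <- igraph::distances(g2, v = v, to = u)
      if (is.finite(d)) best <- min(best, d + 1)
    }
    if (is.finite(best)) best else NA_real_
  }
  for (v in seq_len(n)) out[v] <- girth_of(v)
  out
}
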