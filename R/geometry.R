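# Rigid-body geometry: Kabsch superposition, dihedral measurement and
# torsion driving. All angles in degrees on (-180, 180].

#' Construct a rigid transform
#' @param rotation 3x3 proper rotation matrix
#' @param translation length-3 vector (Angstrom)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Kabsch superposition
#'
#' Least-squares rigid superposition of \code{mobile} onto \code{target}
#' (paired points, equal counts) via SVD of the covariance matrix, with the
#' usual determinant correction so only proper rotations are returned.
#'
#' @param mobile,target n x 3 matrices of paired points, n >= 3,
#'   non-collinear.
#' @return list: \code{transform} (a \code{rigid_transform}) and \code{rmsd}
#'   (Angstrom) of the superposed points.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3L, ncol(target) == 3L,
            nrow(mobile) == nrow(target))
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate input: need >= 3 paired points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  # collinearity check: rank of the centred mobile cloud
  sv_a <- svd(A)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1))
    stop("degenerate input: points are collinear")
  H <- crossprod(A, B)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- ct - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  list(transform = rigid_transform(R, t_vec), rmsd = rmsd)
}

#' RMSD after optimal superposition
#' @param a,b paired n x 3 coordinate matrices
#' @export
superposed_rmsd <- function(a, b) kabsch_superpose(a, b)$rmsd

.wrap_angle <- function(x) {
  # map to (-180, 180]
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Measure a dihedral angle
#' @param coords n x 3 coordinate matrix
#' @param i,j,k,l the four atom indices (dihedral about the j-k axis)
#' @return angle in degrees on (-180, 180]
#' @export
measure_dihedral <- function(coords, i, j, k, l) {
  p <- coords[c(i, j, k, l), , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  .wrap_angle(atan2(y, x) * 180 / pi)
}

#' Reference atoms defining the torsion of a bond
#'
#' Deterministic convention: the dihedral of bond (a, b) is measured over
#' (i, a, b, j) with i the lowest-index heavy neighbour of a (excluding b)
#' and j the lowest-index heavy neighbour of b (excluding a).
#' @param mol a \code{mol_structure}
#' @param a,b bonded heavy atoms
#' @return c(i, a, b, j) or NULL when either side lacks a heavy neighbour
#' @export
torsion_atoms <- function(mol, a, b) {
  adj <- mol_adjacency(mol)
  ni <- setdiff(adj[[a]], b); ni <- ni[mol$elements[ni] != "H"]
  nj <- setdiff(adj[[b]], a); nj <- nj[mol$elements[nj] != "H"]
  if (!length(ni) || !length(nj)) return(NULL)
  c(min(ni), a, b, min(nj))
}

#' Set a torsion angle
#'
#' Rotates every atom on the distal side of the acyclic bond (a, b) about the
#' a->b axis so the dihedral over \code{\link{torsion_atoms}} equals
#' \code{angle_deg}. Bond lengths and bond angles are untouched.
#'
#' @param mol a \code{mol_structure}
#' @param a,b the bond (heavy atoms, acyclic)
#' @param angle_deg target dihedral in degrees, (-180, 180]
#' @return the modified \code{mol_structure}
#' @export
set_torsion <- function(mol, a, b, angle_deg) {
  ta <- torsion_atoms(mol, a, b)
  if (is.null(ta)) stop("bond (", a, ",", b, ") has no torsion-defining neighbours")
  side <- bond_side(mol, a, b)       # errors on ring bonds
  cur <- measure_dihedral(mol$coords, ta[1], ta[2], ta[3], ta[4])
  # rotating the distal side by +theta about a->b decreases the measured
  # dihedral under the atan2 sign convention, hence the negation
  delta <- -.wrap_angle(angle_deg - cur) * pi / 180
  axis <- mol$coords[b, ] - mol$coords[a, ]
  axis <- axis / sqrt(sum(axis^2))
  R <- .rotation_about_axis(axis, delta)
  origin <- mol$coords[b, ]
  moving <- setdiff(side, b)
  if (length(moving)) {
    rel <- sweep(mol$coords[moving, , drop = FALSE], 2, origin)
    mol$coords[moving, ] <- sweep(rel %*% t(R), 2, origin, `+`)
  }
  mol
}

.rotation_about_axis <- function(u, theta) {
  ct <- cos(theta); st <- sin(theta); omc <- 1 - ct
  matrix(c(
    ct + u[1]^2 * omc,        u[1] * u[2] * omc - u[3] * st, u[1] * u[3] * omc + u[2] * st,
    u[2] * u[1] * omc + u[3] * st, ct + u[2]^2 * omc,        u[2] * u[3] * omc - u[1] * st,
    u[3] * u[1] * omc - u[2] * st, u[3] * u[2] * omc + u[1] * st, ct + u[3]^2 * omc
  ), nrow = 3, byrow = TRUE)
}

#' Symmetry-aware ligand RMSD
#'
#' Heavy-atom RMSD between a conformer and a reference with the same
#' molecular graph, after optimal rigid superposition, minimised over all
#' element- and bond-order-preserving graph automorphisms (so e.g. a ring
#' flip or a relabelled symmetric substituent scores zero).
#'
#' @param conformer,reference \code{mol_structure}s with identical graphs
#' @return RMSD in Angstrom
#' @export
lig_rmsd <- function(conformer, reference) {
  stopifnot(is_mol(conformer), is_mol(reference))
  hv <- heavy_atoms(conformer)
  hr <- heavy_atoms(reference)
  if (length(hv) != length(hr) ||
      !identical(conformer$elements[hv], reference$elements[hr]))
    stop("conformer and reference must share the same molecular graph")
  a <- conformer$coords[hv, , drop = FALSE]
  b <- reference$coords[hr, , drop = FALSE]
  autos <- mol_automorphisms(reference)
  if (!length(autos)) autos <- list(seq_along(hr))
  min(vapply(autos, function(p) superposed_rmsd(a, b[p, , drop = FALSE]),
             numeric(1)))
}
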