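#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation (det = +1) and translation aligning a moving
#' point set onto a fixed one, by singular value decomposition of the
#' cross-covariance matrix, with the post-fit root-mean-square deviation.
#'
#' @param moving,fixed Paired n x 3 coordinate matrices (or
#'   [structure_model()] subsets of equal length), n >= 3, not collinear.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   aligned = moving %*% rotation + translation), `rmsd` (Angstrom) and
#'   `aligned` coordinates.
#' @export
superpose <- function(moving, fixed) {
  P <- if (inherits(moving, "structure_model")) coords(moving)
       else as.matrix(moving)
  Q <- if (inherits(fixed, "structure_model")) coords(fixed)
       else as.matrix(fixed)
  if (nrow(P) != nrow(Q)) stop("point sets must be paired (equal length)")
  if (nrow(P) < 3) stop("need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (any(svd(P0)$d[2] < 1e-10 * max(svd(P0)$d)))
    stop("degenerate (collinear) point set")
  H <- crossprod(P0, Q0)                  # 3 x 3
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- sweep(P0 %*% R, 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  list(rotation = R, translation = cq - as.vector(cp %*% R),
       rmsd = rmsd, aligned = aligned)
}

# Pair two chains' atoms by (residue_number, atom_name) intersection,
# restricted to an atom-name selection; returns the two coordinate blocks.
pair_chain_atoms <- function(s, chain_a, chain_b,
                             atom_selection = c("N", "CA", "C", "O")) {
  a <- atom_select(s, chain = chain_a, name = atom_selection)
  b <- atom_select(s, chain = chain_b, name = atom_selection)
  key_a <- paste(a$residue_number, a$atom_name)
  key_b <- paste(b$residue_number, b$atom_name)
  common <- intersect(key_a, key_b)
  if (length(common) == 0) stop("no common atoms between chains ",
                                chain_a, " and ", chain_b)
  list(a = coords(a[match(common, key_a), ]),
       b = coords(b[match(common, key_b), ]))
}

#' Pairwise backbone RMSD between protomers
#'
#' Superposes every chain pair on their shared backbone atoms (paired by
#' residue number and atom name) and reports the post-fit RMSD matrix.
#'
#' @param s A [structure_model()].
#' @param chains Chain identifiers (>= 2).
#' @param atom_selection Backbone atom names (default N, CA, C, O).
#' @return Symmetric matrix of RMSDs (Angstrom), zero diagonal.
#' @export
pairwise_protomer_rmsd <- function(s, chains,
                                   atom_selection = c("N", "CA", "C", "O")) {
  stopifnot(inherits(s, "structure_model"), length(chains) >= 2)
  n <- length(chains)
  M <- matrix(0, n, n, dimnames = list(chains, chains))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pr <- pair_chain_atoms(s, chains[i], chains[j], atom_selection)
    M[i, j] <- M[j, i] <- superpose(pr$a, pr$b)$rmsd
  }
  M
}

#' Pore (symmetry) axis of an oligomer
#'
#' The axis passes through the center of mass of the selected chains with
#' direction normal to the best-fit plane of the chain centers of mass
#' (smallest principal component of the chain-center cloud) — for a C5
#' pentamer this is the five-fold axis.
#'
#' @param s A [structure_model()].
#' @param chains Chain identifiers (>= 3).
#' @param orient_positive_z Flip the direction so its z component is
#'   positive (default `TRUE`); set `FALSE` to keep the raw eigenvector,
#'   e.g. when the cytoplasmic side faces -z.
#' @return List with `point` (center of mass) and `direction` (unit
#'   vector).
#' @export
pore_axis <- function(s, chains, orient_positive_z = TRUE) {
  stopifnot(inherits(s, "structure_model"))
  if (length(chains) < 3) stop("need at least 3 chains to define the axis")
  sel <- atom_select(s, chain = chains)
  centers <- t(vapply(chains, function(ch)
    colMeans(coords(atom_select(s, chain = ch))), numeric(3)))
  ev <- eigen(stats::cov(centers), symmetric = TRUE)
  dir <- ev$vectors[, 3]
  if (orient_positive_z && dir[3] < 0) dir <- -dir
  list(point = colMeans(coords(sel)), direction = dir / sqrt(sum(dir^2)))
}

# Orthonormal frame with third axis along `direction`.
axis_frame <- function(direction) {
  w <- direction / sqrt(sum(direction^2))
  seedv <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seedv - sum(seedv * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  cbind(u, v, w)
}

# Coordinates in the axis frame (origin at axis point, z along direction).
to_axis_frame <- function(xyz, axis) {
  sweep(as.matrix(xyz), 2, axis$point) %*% axis_frame(axis$direction)
}

#' Ring geometry of an atom selection about an axis
#'
#' Orders the selected atoms by azimuth about the axis and reports the
#' cyclic adjacent distances with mean and standard deviation — e.g. the
#' O-O distances of the axial water pentagon.
#'
#' @param s A [structure_model()] (or coordinate matrix).
#' @param selection A [structure_model()] subset (from [atom_select()]) or
#'   n x 3 coordinates, n >= 3.
#' @param axis Axis from [pore_axis()].
#' @return An object of class `ring_geometry`: `members` (ordered
#'   coordinates), `adjacent_distances`, `mean`, `sd`.
#' @export
ring_geometry <- function(s, selection, axis) {
  xyz <- if (inherits(selection, "structure_model")) coords(selection)
         else as.matrix(selection)
  if (nrow(xyz) < 3) stop("ring needs at least 3 atoms")
  local <- to_axis_frame(xyz, axis)
  ord <- order(atan2(local[, 2], local[, 1]))
  # Canonicalize the cyclic order so the reported sequence is invariant
  # under rigid motions (which rotate the azimuth origin and can flip the
  # traversal direction): start at the member with the smallest input row
  # index and traverse towards its lower-index ring neighbour.
  n <- length(ord)
  start <- which.min(ord)
  ord <- ord[((start - 1 + 0:(n - 1)) %% n) + 1]
  if (ord[n] < ord[2]) ord <- ord[c(1, n:2)]
  xyz <- xyz[ord, , drop = FALSE]
  nxt <- c(2:nrow(xyz), 1)
  d <- unname(sqrt(rowSums((xyz[nxt, , drop = FALSE] - xyz)^2)))
  structure(list(members = xyz, adjacent_distances = d,
                 mean = mean(d), sd = stats::sd(d)),
            class = "ring_geometry")
}

#' Minimum interatomic distance between two selections
#'
#' Minimum Euclidean distance over the cross product of two atom
#' selections, heavy atoms only by default.
#'
#' @param sel_a,sel_b Nonempty [structure_model()] subsets
#'   (from [atom_select()]).
#' @param heavy_only Ignore hydrogens (default `TRUE`).
#' @return List with `distance` (Angstrom), `atom_a` and `atom_b` (the
#'   closest pair, as one-row data frames).
#' @export
min_atom_distance <- function(sel_a, sel_b, heavy_only = TRUE) {
  if (heavy_only) {
    sel_a <- sel_a[sel_a$element != "H", , drop = FALSE]
    sel_b <- sel_b[sel_b$element != "H", , drop = FALSE]
  }
  if (nrow(sel_a) == 0) stop("selection A is empty")
  if (nrow(sel_b) == 0) stop("selection B is empty")
  A <- coords(sel_a); B <- coords(sel_b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  ij <- arrayInd(which.min(d2), dim(d2))
  list(distance = sqrt(max(d2[ij], 0)),
       atom_a = as.data.frame(sel_a[ij[1], ]),
       atom_b = as.data.frame(sel_b[ij[2], ]))
}
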