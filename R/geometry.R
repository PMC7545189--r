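#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of two paired coordinate sets: finds the proper
#' rotation \code{R} (det +1, enforced by sign-correcting the smallest singular
#' vector) and translation \code{t} minimizing the r.m.s.d. of
#' \code{coordsB \%*\% t(R) + t} onto \code{coordsA}.
#'
#' @param coordsA,coordsB N x 3 matrices (angstrom), rows paired, N >= 3.
#' @return list: \code{rotation} (3 x 3, orthonormal, det +1),
#'   \code{translation} (length 3), \code{rmsd} (angstrom, after fitting),
#'   \code{n_atoms}.
#' @export
superpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  .stop_if(ncol(coordsA) != 3 || ncol(coordsB) != 3, "coordinates must be N x 3")
  .stop_if(nrow(coordsA) != nrow(coordsB), "coordinate sets must be paired")
  n <- nrow(coordsA)
  .stop_if(n < 3, "need at least 3 paired atoms")

  ca <- colMeans(coordsA); cb <- colMeans(coordsB)
  A <- sweep(coordsA, 2, ca); B <- sweep(coordsB, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  .stop_if(sv$d[2] < 1e-12, "degenerate (collinear or coincident) coordinates")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(ca - R %*% cb)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((A - fitted)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd, n_atoms = n)
}

#' Backbone r.m.s.d. between mapped chains after optimal superposition
#'
#' Collects backbone atoms (N, CA, C, O) for every mapped residue pair,
#' dropping atoms missing on either side pairwise (missing carbonyl O at chain
#' termini is common), then reports the Kabsch-fit r.m.s.d. over the pooled
#' atom pairs.
#'
#' @param chainA,chainB \code{residue_selection}s.
#' @param mapping a \code{residue_mapping} from \code{\link{map_residues}}
#'   pairing residues of \code{chainA} with residues of \code{chainB}.
#' @return r.m.s.d. in angstrom (single number).
#' @export
backbone_rmsd <- function(chainA, chainB, mapping) {
  stopifnot(inherits(mapping, "residue_mapping"))
  .stop_if(nrow(mapping$pairs) == 0L, "empty residue mapping")
  bb <- c("N", "CA", "C", "O")
  aa <- .sel_atoms(chainA); ab <- .sel_atoms(chainB)
  key_a <- .res_key(aa$chain, aa$resno, aa$icode)
  key_b <- .res_key(ab$chain, ab$resno, ab$icode)
  p <- mapping$pairs
  pk_a <- .res_key(p$chain_a, p$resno_a, p$icode_a)
  pk_b <- .res_key(p$chain_b, p$resno_b, p$icode_b)

  ca_rows <- cb_rows <- integer(0)
  for (i in seq_len(nrow(p))) {
    for (at in bb) {
      ra <- which(key_a == pk_a[i] & aa$atom == at)
      rb <- which(key_b == pk_b[i] & ab$atom == at)
      if (length(ra) == 1L && length(rb) == 1L) {
        ca_rows <- c(ca_rows, ra); cb_rows <- c(cb_rows, rb)
      }
    }
  }
  .stop_if(length(ca_rows) < 3, "fewer than 3 paired backbone atoms")
  fit <- superpose(as.matrix(aa[ca_rows, c("x", "y", "z")]),
                   as.matrix(ab[cb_rows, c("x", "y", "z")]))
  fit$rmsd
}

#' Principal axis of a domain
#'
#' First principal component of the C-alpha coordinate cloud, sign-fixed so
#' the axis points from the N- toward the C-terminus (non-negative dot product
#' with the vector from the first to the last C-alpha in the selection). This
#' is the long axis used for immunoglobulin-domain crossing angles.
#'
#' @param selection a \code{residue_selection} with at least 4 C-alpha atoms.
#' @return a \code{domain_axis}: list with \code{centroid} and unit
#'   \code{direction}.
#' @export
principal_axis <- function(selection) {
  a <- .sel_atoms(selection)
  ca <- a[a$atom == "CA" & !a$hetero, c("x", "y", "z"), drop = FALSE]
  .stop_if(nrow(ca) < 4, "need at least 4 C-alpha atoms (have %d)", nrow(ca))
  m <- as.matrix(ca)
  centroid <- colMeans(m)
  sv <- svd(sweep(m, 2, centroid))
  dir <- sv$v[, 1]
  nc <- as.numeric(m[nrow(m), ] - m[1, ])
  if (sum(dir * nc) < 0) dir <- -dir
  dir <- dir / sqrt(sum(dir^2))
  structure(list(centroid = centroid, direction = dir), class = "domain_axis")
}

#' Angle between two domain axes
#'
#' Returns \code{acos(a1 . a2)} in degrees over the full 0-180 range: because
#' both axes are N-to-C oriented, parallel and antiparallel packings are
#' distinguished. Used both for receptor/ligand IgV crossing angles and for
#' inter-domain (elbow) angles within a two-domain ectodomain.
#'
#' @param a1,a2 \code{domain_axis} objects.
#' @return angle in degrees, in [0, 180].
#' @export
axis_angle <- function(a1, a2) {
  stopifnot(inherits(a1, "domain_axis"), inherits(a2, "domain_axis"))
  ct <- sum(a1$direction * a2$direction)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# apply a rigid transform to a model (used by generators and invariance tests)
#' Rigidly transform all coordinates of a model
#'
#' @param model a \code{structure_model}.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector, angstrom.
#' @return the transformed \code{structure_model}.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  model$atoms$x <- xyz[, 1] + translation[1]
  model$atoms$y <- xyz[, 2] + translation[2]
  model$atoms$z <- xyz[, 3] + translation[3]
  model
}

# convenience: rotation matrix about a unit axis by angle (degrees)
#' Rotation matrix about an axis
#' @param axis length-3 vector (normalized internally).
#' @param degrees rotation angle.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis, degrees) {
  u <- axis / sqrt(sum(axis^2))
  th <- degrees * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
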