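# Conformational geometry: optimal-superposition RMSD (Kabsch with the
# determinant correction so reflections are never applied), radius of
# gyration, and backbone phi/psi dihedrals.

#' Optimal-superposition RMSD (Kabsch)
#'
#' Least-squares rigid superposition of `Y` onto `X` (translation plus
#' proper rotation; the SVD determinant correction excludes reflections so
#' chirality is never inverted), followed by the root-mean-square deviation.
#'
#' @param x,y Numeric n x 3 coordinate matrices, n >= 3, not collinear.
#' @param weights Optional per-point weights (default uniform).
#' @return RMSD in the input units.
#' @export
kabsch_rmsd <- function(x, y, weights = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) {
    stopf("zincagg_invalid", "coordinate sets differ in shape")
  }
  n <- nrow(x)
  if (n < 3L) stopf("zincagg_degenerate", "need >= 3 points, got %d", n)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  w <- w / sum(w)
  xc <- sweep(x, 2, colSums(x * w))
  yc <- sweep(y, 2, colSums(y * w))
  h <- t(yc * w) %*% xc
  sv <- svd(h)
  scale <- max(sv$d)
  if (scale <= 0 || sum(sv$d > 1e-10 * scale) < 2L) {
    stopf("zincagg_degenerate",
          "rank-deficient (collinear or coincident) coordinates")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diffm <- xc - yc %*% t(rot)
  sqrt(sum(w * rowSums(diffm^2)))
}

#' Radius of gyration
#'
#' `Rg = sqrt(sum_i m_i |r_i - rbar|^2 / sum_i m_i)` with unit masses by
#' default.
#'
#' @param frame A `zincagg_frame` or a bare n x 3 coordinate matrix (nm).
#' @param selection Optional atom row indices (default all atoms).
#' @param masses Optional per-atom masses.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(frame, selection = NULL, masses = NULL) {
  xyz <- if (inherits(frame, "zincagg_frame")) frame$coords else as.matrix(frame)
  if (!is.null(selection)) xyz <- xyz[selection, , drop = FALSE]
  if (nrow(xyz) == 0L) stopf("zincagg_empty", "empty selection")
  m <- if (is.null(masses)) rep(1, nrow(xyz)) else as.numeric(masses)
  com <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# signed dihedral of four points, IUPAC convention, degrees in (-180, 180]
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  y <- sum(cross3(n1, n2) * b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi dihedrals
#'
#' Requires full-backbone fixtures (atoms N, CA, C per residue);
#' pseudo-atom scaffolds are rejected residue-wise with a warning. Angles
#' follow the IUPAC sign convention, degrees in (-180, 180]. The first
#' residue of a chain has no phi and the last no psi (reported `NA`).
#'
#' @param frame A `zincagg_frame`.
#' @param topology The matching topology.
#' @return Tibble `chain_id`, `resseq`, `phi`, `psi` in degrees.
#' @export
phi_psi <- function(frame, topology) {
  a <- topology$atoms
  out <- list()
  for (ch in unique(a$chain_id[a$resname != "ZN"])) {
    ca <- a[a$chain_id == ch, ]
    resseqs <- sort(unique(ca$resseq))
    atom_at <- function(rs, nm) {
      i <- ca$atom_id[ca$resseq == rs & ca$atom_name == nm]
      if (length(i) != 1L) NA_integer_ else i
    }
    bb <- lapply(resseqs, function(rs) {
      c(N = atom_at(rs, "N"), CA = atom_at(rs, "CA"), C = atom_at(rs, "C"))
    })
    complete <- vapply(bb, function(v) !anyNA(v), logical(1))
    if (any(!complete)) {
      warn(sprintf("chain %s: %d residue(s) missing backbone atoms, skipped",
                   ch, sum(!complete)))
    }
    for (k in seq_along(resseqs)) {
      if (!complete[k]) next
      phi <- NA_real_; psi <- NA_real_
      if (k > 1L && complete[k - 1L]) {
        phi <- dihedral(frame$coords[bb[[k - 1L]]["C"], ],
                        frame$coords[bb[[k]]["N"], ],
                        frame$coords[bb[[k]]["CA"], ],
                        frame$coords[bb[[k]]["C"], ])
      }
      if (k < length(resseqs) && complete[k + 1L]) {
        psi <- dihedral(frame$coords[bb[[k]]["N"], ],
                        frame$coords[bb[[k]]["CA"], ],
                        frame$coords[bb[[k]]["C"], ],
                        frame$coords[bb[[k + 1L]]["N"], ])
      }
      out[[length(out) + 1L]] <- tibble(chain_id = ch, resseq = resseqs[k],
                                        phi = phi, psi = psi)
    }
  }
  if (!length(out)) {
    return(tibble(chain_id = character(), resseq = integer(),
                  phi = numeric(), psi = numeric()))
  }
  bind_rows(out)
}

#' Pairwise RMSD matrix of an ensemble
#'
#' @param ensemble List of equally sized n x 3 coordinate matrices over a
#'   common atom selection.
#' @return Symmetric matrix of [kabsch_rmsd()] values with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(ensemble) {
  m <- length(ensemble)
  if (m < 1L) stopf("zincagg_empty", "empty ensemble")
  dims <- vapply(ensemble, function(x) nrow(as.matrix(x)), integer(1))
  if (length(unique(dims)) != 1L) {
    stopf("zincagg_invalid", "ensemble members differ in atom count")
  }
  d <- matrix(0, m, m)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        d[i, j] <- d[j, i] <- kabsch_rmsd(ensemble[[i]], ensemble[[j]])
      }
    }
  }
  d
}
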