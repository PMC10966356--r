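# Second-order coupled-oscillator forward model: the chirality-
# sensitive coupling coefficients C_ij, the dipole-dipole interaction
# matrix G_ij, and the molar ellipticity / optical activity summed over
# all ordered atom pairs i != j. Both C and G are symmetric, so the
# ordered-pair sum is twice the unordered one; that convention is fixed
# here and absorbed by the polarizability-library scale.

#' Chirality-sensitive coupling coefficient C_ij
#'
#' `C_ij = K * (e_i x e_j) . (r_j - r_i) / lambda^2` with
#' K = 1.426468e26. Vanishes for parallel dipoles and changes sign
#' under mirror reflection; symmetric in (i, j).
#'
#' @param e_i,e_j unit dipole-direction 3-vectors.
#' @param r_i,r_j position 3-vectors (A).
#' @param lam wavelength (nm), positive.
#' @return Scalar coefficient.
#' @export
coupling_C <- function(e_i, e_j, r_i, r_j, lam) {
  if (!is.numeric(lam) || lam <= 0) stop("parameter error: lam must be positive")
  COUPLING_K * sum(cross3(e_i, e_j) * (r_j - r_i)) / lam^2
}

#' Dipole-dipole interaction term G_ij
#'
#' `G_ij = r_ij^-3 * (e_i . e_j - 3 (e_i . e_ij)(e_j . e_ij))` with
#' e_ij the unit vector along the separation; geometry-only, symmetric,
#' defined for i != j.
#'
#' @inheritParams coupling_C
#' @return Scalar interaction value (A^-3).
#' @export
coupling_G <- function(e_i, e_j, r_i, r_j) {
  d <- r_j - r_i
  r <- vnorm(d)
  if (r < 1e-9) stop("singular geometry: coincident dipole positions")
  eij <- d / r
  (sum(e_i * e_j) - 3 * sum(e_i * eij) * sum(e_j * eij)) / r^3
}

# Pairwise kernel matrices for a structure:
#   Chat_ij = K (e_i x e_j).(r_j - r_i)   (C_ij = Chat_ij / lambda^2)
#   G_ij as above; T = Chat * G elementwise; diagonals zero.
pair_kernel <- function(s) {
  a <- s$atoms
  if (any(is.na(a$ex))) stop("dipole directions not assigned; run assign_dipole_directions()")
  n <- nrow(a)
  R <- cbind(a$x, a$y, a$z)
  E <- cbind(a$ex, a$ey, a$ez)
  one <- rep(1, n)
  dx <- outer(one, R[, 1L]) - outer(R[, 1L], one)
  dy <- outer(one, R[, 2L]) - outer(R[, 2L], one)
  dz <- outer(one, R[, 3L]) - outer(R[, 3L], one)
  cx <- outer(E[, 2L], E[, 3L]) - outer(E[, 3L], E[, 2L])
  cy <- outer(E[, 3L], E[, 1L]) - outer(E[, 1L], E[, 3L])
  cz <- outer(E[, 1L], E[, 2L]) - outer(E[, 2L], E[, 1L])
  Chat <- COUPLING_K * (cx * dx + cy * dy + cz * dz)

  D <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(D[upper.tri(D)] < 1e-9))
    stop("singular geometry: coincident atom positions")
  Dsafe <- D; diag(Dsafe) <- Inf
  ee <- E %*% t(E)
  eid <- (E[, 1L] * dx + E[, 2L] * dy + E[, 3L] * dz) / Dsafe          # e_i . e_ij
  ejd <- (dx * matrix(E[, 1L], n, n, byrow = TRUE) +
          dy * matrix(E[, 2L], n, n, byrow = TRUE) +
          dz * matrix(E[, 3L], n, n, byrow = TRUE)) / Dsafe            # e_j . e_ij
  G <- (ee - 3 * eid * ejd) / Dsafe^3
  diag(G) <- 0
  T <- Chat * G
  diag(T) <- 0
  list(Chat = Chat, G = G, T = T)
}

# Interpolate a blended polarizability set onto a wavelength grid and
# expand to per-atom values (with the D-residue real-part flip).
atom_alphas <- function(s, curves, grid) {
  cset <- if (is.list(curves) && !is.null(curves$curves)) curves
          else list(grid = attr(curves, "grid"), curves = curves)
  if (is.null(cset$grid)) stop("curves must carry a wavelength grid")
  if (min(grid) < min(cset$grid) - 1e-9 || max(grid) > max(cset$grid) + 1e-9)
    stop("requested grid extends beyond polarizability-curve coverage")
  labs <- colnames(cset$curves)
  if (anyNA(s$atoms$type_label) || any(!nzchar(s$atoms$type_label)))
    stop("typing error: atoms without type labels; run assign_atom_types()")
  missing_t <- setdiff(unique(s$atoms$type_label), labs)
  if (length(missing_t))
    stop("typing error: no curves for type(s) ", paste(missing_t, collapse = ", "))
  interp <- vapply(labs, function(l) {
    complex(real = stats::approx(cset$grid, Re(cset$curves[, l]), xout = grid)$y,
            imaginary = stats::approx(cset$grid, Im(cset$curves[, l]), xout = grid)$y)
  }, complex(length(grid)))
  interp <- matrix(interp, nrow = length(grid), dimnames = list(NULL, labs))
  A <- t(interp[, s$atoms$type_label, drop = FALSE])   # n_atoms x M
  dimnames(A) <- NULL
  if (any(s$atoms$is_D)) A[s$atoms$is_D, ] <- flip_for_D(A[s$atoms$is_D, , drop = FALSE])
  A
}

#' Molar ellipticity spectrum of a structure
#'
#' `theta(lambda) = -sum_{i != j} Im[alpha_i alpha_j] C_ij G_ij`, summed
#' over all ordered atom pairs. Atoms of D-residues use the real-part-
#' flipped polarizability. The per-residue variant divides by Nr.
#'
#' @param s a [protein_structure()] with dipole directions and type
#'   labels assigned.
#' @param curves a blended set from [assign_protein_polarizabilities()]
#'   (or any list with `grid` and a complex `curves` matrix whose
#'   columns are type labels).
#' @param grid wavelengths (nm); default [default_grid()].
#' @param per_residue divide by the residue count.
#' @return A [cd_spectrum()] of theta in deg cm^2 dmol^-1.
#' @export
molar_ellipticity <- function(s, curves, grid = default_grid(), per_residue = FALSE) {
  if (nrow(s$atoms) < 2L) {
    warning("fewer than 2 atoms: zero spectrum")
    return(cd_spectrum(grid, rep(0, length(grid)), per_residue = per_residue,
                       source = "forward-model"))
  }
  Tm <- pair_kernel(s)$T
  A <- atom_alphas(s, curves, grid)
  re <- Re(A); im <- Im(A)
  theta <- vapply(seq_along(grid), function(k) {
    -(crossprod(re[, k], Tm %*% im[, k])[1L] +
      crossprod(im[, k], Tm %*% re[, k])[1L]) / grid[k]^2
  }, numeric(1))
  if (per_residue) theta <- theta / s$nres
  cd_spectrum(grid, theta, per_residue = per_residue, source = "forward-model")
}

#' Complex optical activity of a structure
#'
#' `o(lambda) = -sum_{i != j} alpha_i alpha_j C_ij G_ij`; its imaginary
#' part equals [molar_ellipticity()] pointwise, its real part the
#' dispersive counterpart.
#'
#' @inheritParams molar_ellipticity
#' @return A [cd_spectrum()] with complex values.
#' @export
optical_activity <- function(s, curves, grid = default_grid(), per_residue = FALSE) {
  if (nrow(s$atoms) < 2L) {
    warning("fewer than 2 atoms: zero spectrum")
    return(cd_spectrum(grid, complex(length(grid)), per_residue = per_residue,
                       source = "forward-model"))
  }
  Tm <- pair_kernel(s)$T
  A <- atom_alphas(s, curves, grid)
  o <- vapply(seq_along(grid), function(k) {
    a <- A[, k]
    -(t(a) %*% Tm %*% a)[1L] / grid[k]^2
  }, complex(1))
  if (per_residue) o <- o / s$nres
  cd_spectrum(grid, o, per_residue = per_residue, source = "forward-model")
}

#' Convert molar ellipticity to molar CD
#'
#' `DeltaEpsilon = theta / 3298.21`.
#'
#' @param theta a [cd_spectrum()] in molar-ellipticity units.
#' @return A [cd_spectrum()] of molar CD.
#' @export
to_molar_cd <- function(theta) {
  cd_spectrum(theta$grid, theta$values / THETA_PER_DELTA_EPS,
              per_residue = isTRUE(theta$meta$per_residue),
              source = theta$meta$source)
}

#' Convert molar CD to molar ellipticity
#'
#' Inverse of [to_molar_cd()].
#'
#' @param de a [cd_spectrum()] of molar CD.
#' @return A [cd_spectrum()] of molar ellipticity.
#' @export
from_molar_cd <- function(de) {
  cd_spectrum(de$grid, de$values * THETA_PER_DELTA_EPS,
              per_residue = isTRUE(de$meta$per_residue),
              source = de$meta$source)
}

#' Pair sum of C_ij G_ij at one wavelength
#'
#' `sum_{i != j} C_ij G_ij`, the denominator of the mean-polarizability
#' equation.
#'
#' @param s a [protein_structure()] with dipoles assigned.
#' @param lam wavelength (nm).
#' @return Scalar.
#' @export
sum_CG <- function(s, lam) {
  if (!is.numeric(lam) || lam <= 0) stop("parameter error: lam must be positive")
  sum(pair_kernel(s)$T) / lam^2
}

# uniform random rotation matrices via quaternions
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

rotate_structure <- function(s, Rm, shift = c(0, 0, 0)) {
  pos <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(Rm)
  s$atoms$x <- pos[, 1L] + shift[1L]
  s$atoms$y <- pos[, 2L] + shift[2L]
  s$atoms$z <- pos[, 3L] + shift[3L]
  if (!any(is.na(s$atoms$ex))) {
    e <- as.matrix(s$atoms[, c("ex", "ey", "ez")]) %*% t(Rm)
    s$atoms$ex <- e[, 1L]; s$atoms$ey <- e[, 2L]; s$atoms$ez <- e[, 3L]
  }
  s
}

#' Rotationally averaged pair sum of C_ij G_ij
#'
#' Mean of [sum_CG()] over uniformly random rigid rotations of the
#' structure. C_ij and G_ij are rotation-invariant scalars, so the
#' average equals the unrotated value; the operation exists to verify
#' that invariance and to serve the training equations, where the
#' average over beam orientations appears explicitly.
#'
#' @param s a [protein_structure()] with dipoles assigned.
#' @param lam wavelength (nm).
#' @param n_rot number of random rotations (>= 1).
#' @param seed integer seed.
#' @return Scalar mean pair sum.
#' @export
rotational_average_CG <- function(s, lam, n_rot = 8L, seed = 1L) {
  if (!is.numeric(n_rot) || n_rot < 1L) stop("parameter error: n_rot must be >= 1")
  set.seed(seed)
  vals <- vapply(seq_len(n_rot), function(k) {
    sum_CG(rotate_structure(s, random_rotation()), lam)
  }, numeric(1))
  mean(vals)
}
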