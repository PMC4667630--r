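#' Euler angles and rotation matrices
#'
#' Single-particle analysis parametrizes particle orientations by three
#' Euler angles (rot, tilt, psi) in degrees, composed intrinsically about
#' z, then the new y, then the new z. Matrices act on column vectors; the
#' image-plane location of a model point `p` (relative to the map center)
#' is the first two components of `M %*% p`, and the third component is
#' the height of the point above the image plane, along the beam.
#'
#' @param rot,tilt,psi Euler angles in degrees. `tilt` lies in
#'   `[0, 180]`; `rot` and `psi` are reported in `[-180, 180)`.
#' @return `euler_to_matrix()` returns a 3x3 rotation matrix.
#' @examples
#' euler_to_matrix(30, 45, 60)
#' matrix_to_euler(euler_to_matrix(30, 45, 60))
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  m <- euler_to_matrix_many(rot[1], tilt[1], psi[1])
  matrix(m[1, ], 3, 3)
}

#' @rdname euler_to_matrix
#' @param m A 3x3 rotation matrix (orthonormal, determinant +1).
#' @return `matrix_to_euler()` returns a named numeric vector
#'   `c(rot, tilt, psi)` in degrees. At gimbal lock (`tilt` 0 or 180)
#'   `rot` is fixed at 0 and the full in-plane rotation is carried by
#'   `psi`; the matrix round-trip is exact even though the individual
#'   angles are then not unique.
#' @export
matrix_to_euler <- function(m) {
  check_rotation_matrix(m)
  e <- matrix_to_euler_many(matrix(as.numeric(m), 1, 9))
  c(rot = e$rot, tilt = e$tilt, psi = e$psi)
}

# Vectorized ZYZ composition: returns n x 9 matrix of column-major entries.
# M = Rz(rot) %*% Ry(tilt) %*% Rz(psi).
euler_to_matrix_many <- function(rot, tilt, psi) {
  r <- rot * pi / 180; t <- tilt * pi / 180; p <- psi * pi / 180
  cr <- cos(r); sr <- sin(r); ct <- cos(t); st <- sin(t)
  cp <- cos(p); sp <- sin(p)
  cbind(
    cr * ct * cp - sr * sp,   # m11
    sr * ct * cp + cr * sp,   # m21
    -st * cp,                 # m31
    -cr * ct * sp - sr * cp,  # m12
    -sr * ct * sp + cr * cp,  # m22
    st * sp,                  # m32
    cr * st,                  # m13
    sr * st,                  # m23
    ct                        # m33
  )
}

# Vectorized inverse of euler_to_matrix_many on n x 9 input.
matrix_to_euler_many <- function(m9, lock_tol = 1e-8) {
  m11 <- m9[, 1]; m21 <- m9[, 2]; m31 <- m9[, 3]
  m12 <- m9[, 4]; m22 <- m9[, 5]; m32 <- m9[, 6]
  m13 <- m9[, 7]; m23 <- m9[, 8]; m33 <- m9[, 9]
  tilt <- acos(pmin(1, pmax(-1, m33))) * 180 / pi
  rot <- atan2(m23, m13) * 180 / pi
  psi <- atan2(m32, -m31) * 180 / pi
  # Gimbal lock: tilt ~ 0 -> M = Rz(rot+psi); tilt ~ 180 -> M = Rz(rot-psi)Ry(180).
  up <- abs(m33 - 1) < lock_tol
  dn <- abs(m33 + 1) < lock_tol
  if (any(up)) {
    rot[up] <- 0
    psi[up] <- atan2(m21[up], m11[up]) * 180 / pi
    tilt[up] <- 0
  }
  if (any(dn)) {
    rot[dn] <- 0
    psi[dn] <- atan2(m21[dn], m22[dn]) * 180 / pi
    tilt[dn] <- 180
  }
  list(rot = wrap_angle(rot), tilt = tilt, psi = wrap_angle(psi))
}

# Wrap angles (degrees) into [-180, 180).
wrap_angle <- function(a) {
  ((a + 180) %% 360) - 180
}

check_rotation_matrix <- function(m, tol = 1e-6) {
  if (!is.matrix(m) || !all(dim(m) == c(3, 3)) || !is.numeric(m)) {
    stop("invalid rotation: expected a numeric 3x3 matrix", call. = FALSE)
  }
  if (max(abs(crossprod(m) - diag(3))) > tol || abs(det(m) - 1) > tol) {
    stop("invalid rotation: matrix is not a proper rotation (orthonormal, det +1)",
         call. = FALSE)
  }
  invisible(m)
}

# Rodrigues rotation about a (not necessarily unit) axis by angle degrees.
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle * pi / 180
  k <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * k + (1 - cos(a)) * (k %*% k)
}

#' Rotation point groups
#'
#' Generate the full set of rotation matrices for a named point group:
#' cyclic `Cn`, dihedral `Dn`, tetrahedral `T` (order 12), octahedral `O`
#' (order 24, fourfold axes on the coordinate axes) or icosahedral `I`
#' (order 60). The icosahedral setting follows the common I2 convention
#' with twofold axes on x, y and z, so the threefold axes lie along the
#' body diagonals (e.g. `(1,1,1)`) and fivefold axes along
#' `(0, 1, phi)` and its even permutations.
#'
#' @param label Symmetry label, e.g. `"C1"`, `"C6"`, `"D7"`, `"T"`,
#'   `"O"`, `"I"`.
#' @return An object of class `point_group`: a list with elements
#'   `label`, `order` and `matrices` (list of 3x3 rotation matrices, the
#'   identity first).
#' @examples
#' point_group("O")$order
#' @export
point_group <- function(label) {
  if (inherits(label, "point_group")) return(label)
  if (!is.character(label) || length(label) != 1) {
    stop("unsupported symmetry: label must be a single string", call. = FALSE)
  }
  lab <- toupper(trimws(label))
  cached <- .group_cache[[lab]]
  if (!is.null(cached)) return(cached)
  phi <- (1 + sqrt(5)) / 2
  mats <- if (grepl("^C[0-9]+$", lab)) {
    n <- as.integer(sub("^C", "", lab))
    if (n < 1) stop("unsupported symmetry: ", label, call. = FALSE)
    lapply(seq_len(n) - 1L, function(k) rotation_about_axis(c(0, 0, 1), 360 * k / n))
  } else if (grepl("^D[0-9]+$", lab)) {
    n <- as.integer(sub("^D", "", lab))
    if (n < 1) stop("unsupported symmetry: ", label, call. = FALSE)
    cn <- lapply(seq_len(n) - 1L, function(k) rotation_about_axis(c(0, 0, 1), 360 * k / n))
    flips <- lapply(seq_len(n) - 1L, function(k) {
      rotation_about_axis(c(cos(pi * k / n), sin(pi * k / n), 0), 180)
    })
    c(cn, flips)
  } else if (lab == "T") {
    group_closure(list(rotation_about_axis(c(0, 0, 1), 180),
                       rotation_about_axis(c(1, 1, 1), 120)), 12)
  } else if (lab == "O") {
    group_closure(list(rotation_about_axis(c(0, 0, 1), 90),
                       rotation_about_axis(c(1, 1, 1), 120)), 24)
  } else if (lab == "I") {
    group_closure(list(rotation_about_axis(c(0, 1, phi), 72),
                       rotation_about_axis(c(1, 1, 1), 120)), 60)
  } else {
    stop("unsupported symmetry: ", label, call. = FALSE)
  }
  mats <- canonical_group_order(mats)
  out <- structure(list(label = lab, order = length(mats), matrices = mats),
                   class = "point_group")
  .group_cache[[lab]] <- out
  out
}

.group_cache <- new.env(parent = emptyenv())

# Closure of a generator set under multiplication, deduplicated.
group_closure <- function(generators, expected_order, tol = 1e-9) {
  elems <- list(diag(3))
  frontier <- generators
  repeat {
    new_elems <- list()
    for (g in frontier) {
      for (e in elems) {
        cand <- g %*% e
        known <- any(vapply(c(elems, new_elems),
                            function(x) max(abs(x - cand)) < tol, logical(1)))
        if (!known) new_elems[[length(new_elems) + 1]] <- cand
      }
    }
    if (length(new_elems) == 0) break
    elems <- c(elems, new_elems)
    frontier <- new_elems
    if (length(elems) > 4 * expected_order) {
      stop("group closure did not terminate; generators inconsistent", call. = FALSE)
    }
  }
  if (length(elems) != expected_order) {
    stop("group closure produced ", length(elems), " elements, expected ",
         expected_order, call. = FALSE)
  }
  elems
}

# Deterministic element order: identity first, then lexicographic on
# rounded entries, so expansions are reproducible across sessions.
canonical_group_order <- function(mats) {
  keys <- vapply(mats, function(m) {
    paste(sprintf("%+.6f", as.numeric(m)), collapse = ",")
  }, character(1))
  is_id <- vapply(mats, function(m) max(abs(m - diag(3))) < 1e-9, logical(1))
  ord <- order(!is_id, keys)
  mats[ord]
}

#' @export
print.point_group <- function(x, ...) {
  cat("<point_group> ", x$label, " (order ", x$order, ")\n", sep = "")
  invisible(x)
}

#' Subunit vector
#'
#' A subunit is located by a vector from the center of the complex to
#' the center of the subunit, given as a unit direction and a length in
#' Angstrom.
#'
#' @param direction Numeric 3-vector; normalized internally.
#' @param length Length in Angstrom. If `NULL`, taken as the norm of
#'   `direction`.
#' @return An object of class `subunit_vector` with fields `direction`
#'   (unit 3-vector) and `length` (Angstrom).
#' @examples
#' subunit_vector(c(1, 1, 0), length = 280)
#' @export
subunit_vector <- function(direction, length = NULL) {
  stopifnot(is.numeric(direction), length(direction) == 3, all(is.finite(direction)))
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("subunit vector has zero length", call. = FALSE)
  if (is.null(length)) length <- nrm
  if (!is.finite(length) || length <= 0) {
    stop("subunit vector length must be positive", call. = FALSE)
  }
  structure(list(direction = direction / nrm, length = as.numeric(length)),
            class = "subunit_vector")
}

#' @export
print.subunit_vector <- function(x, ...) {
  cat(sprintf("<subunit_vector> direction (%.4f, %.4f, %.4f), length %.2f A\n",
              x$direction[1], x$direction[2], x$direction[3], x$length))
  invisible(x)
}

#' Rotation aligning the reference axis with a subunit vector
#'
#' Returns the minimal rotation taking the reference direction `(0,0,1)`
#' onto the vector's direction: the rotation axis is
#' `(0,0,1) x direction` and the angle is the angle between the two.
#' The free azimuthal degree of freedom is thereby fixed. The
#' anti-parallel case `(0,0,-1)` is degenerate and is resolved, stably,
#' as a 180-degree rotation about x.
#'
#' @param v A [subunit_vector()] (or numeric 3-vector).
#' @return A 3x3 rotation matrix `M` with `M %*% c(0,0,1)` equal to the
#'   vector's direction.
#' @export
vector_to_matrix <- function(v) {
  d <- if (inherits(v, "subunit_vector")) v$direction else {
    v / sqrt(sum(v^2))
  }
  cz <- d[3]
  if (cz > 1 - 1e-12) return(diag(3))
  if (cz < -1 + 1e-12) return(rotation_about_axis(c(1, 0, 0), 180))
  axis <- c(-d[2], d[1], 0) # (0,0,1) x d
  rotation_about_axis(axis, acos(cz) * 180 / pi)
}

#' Sub-particle pose and position from a particle pose
#'
#' Composes the whole-particle orientation with a symmetry operator and
#' the subunit-vector rotation to give the orientation of one
#' sub-particle, together with the offset of the subunit center in the
#' particle's image frame. The composition is
#' `M_sub = M_particle %*% M_sym %*% M_vec`, and the offset is
#' `M_particle %*% M_sym %*% (length * direction)`: components 1-2 are
#' the in-plane displacement (Angstrom) from the particle center and
#' component 3 is the height above the image plane, along the beam.
#'
#' @param particle_matrix 3x3 rotation matrix of the particle pose.
#' @param sym_matrix 3x3 rotation matrix of the symmetry operator.
#' @param v A [subunit_vector()].
#' @return A list with `matrix` (3x3 sub-particle rotation) and `offset`
#'   (numeric 3-vector, Angstrom).
#' @export
subparticle_pose <- function(particle_matrix, sym_matrix, v) {
  stopifnot(inherits(v, "subunit_vector"))
  ps <- particle_matrix %*% sym_matrix
  list(matrix = ps %*% vector_to_matrix(v),
       offset = as.numeric(ps %*% (v$length * v$direction)))
}

# Decompose a group orbit of a direction into distinct sites.
#
# Returns, for each symmetry-distinct position of `length * direction`,
# the site position (A), and the coset of group elements mapping the
# reference direction there, ordered canonically by their residual
# in-plane angle (the rotation about the subunit axis relative to the
# first coset member). Positions closer than `merge_tol` A are merged.
orbit_sites <- function(group, v, merge_tol) {
  d <- v$direction
  pos <- lapply(group$matrices, function(g) as.numeric(g %*% d) * v$length)
  site_of <- integer(length(pos))
  centers <- list()
  for (i in seq_along(pos)) {
    hit <- 0L
    for (s in seq_along(centers)) {
      if (sqrt(sum((pos[[i]] - centers[[s]])^2)) < merge_tol) { hit <- s; break }
    }
    if (hit == 0L) {
      centers[[length(centers) + 1]] <- pos[[i]]
      hit <- length(centers)
    }
    site_of[i] <- hit
  }
  mv <- vector_to_matrix(v)
  lapply(seq_along(centers), function(s) {
    idx <- which(site_of == s)
    g_rep <- group$matrices[[idx[1]]]
    # residual in-plane angle of each coset member relative to the representative
    ang <- vapply(idx, function(i) {
      w <- t(mv) %*% t(g_rep) %*% group$matrices[[i]] %*% mv
      (atan2(w[2, 1], w[1, 1]) * 180 / pi) %% 360
    }, numeric(1))
    ord <- order(round(ang, 6))
    list(position = centers[[s]],
         matrices = lapply(idx[ord], function(i) group$matrices[[i]]),
         angles = ang[ord])
  })
}
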