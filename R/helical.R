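# Helical screw symmetry: parameters, crossover distance, screw operators,
# stack expansion and screw-parameter fitting from consecutive rungs.
#
# Sign convention (stated once, used everywhere): twist is the signed rotation
# in degrees per subunit about the screw-axis direction under the right-hand
# rule, with the direction chosen so that the rise is positive. A negative
# twist therefore denotes a left-handed screw, matching the convention in
# which MSA alpha-synuclein filaments have twist about -1.34 to -1.42 degrees
# and rise 4.76 A.

#' Helical screw parameters
#'
#' @param twist signed rotation per subunit, degrees. Negative = left-handed
#'   (right-hand rule about the axis direction, rise positive).
#' @param rise translation per subunit along the axis, Angstrom, > 0.
#' @return object of class `helical_params`.
#' @export
#' @examples
#' helical_params(-1.42, 4.76)
helical_params <- function(twist, rise) {
  if (!is_scalar_num(twist) || !is_scalar_num(rise)) {
    stop_fibril("twist and rise must be finite scalars", "fibril_value_error")
  }
  if (rise <= 0) stop_fibril("rise must be > 0", "fibril_value_error")
  if (abs(twist) > 180 || twist == 0) {
    stop_fibril("twist must satisfy 0 < |twist| <= 180 degrees",
                "fibril_value_error")
  }
  structure(list(twist = twist, rise = rise), class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("<helical_params> twist %.4f deg/subunit, rise %.4f A/subunit\n",
              x$twist, x$rise))
  cat(sprintf("  crossover distance: %.1f A\n", crossover_distance(x)))
  invisible(x)
}

#' Screw axis
#'
#' @param origin point on the axis (Angstrom), length-3.
#' @param direction axis direction; normalised internally, must be nonzero.
#' @return object of class `screw_axis`.
#' @export
screw_axis <- function(origin = c(0, 0, 0), direction = c(0, 0, 1)) {
  stopifnot(length(origin) == 3L, length(direction) == 3L,
            all(is.finite(origin)), all(is.finite(direction)))
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop_fibril("axis direction must be nonzero", "fibril_value_error")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction) / n),
            class = "screw_axis")
}

#' Crossover distance of a twisted filament
#'
#' The axial distance over which the flattened-ribbon appearance of a
#' two-fold-symmetric twisted filament repeats (the half pitch):
#' `rise * 180 / |twist|`. For MSA-like parameters (-1.42 deg, 4.76 A) this
#' is about 603 A, consistent with the ~600 A crossovers seen in 2D class
#' averages.
#'
#' @param params [helical_params()].
#' @return crossover distance in Angstrom.
#' @export
#' @examples
#' crossover_distance(helical_params(-1.42, 4.76)) # ~603 A
crossover_distance <- function(params) {
  stopifnot(inherits(params, "helical_params"))
  if (params$twist == 0) {
    stop_fibril("crossover undefined for zero twist", "fibril_geometry_error")
  }
  params$rise * 180 / abs(params$twist)
}

#' Rigid screw operator
#'
#' The rigid transform realising one helical step: rotation by `twist`
#' degrees about the axis direction (right-hand rule) composed with a
#' translation of `rise` along the direction.
#'
#' @param params [helical_params()].
#' @param axis [screw_axis()].
#' @return object of class `rigid_transform` with elements `R` (3x3 rotation)
#'   and `t` (length-3 translation); apply with [apply_transform()].
#' @export
screw_operator <- function(params, axis = screw_axis()) {
  stopifnot(inherits(params, "helical_params"), inherits(axis, "screw_axis"))
  R <- rotation_about_axis(params$twist * pi / 180, axis$direction)
  # x' = R (x - o) + o + rise * u  =  R x + t
  t <- axis$origin - R %*% axis$origin + params$rise * axis$direction
  rigid_transform(R, as.numeric(t))
}

#' Rigid transform constructor
#' @param R 3x3 proper rotation matrix.
#' @param t length-3 translation.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L)
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param tf a `rigid_transform`.
#' @param x n x 3 coordinate matrix, length-3 vector, atom table, or any
#'   atom-bearing container (`filament_model`, `rung`, `protofilament_fold`).
#' @return transformed object of the same kind.
#' @export
apply_transform <- function(tf, x) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.numeric(x) && is.null(dim(x))) {
    return(as.numeric(tf$R %*% x + tf$t))
  }
  if (is.matrix(x)) {
    return(t(tf$R %*% t(x)) + matrix(tf$t, nrow(x), 3, byrow = TRUE))
  }
  if (inherits(x, c("filament_model", "rung", "protofilament_fold"))) {
    x$atoms <- set_coords(x$atoms, apply_transform(tf, coords(x$atoms)))
    return(x)
  }
  atoms <- atom_table(x)
  set_coords(atoms, apply_transform(tf, coords(atoms)))
}

#' Compose two rigid transforms
#' @param a,b `rigid_transform`s; the result applies `b` first, then `a`.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t + a$t))
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return a `rigid_transform` undoing `tf`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

# Rodrigues rotation about a unit axis, angle in radians
rotation_about_axis <- function(angle, u) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Expand a rung into a helical stack
#'
#' Applies the screw operator 0..n-1 times to produce an n-rung filament
#' model (the "translate the model into a stack" step of map-model building).
#'
#' @param rung a [rung()] (rung 0 of the output).
#' @param params [helical_params()].
#' @param n number of rungs, >= 1.
#' @param axis [screw_axis()]; default z axis through the origin.
#' @param type_label type label for the output model.
#' @return a [filament_model()] with rung indices `0..n-1` and `params`
#'   stored as its helical parameters.
#' @export
expand_stack <- function(rung, params, n, axis = screw_axis(),
                         type_label = "synthetic") {
  stopifnot(inherits(rung, "rung"))
  if (!is_scalar_num(n) || n < 1) {
    stop_fibril("n must be >= 1", "fibril_argument_error")
  }
  n <- as.integer(n)
  op <- screw_operator(params, axis)
  base <- rung$atoms
  base$rung_index <- 0L
  out <- vector("list", n)
  out[[1L]] <- base
  cur <- base
  for (i in seq_len(n - 1L)) {
    cur <- set_coords(cur, apply_transform(op, coords(cur)))
    cur$rung_index <- i
    out[[i + 1L]] <- cur
  }
  filament_model(do.call(rbind, out), type_label = type_label, helical = params)
}

#' Fit helical screw parameters from two rungs
#'
#' Superposes `rung_i` onto `rung_j` (Kabsch over atoms paired by fold label,
#' residue number and atom name) and decomposes the resulting rigid transform
#' into a screw: rotation angle about the screw axis -> twist (sign per the
#' package convention, axis direction chosen so rise > 0), translation along
#' the axis -> rise. The inverse of [expand_stack()] for adjacent rungs.
#'
#' @param rung_i,rung_j two [rung()]s sharing fold labels and atoms.
#' @param degenerate_tol twist magnitudes below this (degrees) are treated as
#'   a degenerate screw (no meaningful axis); default 1e-4.
#' @return list with elements `params` ([helical_params()]), `axis`
#'   ([screw_axis()] with origin nearest the centroid of `rung_i`), and
#'   `rmsd` of the superposition.
#' @export
fit_helical_params <- function(rung_i, rung_j, degenerate_tol = 1e-4) {
  ai <- as_atoms(rung_i); aj <- as_atoms(rung_j)
  key <- function(a) paste(a$fold_label, a$residue_number, a$atom_name, sep = "|")
  ki <- key(ai); kj <- key(aj)
  common <- intersect(ki, kj)
  if (length(common) == 0L) {
    stop_fibril("no paired atoms between rungs", "fibril_pairing_error")
  }
  P <- coords(ai)[match(common, ki), , drop = FALSE]
  Q <- coords(aj)[match(common, kj), , drop = FALSE]
  fit <- kabsch(P, Q)
  R <- fit$R
  tr <- sum(diag(R))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  sv <- sqrt(sum(v^2))
  angle <- atan2(sv, (tr - 1) / 2)          # in [0, pi]
  if (abs(angle) * 180 / pi < degenerate_tol) {
    stop_fibril("degenerate screw: rotation angle ~ 0", "fibril_degenerate_screw_error")
  }
  if (sv < 1e-12) {
    # angle == pi: axis from R + I columns
    M <- R + diag(3)
    u <- M[, which.max(colSums(M^2))]
  } else {
    u <- v / sv
  }
  t_full <- fit$t
  rise <- sum(t_full * u)
  twist <- angle * 180 / pi
  if (rise < 0) {       # flip axis so rise is positive; rotation sense flips
    u <- -u; rise <- -rise; twist <- -twist
  }
  # point on axis: (I - R) p = t_perp, solved in the plane orthogonal to u
  e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  t_perp <- t_full - rise * u
  M <- cbind((diag(3) - R) %*% e1, (diag(3) - R) %*% e2)
  ab <- qr.solve(M, t_perp)
  p <- ab[1] * e1 + ab[2] * e2
  centroid <- colMeans(P)
  origin <- p + sum((centroid - p) * u) * u
  list(params = helical_params(twist, rise),
       axis = screw_axis(origin, u),
       rmsd = fit$rmsd)
}
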