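# Fold and filament comparison: Kabsch superposition, all-atom RMSD,
# per-residue C-alpha displacement profiles, and contact maps.

# Kabsch least-squares superposition of P onto Q (n x 3 matrices, paired
# rows). Returns the proper rotation R (det +1), translation t such that
# P %*% t(R) + t approximates Q, and the residual RMSD.
kabsch <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), all(dim(P) == dim(Q)), ncol(P) == 3L)
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  H <- crossprod(P0, Q0)                      # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- qc - as.numeric(R %*% pc)
  Pm <- t(R %*% t(P)) + matrix(t, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Pm - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Pair atoms between two structures
#'
#' Builds the one-to-one atom pairing used for superposition and RMSD:
#' atoms are matched by protofilament role (A/B, so e.g. PF-IA2 pairs with
#' PF-IIA across filament types), residue number and atom name, within
#' matching rung offsets.
#'
#' @param a,b atom-bearing objects ([filament_model()], [rung()],
#'   [protofilament_fold()] or atom tables).
#' @param atoms restrict to these atom names (e.g. `"CA"`); `NULL` = all
#'   common heavy atoms.
#' @param residues restrict to these residue numbers; `NULL` = all.
#' @param by_fold match folds by role (`"role"`, default), exact label
#'   (`"label"`), or ignore fold identity (`"none"`, valid when each side has
#'   a single fold).
#' @return object of class `atom_pairing`: list with integer index vectors
#'   `ia`, `ib` and a `selection` description.
#' @export
atom_pairing <- function(a, b, atoms = NULL, residues = NULL,
                         by_fold = c("role", "label", "none")) {
  by_fold <- match.arg(by_fold)
  aa <- as_atoms(a); ab <- as_atoms(b)
  fa <- switch(by_fold,
               role = fold_role(aa$fold_label),
               label = aa$fold_label,
               none = rep("*", nrow(aa)))
  fb <- switch(by_fold,
               role = fold_role(ab$fold_label),
               label = ab$fold_label,
               none = rep("*", nrow(ab)))
  # rung offsets normalised so the lowest present rung matches on both sides
  ra <- aa$rung_index - min(aa$rung_index)
  rb <- ab$rung_index - min(ab$rung_index)
  ka <- paste(ra, fa, aa$residue_number, aa$atom_name, sep = "|")
  kb <- paste(rb, fb, ab$residue_number, ab$atom_name, sep = "|")
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop_fibril("ambiguous atom keys; pairing is not one-to-one",
                "fibril_pairing_error")
  }
  keep_a <- rep(TRUE, nrow(aa)); keep_b <- rep(TRUE, nrow(ab))
  if (!is.null(atoms)) {
    keep_a <- keep_a & aa$atom_name %in% atoms
    keep_b <- keep_b & ab$atom_name %in% atoms
  }
  if (!is.null(residues)) {
    keep_a <- keep_a & aa$residue_number %in% residues
    keep_b <- keep_b & ab$residue_number %in% residues
  }
  common <- intersect(ka[keep_a], kb[keep_b])
  if (length(common) == 0L) {
    stop_fibril("empty atom pairing", "fibril_pairing_error")
  }
  structure(
    list(ia = match(common, ka), ib = match(common, kb),
         selection = sprintf("%d paired atoms (%s%s)", length(common),
                             if (is.null(atoms)) "all heavy atoms"
                             else paste(atoms, collapse = ","),
                             if (is.null(residues)) ""
                             else sprintf("; residues %d-%d", min(residues),
                                          max(residues)))),
    class = "atom_pairing"
  )
}

#' Kabsch superposition of one atom set onto another
#'
#' Least-squares rigid superposition (proper rotation only) of `mobile` onto
#' `reference` over a pairing.
#'
#' @param mobile,reference atom-bearing objects.
#' @param pairing an [atom_pairing()]; default pairs all common heavy atoms.
#' @return list with `transform` (a [rigid_transform()] taking mobile
#'   coordinates onto the reference frame) and `rmsd` (Angstrom) over the
#'   pairing.
#' @export
superpose <- function(mobile, reference,
                      pairing = atom_pairing(mobile, reference)) {
  am <- as_atoms(mobile); ar <- as_atoms(reference)
  P <- coords(am)[pairing$ia, , drop = FALSE]
  Q <- coords(ar)[pairing$ib, , drop = FALSE]
  if (nrow(P) < 3L) {
    stop_fibril("need >= 3 atom pairs to superpose", "fibril_degenerate_superposition_error")
  }
  P0 <- sweep(P, 2, colMeans(P))
  if (qr(P0)$rank < 2L) {
    stop_fibril("collinear points: superposition is degenerate",
                "fibril_degenerate_superposition_error")
  }
  fit <- kabsch(P, Q)
  list(transform = rigid_transform(fit$R, fit$t), rmsd = fit$rmsd)
}

#' All-atom RMSD between two models, rungs or folds
#'
#' Superposes on the full common heavy-atom pairing and reports the RMSD over
#' that same pairing. For whole filament models the central rung of each is
#' compared by default (edge rungs of deposited stacks can be sparser).
#'
#' @param a,b atom-bearing objects.
#' @param rung which rung to take from a multi-rung model: `"central"`
#'   (default), an index, or `"all"` for the whole stack.
#' @param by_fold fold matching mode, see [atom_pairing()].
#' @return RMSD in Angstrom, with attributes `n_atoms` and `selection`.
#' @export
rmsd_all_atom <- function(a, b, rung = "central",
                          by_fold = c("role", "label", "none")) {
  by_fold <- match.arg(by_fold)
  take <- function(x) {
    if (inherits(x, "filament_model") && !identical(rung, "all") &&
        n_rungs(x) > 1L) get_rung(x, rung) else x
  }
  a <- take(a); b <- take(b)
  pr <- atom_pairing(a, b, by_fold = by_fold)
  fit <- superpose(a, b, pr)
  structure(fit$rmsd, n_atoms = length(pr$ia), selection = pr$selection)
}

#' Per-residue C-alpha displacement profile between two folds
#'
#' Superposes `fold_a` onto `fold_b` using C-alpha atoms of an alignment
#' selection, then reports per-residue C-alpha--C-alpha distances over a
#' measurement range and their arithmetic mean. This is the standard way of
#' quantifying a local conformational change between two protofilament folds
#' after anchoring on their conformationally shared region. The default
#' alignment anchor in fold-pair comparisons of this kind is the shared
#' N-terminal region; the alignment may also be carried by a different fold
#' of the same filament (pass `align_a`/`align_b`).
#'
#' @param fold_a,fold_b atom-bearing objects to measure between.
#' @param align residue numbers used for the C-alpha alignment (vector or
#'   `c(first, last)` range).
#' @param measure residue range `c(first, last)` over which to report
#'   displacements.
#' @param align_a,align_b objects carrying the alignment atoms; default the
#'   measured folds themselves.
#' @return object of class `displacement_profile`: data.frame with columns
#'   `residue`, `distance` (Angstrom), plus attributes `mean` (Angstrom),
#'   `measure_range`, `alignment` and `excluded` (residues unresolved in
#'   either input).
#' @export
ca_displacement <- function(fold_a, fold_b, align, measure,
                            align_a = fold_a, align_b = fold_b) {
  if (length(align) == 2L) align <- seq(align[1], align[2])
  stopifnot(length(measure) == 2L)
  pr <- atom_pairing(align_a, align_b, atoms = "CA", residues = align,
                     by_fold = "none")
  fit <- superpose(align_a, align_b, pr)
  aa <- as_atoms(fold_a); ab <- as_atoms(fold_b)
  ca_a <- aa[aa$atom_name == "CA", ]
  ca_b <- ab[ab$atom_name == "CA", ]
  wanted <- seq(measure[1], measure[2])
  common <- intersect(intersect(wanted, ca_a$residue_number),
                      ca_b$residue_number)
  excluded <- setdiff(wanted, common)
  if (length(common) == 0L) {
    stop_fibril("no resolved residues in the measurement range",
                "fibril_selection_error")
  }
  pa <- apply_transform(fit$transform,
                        coords(ca_a)[match(common, ca_a$residue_number), ,
                                     drop = FALSE])
  pb <- coords(ca_b)[match(common, ca_b$residue_number), , drop = FALSE]
  d <- sqrt(rowSums((pa - pb)^2))
  structure(
    data.frame(residue = common, distance = d),
    mean = mean(d),
    measure_range = measure,
    alignment = sprintf("CA of residues %d-%d (rmsd %.3f A)",
                        min(align), max(align), fit$rmsd),
    excluded = excluded,
    class = c("displacement_profile", "data.frame")
  )
}

#' @export
print.displacement_profile <- function(x, ...) {
  cat(sprintf("<displacement_profile> residues %d-%d, mean %.2f A\n",
              attr(x, "measure_range")[1], attr(x, "measure_range")[2],
              attr(x, "mean")))
  cat(sprintf("  alignment: %s\n", attr(x, "alignment")))
  if (length(attr(x, "excluded"))) {
    cat("  excluded (unresolved):", paste(attr(x, "excluded"), collapse = ","),
        "\n")
  }
  invisible(x)
}

#' Mean of a displacement profile
#' @param x a `displacement_profile`.
#' @param ... ignored.
#' @return mean C-alpha displacement, Angstrom.
#' @export
mean.displacement_profile <- function(x, ...) attr(x, "mean")

# Grid-hash neighbour search: all unordered pairs (i, j), i < j, with
# distance <= cutoff. Exact (cell side = cutoff, 27-neighbourhood scan).
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), distance = numeric()))
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  buckets <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  res_i <- list(); res_j <- list(); res_d <- list(); k <- 0L
  for (b in names(buckets)) {
    ib <- buckets[[b]]
    c0 <- as.integer(strsplit(b, ",", fixed = TRUE)[[1]])
    neigh <- unlist(lapply(seq_len(nrow(offs)), function(o) {
      buckets[[paste(c0[1] + offs[o, 1], c0[2] + offs[o, 2],
                     c0[3] + offs[o, 3], sep = ",")]]
    }), use.names = FALSE)
    if (is.null(neigh)) next
    for (i in ib) {
      cand <- neigh[neigh > i]
      if (length(cand) == 0L) next
      dd <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
      ok <- dd <= cutoff
      if (any(ok)) {
        k <- k + 1L
        res_i[[k]] <- rep.int(i, sum(ok))
        res_j[[k]] <- cand[ok]
        res_d[[k]] <- dd[ok]
      }
    }
  }
  if (k == 0L) return(data.frame(i = integer(), j = integer(), distance = numeric()))
  out <- data.frame(i = unlist(res_i), j = unlist(res_j),
                    distance = unlist(res_d))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Non-bonded heavy-atom contact map
#'
#' All heavy-atom pairs within `cutoff`, annotated by the residues involved.
#' Pairs within the same residue, and backbone-backbone pairs of directly
#' adjacent residues in the same chain and rung, are excluded as bonded/1-3
#' geometry. Typical cutoffs: 3.5 A for polar contacts, 4.5 A for hydrophobic
#' packing.
#'
#' @param model atom-bearing object (>= 2 rungs required for `scope =
#'   "inter"`).
#' @param cutoff distance cutoff, Angstrom, > 0.
#' @param scope `"intra"` (within a rung), `"inter"` (between different
#'   rungs) or `"all"`.
#' @return data.frame with one row per contact: atom annotations for both
#'   partners (`*_i`, `*_j`) and `distance`.
#' @export
contact_map <- function(model, cutoff = 3.5, scope = c("all", "intra", "inter")) {
  scope <- match.arg(scope)
  if (!is_scalar_num(cutoff) || cutoff <= 0) {
    stop_fibril("cutoff must be > 0", "fibril_argument_error")
  }
  atoms <- as_atoms(model)
  if (scope == "inter" && length(unique(atoms$rung_index)) < 2L) {
    stop_fibril("inter-rung scope needs >= 2 rungs", "fibril_argument_error")
  }
  pr <- neighbor_pairs(coords(atoms), cutoff)
  annotate_pairs(atoms, pr, scope)
}

# shared by contact_map and count_clashes
annotate_pairs <- function(atoms, pr, scope = "all") {
  if (nrow(pr) > 0L) {
    same_rung <- atoms$rung_index[pr$i] == atoms$rung_index[pr$j]
    if (scope == "intra") pr <- pr[same_rung, , drop = FALSE]
    if (scope == "inter") pr <- pr[!same_rung, , drop = FALSE]
  }
  if (nrow(pr) > 0L) {
    same_unit <- atoms$chain_id[pr$i] == atoms$chain_id[pr$j] &
      atoms$rung_index[pr$i] == atoms$rung_index[pr$j] &
      atoms$fold_label[pr$i] == atoms$fold_label[pr$j]
    dres <- abs(atoms$residue_number[pr$i] - atoms$residue_number[pr$j])
    bonded <- same_unit & (dres == 0L |
      (dres == 1L & atoms$atom_name[pr$i] %in% .backbone_atoms &
         atoms$atom_name[pr$j] %in% .backbone_atoms))
    pr <- pr[!bonded, , drop = FALSE]
  }
  ann <- function(col, idx) atoms[[col]][idx]
  out <- data.frame(
    i = pr$i, j = pr$j,
    chain_i = ann("chain_id", pr$i), rung_i = ann("rung_index", pr$i),
    fold_i = ann("fold_label", pr$i), residue_i = ann("residue_number", pr$i),
    resname_i = ann("residue_name", pr$i), atom_i = ann("atom_name", pr$i),
    element_i = ann("element", pr$i),
    chain_j = ann("chain_id", pr$j), rung_j = ann("rung_index", pr$j),
    fold_j = ann("fold_label", pr$j), residue_j = ann("residue_number", pr$j),
    resname_j = ann("residue_name", pr$j), atom_j = ann("atom_name", pr$j),
    element_j = ann("element", pr$j),
    distance = pr$distance
  )
  rownames(out) <- NULL
  out
}
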