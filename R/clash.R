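# Hybrid mixed-polymorph cofilament modelling and inter-rung steric clash
# counting.
#
# Rationale: two filament polymorphs whose protofilament folds agree only
# over a homologous residue window could in principle stack into one mixed
# "cofilament". Building that hybrid explicitly -- one rung of type B placed
# into the lattice of a type A stack by superposing the homologous window --
# and counting van der Waals overlaps between adjacent rungs tests whether
# the mixed interface is sterically possible. For the MSA alpha-synuclein
# Type I2/II2 pair (shared window: residues 57-93 of the A protofilament)
# the hybrid shows severe clashes in the nonhomologous regions, arguing that
# apparent within-filament type mixtures are classification noise.

# Published single-element van der Waals radii (Angstrom). The clash
# criterion is overlap = r_i + r_j - d >= threshold; 0.4 A is the usual
# "clash" threshold, 0.6 A "severe".
.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
.vdw_default <- 1.70

#' Van der Waals radius of an element
#' @param element character vector of element symbols.
#' @return numeric radii in Angstrom (unknown elements get 1.70).
#' @export
vdw_radius <- function(element) {
  r <- .vdw_table[toupper(element)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

#' Build a hybrid two-rung cofilament model
#'
#' Places a rung of one filament type into the lattice of a stack of another
#' type: the incoming rung is superposed, using C-alpha atoms of the
#' homologous residue window of its A-role protofilament, onto the rung
#' above the junction rung of the host stack. The junction rung `k` is the
#' central rung of the host (consistent with the comparison conventions
#' elsewhere in the package). The result is a two-rung model -- host rung
#' `k` (rung index 0) plus the placed rung (rung index 1) -- carrying
#' metadata used by [count_clashes()] to split clashes into homologous
#' window versus nonhomologous remainder.
#'
#' @param stack_a host [filament_model()] with >= 2 rungs.
#' @param rung_b incoming [rung()] (or single-rung model) of the other type.
#' @param homolog_selection inclusive residue range `c(first, last)` shared
#'   between the two A-role folds (e.g. `c(57, 93)`).
#' @param fold fold label carrying the homologous window; default: the
#'   A-role fold of each input (or its only fold).
#' @return a [filament_model()] with `type_label = "hybrid"`, attributes
#'   `homolog_range`, `placed_rung` (= 1) and `superposition_rmsd`.
#' @export
build_hybrid <- function(stack_a, rung_b, homolog_selection, fold = NULL) {
  stopifnot(inherits(stack_a, "filament_model"))
  if (inherits(rung_b, "filament_model")) rung_b <- get_rung(rung_b)
  stopifnot(inherits(rung_b, "rung"), length(homolog_selection) == 2L)
  idx <- sort(unique(stack_a$atoms$rung_index))
  if (length(idx) < 2L) {
    stop_fibril("host stack needs >= 2 rungs", "fibril_argument_error")
  }
  k <- min(idx[floor(length(idx) / 2) + 1L], idx[length(idx) - 1L])
  rung_k <- get_rung(stack_a, k)
  rung_k1 <- get_rung(stack_a, k + 1L)
  pick_fold <- function(r) {
    labs <- fold_labels(r)
    if (!is.null(fold) && fold %in% labs) return(fold)
    arole <- labs[fold_role(labs) == "A"]
    if (length(arole) >= 1L) arole[1] else labs[1]
  }
  fa <- tryCatch(
    select_fold(filament_model(rung_k1$atoms), pick_fold(rung_k1),
                rung = rung_k1$index, residue_range = homolog_selection),
    fibril_selection_error = function(e) {
      stop_fibril(paste0("homolog selection unresolved in host stack: ",
                         conditionMessage(e)), "fibril_selection_error")
    })
  fb <- tryCatch(
    select_fold(filament_model(rung_b$atoms), pick_fold(rung_b),
                rung = rung_b$index, residue_range = homolog_selection),
    fibril_selection_error = function(e) {
      stop_fibril(paste0("homolog selection unresolved in incoming rung: ",
                         conditionMessage(e)), "fibril_selection_error")
    })
  pr <- atom_pairing(fb, fa, atoms = "CA", by_fold = "none")
  fit <- superpose(fb, fa, pr)
  placed <- rung_b$atoms
  placed <- set_coords(placed, apply_transform(fit$transform, coords(placed)))
  placed$rung_index <- 1L
  placed$chain_id <- paste0(placed$chain_id, "'")
  host <- rung_k$atoms
  host$rung_index <- 0L
  out <- filament_model(rbind(host, placed), type_label = "hybrid")
  attr(out, "homolog_range") <- as.integer(homolog_selection)
  attr(out, "homolog_fold") <- c(host = pick_fold(rung_k1),
                                 placed = pick_fold(rung_b))
  attr(out, "placed_rung") <- 1L
  attr(out, "superposition_rmsd") <- fit$rmsd
  out
}

#' Count inter-rung steric clashes
#'
#' Heavy-atom pairs from different rungs whose van der Waals overlap
#' `r_i + r_j - d` is at least `overlap_threshold`. Pairs within one residue
#' and backbone-backbone pairs of adjacent residues in the same chain are
#' excluded (covalent/1-3 geometry). When the model carries hybrid metadata
#' (see [build_hybrid()]) the report is partitioned into clashes inside the
#' homologous window versus the nonhomologous remainder: a clash counts as
#' homologous only if both atoms lie in the homologous window of the
#' window-carrying folds.
#'
#' @param model a [filament_model()] with >= 2 rungs.
#' @param overlap_threshold minimum vdW overlap in Angstrom (default 0.4;
#'   use 0.6 for "severe" clashes).
#' @param scope only `"inter"` (between rungs) is supported.
#' @return object of class `clash_report`: list with `clashes` (data.frame
#'   incl. `overlap`), `count`, `by_region` (named counts, present for
#'   hybrids) and `threshold`.
#' @export
count_clashes <- function(model, overlap_threshold = 0.4, scope = "inter") {
  stopifnot(identical(scope, "inter"))
  atoms <- as_atoms(model)
  if (length(unique(atoms$rung_index)) < 2L) {
    stop_fibril("clash counting needs >= 2 rungs", "fibril_argument_error")
  }
  radii <- vdw_radius(atoms$element)
  cutoff <- 2 * max(radii) - overlap_threshold
  pairs <- annotate_pairs(atoms, neighbor_pairs(coords(atoms), cutoff),
                          scope = "inter")
  pairs$overlap <- radii[pairs$i] + radii[pairs$j] - pairs$distance
  pairs <- pairs[pairs$overlap >= overlap_threshold, , drop = FALSE]
  by_region <- NULL
  hr <- attr(model, "homolog_range")
  if (!is.null(hr) && nrow(pairs) >= 0L) {
    hf <- attr(model, "homolog_fold")
    in_window <- function(res, fold) {
      res >= hr[1] & res <= hr[2] & fold %in% hf
    }
    region <- ifelse(
      in_window(pairs$residue_i, pairs$fold_i) &
        in_window(pairs$residue_j, pairs$fold_j),
      "homologous", "nonhomologous")
    pairs$region <- region
    by_region <- c(homologous = sum(region == "homologous"),
                   nonhomologous = sum(region == "nonhomologous"))
  }
  structure(
    list(clashes = pairs, count = nrow(pairs), by_region = by_region,
         threshold = overlap_threshold),
    class = "clash_report"
  )
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("<clash_report> %d inter-rung clash(es) at overlap >= %.2f A\n",
              x$count, x$threshold))
  if (!is.null(x$by_region)) {
    cat(sprintf("  homologous window: %d, nonhomologous: %d\n",
                x$by_region[["homologous"]], x$by_region[["nonhomologous"]]))
  }
  if (x$count > 0L) {
    cat(sprintf("  max overlap %.2f A (%s%d %s / %s%d %s)\n",
                max(x$clashes$overlap),
                x$clashes$resname_i[which.max(x$clashes$overlap)],
                x$clashes$residue_i[which.max(x$clashes$overlap)],
                x$clashes$atom_i[which.max(x$clashes$overlap)],
                x$clashes$resname_j[which.max(x$clashes$overlap)],
                x$clashes$residue_j[which.max(x$clashes$overlap)],
                x$clashes$atom_j[which.max(x$clashes$overlap)]))
  }
  invisible(x)
}
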