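# Atom tables and the container classes shared by all modules.
#
# Atoms are kept in a plain data.frame with one row per heavy atom:
#   atom_name      PDB atom label ("CA", "CB", ...)
#   element        element symbol ("C", "N", "O", "S", ...)
#   residue_number author (1-based alpha-synuclein) numbering, never renumbered
#   residue_name   3-letter code
#   chain_id       chain label from the source file (or assigned on write)
#   rung_index     helical level, 0 = reference rung
#   fold_label     protofilament fold label ("PF-IA2", "PF-IB", ...)
#   x, y, z        Cartesian coordinates, Angstrom

.atom_cols <- c(
  "atom_name", "element", "residue_number", "residue_name",
  "chain_id", "rung_index", "fold_label", "x", "y", "z"
)

#' Construct/validate an atom table
#'
#' @param df data.frame carrying at least the atom columns (see Details).
#' @return the validated data.frame, columns in canonical order.
#' @details Required columns: `atom_name`, `element`, `residue_number`,
#'   `residue_name`, `chain_id`, `rung_index`, `fold_label`, `x`, `y`, `z`.
#'   Coordinates must be finite; residue numbers >= 1.
#' @export
atom_table <- function(df) {
  missing <- setdiff(.atom_cols, names(df))
  if (length(missing) > 0L) {
    stop_fibril(paste0("atom table missing columns: ",
                       paste(missing, collapse = ", ")), "fibril_schema_error")
  }
  df <- as.data.frame(df)[, .atom_cols]
  df$residue_number <- as.integer(df$residue_number)
  df$rung_index <- as.integer(df$rung_index)
  if (nrow(df) > 0L) {
    if (!all(is.finite(as.matrix(df[, c("x", "y", "z")])))) {
      stop_fibril("non-finite atom coordinates", "fibril_value_error")
    }
    if (any(df$residue_number < 1L)) {
      stop_fibril("residue numbers must be >= 1", "fibril_value_error")
    }
  }
  rownames(df) <- NULL
  df
}

coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

set_coords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Filament model container
#'
#' Ordered rungs of protofilament folds plus (optionally) the helical screw
#' parameters that relate consecutive rungs.
#'
#' @param atoms atom table (see [atom_table()]) covering all rungs.
#' @param type_label filament type: one of `"I1"`, `"I2"`, `"II1"`, `"II2"`,
#'   `"synthetic"`, `"hybrid"`.
#' @param helical optional [helical_params()].
#' @return object of class `filament_model`.
#' @export
filament_model <- function(atoms, type_label = "synthetic", helical = NULL) {
  atoms <- atom_table(atoms)
  if (nrow(atoms) == 0L) {
    stop_fibril("empty model: no protein atoms", "fibril_empty_model_error")
  }
  idx <- sort(unique(atoms$rung_index))
  if (!identical(idx, seq(min(idx), max(idx)))) {
    stop_fibril("rung indices must be consecutive", "fibril_value_error")
  }
  structure(
    list(atoms = atoms, type_label = type_label, helical = helical),
    class = "filament_model"
  )
}

#' @export
print.filament_model <- function(x, ...) {
  cat(sprintf("<filament_model> type %s: %d rungs, %d atoms\n",
              x$type_label, n_rungs(x), nrow(x$atoms)))
  for (f in fold_labels(x)) {
    a <- x$atoms[x$atoms$fold_label == f & x$atoms$rung_index == min(x$atoms$rung_index), ]
    cat(sprintf("  fold %-8s residues %d-%d\n", f,
                min(a$residue_number), max(a$residue_number)))
  }
  if (!is.null(x$helical)) {
    cat(sprintf("  helical: twist %.4f deg, rise %.4f A\n",
                x$helical$twist, x$helical$rise))
  }
  invisible(x)
}

#' Number of rungs in a model
#' @param model a `filament_model`.
#' @return integer count of rungs.
#' @export
n_rungs <- function(model) length(unique(model$atoms$rung_index))

#' Fold labels present in a model or rung
#' @param x a `filament_model` or `rung`.
#' @return character vector of fold labels.
#' @export
fold_labels <- function(x) {
  atoms <- if (inherits(x, "filament_model") || inherits(x, "rung")) x$atoms else x
  sort(unique(atoms$fold_label))
}

#' Extract one rung from a model
#'
#' @param model a `filament_model`.
#' @param index rung index as stored in the model (0-based for generated
#'   stacks), or `"central"` for the central rung `floor(n/2)` — the default
#'   rung used in fold comparisons to avoid stack-edge effects.
#' @return object of class `rung`.
#' @export
get_rung <- function(model, index = "central") {
  idx <- sort(unique(model$atoms$rung_index))
  if (identical(index, "central")) index <- idx[floor(length(idx) / 2) + 1L]
  if (!index %in% idx) {
    stop_fibril(sprintf("no rung with index %s", index), "fibril_selection_error")
  }
  rung(model$atoms[model$atoms$rung_index == index, , drop = FALSE], index = index)
}

#' Rung constructor
#'
#' One helical level of a filament: one copy of each protofilament fold.
#'
#' @param atoms atom table for this level.
#' @param index rung index (default: taken from the atoms).
#' @return object of class `rung`.
#' @export
rung <- function(atoms, index = NULL) {
  atoms <- atom_table(atoms)
  if (is.null(index)) index <- unique(atoms$rung_index)
  if (length(index) != 1L) {
    stop_fibril("a rung must have a single rung_index", "fibril_value_error")
  }
  atoms$rung_index <- as.integer(index)
  structure(list(index = as.integer(index), atoms = atoms), class = "rung")
}

#' @export
print.rung <- function(x, ...) {
  cat(sprintf("<rung %d> %d atoms, folds: %s\n", x$index, nrow(x$atoms),
              paste(fold_labels(x), collapse = ", ")))
  invisible(x)
}

#' Protofilament fold constructor
#'
#' A labelled contiguous residue range with its atoms, e.g. PF-IA2 spanning
#' the ordered core Gly14-Gly93.
#'
#' @param atoms atom table of the fold.
#' @param label fold label, e.g. `"PF-IA2"`, `"PF-IB"`, `"PF-IIA"`.
#' @return object of class `protofilament_fold`.
#' @export
protofilament_fold <- function(atoms, label) {
  atoms <- atom_table(atoms)
  if (nrow(atoms) == 0L) {
    stop_fibril("empty fold selection", "fibril_selection_error")
  }
  structure(
    list(label = label,
         residue_range = range(atoms$residue_number),
         atoms = atoms),
    class = "protofilament_fold"
  )
}

#' @export
print.protofilament_fold <- function(x, ...) {
  cat(sprintf("<protofilament_fold %s> residues %d-%d, %d atoms\n",
              x$label, x$residue_range[1], x$residue_range[2], nrow(x$atoms)))
  invisible(x)
}

# pull the atom table out of any of the containers (or pass one through)
as_atoms <- function(x) {
  if (inherits(x, c("filament_model", "rung", "protofilament_fold"))) x$atoms
  else atom_table(x)
}

# protofilament role (A or B) from a fold label: strip "PF-" and the roman
# type prefix, first remaining A/B letter is the role. PF-IA2 -> A,
# PF-IIB1 -> B, PF-A1 -> A. Used to pair folds across filament types.
fold_role <- function(label) {
  vapply(as.character(label), function(l) {
    core <- sub("^PF-?", "", toupper(l))
    core <- sub("^I+", "", core)
    m <- regmatches(core, regexpr("[AB]", core))
    if (length(m) == 1L) m else core
  }, character(1), USE.NAMES = FALSE)
}
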