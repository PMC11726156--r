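# Reading and writing atomic models (PDB and mmCIF), decomposition of
# deposited filament stacks into rungs and labelled protofilament folds,
# and residue/atom selection.
#
# No structural-biology I/O package is available in the target environment,
# so this file carries a minimal, deliberately strict reader/writer for the
# two standard dialects. Policy on read (common heavy-atom conventions for
# clash and RMSD work): hydrogens are dropped; for alternate locations the
# highest-occupancy conformer is kept, ties broken in favour of altloc "A";
# author residue numbering is kept and never renumbered (all published
# alpha-synuclein core ranges -- 14-93, 21-100, 47-93, 57-93 -- use it).

#' Read an atomic model into a filament model
#'
#' Parses a PDB or mmCIF file, applies the altloc/hydrogen policy, groups
#' chains into rungs by their position along the filament axis, and labels
#' protofilament folds. Rung assignment: chains with identical residue
#' content are screw copies of each other; the axis is estimated from their
#' centroid differences, chains are clustered into rungs by their centroid
#' projection onto it (gap threshold `rung_gap`).
#'
#' Fold labelling (deposited stacks encode rungs as separate chains without
#' explicit labels): within a rung, a chain whose resolved range starts at or
#' below residue `17` is the A protofilament (ordered cores of A folds start
#' near Gly14), otherwise the B protofilament (B cores start at Lys21 or
#' later). Use `fold_map` to override (named vector chain id -> fold label).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param type_label filament type; `"auto"` guesses from fold ranges
#'   (B fold starting >= 30 suggests a Type II filament).
#' @param fold_map optional named character vector mapping chain id to fold
#'   label, overriding the heuristic.
#' @param rung_gap gap (Angstrom) in axis projection separating rungs;
#'   default 2.0 (rise of amyloid filaments is ~4.76 A; chains within a rung
#'   project within ~1 A).
#' @return a [filament_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           type_label = "auto", fold_map = NULL,
                           rung_gap = 2.0) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_fibril(sprintf("cannot read '%s'", path), "fibril_parse_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  raw <- switch(format, pdb = parse_pdb(path), mmcif = parse_mmcif(path))
  raw <- apply_atom_policy(raw)
  if (nrow(raw) == 0L || !any(raw$atom_name == "CA")) {
    stop_fibril("no protein atoms found", "fibril_empty_model_error")
  }
  atoms <- infer_rungs_and_folds(raw, fold_map = fold_map, rung_gap = rung_gap)
  if (identical(type_label, "auto")) type_label <- guess_type(atoms)
  filament_model(atoms, type_label = type_label)
}

# ---- parsing -------------------------------------------------------------

parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "ATOM ")]
  if (length(lines) == 0L) {
    stop_fibril("no ATOM records in PDB file", "fibril_parse_error")
  }
  f <- function(a, b) trimws(substr(lines, a, b))
  num <- function(a, b) suppressWarnings(as.numeric(f(a, b)))
  el <- f(77, 78)
  atom_name <- f(13, 16)
  el[el == ""] <- substr(gsub("[0-9]", "", atom_name[el == ""]), 1, 1)
  df <- data.frame(
    atom_name = atom_name,
    altloc = f(17, 17),
    residue_name = f(18, 20),
    chain_id = f(22, 22),
    residue_number = suppressWarnings(as.integer(f(23, 26))),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    occupancy = num(55, 60),
    element = toupper(el)
  )
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z) || anyNA(df$residue_number)) {
    stop_fibril("malformed ATOM record", "fibril_parse_error")
  }
  df
}

# tokenizer for one mmCIF loop row (handles '...' and "..." quoting)
cif_tokens <- function(line) {
  out <- character(); i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L)); i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L)); i <- j
    }
  }
  out
}

parse_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # locate the atom_site loop
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0L) {
    stop_fibril("no _atom_site loop in mmCIF file", "fibril_parse_error")
  }
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1L
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_") || startsWith(ln, "data_")) break
    body <- c(body, lines[i])
  }
  if (length(body) == 0L) {
    stop_fibril("empty _atom_site loop", "fibril_parse_error")
  }
  mat <- t(vapply(body, function(l) {
    tk <- cif_tokens(l)
    if (length(tk) != length(tags)) {
      stop_fibril("malformed _atom_site row", "fibril_parse_error")
    }
    tk
  }, character(length(tags)), USE.NAMES = FALSE))
  colnames(mat) <- tags
  get <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(mat[, nm])
    rep(NA_character_, nrow(mat))
  }
  keep <- get("group_PDB") %in% c("ATOM", NA_character_)
  mat <- mat[keep, , drop = FALSE]
  resno <- get("auth_seq_id", "label_seq_id")[keep]
  df <- data.frame(
    atom_name = get("auth_atom_id", "label_atom_id")[keep],
    altloc = sub("^[.?]$", "", get("label_alt_id")[keep]),
    residue_name = get("auth_comp_id", "label_comp_id")[keep],
    chain_id = get("auth_asym_id", "label_asym_id")[keep],
    residue_number = suppressWarnings(as.integer(resno)),
    x = suppressWarnings(as.numeric(get("Cartn_x")[keep])),
    y = suppressWarnings(as.numeric(get("Cartn_y")[keep])),
    z = suppressWarnings(as.numeric(get("Cartn_z")[keep])),
    occupancy = suppressWarnings(as.numeric(get("occupancy")[keep])),
    element = toupper(get("type_symbol")[keep])
  )
  df$altloc[is.na(df$altloc)] <- ""
  if (anyNA(df$x) || anyNA(df$residue_number)) {
    stop_fibril("malformed _atom_site coordinates", "fibril_parse_error")
  }
  df
}

# drop hydrogens; resolve altlocs (highest occupancy, ties -> altloc "A")
apply_atom_policy <- function(df) {
  df <- df[!df$element %in% c("H", "D"), , drop = FALSE]
  df$occupancy[is.na(df$occupancy)] <- 1
  has_alt <- df$altloc != ""
  if (any(has_alt)) {
    key <- paste(df$chain_id, df$residue_number, df$atom_name, sep = "|")
    ord <- order(key, -df$occupancy, df$altloc)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(paste(df$chain_id, df$residue_number, df$atom_name,
                               sep = "|")), , drop = FALSE]
  }
  df
}

# ---- rung and fold inference --------------------------------------------

infer_rungs_and_folds <- function(df, fold_map = NULL, rung_gap = 2.0) {
  chains <- unique(df$chain_id)
  cen <- t(vapply(chains, function(ch) {
    colMeans(as.matrix(df[df$chain_id == ch, c("x", "y", "z")]))
  }, numeric(3)))
  # screw-copy signature: resolved residue set + atom count
  sig <- vapply(chains, function(ch) {
    a <- df[df$chain_id == ch, ]
    paste(min(a$residue_number), max(a$residue_number), nrow(a), sep = "_")
  }, character(1))
  axis <- estimate_axis(cen, sig)
  proj <- as.numeric(cen %*% axis)
  counts <- table(sig)
  if (length(counts) >= 1L && length(unique(counts)) == 1L &&
      counts[[1L]] > 1L) {
    # equal numbers of screw copies per fold: rung = rank along the axis
    # within each signature group (robust to per-fold centroid offsets)
    lev <- integer(length(chains))
    for (s in unique(sig)) {
      idx <- which(sig == s)
      lev[idx] <- rank(proj[idx], ties.method = "first") - 1L
    }
  } else {
    lev <- cluster_levels(proj, rung_gap)
  }
  # order rungs along the axis, index from 0
  rung_of_chain <- match(lev, sort(unique(lev))) - 1L
  names(rung_of_chain) <- chains
  df$rung_index <- rung_of_chain[df$chain_id]
  df$fold_label <- NA_character_
  for (ch in chains) {
    sel <- df$chain_id == ch
    if (!is.null(fold_map) && ch %in% names(fold_map)) {
      df$fold_label[sel] <- fold_map[[ch]]
    } else {
      start <- min(df$residue_number[sel])
      df$fold_label[sel] <- if (start <= 17L) "PF-A" else "PF-B"
    }
  }
  atom_table(df[, .atom_cols])
}

# axis from centroid differences of screw-copy chains; fall back to the
# principal axis of chain centroids, or +z for a single rung
estimate_axis <- function(cen, sig) {
  steps <- NULL
  for (s in unique(sig)) {
    idx <- which(sig == s)
    if (length(idx) < 2L) next
    cc <- cen[idx, , drop = FALSE]
    # consecutive copies along the filament: order by projection on the
    # dominant direction of this group's centroids
    pc1 <- svd(sweep(cc, 2, colMeans(cc)))$v[, 1]
    cc <- cc[order(cc %*% pc1), , drop = FALSE]
    steps <- rbind(steps, diff(cc))
  }
  if (is.null(steps)) return(c(0, 0, 1))
  # align all step vectors with the first, then average
  ref <- steps[1, ]
  flips <- sign(steps %*% ref); flips[flips == 0] <- 1
  axis <- colMeans(steps * as.numeric(flips))
  n <- sqrt(sum(axis^2))
  if (n < 1e-9) c(0, 0, 1) else axis / n
}

cluster_levels <- function(proj, gap) {
  ord <- order(proj)
  lev <- integer(length(proj))
  cur <- 0L
  lev[ord[1]] <- 0L
  if (length(proj) > 1L) {
    for (k in 2:length(ord)) {
      if (proj[ord[k]] - proj[ord[k - 1]] > gap) cur <- cur + 1L
      lev[ord[k]] <- cur
    }
  }
  lev
}

guess_type <- function(atoms) {
  b <- atoms[fold_role(atoms$fold_label) == "B", ]
  if (nrow(b) == 0L) return("synthetic")
  if (min(b$residue_number) >= 30L) "II2" else "I2"
}

# ---- selection -----------------------------------------------------------

#' Select a labelled protofilament fold from a model
#'
#' @param model a [filament_model()].
#' @param label fold label as stored in the model (e.g. `"PF-A"`,
#'   `"PF-IA2"`), or a role letter `"A"`/`"B"`.
#' @param rung rung index (default the model's lowest, i.e. the reference
#'   rung) or `"central"`.
#' @param residue_range optional inclusive `c(first, last)`; must lie within
#'   the fold's resolved range.
#' @return a [protofilament_fold()], atoms ordered by residue then canonical
#'   atom order.
#' @export
select_fold <- function(model, label, rung = NULL, residue_range = NULL) {
  atoms <- as_atoms(model)
  if (is.null(rung)) rung <- min(atoms$rung_index)
  if (identical(rung, "central")) {
    idx <- sort(unique(atoms$rung_index))
    rung <- idx[floor(length(idx) / 2) + 1L]
  }
  sel <- atoms$rung_index == rung &
    (atoms$fold_label == label | fold_role(atoms$fold_label) == label)
  if (!any(sel)) {
    stop_fibril(sprintf("no fold '%s' in rung %s", label, rung),
                "fibril_selection_error")
  }
  a <- atoms[sel, , drop = FALSE]
  resolved <- range(a$residue_number)
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    if (residue_range[1] < resolved[1] || residue_range[2] > resolved[2]) {
      stop_fibril(sprintf(
        "requested residues %d-%d outside resolved range %d-%d of %s",
        residue_range[1], residue_range[2], resolved[1], resolved[2], label),
        "fibril_selection_error")
    }
    a <- a[a$residue_number >= residue_range[1] &
             a$residue_number <= residue_range[2], , drop = FALSE]
  }
  if (nrow(a) == 0L) stop_fibril("empty selection", "fibril_selection_error")
  a <- a[order(a$residue_number, atom_order_key(a$atom_name)), , drop = FALSE]
  protofilament_fold(a, label = unique(atoms$fold_label[sel])[1])
}

# ---- writing -------------------------------------------------------------

.chain_alphabet <- c(LETTERS, letters, as.character(0:9))

#' Write a filament model to PDB or mmCIF
#'
#' Each (rung, fold) unit is written as its own chain (A, B, C, ...) in a
#' single model block -- the simplest convention that round-trips through the
#' rung inference of [read_structure()] and loads in standard viewers.
#'
#' @param model a [filament_model()], [rung()] or [protofilament_fold()].
#' @param path output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  atoms <- as_atoms(model)
  if (nrow(atoms) == 0L) {
    stop_fibril("refusing to write an empty model", "fibril_empty_model_error")
  }
  unit <- paste(atoms$rung_index, atoms$fold_label, atoms$chain_id, sep = "|")
  units <- unique(unit[order(atoms$rung_index,
                             fold_role(atoms$fold_label), atoms$chain_id)])
  if (length(units) > length(.chain_alphabet) && format == "pdb") {
    stop_fibril("too many chains for single-character PDB chain ids",
                "fibril_io_error")
  }
  chain_out <- .chain_alphabet[((match(unit, units) - 1L) %%
                                  length(.chain_alphabet)) + 1L]
  ord <- order(match(unit, units), atoms$residue_number,
               atom_order_key(atoms$atom_name))
  atoms <- atoms[ord, ]; chain_out <- chain_out[ord]
  ok <- tryCatch({
    if (format == "pdb") write_pdb_lines(atoms, chain_out, path)
    else write_mmcif_lines(atoms, chain_out, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_fibril(sprintf("cannot write '%s': %s", path,
                        conditionMessage(ok)), "fibril_io_error")
  }
  invisible(path)
}

write_pdb_lines <- function(atoms, chain_out, path) {
  n <- nrow(atoms)
  serial <- ((seq_len(n) - 1L) %% 99999L) + 1L
  # atom-name column convention: names of 1-3 chars start in column 14
  an <- ifelse(nchar(atoms$atom_name) < 4L,
               sprintf(" %-3s", atoms$atom_name),
               sprintf("%-4s", atoms$atom_name))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, an, atoms$residue_name, chain_out, atoms$residue_number,
    atoms$x, atoms$y, atoms$z, 1.0, 0.0, atoms$element)
  writeLines(c(lines, "END"), path)
}

write_mmcif_lines <- function(atoms, chain_out, path) {
  n <- nrow(atoms)
  header <- c(
    "data_fibril",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- sprintf(
    "ATOM %d %s %s . %s %s %d %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
    seq_len(n), atoms$element, atoms$atom_name, atoms$residue_name,
    chain_out, atoms$residue_number, atoms$x, atoms$y, atoms$z,
    atoms$residue_number, atoms$residue_name, chain_out, atoms$atom_name)
  writeLines(c(header, rows, "#"), path)
}
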