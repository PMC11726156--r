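# Per-filament composition analysis of classified cryo-EM segments:
# loading segment tables (TSV or STAR), micrograph filtering, per-filament
# type fractions with the 90%-predominance rule, fraction histograms,
# strongly mixed filament counts and summary statistics.
#
# A "segment" is one boxed window along a picked filament; 3D classification
# assigns each segment a class, and a class -> type map turns that into a
# filament type label (here "I2", "II2" or "other"). Filament identity is
# (micrograph_id, filament_id): filaments never span micrographs.

.required_cols <- c("micrograph_id", "filament_id", "segment_index", "type_label")
.typed_levels <- c("I2", "II2")

#' Validate a table of segment records
#'
#' @param df data.frame with columns `micrograph_id`, `filament_id`,
#'   `segment_index`, `type_label` (values `"I2"`, `"II2"` or `"other"`).
#' @return the validated data.frame (class `segment_table`).
#' @export
segment_records <- function(df) {
  missing <- setdiff(.required_cols, names(df))
  if (length(missing) > 0L) {
    stop_fibril(paste0("segment table missing columns: ",
                       paste(missing, collapse = ", ")),
                "fibril_schema_error")
  }
  df <- as.data.frame(df)[, .required_cols]
  df$micrograph_id <- as.character(df$micrograph_id)
  df$filament_id <- as.character(df$filament_id)
  df$segment_index <- as.integer(df$segment_index)
  df$type_label <- as.character(df$type_label)
  df$type_label[!df$type_label %in% .typed_levels] <- "other"
  key <- paste(df$micrograph_id, df$filament_id, df$segment_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop_fibril("duplicate (micrograph, filament, segment) keys",
                "fibril_integrity_error")
  }
  rownames(df) <- NULL
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Load a segment classification table
#'
#' Reads per-segment class assignments from a TSV or a STAR-style loop and
#' maps classes to filament types.
#'
#' TSV: columns `micrograph_id`/`micrograph`, `filament_id`/`filament`,
#' `segment_index`/`segment`, and `type_label`/`class`. STAR: the first
#' `data_` block's loop with `_rlnMicrographName`, `_rlnHelicalTubeID` and
#' `_rlnClassNumber`; the segment index is the row order within each
#' filament (or `_rlnHelicalTrackLengthAngst` rank when present).
#'
#' @param path input file.
#' @param format `"auto"` (by extension: `.star` vs anything else), `"tsv"`
#'   or `"star"`.
#' @param class_map named vector mapping class values to `"I2"`, `"II2"` or
#'   `"other"`, or the path of a JSON file holding such a map. Segments with
#'   unmapped classes are labelled `"other"`. `NULL` means class values are
#'   already type labels.
#' @return a [segment_records()] table.
#' @export
load_segment_table <- function(path, format = c("auto", "tsv", "star"),
                               class_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_fibril(sprintf("cannot read '%s'", path), "fibril_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.star$", path, ignore.case = TRUE)) "star" else "tsv"
  }
  if (is.character(class_map) && length(class_map) == 1L &&
      file.exists(class_map) && is.null(names(class_map))) {
    class_map <- unlist(jsonlite::read_json(class_map))
  }
  df <- switch(format, tsv = read_segment_tsv(path), star = read_segment_star(path))
  if (!is.null(class_map)) {
    mapped <- unname(class_map[as.character(df$type_label)])
    mapped[is.na(mapped)] <- "other"
    df$type_label <- mapped
  }
  segment_records(df)
}

read_segment_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  alias <- c(micrograph_id = "micrograph", filament_id = "filament",
             segment_index = "segment", type_label = "class")
  for (canon in names(alias)) {
    if (!canon %in% names(df) && alias[[canon]] %in% names(df)) {
      names(df)[names(df) == alias[[canon]]] <- canon
    }
  }
  missing <- setdiff(.required_cols, names(df))
  if (length(missing) > 0L) {
    stop_fibril(paste0("TSV missing columns: ", paste(missing, collapse = ", ")),
                "fibril_schema_error")
  }
  df
}

# minimal STAR loop reader: first data_ block, first loop_ with the needed
# _rln tags; values are whitespace-separated
read_segment_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^_rln", trimws(lines))
  if (length(tag_idx) == 0L) {
    stop_fibril("no _rln column tags in STAR file", "fibril_schema_error")
  }
  tags <- sub("\\s.*$", "", sub("^_", "", trimws(lines[tag_idx])))
  body <- character()
  for (i in (max(tag_idx) + 1L):length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "data_") ||
        startsWith(ln, "loop_") || startsWith(ln, "_")) break
    body <- c(body, ln)
  }
  mat <- t(vapply(body, function(l) {
    tk <- strsplit(l, "\\s+")[[1]]
    if (length(tk) != length(tags)) {
      stop_fibril("malformed STAR row", "fibril_schema_error")
    }
    tk
  }, character(length(tags)), USE.NAMES = FALSE))
  colnames(mat) <- tags
  need <- c("rlnMicrographName", "rlnHelicalTubeID", "rlnClassNumber")
  missing <- setdiff(need, tags)
  if (length(missing) > 0L) {
    stop_fibril(paste0("STAR missing columns: ",
                       paste(missing, collapse = ", ")), "fibril_schema_error")
  }
  df <- data.frame(
    micrograph_id = mat[, "rlnMicrographName"],
    filament_id = mat[, "rlnHelicalTubeID"],
    type_label = mat[, "rlnClassNumber"],
    stringsAsFactors = FALSE
  )
  ord_key <- if ("rlnHelicalTrackLengthAngst" %in% tags) {
    as.numeric(mat[, "rlnHelicalTrackLengthAngst"])
  } else {
    seq_len(nrow(df))
  }
  dt <- data.table::as.data.table(df)
  dt[, segment_index := rank(ord_key[.I], ties.method = "first"),
     by = .(micrograph_id, filament_id)]
  as.data.frame(dt)
}

#' Keep micrographs containing a minimum number of segments of one type
#'
#' The micrograph filter of the composition analysis: with one type far more
#' abundant than the other (e.g. ~13-fold), only micrographs containing at
#' least `min_count` segment(s) of the rarer type are informative about
#' within-filament mixing.
#'
#' @param records a [segment_records()] table.
#' @param require_type type that must be present (default `"I2"`).
#' @param min_count minimum number of such segments per micrograph (>= 1).
#' @return the subset of `records` from qualifying micrographs, with
#'   attributes `n_micrographs_total` and `n_micrographs_selected`.
#' @export
filter_micrographs <- function(records, require_type = "I2", min_count = 1L) {
  records <- segment_records(records)
  stopifnot(min_count >= 1L)
  dt <- data.table::as.data.table(records)
  hits <- dt[type_label == require_type, .N, by = micrograph_id]
  keep <- hits[N >= min_count, micrograph_id]
  out <- records[records$micrograph_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("segment_table", "data.frame")
  attr(out, "n_micrographs_total") <- length(unique(records$micrograph_id))
  attr(out, "n_micrographs_selected") <- length(keep)
  out
}

#' Per-filament composition with the predominance rule
#'
#' Groups segments by filament ((micrograph, filament) pair), counts
#' segments per type and computes `fraction_I2 = n_I2 / (n_I2 + n_II2)` over
#' typed segments only ("other" segments are counted but excluded from the
#' fraction denominator). Categories, with an inclusive threshold
#' ("90% or higher"):
#' `exclusive-I2` (fraction 1), `predominant-I2` (>= threshold),
#' `exclusive-II2` (fraction 0), `predominant-II2` (1 - fraction >=
#' threshold), else `mixed`.
#'
#' @param records a [segment_records()] table (usually pre-filtered with
#'   [filter_micrographs()]).
#' @param threshold predominance threshold in (0.5, 1]; default 0.90.
#' @param min_typed minimum typed segments for a filament to be included
#'   (default 1). Filaments with fewer typed segments are dropped with a
#'   message.
#' @return data.frame (class `filament_compositions`) with one row per
#'   filament: counts `n_I2`, `n_II2`, `n_other`, `n_typed`, `fraction_I2`
#'   and `category`.
#' @export
compose_filaments <- function(records, threshold = 0.90, min_typed = 1L) {
  records <- segment_records(records)
  if (!(threshold > 0.5 && threshold <= 1)) {
    stop_fibril("threshold must lie in (0.5, 1]", "fibril_argument_error")
  }
  dt <- data.table::as.data.table(records)
  comp <- dt[, .(
    n_I2 = sum(type_label == "I2"),
    n_II2 = sum(type_label == "II2"),
    n_other = sum(type_label == "other"),
    n_segments = .N
  ), by = .(micrograph_id, filament_id)]
  comp[, n_typed := n_I2 + n_II2]
  dropped <- comp[n_typed < min_typed]
  if (nrow(dropped) > 0L) {
    message(sprintf("compose_filaments: dropped %d filament(s) with < %d typed segment(s)",
                    nrow(dropped), min_typed))
  }
  comp <- comp[n_typed >= pmax(min_typed, 1L)]
  comp[, fraction_I2 := n_I2 / n_typed]
  eps <- 1e-9
  comp[, category := data.table::fifelse(
    fraction_I2 >= 1 - eps, "exclusive-I2",
    data.table::fifelse(fraction_I2 <= eps, "exclusive-II2",
    data.table::fifelse(fraction_I2 >= threshold - eps, "predominant-I2",
    data.table::fifelse(1 - fraction_I2 >= threshold - eps, "predominant-II2",
                        "mixed"))))]
  out <- as.data.frame(comp)
  attr(out, "threshold") <- threshold
  attr(out, "min_typed") <- min_typed
  attr(out, "n_dropped") <- nrow(dropped)
  class(out) <- c("filament_compositions", "data.frame")
  out
}

#' Filaments with many segments of both types
#'
#' Counts filaments carrying at least `min_each` segments of each type --
#' candidates for genuinely mixed cofilaments (or, when hybrid modelling
#' shows the mixed interface clashes, for classification stochasticity).
#'
#' @param compositions output of [compose_filaments()].
#' @param min_each minimum segments of each type (default 10).
#' @return list with `count` and `filaments` (the qualifying rows).
#' @export
strongly_mixed <- function(compositions, min_each = 10L) {
  stopifnot(min_each >= 1L)
  sel <- compositions$n_I2 >= min_each & compositions$n_II2 >= min_each
  list(count = sum(sel),
       filaments = compositions[sel, , drop = FALSE])
}

#' Summarise a composition analysis
#'
#' Produces the filament-level report: histogram of `fraction_I2` (default
#' 10 equal bins on `[0, 1]`, left-closed with the last bin right-inclusive),
#' the fraction of filaments classified exclusively or predominantly to one
#' type, the strongly mixed count, and segment abundances including the
#' II2:I2 ratio. Percentages are rounded to the nearest integer, half away
#' from zero.
#'
#' @param compositions output of [compose_filaments()].
#' @param records the (filtered) [segment_records()] the compositions were
#'   computed from, for abundance totals and micrograph counts.
#' @param bins number of histogram bins (default 10).
#' @param min_each threshold for [strongly_mixed()] (default 10).
#' @return object of class `composition_report`.
#' @export
summarize_composition <- function(compositions, records, bins = 10L,
                                  min_each = 10L) {
  stopifnot(nrow(compositions) > 0L)
  records <- segment_records(records)
  f <- compositions$fraction_I2
  bin_idx <- pmin(floor(f * bins) + 1L, bins)
  edges <- seq(0, 1, length.out = bins + 1L)
  hist_df <- data.frame(
    bin_low = edges[-(bins + 1L)],
    bin_high = edges[-1L],
    count = tabulate(bin_idx, nbins = bins)
  )
  n_fil <- nrow(compositions)
  excl_pred <- compositions$category != "mixed"
  sm <- strongly_mixed(compositions, min_each = min_each)
  n_I2 <- sum(records$type_label == "I2")
  n_II2 <- sum(records$type_label == "II2")
  report <- list(
    filaments = compositions,
    histogram = hist_df,
    summary = list(
      n_micrographs_selected = attr(records, "n_micrographs_selected") %||%
        length(unique(records$micrograph_id)),
      n_filaments = n_fil,
      n_segments = nrow(records),
      n_I2_segments = n_I2,
      n_II2_segments = n_II2,
      abundance_ratio_II2_I2 = if (n_I2 > 0) n_II2 / n_I2 else NA_real_,
      fraction_exclusive_or_predominant = mean(excl_pred),
      percent_exclusive_or_predominant = percent_share(sum(excl_pred), n_fil),
      strongly_mixed_count = sm$count,
      min_each = min_each,
      threshold = attr(compositions, "threshold")
    )
  )
  class(report) <- "composition_report"
  report
}

#' @export
print.composition_report <- function(x, ...) {
  s <- x$summary
  cat("<composition_report>\n")
  cat(sprintf("  micrographs selected: %d; filaments: %d; segments: %d\n",
              s$n_micrographs_selected, s$n_filaments, s$n_segments))
  cat(sprintf("  segments I2: %d, II2: %d (II2:I2 ratio %.1f)\n",
              s$n_I2_segments, s$n_II2_segments, s$abundance_ratio_II2_I2))
  cat(sprintf("  exclusive or predominant (>= %d%%): %d%% of filaments\n",
              round(100 * s$threshold), s$percent_exclusive_or_predominant))
  cat(sprintf("  strongly mixed (>= %d of each type): %d\n",
              s$min_each, s$strongly_mixed_count))
  cat("  fraction_I2 histogram counts:",
      paste(x$histogram$count, collapse = " "), "\n")
  invisible(x)
}

#' Segment bookkeeping counts of the MSA dataset
#'
#' The published processing-tree segment and micrograph counts of the MSA
#' cryo-EM dataset this package's defaults model, shipped as a plain-text
#' table. These are inputs for share/ratio arithmetic (e.g. type shares of
#' the classified data, the II2:I2 abundance ratio, the micrograph filter
#' fraction), not results computed here.
#'
#' @return data.frame with columns `quantity` and `count`.
#' @export
classification_counts <- function() {
  path <- system.file("extdata", "msa_classification_counts.tsv",
                      package = "fibril", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")
}

count_of <- function(counts, quantity) {
  i <- match(quantity, counts$quantity)
  if (is.na(i)) {
    stop_fibril(sprintf("unknown quantity '%s'", quantity),
                "fibril_argument_error")
  }
  counts$count[i]
}
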