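# Synthetic generators: toy filament coordinate sets with known helical
# parameters and chimeric fold variants, and segment classification tables
# with a stated mixture/noise model, plus analytic expectations. Everything
# here is deliberately cartoonish -- enough geometry to exercise the
# superposition, screw-fitting and clash machinery, with no claim of
# structural realism.

#' Generate a pair of chimeric fold templates
#'
#' Builds two toy protofilament fold templates that are exactly identical
#' over a shared residue window and diverge smoothly outside it -- the
#' geometric relationship of a chimeric protofilament pair whose C-terminal
#' (or N-terminal) region matches a different parent fold.
#'
#' The base fold is a planar C-shaped arc (consecutive C-alpha spacing
#' 3.8 A, arc radius 60 A about the stacking axis) with one side-chain proxy
#' pseudo-atom (CB) per residue at a fixed 1.5 A inward offset. Variant B
#' displaces each residue outside the shared window along a fixed direction
#' tilted out of the rung plane (see `out_of_plane_deg`), with a smooth ramp
#' from the window edge and a low-amplitude smooth modulation drawn from
#' `seed`; amplitudes are scaled so the *mean* C-alpha displacement outside
#' the window equals `divergence` exactly. The out-of-plane component points
#' against the stacking direction: it stands in for the side chains and rung
#' non-planarity of real filaments, without which no inter-rung steric clash
#' is geometrically possible at a 4.76 A rise (max heavy-atom vdW sum
#' 3.6 A). The ground-truth per-residue displacement profile is stored on
#' both templates.
#'
#' @param shared_window inclusive residue range identical between variants
#'   (default `c(57, 93)`).
#' @param divergence target mean C-alpha displacement (Angstrom) outside the
#'   window, > 0.
#' @param seed integer RNG seed for the amplitude modulation.
#' @param residues residue numbers of the fold (default `14:93`, an 80
#'   residue ordered core).
#' @param out_of_plane_deg tilt of the displacement direction out of the
#'   rung plane, degrees (default 65).
#' @param ramp envelope width, residues, over which the displacement grows
#'   from the window edge (default 8).
#' @return list with `a` and `b` (class `fold_template`) and `truth`
#'   (data.frame `residue`, `displacement`).
#' @export
make_fold_pair <- function(shared_window = c(57, 93), divergence = 4.8,
                           seed = 1L, residues = 14:93,
                           out_of_plane_deg = 65, ramp = 8L) {
  if (!is_scalar_num(divergence) || divergence <= 0) {
    stop_fibril("divergence must be > 0", "fibril_argument_error")
  }
  stopifnot(length(shared_window) == 2L)
  outside <- residues[residues < shared_window[1] | residues > shared_window[2]]
  if (length(outside) == 0L) {
    stop_fibril("shared window covers the whole chain: no divergence possible",
                "fibril_no_divergence_error")
  }
  n <- length(residues)
  radius <- 60
  dtheta <- 3.8 / radius
  theta <- (seq_len(n) - (n + 1) / 2) * dtheta
  ca <- cbind(radius * cos(theta), radius * sin(theta), 0)
  cb <- cbind((radius - 1.5) * cos(theta), (radius - 1.5) * sin(theta), 0)
  # smooth ramped amplitude with a low-frequency modulation
  dist_edge <- pmin(abs(residues - shared_window[1]),
                    abs(residues - shared_window[2]))
  s <- pmin(1, dist_edge / ramp)
  envelope <- s^2 * (3 - 2 * s)            # smoothstep
  envelope[residues >= shared_window[1] & residues <= shared_window[2]] <- 0
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  phase <- stats::runif(1, 0, 2 * pi)
  waves <- sample(2:4, 1)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  frac <- (seq_len(n) - 1) / max(1, n - 1)
  amp <- envelope * (1 + 0.15 * sin(waves * 2 * pi * frac + phase))
  scale <- divergence / mean(amp[match(outside, residues)])
  amp <- amp * scale
  beta <- out_of_plane_deg * pi / 180
  radial <- cbind(cos(theta), sin(theta), 0)
  direction <- sweep(radial, 2, c(0, 0, 0)) * cos(beta)
  direction[, 3] <- -sin(beta)
  disp <- direction * amp
  template <- function(name, ca, cb) {
    structure(list(name = name, residues = residues, ca = ca, cb = cb,
                   shared_window = as.integer(shared_window)),
              class = "fold_template")
  }
  truth <- data.frame(residue = residues, displacement = amp)
  a <- template("PF-A1", ca, cb)
  b <- template("PF-A2", ca + disp, cb + disp)
  attr(a, "truth") <- truth; attr(b, "truth") <- truth
  list(a = a, b = b, truth = truth,
       mean_divergence = mean(amp[match(outside, residues)]))
}

#' @export
print.fold_template <- function(x, ...) {
  cat(sprintf("<fold_template %s> residues %d-%d, shared window %d-%d\n",
              x$name, min(x$residues), max(x$residues),
              x$shared_window[1], x$shared_window[2]))
  invisible(x)
}

#' Atom table of a fold template (one rung)
#'
#' @param template a `fold_template` from [make_fold_pair()].
#' @param chain_id chain label (default `"A"`).
#' @return an [atom_table()] with CA and CB pseudo-atoms, rung index 0.
#' @export
template_atoms <- function(template, chain_id = "A") {
  n <- length(template$residues)
  atom_table(data.frame(
    atom_name = rep(c("CA", "CB"), each = n),
    element = "C",
    residue_number = rep(template$residues, 2L),
    residue_name = "ALA",
    chain_id = chain_id,
    rung_index = 0L,
    fold_label = template$name,
    x = c(template$ca[, 1], template$cb[, 1]),
    y = c(template$ca[, 2], template$cb[, 2]),
    z = c(template$ca[, 3], template$cb[, 3])
  ))
}

#' Extrude a fold template into a helical stack
#'
#' Builds a single-protofilament filament model by applying the screw
#' operator (axis: z through the origin, the arc centre of the template)
#' `n - 1` times. The helical parameters are stored on the model as ground
#' truth for round-trip tests against [fit_helical_params()].
#'
#' @param template a `fold_template`.
#' @param params [helical_params()].
#' @param n number of rungs, >= 2.
#' @return a [filament_model()].
#' @export
make_stack <- function(template, params, n) {
  if (!is_scalar_num(n) || n < 2) {
    stop_fibril("n must be >= 2", "fibril_argument_error")
  }
  expand_stack(rung(template_atoms(template)), params, n)
}

# ---- segment tables ------------------------------------------------------

#' Count-distribution specification
#'
#' @param dist `"fixed"` (always `value`) or `"tpois"` (Poisson(`lambda`)
#'   truncated below at `min`).
#' @param value count for `"fixed"`.
#' @param lambda,min parameters for `"tpois"`.
#' @return list of class `count_dist`.
#' @export
count_dist <- function(dist = c("tpois", "fixed"), value = 1L,
                       lambda = 1, min = 1L) {
  dist <- match.arg(dist)
  structure(list(dist = dist, value = as.integer(value),
                 lambda = lambda, min = as.integer(min)),
            class = "count_dist")
}

draw_counts <- function(spec, n) {
  switch(spec$dist,
         fixed = rep.int(spec$value, n),
         tpois = {
           out <- stats::rpois(n, spec$lambda)
           while (any(out < spec$min)) {
             redo <- out < spec$min
             out[redo] <- stats::rpois(sum(redo), spec$lambda)
           }
           out
         })
}

#' Configuration for a synthetic segment classification table
#'
#' The stated mixture/noise model: each filament has a latent true type
#' (`"I2"` with probability `p_I2`, else `"II2"`); each of its segments is
#' labelled with the true type with probability `1 - epsilon - p_other`,
#' with the opposite type with probability `epsilon` (symmetric
#' misclassification), and `"other"` (unmapped/low-resolution class) with
#' probability `p_other`.
#'
#' Defaults model sparse micrographs of the kind selected by the micrograph
#' filter: filaments per micrograph ~ truncated Poisson(1.3, min 1),
#' segments per filament ~ truncated Poisson(25, min 1).
#'
#' @param n_micrographs number of micrographs.
#' @param filaments_per_micrograph,segments_per_filament [count_dist()]s.
#' @param p_I2 per-filament probability of true type I2.
#' @param epsilon per-segment misclassification probability.
#' @param p_other per-segment probability of an `"other"` label.
#' @param seed integer seed; a fixed seed gives identical output.
#' @return list of class `segment_table_config`.
#' @export
segment_table_config <- function(n_micrographs = 50L,
                                 filaments_per_micrograph =
                                   count_dist("tpois", lambda = 1.3, min = 1L),
                                 segments_per_filament =
                                   count_dist("tpois", lambda = 25, min = 1L),
                                 p_I2 = 0.5, epsilon = 0.05, p_other = 0,
                                 seed = 1L) {
  probs <- c(p_I2 = p_I2, epsilon = epsilon, p_other = p_other)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1) ||
      epsilon + p_other > 1) {
    stop_fibril("invalid probabilities in segment table config",
                "fibril_config_error")
  }
  stopifnot(n_micrographs >= 1L, inherits(filaments_per_micrograph, "count_dist"),
            inherits(segments_per_filament, "count_dist"))
  structure(list(n_micrographs = as.integer(n_micrographs),
                 filaments_per_micrograph = filaments_per_micrograph,
                 segments_per_filament = segments_per_filament,
                 p_I2 = p_I2, epsilon = epsilon, p_other = p_other,
                 seed = as.integer(seed)),
            class = "segment_table_config")
}

#' Generate a synthetic segment classification table
#'
#' Draws filament true types and per-segment labels under the mixture model
#' of [segment_table_config()]. Reproducible: the same config (including
#' seed) yields an identical table.
#'
#' @param config a [segment_table_config()].
#' @return list with `records` (a [segment_records()] table) and `truth`
#'   (data.frame `micrograph_id`, `filament_id`, `true_type`).
#' @export
generate_segment_table <- function(config) {
  stopifnot(inherits(config, "segment_table_config"))
  set.seed(config$seed)
  n_fil_per_mg <- draw_counts(config$filaments_per_micrograph,
                              config$n_micrographs)
  mg_ids <- sprintf("mic_%04d", seq_len(config$n_micrographs))
  fil_mg <- rep(mg_ids, n_fil_per_mg)
  n_fil <- length(fil_mg)
  fil_ids <- unlist(lapply(n_fil_per_mg, function(k) seq_len(k)), use.names = FALSE)
  true_type <- ifelse(stats::runif(n_fil) < config$p_I2, "I2", "II2")
  n_seg <- draw_counts(config$segments_per_filament, n_fil)
  flip <- function(t) ifelse(t == "I2", "II2", "I2")
  labels <- vector("list", n_fil)
  for (i in seq_len(n_fil)) {
    u <- stats::runif(n_seg[i])
    labels[[i]] <- ifelse(u < config$p_other, "other",
                          ifelse(u < config$p_other + config$epsilon,
                                 flip(true_type[i]), true_type[i]))
  }
  records <- segment_records(data.frame(
    micrograph_id = rep(fil_mg, n_seg),
    filament_id = as.character(rep(fil_ids, n_seg)),
    segment_index = unlist(lapply(n_seg, seq_len), use.names = FALSE),
    type_label = unlist(labels, use.names = FALSE)
  ))
  truth <- data.frame(micrograph_id = fil_mg,
                      filament_id = as.character(fil_ids),
                      true_type = true_type)
  list(records = records, truth = truth)
}

#' Exact expected fraction of exclusive-or-predominant filaments
#'
#' Analytic twin of [compose_filaments()] under the symmetric
#' misclassification model with no `"other"` labels: for a filament with
#' `n_segments` typed segments and per-segment flip probability `epsilon`,
#' the probability that it is classified exclusively or predominantly
#' (fraction `>= threshold`) as its true type is the binomial lower tail
#' `P(minority <= floor((1 - threshold) * n_segments))`.
#'
#' Note the pipeline's "exclusive or predominant to *either* type" statistic
#' additionally gains the (for small `epsilon`, negligible) upper tail where
#' nearly all labels are flipped.
#'
#' @param n_segments typed segments per filament, >= 1.
#' @param epsilon per-segment misclassification probability.
#' @param threshold predominance threshold (default 0.9).
#' @return probability.
#' @export
#' @examples
#' expected_predominant_fraction(20, 0.05, 0.9) # 0.9245
expected_predominant_fraction <- function(n_segments, epsilon,
                                          threshold = 0.9) {
  stopifnot(n_segments >= 1L, epsilon >= 0, epsilon <= 1)
  kmax <- floor((1 - threshold) * n_segments + 1e-9)
  stats::pbinom(kmax, n_segments, epsilon)
}
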