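# Independent oracles and small fixture builders. These deliberately avoid
# the code paths they check: brute-force enumeration, grid search and O(n^2)
# scans only.

# brute-force rigid superposition RMSD by grid search over ZYZ Euler angles
# (centroids aligned analytically). Returns the minimum RMSD on the grid --
# an upper bound on the true optimum, so kabsch_rmsd <= grid_rmsd must hold.
grid_rmsd_oracle <- function(P, Q, n_grid = 24L) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  angles1 <- seq(0, 2 * pi, length.out = n_grid + 1L)[-(n_grid + 1L)]
  angles2 <- seq(0, pi, length.out = n_grid %/% 2L)
  best <- Inf
  for (a in angles1) for (b in angles2) for (g in angles1) {
    R <- rotz(a) %*% roty(b) %*% rotz(g)
    d <- sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
    if (d < best) best <- d
  }
  best
}

# O(n^2) all-pairs contact scan with the same bonded-pair exclusions as
# contact_map, written directly from the rule
brute_contacts <- function(atoms, cutoff, scope = "all") {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  out <- list(); k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > cutoff) next
      same_rung <- atoms$rung_index[i] == atoms$rung_index[j]
      if (scope == "intra" && !same_rung) next
      if (scope == "inter" && same_rung) next
      same_unit <- same_rung && atoms$chain_id[i] == atoms$chain_id[j] &&
        atoms$fold_label[i] == atoms$fold_label[j]
      dres <- abs(atoms$residue_number[i] - atoms$residue_number[j])
      bb <- c("N", "CA", "C", "O")
      if (same_unit && (dres == 0L ||
          (dres == 1L && atoms$atom_name[i] %in% bb && atoms$atom_name[j] %in% bb))) next
      k <- k + 1L
      out[[k]] <- c(i = i, j = j, distance = d)
    }
  }
  if (k == 0L) return(data.frame(i = integer(), j = integer(), distance = numeric()))
  df <- as.data.frame(do.call(rbind, out))
  df$i <- as.integer(df$i); df$j <- as.integer(df$j)
  df <- df[order(df$i, df$j), ]
  rownames(df) <- NULL
  df
}

# direct categorisation of one (n_I2, n_II2) count pair under the
# predominance rule, written independently from compose_filaments
brute_category <- function(a, b, threshold = 0.9) {
  f <- a / (a + b)
  if (f == 1) "exclusive-I2"
  else if (f == 0) "exclusive-II2"
  else if (f >= threshold) "predominant-I2"
  else if (1 - f >= threshold) "predominant-II2"
  else "mixed"
}

# brute-force per-micrograph filter
brute_filter <- function(records, type = "I2", min_count = 1L) {
  keep <- vapply(unique(records$micrograph_id), function(m) {
    sum(records$type_label[records$micrograph_id == m] == type) >= min_count
  }, logical(1))
  records[records$micrograph_id %in% unique(records$micrograph_id)[keep], ]
}

# random atom table of n points in a box, one chain/fold/rung
random_atoms <- function(n, seed, spread = 20) {
  set.seed(seed)
  atom_table(data.frame(
    atom_name = "CA", element = "C",
    residue_number = seq_len(n) * 3L,  # spaced so no bonded exclusions
    residue_name = "ALA", chain_id = "A", rung_index = 0L,
    fold_label = "PF-A",
    x = runif(n, 0, spread), y = runif(n, 0, spread), z = runif(n, 0, spread)
  ))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# two-strand toy fold for register-shift contact tests: strand 1 residues
# 1..15 along x at y = 0, strand 2 residues 21..35 at y = 4.2 (within a
# 4.5 A packing cutoff of the facing residue), optionally shifted along its
# axis by `shift` residue spacings
two_strand_fold <- function(shift = 0L) {
  sp <- 3.8
  s1 <- data.frame(residue_number = 1:15, x = (0:14) * sp, y = 0)
  s2 <- data.frame(residue_number = 21:35, x = (0:14 + shift) * sp, y = 4.2)
  df <- rbind(s1, s2)
  atom_table(data.frame(
    atom_name = "CA", element = "C", residue_number = df$residue_number,
    residue_name = "ALA", chain_id = "A", rung_index = 0L,
    fold_label = "PF-A", x = df$x, y = df$y, z = 0
  ))
}

# modal strand-2 partner for each strand-1 residue from a contact data.frame
strand_partners <- function(cm) {
  cm <- cm[cm$residue_i <= 15 & cm$residue_j >= 21, ]
  sapply(split(cm, cm$residue_i), function(g) g$residue_j[which.min(g$distance)])
}
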