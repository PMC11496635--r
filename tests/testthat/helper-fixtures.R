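# Fixtures and independent brute-force oracles used across the suite.

# Tiny dataset from explicit per-pixel peak lists.
# peaks: list of list(mz=..., intensity=...), coords optional.
tiny_dataset <- function(peaks, coords = NULL, ...) {
  n <- length(peaks)
  if (is.null(coords)) {
    side <- ceiling(sqrt(n))
    coords <- expand.grid(x = 0:(side - 1L), y = 0:(side - 1L))[seq_len(n), ]
  }
  centroided_dataset(lapply(peaks, function(p) {
    centroided_spectrum(p$mz, p$intensity)
  }), coords, ...)
}

# Exhaustive isotopologue enumeration: every atom assigned independently to
# one of its element's isotopes; isotopologues aggregated into nominal-mass
# shift bins. Only feasible for small molecules (product of isotope counts).
enumerate_pattern_oracle <- function(composition) {
  tab <- isotope_table()
  atoms <- rep(names(composition), composition)
  per_atom <- lapply(atoms, function(el) {
    iso <- tab[[el]]
    data.frame(shift = round(iso$mass - iso$mass[1]), p = iso$abundance,
               m = iso$mass)
  })
  grid <- do.call(expand.grid, lapply(per_atom, function(d) seq_len(nrow(d))))
  shift <- rep(0, nrow(grid)); prob <- rep(1, nrow(grid)); mass <- rep(0, nrow(grid))
  for (j in seq_along(per_atom)) {
    d <- per_atom[[j]][grid[[j]], ]
    shift <- shift + d$shift
    prob <- prob * d$p
    mass <- mass + d$m
  }
  agg <- tapply(prob, shift, sum)
  mz <- tapply(prob * mass, shift, sum) / agg
  o <- order(mz)
  list(shift = as.integer(names(agg))[o], prob = as.vector(agg)[o],
       mass = as.vector(mz)[o])
}

# Per-rank recount of T_i / D_i through a triangular counting matrix,
# independent of the cumsum-based estimator.
fdr_recount_oracle <- function(is_decoy, s_d) {
  n <- length(is_decoy)
  lower <- lower.tri(matrix(0, n, n), diag = TRUE) * 1
  d_i <- as.vector(lower %*% as.numeric(is_decoy))
  t_i <- as.vector(lower %*% as.numeric(!is_decoy))
  ((d_i + 1) / s_d) / ((t_i + 1) + (d_i + 1) / s_d)
}

# Average precision by literal definition: precision at each target rank.
ap_oracle <- function(labels) {
  hits <- 0; total <- 0; found <- 0
  for (k in seq_along(labels)) {
    if (labels[k]) {
      found <- found + 1
      total <- total + sum(labels[seq_len(k)]) / k
    }
  }
  total / found
}

# F-beta curve by explicit confusion-matrix counting at each cutoff.
fbeta_curve_oracle <- function(fdr, is_decoy, beta = 0.5) {
  f <- sort(unique(fdr))
  b <- numeric(length(f))
  for (i in seq_along(f)) {
    tp <- fp <- fn <- 0
    for (j in seq_along(fdr)) {
      pos <- fdr[j] <= f[i]
      if (pos && !is_decoy[j]) tp <- tp + 1
      if (pos && is_decoy[j]) fp <- fp + 1
      if (!pos && !is_decoy[j]) fn <- fn + 1
    }
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    b[i] <- if (precision == 0 && recall == 0) 0 else {
      (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
    }
  }
  list(f = f, b = b)
}

# One-tailed (greater) Fisher p as an explicit hypergeometric tail sum over
# tables at least as extreme as observed, with fixed margins.
fisher_greater_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  xs <- max(0, k - m2):min(m1, k)
  p <- vapply(xs, function(x) {
    exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(n, k))
  }, numeric(1))
  sum(p[xs >= a])
}

# Connected-component count by breadth-first flood fill (4-connectivity),
# independent of the union-find labeller in the package.
components_oracle <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  seen <- matrix(FALSE, nr, nc)
  count <- 0
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!binary[r0, c0] || seen[r0, c0]) next
    count <- count + 1
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- cell[1] + dd[1]; c <- cell[2] + dd[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            binary[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}

# All target/decoy label patterns of length n as a logical matrix
# (TRUE = decoy), one pattern per row.
all_label_patterns <- function(n) {
  ints <- 0:(2^n - 1)
  matrix(vapply(1:n, function(b) bitwAnd(ints, bitwShiftL(1L, b - 1L)) > 0,
                logical(2^n)), ncol = n)
}
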