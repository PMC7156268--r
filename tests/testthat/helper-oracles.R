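# Brute-force oracles and fixture builders. Each oracle is an independent,
# naive reimplementation of the contract it checks: no shared code with the
# package beyond the stated conventions (binning, tie rules).

make_disc <- function(nr, nc = nr, cy = (nr + 1) / 2, cx = (nc + 1) / 2, r) {
  rg <- matrix(seq_len(nr), nr, nc)
  cg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rg - cy)^2 + (cg - cx)^2 <= r^2
}

# Exhaustive Otsu: between-class variance at every interior bin boundary,
# class means computed by direct averaging of binned values; ties resolved
# to the middle tying boundary (the stated convention).
oracle_otsu <- function(v, n_bins = 256L) {
  v <- as.vector(v)
  lo <- min(v); hi <- max(v); span <- hi - lo
  stopifnot(span > 0)
  bin <- pmin(floor((v - lo) / span * n_bins) + 1L, n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * span / n_bins
  binned <- mids[bin]
  sig <- numeric(n_bins - 1L)
  for (k in seq_len(n_bins - 1L)) {
    left <- binned[bin <= k]
    right <- binned[bin > k]
    if (length(left) == 0L || length(right) == 0L) { sig[k] <- 0; next }
    w1 <- length(left) / length(v)
    sig[k] <- w1 * (1 - w1) * (mean(left) - mean(right))^2
  }
  top <- max(sig)
  ties <- which(sig >= top - 1e-12 * max(top, 1))
  k <- ties[ceiling(length(ties) / 2)]
  lo + k / n_bins * span
}

# Flood-fill connected components by explicit queue; labels numbered in
# column-major order of each component's first pixel.
oracle_flood_fill <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 8L)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(offs))) {
        qi <- p[1L] + offs[k, 1L]; qj <- p[2L] + offs[k, 2L]
        if (qi >= 1L && qi <= nr && qj >= 1L && qj <= nc &&
            mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          queue[[length(queue) + 1L]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# Exact two-sided Wilcoxon p by bitmask enumeration of all group-a subsets,
# with midranks and the symmetric doubling convention.
oracle_wilcoxon_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- c()
  for (m in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(m))[1:N]
    if (sum(bits) != n1) next
    us <- c(us, sum(r[bits == 1L]) - n1 * (n1 + 1) / 2)
  }
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Exact two-sided Spearman permutation p: exhaustive distinct tuples via
# expand.grid, rho as Pearson correlation of midranks.
oracle_spearman <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  pearson <- function(u, v) {
    u <- u - mean(u); v <- v - mean(v)
    sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  }
  rho_obs <- pearson(rx, ry)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- grid[apply(grid, 1L, function(p) length(unique(p)) == n), ,
                drop = FALSE]
  rho_all <- apply(perms, 1L, function(p) pearson(rx, ry[p]))
  list(rho = rho_obs, p = mean(abs(rho_all) >= abs(rho_obs) - 1e-9))
}

# Welch t-test p-value by direct quadrature of the t density.
oracle_welch_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a) / n1; v2 <- var(b) / n2
  tt <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  2 * stats::integrate(function(x) stats::dt(x, df), abs(tt), Inf,
                       rel.tol = 1e-10)$value
}

# Standard 40-object aggregate scene used by recovery checks: ten objects in
# each size class (bounds 0.001/0.01/0.1 mm^2 at 0.01 mm/px).
standard_scene <- function(seed, overlap_pairs = 0L, noise_sd = 0.01) {
  objects <- data.frame(
    target_area_mm2 = rep(c(0.0008, 0.005, 0.05, 0.25), each = 10L),
    shape = rep(c("disc", "blob"), 20L))
  gen_aggregate_scene(field_size_px = c(600L, 600L), pixel_size_mm = 0.01,
                      objects = objects, overlap_pairs = overlap_pairs,
                      noise_sd = noise_sd, seed = seed)
}

# Truth per-class totals from generator-side labels.
truth_class_totals <- function(truth, classes = size_class_config()) {
  cls <- floquant:::classify_area(truth$objects$area_mm2, classes)
  vapply(levels(cls), function(l)
    sum(truth$objects$area_mm2[cls == l]), numeric(1))
}

# Two-step brightness phantom: bright core (0.9, 15% of field), dim annulus
# (0.30, 25%), dark background (0.05). A single Otsu pass keeps only the
# core; iterative expansion must capture the annulus too.
two_step_phantom <- function() {
  px <- matrix(0.05, 100, 100)
  rad <- sqrt((matrix(1:100, 100, 100) - 50.5)^2 +
              (matrix(1:100, 100, 100, byrow = TRUE) - 50.5)^2)
  px[rad <= 35.7] <- 0.30
  px[rad <= 21.9] <- 0.90
  list(image = px, colony = rad <= 35.7)
}

iou <- function(a, b) sum(a & b) / sum(a | b)
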