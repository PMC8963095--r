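# Shared fixtures and independent oracles, built in code at test time.

# random binary mask as a plain 3D array
random_mask <- function(shape, p = 0.3) {
  array(as.integer(runif(prod(shape)) < p), dim = shape)
}

# enhanced phantom + constructed labels, the unit every training test eats
make_training_samples <- function(n, grid, seed0 = 100L) {
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(phantom_params(
      grid_shape = rep(grid, 3),
      ellipsoid_semi_axes = round(grid * c(0.38, 0.31, 0.25)),
      seed = seed0 + i))
    e <- enhance_contrast(ph$volume)
    list(volume = e,
         labels = build_label_triplet(e, ph$truth$whole, use_snakes = FALSE),
         truth = ph$truth)
  })
}

# exhaustive voxel-loop confusion counts: the metrics oracle
oracle_counts <- function(p, g) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(p)) {
    if (p[i] == 1L && g[i] == 1L) tp <- tp + 1L
    else if (p[i] == 0L && g[i] == 0L) tn <- tn + 1L
    else if (p[i] == 1L) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

oracle_metrics <- function(p, g) {
  cc <- oracle_counts(p, g)
  inter <- 0
  sp_ <- sg_ <- 0
  for (i in seq_along(p)) {
    inter <- inter + p[i] * g[i]
    sp_ <- sp_ + p[i]
    sg_ <- sg_ + g[i]
  }
  list(DSC = 2 * inter / (sp_ + sg_),
       OC = inter / min(sp_, sg_),
       SP = cc$TN / (cc$FP + cc$TN),
       SN = cc$TP / (cc$TP + cc$FN),
       AUC = 1 - 0.5 * (cc$FP / (cc$FP + cc$TN) + cc$FN / (cc$FN + cc$TP)),
       counts = cc)
}

# brute-force Otsu: enumerate every distinct value as the upper edge of the
# lower class, maximize between-class variance directly
oracle_otsu <- function(x) {
  vals <- sort(unique(as.numeric(x)))
  best <- -Inf
  best_i <- 1L
  for (i in seq_len(length(vals) - 1)) {
    t <- vals[i]
    lo <- x[x <= t]
    hi <- x[x > t]
    w0 <- length(lo) / length(x)
    w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) {
      best <- sb
      best_i <- i
    }
  }
  # threshold reported between the two classes of the optimal split
  (vals[best_i] + vals[best_i + 1]) / 2
}

# boundary voxels of a binary array (6-neighborhood)
boundary_count <- function(m) {
  er <- m
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (d in shifts) {
    s <- array(1L, dim = dim(m))
    src <- dst <- lapply(dim(m), seq_len)
    for (k in 1:3) {
      if (d[k] > 0) {
        dst[[k]] <- (d[k] + 1):dim(m)[k]; src[[k]] <- 1:(dim(m)[k] - d[k])
      } else if (d[k] < 0) {
        dst[[k]] <- 1:(dim(m)[k] + d[k]); src[[k]] <- (1 - d[k]):dim(m)[k]
      }
    }
    s[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    er <- pmin(er, s)
  }
  sum(m == 1L & er == 0L)
}

expect_triplet_invariants <- function(tri) {
  f <- tri$fissures$data
  t <- tri$tissue$data
  w <- tri$whole$data
  expect_true(all((f | t) == (w > 0)))
  expect_identical(sum(f & t), 0L)
  expect_true(all(w[f == 1L] == 1L))
}
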