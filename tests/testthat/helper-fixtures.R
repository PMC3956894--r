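# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# Training structures for the statistical potentials and fragment library:
# two toys of each topology at varied lengths.
fx_train <- function() memo("train", function() {
  specs <- list(c("helix_hairpin", 50, 11), c("beta_hairpin", 44, 21),
                c("three_helix_bundle", 62, 31), c("mixed", 54, 41),
                c("helix_hairpin", 64, 12), c("beta_hairpin", 38, 22),
                c("three_helix_bundle", 56, 32), c("mixed", 60, 42))
  out <- lapply(specs, function(s)
    make_toy(s[1], as.integer(s[2]), seed = as.integer(s[3]))$native)
  names(out) <- vapply(specs, function(s) paste0(s[1], "_", s[3]), "")
  out
})

# The benchmark target: 60-residue helix hairpin.
fx_toy <- function() memo("toy", function() make_toy("helix_hairpin", 60,
                                                     seed = 1))

fx_true_contacts <- function() memo("truec", function()
  native_contacts(fx_toy()$native))

fx_pair_table <- function() memo("pt", function()
  train_pair_potential(fx_train()))

fx_solv_table <- function() memo("st", function()
  train_solv_potential(fx_train()))

fx_em <- function() memo("em", function() {
  em <- energy_model(fx_pair_table(), fx_solv_table())
  calibrate_weights(em, fx_toy()$record$sequence,
                    contacts = fx_true_contacts(), ss_pred = fx_toy()$ss,
                    n_random = 200, seed = 5)
})

fx_lib <- function() memo("lib", function()
  build_library(fx_train(), exclude_target = fx_toy()$record))

fx_shortlists <- function() memo("sls", function()
  shortlists_for_target(fx_lib(), fx_toy()$ss, fx_toy()$record,
                        fx_pair_table(), K = 25))

# Benchmark inputs at the acceptance study conditions (master seed 1).
acc_inputs <- function() memo("acc", function() toy_benchmark_inputs(seed = 1))

# --- independent oracles -----------------------------------------------

# random rotation matrix from quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3)
}

rot_from_axis_angle <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Brute-force least-squares superposition: rotation grid plus local
# refinement; for a fixed rotation the optimal translation aligns centroids.
oracle_rmsd <- function(a, b, n_grid = 400) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  f <- function(R) sqrt(mean(rowSums((ac %*% R - bc)^2)))
  best <- Inf; best_v <- NULL
  for (k in seq_len(n_grid)) {
    R <- random_rotation()
    v <- f(R)
    if (v < best) { best <- v; best_v <- R }
  }
  # refine around the best grid rotation via axis-angle perturbation
  obj <- function(v) f(best_v %*% rot_from_axis_angle(v))
  op <- optim(c(0, 0, 0), obj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
  min(best, op$value)
}

# Weighted Kabsch in plain R (svd), used by the TM oracle's refinement.
r_weighted_kabsch <- function(a, b, w) {
  W <- sum(w)
  ma <- colSums(a * w) / W; mb <- colSums(b * w) / W
  ac <- sweep(a, 2, ma); bc <- sweep(b, 2, mb)
  H <- t(ac) %*% (bc * w)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, t = mb - ma %*% R)
}

# Brute-force TM-score: dense seeded rotation starts, each refined by
# iteratively reweighted least-squares superposition (weights follow the
# TM kernel), which converges to a local maximum of the TM objective.
oracle_tm <- function(x, y, d0 = NULL, n_grid = 300, n_refine = 20) {
  d0 <- if (is.null(d0)) tm_d0(nrow(y)) else d0
  tm_of <- function(xs) mean(1 / (1 + rowSums((xs - y)^2) / d0^2))
  cx <- colMeans(x); cy <- colMeans(y)
  vals <- numeric(n_grid)
  Rs <- vector("list", n_grid)
  xc <- sweep(x, 2, cx)
  for (k in seq_len(n_grid)) {
    R <- random_rotation()
    Rs[[k]] <- R
    vals[k] <- tm_of(sweep(xc %*% R, 2, -cy))
  }
  best <- max(vals)
  irls <- function(xs) {
    prev <- -1
    for (iter in 1:80) {
      r2 <- rowSums((xs - y)^2) / d0^2
      w <- 1 / (1 + r2)^2
      fit <- r_weighted_kabsch(x, y, w)
      xs <- sweep(x %*% fit$R, 2, -as.numeric(fit$t))
      tm <- tm_of(xs)
      if (tm > best) best <<- tm
      if (tm - prev < 1e-10) break
      prev <- tm
    }
  }
  for (k in head(order(-vals), n_refine))
    irls(sweep(xc %*% Rs[[k]], 2, -cy))
  # random-subset alignment seeds: superpose on a random handful of points,
  # then reweight; covers optima whose basins centroid-aligned rotations miss
  n <- nrow(x)
  for (k in seq_len(n_refine * 10)) {
    idx <- sample.int(n, sample(3:min(7, n), 1))
    w <- numeric(n); w[idx] <- 1
    fit <- r_weighted_kabsch(x, y, w + 1e-9)
    irls(sweep(x %*% fit$R, 2, -as.numeric(fit$t)))
  }
  best
}

# Plain double-loop DME
oracle_dme <- function(a, b) {
  n <- nrow(a); s <- 0; m <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    da <- sqrt(sum((a[i, ] - a[j, ])^2))
    db <- sqrt(sum((b[i, ] - b[j, ])^2))
    s <- s + (da - db)^2; m <- m + 1
  }
  sqrt(s / m)
}

# random compact-ish CA-like point clouds for metric tests
random_points <- function(n, spread = 4) {
  matrix(rnorm(3 * n, sd = spread), n, 3)
}
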