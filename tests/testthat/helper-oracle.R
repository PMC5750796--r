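# Independent numeric oracle for the local-hyperplane distance: minimise the
# ridge-regularised weighted objective over alpha with a general-purpose
# optimiser, never touching the package's closed-form solve.
oracle_jc <- function(q, prototypes, w, lambda) {
  prototypes <- as.matrix(prototypes)
  k <- nrow(prototypes)
  mc <- colMeans(prototypes)
  V <- t(prototypes) - mc
  obj <- function(alpha) {
    s <- drop(V %*% alpha) + mc
    sum(w * (s - q)^2) + lambda * sum(alpha^2)
  }
  fit <- stats::optim(rep(0, k), obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  fit$value
}

# brute-force HKNN prediction (uniform weights), built only on oracle_jc
oracle_hknn_predict <- function(train_x, train_y, q, k, lambda) {
  classes <- sort(unique(train_y))
  jc <- vapply(classes, function(cl) {
    rows <- train_x[train_y == cl, , drop = FALSE]
    d2 <- colSums((t(rows) - q)^2)
    take <- order(d2)[seq_len(min(k, nrow(rows)))]
    oracle_jc(q, rows[take, , drop = FALSE], rep(1, length(q)), lambda)
  }, 0)
  classes[which.min(jc)]
}

# small random classification instance for property tests
random_instance <- function(m = 8, n = 4, L = 2) {
  x <- matrix(stats::rnorm(m * n), m, n)
  y <- sample(letters[seq_len(L)], m, replace = TRUE)
  # ensure every class is represented
  y[seq_len(L)] <- letters[seq_len(L)]
  list(x = x, y = y)
}

# seeded standard-normal matrix (deterministic noise channels)
with_seed_matrix <- function(seed, nr, nc) {
  set.seed(seed)
  matrix(stats::rnorm(nr * nc), nr, nc)
}

# tiny deterministic dataset for I/O tests
toy_dataset <- function(m = 4, n = 6, descending = FALSE) {
  wn <- seq(1000, by = 50, length.out = n)
  x <- matrix(seq_len(m * n) / 7 + 0.123456789, m, n)
  if (descending) {
    wn <- rev(wn)
    x <- x[, rev(seq_len(n)), drop = FALSE]
  }
  spectra_dataset(x, wn, labels = rep(c("cancer", "colitis"), length.out = m),
                  sample_ids = paste0("t", seq_len(m)))
}
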