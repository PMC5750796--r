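test_that("closed-form hyperplane distance agrees with numeric minimisation", {
  set.seed(31)
  worst <- 0
  for (rep in 1:60) {
    n <- sample(2:6, 1); k <- sample(1:4, 1)
    lambda <- sample(c(0, 0.1, 1), 1)
    prot <- matrix(rnorm(k * n), k, n)
    q <- rnorm(n)
    w <- runif(n); w <- w / sum(w)
    fit <- hyperplane_distance(q, prot, w, lambda)
    ref <- oracle_jc(q, prot, w, lambda)
    worst <- max(worst, abs(fit$jc - ref) / max(abs(ref), 1e-8))
  }
  expect_lt(worst, 1e-6)
})

test_that("hyperplane geometry matches hand-worked cases", {
  # query at the centroid: alpha = 0, Jc = 0
  prot <- rbind(c(0, 0), c(2, 2))
  fit <- hyperplane_distance(c(1, 1), prot, c(0.5, 0.5), lambda = 0)
  expect_equal(fit$alpha, rep(0, 2))
  expect_equal(fit$jc, 0)

  # hyperplane through (1,0) along x-axis; residual purely in y
  prot <- rbind(c(0, 0), c(2, 0))
  fit <- hyperplane_distance(c(1, 1), prot, c(0.5, 0.5), lambda = 0)
  expect_equal(fit$centroid, c(1, 0))
  expect_equal(fit$jc, 0.5, tolerance = 1e-12)

  # ridge limit: alpha -> 0, Jc -> weighted centroid distance
  w <- c(0.3, 0.7)
  q <- c(3, -1)
  fit_inf <- hyperplane_distance(q, prot, w, lambda = 1e12)
  mc <- colMeans(prot)
  expect_equal(fit_inf$jc, sum(w * (mc - q)^2), tolerance = 1e-4)

  # duplicated prototypes make the system singular at lambda = 0:
  # minimum-norm solve still returns the well-defined minimum value
  dup <- rbind(c(0, 0), c(2, 0), c(2, 0))
  fit_sing <- hyperplane_distance(c(1, 1), dup, c(0.5, 0.5), lambda = 0)
  expect_equal(fit_sing$jc,
               oracle_jc(c(1, 1), dup, c(0.5, 0.5), 0), tolerance = 1e-8)

  expect_error(hyperplane_distance(c(1, NA), prot, w, 0), "non-finite")
})

test_that("monotonicity in lambda: larger ridge penalty never lowers Jc", {
  set.seed(32)
  for (rep in 1:10) {
    prot <- matrix(rnorm(3 * 4), 3, 4)
    q <- rnorm(4); w <- runif(4); w <- w / sum(w)
    lams <- c(0, 0.01, 0.1, 1, 10)
    jc <- vapply(lams, function(l) hyperplane_distance(q, prot, w, l)$jc, 0)
    expect_true(all(diff(jc) >= -1e-10))
  }
})

test_that("prototype selection returns the weighted-nearest class rows", {
  set.seed(33)
  inst <- random_instance(m = 12, n = 4)
  fit <- ewhk(inst$x, inst$y, k = 3, weights = "entropy")
  q <- rnorm(4)
  sel <- select_prototypes(fit, q, "a")
  # oracle: exhaustive sort of all class-a weighted distances
  ia <- which(inst$y == "a")
  d <- vapply(ia, function(i) weighted_distance(inst$x[i, ], q, fit$w), 0)
  expect_equal(sel$index, ia[order(d)][seq_along(sel$index)])
  expect_equal(sel$distance, sort(d)[seq_along(sel$index)])
  # saturation: k beyond the class size returns the whole class, ordered
  sel_all <- select_prototypes(fit, q, "a", k = 100)
  expect_equal(sel_all$index, ia[order(d)])
  # query equal to a training row, k = 1 -> that row
  sel1 <- select_prototypes(fit, inst$x[ia[2], ], "a", k = 1)
  expect_equal(sel1$index, ia[2])
  expect_error(select_prototypes(fit, q, "nosuch"), "unknown class")
})

test_that("classification is exact on training rows and breaks ties lexicographically", {
  set.seed(34)
  inst <- random_instance(m = 10, n = 3)
  fit <- ewhk(inst$x, inst$y, k = 1, lambda = 0)
  # training rows classify to their own label with J = 0 at k = 1
  pred <- predict(fit, inst$x, type = "both")
  expect_identical(pred$class, inst$y)
  expect_equal(pred$scores[cbind(seq_len(10), match(inst$y, fit$levels))],
               rep(0, 10), tolerance = 1e-20)
  # perfectly symmetric classes, query midway -> lexicographic tie to "a"
  x <- rbind(c(-1, 0), c(-2, 0), c(1, 0), c(2, 0))
  y <- c("b", "b", "a", "a")
  sym <- ewhk(x, y, k = 2, lambda = 1, weights = "uniform")
  both <- predict(sym, c(0, 0), type = "both")
  expect_equal(unname(both$scores[1, "a"]), unname(both$scores[1, "b"]))
  expect_identical(both$class, "a")
})

test_that("k = 1 reduces to per-class weighted nearest-neighbour", {
  set.seed(35)
  inst <- random_instance(m = 10, n = 4)
  fit <- ewhk(inst$x, inst$y, k = 1, lambda = 0.5)
  for (rep in 1:5) {
    q <- rnorm(4)
    sc <- predict(fit, q, type = "scores")
    for (cl in fit$levels) {
      rows <- inst$x[inst$y == cl, , drop = FALSE]
      d2 <- apply(rows, 1, function(r) sum(fit$w * (r - q)^2))
      expect_equal(unname(sc[1, cl]), min(d2), tolerance = 1e-12)
    }
  }
})

test_that("uniform mode reproduces brute-force HKNN on random queries", {
  set.seed(36)
  inst <- random_instance(m = 14, n = 3)
  fit <- ewhk(inst$x, inst$y, k = 3, lambda = 0, weights = "uniform")
  expect_equal(fit$w, rep(1, 3))
  queries <- matrix(rnorm(25 * 3), 25, 3)
  got <- predict(fit, queries)
  want <- apply(queries, 1, function(q)
    oracle_hknn_predict(inst$x, inst$y, q, k = 3, lambda = 0))
  expect_identical(got, unname(want))
})

test_that("fitting is deterministic and invariant to training-row permutation", {
  set.seed(37)
  inst <- random_instance(m = 12, n = 5)
  f1 <- ewhk(inst$x, inst$y, k = 3)
  f2 <- ewhk(inst$x, inst$y, k = 3)
  expect_equal(f1$w, f2$w)
  queries <- matrix(rnorm(10 * 5), 10, 5)
  perm <- sample(12)
  fp <- ewhk(inst$x[perm, ], inst$y[perm], k = 3)
  expect_identical(predict(f1, queries), predict(fp, queries))
  # a constant training column gets zero weight in entropy mode
  xc <- cbind(inst$x, 1)
  expect_equal(ewhk(xc, inst$y)$w[6], 0, tolerance = 1e-12)
})

test_that("model fitting validates its inputs", {
  expect_error(ewhk(matrix(1:3, 1, 3), "a"), "at least 2")
  expect_error(ewhk(matrix(1:6, 2, 3), c("a", "b"), k = 0), "k must be")
  expect_error(ewhk(matrix(1:6, 2, 3), c("a", "b"), lambda = -1), "lambda")
  expect_warning(ewhk(matrix(rnorm(6), 2, 3), c("a", "a")), "single-class")
  fit <- ewhk(matrix(rnorm(12), 4, 3), c("a", "b", "a", "b"))
  expect_error(predict(fit, c(1, 2)), "features")
})

test_that("spectra_dataset method and coef accessor work", {
  ds <- preprocess_spectra(simulate_spectra(n_per_class = 5, seed = 38))
  fit <- ewhk(ds, k = 3)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-12)
  expect_error(ewhk(ds, y = ds$labels), "omitted")
  pred <- predict(fit, ds)
  expect_length(pred, 10)
  expect_true(all(pred %in% c("cancer", "colitis")))
})
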