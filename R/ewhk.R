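#' Fit an entropy-weight local-hyperplane k-nearest-neighbour classifier
#'
#' EWHK classifies a query spectrum by its distance to the local affine
#' hull ("local hyperplane") of its k nearest training neighbours within
#' each class, under a feature-weighted metric, and assigns the class whose
#' hyperplane lies closest. With `weights = "entropy"` the metric weights
#' come from [entropy_weights()] computed on the full training matrix
#' (labels are not used for weighting); with `weights = "uniform"` every
#' feature has weight 1 and the classifier reduces to the classical HKNN.
#'
#' Like other nearest-neighbour methods, fitting stores the training data;
#' all computation happens at prediction time.
#'
#' @param x numeric training matrix (m samples by n features) or a
#'   [spectra_dataset()] (its labels are used and `y` must be omitted).
#' @param y class labels, length m. At least one sample per class.
#' @param k neighbours per class used to span the local hyperplane;
#'   clipped per class to the class size at prediction time. Default 5.
#' @param lambda ridge regularisation penalty on the hyperplane
#'   coefficients, >= 0. Default 1.
#' @param weights `"entropy"` (EWHK) or `"uniform"` (HKNN).
#' @param ... unused.
#' @return An object of class `"ewhk"`: list with the training matrix and
#'   labels, the weight vector `w`, the [entropy_weights()] object
#'   `entropy` (or `NULL` in uniform mode), `k`, `lambda`, `weights`
#'   (mode string) and `levels` (sorted class labels).
#' @examples
#' ds <- preprocess_spectra(simulate_spectra(n_per_class = 10, seed = 1))
#' fit <- ewhk(ds, k = 3)
#' fit
#' predict(fit, ds$absorbance[1:2, ])
#' @export
ewhk <- function(x, y = NULL, k = 5L, lambda = 1,
                 weights = c("entropy", "uniform"), ...) {
  weights <- match.arg(weights)
  if (inherits(x, "spectra_dataset")) {
    if (!is.null(y))
      stop("ewhk: y must be omitted when x is a spectra_dataset")
    y <- x$labels
    x <- x$absorbance
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.character(y)
  m <- nrow(x)
  if (m < 2L) stop("ewhk: at least 2 training samples are required")
  if (length(y) != m) stop("ewhk: length(y) must equal nrow(x)")
  if (anyNA(x) || any(!is.finite(x)))
    stop("ewhk: non-finite values in training matrix")
  k <- as.integer(k)
  if (k < 1L) stop("ewhk: k must be >= 1")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("ewhk: lambda must be a single non-negative number")
  levels <- sort(unique(y))
  if (length(levels) < 2L)
    warning("ewhk: single-class training set; every query will be ",
            "assigned to class '", levels, "'")

  if (weights == "entropy") {
    ew <- entropy_weights(x)
    w <- ew$w
  } else {
    ew <- NULL
    w <- rep(1, ncol(x))
  }

  structure(list(x = x, y = y, w = w, entropy = ew, k = k,
                 lambda = lambda, weights = weights, levels = levels,
                 call = match.call()),
            class = "ewhk")
}

#' @export
print.ewhk <- function(x, ...) {
  cat("Entropy-weight local-hyperplane k-NN classifier",
      if (x$weights == "uniform") "(uniform weights: HKNN)", "\n")
  cat("  training samples:", nrow(x$x), " features:", ncol(x$x), "\n")
  cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  cat("  k =", x$k, " lambda =", x$lambda, " weights =", x$weights, "\n")
  invisible(x)
}

#' @export
summary.ewhk <- function(object, ...) {
  print(object)
  tab <- table(object$y)
  cat("  class sizes: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  if (!is.null(object$entropy)) {
    w <- object$w
    cat("  entropy weights: sum =", format(sum(w)),
        " top channel carries", format(100 * max(w), digits = 3),
        "% of total weight\n")
  }
  invisible(object)
}

#' Feature weights of a fitted classifier
#'
#' @param object a fitted [ewhk()] model.
#' @param ... unused.
#' @return The numeric per-feature weight vector used by the metric.
#' @export
coef.ewhk <- function(object, ...) object$w

#' Select the k nearest class prototypes for a query
#'
#' Returns the `min(k, class size)` training rows of class `class` with the
#' smallest [weighted_distance()] to the query, in ascending distance
#' order. Distance ties are broken by ascending training-row index.
#'
#' @param model a fitted [ewhk()] model.
#' @param q numeric query vector.
#' @param class a class label present in the training set.
#' @param k optional override of the model's k.
#' @return List with `rows` (prototype matrix, one prototype per row),
#'   `index` (training-row indices) and `distance`.
#' @export
select_prototypes <- function(model, q, class, k = model$k) {
  stopifnot(inherits(model, "ewhk"))
  idx <- which(model$y == class)
  if (length(idx) == 0L)
    stop("select_prototypes: unknown class '", class, "'")
  if (length(q) != ncol(model$x))
    stop("select_prototypes: query has length ", length(q),
         ", expected ", ncol(model$x))
  d2 <- colSums(model$w * (t(model$x[idx, , drop = FALSE]) - q)^2)
  ord <- order(d2, idx)                 # tie-break: ascending row index
  take <- ord[seq_len(min(k, length(idx)))]
  list(rows = model$x[idx[take], , drop = FALSE],
       index = idx[take], distance = sqrt(d2[take]))
}

#' Weighted distance from a query to a local class hyperplane
#'
#' Builds the affine hull of the prototypes through their centroid
#' \eqn{m_c}, with basis columns \eqn{V_{.i} = p_i - m_c}, and finds the
#' ridge-regularised weighted squared distance
#' \deqn{J_c(q) = \min_\alpha (s - q)^T W (s - q) + \lambda \alpha^T\alpha,
#'   \quad s = V\alpha + m_c,\; W = diag(w)}
#' by solving the normal equations
#' \eqn{(U^T V + \lambda I_k)\alpha = U^T(q - m_c)} with
#' \eqn{U^T = V^T W}. When `lambda = 0` and the system is singular the
#' minimum-norm least-squares solution is used; the minimum value is the
#' same for every minimiser.
#'
#' @param q numeric query vector (length n).
#' @param prototypes numeric matrix of k prototype rows.
#' @param w an [entropy_weights()] object or numeric weight vector.
#' @param lambda ridge penalty, >= 0.
#' @return An object of class `"hyperplane_fit"`: list with `centroid`,
#'   `basis` (n x k matrix V), `alpha`, `s` (closest hyperplane point) and
#'   `jc` (the minimised objective, >= 0).
#' @export
hyperplane_distance <- function(q, prototypes, w, lambda = 0) {
  if (inherits(w, "entropy_weights")) w <- w$w
  prototypes <- as.matrix(prototypes)
  k <- nrow(prototypes)
  n <- ncol(prototypes)
  if (k < 1L) stop("hyperplane_distance: at least one prototype required")
  if (length(q) != n || length(w) != n)
    stop("hyperplane_distance: dimension mismatch")
  if (anyNA(q) || anyNA(prototypes) || any(!is.finite(q)) ||
      any(!is.finite(prototypes)))
    stop("hyperplane_distance: non-finite values in inputs")
  if (lambda < 0) stop("hyperplane_distance: lambda must be >= 0")

  mc <- colMeans(prototypes)
  V <- t(prototypes) - mc               # n x k, columns p_i - m_c
  sw <- sqrt(w)
  A <- sw * V                           # W^(1/2) V
  b <- sw * (q - mc)                    # W^(1/2) (q - m_c)
  M <- crossprod(A) + diag(lambda, k)
  rhs <- crossprod(A, b)
  alpha <- tryCatch(drop(solve(M, rhs)),
                    error = function(e) NULL)
  if (is.null(alpha)) {                 # singular at lambda = 0: min-norm LS
    sv <- svd(A)
    pos <- sv$d > max(sv$d[1], 0) * 1e-10
    dinv <- ifelse(pos, 1 / sv$d, 0)
    alpha <- drop(sv$v %*% (dinv * crossprod(sv$u, b)))
  }
  s <- drop(V %*% alpha) + mc
  jc <- sum(w * (s - q)^2) + lambda * sum(alpha^2)
  structure(list(centroid = mc, basis = V, alpha = alpha, s = s,
                 jc = max(jc, 0)),
            class = "hyperplane_fit")
}

#' @export
print.hyperplane_fit <- function(x, ...) {
  cat("Local hyperplane fit: k =", length(x$alpha),
      " Jc =", format(x$jc), "\n")
  invisible(x)
}

#' Predict class labels for new spectra
#'
#' For each query, computes the regularised hyperplane distance
#' \eqn{J_c(q)} ([hyperplane_distance()]) to each training class from its
#' k nearest prototypes ([select_prototypes()]) and assigns
#' \eqn{\arg\min_c J_c(q)}. Score ties are broken towards the
#' lexicographically smallest class label.
#'
#' @param object a fitted [ewhk()] model.
#' @param newdata numeric matrix of queries (rows), a single query vector,
#'   or a [spectra_dataset()].
#' @param type `"class"` for labels, `"scores"` for the per-class
#'   \eqn{J_c} matrix, `"both"` for a list of the two.
#' @param ... unused.
#' @return A character vector of labels, a numeric score matrix with one
#'   column per class, or a list with elements `class` and `scores`.
#' @export
predict.ewhk <- function(object, newdata,
                         type = c("class", "scores", "both"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "spectra_dataset")) newdata <- newdata$absorbance
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop("predict.ewhk: newdata has ", ncol(newdata),
         " features, model expects ", ncol(object$x))
  classes <- object$levels
  scores <- matrix(NA_real_, nrow(newdata), length(classes),
                   dimnames = list(rownames(newdata), classes))
  for (i in seq_len(nrow(newdata))) {
    q <- newdata[i, ]
    for (c_idx in seq_along(classes)) {
      prot <- select_prototypes(object, q, classes[c_idx])
      scores[i, c_idx] <-
        hyperplane_distance(q, prot$rows, object$w, object$lambda)$jc
    }
  }
  # which.min on lexicographically sorted columns breaks ties to the
  # smallest label
  labels <- classes[apply(scores, 1L, which.min)]
  switch(type,
         class = labels,
         scores = scores,
         both = list(class = labels, scores = scores))
}
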