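#' Canonical discriminant analysis of well features
#'
#' Projects the wells-by-parameters feature matrix onto the canonical
#' discriminant functions: the directions maximising between-group relative
#' to pooled within-group scatter. Solves the generalized eigenproblem
#' `B a = lambda W a` (B between-group, W within-group scatter) via a
#' Cholesky-symmetrized dense eigendecomposition. Coefficients are scaled so
#' canonical scores have unit pooled within-group variance; scores are
#' centred on the grand centroid. The structure matrix holds the pooled
#' within-group correlation of every input variable with every canonical
#' score — the quantity used to rank which parameters drive the group
#' separation. The sign of each function is fixed so its largest-magnitude
#' structure loading is positive.
#'
#' @param x numeric matrix or data.frame (wells x variables), e.g. the nine
#'   network parameters from [feature_table()].
#' @param groups group label per row (>= 2 groups, each with >= 2 rows).
#' @param na_action `"drop"` drops rows with missing values (count
#'   messaged), anything else errors on missing values.
#' @return An object of class `mea_cda` with `coefficients`
#'   (variables x functions), `scores`, `eigenvalues`,
#'   `canonical_correlations`, `structure`, `centroids`, `groups`,
#'   `grand_mean`, `n_dropped`.
#' @export
canonical_discriminant <- function(x, groups, na_action = "drop") {
  X <- as.matrix(x)
  if (!is.numeric(X)) stop("'x' must be numeric", call. = FALSE)
  groups <- as.factor(groups)
  if (length(groups) != nrow(X)) {
    stop("'groups' must have one label per row of 'x'", call. = FALSE)
  }
  n_dropped <- 0L
  bad <- !stats::complete.cases(X)
  if (any(bad)) {
    if (identical(na_action, "drop")) {
      n_dropped <- sum(bad)
      message(sprintf("dropping %d row(s) with missing values", n_dropped))
      X <- X[!bad, , drop = FALSE]
      groups <- droplevels(groups[!bad])
    } else stop("missing values in 'x'", call. = FALSE)
  }
  groups <- droplevels(groups)
  g <- nlevels(groups)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 wells", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))

  grand <- colMeans(X)
  gmeans <- apply(X, 2, tapply, groups, mean)         # g x p
  Xw <- X - gmeans[groups, , drop = FALSE]            # within-group centred
  W <- crossprod(Xw)
  ng <- as.numeric(table(groups))
  Bd <- sweep(gmeans, 2, grand)                       # g x p deviations
  B <- crossprod(Bd * sqrt(ng))
  df_w <- n - g

  R <- tryCatch(chol(W), error = function(e) {
    stop("within-group scatter matrix is singular; remove collinear or ",
         "constant variables (or reduce the variable set)", call. = FALSE)
  })
  Rinv <- backsolve(R, diag(p))
  K <- t(Rinv) %*% B %*% Rinv
  K <- (K + t(K)) / 2
  eig <- eigen(K, symmetric = TRUE)
  q <- min(g - 1, p)
  lambda <- pmax(eig$values[seq_len(q)], 0)
  A <- Rinv %*% eig$vectors[, seq_len(q), drop = FALSE]
  # scale so scores have unit pooled within-group variance: a' (W/df_w) a = 1
  A <- A * sqrt(df_w)

  scores <- sweep(X, 2, grand) %*% A
  Sw <- W / df_w
  scores_w <- Xw %*% A
  structure_m <- crossprod(Xw, scores_w) / df_w / sqrt(diag(Sw))

  # sign convention: largest-|loading| positive per function
  for (k in seq_len(q)) {
    j <- which.max(abs(structure_m[, k]))
    if (structure_m[j, k] < 0) {
      A[, k] <- -A[, k]; scores[, k] <- -scores[, k]
      structure_m[, k] <- -structure_m[, k]
    }
  }
  centroids <- apply(scores, 2, tapply, groups, mean)
  if (q == 1) centroids <- matrix(centroids, ncol = 1,
                                  dimnames = list(levels(groups), NULL))
  fn <- paste0("CD", seq_len(q))
  dimnames(A) <- list(colnames(X), fn)
  dimnames(structure_m) <- list(colnames(X), fn)
  colnames(scores) <- fn
  colnames(centroids) <- fn

  structure(list(coefficients = A, scores = scores, eigenvalues = lambda,
                 canonical_correlations = sqrt(lambda / (1 + lambda)),
                 structure = structure_m, centroids = centroids,
                 groups = groups, grand_mean = grand, n_dropped = n_dropped,
                 variables = colnames(X)),
            class = "mea_cda")
}

#' @export
print.mea_cda <- function(x, ...) {
  q <- length(x$eigenvalues)
  cat(sprintf("Canonical discriminant analysis: %d wells, %d variables, %d groups\n",
              nrow(x$scores), length(x$variables), nlevels(x$groups)))
  cat(sprintf("%d canonical function(s)\n", q))
  tab <- rbind(eigenvalue = x$eigenvalues,
               `canonical correlation` = x$canonical_correlations)
  colnames(tab) <- colnames(x$scores)
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.mea_cda <- function(object, ...) {
  structure(list(cda = object), class = "summary.mea_cda")
}

#' @export
print.summary.mea_cda <- function(x, ...) {
  print(x$cda)
  cat("\nStructure matrix (pooled within-group correlations), ordered by |CD1|:\n")
  sm <- x$cda$structure
  print(round(sm[order(-abs(sm[, 1])), , drop = FALSE], 3))
  cat("\nGroup centroids:\n")
  print(round(x$cda$centroids, 3))
  invisible(x)
}

#' @export
coef.mea_cda <- function(object, ...) object$coefficients

#' Canonical scores for new feature rows
#'
#' @param object an `mea_cda`.
#' @param newdata matrix/data.frame with the fitted variables as columns.
#' @param ... unused.
#' @return Matrix of canonical scores (centred on the training grand mean).
#' @export
predict.mea_cda <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$variables, drop = FALSE])
  sweep(X, 2, object$grand_mean) %*% object$coefficients
}

#' Canonical score plot with group centroid ellipses
#'
#' Scatter of the first two canonical functions (or a one-dimensional strip
#' chart when only one function exists), with per-group 95\% concentration
#' ellipses centred on the group centroids.
#'
#' @param x an `mea_cda`.
#' @param level ellipse coverage level.
#' @param col colors per group.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mea_cda <- function(x, level = 0.95,
                         col = seq_len(nlevels(x$groups)) + 1, ...) {
  g <- x$groups
  if (ncol(x$scores) == 1) {
    graphics::stripchart(split(x$scores[, 1], g), vertical = TRUE,
                         method = "jitter", pch = 19, col = col,
                         ylab = "CD1", ...)
    return(invisible(x))
  }
  s <- x$scores[, 1:2]
  graphics::plot(s, col = col[as.integer(g)], pch = 19,
                 xlab = "CD1", ylab = "CD2", ...)
  r <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = 120)
  circ <- cbind(cos(theta), sin(theta)) * r
  for (k in seq_len(nlevels(g))) {
    sk <- s[g == levels(g)[k], , drop = FALSE]
    if (nrow(sk) < 3) next
    ell <- circ %*% chol(stats::cov(sk))
    graphics::lines(sweep(ell, 2, x$centroids[k, 1:2], "+"), col = col[k])
    graphics::points(x$centroids[k, 1], x$centroids[k, 2], pch = 3,
                     col = col[k], cex = 1.5, lwd = 2)
  }
  graphics::legend("topright", legend = levels(g), col = col, pch = 19,
                   bty = "n")
  invisible(x)
}
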