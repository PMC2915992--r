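# Multiple correspondence analysis of the categorical CNV matrix
# (indicator-matrix CA), its between-class discriminant variant (MCDA),
# correlation-based variable ranking and a label-permutation test.

.cnv_values <- function(x) {
  if (inherits(x, "CNVMatrix")) x$values
  else if (is.matrix(x)) x
  else stop("x must be a CNVMatrix or a matrix")
}

# full disjunctive (indicator) coding over observed levels only
.indicator <- function(v) {
  n <- nrow(v)
  cols <- list(); nms <- character(0); var_of <- integer(0)
  lev_of <- integer(0)
  vn <- colnames(v)
  if (is.null(vn)) vn <- paste0("V", seq_len(ncol(v)))
  for (j in seq_len(ncol(v))) {
    levs <- sort(unique(v[, j]))
    for (l in levs) {
      cols[[length(cols) + 1]] <- as.numeric(v[, j] == l)
      nms <- c(nms, paste0(vn[j], ".", l))
      var_of <- c(var_of, j)
      lev_of <- c(lev_of, l)
    }
  }
  Z <- do.call(cbind, cols)
  colnames(Z) <- nms
  list(Z = Z, var_of = var_of, lev_of = lev_of, var_names = vn)
}

#' Multiple correspondence analysis of a CNV call matrix
#'
#' Correspondence analysis of the full disjunctive (indicator) coding of
#' the three-level calls: the SVD of the standardized residual of the
#' indicator profile matrix.  Subject scores are row principal
#' coordinates; with equal row masses they are centered exactly.  The
#' indicator (not Burt) variant is used, which carries the principle of
#' distributional equivalence: merging identically-distributed columns
#' leaves subject scores unchanged.
#'
#' @param x a \code{CNVMatrix} (typically reduced) or a matrix over
#'   \{-1, 0, +1\}.
#' @param n_axes number of axes to retain (default 2).
#' @return an object of class \code{MCAResult}: \code{eigenvalues}
#'   (all positive ones, non-increasing), \code{scores} (subjects x
#'   retained axes, principal coordinates), \code{standard_scores},
#'   \code{category_coords}, \code{n_axes}.
#' @export
mca <- function(x, n_axes = 2) {
  v <- .cnv_values(x)
  if (nrow(v) < 2) stop("need at least 2 subjects")
  keep <- apply(v, 2, function(col) length(unique(col)) > 1)
  if (!any(keep)) stop("all variables are constant")
  v <- v[, keep, drop = FALSE]
  ind <- .indicator(v)
  Z <- ind$Z
  N <- sum(Z)
  P <- Z / N
  r <- rowSums(P)
  cm <- colSums(P)
  S <- sweep(sweep(P - outer(r, cm), 1, sqrt(r), "/"), 2, sqrt(cm), "/")
  sv <- svd(S)
  pos <- which(sv$d > 1e-10)
  if (length(pos) == 0) stop("degenerate matrix: no positive inertia")
  d <- sv$d[pos]
  std <- sweep(sv$u[, pos, drop = FALSE], 1, sqrt(r), "/")
  scores <- sweep(std, 2, d, "*")
  cat_coord <- sweep(
    sweep(sv$v[, pos, drop = FALSE], 1, sqrt(cm), "/"), 2, d, "*")
  rownames(scores) <- rownames(std) <- rownames(v)
  rownames(cat_coord) <- colnames(Z)
  k <- min(n_axes, length(d))
  structure(list(eigenvalues = d^2,
                 scores = scores[, seq_len(k), drop = FALSE],
                 standard_scores = std,
                 all_scores = scores,
                 category_coords = cat_coord[, seq_len(k), drop = FALSE],
                 row_masses = r, n_axes = k,
                 var_of = ind$var_of, lev_of = ind$lev_of,
                 level_names = colnames(Z)),
            class = "MCAResult")
}

#' @export
print.MCAResult <- function(x, ...) {
  cat(sprintf("MCAResult: %d axes retained of %d; eigenvalues %s ...\n",
              x$n_axes, length(x$eigenvalues),
              paste(signif(head(x$eigenvalues, 3), 3), collapse = ", ")))
  invisible(x)
}

#' Multiple correspondence discriminant analysis
#'
#' Between-class analysis of the MCA subject scores: within the
#' \code{n_axes}-dimensional principal subspace (standard coordinates, in
#' which the total variance is isotropic), finds the orthogonal
#' directions that maximize the variance of the class centroids.  At most
#' \code{l - 1} discriminant directions exist for \code{l} classes.
#'
#' @param x a \code{CNVMatrix} or matrix over \{-1, 0, +1\}.
#' @param labels class label per subject (>= 2 classes, each with >= 2
#'   subjects).
#' @param n_axes dimension of the MCA subspace searched (default 2).
#' @return an object of class \code{MCDAResult}: \code{centroids}
#'   (classes x directions, the V_i(lambda)), \code{subject_scores},
#'   \code{directions}, \code{between_var}, the embedded \code{mca}.
#' @export
mcda <- function(x, labels, n_axes = 2) {
  v <- .cnv_values(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(v)) stop("one label per subject required")
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < 2)) stop("every class needs at least 2 subjects")
  m <- mca(x, n_axes = n_axes)
  K <- min(n_axes, ncol(m$standard_scores))
  X <- m$standard_scores[, seq_len(K), drop = FALSE]
  classes <- names(tab)
  cent <- t(matrix(vapply(classes, function(cl)
    colMeans(X[labels == cl, , drop = FALSE]), numeric(K)), nrow = K))
  rownames(cent) <- classes
  p <- as.numeric(tab[classes]) / length(labels)
  gm <- colSums(cent * p)
  centc <- sweep(cent, 2, gm)
  B <- crossprod(centc * sqrt(p))   # weighted between-class covariance
  eb <- eigen(B, symmetric = TRUE)
  nd <- min(length(classes) - 1, sum(eb$values > 1e-12))
  if (nd == 0) stop("classes are not separated in the retained subspace")
  dirs <- eb$vectors[, seq_len(nd), drop = FALSE]
  # deterministic sign: largest-|.| loading positive
  for (j in seq_len(nd)) {
    i <- which.max(abs(dirs[, j]))
    if (dirs[i, j] < 0) dirs[, j] <- -dirs[, j]
  }
  V <- centc %*% dirs
  rownames(V) <- classes
  colnames(V) <- paste0("D", seq_len(nd))
  subj <- sweep(X, 2, gm) %*% dirs
  structure(list(classes = classes, labels = labels,
                 centroids = V, directions = dirs,
                 subject_scores = subj,
                 between_var = eb$values[seq_len(nd)],
                 n_axes = K, mca = m),
            class = "MCDAResult")
}

#' @export
print.MCDAResult <- function(x, ...) {
  cat(sprintf("MCDAResult: %d classes, %d discriminant direction(s)\n",
              length(x$classes), ncol(x$centroids)))
  invisible(x)
}

#' Rank variables by correlation with the class directions
#'
#' For each variable level j (an indicator column, e.g. "blk12.-1") and
#' each discriminant direction lambda, the correlation between the class
#' centroid coordinates V_i(lambda) and the class-aggregated indicator
#' profile x_ij (proportion of class-i subjects carrying level j),
#'
#'   rho_j(lambda) = sum_i V_i (x_ij - xbar_j) /
#'                   sqrt(sum_i V_i^2 * sum_i (x_ij - xbar_j)^2),
#'
#' with xbar_j the unweighted mean over classes.  A variable's rank score
#' is its maximum |rho| across its levels and all directions; the level
#' attaining it (-1 loss, 0 no-change, +1 gain) is reported.
#'
#' @param fit an \code{MCDAResult}.
#' @param x the matrix it was computed on.
#' @return list with \code{levels} (per indicator level: rho per
#'   direction, max |rho|) and \code{variables} (per variable:
#'   \code{rank_score}, \code{best_level}), both data.frames sorted as in
#'   the input.
#' @export
rank_variables <- function(fit, x) {
  stopifnot(inherits(fit, "MCDAResult"))
  v <- .cnv_values(x)
  keep <- apply(v, 2, function(col) length(unique(col)) > 1)
  v <- v[, keep, drop = FALSE]
  ind <- .indicator(v)
  l <- length(fit$classes)
  agg <- t(vapply(fit$classes, function(cl)
    colMeans(ind$Z[fit$labels == cl, , drop = FALSE]),
    numeric(ncol(ind$Z))))
  V <- fit$centroids
  nd <- ncol(V)
  xc <- sweep(agg, 2, colMeans(agg))
  denom_x <- sqrt(colSums(xc^2))
  rho <- matrix(0, ncol(ind$Z), nd,
                dimnames = list(colnames(ind$Z), colnames(V)))
  for (lam in seq_len(nd)) {
    dv <- sqrt(sum(V[, lam]^2))
    num <- colSums(xc * V[, lam])
    ok <- denom_x > 0 & dv > 0
    rho[ok, lam] <- num[ok] / (denom_x[ok] * dv)
  }
  rho <- pmin(pmax(rho, -1), 1)
  levels_df <- data.frame(level = colnames(ind$Z),
                          variable = ind$var_names[ind$var_of],
                          cnv_level = ind$lev_of, rho,
                          max_abs_rho = apply(abs(rho), 1, max),
                          stringsAsFactors = FALSE, check.names = FALSE)
  vars <- lapply(split(levels_df, levels_df$variable), function(g) {
    i <- which.max(g$max_abs_rho)
    data.frame(variable = g$variable[1], rank_score = g$max_abs_rho[i],
               best_level = g$cnv_level[i], stringsAsFactors = FALSE)
  })
  variables_df <- do.call(rbind, vars)
  variables_df <- variables_df[match(unique(ind$var_names),
                                     variables_df$variable), ]
  rownames(variables_df) <- NULL
  list(levels = levels_df, variables = variables_df)
}

#' Permutation test for variable-class correlation
#'
#' Permutes the class labels, recomputes the MCDA and the per-variable
#' maximum |rho|, and reports p_j = (1 + #\{permuted >= observed\}) /
#' (n_perm + 1).  The matrix is fixed; only labels are permuted, so class
#' sizes are preserved.  Reproducible given \code{seed}.
#'
#' @param x a \code{CNVMatrix} or matrix.
#' @param labels class labels.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed (required).
#' @param n_axes MCA subspace dimension (default 2).
#' @return data.frame: variable, observed max |rho|, permutation p-value.
#' @export
permutation_test <- function(x, labels, n_perm = 999, seed, n_axes = 2) {
  if (missing(seed)) stop("seed is required for reproducibility")
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs_fit <- mcda(x, labels, n_axes = n_axes)
  obs <- rank_variables(obs_fit, x)$variables
  exceed <- integer(nrow(obs))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    score_b <- tryCatch({
      fit_b <- mcda(x, perm, n_axes = n_axes)
      rb <- rank_variables(fit_b, x)$variables
      rb$rank_score[match(obs$variable, rb$variable)]
    }, error = function(e) rep(0, nrow(obs)))
    exceed <- exceed + as.integer(score_b >= obs$rank_score)
  }
  data.frame(variable = obs$variable, rank_score = obs$rank_score,
             p_value = (1 + exceed) / (n_perm + 1),
             stringsAsFactors = FALSE)
}
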