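# Linear projections for class visualisation: PCA and locality preserving
# projections (LPP). Both return scores, loadings and (for PCA) explained
# variance ratios; component signs are fixed so the largest-magnitude
# loading of each component is positive, making score plots reproducible.

as_feature_matrix <- function(table) {
  if (inherits(table, "feature_table")) table$features else as.matrix(table)
}

fix_signs <- function(components) {
  for (j in seq_len(ncol(components))) {
    i <- which.max(abs(components[, j]))
    if (components[i, j] < 0) components[, j] <- -components[, j]
  }
  components
}

projection_result <- function(scores, components, method,
                              explained_variance_ratio = NULL,
                              lpp_params = NULL, center = NULL,
                              eigenvalues = NULL) {
  structure(
    list(scores = scores, components = components, method = method,
         explained_variance_ratio = explained_variance_ratio,
         lpp_params = lpp_params, center = center, eigenvalues = eigenvalues),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %s: %d samples -> %d components\n",
              toupper(x$method), nrow(x$scores), ncol(x$scores)))
  if (!is.null(x$explained_variance_ratio)) {
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Principal component analysis
#'
#' PCA of the centered feature matrix via singular value decomposition.
#' Scores are the centered data projected on the top-k right singular
#' vectors; explained variance ratios come from the squared singular
#' values.
#'
#' @param table a [feature_table()] or numeric matrix.
#' @param k number of components, `k <= min(n - 1, p)`.
#' @return A `projection_result` with `scores` (n x k), `components`
#'   (p x k, unit norm, sign-fixed) and `explained_variance_ratio` (length
#'   k; all ratios over the full decomposition sum to 1).
#' @export
pca_fit <- function(table, k = 2) {
  x <- as_feature_matrix(table)
  n <- nrow(x)
  p <- ncol(x)
  if (k < 1 || k > min(n - 1, p)) {
    stopf("k must be between 1 and min(n - 1, p) = %d", min(n - 1, p))
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- svd(xc)
  evr <- s$d^2 / sum(s$d^2)
  comps <- fix_signs(s$v[, seq_len(k), drop = FALSE])
  rownames(comps) <- colnames(x)
  scores <- xc %*% comps
  rownames(scores) <- rownames(x)
  colnames(scores) <- colnames(comps) <- paste0("comp", seq_len(k))
  projection_result(scores, comps, "pca",
                    explained_variance_ratio = evr[seq_len(k)],
                    center = mu)
}

# Symmetric k-NN adjacency: edge if either point lists the other among its
# k nearest neighbours.
knn_adjacency <- function(d2, k_neighbors) {
  n <- nrow(d2)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])
    ord <- ord[ord != i][seq_len(k_neighbors)]
    adj[i, ord] <- TRUE
  }
  adj | t(adj)
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  cur
}

#' Locality preserving projections
#'
#' Linear embedding that keeps neighbouring samples close: build a
#' symmetric k-nearest-neighbour graph on the centered data, weight edges
#' with a heat kernel `exp(-||xi - xj||^2 / t)` (or 1 in simple-minded
#' mode), form the graph Laplacian `L = D - W`, and solve the generalized
#' eigenproblem `X'LX a = lambda X'DX a`. The projection directions are the
#' eigenvectors of the k smallest eigenvalues. A PCA pre-projection onto
#' the numerical rank of the data is always applied, so rank-deficient
#' (e.g. highly collinear) tables are handled without a singular
#' constraint matrix.
#'
#' @param table a [feature_table()] or numeric matrix.
#' @param k number of embedding dimensions.
#' @param k_neighbors neighbourhood size of the graph (default 5).
#' @param weight_mode `"heat"` or `"simple"`.
#' @param t heat-kernel bandwidth; defaults to the mean squared pairwise
#'   distance.
#' @return A `projection_result` with `scores`, `components` (p x k,
#'   sign-fixed, normalized under the D-metric), `eigenvalues` (the k
#'   smallest generalized eigenvalues, all >= 0 up to round-off) and
#'   `lpp_params`.
#' @export
lpp_fit <- function(table, k = 2, k_neighbors = 5,
                    weight_mode = c("heat", "simple"), t = NULL) {
  weight_mode <- match.arg(weight_mode)
  x <- as_feature_matrix(table)
  n <- nrow(x)
  if (k_neighbors >= n) stopf("k_neighbors must be < number of samples")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)

  # PCA pre-projection to numerical rank
  s <- svd(xc)
  r <- sum(s$d > max(s$d) * 1e-8)
  r <- max(r, 1)
  p_pca <- s$v[, seq_len(r), drop = FALSE]
  z <- xc %*% p_pca
  if (k > min(r, n - 1)) stopf("k too large for the data rank (%d)", r)

  d2 <- as.matrix(stats::dist(z))^2
  adj <- knn_adjacency(d2, k_neighbors)
  if (graph_components(adj) > 1) {
    warning("k-NN graph is disconnected; proceeding per component",
            call. = FALSE)
  }
  if (is.null(t)) t <- mean(d2[upper.tri(d2)])
  w <- if (weight_mode == "heat") exp(-d2 / t) * adj else adj * 1
  dg <- rowSums(w)
  lap <- diag(dg) - w

  a_mat <- crossprod(z, lap %*% z)
  b_mat <- crossprod(z, dg * z)
  a_mat <- (a_mat + t(a_mat)) / 2
  b_mat <- (b_mat + t(b_mat)) / 2
  rch <- tryCatch(chol(b_mat), error = function(e) NULL)
  if (is.null(rch)) stopf("constraint matrix X'DX is singular")
  ri <- backsolve(rch, diag(r))
  cmat <- t(ri) %*% a_mat %*% ri
  eg <- eigen((cmat + t(cmat)) / 2, symmetric = TRUE)
  ord <- order(eg$values)          # ascending: smallest eigenvalues first
  sel <- ord[seq_len(k)]
  vals <- pmax(eg$values[sel], 0)
  vecs <- ri %*% eg$vectors[, sel, drop = FALSE]
  comps <- fix_signs(p_pca %*% vecs)
  rownames(comps) <- colnames(x)
  scores <- xc %*% comps
  rownames(scores) <- rownames(x)
  colnames(scores) <- colnames(comps) <- paste0("comp", seq_len(k))
  projection_result(scores, comps, "lpp",
                    lpp_params = list(k_neighbors = k_neighbors,
                                      weight_mode = weight_mode, t = t),
                    center = mu, eigenvalues = vals)
}

#' Project new data with a fitted projection
#'
#' @param result a `projection_result` from [pca_fit()] or [lpp_fit()].
#' @param table a [feature_table()] or matrix with the training columns.
#' @return Score matrix (n x k).
#' @export
project_scores <- function(result, table) {
  x <- as_feature_matrix(table)
  sweep(x, 2, result$center) %*% result$components
}
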