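#' Nonlinear dimension reduction of a network
#'
#' Runs one of the five decomposition engines used by coalescent embedding
#' and returns the retained per-node coordinates.
#'
#' Engines and retained dimensions (2D / 3D ambient space):
#'
#' * `"ISO"` — Isomap: the (squared) shortest-path kernel is double-centered
#'   in the classical-MDS sense, \eqn{B = -\tfrac12 J (D \circ D) J}, then
#'   decomposed by singular values; dimensions 1–2 / 1–3.
#' * `"ncISO"` — noncentered Isomap: SVD of the raw kernel; the first
#'   dimension points toward the manifold center and is discarded, keeping
#'   dimensions 2–3 / 2–4.
#' * `"LE"` — Laplacian eigenmaps: pre-weights are passed through the heat
#'   function \eqn{\tilde x = e^{-x^2/t}} with \eqn{t} the squared mean of
#'   all pre-weights, the generalized eigenproblem \eqn{Lv = \lambda Dv} is
#'   solved, and the eigenvectors of the 2nd–3rd / 2nd–4th smallest
#'   eigenvalues are kept (the first eigenvalue is 0 with a constant
#'   eigenvector and is dropped).
#' * `"MCE"` — minimum curvilinear embedding: centered MC-kernel, dimension
#'   1 only (2D pipelines only).
#' * `"ncMCE"` — noncentered MCE: SVD of the raw MC-kernel, dimension 2 only
#'   (2D pipelines only).
#'
#' SVD-based coordinates are scaled by the square root of the singular
#' values, eigenmap coordinates are the generalized eigenvectors. Each
#' retained axis is oriented so its largest-magnitude loading is positive,
#' fixing the decomposition sign ambiguity.
#'
#' @param x For `"ISO"`/`"ncISO"` a [shortest_path_kernel()] matrix, for
#'   `"MCE"`/`"ncMCE"` an [mc_kernel()] matrix, for `"LE"` a pre-weighted
#'   edge table.
#' @param reducer One of `"ISO"`, `"ncISO"`, `"LE"`, `"MCE"`, `"ncMCE"`
#'   (case-insensitive).
#' @param dims Ambient embedding dimension, 2 or 3. `"MCE"`/`"ncMCE"`
#'   support 2 only.
#' @return An `n x k` coordinate matrix (k = 1 for MCE/ncMCE, otherwise
#'   `dims`), with attribute `reducer`.
#' @export
reduce_embedding <- function(x, reducer = c("ISO", "ncISO", "LE", "MCE", "ncMCE"),
                             dims = 2) {
  reducer <- match.arg(toupper(reducer[1]), c("ISO", "NCISO", "LE", "MCE", "NCMCE"))
  reducer <- c(ISO = "ISO", NCISO = "ncISO", LE = "LE",
               MCE = "MCE", NCMCE = "ncMCE")[[reducer]]
  if (!dims %in% c(2, 3)) abort("`dims` must be 2 or 3.")
  if (dims == 3 && reducer %in% c("MCE", "ncMCE")) {
    abort("MCE/ncMCE retain a single dimension and support 2D embedding only.")
  }
  Y <- switch(reducer,
    ISO = svd_coords(center_kernel(as_kernel(x)), keep = seq_len(dims)),
    ncISO = svd_coords(as_kernel(x), keep = 1 + seq_len(dims)),
    MCE = svd_coords(center_kernel(as_kernel(x)), keep = 1),
    ncMCE = svd_coords(as_kernel(x), keep = 2),
    LE = laplacian_eigenmaps(x, keep = 1 + seq_len(dims)))
  structure(orient_axes(Y), reducer = reducer)
}

as_kernel <- function(x) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    abort("Expected a square distance-kernel matrix; see shortest_path_kernel().")
  }
  if (any(!is.finite(x))) abort("Kernel has non-finite entries (disconnected input?).")
  x
}

# Classical-MDS double centering of the squared distance kernel.
center_kernel <- function(D) {
  n <- nrow(D)
  D2 <- D * D
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * (J %*% D2 %*% J)
}

svd_coords <- function(K, keep) {
  s <- svd(K, nu = max(keep), nv = 0)
  s$u[, keep, drop = FALSE] %*% diag(sqrt(s$d[keep]), nrow = length(keep))
}

# Generalized eigenproblem L v = lambda D v on the heat-transformed weights,
# solved through the symmetric normalization D^{-1/2} W D^{-1/2}.
laplacian_eigenmaps <- function(edges, keep) {
  edges <- as_edge_tbl(edges, require_weight = TRUE)
  g <- edges_to_igraph(edges, weighted = TRUE)
  check_simple_connected(g)
  n <- igraph::vcount(g)
  t_scale <- mean(edges$weight)^2
  hw <- exp(-edges$weight^2 / t_scale)
  W <- matrix(0, n, n)
  idx <- cbind(edges$from, edges$to)
  W[idx] <- hw
  W[idx[, 2:1, drop = FALSE]] <- hw
  dstr <- rowSums(W)
  if (any(dstr <= 0)) abort("Heat-transformed weights vanished on some node.")
  isq <- 1 / sqrt(dstr)
  M <- W * (isq %o% isq)
  e <- eigen(M, symmetric = TRUE)
  # largest eigenvalues of M <-> smallest generalized Laplacian eigenvalues
  U <- e$vectors[, keep + 0, drop = FALSE]
  # note: column 1 of e$vectors is the discarded constant null-space vector
  V <- U * isq
  V[, seq_along(keep), drop = FALSE]
}

orient_axes <- function(Y) {
  for (k in seq_len(ncol(Y))) {
    j <- which.max(abs(Y[, k]))
    if (Y[j, k] < 0) Y[, k] <- -Y[, k]
  }
  Y
}
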