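#' Hyperbolic-distance correlation of two embeddings
#'
#' Pearson correlation between the upper triangles of the two all-pairs
#' hyperbolic distance matrices — the standard accuracy measure of a
#' hyperbolic embedding against ground truth. Invariant under global
#' rotation and reflection of either coordinate set.
#'
#' @param coords_true,coords_inferred Coordinate tables (`node`, `r`,
#'   `theta`, optional `phi`) over the same node set.
#' @param zeta Curvature parameter.
#' @return Correlation in `[-1, 1]`.
#' @export
hd_correlation <- function(coords_true, coords_inferred, zeta = 1) {
  coords_true <- align_coord_tables(coords_true, coords_inferred)
  if (nrow(coords_true) < 3) abort("Need at least 3 nodes.")
  ut <- upper.tri(diag(nrow(coords_true)))
  a <- pairwise_hyperbolic_distances(coords_true, zeta)[ut]
  b <- pairwise_hyperbolic_distances(coords_inferred, zeta)[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("Distance vector has zero variance; correlation undefined.")
  }
  cor(a, b)
}

align_coord_tables <- function(a, b) {
  if (nrow(a) != nrow(b)) abort("Coordinate tables must cover the same nodes.")
  if ("node" %in% names(a) && "node" %in% names(b)) {
    if (!setequal(a$node, b$node)) {
      abort("Coordinate tables must cover the same nodes.")
    }
    a <- a[match(b$node, a$node), ]
  }
  a
}

#' Concordance score (C-score) of inferred angular coordinates
#'
#' The proportion of node pairs whose shortest angular direction (clockwise
#' vs counter-clockwise) from one node to the other agrees between the true
#' and inferred angles. Because the inferred circle may run in the opposite
#' clock direction, the score is also computed with the inferred angles
#' reversed and the maximum of the two values is returned. Invariant under
#' global rotation of either set; 1 means perfect circular ordering.
#'
#' A pair at angular separation exactly `pi` has no shorter direction; it is
#' counted as agreeing when both representations sit at exactly `pi`, and
#' otherwise its direction is taken as counter-clockwise.
#'
#' @param theta_true,theta_inferred Angles in `[0, 2*pi)`, same node order.
#' @return Score in `(0, 1]`.
#' @export
#' @examples
#' c_score(c(0, 1, 2, 4.5), c(0, 2, 1, 4.5))  # 0.5
c_score <- function(theta_true, theta_inferred) {
  n <- length(theta_true)
  if (n < 2 || length(theta_inferred) != n) {
    abort("Need two angle vectors of equal length >= 2.")
  }
  ut <- upper.tri(diag(n))
  ccw <- function(theta) {
    d <- (outer(theta, theta, "-") %% (2 * pi))[ut]  # direction i -> j, j > i
    d <= pi                                          # ties at pi count as ccw
  }
  ref <- ccw(theta_true)
  s1 <- mean(ref == ccw(theta_inferred))
  s2 <- mean(ref == ccw((2 * pi - theta_inferred) %% (2 * pi)))
  max(s1, s2)
}

#' Align inferred angles to the truth for visualization
#'
#' Tries the 360 one-degree rotations of the inferred angles and of their
#' reflection (the opposite clock direction) and returns the candidate whose
#' plain linear correlation with the true angles is largest. Alignment is a
#' rigid motion of the circle, so the C-score is unchanged.
#'
#' @param theta_true,theta_inferred Angles in `[0, 2*pi)`, same node order.
#' @return The aligned angle vector, with attributes `rotation_deg`,
#'   `reflected` and `correlation`.
#' @export
align_angles <- function(theta_true, theta_inferred) {
  best <- NULL
  for (reflected in c(FALSE, TRUE)) {
    base <- if (reflected) (2 * pi - theta_inferred) %% (2 * pi) else theta_inferred
    for (k in 0:359) {
      cand <- (base + k * pi / 180) %% (2 * pi)
      cc <- suppressWarnings(cor(theta_true, cand))
      if (is.na(cc)) cc <- -Inf
      if (is.null(best) || cc > best$cc) {
        best <- list(cc = cc, cand = cand, k = k, reflected = reflected)
      }
    }
  }
  structure(best$cand, rotation_deg = best$k, reflected = best$reflected,
            correlation = best$cc)
}

#' Normalized mutual information between two node partitions
#'
#' \eqn{NMI = I(C_D, C_T)/\sqrt{H(C_D) H(C_T)}} with natural-log entropies
#' computed from the community-size contingency table. In adjusted mode the
#' expected mutual information under the permutation (hypergeometric) model
#' is subtracted from both numerator and denominator, correcting for chance
#' agreement — appropriate when communities are few relative to the node
#' count, and auto-selected when `N / n_T <= 100` (with `n_T` the number of
#' ground-truth communities).
#'
#' @param detected,truth Community label vectors over the same nodes (any
#'   atomic type; labels are compared within each vector only).
#' @param adjusted `"auto"` (default, see above), `"never"` or `"always"`.
#' @return Score in `[0, 1]` (adjusted values can be slightly negative by
#'   chance).
#' @export
#' @examples
#' nmi(c(1, 1, 2, 2), c(1, 1, 1, 2), adjusted = "never")
nmi <- function(detected, truth, adjusted = c("auto", "never", "always")) {
  adjusted <- match.arg(adjusted)
  if (length(detected) != length(truth)) {
    abort("Partitions must label the same nodes.")
  }
  N <- length(detected)
  tab <- table(detected, truth)
  a <- rowSums(tab)
  b <- colSums(tab)
  use_adjusted <- switch(adjusted,
    always = TRUE, never = FALSE,
    auto = N / length(b) <= 100)

  H <- function(sizes) {
    p <- sizes[sizes > 0] / N
    -sum(p * log(p))
  }
  Hd <- H(a); Ht <- H(b)
  nz <- tab > 0
  pij <- tab[nz] / N
  I <- sum(pij * log(pij / ((a[row(tab)][nz] / N) * (b[col(tab)][nz] / N))))

  if (!use_adjusted) {
    if (Hd == 0 || Ht == 0) {
      abort("A partition with a single community has zero entropy; use adjusted mode.")
    }
    return(I / sqrt(Hd * Ht))
  }
  emi <- expected_mi(a, b, N)
  denom <- sqrt(Hd * Ht) - emi
  if (denom == 0) return(0)
  (I - emi) / denom
}

# Expected mutual information under the permutation model (hypergeometric
# cell counts), accumulated in log space.
expected_mi <- function(a, b, N) {
  total <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - N)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lchoose(bj, nij) + lchoose(N - bj, ai - nij) - lchoose(N, ai)
        total <- total + (nij / N) * log((N * nij) / (ai * bj)) * exp(lp)
      }
    }
  }
  total
}
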