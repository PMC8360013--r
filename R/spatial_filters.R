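## Spatial eigenvector covariates: principal-coordinate (double-centered
## squared-distance) eigenvectors over reach coordinates, exactly for
## moderate n and via a Nystrom-style anchor approximation for large n.

dbl_center <- function(M) {
  rm <- rowMeans(M); cm <- colMeans(M); gm <- mean(M)
  M - outer(rm, rep(1, ncol(M))) - outer(rep(1, nrow(M)), cm) + gm
}

fix_signs <- function(V, tol = 1e-8) {
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > tol)
    if (length(nz) && V[nz[1], j] < 0) V[, j] <- -V[, j]
  }
  V
}

new_eigenvector_set <- function(ids, vectors, values) {
  colnames(vectors) <- paste0("ev", seq_len(ncol(vectors)))
  rownames(vectors) <- ids
  structure(list(ids = ids, vectors = vectors, values = values),
            class = "eigenvector_set")
}

#' @export
print.eigenvector_set <- function(x, ...) {
  cat("Spatial eigenvector set:", ncol(x$vectors), "vectors over",
      nrow(x$vectors), "units\n")
  cat("  eigenvalues:", paste(signif(x$values, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Spatial eigenvectors of a doubly centered distance matrix
#'
#' Extracts the leading eigenvectors (large-scale geographic patterns) of
#' \code{C = -1/2 H D^2 H} where \code{D} is the Euclidean inter-point
#' distance matrix and \code{H} the centering operator — the
#' principal-coordinate convention. \code{method = "approx"} uses a
#' Nystrom-style approximation anchored on k-means cluster centres of the
#' coordinates, suitable for thousands of reaches; its columns are centered
#' and orthonormalized, and at \code{n_anchors >= n} it coincides with the
#' exact decomposition up to sign.
#'
#' Columns are unit-norm, mutually orthogonal, sum to ~0, and carry a fixed
#' sign convention (first non-negligible loading positive). Only
#' positive-eigenvalue vectors are returned; fewer than \code{k} positive
#' eigenvalues is an error.
#'
#' @param coords n x 2 matrix of projected coordinates.
#' @param k number of eigenvectors (default 5).
#' @param method "exact" or "approx".
#' @param n_anchors number of anchor points for the approximation
#'   (>= k + 1).
#' @param seed seed for the k-means anchor selection.
#' @param centering "pcoa" (squared distances; default) or "raw"
#'   (distances themselves) — sensitivity flag.
#' @return object of class \code{eigenvector_set} with \code{ids},
#'   \code{vectors} (n x k, unit columns) and \code{values}
#'   (non-increasing eigenvalues).
#' @export
spatial_eigenvectors <- function(coords, k = 5,
                                 method = c("exact", "approx"),
                                 n_anchors = 100, seed = 1,
                                 centering = c("pcoa", "raw")) {
  method <- match.arg(method)
  centering <- match.arg(centering)
  coords <- as.matrix(coords)
  stop_if_not_finite(coords, "coordinates")
  n <- nrow(coords)
  if (n < k + 1) stop("need at least k + 1 points")
  ids <- rownames(coords) %||% as.character(seq_len(n))
  pow <- if (centering == "pcoa") 2 else 1

  if (method == "exact" || n_anchors >= n) {
    D <- as.matrix(stats::dist(coords))^pow
    C <- -0.5 * dbl_center(D)
    e <- eigen(C, symmetric = TRUE)
    pos <- which(e$values > max(e$values) * 1e-9 & e$values > 0)
    if (length(pos) < k)
      stop("fewer than k positive eigenvalues (degenerate coordinates)")
    V <- fix_signs(e$vectors[, pos[seq_len(k)], drop = FALSE])
    return(new_eigenvector_set(ids, V, e$values[pos[seq_len(k)]]))
  }

  if (n_anchors < k + 1) stop("n_anchors must be >= k + 1")
  anchors <- with_seed(seed, {
    stats::kmeans(coords, centers = n_anchors, iter.max = 100,
                  nstart = 1)$centers
  })
  m <- nrow(anchors)
  Da <- as.matrix(stats::dist(anchors))^pow
  Ca <- -0.5 * dbl_center(Da)
  ea <- eigen(Ca, symmetric = TRUE)
  pos <- which(ea$values > max(ea$values) * 1e-9 & ea$values > 0)
  if (length(pos) < k)
    stop("fewer than k positive anchor eigenvalues; increase n_anchors")
  ## oversample anchor components: projecting through extra eigenpairs and
  ## truncating after the SVD sharpens the leading subspace considerably
  l <- min(length(pos), k + 15L)
  Va <- ea$vectors[, pos[seq_len(l)], drop = FALSE]
  la <- ea$values[pos[seq_len(l)]]
  ## Gower cross-centering of point-to-anchor distances w.r.t. the anchors
  D_na <- outer(rowSums(coords^2), rep(1, m)) +
    outer(rep(1, n), rowSums(anchors^2)) -
    2 * coords %*% t(anchors)
  D_na[D_na < 0] <- 0
  if (pow == 1) D_na <- sqrt(D_na)
  C_na <- -0.5 * (D_na - outer(rowMeans(D_na), rep(1, m)) -
                    outer(rep(1, n), colMeans(Da)) + mean(Da))
  B <- C_na %*% Va %*% diag(1 / sqrt(la), l)
  B <- sweep(B, 2, colMeans(B))   # enforce exact centering
  sv <- svd(B)
  V <- fix_signs(sv$u[, seq_len(k), drop = FALSE])
  new_eigenvector_set(ids, V, sv$d[seq_len(k)]^2)
}

#' Attach reach-level eigenvectors to survey sites
#'
#' @param evs an \code{eigenvector_set} keyed by reach id.
#' @param mapping data frame with \code{site_id}, \code{reach_id} (e.g.
#'   from \code{\link{snap_sites_to_reaches}}).
#' @return data frame of eigenvector columns, one row per site.
#' @export
assign_eigenvectors <- function(evs, mapping) {
  idx <- match(mapping$reach_id, evs$ids)
  if (anyNA(idx))
    stop("unmapped site(s): ",
         paste(utils::head(mapping$site_id[is.na(idx)], 5), collapse = ", "))
  out <- as.data.frame(evs$vectors[idx, , drop = FALSE])
  rownames(out) <- mapping$site_id
  out
}
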