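#' Kabsch least-squares superposition
#'
#' Optimal rigid-body superposition of the selected C-alpha atoms of `mobile`
#' onto `reference` (SVD solution with reflection correction, so the returned
#' rotation is always proper).
#'
#' @param mobile,reference [conformation()] objects sharing a sequence.
#' @param residues 1-based residue selection (default: all).
#' @return List with `rotation` (3x3), `translation` (length 3; the
#'   superposed mobile coordinates are `x %*% t(rotation) + translation`)
#'   and `rmsd` (Angstrom, after superposition).
#' @export
kabsch_superpose <- function(mobile, reference, residues = NULL) {
  stopifnot(inherits(mobile, "Conformation"),
            inherits(reference, "Conformation"))
  if (!identical(mobile$sequence$residues, reference$sequence$residues))
    stop("conformations must share one sequence")
  if (is.null(residues)) residues <- seq_along(mobile$sequence$residues)
  X <- mobile$coords[residues, "CA", , drop = TRUE]
  Y <- reference$coords[residues, "CA", , drop = TRUE]
  kabsch_fit(X, Y)
}

# Core Kabsch fit of point set X (k x 3) onto Y (k x 3).
kabsch_fit <- function(X, Y) {
  if (!is.matrix(X)) X <- rbind(X)
  if (!is.matrix(Y)) Y <- rbind(Y)
  k <- nrow(X)
  if (k < 3) stop("at least 3 atoms are required for superposition")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  if (qr(Xc)$rank < 2 || qr(Yc)$rank < 2)
    stop("degenerate (collinear) atom selection")
  S <- svd(crossprod(Xc, Yc))
  d <- sign(det(S$u %*% t(S$v)))
  D <- diag(c(1, 1, d))
  R <- S$v %*% D %*% t(S$u)            # maps centered X onto centered Y
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(sum((fitted - Yc)^2) / k)
  list(rotation = R, translation = as.numeric(my - R %*% mx), rmsd = rmsd)
}

#' Pairwise C-alpha RMSD matrix of an ensemble
#'
#' Entry (i, j) is the Kabsch RMSD over the selected C-alpha atoms after
#' optimal superposition of each pair (not on a pre-aligned frame).
#'
#' @param e An [ensemble()].
#' @param residues Residue selection (default: all).
#' @return An `RMSDMatrix`: symmetric numeric matrix (Angstrom) with a
#'   `selection` attribute.
#' @export
rmsd_matrix <- function(e, residues = NULL) {
  stopifnot(inherits(e, "Ensemble"))
  if (is.null(residues)) residues <- seq_along(e$sequence$residues)
  if (length(residues) < 3) stop("at least 3 residues are required")
  arr <- ca_array(e, residues)
  m <- .rmsd_matrix_cpp(arr)
  structure(m, selection = residues, class = c("RMSDMatrix", class(m)))
}

#' Greedy neighbor-count (Daura-style) clustering into structural families
#'
#' Iteratively, among the not-yet-assigned structures, neighbors within
#' `cutoff` are counted for every structure; the structure with the most
#' neighbors becomes a family centroid and is removed together with its
#' neighbors, until every structure is assigned. Neighbor counts are
#' recomputed after each removal. Ties on neighbor count are broken by the
#' lowest structure index, making the partition deterministic.
#'
#' @param m An [rmsd_matrix()] (any symmetric distance matrix works).
#' @param cutoff Neighbor cutoff in Angstrom (default 3.0).
#' @return A `ClusterResult`: list with `families` (each a list with
#'   `members`, `centroid`, `size`), `cutoff`, `n`. Families are in
#'   formation order, which has non-increasing sizes.
#' @export
daura_cluster <- function(m, cutoff = 3.0) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), cutoff > 0)
  n <- nrow(m)
  adj <- (m <= cutoff)
  diag(adj) <- FALSE
  alive <- rep(TRUE, n)
  families <- list()
  while (any(alive)) {
    idx <- which(alive)
    counts <- rowSums(adj[idx, idx, drop = FALSE])
    centroid <- idx[which.max(counts)]  # which.max takes the lowest index
    members <- sort(c(centroid, idx[adj[centroid, idx]]))
    alive[members] <- FALSE
    families[[length(families) + 1]] <-
      list(members = members, centroid = centroid, size = length(members))
  }
  structure(list(families = families, cutoff = cutoff, n = n),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult:", length(x$families), "families over", x$n,
      "structures (cutoff", x$cutoff, "A)\n")
  sizes <- vapply(x$families, `[[`, 0L, "size")
  cat("  sizes:", paste(utils::head(sizes, 15), collapse = ", "),
      if (length(sizes) > 15) "..." else "", "\n")
  invisible(x)
}

#' Family membership as a per-structure vector
#'
#' @param r A [daura_cluster()] result.
#' @return Integer vector: family id (formation order) of each structure.
#' @export
family_assignment <- function(r) {
  stopifnot(inherits(r, "ClusterResult"))
  out <- integer(r$n)
  for (f in seq_along(r$families)) out[r$families[[f]]$members] <- f
  out
}

#' Most populated structural families
#'
#' Families holding at least `min_fraction` of all structures, capped at
#' `max_k`, in decreasing size order (mirrors reporting of the top 15
#' families with >= 1 percent of the population).
#'
#' @param r A [daura_cluster()] result.
#' @param min_fraction Minimum family population fraction (default 0.01).
#' @param max_k Maximum number of families returned (default 15).
#' @return A `ClusterResult` containing only the retained families.
#' @export
top_families <- function(r, min_fraction = 0.01, max_k = 15) {
  stopifnot(inherits(r, "ClusterResult"))
  sizes <- vapply(r$families, `[[`, 0L, "size")
  keep <- which(sizes / r$n >= min_fraction)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  keep <- utils::head(keep, max_k)
  structure(list(families = r$families[keep], cutoff = r$cutoff, n = r$n),
            class = "ClusterResult")
}
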