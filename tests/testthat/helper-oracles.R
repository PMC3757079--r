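# Independent oracles and shared fixtures for the test suite.

# Naive re-implementation of greedy neighbor-count clustering, written
# independently of the package version (different data flow and indexing).
naive_daura <- function(m, cutoff = 3.0) {
  remaining <- seq_len(nrow(m))
  assignment <- rep(NA_integer_, nrow(m))
  fam <- 0L
  while (length(remaining) > 0) {
    neigh <- lapply(remaining, function(i)
      remaining[m[i, remaining] <= cutoff & remaining != i])
    sizes <- vapply(neigh, length, 0L)
    pick <- which(sizes == max(sizes))[1]
    fam <- fam + 1L
    group <- c(remaining[pick], neigh[[pick]])
    assignment[group] <- fam
    remaining <- setdiff(remaining, group)
  }
  assignment
}

# Brute-force best-fit RMSD via nested Euler-angle grid refinement over
# proper rotations (translation handled exactly by centroid matching).
grid_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  eval_r <- function(a, b, c) {
    R <- rot(a, b, c)
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  best <- c(0, 0, 0)
  best_r <- eval_r(0, 0, 0)
  span <- pi
  grid_n <- 13
  for (level in 1:6) {
    as <- best[1] + seq(-span, span, length.out = grid_n)
    bs <- best[2] + seq(-span, span, length.out = grid_n)
    cs <- best[3] + seq(-span, span, length.out = grid_n)
    for (a in as) for (b in bs) for (c in cs) {
      r <- eval_r(a, b, c)
      if (r < best_r) {
        best_r <- r
        best <- c(a, b, c)
      }
    }
    span <- span / 5
  }
  best_r
}

kabsch_fit_rmsd <- function(X, Y) idpens:::kabsch_fit(X, Y)$rmsd

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, byrow = TRUE)
}

poly_ala <- function(L = 37) peptide_sequence(strrep("A", L), name = "polyA")

ideal_helix_conf <- function(seq = poly_ala()) {
  L <- length(seq$residues)
  build_chain(seq, rep(-57, L), rep(-47, L))
}

refined_motif_conf <- function(label, seq = iapp_sequence("human")) {
  m <- make_motif(label)
  refine_closure(build_chain(seq, m$phi, m$psi), m, max_iter = 2000)
}

# Small deterministic ensembles reused across test files (cached per run).
cached_ensemble <- local({
  cache <- list()
  function(variant, n, sigma, seed) {
    key <- paste(variant, n, sigma, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- sample_ensemble(
        variant_preset(variant, n = n, sigma = sigma, seed = seed),
        iapp_sequence(variant))
    cache[[key]]
  }
})
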