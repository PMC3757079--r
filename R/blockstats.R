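#' Partition frames into equal consecutive blocks
#'
#' Divides `1..n_frames` into `n_blocks` consecutive index ranges whose sizes
#' differ by at most one; earlier blocks take the remainder. Six blocks over
#' a trajectory is the convention used for block-convergence analysis.
#'
#' @param n_frames Number of frames (must be at least `n_blocks`).
#' @param n_blocks Number of blocks (default 6).
#' @return A `BlockPartition`: list with `blocks` (list of index vectors),
#'   `n_frames`, `sizes`.
#' @export
make_blocks <- function(n_frames, n_blocks = 6) {
  n_frames <- as.integer(n_frames); n_blocks <- as.integer(n_blocks)
  if (n_frames < n_blocks)
    stop("need at least as many frames (", n_frames, ") as blocks (",
         n_blocks, ")")
  base <- n_frames %/% n_blocks
  rem <- n_frames %% n_blocks
  sizes <- rep(base, n_blocks) + c(rep(1L, rem), rep(0L, n_blocks - rem))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  blocks <- Map(seq, starts, ends)
  structure(list(blocks = blocks, n_frames = n_frames, sizes = sizes),
            class = "BlockPartition")
}

#' @export
print.BlockPartition <- function(x, ...) {
  cat("BlockPartition:", length(x$blocks), "blocks over", x$n_frames,
      "frames; sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Block mean and standard deviation of a per-frame series
#'
#' Computes per-block means and reports the mean and sample standard
#' deviation (divisor `last_k - 1`) over the final `last_k` block means —
#' the convention for quoting converged trajectory statistics.
#'
#' @param values One value per frame.
#' @param blocks A [make_blocks()] partition.
#' @param last_k Number of final blocks used (default 3; must be >= 2).
#' @return List with `mean`, `std`, `block_means`.
#' @export
block_mean_std <- function(values, blocks, last_k = 3) {
  stopifnot(inherits(blocks, "BlockPartition"))
  if (length(values) != blocks$n_frames)
    stop("expected one value per frame (", blocks$n_frames, ")")
  if (last_k > length(blocks$blocks))
    stop("last_k exceeds the number of blocks")
  if (last_k < 2)
    stop("last_k must be at least 2 for a standard deviation")
  bm <- vapply(blocks$blocks, function(idx) mean(values[idx]), 0)
  use <- utils::tail(bm, last_k)
  list(mean = mean(use), std = stats::sd(use), block_means = bm)
}

#' Geometric replica-exchange temperature ladder
#'
#' Temperatures exponentially spaced between the endpoints:
#' `T_i = t_min * (t_max / t_min)^(i / (n - 1))`, i = 0..n-1, so the ratio
#' of consecutive temperatures is constant and the endpoints are exact.
#'
#' @param t_min,t_max Endpoint temperatures in Kelvin (defaults 270 and 465).
#' @param n Number of replicas (default 16).
#' @return Numeric vector of length `n`.
#' @examples
#' temperature_ladder()          # 270 ... 465 K over 16 replicas
#' @export
temperature_ladder <- function(t_min = 270, t_max = 465, n = 16) {
  if (!(t_max > t_min && t_min > 0)) stop("require t_max > t_min > 0")
  if (n < 2) stop("need at least 2 replicas")
  tl <- t_min * (t_max / t_min)^((seq_len(n) - 1) / (n - 1))
  tl[1] <- t_min                  # endpoints exact in floating point
  tl[n] <- t_max
  tl
}
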