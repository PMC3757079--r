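SUPERFAMILY_LABELS <- c("helix-coil", "helix-hairpin", "beta-hairpin")

#' Rule-based super-family classification of a secondary-structure string
#'
#' Merge rule over the N-terminal part (residues 1-17) and the C-terminal
#' part (residues 18-37) of a 37-residue assignment: a conformer is
#' helix-rich if its N-part contains more helix ({H, G}) than sheet ({E, B})
#' residues, otherwise it is a beta-hairpin. A helix-rich conformer is a
#' helix-hairpin if its C-part contains more than four sheet residues (a
#' minimal 2:2 beta-hairpin has exactly four, so strictly more is required;
#' exactly four maps to helix-coil), otherwise helix-coil. Ties on the N-part
#' count (helix equal to sheet) fail the "more helix" test and classify as
#' beta-hairpin.
#'
#' @param ss An `SSString` (character vector of codes, length 37).
#' @param n_part,c_part Residue ranges of the two parts.
#' @return One of `"helix-coil"`, `"helix-hairpin"`, `"beta-hairpin"`.
#' @export
classify_superfamily <- function(ss, n_part = 1:17, c_part = 18:37) {
  ss <- unclass(ss)
  if (length(ss) != max(c_part))
    stop("expected a secondary-structure string of length ", max(c_part))
  cls <- ss_classes(ss)
  helix_n <- sum(cls[n_part] == "helix")
  sheet_n <- sum(cls[n_part] == "sheet")
  if (helix_n <= sheet_n) return("beta-hairpin")
  sheet_c <- sum(cls[c_part] == "sheet")
  if (sheet_c > 4) "helix-hairpin" else "helix-coil"
}

#' Per-conformer super-family labels from a clustering
#'
#' With `granularity = "centroid"` (the default, matching the reading that
#' whole structural families are merged), every member of a family inherits
#' the label of the family centroid's secondary structure; with
#' `granularity = "frame"` each conformer is classified from its own string.
#'
#' @param r A [daura_cluster()] result.
#' @param ss_per_conformer Conformers x residues character matrix of codes
#'   (e.g. the `$ss` element of [ss_profile()]).
#' @param granularity `"centroid"` or `"frame"`.
#' @return Character vector of per-conformer labels.
#' @export
classify_families <- function(r, ss_per_conformer,
                              granularity = c("centroid", "frame")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(r, "ClusterResult"))
  if (nrow(ss_per_conformer) != r$n)
    stop("clustering covers ", r$n, " conformers but ",
         nrow(ss_per_conformer), " secondary-structure strings were given")
  labels <- character(r$n)
  if (granularity == "frame") {
    for (i in seq_len(r$n))
      labels[i] <- classify_superfamily(ss_per_conformer[i, ])
  } else {
    for (f in r$families) {
      lab <- classify_superfamily(ss_per_conformer[f$centroid, ])
      labels[f$members] <- lab
    }
  }
  labels
}

#' Super-family abundances with block standard deviations
#'
#' Abundance of each label is computed within each of the `last_k` final
#' blocks of the partition; the reported value is the mean over those blocks
#' and the uncertainty is the sample standard deviation over them (the
#' trajectory-block convention used for convergence reporting).
#'
#' @param labels Per-conformer super-family labels.
#' @param blocks A [make_blocks()] partition covering the conformers.
#' @param last_k Number of final blocks used (default 3).
#' @return A `SuperFamilyReport` data frame: `label`, `abundance`, `std`,
#'   `count` (members over the whole ensemble), with attribute `regions`
#'   recording the N-part/C-part convention.
#' @export
superfamily_abundance <- function(labels, blocks, last_k = 3) {
  stopifnot(inherits(blocks, "BlockPartition"))
  if (blocks$n_frames != length(labels))
    stop("block partition covers ", blocks$n_frames, " frames, not ",
         length(labels))
  if (last_k > length(blocks$blocks))
    stop("last_k exceeds the number of blocks")
  present <- intersect(SUPERFAMILY_LABELS, unique(labels))
  use <- utils::tail(blocks$blocks, last_k)
  frac <- sapply(present, function(lab)
    vapply(use, function(idx) mean(labels[idx] == lab), 0))
  frac <- matrix(frac, nrow = length(use),
                 dimnames = list(NULL, present))
  out <- data.frame(
    label = present,
    abundance = colMeans(frac),
    std = apply(frac, 2, stats::sd),
    count = vapply(present, function(lab) sum(labels == lab), 0L),
    row.names = NULL)
  attr(out, "regions") <- list(n_part = 1:17, c_part = 18:37)
  class(out) <- c("SuperFamilyReport", class(out))
  out
}
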