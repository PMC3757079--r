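#' Per-residue C-alpha RMSF after partial alignment
#'
#' Each conformer is superposed onto the first conformer of the (subset)
#' ensemble over the C-alpha atoms of `align_range` (default residues 1-17,
#' the rigid N-terminal part), the mean C-alpha position of every residue is
#' computed, and `RMSF_i = sqrt(mean_m |r_i(m) - mean_i|^2)`.
#'
#' @param e An [ensemble()] with at least 2 conformers.
#' @param align_range Residues used for superposition (default 1:17).
#' @param label Optional super-family label recorded in the output.
#' @return An `RMSFProfile` data frame: `residue`, `rmsf` (Angstrom),
#'   `label`, `n`, with attribute `align_range`.
#' @export
rmsf <- function(e, align_range = 1:17, label = NA_character_) {
  stopifnot(inherits(e, "Ensemble"))
  n <- length(e)
  if (n < 2) stop("RMSF requires at least 2 conformers")
  L <- length(e$sequence$residues)
  if (any(align_range < 1) || any(align_range > L))
    stop("alignment range outside 1..", L)
  ref <- atom_coords(e$conformations[[1]], "CA")
  ca <- array(NA_real_, dim = c(L, 3, n))
  for (m in seq_len(n)) {
    X <- atom_coords(e$conformations[[m]], "CA")
    fit <- kabsch_fit(X[align_range, , drop = FALSE],
                      ref[align_range, , drop = FALSE])
    ca[, , m] <- sweep(X %*% t(fit$rotation), 2, -fit$translation)
  }
  mean_pos <- apply(ca, c(1, 2), mean)
  dev2 <- sweep(ca, c(1, 2), mean_pos)^2
  out <- data.frame(residue = seq_len(L),
                    rmsf = sqrt(apply(dev2, 1, sum) / n),
                    label = label, n = n)
  attr(out, "align_range") <- align_range
  class(out) <- c("RMSFProfile", class(out))
  out
}

#' RMSF computed separately per super-family
#'
#' Splits the ensemble by per-conformer label and computes one [rmsf()]
#' profile per label present. Labels with fewer than 2 conformers are
#' omitted with a warning.
#'
#' @param e An [ensemble()].
#' @param labels Per-conformer super-family labels.
#' @param align_range Residues used for superposition (default 1:17).
#' @return Named list of `RMSFProfile` data frames.
#' @export
rmsf_by_superfamily <- function(e, labels, align_range = 1:17) {
  stopifnot(inherits(e, "Ensemble"), length(labels) == length(e))
  out <- list()
  for (lab in intersect(SUPERFAMILY_LABELS, unique(labels))) {
    idx <- which(labels == lab)
    if (length(idx) < 2) {
      warning("label '", lab, "' has fewer than 2 conformers; omitted")
      next
    }
    out[[lab]] <- rmsf(e[idx], align_range = align_range, label = lab)
  }
  out
}
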