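#' Single-conformer backbone coordinates
#'
#' A `Conformation` stores per-residue backbone coordinates (Angstrom) for
#' atoms N, H, CA, C, O (H is absent for residue 1 and for prolines) plus an
#' optional C-beta position, with 1-based residue indexing.
#'
#' @param coords Numeric array `L x 5 x 3` with atom dimnames
#'   `c("N","H","CA","C","O")`, or an `L x 18` matrix as returned by the
#'   backbone builder (columns `N.x ... CB.z`), in which case the CB block is
#'   split off automatically.
#' @param sequence A [peptide_sequence()].
#' @param cb Optional `L x 3` matrix of C-beta coordinates (`NA` rows for
#'   glycine).
#' @param label Free-form label.
#' @param validate Check bonded distances and steric clashes.
#' @return An object of class `Conformation`.
#' @export
conformation <- function(coords, sequence, cb = NULL, label = "",
                         validate = TRUE) {
  stopifnot(inherits(sequence, "PeptideSequence"))
  L <- length(sequence$residues)
  if (is.matrix(coords) && ncol(coords) == 18) {
    m <- coords
    coords <- array(NA_real_, dim = c(L, 5, 3),
                    dimnames = list(NULL, c("N", "H", "CA", "C", "O"), NULL))
    for (a in seq_along(c("N", "H", "CA", "C", "O"))) {
      coords[, a, ] <- m[, (a - 1) * 3 + 1:3, drop = FALSE]
    }
    cb <- m[, 16:18, drop = FALSE]
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3,
            dim(coords)[1] == L, dim(coords)[2] == 5, dim(coords)[3] == 3)
  x <- structure(list(coords = coords, cb = cb, sequence = sequence,
                      label = label),
                 class = "Conformation")
  if (validate) validate_conformation(x)
  x
}

validate_conformation <- function(x) {
  co <- x$coords
  L <- dim(co)[1]
  heavy <- c("N", "CA", "C", "O")
  if (anyNA(co[, heavy, ]))
    stop("missing backbone heavy atom at residue ",
         which(apply(is.na(co[, heavy, , drop = FALSE]), 1, any))[1])
  d_nca <- sqrt(rowSums((co[, "N", ] - co[, "CA", ])^2))
  d_cac <- sqrt(rowSums((co[, "CA", ] - co[, "C", ])^2))
  if (any(d_nca < 1.2 | d_nca > 1.8))
    stop("N-CA bond length outside 1.2-1.8 A at residue ",
         which(d_nca < 1.2 | d_nca > 1.8)[1])
  if (any(d_cac < 1.2 | d_cac > 1.8))
    stop("CA-C bond length outside 1.2-1.8 A at residue ",
         which(d_cac < 1.2 | d_cac > 1.8)[1])
  xyz <- flatten_atoms(x)$xyz
  if (nrow(xyz) > 1) {
    dmin <- min(stats::dist(xyz))
    if (dmin < 0.5)
      stop("steric clash: atoms closer than 0.5 A (min ",
           format(dmin, digits = 3), " A)")
  }
  invisible(x)
}

#' @export
print.Conformation <- function(x, ...) {
  cat("Conformation of", x$sequence$name, "(", dim(x$coords)[1],
      "residues )\n")
  invisible(x)
}

# All present atoms of a conformation as a flat table (residue, atom, xyz).
flatten_atoms <- function(conf, include_cb = TRUE) {
  co <- conf$coords
  L <- dim(co)[1]
  atoms <- c("N", "H", "CA", "C", "O")
  res <- rep(seq_len(L), times = length(atoms))
  atom <- rep(atoms, each = L)
  xyz <- do.call(rbind, lapply(atoms, function(a) co[, a, , drop = TRUE]))
  if (include_cb && !is.null(conf$cb)) {
    res <- c(res, seq_len(L))
    atom <- c(atom, rep("CB", L))
    xyz <- rbind(xyz, conf$cb)
  }
  keep <- !apply(is.na(xyz), 1, any)
  ord <- order(res[keep], match(atom[keep], c("N", "H", "CA", "C", "O", "CB")))
  list(residue = res[keep][ord], atom = atom[keep][ord],
       xyz = xyz[keep, , drop = FALSE][ord, , drop = FALSE])
}

# Extract the L x 3 matrix of one backbone atom.
atom_coords <- function(conf, atom = "CA") conf$coords[, atom, , drop = TRUE]

#' Ordered collection of conformations of one peptide
#'
#' @param conformations List of [conformation()] objects sharing one
#'   sequence.
#' @param sequence The shared [peptide_sequence()]; defaults to that of the
#'   first conformation.
#' @param times Optional monotone non-decreasing timestamps (ns), e.g. the
#'   45 ps snapshot interval of a replica trajectory.
#' @param temperature Optional Kelvin annotation.
#' @param truth Optional per-conformer ground-truth motif labels (set by the
#'   synthetic generator).
#' @return An object of class `Ensemble`.
#' @export
ensemble <- function(conformations, sequence = NULL, times = NULL,
                     temperature = NULL, truth = NULL) {
  stopifnot(is.list(conformations), length(conformations) >= 1)
  if (is.null(sequence)) sequence <- conformations[[1]]$sequence
  same <- vapply(conformations, function(cf)
    identical(cf$sequence$residues, sequence$residues), logical(1))
  if (!all(same)) stop("all conformations must share one sequence")
  if (!is.null(times)) {
    stopifnot(length(times) == length(conformations))
    if (any(diff(times) < 0)) stop("times must be monotone non-decreasing")
  }
  structure(list(conformations = conformations, sequence = sequence,
                 times = times, temperature = temperature, truth = truth),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble of", length(x$conformations), "conformations of",
      x$sequence$name, "\n")
  if (!is.null(x$temperature)) cat("  temperature:", x$temperature, "K\n")
  invisible(x)
}

#' @export
length.Ensemble <- function(x) length(x$conformations)

#' Subset an ensemble by conformer index
#' @param x An [ensemble()].
#' @param i Integer or logical index vector.
#' @param ... Unused.
#' @export
`[.Ensemble` <- function(x, i, ...) {
  idx <- seq_along(x$conformations)[i]
  ensemble(x$conformations[idx], x$sequence,
           times = if (!is.null(x$times)) x$times[idx],
           temperature = x$temperature,
           truth = if (!is.null(x$truth)) x$truth[idx])
}

# CA coordinates of every conformer as a k x 3 x n array (selected residues).
ca_array <- function(e, residues = NULL) {
  if (is.null(residues)) residues <- seq_along(e$sequence$residues)
  n <- length(e$conformations)
  arr <- array(NA_real_, dim = c(length(residues), 3, n))
  for (i in seq_len(n))
    arr[, , i] <- e$conformations[[i]]$coords[residues, "CA", ]
  arr
}

# Dihedral angle (degrees) for rows of four atom-position matrices.
dihedral_angle <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) {
    p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4)
  }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
              n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
              n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1])
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2) / b2n
  -atan2(y, x) * 180 / pi
}

#' Backbone dihedral angles of a conformation
#'
#' @param conf A [conformation()].
#' @return Data frame with columns `residue`, `phi`, `psi`, `omega`
#'   (degrees); `phi` is `NA` for residue 1, `psi` and `omega` are `NA`
#'   where undefined.
#' @export
backbone_dihedrals <- function(conf) {
  co <- conf$coords
  L <- dim(co)[1]
  at <- function(idx, atom) matrix(co[idx, atom, ], ncol = 3)
  phi <- psi <- omg <- rep(NA_real_, L)
  if (L >= 2) {
    i <- 2:L
    phi[i] <- dihedral_angle(at(i - 1, "C"), at(i, "N"), at(i, "CA"),
                             at(i, "C"))
    j <- 1:(L - 1)
    psi[j] <- dihedral_angle(at(j, "N"), at(j, "CA"), at(j, "C"),
                             at(j + 1, "N"))
    omg[i] <- dihedral_angle(at(i - 1, "CA"), at(i - 1, "C"), at(i, "N"),
                             at(i, "CA"))
  }
  data.frame(residue = seq_len(L), phi = phi, psi = psi, omega = omg)
}

#' Apply a rigid transform to a conformation or ensemble
#'
#' @param x A [conformation()] or [ensemble()].
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 shift (applied after rotation).
#' @return The transformed object.
#' @export
transform_rigid <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  if (inherits(x, "Ensemble")) {
    x$conformations <- lapply(x$conformations, transform_rigid,
                              rotation = rotation, translation = translation)
    return(x)
  }
  stopifnot(inherits(x, "Conformation"))
  for (a in seq_len(dim(x$coords)[2])) {
    m <- x$coords[, a, , drop = TRUE]
    x$coords[, a, ] <- sweep(m %*% t(rotation), 2, -translation)
  }
  if (!is.null(x$cb))
    x$cb <- sweep(x$cb %*% t(rotation), 2, -translation)
  x
}

# Reconstruct the amide H of residue i in the C(i-1)-N-CA plane, 1.01 A from
# N, opposite the bisector of the two bonds. Residue 1 and prolines have none.
reconstruct_amide_h <- function(coords, residues) {
  L <- dim(coords)[1]
  for (i in 2:L) {
    if (residues[i] == "P") next
    if (!anyNA(coords[i, "H", ])) next
    n <- coords[i, "N", ]
    u1 <- coords[i - 1, "C", ] - n
    u2 <- coords[i, "CA", ] - n
    u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
    h <- -(u1 + u2)
    coords[i, "H", ] <- n + 1.01 * h / sqrt(sum(h^2))
  }
  coords
}
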