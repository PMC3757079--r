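#' Bundled per-atom generalized Born parameter table
#'
#' Partial charges (e), intrinsic radii (Angstrom) and OBC descreening scale
#' factors for the backbone + C-beta atom set. Charges are a neutral
#' backbone charge group (they sum to zero per residue); radii and scales
#' follow the usual Bondi-derived values for implicit-solvent work. Formal
#' side-chain and terminal charges are added separately from the protonation
#' convention (see [solvation_atoms()]). This is a fixture table: absolute
#' energies are not comparable to any particular force field, only
#' orderings, limits and relative values are meaningful.
#'
#' @param path Optional path to a TSV with columns `atom`, `charge`,
#'   `radius`, `scale` overriding the bundled table.
#' @return Data frame with one row per atom name.
#' @export
gb_param_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gb_params.tsv", package = "idpens")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Solvation model parameters
#'
#' @param table Per-atom parameter table ([gb_param_table()]).
#' @param eps_in,eps_out Interior and solvent dielectric constants.
#' @param gamma Surface tension, kcal/(mol A^2) (default 0.005).
#' @param salt_M Effective monovalent salt concentration (mol/L); the
#'   Debye screening constant is `kappa = 0.316 * sqrt(salt_M)` per Angstrom
#'   at 298 K (0.1413 at 0.2 M).
#' @param probe Solvent probe radius (A).
#' @param offset Intrinsic-radius offset used for the reduced radii (A).
#' @param n_points Sphere sample points for the surface area.
#' @param charge_convention Protonation convention as in [formal_charge()].
#' @return A `SolvParams` list.
#' @export
solv_params <- function(table = gb_param_table(), eps_in = 1,
                        eps_out = 78.5, gamma = 0.005, salt_M = 0.2,
                        probe = 1.4, offset = 0.09, n_points = 960,
                        charge_convention = c(K = 1, R = 1, H = 0, D = -1,
                                              E = -1, nterm = 1,
                                              cterm = -1)) {
  stopifnot(all(table$radius > 0), gamma >= 0, salt_M >= 0)
  structure(list(table = table, eps_in = eps_in, eps_out = eps_out,
                 gamma = gamma, salt_M = salt_M,
                 kappa = 0.316 * sqrt(salt_M), probe = probe,
                 offset = offset, obc = c(alpha = 1.0, beta = 0.8,
                                          gamma = 4.85),
                 n_points = as.integer(n_points),
                 charge_convention = charge_convention),
            class = "SolvParams")
}

#' Flat atom table of a conformation with solvation parameters
#'
#' Expands a conformation into one row per present atom (N, H, CA, C, O, CB)
#' with coordinates, partial charge, radius and OBC scale. Formal charges
#' from the protonation convention are placed on the C-beta of charged
#' residues (C-alpha for glycine), the N-terminal charge on the first N, and
#' the C-terminal charge (absent when amidated) on the last O. Charges of
#' absent amide hydrogens (residue 1, prolines) are folded into the N so
#' every residue keeps an integral charge group.
#'
#' @param conf A [conformation()].
#' @param params A [solv_params()].
#' @return Data frame: `residue`, `atom`, `x`, `y`, `z`, `charge`,
#'   `radius`, `scale`.
#' @export
solvation_atoms <- function(conf, params = solv_params()) {
  stopifnot(inherits(conf, "Conformation"))
  f <- flatten_atoms(conf, include_cb = TRUE)
  tab <- params$table
  m <- match(f$atom, tab$atom)
  if (anyNA(m))
    stop("no parameters for atom(s): ",
         paste(unique(f$atom[is.na(m)]), collapse = ", "))
  out <- data.frame(residue = f$residue, atom = f$atom,
                    x = f$xyz[, 1], y = f$xyz[, 2], z = f$xyz[, 3],
                    charge = tab$charge[m], radius = tab$radius[m],
                    scale = tab$scale[m])
  seqres <- conf$sequence$residues
  L <- length(seqres)
  conv <- params$charge_convention
  # fold missing-H charge into N
  hq <- tab$charge[tab$atom == "H"]
  for (i in seq_len(L)) {
    if (!any(out$atom == "H" & out$residue == i)) {
      sel <- which(out$atom == "N" & out$residue == i)
      out$charge[sel] <- out$charge[sel] + hq
    }
  }
  # formal side-chain / terminal charges
  for (i in seq_len(L)) {
    q <- if (seqres[i] %in% names(conv)) conv[[seqres[i]]] else 0
    if (q != 0) {
      sel <- which(out$residue == i & out$atom == "CB")
      if (length(sel) == 0) sel <- which(out$residue == i & out$atom == "CA")
      out$charge[sel] <- out$charge[sel] + q
    }
  }
  if ("nterm" %in% names(conv)) {
    sel <- which(out$residue == 1 & out$atom == "N")
    out$charge[sel] <- out$charge[sel] + conv[["nterm"]]
  }
  if ("cterm" %in% names(conv) && !conf$sequence$c_amidated) {
    sel <- which(out$residue == L & out$atom == "O")
    out$charge[sel] <- out$charge[sel] + conv[["cterm"]]
  }
  out
}

#' OBC-style effective Born radii
#'
#' Pairwise-descreening (HCT) integrals with OBC-II tanh rescaling:
#' `Psi = rho_i_reduced * sum_j I(r_ij, scaled rho_j)` and
#' `1/R_i = 1/rho_i_reduced - tanh(a*Psi - b*Psi^2 + c*Psi^3) / rho_i` with
#' `(a, b, c) = (1.0, 0.8, 4.85)`. Radii are clamped to at least the reduced
#' intrinsic radius.
#'
#' @param atoms An atom table ([solvation_atoms()]) or a [conformation()].
#' @param params A [solv_params()].
#' @return Numeric vector of effective radii (A), one per atom row.
#' @export
born_radii <- function(atoms, params = solv_params()) {
  if (inherits(atoms, "Conformation"))
    atoms <- solvation_atoms(atoms, params)
  X <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(X)
  rho <- atoms$radius - params$offset
  r <- as.matrix(stats::dist(X))
  if (n > 1 && min(r[upper.tri(r)]) < 0.3)
    stop("overlapping atoms closer than 0.3 A")
  sj <- matrix(atoms$scale * rho, n, n, byrow = TRUE)  # scaled reduced rho_j
  rhoi <- matrix(rho, n, n)
  U <- r + sj
  Lo <- pmax(abs(r - sj), rhoi)
  I <- 0.5 * (1 / Lo - 1 / U + 0.25 * (r - sj^2 / r) * (1 / U^2 - 1 / Lo^2) +
                0.5 * log(Lo / U) / r)
  # atom i engulfed by sphere j
  eng <- rhoi < (sj - r)
  I[eng] <- I[eng] + 2 * (1 / rhoi[eng] - 1 / Lo[eng])
  I[rhoi >= U] <- 0                     # sphere j inside atom i
  diag(I) <- 0
  psi <- rho * rowSums(I)
  ob <- params$obc
  inv <- 1 / rho -
    tanh(ob[["alpha"]] * psi - ob[["beta"]] * psi^2 +
           ob[["gamma"]] * psi^3) / atoms$radius
  unname(pmax(1 / inv, rho))
}

#' Generalized Born electrostatic solvation energy
#'
#' `E_GB = -166.03 * sum_{i,j} q_i q_j (1/eps_in - exp(-kappa f_ij)/eps_out)
#' / f_ij` over ordered pairs (the i = j self terms use `f_ii = R_i`), with
#' `f_ij = sqrt(r_ij^2 + R_i R_j exp(-r_ij^2 / (4 R_i R_j)))` and
#' Debye-Hueckel salt screening through `kappa`.
#'
#' @param atoms An atom table or [conformation()].
#' @param radii Effective radii from [born_radii()] (computed if missing).
#' @param params A [solv_params()].
#' @return Energy in kcal/mol.
#' @export
gb_energy <- function(atoms, radii = NULL, params = solv_params()) {
  if (inherits(atoms, "Conformation"))
    atoms <- solvation_atoms(atoms, params)
  if (anyNA(atoms$charge)) stop("missing charge")
  if (is.null(radii)) radii <- born_radii(atoms, params)
  X <- as.matrix(atoms[, c("x", "y", "z")])
  r2 <- as.matrix(stats::dist(X))^2
  RR <- outer(radii, radii)
  f <- sqrt(r2 + RR * exp(-r2 / (4 * RR)))
  qq <- outer(atoms$charge, atoms$charge)
  -166.03 * sum(qq * (1 / params$eps_in -
                        exp(-params$kappa * f) / params$eps_out) / f)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic quasi-uniform sphere sampling (Fibonacci lattice) with a
#' 1.4 A probe over the intrinsic atomic radii.
#'
#' @param atoms An atom table or [conformation()].
#' @param params A [solv_params()].
#' @param n_points Sphere sample points (default from `params`).
#' @return List with `per_atom` (A^2) and `total`.
#' @export
sasa <- function(atoms, params = solv_params(), n_points = params$n_points) {
  if (inherits(atoms, "Conformation"))
    atoms <- solvation_atoms(atoms, params)
  X <- canonical_frame(as.matrix(atoms[, c("x", "y", "z")]))
  a <- .sasa_cpp(X, atoms$radius,
                 probe = params$probe, n_points = as.integer(n_points))
  list(per_atom = a, total = sum(a))
}

# Rotate coordinates into a deterministic molecule-fixed frame (principal
# axes, signs fixed by coordinate skewness) so that the fixed sphere lattice
# gives rigid-motion-invariant areas.
canonical_frame <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  if (nrow(Xc) < 3) return(Xc)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  V <- ev$vectors
  Y <- Xc %*% V
  for (k in 1:3) {
    s <- sum(Y[, k]^3)
    if (abs(s) > 1e-8 && s < 0) Y[, k] <- -Y[, k]
  }
  Y
}

#' Total GB + surface-area solvation energy of one conformation
#'
#' @param conf A [conformation()].
#' @param params A [solv_params()].
#' @return A `SolvationResult` list: `E_gb`, `E_surf` (`gamma * SASA`),
#'   `E_total`.
#' @export
gbsa_total <- function(conf, params = solv_params()) {
  atoms <- solvation_atoms(conf, params)
  radii <- born_radii(atoms, params)
  e_gb <- gb_energy(atoms, radii, params)
  e_surf <- params$gamma * sasa(atoms, params)$total
  structure(list(E_gb = e_gb, E_surf = e_surf, E_total = e_gb + e_surf),
            class = "SolvationResult")
}

#' @export
print.SolvationResult <- function(x, ...) {
  cat(sprintf("GBSA solvation energy: %.2f kcal/mol (GB %.2f + surface %.2f)\n",
              x$E_total, x$E_gb, x$E_surf))
  invisible(x)
}

#' Per-super-family solvation statistics with block uncertainties
#'
#' Computes the GBSA total for every conformer, then reports per-label mean
#' and sample standard deviation over the last `last_k` blocks, an
#' ensemble-average row, and the difference of each label to the helix-coil
#' label (the per-variant relative convention).
#'
#' @param e An [ensemble()].
#' @param labels Per-conformer super-family labels.
#' @param blocks A [make_blocks()] partition.
#' @param params A [solv_params()].
#' @param last_k Final blocks used for statistics (default 3).
#' @param energies Optional pre-computed per-conformer totals (kcal/mol),
#'   bypassing the GBSA evaluation.
#' @return Data frame: `label`, `mean`, `std`, `n`, `delta_vs_helix_coil`;
#'   the last row (`label == "average"`) is the whole-ensemble average.
#' @export
solvation_report <- function(e, labels, blocks, params = solv_params(),
                             last_k = 3, energies = NULL) {
  stopifnot(inherits(e, "Ensemble"), length(labels) == length(e))
  if (is.null(energies))
    energies <- vapply(e$conformations,
                       function(cf) gbsa_total(cf, params)$E_total, 0)
  present <- intersect(SUPERFAMILY_LABELS, unique(labels))
  use <- utils::tail(blocks$blocks, last_k)
  rows <- lapply(c(present, "average"), function(lab) {
    sel_lab <- if (lab == "average") rep(TRUE, length(labels))
      else labels == lab
    bm <- vapply(use, function(idx) {
      sel <- idx[sel_lab[idx]]
      if (length(sel) == 0) NA_real_ else mean(energies[sel])
    }, 0)
    bm <- bm[!is.na(bm)]
    data.frame(label = lab, mean = mean(bm),
               std = if (length(bm) > 1) stats::sd(bm) else 0,
               n = sum(sel_lab))
  })
  out <- do.call(rbind, rows)
  hc <- out$mean[out$label == "helix-coil"]
  out$delta_vs_helix_coil <-
    if (length(hc) == 1) out$mean - hc else NA_real_
  out$delta_vs_helix_coil[out$label == "average"] <- NA_real_
  out
}

#' Cross-variant relative solvation energies
#'
#' Given named per-variant reports from [solvation_report()], returns each
#' variant's ensemble-average solvation energy relative to a reference
#' variant (reference value 0 by construction).
#'
#' @param reports Named list of [solvation_report()] outputs.
#' @param reference Name of the reference variant.
#' @return Data frame: `variant`, `average`, `delta_vs_reference`.
#' @export
relative_solvation <- function(reports, reference) {
  stopifnot(reference %in% names(reports))
  avg <- vapply(reports, function(r) r$mean[r$label == "average"], 0)
  data.frame(variant = names(reports), average = unname(avg),
             delta_vs_reference = unname(avg - avg[[reference]]))
}
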