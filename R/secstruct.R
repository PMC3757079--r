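#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic model for an N-H...O=C hydrogen bond:
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol. A bond is
#' declared when `E < -0.5` kcal/mol. Donor-acceptor pairs with N...O beyond
#' 7 A score 0 (no bond).
#'
#' @param donor_n,donor_h Donor backbone N and amide H positions (length 3).
#' @param acceptor_c,acceptor_o Acceptor carbonyl C and O positions.
#' @return Energy in kcal/mol.
#' @export
hbond_energy <- function(donor_n, donor_h, acceptor_c, acceptor_o) {
  rON <- sqrt(sum((acceptor_o - donor_n)^2))
  if (rON > 7) return(0)
  rCH <- sqrt(sum((acceptor_c - donor_h)^2))
  rOH <- sqrt(sum((acceptor_o - donor_h)^2))
  rCN <- sqrt(sum((acceptor_c - donor_n)^2))
  if (min(rON, rCH, rOH, rCN) < 0.3)
    stop("coincident atoms in hydrogen-bond evaluation")
  27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

KS_CUTOFF <- -0.5

# L x L logical matrix: hb[i, j] <=> carbonyl of residue i accepts the amide
# H of residue j. Residue 1 and prolines never donate.
hbond_matrix <- function(conf, e_cut = KS_CUTOFF) {
  co <- conf$coords
  L <- dim(co)[1]
  O <- co[, "O", ]; C <- co[, "C", ]; N <- co[, "N", ]; H <- co[, "H", ]
  dist2 <- function(A, B)
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  rON <- sqrt(pmax(dist2(O, N), 0))
  rOH <- sqrt(pmax(dist2(O, H), 0))
  rCH <- sqrt(pmax(dist2(C, H), 0))
  rCN <- sqrt(pmax(dist2(C, N), 0))
  E <- 27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[rON > 7] <- 0
  E[is.na(E)] <- 0                      # non-donors (no H)
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  E[sep < 2] <- 0                       # self and adjacent
  E < e_cut
}

#' Assign per-residue secondary structure
#'
#' Two assignment modes over the code alphabet H (alpha-helix), G (3-10
#' helix), E (strand), B (isolated beta-bridge), T (turn), C (coil):
#'
#' * `"hbond"`: DSSP-style patterns on Kabsch-Sander hydrogen bonds -
#'   H from two consecutive i -> i+4 bonds, G from consecutive i -> i+3
#'   bonds, E from ladders of two or more beta-bridges, B for isolated
#'   bridges, T for residues bracketed by an i -> i+3/4/5 bond, else C.
#' * `"dihedral"`: helix if (phi, psi) lies within 40 degrees of (-57, -47),
#'   strand if within 40 degrees of (-139, 135), T if within 40 degrees of a
#'   bundled turn-table entry, else C. Used mainly to ground-truth the
#'   synthetic generator.
#'
#' @param conf A [conformation()].
#' @param mode `"hbond"` (default) or `"dihedral"`.
#' @return Character vector of per-residue codes (class `SSString`).
#' @export
assign_ss <- function(conf, mode = c("hbond", "dihedral")) {
  mode <- match.arg(mode)
  ss <- if (mode == "hbond") assign_ss_hbond(conf) else
    assign_ss_dihedral(conf)
  structure(ss, class = "SSString", mode = mode)
}

assign_ss_hbond <- function(conf) {
  hb <- hbond_matrix(conf)
  L <- nrow(hb)
  turn_at <- function(n) {
    t <- rep(FALSE, L)
    i <- seq_len(L - n)
    t[i] <- hb[cbind(i, i + n)]
    t
  }
  t3 <- turn_at(3); t4 <- turn_at(4); t5 <- turn_at(5)
  ss <- rep("C", L)

  for (i in 2:max(2, L - 4))
    if (t4[i - 1] && t4[i]) ss[i:(i + 3)] <- "H"
  for (i in 2:max(2, L - 3))
    if (t3[i - 1] && t3[i])
      ss[i:(i + 2)][ss[i:(i + 2)] == "C"] <- "G"

  # beta-bridges (Kabsch-Sander patterns); hb[i, j]: O(i) <- H(j)
  hbs <- function(i, j) i >= 1 && j >= 1 && i <= L && j <= L && hb[i, j]
  bridges <- list()
  for (i in 1:(L - 3)) {
    for (j in (i + 3):L) {
      anti <- (hbs(i, j) && hbs(j, i)) ||
        (hbs(i - 1, j + 1) && hbs(j - 1, i + 1))
      par <- (hbs(i - 1, j) && hbs(j, i + 1)) ||
        (hbs(j - 1, i) && hbs(i, j + 1))
      if (anti || par)
        bridges[[length(bridges) + 1]] <-
          c(i = i, j = j, anti = as.integer(anti))
    }
  }
  if (length(bridges) > 0) {
    B <- do.call(rbind, bridges)
    key <- paste(B[, 1], B[, 2], B[, 3])
    laddered <- vapply(seq_len(nrow(B)), function(k) {
      i <- B[k, 1]; j <- B[k, 2]; a <- B[k, 3]
      nb <- if (a == 1) rbind(c(i + 1, j - 1, a), c(i - 1, j + 1, a))
        else rbind(c(i + 1, j + 1, a), c(i - 1, j - 1, a))
      any(paste(nb[, 1], nb[, 2], nb[, 3]) %in% key)
    }, logical(1))
    for (k in seq_len(nrow(B))) {
      idx <- B[k, 1:2]
      code <- if (laddered[k]) "E" else "B"
      repl <- ss[idx] %in% c("C", "T", "B")
      if (code == "E") ss[idx][repl] <- "E"
      else ss[idx][ss[idx] == "C"] <- "B"
    }
  }

  for (n in 3:5) {
    tn <- if (n == 3) t3 else if (n == 4) t4 else t5
    for (i in which(tn)) {
      idx <- (i + 1):(i + n - 1)
      idx <- idx[idx <= L]
      ss[idx][ss[idx] == "C"] <- "T"
    }
  }
  ss
}

# circular angle difference in degrees
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

assign_ss_dihedral <- function(conf) {
  dih <- backbone_dihedrals(conf)
  L <- nrow(dih)
  ss <- rep("C", L)
  near <- function(phi0, psi0, tol = 40)
    !is.na(dih$phi) & !is.na(dih$psi) &
      ang_diff(dih$phi, phi0) <= tol & ang_diff(dih$psi, psi0) <= tol
  is_h <- near(DIHEDRAL_HELIX["phi"], DIHEDRAL_HELIX["psi"])
  is_e <- near(DIHEDRAL_STRAND["phi"], DIHEDRAL_STRAND["psi"])
  tt <- turn_dihedral_table()
  is_t <- rep(FALSE, L)
  for (k in seq_len(nrow(tt))) is_t <- is_t | near(tt$phi[k], tt$psi[k])
  ss[is_t] <- "T"
  ss[is_e & !is_h] <- "E"
  ss[is_h] <- "H"
  ss
}

#' @export
print.SSString <- function(x, ...) {
  cat(paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

# Aggregate 6-code alphabet into the four reported classes.
SS_CLASS_MAP <- c(H = "helix", G = "helix", E = "sheet", B = "sheet",
                  T = "turn", C = "coil")

#' Map secondary-structure codes to aggregate classes
#'
#' Aggregation used throughout reporting: helix = {H, G}, sheet = {E, B},
#' turn = {T}, coil = {C}.
#'
#' @param ss An `SSString` (or plain character vector of codes).
#' @return Character vector of classes.
#' @export
ss_classes <- function(ss) unname(SS_CLASS_MAP[unclass(ss)])

#' Secondary-structure propensity profile of an ensemble
#'
#' Per-residue frequencies of the four aggregate classes over conformers,
#' plus ensemble-level class fractions (residue-averaged propensities).
#' Because turn and coil are often reported jointly for disordered peptides,
#' `merge_turn_coil = TRUE` returns a 3-class profile instead.
#'
#' @param e An [ensemble()].
#' @param mode Assignment mode passed to [assign_ss()].
#' @param merge_turn_coil Merge turn and coil into one class.
#' @return An `SSProfile`: list with `propensities` (residues x classes
#'   matrix), `fractions` (named vector), `ss` (conformers x residues code
#'   matrix), `n`, and `mode`.
#' @export
ss_profile <- function(e, mode = c("hbond", "dihedral"),
                       merge_turn_coil = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(e, "Ensemble"), length(e) >= 1)
  L <- length(e$sequence$residues)
  ssm <- t(vapply(e$conformations,
                  function(cf) unclass(assign_ss(cf, mode)), character(L)))
  classes <- if (merge_turn_coil) c("helix", "sheet", "turn/coil")
    else c("helix", "sheet", "turn", "coil")
  map <- SS_CLASS_MAP
  if (merge_turn_coil) map[c("T", "C")] <- "turn/coil"
  prop <- sapply(classes, function(cl)
    colMeans(matrix(map[ssm] == cl, nrow = nrow(ssm))))
  rownames(prop) <- seq_len(L)
  structure(list(propensities = prop, fractions = colMeans(prop),
                 ss = ssm, n = length(e), mode = mode),
            class = "SSProfile")
}

#' @export
print.SSProfile <- function(x, ...) {
  cat("SSProfile over", x$n, "conformers (mode:", x$mode, ")\n")
  cat("ensemble class fractions:\n")
  print(round(x$fractions, 3))
  invisible(x)
}
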