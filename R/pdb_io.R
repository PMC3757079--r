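#' Read a multi-model PDB file as an Ensemble
#'
#' Each MODEL/ENDMDL block becomes one [conformation()]. Residues are matched
#' to `sequence` by index; backbone atoms N, CA, C, O are required in every
#' model, and missing amide hydrogens are reconstructed geometrically (in the
#' C(i-1)-N-CA plane, 1.01 A from N, opposite the bond bisector). Side-chain
#' atoms other than CB are ignored.
#'
#' @param path Path to a PDB file (single- or multi-model).
#' @param sequence The expected [peptide_sequence()].
#' @return An [ensemble()].
#' @export
read_ensemble <- function(path, sequence) {
  stopifnot(inherits(sequence, "PeptideSequence"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  atom_idx <- grep("^ATOM  ", lines)
  if (length(atom_idx) == 0) stop("no ATOM records in ", path)
  model_starts <- grep("^MODEL", lines)
  model_of <- if (length(model_starts) == 0) rep(1L, length(atom_idx))
    else findInterval(atom_idx, model_starts)
  if (any(model_of == 0)) stop("ATOM records before first MODEL in ", path)
  n_models <- max(model_of)

  aname <- trimws(substr(lines[atom_idx], 13, 16))
  rname <- trimws(substr(lines[atom_idx], 18, 20))
  resno <- as.integer(substr(lines[atom_idx], 23, 26))
  L <- length(sequence$residues)

  # validate each model against the sequence and required backbone atoms
  key1 <- NULL
  for (m in seq_len(n_models)) {
    sel <- model_of == m
    an <- aname[sel]; rn <- resno[sel]; rs <- rname[sel]
    one <- bio3d::aa321(rs[!duplicated(rn)])
    if (length(one) != L)
      stop("model ", m, ": expected ", L, " residues, found ", length(one))
    mism <- which(one != sequence$residues)
    if (length(mism) > 0)
      stop("sequence mismatch at residue ", mism[1], ": file has ",
           one[mism[1]], ", expected ", sequence$residues[mism[1]])
    for (a in c("N", "CA", "C", "O")) {
      have <- unique(rn[an == a])
      missing <- setdiff(seq_len(L), have)
      if (length(missing) > 0)
        stop("model ", m, ", residue ", missing[1],
             ": missing backbone atom ", a)
    }
    key <- paste(rn, an)
    if (m == 1) key1 <- key
    else if (!identical(sort(key), sort(key1)))
      stop("model ", m, ": atom set differs from model 1")
  }

  pdb <- bio3d::read.pdb(path, multi = n_models > 1, verbose = FALSE)
  xyz <- if (n_models > 1) pdb$xyz else matrix(pdb$xyz, nrow = 1)
  at <- pdb$atom
  atoms5 <- c("N", "H", "CA", "C", "O")
  confs <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    co <- array(NA_real_, dim = c(L, 5, 3),
                dimnames = list(NULL, atoms5, NULL))
    xm <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    for (a in atoms5) {
      sel <- which(at$elety == a)
      co[at$resno[sel], a, ] <- xm[sel, , drop = FALSE]
    }
    cb <- matrix(NA_real_, L, 3)
    sel <- which(at$elety == "CB")
    if (length(sel) > 0) cb[at$resno[sel], ] <- xm[sel, , drop = FALSE]
    co <- reconstruct_amide_h(co, sequence$residues)
    confs[[m]] <- conformation(co, sequence,
                               cb = if (any(!is.na(cb))) cb else NULL,
                               label = paste0("model_", m), validate = FALSE)
  }
  ensemble(confs, sequence)
}

#' Write an Ensemble as a multi-model PDB file
#'
#' Standard fixed-width records, one MODEL/ENDMDL block per conformation,
#' occupancy 1.00. Coordinates are rounded to the PDB precision of 0.001 A.
#'
#' @param e An [ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(e, path) {
  stopifnot(inherits(e, "Ensemble"))
  if (!is.character(path) || length(path) != 1 || !nzchar(path))
    stop("invalid output path")
  f <- flatten_atoms(e$conformations[[1]])
  n <- length(e$conformations)
  xyz <- matrix(NA_real_, n, 3 * nrow(f$xyz))
  for (m in seq_len(n)) {
    fm <- flatten_atoms(e$conformations[[m]])
    if (!identical(fm$atom, f$atom) || !identical(fm$residue, f$residue))
      stop("conformation ", m, " has a different atom set than the first")
    xyz[m, ] <- as.vector(t(fm$xyz))
  }
  resid3 <- bio3d::aa123(e$sequence$residues)[f$residue]
  bio3d::write.pdb(file = path, xyz = xyz, resno = f$residue,
                   resid = resid3, elety = f$atom,
                   chain = rep("A", nrow(f$xyz)),
                   o = rep(1, nrow(f$xyz)), b = rep(0, nrow(f$xyz)))
  invisible(path)
}
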