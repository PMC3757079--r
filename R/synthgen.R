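# Canonical backbone dihedral values (degrees). Helix and antiparallel-strand
# values are the standard ideal ones; turn and coil residues draw from small
# bundled tables chosen to keep the three dihedral-space regions (helix,
# strand, turn/coil) well separated.
DIHEDRAL_HELIX <- c(phi = -57, psi = -47)
DIHEDRAL_STRAND <- c(phi = -139, psi = 135)

#' Bundled turn and coil dihedral tables
#'
#' `turn_dihedral_table()` holds beta-turn-like (phi, psi) pairs used to
#' initialise turn/loop segments (closure refinement then adjusts them);
#' `coil_dihedral_table()` holds typical coil pairs assigned cyclically by
#' residue index so that generation is deterministic.
#'
#' @return A data frame with columns `phi` and `psi` (degrees).
#' @export
turn_dihedral_table <- function() {
  data.frame(phi = c(60, 90, -100, -60), psi = c(30, 0, 10, 130))
}

#' @rdname turn_dihedral_table
#' @export
coil_dihedral_table <- function() {
  data.frame(phi = c(-70, -85, -150, -65), psi = c(150, 80, 70, -170))
}

#' Canonical motif specification for a 37-residue peptide
#'
#' Builds the `MotifSpec` for one of the three folds of the IAPP monomer
#' ensemble: helix-coil (coil 1-7, helix 8-17, coil 18-37), helix-hairpin
#' (helix 8-17 plus a C-terminal hairpin with strands 25-27 and 33-36 and
#' loop 28-31) and beta-hairpin (strands 9-17 and 23-33, turn 18-22). Helix
#' segments use (-57, -47), strand segments (-139, 135); turn and coil
#' residues take entries from the bundled tables, cycled by residue index.
#'
#' @param label One of `"helix-coil"`, `"helix-hairpin"`, `"beta-hairpin"`.
#' @param sigma Dihedral jitter standard deviation (degrees) applied to every
#'   residue when sampling.
#' @param length Chain length (default 37).
#' @return An object of class `MotifSpec` with per-residue target `phi`,
#'   `psi`, `omega`, the segment table, optional `closure_residues` and the
#'   intended cross-strand H-bond pairs.
#' @export
make_motif <- function(label = c("helix-coil", "helix-hairpin",
                                 "beta-hairpin"),
                       sigma = 0, length = 37) {
  label <- match.arg(label)
  L <- length
  seg <- switch(label,
    "helix-coil" = data.frame(
      start = c(1, 8, 18), end = c(7, 17, L),
      type = c("coil", "helix", "coil")),
    "helix-hairpin" = data.frame(
      start = c(1, 8, 18, 25, 28, 32, 33, 37),
      end = c(7, 17, 24, 27, 31, 32, 36, L),
      type = c("coil", "helix", "coil", "strand", "turn", "coil", "strand",
               "coil")),
    "beta-hairpin" = data.frame(
      start = c(1, 9, 18, 23, 34), end = c(8, 17, 22, 33, L),
      type = c("coil", "strand", "turn", "strand", "coil")))
  # closure scope: the loop/turn plus one flanking strand residue per side,
  # giving the descent enough freedom to register the innermost H-bonds
  closure <- switch(label, "helix-coil" = NULL,
                    "helix-hairpin" = 27:33, "beta-hairpin" = 17:23)
  # intended cross-strand H-bonds as (acceptor residue, donor residue);
  # the first two rows are the innermost pair. The extension table is one
  # further rung of the same antiparallel ladder, recruited when prolines
  # in the peptide's sequence block bonds of the core registry.
  pairs <- switch(label, "helix-coil" = NULL,
    "helix-hairpin" = cbind(c(27, 33, 25, 35), c(33, 27, 35, 25)),
    "beta-hairpin" = cbind(c(17, 23, 15, 25, 13, 27, 11, 29),
                           c(23, 17, 25, 15, 27, 13, 29, 11)))
  pairs_ext <- switch(label, "helix-coil" = NULL,
    "helix-hairpin" = cbind(c(23, 37), c(37, 23)),
    "beta-hairpin" = cbind(c(9, 31), c(31, 9)))

  phi <- psi <- numeric(L)
  type <- character(L)
  tt <- turn_dihedral_table(); ct <- coil_dihedral_table()
  for (s in seq_len(nrow(seg))) {
    idx <- seg$start[s]:seg$end[s]
    type[idx] <- seg$type[s]
    if (seg$type[s] == "helix") {
      phi[idx] <- DIHEDRAL_HELIX["phi"]; psi[idx] <- DIHEDRAL_HELIX["psi"]
    } else if (seg$type[s] == "strand") {
      phi[idx] <- DIHEDRAL_STRAND["phi"]; psi[idx] <- DIHEDRAL_STRAND["psi"]
    } else {
      tab <- if (seg$type[s] == "turn") tt else ct
      k <- ((idx - 1) %% nrow(tab)) + 1
      phi[idx] <- tab$phi[k]; psi[idx] <- tab$psi[k]
    }
  }
  structure(list(label = label, segments = seg, residue_type = type,
                 phi = phi, psi = psi, omega = rep(180, L),
                 sigma = rep(sigma, L), closure_residues = closure,
                 hbond_pairs = pairs, hbond_pairs_ext = pairs_ext),
            class = "MotifSpec")
}

#' @export
print.MotifSpec <- function(x, ...) {
  cat("MotifSpec:", x$label, "\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Build a backbone conformation from internal coordinates
#'
#' Places backbone atoms N, H, CA, C, O (plus C-beta) by sequential natural
#' extension (NeRF) using standard geometry: N-CA 1.458 A, CA-C 1.525 A,
#' C-N 1.329 A, C=O 1.231 A, angles N-CA-C 111.2, CA-C-N 116.6,
#' C-N-CA 121.9 degrees. The carbonyl O lies in the CA-C-N(i+1) plane.
#'
#' @param seq A [peptide_sequence()].
#' @param phi,psi,omega Per-residue dihedrals in degrees (`phi[1]` is
#'   ignored; `psi[L]` only orients the terminal carbonyl and may be `NA`).
#' @param label Conformation label.
#' @return A [conformation()].
#' @export
build_chain <- function(seq, phi, psi, omega = NULL, label = "") {
  stopifnot(inherits(seq, "PeptideSequence"))
  L <- length(seq$residues)
  if (length(phi) != L || length(psi) != L)
    stop("phi and psi must have one entry per residue (", L, ")")
  if (is.null(omega)) omega <- rep(180, L)
  if (length(omega) != L) stop("omega must have one entry per residue")
  phi[is.na(phi)] <- 180; psi[is.na(psi)] <- 180; omega[is.na(omega)] <- 180
  m <- .build_backbone_cpp(phi, psi, omega, seq$residues == "P",
                           seq$residues == "G")
  conformation(m, seq, label = label, validate = FALSE)
}

#' Refine a hairpin's loop dihedrals to register the cross-strand H-bonds
#'
#' Coordinate descent over the phi/psi of the motif's closure residues,
#' minimising the sum of deviations of the intended O...H distances from
#' 1.95 A, with early stop once every intended cross-strand H-bond scores
#' below the Kabsch-Sander cutoff of -0.5 kcal/mol. Motifs without a closure
#' range are returned unchanged. If descent stalls before closing, a small
#' fixed set of canonical turn initialisations is tried.
#'
#' @param conf A [conformation()] built from `spec` dihedrals.
#' @param spec A [make_motif()] specification.
#' @param max_iter Maximum single-dihedral updates per attempt.
#' @return A [conformation()]; attribute `converged` reports whether all
#'   intended H-bonds are formed (non-converged conformers are flagged so
#'   callers may discard them).
#' @export
refine_closure <- function(conf, spec, max_iter = 500) {
  stopifnot(inherits(conf, "Conformation"), inherits(spec, "MotifSpec"))
  if (is.null(spec$closure_residues)) {
    attr(conf, "converged") <- TRUE
    return(conf)
  }
  dih <- backbone_dihedrals(conf)
  out <- refine_closure_dihedrals(dih$phi, dih$psi, spec,
                                  conf$sequence$residues == "P",
                                  max_iter = max_iter)
  conf2 <- build_chain(conf$sequence, out$phi, out$psi,
                       rep(180, length(out$phi)), label = conf$label)
  attr(conf2, "converged") <- out$converged
  conf2
}

# Candidate cross-strand registries for a hairpin motif, ordered by
# preference. Prolines cannot donate an amide H, so when the canonical
# registry is blocked the candidates are (a) the canonical ladder minus the
# blocked bonds plus one further rung, and (b) shifted antiparallel
# registries (pairing offset by one or two residues) whose donors are all
# proline-free — the registry adjustment real proline-containing hairpins
# adopt. Each candidate carries the free-dihedral set needed to orient the
# participating carbonyls and amides.
candidate_registries <- function(spec, is_pro) {
  closure <- as.integer(spec$closure_residues)
  L <- length(is_pro)
  p <- spec$hbond_pairs
  if (!any(is_pro[p[, 2]]))
    return(list(list(pairs = p, free = closure)))

  cands <- list()
  # (a) canonical minus blocked bonds, plus one outward rung
  pf <- p[!is_pro[p[, 2]], , drop = FALSE]
  ext <- spec$hbond_pairs_ext
  ext <- ext[!is_pro[ext[, 2]], , drop = FALSE]
  free_a <- closure
  if (nrow(ext) > 0) {
    pf <- rbind(pf, ext)
    res <- unique(as.vector(ext))
    free_a <- sort(unique(c(closure, min(res), max(res) - 1, max(res))))
  }
  cands[[1]] <- list(pairs = pf, free = free_a)

  # (b) shifted registries: innermost pair (i0, S - i0), rungs two apart
  i_in <- p[1, 1]; j_in <- p[1, 2]
  s0 <- i_in + j_in
  n_rungs <- nrow(p) / 2
  for (shift in c(1, -1, 2, -2)) {
    for (di in 0:1) {
      i0 <- i_in - di
      S <- s0 + shift
      iset <- i0 - 2 * (seq_len(n_rungs) - 1)
      jset <- S - iset
      if (any(iset < 1) || any(jset > L) || any(jset <= max(closure)))
        next
      pairs <- cbind(as.vector(rbind(iset, jset)),
                     as.vector(rbind(jset, iset)))
      if (any(is_pro[pairs[, 2]])) next
      res <- unique(as.vector(pairs))
      extra <- setdiff(sort(unique(c(res, res - 1))), closure)
      cands[[length(cands) + 1]] <-
        list(pairs = pairs, free = sort(unique(c(closure, extra))))
    }
  }
  cands
}

# Dihedral-space closure refinement for one registry: the hairpin is zipped
# from the turn outwards (the descent first targets only the innermost
# cross-strand pair, then progressively adds the outer pairs, always with
# the steric penalty active), with deterministic turn-table restarts and
# seedless basin-hopping perturbations if the zip shears.
refine_one_registry <- function(phi, psi, spec, is_pro, registry,
                                max_iter = 500, n_hops = 8) {
  omega <- rep(180, length(phi))
  pairs <- registry$pairs
  free <- registry$free
  run <- function(p0, s0) {
    res <- NULL
    for (k in unique(c(seq(2, nrow(pairs), by = 2), nrow(pairs)))) {
      res <- .refine_closure_cpp(p0, s0, omega, is_pro, free,
                                 pairs[1:k, , drop = FALSE],
                                 max_iter = max_iter)
      p0 <- res$phi; s0 <- res$psi
    }
    res
  }
  res <- run(phi, psi)
  if (!res$converged) {
    tt <- turn_dihedral_table()
    for (k in seq_len(nrow(tt))) {
      p0 <- phi; s0 <- psi
      p0[spec$closure_residues] <- tt$phi[k]
      s0[spec$closure_residues] <- tt$psi[k]
      cand <- run(p0, s0)
      if (cand$objective < res$objective || cand$converged) res <- cand
      if (res$converged) break
    }
  }
  hop <- 0
  while (!res$converged && hop < n_hops) {
    hop <- hop + 1
    p0 <- res$phi; s0 <- res$psi
    j <- seq_along(free)
    p0[free] <- p0[free] + 20 * sin(9973 * hop + 7 * j)
    s0[free] <- s0[free] + 20 * sin(7919 * hop + 13 * j)
    cand <- .refine_closure_cpp(p0, s0, omega, is_pro, free, pairs,
                                max_iter = max_iter)
    if (cand$converged || cand$objective < res$objective) res <- cand
    if (!res$converged) res <- simplex_polish(res, spec, is_pro, registry)
  }
  if (!res$converged) res <- simplex_polish(res, spec, is_pro, registry)
  res
}

# Concerted-move polish: Nelder-Mead over the free dihedrals, which can
# rotate a strand as a near-rigid body where one-dihedral-at-a-time descent
# shears. Runs only when the descent has stalled short of full closure.
simplex_polish <- function(res, spec, is_pro, registry) {
  free <- registry$free
  pairs <- registry$pairs
  L <- length(res$phi)
  omega <- rep(180, L)
  unpack <- function(par) {
    phi <- res$phi; psi <- res$psi
    phi[free] <- par[seq_along(free)]
    psi[free] <- par[seq_along(free) + length(free)]
    list(phi = phi, psi = psi)
  }
  fn <- function(par) {
    d <- unpack(par)
    .closure_eval_cpp(d$phi, d$psi, omega, is_pro, pairs,
                      check_conv = FALSE)$objective
  }
  opt <- stats::optim(c(res$phi[free], res$psi[free]), fn,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-9))
  d <- unpack(opt$par)
  ev <- .closure_eval_cpp(d$phi, d$psi, omega, is_pro, pairs)
  # descend once more from the polished point
  fin <- .refine_closure_cpp(d$phi, d$psi, omega, is_pro, free, pairs,
                             max_iter = 500)
  if (fin$converged || fin$objective < min(ev$objective, res$objective))
    return(c(fin, list(registry = registry)))
  if (ev$converged || ev$objective < res$objective)
    return(list(phi = d$phi, psi = d$psi, objective = ev$objective,
                converged = ev$converged, registry = registry))
  res
}

# Refinement across candidate registries: the first registry that converges
# wins; callers may pin a registry (chosen once per motif) so that every
# conformer of an ensemble targets the same bond pattern.
refine_closure_dihedrals <- function(phi, psi, spec, is_pro,
                                     max_iter = 500, registry = NULL) {
  phi[is.na(phi)] <- 180; psi[is.na(psi)] <- 180
  if (!is.null(registry)) {
    # warm start near an already-closed base: plain descent almost always
    # reconverges; escalate to the polish and the full search only on stall
    omega <- rep(180, length(phi))
    res <- .refine_closure_cpp(phi, psi, omega, is_pro, registry$free,
                               registry$pairs, max_iter = max_iter)
    if (!res$converged) res <- simplex_polish(res, spec, is_pro, registry)
    if (!res$converged)
      res <- refine_one_registry(phi, psi, spec, is_pro, registry,
                                 max_iter = max_iter, n_hops = 2)
    res$registry <- registry
    return(res)
  }
  best <- NULL
  for (reg in candidate_registries(spec, is_pro)) {
    res <- refine_one_registry(phi, psi, spec, is_pro, reg,
                               max_iter = max_iter)
    res$registry <- reg
    if (is.null(best) || res$converged ||
        res$objective < best$objective) best <- res
    if (best$converged) break
  }
  best
}

#' Mixture specification for synthetic ensembles
#'
#' @param motifs List of [make_motif()] specs.
#' @param weights Non-negative mixture weights (normalised to sum to 1).
#' @param n Number of conformers.
#' @param seed Integer seed; identical seeds give bit-identical ensembles.
#' @param n_blocks Optional number of equal consecutive blocks used to
#'   emulate trajectory time blocks.
#' @return An object of class `MixtureSpec`.
#' @export
mixture_spec <- function(motifs, weights, n, seed = 1, n_blocks = NULL) {
  stopifnot(length(motifs) == length(weights), n >= 1)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("at least one weight must be positive")
  structure(list(motifs = motifs, weights = weights / sum(weights),
                 n = as.integer(n), seed = as.integer(seed),
                 n_blocks = n_blocks),
            class = "MixtureSpec")
}

#' Variant preset mixtures
#'
#' Super-family mixture weights emulating the reported per-variant fold
#' abundances of the IAPP monomer: pig/rat populate helix-coil (0.87) and
#' helix-hairpin (0.13); cat populates helix-coil (0.28), helix-hairpin
#' (0.25) and beta-hairpin (0.47); human populates helix-coil (0.15),
#' helix-hairpin (0.09) and beta-hairpin (0.75) (weights renormalised).
#'
#' @param variant One of `"pig"`, `"rat"`, `"cat"`, `"human"`.
#' @param n Number of conformers.
#' @param sigma Dihedral jitter (degrees).
#' @param seed Integer seed.
#' @param n_blocks Number of trajectory-style blocks (default 6).
#' @return A [mixture_spec()].
#' @export
variant_preset <- function(variant = c("human", "rat", "cat", "pig"),
                           n = 400, sigma = 3, seed = 1, n_blocks = 6) {
  variant <- match.arg(variant)
  w <- switch(variant,
              pig = c("helix-coil" = 0.87, "helix-hairpin" = 0.13),
              rat = c("helix-coil" = 0.87, "helix-hairpin" = 0.13),
              cat = c("helix-coil" = 0.28, "helix-hairpin" = 0.25,
                      "beta-hairpin" = 0.47),
              human = c("helix-coil" = 0.15, "helix-hairpin" = 0.09,
                        "beta-hairpin" = 0.75))
  motifs <- lapply(names(w), make_motif, sigma = sigma)
  mixture_spec(motifs, unname(w), n = n, seed = seed, n_blocks = n_blocks)
}

#' Sample a synthetic conformer ensemble from a motif mixture
#'
#' For each conformer a mixture component is drawn, every dihedral of the
#' motif's (pre-closed) canonical backbone is jittered by Normal(0, sigma),
#' the chain is rebuilt, and hairpin closure is re-refined. The generator is
#' fully deterministic for a given spec and seed; the calling session's RNG
#' state is left untouched.
#'
#' @param mix A [mixture_spec()].
#' @param seq A [peptide_sequence()]; defaults to the human IAPP preset.
#' @param times If `TRUE`, attach timestamps at the 0.045 ns snapshot
#'   interval of a replica trajectory.
#' @return An [ensemble()] with per-conformer ground-truth labels in
#'   `$truth` and a logical attribute `converged` flagging hairpin closures.
#' @export
sample_ensemble <- function(mix, seq = iapp_sequence("human"), times = FALSE) {
  stopifnot(inherits(mix, "MixtureSpec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(mix$seed)

  L <- length(seq$residues)
  is_pro <- seq$residues == "P"
  k <- length(mix$motifs)
  comp <- sample.int(k, mix$n, replace = TRUE, prob = mix$weights)

  # pre-close each motif's canonical dihedrals once
  base <- lapply(mix$motifs, function(m) {
    if (is.null(m$closure_residues))
      return(list(phi = m$phi, psi = m$psi, converged = TRUE))
    refine_closure_dihedrals(m$phi, m$psi, m, is_pro)
  })

  confs <- vector("list", mix$n)
  converged <- logical(mix$n)
  for (i in seq_len(mix$n)) {
    m <- mix$motifs[[comp[i]]]
    best <- NULL
    best_md <- -Inf
    # redraw the jitter (continuing the seeded stream) if the built
    # conformer contains a steric clash; keep the least-clashing attempt
    for (attempt in 1:20) {
      phi <- base[[comp[i]]]$phi + stats::rnorm(L, 0, m$sigma)
      psi <- base[[comp[i]]]$psi + stats::rnorm(L, 0, m$sigma)
      conv <- TRUE
      if (!is.null(m$closure_residues) && any(m$sigma > 0)) {
        res <- refine_closure_dihedrals(phi, psi, m, is_pro,
                                        registry = base[[comp[i]]]$registry)
        phi <- res$phi; psi <- res$psi; conv <- res$converged
      }
      cf <- build_chain(seq, phi, psi, label = paste0("conf_", i))
      md <- min(stats::dist(flatten_atoms(cf)$xyz))
      if (md > best_md) {
        best <- cf
        best_md <- md
        converged[i] <- conv
      }
      if (best_md >= 0.5) break
    }
    confs[[i]] <- best
  }
  e <- ensemble(confs, seq,
                times = if (times) (seq_len(mix$n) - 1) * 0.045,
                truth = vapply(mix$motifs, `[[`, "", "label")[comp])
  attr(e, "converged") <- converged
  e
}
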