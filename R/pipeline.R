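#' Pipeline run configuration
#'
#' @param input A variant preset name (`"human"`, `"rat"`, `"cat"`, `"pig"`),
#'   a [mixture_spec()], a path to a multi-model PDB file, or an
#'   [ensemble()].
#' @param sequence A [peptide_sequence()]; defaults to the matching variant
#'   preset sequence, or human IAPP.
#' @param n,sigma Generator size and dihedral jitter (degrees), used when
#'   `input` is a preset name.
#' @param seed Integer seed for the generator.
#' @param cutoff Clustering RMSD cutoff (A, default 3.0).
#' @param min_fraction,max_families Family report thresholds.
#' @param ss_mode Secondary-structure mode (`"hbond"` or `"dihedral"`).
#' @param granularity Super-family labelling granularity
#'   ([classify_families()]).
#' @param align_range RMSF alignment range (default 1:17).
#' @param n_blocks,last_k Block-statistics settings (defaults 6 and 3).
#' @param solvation Compute the solvation report (slowest stage; `TRUE` by
#'   default).
#' @param solv Solvation parameters ([solv_params()]).
#' @param out_dir Output directory for report tables, or `NULL` to skip
#'   writing.
#' @return A `RunConfig` list.
#' @export
run_config <- function(input = "human", sequence = NULL, n = 400, sigma = 3,
                       seed = 1, cutoff = 3.0, min_fraction = 0.01,
                       max_families = 15, ss_mode = "hbond",
                       granularity = "centroid", align_range = 1:17,
                       n_blocks = 6, last_k = 3, solvation = TRUE,
                       solv = solv_params(), out_dir = NULL) {
  stopifnot(cutoff > 0, min_fraction >= 0, min_fraction <= 1,
            max_families >= 1, n_blocks >= 1, last_k >= 2,
            last_k <= n_blocks, n >= 1, sigma >= 0)
  structure(list(input = input, sequence = sequence, n = n, sigma = sigma,
                 seed = seed, cutoff = cutoff, min_fraction = min_fraction,
                 max_families = max_families, ss_mode = ss_mode,
                 granularity = granularity, align_range = align_range,
                 n_blocks = n_blocks, last_k = last_k,
                 solvation = solvation, solv = solv, out_dir = out_dir),
            class = "RunConfig")
}

resolve_input <- function(cfg) {
  input <- cfg$input
  if (inherits(input, "Ensemble")) return(input)
  if (inherits(input, "MixtureSpec")) {
    seq <- if (is.null(cfg$sequence)) iapp_sequence("human") else cfg$sequence
    return(sample_ensemble(input, seq))
  }
  if (is.character(input) && length(input) == 1) {
    if (input %in% c("human", "rat", "cat", "pig")) {
      mix <- variant_preset(input, n = cfg$n, sigma = cfg$sigma,
                            seed = cfg$seed, n_blocks = cfg$n_blocks)
      seq <- if (is.null(cfg$sequence)) iapp_sequence(input) else cfg$sequence
      return(sample_ensemble(mix, seq))
    }
    if (is.null(cfg$sequence))
      stop("a sequence is required to read an ensemble from ", input)
    return(read_ensemble(input, cfg$sequence))
  }
  stop("unsupported input")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full ensemble-characterization pipeline
#'
#' Generate (or read) an ensemble, assign secondary structure, compute the
#' pairwise C-alpha RMSD matrix, cluster into structural families at the
#' configured cutoff, merge into super-families, compute per-super-family
#' RMSF profiles and (optionally) the solvation report, and return the
#' report bundle. With `out_dir` set, writes the report tables:
#' class fractions, per-residue propensities, super-family abundances,
#' RMSF per super-family, the solvation table, centroid PDBs, and a JSON
#' run manifest. Identical configuration and seed give byte-identical
#' outputs.
#'
#' @param cfg A [run_config()].
#' @return A list with elements `ensemble`, `profile`, `clusters`,
#'   `families`, `labels`, `abundance`, `rmsf`, `solvation`, `manifest`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "RunConfig"))
  e <- pipeline_stage("generate", resolve_input(cfg))
  n <- length(e)
  prof <- pipeline_stage("assign-ss", ss_profile(e, mode = cfg$ss_mode))
  m <- pipeline_stage("rmsd", rmsd_matrix(e))
  cl <- pipeline_stage("cluster", daura_cluster(m, cutoff = cfg$cutoff))
  fams <- top_families(cl, cfg$min_fraction, cfg$max_families)
  labels <- pipeline_stage("classify",
                           classify_families(cl, prof$ss, cfg$granularity))
  blocks <- make_blocks(n, cfg$n_blocks)
  abundance <- pipeline_stage("abundance",
                              superfamily_abundance(labels, blocks,
                                                    cfg$last_k))
  # representative centroid per label: centroid of its largest family
  abundance$centroid <- vapply(abundance$label, function(lab) {
    for (f in cl$families) {
      flab <- classify_superfamily(prof$ss[f$centroid, ])
      if (flab == lab) return(f$centroid)
    }
    NA_integer_
  }, 0L)
  rmsf_list <- pipeline_stage("rmsf",
                              suppressWarnings(
                                rmsf_by_superfamily(e, labels,
                                                    cfg$align_range)))
  solv_rep <- if (isTRUE(cfg$solvation))
    pipeline_stage("solvate",
                   solvation_report(e, labels, blocks, cfg$solv,
                                    cfg$last_k)) else NULL
  manifest <- list(
    package = "idpens",
    version = as.character(utils::packageVersion("idpens")),
    input = if (is.character(cfg$input)) cfg$input else class(cfg$input),
    seed = cfg$seed, n_conformers = n, sigma = cfg$sigma,
    cutoff = cfg$cutoff, ss_mode = cfg$ss_mode,
    granularity = cfg$granularity, n_blocks = cfg$n_blocks,
    last_k = cfg$last_k, min_fraction = cfg$min_fraction,
    n_families = length(cl$families),
    n_top_families = length(fams$families),
    superfamily_labels = abundance$label,
    superfamily_counts = abundance$count)
  out <- list(ensemble = e, profile = prof, clusters = cl, families = fams,
              labels = labels, abundance = abundance, rmsf = rmsf_list,
              solvation = solv_rep, manifest = manifest)
  if (!is.null(cfg$out_dir))
    pipeline_stage("report", write_reports(out, cfg))
  out
}

# Fixed-format TSV writer so outputs are byte-identical across runs.
write_tsv_fixed <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
}

write_reports <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  frac <- data.frame(class = names(res$profile$fractions),
                     fraction = unname(res$profile$fractions))
  write_tsv_fixed(frac, p("class_fractions.tsv"))
  prop <- data.frame(residue = seq_len(nrow(res$profile$propensities)),
                     res$profile$propensities, check.names = FALSE)
  write_tsv_fixed(prop, p("residue_propensities.tsv"))
  write_tsv_fixed(as.data.frame(res$abundance), p("superfamily_abundance.tsv"))
  if (length(res$rmsf) > 0)
    write_tsv_fixed(do.call(rbind, res$rmsf), p("rmsf_by_superfamily.tsv"))
  if (!is.null(res$solvation))
    write_tsv_fixed(res$solvation, p("solvation_report.tsv"))
  fam <- data.frame(member = seq_len(res$clusters$n),
                    family = family_assignment(res$clusters))
  fam$is_centroid <- fam$member %in%
    vapply(res$clusters$families, `[[`, 0L, "centroid")
  write_tsv_fixed(fam, p("families.tsv"))
  cent <- res$abundance$centroid
  cent <- cent[!is.na(cent)]
  if (length(cent) > 0)
    write_ensemble(res$ensemble[cent], p("centroids.pdb"))
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}

#' Number of super-families present in an abundance report
#'
#' @param report A [superfamily_abundance()] data frame (or pipeline result).
#' @param min_fraction Minimum abundance for a label to count as present.
#' @return Integer count of labels.
#' @export
count_superfamilies <- function(report, min_fraction = 0.01) {
  if (is.list(report) && !is.data.frame(report) &&
      !is.null(report$abundance)) report <- report$abundance
  stopifnot(is.data.frame(report), "abundance" %in% names(report))
  sum(report$abundance >= min_fraction)
}
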