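#' Peptide sequence with termini chemistry and disulfide topology
#'
#' Constructs a `PeptideSequence`: an ordered vector of one-letter amino-acid
#' codes plus the chemical features shared by calcitonin-family peptides
#' (C-terminal amidation and an N-terminal disulfide bond).
#'
#' @param residues Character vector of one-letter codes, or a single string.
#' @param c_amidated Logical; is the C-terminus amidated?
#' @param disulfide Integer pair of 1-based residue indices forming a
#'   disulfide bond (both must be cysteine), or `NULL`.
#' @param name Variant label.
#' @return An object of class `PeptideSequence`.
#' @examples
#' seq <- peptide_sequence(strrep("A", 37), name = "polyA")
#' length(seq$residues)
#' @export
peptide_sequence <- function(residues, c_amidated = FALSE, disulfide = NULL,
                             name = "peptide") {
  if (length(residues) == 1 && nchar(residues) > 1)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(residues, aa)
  if (length(bad) > 0)
    stop("invalid amino-acid code(s): ", paste(unique(bad), collapse = ", "))
  L <- length(residues)
  if (!is.null(disulfide)) {
    disulfide <- as.integer(disulfide)
    if (length(disulfide) != 2 || disulfide[1] == disulfide[2] ||
        any(disulfide < 1) || any(disulfide > L))
      stop("disulfide must be two distinct residue indices within 1..", L)
    if (any(residues[disulfide] != "C"))
      stop("disulfide indices must both be cysteine")
    disulfide <- sort(disulfide)
  }
  structure(list(residues = residues, c_amidated = isTRUE(c_amidated),
                 disulfide = disulfide, name = name),
            class = "PeptideSequence")
}

#' @export
print.PeptideSequence <- function(x, ...) {
  cat("PeptideSequence:", x$name, "(", length(x$residues), "residues )\n")
  cat(" ", paste(x$residues, collapse = ""), "\n")
  if (x$c_amidated) cat("  C-terminus amidated\n")
  if (!is.null(x$disulfide))
    cat("  disulfide:", x$disulfide[1], "-", x$disulfide[2], "\n")
  invisible(x)
}

#' Bundled IAPP variant sequences
#'
#' Returns the 37-residue IAPP (amylin) sequence presets used by the variant
#' ensemble presets. All four share the calcitonin-family features: an
#' N-terminal Cys2-Cys7 disulfide bond and an amidated C-terminus. The human
#' and rat sequences are the standard published ones. The cat and pig entries
#' are synthetic stand-ins built from the human sequence and the key
#' substitutions that distinguish those variants (cat: S29P; pig: S20R and
#' N31K, plus rat-like prolines absent), adequate for backbone-level analyses
#' where only proline positions and charged side chains matter.
#'
#' @param variant One of `"human"`, `"rat"`, `"cat"`, `"pig"`.
#' @return A [peptide_sequence()].
#' @examples
#' iapp_sequence("human")
#' @export
iapp_sequence <- function(variant = c("human", "rat", "cat", "pig")) {
  variant <- match.arg(variant)
  seqs <- c(
    human = "KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY",
    rat   = "KCNTATCATQRLANFLVRSSNNLGPVLPPTNVGSNTY",
    # synthetic stand-ins (see description)
    cat   = "KCNTATCATQRLANFLVHSSNNFGAILSPTNVGSNTY",
    pig   = "KCNTATCATQRLANFLVHSRNNFGAILSSTKVGSNTY"
  )
  peptide_sequence(seqs[[variant]], c_amidated = TRUE, disulfide = c(2, 7),
                   name = paste0(variant, "_IAPP"))
}

#' Formal charge of a peptide under a protonation convention
#'
#' Sums per-residue and terminal charges under an explicit protonation
#' convention. The convention is a parameter because published per-variant
#' charges for IAPP cannot be reproduced by any single uniform rule; the
#' default treats Lys/Arg as +1, His as neutral, Asp/Glu as -1, the free
#' N-terminus as +1 and the C-terminus as -1 unless amidated (then 0).
#'
#' @param seq A [peptide_sequence()].
#' @param convention Named numeric vector of charges. Recognised names:
#'   the one-letter codes `K, R, H, D, E` and the terminal labels
#'   `nterm`, `cterm`.
#' @return Integer-valued total charge.
#' @examples
#' formal_charge(peptide_sequence(strrep("A", 5)))              # 0
#' formal_charge(peptide_sequence("KRH", c_amidated = TRUE))    # +3
#' @export
formal_charge <- function(seq,
                          convention = c(K = 1, R = 1, H = 0, D = -1, E = -1,
                                         nterm = 1, cterm = -1)) {
  stopifnot(inherits(seq, "PeptideSequence"))
  res_codes <- intersect(names(convention), c("K", "R", "H", "D", "E"))
  q <- sum(convention[res_codes][match(seq$residues, res_codes)],
           na.rm = TRUE)
  if ("nterm" %in% names(convention)) q <- q + convention[["nterm"]]
  if ("cterm" %in% names(convention) && !seq$c_amidated)
    q <- q + convention[["cterm"]]
  unname(q)
}

#' Read/write single-entry FASTA sequence records with feature tags
#'
#' The header carries `amidated=true/false` and `ss_bond=i-j` tags, e.g.
#' `>human_IAPP amidated=true ss_bond=2-7`.
#'
#' @param path File path.
#' @return `read_sequence()` returns a [peptide_sequence()];
#'   `write_sequence()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' write_sequence(iapp_sequence("rat"), f)
#' read_sequence(f)
#' @export
read_sequence <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!startsWith(lines[1], ">")) stop("not a FASTA record: ", path)
  header <- sub("^>", "", lines[1])
  fields <- strsplit(header, "\\s+")[[1]]
  name <- fields[1]
  tags <- fields[-1]
  amid <- any(grepl("^amidated=true$", tags, ignore.case = TRUE))
  ss <- grep("^ss_bond=", tags, value = TRUE)
  disulfide <- if (length(ss) == 1)
    as.integer(strsplit(sub("^ss_bond=", "", ss), "-")[[1]]) else NULL
  peptide_sequence(paste(lines[-1], collapse = ""), c_amidated = amid,
                   disulfide = disulfide, name = name)
}

#' @rdname read_sequence
#' @param seq A [peptide_sequence()] to write.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "PeptideSequence"))
  tags <- paste0("amidated=", tolower(seq$c_amidated))
  if (!is.null(seq$disulfide))
    tags <- c(tags, paste0("ss_bond=", seq$disulfide[1], "-",
                           seq$disulfide[2]))
  writeLines(c(paste(c(paste0(">", seq$name), tags), collapse = " "),
               paste(seq$residues, collapse = "")), path)
  invisible(path)
}
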