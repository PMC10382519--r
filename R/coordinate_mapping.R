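#' Protein residue index of a coding-sequence position
#'
#' Maps a 1-based coding-sequence (CDS) position to the 1-based index of the
#' codon containing it, i.e. `ceiling(cds_pos / 3)`. This is the arithmetic
#' linking HGVS c. and p. numbering: c.491 lies in codon 164, c.581 in
#' codon 194.
#'
#' @param cds_pos integer vector of 1-based CDS positions.
#' @return Integer protein positions.
#' @export
#' @examples
#' codon_index(491)  # 164
#' codon_index(581)  # 194
codon_index <- function(cds_pos) {
  cds_pos <- as.numeric(cds_pos)
  if (any(!is.finite(cds_pos)) || any(cds_pos < 1) || any(cds_pos != floor(cds_pos)))
    stop("cds_pos must be a positive integer")
  as.integer(ceiling(cds_pos / 3))
}

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V", Ter = "*")

normalize_aa <- function(x) {
  if (nchar(x) == 3L) {
    key <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
    out <- AA3[[key]]
    if (is.null(out)) stop("unknown three-letter amino acid code: ", x)
    return(out)
  }
  toupper(x)
}

#' Construct a CDS substitution
#'
#' @param cds_pos 1-based coding-sequence position.
#' @param ref,alt reference and alternate bases (A/C/G/T).
#' @return An object of class `fbp_cds_substitution`.
#' @export
cds_substitution <- function(cds_pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!is.numeric(cds_pos) || length(cds_pos) != 1L || cds_pos < 1 ||
      cds_pos != floor(cds_pos))
    stop("cds_pos must be a positive integer")
  if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T"))
    stop("ref and alt must be single DNA bases")
  if (ref == alt) stop("ref and alt must differ")
  structure(list(cds_pos = as.integer(cds_pos), ref = ref, alt = alt),
            class = "fbp_cds_substitution")
}

#' Construct a missense mutation
#'
#' @param wt,mut wild-type and mutant residues (one- or three-letter codes).
#' @param position 1-based protein residue index.
#' @return An object of class `fbp_missense`.
#' @export
missense_mutation <- function(wt, position, mut) {
  wt <- normalize_aa(wt); mut <- normalize_aa(mut)
  if (!is.numeric(position) || length(position) != 1L || position < 1 ||
      position != floor(position))
    stop("position must be a positive integer")
  if (wt == mut) stop("wild-type and mutant residues must differ for a missense mutation")
  structure(list(wt = wt, position = as.integer(position), mut = mut),
            class = "fbp_missense")
}

#' @export
format.fbp_missense <- function(x, ...) sprintf("p.%s%d%s", x$wt, x$position, x$mut)
#' @export
print.fbp_missense <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
#' @export
format.fbp_cds_substitution <- function(x, ...) sprintf("c.%d%s>%s", x$cds_pos, x$ref, x$alt)
#' @export
print.fbp_cds_substitution <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Parse simple HGVS substitution notation
#'
#' Accepts the simple substitution grammars `c.<pos><ref>><alt>` (e.g.
#' "c.491G>A", whitespace-tolerant: "c.491G > A") and `p.<aa><pos><aa>` with
#' one- or three-letter residues (e.g. "p.F194S", "p.Gly164Asp").
#' Deletion/insertion/duplication/splice notation is rejected with an
#' explicit unsupported-notation error.
#'
#' @param s an HGVS string.
#' @return An `fbp_cds_substitution` or `fbp_missense` object; `format()`
#'   on the result gives the canonical form.
#' @export
#' @examples
#' parse_hgvs("c.491G > A")
#' parse_hgvs("p.Gly164Asp")
parse_hgvs <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  raw <- s
  s <- gsub("[[:space:]]+", "", s)
  if (grepl("ins|del|dup|[+*]|_", s))
    stop("unsupported HGVS notation (only simple substitutions are handled): ", raw)
  m <- regmatches(s, regexec("^c\\.([0-9]+)([ACGTacgt])>([ACGTacgt])$", s))[[1]]
  if (length(m) == 4L)
    return(cds_substitution(as.integer(m[2]), m[3], m[4]))
  m <- regmatches(s, regexec("^p\\.([A-Za-z]{1}|[A-Za-z]{3})([0-9]+)([A-Za-z]{1}|[A-Za-z]{3})$", s))[[1]]
  if (length(m) == 4L)
    return(missense_mutation(m[2], as.integer(m[3]), m[4]))
  stop("unsupported HGVS notation (only simple substitutions are handled): ", raw)
}

#' Apply a CDS substitution and report the protein-level outcome
#'
#' Translates the affected codon before and after the substitution with the
#' standard genetic code and reports whether the change is missense,
#' synonymous or nonsense. The supplied CDS must start at the first codon
#' (position 1 = first base of the start codon) and have length divisible
#' by three.
#'
#' @param cds coding sequence: a character string or
#'   [Biostrings::DNAString].
#' @param sub an `fbp_cds_substitution`.
#' @param code named translation table mapping codon to one-letter residue;
#'   defaults to the standard genetic code.
#' @return A list with `outcome` one of "missense", "synonymous",
#'   "nonsense", the affected `codon_index`, `wt_codon`/`mut_codon`,
#'   `wt_aa`/`mut_aa`, and for missense outcomes `mutation`
#'   (an `fbp_missense`).
#' @export
#' @examples
#' apply_cds_substitution("ATGGGTTAA", cds_substitution(5, "G", "A"))
apply_cds_substitution <- function(cds, sub, code = as.list(Biostrings::GENETIC_CODE)) {
  stopifnot(inherits(sub, "fbp_cds_substitution"))
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3 (got ", n, " nt)")
  if (sub$cds_pos > n)
    stop("substitution position ", sub$cds_pos, " beyond CDS length ", n)
  found <- substr(cds, sub$cds_pos, sub$cds_pos)
  if (found != sub$ref)
    stop("reference base mismatch at c.", sub$cds_pos,
         ": expected ", sub$ref, ", CDS has ", found)
  ci <- codon_index(sub$cds_pos)
  start <- 3L * (ci - 1L) + 1L
  wt_codon <- substr(cds, start, start + 2L)
  mut_codon <- wt_codon
  substr(mut_codon, sub$cds_pos - start + 1L, sub$cds_pos - start + 1L) <- sub$alt
  wt_aa <- code[[wt_codon]]
  mut_aa <- code[[mut_codon]]
  if (is.null(wt_aa) || is.null(mut_aa))
    stop("codon not in translation table: ", wt_codon, "/", mut_codon)
  outcome <- if (wt_aa == mut_aa) "synonymous"
             else if (mut_aa == "*") "nonsense"
             else "missense"
  res <- list(outcome = outcome, codon_index = ci,
              wt_codon = wt_codon, mut_codon = mut_codon,
              wt_aa = wt_aa, mut_aa = mut_aa)
  if (outcome == "missense")
    res$mutation <- missense_mutation(wt_aa, ci, mut_aa)
  res
}

#' Read a coding sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used.
#' @return Upper-case character string of the sequence.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA file: ", path)
  toupper(as.character(seqs[[1]]))
}
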