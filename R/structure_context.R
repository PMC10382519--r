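#' Parse a PDB-format structure file
#'
#' Validates the ATOM/HETATM records (fixed-column PDB format) and parses
#' the file with `bio3d::read.pdb`, returning a light-weight atom table
#' preserving chain identifiers, residue numbering, insertion codes,
#' residue and atom names, elements and coordinates, including heteroatom
#' groups (ligands, metals).
#'
#' @param path path to a PDB-format file.
#' @return An object of class `fbp_structure`: list with `atoms`, a
#'   data.frame with columns `type`, `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `element`, `x`, `y`, `z`.
#' @export
parse_structure <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": truncated")
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (anyNA(coords))
      stop("malformed ATOM/HETATM record at line ", i, ": non-numeric coordinates")
  }
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(type = a$type, chain = a$chain, resno = a$resno,
                      insert = ifelse(is.na(a$insert), "", a$insert),
                      resid = a$resid, elety = a$elety,
                      element = toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                                               substr(trimws(a$elety), 1, 1),
                                               a$elesy)),
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source = path), class = "fbp_structure")
}

#' @export
print.fbp_structure <- function(x, ...) {
  cat(sprintf("fbp_structure: %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

heavy_atoms <- function(atoms) atoms[atoms$element != "H", , drop = FALSE]

select_residues <- function(atoms, target) {
  if (is.numeric(target)) atoms[atoms$resno %in% as.integer(target), , drop = FALSE]
  else atoms[atoms$resid %in% toupper(target), , drop = FALSE]
}

min_pairwise_dist <- function(a, b) {
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[, c("x", "y", "z")])
  # squared distances via the cross-product expansion; minimum only
  d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * tcrossprod(am, bm)
  sqrt(max(0, min(d2)))
}

#' Minimum heavy-atom distance from a residue to a target site
#'
#' Minimum Euclidean distance over all heavy-atom pairs (hydrogens
#' excluded) between the query residue and any atom of the target -- a set
#' of residue positions or a ligand residue name. By default the minimum is
#' taken over all chains, which captures inter-subunit pockets of the
#' dimer; `chains = "per_chain"` restricts query and target to the same
#' chain. A query residue that is itself part of the target set is at
#' distance 0 by convention.
#'
#' @param model an `fbp_structure`.
#' @param query_position integer residue number of the query.
#' @param target integer vector of residue positions, or character ligand
#'   residue name(s) (e.g. "AMP", "F6P", "MG").
#' @param chains "all" (default) or "per_chain".
#' @return Distance in Angstrom.
#' @export
min_distance <- function(model, query_position, target, chains = c("all", "per_chain")) {
  stopifnot(inherits(model, "fbp_structure"))
  chains <- match.arg(chains)
  atoms <- heavy_atoms(model$atoms)
  q <- atoms[atoms$resno == as.integer(query_position) & atoms$type == "ATOM", ,
             drop = FALSE]
  if (nrow(q) == 0L)
    stop("query residue ", query_position, " not present in the model")
  if (is.numeric(target) && as.integer(query_position) %in% as.integer(target))
    return(0.0)
  t_atoms <- select_residues(atoms, target)
  if (nrow(t_atoms) == 0L)
    stop("no target atoms found for: ", paste(target, collapse = ", "))
  if (chains == "all") return(min_pairwise_dist(q, t_atoms))
  shared <- intersect(unique(q$chain), unique(t_atoms$chain))
  if (length(shared) == 0L)
    stop("query and target share no chain under per-chain policy")
  min(vapply(shared, function(ch)
    min_pairwise_dist(q[q$chain == ch, ], t_atoms[t_atoms$chain == ch, ]),
    numeric(1)))
}

#' Structure context of a mutated residue
#'
#' Annotates a protein position with its minimum distances to the
#' substrate-binding, metal-binding and AMP sites, whether it is a pivotal
#' (annotated functional-site or linker) residue, whether it lies within
#' the substrate-pocket radius, and its secondary-structure label. The
#' distances come either from a parsed structure `model` or from a
#' precomputed `context_table` (see [fbp1_context_table()]).
#'
#' @param position protein residue position (query numbering).
#' @param sites an `fbp_sites` annotation.
#' @param model optional `fbp_structure`; used when supplied.
#' @param context_table optional precomputed per-position table with
#'   columns `position`, `min_dist_substrate`, `min_dist_metal`,
#'   `min_dist_amp`, `secondary_structure`.
#' @param radius substrate-pocket radius in Angstrom (default 12); a
#'   position is pocket-proximal when its minimum distance to the substrate
#'   site is at most `radius`.
#' @param numbering_offset added to `position` to obtain the structure's
#'   residue numbering (default 0).
#' @param chains chain policy for [min_distance()].
#' @return Object of class `fbp_context`: list with `position`,
#'   `min_dist_substrate`, `min_dist_metal`, `min_dist_amp`,
#'   `pocket_proximal`, `pivotal_site` (site name or NA), `is_pivotal`,
#'   `secondary_structure`.
#' @export
build_context <- function(position, sites, model = NULL, context_table = NULL,
                          radius = 12, numbering_offset = 0,
                          chains = "all") {
  stopifnot(inherits(sites, "fbp_sites"), length(position) == 1L)
  position <- as.integer(position)
  hit <- NA_character_
  for (s in names(sites)) if (position %in% sites[[s]]) { hit <- s; break }

  if (!is.null(model)) {
    struct_pos <- position + numbering_offset
    dist_to <- function(site) {
      if (is.null(sites[[site]])) return(NA_real_)
      min_distance(model, struct_pos, sites[[site]] + numbering_offset,
                   chains = chains)
    }
    d_sub <- dist_to("substrate"); d_met <- dist_to("metal"); d_amp <- dist_to("amp")
    ss <- "ND"
    if (!is.null(context_table) && position %in% context_table$position)
      ss <- context_table$secondary_structure[context_table$position == position]
  } else if (!is.null(context_table)) {
    row <- context_table[context_table$position == position, , drop = FALSE]
    if (nrow(row) == 0L)
      stop("context unavailable: position ", position,
           " is in neither the model nor the precomputed table")
    d_sub <- row$min_dist_substrate; d_met <- row$min_dist_metal
    d_amp <- row$min_dist_amp; ss <- row$secondary_structure
  } else {
    stop("context unavailable: supply a structure model or a precomputed table")
  }

  structure(list(position = position,
                 min_dist_substrate = d_sub, min_dist_metal = d_met,
                 min_dist_amp = d_amp,
                 pocket_proximal = is.finite(d_sub) && d_sub <= radius,
                 pivotal_site = hit, is_pivotal = !is.na(hit),
                 secondary_structure = ss),
            class = "fbp_context")
}

#' @export
print.fbp_context <- function(x, ...) {
  cat(sprintf(
    "residue %d: substrate %.1f A, metal %.1f A, AMP %.1f A | %s%s | %s\n",
    x$position, x$min_dist_substrate, x$min_dist_metal, x$min_dist_amp,
    if (x$is_pivotal) paste0("pivotal (", x$pivotal_site, ") ") else "",
    if (x$pocket_proximal) "pocket-proximal" else "pocket-distant",
    x$secondary_structure))
  invisible(x)
}
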