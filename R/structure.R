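#' Parse a PDB-format structure
#'
#' Reads `ATOM` records via `bio3d::read.pdb`.  Only the first `MODEL` of a
#' multi-model file is used; `HETATM` records (including waters) are dropped;
#' for alternate locations only blank or `'A'` altLoc atoms are kept.
#'
#' @param path Path to a PDB-format text file.
#' @return An object of class `pdb_structure`: a list with an `atoms`
#'   data.frame (`chain`, `resno`, `insert`, `resname`, `atom`, `element`,
#'   `x`, `y`, `z`) ordered as in the file.
#' @export
parse_pdb <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("input file not found: %s", path),
                        class = c("dmi_missing_input", "error")))
  }
  lines <- readLines(path, warn = FALSE)
  # keep only the first model: truncate at the first ENDMDL if MODEL present
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 0) {
    mend <- grep("^ENDMDL", lines)
    first_end <- if (length(mend) > 0) mend[1] else length(lines)
    lines <- lines[seq_len(first_end)]
  }
  if (!any(grepl("^ATOM", lines))) {
    stop("no ATOM records in ", path)
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  keep <- at$type == "ATOM" &
    (is.na(at$alt) | at$alt %in% c("", "A")) &
    !(at$resid %in% c("HOH", "WAT"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no usable ATOM records in ", path)
  element <- toupper(trimws(at$elesy))
  noel <- is.na(element) | element == ""
  if (any(noel)) {
    # fall back on the first alphabetic character of the atom name
    element[noel] <- substr(gsub("[^A-Za-z].*$", "",
                                 gsub("^[0-9]+", "", at$elety[noel])), 1, 1)
  }
  structure(list(atoms = data.frame(
    chain = at$chain,
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    atom = at$elety,
    element = element,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  ch <- split(residue_refs(x$atoms), x$atoms$chain)
  cat(sprintf("PDB structure: %d atoms, %d chain(s)\n",
              nrow(x$atoms), length(ch)))
  for (c in names(ch)) {
    cat(sprintf("  chain %s: %d residues\n", c, length(unique(ch[[c]]))))
  }
  invisible(x)
}

# Residue reference string "chain:resno" (+ insertion code when present).
residue_refs <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resno,
         ifelse(atoms$insert == "", "", atoms$insert))
}

#' Construct a template complex
#'
#' A PepX-style record: one peptide-recognition-domain (PRD) chain bound to
#' one peptide chain.  Usable templates are monomeric on the PRD side and
#' carry a peptide of 5-35 residues; [filter_templates()] enforces this.
#'
#' @param structure A `pdb_structure`.
#' @param template_id Identifier.
#' @param prd_chain,peptide_chain Chain ids in the structure.
#' @param multimer_flag TRUE when the PRD is part of a multimer binding a
#'   single peptide (such templates are excluded).
#' @return An object of class `template_complex`.
#' @export
template_complex <- function(structure, template_id, prd_chain,
                             peptide_chain, multimer_flag = FALSE) {
  stopifnot(inherits(structure, "pdb_structure"))
  at <- structure$atoms
  if (!prd_chain %in% at$chain) stop("PRD chain not in structure")
  if (!peptide_chain %in% at$chain) stop("peptide chain not in structure")
  pep <- at[at$chain == peptide_chain, , drop = FALSE]
  base::structure(list(template_id = template_id, structure = structure,
                 prd_chain = prd_chain, peptide_chain = peptide_chain,
                 peptide_length = length(unique(residue_refs(pep))),
                 multimer_flag = isTRUE(multimer_flag)),
            class = "template_complex")
}

#' Interfacial residues of a template PRD
#'
#' A PRD residue is interfacial when at least one of its atoms lies within
#' `cutoff` (default 4.5 Angstrom, inclusive) of any atom of the bound
#' peptide.
#'
#' @param template A `template_complex`.
#' @param cutoff Contact distance in Angstrom.
#' @return Character vector of PRD residue references (`chain:resno`).
#' @export
interfacial_residues <- function(template, cutoff = 4.5) {
  stopifnot(inherits(template, "template_complex"))
  at <- template$structure$atoms
  prd <- at[at$chain == template$prd_chain, , drop = FALSE]
  pep <- at[at$chain == template$peptide_chain, , drop = FALSE]
  if (nrow(pep) == 0) stop("empty peptide chain in template ",
                           template$template_id)
  d2 <- outer(prd$x, pep$x, "-")^2 + outer(prd$y, pep$y, "-")^2 +
    outer(prd$z, pep$z, "-")^2
  atom_min <- sqrt(apply(d2, 1, min))
  refs <- residue_refs(prd)
  res_min <- tapply(atom_min, factor(refs, levels = unique(refs)), min)
  names(res_min)[res_min <= cutoff]
}

# van der Waals radii (Angstrom); elements outside the table get the default
# with a one-shot warning.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
.vdw_default <- 1.80

# Deterministic golden-spiral point set on the unit sphere.
sphere_points <- function(n) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  theta <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

#' Per-residue solvent accessible surface area (Shrake-Rupley)
#'
#' Deterministic sphere-point sampling: each atom's solvent-accessible sphere
#' (van der Waals radius + probe) is covered with a fixed golden-spiral point
#' set and the accessible fraction is the share of points not buried inside
#' any neighbouring atom's sphere.  Residue ASA is the sum over its atoms.
#'
#' @param structure A `pdb_structure`.
#' @param probe Probe radius in Angstrom (water, 1.4).
#' @param n_points Sample points per atom.
#' @param chain Optional chain id: compute ASA for that chain's atoms in
#'   isolation (used for candidate models stored together with other chains).
#' @return Named numeric vector: residue reference -> ASA in Angstrom^2.
#' @export
residue_asa <- function(structure, probe = 1.4, n_points = 960,
                        chain = NULL) {
  stopifnot(inherits(structure, "pdb_structure"))
  at <- structure$atoms
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms to compute ASA for")
  r <- .vdw_radii[at$element]
  unknown <- unique(at$element[is.na(r)])
  if (length(unknown) > 0) {
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using default van der Waals radius ", .vdw_default)
    r[is.na(r)] <- .vdw_default
  }
  R <- r + probe
  pts <- sphere_points(n_points)
  xyz <- cbind(at$x, at$y, at$z)
  n <- nrow(at)
  asa_atom <- numeric(n)
  # neighbour prescreen on pairwise centre distances
  for (i in seq_len(n)) {
    p <- pts * R[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    dc2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(dc2 < (R[i] + R)^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > R[j]^2
      if (!any(acc)) break
    }
    asa_atom[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  refs <- residue_refs(at)
  res <- tapply(asa_atom, factor(refs, levels = unique(refs)), sum)
  setNames(as.numeric(res), names(res))
}

#' Surface residues by ASA threshold
#'
#' @inheritParams residue_asa
#' @param threshold Minimum ASA (Angstrom^2, inclusive) for a residue to
#'   count as surface-exposed.
#' @return Character vector of surface residue references, with the full ASA
#'   vector attached as attribute `"asa"`.
#' @export
accessible_surface <- function(structure, probe = 1.4, n_points = 960,
                               threshold = 10, chain = NULL) {
  asa <- residue_asa(structure, probe = probe, n_points = n_points,
                     chain = chain)
  base::structure(names(asa)[asa >= threshold], asa = asa)
}

#' Construct a structural alignment record
#'
#' Residue correspondence between a template PRD and a candidate-domain
#' model, with the protein structural distance (PSD) reported by the external
#' structural aligner.  Lower PSD means more similar; templates with PSD >=
#' 0.65 are unusable.
#'
#' @param template_id,protein_id Identifiers.
#' @param psd Non-negative structural distance.
#' @param correspondence Named character vector: template residue reference
#'   -> candidate-model residue reference.  Must be injective.
#' @return An object of class `struct_alignment`.
#' @export
struct_alignment <- function(template_id, protein_id, psd, correspondence) {
  psd <- as.numeric(psd)
  if (is.na(psd) || psd < 0) stop("PSD must be a non-negative number")
  cr <- as.character(correspondence)
  if (anyDuplicated(cr) || anyDuplicated(names(correspondence))) {
    stop("correspondence must be injective")
  }
  structure(list(template_id = as.character(template_id),
                 protein_id = as.character(protein_id),
                 psd = psd,
                 correspondence = setNames(cr, names(correspondence))),
            class = "struct_alignment")
}

#' Assign a PSD bin
#'
#' PSD values are grouped into two bins for the classifier: P1 for [0, 0.3]
#' and P2 for (0.3, 0.65); values of 0.65 and above are rejected (`NA`).
#'
#' @param psd Numeric vector of non-negative structural distances.
#' @return Character vector of `"P1"`, `"P2"` or `NA`.
#' @export
assign_psd_bin <- function(psd) {
  if (any(psd < 0)) stop("PSD must be non-negative")
  ifelse(psd <= 0.3, "P1", ifelse(psd < 0.65, "P2", NA_character_))
}

#' Interface coverage of a structural alignment
#'
#' Fraction of the template PRD's interfacial residues whose aligned
#' counterpart in the candidate model is surface-exposed; the alignment
#' passes when the fraction reaches `min_frac` (default 0.75, inclusive).
#'
#' @param aln A `struct_alignment`.
#' @param interfacial Character vector from [interfacial_residues()].
#' @param surface Character vector from [accessible_surface()] computed on
#'   the candidate model.
#' @param min_frac Minimum passing fraction.
#' @return List with `fraction` and logical `pass`.
#' @export
interface_coverage <- function(aln, interfacial, surface, min_frac = 0.75) {
  stopifnot(inherits(aln, "struct_alignment"))
  if (length(interfacial) == 0) {
    stop("degenerate template: empty interfacial set")
  }
  mapped <- aln$correspondence[interfacial]
  frac <- sum(!is.na(mapped) & mapped %in% surface) / length(interfacial)
  list(fraction = frac, pass = frac >= min_frac)
}

#' Filter usable template complexes
#'
#' Retains monomeric templates whose peptide is 5-35 residues long
#' (inclusive).
#'
#' @param templates List of `template_complex` objects.
#' @return The retained sublist.
#' @export
filter_templates <- function(templates) {
  keep <- vapply(templates, function(t) {
    !t$multimer_flag && t$peptide_length >= 5 && t$peptide_length <= 35
  }, logical(1))
  templates[keep]
}

#' Write a structure to PDB-format text
#'
#' Minimal ATOM-record writer used for synthetic fixtures.
#'
#' @param structure A `pdb_structure`.
#' @param path Output path; when `NULL` the lines are returned.
#' @return The lines (invisibly when written to a file).
#' @export
write_pdb <- function(structure, path = NULL) {
  at <- structure$atoms
  name4 <- ifelse(nchar(at$atom) < 4, sprintf(" %-3s", at$atom), at$atom)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)), name4, at$resname, at$chain, at$resno,
    at$x, at$y, at$z, at$element)
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
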