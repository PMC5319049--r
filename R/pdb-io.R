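# Fixed-column PDB input/output. The reader keeps the verbatim input lines
# so that the annotated writer can provably change nothing but the
# B-factor column (61-66) of ATOM records.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

# common modified residues mapped to their parent amino acid
.AA_MAP <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO",
             SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
             MLY = "LYS", M3L = "LYS")

#' Membrane frame descriptor
#'
#' The coordinate convention assumed throughout: the bilayer center is the
#' origin, the membrane normal is the z-axis, and the hydrophobic slab
#' extends over `|z| <= thickness/2` (PDBTM/OPM convention).
#'
#' @param thickness membrane thickness in angstroms (default 30).
#' @return object of class `membrane_frame` with fields `thickness`,
#'   `half_thickness`, `center`, `normal`.
#' @export
membrane_frame <- function(thickness = 30) {
  if (!is.numeric(thickness) || length(thickness) != 1 || thickness <= 0)
    stop("membrane thickness must be a positive scalar")
  structure(list(thickness = thickness, half_thickness = thickness / 2,
                 center = c(0, 0, 0), normal = c(0, 0, 1)),
            class = "membrane_frame")
}

.num_field <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  bad <- is.na(v) & nzchar(trimws(s))
  bad <- bad | !nzchar(trimws(s))
  if (any(bad))
    stop(sprintf("malformed %s field in PDB line %d", what, lineno[bad][1]),
         call. = FALSE)
  v
}

#' Read a membrane-frame PDB structure
#'
#' Parses fixed-column ATOM records into a residue-indexed structure. The
#' file is expected to be in the membrane coordinate frame (see
#' [membrane_frame()]); coordinates are taken verbatim. Waters, ligands and
#' other non-amino-acid HETATM records are skipped; common modified
#' residues (MSE, SEP, ...) are mapped to their parent amino acid when a
#' C-alpha is present. Only the first MODEL of a multi-model file is read,
#' and for alternate locations the first-listed conformer is kept.
#'
#' @param x path to a PDB file, or a character vector of PDB lines.
#' @param thickness membrane thickness in angstroms (default 30).
#' @return object of class `membrane_protein`: list with `atom` (one row
#'   per atom: name, alt, resname, chain, resseq, icode, x, y, z, b,
#'   element, line, reskey), `residues` (one row per residue: reskey,
#'   chain, resseq, icode, resname, has_ca), `frame`, and `raw_lines` (the
#'   verbatim input).
#' @export
read_membrane_pdb <- function(x, thickness = 30) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE)
  else if (length(x) == 1) strsplit(x, "\n", fixed = TRUE)[[1]]
  else x

  # first MODEL only
  ends <- which(substr(lines, 1, 6) == "ENDMDL")
  scope <- if (length(ends) > 0) seq_len(ends[1]) else seq_along(lines)

  rec <- substr(lines[scope], 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  idx <- scope[is_atom]
  if (length(idx) == 0) stop("no ATOM records found in PDB input", call. = FALSE)

  ln <- lines[idx]
  pad <- function(s, w) formatC(s, width = w, flag = "-")
  ln <- vapply(ln, function(s) if (nchar(s) < 80) pad(s, 80) else s, "",
               USE.NAMES = FALSE)

  atom <- data.frame(
    record  = trimws(substr(ln, 1, 6)),
    serial  = suppressWarnings(as.integer(substr(ln, 7, 11))),
    name    = trimws(substr(ln, 13, 16)),
    alt     = trimws(substr(ln, 17, 17)),
    resname = trimws(substr(ln, 18, 20)),
    chain   = substr(ln, 22, 22),
    resseq  = suppressWarnings(as.integer(substr(ln, 23, 26))),
    icode   = trimws(substr(ln, 27, 27)),
    x = NA_real_, y = NA_real_, z = NA_real_,
    b = suppressWarnings(as.numeric(substr(ln, 61, 66))),
    element = trimws(substr(ln, 77, 78)),
    line = idx,
    stringsAsFactors = FALSE
  )
  atom$x <- .num_field(substr(ln, 31, 38), idx, "x-coordinate")
  atom$y <- .num_field(substr(ln, 39, 46), idx, "y-coordinate")
  atom$z <- .num_field(substr(ln, 47, 54), idx, "z-coordinate")
  if (any(!nzchar(atom$name))) {
    bad <- which(!nzchar(atom$name))[1]
    stop(sprintf("empty atom name in PDB line %d", idx[bad]), call. = FALSE)
  }
  if (any(is.na(atom$resseq))) {
    bad <- which(is.na(atom$resseq))[1]
    stop(sprintf("malformed residue number in PDB line %d", idx[bad]), call. = FALSE)
  }
  atom$element[!nzchar(atom$element)] <-
    substr(gsub("[^A-Za-z]", "", atom$name[!nzchar(atom$element)]), 1, 1)

  # map modified residues, then keep amino acids only (drops waters/ligands)
  mapped <- atom$resname %in% names(.AA_MAP)
  if (any(mapped)) {
    warning(sprintf("mapped %d non-standard residue atoms to parent amino acids (%s)",
                    sum(mapped), paste(unique(atom$resname[mapped]), collapse = ", ")))
    atom$resname[mapped] <- .AA_MAP[atom$resname[mapped]]
    # selenium etc. in mapped residues: treat SE as S for downstream radii
    atom$name[atom$name == "SE"] <- "SD"
    atom$element[atom$element == "SE"] <- "S"
  }
  keep <- atom$resname %in% .AA3
  atom <- atom[keep, , drop = FALSE]
  if (nrow(atom) == 0) stop("no amino-acid ATOM records found", call. = FALSE)

  atom$reskey <- res_key(atom$chain, atom$resseq, atom$icode)

  # alternate locations: keep the first-listed conformer per atom
  dup <- duplicated(paste(atom$reskey, atom$name))
  atom <- atom[!dup, , drop = FALSE]
  rownames(atom) <- NULL

  rk <- unique(atom$reskey)
  first <- atom[match(rk, atom$reskey), ]
  has_ca <- vapply(rk, function(k) any(atom$reskey == k & atom$name == "CA"),
                   logical(1))
  residues <- data.frame(reskey = rk, chain = first$chain,
                         resseq = first$resseq, icode = first$icode,
                         resname = first$resname, has_ca = unname(has_ca),
                         stringsAsFactors = FALSE)
  rownames(residues) <- NULL
  if (!any(residues$has_ca))
    stop("structure contains no residue with a C-alpha atom", call. = FALSE)

  structure(list(atom = atom, residues = residues,
                 chains = unique(residues$chain),
                 frame = membrane_frame(thickness),
                 raw_lines = lines),
            class = "membrane_protein")
}

#' @export
print.membrane_protein <- function(x, ...) {
  cat(sprintf("membrane_protein: %d residues, %d atoms, %d chain(s) [%s]\n",
              nrow(x$residues), nrow(x$atom), length(x$chains),
              paste(x$chains, collapse = ",")))
  zr <- range(ca_coords(x)[, 3])
  cat(sprintf("  C-alpha z range: %.1f .. %.1f A (membrane |z| <= %.1f)\n",
              zr[1], zr[2], x$frame$half_thickness))
  invisible(x)
}

# coordinate matrix of C-alpha atoms, rownames = residue keys
ca_coords <- function(protein) {
  ca <- protein$atom[protein$atom$name == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$reskey
  m
}

# coordinates of one named atom of one residue (or NULL)
atom_coord <- function(protein, reskey, name) {
  i <- which(protein$atom$reskey == reskey & protein$atom$name %in% name)
  if (length(i) == 0) return(NULL)
  as.numeric(protein$atom[i[1], c("x", "y", "z")])
}

# normalise different label representations to a named factor over reskeys
.as_label_vector <- function(labels) {
  if (inherits(labels, "lipacc")) labels <- labels$labels
  if (is.data.frame(labels)) {
    v <- as.character(labels$label)
    names(v) <- labels$reskey
    return(v)
  }
  if (is.logical(labels)) {
    v <- ifelse(labels, "lipid_exposed", "buried")
    names(v) <- names(labels)
    return(v)
  }
  if (is.character(labels) || is.factor(labels)) {
    v <- as.character(labels)
    names(v) <- names(labels)
    return(v)
  }
  stop("cannot interpret labels; expected a lipacc object, data frame or named vector")
}

#' Write a B-factor annotated PDB
#'
#' Re-emits the verbatim input lines of a parsed structure with the
#' B-factor column (columns 61-66) of each amino-acid ATOM record replaced
#' by the residue's lipid-accessibility call: `50.00` for lipid-exposed
#' residues, `0.00` for buried ones. All atoms of a residue share its
#' value; every other column, and every non-ATOM line, is untouched.
#'
#' @param protein a `membrane_protein` from [read_membrane_pdb()].
#' @param labels per-residue labels: a `lipacc` classification object, a
#'   data frame with `reskey`/`label` columns, or a named character vector
#'   with values `"lipid_exposed"`/`"buried"`. `NULL` writes 0.00
#'   everywhere.
#' @param file optional path; when given the lines are written there.
#' @return (invisibly) the output lines.
#' @export
write_annotated_pdb <- function(protein, labels = NULL, file = NULL) {
  stopifnot(inherits(protein, "membrane_protein"))
  lv <- if (is.null(labels)) character(0) else .as_label_vector(labels)
  unknown <- setdiff(names(lv), protein$residues$reskey)
  if (length(unknown) > 0)
    stop(sprintf("label refers to unknown residue(s): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  out <- protein$raw_lines
  bval <- ifelse(lv[protein$atom$reskey] == "lipid_exposed", 50, 0)
  bval[is.na(bval)] <- 0
  repl <- sprintf("%6.2f", bval)
  for (i in seq_len(nrow(protein$atom))) {
    li <- protein$atom$line[i]
    s <- out[li]
    if (nchar(s) < 66) s <- formatC(s, width = 66, flag = "-")
    substr(s, 61, 66) <- repl[i]
    out[li] <- s
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' PyMOL coloring script for annotated structures
#'
#' Returns the static PyMOL script that colors a structure written by
#' [write_annotated_pdb()] in two bins: residues with B-factor 50
#' (lipid exposed) and residues with B-factor 0 (buried).
#'
#' @param file optional path to also write the script to.
#' @return (invisibly) the script text as a character vector of lines.
#' @export
write_color_script <- function(file = NULL) {
  txt <- c(
    "# color a structure by the lipid-accessibility B-factor channel:",
    "# B-factor set to 50 -> lipid exposed; set to 0 -> buried",
    "hide everything",
    "show cartoon",
    "set cartoon_transparency, 0.0",
    "select exposed_b50, b > 25",
    "select buried_b0, b < 25",
    "color orange, exposed_b50",
    "color gray70, buried_b0",
    "deselect",
    "bg_color white"
  )
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
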