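# Backbone-dihedral secondary-structure assignment and architecture
# (alpha-bundle vs beta-barrel) auto-detection. A dihedral window
# classifier with run-length smoothing stands in for a hydrogen-bond
# based assignment; it matches it on idealized geometry and keeps the
# package free of external binaries. Externally computed secondary
# structure strings can be supplied to bypass it.

# phi/psi per residue (NA at chain termini or missing backbone)
backbone_dihedrals <- function(protein) {
  res <- protein$residues
  n <- nrow(res)
  get3 <- function(i, nm) atom_coord(protein, res$reskey[i], nm)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    N <- get3(i, "N"); CA <- get3(i, "CA"); C <- get3(i, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1 && res$chain[i - 1] == res$chain[i]) {
      Cp <- get3(i - 1, "C")
      if (!is.null(Cp)) phi[i] <- dihedral(Cp, N, CA, C)
    }
    if (i < n && res$chain[i + 1] == res$chain[i]) {
      Nn <- get3(i + 1, "N")
      if (!is.null(Nn)) psi[i] <- dihedral(N, CA, C, Nn)
    }
  }
  data.frame(reskey = res$reskey, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

.helix_ok <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) &
    phi >= -145 & phi <= -35 & psi >= -70 & psi <= 50
}

.strand_ok <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) &
    phi >= -180 & phi <= -40 &
    ((psi >= 90 & psi <= 180) | (psi >= -180 & psi <= -170))
}

# label maximal TRUE-runs of at least min_run within each chain
.run_label <- function(ok, chain, min_run) {
  lab <- rep(FALSE, length(ok))
  for (ch in unique(chain)) {
    sel <- which(chain == ch)
    runs <- rle(ok[sel])
    pos <- cumsum(c(1, runs$lengths))
    for (r in seq_along(runs$lengths)) {
      if (runs$values[r] && runs$lengths[r] >= min_run)
        lab[sel[pos[r]:(pos[r + 1] - 1)]] <- TRUE
    }
  }
  lab
}

#' Assign per-residue secondary structure
#'
#' Classifies each residue as helix, strand or loop from its backbone
#' phi/psi dihedrals: helix for phi in \[-145, -35\] and psi in \[-70, 50\]
#' in runs of at least 4 residues; strand for phi in \[-180, -40\] and psi
#' in \[90, 180\] or \[-180, -170\] in runs of at least 3; everything else
#' (including residues with missing backbone atoms) is loop. A chain
#' terminus with an undefined dihedral inherits the adjacent run's label
#' when its remaining defined dihedral fits that run's window.
#'
#' @param protein a `membrane_protein`.
#' @param ss optional externally computed secondary structure: a character
#'   vector over the H/E/L (or H/E/C) alphabet, one letter per residue in
#'   order, or a single string; when given it bypasses the dihedral
#'   classifier.
#' @return named character vector (`"helix"`, `"strand"`, `"loop"`) over
#'   residue keys.
#' @export
assign_secondary_structure <- function(protein, ss = NULL) {
  res <- protein$residues
  n <- nrow(res)
  if (!is.null(ss)) {
    if (length(ss) == 1 && nchar(ss) > 1) ss <- strsplit(ss, "")[[1]]
    if (length(ss) != n)
      stop(sprintf("secondary structure string has %d letters for %d residues",
                   length(ss), n))
    out <- c(H = "helix", E = "strand", L = "loop", C = "loop")[toupper(ss)]
    if (any(is.na(out))) stop("secondary structure string: unknown letter")
    names(out) <- res$reskey
    return(out)
  }

  d <- backbone_dihedrals(protein)
  hok <- .helix_ok(d$phi, d$psi)
  sok <- .strand_ok(d$phi, d$psi)
  helix <- .run_label(hok, res$chain, 4)
  strand <- .run_label(sok & !helix, res$chain, 3)

  out <- rep("loop", n)
  out[helix] <- "helix"
  out[strand] <- "strand"

  # chain termini with one undefined dihedral: join the adjacent run when
  # the defined dihedral fits its window
  undef <- which(is.na(d$phi) | is.na(d$psi))
  for (i in undef) {
    nb <- c(if (i > 1 && res$chain[i - 1] == res$chain[i]) i - 1,
            if (i < n && res$chain[i + 1] == res$chain[i]) i + 1)
    for (j in nb) {
      if (out[j] == "helix" &&
          (is.na(d$phi[i]) || (d$phi[i] >= -145 && d$phi[i] <= -35)) &&
          (is.na(d$psi[i]) || (d$psi[i] >= -70 && d$psi[i] <= 50)) &&
          !(is.na(d$phi[i]) && is.na(d$psi[i]))) {
        out[i] <- "helix"; break
      }
      if (out[j] == "strand" &&
          (is.na(d$phi[i]) || (d$phi[i] >= -180 && d$phi[i] <= -40)) &&
          (is.na(d$psi[i]) ||
             ((d$psi[i] >= 90 & d$psi[i] <= 180) || (d$psi[i] >= -180 & d$psi[i] <= -170))) &&
          !(is.na(d$phi[i]) && is.na(d$psi[i]))) {
        out[i] <- "strand"; break
      }
    }
  }
  names(out) <- res$reskey
  out
}

#' Auto-detect the membrane-facing architecture
#'
#' Votes over the secondary structure of membrane-embedded residues
#' (`|z(CA)| <= half_thickness`): more helix than strand gives an
#' alpha-helical bundle, more strand than helix a beta-barrel. A tie, or
#' no helix/strand residues at all, raises an error instructing the caller
#' to set the type manually (the classifier accepts a user override that
#' always wins over auto-detection).
#'
#' @param protein a `membrane_protein`.
#' @param ss per-residue secondary structure from
#'   [assign_secondary_structure()]; computed when omitted.
#' @param frame a `membrane_frame`; defaults to the protein's.
#' @return `"alpha"` or `"beta"`, with attribute `source = "auto"`.
#' @export
detect_protein_type <- function(protein, ss = NULL, frame = protein$frame) {
  if (is.null(ss)) ss <- assign_secondary_structure(protein)
  ca <- ca_coords(protein)
  z <- ca[, 3]
  mem <- rownames(ca)[abs(z) <= frame$half_thickness]
  v <- ss[mem]
  nh <- sum(v == "helix"); ns <- sum(v == "strand")
  if (nh == ns)
    stop(paste("architecture auto-detection failed (helix and strand counts",
               "in the membrane are equal or both zero); set the protein type",
               "manually with type = \"alpha\" or type = \"beta\""),
         call. = FALSE)
  structure(if (nh > ns) "alpha" else "beta", source = "auto")
}
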