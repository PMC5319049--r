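# Shared helpers: tiny hand-built PDB fragments, derived geometric
# fixtures, and brute-force geometry oracles kept deliberately
# independent of the package's own algorithms.

# format a minimal fixed-column PDB from an atom table
tiny_pdb <- function(atoms) {
  lines <- character(0)
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    nm <- as.character(a$name)
    name4 <- if (nchar(nm) < 4) paste0(" ", formatC(nm, width = 3, flag = "-")) else nm
    el <- substr(gsub("[0-9]", "", nm), 1, 1)
    lines <- c(lines, sprintf(
      "ATOM  %5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, name4, if (is.null(a$alt)) " " else as.character(a$alt),
      as.character(a$resname), as.character(a$chain), a$resseq, " ",
      a$x, a$y, a$z, 1, 0, el))
  }
  c(lines, "END")
}

# a 3-residue single-chain backbone fragment
fragment_pdb <- function() {
  at <- expand.grid(name = c("N", "CA", "C", "O"), resseq = 1:3,
                    stringsAsFactors = FALSE)
  at$chain <- "A"; at$resname <- "ALA"
  at$x <- at$resseq * 3.0 + c(0, 0.5, 1.0, 1.5)
  at$y <- c(0, 1, 0, -1)[match(at$name, c("N", "CA", "C", "O"))]
  at$z <- 0
  tiny_pdb(at)
}

# two antiparallel crossing helices joined into one chain (a hairpin)
hairpin_pdb <- function() {
  base <- lipacc:::.align_chain_z(lipacc:::.build_chain(28, -57, -47))
  down <- lipacc:::.transform_chain(base, lipacc:::rot_x(180), shift = c(9, 0, 0))
  merged <- c(base, down)
  lipacc:::.chains_to_pdb(list(merged))
}

# a helix lying flat in the lower leaflet (no membrane crossing)
surface_helix_pdb <- function() {
  base <- lipacc:::.align_chain_z(lipacc:::.build_chain(28, -57, -47))
  flat <- lipacc:::.transform_chain(
    base, lipacc:::rot_between(c(0, 0, 1), c(1, 0, 0)), shift = c(0, 0, -10))
  lipacc:::.chains_to_pdb(list(flat))
}

# rotate all ATOM coordinates of PDB lines about the z-axis (degrees)
rotate_pdb_z <- function(lines, theta) {
  th <- theta * pi / 180
  vapply(lines, function(s) {
    if (substr(s, 1, 6) != "ATOM  " && substr(s, 1, 6) != "HETATM") return(s)
    x <- as.numeric(substr(s, 31, 38)); y <- as.numeric(substr(s, 39, 46))
    xn <- cos(th) * x - sin(th) * y
    yn <- sin(th) * x + cos(th) * y
    substr(s, 31, 38) <- sprintf("%8.3f", xn)
    substr(s, 39, 46) <- sprintf("%8.3f", yn)
    s
  }, "", USE.NAMES = FALSE)
}

# brute-force convex hull: a point is a hull vertex iff it is an endpoint
# of some edge having all other points strictly on its left
brute_hull_vertices <- function(P, eps = 1e-9) {
  n <- nrow(P)
  if (n < 3) return(seq_len(n))
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cr <- (P[j, 1] - P[i, 1]) * (P[, 2] - P[i, 2]) -
        (P[j, 2] - P[i, 2]) * (P[, 1] - P[i, 1])
      cr <- cr[-c(i, j)]
      if (all(cr > -eps)) { on_hull[i] <- TRUE; on_hull[j] <- TRUE }
    }
  }
  which(on_hull)
}

# fraction of membrane residues on which a classification agrees with the
# generator's ground truth
membrane_agreement <- function(fit, truth, protein) {
  ca <- lipacc:::ca_coords(protein)
  mem <- rownames(ca)[abs(ca[, 3]) <= protein$frame$half_thickness]
  p <- setNames(fit$labels$label, fit$labels$reskey)[mem]
  t <- setNames(truth$label, truth$reskey)[mem]
  mean(p == t)
}

# does the closed polygon P[idx, ] have properly crossing edges?
polygon_self_intersects <- function(P, idx, eps = 1e-9) {
  k <- length(idx)
  seg <- cbind(idx, c(idx[-1], idx[1]))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      sh <- length(intersect(seg[a, ], seg[b, ])) > 0
      if (sh) next
      if (lipacc:::.segments_cross(P[seg[a, 1], ], P[seg[a, 2], ],
                                   P[seg[b, 1], ], P[seg[b, 2], ], eps))
        return(TRUE)
    }
  }
  FALSE
}
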