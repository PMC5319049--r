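# Deterministic synthetic membrane-protein generators with geometric
# per-residue ground truth. Backbones are built from canonical internal
# coordinates (NeRF chain extension), so dihedral-based secondary
# structure is exact by construction; ground truth comes from the
# construction geometry (radial C-beta directions), never from running
# the classifier.

.BOND <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
              ca_cb = 1.53)
.ANGLE <- list(n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7,
               ca_c_o = 120.5, n_ca_cb = 110.5)

# build an n-residue backbone (N, CA, C, O, CB per residue); phi/psi may
# be scalars or per-residue vectors
.build_chain <- function(n, phi, psi, omega = 180) {
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  atoms <- vector("list", n)
  # seed the first residue in an arbitrary frame
  N1 <- c(0, 0, 0)
  CA1 <- c(.BOND$n_ca, 0, 0)
  th <- .ANGLE$n_ca_c * pi / 180
  C1 <- CA1 + .BOND$ca_c * c(-cos(th), sin(th), 0)
  atoms[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in 2:n) {
    prev <- atoms[[i - 1]]
    Ni <- nerf_place(prev$N, prev$CA, prev$C, .BOND$c_n, .ANGLE$ca_c_n, psi[i - 1])
    CAi <- nerf_place(prev$CA, prev$C, Ni, .BOND$n_ca, .ANGLE$c_n_ca, omega)
    Ci <- nerf_place(prev$C, Ni, CAi, .BOND$ca_c, .ANGLE$n_ca_c, phi[i])
    atoms[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  # carbonyl O anti to the next N; C-beta via a backbone torsion (a route
  # independent of the bisector construction used by pseudo_cbeta)
  for (i in seq_len(n)) {
    a <- atoms[[i]]
    a$O <- nerf_place(a$N, a$CA, a$C, .BOND$c_o, .ANGLE$ca_c_o,
                      if (i < n) psi[i] + 180 else -45)
    a$CB <- nerf_place(a$C, a$N, a$CA, .BOND$ca_cb, .ANGLE$n_ca_cb, 122.6)
    atoms[[i]] <- a
  }
  atoms
}

# rigidly transform a chain so its CA principal axis lies along +z
# (z increasing with residue index) and its CA centroid sits at xy = 0,
# z = 0
.align_chain_z <- function(atoms) {
  CA <- t(vapply(atoms, function(a) a$CA, numeric(3)))
  ctr <- colMeans(CA)
  pc <- stats::prcomp(CA, center = TRUE)
  axis <- pc$rotation[, 1]
  if (sum(axis * (CA[nrow(CA), ] - CA[1, ])) < 0) axis <- -axis
  Rm <- rot_between(axis, c(0, 0, 1))
  lapply(atoms, function(a) lapply(a, function(p) as.numeric(Rm %*% (p - ctr))))
}

.transform_chain <- function(atoms, Rm = diag(3), shift = c(0, 0, 0)) {
  lapply(atoms, function(a) lapply(a, function(p) as.numeric(Rm %*% p + shift)))
}

# format chains (list of per-residue atom lists) as PDB text
.chains_to_pdb <- function(chains, resnames = "ALA") {
  lines <- character(0)
  serial <- 1L
  for (ci in seq_along(chains)) {
    ch_id <- LETTERS[ci]
    atoms <- chains[[ci]]
    for (ri in seq_along(atoms)) {
      rn <- if (length(resnames) == 1) resnames else resnames[ri]
      for (nm in names(atoms[[ri]])) {
        p <- atoms[[ri]][[nm]]
        el <- substr(gsub("[0-9]", "", nm), 1, 1)
        name4 <- if (nchar(nm) < 4) paste0(" ", formatC(nm, width = 3, flag = "-"))
                 else nm
        lines <- c(lines, sprintf(
          "ATOM  %5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, " ", rn, ch_id, ri, " ", p[1], p[2], p[3], 1, 0, el))
        serial <- serial + 1L
      }
    }
    lines <- c(lines, sprintf("TER   %5d      %3s %s%4d", serial,
                              if (length(resnames) == 1) resnames
                              else resnames[length(atoms)],
                              ch_id, length(atoms)))
    serial <- serial + 1L
  }
  c(lines, "END")
}

.add_noise <- function(chains, noise_sd, seed) {
  if (noise_sd <= 0) return(chains)
  with_seed(seed, {
    lapply(chains, function(atoms) lapply(atoms, function(a)
      lapply(a, function(p) p + stats::rnorm(3, 0, noise_sd))))
  })
}

# spans + truth helpers operating on final chain coordinates
.fixture_spans <- function(chains, half = 15) {
  out <- list()
  for (ci in seq_along(chains)) {
    z <- vapply(chains[[ci]], function(a) a$CA[3], numeric(1))
    inm <- which(abs(z) <= half)
    if (length(inm) >= 5) {
      up <- z[max(inm)] > z[min(inm)]
      out[[length(out) + 1]] <- data.frame(
        chain = LETTERS[ci], start = min(inm), end = max(inm),
        orientation = if (up) "n_to_c_up" else "n_to_c_down",
        stringsAsFactors = FALSE)
    }
  }
  .new_span_set(do.call(rbind, out), source = "fixture")
}

#' Synthetic alpha-helical bundle with ground truth
#'
#' Builds an idealized bundle of vertical alpha-helices (phi = -57,
#' psi = -47, canonical bond geometry; backbone N/CA/C/O plus C-beta) in
#' the membrane coordinate frame: one central helix at the origin
#' surrounded by `n_units - 1` helices equally spaced on a ring, each
#' crossing the slab with C-alpha z spanning about +/-(half_thickness+5).
#' `n_units = 1` gives a single transmembrane helix.
#'
#' Ground truth comes from the construction geometry: central-helix
#' membrane residues are buried; a ring-helix membrane residue is lipid
#' exposed when its C-alpha to C-beta xy-direction points within 90
#' degrees of its helix's outward radial direction, buried otherwise. With
#' one or two helices every membrane residue is exposed (two crossing
#' helices cannot shield each other from lipid). Residues outside the
#' membrane are always buried.
#'
#' @param n_units number of helices (1 = single helix; default 9).
#' @param ring_radius ring radius in angstroms (default 12).
#' @param res_per_unit residues per helix (default: enough to span
#'   +/-20 A).
#' @param seed RNG seed for the coordinate noise (identical spec + seed
#'   gives byte-identical output).
#' @param noise_sd Gaussian coordinate noise in angstroms (default 0).
#' @return list with `protein` (a `membrane_protein`), `truth` (data frame
#'   `reskey`, `label`, `rationale`), `spans` (a `span_set`) and `pdb`
#'   (the PDB text lines).
#' @export
make_helical_bundle <- function(n_units = 9, ring_radius = 12,
                                res_per_unit = NULL, seed = 1, noise_sd = 0) {
  if (n_units < 1) stop("n_units must be >= 1")
  if (is.null(res_per_unit)) res_per_unit <- 28L
  base <- .align_chain_z(.build_chain(res_per_unit, phi = -57, psi = -47))

  chains <- vector("list", n_units)
  radial <- vector("list", n_units)
  if (n_units == 1) {
    chains[[1]] <- base
    radial[[1]] <- c(0, 0)
  } else {
    chains[[1]] <- base                     # central helix
    radial[[1]] <- c(0, 0)
    for (k in seq_len(n_units - 1)) {
      ang <- 360 * (k - 1) / (n_units - 1)
      ch <- base
      if (k %% 2 == 1) ch <- .transform_chain(ch, rot_x(180))  # antiparallel
      ch <- .transform_chain(ch, rot_z(ang),
                             shift = c(ring_radius * cos(ang * pi / 180),
                                       ring_radius * sin(ang * pi / 180), 0))
      chains[[k + 1]] <- ch
      radial[[k + 1]] <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    }
  }
  chains <- .add_noise(chains, noise_sd, seed)

  pdb <- .chains_to_pdb(chains)
  protein <- suppressWarnings(read_membrane_pdb(pdb))
  spans <- .fixture_spans(chains)

  truth <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    atoms <- chains[[ci]]
    z <- vapply(atoms, function(a) a$CA[3], numeric(1))
    in_mem <- abs(z) <= 15
    lab <- rep("buried", length(atoms))
    why <- rep("outside membrane", length(atoms))
    why[in_mem] <- "central helix: protein core"
    if (n_units <= 2) {
      # one or two crossing helices cannot shield each other from lipid
      lab[in_mem] <- "lipid_exposed"
      why[in_mem] <- "trivial span count: membrane region fully lipid exposed"
    } else if (ci > 1) {
      rdir <- radial[[ci]]
      cbdir <- t(vapply(atoms, function(a) (a$CB - a$CA)[1:2], numeric(2)))
      outward <- (cbdir[, 1] * rdir[1] + cbdir[, 2] * rdir[2]) > 0
      lab[in_mem & outward] <- "lipid_exposed"
      why[in_mem] <- ifelse(outward[in_mem],
                            "ring helix: C-beta within 90 deg of outward radial",
                            "ring helix: C-beta faces bundle interior")
    }
    data.frame(reskey = res_key(LETTERS[ci], seq_along(atoms)),
               label = lab, rationale = why, stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(protein = protein, truth = truth, spans = spans, pdb = pdb)
}

#' Synthetic single transmembrane helix
#'
#' Convenience wrapper for [make_helical_bundle()] with `n_units = 1`.
#' @param ... passed to [make_helical_bundle()].
#' @export
make_single_helix <- function(...) make_helical_bundle(n_units = 1, ...)

#' Synthetic beta-barrel with ground truth
#'
#' Builds `n_units` idealized vertical beta-strands (phi = -120,
#' psi = +130) on a cylinder whose radius follows from the strand count at
#' 4.4 A inter-strand spacing, alternating strand direction
#' (antiparallel). Each strand is oriented so its even-residue C-beta
#' vectors point radially outward; along a strand the C-betas then
#' alternate outward/inward, which defines the ground truth: outward
#' C-beta means lipid exposed, inward means lumen-facing and buried.
#'
#' @param n_units number of strands (>= 8; default 8).
#' @param res_per_unit residues per strand (default 13, spanning about
#'   +/-20 A at ~3.4 A rise per residue).
#' @param seed,noise_sd as in [make_helical_bundle()].
#' @return list with `protein`, `truth`, `spans`, `pdb` as in
#'   [make_helical_bundle()].
#' @export
make_beta_barrel <- function(n_units = 8, res_per_unit = 13, seed = 1,
                             noise_sd = 0) {
  if (n_units < 8) stop("a beta-barrel needs at least 8 strands")
  base <- .align_chain_z(.build_chain(res_per_unit, phi = -120, psi = 130))

  # orient the pleat: mean even-residue C-beta xy-direction -> +x
  cbdir <- t(vapply(base, function(a) (a$CB - a$CA)[1:2], numeric(2)))
  even <- seq(2, length(base), by = 2)
  mdir <- colMeans(cbdir[even, , drop = FALSE])
  base <- .transform_chain(base, rot_z(-atan2(mdir[2], mdir[1]) * 180 / pi))

  radius <- n_units * 4.4 / (2 * pi)
  chains <- vector("list", n_units)
  for (k in seq_len(n_units)) {
    ang <- 360 * (k - 1) / n_units
    ch <- base
    if (k %% 2 == 0) ch <- .transform_chain(ch, rot_x(180))
    # rotation about x flips the outward direction to -x for odd pleats;
    # re-orient so even-residue C-betas still point to +x
    if (k %% 2 == 0) {
      cb2 <- t(vapply(ch, function(a) (a$CB - a$CA)[1:2], numeric(2)))
      m2 <- colMeans(cb2[even, , drop = FALSE])
      ch <- .transform_chain(ch, rot_z(-atan2(m2[2], m2[1]) * 180 / pi))
    }
    ch <- .transform_chain(ch, rot_z(ang),
                           shift = c(radius * cos(ang * pi / 180),
                                     radius * sin(ang * pi / 180), 0))
    chains[[k]] <- ch
  }
  chains <- .add_noise(chains, noise_sd, seed)

  pdb <- .chains_to_pdb(chains)
  protein <- suppressWarnings(read_membrane_pdb(pdb))
  spans <- .fixture_spans(chains)

  truth <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    atoms <- chains[[ci]]
    z <- vapply(atoms, function(a) a$CA[3], numeric(1))
    in_mem <- abs(z) <= 15
    ca_xy <- t(vapply(atoms, function(a) a$CA[1:2], numeric(2)))
    cbd <- t(vapply(atoms, function(a) (a$CB - a$CA)[1:2], numeric(2)))
    rn <- sqrt(rowSums(ca_xy^2))
    outward <- rowSums(cbd * ca_xy / pmax(rn, 1e-9)) > 0
    lab <- ifelse(in_mem & outward, "lipid_exposed", "buried")
    why <- ifelse(!in_mem, "outside membrane",
                  ifelse(outward, "C-beta points out of the barrel wall",
                         "C-beta faces the barrel lumen"))
    data.frame(reskey = res_key(LETTERS[ci], seq_along(atoms)),
               label = lab, rationale = why, stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(protein = protein, truth = truth, spans = spans, pdb = pdb)
}

#' Synthetic 2D point clouds for hull tests
#'
#' Deterministic planar clouds exercising the hull geometry in isolation.
#' Shapes: `square_with_center` (the four unit-square corners plus the
#' center), `C_shape` (an open annular arc, strongly concave), `ring`
#' (circle of radius 10) and `uniform_random` (`n` points uniform in the
#' `[0, 30]^2` box under `seed`).
#'
#' @param shape one of `"square_with_center"`, `"C_shape"`, `"ring"`,
#'   `"uniform_random"`.
#' @param n number of points for `uniform_random`.
#' @param seed RNG seed for `uniform_random`.
#' @return numeric matrix with columns `x`, `y`.
#' @export
make_point_cloud <- function(shape = c("square_with_center", "C_shape",
                                       "ring", "uniform_random"),
                             n = 50, seed = 1) {
  shape <- match.arg(shape)
  pts <- switch(shape,
    square_with_center = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5)),
    C_shape = {
      ang <- seq(40, 320, by = 12) * pi / 180
      do.call(rbind, lapply(c(6, 8, 10), function(r)
        cbind(r * cos(ang), r * sin(ang))))
    },
    ring = {
      ang <- seq(0, 350, by = 10) * pi / 180
      cbind(10 * cos(ang), 10 * sin(ang))
    },
    uniform_random = with_seed(seed,
      cbind(stats::runif(n, 0, 30), stats::runif(n, 0, 30)))
  )
  colnames(pts) <- c("x", "y")
  rownames(pts) <- paste0("p", seq_len(nrow(pts)))
  pts
}
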