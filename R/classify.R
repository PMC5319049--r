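# The classification pipeline: membrane slicing, the sidechain
# C-beta/C-alpha/COM angle rule, and the main per-residue
# lipid-accessibility classifier with its span-count exceptions.

#' Classifier parameters
#'
#' The five tunable parameters of the classifier plus the two span-count
#' thresholds of the exception rules. Defaults: slices 10 A thick (one
#' third of the 30 A slab, covering the two leaflets and the core),
#' concave-hull distance cutoff 10 A (about the C-alpha spacing across
#' neighboring helices), shell radius 6 A (about half a helix diameter),
#' angle cutoff 65 degrees for beta-barrels (below 90 to absorb barrel
#' curvature) and 45 degrees for small helical bundles. The membrane
#' thickness must be an integer multiple of the slice width so the last
#' slice is not left data-sparse.
#'
#' @param slice_width horizontal slice width, angstroms.
#' @param dist_cutoff concave-hull edge-length cutoff, angstroms.
#' @param shell_radius concave-shell capture radius, angstroms.
#' @param angle_cutoff_beta angle cutoff applied to beta-barrels, degrees.
#' @param angle_cutoff_small_helical angle cutoff applied to helical
#'   bundles with few spans, degrees.
#' @param thickness membrane thickness, angstroms.
#' @param small_bundle_max_spans helical bundles with more spans than this
#'   use shell membership alone (default 7).
#' @param trivial_span_max with this many spans or fewer, every membrane
#'   residue is lipid exposed (default 2).
#' @return object of class `classifier_params`.
#' @export
classifier_params <- function(slice_width = 10, dist_cutoff = 10,
                              shell_radius = 6, angle_cutoff_beta = 65,
                              angle_cutoff_small_helical = 45,
                              thickness = 30, small_bundle_max_spans = 7,
                              trivial_span_max = 2) {
  num1 <- function(x, nm, lo = 0, open_lo = TRUE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        (open_lo && x <= lo) || (!open_lo && x < lo))
      stop(sprintf("%s must be a %s %s", nm,
                   if (open_lo) "positive" else "non-negative", "number"),
           call. = FALSE)
    as.numeric(x)
  }
  p <- list(
    slice_width = num1(slice_width, "slice_width"),
    dist_cutoff = num1(dist_cutoff, "dist_cutoff"),
    shell_radius = num1(shell_radius, "shell_radius", open_lo = FALSE),
    angle_cutoff_beta = num1(angle_cutoff_beta, "angle_cutoff_beta"),
    angle_cutoff_small_helical = num1(angle_cutoff_small_helical,
                                      "angle_cutoff_small_helical"),
    thickness = num1(thickness, "thickness"),
    small_bundle_max_spans = as.integer(small_bundle_max_spans),
    trivial_span_max = as.integer(trivial_span_max)
  )
  if (p$angle_cutoff_beta >= 180 || p$angle_cutoff_small_helical >= 180)
    stop("angle cutoffs must lie in (0, 180) degrees", call. = FALSE)
  ratio <- p$thickness / p$slice_width
  if (abs(ratio - round(ratio)) > 1e-8)
    stop(sprintf(paste("membrane thickness (%g A) must be an integer multiple",
                       "of the slice width (%g A)"),
                 p$thickness, p$slice_width), call. = FALSE)
  structure(p, class = "classifier_params")
}

#' @export
print.classifier_params <- function(x, ...) {
  cat(sprintf(paste0("classifier_params: slice %g A | dist cutoff %g A | ",
                     "shell %g A | angle %g/%g deg (beta/small bundle) | ",
                     "thickness %g A\n"),
              x$slice_width, x$dist_cutoff, x$shell_radius,
              x$angle_cutoff_beta, x$angle_cutoff_small_helical, x$thickness))
  invisible(x)
}

#' Cut the membrane region into horizontal slices
#'
#' Tiles the slab `[-half_thickness, +half_thickness]` with slices of
#' `slice_width` along the membrane normal. Each membrane residue (by its
#' C-alpha z) falls in exactly one slice; slices are half-open
#' `[z_min, z_max)` except the last, which is closed so residues exactly
#' at the upper boundary are kept. Residues with `|z| > half_thickness`
#' belong to no slice.
#'
#' @param protein a `membrane_protein`.
#' @param params a `classifier_params`.
#' @return list of slices, each a list with `z_min`, `z_max`, `reskeys`,
#'   `points` (xy matrix, rownames = residue keys) and `com_xy` (C-alpha
#'   center of mass of the slice).
#' @export
slice_membrane <- function(protein, params = classifier_params()) {
  stopifnot(inherits(protein, "membrane_protein"),
            inherits(params, "classifier_params"))
  half <- params$thickness / 2
  nsl <- as.integer(round(params$thickness / params$slice_width))
  ca <- ca_coords(protein)
  z <- ca[, 3]
  idx <- floor((z + half) / params$slice_width) + 1
  idx[z == half] <- nsl                       # closed last slice
  idx[z < -half | z > half] <- NA

  lapply(seq_len(nsl), function(s) {
    sel <- which(!is.na(idx) & idx == s)
    pts <- ca[sel, 1:2, drop = FALSE]
    colnames(pts) <- c("x", "y")
    list(z_min = -half + (s - 1) * params$slice_width,
         z_max = -half + s * params$slice_width,
         reskeys = rownames(ca)[sel],
         points = pts,
         com_xy = if (length(sel) > 0) colMeans(pts) else c(NA_real_, NA_real_))
  })
}

#' Idealized C-beta position from backbone geometry
#'
#' Constructs a tetrahedral C-beta branch off the C-alpha from the N, CA
#' and C positions (bond length 1.53 A, tetrahedral branch angles,
#' L-amino-acid chirality). Used for glycines without a 2HA hydrogen and
#' for residues with missing sidechains.
#'
#' @param protein a `membrane_protein`.
#' @param reskey residue key.
#' @return numeric xyz position.
#' @export
pseudo_cbeta <- function(protein, reskey) {
  N <- atom_coord(protein, reskey, "N")
  CA <- atom_coord(protein, reskey, "CA")
  C <- atom_coord(protein, reskey, "C")
  if (is.null(N) || is.null(CA) || is.null(C))
    stop(sprintf("residue %s lacks the backbone atoms needed for a pseudo C-beta",
                 reskey), call. = FALSE)
  u <- vunit(N - CA); v <- vunit(C - CA)
  m <- -vunit(u + v)                 # in-plane bisector away from N and C
  nrm <- vunit(vcross(u, v))         # out-of-plane, sign fixes L chirality
  w <- vunit(0.620 * m + 0.785 * nrm)
  CA + 1.53 * w
}

# resolve the sidechain reference atom: CB, glycine 2HA, or pseudo C-beta
.sidechain_ref <- function(protein, reskey) {
  cb <- atom_coord(protein, reskey, "CB")
  if (!is.null(cb)) return(cb)
  res <- protein$residues
  rn <- res$resname[match(reskey, res$reskey)]
  if (identical(rn, "GLY")) {
    ha <- atom_coord(protein, reskey, c("2HA", "HA2"))
    if (!is.null(ha)) return(ha)
  }
  ok <- tryCatch(pseudo_cbeta(protein, reskey), error = function(e) NULL)
  ok
}

#' Sidechain orientation angle at the C-alpha
#'
#' The angle at the C-alpha vertex between the ray towards the sidechain
#' reference atom (C-beta; for glycine the 2HA hydrogen, or an idealized
#' pseudo C-beta when neither exists) and the ray towards the slice
#' center of mass, measured in the xy projection. Angles near 180 degrees
#' mean the sidechain points away from the slice interior (towards lipid);
#' near 0 degrees, towards the interior (pore or core).
#'
#' @param protein a `membrane_protein`.
#' @param reskey residue key.
#' @param com_xy numeric length-2 xy center of mass of the residue's slice.
#' @return angle in degrees in `[0, 180]`, or `NA` when undefined (zero
#'   length projection of either ray).
#' @export
sidechain_angle <- function(protein, reskey, com_xy) {
  ca <- atom_coord(protein, reskey, "CA")
  if (is.null(ca)) return(NA_real_)
  ref <- .sidechain_ref(protein, reskey)
  if (is.null(ref)) return(NA_real_)
  u <- (ref - ca)[1:2]
  v <- com_xy - ca[1:2]
  vangle(c(u, 0), c(v, 0))
}

#' Classify lipid-accessible residues of a membrane protein
#'
#' The main entry point. The membrane region (`|z(CA)| <= thickness/2`)
#' is cut into horizontal slices; per slice the projected C-alpha points
#' yield a convex hull, a concave hull (distance cutoff) and a concave
#' shell (shell radius). Residues in the concave shell are lipid exposed,
#' with three exceptions: (1) with `trivial_span_max` (2) or fewer
#' transmembrane spans, every membrane residue is exposed; (2) in
#' beta-barrels a shell residue is exposed only when its sidechain angle
#' ([sidechain_angle()]) exceeds `angle_cutoff_beta` (65 degrees), which
#' separates lumen-facing from lipid-facing sidechains; (3) in helical
#' bundles with `small_bundle_max_spans` (7) or fewer spans the same test
#' is applied at `angle_cutoff_small_helical` (45 degrees) to counter the
#' shell's over-prediction in small bundles. Comparisons with the angle
#' cutoff are strict; an undefined angle (or missing sidechain atoms while
#' an angle rule is active) leaves the residue buried. Residues outside
#' the membrane are always buried.
#'
#' @param protein a `membrane_protein` from [read_membrane_pdb()].
#' @param params a `classifier_params`.
#' @param spans a `span_set`; derived geometrically via [derive_spans()]
#'   when omitted. Span counts are pooled over all chains.
#' @param type `"auto"` (default; uses [detect_protein_type()]),
#'   `"alpha"` or `"beta"`. A user-supplied type always wins.
#' @param ss optional externally computed secondary structure passed to
#'   [assign_secondary_structure()] for auto-detection.
#' @return An object of class `lipacc`: list with `labels` (data frame
#'   with `reskey`, `label` = lipid_exposed/buried, `provenance` =
#'   outside_membrane/span_exception/shell/angle_pass/angle_fail, `slice`,
#'   `in_shell`, `angle`), plus `params`, `spans`, `type`, `slices`,
#'   `hulls` and `shells` for inspection/plotting. `provenance = "shell"`
#'   means shell membership alone decided the call (either way).
#' @seealso [write_annotated_pdb()], [residue_report()],
#'   [confusion_counts()]
#' @export
lipid_accessibility <- function(protein, params = classifier_params(),
                                spans = NULL, type = c("auto", "alpha", "beta"),
                                ss = NULL) {
  stopifnot(inherits(protein, "membrane_protein"),
            inherits(params, "classifier_params"))
  type <- match.arg(type)
  if (is.null(spans)) spans <- derive_spans(protein,
                                            membrane_frame(params$thickness))
  nsp <- n_spans(spans)

  ptype <- if (type == "auto") {
    as.character(detect_protein_type(protein,
                                     ss = if (is.null(ss)) assign_secondary_structure(protein)
                                          else assign_secondary_structure(protein, ss),
                                     frame = membrane_frame(params$thickness)))
  } else type

  res <- protein$residues
  half <- params$thickness / 2
  ca <- ca_coords(protein)
  z <- ca[match(res$reskey, rownames(ca)), 3]
  in_mem <- !is.na(z) & abs(z) <= half

  lab <- data.frame(reskey = res$reskey,
                    label = "buried",
                    provenance = "outside_membrane",
                    slice = NA_integer_,
                    in_shell = FALSE,
                    angle = NA_real_,
                    stringsAsFactors = FALSE)

  slices <- slice_membrane(protein, params)
  hulls <- vector("list", length(slices))
  shells <- vector("list", length(slices))

  if (nsp <= params$trivial_span_max) {
    lab$label[in_mem] <- "lipid_exposed"
    lab$provenance[in_mem] <- "span_exception"
    for (s in seq_along(slices))
      lab$slice[match(slices[[s]]$reskeys, lab$reskey)] <- s
  } else {
    angle_rule <- if (ptype == "beta") "beta"
    else if (nsp <= params$small_bundle_max_spans) "small_helical"
    else "none"
    cutoff <- switch(angle_rule,
                     beta = params$angle_cutoff_beta,
                     small_helical = params$angle_cutoff_small_helical,
                     none = NA_real_)

    for (s in seq_along(slices)) {
      sl <- slices[[s]]
      if (length(sl$reskeys) == 0) next
      ii <- match(sl$reskeys, lab$reskey)
      lab$slice[ii] <- s
      cvx <- convex_hull(sl$points)
      ccv <- concave_hull(sl$points, cvx, params$dist_cutoff)
      shl <- concave_shell(sl$points, ccv, params$shell_radius)
      hulls[[s]] <- list(convex = cvx, concave = ccv)
      shells[[s]] <- shl
      member <- seq_along(sl$reskeys) %in% shl$shell
      lab$in_shell[ii] <- member
      lab$provenance[ii] <- "shell"
      if (angle_rule == "none") {
        lab$label[ii[member]] <- "lipid_exposed"
      } else {
        for (k in which(member)) {
          ang <- sidechain_angle(protein, sl$reskeys[k], sl$com_xy)
          lab$angle[ii[k]] <- ang
          if (!is.na(ang) && ang > cutoff) {
            lab$label[ii[k]] <- "lipid_exposed"
            lab$provenance[ii[k]] <- "angle_pass"
          } else {
            lab$provenance[ii[k]] <- "angle_fail"
          }
        }
        if (any(member & is.na(lab$angle[ii])))
          warning(sprintf(paste("%d shell residue(s) lack the atoms needed for",
                                "the sidechain angle test and stay buried"),
                          sum(member & is.na(lab$angle[ii]))))
      }
    }
    # membrane residues without a C-alpha cannot enter the geometry
    lab$provenance[in_mem & is.na(lab$slice)] <- "shell"
  }

  structure(list(labels = lab, params = params, spans = spans,
                 type = ptype, type_source = if (type == "auto") "auto" else "user",
                 slices = slices, hulls = hulls, shells = shells,
                 n_spans = nsp),
            class = "lipacc")
}

#' Per-residue classification report
#'
#' @param object a `lipacc` classification.
#' @param file optional path; when given the report is written as TSV.
#' @return data frame with residue key, slice index, shell membership,
#'   sidechain angle, label and provenance.
#' @export
residue_report <- function(object, file = NULL) {
  stopifnot(inherits(object, "lipacc"))
  df <- object$labels
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @export
print.lipacc <- function(x, ...) {
  n_exp <- sum(x$labels$label == "lipid_exposed")
  n_mem <- sum(x$labels$provenance != "outside_membrane")
  cat(sprintf("lipid accessibility classification (%s, %d TM span(s), %s)\n",
              x$type, x$n_spans,
              if (x$type_source == "auto") "auto-detected" else "user-set"))
  cat(sprintf("  %d of %d membrane residues lipid exposed (%d residues total)\n",
              n_exp, n_mem, nrow(x$labels)))
  invisible(x)
}

#' @export
summary.lipacc <- function(object, ...) {
  lab <- object$labels
  per_slice <- lapply(seq_along(object$slices), function(s) {
    sel <- !is.na(lab$slice) & lab$slice == s
    data.frame(slice = s,
               z_min = object$slices[[s]]$z_min,
               z_max = object$slices[[s]]$z_max,
               n = sum(sel),
               exposed = sum(sel & lab$label == "lipid_exposed"))
  })
  out <- list(type = object$type, n_spans = object$n_spans,
              params = object$params,
              per_slice = do.call(rbind, per_slice),
              provenance = table(lab$provenance))
  class(out) <- "summary.lipacc"
  out
}

#' @export
print.summary.lipacc <- function(x, ...) {
  cat(sprintf("architecture: %s | spans: %d\n", x$type, x$n_spans))
  print(x$params)
  cat("per-slice calls:\n")
  print(x$per_slice, row.names = FALSE)
  cat("provenance:\n")
  print(x$provenance)
  invisible(x)
}

#' Plot the per-slice hull geometry of a classification
#'
#' One panel per membrane slice: projected C-alpha points colored by call
#' (exposed/buried), with the concave-hull boundary polygon drawn.
#'
#' @param x a `lipacc` object.
#' @param ... passed to `plot.default`.
#' @export
plot.lipacc <- function(x, ...) {
  ns <- length(x$slices)
  op <- graphics::par(mfrow = c(1, ns), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (s in seq_len(ns)) {
    sl <- x$slices[[s]]
    if (length(sl$reskeys) == 0) { graphics::plot.new(); next }
    lab <- x$labels[match(sl$reskeys, x$labels$reskey), ]
    col <- ifelse(lab$label == "lipid_exposed", "orange", "grey40")
    plot(sl$points, col = col, pch = 19, asp = 1,
         main = sprintf("slice %d: z in [%g, %g]", s, sl$z_min, sl$z_max),
         xlab = "x", ylab = "y", ...)
    h <- x$hulls[[s]]$concave
    if (!is.null(h) && length(h$boundary) >= 2) {
      b <- c(h$boundary, h$boundary[1])
      graphics::lines(h$points[b, 1], h$points[b, 2], col = "steelblue")
    }
    graphics::points(sl$com_xy[1], sl$com_xy[2], pch = 3, cex = 1.4)
  }
  invisible(x)
}
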