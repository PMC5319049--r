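# Confusion-matrix evaluation against ground truth, and the relative
# accessible-surface-area baseline classifier.

#' Confusion counts against ground truth
#'
#' Tallies TP/TN/FP/FN over a set of residues, with `lipid_exposed` as the
#' positive class.
#'
#' @param predicted,truth label sources: `lipacc` objects, data frames
#'   with `reskey`/`label`, or named character vectors.
#' @param scope residue keys to evaluate; defaults to all keys of
#'   `truth`. Every key in scope must be present in both label maps.
#' @return object of class `confusion_counts`: list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(predicted, truth, scope = NULL) {
  p <- .as_label_vector(predicted)
  t <- .as_label_vector(truth)
  if (is.null(scope)) scope <- names(t)
  miss <- setdiff(scope, names(p))
  if (length(miss) > 0)
    stop(sprintf("residue %s missing from predicted labels", miss[1]))
  miss <- setdiff(scope, names(t))
  if (length(miss) > 0)
    stop(sprintf("residue %s missing from truth labels", miss[1]))
  pp <- p[scope] == "lipid_exposed"
  tt <- t[scope] == "lipid_exposed"
  structure(list(TP = sum(pp & tt), TN = sum(!pp & !tt),
                 FP = sum(pp & !tt), FN = sum(!pp & tt)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\n", x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Accuracy, sensitivity and specificity
#'
#' Computes, in percent: accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity
#' TP/(TP+FN) and specificity TN/(TN+FP). Values are kept at full
#' precision; printing rounds half-up to one decimal. A metric with a
#' zero denominator is `NA` for that metric only.
#'
#' @param counts a `confusion_counts`, or a list/vector with TP, TN, FP,
#'   FN components.
#' @return object of class `lipacc_metrics`: list with `accuracy`,
#'   `sensitivity`, `specificity` (percent, unrounded).
#' @export
classification_metrics <- function(counts) {
  cts <- lapply(c("TP", "TN", "FP", "FN"), function(k) as.numeric(counts[[k]]))
  names(cts) <- c("TP", "TN", "FP", "FN")
  if (any(vapply(cts, function(v) length(v) != 1 || is.na(v) || v < 0, TRUE)))
    stop("counts must contain non-negative TP, TN, FP, FN")
  tot <- cts$TP + cts$TN + cts$FP + cts$FN
  if (tot == 0) stop("cannot compute metrics from all-zero counts")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(accuracy = rate(cts$TP + cts$TN, tot),
                 sensitivity = rate(cts$TP, cts$TP + cts$FN),
                 specificity = rate(cts$TN, cts$TN + cts$FP),
                 counts = cts),
            class = "lipacc_metrics")
}

#' @export
print.lipacc_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", round_half_up(v, 1))
  cat(sprintf("accuracy %s%%  sensitivity %s%%  specificity %s%%\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity)))
  invisible(x)
}

#' Metrics summary block
#'
#' Formats counts and metrics as a one-row table (TP TN FP FN acc sens
#' spec), the layout used for benchmark reporting.
#'
#' @param metrics a `lipacc_metrics`.
#' @param label row label.
#' @return character vector of lines.
#' @export
format_metrics_block <- function(metrics, label = "prediction") {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", round_half_up(v, 1))
  c(sprintf("%-12s %8s %8s %8s %8s %6s %6s %6s", "", "TP", "TN", "FP", "FN",
            "acc", "sens", "spec"),
    sprintf("%-12s %8d %8d %8d %8d %6s %6s %6s", label,
            metrics$counts$TP, metrics$counts$TN, metrics$counts$FP,
            metrics$counts$FN, fmt(metrics$accuracy), fmt(metrics$sensitivity),
            fmt(metrics$specificity)))
}

# ---- solvent accessible surface area -------------------------------------

# deterministic golden-spiral unit sphere point set
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# theoretical maximum accessible surface areas (Gly-X-Gly, A^2) used to
# normalize per-residue SASA to relative SASA
.MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Shrake-Rupley solvent accessible surface area
#'
#' Rolling-probe SASA over the heavy atoms of a structure: each atom's
#' van der Waals sphere is expanded by the probe radius and covered with a
#' fixed deterministic golden-spiral point set; the accessible fraction is
#' the fraction of points not buried inside any neighboring expanded
#' sphere.
#'
#' @param protein a `membrane_protein`.
#' @param probe probe radius in angstroms (default 1.4, a water molecule).
#' @param n_points sphere points per atom (default 960; fixed point set,
#'   so results are deterministic).
#' @return named numeric vector of per-residue SASA in square angstroms.
#' @export
residue_sasa <- function(protein, probe = 1.4, n_points = 960) {
  at <- protein$atom
  heavy <- toupper(at$element) != "H" & !grepl("^[0-9]*H", at$name)
  at <- at[heavy, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .VDW[toupper(at$element)]
  rad[is.na(rad)] <- 1.70
  R <- rad + probe
  n <- nrow(xyz)
  sp <- .sphere_points(n_points)

  asa <- numeric(n)
  cutoff2 <- (max(R) * 2)^2
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R + R[i])^2 & d2 > 1e-12)
    P <- sp * R[i]
    P <- cbind(P[, 1] + xyz[i, 1], P[, 2] + xyz[i, 2], P[, 3] + xyz[i, 3])
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (P[free, 1] - xyz[j, 1])^2 + (P[free, 2] - xyz[j, 2])^2 +
        (P[free, 3] - xyz[j, 3])^2
      keep <- dj2 >= R[j]^2
      free[free] <- keep
    }
    asa[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  tapply(asa, at$reskey, sum)[unique(at$reskey)]
}

#' Relative-SASA baseline classifier
#'
#' The standard surface-area baseline: per-residue SASA ([residue_sasa()])
#' is normalized by the residue type's theoretical maximum (Gly-X-Gly
#' reference values) to a relative SASA, and membrane residues with
#' `rASA >= cutoff` are called lipid exposed. This baseline cannot tell
#' lipid-facing from water-facing surface: pore-lining residues with high
#' rASA are false positives for it.
#'
#' @param protein a `membrane_protein`.
#' @param frame a `membrane_frame`; defaults to the protein's.
#' @param cutoff rASA threshold in (0, 1); default 0.2.
#' @param probe,n_points passed to [residue_sasa()].
#' @return data frame with `reskey`, `rasa`, `label` (lipid_exposed for
#'   membrane residues at or above the cutoff, buried otherwise).
#' @export
rasa_baseline <- function(protein, frame = protein$frame, cutoff = 0.2,
                          probe = 1.4, n_points = 960) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie in (0, 1)")
  sasa <- residue_sasa(protein, probe = probe, n_points = n_points)
  res <- protein$residues
  rasa <- as.numeric(sasa[res$reskey]) / .MAX_ASA[res$resname]
  missing_atoms <- !(res$reskey %in% names(sasa))
  if (any(missing_atoms)) {
    warning(sprintf("%d residue(s) with no heavy atoms: buried by default",
                    sum(missing_atoms)))
    rasa[missing_atoms] <- 0
  }
  ca <- ca_coords(protein)
  z <- ca[match(res$reskey, rownames(ca)), 3]
  in_mem <- !is.na(z) & abs(z) <= frame$half_thickness
  data.frame(reskey = res$reskey, rasa = rasa,
             label = ifelse(in_mem & !is.na(rasa) & rasa >= cutoff,
                            "lipid_exposed", "buried"),
             stringsAsFactors = FALSE)
}
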