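# Transmembrane spans: Rosetta-style span file I/O and a geometric
# fallback that derives spans from C-alpha z-coordinates when no span
# file is supplied.

.new_span_set <- function(df, source) {
  rownames(df) <- NULL
  structure(df, source = source, class = c("span_set", "data.frame"))
}

#' Number of transmembrane spans
#' @param spans a `span_set`.
#' @return integer span count (pooled over all chains).
#' @export
n_spans <- function(spans) {
  stopifnot(inherits(spans, "span_set"))
  nrow(spans)
}

#' Read a Rosetta-style span file
#'
#' Expected layout: a free-text header line; a line with the span count
#' and the residue count; optional topology keyword lines (for example
#' `antiparallel`, `n2c`); then one start/end residue-number pair per
#' span. The declared span count must match the number of listed pairs.
#'
#' @param x path to a span file or a character vector of its lines.
#' @return a `span_set`: data frame with columns `start`, `end`,
#'   `orientation`, and attribute `source = "file"`.
#' @export
read_span_file <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE)
  else if (length(x) == 1) strsplit(x, "\n", fixed = TRUE)[[1]]
  else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("span file too short", call. = FALSE)

  counts <- strsplit(lines[2], "[[:space:]]+")[[1]]
  ndecl <- suppressWarnings(as.integer(counts[1]))
  if (is.na(ndecl)) stop("span file: second line must start with the span count",
                         call. = FALSE)

  body <- lines[-(1:2)]
  is_pair <- grepl("^[0-9]+([[:space:]]+[0-9]+)+$", body)
  pairs <- body[is_pair]
  if (any(!is_pair & grepl("[0-9]", body) & !grepl("^[a-zA-Z]", body)))
    stop("span file: non-numeric residue pair", call. = FALSE)
  if (length(pairs) != ndecl)
    stop(sprintf("span file declares %d spans but lists %d pairs",
                 ndecl, length(pairs)), call. = FALSE)

  se <- t(vapply(strsplit(pairs, "[[:space:]]+"),
                 function(v) as.integer(v[1:2]), integer(2)))
  if (any(is.na(se))) stop("span file: non-numeric residue pair", call. = FALSE)
  if (any(se[, 1] > se[, 2]))
    stop("span file: span start exceeds span end", call. = FALSE)
  .new_span_set(data.frame(chain = NA_character_, start = se[, 1], end = se[, 2],
                           orientation = "unknown", stringsAsFactors = FALSE),
                source = "file")
}

#' Write a Rosetta-style span file
#'
#' @param spans a `span_set`.
#' @param n_res total residue count to record in the header line.
#' @param file optional output path.
#' @return (invisibly) the file lines.
#' @export
write_span_file <- function(spans, n_res, file = NULL) {
  stopifnot(inherits(spans, "span_set"))
  txt <- c("TM span prediction",
           sprintf("%d %d", nrow(spans), n_res),
           "antiparallel",
           "n2c",
           sprintf("%5d %5d", spans$start, spans$end))
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Derive transmembrane spans from geometry
#'
#' Heuristic used when no span file is available: within each chain,
#' maximal runs of consecutive residues whose C-alpha satisfies
#' `|z| <= half_thickness` are candidate spans; a run is accepted when it
#' actually crosses the slab (its minimum z reaches within `leaflet_tol`
#' of the lower leaflet boundary and its maximum z within `leaflet_tol` of
#' the upper one) and contains at least `min_len` residues. Re-entrant
#' loops and surface helices therefore do not count as spans. User-supplied
#' span files always take precedence over this heuristic.
#'
#' @param protein a `membrane_protein`.
#' @param frame a `membrane_frame`; defaults to the protein's.
#' @param leaflet_tol how close (angstroms) a run must come to each leaflet
#'   boundary to count as crossing (default 4).
#' @param min_len minimum residues per span (default 5).
#' @return a `span_set` with attribute `source = "derived"`; may be empty.
#' @export
derive_spans <- function(protein, frame = protein$frame, leaflet_tol = 4,
                         min_len = 5) {
  stopifnot(inherits(protein, "membrane_protein"))
  half <- frame$half_thickness
  res <- protein$residues
  ca <- ca_coords(protein)
  z <- ca[match(res$reskey, rownames(ca)), 3]

  in_mem <- !is.na(z) & abs(z) <= half
  out <- list()
  for (ch in unique(res$chain)) {
    sel <- which(res$chain == ch)
    runs <- rle(in_mem[sel])
    pos <- cumsum(c(1, runs$lengths))
    for (r in seq_along(runs$lengths)) {
      if (!runs$values[r] || runs$lengths[r] < min_len) next
      ii <- sel[pos[r]:(pos[r + 1] - 1)]
      zr <- z[ii]
      if (min(zr) <= -(half - leaflet_tol) && max(zr) >= (half - leaflet_tol)) {
        up <- z[ii[length(ii)]] > z[ii[1]]
        out[[length(out) + 1]] <- data.frame(
          chain = ch, start = res$resseq[ii[1]], end = res$resseq[ii[length(ii)]],
          orientation = if (up) "n_to_c_up" else "n_to_c_down",
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(out) == 0)
    data.frame(chain = character(0), start = integer(0), end = integer(0),
               orientation = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, out)
  .new_span_set(df, source = "derived")
}

#' @export
print.span_set <- function(x, ...) {
  cat(sprintf("span_set (%s): %d transmembrane span(s)\n",
              attr(x, "source") %||% "?", nrow(x)))
  if (nrow(x) > 0) print.data.frame(x)
  invisible(x)
}
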