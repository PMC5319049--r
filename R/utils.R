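# small internal helpers shared across modules

#' Build the canonical residue key "chain:resseq[icode]"
#'
#' Residue keys identify residues uniquely across the package (labels,
#' ground truth, reports). Insertion codes are appended verbatim so that
#' e.g. "A:52" and "A:52A" never collide.
#'
#' @param chain chain identifier (single character)
#' @param resseq residue sequence number (integer)
#' @param icode insertion code, `""` when absent
#' @return character vector of residue keys
#' @keywords internal
res_key <- function(chain, resseq, icode = "") {
  paste0(chain, ":", resseq, ifelse(icode == "" | is.na(icode), "", icode))
}

# run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# half-up rounding (2.25 -> 2.3 at 1 digit), the convention used for
# reporting percentages; base round() is half-even
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
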