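#' Structure canonicalization backends
#'
#' A canonicalizer is any deterministic function mapping a character vector of
#' structure strings to a character vector of canonical structure strings, and
#' it must be idempotent (canonicalizing twice equals canonicalizing once).
#' Two compounds are considered identical if and only if their canonical
#' structure strings are equal, so the choice of canonicalizer defines compound
#' identity throughout the package.
#'
#' `canonicalizer_openbabel()` returns the Open Babel canonical-SMILES routine
#' (via \pkg{ChemmineOB}); it is the default for real chemical structures.
#' `canonicalizer_identity()` trims surrounding whitespace and leaves the
#' string untouched; it is appropriate for opaque compound identifiers such as
#' those produced by the synthetic-data generator.
#'
#' @return A function of class `mix_canonicalizer` with a `backend_id`
#'   attribute.
#' @examples
#' canon <- canonicalizer_identity()
#' canon(c(" CPD001", "CPD002 "))
#' @export
canonicalizer_identity <- function() {
  f <- function(structures) {
    out <- trimws(as.character(structures))
    if (any(is.na(out) | out == "")) {
      stop_mixqspr("empty or missing structure string", "mixqspr_structure_error")
    }
    out
  }
  structure(f, class = c("mix_canonicalizer", "function"), backend_id = "identity")
}

#' @rdname canonicalizer_identity
#' @export
canonicalizer_openbabel <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop_mixqspr("ChemmineOB is required for the Open Babel canonicalizer",
                 "mixqspr_config_error")
  }
  f <- function(structures) {
    structures <- trimws(as.character(structures))
    out <- vapply(structures, function(s) {
      if (is.na(s) || s == "") {
        stop_mixqspr("empty or missing structure string", "mixqspr_structure_error")
      }
      res <- tryCatch(
        ChemmineOB::convertFormat("SMI", "CAN", s),
        error = function(e) NA_character_
      )
      res <- sub("[\t\n ].*$", "", res)
      if (is.na(res) || res == "") {
        stop_mixqspr(sprintf("structure '%s' could not be parsed as SMILES", s),
                     "mixqspr_structure_error")
      }
      res
    }, character(1), USE.NAMES = FALSE)
    out
  }
  structure(f, class = c("mix_canonicalizer", "function"), backend_id = "openbabel_cansmi")
}

#' Canonicalize structure strings
#'
#' Applies a canonicalization backend to one or more structure strings.
#'
#' @param structures character vector of structure strings (SMILES or opaque
#'   identifiers, depending on the backend).
#' @param canonicalizer a backend from [canonicalizer_identity()] or
#'   [canonicalizer_openbabel()], or any deterministic idempotent
#'   string-to-string function.
#' @return character vector of canonical structure strings.
#' @export
canonicalize_structure <- function(structures, canonicalizer = canonicalizer_identity()) {
  canonicalizer(structures)
}

# read first molecule of an SDF/MOL file and return its canonical SMILES
read_structure_file <- function(path, canonicalizer) {
  if (!file.exists(path)) {
    stop_mixqspr(sprintf("structure file '%s' not found", path), "mixqspr_structure_error")
  }
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop_mixqspr("ChemmineR is required to read SDF structure files",
                 "mixqspr_config_error")
  }
  sdf <- ChemmineR::read.SDFset(path)
  smi <- as.character(ChemmineR::sdf2smiles(sdf[1]))
  canonicalizer(smi)
}
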