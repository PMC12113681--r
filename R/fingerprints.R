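# SMILES handling delegates to RDKit, invoked as a single batched
# subprocess through the system `python`; nothing here re-implements
# circular-fingerprint hashing.

rdkit_script <- function() {
  path <- system.file("python", "ecfp.py", package = "bchescreen")
  if (!nzchar(path)) {
    # During development (pkgload) the inst/ prefix is still present.
    path <- system.file("inst", "python", "ecfp.py", package = "bchescreen")
  }
  if (!nzchar(path)) abort("Bundled RDKit helper script not found.")
  path
}

run_rdkit <- function(smiles, args) {
  infile <- tempfile("smiles_")
  on.exit(unlink(infile))
  writeLines(smiles, infile)
  out <- suppressWarnings(system2(
    "python", c(shQuote(rdkit_script()), args),
    stdin = infile, stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    abort("RDKit helper failed; is the `python` RDKit installation available?")
  }
  if (length(out) != length(smiles)) {
    abort("RDKit helper returned an unexpected number of records.")
  }
  out
}

#' Canonicalise SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES; `NA` where the input does
#'   not parse.
#' @export
canonicalize_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character())
  out <- run_rdkit(as.character(smiles), "canon")
  out[!nzchar(out)] <- NA_character_
  out
}

#' Hashed circular (ECFP/Morgan) fingerprints
#'
#' Computes binary extended-connectivity fingerprints for a vector of SMILES.
#' The default radius 2 over 2048 bits is the ECFP4 descriptor used throughout
#' the screening pipeline. Identical structures always map to identical bit
#' vectors.
#'
#' @param smiles Character vector of SMILES strings.
#' @param radius Circular-neighbourhood radius (ECFP diameter / 2); >= 1.
#' @param n_bits Fingerprint length; a power of two.
#' @return Integer 0/1 matrix with `length(smiles)` rows and `n_bits` columns.
#' @examples
#' \donttest{
#' fp <- featurize_ecfp(c("CCO", "c1ccccc1"))
#' rowSums(fp)
#' }
#' @export
featurize_ecfp <- function(smiles, radius = 2, n_bits = 2048) {
  if (radius < 1 || radius != round(radius)) {
    abort("`radius` must be a positive integer.")
  }
  if (n_bits < 2 || bitwAnd(as.integer(n_bits), as.integer(n_bits) - 1L) != 0L) {
    abort("`n_bits` must be a power of two.")
  }
  if (length(smiles) == 0) {
    return(matrix(integer(), nrow = 0, ncol = n_bits))
  }
  out <- run_rdkit(as.character(smiles), c("fp", radius, n_bits))
  invalid <- which(out == "INVALID")
  if (length(invalid) > 0) {
    abort(sprintf(
      "Invalid SMILES at row%s %s: %s",
      if (length(invalid) > 1) "s" else "",
      paste(utils::head(invalid, 5), collapse = ", "),
      paste(utils::head(smiles[invalid], 5), collapse = ", ")
    ))
  }
  mat <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  for (i in seq_along(out)) {
    if (nzchar(out[i])) {
      bits <- as.integer(strsplit(out[i], " ", fixed = TRUE)[[1]]) + 1L
      mat[i, bits] <- 1L
    }
  }
  rownames(mat) <- names(smiles)
  mat
}
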