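# Morgan (circular, hashed) fingerprints. The bit convention is pinned to
# RDKit's MorganGenerator, invoked through the system `python` interpreter in
# one batch subprocess per call; fixtures under tests/ freeze the convention.

.fp_python <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    py <- Sys.which("python")
    if (!nzchar(py)) py <- Sys.which("python3")
    if (!nzchar(py)) {
      stop("fingerprinting requires a `python` interpreter with rdkit on PATH",
           call. = FALSE)
    }
    cached <<- py
    cached
  }
})

.fp_script <- '
import sys
from rdkit import Chem
from rdkit.Chem import rdFingerprintGenerator
from rdkit import RDLogger
RDLogger.DisableLog("rdApp.*")
n_bits, radius = int(sys.argv[1]), int(sys.argv[2])
gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=n_bits)
for line in sys.stdin:
    smi = line.strip()
    if not smi:
        continue
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        sys.stdout.write("ERR\\t" + smi + "\\n")
    else:
        sys.stdout.write("OK\\t" + gen.GetFingerprint(mol).ToBitString() + "\\n")
'

#' Compute hashed circular (Morgan) fingerprints for SMILES strings
#'
#' Deterministic hashed circular-substructure fingerprints, the standard
#' binary descriptor for small molecules. Defaults are 256 bits at radius 3.
#'
#' @param smiles Character vector of SMILES strings.
#' @param n_bits Fingerprint length in bits.
#' @param radius Circular neighborhood radius.
#' @return Integer 0/1 matrix with one row per molecule, rows named by the
#'   input names (or the SMILES themselves).
#' @export
fingerprint_drugs <- function(smiles, n_bits = 256L, radius = 3L) {
  stopifnot(length(smiles) >= 1L, n_bits >= 8L, radius >= 0L)
  py <- .fp_python()
  script <- tempfile(fileext = ".py")
  on.exit(unlink(script), add = TRUE)
  writeLines(.fp_script, script)
  out <- suppressWarnings(system2(py, c(script, n_bits, radius),
                                  input = smiles, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("fingerprint backend failed (is rdkit installed for `python`?)",
         call. = FALSE)
  }
  parts <- strsplit(out, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) p[[1L]] == "ERR", logical(1))
  if (any(bad)) {
    stop("invalid SMILES: ",
         paste(vapply(parts[bad], `[[`, character(1), 2L), collapse = ", "),
         call. = FALSE)
  }
  bits <- vapply(parts, `[[`, character(1), 2L)
  mat <- t(vapply(strsplit(bits, "", fixed = TRUE),
                  function(b) as.integer(b == "1"), integer(n_bits)))
  rownames(mat) <- if (!is.null(names(smiles))) names(smiles) else smiles
  colnames(mat) <- paste0("b", seq_len(n_bits) - 1L)
  mat
}

#' Fingerprint a single molecule
#'
#' @inheritParams fingerprint_drugs
#' @param smiles A single SMILES string.
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
fingerprint_drug <- function(smiles, n_bits = 256L, radius = 3L) {
  stopifnot(length(smiles) == 1L)
  drop(fingerprint_drugs(smiles, n_bits = n_bits, radius = radius)[1L, ])
}
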