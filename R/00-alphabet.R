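# Nucleotide alphabet shared across modules (collates before all other
# files; several of them build lookup tables from these at load time).

#' IUPAC nucleotide expansions
#'
#' Named list mapping every IUPAC nucleotide code to the set of unambiguous
#' bases it stands for. `U` is normalized to `T` on read and never appears
#' here; `-` (gap) is not a code and has no expansion.
#'
#' @format A named list of character vectors.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_BASES <- c("A", "C", "G", "T")
ALLOWED_CHARS <- c(names(IUPAC_CODES), "-")
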