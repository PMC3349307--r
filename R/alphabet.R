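#' The 16 ordered dinucleotides
#'
#' Returns the fixed, frozen ordering of the 16 ordered nucleotide pairs
#' over \{A, C, G, T\} used for every 16-dimensional frequency layer, every
#' frequency-matrix column and every flattened profile vector in this
#' package.  The pairs are ordered pairs: \code{"AT"} and \code{"TA"} are
#' distinct, so profiles are strand-specific by construction.
#'
#' @return Character vector of length 16: AT, AA, AC, AG, TT, TA, TC, TG,
#'   GT, GA, GC, GG, CT, CA, CC, CG.
#' @examples
#' dinucleotides()
#' @export
dinucleotides <- function() DINUCLEOTIDES

# frozen pair order; distance values are order-invariant but serialized
# profiles must be reproducible byte-for-byte
DINUCLEOTIDES <- c(
  "AT", "AA", "AC", "AG",
  "TT", "TA", "TC", "TG",
  "GT", "GA", "GC", "GG",
  "CT", "CA", "CC", "CG"
)

BASES <- c("A", "C", "G", "T")
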