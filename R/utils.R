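# Condition helpers: every user-facing failure carries a class so the CLI
# can map it to an exit code (input/format -> 1, usage -> 2).

csift_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "contigsift_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_input  <- function(msg) csift_stop(msg, "contigsift_input_error")
stop_format <- function(msg) csift_stop(msg, "contigsift_format_error")
stop_param  <- function(msg) csift_stop(msg, "contigsift_parameter_error")
stop_usage  <- function(msg) csift_stop(msg, "contigsift_usage_error")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()];
#' `N` maps to `N`.
#'
#' @param x A character scalar over `{A,C,G,T,N}`.
#' @return A character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a DNA string into consecutive codons (drops a trailing partial codon).
codons_of <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  at <- seq.int(1L, by = 3L, length.out = n)
  substring(x, at, at + 2L)
}

# Half-up rounding of a non-negative scalar (base round() is half-even).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

STOP_CODONS <- c("TAA", "TAG", "TGA")

# The seven canonical ranks used throughout.
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
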