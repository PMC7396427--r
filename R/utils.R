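#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used by
#' the package's display tables (base R's `round()` rounds ties to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(0.425, 2)   # 0.43
#' round_half_up(-0.2735, 3) # -0.274
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' The 64 codons in canonical order
#'
#' DNA triplets ordered with bases T, C, A, G varying slowest to fastest
#' (TTT, TTC, TTA, TTG, TCT, ..., GGG), the classic codon-table layout.
#'
#' @param rna if `TRUE`, return RNA triplets (T written as U).
#' @return character vector of 64 codons.
#' @export
codon_alphabet <- function(rna = FALSE) {
  b <- c("T", "C", "A", "G")
  x <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  if (rna) dna_to_rna(x) else x
}

#' Convert between DNA and RNA codon spelling
#'
#' @param x character vector of triplets.
#' @return `x` with T/U swapped.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# reverse complement of a plain character string (delegates to Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# normalize strand symbols: accepts "+", "-", and the typographic minus
normalize_strand <- function(strand) {
  s <- gsub("−", "-", as.character(strand))
  if (!all(s %in% c("+", "-"))) {
    stop("strand must be '+' or '-', got: ",
         paste(unique(setdiff(s, c("+", "-"))), collapse = ", "))
  }
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
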