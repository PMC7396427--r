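#' Genetic code tables
#'
#' A genetic code bundles the codon-to-amino-acid map, the induced partition
#' of the 64 codons into synonymous families (stop codons form their own
#' family), and the permitted start codons. Three NCBI translation tables are
#' built in: the standard code (table 1), the invertebrate mitochondrial code
#' (table 5: AGA/AGG = Ser, AUA = Met, UGA = Trp) and the echinoderm/flatworm
#' mitochondrial code (table 9: additionally AAA = Asn). The synonymous-family
#' partition drives RSCU denominators, the codon-to-amino-acid map drives
#' amino-acid usage, so the two can be taken from different codes (see
#' [rscu()] and [aa_usage()]).
#'
#' @param code one of `"standard"`, `"invertebrate_mito"`,
#'   `"echinoderm_mito"`, an NCBI translation-table id accepted by
#'   [Biostrings::getGeneticCode()], or an existing `genetic_code` object
#'   (returned unchanged).
#' @return an object of class `genetic_code` with elements `id`,
#'   `aa_of_codon` (named character vector over the 64 DNA codons, stops as
#'   `"*"`), `families` (list of codon vectors, one per amino acid / stop)
#'   and `starts` (permitted start codons).
#' @examples
#' gc5 <- genetic_code("invertebrate_mito")
#' gc5$aa_of_codon[["AGA"]]  # "S"
#' @export
genetic_code <- function(code = c("standard", "invertebrate_mito",
                                  "echinoderm_mito")) {
  if (inherits(code, "genetic_code")) return(code)
  id_map <- c(standard = "1", invertebrate_mito = "5", echinoderm_mito = "9")
  if (is.character(code) && length(code) == 1L && code %in% names(id_map)) {
    id <- id_map[[code]]
    label <- code
  } else {
    id <- as.character(code[[1L]])
    label <- paste0("ncbi_table_", id)
  }
  tbl <- Biostrings::getGeneticCode(id, full.search = TRUE)
  starts <- attr(tbl, "alt_init_codons")
  genetic_code_from_map(tbl, starts = c("ATG", starts), id = label)
}

#' Build a genetic code from an explicit codon map
#'
#' @param aa_of_codon named character vector mapping all 64 codons (DNA or
#'   RNA spelling) to one-letter amino acids, stops as `"*"`.
#' @param starts permitted start codons (ATG is always included).
#' @param id label for the code.
#' @return a `genetic_code` object; see [genetic_code()].
#' @export
genetic_code_from_map <- function(aa_of_codon, starts = "ATG", id = "custom") {
  codons <- codon_alphabet()
  names(aa_of_codon) <- toupper(rna_to_dna(names(aa_of_codon)))
  if (!all(codons %in% names(aa_of_codon))) {
    stop("aa_of_codon must cover all 64 codons; missing: ",
         paste(utils::head(setdiff(codons, names(aa_of_codon))), collapse = ", "))
  }
  aa <- stats::setNames(unname(as.character(aa_of_codon[codons])), codons)
  fam <- split(codons, aa)
  starts <- unique(toupper(rna_to_dna(c("ATG", starts))))
  structure(list(id = id, aa_of_codon = aa, families = fam, starts = starts),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", x$id, "\n")
  cat("  families:", length(x$families),
      "(stop family size", length(x$families[["*"]]), ")\n")
  cat("  start codons:", paste(x$starts, collapse = " "), "\n")
  invisible(x)
}
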