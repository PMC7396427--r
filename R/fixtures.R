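#' Packaged fixtures: the focal sea-cucumber mitogenome
#'
#' The package ships the published annotation table and protein-coding
#' codon-count table of the *Phyllophorus liuwutiensis* mitochondrial genome
#' (GenBank MN198190; 15,969 bp, 13 PCGs + 22 tRNAs + 2 rRNAs + 1 putative
#' control region) as plain-text fixtures under `extdata/`.
#'
#' `focal_annotation()` loads the 38-record annotation;
#' `focal_codon_table()` loads the 64-codon table with its published
#' amino-acid labels (invertebrate-mitochondrial code) and published RSCU
#' column; `focal_codon_counts()` returns the counts as a [codon_counts()]
#' table; `focal_composition()` loads published whole-genome / PCG /
#' control-region base percentages with their published skews;
#' `focal_gene_order()` derives the 37-gene signed order.
#'
#' @return see Description; one object per accessor.
#' @examples
#' sum(focal_codon_counts())  # 5323 codons
#' @export
focal_annotation <- function() {
  read_annotation_tsv(mitocirc_extdata("pliuwutiensis_annotation.tsv"),
                      genome_length = 15969L, circular = TRUE,
                      genome_id = "P_liuwutiensis")
}

#' @rdname focal_annotation
#' @export
focal_codon_table <- function() {
  utils::read.delim(mitocirc_extdata("pliuwutiensis_codons.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname focal_annotation
#' @export
focal_codon_counts <- function() {
  tab <- focal_codon_table()
  codon_counts(stats::setNames(tab$count, tab$codon))
}

#' @rdname focal_annotation
#' @export
focal_composition <- function() {
  utils::read.delim(mitocirc_extdata("pliuwutiensis_composition.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname focal_annotation
#' @export
focal_gene_order <- function() {
  order_from_annotation(focal_annotation())
}

mitocirc_extdata <- function(file) {
  system.file("extdata", file, package = "mitocirc", mustWork = TRUE)
}
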