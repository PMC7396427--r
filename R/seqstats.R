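#' Base composition of a sequence
#'
#' Counts A/C/G/T residues and reports per-base percentages of the counted
#' bases. Characters outside A/C/G/T (ambiguity codes, N) are tallied
#' separately and excluded from the percentages.
#'
#' @param x character scalar, [genome_sequence()], or `Biostrings::DNAString`.
#' @return object of class `base_composition`: list with `counts` (named
#'   integer, A/C/G/T), `percent` (named numeric summing to 100),
#'   `at_percent`, `gc_percent`, and `n_other`.
#' @examples
#' base_composition("AATT")$percent
#' @export
base_composition <- function(x) {
  if (inherits(x, "genome_sequence")) x <- x$residues
  x <- as.character(x)
  stopifnot(length(x) == 1L)
  if (!nzchar(x)) stop("base_composition(): empty sequence")
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
  counts <- stats::setNames(as.integer(tab), c("A", "C", "G", "T"))
  n_other <- length(chars) - sum(counts)
  if (sum(counts) == 0L) stop("base_composition(): no A/C/G/T residues")
  percent <- 100 * counts / sum(counts)
  structure(list(counts = counts, percent = percent,
                 at_percent = unname(percent[["A"]] + percent[["T"]]),
                 gc_percent = unname(percent[["G"]] + percent[["C"]]),
                 n_other = n_other),
            class = "base_composition")
}

#' @export
print.base_composition <- function(x, ...) {
  p <- round_half_up(x$percent, 2)
  cat(sprintf("T %.2f%%  C %.2f%%  A %.2f%%  G %.2f%%  (A+T %.2f%%)\n",
              p[["T"]], p[["C"]], p[["A"]], p[["G"]],
              round_half_up(x$at_percent, 2)))
  if (x$n_other > 0L) cat("  non-ACGT residues excluded:", x$n_other, "\n")
  invisible(x)
}

#' Strand-skew statistic
#'
#' `skew(x, y) = (x - y) / (x + y)`: GC-skew is `skew(G, C)`, AT-skew is
#' `skew(A, T)`. The statistic is invariant under common scaling of the two
#' inputs, so raw counts and printed percentages give the same value.
#'
#' @param x,y non-negative quantities (counts or percentages) for the first
#'   and second base; vectorized.
#' @return numeric in `[-1, 1]`.
#' @examples
#' skew(12.64, 22.16)  # whole-genome GC-skew from percentages
#' @export
skew <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("skew(): numeric inputs required")
  if (any(x < 0 | y < 0)) stop("skew(): inputs must be non-negative")
  s <- x + y
  if (any(s == 0)) stop("skew(): undefined, both quantities are zero")
  (x - y) / s
}

#' Per-feature composition and skew report
#'
#' One row per annotated feature plus aggregate rows: `PCGs` (all
#' protein-coding genes concatenated), `CRs` (all control regions
#' concatenated, when present) and `genome` (the whole positive strand).
#' Minus-strand features are measured on their coding strand (reverse
#' complement). Skews are `NA` when their denominator is zero.
#'
#' @param sequence a [genome_sequence()] with `nchar` equal to the
#'   annotation's `genome_length`.
#' @param annotation a [mito_annotation()].
#' @return data.frame with columns `region`, `category`, `strand`,
#'   `length`, `t_percent`, `c_percent`, `a_percent`, `g_percent`,
#'   `at_percent`, `gc_percent`, `gc_skew`, `at_skew`.
#' @export
composition_report <- function(sequence, annotation) {
  stopifnot(inherits(sequence, "genome_sequence"),
            inherits(annotation, "mito_annotation"))
  if (nchar(sequence$residues) != annotation$genome_length) {
    stop("sequence length != annotation genome_length")
  }
  rec <- annotation$records
  feat_seq <- vapply(seq_len(nrow(rec)), function(i) {
    region_sequence(sequence, rec$start[i], rec$end[i], rec$strand[i])
  }, "")
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    comp_row(rec$gene[i], rec$category[i], rec$strand[i], feat_seq[i])
  })
  agg <- list()
  is_pcg <- rec$category == "PCG"
  if (any(is_pcg)) {
    agg <- c(agg, list(comp_row("PCGs", "aggregate", "+",
                                paste(feat_seq[is_pcg], collapse = ""))))
  }
  is_cr <- rec$category == "control_region"
  if (any(is_cr)) {
    agg <- c(agg, list(comp_row("CRs", "aggregate", "+",
                                paste(feat_seq[is_cr], collapse = ""))))
  }
  agg <- c(agg, list(comp_row("genome", "aggregate", "+", sequence$residues)))
  out <- do.call(rbind, c(rows, agg))
  rownames(out) <- NULL
  out
}

comp_row <- function(region, category, strand, s) {
  bc <- base_composition(s)
  p <- bc$percent
  gc_den <- bc$counts[["G"]] + bc$counts[["C"]]
  at_den <- bc$counts[["A"]] + bc$counts[["T"]]
  data.frame(region = region, category = category, strand = strand,
             length = nchar(s),
             t_percent = unname(p[["T"]]), c_percent = unname(p[["C"]]),
             a_percent = unname(p[["A"]]), g_percent = unname(p[["G"]]),
             at_percent = bc$at_percent, gc_percent = bc$gc_percent,
             gc_skew = if (gc_den > 0)
               skew(bc$counts[["G"]], bc$counts[["C"]]) else NA_real_,
             at_skew = if (at_den > 0)
               skew(bc$counts[["A"]], bc$counts[["T"]]) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Codon count table
#'
#' Canonical container for counts of the 64 codons. Accepts a named vector
#' over codons in DNA or RNA spelling; missing codons are filled with zero.
#'
#' @param x named numeric vector of codon counts.
#' @return object of class `codon_counts`: named integer vector over the 64
#'   DNA codons in canonical order ([codon_alphabet()]).
#' @export
codon_counts <- function(x) {
  if (inherits(x, "codon_counts")) return(x)
  if (is.null(names(x))) stop("codon_counts(): input must be named by codon")
  nm <- toupper(rna_to_dna(names(x)))
  unknown <- setdiff(nm, codon_alphabet())
  if (length(unknown)) stop("codon_counts(): unknown codon(s): ",
                            paste(utils::head(unknown), collapse = ", "))
  if (anyDuplicated(nm)) stop("codon_counts(): duplicated codons")
  if (any(x < 0)) stop("codon_counts(): negative counts")
  out <- stats::setNames(integer(64L), codon_alphabet())
  out[nm] <- as.integer(round(x))
  class(out) <- "codon_counts"
  out
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("Codon counts:", sum(x), "codons,", sum(x > 0), "of 64 codons used\n")
  invisible(unclass(x))
}

#' Count codons in a set of coding sequences
#'
#' Tallies frame-0 triplets across in-frame coding sequences. Trailing 1-2
#' bases of a sequence whose length is not divisible by 3 are dropped with a
#' warning; triplets containing non-ACGT characters are skipped with a
#' warning.
#'
#' @param cds_list character vector or list of coding sequences (5' to 3' on
#'   the coding strand).
#' @return a [codon_counts()] table.
#' @examples
#' count_codons("ATGAAATAA")
#' @export
count_codons <- function(cds_list) {
  if (is.list(cds_list)) cds_list <- unlist(cds_list, use.names = FALSE)
  stopifnot(is.character(cds_list))
  counts <- stats::setNames(integer(64L), codon_alphabet())
  n_skipped <- 0L
  for (s in cds_list) {
    s <- toupper(s)
    n <- nchar(s)
    r <- n %% 3L
    if (r != 0L) {
      warning("sequence length ", n, " not divisible by 3; dropping trailing ",
              r, " base(s)")
      n <- n - r
    }
    if (n == 0L) next
    cods <- substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
    ok <- cods %in% names(counts)
    if (any(!ok)) n_skipped <- n_skipped + sum(!ok)
    tab <- table(factor(cods[ok], levels = names(counts)))
    counts <- counts + as.integer(tab)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " codon(s) with ambiguous bases skipped")
  }
  codon_counts(counts)
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon `c` in a synonymous family of size `s` with family total `n_F`,
#' `RSCU(c) = count(c) * s / n_F`; families with zero total get 0 for every
#' member. Stop codons form their own family. The family partition comes
#' from `code`, which need not be the code used for amino-acid labeling
#' (mitochondrial codon tables are often printed with mitochondrial
#' amino-acid labels but standard-code families).
#'
#' @param counts a [codon_counts()] table (or coercible named vector).
#' @param code a [genetic_code()] (or name) supplying the synonymous-family
#'   partition.
#' @return named numeric vector of RSCU values over the 64 DNA codons, with
#'   `sum(RSCU) = family size` within each family of nonzero total.
#' @export
rscu <- function(counts, code = genetic_code("standard")) {
  counts <- codon_counts(counts)
  code <- genetic_code(code)
  out <- stats::setNames(numeric(64L), names(counts))
  for (fam in code$families) {
    tot <- sum(counts[fam])
    out[fam] <- if (tot > 0) as.numeric(counts[fam]) * length(fam) / tot else 0
  }
  out
}

#' Amino-acid usage from codon counts
#'
#' Percentage of total codons assigned to each amino acid under the given
#' genetic code; stop codons are reported as their own `*` row and are
#' included in the denominator.
#'
#' @inheritParams rscu
#' @param code a [genetic_code()] (or name) supplying the codon-to-amino-acid
#'   labels.
#' @return data.frame with columns `amino_acid` (one-letter, `*` for stop),
#'   `count`, `percent`, sorted by decreasing percent.
#' @export
aa_usage <- function(counts, code = genetic_code("standard")) {
  counts <- codon_counts(counts)
  code <- genetic_code(code)
  total <- sum(counts)
  if (total == 0L) stop("aa_usage(): zero total codon count")
  by_aa <- tapply(as.numeric(counts), code$aa_of_codon[names(counts)], sum)
  out <- data.frame(amino_acid = names(by_aa),
                    count = as.integer(by_aa),
                    percent = 100 * as.numeric(by_aa) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent, out$amino_acid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract coding sequences from an annotated genome
#'
#' One subsequence per PCG record, reverse-complemented for minus-strand
#' genes and concatenated across the origin for origin-spanning genes. A
#' warning is raised (and the sequence still returned) when a PCG length is
#' not divisible by 3.
#'
#' @inheritParams composition_report
#' @return named list of coding sequences (character), in start order.
#' @export
extract_cds <- function(sequence, annotation) {
  stopifnot(inherits(sequence, "genome_sequence"),
            inherits(annotation, "mito_annotation"))
  rec <- annotation$records
  rec <- rec[rec$category == "PCG", , drop = FALSE]
  out <- lapply(seq_len(nrow(rec)), function(i) {
    s <- region_sequence(sequence, rec$start[i], rec$end[i], rec$strand[i])
    if (nchar(s) %% 3L != 0L) {
      warning("PCG ", rec$gene[i], " length ", nchar(s),
              " not divisible by 3")
    }
    s
  })
  stats::setNames(out, rec$gene)
}
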