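#' Summary census of an annotated mitogenome
#'
#' Headline numbers of the annotation: gene counts by category and strand,
#' total protein-coding length, overlap and spacer extremes, and the
#' putative control-region length.
#'
#' @param annotation a [mito_annotation()].
#' @return one-row data.frame with columns `genome_id`, `genome_length`,
#'   `n_pcg`, `n_trna`, `n_rrna`, `n_control_region`, `n_minus_strand`,
#'   `pcg_total_bp`, `n_overlaps`, `max_overlap_bp`, `longest_spacer_bp`,
#'   `control_region_bp`.
#' @export
annotation_summary <- function(annotation) {
  stopifnot(inherits(annotation, "mito_annotation"))
  rec <- annotation$records
  sp <- if (nrow(rec) >= 2L) suppressWarnings(spacers(annotation)) else
    data.frame(gap = integer())
  cr_len <- tryCatch(identify_control_region(annotation)$length,
                     error = function(e) NA_integer_)
  data.frame(
    genome_id = annotation$genome_id,
    genome_length = annotation$genome_length,
    n_pcg = sum(rec$category == "PCG"),
    n_trna = sum(rec$category == "tRNA"),
    n_rrna = sum(rec$category == "rRNA"),
    n_control_region = sum(rec$category == "control_region"),
    n_minus_strand = sum(rec$strand == "-"),
    pcg_total_bp = sum(rec$length[rec$category == "PCG"]),
    n_overlaps = sum(sp$gap < 0L),
    max_overlap_bp = if (any(sp$gap < 0L)) max(-sp$gap[sp$gap < 0L]) else 0L,
    longest_spacer_bp = if (any(sp$gap > 0L)) max(sp$gap) else 0L,
    control_region_bp = cr_len,
    stringsAsFactors = FALSE)
}

#' Assemble the genome statistics report
#'
#' Bundles the annotation census, spacer/overlap tables, noncoding regions,
#' the putative control region, and (when a sequence is supplied) the
#' per-feature composition/skew table, optionally writing each table to
#' `out_dir` in TSV and/or JSON. Reports are deterministic: rerunning on the
#' same inputs reproduces byte-identical files.
#'
#' @param annotation a [mito_annotation()].
#' @param sequence optional [genome_sequence()].
#' @param out_dir optional directory for report files (created if needed).
#' @param format output formats, subset of `c("tsv", "json")`.
#' @return invisibly, a named list of the report tables.
#' @export
report_stats <- function(annotation, sequence = NULL, out_dir = NULL,
                         format = c("tsv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  tables <- list(
    summary = annotation_summary(annotation),
    spacers = spacers(annotation),
    overlaps = overlaps(annotation),
    noncoding = noncoding_regions(annotation, include_cr_feature = FALSE),
    control_region = identify_control_region(annotation, sequence))
  if (!is.null(sequence)) {
    tables$composition <- composition_report(sequence, annotation)
  }
  write_report_tables(tables, out_dir, format, prefix = "stats")
  invisible(tables)
}

#' Assemble the codon usage report
#'
#' Codon counts, RSCU and amino-acid usage under separate label and family
#' codes: `label_code` names the code whose amino-acid letters annotate the
#' codons (mitochondrial tables are conventionally labeled with the
#' mitochondrial code), while `family_code` names the code whose synonymous
#' families set the RSCU denominators. Counts may be supplied directly or
#' derived from a sequence plus annotation via [extract_cds()].
#'
#' @param counts a [codon_counts()] table, or `NULL` to derive from
#'   `sequence` + `annotation`.
#' @param sequence,annotation used when `counts` is `NULL`.
#' @param label_code,family_code [genetic_code()] names or objects.
#' @inheritParams report_stats
#' @return invisibly, a list with `codon_table` (codon in RNA spelling,
#'   amino-acid label, count, RSCU), `aa_usage`, and `total`.
#' @export
report_codon <- function(counts = NULL, sequence = NULL, annotation = NULL,
                         label_code = "invertebrate_mito",
                         family_code = "standard",
                         out_dir = NULL, format = c("tsv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  if (is.null(counts)) {
    if (is.null(sequence) || is.null(annotation)) {
      stop("supply counts, or sequence plus annotation")
    }
    counts <- count_codons(unlist(extract_cds(sequence, annotation)))
  }
  counts <- codon_counts(counts)
  label_code <- genetic_code(label_code)
  family_code <- genetic_code(family_code)
  r <- rscu(counts, family_code)
  codon_table <- data.frame(
    codon = dna_to_rna(names(counts)),
    aa_label = unname(label_code$aa_of_codon[names(counts)]),
    count = as.integer(counts),
    rscu = round_half_up(unname(r), 2),
    stringsAsFactors = FALSE)
  usage <- aa_usage(counts, label_code)
  usage$percent <- round_half_up(usage$percent, 2)
  tables <- list(codon_table = codon_table, aa_usage = usage,
                 total = data.frame(total_codons = sum(counts)))
  write_report_tables(tables, out_dir, format, prefix = "codon")
  invisible(tables)
}

#' Assemble the gene-order comparison report
#'
#' Conserved block decomposition, singleton list, breakpoint count and the
#' two linear renderings for a pair of signed circular gene orders.
#'
#' @param a,b [gene_order()] objects.
#' @param strict error (rather than warn) on unequal gene sets.
#' @inheritParams report_stats
#' @return invisibly, a list with `blocks` (one row per block: members as a
#'   hyphenated string, size, relative orientation), `singletons`,
#'   `breakpoints`, `render_a`, `render_b`.
#' @export
report_compare <- function(a, b, strict = FALSE, out_dir = NULL,
                           format = c("tsv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  dec <- conserved_blocks(a, b, strict = strict)
  bp <- breakpoint_distance(a, b, strict = strict)
  blocks <- data.frame(
    block = seq_along(dec$blocks),
    genes = vapply(dec$blocks, function(bk) {
      paste(ifelse(bk$sign < 0L, paste0("-", bk$label), bk$label),
            collapse = "-")
    }, ""),
    size = vapply(dec$blocks, nrow, 1L),
    orientation = ifelse(dec$orientations < 0L, "-", "+"),
    stringsAsFactors = FALSE)
  tables <- list(
    blocks = blocks,
    singletons = data.frame(gene = dec$singletons, stringsAsFactors = FALSE),
    comparison = data.frame(genome_a = a$genome_id, genome_b = b$genome_id,
                            shared_genes = dec$n_shared,
                            n_blocks = length(dec$blocks),
                            breakpoints = bp,
                            render_a = render_linear(a),
                            render_b = render_linear(b),
                            stringsAsFactors = FALSE))
  write_report_tables(tables, out_dir, format, prefix = "compare")
  invisible(tables)
}

# write each table under out_dir as <prefix>_<name>.{tsv,json}
write_report_tables <- function(tables, out_dir, format, prefix) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (!is.data.frame(tab)) next
    base <- file.path(out_dir, paste0(prefix, "_", nm))
    if ("tsv" %in% format) {
      utils::write.table(tab, paste0(base, ".tsv"), sep = "\t", quote = FALSE,
                         na = "", row.names = FALSE)
    }
    if ("json" %in% format) {
      jsonlite::write_json(tab, paste0(base, ".json"), dataframe = "rows",
                           auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
    }
  }
  invisible(NULL)
}
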