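#' Mitogenome annotation object
#'
#' Container for the feature table of one (usually circular) mitochondrial
#' genome. Records carry 1-based inclusive coordinates on the external
#' convention of published annotation tables; a feature with `end < start`
#' spans the origin of a circular genome. Records are stored sorted by start
#' coordinate and feature names are made unique by suffixing `_2`, `_3`, ...
#' in start order.
#'
#' @param records data.frame with columns `gene`, `strand` (`+`/`-`),
#'   `start`, `end`, and optionally `category`, `start_codon`, `stop_codon`.
#'   Missing categories are inferred from the name (`trn*` is tRNA,
#'   `12S`/`16S`/`rrn*` is rRNA, names mentioning CR/control/D-loop are
#'   control_region, everything else PCG).
#' @param genome_length genome size in bp.
#' @param circular logical flag; origin-spanning features require `TRUE`.
#' @param genome_id identifier for the genome.
#' @return an object of class `mito_annotation`: a list with `genome_id`,
#'   `genome_length`, `circular`, and the canonicalized `records` data.frame
#'   (with a computed `length` column).
#' @examples
#' ann <- mito_annotation(
#'   data.frame(gene = c("cox1", "trna-lys"), strand = "+",
#'              start = c(10, 1600), end = c(1500, 1670)),
#'   genome_length = 2000)
#' ann$records$length
#' @export
mito_annotation <- function(records, genome_length, circular = TRUE,
                            genome_id = "genome") {
  genome_length <- as.integer(genome_length)
  stopifnot(length(genome_length) == 1L, genome_length >= 1L)
  if (is.null(records) || nrow(records) == 0L) {
    rec <- data.frame(gene = character(), category = character(),
                      strand = character(), start = integer(), end = integer(),
                      length = integer(), start_codon = character(),
                      stop_codon = character(), stringsAsFactors = FALSE)
    return(structure(list(genome_id = genome_id,
                          genome_length = genome_length,
                          circular = isTRUE(circular), records = rec),
                     class = "mito_annotation"))
  }
  need <- c("gene", "strand", "start", "end")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("annotation records lack column(s): ",
                         paste(miss, collapse = ", "))
  rec <- data.frame(gene = as.character(records$gene),
                    strand = normalize_strand(records$strand),
                    start = as.integer(records$start),
                    end = as.integer(records$end),
                    stringsAsFactors = FALSE)
  rec$category <- if ("category" %in% names(records)) {
    cat <- as.character(records$category)
    ifelse(is.na(cat) | cat == "", infer_category(rec$gene), cat)
  } else {
    infer_category(rec$gene)
  }
  valid_cat <- c("PCG", "tRNA", "rRNA", "control_region", "other")
  bad <- setdiff(unique(rec$category), valid_cat)
  if (length(bad)) stop("unknown feature category: ", paste(bad, collapse = ", "))
  for (cc in c("start_codon", "stop_codon")) {
    v <- if (cc %in% names(records)) as.character(records[[cc]]) else NA_character_
    v[!is.na(v) & v == ""] <- NA_character_
    rec[[cc]] <- v
  }
  has_codon <- !is.na(rec$start_codon) | !is.na(rec$stop_codon)
  if (any(has_codon & rec$category != "PCG")) {
    stop("start/stop codons are only allowed for PCG records: ",
         paste(rec$gene[has_codon & rec$category != "PCG"], collapse = ", "))
  }
  out_of_range <- which(is.na(rec$start) | is.na(rec$end) |
                          rec$start < 1L | rec$start > genome_length |
                          rec$end < 1L | rec$end > genome_length)
  if (length(out_of_range)) {
    stop("coordinate outside [1, ", genome_length, "] at record ",
         out_of_range[1L], " (", rec$gene[out_of_range[1L]], ")")
  }
  if (!isTRUE(circular) && any(rec$end < rec$start)) {
    stop("end < start is only permitted on a circular genome: ",
         paste(rec$gene[rec$end < rec$start], collapse = ", "))
  }
  rec <- rec[order(rec$start), , drop = FALSE]
  rec$gene <- dedup_names(rec$gene)
  rec$length <- feature_length(rec$start, rec$end, genome_length,
                               circular = isTRUE(circular))
  rec <- rec[, c("gene", "category", "strand", "start", "end", "length",
                 "start_codon", "stop_codon")]
  rownames(rec) <- NULL
  structure(list(genome_id = genome_id, genome_length = genome_length,
                 circular = isTRUE(circular), records = rec),
            class = "mito_annotation")
}

# infer a feature category from its name
infer_category <- function(name) {
  n <- tolower(name)
  ifelse(grepl("^trn", n), "tRNA",
  ifelse(grepl("^(12s|16s|rrn|s-rrna|l-rrna)", n), "rRNA",
  ifelse(grepl("control|d.?loop|putative|(^|[^a-z])cr([^a-z]|$)", n),
         "control_region", "PCG")))
}

# make names unique by suffixing _2, _3, ... in input order
dedup_names <- function(x) {
  out <- x
  for (nm in unique(x[duplicated(x)])) {
    idx <- which(x == nm)
    out[idx[-1L]] <- paste0(nm, "_", seq_along(idx)[-1L])
  }
  if (anyDuplicated(out)) stop("duplicate feature names persist after suffixing")
  out
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat("Mitogenome annotation:", x$genome_id, "\n")
  cat("  ", x$genome_length, "bp,",
      if (x$circular) "circular," else "linear,",
      nrow(x$records), "features\n")
  if (nrow(x$records)) {
    print(table(x$records$category))
  }
  invisible(x)
}

#' Read an annotation table (TSV)
#'
#' Reads a tab-separated feature table with header columns `gene`, `strand`,
#' `start`, `end` and optionally `category`, `start_codon`, `stop_codon`,
#' using 1-based inclusive coordinates. The genome length is required
#' metadata because the table alone cannot define the circular gap after the
#' last feature.
#'
#' @param file path or connection to the TSV.
#' @inheritParams mito_annotation
#' @return a [mito_annotation()] object.
#' @export
read_annotation_tsv <- function(file, genome_length, circular = TRUE,
                                genome_id = "genome") {
  df <- utils::read.delim(file, header = TRUE, sep = "\t", quote = "",
                          na.strings = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("annotation TSV parse error: no records")
  need <- c("gene", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation TSV parse error: missing column(s) ",
                         paste(miss, collapse = ", "))
  for (cc in c("start", "end")) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad)) stop("annotation TSV parse error: non-integer ", cc,
                          " at data line ", bad[1L])
    df[[cc]] <- v
  }
  mito_annotation(df, genome_length = genome_length, circular = circular,
                  genome_id = genome_id)
}

#' Write an annotation table (TSV)
#'
#' Emits the canonical dialect read by [read_annotation_tsv()]: tab-separated,
#' one record per line, sorted by start coordinate, empty strings for absent
#' codon fields. Reading the output back reproduces the annotation exactly.
#'
#' @param annotation a [mito_annotation()] object.
#' @param file path or connection to write to.
#' @return invisibly, the annotation.
#' @export
write_annotation_tsv <- function(annotation, file) {
  stopifnot(inherits(annotation, "mito_annotation"))
  rec <- annotation$records[, c("gene", "strand", "start", "end", "category",
                                "start_codon", "stop_codon")]
  utils::write.table(rec, file, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  invisible(annotation)
}

#' Genome sequence object
#'
#' A plain container for one genome's residues with a circularity flag.
#'
#' @param id sequence identifier.
#' @param residues character scalar over A/C/G/T/N (case-insensitive).
#' @param circular logical flag.
#' @return an object of class `genome_sequence`.
#' @export
genome_sequence <- function(id, residues, circular = TRUE) {
  residues <- toupper(as.character(residues))
  stopifnot(length(residues) == 1L)
  if (!nzchar(residues)) stop("genome_sequence(): empty residues")
  if (grepl("[^ACGTN]", residues)) {
    stop("genome_sequence(): residues outside {A,C,G,T,N}")
  }
  structure(list(id = as.character(id), residues = residues,
                 circular = isTRUE(circular)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("Genome sequence:", x$id, "-", nchar(x$residues), "bp,",
      if (x$circular) "circular" else "linear", "\n")
  invisible(x)
}

#' Extract the sequence of a genomic region
#'
#' Subsequence on 1-based inclusive coordinates; `end < start` wraps across
#' the origin of a circular genome, and minus-strand regions are returned
#' reverse-complemented (the coding-strand reading).
#'
#' @param sequence a [genome_sequence()].
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return character scalar with the region's residues.
#' @export
region_sequence <- function(sequence, start, end, strand = "+") {
  stopifnot(inherits(sequence, "genome_sequence"))
  s <- sequence$residues
  L <- nchar(s)
  if (start < 1L || start > L || end < 1L || end > L) {
    stop("region [", start, ", ", end, "] outside sequence of length ", L)
  }
  out <- if (end >= start) {
    substr(s, start, end)
  } else {
    if (!sequence$circular) stop("end < start on a linear genome")
    paste0(substr(s, start, L), substr(s, 1L, end))
  }
  if (normalize_strand(strand) == "-") out <- revcomp(out)
  out
}

#' Read/write FASTA
#'
#' Thin wrappers around Biostrings for moving [genome_sequence()] objects in
#' and out of FASTA files.
#'
#' @param file path to a FASTA file.
#' @param circular circularity flag attached to every sequence read.
#' @return `read_fasta()` returns a list of [genome_sequence()] objects
#'   (named by FASTA id); `write_fasta()` returns its input invisibly.
#' @export
read_fasta <- function(file, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(file)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    genome_sequence(ids[i], as.character(set[[i]]), circular = circular)
  })
  stats::setNames(out, ids)
}

#' @param sequences a [genome_sequence()] or list of them.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, file) {
  if (inherits(sequences, "genome_sequence")) sequences <- list(sequences)
  set <- Biostrings::DNAStringSet(vapply(sequences, function(s) s$residues, ""))
  names(set) <- vapply(sequences, function(s) s$id, "")
  Biostrings::writeXStringSet(set, file, width = 70L)
  invisible(sequences)
}
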