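#' Minimal GenBank flat-file reader
#'
#' Parses the subset of the GenBank flat-file format needed for mitogenome
#' annotations: the LOCUS length and circular flag, CDS / tRNA / rRNA /
#' D-loop / misc_feature entries with `complement(...)` and origin-spanning
#' `join(a..L,1..b)` locations, `/gene` (or `/product`) names, and the ORIGIN
#' sequence block. Feature keys map to categories as CDS = PCG, tRNA = tRNA,
#' rRNA = rRNA, D-loop = control_region, misc_feature = other; `complement()`
#' maps to strand `-`. The package's own writer additionally emits
#' `/start_codon` and `/stop_codon` qualifiers on CDS features, which are
#' read back when present.
#'
#' @param file path to a GenBank flat file.
#' @return list with elements `sequence` (a [genome_sequence()]) and
#'   `annotation` (a [mito_annotation()]).
#' @export
read_genbank <- function(file) {
  lines <- readLines(file, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("GenBank parse error: no LOCUS line")
  toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
  genome_id <- toks[2L]
  len_tok <- which(toks == "bp") - 1L
  genome_length <- suppressWarnings(as.integer(toks[len_tok]))
  if (is.na(genome_length)) stop("GenBank parse error: no length on LOCUS line")
  circular <- any(grepl("circular", locus[1L], ignore.case = TRUE))

  ori_at <- grep("^ORIGIN", lines)
  if (!length(ori_at)) stop("GenBank parse error: missing ORIGIN sequence")
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[end_at > ori_at[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[seq(ori_at[1L] + 1L, end_at - 1L)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(residues)) stop("GenBank parse error: missing ORIGIN sequence")
  if (nchar(residues) != genome_length) {
    stop("GenBank parse error: ORIGIN length ", nchar(residues),
         " != LOCUS length ", genome_length)
  }

  feat_at <- grep("^FEATURES", lines)
  recs <- NULL
  if (length(feat_at)) {
    block <- lines[seq(feat_at[1L] + 1L, ori_at[1L] - 1L)]
    recs <- parse_genbank_features(block, genome_length)
  }
  if (is.null(recs) || nrow(recs) == 0L) {
    warning("GenBank file has no annotated features")
    recs <- NULL
  }
  list(sequence = genome_sequence(genome_id, residues, circular = circular),
       annotation = mito_annotation(recs, genome_length = genome_length,
                                    circular = circular,
                                    genome_id = genome_id))
}

# parse the FEATURES block into a records data.frame
parse_genbank_features <- function(block, genome_length) {
  is_header <- grepl("^ {5}[A-Za-z0-9'_-]+ +\\S", block) &
    !grepl("^ *\\/", block)
  idx <- which(is_header)
  if (!length(idx)) return(NULL)
  out <- list()
  for (k in seq_along(idx)) {
    from <- idx[k]
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
    body <- block[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", body[1L])
    if (key == "source") next
    qual_at <- grep("^ *\\/", body)
    loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(body)
    loc <- gsub("\\s", "", paste(sub("^ {5}\\S+", "", body[1L]),
                                 paste(body[setdiff(seq_len(loc_end), 1L)],
                                       collapse = ""), sep = ""))
    pl <- parse_genbank_location(loc, genome_length)
    quals <- paste(trimws(body[qual_at]), collapse = "\n")
    name <- genbank_qualifier(quals, "gene") %||%
      genbank_qualifier(quals, "product") %||% paste0(key, "_", k)
    category <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       `D-loop` = "control_region", "other")
    out[[length(out) + 1L]] <- data.frame(
      gene = name, strand = pl$strand, start = pl$start, end = pl$end,
      category = category,
      start_codon = if (category == "PCG")
        genbank_qualifier(quals, "start_codon") %||% NA_character_
        else NA_character_,
      stop_codon = if (category == "PCG")
        genbank_qualifier(quals, "stop_codon") %||% NA_character_
        else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

genbank_qualifier <- function(quals, name) {
  m <- regmatches(quals, regexec(paste0("/", name, "=\"([^\"]*)\""), quals))[[1L]]
  if (length(m) == 2L) m[2L] else NULL
}

# locations: a..b, complement(a..b), join(a..L,1..b), complement(join(...)), a
parse_genbank_location <- function(loc, genome_length) {
  strand <- "+"
  x <- loc
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) {
    x <- sub("^join\\((.*)\\)$", "\\1", x)
    parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
    rng <- lapply(parts, parse_genbank_range)
    if (length(rng) != 2L || rng[[1L]]$end != genome_length ||
        rng[[2L]]$start != 1L) {
      stop("GenBank parse error: unsupported join location '", loc, "'")
    }
    start <- rng[[1L]]$start
    end <- rng[[2L]]$end
  } else {
    r <- parse_genbank_range(x)
    start <- r$start
    end <- r$end
  }
  if (start < 1L || end < 1L || start > genome_length || end > genome_length) {
    stop("GenBank parse error: feature location '", loc,
         "' beyond sequence length ", genome_length)
  }
  list(start = start, end = end, strand = strand)
}

parse_genbank_range <- function(x) {
  x <- gsub("[<>]", "", x)
  if (grepl("\\.\\.", x)) {
    ab <- as.integer(strsplit(x, "..", fixed = TRUE)[[1L]])
    list(start = ab[1L], end = ab[2L])
  } else {
    p <- as.integer(x)
    list(start = p, end = p)
  }
}

#' Write a minimal GenBank flat file
#'
#' Emits a flat file readable by [read_genbank()]: LOCUS, FEATURES with one
#' entry per annotation record (plus a `source` feature), and the ORIGIN
#' block. Minus-strand features are written as `complement(...)` and
#' origin-spanning features as `join(start..L,1..end)`. CDS start/stop codons
#' recorded in the annotation are emitted as `/start_codon` and
#' `/stop_codon` qualifiers (a package dialect; standard parsers ignore
#' unknown qualifiers).
#'
#' @param sequence a [genome_sequence()].
#' @param annotation a [mito_annotation()] for the same genome.
#' @param file path to write to.
#' @return invisibly, `file`.
#' @export
write_genbank <- function(sequence, annotation, file) {
  stopifnot(inherits(sequence, "genome_sequence"),
            inherits(annotation, "mito_annotation"))
  L <- nchar(sequence$residues)
  if (L != annotation$genome_length) {
    stop("sequence length ", L, " != annotation genome_length ",
         annotation$genome_length)
  }
  topo <- if (sequence$circular) "circular" else "linear"
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s INV 01-JAN-2026",
            sequence$id, L, topo),
    sprintf("DEFINITION  %s.", sequence$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L))
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
              control_region = "D-loop", other = "misc_feature")
  rec <- annotation$records
  for (i in seq_len(nrow(rec))) {
    loc <- if (rec$end[i] >= rec$start[i]) {
      sprintf("%d..%d", rec$start[i], rec$end[i])
    } else {
      sprintf("join(%d..%d,1..%d)", rec$start[i], L, rec$end[i])
    }
    if (rec$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     %-15s %s", key_of[[rec$category[i]]], loc),
             sprintf("                     /gene=\"%s\"", rec$gene[i]))
    if (rec$category[i] == "PCG" && !is.na(rec$start_codon[i])) {
      out <- c(out, sprintf("                     /start_codon=\"%s\"",
                            rec$start_codon[i]))
    }
    if (rec$category[i] == "PCG" && !is.na(rec$stop_codon[i])) {
      out <- c(out, sprintf("                     /stop_codon=\"%s\"",
                            rec$stop_codon[i]))
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(sequence$residues)
  starts <- seq(1L, L, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, L))
    tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, file)
  invisible(file)
}
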