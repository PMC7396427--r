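#' Specification for synthetic mitogenome generation
#'
#' Bundles the parameters of the seeded generator. Defaults emulate the
#' focal sea-cucumber mitogenome: the packaged 15,969 bp annotation as the
#' geometry template, whole-genome base fractions A 0.356 / T 0.296 /
#' C 0.222 / G 0.126, an AT boost of +0.05 inside control regions, and a
#' codon bias proportional to the packaged codon-count table. A single
#' integer seed drives one pseudo-random stream; all stochastic choices draw
#' from it in documented order, so outputs are reproducible.
#'
#' @param seed mandatory integer seed.
#' @param genome_length genome size in bp.
#' @param target_composition base fractions (named A/C/G/T) summing to 1.
#' @param annotation_template `"focal"` (the packaged annotation) or a
#'   [mito_annotation()] whose geometry fits `genome_length`.
#' @param codon_bias optional named distribution over codons for planted
#'   coding sequence; `NULL` uses the packaged codon-count distribution.
#' @param cr_at_boost increase of the A+T mass inside control regions.
#' @param start_codons,stop_codons codon pools for planted CDS ends.
#' @param n_events number of rearrangement events for [synth_order_pair()].
#' @param event_mix named fractions over
#'   inversion/transposition/reverse_transposition/tdrl, summing to 1.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(seed,
                       genome_length = 15969L,
                       target_composition = c(A = 0.356, C = 0.222,
                                              G = 0.126, T = 0.296),
                       annotation_template = "focal",
                       codon_bias = NULL,
                       cr_at_boost = 0.05,
                       start_codons = "ATG",
                       stop_codons = "TAA",
                       n_events = 2L,
                       event_mix = c(inversion = 0.25, transposition = 0.25,
                                     reverse_transposition = 0.25,
                                     tdrl = 0.25)) {
  if (missing(seed)) stop("synth_spec(): seed is mandatory")
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  comp <- target_composition[c("A", "C", "G", "T")]
  if (anyNA(comp)) stop("target_composition must name A, C, G and T")
  if (abs(sum(comp) - 1) > 1e-9) {
    stop("target_composition fractions must sum to 1 (got ", sum(comp), ")")
  }
  if (abs(sum(event_mix) - 1) > 1e-9) stop("event_mix must sum to 1")
  kinds <- c("inversion", "transposition", "reverse_transposition", "tdrl")
  if (!all(names(event_mix) %in% kinds)) {
    stop("event_mix names must be among: ", paste(kinds, collapse = ", "))
  }
  if (!is.null(codon_bias)) {
    codon_bias <- as.numeric(codon_counts(codon_bias))
    names(codon_bias) <- codon_alphabet()
  }
  structure(list(seed = seed, genome_length = as.integer(genome_length),
                 target_composition = comp,
                 annotation_template = annotation_template,
                 codon_bias = codon_bias, cr_at_boost = cr_at_boost,
                 start_codons = toupper(start_codons),
                 stop_codons = toupper(stop_codons),
                 n_events = as.integer(n_events), event_mix = event_mix),
            class = "synth_spec")
}

synth_template <- function(spec) {
  ann <- if (identical(spec$annotation_template, "focal")) {
    focal_annotation()
  } else {
    spec$annotation_template
  }
  stopifnot(inherits(ann, "mito_annotation"))
  if (max(c(ann$records$start, ann$records$end, 0L)) > spec$genome_length) {
    stop("template overflow: template features exceed genome_length ",
         spec$genome_length)
  }
  mito_annotation(ann$records, genome_length = spec$genome_length,
                  circular = ann$circular, genome_id = ann$genome_id)
}

# 1-based positions covered by a feature, wrapping the origin when end<start
feature_positions <- function(start, end, L) {
  if (end >= start) seq.int(start, end) else c(seq.int(start, L), seq.int(1L, end))
}

#' Generate a synthetic annotated mitogenome
#'
#' Builds a genome sequence over the template's geometry: background and RNA
#' positions are drawn i.i.d. from the target composition, control-region
#' positions from an AT-boosted composition, and each protein-coding gene is
#' filled with an in-frame CDS (start codon, interior codons drawn from the
#' codon-bias distribution with stop codons excluded, terminal stop codon),
#' reverse-complemented onto minus strands and wrapped across the origin
#' where the template requires it. When two coding genes overlap, the gene
#' written later (by start coordinate) owns the shared bases; the returned
#' ground-truth CDS are read back from the finished sequence by direct
#' character indexing, independently of [extract_cds()].
#'
#' @param spec a [synth_spec()].
#' @return list with `sequence` (a [genome_sequence()]), `annotation`
#'   (a [mito_annotation()]), `cds` (named list of planted coding
#'   sequences), and `spec`. Deterministic given `spec$seed`.
#' @export
synth_genome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  ann <- synth_template(spec)
  L <- spec$genome_length
  comp <- spec$target_composition
  bias <- spec$codon_bias %||% {
    cc <- focal_codon_counts()
    stats::setNames(as.numeric(cc) / sum(cc), names(cc))
  }
  code <- genetic_code("invertebrate_mito")
  interior <- bias
  interior[code$families[["*"]]] <- 0
  interior <- interior / sum(interior)
  rec <- ann$records
  chars <- withr::with_seed(spec$seed, {
    ch <- sample(names(comp), L, replace = TRUE, prob = comp)
    # control regions: AT-boosted background
    cr <- rec[rec$category == "control_region", , drop = FALSE]
    if (nrow(cr)) {
      at <- comp[["A"]] + comp[["T"]]
      at2 <- min(at + spec$cr_at_boost, 0.98)
      boosted <- comp
      boosted[c("A", "T")] <- comp[c("A", "T")] * at2 / at
      boosted[c("C", "G")] <- comp[c("C", "G")] * (1 - at2) / (1 - at)
      for (i in seq_len(nrow(cr))) {
        pos <- feature_positions(cr$start[i], cr$end[i], L)
        ch[pos] <- sample(names(boosted), length(pos), replace = TRUE,
                          prob = boosted)
      }
    }
    # protein-coding genes: planted in-frame CDS
    pcg <- rec[rec$category == "PCG", , drop = FALSE]
    for (i in seq_len(nrow(pcg))) {
      len <- pcg$length[i]
      n_cod <- len %/% 3L
      cds <- character()
      if (n_cod >= 1L) {
        start_c <- if (length(spec$start_codons) == 1L) spec$start_codons else
          sample(spec$start_codons, 1L)
        stop_c <- if (length(spec$stop_codons) == 1L) spec$stop_codons else
          sample(spec$stop_codons, 1L)
        mid <- if (n_cod > 2L) {
          sample(names(interior), n_cod - 2L, replace = TRUE, prob = interior)
        } else character()
        cds <- utils::head(c(start_c, mid, stop_c), n_cod)
      }
      filled <- strsplit(paste(cds, collapse = ""), "", fixed = TRUE)[[1L]]
      leftover <- len - length(filled)
      if (leftover > 0L) {
        filled <- c(filled, sample(names(comp), leftover, replace = TRUE,
                                   prob = comp))
      }
      pos <- feature_positions(pcg$start[i], pcg$end[i], L)
      if (pcg$strand[i] == "-") {
        filled <- rev(chartr("ACGT", "TGCA", filled))
      }
      ch[pos] <- filled
    }
    ch
  })
  # ground truth read-back by direct character indexing
  pcg <- rec[rec$category == "PCG", , drop = FALSE]
  planted <- lapply(seq_len(nrow(pcg)), function(i) {
    pos <- feature_positions(pcg$start[i], pcg$end[i], L)
    v <- chars[pos]
    if (pcg$strand[i] == "-") v <- rev(chartr("ACGT", "TGCA", v))
    paste(v, collapse = "")
  })
  list(sequence = genome_sequence(paste0("synth_", spec$seed),
                                  paste(chars, collapse = ""),
                                  circular = ann$circular),
       annotation = mito_annotation(rec, genome_length = L,
                                    circular = ann$circular,
                                    genome_id = paste0("synth_", spec$seed)),
       cds = stats::setNames(planted, pcg$gene),
       spec = spec)
}

#' Generate a seeded pair of gene orders related by known events
#'
#' Starts from the template's gene order and applies `spec$n_events`
#' rearrangement events with kinds drawn from `spec$event_mix` and random
#' valid positions, logging each event, so the expected block structure is
#' known ground truth.
#'
#' @param spec a [synth_spec()].
#' @param base optional [gene_order()] to start from (default: the
#'   template's order).
#' @return list with `a` (the base order), `b` (the rearranged order), and
#'   `log` (list of per-event records: `kind`, `i`, `j`, `dest`, `span` of
#'   labels moved, in pre-event coordinates). Label sets of `a` and `b` are
#'   always equal.
#' @export
synth_order_pair <- function(spec, base = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  base <- base %||% order_from_annotation(synth_template(spec))
  derived <- gene_order(base$labels, base$signs,
                        paste0(base$genome_id, "_derived"))
  log <- list()
  derived <- withr::with_seed(spec$seed, {
    o <- derived
    for (e in seq_len(spec$n_events)) {
      n <- length(o)
      kind <- sample(names(spec$event_mix), 1L, prob = spec$event_mix)
      span_len <- sample.int(max(1L, n %/% 4L), 1L)
      i <- sample.int(n - span_len + 1L, 1L)
      j <- i + span_len - 1L
      dest <- NULL
      if (kind %in% c("transposition", "reverse_transposition")) {
        cand <- setdiff(0:n, seq(i - 1L, j))
        if (!length(cand)) next
        dest <- cand[sample.int(length(cand), 1L)]
      }
      ev <- rearrangement_event(kind, i, j, dest)
      log[[length(log) + 1L]] <- list(kind = kind, i = i, j = j,
                                      dest = dest,
                                      span = o$labels[i:j])
      o <- apply_event(o, ev)
    }
    o
  })
  list(a = base, b = derived, log = log)
}
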