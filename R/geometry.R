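#' Feature length on a (possibly circular) genome
#'
#' Length in bp of a feature given 1-based inclusive coordinates. On a
#' circular genome `end < start` denotes an origin-spanning feature whose
#' length is `genome_length - start + 1 + end`.
#'
#' @param start,end 1-based inclusive coordinates (vectorized).
#' @param genome_length genome size in bp.
#' @param circular logical; `end < start` errors when `FALSE`.
#' @return integer vector of lengths.
#' @examples
#' feature_length(10776, 12605, 15969)  # nad5: 1830
#' @export
feature_length <- function(start, end, genome_length, circular = TRUE) {
  start <- as.integer(start)
  end <- as.integer(end)
  genome_length <- as.integer(genome_length)
  if (any(start < 1L | end < 1L | start > genome_length | end > genome_length)) {
    stop("coordinates outside [1, ", genome_length, "]")
  }
  wrap <- end < start
  if (any(wrap) && !isTRUE(circular)) {
    stop("end < start on a linear genome")
  }
  ifelse(wrap, genome_length - start + 1L + end, end - start + 1L)
}

#' Intergenic spacers between adjacent features
#'
#' For features taken in start-coordinate order around the genome, the gap
#' between consecutive features is `next_start - prev_end - 1` bp; on a
#' circular genome the wrap-around pair contributes
#' `first_start + genome_length - last_end - 1`. Negative gaps are overlaps.
#' Adjacency is purely positional: strand is ignored.
#'
#' @param annotation a [mito_annotation()] with at least two records.
#' @return data.frame with columns `prev_name`, `next_name`, `gap` (bp;
#'   negative = overlap), one row per adjacent pair (n rows for n features on
#'   a circular genome, n - 1 on a linear one).
#' @export
spacers <- function(annotation) {
  stopifnot(inherits(annotation, "mito_annotation"))
  rec <- annotation$records
  if (nrow(rec) < 2L) stop("spacers(): need at least two features")
  if (is.unsorted(rec$start)) {
    warning("records not sorted by start; sorting internally")
    rec <- rec[order(rec$start), , drop = FALSE]
  }
  adjacent_gaps(rec, annotation$genome_length, annotation$circular)
}

# gap table for a record data.frame already sorted by start
adjacent_gaps <- function(rec, L, circular) {
  n <- nrow(rec)
  prev <- seq_len(n - 1L)
  gaps <- rec$start[prev + 1L] - rec$end[prev] - 1L
  out <- data.frame(prev_name = rec$gene[prev], next_name = rec$gene[prev + 1L],
                    gap = as.integer(gaps), stringsAsFactors = FALSE)
  if (circular && n >= 2L) {
    last_end <- rec$end[n]
    wrap_gap <- if (last_end >= rec$start[n]) {
      rec$start[1L] + L - last_end - 1L
    } else {
      # last feature already spans the origin; it ends at last_end < start
      rec$start[1L] - last_end - 1L
    }
    out <- rbind(out, data.frame(prev_name = rec$gene[n],
                                 next_name = rec$gene[1L],
                                 gap = as.integer(wrap_gap),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Overlapping adjacent features
#'
#' The subset of [spacers()] with negative gaps, sorted by overlap size
#' (largest first). Only adjacent-pair overlaps are counted; a feature fully
#' contained in a non-adjacent feature triggers a warning but is not listed.
#'
#' @inheritParams spacers
#' @return data.frame like [spacers()], restricted to `gap < 0`, ordered by
#'   decreasing `|gap|`.
#' @export
overlaps <- function(annotation) {
  sp <- spacers(annotation)
  warn_nonadjacent_containment(annotation)
  ov <- sp[sp$gap < 0L, , drop = FALSE]
  ov <- ov[order(ov$gap), , drop = FALSE]
  rownames(ov) <- NULL
  ov
}

# warn when non-adjacent features intersect (containment etc.)
warn_nonadjacent_containment <- function(annotation) {
  rec <- annotation$records
  n <- nrow(rec)
  if (n < 3L) return(invisible(NULL))
  L <- annotation$genome_length
  ivs <- lapply(seq_len(n), function(i) {
    if (rec$end[i] >= rec$start[i]) {
      matrix(c(rec$start[i], rec$end[i]), ncol = 2L)
    } else {
      rbind(c(rec$start[i], L), c(1L, rec$end[i]))
    }
  })
  hits <- character()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      adjacent <- (j == i + 1L) || (annotation$circular && i == 1L && j == n)
      if (adjacent) next
      inter <- any(outer(seq_len(nrow(ivs[[i]])), seq_len(nrow(ivs[[j]])),
                         Vectorize(function(a, b) {
                           ivs[[i]][a, 1L] <= ivs[[j]][b, 2L] &&
                             ivs[[j]][b, 1L] <= ivs[[i]][a, 2L]
                         })))
      if (inter) hits <- c(hits, paste0(rec$gene[i], "/", rec$gene[j]))
    }
  }
  if (length(hits)) {
    warning("non-adjacent feature pairs intersect (not counted as overlaps): ",
            paste(hits, collapse = ", "))
  }
  invisible(NULL)
}

#' Noncoding regions of an annotated genome
#'
#' Positive intergenic gaps converted to coordinate regions. With
#' `include_cr_feature = FALSE` (the default) annotated control-region
#' features are treated as noncoding sequence: they are removed from the
#' feature set before gaps are computed, so the control region merges with
#' any flanking gaps into a single noncoding region. With
#' `include_cr_feature = TRUE` the control region counts as an annotated
#' feature and only the gaps between features are reported.
#'
#' @inheritParams spacers
#' @param include_cr_feature logical; see Details.
#' @return data.frame with columns `start`, `end` (1-based inclusive,
#'   possibly wrapping the origin), `length`, `prev_name`, `next_name`.
#' @export
noncoding_regions <- function(annotation, include_cr_feature = FALSE) {
  stopifnot(inherits(annotation, "mito_annotation"))
  rec <- annotation$records
  if (!include_cr_feature) {
    rec <- rec[rec$category != "control_region", , drop = FALSE]
  }
  L <- annotation$genome_length
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      prev_name = character(), next_name = character(),
                      stringsAsFactors = FALSE)
  n <- nrow(rec)
  if (n == 0L) return(empty)
  rec <- rec[order(rec$start), , drop = FALSE]
  if (n == 1L) {
    if (!annotation$circular) return(empty)
    gap <- L - rec$length[1L]
    if (gap <= 0L) return(empty)
    return(data.frame(start = rec$end[1L] %% L + 1L,
                      end = (rec$start[1L] - 2L) %% L + 1L,
                      length = gap, prev_name = rec$gene[1L],
                      next_name = rec$gene[1L], stringsAsFactors = FALSE))
  }
  gp <- adjacent_gaps(rec, L, annotation$circular)
  ends <- c(rec$end[-n], rec$end[n])
  starts_next <- c(rec$start[-1L], rec$start[1L])
  keep <- which(gp$gap > 0L)
  if (!length(keep)) return(empty)
  data.frame(start = ends[keep] %% L + 1L,
             end = (starts_next[keep] - 2L) %% L + 1L,
             length = gp$gap[keep],
             prev_name = gp$prev_name[keep],
             next_name = gp$next_name[keep],
             stringsAsFactors = FALSE)
}

#' Identify the putative control region
#'
#' The control region of a mitogenome is its major noncoding, AT-rich
#' region. This returns the longest noncoding region (annotated control
#' regions counting as noncoding), breaking ties by lower start coordinate.
#' When the genome sequence is supplied, the region's A+T fraction is
#' reported and a warning is raised if it falls below `at_threshold`.
#'
#' @inheritParams spacers
#' @param sequence optional [genome_sequence()] for AT-richness checking.
#' @param at_threshold minimum A+T fraction (default 0.60) for an AT-richness
#'   warning when `sequence` is given.
#' @return one-row data.frame as in [noncoding_regions()], with an extra
#'   `at_fraction` column when `sequence` is supplied.
#' @export
identify_control_region <- function(annotation, sequence = NULL,
                                    at_threshold = 0.60) {
  regs <- noncoding_regions(annotation, include_cr_feature = FALSE)
  if (nrow(regs) == 0L) stop("no noncoding region in annotation")
  best <- regs[order(-regs$length, regs$start), , drop = FALSE][1L, , drop = FALSE]
  if (!is.null(sequence)) {
    bc <- base_composition(region_sequence(sequence, best$start, best$end, "+"))
    at <- unname(bc$at_percent) / 100
    best$at_fraction <- at
    if (at < at_threshold) {
      warning(sprintf(
        "best candidate control region has A+T fraction %.3f < threshold %.2f",
        at, at_threshold))
    }
  }
  rownames(best) <- NULL
  best
}
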