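#' Canonical mitochondrial gene alphabet
#'
#' The 37 genes of the standard metazoan mitogenome: 13 protein-coding genes,
#' the two rRNAs (rrnS, rrnL) and 22 tRNAs named by one-letter amino-acid
#' code with the serine and leucine isoacceptors distinguished as S1 (AGN),
#' S2 (UCN), L1 (CUN) and L2 (UUR).
#'
#' @return character vector of 37 canonical labels.
#' @export
mito_gene_alphabet <- function() {
  c("cox1", "cox2", "cox3", "cob", "nad1", "nad2", "nad3", "nad4", "nad4L",
    "nad5", "nad6", "atp6", "atp8", "rrnS", "rrnL",
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2", "M", "N", "P",
    "Q", "R", "S1", "S2", "T", "V", "W", "Y")
}

#' Normalize gene names to canonical labels
#'
#' Maps the naming conventions of published annotation tables onto the
#' canonical alphabet of [mito_gene_alphabet()]: `cytb` to `cob`, `12S`/
#' `rrn12` to `rrnS`, `16S`/`rrn16` to `rrnL`, tRNAs named by three-letter
#' amino acid (optionally with anticodon, e.g. `trna-ser(tga)` = S2,
#' `trna-ser(gct)` = S1, `trna-leu(tag)` = L1, `trna-leu(taa)` = L2) or by
#' one-letter code (`trnP`, `trnS2`). Matching is case-insensitive.
#'
#' @param x character vector of gene names.
#' @param name_map optional named character vector of extra synonyms
#'   (lower-case name to canonical label), consulted first.
#' @return character vector of canonical labels; unmapped names are an error
#'   naming the offender.
#' @export
normalize_gene_labels <- function(x, name_map = NULL) {
  vapply(as.character(x), normalize_one_label, "", name_map = name_map,
         USE.NAMES = FALSE)
}

normalize_one_label <- function(name, name_map = NULL) {
  k <- tolower(gsub("[ _]", "", trimws(name)))
  k <- gsub("−", "-", k)
  if (!is.null(name_map) && k %in% tolower(names(name_map))) {
    return(unname(name_map[[match(k, tolower(names(name_map)))]]))
  }
  canon <- mito_gene_alphabet()
  hit <- match(k, tolower(canon))
  if (!is.na(hit)) return(canon[hit])
  direct <- c(cytb = "cob", cob = "cob", "cytochromeb" = "cob",
              "12s" = "rrnS", "16s" = "rrnL", rrn12 = "rrnS", rrn16 = "rrnL",
              rrns = "rrnS", rrnl = "rrnL", srrna = "rrnS", lrrna = "rrnL",
              "12srrna" = "rrnS", "16srrna" = "rrnL")
  if (k %in% names(direct)) return(unname(direct[[k]]))
  aa3 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C", gln = "Q",
           glu = "E", gly = "G", his = "H", ile = "I", lys = "K", met = "M",
           phe = "F", pro = "P", thr = "T", trp = "W", tyr = "Y", val = "V")
  m <- regmatches(k, regexec(
    "^trn[a]?-?([a-z]{3})(\\(([a-z]{3})\\))?$", k))[[1L]]
  if (length(m)) {
    aa <- m[2L]
    anti <- m[4L]
    if (aa == "leu") {
      if (identical(anti, "tag")) return("L1")
      if (identical(anti, "taa")) return("L2")
      stop("ambiguous leucine tRNA name (need anticodon tag/taa): ", name)
    }
    if (aa == "ser") {
      if (identical(anti, "tga")) return("S2")
      if (identical(anti, "gct")) return("S1")
      stop("ambiguous serine tRNA name (need anticodon tga/gct): ", name)
    }
    if (aa %in% names(aa3)) return(unname(aa3[[aa]]))
  }
  m <- regmatches(k, regexec("^trn[a]?-?(leu|ser)([12])$", k))[[1L]]
  if (length(m)) {
    return(paste0(if (m[2L] == "leu") "L" else "S", m[3L]))
  }
  m <- regmatches(k, regexec("^trn[a]?-?([a-z])([12])?$", k))[[1L]]
  if (length(m)) {
    lab <- paste0(toupper(m[2L]), m[3L])
    if (lab %in% canon) return(lab)
  }
  stop("cannot map gene name to canonical label: '", name, "'")
}

#' Signed circular gene order
#'
#' A circular sequence of unique gene labels with transcription orientation,
#' the standard model of mitogenome gene arrangement (a signed circular
#' permutation).
#'
#' @param labels character vector of unique labels (no whitespace or `-`).
#' @param orientations orientations as `+1`/`-1` or `"+"`/`"-"`; defaults to
#'   all forward.
#' @param genome_id identifier.
#' @return object of class `gene_order`: list with `genome_id`, `labels`,
#'   `signs` (integer `+1`/`-1`).
#' @export
gene_order <- function(labels, orientations = NULL, genome_id = "order") {
  labels <- as.character(labels)
  if (!length(labels)) stop("gene_order(): empty label list")
  if (anyDuplicated(labels)) {
    stop("gene_order(): duplicated labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(grepl("[-[:space:]\\[\\]]", labels))) {
    stop("gene_order(): labels must not contain '-', brackets or whitespace")
  }
  signs <- if (is.null(orientations)) {
    rep(1L, length(labels))
  } else if (is.character(orientations)) {
    ifelse(normalize_strand(orientations) == "+", 1L, -1L)
  } else {
    s <- as.integer(sign(orientations))
    if (any(s == 0L)) stop("gene_order(): orientations must be nonzero")
    s
  }
  stopifnot(length(signs) == length(labels))
  structure(list(genome_id = as.character(genome_id), labels = labels,
                 signs = signs),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(format_gene_order(x), "\n")
  invisible(x)
}

format_gene_order <- function(x) {
  paste0(x$genome_id, ": ",
         paste(ifelse(x$signs < 0L, paste0("-", x$labels), x$labels),
               collapse = " "))
}

#' @export
length.gene_order <- function(x) length(x$labels)

#' Gene order from an annotation
#'
#' Features sorted by start coordinate with orientation taken from the
#' strand; control-region features are excluded and names are normalized via
#' [normalize_gene_labels()].
#'
#' @param annotation a [mito_annotation()].
#' @param name_map optional extra synonyms, see [normalize_gene_labels()].
#' @return a [gene_order()].
#' @export
order_from_annotation <- function(annotation, name_map = NULL) {
  stopifnot(inherits(annotation, "mito_annotation"))
  rec <- annotation$records
  rec <- rec[rec$category != "control_region", , drop = FALSE]
  if (!nrow(rec)) stop("annotation has no gene features")
  gene_order(normalize_gene_labels(rec$gene, name_map = name_map),
             orientations = rec$strand, genome_id = annotation$genome_id)
}

#' Rotate / reflect a circular gene order
#'
#' `rotate_order()` moves the element named `to_label` (or at offset `k`)
#' to the front; `reverse_complement_order()` reads the circle from the
#' other strand (labels reversed, all orientations flipped). Both leave the
#' molecule's biological identity unchanged.
#'
#' @param order a [gene_order()].
#' @param to_label label to rotate to the front.
#' @param k integer offset (used when `to_label` is `NULL`).
#' @return a [gene_order()].
#' @export
rotate_order <- function(order, to_label = NULL, k = 0L) {
  n <- length(order)
  if (!is.null(to_label)) {
    k <- match(to_label, order$labels) - 1L
    if (is.na(k)) stop("label not in order: ", to_label)
  }
  idx <- ((seq_len(n) - 1L + k) %% n) + 1L
  gene_order(order$labels[idx], order$signs[idx], order$genome_id)
}

#' @rdname rotate_order
#' @export
reverse_complement_order <- function(order) {
  gene_order(rev(order$labels), -rev(order$signs), order$genome_id)
}

# circular signed adjacencies as a data.frame (empty for n < 2)
signed_adjacencies <- function(o) {
  n <- length(o)
  if (n < 2L) {
    return(data.frame(x = character(), sx = integer(),
                      y = character(), sy = integer()))
  }
  i <- seq_len(n)
  j <- c(seq_len(n)[-1L], 1L)
  data.frame(x = o$labels[i], sx = o$signs[i],
             y = o$labels[j], sy = o$signs[j], stringsAsFactors = FALSE)
}

adj_key <- function(x, sx, y, sy) paste0(x, ":", sx, ">", y, ":", sy)

# restrict both orders to their shared label set (order-preserving)
restrict_to_shared <- function(a, b, strict = FALSE) {
  shared <- intersect(a$labels, b$labels)
  if (!setequal(a$labels, b$labels)) {
    missing_a <- setdiff(b$labels, a$labels)
    missing_b <- setdiff(a$labels, b$labels)
    msg <- paste0("gene sets differ (only in ", a$genome_id, ": ",
                  paste(missing_b, collapse = ","), "; only in ",
                  b$genome_id, ": ", paste(missing_a, collapse = ","), ")")
    if (strict) stop(msg)
    warning(msg, "; restricting to the ", length(shared), " shared labels")
  }
  if (!length(shared)) stop("no shared labels between the two orders")
  keep <- function(o) {
    sel <- o$labels %in% shared
    gene_order(o$labels[sel], o$signs[sel], o$genome_id)
  }
  list(a = keep(a), b = keep(b))
}

#' Conserved block decomposition of two signed circular gene orders
#'
#' A signed adjacency (x, y) of order `a` is conserved when (x, y) or its
#' full reversal (-y, -x) is adjacent in order `b`; conserved blocks are the
#' maximal circular runs of `a` whose internal adjacencies are all
#' conserved. Equivalently, each block is a maximal run of genes contiguous
#' and co-oriented (or fully reversed) in both genomes. Blocks appearing
#' reversed in `b` carry relative orientation `-1`. Comparison is invariant
#' under rotation of either order and under reading either molecule from the
#' other strand.
#'
#' @param a,b [gene_order()] objects. Unequal label sets are restricted to
#'   the intersection with a warning, or are an error when `strict = TRUE`.
#' @param strict logical; error on unequal label sets.
#' @return object of class `block_decomposition`: list with `blocks` (list
#'   of data.frames with columns `label`, `sign`, in the order and
#'   orientation of `a`), `orientations` (relative orientation of each block
#'   in `b`, `+1`/`-1`), `singletons` (labels in no block of size >= 2) and
#'   `n_shared`. Blocks are reported in their order of appearance in `a`,
#'   starting from the block containing `cox1` when present.
#' @export
conserved_blocks <- function(a, b, strict = FALSE) {
  stopifnot(inherits(a, "gene_order"), inherits(b, "gene_order"))
  r <- restrict_to_shared(a, b, strict = strict)
  a2 <- r$a
  b2 <- r$b
  n <- length(a2)
  if (n == 1L) {
    blk <- list(data.frame(label = a2$labels, sign = a2$signs,
                           stringsAsFactors = FALSE))
    ori <- a2$signs[1L] * b2$signs[match(a2$labels[1L], b2$labels)]
    return(new_block_decomposition(blk, ori, a2$labels, n))
  }
  A <- signed_adjacencies(a2)
  B <- signed_adjacencies(b2)
  b_fwd <- adj_key(B$x, B$sx, B$y, B$sy)
  b_rev <- adj_key(B$y, -B$sy, B$x, -B$sx)
  a_keys <- adj_key(A$x, A$sx, A$y, A$sy)
  cons <- a_keys %in% c(b_fwd, b_rev)
  if (all(cons)) {
    blk <- list(data.frame(label = a2$labels, sign = a2$signs,
                           stringsAsFactors = FALSE))
    ori <- if (a_keys[1L] %in% b_fwd) 1L else -1L
    return(new_block_decomposition(blk, ori, a2$labels, n))
  }
  # adjacency i joins elements i and i+1 (circularly); cut at broken ones
  breaks <- which(!cons)
  starts <- (breaks %% n) + 1L
  blocks <- list()
  oris <- integer()
  for (s in starts) {
    members <- s
    i <- s
    while (cons[i]) {
      i <- (i %% n) + 1L
      members <- c(members, i)
    }
    blk <- data.frame(label = a2$labels[members], sign = a2$signs[members],
                      stringsAsFactors = FALSE)
    ori <- if (nrow(blk) >= 2L) {
      k <- adj_key(blk$label[1L], blk$sign[1L], blk$label[2L], blk$sign[2L])
      if (k %in% b_fwd) 1L else -1L
    } else {
      blk$sign[1L] * b2$signs[match(blk$label[1L], b2$labels)]
    }
    blocks[[length(blocks) + 1L]] <- blk
    oris <- c(oris, ori)
  }
  # report in order of appearance in a, starting from cox1's block if present
  first_pos <- vapply(blocks, function(bk) match(bk$label[1L], a2$labels), 1L)
  ord <- order(first_pos)
  blocks <- blocks[ord]
  oris <- oris[ord]
  has_cox1 <- which(vapply(blocks, function(bk) "cox1" %in% bk$label, TRUE))
  if (length(has_cox1)) {
    rot <- c(has_cox1[1L]:length(blocks),
             seq_len(has_cox1[1L] - 1L))
    blocks <- blocks[rot]
    oris <- oris[rot]
  }
  singles <- unlist(lapply(blocks[vapply(blocks, nrow, 1L) == 1L],
                           function(bk) bk$label))
  new_block_decomposition(blocks, oris, singles %||% character(), n)
}

new_block_decomposition <- function(blocks, orientations, singletons, n_shared) {
  big <- vapply(blocks, nrow, 1L) >= 2L
  structure(list(blocks = blocks, orientations = orientations,
                 singletons = if (all(big)) character() else
                   unlist(lapply(blocks[!big], function(bk) bk$label)),
                 n_shared = n_shared),
            class = "block_decomposition")
}

#' @export
print.block_decomposition <- function(x, ...) {
  cat("Block decomposition:", length(x$blocks), "block(s),",
      length(x$singletons), "singleton(s) over", x$n_shared, "shared genes\n")
  for (i in seq_along(x$blocks)) {
    bk <- x$blocks[[i]]
    cat(sprintf("  [%d]%s %s\n", i,
                if (x$orientations[i] < 0L) " (reversed)" else "",
                paste(ifelse(bk$sign < 0L, paste0("-", bk$label), bk$label),
                      collapse = " ")))
  }
  invisible(x)
}

#' Breakpoint distance between signed circular gene orders
#'
#' The number of signed adjacencies of `a` not conserved in `b` (an
#' adjacency is conserved when it or its full reversal is adjacent in `b`).
#' Symmetric in its arguments for equal label sets.
#'
#' @inheritParams conserved_blocks
#' @return non-negative integer count.
#' @export
breakpoint_distance <- function(a, b, strict = FALSE) {
  stopifnot(inherits(a, "gene_order"), inherits(b, "gene_order"))
  r <- restrict_to_shared(a, b, strict = strict)
  A <- signed_adjacencies(r$a)
  B <- signed_adjacencies(r$b)
  if (!nrow(A)) return(0L)
  b_keys <- c(adj_key(B$x, B$sx, B$y, B$sy), adj_key(B$y, -B$sy, B$x, -B$sx))
  sum(!(adj_key(A$x, A$sx, A$y, A$sy) %in% b_keys))
}

#' Rearrangement events on gene orders
#'
#' Constructs one of the four classical mitogenome rearrangement events:
#' inversion (a run is reversed in place with orientations flipped),
#' transposition (a run moves elsewhere), reverse transposition (moves and
#' flips), and tandem duplication-random loss (TDRL: a run is duplicated in
#' tandem and one copy of each duplicated gene is lost at random, preserving
#' the gene set).
#'
#' @param kind one of `"inversion"`, `"transposition"`,
#'   `"reverse_transposition"`, `"tdrl"`.
#' @param i,j first and last position (1-based, `i <= j`) of the affected
#'   run in the pre-event order.
#' @param dest for (reverse) transpositions: the position in the pre-event
#'   order after which the run is re-inserted (`0` = front); must lie
#'   outside `[i - 1, j]`.
#' @return object of class `rearrangement_event`.
#' @export
rearrangement_event <- function(kind = c("inversion", "transposition",
                                         "reverse_transposition", "tdrl"),
                                i, j, dest = NULL) {
  kind <- match.arg(kind)
  i <- as.integer(i)
  j <- as.integer(j)
  stopifnot(length(i) == 1L, length(j) == 1L, i >= 1L, j >= i)
  if (kind %in% c("transposition", "reverse_transposition")) {
    if (is.null(dest)) stop("dest is required for transpositions")
    dest <- as.integer(dest)
    if (dest >= i - 1L && dest <= j) {
      stop("dest must lie outside the moved run")
    }
  }
  structure(list(kind = kind, i = i, j = j, dest = dest),
            class = "rearrangement_event")
}

#' Apply a rearrangement event to a gene order
#'
#' @param order a [gene_order()].
#' @param event a [rearrangement_event()].
#' @param seed optional integer seed for the random losses of a TDRL event;
#'   when `NULL` the current RNG stream is used.
#' @return the rearranged [gene_order()]; the label set is always preserved.
#' @export
apply_event <- function(order, event, seed = NULL) {
  stopifnot(inherits(order, "gene_order"),
            inherits(event, "rearrangement_event"))
  n <- length(order)
  if (event$j > n) stop("event span exceeds order length ", n)
  idx <- event$i:event$j
  labels <- order$labels
  signs <- order$signs
  out <- switch(event$kind,
    inversion = {
      labels[idx] <- rev(labels[idx])
      signs[idx] <- -rev(signs[idx])
      list(labels = labels, signs = signs)
    },
    transposition = move_run(labels, signs, idx, event$dest, flip = FALSE),
    reverse_transposition = move_run(labels, signs, idx, event$dest,
                                     flip = TRUE),
    tdrl = {
      pick <- function() sample(c(TRUE, FALSE), length(idx), replace = TRUE)
      keep_first <- if (is.null(seed)) pick() else
        withr::with_seed(seed, pick())
      before <- seq_len(event$i - 1L)
      after <- if (event$j < n) seq(event$j + 1L, n) else integer()
      new_idx <- c(before, idx[keep_first], idx[!keep_first], after)
      list(labels = labels[new_idx], signs = signs[new_idx])
    })
  gene_order(out$labels, out$signs, order$genome_id)
}

move_run <- function(labels, signs, idx, dest, flip) {
  n <- length(labels)
  if (dest > n) stop("dest exceeds order length")
  rest <- setdiff(seq_len(n), idx)
  pos <- if (dest == 0L) 0L else match(dest, rest)
  run_lab <- labels[idx]
  run_sgn <- signs[idx]
  if (flip) {
    run_lab <- rev(run_lab)
    run_sgn <- -rev(run_sgn)
  }
  list(labels = append(labels[rest], run_lab, after = pos),
       signs = append(signs[rest], run_sgn, after = pos))
}

#' Linear rendering of a circular gene order
#'
#' One-line, hyphen-separated rendering starting at `start_label`
#' (defaulting to `cox1` when present), with minus-orientation labels
#' wrapped in brackets. `parse_linear()` is the inverse reader.
#'
#' @param order a [gene_order()].
#' @param start_label label to start the line at.
#' @return `render_linear()`: character scalar; `parse_linear()`: a
#'   [gene_order()].
#' @examples
#' o <- gene_order(c("cox1", "R", "nad6"), c(1, 1, -1))
#' render_linear(o)  # "cox1-R-[nad6]"
#' @export
render_linear <- function(order, start_label = NULL) {
  stopifnot(inherits(order, "gene_order"))
  if (is.null(start_label)) {
    start_label <- if ("cox1" %in% order$labels) "cox1" else order$labels[1L]
  }
  o <- rotate_order(order, to_label = start_label)
  paste(ifelse(o$signs < 0L, paste0("[", o$labels, "]"), o$labels),
        collapse = "-")
}

#' @param text a line produced by [render_linear()].
#' @param genome_id identifier for the parsed order.
#' @rdname render_linear
#' @export
parse_linear <- function(text, genome_id = "order") {
  toks <- strsplit(trimws(text), "-", fixed = TRUE)[[1L]]
  toks <- toks[nzchar(toks)]
  neg <- grepl("^\\[.*\\]$", toks)
  labels <- ifelse(neg, substr(toks, 2L, nchar(toks) - 1L), toks)
  gene_order(labels, ifelse(neg, -1L, 1L), genome_id)
}

#' Read/write gene orders in text format
#'
#' One genome per line, `id: g1 -g2 g3 ...`, minus signs marking
#' reverse-orientation genes.
#'
#' @param file path to the text file.
#' @return `read_gene_orders()`: named list of [gene_order()] objects;
#'   `write_gene_orders()`: invisibly, its input.
#' @export
read_gene_orders <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed gene-order line: ", ln)
    toks <- strsplit(trimws(parts[2L]), "\\s+")[[1L]]
    neg <- startsWith(toks, "-")
    gene_order(ifelse(neg, substring(toks, 2L), toks),
               ifelse(neg, -1L, 1L), trimws(parts[1L]))
  })
  stats::setNames(out, vapply(out, function(o) o$genome_id, ""))
}

#' @param orders a [gene_order()] or list of them.
#' @rdname read_gene_orders
#' @export
write_gene_orders <- function(orders, file) {
  if (inherits(orders, "gene_order")) orders <- list(orders)
  writeLines(vapply(orders, format_gene_order, ""), file)
  invisible(orders)
}
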