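# Independent oracles and generators used across the suite.

# Exhaustive conserved-run search: every circular contiguous run of `a` is
# checked for contiguity + co-orientation in `b` via position arithmetic
# (no adjacency sets); maximal conserved runs are returned as index vectors.
bf_conserved_blocks <- function(a, b) {
  n <- length(a$labels)
  nb <- length(b$labels)
  run_ok <- function(idx) {
    la <- a$labels[idx]
    sa <- a$signs[idx]
    pb <- match(la, b$labels)
    sb <- b$signs[pb]
    m <- length(idx)
    if (m == 1L) return(TRUE)
    fwd <- all((pb[-1L] - pb[-m]) %% nb == 1L) && all(sb == sa)
    bwd <- all((pb[-m] - pb[-1L]) %% nb == 1L) && all(sb == -sa)
    fwd || bwd
  }
  runs <- list()
  for (l in seq_len(n)) {
    for (s in seq_len(n)) {
      if (l == n && s > 1L) next
      idx <- ((s - 1L + 0:(l - 1L)) %% n) + 1L
      if (run_ok(idx)) runs[[length(runs) + 1L]] <- idx
    }
  }
  sets <- lapply(runs, sort)
  keep <- vapply(seq_along(runs), function(i) {
    !any(vapply(seq_along(runs), function(j) {
      j != i && length(runs[[j]]) > length(runs[[i]]) &&
        all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))
  runs[keep]
}

# canonical signature of a block decomposition: sorted label sets
block_signatures <- function(blocks_labels) {
  sort(vapply(blocks_labels, function(x) paste(sort(x), collapse = ","), ""))
}

random_signed_order <- function(n, id = "rand") {
  gene_order(sample(paste0("g", seq_len(n))),
             sample(c(-1L, 1L), n, replace = TRUE), id)
}

# random non-origin-spanning annotation (overlaps allowed)
random_annotation <- function(n, L) {
  starts <- sort(sample.int(L, n))
  lens <- sample.int(max(1L, L %/% n), n, replace = TRUE)
  mito_annotation(
    data.frame(gene = paste0("f", seq_len(n)),
               strand = sample(c("+", "-"), n, replace = TRUE),
               start = starts, end = pmin(starts + lens - 1L, L)),
    genome_length = L, genome_id = "rand")
}

# k disjoint inversion events on an order of length n, as (i, j) pairs
random_disjoint_inversions <- function(n, k) {
  cuts <- sort(sample(seq_len(n - 1L), 2L * k))
  lapply(seq_len(k), function(q) c(cuts[2L * q - 1L] + 1L, cuts[2L * q]))
}
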