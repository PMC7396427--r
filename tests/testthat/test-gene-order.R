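test_that("gene names normalize onto the canonical 37-gene alphabet", {
  expect_identical(normalize_gene_labels(
    c("trna-pro", "trna-ser(tga)", "trna-ser(gct)", "trna-leu(tag)",
      "trna-leu(taa)", "cytb", "12S", "16S", "nad4l", "COX1", "trnK")),
    c("P", "S2", "S1", "L1", "L2", "cob", "rrnS", "rrnL", "nad4L", "cox1",
      "K"))
  expect_error(normalize_gene_labels("mystery-gene"), "mystery-gene")
  expect_error(normalize_gene_labels("trna-leu"), "ambiguous")
  # user-supplied synonyms take precedence
  expect_identical(normalize_gene_labels("ND1", name_map = c(nd1 = "nad1")),
                   "nad1")
})

test_that("the focal gene order follows the published arrangement", {
  o <- focal_gene_order()
  expect_length(o, 37L)
  expect_setequal(o$labels, mito_gene_alphabet())
  head_lab <- c("P", "Q", "N", "L1", "A", "W", "C", "V", "D", "M", "Y", "G",
                "L2", "nad1", "I", "nad2")
  head_sgn <- c(1, -1, 1, 1, -1, 1, 1, -1, -1, 1, 1, 1, 1, 1, 1, 1)
  expect_identical(o$labels[1:16], head_lab)
  expect_identical(o$signs[1:16], as.integer(head_sgn))
  # the long conserved run downstream of cox1
  i <- match("cox1", o$labels)
  run <- c("cox1", "R", "nad4L", "cox2", "K", "atp8", "atp6", "cox3", "S2",
           "nad3", "nad4", "H", "S1", "nad5", "nad6", "cob", "F", "rrnS",
           "E", "T")
  expect_identical(o$labels[i:(i + 19L)], run)
  expect_identical(o$signs[i + match(c("S2", "nad6"), run) - 1L],
                   c(-1L, -1L))
})

test_that("identity and full reversal give a single conserved block", {
  o <- focal_gene_order()
  d <- conserved_blocks(o, o)
  expect_length(d$blocks, 1L)
  expect_identical(d$orientations, 1L)
  expect_length(d$singletons, 0L)
  expect_identical(breakpoint_distance(o, o), 0L)
  rc <- reverse_complement_order(o)
  d2 <- conserved_blocks(o, rc)
  expect_length(d2$blocks, 1L)
  expect_identical(d2$orientations, -1L)
  expect_identical(breakpoint_distance(o, rc), 0L)
})

test_that("block decomposition equals the exhaustive conserved-run search", {
  n_cases <- 120L
  for (case in seq_len(n_cases)) {
    withr::with_seed(1000L + case, {
      n <- sample(3:8, 1L)
      a <- random_signed_order(n, "a")
      b <- gene_order(sample(a$labels), sample(c(-1L, 1L), n, TRUE), "b")
      got <- conserved_blocks(a, b)
      oracle <- bf_conserved_blocks(a, b)
      expect_identical(
        block_signatures(lapply(got$blocks, function(bk) bk$label)),
        block_signatures(lapply(oracle, function(idx) a$labels[idx])))
      # breakpoints = blocks whenever the orders are not equivalent
      bp <- breakpoint_distance(a, b)
      expect_identical(bp, breakpoint_distance(b, a))
      if (bp > 0L) expect_identical(length(got$blocks), bp)
    })
  }
})

test_that("comparison is invariant under rotation and strand flips", {
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- sample(5:12, 1L)
      a <- random_signed_order(n, "a")
      b <- gene_order(sample(a$labels), sample(c(-1L, 1L), n, TRUE), "b")
      ref_bp <- breakpoint_distance(a, b)
      ref_nb <- length(conserved_blocks(a, b)$blocks)
      a_rot <- rotate_order(a, k = sample.int(n, 1L))
      b_rot <- rotate_order(b, k = sample.int(n, 1L))
      expect_identical(breakpoint_distance(a_rot, b_rot), ref_bp)
      expect_identical(length(conserved_blocks(a_rot, b_rot)$blocks), ref_nb)
      b_rc <- reverse_complement_order(b)
      expect_identical(breakpoint_distance(a, b_rc), ref_bp)
      expect_identical(length(conserved_blocks(a, b_rc)$blocks), ref_nb)
    }
  })
})

test_that("a single interior inversion creates exactly two breakpoints", {
  o <- focal_gene_order()
  ev <- rearrangement_event("inversion", 5, 9)
  b <- apply_event(o, ev)
  expect_identical(breakpoint_distance(o, b), 2L)
  d <- conserved_blocks(o, b)
  expect_length(d$blocks, 2L)
  sizes <- sort(vapply(d$blocks, nrow, 1L))
  expect_identical(sizes, c(5L, 32L))
})

test_that("rearrangement events act as defined and are label-closed", {
  o <- gene_order(c("a", "b", "c", "d", "e", "f"), c(1, 1, -1, 1, 1, -1))
  # single-gene inversion flips orientation in place
  inv <- apply_event(o, rearrangement_event("inversion", 2, 2))
  expect_identical(inv$labels, o$labels)
  expect_identical(inv$signs, c(1L, -1L, -1L, 1L, 1L, -1L))
  # transposition then its exact inverse restores the order
  tr <- apply_event(o, rearrangement_event("transposition", 2, 3, dest = 5))
  expect_identical(tr$labels, c("a", "d", "e", "b", "c", "f"))
  back <- apply_event(tr, rearrangement_event("transposition", 4, 5, dest = 1))
  expect_identical(back$labels, o$labels)
  expect_identical(back$signs, o$signs)
  # reverse transposition moves and flips
  rt <- apply_event(o, rearrangement_event("reverse_transposition", 1, 2,
                                           dest = 4))
  expect_identical(rt$labels, c("c", "d", "b", "a", "e", "f"))
  expect_identical(rt$signs, c(-1L, 1L, -1L, -1L, 1L, -1L))
  # TDRL preserves the label set for any seed
  for (seed in 1:10) {
    td <- apply_event(o, rearrangement_event("tdrl", 2, 5), seed = seed)
    expect_setequal(td$labels, o$labels)
    expect_length(td$labels, 6L)
  }
  expect_error(apply_event(o, rearrangement_event("inversion", 3, 9)),
               "exceeds")
})

test_that("k disjoint inversions give at most 2k + 1 blocks", {
  base <- focal_gene_order()
  for (k in 1:5) {
    for (seed in 1:6) {
      withr::with_seed(seed * 100L + k, {
        events <- random_disjoint_inversions(length(base), k)
        o <- base
        for (ij in events) {
          o <- apply_event(o, rearrangement_event("inversion", ij[1], ij[2]))
        }
        d <- conserved_blocks(base, o)
        expect_lte(length(d$blocks), 2L * k + 1L)
      })
    }
  }
})

test_that("linear rendering brackets reverse-strand genes and inverts", {
  o <- focal_gene_order()
  line <- render_linear(o, start_label = "cox1")
  expect_match(line, "^cox1-R-nad4L-cox2-K-atp8-atp6-cox3-")
  expect_match(line, "-nad5-\\[nad6\\]-cob-F-rrnS-E-T-P-", fixed = FALSE)
  expect_match(line, "\\[S2\\]")  # minus-strand serine tRNA (UCN)
  back <- parse_linear(line, genome_id = o$genome_id)
  expect_identical(back$labels, rotate_order(o, "cox1")$labels)
  expect_identical(back$signs, rotate_order(o, "cox1")$signs)
  expect_identical(render_linear(gene_order("cox1")), "cox1")
})

test_that("gene-order text files round trip", {
  o <- focal_gene_order()
  o2 <- reverse_complement_order(o)
  o2$genome_id <- "flipped"
  tf <- withr::local_tempfile(fileext = ".txt")
  write_gene_orders(list(o, o2), tf)
  back <- read_gene_orders(tf)
  expect_identical(back[[o$genome_id]]$labels, o$labels)
  expect_identical(back[[o$genome_id]]$signs, o$signs)
  expect_identical(back[["flipped"]]$signs, o2$signs)
})

test_that("unequal gene sets are intersected, or rejected in strict mode", {
  a <- gene_order(c("x", "y", "z", "w"), c(1, 1, 1, 1), "a")
  b <- gene_order(c("y", "x", "q", "w"), c(1, 1, 1, 1), "b")
  expect_error(conserved_blocks(a, b, strict = TRUE), "gene sets differ")
  expect_warning(d <- conserved_blocks(a, b), "restricting")
  expect_identical(d$n_shared, 3L)
})
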