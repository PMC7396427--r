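test_that("base_composition counts and percentages are exact", {
  bc <- base_composition("AATT")
  expect_equal(unname(bc$percent[c("A", "T", "G", "C")]), c(50, 50, 0, 0))
  expect_error(base_composition(""), "empty")
  # ambiguity codes are excluded from percentages but tallied
  bc2 <- base_composition("AANN")
  expect_identical(bc2$n_other, 2L)
  expect_equal(unname(bc2$percent[["A"]]), 100)
  # independent recount on a seeded 10 kb sequence via Biostrings
  withr::with_seed(42, {
    s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE,
                      prob = c(.4, .25, .1, .25)), collapse = "")
  })
  bc3 <- base_composition(s)
  oracle <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                        c("A", "C", "G", "T"))
  expect_identical(unname(bc3$counts), as.integer(oracle))
  expect_equal(sum(bc3$percent), 100)
})

test_that("skew follows (x - y)/(x + y) and is scale invariant", {
  expect_equal(skew(5, 5), 0)
  expect_error(skew(0, 0), "undefined")
  expect_error(skew(-1, 2), "non-negative")
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- runif(1, 0, 50)
      y <- runif(1, 0, 50)
      k <- runif(1, 0.01, 100)
      expect_equal(skew(k * x, k * y), skew(x, y))
      expect_true(abs(skew(x, y)) <= 1)
    }
  })
})

test_that("composition_report rows agree with direct recomputation", {
  g <- synth_genome(synth_spec(seed = 3))
  rep <- composition_report(g$sequence, g$annotation)
  # aggregate PCG row equals composition of the concatenated planted CDS
  pcg_row <- rep[rep$region == "PCGs", ]
  oracle <- base_composition(paste(unlist(g$cds), collapse = ""))
  expect_equal(pcg_row$a_percent, unname(oracle$percent[["A"]]))
  expect_equal(pcg_row$t_percent, unname(oracle$percent[["T"]]))
  expect_equal(pcg_row$gc_skew,
               skew(oracle$counts[["G"]], oracle$counts[["C"]]))
  expect_identical(pcg_row$length, sum(nchar(unlist(g$cds))))
  # genome row equals whole-sequence composition
  gen <- rep[rep$region == "genome", ]
  expect_equal(gen$at_percent, base_composition(g$sequence)$at_percent)
})

test_that("degenerate compositions are reported with NA skews", {
  ann <- mito_annotation(
    data.frame(gene = "a", strand = "+", start = 1, end = 100),
    genome_length = 100L)
  seq <- genome_sequence("allA", strrep("A", 100))
  rep <- composition_report(seq, ann)
  expect_equal(rep$a_percent, c(100, 100, 100))
  expect_equal(rep$at_skew, c(1, 1, 1))
  expect_true(all(is.na(rep$gc_skew)))
  # a single feature covering the whole circle equals the genome row
  expect_equal(rep[1, -(1:3)], rep[rep$region == "genome", -(1:3)],
               ignore_attr = TRUE)
})

test_that("count_codons tallies frame-0 triplets with warnings on defects", {
  cc <- count_codons("ATGAAATAA")
  expect_identical(unname(cc[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_identical(sum(cc), 3L)
  expect_warning(cc2 <- count_codons("ATGAAATAAG"), "not divisible by 3")
  expect_identical(sum(cc2), 3L)
  expect_warning(cc3 <- count_codons("ATGNNATAA"), "ambiguous")
  expect_identical(sum(cc3), 2L)
  # independent sliding-triplet recount on seeded CDS
  withr::with_seed(8, {
    cds <- vapply(1:5, function(i) {
      paste(sample(c("A", "C", "G", "T"), 3 * sample(50:150, 1),
                   replace = TRUE), collapse = "")
    }, "")
  })
  cc4 <- count_codons(cds)
  oracle <- table(unlist(lapply(cds, function(s) {
    vapply(seq(1, nchar(s) - 2, by = 3), function(k) substr(s, k, k + 2), "")
  })))
  expect_identical(unname(cc4[names(oracle)]), as.integer(oracle))
  expect_identical(sum(cc4), sum(nchar(cds)) %/% 3L)
})

test_that("RSCU satisfies the family-sum identity under any code", {
  # uniform counts give RSCU 1 for every codon
  uni <- codon_counts(stats::setNames(rep(1, 64), codon_alphabet()))
  expect_equal(unname(rscu(uni, genetic_code("standard"))), rep(1, 64))
  # family sums equal family sizes for random tables under each built-in code
  for (seed in 1:8) {
    counts <- withr::with_seed(seed, {
      codon_counts(stats::setNames(rpois(64, 40), codon_alphabet()))
    })
    for (code_name in c("standard", "invertebrate_mito", "echinoderm_mito")) {
      code <- genetic_code(code_name)
      r <- rscu(counts, code)
      for (fam in code$families) {
        tot <- sum(counts[fam])
        expected <- if (tot > 0) length(fam) else 0
        expect_equal(sum(r[fam]), expected)
      }
    }
  }
  # a family with zero total reports 0 for all members
  counts <- stats::setNames(rep(2, 64), codon_alphabet())
  counts[genetic_code("standard")$families[["C"]]] <- 0
  r <- rscu(codon_counts(counts), genetic_code("standard"))
  expect_equal(unname(r[c("TGT", "TGC")]), c(0, 0))
})

test_that("amino-acid usage percentages normalize to 100", {
  for (seed in 1:5) {
    counts <- withr::with_seed(seed, {
      codon_counts(stats::setNames(rpois(64, 25), codon_alphabet()))
    })
    u <- aa_usage(counts, genetic_code("invertebrate_mito"))
    expect_lt(abs(sum(u$percent) - 100), 0.05)
    expect_true("*" %in% u$amino_acid)
  }
  # counts concentrated on one codon
  one <- stats::setNames(rep(0, 64), codon_alphabet())
  one["GGA"] <- 12
  u <- aa_usage(codon_counts(one), genetic_code("standard"))
  expect_equal(u$percent[u$amino_acid == "G"], 100)
  expect_error(aa_usage(codon_counts(stats::setNames(rep(0, 64),
                                                     codon_alphabet()))),
               "zero total")
})

test_that("planted codon bias is recovered as RSCU > 1 for favored codons", {
  code <- genetic_code("standard")
  # favor one codon (weight 6) per multi-codon family
  favored <- vapply(code$families, function(fam) fam[1L], "")
  weights <- stats::setNames(rep(1, 64), codon_alphabet())
  weights[favored] <- 6
  withr::with_seed(99, {
    cods <- sample(codon_alphabet(), 3000, replace = TRUE,
                   prob = weights / sum(weights))
  })
  r <- rscu(count_codons(paste(cods, collapse = "")), code)
  multi <- code$families[vapply(code$families, length, 1L) >= 2L]
  for (fam in multi) {
    expect_true(r[fam[1L]] > 1)
    expect_true(all(r[fam[-1L]] < r[fam[1L]]))
  }
})

test_that("extract_cds honors strand, frame and the origin", {
  # minus-strand gene: planted ATG...TAA is recovered on the coding strand
  cds <- "ATGGCCGCTTAA"
  genome <- paste0("TTTT", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cds))), "TTTT")
  ann <- mito_annotation(
    data.frame(gene = "nad6", strand = "-", start = 5,
               end = 4 + nchar(cds), category = "PCG"),
    genome_length = nchar(genome))
  got <- extract_cds(genome_sequence("g", genome), ann)
  expect_identical(got$nad6, cds)
  # origin-spanning PCG has length matching feature_length
  ann2 <- mito_annotation(
    data.frame(gene = "cox1", strand = "+", start = 95, end = 10,
               category = "PCG"),
    genome_length = 100L)
  seq2 <- genome_sequence("g2", strrep("ACGT", 25))
  expect_warning(got2 <- extract_cds(seq2, ann2), "not divisible by 3")
  expect_identical(nchar(got2$cox1), feature_length(95, 10, 100))
})
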