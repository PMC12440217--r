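two_gene_table <- function(sa, ea, sb, eb, strand_a = "+", strand_b = "+",
                           topology = "linear", len = 50000L,
                           rep_a = "r1", rep_b = "r1") {
  recs <- data.frame(
    genome_id = "g1", replicon_id = c(rep_a, rep_b),
    gene_id = c("geneA", "geneB"), start = c(sa, sb), end = c(ea, eb),
    strand = c(strand_a, strand_b),
    labels = c("KEGG:K22719", "PFAM:PF04748"), stringsAsFactors = FALSE)
  reps <- data.frame(genome_id = "g1",
                     replicon_id = unique(c(rep_a, rep_b)),
                     length_bp = len, topology = topology,
                     stringsAsFactors = FALSE)
  genome_table(recs, replicons = reps)
}

test_that("gene_gap measures the intergenic gap of half-open intervals", {
  gt <- two_gene_table(100, 400, 403, 900)
  a <- gt$records[gt$records$gene_id == "geneA", ]
  b <- gt$records[gt$records$gene_id == "geneB", ]
  expect_identical(gene_gap(a, b), 3L)          # the envC-sddA arrangement
  expect_identical(gene_gap(b, a), 3L)          # symmetric

  gt <- two_gene_table(100, 400, 350, 600)
  expect_identical(gene_gap(gt$records[1, ], gt$records[2, ]), 0L)  # overlap
  gt <- two_gene_table(100, 400, 400, 600)
  expect_identical(gene_gap(gt$records[1, ], gt$records[2, ]), 0L)  # abutting

  gt <- two_gene_table(0, 100, 900, 1000, topology = "circular", len = 1000L)
  a <- gt$records[1, ]; b <- gt$records[2, ]
  expect_identical(gene_gap(a, b, topology = "circular", length_bp = 1000L), 0L)
  # wrap is never taken silently on linear replicons
  expect_identical(gene_gap(a, b), 800L)

  gt <- two_gene_table(0, 100, 900, 1000, rep_b = "r2")
  expect_error(gene_gap(gt$records[1, ], gt$records[2, ]),
               "different replicons")
})

test_that("closest_pair selects the minimal-gap admissible pair", {
  gt <- two_gene_table(100, 400, 403, 900)
  cp <- closest_pair(gt, builtin_query("envC"), builtin_query("sddA"), "g1")
  expect_identical(cp$distance_bp, 3L)
  expect_true(cp$same_strand)
  expect_identical(cp$gene_a_id, "geneA")

  # families on different replicons: no pair, but presence still counts
  gt2 <- two_gene_table(100, 400, 403, 900, rep_b = "r2")
  expect_null(closest_pair(gt2, builtin_query("envC"),
                           builtin_query("sddA"), "g1"))
  ls2 <- linkage_summary(gt2, builtin_query("envC"), builtin_query("sddA"))
  expect_identical(ls2$summary$n_genomes_with_both, 1L)
  expect_identical(ls2$summary$n_genomes_with_pair, 0L)

  # a single gene matching both families is not a pair with itself
  both <- data.frame(genome_id = "g1", replicon_id = "r1", gene_id = "dual",
                     start = 10, end = 500, strand = "+",
                     labels = "KEGG:K22719;PFAM:PF04748")
  gt3 <- genome_table(both)
  expect_null(closest_pair(gt3, builtin_query("envC"),
                           builtin_query("sddA"), "g1"))
  # ... but pairs with a second distinct matching gene
  gt4 <- genome_table(rbind(both,
    data.frame(genome_id = "g1", replicon_id = "r1", gene_id = "solo",
               start = 700, end = 1200, strand = "-",
               labels = "PFAM:PF04748")))
  cp4 <- closest_pair(gt4, builtin_query("envC"), builtin_query("sddA"), "g1")
  expect_identical(sort(c(cp4$gene_a_id, cp4$gene_b_id)), c("dual", "solo"))
  expect_identical(cp4$distance_bp, 200L)
  expect_false(cp4$same_strand)
})

test_that("closest_pair equals exhaustive enumeration on random genomes", {
  withr::local_seed(314)
  qa <- builtin_query("envC")
  qb <- builtin_query("sddA")
  match_a <- function(labels) vapply(labels, naive_match, logical(1),
                                     include = qa$include,
                                     exclude = qa$exclude,
                                     require = qa$require)
  match_b <- function(labels) vapply(labels, naive_match, logical(1),
                                     include = qb$include,
                                     exclude = qb$exclude,
                                     require = qb$require)
  checked_pairs <- 0L
  for (batch in 1:5) {
    gt <- random_genome_table(n_genomes = 20, max_genes = 50)
    for (g in unique(gt$records$genome_id)) {
      got <- closest_pair(gt, qa, qb, g)
      want <- brute_closest_pair(gt$records, gt$replicons, g,
                                 match_a, match_b)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_identical(got$distance_bp, as.integer(want$gap))
        expect_identical(got$gene_a_id, want$a)
        expect_identical(got$gene_b_id, want$b)
        expect_identical(got$same_strand, want$same)
        checked_pairs <- checked_pairs + 1L
      }
    }
  }
  expect_gt(checked_pairs, 20L)  # the random tables must actually exercise pairs
})

test_that("closest_pair is invariant under row permutation and query swap", {
  withr::local_seed(2718)
  gt <- random_genome_table(n_genomes = 15, max_genes = 40)
  qa <- builtin_query("envC"); qb <- builtin_query("sddA")
  perm <- genome_table(gt$records[sample(nrow(gt$records)), , drop = FALSE],
                       replicons = gt$replicons)
  for (g in unique(gt$records$genome_id)) {
    cp1 <- closest_pair(gt, qa, qb, g)
    cp2 <- closest_pair(perm, qa, qb, g)
    cp3 <- closest_pair(gt, qb, qa, g)
    expect_identical(cp1, cp2)
    if (is.null(cp1)) {
      expect_null(cp3)
    } else {
      expect_identical(cp3$distance_bp, cp1$distance_bp)
      expect_identical(cp3$same_strand, cp1$same_strand)
      expect_setequal(c(cp3$gene_a_id, cp3$gene_b_id),
                      c(cp1$gene_a_id, cp1$gene_b_id))
    }
  }
})

test_that("linkage_summary aggregates are consistent with its own pair table", {
  withr::local_seed(55)
  sim <- generate_pangenome(pangenome_config(n_genomes = 60, p_link = 0.5),
                            seed = 9)
  ls <- linkage_summary(sim$table, builtin_query("envC"),
                        builtin_query("sddA"))
  s <- ls$summary
  expect_identical(s$n_genomes_with_pair, nrow(ls$pairs))
  expect_identical(s$n_same_strand, sum(ls$pairs$same_strand))
  expect_equal(s$fraction_same_strand, mean(ls$pairs$same_strand))
  expect_equal(s$fraction_within_threshold,
               mean(ls$pairs$distance_bp <= s$threshold_bp))
  expect_identical(sum(ls$distance_histogram$count), s$n_genomes_with_pair)
  expect_lte(s$n_same_strand, s$n_genomes_with_pair)
  expect_lte(s$n_genomes_with_pair, s$n_genomes_with_both)
})

test_that("ten planted same-strand pairs under 2 kb give fractions of exactly 1", {
  sim <- generate_pangenome(
    pangenome_config(n_genomes = 10, p_link = 1,
                     presence = c(sddA = 1, envC = 1, gpmM = 0, amiC = 0),
                     gap_range = c(0L, 1999L)), seed = 4)
  ls <- linkage_summary(sim$table, builtin_query("envC"),
                        builtin_query("sddA"))
  expect_identical(ls$summary$n_genomes_with_pair, 10L)
  expect_identical(ls$summary$fraction_same_strand, 1)
  expect_identical(ls$summary$fraction_within_threshold, 1)
})
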