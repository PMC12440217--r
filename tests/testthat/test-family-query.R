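make_gene <- function(id, labels, genome = "g1") {
  data.frame(genome_id = genome, replicon_id = paste0(genome, "_r1"),
             gene_id = id, start = 1000 * match(id, sprintf("x%02d", 1:99),
                                                nomatch = 1),
             end = 1000 * match(id, sprintf("x%02d", 1:99), nomatch = 1) + 500,
             strand = "+", labels = labels, stringsAsFactors = FALSE)
}

test_that("built-in family definitions implement include/exclude/require semantics", {
  genes <- rbind(
    make_gene("x01", "KEGG:K22719"),                  # clean envC
    make_gene("x02", "KEGG:K22719;KEGG:K06194"),      # envC excluded (NlpD term)
    make_gene("x03", "PFAM:PF01520"),                 # amidase without AMIN
    make_gene("x04", "PFAM:PF01520;PFAM:PF11741"),    # true amiC
    make_gene("x05", ""),                             # unannotated
    make_gene("x06", "PFAM:PF04748"),                 # sddA via PFAM
    make_gene("x07", "KEGG:K09798"))                  # sddA via KEGG
  gt <- genome_table(genes)

  expect_setequal(match_genes(gt, builtin_query("envC"))$gene_id, "x01")
  expect_setequal(match_genes(gt, builtin_query("amiC"))$gene_id, "x04")
  expect_setequal(match_genes(gt, builtin_query("sddA"))$gene_id,
                  c("x06", "x07"))
  expect_error(builtin_query("nope"), "sddA.*envC.*gpmM.*amiC|valid names")
})

test_that("query construction rejects overlapping include/exclude and empty include", {
  expect_error(family_query("bad", include = "X", exclude = "X"), "overlap")
  expect_error(family_query("bad", include = character()), "non-empty")
})

test_that("matching agrees with a naive set-algebra oracle on random genes and queries", {
  withr::local_seed(42)
  genes <- do.call(rbind, lapply(1:1000, function(i) {
    nlab <- sample(0:4, 1)
    make_gene(sprintf("x%04d", i),
              paste(sample(LABEL_POOL, nlab), collapse = ";"))
  }))
  genes$start <- seq_len(nrow(genes)) * 10
  genes$end <- genes$start + 5
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  gt <- genome_table(genes)
  for (rep in 1:20) {
    inc <- sample(LABEL_POOL, sample(1:3, 1))
    exc <- sample(setdiff(LABEL_POOL, inc), sample(0:2, 1))
    req <- sample(LABEL_POOL, sample(0:2, 1))
    q <- family_query("rand", inc, exc, req)
    got <- match_genes(gt, q)$gene_id
    want <- gt$records$gene_id[vapply(gt$records$labels, naive_match,
                                      logical(1), include = inc,
                                      exclude = exc, require = req)]
    expect_setequal(got, want)
  }
})

test_that("per-genome counts cover every genome (zeros included) and sum to match totals", {
  withr::local_seed(7)
  gt <- random_genome_table(n_genomes = 12, max_genes = 25)
  for (fam in c("sddA", "envC", "gpmM", "amiC")) {
    q <- builtin_query(fam)
    cnt <- count_per_genome(gt, q)
    expect_setequal(names(cnt), unique(gt$records$genome_id))
    expect_identical(sum(cnt), nrow(match_genes(gt, q)))
    expect_true(all(cnt >= 0L))
  }
})

test_that("query evaluation is monotone in include and antitone in exclude", {
  withr::local_seed(99)
  gt <- random_genome_table(n_genomes = 8, max_genes = 30)
  for (rep in 1:10) {
    inc <- sample(LABEL_POOL, 2)
    exc <- sample(setdiff(LABEL_POOL, inc), 1)
    extra_inc <- sample(setdiff(LABEL_POOL, c(inc, exc)), 1)
    extra_exc <- sample(setdiff(LABEL_POOL, c(inc, exc, extra_inc)), 1)
    base <- match_genes(gt, family_query("q", inc, exc))$gene_id
    wider <- match_genes(gt, family_query("q", c(inc, extra_inc), exc))$gene_id
    narrower <- match_genes(gt, family_query("q", inc, c(exc, extra_exc)))$gene_id
    expect_true(all(base %in% wider))
    expect_true(all(narrower %in% base))
  }
})
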