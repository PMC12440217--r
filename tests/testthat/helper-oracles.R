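# Independent oracles and fixture builders. These deliberately reimplement
# the checked logic in the most naive way possible (per-gene set algebra,
# exhaustive pair enumeration) and must stay independent of the package
# internals they verify.

# naive boolean family predicate on one gene's label string
naive_match <- function(label_string, include, exclude = character(),
                        require = character()) {
  terms <- toupper(unlist(strsplit(label_string, ";", fixed = TRUE)))
  terms <- terms[nzchar(terms)]
  any(toupper(include) %in% terms) &&
    !any(toupper(exclude) %in% terms) &&
    all(toupper(require) %in% terms)
}

# naive interval gap (0-based half-open), with optional circular wrap
naive_gap <- function(s1, e1, s2, e2, topology = "linear", len = NA) {
  if (s1 > s2) { tmp <- c(s1, e1); s1 <- s2; e1 <- e2; s2 <- tmp[1]; e2 <- tmp[2] }
  lin <- if (s2 >= e1) s2 - e1 else 0
  if (topology == "circular" && !is.na(len)) {
    wrap <- len - max(e1, e2) + min(s1, s2)
    if (wrap < 0) wrap <- 0
    lin <- min(lin, wrap)
  }
  lin
}

# exhaustive O(n^2) closest-pair enumeration over one genome's records
brute_closest_pair <- function(records, replicons, genome_id,
                               match_a, match_b) {
  rec <- records[records$genome_id == genome_id, , drop = FALSE]
  ga <- rec[match_a(rec$labels), , drop = FALSE]
  gb <- rec[match_b(rec$labels), , drop = FALSE]
  if (nrow(ga) == 0 || nrow(gb) == 0) return(NULL)
  reps <- replicons[replicons$genome_id == genome_id, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(ga))) for (j in seq_len(nrow(gb))) {
    if (ga$gene_id[i] == gb$gene_id[j]) next
    if (ga$replicon_id[i] != gb$replicon_id[j]) next
    k <- match(ga$replicon_id[i], reps$replicon_id)
    gap <- naive_gap(ga$start[i], ga$end[i], gb$start[j], gb$end[j],
                     topology = reps$topology[k], len = reps$length_bp[k])
    cand <- list(gap = gap, a = ga$gene_id[i], b = gb$gene_id[j],
                 same = ga$strand[i] == gb$strand[j])
    if (is.null(best)) { best <- cand; next }
    lo_c <- min(cand$a, cand$b); hi_c <- max(cand$a, cand$b)
    lo_b <- min(best$a, best$b); hi_b <- max(best$a, best$b)
    if (cand$gap < best$gap ||
        (cand$gap == best$gap &&
         (lo_c < lo_b || (lo_c == lo_b && hi_c < hi_b) ||
          (lo_c == lo_b && hi_c == hi_b && cand$a < best$a))))
      best <- cand
  }
  best
}

LABEL_POOL <- c("PFAM:PF04748", "KEGG:K09798", "KEGG:K22719", "KEGG:K19304",
                "KEGG:K06194", "KEGG:K12943", "TIGRFAM:TIGR01307",
                "KEGG:K01448", "PFAM:PF01520", "PFAM:PF11741",
                "PFAM:PF00905", "KEGG:K03587")

# random genome with <= max_genes genes on 1-2 replicons (possibly circular)
random_records <- function(genome_id, max_genes = 50, replicon_len = 50000) {
  n <- sample.int(max_genes, 1)
  n_rep <- sample(1:2, 1)
  rows <- lapply(seq_len(n), function(k) {
    len <- sample(100:2000, 1)
    s <- sample.int(replicon_len - len, 1) - 1
    nlab <- sample(0:3, 1)
    data.frame(genome_id = genome_id,
               replicon_id = paste0(genome_id, "_r", sample.int(n_rep, 1)),
               gene_id = sprintf("%s_%03d", genome_id, k),
               start = s, end = s + len,
               strand = sample(c("+", "-"), 1),
               labels = paste(sample(LABEL_POOL, nlab), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

random_genome_table <- function(n_genomes = 20, max_genes = 50,
                                replicon_len = 50000, p_circular = 0.3) {
  recs <- do.call(rbind, lapply(seq_len(n_genomes), function(i)
    random_records(sprintf("rg%03d", i), max_genes, replicon_len)))
  rep_map <- unique(recs[c("genome_id", "replicon_id")])
  replicons <- data.frame(
    rep_map,
    length_bp = replicon_len,
    topology = ifelse(runif(nrow(rep_map)) < p_circular,
                      "circular", "linear"),
    stringsAsFactors = FALSE)
  genome_table(recs, replicons = replicons)
}

# tiny straight-rod mask fixture: rows x cols rectangle inside a padded image
rect_mask <- function(h = 10, w = 50, pad = 6) {
  m <- matrix(0L, h + 2 * pad, w + 2 * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- 1L
  m
}

disk_mask <- function(d = 11, pad = 6) {
  r <- d / 2
  n <- d + 2 * pad
  ctr <- (n + 1) / 2
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 <= r^2) m[i, j] <- 1L
  m
}

rotate90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# 200-cell rendered field shared by the geometry/midcell acceptance checks
# (computed once per test run)
acceptance_cells <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sims <- lapply(1:5, function(i) {
      model <- rep(c("septal", "uniform"), length.out = 40)
      generate_cells(cell_sim_config(n_cells = 40, model = model),
                     seed = 100 + i)
    })
    res <- lapply(seq_along(sims), function(i) {
      out <- analyze_cells(sims[[i]]$mask, sims[[i]]$fluor, 0.1,
                           replicate_id = paste0("rep", i))
      merge(out$cells, sims[[i]]$truth, by = "cell_id",
            suffixes = c("_meas", "_true"))
    })
    cache <<- do.call(rbind, res)
    cache
  }
})
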