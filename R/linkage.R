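#' Intergenic gap between two genes on the same replicon
#'
#' Distance in base pairs between two half-open gene intervals: the number of
#' bases strictly between them. Overlapping or abutting genes have gap 0. On
#' a replicon declared circular with known length the shorter of the two arcs
#' is returned; on linear (or unknown-topology) replicons only the linear gap
#' is used, so draft assemblies never get silent wraparound distances.
#'
#' @param a,b single-row gene records (rows of \code{genome_table$records});
#'   must lie on the same replicon.
#' @param topology \code{"linear"} (default) or \code{"circular"}.
#' @param length_bp replicon length, required when \code{topology =
#'   "circular"}.
#' @return Non-negative integer gap in bp.
#' @examples
#' a <- data.frame(genome_id = "g", replicon_id = "r", gene_id = "a",
#'                 start = 100, end = 400, strand = "+", labels = "")
#' b <- data.frame(genome_id = "g", replicon_id = "r", gene_id = "b",
#'                 start = 403, end = 900, strand = "+", labels = "")
#' gene_gap(a, b)  # 3
#' @export
gene_gap <- function(a, b, topology = "linear", length_bp = NA) {
  if (a$replicon_id != b$replicon_id)
    stop("genes are on different replicons: ", a$replicon_id, " vs ",
         b$replicon_id)
  gap_bp(a$start, a$end, b$start, b$end, topology = topology,
         length_bp = length_bp)
}

# vectorized core: linear gap of half-open intervals, optionally the
# circular complement arc when topology is declared
gap_bp <- function(s1, e1, s2, e2, topology = "linear", length_bp = NA) {
  linear <- pmax(0L, pmax(s1, s2) - pmin(e1, e2))
  circ <- topology == "circular" & !is.na(length_bp)
  if (any(circ)) {
    wrap <- pmax(0L, length_bp - pmax(e1, e2) + pmin(s1, s2))
    linear[circ] <- pmin(linear, wrap)[circ]
  }
  as.integer(linear)
}

#' Closest pair between two gene families in one genome
#'
#' Implements the per-genome selection underlying the neighborhood-linkage
#' statistics: among all pairs of one family-A gene and one family-B gene
#' that are distinct genes on the same replicon, the pair with the smallest
#' intergenic gap. Ties are broken deterministically by lexicographic
#' \code{(gene_a_id, gene_b_id)}.
#'
#' @param table a \code{\link{genome_table}}.
#' @param query_a,query_b \code{\link{family_query}} objects.
#' @param genome_id the genome to examine.
#' @return One-row data.frame with columns \code{genome_id},
#'   \code{replicon_id}, \code{gene_a_id}, \code{gene_b_id},
#'   \code{distance_bp}, \code{same_strand}; or \code{NULL} when either
#'   family is absent from the genome or the families never share a
#'   replicon.
#' @export
closest_pair <- function(table, query_a, query_b, genome_id) {
  stopifnot(inherits(table, "genome_table"))
  if (!genome_id %in% table$records$genome_id)
    stop("genome not in table: ", genome_id)
  rec <- table$records[table$records$genome_id == genome_id, , drop = FALSE]
  ga <- rec[query_matches(rec$labels, query_a), , drop = FALSE]
  gb <- rec[query_matches(rec$labels, query_b), , drop = FALSE]
  if (nrow(ga) == 0L || nrow(gb) == 0L) return(NULL)
  closest_pair_records(ga, gb, table$replicons, genome_id)
}

# Minimal-gap admissible pair over all shared replicons. Ties are broken by
# the lexicographically smallest unordered id pair, so that swapping the two
# queries can only relabel gene_a/gene_b, never change distance or strand.
closest_pair_records <- function(ga, gb, replicons, genome_id) {
  shared <- intersect(ga$replicon_id, gb$replicon_id)
  if (length(shared) == 0L) return(NULL)
  reps <- replicons[replicons$genome_id == genome_id, , drop = FALSE]
  cand <- lapply(shared, function(rid) {
    ra <- ga[ga$replicon_id == rid, , drop = FALSE]
    rb <- gb[gb$replicon_id == rid, , drop = FALSE]
    topo <- reps$topology[match(rid, reps$replicon_id)]
    rlen <- reps$length_bp[match(rid, reps$replicon_id)]
    if (is.na(topo)) topo <- "linear"
    ia <- rep(seq_len(nrow(ra)), times = nrow(rb))
    ib <- rep(seq_len(nrow(rb)), each = nrow(ra))
    keep <- ra$gene_id[ia] != rb$gene_id[ib]  # a gene is never paired with itself
    if (!any(keep)) return(NULL)
    ia <- ia[keep]; ib <- ib[keep]
    data.frame(
      genome_id = genome_id, replicon_id = rid,
      gene_a_id = ra$gene_id[ia], gene_b_id = rb$gene_id[ib],
      distance_bp = gap_bp(ra$start[ia], ra$end[ia],
                           rb$start[ib], rb$end[ib],
                           topology = topo, length_bp = rlen),
      same_strand = ra$strand[ia] == rb$strand[ib],
      stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  ord <- order(cand$distance_bp,
               pmin(cand$gene_a_id, cand$gene_b_id),
               pmax(cand$gene_a_id, cand$gene_b_id),
               cand$gene_a_id)
  out <- cand[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate neighborhood-linkage statistics between two families
#'
#' Runs \code{\link{closest_pair}} over every genome in the table and
#' aggregates: how often the closest pair lies on the same strand, and the
#' distribution of intergenic distances, with a headline fraction at a
#' distance threshold (default 2 kb). Genomes where the two families
#' co-occur but never share a replicon count towards
#' \code{n_genomes_with_both} (presence semantics) but not towards the
#' strand/distance statistics, whose denominator is
#' \code{n_genomes_with_pair}; both denominators are reported.
#'
#' @param table a \code{\link{genome_table}}.
#' @param query_a,query_b \code{\link{family_query}} objects.
#' @param breaks histogram bin edges in bp (half-open bins \code{[lo, hi)});
#'   default 500-bp bins on [0, 10000). Distances beyond the last edge fall
#'   into an overflow bin.
#' @param threshold_bp headline distance threshold; the reported
#'   \code{fraction_within_threshold} is the fraction of closest pairs with
#'   \code{distance_bp <= threshold_bp}.
#' @return List of class \code{linkage_summary} with elements
#'   \code{summary} (one-row data.frame: \code{n_genomes_with_both},
#'   \code{n_genomes_with_pair}, \code{n_same_strand},
#'   \code{fraction_same_strand}, \code{fraction_within_threshold},
#'   \code{threshold_bp}), \code{pairs} (per-genome closest-pair
#'   data.frame) and \code{distance_histogram} (data.frame \code{bin_lo},
#'   \code{bin_hi}, \code{count}; counts sum to \code{n_genomes_with_pair}).
#' @export
linkage_summary <- function(table, query_a, query_b,
                            breaks = seq(0, 10000, by = 500),
                            threshold_bp = 2000L) {
  stopifnot(inherits(table, "genome_table"))
  rec <- table$records
  genomes <- sort(unique(rec$genome_id))
  ma <- query_matches(rec$labels, query_a)
  mb <- query_matches(rec$labels, query_b)
  pairs <- vector("list", length(genomes))
  n_both <- 0L
  for (i in seq_along(genomes)) {
    g <- genomes[i]
    sel <- rec$genome_id == g
    ga <- rec[sel & ma, , drop = FALSE]
    gb <- rec[sel & mb, , drop = FALSE]
    if (nrow(ga) == 0L || nrow(gb) == 0L) next
    n_both <- n_both + 1L
    pairs[[i]] <- closest_pair_records(ga, gb, table$replicons, g)
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(genome_id = character(), replicon_id = character(),
                        gene_a_id = character(), gene_b_id = character(),
                        distance_bp = integer(), same_strand = logical(),
                        stringsAsFactors = FALSE)
  n_pair <- nrow(pairs)
  n_same <- sum(pairs$same_strand)
  hist_df <- distance_histogram(pairs$distance_bp, breaks)
  summary <- data.frame(
    n_genomes_with_both = n_both,
    n_genomes_with_pair = n_pair,
    n_same_strand = n_same,
    fraction_same_strand = if (n_pair > 0L) n_same / n_pair else NA_real_,
    fraction_within_threshold =
      if (n_pair > 0L) mean(pairs$distance_bp <= threshold_bp) else NA_real_,
    threshold_bp = as.integer(threshold_bp))
  structure(list(summary = summary, pairs = pairs,
                 distance_histogram = hist_df),
            class = "linkage_summary")
}

distance_histogram <- function(d, breaks) {
  breaks <- sort(unique(as.numeric(breaks)))
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1L]
  lo <- c(lo, breaks[length(breaks)])
  hi <- c(hi, Inf)  # overflow bin
  counts <- vapply(seq_along(lo), function(i) sum(d >= lo[i] & d < hi[i]),
                   integer(1))
  data.frame(bin_lo = lo, bin_hi = hi, count = counts)
}

#' @export
print.linkage_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("linkage_summary: %d genome(s) with both families, %d with a same-replicon pair\n",
              s$n_genomes_with_both, s$n_genomes_with_pair))
  if (s$n_genomes_with_pair > 0L)
    cat(sprintf("  same strand: %d/%d (%.1f%%); within %d bp: %.1f%%\n",
                s$n_same_strand, s$n_genomes_with_pair,
                100 * s$fraction_same_strand, s$threshold_bp,
                100 * s$fraction_within_threshold))
  invisible(x)
}
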