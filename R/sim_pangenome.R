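#' Configuration for the synthetic annotated pangenome
#'
#' Describes a set of genomes in which gene families appear independently
#' with given probabilities and, whenever the two focal families co-occur in
#' a genome, they are planted as an adjacent same-strand pair (operon-style
#' linkage) with probability \code{p_link}, with the intergenic gap drawn
#' uniformly from \code{gap_range}. Unplanted genes are placed uniformly at
#' random without overlap, with strands Bernoulli(0.5). Decoy genes carry
#' label combinations that must be rejected by the built-in family queries
#' (e.g. \{K22719, K06194\} for the envC exclusion and \{PF01520\} without
#' PF11741 for the amiC requirement), so query exclusion logic is exercised.
#'
#' @param n_genomes number of genomes.
#' @param replicon_length_bp length of each replicon.
#' @param n_replicons replicons per genome (genes are spread uniformly;
#'   planted pairs always share replicon 1).
#' @param topology \code{"linear"} or \code{"circular"}.
#' @param presence named vector of per-family presence probabilities; names
#'   must be built-in family names.
#' @param focal character vector of length 2: the two families whose
#'   linkage is planted.
#' @param p_link probability that a co-occurring focal pair is planted
#'   adjacent and co-oriented.
#' @param gap_range integer range \code{c(g_min, g_max)} for the planted
#'   intergenic gap (uniform, inclusive).
#' @param n_decoys decoy genes per genome.
#' @param gene_length_range gene length range in bp (uniform).
#' @return List of class \code{pangenome_config}.
#' @export
pangenome_config <- function(n_genomes = 500L,
                             replicon_length_bp = 4600000L,
                             n_replicons = 1L,
                             topology = "linear",
                             presence = c(sddA = 0.8, envC = 0.8,
                                          gpmM = 0.9, amiC = 0.7),
                             focal = c("envC", "sddA"),
                             p_link = 0.8,
                             gap_range = c(0L, 2000L),
                             n_decoys = 3L,
                             gene_length_range = c(300L, 3000L)) {
  stopifnot(n_genomes >= 1L, replicon_length_bp > 0L, n_replicons >= 1L,
            topology %in% c("linear", "circular"),
            all(presence >= 0 & presence <= 1),
            length(focal) == 2L, all(focal %in% names(presence)),
            p_link >= 0, p_link <= 1,
            length(gap_range) == 2L, gap_range[1L] <= gap_range[2L],
            gene_length_range[1L] <= gene_length_range[2L])
  structure(list(n_genomes = as.integer(n_genomes),
                 replicon_length_bp = as.integer(replicon_length_bp),
                 n_replicons = as.integer(n_replicons),
                 topology = topology, presence = presence, focal = focal,
                 p_link = p_link, gap_range = as.integer(gap_range),
                 n_decoys = as.integer(n_decoys),
                 gene_length_range = as.integer(gene_length_range)),
            class = "pangenome_config")
}

# labels planted for each built-in family (one representative term set; the
# family queries must accept exactly these)
FAMILY_PLANT_LABELS <- c(
  sddA = "PFAM:PF04748",
  envC = "KEGG:K22719",
  gpmM = "TIGRFAM:TIGR01307",
  amiC = "KEGG:K01448;PFAM:PF11741")

# decoy label sets: each must be rejected by every built-in family query
DECOY_LABEL_POOL <- c(
  "KEGG:K22719;KEGG:K06194",   # EnvC term plus NlpD term -> excluded
  "KEGG:K22719;KEGG:K19304",   # EnvC term plus MepM term -> excluded
  "KEGG:K22719;KEGG:K12943",   # EnvC term plus YgeR term -> excluded
  "PFAM:PF01520",              # amidase domain without AMIN -> not amiC
  "KEGG:K01448",               # amidase term without AMIN -> not amiC
  "PFAM:PF00905",              # unrelated PBP domain
  "KEGG:K03587",               # unrelated division gene (ftsI)
  "")                          # unannotated gene

#' Generate a synthetic annotated pangenome with planted linkage
#'
#' Emits a \code{\link{genome_table}} together with a per-genome truth
#' table recording which families are present, whether operon-style linkage
#' between the two focal families was planted, and the planted gap and
#' strand, for end-to-end recovery tests of the family-query and
#' neighborhood-linkage stages. Output is deterministic given
#' \code{seed}. A small two-level synthetic taxonomy (phylum/class) is
#' attached.
#'
#' @param config a \code{\link{pangenome_config}}.
#' @param seed integer random seed.
#' @return List with elements \code{table} (\code{genome_table}) and
#'   \code{truth} (data.frame: \code{genome_id}, \code{has_<family>}...,
#'   \code{planted}, \code{planted_gap_bp}, \code{planted_strand}).
#' @export
generate_pangenome <- function(config = pangenome_config(), seed = 1L) {
  stopifnot(inherits(config, "pangenome_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  fams <- names(config$presence)
  recs <- vector("list", config$n_genomes)
  truth <- vector("list", config$n_genomes)
  phyla <- c("Synthophyla_A", "Synthophyla_B")
  tax <- data.frame(genome_id = character(config$n_genomes),
                    phylum = character(config$n_genomes),
                    class = character(config$n_genomes),
                    stringsAsFactors = FALSE)

  for (i in seq_len(config$n_genomes)) {
    gid <- sprintf("g%04d", i)
    present <- runif(length(fams)) < config$presence
    names(present) <- fams
    focal_a <- config$focal[1L]; focal_b <- config$focal[2L]
    planted <- FALSE
    planted_gap <- NA_integer_
    planted_strand <- NA_character_
    # per replicon: matrix of occupied [start,end) intervals
    placed <- vector("list", config$n_replicons)
    genes <- list()
    # sample() on a length-1 vector would sample from 1:x
    runi <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
    glen <- function() runi(config$gene_length_range[1L],
                            config$gene_length_range[2L])
    place_block <- function(total_len, replicon) {
      # returns a free start for a block of total_len on the replicon,
      # or NA after bounded retries
      occ <- placed[[replicon]]
      for (try in 1:100) {
        s <- sample.int(config$replicon_length_bp - total_len, 1L) - 1L
        e <- s + total_len
        if (is.null(occ) || all(e <= occ[, 1L] | s >= occ[, 2L]))
          return(s)
      }
      NA_integer_
    }
    add_gene <- function(id, replicon, s, e, strand, labels) {
      placed[[replicon]] <<- rbind(placed[[replicon]], c(s, e))
      genes[[length(genes) + 1L]] <<- data.frame(
        genome_id = gid, replicon_id = sprintf("%s_r%d", gid, replicon),
        gene_id = id, start = s, end = e, strand = strand, labels = labels,
        stringsAsFactors = FALSE)
    }
    pick_replicon <- function() sample.int(config$n_replicons, 1L)

    rest <- fams[present]
    if (present[focal_a] && present[focal_b]) {
      planted <- runif(1) < config$p_link
      if (planted) {
        la <- glen(); lb <- glen()
        planted_gap <- runi(config$gap_range[1L], config$gap_range[2L])
        planted_strand <- if (runif(1) < 0.5) "+" else "-"
        s <- place_block(la + planted_gap + lb, 1L)
        if (is.na(s))
          stop("could not place planted pair in genome ", gid,
               "; increase replicon_length_bp")
        add_gene(paste0(gid, "_", focal_a), 1L, s, s + la,
                 planted_strand, FAMILY_PLANT_LABELS[[focal_a]])
        add_gene(paste0(gid, "_", focal_b), 1L,
                 s + la + planted_gap, s + la + planted_gap + lb,
                 planted_strand, FAMILY_PLANT_LABELS[[focal_b]])
        rest <- setdiff(rest, c(focal_a, focal_b))
      }
    }
    for (fam in rest) {
      len <- glen()
      rep_i <- pick_replicon()
      s <- place_block(len, rep_i)
      if (is.na(s))
        stop("could not place gene in genome ", gid,
             "; increase replicon_length_bp")
      add_gene(paste0(gid, "_", fam), rep_i, s, s + len,
               if (runif(1) < 0.5) "+" else "-", FAMILY_PLANT_LABELS[[fam]])
    }
    if (config$n_decoys > 0L) {
      for (d in seq_len(config$n_decoys)) {
        len <- glen()
        rep_i <- pick_replicon()
        s <- place_block(len, rep_i)
        if (is.na(s))
          stop("could not place decoy in genome ", gid,
               "; increase replicon_length_bp")
        add_gene(sprintf("%s_decoy%02d", gid, d), rep_i, s, s + len,
                 if (runif(1) < 0.5) "+" else "-",
                 sample(DECOY_LABEL_POOL, 1L))
      }
    }
    recs[[i]] <- do.call(rbind, genes)
    truth[[i]] <- data.frame(
      genome_id = gid,
      setNames(as.data.frame(as.list(present)), paste0("has_", fams)),
      planted = planted, planted_gap_bp = planted_gap,
      planted_strand = planted_strand, stringsAsFactors = FALSE)
    ph <- sample(phyla, 1L)
    tax$genome_id[i] <- gid
    tax$phylum[i] <- ph
    tax$class[i] <- paste0(ph, "_c", sample.int(2L, 1L))
  }
  records <- do.call(rbind, recs)
  rep_map <- unique(records[c("genome_id", "replicon_id")])
  replicons <- data.frame(rep_map,
                          length_bp = config$replicon_length_bp,
                          topology = config$topology,
                          stringsAsFactors = FALSE)
  list(table = genome_table(records, replicons = replicons, taxonomy = tax),
       truth = do.call(rbind, truth))
}
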