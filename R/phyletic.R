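#' Per-genome copy-number (phyletic) profile matrix
#'
#' One row per genome, one column per family, values = copy counts from
#' \code{\link{count_per_genome}}; absent families are 0, never missing.
#'
#' @param table a \code{\link{genome_table}}.
#' @param queries list of \code{\link{family_query}} objects with distinct
#'   names.
#' @return Integer matrix with genome ids as row names and family names as
#'   column names, rows sorted by genome id; the table's taxonomy (if any)
#'   is attached as attribute \code{"taxonomy"}.
#' @export
profile_matrix <- function(table, queries) {
  stopifnot(inherits(table, "genome_table"), length(queries) >= 1L)
  if (inherits(queries, "family_query")) queries <- list(queries)
  fams <- vapply(queries, function(q) q$name, character(1))
  if (anyDuplicated(fams))
    stop("duplicate family names: ",
         paste(unique(fams[duplicated(fams)]), collapse = ", "))
  cols <- lapply(queries, function(q) count_per_genome(table, q))
  genomes <- sort(unique(table$records$genome_id))
  m <- matrix(0L, nrow = length(genomes), ncol = length(fams),
              dimnames = list(genomes, fams))
  for (j in seq_along(cols)) m[names(cols[[j]]), j] <- cols[[j]]
  attr(m, "taxonomy") <- table$taxonomy
  m
}

#' Aggregate a profile matrix by taxon
#'
#' Summarizes family presence per taxon at a chosen rank: number of genomes,
#' fraction of genomes carrying at least one copy, and mean copy number.
#' Genomes lacking taxonomy at the requested rank are grouped under
#' \code{"unassigned"}.
#'
#' @param matrix a \code{\link{profile_matrix}} result (taxonomy attached),
#'   or any integer matrix plus an explicit \code{taxonomy} data.frame.
#' @param level taxonomic rank: a column name of the taxonomy table.
#' @param taxonomy optional override of the attached taxonomy.
#' @return data.frame with columns \code{taxon}, \code{family},
#'   \code{n_genomes}, \code{fraction_present}, \code{mean_copies}; one row
#'   per taxon x family.
#' @export
aggregate_by_taxon <- function(matrix, level, taxonomy = NULL) {
  taxonomy <- taxonomy %||% attr(matrix, "taxonomy")
  if (is.null(taxonomy))
    stop("no taxonomy attached to the profile matrix")
  if (!level %in% setdiff(names(taxonomy), "genome_id"))
    stop("unknown taxonomic rank '", level, "'; available: ",
         paste(setdiff(names(taxonomy), "genome_id"), collapse = ", "))
  taxon <- taxonomy[[level]][match(rownames(matrix), taxonomy$genome_id)]
  taxon[is.na(taxon) | !nzchar(taxon)] <- "unassigned"
  out <- lapply(sort(unique(taxon)), function(tx) {
    sub <- matrix[taxon == tx, , drop = FALSE]
    data.frame(taxon = tx, family = colnames(matrix),
               n_genomes = nrow(sub),
               fraction_present = colMeans(sub >= 1L),
               mean_copies = colMeans(sub),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export a profile matrix for tree visualization
#'
#' Writes (a) a plain TSV keyed by \code{genome_id} with one column per
#' family and (b) an iTOL-style multi-value bar dataset
#' (\code{DATASET_MULTIBAR} dialect, iTOL dataset format as of v6) whose
#' data lines are \code{genome_id,count,count,...}. If a Newick tree is
#' given its tip order determines row order (tips absent from the matrix
#' are skipped; genomes absent from the tree are appended alphabetically);
#' the tree is used for ordering only, never modified or inferred.
#'
#' @param matrix a \code{\link{profile_matrix}} result.
#' @param path output TSV path; the iTOL text is written next to it with
#'   extension \code{.itol.txt}.
#' @param tree optional \code{ape::phylo} object or path to a Newick file.
#' @param dataset_label label stored in the iTOL header.
#' @return Invisibly, the paths written.
#' @export
export_tree_dataset <- function(matrix, path, tree = NULL,
                                dataset_label = "family copy number") {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L)
    stop("profile matrix is empty")
  ord <- rownames(matrix)
  if (!is.null(tree)) {
    if (is.character(tree)) tree <- ape::read.tree(tree)
    tips <- tree$tip.label
    ord <- c(intersect(tips, ord), sort(setdiff(ord, tips)))
  }
  m <- matrix[ord, , drop = FALSE]
  df <- data.frame(genome_id = rownames(m), as.data.frame(m),
                   row.names = NULL, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  itol_path <- paste0(sub("\\.[^.]*$", "", path), ".itol.txt")
  con <- file(itol_path, "w")
  on.exit(close(con))
  writeLines(c(
    "DATASET_MULTIBAR",
    "SEPARATOR COMMA",
    paste0("DATASET_LABEL,", dataset_label),
    "COLOR,#1f78b4",
    paste0("FIELD_LABELS,", paste(colnames(m), collapse = ",")),
    paste0("FIELD_COLORS,",
           paste(rep(c("#1f78b4", "#33a02c", "#e31a1c", "#ff7f00"),
                     length.out = ncol(m)), collapse = ",")),
    "DATA"), con)
  writeLines(paste(rownames(m), apply(m, 1L, paste, collapse = ","),
                   sep = ","), con)
  invisible(c(tsv = path, itol = itol_path))
}

#' Read back an exported profile TSV
#' @param path path written by \code{\link{export_tree_dataset}}.
#' @return Integer matrix with genome ids as row names.
#' @export
read_tree_dataset <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$genome_id
  m
}
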