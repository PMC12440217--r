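#' Define a gene family as a boolean annotation query
#'
#' A gene matches a family query iff it carries at least one \code{include}
#' term, none of the \code{exclude} terms, and all of the \code{require}
#' terms. Terms are namespaced annotation accessions such as
#' \code{"PFAM:PF04748"} or \code{"KEGG:K22719"}; case is normalized on
#' construction.
#'
#' @param name family name (used as column name in profiles and outputs).
#' @param include character vector, non-empty: match if the gene has any.
#' @param exclude character vector: match forbidden if the gene has any.
#' @param require character vector: the gene must have all.
#' @return An object of class \code{family_query}.
#' @export
family_query <- function(name, include, exclude = character(),
                         require = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  include <- toupper(trimws(as.character(include)))
  exclude <- toupper(trimws(as.character(exclude)))
  require <- toupper(trimws(as.character(require)))
  include <- include[nzchar(include)]
  exclude <- exclude[nzchar(exclude)]
  require <- require[nzchar(require)]
  if (length(include) == 0L)
    stop("family query '", name, "': include set must be non-empty")
  overlap <- intersect(include, exclude)
  if (length(overlap) > 0L)
    stop("family query '", name, "': include and exclude overlap: ",
         paste(overlap, collapse = ", "))
  structure(list(name = name, include = sort(unique(include)),
                 exclude = sort(unique(exclude)),
                 require = sort(unique(require))),
            class = "family_query")
}

#' @export
print.family_query <- function(x, ...) {
  cat("family_query '", x$name, "'\n", sep = "")
  cat("  include:", paste(x$include, collapse = ", "), "\n")
  if (length(x$exclude))
    cat("  exclude:", paste(x$exclude, collapse = ", "), "\n")
  if (length(x$require))
    cat("  require:", paste(x$require, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in family definitions
#'
#' Returns one of the four built-in gene-family queries used in the
#' envC--sddA neighborhood analysis. The definitions are shipped as a YAML
#' config file (\code{system.file("extdata", "families.yaml", package =
#' "septolink")}) rather than hard-coded, so they can be copied and edited as
#' annotation databases drift:
#' \describe{
#'   \item{sddA}{divergent polysaccharide deacetylase: \code{PFAM:PF04748}
#'     or \code{KEGG:K09798} (YibQ-like).}
#'   \item{envC}{murein hydrolase activator EnvC: \code{KEGG:K22719}, not
#'     also annotated with the other LytM activator terms \code{K19304}
#'     (MepM), \code{K06194} (NlpD) or \code{K12943} (YgeR).}
#'   \item{gpmM}{2,3-bisphosphoglycerate-independent phosphoglycerate
#'     mutase: \code{TIGRFAM:TIGR01307} (single-copy control family).}
#'   \item{amiC}{septal amidase AmiC: \code{KEGG:K01448} or
#'     \code{PFAM:PF01520}, additionally requiring an AMIN targeting domain
#'     \code{PFAM:PF11741}.}
#' }
#'
#' @param family one of \code{"sddA"}, \code{"envC"}, \code{"gpmM"},
#'   \code{"amiC"}.
#' @param config path to a YAML family-definition file; defaults to the
#'   shipped one.
#' @return A \code{\link{family_query}}.
#' @export
builtin_query <- function(family, config = NULL) {
  defs <- load_family_config(config)
  if (!family %in% names(defs))
    stop("unknown family '", family, "'; valid names: ",
         paste(names(defs), collapse = ", "))
  defs[[family]]
}

#' Load family definitions from a YAML config file
#'
#' Each top-level entry names a family and holds \code{include} /
#' \code{exclude} / \code{require} term lists.
#'
#' @param config path; \code{NULL} for the shipped definitions.
#' @return Named list of \code{\link{family_query}} objects.
#' @export
load_family_config <- function(config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "families.yaml", package = "septolink")
  raw <- yaml::read_yaml(config)
  out <- lapply(names(raw), function(nm) {
    d <- raw[[nm]]
    family_query(nm,
                 include = unlist(d$include),
                 exclude = unlist(d$exclude %||% character()),
                 require = unlist(d$require %||% character()))
  })
  setNames(out, names(raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorized predicate over the label strings of a genome_table
query_matches <- function(labels, query) {
  terms <- split_labels(labels)
  vapply(terms, function(tt) {
    length(intersect(tt, query$include)) > 0L &&
      length(intersect(tt, query$exclude)) == 0L &&
      all(query$require %in% tt)
  }, logical(1))
}

#' Genes matching a family query
#'
#' @param table a \code{\link{genome_table}}.
#' @param query a \code{\link{family_query}}.
#' @return data.frame of matching gene records in stable
#'   (genome_id, replicon_id, start) order; zero rows when nothing matches.
#' @export
match_genes <- function(table, query) {
  stopifnot(inherits(table, "genome_table"), inherits(query, "family_query"))
  rec <- table$records
  hit <- rec[query_matches(rec$labels, query), , drop = FALSE]
  hit <- hit[order(hit$genome_id, hit$replicon_id, hit$start, hit$gene_id), ,
             drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Per-genome copy number of a family
#'
#' Counts matching genes per genome; every genome present in the table
#' appears, with count 0 when the family is absent, so the counts sum to
#' \code{nrow(match_genes(table, query))}.
#'
#' @inheritParams match_genes
#' @return Named integer vector, one element per genome (sorted by
#'   genome_id).
#' @export
count_per_genome <- function(table, query) {
  stopifnot(inherits(table, "genome_table"))
  genomes <- sort(unique(table$records$genome_id))
  hits <- match_genes(table, query)
  counts <- table(factor(hits$genome_id, levels = genomes))
  setNames(as.integer(counts), genomes)
}
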