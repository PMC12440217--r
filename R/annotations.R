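#' @importFrom stats approx median sd rnorm runif rbinom coef lm setNames
#' @importFrom utils read.delim write.table head tail
NULL

VALID_STRANDS <- c("+", "-")
KNOWN_NAMESPACES <- c("PFAM", "KEGG", "TIGRFAM")

#' Construct a genome annotation table
#'
#' The central container of the comparative-genomics half of the package: a
#' set of gene records across one or more genomes, each gene carrying a
#' genomic location and a set of namespaced functional labels
#' (\code{PFAM:}, \code{KEGG:}, \code{TIGRFAM:} accessions), as found in
#' consistently annotated pangenome databases.
#'
#' Coordinates are 0-based half-open throughout the package: a gene occupying
#' base pairs 101..400 in 1-based inclusive (GFF3) convention has
#' \code{start = 100}, \code{end = 400}. This makes gap and length arithmetic
#' subtraction-only.
#'
#' @param records data.frame with columns \code{genome_id}, \code{replicon_id},
#'   \code{gene_id}, \code{start}, \code{end} (0-based half-open integers),
#'   \code{strand} (\code{"+"} or \code{"-"}) and \code{labels}
#'   (semicolon-separated \code{NAMESPACE:ACCESSION} terms; may be \code{""}).
#' @param replicons optional data.frame with columns \code{genome_id},
#'   \code{replicon_id}, \code{length_bp} (integer or \code{NA} when unknown)
#'   and \code{topology} (\code{"linear"} or \code{"circular"}). Replicons
#'   referenced by \code{records} but absent here are registered as linear
#'   with unknown length.
#' @param taxonomy optional data.frame keyed by \code{genome_id} with one
#'   column per taxonomic rank (e.g. \code{phylum}, \code{class}).
#'
#' @return An object of class \code{genome_table}.
#' @export
genome_table <- function(records, replicons = NULL, taxonomy = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("genome_id", "replicon_id", "gene_id", "start", "end",
              "strand", "labels")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L)
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  records <- records[needed]
  records$genome_id <- as.character(records$genome_id)
  records$replicon_id <- as.character(records$replicon_id)
  records$gene_id <- as.character(records$gene_id)
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  records$strand <- as.character(records$strand)
  records$labels <- normalize_labels(as.character(records$labels))

  bad <- which(!(records$start >= 0L & records$start < records$end))
  if (length(bad) > 0L)
    stop("malformed coordinates (need 0 <= start < end) in record(s): ",
         paste(records$gene_id[bad], collapse = ", "))
  bad <- which(!records$strand %in% VALID_STRANDS)
  if (length(bad) > 0L)
    stop("unknown strand symbol in record(s): ",
         paste(records$gene_id[bad], collapse = ", "),
         " (must be one of '+', '-')")
  dup <- duplicated(paste(records$genome_id, records$gene_id, sep = "\r"))
  if (any(dup))
    stop("duplicate gene_id within genome: ",
         paste(unique(paste0(records$genome_id[dup], "/",
                             records$gene_id[dup])), collapse = ", "))

  replicons <- complete_replicons(records, replicons)

  # genes running past a declared replicon length are rejected at load
  key <- paste(records$genome_id, records$replicon_id, sep = "\r")
  rkey <- paste(replicons$genome_id, replicons$replicon_id, sep = "\r")
  rlen <- replicons$length_bp[match(key, rkey)]
  over <- which(!is.na(rlen) & records$end > rlen)
  if (length(over) > 0L)
    stop("gene(s) extend past declared replicon length: ",
         paste(records$gene_id[over], collapse = ", "))

  if (!is.null(taxonomy)) {
    stopifnot(is.data.frame(taxonomy), "genome_id" %in% names(taxonomy))
    taxonomy$genome_id <- as.character(taxonomy$genome_id)
  }

  records <- records[order(records$genome_id, records$replicon_id,
                           records$start, records$gene_id), , drop = FALSE]
  rownames(records) <- NULL
  unknown_ns <- setdiff(unique(unlist(lapply(
    split_labels(records$labels), term_namespace))), c(KNOWN_NAMESPACES, character()))
  if (length(unknown_ns) > 0L)
    message("note: labels with unknown namespace(s) preserved verbatim: ",
            paste(unknown_ns, collapse = ", "))
  structure(list(records = records, replicons = replicons,
                 taxonomy = taxonomy),
            class = "genome_table")
}

complete_replicons <- function(records, replicons) {
  seen <- unique(records[c("genome_id", "replicon_id")])
  if (is.null(replicons)) {
    replicons <- data.frame(seen, length_bp = NA_integer_,
                            topology = "linear", stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(replicons))
    need <- c("genome_id", "replicon_id")
    stopifnot(all(need %in% names(replicons)))
    if (is.null(replicons$length_bp)) replicons$length_bp <- NA_integer_
    if (is.null(replicons$topology)) replicons$topology <- "linear"
    replicons$genome_id <- as.character(replicons$genome_id)
    replicons$replicon_id <- as.character(replicons$replicon_id)
    replicons$length_bp <- as.integer(replicons$length_bp)
    replicons$topology <- as.character(replicons$topology)
    stopifnot(all(replicons$topology %in% c("linear", "circular")))
    key <- paste(seen$genome_id, seen$replicon_id, sep = "\r")
    rkey <- paste(replicons$genome_id, replicons$replicon_id, sep = "\r")
    extra <- seen[!key %in% rkey, , drop = FALSE]
    if (nrow(extra) > 0L)
      replicons <- rbind(
        replicons[c("genome_id", "replicon_id", "length_bp", "topology")],
        data.frame(extra, length_bp = NA_integer_, topology = "linear",
                   stringsAsFactors = FALSE))
  }
  replicons <- replicons[order(replicons$genome_id, replicons$replicon_id), ,
                         drop = FALSE]
  rownames(replicons) <- NULL
  replicons
}

#' @export
print.genome_table <- function(x, ...) {
  cat(sprintf("genome_table: %d gene(s) across %d genome(s), %d replicon(s)\n",
              nrow(x$records), length(unique(x$records$genome_id)),
              nrow(x$replicons)))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy: %s\n",
                paste(setdiff(names(x$taxonomy), "genome_id"),
                      collapse = " > ")))
  invisible(x)
}

# "pfam:pf04748" -> "PFAM:PF04748"; namespace and accession upper-cased,
# terms de-duplicated and sorted so equal label sets compare equal as strings
normalize_labels <- function(labels) {
  labels[is.na(labels)] <- ""
  vapply(strsplit(labels, ";", fixed = TRUE), function(terms) {
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0L) return("")
    paste(sort(unique(toupper(terms))), collapse = ";")
  }, character(1))
}

split_labels <- function(labels) {
  out <- strsplit(labels, ";", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}

term_namespace <- function(terms) {
  sub(":.*$", "", terms[grepl(":", terms, fixed = TRUE)])
}

#' Read a genome annotation table
#'
#' Reads gene annotations from either a GFF3 file (genes only; 1-based
#' inclusive coordinates converted to the internal 0-based half-open
#' convention; functional labels carried in the attribute keys \code{pfam},
#' \code{kegg}, \code{tigrfam}, comma-separated; \code{genome_id} as a gene
#' attribute) or the package's TSV dialect (columns \code{genome_id},
#' \code{replicon_id}, \code{gene_id}, \code{start}, \code{end},
#' \code{strand}, \code{labels}, already 0-based half-open).
#'
#' In GFF3 input the seqid column is the replicon id, and
#' \code{##sequence-region} pragmas, when present, declare replicon lengths.
#'
#' @param path file path.
#' @param format \code{"gff3"} or \code{"tsv"}; default guessed from the
#'   file extension.
#' @param replicons,taxonomy optional tables forwarded to
#'   \code{\link{genome_table}} (TSV input only; GFF3 carries its own
#'   sequence-region information).
#' @param circular character vector of replicon ids to declare circular
#'   (GFF3 input; the format itself does not state topology).
#' @return A \code{\link{genome_table}}.
#' @export
read_annotations <- function(path, format = c("auto", "gff3", "tsv"),
                             replicons = NULL, taxonomy = NULL,
                             circular = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    read_annotations_gff3(path, circular = circular, taxonomy = taxonomy)
  } else {
    read_annotations_tsv(path, replicons = replicons, taxonomy = taxonomy)
  }
}

read_annotations_tsv <- function(path, replicons = NULL, taxonomy = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("genome_id", "replicon_id", "gene_id", "start", "end",
              "strand", "labels")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop("TSV is missing columns: ", paste(missing_cols, collapse = ", "))
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0L)
    # +1 header line to report the physical line number in the file
    stop("malformed coordinates at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path,
         " (need 0 <= start < end)")
  bad <- which(!df$strand %in% VALID_STRANDS)
  if (length(bad) > 0L)
    stop("unknown strand symbol at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  df$start <- start
  df$end <- end
  genome_table(df, replicons = replicons, taxonomy = taxonomy)
}

read_annotations_gff3 <- function(path, circular = character(),
                                  taxonomy = NULL) {
  # rtracklayer errors on sequenceRegionsAsSeqinfo when no pragma exists
  has_region <- any(startsWith(readLines(path, warn = FALSE),
                               "##sequence-region"))
  gr <- rtracklayer::import.gff3(path, sequenceRegionsAsSeqinfo = has_region)
  gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
  if (length(gr) == 0L) stop("no gene/CDS features in ", path)
  md <- S4Vectors::mcols(gr)
  genome_id <- if ("genome_id" %in% names(md)) {
    as.character(md$genome_id)
  } else {
    rep(sub("\\.gff3?$", "", basename(path), ignore.case = TRUE), length(gr))
  }
  gene_id <- if ("ID" %in% names(md) && !all(is.na(md$ID))) {
    as.character(md$ID)
  } else stop("GFF3 gene features need an ID attribute: ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("unknown strand symbol '*' for gene(s): ",
         paste(gene_id[strand == "*"], collapse = ", "))
  labels <- gff3_labels(md)
  records <- data.frame(
    genome_id = genome_id,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = gene_id,
    start = BiocGenerics::start(gr) - 1L,  # 1-based inclusive -> 0-based half-open
    end = BiocGenerics::end(gr),
    strand = strand,
    labels = labels,
    stringsAsFactors = FALSE)
  sl <- GenomeInfoDb::seqlengths(gr)
  rep_tab <- NULL
  if (length(sl) > 0L) {
    rep_map <- unique(records[c("genome_id", "replicon_id")])
    rep_tab <- data.frame(
      rep_map,
      length_bp = as.integer(sl[rep_map$replicon_id]),
      topology = ifelse(rep_map$replicon_id %in% circular,
                        "circular", "linear"),
      stringsAsFactors = FALSE)
  } else if (length(circular) > 0L) {
    rep_map <- unique(records[c("genome_id", "replicon_id")])
    rep_tab <- data.frame(
      rep_map, length_bp = NA_integer_,
      topology = ifelse(rep_map$replicon_id %in% circular,
                        "circular", "linear"),
      stringsAsFactors = FALSE)
  }
  genome_table(records, replicons = rep_tab, taxonomy = taxonomy)
}

gff3_labels <- function(md) {
  per_ns <- lapply(c(pfam = "PFAM", kegg = "KEGG", tigrfam = "TIGRFAM"),
                   function(x) NULL)
  n <- nrow(md)
  out <- rep("", n)
  for (key in c("pfam", "kegg", "tigrfam")) {
    if (!key %in% names(md)) next
    vals <- md[[key]]
    ns <- toupper(key)
    txt <- vapply(seq_len(n), function(i) {
      v <- unlist(vals[i])
      v <- v[!is.na(v) & nzchar(v)]
      if (length(v) == 0L) return("")
      paste0(ns, ":", toupper(unlist(strsplit(v, ",", fixed = TRUE))),
             collapse = ";")
    }, character(1))
    out <- ifelse(nzchar(out) & nzchar(txt), paste(out, txt, sep = ";"),
                  paste0(out, txt))
  }
  out
}

#' Write a genome annotation table
#'
#' Writes a \code{genome_table} either in the package's TSV dialect or as
#' GFF3 (converting the internal 0-based half-open coordinates back to
#' 1-based inclusive). Both formats round trip through
#' \code{\link{read_annotations}}.
#'
#' @param table a \code{\link{genome_table}}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"gff3"}.
#' @export
write_annotations <- function(table, path, format = c("tsv", "gff3")) {
  stopifnot(inherits(table, "genome_table"))
  format <- match.arg(format)
  if (format == "tsv") {
    write_table(table$records, path, format = "tsv",
                key = c("genome_id", "replicon_id", "start", "gene_id"))
    return(invisible(NULL))
  }
  rec <- table$records
  terms <- split_labels(rec$labels)
  attr_of <- function(ns) vapply(terms, function(tt) {
    hit <- tt[startsWith(tt, paste0(ns, ":"))]
    if (length(hit) == 0L) NA_character_ else
      paste(sub("^[A-Z]+:", "", hit), collapse = ",")
  }, character(1))
  gr <- GenomicRanges::GRanges(
    seqnames = rec$replicon_id,
    ranges = IRanges::IRanges(start = rec$start + 1L, end = rec$end),
    strand = rec$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "gene", ID = rec$gene_id, genome_id = rec$genome_id,
    pfam = attr_of("PFAM"), kegg = attr_of("KEGG"),
    tigrfam = attr_of("TIGRFAM"))
  known <- table$replicons[!is.na(table$replicons$length_bp), , drop = FALSE]
  if (nrow(known) > 0L) {
    sl <- setNames(known$length_bp, known$replicon_id)
    keep <- intersect(names(sl), GenomeInfoDb::seqlevels(gr))
    GenomeInfoDb::seqlengths(gr)[keep] <- sl[keep]
  }
  rtracklayer::export.gff3(gr, path)
  if (nrow(known) > 0L) {
    # export.gff3 does not emit sequence-region pragmas itself
    lines <- readLines(path, warn = FALSE)
    pragmas <- sprintf("##sequence-region %s 1 %d",
                       known$replicon_id, known$length_bp)
    writeLines(c(lines[1L], pragmas, lines[-1L]), path)
  }
  invisible(NULL)
}

#' Write a tabular result deterministically
#'
#' All tabular outputs of the package go through this writer: column order is
#' taken from the data frame, rows are sorted by the given key columns, and
#' re-reading with \code{\link{read_result}} reproduces the table.
#'
#' @param table a data.frame (may have zero rows: a header-only file is
#'   written).
#' @param path output path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @param key character vector of column names to sort rows by; default all
#'   columns left to right.
#' @export
write_table <- function(table, path, format = c("tsv", "csv"), key = NULL) {
  if (is.null(table)) stop("table is NULL")
  stopifnot(is.data.frame(table))
  format <- match.arg(format)
  if (is.null(key)) key <- names(table)
  key <- intersect(key, names(table))
  if (nrow(table) > 0L && length(key) > 0L) {
    table <- table[do.call(order, unname(table[key])), , drop = FALSE]
  }
  write.table(table, path, sep = if (format == "tsv") "\t" else ",",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

#' Read back a table written by \code{write_table}
#' @param path file path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return data.frame.
#' @export
read_result <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  read.delim(path, sep = if (format == "tsv") "\t" else ",",
             stringsAsFactors = FALSE)
}
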