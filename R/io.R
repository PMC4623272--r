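# Readers and writers for the plain-text formats the pipeline exchanges.
# Internal coordinates are 0-based half-open; locus tables on disk are
# 1-based inclusive (genome-browser convention).

#' Read and write trace FASTA files
#'
#' Trace reads are stored as FASTA with headers of the form
#' `>trace_id project=<ID>`; the project token identifies the sequencing
#' project (the reference individual's reads versus others).
#'
#' @param path File path.
#' @return `read_traces_fasta`: data.frame(trace_id, project, sequence).
#' @export
read_traces_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  hdr <- names(dss)
  id <- sub("\\s.*$", "", hdr)
  project <- ifelse(grepl("project=", hdr),
                    sub(".*project=(\\S+).*", "\\1", hdr), NA_character_)
  data.frame(trace_id = id, project = project,
             sequence = as.character(dss), row.names = NULL)
}

#' @rdname read_traces_fasta
#' @param traces data.frame with `trace_id`, `project`, `sequence`.
#' @export
write_traces_fasta <- function(traces, path) {
  dss <- Biostrings::DNAStringSet(traces$sequence)
  names(dss) <- paste0(traces$trace_id, " project=", traces$project)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a contig placement table
#'
#' Tab-separated with columns `contig`, `chrom`, `offset` (0-based start of
#' the contig on the chromosome), `orientation` (+/-) and optionally
#' `length` (required to lift hits on reverse-oriented contigs). Malformed
#' rows are reported with their line number.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_placement <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "chrom", "offset", "orientation")
  if (!all(need %in% names(tab))) {
    stop("placement table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(is.na(tab$offset) | tab$offset < 0 |
                 !tab$orientation %in% c("+", "-") |
                 is.na(tab$contig) | tab$contig == "")
  if (length(bad) > 0) {
    stop("malformed placement row(s) at line ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  if (anyDuplicated(tab$contig)) {
    stop("placement table must have one row per contig")
  }
  tab
}

#' Read a repeat annotation
#'
#' Accepts either BED (chrom, start, end, name; 0-based half-open, no
#' header) or a RepeatMasker-style table with columns `genoName`,
#' `genoStart`, `genoEnd`, `repName` (and optionally `repClass`).
#'
#' @param path File path.
#' @return data.frame(chrom, start, end, name).
#' @export
read_repeats <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("genoName", first)) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    data.frame(chrom = tab$genoName, start = tab$genoStart,
               end = tab$genoEnd, name = tab$repName)
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(tab)[1:3] <- c("chrom", "start", "end")
    tab$name <- if (ncol(tab) >= 4) tab[[4]] else "."
    tab[, c("chrom", "start", "end", "name")]
  }
}

#' Read gene models from a refGene-style table or BED12
#'
#' The refGene-style layout has columns `gene_id`, `chrom`, `strand`,
#' `tx_start`, `tx_end`, `exon_starts`, `exon_ends` (comma-separated lists)
#' and optionally `source` (`validated`/`putative`); coordinates 0-based
#' half-open. BED12 files (12 tab-separated columns, no header) are
#' converted: blocks become exons and the name column the gene id.
#'
#' @param path File path.
#' @return data.frame in refGene-style layout.
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("tx_start", first)) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (is.null(tab$source)) tab$source <- "validated"
    return(tab)
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12) stop("expected refGene-style header or BED12")
  starts <- mapply(function(s, offs) {
    o <- as.integer(strsplit(offs, ",")[[1]])
    paste(s + o, collapse = ",")
  }, tab[[2]], tab[[12]])
  ends <- mapply(function(s, offs, sizes) {
    o <- as.integer(strsplit(offs, ",")[[1]])
    z <- as.integer(strsplit(sizes, ",")[[1]])
    paste(s + o + z, collapse = ",")
  }, tab[[2]], tab[[12]], tab[[11]])
  data.frame(gene_id = tab[[4]], chrom = tab[[1]], strand = tab[[6]],
             tx_start = tab[[2]], tx_end = tab[[3]],
             exon_starts = unname(starts), exon_ends = unname(ends),
             source = "validated")
}

#' Write and read a locus table
#'
#' On disk the table is 1-based inclusive with identity printed to one
#' decimal; in memory it is 0-based half-open with full precision.
#'
#' @param loci Locus data.frame from [discover_loci()] or [filter_hits()].
#' @param path File path.
#' @export
write_locus_table <- function(loci, path) {
  out <- loci
  out$start <- out$start + 1L        # 1-based inclusive
  out$identity <- sprintf("%.1f", out$identity)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_locus_table
#' @export
read_locus_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$start <- tab$start - 1L
  tab$identity <- as.numeric(tab$identity)
  tab
}

#' Write kept loci as BED
#'
#' @param loci Locus data.frame; only rows with `filter_status == "kept"`
#'   are written.
#' @param path File path.
#' @export
write_loci_bed <- function(loci, path) {
  kept <- loci[loci$filter_status == "kept", , drop = FALSE]
  bed <- data.frame(kept$chrom, kept$start, kept$end, kept$locus_id,
                    sprintf("%.1f", kept$identity), kept$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
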