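#' Read / write FASTA as a named character vector
#' @param path file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 80L)
  invisible(path)
}

#' Write simulated paired reads as a FASTQ file pair
#'
#' Files are suffixed `_1.fastq` / `_2.fastq`; quality strings are a
#' constant 'I' (Phred 40), since qualities are unused downstream.
#'
#' @param reads a `read_sim` or its `reads` table.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  tab <- if (inherits(reads, "read_sim")) reads$reads else reads
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    sq <- Biostrings::DNAStringSet(tab[[paste0("seq", m)]])
    names(sq) <- paste0(tab$read_id, "/", m)
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(sq)))
    Biostrings::writeXStringSet(sq, paths[m], format = "fastq",
                                qualities = qual)
  }
  invisible(paths)
}

#' Write toy gene models for simulated triplets as GFF3
#'
#' Each simulated gene becomes its own contig with a single full-length
#' exon and CDS (so every gene has a start codon), in 1-based closed
#' GFF3 coordinates.
#'
#' @param sim a `triplet_sim`.
#' @param path output GFF3 path.
#' @export
write_toy_gff3 <- function(sim, path) {
  genes <- sim$genes
  L <- nchar(sim$sequences[genes$gene_id])
  feat <- function(type, id, parent = NA) {
    gr <- GenomicRanges::GRanges(genes$gene_id,
                                 IRanges::IRanges(1L, unname(L)),
                                 strand = "+")
    gr$type <- type
    gr$ID <- paste0(id, genes$gene_id)
    if (!is.na(parent)) gr$Parent <- paste0(parent, genes$gene_id)
    gr$source <- "triadpart"
    gr$phase <- if (type == "CDS") 0L else NA_integer_
    gr
  }
  gr <- c(feat("gene", "gene:"), feat("mRNA", "mrna:", "gene:"),
          feat("exon", "exon:", "mrna:"), feat("CDS", "cds:", "mrna:"))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Load gene records from a GFF3 file and its contig FASTA
#'
#' One record per `gene` feature: coordinates of the first exon (the
#' 5'-most exon on the gene's strand), `has_start_codon` true iff the
#' gene has any CDS feature, and the subgenome parsed from the contig
#' name via `subgenome_pattern` (a regex whose first capture group must
#' be A, B or D; unmatched names give subgenome NA, which disables the
#' chromosome-group agreement check but not clustering).
#'
#' @param gff3_path,fasta_path input files.
#' @param subgenome_pattern regex applied to the contig (seqid) name;
#'   default matches wheat-style names ending in 1A..7D (also captures
#'   the homeologous group digit).
#' @return list: `genes` (data.table: gene_id, seqid, strand, subgenome,
#'   chromosome_group, first_exon_start, first_exon_end,
#'   has_start_codon), `contigs` (named character).
#' @export
load_gene_models <- function(gff3_path, fasta_path,
                             subgenome_pattern = "([1-7])([ABD])$") {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  contigs <- read_fasta(fasta_path)
  ty <- as.character(gr$type)
  genes <- gr[ty == "gene"]
  if (!length(genes)) stop("no gene features in ", gff3_path)
  gid <- sub("^gene:", "", genes$ID)
  seqid <- as.character(GenomicRanges::seqnames(genes))
  miss <- setdiff(seqid, names(contigs))
  if (length(miss))
    stop("contig(s) missing from FASTA: ", paste(miss, collapse = ", "))
  mm <- regmatches(seqid, regexec(subgenome_pattern, seqid))
  chrom_group <- vapply(mm, function(m)
    if (length(m) >= 3) suppressWarnings(as.integer(m[2])) else NA_integer_,
    integer(1))
  subg <- vapply(mm, function(m)
    if (length(m) >= 3) m[3] else NA_character_, character(1))

  exons <- gr[ty == "exon"]
  cds <- gr[ty == "CDS"]
  parent_gene <- function(feats) {
    par <- vapply(feats$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    sub("^(mrna:|gene:)", "", par)
  }
  ex_gene <- sub("^(exon:|mrna:)", "", parent_gene(exons))
  cds_gene <- sub("^(cds:|mrna:)", "", parent_gene(cds))
  strand <- as.character(GenomicRanges::strand(genes))
  fe_start <- fe_end <- rep(NA_integer_, length(genes))
  for (i in seq_along(genes)) {
    ex <- exons[ex_gene == gid[i]]
    if (!length(ex)) next
    first <- if (strand[i] == "-") {
      ex[which.max(GenomicRanges::end(ex))]
    } else ex[which.min(GenomicRanges::start(ex))]
    fe_start[i] <- GenomicRanges::start(first)
    fe_end[i] <- GenomicRanges::end(first)
  }
  list(genes = data.table(
    gene_id = gid, seqid = seqid, strand = strand, subgenome = subg,
    chromosome_group = chrom_group, first_exon_start = fe_start,
    first_exon_end = fe_end, has_start_codon = gid %in% cds_gene),
    contigs = contigs)
}

#' Parse a 12-column tabular pairwise-alignment file
#'
#' The standard tab-separated columns: query, subject, identity, length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore.
#' Coverage is computed as the aligned length over the shorter sequence
#' when `seq_lengths` is supplied, otherwise over the query span is NOT
#' assumed — the coverage_pct column is NA and filtering must rely on a
#' caller-provided value.
#'
#' @param path file path.
#' @param seq_lengths optional named vector of full sequence lengths used
#'   to compute coverage of the shorter sequence.
#' @return data.frame of pair-alignment records (query_id, subject_id,
#'   identity_pct, aln_length, mismatches, gap_opens, qstart, qend,
#'   sstart, send, e_value, bitscore, coverage_pct).
#' @export
parse_alignment_table <- function(path, seq_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(query_id = character(), subject_id = character(),
                      identity_pct = numeric(), aln_length = integer(),
                      mismatches = integer(), gap_opens = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      e_value = numeric(), bitscore = numeric(),
                      coverage_pct = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("malformed alignment table: line(s) ",
         paste(head(which(nf != 12L), 5), collapse = ", "),
         " have ", paste(unique(nf[nf != 12L]), collapse = "/"),
         " columns (expected 12)")
  m <- do.call(rbind, fields)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity_pct = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  out$coverage_pct <- if (!is.null(seq_lengths)) {
    shorter <- pmin(seq_lengths[out$query_id], seq_lengths[out$subject_id])
    100 * out$aln_length / shorter
  } else NA_real_
  out
}

#' Write / read a TSV table with optional `#` comment header
#' @param x a data.frame.
#' @param path file path.
#' @param comment optional character vector written as `# ` header lines.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
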