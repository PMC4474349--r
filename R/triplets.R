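#' Identity and coverage statistics of a pairwise alignment
#'
#' Computes BLAST-style percent identity and coverage from two gapped,
#' equal-length aligned strings. Identity is matches over alignment
#' columns; coverage is the number of aligned residues of the shorter
#' sequence over that sequence's full length. Full lengths default to the
#' ungapped lengths within the alignment (appropriate for global
#' alignments); pass them explicitly for local alignments.
#'
#' @param aligned_x,aligned_y gapped aligned sequences (same number of
#'   columns; `-` is the gap character).
#' @param full_length_x,full_length_y full (unaligned) sequence lengths.
#' @param query_id,subject_id,e_value optional metadata carried through.
#' @return one-row data.frame: query_id, subject_id, identity_pct,
#'   coverage_pct, matches, columns, e_value.
#' @export
compute_alignment_stats <- function(aligned_x, aligned_y,
                                    full_length_x = NULL,
                                    full_length_y = NULL,
                                    query_id = NA_character_,
                                    subject_id = NA_character_,
                                    e_value = 0) {
  cx <- strsplit(toupper(aligned_x), "", fixed = TRUE)[[1]]
  cy <- strsplit(toupper(aligned_y), "", fixed = TRUE)[[1]]
  if (length(cx) != length(cy))
    stop("aligned sequences must have the same number of columns")
  ncols <- length(cx)
  res_x <- sum(cx != "-")
  res_y <- sum(cy != "-")
  lx <- full_length_x %||% res_x
  ly <- full_length_y %||% res_y
  if (ncols == 0L || lx == 0L || ly == 0L) {
    identity <- 0
    coverage <- 0
    matches <- 0L
  } else {
    matches <- sum(cx == cy & cx != "-")
    identity <- 100 * matches / ncols
    aligned_len <- min(res_x, res_y)
    coverage <- 100 * aligned_len / min(lx, ly)
  }
  data.frame(query_id = query_id, subject_id = subject_id,
             identity_pct = identity, coverage_pct = coverage,
             matches = matches, columns = ncols, e_value = e_value,
             stringsAsFactors = FALSE)
}

#' Globally align two sequences and return their alignment statistics
#'
#' Convenience wrapper around [Biostrings::pairwiseAlignment()] (global,
#' unit match/mismatch scores) feeding [compute_alignment_stats()]. Used
#' at desk scale; genome-scale searches are expected to arrive as a
#' 12-column tabular alignment file instead (see
#' [parse_alignment_table()]).
#'
#' @param x,y nucleotide sequences (plain character).
#' @inheritParams compute_alignment_stats
#' @export
align_pair_stats <- function(x, y, query_id = NA_character_,
                             subject_id = NA_character_) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(x), Biostrings::DNAString(y), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 5, gapExtension = 2)
  compute_alignment_stats(
    as.character(Biostrings::alignedPattern(al)),
    as.character(Biostrings::alignedSubject(al)),
    full_length_x = nchar(x), full_length_y = nchar(y),
    query_id = query_id, subject_id = subject_id)
}

#' Cluster pass-filter alignments into homeologous triplets
#'
#' Builds the graph whose edges are pairwise alignments passing all three
#' filters (e-value, coverage, identity) and takes its connected
#' components. A component is emitted as a homeologous triplet iff it has
#' exactly one member from each subgenome, all three pairwise edges pass
#' the filters, and — when the chromosome (homeologous) group is known for
#' all three genes — the groups agree. Every other component is logged
#' with its rejection reason; components larger than three are never
#' rescued by sub-selection.
#'
#' @param alignments data.frame with columns query_id, subject_id,
#'   identity_pct, coverage_pct, e_value.
#' @param genes data.frame with columns gene_id, subgenome (A/B/D) and
#'   optionally chromosome_group (integer or NA).
#' @param evalue_max,coverage_min,identity_min retention filters.
#' @return list with `triplets` (triplet_id, gene_A, gene_B, gene_D,
#'   chromosome_group) and `rejections` (component id, member gene ids,
#'   reason).
#' @export
cluster_triplets <- function(alignments, genes,
                             evalue_max = 1e-10, coverage_min = 75,
                             identity_min = 90) {
  genes <- as.data.frame(genes)
  stopifnot(all(c("gene_id", "subgenome") %in% names(genes)))
  if (!"chromosome_group" %in% names(genes))
    genes$chromosome_group <- NA_integer_
  al <- as.data.frame(alignments)
  pass <- al[al$e_value <= evalue_max &
               al$coverage_pct >= coverage_min &
               al$identity_pct >= identity_min &
               al$query_id != al$subject_id, , drop = FALSE]
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pass_edges <- unique(edge_key(pass$query_id, pass$subject_id))
  g <- igraph::graph_from_data_frame(
    do.call(rbind, strsplit(pass_edges, "\r", fixed = TRUE)) |>
      (\(m) data.frame(from = m[, 1], to = m[, 2]))(),
    directed = FALSE, vertices = genes$gene_id)
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)

  triplets <- list()
  rejections <- list()
  k <- 0L
  for (ci in seq_along(member)) {
    ids <- sort(member[[ci]])
    info <- genes[match(ids, genes$gene_id), ]
    reason <- NULL
    if (length(ids) == 1L) {
      reason <- "singleton"
    } else if (length(ids) != 3L) {
      reason <- sprintf("component size %d != 3", length(ids))
    } else if (!setequal(info$subgenome, SUBGENOMES) ||
               anyDuplicated(info$subgenome)) {
      reason <- sprintf("subgenome multiset {%s} != {A,B,D}",
                        paste(sort(info$subgenome), collapse = ","))
    } else if (!all(edge_key(ids[c(1, 1, 2)], ids[c(2, 3, 3)]) %in%
                    pass_edges)) {
      reason <- "missing pass-filter pairwise alignment"
    } else if (all(!is.na(info$chromosome_group)) &&
               length(unique(info$chromosome_group)) != 1L) {
      reason <- "chromosome groups disagree"
    }
    if (is.null(reason)) {
      k <- k + 1L
      o <- match(SUBGENOMES, info$subgenome)
      triplets[[k]] <- data.frame(
        triplet_id = sprintf("TRI%04d", k),
        gene_A = info$gene_id[o[1]], gene_B = info$gene_id[o[2]],
        gene_D = info$gene_id[o[3]],
        chromosome_group = info$chromosome_group[o[1]],
        stringsAsFactors = FALSE)
    } else if (length(ids) > 1L || reason == "singleton") {
      rejections[[length(rejections) + 1L]] <- data.frame(
        component = ci, genes = paste(ids, collapse = ","),
        reason = reason, stringsAsFactors = FALSE)
    }
  }
  list(triplets = if (k > 0) do.call(rbind, triplets) else
         data.frame(triplet_id = character(), gene_A = character(),
                    gene_B = character(), gene_D = character(),
                    chromosome_group = integer()),
       rejections = if (length(rejections)) do.call(rbind, rejections) else
         data.frame(component = integer(), genes = character(),
                    reason = character()))
}

#' Column-wise multiple alignment of a triplet
#'
#' Equal-length sequences (the synthetic, indel-free case) are aligned by
#' the identity. Otherwise the B and D members are each globally aligned
#' to the A member and the two pairwise alignments are merged on A's
#' coordinates (progressive merge; gaps in A from either alignment are
#' interleaved).
#'
#' @param seqs named character vector with elements A, B, D.
#' @return named character vector A/B/D of gapped, equal-length rows.
#' @export
triplet_msa <- function(seqs) {
  stopifnot(setequal(names(seqs), SUBGENOMES))
  seqs <- seqs[SUBGENOMES]
  if (length(unique(nchar(seqs))) == 1L) return(seqs)
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  g1 <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqs[["A"]]), Biostrings::DNAString(seqs[["B"]]),
    type = "global", substitutionMatrix = sub,
    gapOpening = 5, gapExtension = 2)
  g2 <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqs[["A"]]), Biostrings::DNAString(seqs[["D"]]),
    type = "global", substitutionMatrix = sub,
    gapOpening = 5, gapExtension = 2)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(g1)), "")[[1]]
  b1 <- strsplit(as.character(Biostrings::alignedSubject(g1)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedPattern(g2)), "")[[1]]
  d2 <- strsplit(as.character(Biostrings::alignedSubject(g2)), "")[[1]]
  outA <- outB <- outD <- character(0)
  i <- j <- 1L
  while (i <= length(a1) || j <= length(a2)) {
    if (i <= length(a1) && a1[i] == "-") {
      outA <- c(outA, "-"); outB <- c(outB, b1[i]); outD <- c(outD, "-")
      i <- i + 1L
    } else if (j <= length(a2) && a2[j] == "-") {
      outA <- c(outA, "-"); outB <- c(outB, "-"); outD <- c(outD, d2[j])
      j <- j + 1L
    } else {
      outA <- c(outA, a1[i]); outB <- c(outB, b1[i]); outD <- c(outD, d2[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  c(A = paste(outA, collapse = ""), B = paste(outB, collapse = ""),
    D = paste(outD, collapse = ""))
}

#' Call subgenome-diagnostic SNP sites from a triplet alignment
#'
#' Emits every alignment column where at least two distinct non-gap,
#' non-N alleles occur among the three homeologs, together with the
#' discrimination pattern (the partition of A/B/D the alleles induce:
#' one-vs-two, e.g. `"D|AB"`, or all-distinct `"A|B|D"`). Columns
#' containing a gap or an N are skipped.
#'
#' @param aln named character vector A/B/D of equal-length (gapped)
#'   alignment rows, e.g. from [triplet_msa()].
#' @param triplet_id optional id carried into the output.
#' @return data.table: triplet_id, pos0 (0-based alignment column),
#'   allele_A, allele_B, allele_D, pattern.
#' @export
call_diagnostic_sites <- function(aln, triplet_id = NA_character_) {
  stopifnot(setequal(names(aln), SUBGENOMES))
  a <- strsplit(toupper(aln[["A"]]), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aln[["B"]]), "", fixed = TRUE)[[1]]
  d <- strsplit(toupper(aln[["D"]]), "", fixed = TRUE)[[1]]
  stopifnot(length(a) == length(b), length(a) == length(d))
  clean <- a %in% DNA & b %in% DNA & d %in% DNA
  poly <- clean & (a != b | a != d | b != d)
  idx <- which(poly)
  data.table(triplet_id = triplet_id, pos0 = idx - 1L,
             allele_A = a[idx], allele_B = b[idx], allele_D = d[idx],
             pattern = site_pattern(a[idx], b[idx], d[idx]))
}
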