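IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_classes <- function(pattern) {
  sym <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(sym, names(IUPAC_MAP))
  if (length(bad))
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  IUPAC_MAP[sym]
}

# "(A/G/T)" slash groups -> the IUPAC code with exactly that class
normalize_slash_notation <- function(pattern) {
  while (grepl("\\(", pattern)) {
    grp <- regmatches(pattern, regexpr("\\(([ACGT]/)+[ACGT]\\)", pattern))
    if (!length(grp)) stop("unbalanced or invalid (X/Y) group in pattern")
    bases <- sort(strsplit(gsub("[()]", "", grp), "/", fixed = TRUE)[[1]])
    code <- names(Filter(function(cl) identical(sort(cl), bases), IUPAC_MAP))
    if (!length(code)) stop("no IUPAC code for class {",
                            paste(bases, collapse = ","), "}")
    pattern <- sub(grp, code[1], pattern, fixed = TRUE)
  }
  pattern
}

#' Define a degenerate DNA motif in IUPAC notation
#'
#' Accepts plain IUPAC strings or slash-group notation such as
#' `(A/G/T)(A/G)CCGACN(A/T)`, which is normalized to its exact IUPAC
#' equivalent (`DRCCGACNW`).
#'
#' @param name motif name.
#' @param pattern pattern over IUPAC codes (length >= 4).
#' @return list of class `iupac_motif` with `name` and `pattern`.
#' @export
iupac_motif <- function(name, pattern) {
  pattern <- normalize_slash_notation(toupper(pattern))
  iupac_classes(pattern)  # validates
  if (nchar(pattern) < 4) stop("motif pattern must have length >= 4")
  structure(list(name = name, pattern = pattern), class = "iupac_motif")
}

#' The heat-shock element in both orientations
#'
#' HSF-binding cis-element: `GAANNTTC` and its reverse orientation
#' `TTCNNGAA`. Both are scanned on the promoter's forward strand, which
#' covers the element on either strand.
#' @return list of two [iupac_motif()]s.
#' @export
hse_motifs <- function() {
  list(iupac_motif("HSE_fwd", "GAANNTTC"),
       iupac_motif("HSE_rev", "TTCNNGAA"))
}

#' The dehydration-responsive element
#'
#' DREB-binding cis-element `(A/G/T)(A/G)CCGACN(A/T)`, i.e. IUPAC
#' `DRCCGACNW`.
#' @return an [iupac_motif()].
#' @export
dre_motif <- function() iupac_motif("DRE", "(A/G/T)(A/G)CCGACN(A/T)")

#' Scan a sequence for all (overlapping) matches of a degenerate motif
#'
#' Reports every offset where each sequence base belongs to the IUPAC
#' class of the corresponding pattern symbol. The scan is forward-strand
#' only by default (the HSE's reverse orientation is supplied as its own
#' pattern); `revcomp = TRUE` additionally scans the reverse complement
#' of the pattern, still reporting forward-strand offsets. An `N` in the
#' sequence matches nothing.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param motif an [iupac_motif()].
#' @param revcomp also scan the pattern's reverse complement.
#' @return data.table: pos0 (0-based offset), motif, strand ("+" or "-").
#' @export
scan_motif <- function(sequence, motif, revcomp = FALSE) {
  stopifnot(inherits(motif, "iupac_motif"))
  hits <- scan_one(sequence, motif$pattern)
  out <- data.table(pos0 = hits, motif = motif$name,
                    strand = rep("+", length(hits)))
  if (revcomp) {
    rcpat <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                    paste(rev(strsplit(motif$pattern, "")[[1]]),
                          collapse = ""))
    rh <- scan_one(sequence, rcpat)
    out <- rbind(out, data.table(pos0 = rh, motif = motif$name,
                                 strand = rep("-", length(rh))))
  }
  setorder(out, pos0)
  out[]
}

# Vectorized sweep over pattern positions: offset i matches iff every
# sequence base under the window is in the class of its pattern symbol.
scan_one <- function(sequence, pattern) {
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  classes <- iupac_classes(pattern)
  m <- length(classes)
  L <- length(s)
  if (L < m) return(integer(0))
  ok <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m))
    ok <- ok & s[j:(L - m + j)] %in% classes[[j]]
  which(ok) - 1L
}

#' Scan a set of promoters for a list of motifs
#'
#' @param promoters named character vector of promoter sequences.
#' @param motifs list of [iupac_motif()]s.
#' @param revcomp passed to [scan_motif()].
#' @return data.table: gene_id, pos0, motif, strand.
#' @export
scan_promoters <- function(promoters, motifs, revcomp = FALSE) {
  out <- list()
  for (g in names(promoters))
    for (m in motifs) {
      h <- scan_motif(promoters[[g]], m, revcomp = revcomp)
      if (nrow(h)) out[[length(out) + 1L]] <- data.table(gene_id = g, h)
    }
  if (!length(out))
    return(data.table(gene_id = character(), pos0 = integer(),
                      motif = character(), strand = character()))
  rbindlist(out)
}

#' Extract the 2 kb promoter upstream of a gene's first exon
#'
#' For a plus-strand gene whose first exon starts at 1-based position
#' `s`, returns contig bases `[s - size, s - 1]`, truncated at the contig
#' start (with a warning). For a minus-strand gene whose first exon ends
#' at `e`, returns the reverse complement of bases `[e + 1, e + size]`,
#' truncated at the contig end. Genes without an annotated start codon
#' must be filtered out by the caller (see [load_gene_models()]).
#'
#' @param contig_seq the contig sequence (character).
#' @param first_exon_start,first_exon_end 1-based first-exon boundaries.
#' @param strand "+" or "-".
#' @param size promoter length (default 2000).
#' @return list: seq (possibly shorter than `size`), truncated (logical).
#' @export
extract_promoter <- function(contig_seq, first_exon_start = NULL,
                             first_exon_end = NULL, strand = c("+", "-"),
                             size = 2000) {
  strand <- match.arg(strand)
  L <- nchar(contig_seq)
  if (strand == "+") {
    if (is.null(first_exon_start)) stop("plus-strand gene needs first_exon_start")
    s <- first_exon_start
    from <- max(1L, s - size)
    to <- s - 1L
    if (to < from) return(list(seq = "", truncated = TRUE))
    truncated <- (s - size) < 1L
    if (truncated) warning("promoter truncated at contig start")
    list(seq = substr(contig_seq, from, to), truncated = truncated)
  } else {
    if (is.null(first_exon_end)) stop("minus-strand gene needs first_exon_end")
    e <- first_exon_end
    from <- e + 1L
    to <- min(L, e + size)
    if (to < from) return(list(seq = "", truncated = TRUE))
    truncated <- (e + size) > L
    if (truncated) warning("promoter truncated at contig end")
    list(seq = revcomp(substr(contig_seq, from, to)), truncated = truncated)
  }
}

#' Ternary expression-trend signature over the stress design
#'
#' Thresholds each condition's log2 fold change versus control at
#' `lfc_threshold` into up / flat / down, then tags the profile:
#' `DS/HD-induced` iff up in at least one drought and one combined
#' condition while flat or down in every heat condition; `HS/HD-induced`
#' symmetrically; otherwise `other`. Condition families are recognized by
#' their label prefix before `-` (DS, HS, HD).
#'
#' @param expr named numeric expression per condition (must include the
#'   control).
#' @param control control condition name.
#' @param lfc_threshold |log2FC| threshold for up/down (default 1).
#' @param pseudocount guard against zero expression.
#' @return list: states (named character per stress condition), group.
#' @export
trend_signature <- function(expr, control = "CK", lfc_threshold = 1,
                            pseudocount = 0.5) {
  stopifnot(control %in% names(expr))
  stress <- setdiff(names(expr), control)
  lfc <- log2((expr[stress] + pseudocount) /
                (expr[[control]] + pseudocount))
  states <- ifelse(lfc >= lfc_threshold, "up",
                   ifelse(lfc <= -lfc_threshold, "down", "flat"))
  names(states) <- stress
  fam <- sub("-.*$", "", stress)
  up_in <- function(f) any(states[fam == f] == "up")
  quiet_in <- function(f) all(states[fam == f] %in% c("flat", "down"))
  group <- if (up_in("DS") && up_in("HD") && quiet_in("HS")) {
    "DS/HD-induced"
  } else if (up_in("HS") && up_in("HD") && quiet_in("DS")) {
    "HS/HD-induced"
  } else "other"
  list(states = states, group = group)
}

#' Predict co-expressed TF targets from motif hits and trend matching
#'
#' A gene is a predicted target of a TF group iff its promoter carries at
#' least one hit of the group's binding motif AND its expression-trend
#' group matches the TF group's (DS/HD-induced for the drought/combined
#' groups, HS/HD-induced for the heat/combined groups). Adding motif hits
#' can therefore never remove a gene from the target set.
#'
#' @param hits motif-hit table (gene_id, motif) from [scan_promoters()].
#' @param signatures data.frame with gene_id and group (trend group tag
#'   per gene, from [trend_signature()]).
#' @param motif_names motif names counted as the group's binding element.
#' @param trend_group required trend group tag.
#' @return sorted character vector of target gene ids.
#' @export
predict_targets <- function(hits, signatures, motif_names, trend_group) {
  hits <- as.data.frame(hits)
  sg <- as.data.frame(signatures)
  with_motif <- unique(hits$gene_id[hits$motif %in% motif_names])
  matching <- sg$gene_id[sg$group == trend_group]
  sort(intersect(with_motif, matching))
}

#' Target-set sizes and pairwise overlaps
#'
#' @param sets named list of target-set character vectors.
#' @return data.frame of set sizes and all pairwise intersection sizes.
#' @export
target_overlap <- function(sets) {
  nm <- names(sets)
  out <- data.frame(set = nm, size = vapply(sets, length, integer(1)),
                    row.names = NULL)
  if (length(sets) >= 2) {
    cmb <- utils::combn(nm, 2)
    ov <- apply(cmb, 2, function(p)
      length(intersect(sets[[p[1]]], sets[[p[2]]])))
    out <- list(sizes = out,
                overlaps = data.frame(set1 = cmb[1, ], set2 = cmb[2, ],
                                      overlap = ov))
  } else {
    out <- list(sizes = out,
                overlaps = data.frame(set1 = character(),
                                      set2 = character(),
                                      overlap = integer()))
  }
  out
}
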