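#' Per-read observations at diagnostic sites from simulated reads
#'
#' Projects every simulated read pair onto the diagnostic sites of its
#' triplet (the synthetic homeologs are colinear and indel-free, so the
#' read occupies the same coordinates on all three homeologs, which also
#' means every read is automatically "placed on all three homeologs").
#' Mate 1 covers `[start0, start0 + read_length)`; mate 2 covers the
#' fragment's 3' end and its stored sequence is the reverse complement,
#' so observed reference-strand bases are complemented back.
#'
#' @param reads a `read_sim` from [simulate_reads()] or its `reads` table.
#' @param sites diagnostic-site table (triplet_id, pos0, allele_A/B/D).
#' @param read_length read length in bp.
#' @return data.table: read_id, mate, triplet_id, pos0, obs_base,
#'   match_A, match_B, match_D.
#' @export
read_site_observations <- function(reads, sites, read_length = 100L) {
  tab <- if (inherits(reads, "read_sim")) reads$reads else setDT(copy(reads))
  tab <- copy(tab)
  rl <- as.integer(read_length)
  st <- setDT(copy(sites))
  if (nrow(tab) == 0L || nrow(st) == 0L)
    return(data.table(read_id = character(), mate = integer(),
                      triplet_id = character(), pos0 = integer(),
                      obs_base = character(), match_A = logical(),
                      match_B = logical(), match_D = logical()))
  tab[, `:=`(m1s = start0, m1e = start0 + rl - 1L,
             m2s = start0 + insert - rl, m2e = start0 + insert - 1L)]
  o1 <- st[tab, on = .(triplet_id, pos0 >= m1s, pos0 <= m1e),
           nomatch = NULL, allow.cartesian = TRUE,
           .(read_id = i.read_id, mate = 1L, triplet_id,
             pos0 = x.pos0, off = x.pos0 - i.start0, seq = i.seq1,
             allele_A = x.allele_A, allele_B = x.allele_B,
             allele_D = x.allele_D)]
  o1[, obs_base := substr(seq, off + 1L, off + 1L)]
  o2 <- st[tab, on = .(triplet_id, pos0 >= m2s, pos0 <= m2e),
           nomatch = NULL, allow.cartesian = TRUE,
           .(read_id = i.read_id, mate = 2L, triplet_id,
             pos0 = x.pos0, off = x.pos0 - (i.start0 + i.insert - rl),
             seq = i.seq2,
             allele_A = x.allele_A, allele_B = x.allele_B,
             allele_D = x.allele_D)]
  # mate 2 is stored reverse-complemented: reference position offset k
  # maps to read character rl - k, complemented
  o2[, obs_base := chartr("ACGT", "TGCA",
                          substr(seq, rl - off, rl - off))]
  obs <- rbind(o1, o2)[, .(read_id, mate, triplet_id, pos0, obs_base,
                           match_A = obs_base == allele_A,
                           match_B = obs_base == allele_B,
                           match_D = obs_base == allele_D)]
  obs[]
}

#' Classify read pairs into the ten diagnostic-SNP groups
#'
#' Pools both mates of each pair: the pair's support set is the set of
#' homeologs whose alleles match the observed base at every diagnostic
#' site overlapped by either mate. Pairs overlapping no site support all
#' of A/B/D. Group labels: the seven support patterns `A, B, D, AB, AD,
#' BD, ABD`, the `ABD_nosite` subclass (three-way support arising from
#' zero site overlap — with point diagnostic sites this is the only way a
#' pair can support all three), and two conflict classes:
#' `CONFLICT_within` (some single mate matches no homeolog at its own
#' sites) and `CONFLICT_between` (each mate is individually consistent
#' but their supports are disjoint). Conflict pairs carry an empty
#' support and are excluded from counting.
#'
#' @param pairs data.table of read pairs (read_id, triplet_id, and any
#'   carry-through columns such as sample).
#' @param obs observation table from [read_site_observations()] (or the
#'   SAM-derived equivalent).
#' @return `pairs` with columns `support` (subset of "ABD" or "") and
#'   `group` added.
#' @export
classify_reads <- function(pairs, obs) {
  pairs <- setDT(copy(as.data.frame(pairs)))
  stopifnot(all(c("read_id", "triplet_id") %in% names(pairs)))
  if (nrow(obs)) {
    per_mate <- obs[, .(n_sites = .N, okA = all(match_A), okB = all(match_B),
                        okD = all(match_D)), by = .(read_id, mate)]
    per_mate[, mate_conflict := !(okA | okB | okD)]
    per_pair <- per_mate[, .(
      n_sites = sum(n_sites),
      okA = all(okA), okB = all(okB), okD = all(okD),
      within = any(mate_conflict)), by = read_id]
  } else {
    per_pair <- data.table(read_id = character(), n_sites = integer(),
                           okA = logical(), okB = logical(),
                           okD = logical(), within = logical())
  }
  out <- merge(pairs, per_pair, by = "read_id", all.x = TRUE, sort = FALSE)
  out[is.na(n_sites), `:=`(n_sites = 0L, okA = TRUE, okB = TRUE,
                           okD = TRUE, within = FALSE)]
  out[, support := paste0(ifelse(okA, "A", ""), ifelse(okB, "B", ""),
                          ifelse(okD, "D", ""))]
  out[, group := support]
  out[n_sites == 0L, group := "ABD_nosite"]
  out[support == "" & within, `:=`(group = "CONFLICT_within")]
  out[support == "" & !within, `:=`(group = "CONFLICT_between")]
  out[support == "", support := ""]
  out[, c("okA", "okB", "okD", "within") := NULL]
  out[]
}

#' Classify a single read pair from its diagnostic-site observations
#'
#' Single-pair convenience wrapper over [classify_reads()].
#'
#' @param observations data.frame with columns mate (1/2), pos0 and
#'   obs_base for every diagnostic site overlapped by either mate (zero
#'   rows for a pair overlapping no site).
#' @param sites diagnostic sites of the triplet (pos0, allele_A/B/D).
#' @return list with `support` and `group`.
#' @export
classify_read_pair <- function(observations, sites) {
  obs <- setDT(copy(as.data.frame(observations)))
  st <- as.data.frame(sites)
  if (nrow(obs)) {
    m <- match(obs$pos0, st$pos0)
    if (anyNA(m)) stop("observation at a position with no diagnostic site")
    obs[, `:=`(read_id = "pair", triplet_id = "t",
               match_A = obs_base == st$allele_A[m],
               match_B = obs_base == st$allele_B[m],
               match_D = obs_base == st$allele_D[m])]
  }
  res <- classify_reads(data.table(read_id = "pair", triplet_id = "t"), obs)
  list(support = res$support, group = res$group)
}

GROUP_LEVELS <- c("A", "B", "D", "AB", "AD", "BD", "ABD", "ABD_nosite",
                  "CONFLICT_within", "CONFLICT_between")

#' Proportional allocation of ambiguous read-group counts
#'
#' Specific reads count fully toward their homeolog; two- and three-way
#' ambiguous reads are divided proportionally to the specific counts of
#' their member homeologs, e.g.
#' `A = n_A + n_AB * n_A/(n_A + n_B) + n_AD * n_A/(n_A + n_D) +
#'  n_ABD * n_A/(n_A + n_B + n_D)`.
#' When a denominator is zero the ambiguous mass is split equally among
#' the member homeologs, so classified (non-conflict) read mass is always
#' conserved. All arguments are vectorized.
#'
#' @param n_A,n_B,n_D specific read counts.
#' @param n_AB,n_AD,n_BD,n_ABD ambiguous read counts (three-way includes
#'   pairs overlapping no diagnostic site).
#' @return data.frame with allocated fractional counts A, B, D.
#' @export
allocate_counts <- function(n_A, n_B, n_D, n_AB = 0, n_AD = 0, n_BD = 0,
                            n_ABD = 0) {
  len <- max(lengths(list(n_A, n_B, n_D, n_AB, n_AD, n_BD, n_ABD)))
  v <- lapply(list(n_A = n_A, n_B = n_B, n_D = n_D, n_AB = n_AB,
                   n_AD = n_AD, n_BD = n_BD, n_ABD = n_ABD), rep_len, len)
  if (any(unlist(v) < 0)) stop("group counts must be non-negative")
  share2 <- function(amb, x, y) {
    tot <- x + y
    ifelse(tot > 0, amb * x / ifelse(tot > 0, tot, 1), amb / 2)
  }
  tot3 <- v$n_A + v$n_B + v$n_D
  share3 <- function(amb, x)
    ifelse(tot3 > 0, amb * x / ifelse(tot3 > 0, tot3, 1), amb / 3)
  data.frame(
    A = v$n_A + share2(v$n_AB, v$n_A, v$n_B) +
      share2(v$n_AD, v$n_A, v$n_D) + share3(v$n_ABD, v$n_A),
    B = v$n_B + share2(v$n_AB, v$n_B, v$n_A) +
      share2(v$n_BD, v$n_B, v$n_D) + share3(v$n_ABD, v$n_B),
    D = v$n_D + share2(v$n_AD, v$n_D, v$n_A) +
      share2(v$n_BD, v$n_D, v$n_B) + share3(v$n_ABD, v$n_D))
}

#' Per-triplet, per-sample homeolog count table
#'
#' Tabulates classified read pairs into the ten groups and applies
#' [allocate_counts()] per triplet x sample cell. Conflict reads
#' contribute nothing to the allocation.
#'
#' @param assignments output of [classify_reads()]; must carry a `sample`
#'   column.
#' @return list with `wide` (one row per triplet x sample: group counts
#'   n_A..n_ABD, n_conflict, allocated alloc_A/B/D) and `long` (one row
#'   per triplet x subgenome x sample with the allocated count, the input
#'   to the balance and stress modules).
#' @export
homeolog_count_table <- function(assignments) {
  asn <- setDT(copy(as.data.frame(assignments)))
  stopifnot(all(c("triplet_id", "sample", "group") %in% names(asn)))
  asn[, grp := ifelse(group == "ABD_nosite", "ABD",
               ifelse(group %in% c("CONFLICT_within", "CONFLICT_between"),
                      "CONFLICT", group))]
  cnt <- dcast(asn[, .N, by = .(triplet_id, sample, grp)],
               triplet_id + sample ~ grp, value.var = "N", fill = 0L)
  for (g in c("A", "B", "D", "AB", "AD", "BD", "ABD", "CONFLICT"))
    if (!g %in% names(cnt)) cnt[, (g) := 0L]
  setnames(cnt, c("A", "B", "D", "AB", "AD", "BD", "ABD", "CONFLICT"),
           c("n_A", "n_B", "n_D", "n_AB", "n_AD", "n_BD", "n_ABD",
             "n_conflict"))
  al <- allocate_counts(cnt$n_A, cnt$n_B, cnt$n_D, cnt$n_AB, cnt$n_AD,
                        cnt$n_BD, cnt$n_ABD)
  cnt[, `:=`(alloc_A = al$A, alloc_B = al$B, alloc_D = al$D)]
  long <- melt(cnt,
               id.vars = c("triplet_id", "sample"),
               measure.vars = c("alloc_A", "alloc_B", "alloc_D"),
               variable.name = "subgenome", value.name = "count")
  long[, subgenome := sub("^alloc_", "", as.character(subgenome))]
  list(wide = cnt[], long = long[])
}

#' Diagnostic-site observations from SAM placements
#'
#' Reads alignments of reads against a reference made of the individual
#' homeolog sequences (named `<triplet>_<subgenome>`), keeps read/mate
#' records placed on all three homeologs of one triplet with gapless
#' (M-only) alignments, and extracts the observed base at every
#' diagnostic site each placement overlaps. A read matches a homeolog
#' only if its placement on that homeolog agrees with that homeolog's
#' allele at every overlapped site.
#'
#' @param sam_path SAM file (text; converted internally).
#' @param sites diagnostic-site table (triplet_id, pos0, allele_A/B/D).
#' @return list with `obs` (as [read_site_observations()]) and `pairs`
#'   (read_id, triplet_id) for the retained reads; reads not placed on
#'   all three homeologs are dropped.
#' @export
read_placements_sam <- function(sam_path, sites) {
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos) & grepl("^[0-9]+M$", x$cigar)
  dt <- data.table(read_id = x$qname[keep],
                   mate = ifelse(bitwAnd(x$flag[keep], 128L) > 0L, 2L, 1L),
                   ref = as.character(x$rname[keep]),
                   pos0 = x$pos[keep] - 1L,
                   seq = as.character(x$seq[keep]))
  dt[, `:=`(triplet_id = sub("_[ABD]$", "", ref),
            subgenome = sub("^.*_", "", ref),
            len = nchar(seq))]
  # retain only read/mates placed on all three homeologs of one triplet
  cov <- dt[, .(nsub = uniqueN(subgenome)), by = .(read_id, mate, triplet_id)]
  dt <- merge(dt, cov[nsub == 3L, .(read_id, mate, triplet_id)],
              by = c("read_id", "mate", "triplet_id"))
  st <- setDT(copy(sites))
  dt[, `:=`(ps = pos0, pe = pos0 + len - 1L)]
  ov <- st[dt, on = .(triplet_id, pos0 >= ps, pos0 <= pe),
           nomatch = NULL, allow.cartesian = TRUE,
           .(read_id = i.read_id, mate = i.mate, triplet_id,
             subgenome = i.subgenome, pos0 = x.pos0,
             obs_base = substr(i.seq, x.pos0 - i.pos0 + 1L,
                               x.pos0 - i.pos0 + 1L),
             allele_A = x.allele_A, allele_B = x.allele_B,
             allele_D = x.allele_D)]
  # per-homeolog matching: placement on homeolog h is compared to h's allele
  ov[, allele_self := fifelse(subgenome == "A", allele_A,
                              fifelse(subgenome == "B", allele_B, allele_D))]
  agg <- ov[, .(ok = all(obs_base == allele_self), n = .N),
            by = .(read_id, mate, triplet_id, pos0, subgenome)]
  obs <- dcast(agg, read_id + mate + triplet_id + pos0 ~ subgenome,
               value.var = "ok")
  for (s in SUBGENOMES) if (!s %in% names(obs)) obs[, (s) := NA]
  setnames(obs, SUBGENOMES, paste0("match_", SUBGENOMES))
  obs[, obs_base := NA_character_]
  obs[is.na(match_A), match_A := TRUE]
  obs[is.na(match_B), match_B := TRUE]
  obs[is.na(match_D), match_D := TRUE]
  pairs <- unique(dt[, .(read_id, triplet_id)])
  list(obs = obs[], pairs = pairs)
}
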