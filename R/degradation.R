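# Comparative genome-degradation metrics: the orthologue truncation
# (pseudogenization) rule, coding density, the prophage-gene similarity rule,
# synteny blocks with CDS-density differentials, and divergence-time
# arithmetic.

#' Flag truncated (likely pseudogenized) orthologues
#'
#' For each orthogroup with members in both strains, each strain's longest
#' member is compared with the other strain's longest member; a strain is
#' flagged when its longest CDS spans at most `truncation_ratio` (default
#' 60 %) of the counterpart length.  A ratio of exactly the threshold is
#' flagged ("at most").
#'
#' @param orthogroups Orthogroup data.frame (see [read_orthogroups()]),
#'   restricted to two strains.
#' @param truncation_ratio Flagging threshold (default 0.60).
#' @return A data.frame with one row per (orthogroup, strain): columns
#'   `orthogroup_id`, `strain`, `longest_own_bp`, `counterpart_bp`, `ratio`,
#'   `flagged`.
#' @export
call_truncations <- function(orthogroups, truncation_ratio = 0.60) {
  strains <- sort(unique(orthogroups$strain))
  if (length(strains) != 2L) {
    stop("call_truncations expects exactly two strains, got ",
         length(strains))
  }
  empty <- data.frame(orthogroup_id = character(), strain = character(),
                      longest_own_bp = integer(), counterpart_bp = integer(),
                      ratio = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(orthogroups) == 0L) return(empty)
  longest <- aggregate(length_bp ~ orthogroup_id + strain, data = orthogroups,
                       FUN = max)
  wide <- merge(longest[longest$strain == strains[1], c("orthogroup_id", "length_bp")],
                longest[longest$strain == strains[2], c("orthogroup_id", "length_bp")],
                by = "orthogroup_id", suffixes = c("_1", "_2"),
                all = TRUE)
  one_sided <- is.na(wide$length_bp_1) | is.na(wide$length_bp_2)
  if (any(one_sided)) {
    message(sum(one_sided),
            " orthogroup(s) with a strain absent skipped in call_truncations")
    wide <- wide[!one_sided, , drop = FALSE]
  }
  if (nrow(wide) == 0L) return(empty)
  out <- rbind(
    data.frame(orthogroup_id = wide$orthogroup_id, strain = strains[1],
               longest_own_bp = wide$length_bp_1,
               counterpart_bp = wide$length_bp_2,
               stringsAsFactors = FALSE),
    data.frame(orthogroup_id = wide$orthogroup_id, strain = strains[2],
               longest_own_bp = wide$length_bp_2,
               counterpart_bp = wide$length_bp_1,
               stringsAsFactors = FALSE))
  out$ratio <- out$longest_own_bp / out$counterpart_bp
  out$flagged <- out$ratio <= truncation_ratio
  out <- out[order(out$orthogroup_id, out$strain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coding density of a genome
#'
#' 100 x (length of the union of CDS intervals) / (genome length); overlapping
#' CDSs are counted once.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param cds A CDS `GRanges`.
#' @return Percent coding, numeric scalar.
#' @export
coding_density <- function(genome, cds) {
  glen <- sum(Biostrings::width(genome))
  if (length(cds) == 0L) return(0)
  red <- GenomicRanges::reduce(cds, ignore.strand = TRUE)
  100 * sum(IRanges::width(red)) / glen
}

#' Classify genes as prophage related
#'
#' A gene is flagged when any of its protein-vs-viral-protein hits is at least
#' `min_identity` percent identical over at least `min_cov` percent of the
#' viral protein's length.  Coverage is `100 * aln_length / viral length`.
#' The best hit among passing hits (highest bitscore) is reported; for
#' unflagged genes the highest-bitscore hit overall is reported.
#'
#' @param protein_hits Hits data.frame (see [read_hits_table()]) with query =
#'   gene, subject = viral protein; lengths in amino acids.
#' @param viral_lengths Named numeric vector or data.frame
#'   (`subject_id`, `length_aa`) of viral protein lengths.
#' @param min_identity Identity threshold in percent (default 60).
#' @param min_cov Coverage threshold in percent of the viral protein
#'   (default 50).
#' @return Data.frame with one row per query gene: `locus_tag`,
#'   `best_viral_hit`, `pct_identity`, `viral_coverage`, `flagged`.
#' @export
classify_prophage_loci <- function(protein_hits, viral_lengths,
                                   min_identity = 60, min_cov = 50) {
  if (is.data.frame(viral_lengths)) {
    viral_lengths <- setNames(as.numeric(viral_lengths$length_aa),
                              viral_lengths$subject_id)
  }
  h <- protein_hits
  missing <- setdiff(unique(h$sseqid), names(viral_lengths))
  if (length(missing)) {
    stop("viral protein length missing for subject: ", missing[1])
  }
  h$viral_coverage <- 100 * h$length / viral_lengths[h$sseqid]
  h$pass <- h$pident >= min_identity & h$viral_coverage >= min_cov
  out <- lapply(split(h, h$qseqid), function(g) {
    cand <- if (any(g$pass)) g[g$pass, , drop = FALSE] else g
    best <- cand[order(-cand$bitscore, -cand$length)[1], , drop = FALSE]
    data.frame(locus_tag = best$qseqid,
               best_viral_hit = if (any(g$pass)) best$sseqid else NA_character_,
               pct_identity = best$pident,
               viral_coverage = best$viral_coverage,
               flagged = any(g$pass), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$locus_tag), , drop = FALSE]
}

#' Build syntenic blocks from pairwise alignment hits
#'
#' Hits shorter than `min_len` or below `min_identity` percent identity are
#' discarded (a hit of exactly the threshold is kept in both cases: the
#' filters drop hits *below* 1000 bp and *under* 95 %).  The survivors are
#' taken best-first by bitscore (ties: longer alignment, then subject
#' coordinates), and a hit is retained iff its interval on genome A overlaps
#' no previously retained A-interval — a greedy "single best match for any
#' region" rule.  For each retained block, CDS density on either genome is the
#' number of CDSs whose midpoint lies in the block interval, per kb.
#'
#' @param hits Hits data.frame with query = genome A, subject = genome B.
#' @param cds_a,cds_b CDS `GRanges` for genomes A and B.
#' @param min_len Minimum alignment length in bp (default 1000).
#' @param min_identity Minimum percent identity (default 95).
#' @return A data.frame of class `synteny_blocks`: `a_contig`, `a_start`,
#'   `a_end`, `b_contig`, `b_start`, `b_end`, `reverse`, `pct_identity`,
#'   `n_cds_a`, `n_cds_b`, `cds_per_kb_a`, `cds_per_kb_b`, `density_diff`
#'   (a - b).
#' @export
build_synteny_blocks <- function(hits, cds_a, cds_b,
                                 min_len = 1000L, min_identity = 95) {
  h <- hits[hits$length >= min_len & hits$pident >= min_identity, ,
            drop = FALSE]
  empty <- data.frame(a_contig = character(), a_start = integer(),
                      a_end = integer(), b_contig = character(),
                      b_start = integer(), b_end = integer(),
                      reverse = logical(), pct_identity = numeric(),
                      n_cds_a = integer(), n_cds_b = integer(),
                      cds_per_kb_a = numeric(), cds_per_kb_b = numeric(),
                      density_diff = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("synteny_blocks", class(empty))
  if (nrow(h) == 0L) return(empty)
  h$s_lo <- pmin(h$sstart, h$send)
  h <- h[order(-h$bitscore, -h$length, h$sseqid, h$s_lo), , drop = FALSE]
  taken <- list()  # per A contig, IRanges of claimed intervals
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ctg <- h$qseqid[i]
    q <- IRanges::IRanges(h$qstart[i], h$qend[i])
    t <- taken[[ctg]]
    if (is.null(t) || length(IRanges::findOverlaps(q, t)) == 0L) {
      keep[i] <- TRUE
      taken[[ctg]] <- if (is.null(t)) q else c(t, q)
    }
  }
  h <- h[keep, , drop = FALSE]

  midpoint_count <- function(cds, ctg, lo, hi) {
    if (length(cds) == 0L) return(integer(length(ctg)))
    mid <- (GenomicRanges::start(cds) + GenomicRanges::end(cds)) %/% 2L
    cctg <- as.character(GenomicRanges::seqnames(cds))
    vapply(seq_along(ctg), function(i) {
      sum(cctg == ctg[i] & mid >= lo[i] & mid <= hi[i])
    }, integer(1))
  }
  b_lo <- pmin(h$sstart, h$send); b_hi <- pmax(h$sstart, h$send)
  n_a <- midpoint_count(cds_a, h$qseqid, h$qstart, h$qend)
  n_b <- midpoint_count(cds_b, h$sseqid, b_lo, b_hi)
  kb_a <- (h$qend - h$qstart + 1L) / 1000
  kb_b <- (b_hi - b_lo + 1L) / 1000
  out <- data.frame(a_contig = h$qseqid, a_start = h$qstart, a_end = h$qend,
                    b_contig = h$sseqid, b_start = b_lo, b_end = b_hi,
                    reverse = h$s_reverse, pct_identity = h$pident,
                    n_cds_a = n_a, n_cds_b = n_b,
                    cds_per_kb_a = n_a / kb_a, cds_per_kb_b = n_b / kb_b,
                    density_diff = n_a / kb_a - n_b / kb_b,
                    stringsAsFactors = FALSE)
  out <- out[order(out$a_contig, out$a_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("synteny_blocks", class(out))
  out
}

#' Summarise CDS-count differences across syntenic blocks
#'
#' Blocks are partitioned by the sign of (CDS count in the A interval - CDS
#' count in the B interval); bp sums use A-interval lengths.
#'
#' @param blocks A `synteny_blocks` data.frame.
#' @return List with `n_blocks`, `n_fewer_a`, `n_more_a`, `n_equal` and the
#'   corresponding `bp_*` sums.
#' @export
summarize_block_density <- function(blocks) {
  d <- blocks$n_cds_a - blocks$n_cds_b
  bp <- blocks$a_end - blocks$a_start + 1L
  list(n_blocks = nrow(blocks),
       n_fewer_a = sum(d < 0L), n_more_a = sum(d > 0L), n_equal = sum(d == 0L),
       bp_fewer_a = sum(bp[d < 0L]), bp_more_a = sum(bp[d > 0L]),
       bp_equal = sum(bp[d == 0L]))
}

#' Convert per-site divergence into a divergence time
#'
#' With both lineages accumulating changes since the split, the elapsed time
#' is `t = d / (2 r)` (the default); `formula = "d-over-r"` gives the
#' single-lineage reading `t = d / r`.
#'
#' @param per_site_divergence Observed per-site divergence, in `[0, 1)`.
#' @param rate Substitution rate per site per year (> 0).
#' @param formula `"d-over-2r"` (default) or `"d-over-r"`.
#' @return Years since divergence.
#' @export
estimate_divergence_time <- function(per_site_divergence, rate,
                                     formula = c("d-over-2r", "d-over-r")) {
  formula <- match.arg(formula)
  if (rate <= 0) stop("rate must be > 0")
  if (per_site_divergence < 0 || per_site_divergence >= 1) {
    stop("per_site_divergence must be in [0, 1)")
  }
  per_site_divergence / (if (formula == "d-over-2r") 2 * rate else rate)
}
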