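# Synthetic genome-evolution generator.  Emulates the statistical structure
# the analyses assume: an AT-rich annotated bacterial genome, lineages
# diverging for a known number of years at a known third-position rate with a
# GC>AT-biased spectrum, per-library Poisson depth tracks with contiguous
# dropouts, rearranged genome pairs with exact block ground truth, and
# orthogroup tables with known truncations.  Every stage is deterministic
# given the config seed; each stage draws from a generator seeded at a fixed,
# documented offset (+0 genome, +1 evolution, +2 depth, +3 rearrangement,
# +4 orthogroups) so stages are independently reproducible.

#' Simulation configuration
#'
#' Defaults describe a 1 Mb AT-rich endosymbiont chromosome (GC 0.27), 800
#' non-overlapping CDSs of 300-1500 bp (~72 % coding), a third-position
#' substitution rate of 1e-5 per site per year over 10 years with a spectrum
#' placing 60 % of changes in the GC>AT class, three sequencing libraries at
#' mean depth 20 with 5 % of the genome dropped out in contiguous segments,
#' and 5 inversions + 2 translocations for the rearranged pair.
#'
#' @param genome_length Genome length in bp.
#' @param n_cds Number of CDSs to place.
#' @param gc_content Target GC fraction.
#' @param cds_length_range Min/max CDS length in bp (multiples of 3).
#' @param rate_per_site_per_year Third-position substitution rate.
#' @param years Elapsed simulation time in years.
#' @param nonthird_rate_fraction Rate at non-third positions (codon positions
#'   1/2 and intergenic) as a fraction of the third-position rate.
#' @param spectrum_weights Named 6-vector over the strand-collapsed classes,
#'   non-negative, summing to 1.
#' @param n_libraries,mean_depth,dropout_fraction,n_dropout_segments Depth
#'   track parameters.
#' @param n_inversions,n_translocations,identity_jitter_sd,min_block_bp
#'   Rearranged-pair parameters; `min_block_bp` is the smallest syntenic
#'   fragment the generator will create.
#' @param n_orthogroups,truncated_fraction Orthogroup table parameters.
#' @param seed Integer RNG seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 1000000L,
                              n_cds = 800L,
                              gc_content = 0.27,
                              cds_length_range = c(300L, 1500L),
                              rate_per_site_per_year = 1e-5,
                              years = 10,
                              nonthird_rate_fraction = 0.5,
                              spectrum_weights = c("GC>AT" = 0.60,
                                                   "GC>TA" = 0.10,
                                                   "GC>CG" = 0.05,
                                                   "AT>GC" = 0.10,
                                                   "AT>TA" = 0.10,
                                                   "AT>CG" = 0.05),
                              n_libraries = 3L,
                              mean_depth = 20,
                              dropout_fraction = 0.05,
                              n_dropout_segments = 10L,
                              n_inversions = 5L,
                              n_translocations = 2L,
                              identity_jitter_sd = 0,
                              min_block_bp = 5000L,
                              n_orthogroups = 300L,
                              truncated_fraction = 0.10,
                              seed = 1L) {
  stopifnot(genome_length > 0, n_cds >= 0,
            gc_content > 0, gc_content < 1,
            length(cds_length_range) == 2L,
            all(cds_length_range %% 3L == 0L),
            cds_length_range[1] <= cds_length_range[2],
            rate_per_site_per_year >= 0, years >= 0,
            nonthird_rate_fraction >= 0,
            n_libraries >= 1L, mean_depth > 0,
            dropout_fraction >= 0, dropout_fraction <= 1,
            n_inversions >= 0L, n_translocations >= 0L,
            identity_jitter_sd >= 0, min_block_bp >= 1L,
            truncated_fraction >= 0, truncated_fraction <= 1)
  if (is.null(names(spectrum_weights)) ||
      !identical(sort(names(spectrum_weights)), sort(.spectrum_classes))) {
    stop("spectrum_weights must be named with the six classes: ",
         paste(.spectrum_classes, collapse = ", "))
  }
  spectrum_weights <- spectrum_weights[.spectrum_classes]
  if (any(spectrum_weights < 0)) stop("spectrum_weights must be non-negative")
  if (abs(sum(spectrum_weights) - 1) > 1e-8) {
    stop("spectrum_weights must sum to 1")
  }
  structure(as.list(environment()), class = "simulation_config")
}

.seed_for <- function(config, offset) {
  if (!is.null(config$seed)) set.seed(as.integer(config$seed) + offset)
  invisible(NULL)
}

#' Simulate an annotated genome
#'
#' i.i.d. nucleotides at the target GC content; `n_cds` non-overlapping CDSs
#' with lengths divisible by 3, random strands, phase 0, and random intergenic
#' gaps (drawn by a multinomial split of the non-coding residue, so placement
#' is exact and packing never fails while the CDSs fit).
#'
#' @param config A `simulation_config`.
#' @return List with `genome` (single-contig `DNAStringSet`, contig
#'   `"contig_1"`) and `cds` (a `GRanges`).
#' @export
simulate_annotated_genome <- function(config) {
  .seed_for(config, 0L)
  L <- as.integer(config$genome_length)
  gc <- config$gc_content
  idx <- sample.int(4L, L, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  genome <- Biostrings::DNAStringSet(rawToChar(charToRaw("ACGT")[idx]))
  names(genome) <- "contig_1"
  n <- as.integer(config$n_cds)
  if (n == 0L) {
    return(list(genome = genome, cds = GenomicRanges::GRanges()))
  }
  rng <- as.integer(config$cds_length_range) %/% 3L
  lens <- 3L * sample(seq(rng[1], rng[2]), n, replace = TRUE)
  spare <- L - sum(lens)
  if (spare < 0L) {
    stop("infeasible packing: total CDS length exceeds genome length")
  }
  gaps <- as.integer(rmultinom(1L, spare, rep(1, n + 1L)))
  starts <- cumsum(gaps[seq_len(n)] + c(0L, lens[-n])) + 1L
  cds <- GenomicRanges::GRanges("contig_1",
                                IRanges::IRanges(starts, width = lens),
                                strand = sample(c("+", "-"), n, replace = TRUE))
  cds$locus_tag <- sprintf("SIM_%05d", seq_len(n))
  cds$product <- "hypothetical protein"
  cds$phase <- 0L
  list(genome = genome, cds = cds)
}

.alt_for_class <- c("GC>AT" = "A/T", "GC>TA" = "T/A", "GC>CG" = "C/G",
                    "AT>GC" = "G/C", "AT>TA" = "T/A", "AT>CG" = "C/G")
# first letter applies when ref is G or A, second when ref is C or T

.alt_base <- function(ref, cls) {
  pair <- strsplit(.alt_for_class[cls], "/", fixed = TRUE)
  first <- ref %in% c("G", "A")
  vapply(seq_along(ref), function(i) pair[[i]][if (first[i]) 1L else 2L],
         character(1))
}

#' Evolve a genome for a known time at a known rate
#'
#' The number of mutations at third codon positions is binomial with per-site
#' probability `rate * years`; non-third sites (codon positions 1/2 and
#' intergenic) mutate at `nonthird_rate_fraction` of that rate.  Substitution
#' classes are multinomial draws from `spectrum_weights`, and each mutation is
#' placed uniformly on a site whose reference base is compatible with its
#' class, so the realized class distribution matches the configured spectrum
#' regardless of base composition (GC-source classes concentrate on the
#' genome's minority G/C sites, as a GC>AT-biased mutational process does).
#' At most one mutation is placed per site: valid in the single-hit regime
#' `rate * years << 1` this package targets.
#'
#' @param genome Ancestral `DNAStringSet`.
#' @param cpmap A `codon_map` for the ancestral genome.
#' @param config A `simulation_config`.
#' @return List with `genome` (evolved copy) and `truth`: `variants` (every
#'   change as a SNP record with its codon position), `true_rate`,
#'   `n_third_changes`, and `effects` (the simulator's own synonymous /
#'   nonsynonymous tally for coding changes, computed per variant against the
#'   ancestral codon).
#' @export
evolve_sequence <- function(genome, cpmap, config) {
  .seed_for(config, 1L)
  p3 <- config$rate_per_site_per_year * config$years
  if (p3 > 0.01) {
    warning("rate * years = ", signif(p3, 3),
            " is outside the single-hit regime the simulator assumes")
  }
  po <- p3 * config$nonthird_rate_fraction
  w <- config$spectrum_weights
  code <- .get_code("4")
  out_seqs <- character(length(genome))
  var_parts <- list()
  n_syn <- 0L; n_nonsyn <- 0L
  for (ci in seq_along(genome)) {
    ctg <- names(genome)[ci]
    chr <- as.character(genome[[ci]])
    raw <- charToRaw(chr)
    is_g <- raw == as.raw(71L); is_c <- raw == as.raw(67L)
    gc_site <- is_g | is_c
    at_site <- raw == as.raw(65L) | raw == as.raw(84L)
    m <- cpmap$contig[[ctg]]
    third <- m$codon_pos == 3L
    pools <- list(t_gc = which(third & gc_site), t_at = which(third & at_site),
                  o_gc = which(!third & gc_site), o_at = which(!third & at_site))
    n3 <- length(pools$t_gc) + length(pools$t_at)
    no <- length(pools$o_gc) + length(pools$o_at)
    m3 <- if (p3 > 0) rbinom(1L, n3, min(p3, 1)) else 0L
    mo <- if (po > 0) rbinom(1L, no, min(po, 1)) else 0L
    place <- function(nmut, gc_pool, at_pool) {
      if (nmut == 0L) return(NULL)
      cls <- sample(names(w), nmut, replace = TRUE, prob = w)
      from_gc <- startsWith(cls, "GC")
      n_gc <- sum(from_gc)
      if (n_gc > length(gc_pool) || (nmut - n_gc) > length(at_pool)) {
        stop("not enough compatible sites for the drawn substitution classes")
      }
      sites <- integer(nmut)
      sites[from_gc] <- sample(gc_pool, n_gc)
      sites[!from_gc] <- sample(at_pool, nmut - n_gc)
      data.frame(pos = sites, class = cls, stringsAsFactors = FALSE)
    }
    mut <- rbind(place(m3, pools$t_gc, pools$t_at),
                 place(mo, pools$o_gc, pools$o_at))
    if (is.null(mut) || nrow(mut) == 0L) {
      out_seqs[ci] <- chr
      next
    }
    mut <- mut[order(mut$pos), , drop = FALSE]
    ref <- substring(chr, mut$pos, mut$pos)
    alt <- .alt_base(ref, mut$class)
    new_raw <- raw
    new_raw[mut$pos] <- charToRaw(paste(alt, collapse = ""))
    out_seqs[ci] <- rawToChar(new_raw)
    cp <- m$codon_pos[mut$pos]
    # per-variant effect tally against the ancestral codon
    coding <- which(cp > 0L & !is.na(m$owner[mut$pos]))
    if (length(coding)) {
      cds <- cpmap$cds
      for (j in coding) {
        ow <- m$owner[mut$pos[j]]
        st <- GenomicRanges::start(cds)[ow]; en <- GenomicRanges::end(cds)[ow]
        ph <- as.integer(cds$phase)[ow]
        strd <- as.character(GenomicRanges::strand(cds))[ow]
        p <- mut$pos[j]
        if (strd == "+") {
          cs <- st + ph + 3L * ((p - st - ph) %/% 3L)
        } else {
          ce <- en - ph - 3L * (((en - ph) - p) %/% 3L)
          cs <- ce - 2L
        }
        top_ref <- substring(chr, cs, cs + 2L)
        top_alt <- top_ref
        substr(top_alt, p - cs + 1L, p - cs + 1L) <- alt[j]
        if (strd == "-") {
          top_ref <- .revcomp(top_ref); top_alt <- .revcomp(top_alt)
        }
        if (identical(unname(code[top_ref]), unname(code[top_alt]))) {
          n_syn <- n_syn + 1L
        } else {
          n_nonsyn <- n_nonsyn + 1L
        }
      }
    }
    var_parts[[length(var_parts) + 1L]] <- data.frame(
      contig = ctg, pos = mut$pos, ref = ref, alt = alt, vtype = "snp",
      sample_id = "evolved", codon_pos = cp, stringsAsFactors = FALSE)
  }
  variants <- if (length(var_parts)) do.call(rbind, var_parts) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), vtype = character(), sample_id = character(),
               codon_pos = integer(), stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  evolved <- Biostrings::DNAStringSet(out_seqs)
  names(evolved) <- names(genome)
  list(genome = evolved,
       truth = list(variants = variants,
                    true_rate = config$rate_per_site_per_year,
                    n_third_changes = sum(variants$codon_pos == 3L),
                    effects = c(synonymous = n_syn, nonsynonymous = n_nonsyn)))
}

#' Simulate per-library depth tracks
#'
#' Per library, per-position depth is Poisson at `mean_depth`; then
#' `dropout_fraction` of the genome is forced to zero as contiguous segments
#' (contiguous, not i.i.d., so that the "entirely covered CDS" filter is
#' exercised realistically).
#'
#' @param genome A `DNAStringSet`.
#' @param config A `simulation_config`.
#' @return List of `depth_track` objects, one per library.
#' @export
simulate_depth_tracks <- function(genome, config) {
  .seed_for(config, 2L)
  lens <- setNames(Biostrings::width(genome), names(genome))
  lapply(seq_len(config$n_libraries), function(lib) {
    depth <- lapply(lens, function(L) {
      d <- rpois(L, config$mean_depth)
      drop_total <- round(config$dropout_fraction * L)
      if (drop_total >= L) {
        d[] <- 0L
      } else if (drop_total > 0L) {
        nseg <- max(1L, min(config$n_dropout_segments, drop_total))
        seg <- as.integer(rmultinom(1L, drop_total, rep(1, nseg)))
        gaps <- as.integer(rmultinom(1L, L - drop_total, rep(1, nseg + 1L)))
        starts <- cumsum(gaps[seq_len(nseg)] + c(0L, seg[-nseg])) + 1L
        for (s in seq_len(nseg)) {
          if (seg[s] > 0L) d[starts[s]:(starts[s] + seg[s] - 1L)] <- 0L
        }
      }
      as.integer(d)
    })
    structure(list(sample_id = sprintf("lib%02d", lib), depth = depth),
              class = "depth_track")
  })
}

# ---- rearranged pair ------------------------------------------------------

# Genome B is a permutation of genome A represented as an ordered list of
# fragments, each an A interval with an orientation.  Rearrangements split
# and reorder fragments; the fragment list at the end *is* the ground-truth
# block set.

.frag_widths <- function(frags) frags$a_end - frags$a_start + 1L

.frag_split <- function(frags, cut) {
  w <- .frag_widths(frags)
  cum <- cumsum(w)
  if (cut <= 0L || cut >= cum[length(cum)] || cut %in% cum) return(frags)
  i <- which(cum > cut)[1]
  b0 <- if (i == 1L) 0L else cum[i - 1L]
  o <- cut - b0
  f <- frags[i, , drop = FALSE]
  if (f$orient == "+") {
    top <- data.frame(a_start = f$a_start, a_end = f$a_start + o - 1L,
                      orient = "+", stringsAsFactors = FALSE)
    bot <- data.frame(a_start = f$a_start + o, a_end = f$a_end,
                      orient = "+", stringsAsFactors = FALSE)
  } else {
    top <- data.frame(a_start = f$a_end - o + 1L, a_end = f$a_end,
                      orient = "-", stringsAsFactors = FALSE)
    bot <- data.frame(a_start = f$a_start, a_end = f$a_end - o,
                      orient = "-", stringsAsFactors = FALSE)
  }
  rbind(frags[seq_len(i - 1L), , drop = FALSE], top, bot,
        if (i < nrow(frags)) frags[(i + 1L):nrow(frags), , drop = FALSE])
}

.frag_rows_between <- function(frags, c1, c2) {
  cum <- cumsum(.frag_widths(frags))
  b_start <- c(0L, cum[-length(cum)])
  which(b_start >= c1 & cum <= c2)
}

.frag_merge <- function(frags) {
  if (nrow(frags) <= 1L) return(frags)
  out <- frags[1L, , drop = FALSE]
  for (i in 2:nrow(frags)) {
    f <- frags[i, , drop = FALSE]
    l <- out[nrow(out), ]
    if (f$orient == l$orient &&
        ((f$orient == "+" && l$a_end + 1L == f$a_start) ||
         (f$orient == "-" && l$a_start == f$a_end + 1L))) {
      out$a_start[nrow(out)] <- min(l$a_start, f$a_start)
      out$a_end[nrow(out)] <- max(l$a_end, f$a_end)
    } else {
      out <- rbind(out, f)
    }
  }
  out
}

#' Simulate a rearranged genome pair with ground-truth syntenic blocks
#'
#' Applies the configured number of random segment inversions and
#' translocations (segments 5-15 % of the genome, all resulting fragments at
#' least `min_block_bp`), lifts CDS coordinates over (CDSs spanning a
#' breakpoint are dropped and recorded), and emits one alignment hit per true
#' block with optional identity jitter.
#'
#' @param genome Single-contig `DNAStringSet` for genome A.
#' @param cds CDS `GRanges` for genome A.
#' @param config A `simulation_config`.
#' @return List with `genome_b`, `cds_b`, `hits`, and `truth` (a list with
#'   `blocks`: data.frame `a_start`, `a_end`, `b_start`, `b_end`, `reverse`;
#'   and `lost_cds`: locus_tags dropped at breakpoints).
#' @export
simulate_rearranged_pair <- function(genome, cds, config) {
  .seed_for(config, 3L)
  if (length(genome) != 1L) {
    stop("simulate_rearranged_pair expects a single-contig genome")
  }
  L <- Biostrings::width(genome)[1]
  ctg_a <- names(genome)[1]
  ctg_b <- paste0(ctg_a, "_alt")
  frags <- data.frame(a_start = 1L, a_end = L, orient = "+",
                      stringsAsFactors = FALSE)
  min_bp <- as.integer(config$min_block_bp)
  seg_lo <- max(min_bp, as.integer(round(0.05 * L)))
  seg_hi <- min(L - 2L * min_bp, max(2L * min_bp, as.integer(round(0.15 * L))))
  if (config$n_inversions + config$n_translocations > 0L && seg_hi < seg_lo) {
    stop("segments exhaust genome: genome too short for min_block_bp")
  }
  pick_segment <- function() {
    len <- as.integer(round(runif(1, seg_lo, seg_hi)))
    c1 <- sample.int(L - len, 1L) - 1L   # boundary in [0, L - len - 1]
    c(c1, c1 + len)
  }
  n_ops <- config$n_inversions + config$n_translocations
  ops <- c(rep("inv", config$n_inversions),
           rep("trans", config$n_translocations))
  if (n_ops > 0L) ops <- sample(ops)
  for (op in ops) {
    done <- FALSE
    for (try in seq_len(200L)) {
      cand <- frags
      seg <- pick_segment()
      cand <- .frag_split(cand, seg[1])
      cand <- .frag_split(cand, seg[2])
      rows <- .frag_rows_between(cand, seg[1], seg[2])
      if (length(rows) == 0L) next
      if (op == "inv") {
        mid <- cand[rev(rows), , drop = FALSE]
        mid$orient <- ifelse(mid$orient == "+", "-", "+")
        cand <- rbind(cand[seq_len(min(rows) - 1L), , drop = FALSE], mid,
                      if (max(rows) < nrow(cand))
                        cand[(max(rows) + 1L):nrow(cand), , drop = FALSE])
      } else {
        mid <- cand[rows, , drop = FALSE]
        rest <- cand[-rows, , drop = FALSE]
        rest_len <- sum(.frag_widths(rest))
        c3 <- sample.int(rest_len + 1L, 1L) - 1L
        rest <- .frag_split(rest, c3)
        cum <- cumsum(.frag_widths(rest))
        at <- sum(cum <= c3)
        cand <- rbind(rest[seq_len(at), , drop = FALSE], mid,
                      if (at < nrow(rest))
                        rest[(at + 1L):nrow(rest), , drop = FALSE])
      }
      cand <- .frag_merge(cand)
      if (min(.frag_widths(cand)) >= min_bp) {
        frags <- cand
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("segments exhaust genome: could not place rearrangement with all ",
           "fragments >= min_block_bp")
    }
  }
  frags <- .frag_merge(frags)
  rownames(frags) <- NULL
  w <- .frag_widths(frags)
  cum <- cumsum(w)
  b_start <- c(1L, cum[-length(cum)] + 1L)
  b_end <- cum
  # genome B sequence
  pieces <- lapply(seq_len(nrow(frags)), function(i) {
    s <- Biostrings::subseq(genome[[1]], frags$a_start[i], frags$a_end[i])
    if (frags$orient[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  })
  genome_b <- Biostrings::DNAStringSet(paste(unlist(pieces), collapse = ""))
  names(genome_b) <- ctg_b
  # CDS liftover
  cds_b_rows <- list(); lost <- character()
  if (length(cds) > 0L) {
    cst <- GenomicRanges::start(cds); cen <- GenomicRanges::end(cds)
    cstr <- as.character(GenomicRanges::strand(cds))
    for (j in seq_along(cds)) {
      i <- which(frags$a_start <= cst[j] & frags$a_end >= cen[j])
      if (length(i) != 1L) { lost <- c(lost, cds$locus_tag[j]); next }
      if (frags$orient[i] == "+") {
        nb_s <- b_start[i] + (cst[j] - frags$a_start[i])
        nb_e <- b_start[i] + (cen[j] - frags$a_start[i])
        nstr <- cstr[j]
      } else {
        nb_s <- b_start[i] + (frags$a_end[i] - cen[j])
        nb_e <- b_start[i] + (frags$a_end[i] - cst[j])
        nstr <- if (cstr[j] == "+") "-" else "+"
      }
      cds_b_rows[[length(cds_b_rows) + 1L]] <- data.frame(
        start = nb_s, end = nb_e, strand = nstr,
        locus_tag = cds$locus_tag[j], product = cds$product[j],
        phase = cds$phase[j], stringsAsFactors = FALSE)
    }
  }
  cds_b <- if (length(cds_b_rows)) {
    d <- do.call(rbind, cds_b_rows)
    g <- GenomicRanges::GRanges(ctg_b, IRanges::IRanges(d$start, d$end),
                                strand = d$strand)
    g$locus_tag <- d$locus_tag; g$product <- d$product
    g$phase <- as.integer(d$phase)
    sort(g, ignore.strand = TRUE)
  } else GenomicRanges::GRanges()
  # one hit per true block
  nb <- nrow(frags)
  pident <- pmin(100, 100 - abs(rnorm(nb, 0, config$identity_jitter_sd)))
  hits <- data.frame(
    qseqid = ctg_a, sseqid = ctg_b, pident = pident, length = w,
    mismatch = as.integer(round(w * (100 - pident) / 100)), gapopen = 0L,
    qstart = frags$a_start, qend = frags$a_end,
    sstart = ifelse(frags$orient == "+", b_start, b_end),
    send = ifelse(frags$orient == "+", b_end, b_start),
    evalue = 0, bitscore = round(1.9 * w), stringsAsFactors = FALSE)
  hits$s_reverse <- hits$sstart > hits$send
  truth_blocks <- data.frame(a_start = frags$a_start, a_end = frags$a_end,
                             b_start = b_start, b_end = b_end,
                             reverse = frags$orient == "-",
                             stringsAsFactors = FALSE)
  list(genome_b = genome_b, cds_b = cds_b, hits = hits,
       truth = list(blocks = truth_blocks, lost_cds = lost))
}

#' Simulate an orthogroup table with known truncations
#'
#' Two strains (`A`, `B`); `truncated_fraction` of orthogroups have one
#' strain's longest member eroded to 25-55 % of the counterpart (always below
#' the 60 % rule), the rest jitter within +/-15 % (never below it).  Some
#' orthogroups carry a shorter second member to exercise the longest-member
#' rule.
#'
#' @param config A `simulation_config`.
#' @return List with `table` (a data.frame as in [read_orthogroups()]) and
#'   `truth` (data.frame `orthogroup_id`, `strain` of truncated calls).
#' @export
simulate_orthogroups <- function(config) {
  .seed_for(config, 4L)
  n <- as.integer(config$n_orthogroups)
  base_len <- 3L * sample(100:600, n, replace = TRUE)
  trunc_idx <- sort(sample.int(n, round(config$truncated_fraction * n)))
  trunc_strain <- sample(c("A", "B"), length(trunc_idx), replace = TRUE)
  rows <- list()
  truth <- list()
  for (i in seq_len(n)) {
    og <- sprintf("OG%04d", i)
    len <- setNames(integer(2), c("A", "B"))
    jit <- runif(2, 0.85, 1.15)
    len["A"] <- 3L * as.integer(round(base_len[i] * jit[1] / 3))
    len["B"] <- 3L * as.integer(round(base_len[i] * jit[2] / 3))
    ti <- match(i, trunc_idx)
    if (!is.na(ti)) {
      s <- trunc_strain[ti]
      other <- setdiff(c("A", "B"), s)
      len[s] <- max(3L, 3L * as.integer(round(len[other] *
                                              runif(1, 0.25, 0.55) / 3)))
      truth[[length(truth) + 1L]] <- data.frame(orthogroup_id = og, strain = s,
                                                stringsAsFactors = FALSE)
    }
    for (s in c("A", "B")) {
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup_id = og, strain = s,
        locus_tag = sprintf("%s_%s_1", og, s), length_bp = len[[s]],
        stringsAsFactors = FALSE)
      if (runif(1) < 0.2) {
        rows[[length(rows) + 1L]] <- data.frame(
          orthogroup_id = og, strain = s,
          locus_tag = sprintf("%s_%s_2", og, s),
          length_bp = max(3L, 3L * as.integer(round(len[[s]] *
                                                    runif(1, 0.3, 0.9) / 3))),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(table = do.call(rbind, rows),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(orthogroup_id = character(), strain = character(),
                    stringsAsFactors = FALSE))
}

#' Simulate a complete dataset
#'
#' Runs every generator stage in the documented order and returns all
#' components plus ground truth.
#'
#' @param config A `simulation_config`.
#' @return List with `config`, `genome`, `cds`, `cpmap`, `evolved` (genome +
#'   truth), `tracks`, `pair` (rearranged pair), `orthogroups`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  anno <- simulate_annotated_genome(config)
  cpmap <- build_codon_position_map(anno$genome, anno$cds)
  evolved <- evolve_sequence(anno$genome, cpmap, config)
  tracks <- simulate_depth_tracks(anno$genome, config)
  pair <- simulate_rearranged_pair(anno$genome, anno$cds, config)
  og <- simulate_orthogroups(config)
  list(config = config, genome = anno$genome, cds = anno$cds, cpmap = cpmap,
       evolved = evolved, tracks = tracks, pair = pair, orthogroups = og)
}

#' Write a simulated dataset as standard-format fixture files
#'
#' Emits FASTA, GFF3, VCF (true variants), per-library depth TSVs, an
#' alignment-hits TSV, an orthogroup TSV, and a JSON manifest holding the
#' config, seed, md5 checksums of every file, and ground-truth summaries.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly; also written to `manifest.json`.
#' @export
write_fixture_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  fp <- function(x) file.path(dir, x)
  write_fasta(sim$genome, fp("reference.fasta"))
  write_gff3_cds(sim$cds, fp("reference.gff3"))
  write_vcf(sim$evolved$truth$variants, fp("evolved.vcf"), contigs = lens)
  depth_files <- character(0)
  for (tr in sim$tracks) {
    f <- paste0("depth_", tr$sample_id, ".tsv")
    write_depth(tr, fp(f))
    depth_files <- c(depth_files, f)
  }
  write_fasta(sim$pair$genome_b, fp("genome_b.fasta"))
  write_gff3_cds(sim$pair$cds_b, fp("genome_b.gff3"))
  write_hits_table(sim$pair$hits, fp("hits.tsv"))
  write_orthogroups(sim$orthogroups$table, fp("orthogroups.tsv"))
  files <- c("reference.fasta", "reference.gff3", "evolved.vcf", depth_files,
             "genome_b.fasta", "genome_b.gff3", "hits.tsv", "orthogroups.tsv")
  sums <- as.list(tools::md5sum(file.path(dir, files)))
  names(sums) <- files
  cfg <- sim$config
  manifest <- list(
    tool = "spirorate", version = as.character(packageVersion("spirorate")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "spectrum_weights")],
    spectrum_weights = as.list(cfg$spectrum_weights),
    files = sums,
    truth = list(true_rate = sim$evolved$truth$true_rate,
                 n_true_variants = nrow(sim$evolved$truth$variants),
                 n_third_changes = sim$evolved$truth$n_third_changes,
                 n_true_blocks = nrow(sim$pair$truth$blocks),
                 n_truncated = nrow(sim$orthogroups$truth)))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
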