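# The codon-position map labels every genome position with its codon position
# (1, 2, 3) within the CDS that owns it, or none.  Third positions are the
# rate denominator: most changes there are synonymous, so counting changes at
# third positions approximates the neutral substitution rate.

#' Build a per-position codon-position map
#'
#' Every CDS whose `(length - phase)` is divisible by 3 contributes frame
#' labels: on the plus strand codon positions cycle 1,2,3 from `start + phase`;
#' on the minus strand they cycle 1,2,3 from `end - phase` downward.  CDSs
#' failing the divisibility test have an undefined frame (they are typically
#' pseudogenes) and are excluded with a message.  Positions covered by two or
#' more CDSs are ambiguous and labelled none: a site cannot have two codon
#' positions.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param cds A CDS `GRanges` with `locus_tag` and `phase` metadata.
#' @return A `codon_map`: list with per-contig integer vectors `codon_pos`
#'   (0 = none), `owner` (index into `$cds`, NA = none/ambiguous), logical
#'   `in_cds` (covered by any CDS, including excluded ones), plus `cds` (the
#'   frame-valid CDS subset), `excluded` (locus_tags dropped) and
#'   `genome_lengths`.
#' @export
build_codon_position_map <- function(genome, cds) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  ctg <- as.character(GenomicRanges::seqnames(cds))
  missing_ctg <- !(ctg %in% names(lens))
  if (any(missing_ctg)) {
    stop("CDS contig absent from genome for locus_tag ",
         cds$locus_tag[which(missing_ctg)[1]])
  }
  st <- GenomicRanges::start(cds); en <- GenomicRanges::end(cds)
  if (any(st < 1L | en > lens[ctg])) {
    bad <- which(st < 1L | en > lens[ctg])[1]
    stop("CDS outside contig bounds: ", cds$locus_tag[bad])
  }
  ph <- as.integer(cds$phase)
  valid <- (IRanges::width(cds) - ph) %% 3L == 0L
  excluded <- cds$locus_tag[!valid]
  if (length(excluded)) {
    message(length(excluded),
            " CDS(s) with (length - phase) not divisible by 3 excluded from ",
            "the codon map: ", paste(head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ...")
  }
  cds_valid <- cds[valid]
  vctg <- as.character(GenomicRanges::seqnames(cds_valid))
  vst <- GenomicRanges::start(cds_valid); ven <- GenomicRanges::end(cds_valid)
  vph <- as.integer(cds_valid$phase)
  vstr <- as.character(GenomicRanges::strand(cds_valid))
  maps <- list()
  for (x in names(lens)) {
    n <- lens[[x]]
    # all CDSs (valid or not) contribute to coverage counts for ambiguity and
    # the in-CDS flag
    sel_all <- which(ctg == x)
    cover_all <- if (length(sel_all)) {
      as.integer(IRanges::coverage(IRanges::IRanges(st[sel_all], en[sel_all]),
                                   width = n))
    } else integer(n)
    codon_pos <- integer(n)
    owner <- rep(NA_integer_, n)
    for (i in which(vctg == x)) {
      if (vstr[i] == "+") {
        p <- (vst[i] + vph[i]):ven[i]
      } else {
        p <- (ven[i] - vph[i]):vst[i]        # counted from the end downward
      }
      codon_pos[p] <- rep_len(1:3, length(p))
      owner[p] <- i
    }
    amb <- cover_all >= 2L
    codon_pos[amb] <- 0L
    owner[amb] <- NA_integer_
    maps[[x]] <- list(codon_pos = codon_pos, owner = owner,
                      in_cds = cover_all > 0L)
  }
  structure(list(contig = maps, cds = cds_valid, excluded = excluded,
                 genome_lengths = lens),
            class = "codon_map")
}

# logical per-position vector marking mask membership for one contig
.mask_logical <- function(mask, ctg, n) {
  v <- logical(n)
  mr <- mask$ranges[[ctg]]
  if (!is.null(mr) && length(mr) > 0L) {
    cov <- IRanges::coverage(mr, width = n)
    v <- as.vector(cov) > 0L
  }
  v
}

#' Count considered third codon positions
#'
#' The rate denominator: third-codon-position sites within the retained CDSs,
#' optionally intersected with a coverage mask (the default analysis uses the
#' all-libraries intersection mask).
#'
#' @param cpmap A `codon_map`.
#' @param retained_cds `GRanges` of retained CDSs (subset of `cpmap$cds`).
#' @param mask Optional `coverage_mask`; if supplied, only masked-in third
#'   positions are counted.
#' @return Integer site count.
#' @export
count_third_position_sites <- function(cpmap, retained_cds, mask = NULL) {
  keep_idx <- match(retained_cds$locus_tag, cpmap$cds$locus_tag)
  if (anyNA(keep_idx)) {
    stop("retained CDS not present in codon map: ",
         retained_cds$locus_tag[which(is.na(keep_idx))[1]])
  }
  total <- 0L
  for (ctg in names(cpmap$contig)) {
    m <- cpmap$contig[[ctg]]
    sel <- m$codon_pos == 3L & m$owner %in% keep_idx
    if (!is.null(mask)) {
      sel <- sel & .mask_logical(mask, ctg, length(m$codon_pos))
    }
    total <- total + sum(sel)
  }
  total
}
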