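# Coverage masks: the set of reference positions whose sequencing depth meets
# a threshold in a library, intersected across libraries.  Variants and CDSs
# are only considered where *every* library meets the threshold (default 5x),
# so that an apparent change is never an artefact of missing data in one
# sample.

#' Build a coverage mask from one depth track
#'
#' The mask holds exactly the positions with depth >= `min_depth`, merged into
#' maximal intervals per contig.
#'
#' @param track A `depth_track` (see [read_depth()]).
#' @param min_depth Minimum depth, >= 1 (default 5).
#' @return A `coverage_mask`: list with `ranges` (named list of [IRanges::IRanges])
#'   and `min_depth`.
#' @export
build_coverage_mask <- function(track, min_depth = 5L) {
  stopifnot(min_depth >= 1L)
  rngs <- lapply(track$depth, function(d) {
    methods::as(S4Vectors::Rle(d >= min_depth), "IRanges")
  })
  structure(list(ranges = rngs, min_depth = as.integer(min_depth)),
            class = "coverage_mask")
}

#' Intersect coverage masks across libraries
#'
#' Retains positions present in every input mask; the recorded `min_depth` is
#' the maximum of the inputs' thresholds.
#'
#' @param masks A list of `coverage_mask` objects over the same contigs.
#' @return A `coverage_mask`.
#' @export
intersect_masks <- function(masks) {
  stopifnot(length(masks) >= 1L)
  ctgs <- names(masks[[1L]]$ranges)
  for (m in masks) {
    if (!identical(sort(names(m$ranges)), sort(ctgs))) {
      stop("coverage mask contig mismatch: masks cover different contigs")
    }
  }
  rngs <- lapply(setNames(ctgs, ctgs), function(ctg) {
    Reduce(IRanges::intersect, lapply(masks, function(m) m$ranges[[ctg]]))
  })
  structure(list(ranges = rngs,
                 min_depth = max(vapply(masks, `[[`, integer(1), "min_depth"))),
            class = "coverage_mask")
}

#' Number of positions retained by a mask
#' @param mask A `coverage_mask`.
#' @return Integer count of masked-in positions.
#' @export
mask_size <- function(mask) {
  sum(vapply(mask$ranges, function(r) sum(IRanges::width(r)), numeric(1)))
}

# A range is entirely inside the mask iff it lies within a single mask
# interval: mask intervals are maximally merged, so containment in the union
# implies containment in one interval.
.within_mask <- function(contig, start, end, mask) {
  ok <- logical(length(contig))
  for (ctg in unique(contig)) {
    i <- which(contig == ctg)
    mr <- mask$ranges[[ctg]]
    if (is.null(mr) || length(mr) == 0L) next
    q <- IRanges::IRanges(start[i], end[i])
    hits <- IRanges::findOverlaps(q, mr, type = "within")
    ok[i[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  ok
}

#' Select CDSs entirely covered by a mask
#'
#' A single uncovered base disqualifies a CDS ("entirely covered" rule).
#'
#' @param cds A CDS `GRanges`.
#' @param mask A `coverage_mask`.
#' @return The subset of `cds` whose every position lies in the mask.
#' @export
select_fully_covered_cds <- function(cds, mask) {
  if (length(cds) == 0L) return(cds)
  ok <- .within_mask(as.character(GenomicRanges::seqnames(cds)),
                     GenomicRanges::start(cds), GenomicRanges::end(cds), mask)
  cds[ok]
}

#' Filter variants by a coverage mask
#'
#' A variant is retained iff every reference position it spans
#' (`[pos, pos + nchar(ref) - 1]`) lies in the mask.
#'
#' @param variants Variant data.frame (see [read_vcf()]).
#' @param mask A `coverage_mask`.
#' @return The retained subset of `variants`.
#' @export
filter_variants_by_mask <- function(variants, mask) {
  if (nrow(variants) == 0L) return(variants)
  ok <- .within_mask(variants$contig, variants$pos,
                     variants$pos + nchar(variants$ref) - 1L, mask)
  variants[ok, , drop = FALSE]
}
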