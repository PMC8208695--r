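# Shared in-code fixtures: tiny genomes, CDS sets and depth tracks built
# programmatically so tests never depend on external data.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(IRanges)
})

make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

make_cds <- function(contig, start, end, strand = "+", phase = 0L,
                     tag = sprintf("g%02d", seq_along(start)),
                     product = "hypothetical protein") {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                               strand = strand)
  gr$locus_tag <- tag
  gr$product <- rep_len(product, length(gr))
  gr$phase <- as.integer(rep_len(phase, length(gr)))
  gr
}

make_track <- function(depths, sample_id = "lib1") {
  structure(list(sample_id = sample_id,
                 depth = lapply(depths, as.integer)),
            class = "depth_track")
}

make_variants <- function(contig, pos, ref, alt, sample_id = "iso1") {
  data.frame(contig = as.character(contig), pos = as.integer(pos),
             ref = as.character(ref), alt = as.character(alt),
             vtype = variant_type(as.character(ref), as.character(alt)),
             sample_id = rep_len(sample_id, length(pos)),
             stringsAsFactors = FALSE)
}

# uniform full-coverage track set for a genome
full_tracks <- function(genome, depth = 10L, n = 2L) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  lapply(seq_len(n), function(i) {
    make_track(lapply(lens, function(L) rep(depth, L)),
               sample_id = sprintf("lib%02d", i))
  })
}
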