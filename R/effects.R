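# Variant-effect classification under a configurable genetic code (default
# translation table 4, the Mollicutes code in which TGA encodes tryptophan),
# and the strand-collapsed substitution spectrum.

.revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.get_code <- function(genetic_code) {
  id <- as.character(genetic_code)
  tryCatch(Biostrings::getGeneticCode(id),
           error = function(e) stop("unsupported genetic code table id: ", id))
}

#' Decompose variants into single-nucleotide substitutions
#'
#' SNPs pass through; MNPs and equal-length complex records are decomposed
#' base-by-base into one record per differing base.  Indels and
#' length-changing complex records are dropped: "changes at third codon
#' positions" is only well-defined for substitutions.
#'
#' @param variants Variant data.frame (see [read_vcf()]).
#' @return A data.frame of single-base records (`ref`/`alt` length 1).
#' @export
decompose_snvs <- function(variants) {
  empty <- data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), vtype = character(),
                      sample_id = character(), stringsAsFactors = FALSE)
  if (nrow(variants) == 0L) return(empty)
  snp <- variants[variants$vtype == "snp", , drop = FALSE]
  multi <- variants[variants$vtype == "mnp" |
                    (variants$vtype == "complex" &
                     nchar(variants$ref) == nchar(variants$alt)), ,
                    drop = FALSE]
  parts <- list(snp[, names(empty), drop = FALSE])
  if (nrow(multi) > 0L) {
    for (i in seq_len(nrow(multi))) {
      r <- strsplit(multi$ref[i], "", fixed = TRUE)[[1]]
      a <- strsplit(multi$alt[i], "", fixed = TRUE)[[1]]
      d <- which(r != a)
      if (length(d)) {
        parts[[length(parts) + 1L]] <- data.frame(
          contig = multi$contig[i], pos = multi$pos[i] + d - 1L,
          ref = r[d], alt = a[d], vtype = "snp",
          sample_id = multi$sample_id[i], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify variant effects
#'
#' Coding single-nucleotide substitutions are translated under the configured
#' genetic code and labelled `synonymous` or `nonsynonymous`.  MNPs confined
#' to one codon are classified on the whole-codon amino-acid change.  Indels
#' inside a CDS are `frameshift` when the net length change is not a multiple
#' of 3, else `inframe_indel`.  Variants outside all CDSs are `intergenic`;
#' everything else (ambiguous frame, codons containing N, multi-codon MNPs,
#' length-changing complex records) is `complex`.
#'
#' @param variants Variant data.frame (typically mask-filtered).
#' @param cpmap A `codon_map` for the reference.
#' @param genome The reference [Biostrings::DNAStringSet].
#' @param genetic_code NCBI genetic code table id (default `"4"`).
#' @return `variants` with added columns `effect`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa` (codon/aa columns NA outside single-codon calls).
#' @export
classify_variant_effect <- function(variants, cpmap, genome, genetic_code = "4") {
  code <- .get_code(genetic_code)
  n <- nrow(variants)
  effect <- rep(NA_character_, n)
  ref_codon <- alt_codon <- ref_aa <- alt_aa <- rep(NA_character_, n)
  if (n == 0L) {
    out <- variants
    out$effect <- effect; out$ref_codon <- ref_codon; out$alt_codon <- alt_codon
    out$ref_aa <- ref_aa; out$alt_aa <- alt_aa
    return(out)
  }
  chrs <- as.character(genome)
  bad_ctg <- setdiff(unique(variants$contig), names(chrs))
  if (length(bad_ctg)) stop("variant contig absent from genome: ", bad_ctg[1])

  span_in_cds <- function(ctg, from, to) {
    m <- cpmap$contig[[ctg]]
    any(m$in_cds[from:to])
  }

  codon_of <- function(ctg, p) {
    # returns list(ref_codon, start_top, strand, offset_in_top_triplet) or NULL
    m <- cpmap$contig[[ctg]]
    ow <- m$owner[p]
    if (is.na(ow) || m$codon_pos[p] == 0L) return(NULL)
    st <- GenomicRanges::start(cpmap$cds)[ow]
    en <- GenomicRanges::end(cpmap$cds)[ow]
    ph <- as.integer(cpmap$cds$phase)[ow]
    strd <- as.character(GenomicRanges::strand(cpmap$cds))[ow]
    if (strd == "+") {
      off <- p - (st + ph)
      cs <- st + ph + 3L * (off %/% 3L)
      list(top_start = cs, strand = "+", off_top = p - cs + 1L, owner = ow)
    } else {
      off <- (en - ph) - p
      ce <- en - ph - 3L * (off %/% 3L)
      list(top_start = ce - 2L, strand = "-", off_top = p - (ce - 2L) + 1L,
           owner = ow)
    }
  }

  translate1 <- function(codon) {
    aa <- unname(code[codon])
    if (is.null(aa) || length(aa) == 0L) NA_character_ else aa
  }

  for (i in seq_len(n)) {
    ctg <- variants$contig[i]
    p <- variants$pos[i]
    vt <- variants$vtype[i]
    lr <- nchar(variants$ref[i]); la <- nchar(variants$alt[i])
    in_cds <- span_in_cds(ctg, p, p + lr - 1L)
    if (!in_cds) { effect[i] <- "intergenic"; next }
    if (vt == "ins" || vt == "del") {
      effect[i] <- if ((la - lr) %% 3L != 0L) "frameshift" else "inframe_indel"
      next
    }
    if (vt == "complex" && lr != la) { effect[i] <- "complex"; next }
    # substitution (snp, mnp, equal-length complex)
    info <- codon_of(ctg, p)
    if (is.null(info)) { effect[i] <- "complex"; next }
    last_top <- info$top_start + 2L
    if (p + lr - 1L > last_top) { effect[i] <- "complex"; next }  # crosses codon
    # all substituted bases sit in one codon of one CDS
    m <- cpmap$contig[[ctg]]
    if (lr > 1L && any(is.na(m$owner[p:(p + lr - 1L)]) |
                       m$owner[p:(p + lr - 1L)] != info$owner)) {
      effect[i] <- "complex"; next
    }
    top_ref <- substring(chrs[[ctg]], info$top_start, last_top)
    top_alt <- top_ref
    o <- info$off_top
    substr(top_alt, o, o + lr - 1L) <- variants$alt[i]
    if (info$strand == "+") {
      rc <- top_ref; ac <- top_alt
    } else {
      rc <- .revcomp(top_ref); ac <- .revcomp(top_alt)
    }
    a1 <- translate1(rc); a2 <- translate1(ac)
    if (is.na(a1) || is.na(a2)) { effect[i] <- "complex"; next }
    ref_codon[i] <- rc; alt_codon[i] <- ac; ref_aa[i] <- a1; alt_aa[i] <- a2
    effect[i] <- if (a1 == a2) "synonymous" else "nonsynonymous"
  }
  out <- variants
  out$effect <- effect
  out$ref_codon <- ref_codon; out$alt_codon <- alt_codon
  out$ref_aa <- ref_aa; out$alt_aa <- alt_aa
  out
}

#' Count third-codon-position changes
#'
#' SNP records at third-position sites inside retained CDSs count 1 each;
#' MNP/equal-length complex records are decomposed base-by-base and each
#' differing base at a third-position site counts 1.  Indels and
#' length-changing complex records count 0.
#'
#' @param variants Variant data.frame (already mask-filtered).
#' @param cpmap A `codon_map`.
#' @param retained_cds `GRanges` of retained CDSs (subset of `cpmap$cds`).
#' @return Integer change count.
#' @export
count_third_position_changes <- function(variants, cpmap, retained_cds) {
  sn <- decompose_snvs(variants)
  if (nrow(sn) == 0L) return(0L)
  keep_idx <- match(retained_cds$locus_tag, cpmap$cds$locus_tag)
  k <- 0L
  for (ctg in unique(sn$contig)) {
    m <- cpmap$contig[[ctg]]
    p <- sn$pos[sn$contig == ctg]
    k <- k + sum(m$codon_pos[p] == 3L & m$owner[p] %in% keep_idx)
  }
  as.integer(k)
}

.spectrum_classes <- c("GC>AT", "GC>TA", "GC>CG", "AT>GC", "AT>TA", "AT>CG")

#' Strand-collapsed class of a single-nucleotide substitution
#'
#' `G>A` and `C>T` both count as `GC>AT`, and so on for the six classes.
#' Substitutions involving `N` return NA.
#'
#' @param ref,alt Single-character vectors.
#' @return Character vector over the six classes (or NA).
#' @export
snv_class <- function(ref, alt) {
  key <- paste0(ref, alt)
  map <- c(GA = "GC>AT", CT = "GC>AT",
           GT = "GC>TA", CA = "GC>TA",
           GC = "GC>CG", CG = "GC>CG",
           AG = "AT>GC", TC = "AT>GC",
           AT = "AT>TA", TA = "AT>TA",
           AC = "AT>CG", TG = "AT>CG")
  unname(map[key])
}

#' Summarise the substitution spectrum
#'
#' Every single-nucleotide substitution (after MNP decomposition) is assigned
#' to one of six strand-collapsed classes; `gc_to_at_fraction` is the GC>AT
#' share of classified substitutions (NA when there are none).
#'
#' @param variants Variant data.frame.
#' @return A `spectrum_table`: list with `counts` (named integer vector over
#'   the six classes), `n_snvs`, and `gc_to_at_fraction`.
#' @export
substitution_spectrum <- function(variants) {
  sn <- decompose_snvs(variants)
  cls <- snv_class(sn$ref, sn$alt)
  cls <- cls[!is.na(cls)]
  counts <- table(factor(cls, levels = .spectrum_classes))
  counts <- setNames(as.integer(counts), .spectrum_classes)
  nv <- sum(counts)
  structure(list(counts = counts, n_snvs = nv,
                 gc_to_at_fraction = if (nv > 0L) counts[["GC>AT"]] / nv
                                     else NA_real_),
            class = "spectrum_table")
}
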