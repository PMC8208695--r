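#' @import methods
#' @importFrom stats rbinom rpois runif rnorm setNames aggregate chisq.test
#' @importFrom utils packageVersion head tail
NULL

# All coordinates in this package are 1-based inclusive, the native
# IRanges/Biostrings convention.  GFF3 and VCF use the same convention, so
# conversion only happens for formats that do not (none of the ones consumed
# here); BLAST tabular subject coordinates may run high-to-low and are kept
# as read, with a `s_reverse` flag.

#' Read a FASTA file into a normalized DNAStringSet
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any symbol outside
#' `{A,C,G,T,N}` (e.g. IUPAC ambiguity codes) is mapped to `N` with a warning.
#' Ambiguous sites are excluded from every downstream denominator, so this
#' normalization is lossless for the analyses in this package.
#'
#' @param path Path to a FASTA text file.
#' @return A named [Biostrings::DNAStringSet]; names are the first whitespace-
#'   delimited token of each header line.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("FASTA format error in ", path, ": ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate contig_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- toupper(as.character(seqs))
  x <- chartr("U", "T", x)
  n_bad <- sum(nchar(gsub("[ACGTN]", "", x)))
  if (n_bad > 0L) {
    warning(n_bad, " non-{A,C,G,T,N} symbol(s) mapped to N in ", path)
    x <- gsub("[^ACGTN]", "N", x)
  }
  out <- Biostrings::DNAStringSet(x)
  names(out) <- ids
  out
}

#' Write a DNAStringSet to FASTA
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path, width = 70L)
  invisible(path)
}

#' Read CDS features from a GFF3 file
#'
#' Only rows with feature type `CDS` are consumed.  The returned
#' [GenomicRanges::GRanges] carries `locus_tag`, `product` and `phase`
#' metadata columns.  A missing `locus_tag`/`ID` attribute is synthesized as
#' `contig:start-end` with a message.
#'
#' @param path Path to a GFF3 file.
#' @return A `GRanges` of CDS features.
#' @export
read_gff3_cds <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 format error in ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (length(gr) == 0L) {
    return(GenomicRanges::GRanges(locus_tag = character(),
                                  product = character(), phase = integer()))
  }
  strd <- as.character(GenomicRanges::strand(gr))
  if (any(!strd %in% c("+", "-"))) {
    stop("GFF3 format error: CDS strand must be + or - in ", path)
  }
  tags <- if (!is.null(gr$locus_tag)) gr$locus_tag else rep(NA_character_, length(gr))
  if (!is.null(gr$ID)) tags[is.na(tags)] <- gr$ID[is.na(tags)]
  miss <- is.na(tags)
  if (any(miss)) {
    tags[miss] <- paste0(as.character(GenomicRanges::seqnames(gr))[miss], ":",
                         GenomicRanges::start(gr)[miss], "-",
                         GenomicRanges::end(gr)[miss])
    message(sum(miss), " CDS record(s) without locus_tag/ID; synthesized tags")
  }
  phase <- if (!is.null(gr$phase)) as.integer(gr$phase) else rep(NA_integer_, length(gr))
  if (anyNA(phase)) {
    message(sum(is.na(phase)), " CDS record(s) without phase; assuming 0")
    phase[is.na(phase)] <- 0L
  }
  prod <- if (!is.null(gr$product)) gr$product else rep("", length(gr))
  prod[is.na(prod)] <- ""
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = strd)
  out$locus_tag <- tags
  out$product <- prod
  out$phase <- phase
  out
}

#' Write CDS features to GFF3
#' @param cds A `GRanges` with `locus_tag`, `product`, `phase` metadata.
#' @param path Output path.
#' @export
write_gff3_cds <- function(cds, path) {
  gr <- cds
  gr$type <- "CDS"
  gr$ID <- gr$locus_tag
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Derive the variant type from allele lengths
#'
#' `snp`: both alleles length 1; `mnp`: equal lengths > 1; `ins`: the
#' reference is a prefix of a longer alternate; `del`: the alternate is a
#' prefix of a longer reference; `complex`: any other length-changing record
#' (snippy-style mixed events).
#'
#' @param ref,alt Character vectors of alleles.
#' @return Character vector over `{snp, mnp, ins, del, complex}`.
#' @export
variant_type <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- rep("complex", length(ref))
  out[lr == 1L & la == 1L] <- "snp"
  out[lr == la & lr > 1L] <- "mnp"
  is_ins <- la > lr & substr(alt, 1L, lr) == ref
  is_del <- lr > la & substr(ref, 1L, la) == alt
  out[is_ins] <- "ins"
  out[is_del] <- "del"
  out
}

#' Read variant records from a VCF file
#'
#' Multi-allelic rows are split into one record per ALT allele.  Records with
#' missing (`.`) or symbolic/breakend ALT alleles are skipped with a warning.
#'
#' @param path Path to a VCF text file.
#' @param sample_id Label attached to every record (e.g. the isolate name).
#' @return A data.frame with columns `contig`, `pos` (1-based), `ref`, `alt`,
#'   `vtype`, `sample_id`.
#' @export
read_vcf <- function(path, sample_id) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF format error in ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)) || nrow(fix) == 0L) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), vtype = character(),
                      sample_id = character(), stringsAsFactors = FALSE))
  }
  contig <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt_raw <- fix[, "ALT"]
  alts <- strsplit(ifelse(is.na(alt_raw), ".", alt_raw), ",", fixed = TRUE)
  n_per <- lengths(alts)
  idx <- rep.int(seq_along(alts), n_per)
  alt <- toupper(unlist(alts, use.names = FALSE))
  keep <- alt != "." & alt != "*" & !grepl("[][<>]", alt)
  if (any(!keep)) {
    warning(sum(!keep), " symbolic/missing ALT allele(s) skipped in ", path)
  }
  idx <- idx[keep]; alt <- alt[keep]
  data.frame(contig = contig[idx], pos = pos[idx], ref = ref[idx], alt = alt,
             vtype = variant_type(ref[idx], alt), sample_id = sample_id,
             stringsAsFactors = FALSE)
}

#' Write variant records to a minimal VCF 4.2 file
#' @param variants Variant data.frame (see [read_vcf()]).
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for `##contig` headers.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- if (nrow(variants) > 0L) {
    v <- variants[order(variants$contig, variants$pos), , drop = FALSE]
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", v$contig, v$pos, v$ref, v$alt)
  } else character()
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a per-position depth table
#'
#' Consumes samtools-depth-style TSV rows (`contig`, 1-based `pos`, `depth`,
#' no header).  Positions absent from the file are depth 0.
#'
#' @param path Path to the TSV.
#' @param contigs Named integer vector of contig lengths (defines the dense
#'   track extent).
#' @param sample_id Library label.
#' @return A `depth_track`: list with `sample_id` and `depth`, a named list of
#'   integer vectors (one per contig).
#' @export
read_depth <- function(path, contigs, sample_id) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  contigs <- setNames(as.integer(contigs), names(contigs))
  tracks <- lapply(contigs, integer)
  if (file.size(path) > 0L) {
    d <- data.table::fread(path, header = FALSE, sep = "\t",
                           col.names = c("contig", "pos", "depth"))
    bad_ctg <- setdiff(unique(d$contig), names(contigs))
    if (length(bad_ctg)) stop("depth format error: unknown contig ", bad_ctg[1])
    for (ctg in names(contigs)) {
      sub <- d[d$contig == ctg, ]
      v <- integer(contigs[[ctg]])
      if (nrow(sub)) {
        if (any(sub$pos < 1L | sub$pos > contigs[[ctg]])) {
          stop("depth format error: position outside contig ", ctg)
        }
        v[sub$pos] <- as.integer(sub$depth)
      }
      tracks[[ctg]] <- v
    }
  } else {
    tracks <- lapply(contigs, function(n) integer(n))
  }
  structure(list(sample_id = sample_id, depth = tracks), class = "depth_track")
}

#' Write a depth track as samtools-depth-style TSV (zero positions omitted)
#' @param track A `depth_track`.
#' @param path Output path.
#' @export
write_depth <- function(track, path) {
  parts <- lapply(names(track$depth), function(ctg) {
    d <- track$depth[[ctg]]
    nz <- which(d > 0L)
    if (!length(nz)) return(NULL)
    data.table::data.table(contig = ctg, pos = nz, depth = d[nz])
  })
  dt <- data.table::rbindlist(parts)
  if (nrow(dt) == 0L) {
    file.create(path)
  } else {
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

.outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read a BLAST-style tabular hits file (outfmt 6)
#'
#' Subject coordinates are retained as read; rows with `sstart > send` are
#' flagged `s_reverse = TRUE`.
#'
#' @param path Path to a 12-column tab-separated hits file (no header).
#' @return A data.frame with the standard outfmt-6 column names plus
#'   `s_reverse`.
#' @export
read_hits_table <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path)
  h <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(h) != 12L) stop("hits format error: expected 12 columns, got ", ncol(h))
  data.table::setnames(h, .outfmt6_cols)
  num_cols <- setdiff(.outfmt6_cols, c("qseqid", "sseqid"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(h[[cn]]))
    if (anyNA(v)) stop("hits format error: non-numeric values in column ", cn)
    data.table::set(h, j = cn, value = v)
  }
  h <- as.data.frame(h)
  for (cn in c("length", "mismatch", "gapopen", "qstart", "qend",
               "sstart", "send")) h[[cn]] <- as.integer(h[[cn]])
  if (any(h$length < 1L)) stop("hits format error: aln_length < 1")
  if (any(h$pident < 0 | h$pident > 100)) {
    stop("hits format error: pct_identity outside [0, 100]")
  }
  h$s_reverse <- h$sstart > h$send
  h
}

#' Write alignment hits as a 12-column tabular file
#' @param hits Hits data.frame (outfmt-6 columns; extra columns dropped).
#' @param path Output path.
#' @export
write_hits_table <- function(hits, path) {
  data.table::fwrite(hits[, .outfmt6_cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read an orthogroup membership table
#'
#' Expects a header line with columns `orthogroup_id`, `strain`, `locus_tag`,
#' `length_bp` (one row per member CDS).
#'
#' @param path Path to the TSV.
#' @return A data.frame with those four columns.
#' @export
read_orthogroups <- function(path) {
  if (!file.exists(path)) stop("orthogroup file not found: ", path)
  og <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("orthogroup_id", "strain", "locus_tag", "length_bp")
  if (!all(need %in% names(og))) {
    stop("orthogroup format error: need columns ", paste(need, collapse = ", "))
  }
  og$length_bp <- as.integer(og$length_bp)
  if (any(og$length_bp <= 0L)) stop("orthogroup format error: length_bp must be > 0")
  og[need]
}

#' Write an orthogroup membership table
#' @param og Orthogroup data.frame (see [read_orthogroups()]).
#' @param path Output path.
#' @export
write_orthogroups <- function(og, path) {
  data.table::fwrite(og, path, sep = "\t")
  invisible(path)
}
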