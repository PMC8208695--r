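og_table <- function(lenA, lenB, og = sprintf("OG%02d", seq_along(lenA))) {
  rbind(data.frame(orthogroup_id = og, strain = "A",
                   locus_tag = paste0(og, "_A"), length_bp = lenA,
                   stringsAsFactors = FALSE),
        data.frame(orthogroup_id = og, strain = "B",
                   locus_tag = paste0(og, "_B"), length_bp = lenB,
                   stringsAsFactors = FALSE))
}

test_that("truncation calls follow the at-most-60-percent rule", {
  calls <- call_truncations(og_table(c(300L, 400L, 600L), c(600L, 600L, 600L)))
  a <- calls[calls$strain == "A", ]
  expect_equal(a$ratio, c(0.5, 400 / 600, 1.0))
  expect_equal(a$flagged, c(TRUE, FALSE, FALSE))
  b <- calls[calls$strain == "B", ]
  expect_equal(b$flagged, c(FALSE, FALSE, FALSE))
})

test_that("the longest member represents each strain", {
  og <- rbind(og_table(900L, 600L, "OG01"),
              data.frame(orthogroup_id = "OG01", strain = "A",
                         locus_tag = "OG01_A2", length_bp = 240L,
                         stringsAsFactors = FALSE))
  calls <- call_truncations(og)
  expect_equal(calls$longest_own_bp[calls$strain == "A"], 900L)
  expect_false(any(calls$flagged))
})

test_that("truncation labelling is symmetric in the strain labels", {
  og <- og_table(c(300L, 1200L), c(600L, 500L))
  swapped <- og
  swapped$strain <- ifelse(og$strain == "A", "B", "A")
  a <- call_truncations(og)
  b <- call_truncations(swapped)
  b$strain <- ifelse(b$strain == "A", "B", "A")
  b <- b[order(b$orthogroup_id, b$strain), ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("single-strain orthogroups are skipped with a message", {
  og <- rbind(og_table(300L, 600L, "OG01"),
              data.frame(orthogroup_id = "OG02", strain = "A",
                         locus_tag = "x", length_bp = 500L,
                         stringsAsFactors = FALSE))
  expect_message(calls <- call_truncations(og), "skipped")
  expect_equal(unique(calls$orthogroup_id), "OG01")
})

test_that("coding density counts overlapping CDSs once", {
  g <- make_genome(c1 = paste(rep("A", 1000), collapse = ""))
  expect_equal(coding_density(g, make_cds("c1", 1L, 650L)), 65.0)
  expect_equal(coding_density(g, make_cds("c1", 1L, 6L)[0]), 0)
  two <- make_cds("c1", c(101L, 101L), c(400L, 400L), strand = c("+", "-"),
                  tag = c("x", "y"))
  expect_equal(coding_density(g, two), 30.0)
  # permutation and duplication invariance
  set.seed(1)
  many <- make_cds("c1", c(1L, 201L, 101L), c(150L, 300L, 250L),
                   tag = c("a", "b", "c"))
  expect_equal(coding_density(g, many[c(3, 1, 2)]), coding_density(g, many))
  expect_equal(coding_density(g, c(many, many)), coding_density(g, many))
})

test_that("prophage calls require both identity and coverage thresholds", {
  hit <- function(q, s, pid, len, score = 100) {
    data.frame(qseqid = q, sseqid = s, pident = pid, length = len,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = len,
               sstart = 1L, send = len, evalue = 0, bitscore = score,
               s_reverse = FALSE, stringsAsFactors = FALSE)
  }
  vl <- c(v1 = 100)
  expect_true(classify_prophage_loci(hit("g1", "v1", 65, 60), vl)$flagged)
  expect_false(classify_prophage_loci(hit("g1", "v1", 65, 40), vl)$flagged)
  expect_false(classify_prophage_loci(hit("g1", "v1", 55, 90), vl)$flagged)
  # boundary: exactly 60 % identity over exactly 50 % coverage passes
  expect_true(classify_prophage_loci(hit("g1", "v1", 60, 50), vl)$flagged)
  # best passing hit wins by bitscore
  h <- rbind(hit("g1", "v1", 70, 60, score = 80),
             hit("g1", "v2", 65, 60, score = 120),
             hit("g1", "v3", 20, 90, score = 500))
  out <- classify_prophage_loci(h, c(v1 = 100, v2 = 100, v3 = 100))
  expect_equal(out$best_viral_hit, "v2")
  expect_error(classify_prophage_loci(hit("g1", "vX", 70, 60), vl), "vX")
})

test_that("synteny filters drop short and dissimilar hits at the stated bounds", {
  base <- data.frame(qseqid = "A", sseqid = "B", mismatch = 0L, gapopen = 0L,
                     sstart = 1L, evalue = 0, s_reverse = FALSE,
                     stringsAsFactors = FALSE)
  mk <- function(pid, len, qs, score) {
    cbind(base, data.frame(pident = pid, length = len, qstart = qs,
                           qend = qs + len - 1L, send = len, bitscore = score))
  }
  hits <- rbind(mk(99, 900L, 1L, 1700),      # below 1000 bp -> discarded
                mk(94, 2000L, 2000L, 3500),  # under 95 % -> discarded
                mk(95, 1000L, 5000L, 1800))  # both exactly at bound -> kept
  blocks <- build_synteny_blocks(hits, GRanges(), GRanges())
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$a_start, 5000L)
})

test_that("greedy best-first keeps a single best match per region", {
  # five hits worked by hand: retained must be scores 900 (claims 1-2000),
  # 700 (2500-4000), 500 (4200-5000); 600 overlaps the 900 block, and 400
  # overlaps the 700 block, so both lose.
  h <- data.frame(
    qseqid = "A", sseqid = "B",
    pident = 99, length = c(2000L, 1500L, 1200L, 1000L, 900L) + 100L,
    mismatch = 0L, gapopen = 0L,
    qstart = c(1L, 1500L, 2500L, 3800L, 4200L),
    qend = c(2000L, 2600L, 4000L, 4900L, 5000L),
    sstart = c(1L, 3000L, 5000L, 7000L, 9000L),
    send = c(2000L, 4100L, 6500L, 8100L, 9800L),
    evalue = 0, bitscore = c(900, 600, 700, 400, 500),
    s_reverse = FALSE, stringsAsFactors = FALSE)
  blocks <- build_synteny_blocks(h, GRanges(), GRanges())
  expect_equal(sort(blocks$a_start), c(1L, 2500L, 4200L))
  # retained A intervals are pairwise disjoint
  ir <- IRanges(blocks$a_start, blocks$a_end)
  expect_equal(length(findOverlaps(ir, ir)), nrow(blocks))
})

test_that("block density uses CDS midpoints per kb and the A-minus-B sign", {
  h <- data.frame(qseqid = "A", sseqid = "B", pident = 100, length = 2000L,
                  mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 2000L,
                  sstart = 1001L, send = 3000L, evalue = 0, bitscore = 100,
                  s_reverse = FALSE, stringsAsFactors = FALSE)
  cds_a <- make_cds("A", c(1L, 1801L), c(300L, 2400L), tag = c("a1", "a2"))
  # a1 midpoint 150 inside; a2 midpoint 2100 outside
  cds_b <- make_cds("B", c(1101L, 1401L, 2801L), c(1300L, 1600L, 3400L),
                    tag = c("b1", "b2", "b3"))
  # b midpoints 1200, 1500 inside [1001,3000]; 3100 outside
  blocks <- build_synteny_blocks(h, cds_a, cds_b)
  expect_equal(blocks$n_cds_a, 1L)
  expect_equal(blocks$n_cds_b, 2L)
  expect_equal(blocks$cds_per_kb_a, 0.5)
  expect_equal(blocks$density_diff, 0.5 - 1.0)
})

test_that("block summaries partition counts and base pairs", {
  blocks <- data.frame(a_contig = "A",
                       a_start = c(1L, 3001L, 6001L),
                       a_end = c(2000L, 5000L, 7000L),
                       n_cds_a = c(1L, 5L, 2L), n_cds_b = c(3L, 4L, 2L))
  s <- summarize_block_density(blocks)
  expect_equal(c(s$n_fewer_a, s$n_more_a, s$n_equal), c(1L, 1L, 1L))
  expect_equal(s$n_blocks, s$n_fewer_a + s$n_more_a + s$n_equal)
  expect_equal(s$bp_fewer_a + s$bp_more_a + s$bp_equal,
               sum(blocks$a_end - blocks$a_start + 1L))
  s0 <- summarize_block_density(blocks[0, ])
  expect_equal(s0$n_blocks, 0L)
  blocks$n_cds_b <- blocks$n_cds_a
  se <- summarize_block_density(blocks)
  expect_equal(c(se$n_fewer_a, se$n_more_a, se$n_equal), c(0L, 0L, 3L))
})

test_that("divergence-time arithmetic follows t = d / (2r)", {
  expect_equal(estimate_divergence_time(0.02, 1e-5), 1000)
  expect_equal(estimate_divergence_time(0, 1e-5), 0)
  expect_equal(estimate_divergence_time(0.02, 0.5e-5),
               2 * estimate_divergence_time(0.02, 1e-5))
  expect_equal(estimate_divergence_time(0.02, 1e-5, formula = "d-over-r"),
               2000)
  expect_error(estimate_divergence_time(0.02, 0), "rate")
  expect_error(estimate_divergence_time(1.2, 1e-5), "divergence")
})
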