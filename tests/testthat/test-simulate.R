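small_cfg <- function(...) {
  simulation_config(genome_length = 60000L, n_cds = 50L, n_libraries = 2L,
                    seed = 101L, ...)
}

test_that("genome simulation is deterministic and respects its contract", {
  cfg <- small_cfg()
  a <- simulate_annotated_genome(cfg)
  b <- simulate_annotated_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.data.frame(a$cds), as.data.frame(b$cds))
  expect_equal(length(a$cds), 50L)
  expect_true(all(width(a$cds) %% 3 == 0))
  ir <- ranges(a$cds)
  expect_equal(length(findOverlaps(ir, ir)), length(ir))  # non-overlapping
  expect_error(simulate_annotated_genome(
    simulation_config(genome_length = 1000L, n_cds = 10L,
                      cds_length_range = c(300L, 300L), seed = 1L)),
    "infeasible packing")
})

test_that("realized GC content matches the AT-rich target", {
  cfg <- simulation_config(genome_length = 1000000L, n_cds = 0L, seed = 3L)
  g <- simulate_annotated_genome(cfg)$genome
  gc <- sum(Biostrings::letterFrequency(g, c("G", "C"))) / width(g)
  expect_lt(abs(gc - 0.27), 0.01)
})

test_that("zero rate evolves nothing and truth records every change", {
  cfg <- small_cfg(rate_per_site_per_year = 0)
  sim <- simulate_annotated_genome(cfg)
  cpmap <- build_codon_position_map(sim$genome, sim$cds)
  ev <- evolve_sequence(sim$genome, cpmap, cfg)
  expect_identical(as.character(ev$genome), as.character(sim$genome))
  expect_equal(nrow(ev$truth$variants), 0L)

  cfg2 <- small_cfg(rate_per_site_per_year = 1e-4)
  ev2 <- evolve_sequence(sim$genome, cpmap, cfg2)
  v <- ev2$truth$variants
  expect_gt(nrow(v), 0L)
  anc <- as.character(sim$genome[[1]])
  evo <- as.character(ev2$genome[[1]])
  expect_equal(substring(anc, v$pos, v$pos), v$ref)
  expect_equal(substring(evo, v$pos, v$pos), v$alt)
  # untouched positions identical
  expect_equal(sum(charToRaw(anc) != charToRaw(evo)), nrow(v))
})

test_that("an all-GC>AT spectrum only hits G/C sites and yields A/T", {
  w <- c("GC>AT" = 1, "GC>TA" = 0, "GC>CG" = 0,
         "AT>GC" = 0, "AT>TA" = 0, "AT>CG" = 0)
  cfg <- small_cfg(spectrum_weights = w, rate_per_site_per_year = 1e-4)
  sim <- simulate_annotated_genome(cfg)
  cpmap <- build_codon_position_map(sim$genome, sim$cds)
  v <- evolve_sequence(sim$genome, cpmap, cfg)$truth$variants
  expect_true(all(v$ref %in% c("G", "C")))
  expect_true(all(v$alt %in% c("A", "T")))
  expect_true(all(ifelse(v$ref == "G", v$alt == "A", v$alt == "T")))
})

test_that("third-position change counts concentrate at rate x years x sites", {
  cfg <- simulation_config(genome_length = 300000L, n_cds = 240L,
                           rate_per_site_per_year = 1e-5, years = 10,
                           seed = 55L)
  sim <- simulate_annotated_genome(cfg)
  cpmap <- build_codon_position_map(sim$genome, sim$cds)
  L3 <- count_third_position_sites(cpmap, cpmap$cds)
  mu <- cfg$rate_per_site_per_year * cfg$years * L3
  ok <- 0L
  for (s in 1:20) {
    c2 <- cfg; c2$seed <- 600L + s
    k <- evolve_sequence(sim$genome, cpmap, c2)$truth$n_third_changes
    if (abs(k - mu) <= 3 * sqrt(mu)) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("classifying the true variants reproduces the simulator's tally", {
  cfg <- small_cfg(rate_per_site_per_year = 5e-5)
  sim <- simulate_annotated_genome(cfg)
  cpmap <- build_codon_position_map(sim$genome, sim$cds)
  ev <- evolve_sequence(sim$genome, cpmap, cfg)
  eff <- classify_variant_effect(ev$truth$variants, cpmap, sim$genome)
  expect_equal(sum(eff$effect == "synonymous"),
               unname(ev$truth$effects["synonymous"]))
  expect_equal(sum(eff$effect == "nonsynonymous"),
               unname(ev$truth$effects["nonsynonymous"]))
})

test_that("the realized spectrum matches the configured weights", {
  cfg <- simulation_config(genome_length = 200000L, n_cds = 160L,
                           rate_per_site_per_year = 1e-4, seed = 9L)
  sim <- simulate_annotated_genome(cfg)
  cpmap <- build_codon_position_map(sim$genome, sim$cds)
  pvals <- vapply(1:5, function(s) {
    c2 <- cfg; c2$seed <- 40L + s
    v <- evolve_sequence(sim$genome, cpmap, c2)$truth$variants
    sp <- substitution_spectrum(v)
    suppressWarnings(chisq.test(sp$counts, p = cfg$spectrum_weights)$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("depth tracks have the configured mean, dropout and determinism", {
  g <- make_genome(c1 = strrep("A", 100000L))
  cfg <- simulation_config(mean_depth = 20, dropout_fraction = 0,
                           n_libraries = 2L, seed = 12L)
  tr <- simulate_depth_tracks(g, cfg)
  expect_length(tr, 2L)
  expect_lt(abs(mean(tr[[1]]$depth$c1) - 20), 0.2)
  tr2 <- simulate_depth_tracks(g, cfg)
  expect_identical(tr, tr2)

  cfg1 <- simulation_config(dropout_fraction = 1, seed = 12L)
  expect_true(all(simulate_depth_tracks(g, cfg1)[[1]]$depth$c1 == 0L))

  cfg3 <- simulation_config(dropout_fraction = 0.3, seed = 12L)
  d <- simulate_depth_tracks(g, cfg3)[[1]]$depth$c1
  expect_equal(sum(d == 0L) / length(d), 0.3, tolerance = 0.01)
})

test_that("rearranged pairs carry exact block ground truth", {
  cfg <- small_cfg(n_inversions = 0L, n_translocations = 0L,
                   identity_jitter_sd = 0)
  sim <- simulate_annotated_genome(cfg)
  pr <- simulate_rearranged_pair(sim$genome, sim$cds, cfg)
  expect_equal(nrow(pr$truth$blocks), 1L)
  expect_equal(pr$hits$pident, 100)
  expect_identical(as.character(pr$genome_b[[1]]), as.character(sim$genome[[1]]))

  cfg1 <- small_cfg(n_inversions = 1L, n_translocations = 0L,
                    min_block_bp = 2000L)
  pr1 <- simulate_rearranged_pair(sim$genome, sim$cds, cfg1)
  expect_equal(nrow(pr1$truth$blocks), 3L)
  expect_equal(sum(pr1$truth$blocks$reverse), 1L)

  # sequence-level inverse map: every block's B sequence equals its A
  # sequence (reverse-complemented for inverted blocks)
  cfg2 <- small_cfg(n_inversions = 3L, n_translocations = 2L,
                    min_block_bp = 2000L)
  pr2 <- simulate_rearranged_pair(sim$genome, sim$cds, cfg2)
  blk <- pr2$truth$blocks
  expect_equal(sum(blk$a_end - blk$a_start + 1L), width(sim$genome)[1])
  for (i in seq_len(nrow(blk))) {
    sa <- subseq(sim$genome[[1]], blk$a_start[i], blk$a_end[i])
    sb <- subseq(pr2$genome_b[[1]], blk$b_start[i], blk$b_end[i])
    if (blk$reverse[i]) sa <- reverseComplement(sa)
    expect_identical(as.character(sa), as.character(sb))
  }
  # lifted CDSs carry the same sequence content
  if (length(pr2$cds_b) > 0L) {
    j <- which(sim$cds$locus_tag == pr2$cds_b$locus_tag[1])
    sa <- subseq(sim$genome[[1]], start(sim$cds)[j], end(sim$cds)[j])
    if (as.character(strand(sim$cds))[j] != as.character(strand(pr2$cds_b))[1]) {
      sa <- reverseComplement(sa)
    }
    sb <- subseq(pr2$genome_b[[1]], start(pr2$cds_b)[1], end(pr2$cds_b)[1])
    expect_identical(as.character(sa), as.character(sb))
  }
})

test_that("orthogroup simulation marks exactly the eroded members", {
  cfg <- small_cfg(n_orthogroups = 200L, truncated_fraction = 0.15)
  og <- simulate_orthogroups(cfg)
  calls <- call_truncations(og$table)
  flagged <- calls[calls$flagged, c("orthogroup_id", "strain")]
  rownames(flagged) <- NULL
  truth <- og$truth[order(og$truth$orthogroup_id), ]
  rownames(truth) <- NULL
  expect_equal(flagged, truth)
  expect_equal(nrow(truth), 30L)
})

test_that("fixture sets are reproducible and round-trip through the readers", {
  cfg <- simulation_config(genome_length = 30000L, n_cds = 25L,
                           n_libraries = 2L, n_inversions = 1L,
                           n_translocations = 1L, min_block_bp = 1500L,
                           n_orthogroups = 40L, seed = 77L)
  sim <- simulate_dataset(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_set(sim, d1)
  m2 <- write_fixture_set(simulate_dataset(cfg), d2)
  expect_identical(m1$files, m2$files)  # same checksums under the same seed
  expect_true(all(file.exists(file.path(d1, names(m1$files)))))

  g <- read_fasta(file.path(d1, "reference.fasta"))
  expect_identical(as.character(g), as.character(sim$genome))
  cds <- read_gff3_cds(file.path(d1, "reference.gff3"))
  expect_equal(start(cds), start(sim$cds))
  expect_equal(cds$locus_tag, sim$cds$locus_tag)
  v <- read_vcf(file.path(d1, "evolved.vcf"), sample_id = "evolved")
  tv <- sim$evolved$truth$variants[order(sim$evolved$truth$variants$pos), ]
  expect_equal(v$pos, tv$pos)
  expect_equal(v$alt, tv$alt)
  lens <- setNames(width(sim$genome), names(sim$genome))
  tr <- read_depth(file.path(d1, "depth_lib01.tsv"), lens, "lib01")
  expect_equal(tr$depth, sim$tracks[[1]]$depth)
  h <- read_hits_table(file.path(d1, "hits.tsv"))
  expect_equal(h$qstart, sim$pair$hits$qstart)
  expect_equal(read_orthogroups(file.path(d1, "orthogroups.tsv")),
               sim$orthogroups$table)
})
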