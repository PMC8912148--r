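test_that("truncation cuts to fixed lengths and discards short pairs", {
  set.seed(1)
  fwd <- c(rand_dna(300), rand_dna(200), rand_dna(150))
  rev <- c(rand_dna(300), rand_dna(250), rand_dna(300))
  tr <- truncate_pairs(fwd, rev)
  expect_equal(nchar(tr$fwd), c(200L, 200L))
  expect_equal(nchar(tr$rev), c(250L, 250L))
  expect_equal(tr$fwd[2], fwd[2]) # exact-length pair unchanged
  expect_equal(tr$n_discarded, 1L)
})

test_that("pair merging finds the maximal clean overlap", {
  set.seed(2)
  tpl <- rand_dna(350)
  fwd <- substr(tpl, 1, 200)
  rev <- rc(substr(tpl, 101, 350))
  m <- merge_pairs(fwd, rev)
  expect_equal(m$merged, tpl)
  expect_equal(m$n_failed, 0L)

  # overlap below the minimum fails
  tpl2 <- rand_dna(439) # 200 + 250 - 439 = 11 < 12
  m2 <- merge_pairs(substr(tpl2, 1, 200), rc(substr(tpl2, 190, 439)))
  expect_true(is.na(m2$merged))
  expect_equal(m2$n_failed, 1L)
})

test_that("merge mismatch tolerance keeps the forward base", {
  # 40-mer template; brute-force all overlaps to find the expected one
  set.seed(3)
  tpl <- rand_dna(40)
  fwd <- substr(tpl, 1, 25)
  rev_seq <- substr(tpl, 16, 40) # overlap 10 over positions 16..25
  pos <- 20 # inside the overlap
  orig <- substr(tpl, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), orig)[1]
  rev_mut <- mutate_at(rev_seq, pos - 15, alt)
  m0 <- merge_pairs(fwd, rc(rev_mut), min_overlap = 8, max_mismatch = 0)
  expect_true(is.na(m0$merged))
  m1 <- merge_pairs(fwd, rc(rev_mut), min_overlap = 8, max_mismatch = 1)
  expect_equal(m1$merged, tpl) # forward base wins the conflict

  # brute-force oracle: the merge uses the largest overlap with <= 1
  # mismatch between the forward tail and the template-strand segment
  mm_at <- vapply(8:25, function(o) {
    a <- charToRaw(substr(fwd, 25 - o + 1, 25))
    b <- charToRaw(substr(rev_mut, 1, o))
    sum(a != b)
  }, numeric(1))
  best_o <- max((8:25)[mm_at <= 1])
  expect_equal(best_o, 10)
  expect_equal(nchar(m1$merged), 25 + nchar(rev_mut) - best_o)
})

test_that("denoiser absorbs by the ratio/Hamming rule", {
  t1 <- dereplicate_denoise(rep("AAAA", 100))
  expect_equal(t1$count, 100L)

  t2 <- dereplicate_denoise(c(rep("AAAA", 100), rep("AAAT", 5)))
  expect_equal(nrow(t2), 1)
  expect_equal(t2$sequence, "AAAA")
  expect_equal(t2$count, 105L)

  # ratio 2 < 10: both survive
  t3 <- dereplicate_denoise(c(rep("AAAA", 100), rep("AAAT", 50)))
  expect_equal(nrow(t3), 2)
  expect_equal(t3$count, c(100L, 50L))

  expect_error(dereplicate_denoise(character(0)), "no merged reads")
})

test_that("denoising is invariant to input read order", {
  set.seed(4)
  base <- rand_dna(60)
  reads <- c(rep(base, 200),
             rep(mutate_at(base, 5, "A"), 3),
             rep(mutate_at(base, 40, "C"), 7),
             rep(rand_dna(60), 30))
  reads <- reads[nchar(reads) == 60]
  a <- dereplicate_denoise(reads)
  b <- dereplicate_denoise(sample(reads))
  expect_equal(a$sequence, b$sequence)
  expect_equal(a$count, b$count)
})

test_that("bimera removal needs two adequate parents and an interior split", {
  set.seed(5)
  p1 <- rand_dna(300)
  p2 <- rand_dna(300)
  chim <- paste0(substr(p1, 1, 150), substr(p2, 151, 300))
  tab <- asv_table(c(p1, p2, chim), c(100L, 100L, 10L))
  out <- remove_bimeras(tab)
  expect_equal(sort(out$sequence), sort(c(p1, p2)))
  expect_equal(attr(out, "n_bimeras"), 1L)

  # two ASVs only: a candidate cannot be its own parent
  tab2 <- asv_table(c(p1, chim), c(100L, 10L))
  out2 <- remove_bimeras(tab2)
  expect_equal(nrow(out2), 2)

  # breakpoint too close to an end is not called
  edge <- paste0(substr(p1, 1, 10), substr(p2, 11, 300))
  tab3 <- asv_table(c(p1, p2, edge), c(100L, 100L, 10L))
  expect_equal(attr(remove_bimeras(tab3), "n_bimeras"), 0L)

  # abundant sequences are not candidates against weak parents
  tab4 <- asv_table(c(p1, p2, chim), c(15L, 15L, 10L))
  expect_equal(attr(remove_bimeras(tab4), "n_bimeras"), 0L)
})

test_that("labelled chimeras from the simulator are removed, templates kept", {
  cfg <- sim_config(per_sample_depth = 3000, error_rate = 0,
                    chimera_fraction = 0.05, contaminant_fraction = 0,
                    n_nonflora_global = 0, seed = 8)
  ref <- generate_flora_and_dbs(cfg)
  sp <- ref$flora$species[c(10, 13, 15)]
  comp <- stats::setNames(c(0.5, 0.3, 0.2), sp)
  set.seed(9)
  sim <- simulate_sample(comp, ref, cfg, "rbcL")
  tr <- truncate_pairs(sim$fwd, sim$rev)
  mg <- merge_pairs(tr$fwd, tr$rev)
  den <- dereplicate_denoise(mg$merged[!is.na(mg$merged)])
  deb <- remove_bimeras(den)
  tpls <- unname(ref$templates$rbcL[sp])
  chim_seqs <- setdiff(den$sequence, tpls)
  removed <- setdiff(den$sequence, deb$sequence)
  expect_gte(length(chim_seqs), 5)
  # every removal is a labelled chimera, and at least 90% of them go
  expect_true(all(removed %in% chim_seqs))
  expect_gte(length(removed) / length(chim_seqs), 0.9)
  expect_true(all(tpls %in% deb$sequence))
})

test_that("the relative-abundance filter uses a strict less-than rule", {
  mk <- function(counts) asv_table(vapply(seq_along(counts),
                                          function(i) rand_dna(30),
                                          character(1)), counts)
  set.seed(6)
  tab <- mk(c(9801L, 100L, 99L)) # total 10000
  out <- abundance_filter(tab)
  expect_equal(sort(out$count), c(100L, 9801L))

  one <- mk(5L)
  expect_equal(abundance_filter(one)$count, 5L)

  # 10/1000 = 1.0% exactly: retained
  tab3 <- mk(c(900L, 90L, 10L))
  expect_equal(sort(abundance_filter(tab3)$count), c(10L, 90L, 900L))
})

test_that("rarefaction subsamples to exact depth or flags exclusion", {
  set.seed(7)
  seqs <- vapply(1:2, function(i) rand_dna(30), character(1))
  tab <- asv_table(seqs, c(600L, 400L))
  r <- rarefy_table(tab, depth = 1000)
  expect_equal(sum(r$count), 1000L)
  expect_equal(r$count, c(600L, 400L)) # already at depth: unchanged

  shallow <- asv_table(seqs, c(300L, 200L))
  ex <- rarefy_table(shallow, depth = 1000)
  expect_true(attr(ex, "excluded"))
  expect_error(rarefy_table(tab, depth = 0), "positive")

  big <- asv_table(seqs, c(9000L, 1000L))
  draws <- vapply(1:200, function(s) {
    r <- rarefy_table(big, depth = 1000, seed = s)
    r$count[r$sequence == seqs[2]]
  }, numeric(1))
  # multivariate hypergeometric: mean 100, sd ~ 9.02
  sd_hyp <- sqrt(1000 * 0.1 * 0.9 * (10000 - 1000) / (10000 - 1))
  expect_equal(mean(draws), 100, tolerance = 3 * sd_hyp / sqrt(200) / 100)
  expect_equal(sd(draws), sd_hyp, tolerance = 0.25)
})

test_that("read-level rarefaction expectation is exact", {
  expect_equal(rarefaction_curve(c(5, 5), 2), 2 - 2 * choose(5, 2) / choose(10, 2))
  expect_equal(rarefaction_curve(c(3, 7, 2), 12), 3) # full depth: richness
  expect_equal(rarefaction_curve(c(4, 4), 1), 1)
  expect_error(rarefaction_curve(c(2, 2), 5), "exceeds")
  # cross-check against the standard implementation
  set.seed(8)
  counts <- c(50, 20, 10, 5, 1, 1)
  depths <- c(10, 30, 60, 87)
  expect_equal(rarefaction_curve(counts, depths),
               as.numeric(vegan::rarefy(counts, sample = depths)),
               tolerance = 1e-10)
})

test_that("a noiseless single-species sample yields one ASV of 1000 reads", {
  cfg <- sim_config(per_sample_depth = 2000, error_rate = 0,
                    chimera_fraction = 0, contaminant_fraction = 0,
                    n_nonflora_global = 0, seed = 10)
  ref <- generate_flora_and_dbs(cfg)
  sp <- ref$flora$species[1]
  set.seed(3)
  sim <- simulate_sample(stats::setNames(1, sp), ref, cfg, "rbcL")
  pr <- process_sample_reads(sim$fwd, sim$rev, seed = 1)
  expect_equal(nrow(pr$table), 1)
  expect_equal(pr$table$count, 1000L)
  expect_equal(pr$table$sequence, unname(ref$templates$rbcL[sp]))
  # read accounting: all input reads are explained by the stage log
  lg <- pr$log
  expect_equal(lg$input, lg$discarded_short + lg$merge_failed + lg$merged)
})
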