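test_that("generator builds the configured ambiguity structure", {
  cfg <- sim_config(n_species = 20, n_shared_groups = 2, seed = 1)
  ref <- generate_flora_and_dbs(cfg)
  expect_equal(nrow(ref$flora), 20)
  for (m in c("rbcL", "ITS2")) {
    g <- ambiguity_groups(ref$local[[m]])
    sizes <- vapply(g, nrow, 1L)
    expect_equal(sum(sizes >= 2), 2)
    # each shared group is congeneric
    for (gg in g[sizes >= 2]) {
      expect_equal(length(unique(gg$genus)), 1)
      expect_gte(length(unique(gg$species)), 2)
    }
    # local taxa are a subset of global taxa; extras are the distractors
    extra <- setdiff(ref$global[[m]]$records$species,
                     ref$local[[m]]$records$species)
    expect_equal(length(extra), cfg$n_nonflora_global)
    expect_false(any(extra %in% ref$flora$species))
    expect_false(any(grepl("[^ACGT]", ref$global[[m]]$records$sequence)))
  }
})

test_that("generator is deterministic: same seed gives identical FASTA", {
  cfg <- sim_config(seed = 33)
  r1 <- generate_flora_and_dbs(cfg)
  r2 <- generate_flora_and_dbs(cfg)
  p1 <- withr::local_tempfile(fileext = ".fasta")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(r1$global$rbcL, p1)
  write_reference_fasta(r2$global$rbcL, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(r1$templates, r2$templates)
})

test_that("undersized configurations are rejected", {
  expect_error(sim_config(n_species = 3, n_shared_groups = 2), "n_species")
  expect_error(sim_config(error_rate = 1.5), "rates")
})

test_that("congeneric divergence lands below the identity threshold", {
  ref <- generate_flora_and_dbs(sim_config(seed = 11))
  tax <- ref$taxonomy[ref$taxonomy$in_flora & ref$taxonomy$shared_group == 0, ]
  idents <- c()
  for (m in c("rbcL", "ITS2")) {
    tpl <- ref$templates[[m]]
    for (g in unique(tax$genus)) {
      sp <- tax$species[tax$genus == g]
      if (length(sp) < 2) next
      prs <- utils::combn(sp, 2)
      for (k in seq_len(ncol(prs))) {
        a <- charToRaw(tpl[[prs[1, k]]])
        b <- charToRaw(tpl[[prs[2, k]]])
        idents <- c(idents, 100 * mean(a == b))
      }
    }
  }
  # divergence 0.05 puts congeners near 95% identity, well under 98
  expect_lt(mean(idents), 98)
  expect_gt(mean(idents), 92)
  expect_equal(mean(idents), 95, tolerance = 0.02)
})

test_that("noiseless single-source reads reproduce the template", {
  cfg <- sim_config(per_sample_depth = 50, error_rate = 0,
                    chimera_fraction = 0, contaminant_fraction = 0,
                    n_nonflora_global = 0, seed = 2)
  ref <- generate_flora_and_dbs(cfg)
  sp <- ref$flora$species[10]
  set.seed(1)
  sim <- simulate_sample(stats::setNames(1, sp), ref, cfg, "ITS2")
  tpl <- ref$templates$ITS2[[sp]]
  expect_true(all(sim$fwd == substr(tpl, 1, 300)))
  expect_true(all(sim$rev == substr(rc(tpl), 1, 300)))
  expect_true(all(!sim$meta$chimera))
  expect_error(simulate_sample(numeric(0), ref, cfg, "ITS2"), "empty")
})

test_that("minor diet components appear at their binomial expectation", {
  cfg <- sim_config(per_sample_depth = 10000, error_rate = 0,
                    chimera_fraction = 0, contaminant_fraction = 0,
                    n_nonflora_global = 0, seed = 3)
  ref <- generate_flora_and_dbs(cfg)
  comp <- stats::setNames(c(0.99, 0.01), ref$flora$species[c(1, 10)])
  b_counts <- vapply(1:20, function(s) {
    set.seed(s)
    sim <- simulate_sample(comp, ref, cfg, "rbcL")
    sum(sim$meta$source == ref$flora$species[10])
  }, numeric(1))
  # mean 100, binomial sd ~ sqrt(10000 * .01 * .99) ~ 9.9
  expect_equal(mean(b_counts), 100, tolerance = 3 * 9.95 / sqrt(20) / 100)
  expect_true(all(b_counts > 50) && all(b_counts < 150))
})

test_that("chimeric reads are labelled and match a two-parent splice", {
  cfg <- sim_config(per_sample_depth = 2000, error_rate = 0,
                    chimera_fraction = 0.05, contaminant_fraction = 0,
                    n_nonflora_global = 0, seed = 4)
  ref <- generate_flora_and_dbs(cfg)
  comp <- stats::setNames(c(0.5, 0.5), ref$flora$species[c(10, 15)])
  set.seed(7)
  sim <- simulate_sample(comp, ref, cfg, "rbcL")
  expect_equal(mean(sim$meta$chimera), 0.05, tolerance = 1e-9)
  tpls <- unname(ref$templates$rbcL[ref$flora$species])
  chim_idx <- which(sim$meta$chimera)
  for (i in chim_idx[1:10]) {
    lab <- sim$meta$source[i]
    parents <- strsplit(sub("@.*", "", lab), "+", fixed = TRUE)[[1]]
    bp <- as.integer(sub(".*@", "", lab))
    expected <- paste0(substr(ref$templates$rbcL[[parents[1]]], 1, bp),
                       substr(ref$templates$rbcL[[parents[2]]], bp + 1, 420))
    expect_false(expected %in% tpls)
    expect_equal(sim$fwd[i], substr(expected, 1, 300))
    expect_equal(sim$rev[i], substr(rc(expected), 1, 300))
    expect_true(bp >= 20 && bp <= 400)
  }
})

test_that("paired FASTQ write/read round-trips reads and truth labels", {
  cfg <- sim_config(per_sample_depth = 30, seed = 6)
  ref <- generate_flora_and_dbs(cfg)
  comp <- stats::setNames(c(0.6, 0.4), ref$flora$species[c(7, 8)])
  set.seed(2)
  sim <- simulate_sample(comp, ref, cfg, "ITS2", sample_id = "S09")
  fp <- withr::local_tempfile(fileext = ".fastq")
  rp <- withr::local_tempfile(fileext = ".fastq")
  write_sample_fastq(sim, fp, rp)
  back <- read_sample_fastq(fp, rp)
  expect_equal(back$fwd, sim$fwd)
  expect_equal(back$rev, sim$rev)
  expect_equal(back$meta$source, sim$meta$source)
  expect_equal(back$meta$chimera, sim$meta$chimera)
})
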