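# A small two-database world: three local flora species (two sharing a
# genus), plus a global database that adds a non-flora distractor.
make_world <- function(seed = 21, len = 200) {
  set.seed(seed)
  s1 <- rand_dna(len)
  s2 <- mutate_at(s1, c(30, 80, 150), c("A", "C", "G")) # congener of s1
  s3 <- rand_dna(len)
  s4 <- rand_dna(len) # non-flora distractor
  local <- make_db(data.frame(
    id = c("L1", "L2", "L3"),
    family = c("Ericaceae", "Ericaceae", "Rosaceae"),
    genus = c("Vaccinium", "Vaccinium", "Sorbus"),
    species = c("Vaccinium ovalifolium", "Vaccinium uliginosum",
                "Sorbus commixta"),
    sequence = c(s1, s2, s3), stringsAsFactors = FALSE),
    origin = "local")
  global <- make_db(data.frame(
    id = c("G1", "G2", "G3", "G4"),
    family = c("Ericaceae", "Ericaceae", "Rosaceae", "Poaceae"),
    genus = c("Vaccinium", "Vaccinium", "Sorbus", "Bromus"),
    species = c("Vaccinium ovalifolium", "Vaccinium uliginosum",
                "Sorbus commixta", "Bromus inermis"),
    sequence = c(s1, s2, s3, s4), stringsAsFactors = FALSE),
    origin = "global")
  flora <- make_flora(local$records)
  list(local = local, global = global, flora = flora,
       seqs = c(s1, s2, s3, s4))
}

test_that("database arbitration restricts global hits to the flora first", {
  hit <- function(species, family, genus, bitscore, identity) {
    data.frame(id = "x", family = family, genus = genus, species = species,
               score = 0, bitscore = bitscore, identity = identity,
               length = 100, strand = "+", stringsAsFactors = FALSE)
  }
  flora <- make_flora(data.frame(family = "Ericaceae", genus = "Kalmia",
                                 species = "Kalmia procumbens"))
  lh <- hit("Kalmia procumbens", "Ericaceae", "Kalmia", 400, 99)
  gh_out <- hit("Bromus inermis", "Poaceae", "Bromus", 420, 100)
  # higher-scoring global hit is off-flora: local adopted
  r <- resolve_databases(lh, gh_out, flora)
  expect_equal(r$source, "local")
  expect_equal(r$candidates$species, "Kalmia procumbens")
  # equal scores: local adopted
  gh_tie <- hit("Kalmia procumbens", "Ericaceae", "Kalmia", 400, 99)
  expect_equal(resolve_databases(lh, gh_tie, flora)$source, "local")
  # local empty, admissible flora hit in global: global adopted
  r3 <- resolve_databases(NULL, gh_tie, flora)
  expect_equal(r3$source, "global")
  # both empty (or global entirely off-flora): unassigned
  expect_true(is.na(resolve_databases(NULL, gh_out, flora)$source))
  # stronger global flora hit beats local
  gh_hi <- hit("Kalmia procumbens", "Ericaceae", "Kalmia", 430, 100)
  expect_equal(resolve_databases(lh, gh_hi, flora)$source, "global")
})

test_that("unique best hits give species-rank assignments", {
  w <- make_world()
  a <- assign_asv(w$seqs[3], w$local, w$global, w$flora)
  expect_equal(a$rank, "species")
  expect_equal(a$species, "Sorbus commixta")
  expect_equal(a$source, "local")
  expect_equal(a$identity, 100)
})

test_that("equal-best congeneric hits collapse to the genus", {
  # make the two Vaccinium references identical so the query ties
  set.seed(22)
  s <- rand_dna(200)
  local <- make_db(data.frame(
    id = c("L1", "L2"), family = "Ericaceae", genus = "Vaccinium",
    species = c("Vaccinium shikokianum", "Vaccinium smallii"),
    sequence = c(s, s), stringsAsFactors = FALSE))
  flora <- make_flora(local$records)
  a <- assign_asv(s, local, local, flora)
  expect_equal(a$rank, "genus")
  expect_equal(a$genus, "Vaccinium")
  expect_equal(a$n_tied, 2L)
})

test_that("ties across families are unresolved; no hits are unassigned", {
  set.seed(23)
  s <- rand_dna(200)
  db <- make_db(data.frame(
    id = c("L1", "L2"), family = c("Poaceae", "Rosaceae"),
    genus = c("Poa", "Rubus"), species = c("Poa alpina", "Rubus vernus"),
    sequence = c(s, s), stringsAsFactors = FALSE))
  flora <- make_flora(db$records)
  expect_equal(assign_asv(s, db, db, flora)$rank, "unresolved")
  far <- rand_dna(200)
  expect_equal(assign_asv(far, db, db, flora)$rank, "unassigned")
})

test_that("non-flora global species never win at species rank", {
  w <- make_world()
  # query is exactly the distractor: global's best hit is off-flora and
  # the local alignments are too weak, so the ASV stays unassigned
  a <- assign_asv(w$seqs[4], w$local, w$global, w$flora)
  expect_equal(a$rank, "unassigned")
})

test_that("deleting the global database never changes local-sourced calls", {
  w <- make_world()
  set.seed(24)
  empty_global <- make_db(data.frame(
    id = "Z1", family = "Poaceae", genus = "Bromus",
    species = "Bromus inermis", sequence = rand_dna(200),
    stringsAsFactors = FALSE), origin = "global")
  for (q in w$seqs[1:3]) {
    with_g <- assign_asv(q, w$local, w$global, w$flora)
    without_g <- assign_asv(q, w$local, empty_global, w$flora)
    if (identical(with_g$source, "local")) {
      expect_equal(with_g[c("family", "genus", "species", "rank")],
                   without_g[c("family", "genus", "species", "rank")])
    }
  }
})

test_that("marker merging keeps the lowest taxonomic rank", {
  fam <- taxon("Asteraceae", rank = "family")
  sol <- taxon("Asteraceae", "Solidago", "Solidago virgaurea")
  out <- merge_markers(fam, sol)
  expect_equal(nrow(out), 1)
  expect_equal(out$rank, "species")
  expect_equal(out$species, "Solidago virgaurea")

  vac <- taxon("Ericaceae", "Vaccinium", rank = "genus")
  out2 <- merge_markers(vac, vac)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$rank, "genus")

  spA <- taxon("Rosaceae", "Sorbus", "Sorbus commixta")
  out3 <- merge_markers(spA, NULL)
  expect_equal(out3$species, "Sorbus commixta")

  # unresolved entries drop when any resolved taxon remains
  unres <- taxon(rank = "unresolved")
  out4 <- merge_markers(rbind(spA, unres), NULL)
  expect_equal(out4$rank, "species")
  out5 <- merge_markers(unres, NULL)
  expect_equal(out5$rank, "unresolved")

  # disjoint evidence is a union
  out6 <- merge_markers(spA, sol)
  expect_equal(nrow(out6), 2)
})
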