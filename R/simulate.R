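#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the seeded fixture generator: the size of the
#' synthetic flora, per-marker amplicon lengths, the substitution
#' divergence between congeneric species, how many groups of species
#' share an identical sequence (and therefore can only ever be called
#' at genus rank), how many non-flora distractor species the global
#' database carries, and the read-level noise model (per-base
#' substitution errors, two-parent chimeras, non-flora contaminant
#' reads). All downstream randomness is a pure function of `seed`.
#'
#' @param n_species Number of flora species.
#' @param n_genera Number of genera among flora species.
#' @param n_families Number of families among flora genera.
#' @param marker_lengths Named integer vector of amplicon lengths per
#'   marker. Defaults to 420 (rbcL) and 350 (ITS2); both fit the fixed
#'   200/250 truncation with at least a 12-base merge overlap.
#' @param interspecific_divergence Expected substitution fraction
#'   between congeneric species (pairwise); each species is derived
#'   from its genus ancestor at half this rate.
#' @param n_shared_groups Number of identical-sequence species groups
#'   per marker. Each group occupies a genus of its own.
#' @param shared_group_size Species per identical-sequence group.
#' @param n_nonflora_global Distractor species present only in the
#'   global database (and absent from the flora).
#' @param per_sample_depth Read pairs generated per sample per marker.
#' @param read_length Instrument read length before truncation.
#' @param error_rate Per-base substitution probability, applied
#'   independently to each mate.
#' @param chimera_fraction Fraction of reads spliced from two parent
#'   templates at a uniform interior breakpoint (at least 20 bases from
#'   either end).
#' @param contaminant_fraction Fraction of reads drawn from non-flora
#'   global species.
#' @param seed Integer seed fixing all generator randomness.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 20L, n_genera = 8L, n_families = 4L,
                       marker_lengths = c(rbcL = 420L, ITS2 = 350L),
                       interspecific_divergence = 0.05,
                       n_shared_groups = 2L, shared_group_size = 3L,
                       n_nonflora_global = 5L,
                       per_sample_depth = 5000L, read_length = 300L,
                       error_rate = 0.002, chimera_fraction = 0.05,
                       contaminant_fraction = 0.02, seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_genera = as.integer(n_genera),
              n_families = as.integer(n_families),
              marker_lengths = marker_lengths,
              interspecific_divergence = interspecific_divergence,
              n_shared_groups = as.integer(n_shared_groups),
              shared_group_size = as.integer(shared_group_size),
              n_nonflora_global = as.integer(n_nonflora_global),
              per_sample_depth = as.integer(per_sample_depth),
              read_length = as.integer(read_length),
              error_rate = error_rate,
              chimera_fraction = chimera_fraction,
              contaminant_fraction = contaminant_fraction,
              seed = as.integer(seed))
  fr <- c(cfg$interspecific_divergence, cfg$error_rate,
          cfg$chimera_fraction, cfg$contaminant_fraction)
  if (any(fr < 0 | fr > 1)) stop("rates and fractions must lie in [0, 1]")
  if (cfg$per_sample_depth < 0) stop("per_sample_depth must be >= 0")
  if (cfg$n_species < 2L * cfg$n_shared_groups) {
    stop("n_species must be at least 2 * n_shared_groups")
  }
  if (cfg$n_shared_groups * cfg$shared_group_size > cfg$n_species) {
    stop("shared groups cannot use more species than n_species")
  }
  if (cfg$n_genera < cfg$n_shared_groups + 1L) {
    stop("need at least n_shared_groups + 1 genera")
  }
  if (cfg$n_families > cfg$n_genera) stop("more families than genera")
  if (is.null(names(cfg$marker_lengths)) ||
      !all(nzchar(names(cfg$marker_lengths)))) {
    stop("marker_lengths must be a named vector")
  }
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste(bases, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a synthetic flora and its reference databases
#'
#' Builds a three-level taxonomy (families > genera > species), one
#' random ancestral sequence per genus and marker, and species
#' sequences derived from their genus ancestor by i.i.d. substitutions
#' at half the configured interspecific divergence (no indels, so
#' identity thresholds are exercised cleanly). Each identical-sequence
#' group fills a genus of its own: all of its members receive the same
#' sequence in both markers, as happens for closely related congeners
#' whose barcodes do not diverge. The local database holds exactly the
#' flora; the global database is a superset that adds non-flora
#' distractor species from separate families.
#'
#' @param config A [sim_config()].
#' @return A list with `flora` (flora data frame), `local` and `global`
#'   (per-marker `reference_db` lists), `taxonomy` (species table with
#'   a `shared_group` column; distractors flagged by `in_flora =
#'   FALSE`), and `templates` (per-marker named vectors of amplicon
#'   sequences for all species, flora and distractors).
#' @export
generate_flora_and_dbs <- function(config) {
  set.seed(config$seed)
  markers <- names(config$marker_lengths)
  n_sp <- config$n_species
  n_gen <- config$n_genera
  n_fam <- config$n_families

  genus_names <- sprintf("Genus%02d", seq_len(n_gen))
  family_names <- sprintf("Family%02d", seq_len(n_fam))
  genus_family <- family_names[((seq_len(n_gen) - 1L) %% n_fam) + 1L]

  # Shared groups occupy their own genera (the first n_shared_groups);
  # remaining species are spread round-robin over the other genera.
  sp_genus <- integer(n_sp)
  idx <- 1L
  for (g in seq_len(config$n_shared_groups)) {
    sp_genus[idx:(idx + config$shared_group_size - 1L)] <- g
    idx <- idx + config$shared_group_size
  }
  free_genera <- seq.int(config$n_shared_groups + 1L, n_gen)
  if (idx <= n_sp) {
    sp_genus[idx:n_sp] <- free_genera[
      ((seq_len(n_sp - idx + 1L) - 1L) %% length(free_genera)) + 1L]
  }
  sp_genus <- sort(sp_genus)
  counter <- stats::ave(sp_genus, sp_genus, FUN = seq_along)
  taxonomy <- data.frame(
    id = sprintf("LOC%03d", seq_len(n_sp)),
    family = genus_family[sp_genus],
    genus = genus_names[sp_genus],
    species = sprintf("%s species%02d", genus_names[sp_genus], counter),
    shared_group = ifelse(sp_genus <= config$n_shared_groups, sp_genus, 0L),
    in_flora = TRUE,
    stringsAsFactors = FALSE)

  if (config$n_nonflora_global > 0) {
    nf <- data.frame(
      id = sprintf("GLB%03d", seq_len(config$n_nonflora_global)),
      family = sprintf("ExoticFamily%02d", seq_len(config$n_nonflora_global)),
      genus = sprintf("ExoticGenus%02d", seq_len(config$n_nonflora_global)),
      species = sprintf("ExoticGenus%02d exoticum", seq_len(config$n_nonflora_global)),
      shared_group = 0L, in_flora = FALSE, stringsAsFactors = FALSE)
    taxonomy <- rbind(taxonomy, nf)
  }

  templates <- list()
  for (m in markers) {
    len <- config$marker_lengths[[m]]
    anc <- vapply(genus_names, function(g) random_dna(len), character(1))
    seqs <- character(nrow(taxonomy))
    names(seqs) <- taxonomy$species
    for (i in seq_len(nrow(taxonomy))) {
      if (!taxonomy$in_flora[i]) {
        seqs[i] <- random_dna(len)
      } else if (taxonomy$shared_group[i] > 0L) {
        first <- match(TRUE, taxonomy$shared_group == taxonomy$shared_group[i])
        if (first < i) {
          seqs[i] <- seqs[first]
          next
        }
        seqs[i] <- mutate_dna(anc[[taxonomy$genus[i]]],
                              config$interspecific_divergence / 2)
      } else {
        repeat {
          s <- mutate_dna(anc[[taxonomy$genus[i]]],
                          config$interspecific_divergence / 2)
          if (!s %in% seqs[seq_len(i - 1L)]) break
        }
        seqs[i] <- s
      }
    }
    templates[[m]] <- seqs
  }

  flora <- taxonomy[taxonomy$in_flora,
                    c("family", "genus", "species"), drop = FALSE]
  flora$rank <- "species"
  rownames(flora) <- NULL
  class(flora) <- c("flora_list", "data.frame")

  make_db <- function(rows, marker, origin) {
    rec <- data.frame(id = rows$id, family = rows$family, genus = rows$genus,
                      species = rows$species,
                      sequence = templates[[marker]][rows$species],
                      stringsAsFactors = FALSE)
    rec <- rec[order(rec$id), , drop = FALSE]
    rownames(rec) <- NULL
    rec$group <- match(rec$sequence, unique(rec$sequence))
    structure(list(marker = marker, origin = origin, records = rec,
                   n_rejected = 0L), class = "reference_db")
  }
  local <- lapply(markers, function(m)
    make_db(taxonomy[taxonomy$in_flora, ], m, "local"))
  global <- lapply(markers, function(m) make_db(taxonomy, m, "global"))
  names(local) <- names(global) <- markers

  list(flora = flora, local = local, global = global,
       taxonomy = taxonomy, templates = templates)
}

#' Generate a per-sample diet composition table
#'
#' Draws, for each fecal sample, a handful of flora species with
#' Dirichlet-like mixture proportions. Species receive geometrically
#' decaying base weights so a few taxa dominate across samples, the
#' pattern seen in real fecal collections where one or two shrubs
#' dominate the diet.
#'
#' @param ref Output of [generate_flora_and_dbs()].
#' @param n_samples Number of fecal samples.
#' @param periods Character vector of period labels recycled across
#'   samples.
#' @param min_taxa,max_taxa Range of species per sample.
#' @param seed Integer seed.
#' @return A data frame of class `diet_truth` with columns `sample`,
#'   `period`, `species`, `proportion`; proportions sum to 1 per sample.
#' @export
generate_diet_truth <- function(ref, n_samples = 6L, periods = "P1",
                                min_taxa = 4L, max_taxa = 8L, seed = 1L) {
  set.seed(seed)
  species <- ref$flora$species
  weights <- 0.7^seq_along(species)
  rows <- lapply(seq_len(n_samples), function(i) {
    k <- sample(seq.int(min_taxa, max_taxa), 1)
    sp <- sample(species, k, prob = weights)
    p <- stats::rgamma(k, shape = 2)
    data.frame(sample = sprintf("S%02d", i),
               period = periods[((i - 1L) %% length(periods)) + 1L],
               species = sp, proportion = p / sum(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diet_truth", "data.frame")
  out
}

#' Simulate paired reads for one fecal sample and marker
#'
#' Reads are drawn from species amplicon templates in proportion to the
#' sample's true composition. A configured fraction of reads are
#' two-parent chimeras (spliced at a uniform breakpoint at least 20
#' bases from either template end) and another fraction are
#' contaminants drawn from non-flora global species. Each mate then
#' receives i.i.d. per-base substitution errors. Base qualities are
#' constant (Q37) since downstream trimming is positional. Every read
#' is labelled with its source and chimera status so recovery can be
#' scored against the truth.
#'
#' @param composition Named numeric vector of mixture proportions
#'   (names are flora species present in the templates); must sum to 1.
#' @param ref Output of [generate_flora_and_dbs()].
#' @param config The [sim_config()] used to build `ref`.
#' @param marker Marker name.
#' @param sample_id Sample label used in read ids.
#' @return A list with `fwd`, `rev` (character vectors of read
#'   sequences), `quality` (constant quality character), and `meta`
#'   (data frame with `id`, `source`, `chimera`).
#' @export
simulate_sample <- function(composition, ref, config, marker,
                            sample_id = "S01") {
  if (length(composition) == 0) stop("empty composition")
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("composition proportions must sum to 1")
  }
  tpl <- ref$templates[[marker]]
  if (is.null(tpl)) stop("unknown marker: ", marker)
  missing <- setdiff(names(composition), names(tpl))
  if (length(missing)) stop("composition species not in templates: ",
                            paste(missing, collapse = ", "))
  len <- config$marker_lengths[[marker]]
  depth <- config$per_sample_depth
  n_chim <- round(config$chimera_fraction * depth)
  nonflora <- ref$taxonomy$species[!ref$taxonomy$in_flora]
  n_cont <- if (length(nonflora)) round(config$contaminant_fraction * depth) else 0L
  n_main <- depth - n_chim - n_cont

  src_main <- sample(names(composition), n_main, replace = TRUE,
                     prob = composition)
  templates_out <- tpl[src_main]
  source_lab <- src_main
  chim_flag <- rep(FALSE, n_main)

  if (n_chim > 0) {
    pa <- sample(names(composition), n_chim, replace = TRUE, prob = composition)
    pb <- vapply(pa, function(a) {
      pool <- if (length(composition) > 1) setdiff(names(composition), a)
              else names(composition)
      if (length(pool) == 1) pool else
        sample(pool, 1, prob = composition[pool])
    }, character(1))
    bp <- sample(seq.int(20L, len - 20L), n_chim, replace = TRUE)
    chim_seq <- vapply(seq_len(n_chim), function(i) {
      paste0(substr(tpl[[pa[i]]], 1, bp[i]),
             substr(tpl[[pb[i]]], bp[i] + 1L, len))
    }, character(1))
    templates_out <- c(templates_out, chim_seq)
    source_lab <- c(source_lab, sprintf("%s+%s@%d", pa, pb, bp))
    chim_flag <- c(chim_flag, rep(TRUE, n_chim))
  }
  if (n_cont > 0) {
    src_c <- sample(nonflora, n_cont, replace = TRUE)
    templates_out <- c(templates_out, tpl[src_c])
    source_lab <- c(source_lab, src_c)
    chim_flag <- c(chim_flag, rep(FALSE, n_cont))
  }

  rl <- min(config$read_length, len)
  fwd <- substr(templates_out, 1L, rl)
  rev <- substr(revcomp(templates_out), 1L, rl)
  fwd <- add_read_errors(fwd, config$error_rate)
  rev <- add_read_errors(rev, config$error_rate)
  meta <- data.frame(
    id = sprintf("%s_%s_%05d", sample_id, marker, seq_along(fwd)),
    source = unname(source_lab), chimera = chim_flag,
    stringsAsFactors = FALSE)
  list(fwd = unname(fwd), rev = unname(rev), quality = "F", meta = meta)
}

add_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  for (i in which(n_err > 0)) {
    bases <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(bases), n_err[i])
    for (p in pos) {
      bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
    }
    reads[i] <- paste(bases, collapse = "")
  }
  reads
}

#' Write simulated paired reads as FASTQ
#'
#' Read ids carry the truth labels (`src=` and `chimera=` tags) so that
#' downstream recovery can be scored from the files alone.
#'
#' @param sim Output of [simulate_sample()].
#' @param fwd_path,rev_path Output FASTQ paths for the two mates.
#' @return Invisibly, the two paths.
#' @export
write_sample_fastq <- function(sim, fwd_path, rev_path) {
  ids <- sprintf("%s src=%s chimera=%d", sim$meta$id,
                 gsub(" ", "_", sim$meta$source), as.integer(sim$meta$chimera))
  write_one <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    qual <- Biostrings::BStringSet(strrep(sim$quality, nchar(seqs)))
    writeXStringSet_fastq(x, qual, path)
  }
  write_one(sim$fwd, fwd_path)
  write_one(sim$rev, rev_path)
  invisible(c(fwd_path, rev_path))
}

writeXStringSet_fastq <- function(x, qual, path) {
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
}

#' Read paired FASTQ files back into sequence vectors
#'
#' @param fwd_path,rev_path Paths to the two mate FASTQ files.
#' @return A list with `fwd`, `rev` (character vectors) and `meta`
#'   parsed from the read ids (truth labels when present).
#' @export
read_sample_fastq <- function(fwd_path, rev_path) {
  f <- Biostrings::readDNAStringSet(fwd_path, format = "fastq")
  r <- Biostrings::readDNAStringSet(rev_path, format = "fastq")
  ids <- names(f)
  src <- sub(".*src=([^ ]+).*", "\\1", ids)
  src <- gsub("_", " ", src)
  chim <- grepl("chimera=1", ids)
  list(fwd = unname(as.character(f)), rev = unname(as.character(r)),
       meta = data.frame(id = sub(" .*", "", ids), source = src,
                         chimera = chim, stringsAsFactors = FALSE))
}
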