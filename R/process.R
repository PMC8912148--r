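#' Construct an ASV count table
#'
#' An ASV table is a data frame of unique sequences with positive
#' integer counts, ordered canonically (descending count, then
#' lexicographically by sequence) so that pipeline output does not
#' depend on input read order. Attributes record the sample, marker
#' and processing stage.
#'
#' @param sequence Character vector of unique sequences.
#' @param count Positive integer counts.
#' @param sample,marker,stage Metadata attached as attributes; `stage`
#'   is one of `merged`, `denoised`, `debimerized`, `filtered`,
#'   `rarefied`.
#' @return A data frame of class `asv_table`.
#' @export
asv_table <- function(sequence, count, sample = NA_character_,
                      marker = NA_character_, stage = "merged") {
  stopifnot(length(sequence) == length(count))
  if (anyDuplicated(sequence)) stop("ASV sequences must be unique")
  if (length(count) && any(count <= 0)) stop("ASV counts must be positive")
  ord <- order(-count, sequence)
  out <- data.frame(sequence = sequence[ord],
                    count = as.integer(count[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "sample") <- sample
  attr(out, "marker") <- marker
  attr(out, "stage") <- stage
  class(out) <- c("asv_table", "data.frame")
  out
}

set_stage <- function(tab, stage) {
  attr(tab, "stage") <- stage
  tab
}

#' Truncate read pairs to fixed lengths
#'
#' Forward reads are cut to `fwd_len` bases and reverse reads to
#' `rev_len` bases. Pairs in which either mate is shorter than its
#' target length are discarded (a counted outcome, not an error). The
#' asymmetric defaults reflect fixed, positional truncation chosen
#' from the quality profiles of the two mates.
#'
#' @param fwd,rev Character vectors of mate sequences (same length).
#' @param fwd_len,rev_len Target lengths (defaults 200 and 250).
#' @return List with truncated `fwd`, `rev`, the logical `kept` index
#'   into the input, and `n_discarded`.
#' @export
truncate_pairs <- function(fwd, rev, fwd_len = 200L, rev_len = 250L) {
  stopifnot(length(fwd) == length(rev))
  keep <- nchar(fwd) >= fwd_len & nchar(rev) >= rev_len
  list(fwd = substr(fwd[keep], 1L, fwd_len),
       rev = substr(rev[keep], 1L, rev_len),
       kept = keep, n_discarded = sum(!keep))
}

hamming_raw <- function(a, b) sum(a != b)

#' Merge truncated read pairs by overlap
#'
#' The reverse mate is reverse-complemented and the largest overlap of
#' at least `min_overlap` bases with at most `max_mismatch` mismatches
#' between the forward tail and the reverse-complement head is taken;
#' the merged sequence keeps the forward base at any overlap conflict.
#' Pairs with no admissible overlap fail (counted, not an error).
#'
#' @param fwd,rev Character vectors of truncated mates.
#' @param min_overlap Minimum overlap length (default 12).
#' @param max_mismatch Maximum mismatches tolerated in the overlap
#'   (default 0).
#' @return List with `merged` (character, `NA` for failed pairs) and
#'   `n_failed`.
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 12L, max_mismatch = 0L) {
  stopifnot(length(fwd) == length(rev))
  n <- length(fwd)
  if (n == 0) return(list(merged = character(0), n_failed = 0L))
  rc <- revcomp(rev)
  merged <- rep(NA_character_, n)
  nf <- nchar(fwd)
  nr <- nchar(rc)
  if (max_mismatch == 0 && length(unique(nf)) == 1 &&
      length(unique(nr)) == 1) {
    # Uniform-length fast path: one vectorized equality test per
    # candidate overlap, largest overlap first.
    lf <- nf[1]; lr <- nr[1]
    todo <- seq_len(n)
    for (o in seq.int(min(lf, lr), min_overlap)) {
      if (!length(todo)) break
      hit <- substr(fwd[todo], lf - o + 1L, lf) == substr(rc[todo], 1L, o)
      if (any(hit)) {
        idx <- todo[hit]
        merged[idx] <- paste0(fwd[idx], substr(rc[idx], o + 1L, lr))
        todo <- todo[!hit]
      }
    }
  } else {
    for (i in seq_len(n)) {
      fa <- charToRaw(fwd[i]); ra <- charToRaw(rc[i])
      for (o in seq.int(min(nf[i], nr[i]), min_overlap)) {
        mm <- hamming_raw(fa[(nf[i] - o + 1L):nf[i]], ra[1:o])
        if (mm <= max_mismatch) {
          merged[i] <- paste0(fwd[i], substr(rc[i], o + 1L, nr[i]))
          break
        }
      }
    }
  }
  list(merged = merged, n_failed = sum(is.na(merged)))
}

#' Dereplicate merged reads and denoise into ASVs
#'
#' Unique sequences are counted, then low-abundance uniques are
#' absorbed into near-identical high-abundance parents: a unique is
#' absorbed when a distinct unique of the same length within Hamming
#' distance `max_hamming` carries at least `parent_ratio` times its
#' count (the largest such parent wins; ties break to the
#' lexicographically smaller sequence). Absorption iterates to a fixed
#' point. This ratio/Hamming rule keeps the single-nucleotide
#' resolution of ASV denoising: a genuine one-base variant survives as
#' its own ASV whenever its abundance is within a factor
#' `parent_ratio` of its neighbour.
#'
#' @param merged Character vector of merged reads (NAs ignored), or an
#'   `asv_table` of pre-counted uniques.
#' @param parent_ratio Minimum parent/child count ratio for absorption
#'   (default 10).
#' @param max_hamming Maximum Hamming distance to a parent (default 1).
#' @param sample,marker Metadata for the returned table.
#' @return An `asv_table` at stage `denoised`.
#' @export
dereplicate_denoise <- function(merged, parent_ratio = 10, max_hamming = 1L,
                                sample = NA_character_,
                                marker = NA_character_) {
  if (inherits(merged, "asv_table")) {
    seqs <- merged$sequence
    cnt <- merged$count
  } else {
    merged <- merged[!is.na(merged)]
    if (length(merged) == 0) stop("no merged reads to denoise")
    tab <- table(merged)
    seqs <- names(tab)
    cnt <- as.integer(tab)
  }
  raws <- lapply(seqs, charToRaw)
  lens <- nchar(seqs)
  repeat {
    ord <- order(cnt, seqs) # ascending abundance: children first
    absorbed <- FALSE
    for (ci in ord) {
      if (cnt[ci] == 0L) next
      cand <- which(cnt >= parent_ratio * cnt[ci] & lens == lens[ci])
      cand <- cand[cand != ci]
      if (!length(cand)) next
      d <- vapply(cand, function(j) hamming_raw(raws[[ci]], raws[[j]]),
                  integer(1))
      cand <- cand[d <= max_hamming]
      if (!length(cand)) next
      best <- cand[order(-cnt[cand], seqs[cand])][1]
      cnt[best] <- cnt[best] + cnt[ci]
      cnt[ci] <- 0L
      absorbed <- TRUE
    }
    if (!absorbed) break
    keep <- cnt > 0L
    seqs <- seqs[keep]; cnt <- cnt[keep]
    raws <- raws[keep]; lens <- lens[keep]
  }
  asv_table(seqs, cnt, sample = sample, marker = marker, stage = "denoised")
}

lcp_len <- function(a, b) {
  m <- min(length(a), length(b))
  if (m == 0L) return(0L)
  d <- which(a[seq_len(m)] != b[seq_len(m)])
  if (length(d)) d[1] - 1L else m
}

#' Remove two-parent chimeric ASVs (bimeras)
#'
#' An ASV is removed when two distinct other ASVs, each with at least
#' `min_parent_ratio` times its count, can be spliced at a breakpoint
#' at least `min_flank` bases from both ends so that the candidate's
#' prefix exactly matches one parent and its suffix exactly matches
#' the other. This is the de novo two-parent model of PCR chimera
#' formation.
#'
#' @param tab An `asv_table` (stage `denoised`).
#' @param min_parent_ratio Parent/candidate abundance ratio (default 2).
#' @param min_flank Minimum distance of the breakpoint from either end
#'   (default 20 bases).
#' @return The table with bimeras removed, at stage `debimerized`;
#'   attribute `"n_bimeras"` counts removals.
#' @export
remove_bimeras <- function(tab, min_parent_ratio = 2, min_flank = 20L) {
  n <- nrow(tab)
  if (n < 3L) {
    out <- set_stage(tab, "debimerized")
    attr(out, "n_bimeras") <- 0L
    return(out)
  }
  raws <- lapply(tab$sequence, charToRaw)
  revs <- lapply(raws, rev)
  lens <- nchar(tab$sequence)
  is_bimera <- logical(n)
  for (ci in seq_len(n)) {
    parents <- which(tab$count >= min_parent_ratio * tab$count[ci])
    parents <- parents[parents != ci]
    if (length(parents) < 2L) next
    pl <- vapply(parents, function(j) lcp_len(raws[[ci]], raws[[j]]), integer(1))
    sl <- vapply(parents, function(j) lcp_len(revs[[ci]], revs[[j]]), integer(1))
    L <- lens[ci]
    hi <- pmin(pl, L - min_flank)   # latest admissible breakpoint per prefix parent
    lo <- pmax(min_flank, L - sl)   # earliest admissible breakpoint per suffix parent
    # A splice exists iff some distinct pair (a, b) has lo[b] <= hi[a];
    # checking the best prefix parent against the best suffix parent
    # (and the runners-up when they coincide) covers all pairs.
    a1 <- which.max(hi)
    b1 <- which.min(lo)
    feasible <- function(a, b) {
      length(a) == 1 && length(b) == 1 && a != b &&
        hi[a] >= min_flank && lo[b] <= L - min_flank && lo[b] <= hi[a]
    }
    if (a1 != b1) {
      is_bimera[ci] <- feasible(a1, b1)
    } else if (length(parents) >= 2L) {
      a2 <- order(hi, decreasing = TRUE)[2]
      b2 <- order(lo)[2]
      is_bimera[ci] <- feasible(a1, b2) || feasible(a2, b1)
    }
  }
  out <- asv_table(tab$sequence[!is_bimera], tab$count[!is_bimera],
                   sample = attr(tab, "sample"), marker = attr(tab, "marker"),
                   stage = "debimerized")
  attr(out, "n_bimeras") <- sum(is_bimera)
  out
}

#' Remove low-frequency ASVs
#'
#' ASVs contributing strictly less than `min_frac` of the table's total
#' count are excluded, in a single pass against the pre-filter total.
#'
#' @param tab An `asv_table`.
#' @param min_frac Minimum relative abundance retained (default 0.01,
#'   i.e. the 1 percent rule).
#' @return Filtered `asv_table` at stage `filtered`.
#' @export
abundance_filter <- function(tab, min_frac = 0.01) {
  total <- sum(tab$count)
  keep <- tab$count / total >= min_frac
  asv_table(tab$sequence[keep], tab$count[keep],
            sample = attr(tab, "sample"), marker = attr(tab, "marker"),
            stage = "filtered")
}

#' Rarefy an ASV table to a fixed depth
#'
#' Subsamples the counts without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, normalizing sequencing
#' effort across samples. Tables whose total is below `depth` cannot be
#' rarefied and are returned flagged as excluded.
#'
#' @param tab An `asv_table`.
#' @param depth Rarefaction depth (default 1000).
#' @param seed Optional integer seed for reproducible subsampling.
#' @return Rarefied `asv_table` at stage `rarefied`; if the table is
#'   too shallow it is returned unchanged with attribute
#'   `"excluded" = TRUE`.
#' @export
rarefy_table <- function(tab, depth = 1000L, seed = NULL) {
  if (depth <= 0) stop("depth must be positive")
  total <- sum(tab$count)
  if (total < depth) {
    attr(tab, "excluded") <- TRUE
    return(tab)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(tab$count, nrow = 1, dimnames = list(NULL, tab$sequence))
  # rrarefy warns when every count exceeds 1 (it suspects non-count
  # data); ASV tables are genuine counts, so the warning is spurious.
  r <- as.integer(suppressWarnings(vegan::rrarefy(m, depth)))
  keep <- r > 0L
  out <- asv_table(tab$sequence[keep], r[keep],
                   sample = attr(tab, "sample"), marker = attr(tab, "marker"),
                   stage = "rarefied")
  attr(out, "excluded") <- FALSE
  out
}

#' Expected ASV richness under read-level rarefaction
#'
#' Exact hypergeometric expectation of the number of distinct ASVs in
#' a random subsample of `m` reads:
#' `E[S_m] = sum_i (1 - choose(N - N_i, m) / choose(N, m))`.
#'
#' @param counts Integer vector of per-ASV read counts.
#' @param depths Subsample sizes (each must not exceed the total).
#' @return Numeric vector of expected richness, one per depth.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths > N)) stop("rarefaction depth exceeds total count")
  if (any(depths < 1)) stop("rarefaction depth must be at least 1")
  vapply(depths, function(m) {
    sum(1 - exp(lchoose(N - counts, m) - lchoose(N, m)))
  }, numeric(1))
}

#' Run the full read-processing chain for one sample and marker
#'
#' Truncate, merge, denoise, remove bimeras, apply the relative
#' abundance filter and rarefy, with per-stage read accounting.
#'
#' @param fwd,rev Raw mate sequences.
#' @param sample,marker Metadata labels.
#' @param fwd_len,rev_len Truncation lengths.
#' @param min_overlap,max_mismatch Merge parameters.
#' @param parent_ratio,max_hamming Denoiser parameters.
#' @param min_frac Relative-abundance threshold.
#' @param depth Rarefaction depth.
#' @param seed Optional seed for the rarefaction draw.
#' @return List with the final `table` (or `NULL` when the sample fails
#'   the rarefaction depth), `excluded` flag, all intermediate stage
#'   tables in `stages`, and a read-accounting `log`.
#' @export
process_sample_reads <- function(fwd, rev, sample = NA_character_,
                                 marker = NA_character_,
                                 fwd_len = 200L, rev_len = 250L,
                                 min_overlap = 12L, max_mismatch = 0L,
                                 parent_ratio = 10, max_hamming = 1L,
                                 min_frac = 0.01, depth = 1000L,
                                 seed = NULL) {
  tr <- truncate_pairs(fwd, rev, fwd_len, rev_len)
  mg <- merge_pairs(tr$fwd, tr$rev, min_overlap, max_mismatch)
  merged <- mg$merged[!is.na(mg$merged)]
  if (length(merged) == 0) {
    return(list(table = NULL, excluded = TRUE, stages = list(),
                log = list(input = length(fwd),
                           discarded_short = tr$n_discarded,
                           merge_failed = mg$n_failed, merged = 0L)))
  }
  den <- dereplicate_denoise(merged, parent_ratio, max_hamming,
                             sample = sample, marker = marker)
  deb <- remove_bimeras(den)
  fil <- abundance_filter(deb, min_frac)
  rar <- rarefy_table(fil, depth, seed = seed)
  excluded <- isTRUE(attr(rar, "excluded"))
  log <- list(input = length(fwd),
              discarded_short = tr$n_discarded,
              merge_failed = mg$n_failed,
              merged = length(merged),
              denoised_asvs = nrow(den),
              bimeras_removed = attr(deb, "n_bimeras"),
              filtered_asvs = nrow(fil),
              rarefied = !excluded)
  list(table = if (excluded) NULL else rar, excluded = excluded,
       stages = list(denoised = den, debimerized = deb, filtered = fil,
                     rarefied = if (excluded) NULL else rar),
       log = log)
}
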