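#' Arbitrate between local and global database hits
#'
#' Global hits are restricted to flora species before any comparison,
#' so a spurious out-of-region top hit cannot mask a valid regional
#' one. The best local and best flora-restricted global hits are then
#' compared by bitscore, with identity as tie-break; a full tie is
#' adopted from the local database (the curated database wins ties).
#' All hits of the winning database attaining its top bitscore are
#' returned: equal-score ties feed the lowest-common-ancestor collapse.
#'
#' @param local_hits,global_hits Threshold-filtered hit data frames
#'   (see [threshold_filter()]); either may be empty or `NULL`.
#' @param flora A flora list; applied to `global_hits`.
#' @return A list with `candidates` (data frame of winning-tie hits;
#'   zero rows when unassigned) and `source` (`"local"`, `"global"` or
#'   `NA` when unassigned).
#' @export
resolve_databases <- function(local_hits, global_hits, flora) {
  empty <- function(h) is.null(h) || nrow(h) == 0
  if (!empty(global_hits)) {
    global_hits <- global_hits[in_flora(global_hits, flora), , drop = FALSE]
  }
  if (empty(local_hits) && empty(global_hits)) {
    return(list(candidates = NULL, source = NA_character_))
  }
  best <- function(h) {
    h <- h[order(-h$bitscore, -h$identity), , drop = FALSE]
    h[1, ]
  }
  use_local <- if (empty(global_hits)) TRUE
  else if (empty(local_hits)) FALSE
  else {
    bl <- best(local_hits); bg <- best(global_hits)
    if (bl$bitscore != bg$bitscore) bl$bitscore > bg$bitscore
    else if (bl$identity != bg$identity) bl$identity > bg$identity
    else TRUE # full tie: the local database is adopted
  }
  hits <- if (use_local) local_hits else global_hits
  top <- max(hits$bitscore)
  list(candidates = hits[hits$bitscore >= top - 1e-9, , drop = FALSE],
       source = if (use_local) "local" else "global")
}

#' Assign one ASV to a taxon
#'
#' Scores the ASV against the local and global databases, applies the
#' identity/bitscore thresholds, arbitrates between databases (local
#' wins ties; global hits restricted to the flora), and collapses
#' equal-score ties to their lowest common ancestor. An ASV tied
#' between families is recorded as unresolved; an ASV with no
#' admissible hit is unassigned.
#'
#' @param seq The ASV sequence (character).
#' @param local_db,global_db `reference_db` objects for one marker.
#' @param flora A flora list.
#' @param scheme A [scoring_scheme()].
#' @param min_identity,min_bitscore Hit admission thresholds.
#' @return A one-row data frame: `family`, `genus`, `species`, `rank`
#'   (or rank `"unassigned"`), `source`, `identity`, `bitscore`,
#'   `n_tied`.
#' @export
assign_asv <- function(seq, local_db, global_db, flora,
                       scheme = scoring_scheme(),
                       min_identity = 98, min_bitscore = 300) {
  lh <- threshold_filter(score_against_db(seq, local_db, scheme),
                         min_identity, min_bitscore)
  gh <- threshold_filter(score_against_db(seq, global_db, scheme),
                         min_identity, min_bitscore)
  res <- resolve_databases(lh, gh, flora)
  if (is.null(res$candidates)) {
    return(data.frame(family = "", genus = "", species = "",
                      rank = "unassigned", source = NA_character_,
                      identity = NA_real_, bitscore = NA_real_,
                      n_tied = 0L, stringsAsFactors = FALSE))
  }
  cand <- res$candidates
  cand$rank <- "species"
  lca <- ambiguity_lca(cand[, c("family", "genus", "species", "rank")])
  data.frame(lca, source = res$source,
             identity = max(cand$identity), bitscore = max(cand$bitscore),
             n_tied = nrow(unique(cand[, c("family", "genus", "species")])),
             stringsAsFactors = FALSE)
}

#' Assign every ASV of a rarefied table
#'
#' @param tab An `asv_table`.
#' @param local_db,global_db `reference_db` objects for the table's
#'   marker.
#' @param flora A flora list.
#' @param scheme A [scoring_scheme()].
#' @param min_identity,min_bitscore Hit admission thresholds.
#' @return A data frame with one row per ASV (columns of
#'   [assign_asv()] plus `sequence`, `count`, `sample`, `marker`).
#' @export
assign_table <- function(tab, local_db, global_db, flora,
                         scheme = scoring_scheme(),
                         min_identity = 98, min_bitscore = 300) {
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    a <- assign_asv(tab$sequence[i], local_db, global_db, flora,
                    scheme, min_identity, min_bitscore)
    cbind(data.frame(sample = attr(tab, "sample"),
                     marker = attr(tab, "marker"),
                     sequence = tab$sequence[i], count = tab$count[i],
                     stringsAsFactors = FALSE), a)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

is_strict_ancestor <- function(anc, taxa) {
  # TRUE when `anc` (one row) is a genus- or family-rank ancestor of
  # any *other* row in `taxa`.
  if (anc$rank == "genus") {
    any(taxa$rank == "species" & taxa$genus == anc$genus &
          taxa$family == anc$family)
  } else if (anc$rank == "family") {
    any(taxa$rank %in% c("species", "genus") & taxa$family == anc$family)
  } else {
    FALSE
  }
}

#' Merge per-marker taxon sets at the lowest taxonomic rank
#'
#' The union of the two markers' per-sample assignments is taken, then
#' any taxon that is a strict ancestor (genus or family) of another
#' retained taxon is dropped: when one marker resolves a plant only to
#' family and the other resolves it to species, the species-rank call
#' is kept. Unresolved entries are dropped whenever any resolved taxon
#' remains, otherwise reported as-is.
#'
#' @param rbcl_taxa,its2_taxa Data frames of per-sample taxa (columns
#'   `family`, `genus`, `species`, `rank`); either may be `NULL` or
#'   empty.
#' @return Data frame of the merged per-sample taxon set.
#' @export
merge_markers <- function(rbcl_taxa, its2_taxa) {
  cols <- c("family", "genus", "species", "rank")
  none <- data.frame(family = character(0), genus = character(0),
                     species = character(0), rank = character(0),
                     stringsAsFactors = FALSE)
  pick <- function(x) {
    if (is.null(x) || nrow(x) == 0) none else x[, cols, drop = FALSE]
  }
  merged <- unique(rbind(pick(rbcl_taxa), pick(its2_taxa)))
  if (nrow(merged) == 0) return(merged)
  if (any(merged$rank != "unresolved")) {
    merged <- merged[merged$rank != "unresolved", , drop = FALSE]
  }
  keep <- vapply(seq_len(nrow(merged)), function(i) {
    !is_strict_ancestor(merged[i, ], merged[-i, , drop = FALSE])
  }, logical(1))
  out <- merged[keep, , drop = FALSE]
  out <- out[order(out$family, out$genus, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}
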