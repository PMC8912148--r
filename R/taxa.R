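#' Construct a taxon record
#'
#' A taxon is a one-row data frame with columns `family`, `genus`,
#' `species` and `rank`. The taxonomy is a strict three-level tree
#' (family > genus > species); infraspecific epithets stay inside the
#' species string. `rank` is one of `"species"`, `"genus"`, `"family"`
#' or `"unresolved"`.
#'
#' @param family Family name (non-empty for any resolved rank).
#' @param genus Genus name; empty for family-rank or unresolved taxa.
#' @param species Species epithet (may carry infraspecific parts);
#'   empty unless `rank` is `"species"`.
#' @param rank Taxonomic rank. Inferred from the deepest non-empty
#'   field when missing.
#' @return A one-row data frame with columns `family`, `genus`,
#'   `species`, `rank`.
#' @export
#' @examples
#' taxon("Ericaceae", "Vaccinium", "Vaccinium ovalifolium")
#' taxon("Asteraceae", rank = "family")
taxon <- function(family = "", genus = "", species = "", rank = NULL) {
  if (is.null(rank)) {
    rank <- if (nzchar(species)) "species"
    else if (nzchar(genus)) "genus"
    else if (nzchar(family)) "family"
    else "unresolved"
  }
  rank <- match.arg(rank, c("species", "genus", "family", "unresolved"))
  if (rank == "species" && !nzchar(species)) {
    stop("species-rank taxon requires a non-empty species name")
  }
  if (rank == "family") genus <- ""
  if (rank %in% c("genus", "family")) species <- ""
  if (rank == "unresolved") {
    family <- ""
    genus <- ""
    species <- ""
  }
  data.frame(family = family, genus = genus, species = species,
             rank = rank, stringsAsFactors = FALSE)
}

#' Human-readable label for taxa
#'
#' Species-rank taxa are labelled by their species string, genus-rank
#' taxa as `"<genus> sp."`, family-rank taxa by the family name and
#' unresolved taxa as `"unresolved"`.
#'
#' @param taxa Data frame with columns `family`, `genus`, `species`, `rank`.
#' @return Character vector of labels, one per row.
#' @export
taxon_label <- function(taxa) {
  vapply(seq_len(nrow(taxa)), function(i) {
    switch(taxa$rank[i],
      species = taxa$species[i],
      genus = paste(taxa$genus[i], "sp."),
      family = taxa$family[i],
      unresolved = "unresolved")
  }, character(1))
}

rank_level <- function(rank) {
  match(rank, c("unresolved", "family", "genus", "species"))
}

#' Lowest common ancestor of a set of taxa
#'
#' Collapses a set of tied candidate taxa to the lowest rank that
#' contains all of them: a single distinct taxon is returned as-is,
#' congeners collapse to their genus, confamilial taxa to their family,
#' and anything spanning several families is unresolved. This is the
#' rule applied when a sequence matches two or more references with
#' the same score.
#'
#' @param taxa Data frame of candidate taxa (columns `family`, `genus`,
#'   `species`, `rank`), typically species-rank reference records.
#' @return A one-row taxon data frame (see [taxon()]).
#' @export
#' @examples
#' vac <- rbind(
#'   taxon("Ericaceae", "Vaccinium", "Vaccinium shikokianum"),
#'   taxon("Ericaceae", "Vaccinium", "Vaccinium uliginosum"))
#' ambiguity_lca(vac) # genus Vaccinium
ambiguity_lca <- function(taxa) {
  if (is.null(taxa) || nrow(taxa) == 0) {
    stop("ambiguity_lca() requires a non-empty set of taxa")
  }
  taxa <- unique(taxa[, c("family", "genus", "species", "rank")])
  if (nrow(taxa) == 1) {
    return(taxa)
  }
  # The LCA rank is bounded above by the shallowest input rank: a
  # genus-rank candidate can never yield a species-rank consensus.
  max_rank <- min(rank_level(taxa$rank))
  genera <- unique(taxa$genus[nzchar(taxa$genus)])
  families <- unique(taxa$family[nzchar(taxa$family)])
  all_genus <- all(nzchar(taxa$genus)) && length(genera) == 1
  all_family <- all(nzchar(taxa$family)) && length(families) == 1
  if (all_genus && max_rank >= rank_level("genus")) {
    return(taxon(taxa$family[1], genera, rank = "genus"))
  }
  if (all_family && max_rank >= rank_level("family")) {
    return(taxon(families, rank = "family"))
  }
  taxon(rank = "unresolved")
}
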