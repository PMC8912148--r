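#' Nucleotide local-alignment scoring scheme
#'
#' Raw Smith-Waterman scores are converted to bitscores with the
#' standard Karlin-Altschul normalization
#' `B = (lambda * S - ln K) / ln 2`. The defaults are the classic
#' megablast-style nucleotide parameters (match +2, mismatch -3, gap
#' open 5, gap extend 2, lambda 0.625, K 0.41), so the conventional
#' 300-bit reporting threshold keeps its usual meaning.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening penalty (positive; a gap of length k
#'   costs `gap_open + k * gap_extend`).
#' @param gap_extend Gap extension penalty per base (positive).
#' @param lambda,K Karlin-Altschul parameters for the bitscore.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2, lambda = 0.625, K = 0.41) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Convert a raw alignment score to a bitscore
#'
#' @param score Raw local-alignment score(s).
#' @param scheme A [scoring_scheme()].
#' @return Bitscore(s): `(lambda * score - ln K) / ln 2`.
#' @export
bitscore <- function(score, scheme = scoring_scheme()) {
  (scheme$lambda * score - log(scheme$K)) / log(2)
}

submat_for <- function(scheme) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = scheme$match, mismatch = scheme$mismatch, baseOnly = TRUE)
}

#' Optimal local alignment of two sequences
#'
#' Affine-gap Smith-Waterman alignment of a single query/subject pair
#' under a [scoring_scheme()], optionally searching both strands of
#' the query (the better orientation wins).
#'
#' @param query,subject DNA sequences (character).
#' @param scheme A [scoring_scheme()].
#' @param both_strands Also align the reverse complement of the query
#'   (default FALSE).
#' @return A one-row data frame with `score`, `bitscore`, `identity`
#'   (percent matching columns over the local alignment), `length`
#'   (alignment columns) and `strand`.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        both_strands = FALSE) {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  mat <- submat_for(scheme)
  run <- function(q) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(q),
      subject = Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = mat,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    data.frame(score = Biostrings::score(aln),
               identity = Biostrings::pid(aln, type = "PID1"),
               length = Biostrings::nchar(aln))
  }
  hit <- run(query)
  hit$strand <- "+"
  if (both_strands) {
    minus <- run(revcomp(query))
    minus$strand <- "-"
    if (minus$score > hit$score) hit <- minus
  }
  hit$bitscore <- bitscore(hit$score, scheme)
  hit[, c("score", "bitscore", "identity", "length", "strand")]
}

#' Score a query against every record of a reference database
#'
#' Optimal affine-gap local (Smith-Waterman) alignment of the query
#' against each reference sequence, on both strands when
#' `both_strands`; per reference the better orientation is kept.
#' Identity is the percentage of matching columns over the optimal
#' local alignment's columns (internal gaps included).
#'
#' @param query A single DNA sequence (character).
#' @param db A `reference_db`.
#' @param scheme A [scoring_scheme()].
#' @param both_strands Search the reverse complement too (default TRUE).
#' @return A data frame with one row per reference record: `id`,
#'   `family`, `genus`, `species`, `score`, `bitscore`, `identity`,
#'   `length` (aligned query span), `strand`.
#' @export
score_against_db <- function(query, db, scheme = scoring_scheme(),
                             both_strands = TRUE) {
  stopifnot(nchar(query) > 0)
  subjects <- Biostrings::DNAStringSet(db$records$sequence)
  mat <- submat_for(scheme)
  run <- function(q) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = subjects, subject = Biostrings::DNAString(q),
      type = "local", substitutionMatrix = mat,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    data.frame(score = Biostrings::score(aln),
               identity = Biostrings::pid(aln, type = "PID1"),
               length = Biostrings::nchar(aln))
  }
  plus <- run(query)
  plus$strand <- "+"
  best <- plus
  if (both_strands) {
    minus <- run(revcomp(query))
    minus$strand <- "-"
    take <- minus$score > plus$score
    best[take, ] <- minus[take, ]
  }
  out <- cbind(db$records[, c("id", "family", "genus", "species")], best)
  out$bitscore <- bitscore(out$score, scheme)
  rownames(out) <- NULL
  out[, c("id", "family", "genus", "species", "score", "bitscore",
          "identity", "length", "strand")]
}

#' Filter alignment hits on identity and bitscore
#'
#' Hits with identity below `min_identity` percent or bitscore below
#' `min_bitscore` are excluded; both boundaries are inclusive.
#'
#' @param hits Data frame from [score_against_db()].
#' @param min_identity Minimum percent identity (default 98).
#' @param min_bitscore Minimum bitscore (default 300).
#' @return The retained rows.
#' @export
threshold_filter <- function(hits, min_identity = 98, min_bitscore = 300) {
  eps <- 1e-9
  hits[hits$identity >= min_identity - eps &
         hits$bitscore >= min_bitscore - eps, , drop = FALSE]
}
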