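pairwise_rank_z <- function(xi, xj) {
  # Standardized Wilcoxon rank-sum statistic with mid-ranks and the
  # tie-corrected variance, for one pair of groups.
  ni <- length(xi)
  nj <- length(xj)
  N <- ni + nj
  r <- rank(c(xi, xj))
  W <- sum(r[seq_len(ni)])
  E <- ni * (N + 1) / 2
  V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(0)
  (W - E) / sqrt(V)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups, the two groups are pooled and mid-ranked,
#' the standardized rank-sum statistic `z` is computed with the
#' tie-corrected variance, and the two-sided p-value is referred to
#' the studentized range distribution with `k` groups and infinite
#' degrees of freedom: `p = P(Q_{k,Inf} >= sqrt(2) |z|)`. This is the
#' asymptotic version of the procedure, appropriate for moderate group
#' sizes with ties; the family-wise error across all pairs is
#' controlled at the nominal level.
#'
#' @param values Numeric vector of observations (e.g. per-sample taxon
#'   counts).
#' @param groups Group labels, same length as `values`; at least 2
#'   groups with at least 2 observations each.
#' @param alpha Significance level for the `signif` flag.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p`, `signif`.
#' @export
#' @examples
#' x <- c(rnorm(10), rnorm(10, 2), rnorm(10))
#' g <- rep(c("a", "b", "c"), each = 10)
#' steel_dwass(x, g)
steel_dwass <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  split_x <- split(values, groups)
  k <- length(split_x)
  if (k < 2) stop("need at least 2 groups")
  small <- names(split_x)[lengths(split_x) < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  }
  labs <- names(split_x)
  pairs <- utils::combn(labs, 2)
  rows <- apply(pairs, 2, function(pr) {
    z <- pairwise_rank_z(split_x[[pr[1]]], split_x[[pr[2]]])
    p <- stats::ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2], z = z, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$signif <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Permutation reference for the Steel-Dwass comparison
#'
#' Monte-Carlo oracle: group labels are permuted `B` times and, for
#' each permutation, the maximum over all pairs of the absolute
#' standardized pairwise rank statistic is recorded. Each observed
#' pair's p-value is the tail probability of that max-statistic null
#' distribution, which is the resampling analogue of the studentized
#' range reference used by [steel_dwass()].
#'
#' @param values,groups As in [steel_dwass()].
#' @param B Number of permutations (at least 1000).
#' @param seed Integer seed.
#' @return Data frame with `group1`, `group2`, `z` (observed), `p`
#'   (Monte-Carlo, with the add-one correction).
#' @export
steel_dwass_permutation <- function(values, groups, B = 10000L, seed = 1L) {
  if (B < 1000) stop("B must be at least 1000")
  groups <- as.character(groups)
  split_x <- split(values, groups)
  labs <- names(split_x)
  sizes <- lengths(split_x)
  pairs <- utils::combn(labs, 2)
  obs <- apply(pairs, 2, function(pr) {
    abs(pairwise_rank_z(split_x[[pr[1]]], split_x[[pr[2]]]))
  })
  set.seed(seed)
  maxz <- vapply(seq_len(B), function(b) {
    perm <- sample(values)
    # slice the permuted pool into the original group sizes
    px <- list()
    off <- 0L
    for (g in labs) {
      px[[g]] <- perm[(off + 1L):(off + sizes[[g]])]
      off <- off + sizes[[g]]
    }
    max(apply(pairs, 2, function(pr) {
      abs(pairwise_rank_z(px[[pr[1]]], px[[pr[2]]]))
    }))
  }, numeric(1))
  p <- vapply(obs, function(z) (1 + sum(maxz >= z - 1e-12)) / (B + 1),
              numeric(1))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = obs, p = p,
             stringsAsFactors = FALSE)
}
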