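#' Build a sample-by-taxon incidence matrix
#'
#' Detection is binary: a taxon is present in a sample when it appears
#' in the sample's final merged taxon set. Genus- and family-rank taxa
#' are columns in their own right. Samples with empty sets contribute
#' zero rows (they still count as sampling units).
#'
#' @param sample_sets Named list of character vectors of taxon labels,
#'   one per sample.
#' @param period Optional period label stored as an attribute.
#' @return Binary integer matrix (samples x taxa) of class
#'   `incidence_matrix`, taxa in sorted order.
#' @export
build_incidence <- function(sample_sets, period = NA_character_) {
  if (is.null(names(sample_sets)) || anyDuplicated(names(sample_sets))) {
    stop("sample_sets must be a uniquely named list")
  }
  taxa <- sort(unique(unlist(sample_sets, use.names = FALSE)))
  m <- matrix(0L, nrow = length(sample_sets), ncol = length(taxa),
              dimnames = list(names(sample_sets), taxa))
  for (i in seq_along(sample_sets)) {
    m[i, match(unique(sample_sets[[i]]), taxa)] <- 1L
  }
  attr(m, "period") <- period
  class(m) <- c("incidence_matrix", class(m))
  m
}

#' Incidence frequencies and their summary counts
#'
#' From a binary incidence matrix (or directly from incidence
#' frequencies), computes the quantities that drive all
#' incidence-based estimators: per-taxon detection counts `Y`, the
#' number of sampling units `T`, total incidences `U = sum(Y)`, and
#' the numbers of taxa detected in exactly one (`Q1`) and exactly two
#' (`Q2`) sampling units.
#'
#' @param x An `incidence_matrix`, or a numeric vector of incidence
#'   frequencies (then `n_units` is required).
#' @param n_units Number of sampling units when `x` is a vector.
#' @return List with `Y`, `T`, `U`, `Q1`, `Q2`, `richness`.
#' @export
incidence_stats <- function(x, n_units = NULL) {
  if (inherits(x, "incidence_matrix") || is.matrix(x)) {
    Y <- colSums(x > 0)
    T_ <- nrow(x)
  } else {
    if (is.null(n_units)) stop("n_units required for a frequency vector")
    Y <- x
    T_ <- n_units
  }
  Y <- Y[Y > 0]
  if (any(Y > T_)) stop("incidence frequency exceeds number of units")
  list(Y = unname(Y), T = T_, U = sum(Y),
       Q1 = sum(Y == 1), Q2 = sum(Y == 2), richness = length(Y))
}

#' Incidence-based sample coverage
#'
#' The Chao incidence-data coverage estimator
#' `C = 1 - (Q1/U) * ((T-1) Q1 / ((T-1) Q1 + 2 Q2))`:
#' the estimated fraction of the total incidence probability accounted
#' for by the taxa already detected. With no uniques (`Q1 = 0`) the
#' survey is judged complete and coverage is 1.
#'
#' @param x Incidence frequencies or an `incidence_matrix`.
#' @param n_units Number of sampling units when `x` is a vector.
#' @return Coverage estimate in `[0, 1]`.
#' @export
#' @examples
#' sample_coverage(c(4, 1, 4, 14, 3, 7, 2, 5, 8, 6, 3, 1, 2, 2, 2),
#'                 n_units = 17) # 0.975
sample_coverage <- function(x, n_units = NULL) {
  s <- incidence_stats(x, n_units)
  if (s$U == 0) stop("no incidences: coverage undefined")
  if (s$Q1 == 0) return(1)
  1 - (s$Q1 / s$U) * ((s$T - 1) * s$Q1 / ((s$T - 1) * s$Q1 + 2 * s$Q2))
}

#' Observed Hill-Shannon diversity of incidence data
#'
#' The exponential of the Shannon entropy of the relative incidences
#' `Y_i / U`: the effective number of equally frequent taxa. Equals
#' the richness exactly when all taxa have equal incidence.
#'
#' @inheritParams sample_coverage
#' @return Observed Hill-Shannon diversity (order q = 1).
#' @export
hill_shannon_obs <- function(x, n_units = NULL) {
  s <- incidence_stats(x, n_units)
  if (s$U == 0) stop("no incidences: diversity undefined")
  p <- s$Y / s$U
  exp(-sum(p * log(p)))
}

#' Asymptotic Hill-Shannon diversity of incidence data
#'
#' The Chao-Jost asymptotic estimator for incidence data: entropy is
#' estimated from the incidence frequencies with an explicit
#' correction for undetected taxa driven by the uniques and duplicates
#' (`Q1`, `Q2`), and exponentiated. With no uniques the correction
#' vanishes and the estimate equals the observed diversity. The
#' estimator is
#' `H = (T/U) * [ sum_{Y_i <= T-1} (Y_i/T) sum_{k=Y_i}^{T-1} 1/k
#'   + (Q1/T) (1-A)^{1-T} ( -ln A - sum_{r=1}^{T-1} (1-A)^r / r ) ]
#'   + ln(U/T)`
#' with `A = 2 Q2 / ((T-1) Q1 + 2 Q2)` when `Q2 > 0`,
#' `A = 2 / ((T-1)(Q1 - 1) + 2)` when `Q2 = 0, Q1 > 0`, else `A = 1`;
#' the reported diversity is `exp(H)`.
#'
#' @inheritParams sample_coverage
#' @return Asymptotic Hill-Shannon diversity estimate.
#' @export
hill_shannon_asym <- function(x, n_units = NULL) {
  s <- incidence_stats(x, n_units)
  if (s$T < 2) stop("need at least 2 sampling units")
  if (s$U == 0) stop("no incidences: diversity undefined")
  T_ <- s$T; U <- s$U; Y <- s$Y; Q1 <- s$Q1; Q2 <- s$Q2
  A <- if (Q2 > 0) 2 * Q2 / ((T_ - 1) * Q1 + 2 * Q2)
  else if (Q1 > 0) 2 / ((T_ - 1) * (Q1 - 1) + 2)
  else 1
  Yl <- Y[Y <= T_ - 1]
  s1 <- sum(vapply(Yl, function(y) (y / T_) * sum(1 / (y:(T_ - 1))),
                   numeric(1)))
  s2 <- 0
  if (Q1 > 0 && A < 1) {
    r <- seq_len(T_ - 1)
    s2 <- (Q1 / T_) * (1 - A)^(1 - T_) *
      (-log(A) - sum((1 - A)^r / r))
  }
  exp((T_ / U) * (s1 + s2) + log(U / T_))
}

#' Per-taxon detection frequency
#'
#' Percentage of samples in which each taxon was detected,
#' `100 * Y_i / T`.
#'
#' @inheritParams sample_coverage
#' @param digits Decimal places for half-up rounding; `NULL` for
#'   unrounded values.
#' @return Named numeric vector of percentages.
#' @export
detection_frequency <- function(x, n_units = NULL, digits = 1) {
  if (inherits(x, "incidence_matrix") || is.matrix(x)) {
    Y <- colSums(x > 0)
    T_ <- nrow(x)
  } else {
    if (is.null(n_units)) stop("n_units required for a frequency vector")
    Y <- x
    T_ <- n_units
  }
  pct <- 100 * Y / T_
  if (!is.null(digits)) pct <- round_half_up(pct, digits)
  pct
}

#' Half-up decimal rounding
#'
#' Rounds halves away from zero (so 0.25 at one digit becomes 0.3),
#' the convention used for report-table percentages, rather than the
#' round-half-even rule of [round()].
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise identification accuracy by taxonomic rank
#'
#' Counts distinct taxa called at species, genus and family rank, plus
#' those not resolvable to a family, with percentages of the total.
#' The species-rank percentage is the identification accuracy.
#'
#' @param ranks Character vector of ranks, one per distinct taxon
#'   (`"species"`, `"genus"`, `"family"`, `"unresolved"`), or a data
#'   frame with a `rank` column.
#' @param digits Decimal places for the half-up rounded percentages.
#' @return Data frame with `rank`, `n`, `pct`.
#' @export
rank_summary <- function(ranks, digits = 1) {
  if (is.data.frame(ranks)) ranks <- ranks$rank
  lev <- c("species", "genus", "family", "unresolved")
  stopifnot(all(ranks %in% lev))
  n <- as.integer(table(factor(ranks, levels = lev)))
  data.frame(rank = lev, n = n,
             pct = round_half_up(100 * n / sum(n), digits),
             stringsAsFactors = FALSE)
}

#' Sample-based rarefaction of incidence data
#'
#' Exact hypergeometric expectation of taxon richness among `t`
#' sampling units drawn without replacement from the `T` observed
#' units: `E[S_t] = sum_i (1 - choose(T - Y_i, t) / choose(T, t))`.
#' Monotone nondecreasing in `t` and equal to the observed richness at
#' `t = T`. Extrapolation beyond `T` is out of scope and errors.
#'
#' @inheritParams sample_coverage
#' @param t Integer vector of subsample sizes, each in `[1, T]`.
#' @return Numeric vector of expected richness values.
#' @export
sample_based_rarefaction <- function(x, t, n_units = NULL) {
  s <- incidence_stats(x, n_units)
  if (any(t > s$T)) stop("t exceeds the number of sampling units")
  if (any(t < 1)) stop("t must be at least 1")
  vapply(t, function(tt) {
    sum(1 - exp(lchoose(s$T - s$Y, tt) - lchoose(s$T, tt)))
  }, numeric(1))
}

#' Per-period diversity and coverage summary
#'
#' Builds the standard per-period report: number of sampling units,
#' observed richness, observed and asymptotic Hill-Shannon diversity,
#' and percent sample coverage, one row per period plus a pooled
#' `Total` row.
#'
#' @param counts Numeric matrix of incidence frequencies (taxa x
#'   periods).
#' @param n_samples Named integer vector of sampling units per period
#'   (names matching `colnames(counts)`).
#' @param digits Decimal places for half-up rounding of the reported
#'   columns; `NULL` for unrounded values.
#' @return Data frame with columns `period`, `n_samples`, `richness`,
#'   `shannon_obs`, `shannon_est`, `coverage_pct`.
#' @export
diversity_summary <- function(counts, n_samples, digits = 1) {
  counts <- as.matrix(counts)
  stopifnot(identical(colnames(counts), names(n_samples)))
  one <- function(Y, T_, label) {
    data.frame(period = label, n_samples = T_,
               richness = sum(Y > 0),
               shannon_obs = hill_shannon_obs(Y, T_),
               shannon_est = hill_shannon_asym(Y, T_),
               coverage_pct = 100 * sample_coverage(Y, T_),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(colnames(counts), function(p) {
    one(counts[, p], n_samples[[p]], p)
  })
  rows <- c(rows, list(one(rowSums(counts), sum(n_samples), "Total")))
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    num <- c("shannon_obs", "shannon_est", "coverage_pct")
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  rownames(out) <- NULL
  out
}
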