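# Independent oracles and small fixture builders used across tests.

# Plain-R Gotoh dynamic program for affine-gap local alignment.
# Written independently of the package's alignment wrapper; a gap of
# length k costs gap_open + k * gap_ext, matching the package scheme.
gotoh_local_score <- function(a, b, match = 2, mismatch = -3,
                              gap_open = 5, gap_ext = 2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Build a reference_db by writing and re-reading a FASTA, exercising
# the parser on the pipe-delimited header dialect.
make_db <- function(records, marker = "rbcL", origin = "local") {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    c(sprintf(">%s|%s|%s|%s", records$id[i], records$family[i],
              records$genus[i], records$species[i]),
      records$sequence[i])
  }))
  writeLines(lines, path)
  read_reference_fasta(path, marker, origin)
}

make_flora <- function(df) {
  df <- unique(df[, c("family", "genus", "species")])
  df$rank <- "species"
  class(df) <- c("flora_list", "data.frame")
  df
}

# Mutate a sequence at explicit positions (deterministic helper).
mutate_at <- function(seq, pos, to) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- to[i]
  seq
}

table4_counts <- function(tab = diet_incidence_fixture()) {
  ns <- attr(tab, "n_samples")
  m <- as.matrix(tab[, names(ns)])
  rownames(m) <- tab$taxon
  list(counts = m, n_samples = ns, rank = tab$rank)
}
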