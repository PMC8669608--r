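# Independent brute-force oracles and small data generators used across
# the suite.  These deliberately re-derive quantities by the most naive
# route available (explicit loops, string pattern names, pair
# enumeration) so they share no code path with the implementation.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(L) paste(sample(AA20, L, replace = TRUE),
                                collapse = "")

# term-by-term evaluation of the cross-covariance sum
brute_cc <- function(seq, table, lg = 2, normalize = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  props <- colnames(table)
  out <- numeric(0)
  for (lag in seq_len(lg)) for (k in props) for (j in setdiff(props, k)) {
    xk <- table[chars, k]
    xj <- table[chars, j]
    mk <- sum(xk) / L
    mj <- sum(xj) / L
    s <- 0
    for (i in seq_len(L - lag)) s <- s + (xk[i] - mk) * (xj[i + lag] - mj)
    if (normalize) s <- s / (L - lag)
    out <- c(out, stats::setNames(s, sprintf("cc(%s,%s,%d)", k, j, lag)))
  }
  out
}

# window scanner building each pattern's NAME and counting by name lookup
brute_monodikgap <- function(seq, kgap = 2) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  desc <- enumerate_monodikgap(kgap)
  out <- stats::setNames(numeric(length(desc)), desc)
  for (g in seq_len(kgap)) {
    span <- 3 + g
    nwin <- L - span + 1
    if (nwin < 1) next
    for (i in seq_len(nwin)) {
      nm <- paste0(chars[i], strrep("_", g), chars[i + g + 1],
                   chars[i + g + 2])
      out[nm] <- out[nm] + 1
    }
    block <- ((g - 1) * 8000 + 1):(g * 8000)
    out[block] <- out[block] / nwin
  }
  out
}

# all-pairs Mann-Whitney estimate of the ROC area
brute_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  tot <- 0
  for (p in sp) for (n in sn)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(sp) * length(sn))
}

# mean-of-three pair distance computed by explicit loops
brute_pair_distance <- function(a, b, emax) {
  eucl <- sqrt(sum((a - b)^2)) / emax
  cosd <- 1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  tani <- sum(a * b) / (sum(a^2) + sum(b^2) - sum(a * b))
  (eucl + cosd + (1 - tani)) / 3
}

# small labeled matrix: `signal` informative gaussian columns (mean shift
# = effect) plus `noise` pure-noise columns
toy_matrix <- function(n = 100, signal = 2, noise = 3, effect = 2,
                       seed = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), each = n / 2)
  cols <- c(
    lapply(seq_len(signal), function(i) rnorm(n, mean = effect * (y == 1))),
    lapply(seq_len(noise), function(i) rnorm(n)))
  vals <- do.call(cbind, cols)
  colnames(vals) <- c(sprintf("sig%d", seq_len(signal)),
                      sprintf("noise%d", seq_len(noise)))
  feature_matrix(vals, y)
}

write_tmp_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(id)
    c(paste0(">", id), entries[[id]]))), path)
  path
}
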