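# Sequence -> fixed-length descriptor vectors: grouped amino-acid
# composition (GAAC), cross-covariance of physicochemical profiles (CC),
# and gapped k-mer composition (monoDiKGap), plus their concatenation.

seq_to_index <- function(seq) {
  idx <- match(strsplit(seq, "")[[1]], AA_ALPHABET)
  if (anyNA(idx)) stop("sequence contains non-standard residues; validate first")
  idx
}

#' Grouped amino-acid composition (GAAC)
#'
#' Frequency of each of the five physicochemical residue groups
#' (see [gaac_groups()]): f(g) = N(g) / N where N(g) counts residues of
#' group g and N is the sequence length.  The five components sum to 1.
#'
#' @param seq a validated amino-acid sequence (length >= 1).
#' @return Named numeric 5-vector, groups in fixed order g1..g5.
#' @export
#' @examples
#' gaac_encode("EAHGAFLMDKPSMFNERV") * 18   # group counts 7 2 3 3 3
gaac_encode <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  groups <- gaac_groups()
  grp_of <- rep(seq_along(groups), lengths(groups))
  names(grp_of) <- unlist(groups)
  idx <- seq_to_index(seq)
  counts <- tabulate(grp_of[AA_ALPHABET[idx]], nbins = 5L)
  stats::setNames(counts / length(idx), names(groups))
}

cc_property_pairs <- function(props = c("hydrophobicity", "hydrophilicity", "mass"),
                              lg = 2L) {
  out <- character(0)
  for (lag in seq_len(lg))
    for (k in props)
      for (j in setdiff(props, k))
        out <- c(out, sprintf("cc(%s,%s,%d)", k, j, lag))
  out
}

#' Cross-covariance (CC) descriptor
#'
#' For each ordered pair of distinct physicochemical properties (k, j) and
#' each lag in 1..`lg`, the centered cross-product sum
#' CC(k, j, lag) = sum_{i=1}^{L-lag} (x_{i,k} - mean_k)(x_{i+lag,j} - mean_j),
#' where x_{i,k} is the (standardized) value of property k for the residue
#' at position i and mean_k is the mean of property k over the sequence's
#' own residues.  With 3 properties and `lg = 2` this yields 12 components.
#' The plain sum is the default; `normalize = TRUE` divides each component
#' by its number of summands (L - lag), as many descriptor suites do.
#'
#' @param seq a validated amino-acid sequence with length > `lg`.
#' @param table a [load_physchem()] property matrix.
#' @param lg maximum lag (default 2).
#' @param normalize divide each component by (L - lag)?  Default `FALSE`.
#' @return Named numeric vector of length 3 * 2 * `lg`, descriptor names
#'   `"cc(propK,propJ,lag)"`.
#' @export
cc_encode <- function(seq, table = load_physchem(), lg = 2L,
                      normalize = FALSE) {
  if (lg < 1) stop("lg must be >= 1")
  idx <- seq_to_index(seq)
  L <- length(idx)
  if (L <= lg) stop("sequence too short for lag ", lg, " (length ", L, ")")
  x <- table[idx, , drop = FALSE]          # L x 3 property profile
  mu <- colMeans(x)
  props <- colnames(table)
  out <- numeric(0)
  for (lag in seq_len(lg)) {
    i1 <- seq_len(L - lag)
    for (k in props) for (j in setdiff(props, k)) {
      v <- sum((x[i1, k] - mu[k]) * (x[i1 + lag, j] - mu[j]))
      if (normalize) v <- v / (L - lag)
      out <- c(out, v)
    }
  }
  stats::setNames(out, cc_property_pairs(props, lg))
}

#' Enumerate the monoDiKGap descriptor space
#'
#' For each gap width g in 1..`kgap`, all 20^3 = 8000 patterns of one
#' residue, g gap positions, then two residues — written e.g. `"A_AA"`
#' (g = 1) or `"A__AA"` (g = 2) — in lexicographic residue order.  Total
#' `kgap` * 8000 descriptors; 16,000 for the default `kgap = 2`.
#'
#' @param kgap maximum gap width (>= 1, default 2).
#' @return Character vector of descriptor names, gap-1 block first.
#' @export
enumerate_monodikgap <- function(kgap = 2L) {
  if (kgap < 1) stop("kgap must be >= 1")
  a <- rep(AA_ALPHABET, each = 400L)
  b <- rep(rep(AA_ALPHABET, each = 20L), times = 20L)
  c_ <- rep(AA_ALPHABET, times = 400L)
  unlist(lapply(seq_len(kgap), function(g)
    paste0(a, strrep("_", g), b, c_)))
}

#' monoDiKGap gapped k-mer composition
#'
#' Slides a window of span 3 + g over the sequence for each gap width g in
#' 1..`kgap` and counts the pattern (residue, g-gap, residue, residue) in
#' each window.  Each gap block is reported as count / number of windows
#' (L - span + 1), so a block sums to 1 whenever at least one window
#' exists; sequences shorter than the span yield an all-zero block.
#'
#' @param seq a validated amino-acid sequence.
#' @param kgap maximum gap width (default 2).
#' @return Named numeric vector of length `kgap` * 8000, ordered as
#'   [enumerate_monodikgap()].
#' @export
monodikgap_encode <- function(seq, kgap = 2L) {
  if (kgap < 1) stop("kgap must be >= 1")
  idx <- seq_to_index(seq)
  L <- length(idx)
  blocks <- lapply(seq_len(kgap), function(g) {
    span <- 3L + g
    nwin <- L - span + 1L
    if (nwin < 1L) return(numeric(8000L))
    i <- seq_len(nwin)
    pat <- (idx[i] - 1L) * 400L + (idx[i + g + 1L] - 1L) * 20L + idx[i + g + 2L]
    tabulate(pat, nbins = 8000L) / nwin
  })
  stats::setNames(unlist(blocks), enumerate_monodikgap(kgap))
}

#' Encode a dataset into a (hybrid) feature matrix
#'
#' Concatenates the requested encoder blocks in the fixed order
#' (monoDiKGap, CC, GAAC); row order follows the dataset.  The monoDiKGap
#' block may be restricted to a previously selected descriptor subset
#' (e.g. the output of [adaboost_select()]), which is how the
#' "466 + 12 + 5 = 483"-style hybrid spaces are formed.
#'
#' @param d a validated [protein_dataset()].
#' @param parts non-empty subset of `c("monodikgap", "cc", "gaac")`.
#' @param monodikgap_subset optional restriction of the monoDiKGap block:
#'   a `ranked_features` object or a character vector of descriptors.
#' @param kgap,lg,table,cc_normalize encoder parameters, passed through.
#' @return A [feature_matrix()] carrying the dataset's labels.
#' @export
hybrid_encode <- function(d, parts = c("monodikgap", "cc", "gaac"),
                          monodikgap_subset = NULL,
                          kgap = 2L, lg = 2L, table = load_physchem(),
                          cc_normalize = FALSE) {
  parts <- match.arg(parts, c("monodikgap", "cc", "gaac"),
                     several.ok = TRUE)
  if (length(parts) == 0) stop("parts must be non-empty")
  if (nrow(d) == 0) stop("empty dataset")
  blocks <- list()
  if ("monodikgap" %in% parts) {
    mk <- t(vapply(d$sequence, monodikgap_encode, numeric(kgap * 8000L),
                   kgap = kgap, USE.NAMES = FALSE))
    colnames(mk) <- enumerate_monodikgap(kgap)
    if (!is.null(monodikgap_subset)) {
      keep <- if (inherits(monodikgap_subset, "ranked_features"))
        monodikgap_subset$descriptor else as.character(monodikgap_subset)
      missing <- setdiff(keep, colnames(mk))
      if (length(missing))
        stop("unknown monoDiKGap descriptors in subset: ",
             paste(utils::head(missing, 5), collapse = ", "))
      mk <- mk[, keep, drop = FALSE]
    }
    blocks$monodikgap <- mk
  }
  if ("cc" %in% parts) {
    blocks$cc <- t(vapply(d$sequence, cc_encode, numeric(6L * lg),
                          table = table, lg = lg, normalize = cc_normalize,
                          USE.NAMES = FALSE))
    colnames(blocks$cc) <- cc_property_pairs(colnames(table), lg)
  }
  if ("gaac" %in% parts) {
    blocks$gaac <- t(vapply(d$sequence, gaac_encode, numeric(5L),
                            USE.NAMES = FALSE))
    colnames(blocks$gaac) <- names(gaac_groups())
  }
  vals <- do.call(cbind, blocks[c("monodikgap", "cc", "gaac")])
  if (anyDuplicated(colnames(vals))) stop("descriptor collision across parts")
  rownames(vals) <- d$id
  feature_matrix(vals, d$label)
}
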