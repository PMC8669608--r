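# Sequence and feature-matrix I/O: FASTA reading/writing, residue
# validation, greedy identity reduction, TSV feature matrices.

#' Construct a protein dataset
#'
#' A `protein_dataset` is an ordered collection of identified amino-acid
#' sequences with optional binary labels (+1 druggable / -1
#' non-druggable).
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of sequences (uppercased).
#' @param label optional numeric vector of +1/-1 labels (NA allowed).
#' @param provenance free-text notes on source files / filters applied.
#' @return A `protein_dataset` (data frame with columns `id`, `sequence`,
#'   `label` and a `provenance` attribute).
#' @export
protein_dataset <- function(id, sequence, label = NA_real_,
                            provenance = character()) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("id and sequence must have the same length")
  if (anyDuplicated(id))
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  label <- rep_len(as.numeric(label), length(id))
  if (!all(is.na(label) | label %in% c(-1, 1)))
    stop("labels must be +1, -1 or NA")
  d <- data.frame(id = id, sequence = sequence, label = label,
                  stringsAsFactors = FALSE)
  structure(d, provenance = provenance,
            class = c("protein_dataset", "data.frame"))
}

#' @export
print.protein_dataset <- function(x, ...) {
  cat(sprintf("protein_dataset: %d records (%d positive, %d negative, %d unlabeled)\n",
              nrow(x), sum(x$label == 1, na.rm = TRUE),
              sum(x$label == -1, na.rm = TRUE), sum(is.na(x$label))))
  for (p in attr(x, "provenance")) cat(" -", p, "\n")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' One record per FASTA entry; sequences are uppercased and entry order is
#' preserved.  The record id is the header token up to the first
#' whitespace.  An empty file yields an empty dataset.
#'
#' @param path FASTA file (multi-line sequences allowed).
#' @param label optional label (+1 or -1) attached to every record.
#' @return A [protein_dataset()].
#' @export
read_fasta <- function(path, label = NA_real_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first) && !startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: line ", first, " of ", path,
         " does not start a '>' header")
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0)
    return(protein_dataset(character(), character(),
                           provenance = paste("read", path)))
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1)
  protein_dataset(ids, as.character(aa), label,
                  provenance = paste("read", path))
}

#' Write a protein dataset to FASTA
#'
#' @param d a [protein_dataset()].
#' @param path output file.
#' @param width line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(d, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(">", d$id[i]), con)
    s <- d$sequence[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Remove records containing non-standard residues
#'
#' A record is kept only if its sequence is non-empty and consists
#' entirely of the 20 standard one-letter codes.  Sequences containing the
#' ambiguity/non-standard codes B, J, O, U, X or Z (or any other symbol)
#' are rejected, never repaired.  Idempotent.
#'
#' @param d a [protein_dataset()].
#' @return List with `dataset` (retained records) and `rejected`
#'   (data frame of `id`, `reason`).
#' @export
validate_records <- function(d) {
  reasons <- vapply(d$sequence, function(s) {
    if (!nzchar(s)) return("empty sequence")
    chars <- unique(strsplit(s, "")[[1]])
    bad <- setdiff(chars, AA_ALPHABET)
    if (length(bad) == 0) return(NA_character_)
    paste("contains", paste(sort(bad), collapse = ", "))
  }, "", USE.NAMES = FALSE)
  keep <- is.na(reasons)
  kept <- protein_dataset(d$id[keep], d$sequence[keep], d$label[keep],
                          provenance = c(attr(d, "provenance"),
                                         sprintf("validated: %d kept, %d rejected",
                                                 sum(keep), sum(!keep))))
  list(dataset = kept,
       rejected = data.frame(id = d$id[!keep], reason = reasons[!keep],
                             stringsAsFactors = FALSE))
}

# Ungapped identity of two sequences: maximum number of matching positions
# over all offsets of the shorter within the longer, divided by the
# shorter length.
ungapped_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  la <- length(sa); lb <- length(sb)
  best <- 0L
  for (off in 0:(lb - la)) {
    m <- sum(sa == sb[(off + 1):(off + la)])
    if (m > best) best <- m
    if (best == la) break
  }
  best / la
}

#' Greedy sequence-identity reduction
#'
#' A self-contained greedy stand-in for CD-HIT-style redundancy removal:
#' records are processed longest-first (ties broken lexicographically by
#' id); a record is kept iff its pairwise identity to every already-kept
#' record is below `threshold`.  Identity is the best ungapped overlay of
#' the shorter sequence on the longer one, scored as matches / shorter
#' length.  This is deliberately simple and is NOT equivalent to CD-HIT's
#' word-indexed clustering; it removes near-duplicates so the pipeline has
#' no external binary dependency.
#'
#' @param d a validated [protein_dataset()].
#' @param threshold identity threshold in (0, 1]; records at or above it
#'   relative to a kept record are dropped (default 0.6).
#' @return A [protein_dataset()] of kept records, in the greedy order.
#' @export
greedy_identity_filter <- function(d, threshold = 0.6) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  ord <- order(-nchar(d$sequence), d$id)
  kept <- integer(0)
  for (i in ord) {
    redundant <- FALSE
    for (j in kept) {
      if (ungapped_identity(d$sequence[i], d$sequence[j]) >= threshold) {
        redundant <- TRUE; break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  protein_dataset(d$id[kept], d$sequence[kept], d$label[kept],
                  provenance = c(attr(d, "provenance"),
                                 sprintf("greedy identity filter at %.2f: %d of %d kept",
                                         threshold, length(kept), nrow(d))))
}

#' Construct a feature matrix
#'
#' An n-samples x d-features numeric matrix with unique named descriptors
#' and per-sample +1/-1 labels.
#'
#' @param values numeric matrix; rownames = sample ids, colnames =
#'   feature descriptors.
#' @param labels numeric vector of +1/-1 (NA allowed), one per row.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, labels = rep(NA_real_, nrow(values))) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("feature descriptors must be present and unique")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (length(labels) != nrow(values))
    stop("one label per sample required")
  if (anyNA(values))
    stop("feature matrix must not contain missing values")
  structure(list(values = values, labels = as.numeric(labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == 1, na.rm = TRUE),
              sum(x$labels == -1, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Row/column subset preserving class and labels.
subset_features <- function(m, rows = seq_len(nrow(m$values)),
                            cols = colnames(m$values)) {
  feature_matrix(m$values[rows, cols, drop = FALSE], m$labels[rows])
}

#' Write / read a feature matrix as TSV
#'
#' Plain tab-separated text with a header row: `id`, `label`, then one
#' column per feature descriptor.  Labels are written as 1/-1; on reading,
#' 0 is accepted as an alias for -1.  Round-trips up to floating-point
#' representation.
#'
#' @param m a [feature_matrix()].
#' @param path output / input file.
#' @return `write_matrix`: `path`, invisibly.  `read_matrix`: a
#'   [feature_matrix()].
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m$values), label = m$labels,
                   m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("feature matrix file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (!all(c("id", "label") %in% names(df)))
    stop("feature matrix TSV must have 'id' and 'label' columns")
  feat_idx <- which(!names(df) %in% c("id", "label"))
  feat_cols <- names(df)[feat_idx]
  if (anyDuplicated(feat_cols))
    stop("duplicate feature descriptors in header")
  vals <- matrix(NA_real_, nrow(df), length(feat_cols),
                 dimnames = list(df$id, feat_cols))
  for (j in seq_along(feat_idx)) {
    v <- suppressWarnings(as.numeric(df[[feat_idx[j]]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      stop(sprintf("non-numeric value at row %d, column '%s'",
                   row, feat_cols[j]))
    }
    vals[, j] <- v
  }
  lab <- suppressWarnings(as.numeric(df$label))
  lab[!is.na(lab) & lab == 0] <- -1
  if (!all(is.na(lab) | lab %in% c(-1, 1)))
    stop("labels must be 1, -1 or 0 (read as -1)")
  feature_matrix(vals, lab)
}
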