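#' Load a 20 x 3 physicochemical property table
#'
#' Reads a per-residue table of hydrophobicity, hydrophilicity and
#' side-chain mass.  The packaged default follows the property triple in
#' common use for pseudo-amino-acid-composition descriptors (Tanford-style
#' hydrophobicity, Hopp-Woods hydrophilicity, side-chain mass in Da).
#' Because the three scales have arbitrary and very different units, each
#' column is standardized to mean 0 and unit (population) variance across
#' the 20 residues before it enters the cross-covariance sum; set
#' `standardize = FALSE` to keep the raw scales.
#'
#' @param path TSV with columns `residue`, `hydrophobicity`,
#'   `hydrophilicity`, `mass`; one row per standard amino acid.  Default:
#'   the packaged table.
#' @param standardize standardize each property column over the 20
#'   residues (default `TRUE`).
#' @return A `physchem_table`: numeric 20 x 3 matrix, rownames the
#'   amino-acid one-letter codes (alphabetical), columns
#'   `hydrophobicity`, `hydrophilicity`, `mass`.
#' @export
#' @examples
#' tab <- load_physchem()
#' colMeans(tab)   # ~0 after standardization
load_physchem <- function(path = system.file("extdata", "physchem_pseaac.tsv",
                                             package = "drughybrid"),
                          standardize = TRUE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "hydrophobicity", "hydrophilicity", "mass")
  if (!all(need %in% names(raw)))
    stop("property table must have columns: ", paste(need, collapse = ", "))
  if (!setequal(raw$residue, AA_ALPHABET))
    stop("property table must cover exactly the 20 standard amino acids")
  m <- as.matrix(raw[, need[-1]])
  rownames(m) <- raw$residue
  m <- m[AA_ALPHABET, , drop = FALSE]
  if (standardize) {
    # population sd (divide by n), so the 20-residue column has exactly
    # unit variance
    m <- scale(m, center = TRUE, scale = FALSE)
    sds <- sqrt(colMeans(m^2))
    m <- sweep(m, 2, sds, "/")
    attributes(m)[c("scaled:center", "scaled:scale")] <- NULL
  }
  structure(m, class = c("physchem_table", class(m)))
}

#' Five physicochemical residue groups used by the GAAC encoder
#'
#' Aliphatic (g1: GAVLMI), aromatic (g2: FYW), positively charged
#' (g3: KRH), negatively charged (g4: DE) and uncharged polar/small
#' (g5: STCPNQ).  The five sets partition the 20-letter alphabet.
#'
#' @return Named list of five character vectors of residue codes.
#' @export
gaac_groups <- function() {
  list(
    g1.aliphatic = c("G","A","V","L","M","I"),
    g2.aromatic  = c("F","Y","W"),
    g3.positive  = c("K","R","H"),
    g4.negative  = c("D","E"),
    g5.uncharged = c("S","T","C","P","N","Q")
  )
}
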