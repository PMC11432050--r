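## ECFP4 fingerprints and Tanimoto similarity; within- and between-set
## averages for diversity reporting.

#' Compute ECFP4 fingerprints
#'
#' Circular (Morgan-type) fingerprints of radius 2, computed with
#' OpenBabel's ECFP4 implementation (natively 4096 bits) and folded by OR
#' to `nBits`. Deterministic; unparseable structures are rejected with a
#' reason.
#'
#' @param mset a [MoleculeSet].
#' @param nBits folded fingerprint length; must divide the native width
#'   (default 2048).
#' @return a [FingerprintSet].
#' @export
ecfp4 <- function(mset, nBits = 2048) {
  stopifnot(is(mset, "MoleculeSet"))
  if (!length(mset@id)) stop("no molecules to fingerprint")
  sdf <- ChemmineR::smiles2sdf(setNames(mset@smiles, mset@id))
  fpset <- ChemmineR::fingerprintOB(sdf, "ECFP4")
  m <- fpset@fpma > 0
  native <- ncol(m)
  if (native %% nBits != 0)
    stop("nBits (", nBits, ") must divide the native width (", native, ")")
  folds <- native / nBits
  if (folds > 1L) {
    out <- matrix(FALSE, nrow(m), nBits, dimnames = list(rownames(m), NULL))
    for (f in seq_len(folds))
      out <- out | m[, seq.int((f - 1L) * nBits + 1L, f * nBits),
                     drop = FALSE]
    m <- out
  }
  rownames(m) <- mset@id
  new("FingerprintSet", bits = m, type = "ECFP4")
}

#' Construct a FingerprintSet from a logical matrix
#'
#' @param bits logical matrix, molecules as rownames.
#' @param type free-text type tag.
#' @return a [FingerprintSet].
#' @export
FingerprintSet <- function(bits, type = NA_character_) {
  new("FingerprintSet", bits = bits, type = type)
}

#' Tanimoto similarity of two bit sets
#'
#' `|a AND b| / |a OR b|`; two all-zero fingerprints are defined to have
#' similarity 1. Symmetric, in `[0, 1]`, and 1 on identical fingerprints.
#'
#' @param a,b logical vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b))
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  u <- sum(a | b)
  if (u == 0) 1 else sum(a & b) / u
}

## all-pairs Tanimoto between the rows of two logical matrices
.tanimotoMatrix <- function(a, b) {
  am <- a * 1
  bm <- b * 1
  inter <- am %*% t(bm)
  popA <- rowSums(am)
  popB <- rowSums(bm)
  uni <- outer(popA, popB, "+") - inter
  out <- ifelse(uni == 0, 1, inter / uni)
  dimnames(out) <- list(rownames(a), rownames(b))
  out
}

#' Mean pairwise Tanimoto similarity
#'
#' `mode = "between"`: mean over all |A| x |B| cross pairs (e.g. predicted
#' drugs vs known actives). `mode = "within"`: mean over all unordered
#' distinct pairs of one set -- self-pairs are excluded, so a set of two
#' identical and one disjoint fingerprint averages 1/3, not more.
#'
#' @param setA a [FingerprintSet].
#' @param setB a second [FingerprintSet] (between mode only).
#' @param mode `"within"` or `"between"`.
#' @return the mean similarity.
#' @export
meanPairwise <- function(setA, setB = NULL,
                         mode = c("within", "between")) {
  mode <- match.arg(mode)
  stopifnot(is(setA, "FingerprintSet"))
  if (mode == "between") {
    stopifnot(is(setB, "FingerprintSet"))
    if (ncol(setA@bits) != ncol(setB@bits))
      stop("fingerprint length mismatch between sets")
    if (!nrow(setA@bits) || !nrow(setB@bits))
      stop("both sets must be nonempty")
    mean(.tanimotoMatrix(setA@bits, setB@bits))
  } else {
    n <- nrow(setA@bits)
    if (n < 2L) stop("within-set mean requires at least 2 fingerprints")
    tm <- .tanimotoMatrix(setA@bits, setA@bits)
    mean(tm[upper.tri(tm)])
  }
}

#' All-pairs Tanimoto matrix between two fingerprint sets
#'
#' @param setA,setB [FingerprintSet]s of equal bit length (`setB` defaults
#'   to `setA`).
#' @return numeric matrix of similarities.
#' @export
tanimotoMatrix <- function(setA, setB = setA) {
  stopifnot(is(setA, "FingerprintSet"), is(setB, "FingerprintSet"))
  if (ncol(setA@bits) != ncol(setB@bits))
    stop("fingerprint length mismatch between sets")
  .tanimotoMatrix(setA@bits, setB@bits)
}
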