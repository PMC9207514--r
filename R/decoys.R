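#' Binary fingerprint sets
#'
#' A fingerprint is the set of on-bit positions (1-based) of a fixed-length
#' binary vector; a fingerprint set bundles several fingerprints of the
#' same length with their compound ids.  `fingerprint_set()` builds one
#' from a list of on-bit index vectors; `fp_from_matrix()` converts a 0/1
#' matrix (rows = compounds) and `fp_to_matrix()` converts back.
#'
#' @param bits list of integer vectors of on-bit positions, each within
#'   `1..n_bits`; duplicates are dropped (set semantics).
#' @param n_bits fingerprint length shared by all members.
#' @param ids optional character ids, one per fingerprint; defaults to
#'   `fp1, fp2, ...`.
#' @return An object of class `fingerprint_set` with elements `ids`,
#'   `bits` and `n_bits`.
#' @export
fingerprint_set <- function(bits, n_bits, ids = NULL) {
  stopifnot(is.list(bits))
  n_bits <- as.integer(n_bits)
  if (n_bits < 1L) stop("'n_bits' must be >= 1")
  bits <- lapply(bits, function(b) {
    b <- sort(unique(as.integer(b)))
    if (length(b) && (b[[1L]] < 1L || b[[length(b)]] > n_bits))
      stop("bit indices must lie in 1..", n_bits)
    b
  })
  if (is.null(ids)) ids <- paste0("fp", seq_along(bits))
  ids <- as.character(ids)
  if (length(ids) != length(bits))
    stop("'ids' must have one entry per fingerprint")
  structure(list(ids = ids, bits = bits, n_bits = n_bits),
            class = "fingerprint_set")
}

#' @export
length.fingerprint_set <- function(x) length(x$bits)

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("Fingerprint set:", length(x), "compounds,", x$n_bits, "bits\n")
  invisible(x)
}

#' @rdname fingerprint_set
#' @param m numeric/integer matrix with entries in \{0, 1\}.
#' @export
fp_from_matrix <- function(m, ids = rownames(m)) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("matrix entries must be 0/1")
  fingerprint_set(lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1)),
                  n_bits = ncol(m), ids = ids)
}

#' @rdname fingerprint_set
#' @param fps a `fingerprint_set`.
#' @export
fp_to_matrix <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  m <- matrix(0, nrow = length(fps), ncol = fps$n_bits,
              dimnames = list(fps$ids, paste0("bit", seq_len(fps$n_bits))))
  for (i in seq_along(fps$bits)) m[i, fps$bits[[i]]] <- 1
  m
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{T(A, B) = |A \cap B| / |A \cup B|} on the on-bit sets: 1 means
#' identical fingerprints, 0 disjoint ones.  Two empty fingerprints are
#' defined to have similarity 0 (avoiding 0/0).
#'
#' @param a,b integer vectors of on-bit positions, or two
#'   `fingerprint_set`s of length 1.  When both carry a bit length the
#'   lengths must agree.
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4))  # 2 shared of 4 total -> 0.5
#' @export
tanimoto <- function(a, b) {
  na <- nb <- NULL
  if (inherits(a, "fingerprint_set")) {
    if (length(a) != 1L) stop("'a' must hold a single fingerprint")
    na <- a$n_bits; a <- a$bits[[1L]]
  }
  if (inherits(b, "fingerprint_set")) {
    if (length(b) != 1L) stop("'b' must hold a single fingerprint")
    nb <- b$n_bits; b <- b$bits[[1L]]
  }
  if (!is.null(na) && !is.null(nb) && na != nb)
    stop("fingerprints have different bit lengths (", na, " vs ", nb, ")")
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Summed Tanimoto similarity of each decoy to a positive set
#'
#' For each candidate decoy \eqn{g_i}, computes
#' \eqn{sum_i = \sum_j T(g_i, c_j)} over all positives \eqn{c_j} — the
#' aggregate similarity the decoy ranking is based on.  Each value lies in
#' \[0, m\] for m positives.
#'
#' @param positives,decoys `fingerprint_set`s with equal `n_bits`.
#' @return Numeric vector, one sum per decoy.
#' @export
summed_similarity <- function(positives, decoys) {
  stopifnot(inherits(positives, "fingerprint_set"),
            inherits(decoys, "fingerprint_set"))
  if (positives$n_bits != decoys$n_bits)
    stop("fingerprint bit lengths differ (", positives$n_bits, " vs ",
         decoys$n_bits, ")")
  P <- fp_to_matrix(positives)            # m x B
  D <- fp_to_matrix(decoys)               # n x B
  inter <- D %*% t(P)                     # n x m intersection counts
  sp <- rowSums(P)
  sd_ <- rowSums(D)
  un <- outer(sd_, sp, `+`) - inter
  tan <- ifelse(un == 0, 0, inter / un)
  unname(rowSums(tan))
}

#' Select the least-similar decoys as negative examples
#'
#' Implements the negative sample selection rule: every decoy in the pool
#' is scored by its summed Tanimoto similarity to all `m` positives, the
#' pool is sorted by that sum in ascending order (ties broken by input
#' order, so results are reproducible), and the first `ratio * m` decoys —
#' those least similar in aggregate to the positive set — become the
#' negative compound set.  The default `ratio = 2` yields a 1:2
#' positive:negative class balance (e.g. 134 negatives for 67 positives).
#'
#' @param positives `fingerprint_set` of the m known related compounds.
#' @param decoys `fingerprint_set` of the candidate decoy pool; must hold
#'   at least `ratio * m` members.
#' @param ratio negatives per positive (positive integer, default 2).
#' @return An object of class `decoy_selection`: list with `ids` and
#'   `indices` of the selected decoys (in ascending similarity order),
#'   `summed_similarity` (full pool profile), `ratio` and `m`.
#' @export
select_decoys <- function(positives, decoys, ratio = 2L) {
  ratio <- as.integer(ratio)
  if (ratio < 1L) stop("'ratio' must be a positive integer")
  m <- length(positives)
  need <- ratio * m
  if (length(decoys) < need)
    stop("decoy pool too small: need ", need, " (ratio ", ratio,
         " x ", m, " positives) but only ", length(decoys), " available")
  sums <- summed_similarity(positives, decoys)
  ord <- order(sums)                       # stable: ties keep input order
  idx <- ord[seq_len(need)]
  structure(list(ids = decoys$ids[idx],
                 indices = idx,
                 summed_similarity = sums,
                 ratio = ratio,
                 m = m),
            class = "decoy_selection")
}

#' @export
print.decoy_selection <- function(x, ...) {
  cat("Decoy selection: ", length(x$indices), " negatives (ratio ",
      x$ratio, " x ", x$m, " positives)\n", sep = "")
  cat("  summed-similarity range of selected: [",
      format(min(x$summed_similarity[x$indices]), digits = 4), ", ",
      format(max(x$summed_similarity[x$indices]), digits = 4), "]\n",
      sep = "")
  invisible(x)
}
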