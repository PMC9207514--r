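#' Synthetic fingerprint classes
#'
#' Draws binary fingerprints for two classes from per-bit Bernoulli
#' profiles.  The default profiles give each class its own high-probability
#' bit block (first quarter of the bits for positives, third quarter for
#' negatives) over a low uniform background, so within-class Tanimoto
#' similarity exceeds between-class similarity — the structure real
#' fingerprint families show and the decoy-selection ordering relies on.
#'
#' @param n_pos,n_neg class sizes.
#' @param n_bits fingerprint length, at least 8 (default 64).
#' @param pos_profile,neg_profile optional numeric vectors of per-bit
#'   on-probabilities (length `n_bits`, values in \[0, 1\]); defaults as
#'   described above.
#' @param seed integer seed (required: fixtures must be reproducible).
#' @return List with `fps` (a [fingerprint_set()] of the positives followed
#'   by the negatives) and `labels` (1 for positives, 0 for negatives).
#' @export
sim_fingerprints <- function(n_pos = 50L, n_neg = 50L, n_bits = 64L,
                             pos_profile = NULL, neg_profile = NULL,
                             seed) {
  if (missing(seed)) stop("'seed' is required")
  n_bits <- as.integer(n_bits)
  if (n_bits < 8L) stop("'n_bits' must be >= 8")
  if (is.null(pos_profile)) {
    pos_profile <- rep(0.02, n_bits)
    pos_profile[seq_len(n_bits %/% 4L)] <- 0.6
  }
  if (is.null(neg_profile)) {
    neg_profile <- rep(0.02, n_bits)
    neg_profile[(n_bits %/% 2L + 1L):(3L * n_bits %/% 4L)] <- 0.6
  }
  for (p in list(pos_profile, neg_profile))
    if (length(p) != n_bits || any(p < 0 | p > 1))
      stop("profiles must be length n_bits with probabilities in [0, 1]")
  set.seed(as.integer(seed))
  draw <- function(profile) which(stats::runif(n_bits) < profile)
  bits <- c(lapply(seq_len(n_pos), function(i) draw(pos_profile)),
            lapply(seq_len(n_neg), function(i) draw(neg_profile)))
  ids <- c(sprintf("pos%03d", seq_len(n_pos)),
           sprintf("neg%03d", seq_len(n_neg)))
  list(fps = fingerprint_set(bits, n_bits = n_bits, ids = ids),
       labels = c(rep(1L, n_pos), rep(0L, n_neg)))
}

#' Synthetic separable continuous features
#'
#' Two multivariate Gaussian blobs: the unrelated class is centered at the
#' origin and the related class is shifted by `separation` standard
#' deviations along every coordinate, then all columns are min-max scaled
#' to \[0, 1\].  At the default `separation = 4` a threshold on any single
#' coordinate already separates the classes almost perfectly, which is
#' exactly the regime needed to check that the trainer can recover an
#' adequate model.
#'
#' @param n_pos,n_neg class sizes.
#' @param d number of features (default 8).
#' @param separation class-mean distance per coordinate, in sd units
#'   (default 4).
#' @param sd within-class standard deviation (default 1).
#' @param seed integer seed (required).
#' @return List with `x` (matrix `(n_pos + n_neg) x d`, scaled to
#'   \[0, 1\]) and `y` (1 = related, 0 = unrelated).
#' @export
sim_blobs <- function(n_pos = 60L, n_neg = 60L, d = 8L, separation = 4,
                      sd = 1, seed) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(as.integer(seed))
  x1 <- matrix(stats::rnorm(n_pos * d, mean = separation * sd, sd = sd),
               nrow = n_pos)
  x0 <- matrix(stats::rnorm(n_neg * d, mean = 0, sd = sd), nrow = n_neg)
  x <- rbind(x1, x0)
  colnames(x) <- paste0("f", seq_len(d))
  rownames(x) <- c(sprintf("pos%03d", seq_len(n_pos)),
                   sprintf("neg%03d", seq_len(n_neg)))
  x <- minmax_apply(x, minmax_fit(x))
  list(x = x, y = c(rep(1L, n_pos), rep(0L, n_neg)))
}

#' Synthetic decoy pool
#'
#' Builds a candidate decoy pool whose members span a gradient of summed
#' Tanimoto similarity to a given positive set, so the least-similar-first
#' selection is exercised non-trivially.  Each decoy copies a fraction of
#' a random positive's on-bits and fills the rest from bits unused by any
#' positive; the copied fraction is drawn uniformly from
#' `[0, 1 - dissimilarity]`.  At `dissimilarity = 1` every decoy is
#' bit-disjoint from every positive and all summed similarities are 0.
#'
#' @param positives a [fingerprint_set()] of the positive compounds.
#' @param pool_size number of decoys to generate.
#' @param dissimilarity in \[0, 1\]; larger values make the pool globally
#'   less similar to the positives (default 0.5).
#' @param seed integer seed (required).
#' @return A [fingerprint_set()] of `pool_size` decoys with the positives'
#'   bit length.
#' @export
sim_decoy_pool <- function(positives, pool_size = 500L,
                           dissimilarity = 0.5, seed) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(inherits(positives, "fingerprint_set"))
  if (pool_size < 1L) stop("'pool_size' must be >= 1")
  if (dissimilarity < 0 || dissimilarity > 1)
    stop("'dissimilarity' must lie in [0, 1]")
  set.seed(as.integer(seed))
  n_bits <- positives$n_bits
  used <- sort(unique(unlist(positives$bits)))
  free <- setdiff(seq_len(n_bits), used)
  if (length(free) == 0L)
    stop("the positives use every bit; no disjoint bits available ",
         "for decoy generation")
  sizes <- lengths(positives$bits)
  target <- max(1L, as.integer(round(stats::median(sizes))))
  bits <- lapply(seq_len(pool_size), function(i) {
    f <- stats::runif(1, 0, 1 - dissimilarity)
    src <- positives$bits[[sample.int(length(positives$bits), 1L)]]
    n_copy <- min(length(src), as.integer(round(f * target)))
    copied <- if (n_copy > 0L) sample(src, n_copy) else integer(0)
    n_fill <- min(length(free), target - n_copy)
    filler <- if (n_fill > 0L) sample(free, n_fill) else integer(0)
    sort(unique(c(copied, filler)))
  })
  fingerprint_set(bits, n_bits = n_bits,
                  ids = sprintf("decoy%04d", seq_len(pool_size)))
}
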