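# Independent oracles, deliberately coded without reusing package internals.

# Scalar recursive FNT evaluator: walks the node list directly and computes
# the weighted sum and Gaussian activation with plain arithmetic.
oracle_eval <- function(node, x) {
  if (identical(node$type, "x")) return(x[[node$feature]])
  net <- 0
  for (j in seq_along(node$children))
    net <- net + node$weights[[j]] * oracle_eval(node$children[[j]], x)
  exp(-((net - node$a) / node$b)^2)
}

# Set-arithmetic Tanimoto, straight from the definition.
oracle_tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- sum(a %in% b)
  un <- length(a) + length(b) - inter
  if (un == 0) 0 else inter / un
}

# Naive double-loop summed similarity profile.
oracle_summed_similarity <- function(pos_bits, decoy_bits) {
  vapply(decoy_bits, function(g) {
    s <- 0
    for (cj in pos_bits) s <- s + oracle_tanimoto(g, cj)
    s
  }, numeric(1))
}

# AUC by exhaustive enumeration of positive-negative pairs.
oracle_auc_pairs <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (if (p > n) 1 else if (p == n) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# Trapezoidal ROC integration (valid cross-check on tie-free scores).
oracle_auc_trapezoid <- function(y, s) {
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]
  tpr <- cumsum(y == 1) / sum(y == 1)
  fpr <- cumsum(y == 0) / sum(y == 0)
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# A random FNT drawn through the grammar layer, for property sweeps.
random_model <- function(d = 5, max_depth = 4, arities = 2:3) {
  g <- fnt_grammar(arities, d)
  derivation_to_fnt(random_derivation(g, max_depth), input_dim = d,
                    max_depth = max_depth)
}
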