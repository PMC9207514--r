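#' Context-free grammar for flexible neural trees
#'
#' The structure search is grammar-guided: candidate trees are derivation
#' trees of a small context-free grammar \eqn{G = \{N, T, P, \Sigma\}} so
#' that every individual produced by the genetic operators is syntactically
#' valid by construction.  For an arity set \eqn{K} and \eqn{n} input
#' features the grammar is
#' \preformatted{
#'   s   -> exp
#'   exp -> op_k exp ... exp   (k copies, one rule per arity k in K)
#'   exp -> var
#'   op_k -> +_k
#'   var  -> x_1 | ... | x_n
#' }
#' in prefix form: the operator symbol precedes its operand expressions.
#'
#' @param arities integer set of neuron arities, a subset of `2:8`.
#' @param n_features number of input features (terminals `x_1 ... x_n`).
#' @return An object of class `fnt_grammar` with elements `nonterminals`,
#'   `terminals`, `productions` (list of `lhs`/`rhs` pairs), `start`,
#'   `arities` and `n_features`.
#' @examples
#' g <- fnt_grammar(arities = c(2, 3), n_features = 4)
#' g$nonterminals
#' @export
fnt_grammar <- function(arities, n_features) {
  arities <- sort(unique(as.integer(arities)))
  if (length(arities) == 0L)
    stop("'arities' must contain at least one arity")
  if (any(arities < 2L | arities > 8L))
    stop("arities must lie in 2..8")
  n_features <- as.integer(n_features)
  if (n_features < 1L) stop("'n_features' must be >= 1")

  op_syms <- paste0("op", arities)
  nonterminals <- c("s", "exp", "var", op_syms)
  terminals <- c(paste0("+", arities), paste0("x", seq_len(n_features)))

  productions <- list(list(lhs = "s", rhs = "exp"))
  for (k in arities)
    productions <- c(productions, list(
      list(lhs = "exp", rhs = c(paste0("op", k), rep("exp", k)))))
  productions <- c(productions, list(list(lhs = "exp", rhs = "var")))
  for (k in arities)
    productions <- c(productions, list(
      list(lhs = paste0("op", k), rhs = paste0("+", k))))
  for (j in seq_len(n_features))
    productions <- c(productions, list(
      list(lhs = "var", rhs = paste0("x", j))))

  structure(list(nonterminals = nonterminals,
                 terminals = terminals,
                 productions = productions,
                 start = "s",
                 arities = arities,
                 n_features = n_features),
            class = "fnt_grammar")
}

#' @export
print.fnt_grammar <- function(x, ...) {
  cat("FNT grammar: arities {", paste(x$arities, collapse = ", "),
      "}, ", x$n_features, " features\n", sep = "")
  cat("  N = {", paste(x$nonterminals, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

## Derivation-tree nodes are plain lists: non-terminal nodes carry the
## symbol and the children their applied production generated; leaves carry
## a terminal symbol and NULL children.
dt_node <- function(symbol, children = NULL) {
  list(symbol = symbol, children = children)
}

dt_is_leaf <- function(node) is.null(node$children)

## Depth of the FNT a derivation induces: exp nodes expanded to an operator
## contribute a level, exp -> var contributes the terminal level.
induced_exp_depth <- function(exp_node) {
  first <- exp_node$children[[1L]]
  if (identical(first$symbol, "var")) return(1L)
  1L + max(vapply(exp_node$children[-1L], induced_exp_depth, integer(1)))
}

#' @rdname random_derivation
#' @param tree a derivation tree.
#' @export
derivation_depth <- function(tree) {
  stopifnot(identical(tree$symbol, "s"))
  induced_exp_depth(tree$children[[1L]])
}

exp_is_operator <- function(exp_node) {
  !identical(exp_node$children[[1L]]$symbol, "var")
}

#' Random grammar-guided derivation
#'
#' Draws a random derivation tree of the FNT grammar, expanding
#' non-terminals in top-down, left-to-right order.  Rules are chosen
#' uniformly among those whose expansion can still complete within the
#' depth budget, so the induced FNT never exceeds `max_depth`; a draw whose
#' root expands straight to a bare feature is rejected and redrawn (the
#' output layer must be a neuron), with the rejection loop capped at 1000
#' attempts.  Randomness comes from the R random number generator, so a
#' prior `set.seed()` makes draws reproducible.
#'
#' @param grammar an [fnt_grammar()].
#' @param max_depth bound on the induced FNT depth (root = level 1);
#'   at least 2.
#' @return A derivation tree (nested list; the root has symbol `"s"`).
#' @export
random_derivation <- function(grammar, max_depth) {
  stopifnot(inherits(grammar, "fnt_grammar"))
  max_depth <- as.integer(max_depth)
  if (max_depth < 2L) stop("'max_depth' must be >= 2")
  for (attempt in seq_len(1000L)) {
    exp <- expand_exp(grammar, max_depth)
    if (exp_is_operator(exp))
      return(dt_node("s", list(exp)))
  }
  stop("failed to generate a valid derivation in 1000 attempts; ",
       "check the grammar and max_depth")
}

## Expand an exp non-terminal within `budget` remaining FNT levels
## (budget >= 1).  An operator expansion consumes one level and needs
## budget >= 2 for its children.
expand_exp <- function(grammar, budget) {
  choices <- "var"
  if (budget >= 2L) choices <- c(paste0("op", grammar$arities), "var")
  pick <- choices[[sample.int(length(choices), 1L)]]
  if (identical(pick, "var")) {
    j <- sample.int(grammar$n_features, 1L)
    var <- dt_node("var", list(dt_node(paste0("x", j))))
    return(dt_node("exp", list(var)))
  }
  k <- as.integer(sub("^op", "", pick))
  op <- dt_node(pick, list(dt_node(paste0("+", k))))
  kids <- c(list(op),
            lapply(seq_len(k), function(i) expand_exp(grammar, budget - 1L)))
  dt_node("exp", kids)
}

#' Instantiate an FNT from a derivation tree
#'
#' Reads the topology off a derivation tree and draws each neuron's weights
#' and activation parameters uniformly from per-kind bounds.  A drawn `b`
#' of magnitude below `1e-8` is redrawn.
#'
#' @param tree a derivation tree from [random_derivation()].
#' @param input_dim number of input features of the resulting model.
#' @param max_depth depth bound recorded on the model.
#' @param bounds list with numeric length-2 elements `w`, `a`, `b`: the
#'   uniform initialization ranges for weights and activation parameters.
#' @return An [fnt_model()].
#' @export
derivation_to_fnt <- function(tree, input_dim, max_depth = 5L,
                              bounds = list(w = c(-1, 1), a = c(0, 1),
                                            b = c(0.01, 1))) {
  stopifnot(identical(tree$symbol, "s"))
  draw <- function(rg, n = 1L) stats::runif(n, rg[[1L]], rg[[2L]])
  exp_to_node <- function(exp) {
    first <- exp$children[[1L]]
    if (identical(first$symbol, "var")) {
      leaf <- first$children[[1L]]$symbol
      return(fnt_terminal(as.integer(sub("^x", "", leaf))))
    }
    kids <- lapply(exp$children[-1L], exp_to_node)
    b <- draw(bounds$b)
    while (abs(b) < 1e-8) b <- draw(bounds$b)
    fnt_operator(kids,
                 weights = draw(bounds$w, length(kids)),
                 a = draw(bounds$a), b = b)
  }
  fnt_model(exp_to_node(tree$children[[1L]]),
            input_dim = input_dim, max_depth = max_depth)
}

## Paths (child-index vectors from the root) of every non-terminal node
## below the start symbol, with its symbol and the number of operator
## levels above it (used as the regrow budget offset).
dt_nonterminal_paths <- function(tree) {
  acc <- list()
  walk <- function(node, path, op_above) {
    if (dt_is_leaf(node)) return(invisible(NULL))
    if (!identical(node$symbol, "s"))
      acc[[length(acc) + 1L]] <<- list(path = path, symbol = node$symbol,
                                       op_above = op_above)
    below <- op_above
    if (identical(node$symbol, "exp") && exp_is_operator(node))
      below <- op_above + 1L
    for (i in seq_along(node$children))
      walk(node$children[[i]], c(path, i), below)
  }
  walk(tree, integer(0), 0L)
  acc
}

dt_get <- function(tree, path) {
  for (i in path) tree <- tree$children[[i]]
  tree
}

dt_set <- function(tree, path, value) {
  if (length(path) == 0L) return(value)
  i <- path[[1L]]
  tree$children[[i]] <- dt_set(tree$children[[i]], path[-1L], value)
  tree
}

dt_leaf_symbols <- function(tree) {
  acc <- character(0)
  walk <- function(node) {
    if (dt_is_leaf(node)) { acc[[length(acc) + 1L]] <<- node$symbol; return() }
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  acc
}

dt_valid <- function(tree, max_depth) {
  exp_is_operator(tree$children[[1L]]) && derivation_depth(tree) <= max_depth
}

#' Genetic operators on derivation trees
#'
#' `dt_crossover()` picks a non-terminal symbol present in both parents
#' (below the start symbol), one node with that symbol in each tree,
#' uniformly at random, and swaps the two subtrees.  An offspring whose
#' induced FNT would exceed `max_depth`, or whose root would become a bare
#' feature, is discarded and the corresponding parent returned unchanged;
#' when the parents share no non-terminal label both are returned
#' unchanged.  `dt_mutate()` picks a uniformly random non-terminal node,
#' deletes its subtree and regrows it within the remaining depth budget.
#' Both operators are driven by the R random number generator.
#'
#' @param t1,t2,tree derivation trees over the same grammar.
#' @param grammar the [fnt_grammar()] the trees were drawn from.
#' @param max_depth induced FNT depth bound.
#' @return `dt_crossover()`: list of two derivation trees;
#'   `dt_mutate()`: a derivation tree.
#' @export
dt_crossover <- function(t1, t2, max_depth) {
  n1 <- dt_nonterminal_paths(t1)
  n2 <- dt_nonterminal_paths(t2)
  s1 <- vapply(n1, `[[`, character(1), "symbol")
  s2 <- vapply(n2, `[[`, character(1), "symbol")
  common <- intersect(s1, s2)
  if (length(common) == 0L) return(list(t1, t2))
  lab <- common[[sample.int(length(common), 1L)]]
  i1 <- which(s1 == lab); i1 <- i1[[sample.int(length(i1), 1L)]]
  i2 <- which(s2 == lab); i2 <- i2[[sample.int(length(i2), 1L)]]
  p1 <- n1[[i1]]$path; p2 <- n2[[i2]]$path
  sub1 <- dt_get(t1, p1); sub2 <- dt_get(t2, p2)
  c1 <- dt_set(t1, p1, sub2)
  c2 <- dt_set(t2, p2, sub1)
  if (!dt_valid(c1, max_depth)) c1 <- t1
  if (!dt_valid(c2, max_depth)) c2 <- t2
  list(c1, c2)
}

#' @rdname dt_crossover
#' @export
dt_mutate <- function(tree, grammar, max_depth) {
  nodes <- dt_nonterminal_paths(tree)
  pick <- nodes[[sample.int(length(nodes), 1L)]]
  at_root <- length(pick$path) == 1L  # the root exp, child of s
  new_sub <- switch(
    substr(pick$symbol, 1L, 2L),
    ex = {  # exp: regrow within the remaining budget
      budget <- max(1L, max_depth - pick$op_above)
      if (at_root) {
        repeat {
          cand <- expand_exp(grammar, budget)
          if (exp_is_operator(cand)) break
        }
        cand
      } else expand_exp(grammar, budget)
    },
    va = {  # var: redraw the feature
      j <- sample.int(grammar$n_features, 1L)
      dt_node("var", list(dt_node(paste0("x", j))))
    },
    dt_get(tree, pick$path)  # op_k: only one production, unchanged
  )
  dt_set(tree, pick$path, new_sub)
}

#' Tournament parent selection
#'
#' Samples `k` individuals without replacement (fewer if the population is
#' smaller) and returns the index of the fittest; lower fitness is better
#' and ties go to the lowest population index.
#'
#' @param fitness numeric vector of finite fitness values, lower = better.
#' @param k tournament size (default 3).
#' @return Integer index into the population.
#' @export
tournament_select <- function(fitness, k = 3L) {
  n <- length(fitness)
  if (n == 0L) stop("empty population")
  if (!all(is.finite(fitness))) stop("fitness values must be finite")
  idx <- sample.int(n, min(k, n))
  best <- min(fitness[idx])
  min(idx[fitness[idx] == best])
}
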