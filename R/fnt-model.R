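#' Flexible neural tree nodes
#'
#' A flexible neural tree (FNT) is a tree-shaped neural network.  Leaves are
#' input features; every internal node is a "flexible neuron" of arity
#' \eqn{n}: it computes the weighted sum \eqn{net = \sum_j w_j x_j} of its
#' child outputs and passes it through the two-parameter Gaussian activation
#' \eqn{y = \exp(-((net - a)/b)^2)}, so every neuron output lies in
#' \eqn{(0, 1]}.
#'
#' `fnt_terminal(feature)` creates a leaf that returns the `feature`-th
#' input value (1-based).  `fnt_operator(children, weights, a, b)` creates a
#' flexible neuron over `children` (a list of nodes), with one weight per
#' child.  `b` may not be 0 (it sits in the denominator of the activation);
#' values of magnitude below `1e-8` are pushed to `sign(b) * 1e-8`.
#'
#' @param feature 1-based index into the input feature vector.
#' @param children list of child nodes (each from `fnt_terminal()` or
#'   `fnt_operator()`); at least 2.
#' @param weights numeric vector, one weight per child.
#' @param a,b activation parameters (scalars); `b != 0`.
#' @return A node object (plain list, class `fnt_node`).
#' @seealso [fnt_model()], [fnt_evaluate()]
#' @export
fnt_terminal <- function(feature) {
  feature <- as.integer(feature)
  if (length(feature) != 1L || is.na(feature) || feature < 1L)
    stop("'feature' must be a single positive integer")
  structure(list(type = "x", feature = feature), class = "fnt_node")
}

#' @rdname fnt_terminal
#' @export
fnt_operator <- function(children, weights, a, b) {
  if (!is.list(children) || length(children) < 2L)
    stop("an operator node needs at least 2 children")
  if (length(weights) != length(children))
    stop("need exactly one weight per child (", length(children),
         " children, ", length(weights), " weights)")
  if (!all(is.finite(weights)) || !is.finite(a) || !is.finite(b))
    stop("weights, a and b must be finite")
  structure(list(type = "op",
                 weights = as.numeric(weights),
                 a = as.numeric(a),
                 b = guard_b(as.numeric(b)),
                 children = children),
            class = "fnt_node")
}

## b appears in the denominator of the Gaussian activation; keep it away
## from zero while preserving its sign.
guard_b <- function(b) {
  eps <- 1e-8
  if (abs(b) < eps) b <- if (b < 0) -eps else eps
  b
}

is_operator <- function(node) identical(node$type, "op")

#' Flexible neural tree model
#'
#' Wraps a node tree together with the input dimension it expects and the
#' depth bound it was grown under.  The root must be an operator node (the
#' output layer is a flexible neuron, not a raw feature), every terminal's
#' feature index must be within `input_dim`, and the tree depth (root =
#' level 1) must not exceed `max_depth`.
#'
#' @param root an operator node from [fnt_operator()].
#' @param input_dim number of input features the tree reads from.
#' @param max_depth maximum allowed number of node levels.
#' @return An object of class `fnt_model`.
#' @examples
#' m <- fnt_model(
#'   fnt_operator(list(fnt_terminal(1), fnt_terminal(2)),
#'                weights = c(1, 1), a = 1, b = 1),
#'   input_dim = 2)
#' fnt_evaluate(m, c(0.5, 0.5))  # net = 1 = a, so exactly 1
#' @export
fnt_model <- function(root, input_dim, max_depth = 5L) {
  if (!inherits(root, "fnt_node") || !is_operator(root))
    stop("'root' must be an operator node (the output layer is a neuron)")
  input_dim <- as.integer(input_dim)
  max_depth <- as.integer(max_depth)
  model <- structure(list(root = root,
                          input_dim = input_dim,
                          max_depth = max_depth),
                     class = "fnt_model")
  validate_fnt_model(model)
  model
}

validate_fnt_model <- function(model) {
  stopifnot(inherits(model, "fnt_model"))
  if (!is_operator(model$root)) stop("root must be an operator node")
  d <- fnt_depth(model)
  if (d > model$max_depth)
    stop("tree depth ", d, " exceeds max_depth ", model$max_depth)
  check_node <- function(node) {
    if (is_operator(node)) {
      if (length(node$weights) != length(node$children))
        stop("operator node weight/child count mismatch")
      if (node$b == 0) stop("activation parameter b must be non-zero")
      lapply(node$children, check_node)
    } else {
      if (node$feature > model$input_dim)
        stop("terminal feature index ", node$feature,
             " exceeds input_dim ", model$input_dim)
    }
    invisible(NULL)
  }
  check_node(model$root)
  invisible(model)
}

#' Tree depth of an FNT
#'
#' Number of node levels, counting the root as level 1; a neuron over bare
#' features has depth 2.
#'
#' @param model an [fnt_model()].
#' @return Integer depth.
#' @export
fnt_depth <- function(model) {
  node_depth <- function(node) {
    if (!is_operator(node)) return(1L)
    1L + max(vapply(node$children, node_depth, integer(1)))
  }
  node_depth(model$root)
}

#' Evaluate a flexible neural tree
#'
#' Computes the tree output bottom-up: terminals return the corresponding
#' input feature, each neuron computes its weighted sum and Gaussian
#' activation.  `x` may be a single feature vector or a matrix with one row
#' per observation and `input_dim` columns; the result is one score per
#' observation, each in \eqn{(0, 1]}.
#'
#' @param model an [fnt_model()].
#' @param x numeric vector of length `input_dim`, or matrix with
#'   `input_dim` columns.
#' @return Numeric vector of tree outputs.
#' @export
fnt_evaluate <- function(model, x) {
  validate_fnt_model(model)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$input_dim)
    stop("x has ", ncol(x), " columns but the model expects ",
         model$input_dim)
  if (nrow(x) == 0L) return(numeric(0))
  if (!all(is.finite(x))) stop("x must be finite")
  eval_node(model$root, x)
}

eval_node <- function(node, x) {
  if (!is_operator(node)) return(x[, node$feature])
  kids <- vapply(node$children, eval_node, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) kids <- matrix(kids, nrow = 1L)
  net <- drop(kids %*% node$weights)
  exp(-((net - node$a) / node$b)^2)
}

#' Classify with a flexible neural tree
#'
#' A compound is called related (label 1) when the tree output is strictly
#' greater than `threshold`; a score exactly at the threshold is unrelated.
#'
#' @inheritParams fnt_evaluate
#' @param threshold decision cutoff on the tree score; default 0.5.
#' @return Integer vector of 0/1 labels.
#' @export
fnt_predict_label <- function(model, x, threshold = 0.5) {
  as.integer(fnt_evaluate(model, x) > threshold)
}

#' Flatten and restore FNT parameters
#'
#' The tunable parameters of an FNT are, for each operator node, its child
#' weights followed by its activation parameters `a` and `b`.
#' `fnt_params()` flattens them in pre-order traversal into a single numeric
#' vector; `fnt_set_params()` writes such a vector back into a tree of the
#' same topology (restoring any `b` of magnitude below `1e-8` to
#' `sign(b) * 1e-8`).  `fnt_param_kinds()` labels each slot `"w"`, `"a"` or
#' `"b"`, which the trainer uses to assign per-kind search bounds.
#'
#' @param model an [fnt_model()].
#' @param values numeric vector of length `fnt_n_params(model)`.
#' @return `fnt_params()`: numeric vector; `fnt_set_params()`: a new
#'   `fnt_model`; `fnt_n_params()`: integer; `fnt_param_kinds()`: character
#'   vector.
#' @export
fnt_params <- function(model) {
  collect <- function(node) {
    if (!is_operator(node)) return(numeric(0))
    c(node$weights, node$a, node$b,
      unlist(lapply(node$children, collect), use.names = FALSE))
  }
  collect(model$root)
}

#' @rdname fnt_params
#' @export
fnt_n_params <- function(model) {
  count <- function(node) {
    if (!is_operator(node)) return(0L)
    length(node$children) + 2L +
      sum(vapply(node$children, count, integer(1)))
  }
  count(model$root)
}

#' @rdname fnt_params
#' @export
fnt_param_kinds <- function(model) {
  collect <- function(node) {
    if (!is_operator(node)) return(character(0))
    c(rep("w", length(node$children)), "a", "b",
      unlist(lapply(node$children, collect), use.names = FALSE))
  }
  collect(model$root)
}

#' @rdname fnt_params
#' @export
fnt_set_params <- function(model, values) {
  values <- as.numeric(values)
  n <- fnt_n_params(model)
  if (length(values) != n)
    stop("parameter vector has length ", length(values),
         " but the model has ", n, " parameters")
  pos <- 0L
  inject <- function(node) {
    if (!is_operator(node)) return(node)
    k <- length(node$children)
    node$weights <- values[(pos + 1L):(pos + k)]
    node$a <- values[pos + k + 1L]
    node$b <- guard_b(values[pos + k + 2L])
    pos <<- pos + k + 2L
    node$children <- lapply(node$children, inject)
    node
  }
  model$root <- inject(model$root)
  model
}

#' Serialize an FNT model to JSON
#'
#' Writes the full tree (topology and parameters) plus `input_dim` and
#' `max_depth` as a versioned JSON document, and reads it back.  Numbers are
#' serialized at full precision, so a round-trip reproduces the model
#' exactly.
#'
#' @param model an [fnt_model()].
#' @param path file to write; if `NULL`, the JSON text is returned.
#' @return `fnt_to_json()`: the JSON string (invisibly when `path` is
#'   given); `fnt_from_json()`: an `fnt_model`.
#' @export
fnt_to_json <- function(model, path = NULL) {
  validate_fnt_model(model)
  node_to_list <- function(node) {
    if (!is_operator(node))
      return(list(kind = "terminal", feature_index = node$feature))
    list(kind = "operator",
         arity = length(node$children),
         weights = node$weights,
         a = node$a,
         b = node$b,
         children = lapply(node$children, node_to_list))
  }
  doc <- list(format = "fnt-model/1",
              input_dim = model$input_dim,
              max_depth = model$max_depth,
              root = node_to_list(model$root))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname fnt_to_json
#' @param json JSON text or path to a file written by `fnt_to_json()`.
#' @export
fnt_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(doc$format, "fnt-model/1"))
    stop("not an FNT model document (format tag: ",
         deparse(doc$format), ")")
  node_from_list <- function(rec) {
    if (identical(rec$kind, "terminal"))
      return(fnt_terminal(rec$feature_index))
    fnt_operator(lapply(rec$children, node_from_list),
                 weights = unlist(rec$weights),
                 a = rec$a, b = rec$b)
  }
  fnt_model(node_from_list(doc$root),
            input_dim = doc$input_dim,
            max_depth = doc$max_depth)
}

#' @export
print.fnt_model <- function(x, ...) {
  n_op <- function(node) {
    if (!is_operator(node)) return(0L)
    1L + sum(vapply(node$children, n_op, integer(1)))
  }
  cat("Flexible neural tree\n")
  cat("  input features :", x$input_dim, "\n")
  cat("  depth          :", fnt_depth(x), "(max", paste0(x$max_depth, ")"), "\n")
  cat("  neurons        :", n_op(x$root), "\n")
  cat("  parameters     :", fnt_n_params(x), "\n")
  invisible(x)
}
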