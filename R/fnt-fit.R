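#' Control parameters for the hybrid FNT trainer
#'
#' Collects the tunable settings of the structure/parameter co-evolution.
#' Defaults follow the published study conditions where stated (population
#' 30, maximum tree depth 5, arity set \{2,3,4,5\}); the remaining knobs
#' are documented package choices.
#'
#' @param pop_size GP population size (also the salp count of the final
#'   deep parameter search).  Default 30.
#' @param max_depth maximum FNT depth, root = level 1.  Default 5.
#' @param arities neuron arity set.  Default `2:5`.
#' @param gp_generations number of GP generations of structure search.
#' @param crossover_rate probability an offspring pair is produced by
#'   subtree crossover rather than replication.
#' @param mutation_rate per-offspring probability of subtree mutation.
#' @param tournament_k tournament size for parent selection.
#' @param ssa_screen_pop,ssa_screen_iter salp count and iterations of the
#'   cheap per-individual parameter polish applied during the GP phase.
#' @param ssa_final_pop,ssa_final_iter salp count and iterations of the
#'   deep parameter search on the best structure after the GP phase.
#' @param bounds list of length-2 numeric ranges `w`, `a`, `b`: the search
#'   box (and initialization range) for weights and activation parameters.
#'   Defaults: weights in \[-1, 1\], `a` in \[0, 1\], `b` in \[0.01, 1\].
#' @param threshold score cutoff for the related/unrelated call; a
#'   compound is related when its score is strictly above it.  Default 0.5.
#' @return A list of class `fnt_control`.
#' @export
fnt_control <- function(pop_size = 30L, max_depth = 5L, arities = 2:5,
                        gp_generations = 10L,
                        crossover_rate = 0.8, mutation_rate = 0.2,
                        tournament_k = 3L,
                        ssa_screen_pop = 10L, ssa_screen_iter = 15L,
                        ssa_final_pop = 30L, ssa_final_iter = 100L,
                        bounds = list(w = c(-1, 1), a = c(0, 1),
                                      b = c(0.01, 1)),
                        threshold = 0.5) {
  ctrl <- list(pop_size = as.integer(pop_size),
               max_depth = as.integer(max_depth),
               arities = as.integer(arities),
               gp_generations = as.integer(gp_generations),
               crossover_rate = crossover_rate,
               mutation_rate = mutation_rate,
               tournament_k = as.integer(tournament_k),
               ssa_screen_pop = as.integer(ssa_screen_pop),
               ssa_screen_iter = as.integer(ssa_screen_iter),
               ssa_final_pop = as.integer(ssa_final_pop),
               ssa_final_iter = as.integer(ssa_final_iter),
               bounds = bounds,
               threshold = threshold)
  if (ctrl$pop_size < 2L) stop("'pop_size' must be >= 2")
  if (ctrl$max_depth < 2L) stop("'max_depth' must be >= 2")
  for (nm in c("w", "a", "b"))
    if (length(ctrl$bounds[[nm]]) != 2L ||
        ctrl$bounds[[nm]][[1L]] >= ctrl$bounds[[nm]][[2L]])
      stop("bounds$", nm, " must be a valid (low, high) range")
  class(ctrl) <- "fnt_control"
  ctrl
}

#' Training fitness of an FNT
#'
#' Root-mean-square error between the continuous tree output and the 0/1
#' labels; lower is better and the value lies in \[0, 1\] because the tree
#' output does.  This is the objective both evolutionary layers minimize.
#'
#' @param model an [fnt_model()].
#' @param x feature matrix scaled to \[0, 1\], rows = compounds.
#' @param y 0/1 labels, one per row of `x`.
#' @return Scalar RMSE.
#' @export
fnt_fitness <- function(model, x, y) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  if (nrow(x) == 0L) stop("empty training data")
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  sqrt(mean((fnt_evaluate(model, x) - as.numeric(y))^2))
}

## Per-parameter search box from the per-kind bounds.
param_box <- function(model, bounds) {
  kinds <- fnt_param_kinds(model)
  list(lower = vapply(kinds, function(k) bounds[[k]][[1L]], numeric(1)),
       upper = vapply(kinds, function(k) bounds[[k]][[2L]], numeric(1)))
}

## Flatten a tree into a post-order evaluation schedule so the optimizer
## can score a parameter vector without rebuilding the node structure.
## Parameter positions follow the pre-order weights/a/b layout of
## fnt_params().  Each schedule entry holds, per child, either a feature
## column (kind 0) or an earlier entry's output (kind 1).
compile_structure <- function(model) {
  ops <- list()
  pos <- 0L
  walk <- function(node) {
    if (!is_operator(node)) return(c(0L, node$feature))
    k <- length(node$children)
    w <- (pos + 1L):(pos + k)
    a <- pos + k + 1L
    b <- pos + k + 2L
    pos <<- pos + k + 2L
    kids <- lapply(node$children, walk)
    id <- length(ops) + 1L
    ops[[id]] <<- list(kids = kids, w = w, a = a, b = b)
    c(1L, id)
  }
  root <- walk(model$root)
  list(ops = ops, root = root[[2L]], n_params = pos)
}

eval_compiled <- function(schedule, v, xcols) {
  vals <- vector("list", length(schedule$ops))
  for (id in seq_along(schedule$ops)) {
    op <- schedule$ops[[id]]
    w <- v[op$w]
    net <- 0
    for (j in seq_along(op$kids)) {
      kd <- op$kids[[j]]
      cv <- if (kd[[1L]] == 0L) xcols[[kd[[2L]]]] else vals[[kd[[2L]]]]
      net <- net + w[[j]] * cv
    }
    b <- guard_b(v[[op$b]])
    vals[[id]] <- exp(-((net - v[[op$a]]) / b)^2)
  }
  vals[[schedule$root]]
}

## SSA polish of one structure's parameters; the current parameter vector
## is seeded into the swarm so the result can only improve on it.
polish_params <- function(model, x, y, bounds, n_pop, max_iter) {
  box <- param_box(model, bounds)
  schedule <- compile_structure(model)
  xcols <- lapply(seq_len(ncol(x)), function(j) x[, j])
  yn <- as.numeric(y)
  fitfn <- function(v) sqrt(mean((eval_compiled(schedule, v, xcols) - yn)^2))
  out <- ssa_optimize(fitfn, box$lower, box$upper, n_pop = n_pop,
                      max_iter = max_iter,
                      init = matrix(fnt_params(model), nrow = 1L))
  list(model = fnt_set_params(model, out$par), fitness = out$value,
       trace = out$trace)
}

#' Fit a flexible neural tree classifier
#'
#' Trains an FNT on a labeled feature matrix with the hybrid evolutionary
#' scheme: grammar-guided genetic programming searches tree structures
#' while the salp swarm algorithm tunes each candidate's weights and
#' activation parameters.  Every individual receives a short parameter
#' polish (`ssa_screen_pop` salps for `ssa_screen_iter` iterations) before
#' its fitness — the RMSE of the tree output against the 0/1 labels — is
#' read; generations then apply elitist replication, tournament selection,
#' subtree crossover and mutation.  After the GP phase the best structure
#' gets a deep parameter search (`ssa_final_pop` x `ssa_final_iter`).
#'
#' Features are min-max scaled to \[0, 1\] internally (the scaling is
#' stored and re-applied by `predict`), so inputs can be raw fingerprints
#' or descriptors.  With a fixed `seed` the fit is fully reproducible:
#' same structure, parameters and predictions.
#'
#' @param x numeric feature matrix or data frame, one row per compound.
#' @param y labels: 0/1, logical, or a two-level factor whose second level
#'   is taken as the positive (related) class.  Both classes must have at
#'   least 2 members.
#' @param control an [fnt_control()] object.
#' @param seed optional integer seed for end-to-end reproducibility.
#' @return An object of class `fnt_fit` with components `model` (the
#'   fitted [fnt_model()]), `fitness` (final training RMSE), `trace`
#'   (list: `gp`, best fitness per generation; `final_ssa`, the deep
#'   search trace), `scaling`, `control`, `seed`, `feature_names`,
#'   `fitted_scores` and `y`.  Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' blobs <- sim_blobs(n_pos = 30, n_neg = 30, d = 4, seed = 7)
#' fit <- fnt_fit(blobs$x, blobs$y, seed = 7,
#'                control = fnt_control(pop_size = 6, gp_generations = 2,
#'                                      ssa_screen_iter = 5,
#'                                      ssa_final_iter = 10))
#' fit
#' @export
fnt_fit <- function(x, y, control = fnt_control(), seed = NULL) {
  cl <- match.call()
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- coerce_labels(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  tab <- table(y)
  if (length(tab) < 2L)
    stop("training data contains a single class; need both 0 and 1 labels")
  if (min(tab) < 2L) stop("need at least 2 samples per class")
  if (!is.null(seed)) set.seed(as.integer(seed))

  scaling <- minmax_fit(x)
  xs <- minmax_apply(x, scaling)
  ctrl <- control
  grammar <- fnt_grammar(ctrl$arities, ncol(x))

  new_individual <- function(dtree) {
    model <- derivation_to_fnt(dtree, ncol(x), ctrl$max_depth, ctrl$bounds)
    pol <- polish_params(model, xs, y, ctrl$bounds,
                         ctrl$ssa_screen_pop, ctrl$ssa_screen_iter)
    list(dtree = dtree, model = pol$model, fitness = pol$fitness)
  }

  pop <- lapply(seq_len(ctrl$pop_size), function(i)
    new_individual(random_derivation(grammar, ctrl$max_depth)))

  gp_trace <- numeric(ctrl$gp_generations + 1L)
  fitness_of <- function(p) vapply(p, `[[`, numeric(1), "fitness")
  gp_trace[[1L]] <- min(fitness_of(pop))

  for (g in seq_len(ctrl$gp_generations)) {
    fit <- fitness_of(pop)
    elite <- pop[[min(which(fit == min(fit)))]]
    nxt <- list(elite)
    while (length(nxt) < ctrl$pop_size) {
      if (stats::runif(1) < ctrl$crossover_rate) {
        i <- tournament_select(fit, ctrl$tournament_k)
        j <- tournament_select(fit, ctrl$tournament_k)
        kids <- dt_crossover(pop[[i]]$dtree, pop[[j]]$dtree,
                             ctrl$max_depth)
      } else {
        i <- tournament_select(fit, ctrl$tournament_k)
        kids <- list(pop[[i]]$dtree)
      }
      for (kd in kids) {
        if (length(nxt) >= ctrl$pop_size) break
        if (stats::runif(1) < ctrl$mutation_rate)
          kd <- dt_mutate(kd, grammar, ctrl$max_depth)
        nxt[[length(nxt) + 1L]] <- new_individual(kd)
      }
    }
    pop <- nxt
    gp_trace[[g + 1L]] <- min(fitness_of(pop))
  }

  fit <- fitness_of(pop)
  best <- pop[[min(which(fit == min(fit)))]]
  deep <- polish_params(best$model, xs, y, ctrl$bounds,
                        ctrl$ssa_final_pop, ctrl$ssa_final_iter)

  scores <- fnt_evaluate(deep$model, xs)
  structure(list(model = deep$model,
                 fitness = deep$fitness,
                 trace = list(gp = gp_trace, final_ssa = deep$trace),
                 scaling = scaling,
                 control = ctrl,
                 seed = seed,
                 feature_names = colnames(x),
                 fitted_scores = scores,
                 y = y,
                 call = cl),
            class = "fnt_fit")
}

coerce_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) > 2L) stop("y must have at most two levels")
    y <- as.integer(y) - 1L
  } else if (is.logical(y)) {
    y <- as.integer(y)
  } else {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("y must contain only 0/1 labels")
  }
  as.integer(y)
}

#' Predict from a fitted FNT classifier
#'
#' Applies the stored min-max scaling (values outside the training range
#' are clipped to \[0, 1\]) and evaluates the fitted tree.  Scores lie in
#' \eqn{(0, 1]}; a compound is labeled related (1) when its score is
#' strictly greater than the threshold.
#'
#' @param object an `fnt_fit` object.
#' @param newdata feature matrix with the training columns.
#' @param type `"score"` for the continuous tree output, `"label"` for
#'   0/1 calls.
#' @param threshold decision cutoff; defaults to the trained control's
#'   threshold (0.5).
#' @param ... unused.
#' @return Numeric scores or integer labels, one per row of `newdata`.
#' @export
predict.fnt_fit <- function(object, newdata, type = c("score", "label"),
                            threshold = NULL, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$model$input_dim)
    stop("newdata has ", ncol(newdata), " columns but the model expects ",
         object$model$input_dim)
  if (nrow(newdata) == 0L)
    return(if (type == "score") numeric(0) else integer(0))
  xs <- minmax_apply(newdata, object$scaling)
  scores <- fnt_evaluate(object$model, xs)
  if (type == "score") return(scores)
  thr <- if (is.null(threshold)) object$control$threshold else threshold
  as.integer(scores > thr)
}

#' @export
print.fnt_fit <- function(x, ...) {
  cat("Flexible neural tree classifier (GGGP structure + SSA parameters)\n")
  cat("  training samples :", length(x$y),
      sprintf("(%d related / %d unrelated)", sum(x$y == 1L), sum(x$y == 0L)),
      "\n")
  cat("  tree depth       :", fnt_depth(x$model), "of max",
      x$model$max_depth, "\n")
  cat("  parameters       :", fnt_n_params(x$model), "\n")
  cat("  training RMSE    :", format(x$fitness, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.fnt_fit <- function(object, ...) {
  m <- classification_metrics(object$y, object$fitted_scores,
                              threshold = object$control$threshold)
  out <- list(fit = object, train_metrics = m)
  class(out) <- "summary.fnt_fit"
  out
}

#' @export
print.summary.fnt_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTraining-set performance (threshold ",
      x$fit$control$threshold, "):\n", sep = "")
  print(x$train_metrics)
  invisible(x)
}

#' @export
coef.fnt_fit <- function(object, ...) fnt_params(object$model)

#' @export
fitted.fnt_fit <- function(object, ...) object$fitted_scores

#' @export
residuals.fnt_fit <- function(object, ...) {
  as.numeric(object$y) - object$fitted_scores
}

#' Plot the optimization trace of a fitted FNT
#'
#' Shows the best training RMSE across GP generations and across the final
#' deep SSA phase.
#'
#' @param x an `fnt_fit` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fnt_fit <- function(x, ...) {
  gp <- x$trace$gp
  fs <- x$trace$final_ssa
  xs <- c(seq_along(gp), length(gp) + seq_along(fs))
  ys <- c(gp, fs)
  graphics::plot(xs, ys, type = "s", xlab = "optimization step",
                 ylab = "best training RMSE", ...)
  graphics::abline(v = length(gp) + 0.5, lty = 2, col = "grey50")
  invisible(x)
}

#' Save and load a fitted FNT classifier
#'
#' The fitted tree, feature scaling and decision threshold are written as
#' a versioned JSON document so a trained screen can be re-applied later
#' or from the command line.
#'
#' @param object an `fnt_fit` object.
#' @param path file path.
#' @return `fnt_save()`: the path, invisibly; `fnt_load()`: an object
#'   usable with `predict()` (class `fnt_fit`).
#' @export
fnt_save <- function(object, path) {
  stopifnot(inherits(object, "fnt_fit"))
  doc <- list(format = "fnt-fit/1",
              model = jsonlite::fromJSON(fnt_to_json(object$model),
                                         simplifyVector = FALSE),
              scaling = list(min = object$scaling$min,
                             max = object$scaling$max),
              threshold = object$control$threshold,
              feature_names = object$feature_names,
              seed = object$seed)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              null = "null"), path)
  invisible(path)
}

#' @rdname fnt_save
#' @export
fnt_load <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "fnt-fit/1"))
    stop("not a saved FNT classifier (format tag: ", deparse(doc$format), ")")
  model <- fnt_from_json(jsonlite::toJSON(doc$model, auto_unbox = TRUE,
                                          digits = I(17)))
  structure(list(model = model,
                 fitness = NA_real_,
                 trace = NULL,
                 scaling = list(min = unlist(doc$scaling$min),
                                max = unlist(doc$scaling$max)),
                 control = fnt_control(threshold = doc$threshold),
                 seed = doc$seed,
                 feature_names = unlist(doc$feature_names),
                 fitted_scores = NULL,
                 y = NULL),
            class = "fnt_fit")
}
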