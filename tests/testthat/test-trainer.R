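# Hybrid GGGP + SSA trainer and the fnt_fit interface

tiny_ctrl <- function(gp_generations = 2) {
  fnt_control(pop_size = 5, gp_generations = gp_generations,
              ssa_screen_pop = 4, ssa_screen_iter = 4,
              ssa_final_pop = 6, ssa_final_iter = 8)
}

test_that("training fitness is the RMSE of scores against labels", {
  # neuron with zero weights and a = 0 outputs exactly 1 for every input
  m <- fnt_model(fnt_operator(list(fnt_terminal(1), fnt_terminal(2)),
                              weights = c(0, 0), a = 0, b = 1),
                 input_dim = 2)
  x <- matrix(runif(10), ncol = 2)
  expect_identical(fnt_fitness(m, x, rep(1, 5)), 0)   # perfect fit
  # constant 0.5 output on balanced labels gives RMSE 0.5
  m5 <- fnt_set_params(m, c(0, 0, sqrt(log(2)), 1))
  y <- c(1, 1, 0, 0)
  expect_equal(fnt_fitness(m5, x[1:4, ], y), 0.5, tolerance = 1e-9)
  # invariant under row permutation
  set.seed(4)
  x2 <- matrix(runif(24), ncol = 2)
  y2 <- rep(c(0, 1), 6)
  p <- sample(12)
  expect_equal(fnt_fitness(m5, x2, y2), fnt_fitness(m5, x2[p, ], y2[p]),
               tolerance = 1e-15)
  expect_error(fnt_fitness(m, x[0, , drop = FALSE], integer(0)), "empty")
})

test_that("degenerate training data is rejected", {
  x <- matrix(runif(20), ncol = 2)
  expect_error(fnt_fit(x, rep(1, 10), control = tiny_ctrl()),
               "single class")
  expect_error(fnt_fit(x, c(1, rep(0, 9)), control = tiny_ctrl()),
               "2 samples per class")
  expect_error(fnt_fit(x, c(rep(1, 5), rep(2, 5)), control = tiny_ctrl()),
               "0/1")
})

test_that("fitting is deterministic under a fixed seed", {
  b <- sim_blobs(n_pos = 12, n_neg = 12, d = 3, seed = 2)
  f1 <- fnt_fit(b$x, b$y, control = tiny_ctrl(), seed = 123)
  f2 <- fnt_fit(b$x, b$y, control = tiny_ctrl(), seed = 123)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$model, f2$model)
  expect_identical(predict(f1, b$x), predict(f2, b$x))
  expect_identical(f1$trace, f2$trace)
})

test_that("best-so-far fitness is monotone across generations and the deep polish", {
  b <- sim_blobs(n_pos = 12, n_neg = 12, d = 3, seed = 5)
  fit <- fnt_fit(b$x, b$y, control = tiny_ctrl(gp_generations = 4),
                 seed = 31)
  expect_true(all(diff(fit$trace$gp) <= 0))
  expect_true(all(diff(fit$trace$final_ssa) <= 0))
  expect_lte(fit$fitness, min(fit$trace$gp))
  expect_identical(fit$fitness, fit$trace$final_ssa[length(fit$trace$final_ssa)])
})

test_that("predictions respect the activation range and the strict threshold", {
  b <- sim_blobs(n_pos = 12, n_neg = 12, d = 3, seed = 8)
  fit <- fnt_fit(b$x, b$y, control = tiny_ctrl(), seed = 9)
  sc <- predict(fit, b$x, type = "score")
  expect_true(all(sc > 0 & sc <= 1))
  lb <- predict(fit, b$x, type = "label")
  expect_identical(lb, as.integer(sc > 0.5))
  # exact-threshold scores are unrelated
  expect_identical(predict(fit, b$x, type = "label", threshold = max(sc)),
                   as.integer(sc > max(sc)))
  expect_identical(predict(fit, b$x[0, , drop = FALSE]), numeric(0))
  expect_error(predict(fit, b$x[, 1:2]), "columns")
})

test_that("accessor methods expose the fitted model", {
  b <- sim_blobs(n_pos = 10, n_neg = 10, d = 3, seed = 13)
  fit <- fnt_fit(b$x, b$y, control = tiny_ctrl(), seed = 14)
  expect_identical(coef(fit), fnt_params(fit$model))
  expect_identical(fitted(fit), fit$fitted_scores)
  expect_equal(residuals(fit), as.numeric(b$y) - fitted(fit),
               tolerance = 1e-15)
  expect_output(print(fit), "Flexible neural tree")
  expect_output(print(summary(fit)), "Training-set performance")
})

test_that("a saved model predicts identically after reload", {
  b <- sim_blobs(n_pos = 10, n_neg = 10, d = 3, seed = 17)
  fit <- fnt_fit(b$x, b$y, control = tiny_ctrl(), seed = 18)
  path <- withr::local_tempfile(fileext = ".json")
  fnt_save(fit, path)
  back <- fnt_load(path)
  expect_equal(predict(back, b$x), predict(fit, b$x), tolerance = 1e-15)
  expect_identical(predict(back, b$x, type = "label"),
                   predict(fit, b$x, type = "label"))
})

test_that("the compiled fitness path agrees with the reference evaluator", {
  set.seed(55)
  for (i in 1:20) {
    m <- random_model(d = 4, max_depth = 4, arities = 2:4)
    x <- matrix(runif(48), ncol = 4)
    y <- rep(c(0, 1), 6)
    schedule <- fntscreen:::compile_structure(m)
    xcols <- lapply(1:4, function(j) x[, j])
    v <- fnt_params(m)
    compiled <- fntscreen:::eval_compiled(schedule, v, xcols)
    expect_equal(compiled, fnt_evaluate(m, x), tolerance = 1e-14)
  }
})
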