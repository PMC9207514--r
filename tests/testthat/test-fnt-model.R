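# Flexible neural tree representation and evaluation

two_terminal_model <- function(w = c(1, 1), a = 1, b = 1) {
  fnt_model(fnt_operator(list(fnt_terminal(1), fnt_terminal(2)),
                         weights = w, a = a, b = b),
            input_dim = 2)
}

test_that("Gaussian neuron evaluates its closed form", {
  m <- two_terminal_model(a = 1, b = 1)
  # net = 0.5 + 0.5 = 1 = a, so the activation peaks at exactly 1
  expect_identical(fnt_evaluate(m, c(0.5, 0.5)), 1)

  m2 <- two_terminal_model(a = 0, b = 1)
  expect_equal(fnt_evaluate(m2, c(0.5, 0.5)), exp(-1), tolerance = 1e-15)

  # matrix input evaluates row-wise
  x <- rbind(c(0.5, 0.5), c(0, 0), c(1, 1))
  expect_equal(fnt_evaluate(m2, x), exp(-c(1, 0, 4)), tolerance = 1e-15)
})

test_that("evaluation agrees with an independent recursive oracle", {
  set.seed(101)
  for (i in 1:200) {
    m <- random_model(d = 5, max_depth = 4, arities = 2:3)
    x <- runif(5, -2, 2)
    expect_equal(fnt_evaluate(m, x), oracle_eval(m$root, x),
                 tolerance = 1e-12)
  }
})

test_that("every neuron output lies in the Gaussian activation range", {
  set.seed(7)
  for (i in 1:50) {
    m <- random_model(d = 4, max_depth = 5, arities = 2:4)
    # mathematically (0, 1]; exp() underflows to exactly 0 for extreme
    # net inputs, so the representable range is [0, 1]
    y <- fnt_evaluate(m, matrix(runif(40, -5, 5), ncol = 4))
    expect_true(all(y >= 0 & y <= 1))
    y01 <- fnt_evaluate(m, matrix(runif(40), ncol = 4))
    expect_true(all(y01 >= 0 & y01 <= 1))
  }
})

test_that("label rule is strictly greater-than the threshold", {
  m <- two_terminal_model(a = 0, b = 1)
  x <- c(0.5, 0.5)
  y <- fnt_evaluate(m, x)
  expect_identical(fnt_predict_label(m, x, threshold = y), 0L)       # == thr
  expect_identical(fnt_predict_label(m, x, threshold = y - 1e-9), 1L)
  expect_identical(fnt_predict_label(m, x, threshold = y + 1e-9), 0L)
})

test_that("parameter vector layout and round-trip", {
  m <- two_terminal_model(w = c(0.3, -0.7), a = 0.2, b = 0.9)
  expect_identical(fnt_n_params(m), 4L)  # 2 weights + a + b
  expect_identical(fnt_params(m), c(0.3, -0.7, 0.2, 0.9))
  expect_identical(fnt_param_kinds(m), c("w", "w", "a", "b"))

  # nested: root +2 whose left child is +3 over terminals -> (2+2)+(3+2)
  inner <- fnt_operator(list(fnt_terminal(1), fnt_terminal(2),
                             fnt_terminal(3)),
                        weights = c(1, 2, 3), a = 0.5, b = 0.5)
  m2 <- fnt_model(fnt_operator(list(inner, fnt_terminal(4)),
                               weights = c(1, -1), a = 0, b = 1),
                  input_dim = 4)
  expect_identical(fnt_n_params(m2), 9L)
  expect_identical(fnt_set_params(m2, fnt_params(m2)), m2)
})

test_that("injected parameters reproduce the donor model", {
  set.seed(33)
  g <- fnt_grammar(2:3, 4)
  dt <- random_derivation(g, 4)
  donor <- derivation_to_fnt(dt, 4, 4)
  receiver <- derivation_to_fnt(dt, 4, 4)  # same topology, new params
  receiver <- fnt_set_params(receiver, fnt_params(donor))
  x <- matrix(runif(200), ncol = 4)
  expect_equal(fnt_evaluate(receiver, x), fnt_evaluate(donor, x),
               tolerance = 1e-12)
})

test_that("b is guarded away from zero", {
  m <- two_terminal_model()
  m0 <- fnt_set_params(m, c(1, 1, 0, 0))       # b = 0
  expect_identical(fnt_params(m0)[4], 1e-8)
  expect_true(is.finite(fnt_evaluate(m0, c(0.1, 0.2))))
  mneg <- fnt_set_params(m, c(1, 1, 0, -1e-12))
  expect_identical(fnt_params(mneg)[4], -1e-8)
})

test_that("invalid construction and inputs are rejected", {
  expect_error(fnt_model(fnt_terminal(1), input_dim = 2), "operator")
  expect_error(fnt_set_params(two_terminal_model(), c(1, 2)), "length")
  expect_error(fnt_evaluate(two_terminal_model(), c(1, 2, 3)), "columns")
  expect_error(fnt_operator(list(fnt_terminal(1)), weights = 1,
                            a = 0, b = 1), "children")
  expect_error(
    fnt_model(fnt_operator(list(fnt_terminal(1), fnt_terminal(5)),
                           weights = c(1, 1), a = 0, b = 1),
              input_dim = 2),
    "input_dim")
})

test_that("tree depth counts node levels from the root", {
  expect_identical(fnt_depth(two_terminal_model()), 2L)
  inner <- fnt_operator(list(fnt_terminal(1), fnt_terminal(2)),
                        weights = c(1, 1), a = 0, b = 1)
  outer <- fnt_model(fnt_operator(list(inner, fnt_terminal(1)),
                                  weights = c(1, 1), a = 0, b = 1),
                     input_dim = 2, max_depth = 3)
  expect_identical(fnt_depth(outer), 3L)
})

test_that("JSON serialization round-trips exactly", {
  set.seed(5)
  m <- random_model(d = 4, max_depth = 4)
  txt <- fnt_to_json(m)
  m2 <- fnt_from_json(txt)
  expect_identical(fnt_params(m2), fnt_params(m))
  x <- matrix(runif(40), ncol = 4)
  expect_identical(fnt_evaluate(m2, x), fnt_evaluate(m, x))
  expect_error(fnt_from_json('{"format": "something-else"}'), "format tag")
})
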