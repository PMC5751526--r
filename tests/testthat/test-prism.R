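test_that("the example model matches its golden file byte for byte", {
  art <- emit_model(example_problem())
  golden <- paste(readLines(test_path("golden-pex.pm")), collapse = "\n")
  expect_identical(art$model, golden)
  expect_identical(art$property,
                   paste(readLines(test_path("golden-pex.props")), collapse = "\n"))
  # emission is idempotent
  expect_identical(emit_model(example_problem())$model, art$model)
})

test_that("generated code carries the expected formulas, probabilities and guards", {
  art <- emit_model(example_problem())
  expect_match(art$model, "formula f11 = x1\\+u-x1\\*u;")
  expect_match(art$model, "formula f12 = x1\\*x2;")
  expect_match(art$model, "formula f21 = x1\\*\\(1-u\\);")
  expect_match(art$model, "0.3 : \\(s'=true\\) \\+ 0.7 : \\(s'=false\\)")
  expect_match(art$model, "0.1 : \\(p1'=1\\) \\+ 0.9 : \\(p1'=0\\)")
  expect_match(art$model, "\\[PBN\\] t<=3 & u=1 : 1;")
  expect_match(art$model, "t=4 & x1=0 & x2=1 : 2;")
  expect_match(art$model, "t=4 & x1=1 & x2=0 : 4;")
  expect_match(art$model, "t=4 & x1=1 & x2=1 : 6;")
  expect_false(grepl("x1=0 & x2=0", art$model))  # zero entries omitted
  expect_true(startsWith(art$model, "mdp;"))
  expect_true(all(grepl("\\[PBN\\]", grep("->", strsplit(art$model, "\n")[[1]],
                                          value = TRUE))))
})

test_that("properties target t = K+1, with counter bounds when constrained", {
  expect_identical(emit_property(example_problem()), "Rmin=? [ F (t=5) ]")
  expect_identical(emit_property(example_problem(horizon = 0)), "Rmin=? [ F (t=1) ]")
  expect_identical(emit_property(example_problem(), constraints = 3),
                   "Rmin=? [ F (t=5 & ct1<=3) ]")
})

test_that("reward blocks follow the horizon guards and drop zero entries", {
  p <- example_problem()
  rw <- emit_rewards(p$costs, 4, p$network)
  expect_identical(rw[1], 'rewards "cost"')
  expect_identical(rw[length(rw)], "endrewards")
  expect_match(rw, "t<=3", all = FALSE)
  expect_match(rw, "t=4", all = FALSE)
  zero <- cost_spec(horizon = 4)
  expect_identical(emit_rewards(zero, 4, p$network),
                   c('rewards "cost"', "endrewards"))
  neg <- cost_spec(terminal = data.frame(x = "11", cost = 1), horizon = 4)
  neg$terminal$cost <- -1
  expect_error(emit_rewards(neg, 4, p$network), "negative cost")
})

test_that("every stored literal appears verbatim in the model text", {
  for (seed in c(1, 4)) {
    prob <- rand_problem_decimal(seed, n = 2, K = 3)
    art <- emit_model(prob)
    net <- prob$network
    lits <- c(net$q_str, net$p_str,
              unlist(lapply(net$nodes, function(nd) nd$prob_str)),
              prob$costs$control$cost_str,
              prob$costs$terminal$cost_str[prob$costs$terminal$cost > 0])
    for (lit in lits) {
      expect_true(grepl(lit, art$model, fixed = TRUE), info = lit)
    }
    expect_true(all(c("q", "p") %in% art$manifest$name))
  }
})

test_that("interpreting the generated code reproduces the native optimum exactly", {
  p <- example_problem()
  for (u0 in 0:1) {
    iv <- interpret_prism(emit_model(p, forced_u0 = u0))
    nv <- solve_with_forced_first_action(p, u0)$value
    expect_identical(iv$value, nv, info = paste("u0 =", u0))
  }
  for (seed in 1:4) {
    prob <- rand_problem_decimal(seed, n = 2, K = 2)
    iv <- interpret_prism(emit_model(prob, forced_u0 = 0))
    nv <- solve_with_forced_first_action(prob, 0)$value
    expect_identical(iv$value, nv, info = paste("seed", seed))
  }
})

test_that("constrained generated code agrees with the constrained solver", {
  p <- example_problem()
  art <- emit_model(p, constraints = 1, forced_u0 = 0)
  expect_match(art$model, "module CT1")
  expect_match(art$model, "ct1 : \\[0..4\\] init 0;")
  iv <- interpret_prism(art)
  nv <- solve_with_forced_first_action(p, 0, constraints = 1)$value
  expect_equal(iv$value, nv, tolerance = 1e-12)
})

test_that("artifacts write to disk with LF endings", {
  dir <- withr::local_tempdir()
  paths <- write_prism(emit_model(example_problem()), dir, "pex")
  expect_true(file.exists(paths[1]) && file.exists(paths[2]))
  raw <- readBin(paths[1], "raw", file.size(paths[1]))
  expect_false(any(raw == as.raw(13)))   # no CR
  expect_identical(paste(readLines(paths[2]), collapse = "\n"), "Rmin=? [ F (t=5) ]")
})
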