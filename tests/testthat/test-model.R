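test_that("the example network validates cleanly and corruptions are caught", {
  net <- example_network()
  expect_identical(nrow(validate_spec(net)), 0L)

  bad <- net
  bad$nodes[[1]]$probs <- c(0.3, 0.6)
  bad$nodes[[1]]$prob_str <- c("0.3", "0.6")
  rep1 <- validate_spec(bad)
  expect_match(rep1$message, "sum to 0.9", all = FALSE)

  bad2 <- net; bad2$q <- 1.2; bad2$q_str <- "1.2"
  expect_match(validate_spec(bad2)$message, "outside \\[0, 1\\]", all = FALSE)

  p <- example_problem()
  costs_bad <- p$costs
  costs_bad$terminal$cost[1] <- -1
  expect_match(validate_spec(net, costs_bad)$message, "negative terminal", all = FALSE)
  costs_bad2 <- p$costs
  costs_bad2$terminal$x[1] <- "0"
  expect_match(validate_spec(net, costs_bad2)$message, "bad state key", all = FALSE)
  expect_identical(nrow(validate_spec(p$network, p$costs)), 0L)
})

test_that("random networks are reproducible, valid, and sized as requested", {
  a <- random_network(2, 1, l = 2, q = 0.2, p = 0.1, seed = 7)
  b <- random_network(2, 1, l = 2, q = 0.2, p = 0.1, seed = 7)
  expect_identical(
    lapply(a$nodes, function(nd) nd$expr_text),
    lapply(b$nodes, function(nd) nd$expr_text)
  )
  expect_identical(
    lapply(a$nodes, function(nd) nd$prob_str),
    lapply(b$nodes, function(nd) nd$prob_str)
  )
  for (seed in 1:15) {
    net <- random_network(n = sample(1:3, 1), m = sample(0:2, 1),
                          max_indegree = 2, l = sample(1:3, 1),
                          q = 0.3, p = 0.05, seed = seed)
    expect_identical(nrow(validate_spec(net)), 0L)
    # selection probabilities sum to one exactly in the stored decimals
    for (nd in net$nodes) {
      s <- pbnctrl:::dec_sum(lapply(nd$prob_str, pbnctrl:::dec_parse))
      expect_identical(pbnctrl:::dec_format(s), "1")
    }
    # indegree bound: distinct gene variables per function
    for (nd in net$nodes) for (e in nd$exprs) {
      vars <- pbnctrl:::expr_vars(e)
      expect_lte(sum(names(vars) == "gene"), 2)
    }
  }
  expect_equal(n_constituent_networks(random_network(3, 1, l = 2, seed = 1)), 8)
  expect_equal(n_constituent_networks(example_network()), 4)
  expect_error(random_network(0, 1), "invalid sizes")
})

test_that("cost tables default to zero and resolve sparse entries", {
  p <- example_problem()
  cm <- pbnctrl:::cost_matrices(p$network, p$costs)
  expect_identical(cm$gK, c(0, 2, 4, 6))
  expect_identical(cm$g[, 2], rep(1, 4))   # u = 1 costs 1 in every state
  expect_identical(cm$g[, 1], rep(0, 4))
  # state-specific control cost entries override the default
  costs <- cost_spec(
    control = data.frame(x = c(NA, "11"), u = c("1", "1"), cost = c(1, 5)),
    terminal = NULL, horizon = 2
  )
  cm2 <- pbnctrl:::cost_matrices(p$network, costs)
  expect_identical(cm2$g[4, 2], 5)
  expect_identical(cm2$g[1, 2], 1)
  expect_identical(cm2$gK, rep(0, 4))
})

test_that("model files round-trip losslessly", {
  dir <- withr::local_tempdir()
  pex <- read_model(system.file("extdata", "pex.yaml", package = "pbnctrl"))
  expect_identical(pex$network$q_str, "0.3")
  expect_identical(pex$network$p_str, "0.1")
  expect_identical(pex$costs$horizon, 4L)
  expect_identical(pex$x0, c(1L, 1L))
  for (seed in 1:8) {
    prob <- rand_problem_decimal(seed, n = 2, K = 3)
    for (ext in c("yaml", "json")) {
      f <- file.path(dir, sprintf("m%d.%s", seed, ext))
      write_model(prob, f)
      back <- read_model(f)
      expect_identical(back$network$q_str, prob$network$q_str)
      expect_identical(
        lapply(back$network$nodes, function(nd) nd$expr_text),
        lapply(prob$network$nodes, function(nd) nd$expr_text)
      )
      expect_identical(
        lapply(back$network$nodes, function(nd) nd$prob_str),
        lapply(prob$network$nodes, function(nd) nd$prob_str)
      )
      expect_identical(back$costs$terminal$cost, prob$costs$terminal$cost)
      expect_identical(back$x0, prob$x0)
      expect_identical(back$d0, prob$d0)
    }
  }
})

test_that("malformed model files are rejected with pointed messages", {
  dir <- withr::local_tempdir()
  pex <- read_model(system.file("extdata", "pex.yaml", package = "pbnctrl"))
  raw <- yaml::read_yaml(system.file("extdata", "pex.yaml", package = "pbnctrl"))

  bad1 <- raw; bad1$q <- NULL
  f1 <- file.path(dir, "bad1.yaml"); yaml::write_yaml(bad1, f1)
  expect_error(read_model(f1), "misses /q")

  bad2 <- raw; bad2$nodes[[1]][[1]]$prob <- "0.2"   # sum 0.9
  f2 <- file.path(dir, "bad2.yaml"); yaml::write_yaml(bad2, f2)
  expect_error(read_model(f2), "sum to 0.9")

  bad3 <- raw; bad3$nodes[[1]][[1]]$expr <- "x7 | u"
  f3 <- file.path(dir, "bad3.yaml"); yaml::write_yaml(bad3, f3)
  expect_error(read_model(f3), "unknown variable 'x7'")
})
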