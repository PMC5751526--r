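test_that("the simulator is reproducible and exact in the deterministic limit", {
  net0 <- pbn_network(2, 1, list(pbn_node(c("x1 | u", "x1 & x2"), c("0.3", "0.7")),
                                 pbn_node(c("x1 & !u", "x2"), c("0.2", "0.8"))),
                      q = 0, p = 0)
  p0 <- control_problem(net0, example_problem()$costs, "11")
  sol0 <- solve_finite_horizon(p0, timing = "direct")
  sim0 <- simulate_policy(p0, sol0$policy, n_traj = 200, seed = 3)
  expect_identical(stats::sd(sim0$samples), 0)
  expect_equal(sim0$mean, sol0$value, tolerance = 1e-12)

  p <- example_problem()
  sol <- solve_finite_horizon(p)
  a <- simulate_policy(p, sol$policy, n_traj = 5000, seed = 11)
  b <- simulate_policy(p, sol$policy, n_traj = 5000, seed = 11)
  expect_identical(a$samples, b$samples)
  c2 <- simulate_policy(p, sol$policy, n_traj = 5000, seed = 12)
  expect_false(identical(a$samples, c2$samples))
})

test_that("Monte-Carlo means concentrate on the exact policy value", {
  # across random small instances, |MC - exact| < 4 SE in nearly all cases
  hits <- 0L
  n_inst <- 12L
  for (seed in seq_len(n_inst)) {
    prob <- rand_problem_decimal(seed + 40, n = 2, K = 3)
    sol <- solve_finite_horizon(prob)
    sim <- simulate_policy(prob, sol$policy, n_traj = 4000, seed = seed)
    ve <- evaluate_policy(prob, sol$policy)
    if (abs(sim$mean - ve) < 4 * max(sim$se, 1e-12)) hits <- hits + 1L
  }
  expect_gte(hits, n_inst - 1L)
})

test_that("solve and validate subcommands behave end to end", {
  dir <- withr::local_tempdir()
  model <- system.file("extdata", "pex.yaml", package = "pbnctrl")

  out <- capture.output(status <- run_cli(c("solve", "--model", model)),
                        type = "output")
  expect_identical(status, 0L)
  expect_equal(as.numeric(out[length(out)]), 4.137891, tolerance = 1e-5)

  out1 <- capture.output(status1 <- run_cli(c("solve", "--model", model,
                                              "--force-u0", "1")))
  expect_identical(status1, 0L)
  expect_equal(as.numeric(out1[length(out1)]), 4.441219, tolerance = 1e-5)

  # policy written, then evaluated back through the eval subcommand
  outdir <- file.path(dir, "sol")
  capture.output(run_cli(c("solve", "--model", model, "--out", outdir)))
  expect_true(file.exists(file.path(outdir, "policy.tsv")))
  oute <- capture.output(se <- run_cli(c("eval", "--model", model,
                                         "--policy", file.path(outdir, "policy.tsv"))))
  expect_identical(se, 0L)
  expect_equal(as.numeric(oute[length(oute)]), 4.137891, tolerance = 1e-5)

  # corrupted model: nonzero exit, violation listed
  bad <- yaml::read_yaml(model)
  bad$nodes[[1]][[1]]$prob <- "0.2"
  badf <- file.path(dir, "bad.yaml")
  yaml::write_yaml(bad, badf)
  outv <- capture.output(sv <- run_cli(c("validate", "--model", badf)))
  expect_identical(sv, 1L)
  expect_match(outv, "sum to 0.9", all = FALSE)
  outg <- capture.output(sg <- run_cli(c("validate", "--model", model)))
  expect_identical(sg, 0L)
  expect_identical(outg[length(outg)], "valid")

  # usage errors
  expect_identical(suppressMessages(run_cli(c("solve"))), 1L)
  expect_identical(suppressMessages(run_cli(c("frobnicate"))), 1L)
})

test_that("export-prism and random-model write usable artifacts", {
  dir <- withr::local_tempdir()
  model <- system.file("extdata", "pex.yaml", package = "pbnctrl")
  capture.output(s <- run_cli(c("export-prism", "--model", model, "--out", dir)))
  expect_identical(s, 0L)
  expect_true(file.exists(file.path(dir, "pex.pm")))
  expect_true(file.exists(file.path(dir, "pex.props")))
  # identical invocations are byte-identical
  dir2 <- withr::local_tempdir()
  capture.output(run_cli(c("export-prism", "--model", model, "--out", dir2)))
  expect_identical(readLines(file.path(dir, "pex.pm")),
                   readLines(file.path(dir2, "pex.pm")))

  rf <- file.path(dir, "rand.yaml")
  capture.output(sr <- run_cli(c("random-model", "--genes", "2", "--seed", "5",
                                 "--out", rf)))
  expect_identical(sr, 0L)
  back <- read_model(rf)
  expect_identical(nrow(validate_spec(back$network, back$costs)), 0L)
  outs <- capture.output(ss <- run_cli(c("solve", "--model", rf)))
  expect_identical(ss, 0L)
})

test_that("simulate subcommand reports mean and standard error", {
  model <- system.file("extdata", "pex.yaml", package = "pbnctrl")
  out <- capture.output(s <- run_cli(c("simulate", "--model", model,
                                       "--traj", "2000", "--seed", "9")))
  expect_identical(s, 0L)
  nums <- as.numeric(strsplit(trimws(out[length(out)]), "\\s+")[[1]])
  expect_length(nums, 2)
  expect_lt(abs(nums[1] - 4.137891), 5 * nums[2])
})
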