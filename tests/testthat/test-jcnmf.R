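# jcnmf_core: conserved correlation estimation and the factorization

test_that("conserved correlation equals the average-then-clip PCC oracle", {
  # perfect correlation between proportional tissue rows
  vals <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8, 5, 1, 0, 2), nrow = 3,
                 byrow = TRUE,
                 dimnames = list(c("t1", "t2", "t3"), paste0("g", 1:4)))
  em <- expression_matrix(vals)
  cc <- estimate_conserved_correlation(em, em)
  expect_equal(cc$R["t1", "t2"], 1)

  # independent elementwise oracle on random data
  X1 <- make_expression(3, 50, seed = 100)
  X2 <- make_expression(3, 50, seed = 101)
  cc2 <- estimate_conserved_correlation(X1, X2)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    oracle[i, j] <- mean(c(stats::cor(X1$values[i, ], X1$values[j, ]),
                           stats::cor(X2$values[i, ], X2$values[j, ])))
  }
  oracle[oracle < 0] <- 0
  diag(oracle) <- 1
  expect_equal(unname(cc2$R), oracle, tolerance = 1e-12)
  expect_true(all(cc2$R >= 0 & cc2$R <= 1))
  expect_identical(cc2$R, t(cc2$R))

  # zero-variance tissue named in the error
  flat <- expression_matrix(matrix(c(1, 1, 1, 2, 5, 3), 2, byrow = TRUE,
                                   dimnames = list(c("flatT", "okT"),
                                                   paste0("g", 1:3))))
  expect_error(estimate_conserved_correlation(flat, flat), "flatT")
})

test_that("exact low-rank input is reconstructed in mode none", {
  set.seed(10)
  W <- matrix(stats::runif(7 * 3), 7, 3)
  H <- matrix(stats::runif(3 * 40), 3, 40)
  X <- expression_matrix(`dimnames<-`(W %*% H, list(paste0("t", 1:7),
                                                    paste0("g", 1:40))))
  fit <- jcnmf(X, X, k = 3, mode = "none", max_iter = 2000, tol = 1e-12,
               seed = 1, restarts = 3)
  rel <- norm(X$values - fit$W1 %*% fit$H1, "F") / norm(X$values, "F")
  expect_lt(rel, 1e-3)
  expect_true(all(fit$W1 >= 0) && all(fit$H1 >= 0))
})

test_that("hard mode shares W exactly; parameter errors are caught", {
  X1 <- make_expression(4, 20, seed = 20)
  X2 <- make_expression(4, 20, seed = 21)
  fit <- jcnmf(X1, X2, k = 2, mode = "hard", max_iter = 200, seed = 3,
               restarts = 1)
  expect_identical(fit$W1, fit$W2)
  expect_identical(fit$constraint_residual, 0)

  expect_error(jcnmf(X1, X2, k = 10, mode = "none"), "parameter error")
  zero <- expression_matrix(matrix(0, 4, 20,
                                   dimnames = dimnames(X1$values)))
  expect_error(jcnmf(zero, X2, k = 2, mode = "none"), "degenerate")
})

test_that("objective is monotone non-increasing and lambda = 0 matches mode none", {
  for (seed in 1:20) {
    X1 <- make_expression(5, 30, seed = 200 + seed)
    X2 <- make_expression(5, 30, seed = 300 + seed)
    fit <- jcnmf(X1, X2, k = 3, mode = "none", max_iter = 150, tol = 0,
                 seed = seed, restarts = 1)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-12 * tr[-length(tr)]))

    fsoft <- jcnmf(X1, X2, k = 3, mode = "soft", lambda = 0, max_iter = 150,
                   tol = 0, seed = seed, restarts = 1)
    expect_lt(abs(fsoft$objective - fit$objective),
              1e-10 * max(1, fit$objective))
  }
  # soft mode: trace non-increasing within 1e-9 relative per step
  for (seed in 1:20) {
    X1 <- make_expression(5, 30, seed = 400 + seed)
    X2 <- make_expression(5, 30, seed = 500 + seed)
    fit <- jcnmf(X1, X2, k = 3, mode = "soft", lambda = 1, max_iter = 150,
                 tol = 0, seed = seed, restarts = 1)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * tr[-length(tr)]))
  }
})

test_that("constraint residual is non-increasing in lambda on synthetic data", {
  # scaled-down instances (n = 250 instead of the default 500) to keep the
  # suite fast; the full-size case is covered by the acceptance suite
  for (seed in 1:5) {
    ds <- generate_paired_dataset(synthetic_spec(n = 250, seed = seed))
    res <- vapply(c(0, 0.1, 1, 10), function(lam) {
      jcnmf(ds$case, ds$control, mode = "soft", lambda = lam,
            max_iter = 5000, seed = seed, restarts = 2)$constraint_residual
    }, numeric(1))
    expect_true(all(diff(res) <= 1e-8))
  }
})

test_that("fits are reproducible and scale-covariant", {
  X1 <- make_expression(5, 30, seed = 600)
  X2 <- make_expression(5, 30, seed = 601)
  f1 <- jcnmf(X1, X2, k = 3, mode = "soft", max_iter = 100, seed = 9,
              restarts = 2)
  f2 <- jcnmf(X1, X2, k = 3, mode = "soft", max_iter = 100, seed = 9,
              restarts = 2)
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$H2, f2$H2)
  expect_identical(f1$objective_trace, f2$objective_trace)

  # scaling X by c scales the mode-none objective by c^2 (init is
  # scale-covariant by construction)
  c_ <- 3.7
  g1 <- jcnmf(X1, X2, k = 3, mode = "none", max_iter = 100, tol = 0,
              seed = 9, restarts = 1)
  sc <- function(em) expression_matrix(em$values * c_, em$condition_label)
  g2 <- jcnmf(sc(X1), sc(X2), k = 3, mode = "none", max_iter = 100, tol = 0,
              seed = 9, restarts = 1)
  expect_equal(g2$objective_trace, c_^2 * g1$objective_trace,
               tolerance = 1e-10)
})

test_that("factorization artifacts are written", {
  X1 <- make_expression(4, 15, seed = 700)
  X2 <- make_expression(4, 15, seed = 701)
  fit <- jcnmf(X1, X2, k = 2, mode = "soft", max_iter = 50, seed = 1,
               restarts = 1)
  dir <- withr::local_tempdir()
  write_factorization(fit, dir)
  for (f in c("W1.tsv", "H1.tsv", "W2.tsv", "H2.tsv", "factorization.json")) {
    expect_tsv_file(file.path(dir, f))
  }
  meta <- jsonlite::read_json(file.path(dir, "factorization.json"))
  expect_equal(meta$k, 2)
})
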