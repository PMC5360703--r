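one_block_model <- function() {
  gen_model(list(gm_variable("X", "observation", 2)),
            list(gm_block("X", table = c(0.5, 0.5))))
}

test_that("complete-data evidence follows the sequential predictive rule", {
  m <- one_block_model()
  r1 <- log_marginal_complete(m, data.frame(X = 0L))
  expect_equal(r1$log_evidence, log(1 / 2), tolerance = 1e-12)
  r2 <- log_marginal_complete(m, data.frame(X = c(0L, 0L)))
  expect_equal(r2$log_evidence, log(1 / 2) + log(2 / 3), tolerance = 1e-12)
  expect_error(log_marginal_complete(m, data.frame(X = 0L), alpha = 0),
               "prior error")
  expect_error(log_marginal_complete(m, data.frame(Y = 0L)),
               "incomplete-data")
})

test_that("complete-data evidence matches quadrature over the parameter simplex", {
  # binary child with one binary parent: the marginal likelihood is a
  # product of two independent beta-binomial integrals
  set.seed(31)
  for (alpha in c(0.5, 1, 2)) {
    tab <- rdirichlet_cols(2, 2)
    m <- gen_model(list(gm_variable("P", "observation", 2),
                        gm_variable("X", "observation", 2)),
                   list(gm_block("P", table = c(0.5, 0.5)),
                        gm_block("X", "P", tab)))
    d <- data.frame(P = c(0L, 0L, 1L, 1L, 1L), X = c(0L, 1L, 1L, 1L, 0L))
    got <- log_marginal_complete(m, d, alpha = alpha)
    quad <- function(n1, n0) stats::integrate(function(t)
      t^n1 * (1 - t)^n0 * stats::dbeta(t, alpha, alpha), 0, 1,
      rel.tol = 1e-10)$value
    want <- log(quad(1, 1)) + log(quad(2, 1)) + # X given P = 0, P = 1
      log(quad(3, 2))                           # the P prior block
    expect_equal(got$log_evidence, want, tolerance = 1e-3)
  }
})

test_that("evidence decomposes exactly as accuracy minus complexity", {
  set.seed(37)
  for (i in 1:15) {
    m <- random_model(4, joint_block = i %% 2 == 0)
    d <- as.data.frame(matrix(unlist(lapply(m$cards, function(k)
      sample(0:(k - 1), 12, replace = TRUE))), ncol = length(m$cards),
      dimnames = list(NULL, names(m$cards))))
    for (alpha in c(0.5, 1, 3)) {
      r <- log_marginal_complete(m, d, alpha = alpha)
      expect_lt(abs(r$log_evidence - (r$accuracy - r$complexity)), 1e-9)
      expect_gte(r$complexity, 0)
      expect_equal(r$log_evidence,
                   oracle_complete_evidence(m, d, alpha), tolerance = 1e-9)
    }
  }
})

test_that("evidence is invariant to record order", {
  set.seed(41)
  m <- random_model(4)
  d <- as.data.frame(matrix(unlist(lapply(m$cards, function(k)
    sample(0:(k - 1), 20, replace = TRUE))), ncol = length(m$cards),
    dimnames = list(NULL, names(m$cards))))
  r1 <- log_marginal_complete(m, d)
  r2 <- log_marginal_complete(m, d[sample(nrow(d)), , drop = FALSE])
  expect_equal(r1$log_evidence, r2$log_evidence, tolerance = 1e-12)
})

test_that("a childless latent with a uniform prior marginalizes out", {
  m <- gen_model(
    list(gm_variable("L", "latent_low", 3),
         gm_variable("X", "observation", 2)),
    list(gm_block("L", table = rep(1 / 3, 3)),
         gm_block("X", table = c(0.5, 0.5))))
  d <- data.frame(X = c(0L, 1L, 1L))
  rest <- gen_model(list(gm_variable("X", "observation", 2)),
                    list(gm_block("X", table = c(0.5, 0.5))))
  got <- log_marginal_latent_exact(m, d)
  expect_equal(got$method, "latent_exact")
  expect_equal(got$log_evidence,
               log_marginal_complete(rest, d)$log_evidence,
               tolerance = 1e-10)
})

test_that("latent-exact evidence equals the brute-force completion sum", {
  # two records, one binary latent cause: exactly four completions
  m <- gen_model(
    list(gm_variable("L", "latent_low", 2),
         gm_variable("X", "observation", 2)),
    list(gm_block("L", table = c(0.5, 0.5)),
         gm_block("X", "L", matrix(c(0.9, 0.1, 0.2, 0.8), 2))))
  d <- data.frame(X = c(0L, 1L))
  got <- log_marginal_latent_exact(m, d)
  want <- oracle_latent_evidence(m, d, hidden = "L")
  expect_equal(got$log_evidence, want, tolerance = 1e-10)
  expect_error(log_marginal_latent_exact(m, data.frame(X = rep(0L, 25))),
               "budget")
})

test_that("deterministic feature tables restrict the contributing completions", {
  cfg <- structure_config(F = 2, epsilon = 0)
  fb <- matrix(0, 4, 2); fb[1, 1] <- 1; fb[4, 2] <- 1
  m <- build_m2(cfg, tables = list("F1,F2|L1" = fb))
  d <- simulate_world(make_world(world_spec(
    "latent", cfg, determinism = list(feature_slack = 0, goal_slack = 0.1),
    patterns = list(low = c(0L, 3L)), seed = 2)), 2, seed = 3)
  # with the sensor model and the deterministic feature table both treated
  # as known, each record admits exactly one consistent hidden
  # configuration (features forced by the noiseless observations, the
  # latent state forced by the feature table), so one of the 64 joint
  # completions carries all the evidence
  r <- log_marginal_latent_exact(m, d,
                                 fixed_tags = c("observation", "feature"))
  expect_equal(r$detail$contributing, 1)
  expect_true(is.finite(r$log_evidence))
})

test_that("EM objective is monotone and reduces to closed-form MAP on complete data", {
  cfg <- structure_config(F = 2, n_L1 = 2, epsilon = 0.1)
  w <- make_world(world_spec("latent", cfg, seed = 8))
  d <- simulate_world(w, 120, seed = 9)
  fit <- suppressWarnings(fit_em(build_m2(cfg), d, seed = 10, restarts = 1,
                                 max_iter = 150, tol = 1e-8))
  expect_true(all(diff(fit$trace) > -1e-7))

  # latents observed: EM equals the one-step closed-form MAP estimate
  m2 <- build_m2(cfg)
  fitc <- fit_em(m2, d, seed = 1, observed = names(m2$cards))
  expect_equal(fitc$iterations, 1L)
  M <- as.matrix(d[, names(m2$cards)])
  for (bi in seq_along(m2$blocks)) {
    b <- m2$blocks[[bi]]
    if (b$tag == "observation") next
    N <- goalcat:::block_counts(m2, b, M)
    want <- sweep(N, 2, pmax(colSums(N), 1), "/")
    want[, colSums(N) == 0] <- 1 / nrow(N)
    expect_equal(fitc$model$blocks[[bi]]$table, want, tolerance = 1e-12)
  }
  expect_error(fit_em(m2, d), "seed")
})

test_that("BIC evidence uses free-parameter counts and a log-n penalty", {
  m <- one_block_model()
  d1 <- data.frame(X = 0L)
  r1 <- approx_evidence_bic(m, d1, seed = 1)
  expect_equal(r1$complexity, 0) # log(1) = 0
  expect_equal(r1$log_evidence, r1$accuracy)
  d <- data.frame(X = c(0L, 0L, 1L, 0L))
  r <- approx_evidence_bic(m, d, seed = 1)
  expect_equal(r$detail$k, 1)
  expect_equal(r$complexity, 0.5 * log(4))
  # no latents: the likelihood term is the closed-form ML fit
  expect_equal(r$accuracy, 3 * log(3 / 4) + log(1 / 4), tolerance = 1e-10)
})

test_that("BIC ranking agrees with exact evidence on tiny latent datasets", {
  cfg <- structure_config(F = 2, n_f = 2, n_L1 = 2, epsilon = 0.1)
  agree <- 0
  reps <- 50
  for (r in seq_len(reps)) {
    w <- make_world(world_spec("latent", cfg, seed = 1000 + r))
    d <- simulate_world(w, 10, seed = 2000 + r)
    attr(d, "latent_cols") <- "L1" # features observed, latent cause hidden
    cands <- list(flat = build_m1(cfg), latent = build_m2(cfg))
    rex <- select_model(cands, d, method = "latent_exact")
    rb <- suppressWarnings(select_model(cands, d, method = "bic",
                                        seed = 3000 + r, restarts = 3))
    agree <- agree + (rex$model[1] == rb$model[1])
  }
  expect_gte(agree / reps, 0.9)
})

test_that("select_model breaks ties by input order and checks schemas", {
  m <- one_block_model()
  d <- data.frame(X = c(0L, 1L, 0L))
  rank <- select_model(list(first = m, second = m), d, method = "complete")
  expect_equal(rank$model, c("first", "second"))
  expect_equal(rank$log_evidence[1], rank$log_evidence[2])

  other <- gen_model(list(gm_variable("Y", "observation", 2)),
                     list(gm_block("Y", table = c(0.5, 0.5))))
  expect_error(select_model(list(a = m, b = other), d, method = "complete"),
               "schema")
})

test_that("mean per-record evidence stabilizes as records accumulate", {
  cfg <- structure_config(F = 2, n_L1 = 2, epsilon = 0.1)
  w <- make_world(world_spec("latent", cfg, seed = 44))
  m2 <- build_m2(cfg)
  per <- vapply(c(50, 200, 800), function(n) {
    d <- simulate_world(w, n, seed = 45)
    r <- suppressWarnings(approx_evidence_bic(m2, d, seed = 46,
                                              restarts = 2))
    r$log_evidence / n
  }, numeric(1))
  # per-record evidence under the true structure approaches a constant;
  # successive differences shrink and stay within a few standard errors
  expect_lt(abs(per[3] - per[2]), abs(per[2] - per[1]) + 0.2)
  expect_lt(abs(per[3] - per[2]), 0.25)
})
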