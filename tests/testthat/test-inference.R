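test_that("fully symmetric models give uniform action posteriors", {
  m <- build_m2(structure_config(F = 2, n_a = 3))
  pt <- infer_action(m, c(O1 = 0L, O2 = 1L))
  expect_equal(pt$prob, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(attr(pt, "best"), 0) # lowest-index tie-break
  expect_equal(sort(attr(pt, "ties")), 0:2)
})

test_that("uninformative likelihoods return the prior", {
  # epsilon = 0.5 observations carry no information about binary features
  cfg <- structure_config(F = 2, n_f = 2, epsilon = 0.5)
  fb <- matrix(c(0.97, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.97), 4)
  m <- build_m2(cfg, tables = list("F1,F2|L1" = fb))
  post <- infer_category(m, c(O1 = 1L, O2 = 1L))
  expect_equal(post$prob, c(0.5, 0.5), tolerance = 1e-12)
  # no observations at all: prior marginals
  m3 <- build_m3(structure_config())
  p0 <- infer_category(m3)
  expect_equal(p0$prob, rep(0.25, 4), tolerance = 1e-12)
})

test_that("posteriors match the frozen hand-checked chain", {
  fx <- load_fixture("chain3")
  m <- fx$payload
  px <- posterior(m, c(Z = 1L), "X", allow_any = TRUE)
  expect_equal(px$prob[px$X == 1], fx$oracle$posterior_x1_given_z1$value,
               tolerance = 1e-12)
  py <- posterior(m, c(Z = 1L), "Y", allow_any = TRUE)
  expect_equal(py$prob[py$Y == 1], fx$oracle$posterior_y1_given_z1$value,
               tolerance = 1e-12)
})

test_that("exact posteriors equal full-joint-table conditioning", {
  set.seed(23)
  for (i in 1:30) {
    m <- random_model(sample(3:5, 1), joint_block = i %% 3 == 0)
    vars <- names(m$cards)
    clamped_v <- sample(vars, sample(0:2, 1))
    clamped <- setNames(vapply(clamped_v, function(v)
      sample(0:(m$cards[[v]] - 1), 1), integer(1)), clamped_v)
    query <- sample(setdiff(vars, clamped_v),
                    sample(1:min(2, length(setdiff(vars, clamped_v))), 1))
    got <- tryCatch(posterior(m, clamped, sort(query)),
                    error = function(e) e)
    if (inherits(got, "error")) {
      expect_match(conditionMessage(got), "impossible-evidence")
      next
    }
    want <- oracle_posterior(m, clamped, sort(query))
    expect_equal(got$prob, want, tolerance = 1e-10)
    expect_equal(sum(got$prob), 1, tolerance = 1e-10)
  }
})

test_that("clamping is restricted to observation-role variables by default", {
  m <- build_m2(structure_config())
  expect_error(posterior(m, c(L1 = 0L), "A"), "observation-role")
  expect_silent(posterior(m, c(L1 = 0L), "A", allow_any = TRUE))
})

test_that("impossible evidence and blown budgets raise informative errors", {
  cfg <- structure_config(F = 2, epsilon = 0)
  fb <- matrix(0, 4, 2); fb[1, 1] <- 1; fb[4, 2] <- 1
  m <- build_m2(cfg, tables = list("F1,F2|L1" = fb))
  # the pattern (1, 0) is generated by no latent state and epsilon is 0
  expect_error(posterior(m, c(O1 = 1L, O2 = 0L), "L1"),
               "impossible-evidence")
  expect_error(posterior(m, c(O1 = 1L), "L1", budget = 8),
               "budget")
})

test_that("context flips the inferred best action in the contextual world", {
  world <- make_world(load_fixture("lion_context")$payload)
  predator_obs <- c(O1 = 1L, O2 = 1L, O3 = 1L, O4 = 1L)
  wild <- infer_action(world, c(predator_obs, OC = 0L))
  zoo <- infer_action(world, c(predator_obs, OC = 1L))
  expect_equal(attr(wild, "best"), 0) # avoid
  expect_equal(max(wild$prob), 1)
  expect_equal(attr(zoo, "best"), 1) # approach
  prey_obs <- c(O1 = 0L, O2 = 0L, O3 = 0L, O4 = 0L)
  expect_equal(attr(infer_action(world, c(prey_obs, OC = 0L)), "best"), 1)
})

test_that("noiseless observations never raise latent-posterior entropy", {
  cfg <- structure_config(F1 = 2, F2 = 2, epsilon = 0)
  hb <- matrix(0, 8, 2); hb[1, 1] <- 1; hb[8, 2] <- 1
  lb <- matrix(0, 4, 2); lb[1, 1] <- 1; lb[4, 2] <- 1
  m <- build_m3(cfg, tables = list("F3,F4,L1|L2" = hb, "F1,F2|L1" = lb))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  obs <- c(O3 = 0L, O4 = 0L)
  h0 <- ent(posterior(m, obs, "L2")$prob)
  h1 <- ent(posterior(m, c(obs, O1 = 0L), "L2")$prob)
  expect_lte(h1, h0 + 1e-12)
})
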