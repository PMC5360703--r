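test_that("structure_config validates cardinalities and noise", {
  expect_error(structure_config(n_L1 = 1), "n_L1")
  expect_error(structure_config(F = 0), "F must")
  expect_error(structure_config(epsilon = 0.7), "epsilon")
  cfg <- structure_config()
  expect_s3_class(cfg, "structure_config")
  expect_equal(cfg$n_a, 2L)
})

test_that("structure one has the expected blocks and noise tables", {
  cfg <- structure_config(F = 3, n_f = 2)
  m <- build_m1(cfg)
  tags <- vapply(m$blocks, function(b) b$tag, character(1))
  expect_equal(sum(tags == "feature_prior"), 3)
  expect_equal(sum(tags == "observation"), 3)
  expect_equal(sum(tags == "action_prior"), 1)
  expect_equal(sum(tags == "goal"), 1)

  m0 <- build_m1(structure_config(F = 2, epsilon = 0))
  obs <- block_by_tag(m0, "observation")
  expect_equal(obs$table, diag(2))

  # symmetric confusion at epsilon = 0.3, three states
  m3 <- build_m2(structure_config(F = 2, n_f = 3, epsilon = 0.3))
  obs3 <- block_by_tag(m3, "observation")
  expect_equal(diag(obs3$table), rep(0.7, 3))
  expect_equal(obs3$table[2, 1], 0.15)
})

test_that("every constructor output passes validate_model over a cfg grid", {
  set.seed(5)
  for (i in 1:12) {
    cfg <- random_cfg()
    expect_identical(validate_model(build_m1(cfg)), character(0))
    expect_identical(validate_model(build_m2(cfg)), character(0))
    expect_identical(validate_model(build_m2(cfg, features = "split")),
                     character(0))
    expect_identical(validate_model(build_m3(cfg)), character(0))
    expect_identical(validate_model(build_m4(cfg)), character(0))
    expect_identical(validate_model(build_m3_folded(cfg)), character(0))
  }
})

test_that("deterministic latent-to-feature tables give point posteriors", {
  cfg <- structure_config(F = 2, n_f = 2, n_L1 = 2, epsilon = 0)
  fb <- matrix(0, 4, 2)
  fb[1, 1] <- 1 # L1 = 0 -> pattern (0, 0)
  fb[4, 2] <- 1 # L1 = 1 -> pattern (1, 1)
  m <- build_m2(cfg, tables = list("F1,F2|L1" = fb))
  post <- infer_category(m, c(O1 = 1L, O2 = 1L))
  expect_equal(post$prob[post$L1 == 1], 1)
})

test_that("observing only the high-order subset identifies L2 in structure three", {
  cfg <- structure_config(F1 = 2, F2 = 2, n_L1 = 2, n_L2 = 2, epsilon = 0)
  # L2 = 0 -> (high pattern (0,0), L1 = 0); L2 = 1 -> ((1,1), L1 = 1)
  hb <- matrix(0, 8, 2)
  hb[1, 1] <- 1
  hb[8, 2] <- 1
  m <- build_m3(cfg, tables = list("F3,F4,L1|L2" = hb))
  post <- posterior(m, c(O3 = 1L, O4 = 1L), query = c("L2", "L1"))
  expect_equal(post$prob[post$L2 == 1 & post$L1 == 1], 1)
  # and the L1 posterior equals P(L1 | L2) for the identified L2 state
  pl1 <- posterior(m, c(O3 = 1L, O4 = 1L), query = "L1")
  expect_equal(pl1$prob, c(0, 1), tolerance = 1e-12)
})

test_that("a deterministic contextual goal rule zeroes rule-violating joints", {
  world <- make_world(load_fixture("lion_context")$payload)
  # predator (L1=0) in the wild (C=0) approached (A=1): goal cannot be attained
  assign <- c(L2 = 0L, L1 = 0L, F1 = 1L, F2 = 1L, F3 = 1L, F4 = 1L,
              O1 = 1L, O2 = 1L, O3 = 1L, O4 = 1L,
              C = 0L, OC = 0L, A = 1L, G = 1L)
  expect_equal(joint_probability(world, assign), 0)
  # avoiding it attains the goal with positive probability
  assign["A"] <- 0L
  expect_gt(joint_probability(world, assign), 0)
})

test_that("table overrides are shape-checked and reachable by block name", {
  cfg <- structure_config(F = 2)
  expect_error(build_m1(cfg, tables = list(nope = diag(2))), "unknown block")
  expect_error(build_m1(cfg, tables = list("G|F1,F2,A" = diag(3))),
               "wrong shape")
})
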