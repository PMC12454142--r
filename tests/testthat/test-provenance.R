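test_that("primary-equivalent conversion divides by the extraction rate", {
  flows <- data.frame(commodity = "flour", origin = "A", dest = "B", mass = 2)
  conv <- data.frame(commodity = "flour", primary = "wheat", factor = 1 / 0.8)
  out <- primary_equivalent_flows(flows, conv)
  expect_equal(out$mass, 2.5)
  expect_identical(out$commodity, "wheat")
  # factor 1 -> unchanged
  conv1 <- data.frame(commodity = "flour", primary = "flour", factor = 1)
  expect_equal(primary_equivalent_flows(flows, conv1)$mass, 2)
  # two processed streams onto one primary accumulate
  flows2 <- data.frame(commodity = c("flour", "bread"), origin = "A",
                       dest = "B", mass = c(2, 1))
  conv2 <- data.frame(commodity = c("flour", "bread"),
                      primary = "wheat", factor = c(1.25, 2))
  expect_equal(primary_equivalent_flows(flows2, conv2)$mass, 2 * 1.25 + 1 * 2)
  expect_error(primary_equivalent_flows(flows2, conv), "bread")
})

test_that("no trade gives the identity provenance matrix", {
  P <- c(10, 5, 2)
  T <- matrix(0, 3, 3)
  expect_equal(provenance_shares(P, T), diag(3))
})

test_that("a re-export chain resolves to true origins", {
  # P = (10, 5, 0); A exports 5 to B, B exports 4 to C:
  # A's use is pure A; B's supply is half A half B; C consumes B's mix
  P <- c(10, 5, 0)
  T <- matrix(0, 3, 3); T[1, 2] <- 5; T[2, 3] <- 4
  S <- provenance_shares(P, T)
  expect_equal(S[1, ], c(1, 0, 0))
  expect_equal(S[2, ], c(0.5, 0.5, 0))
  expect_equal(S[3, ], c(0.5, 0.5, 0))
  # iterative oracle agrees to tight tolerance
  S_it <- provenance_shares_iterative(P, T)
  expect_equal(S, S_it, tolerance = 1e-12)
})

test_that("cyclic trade solves to the fixed point of the iteration", {
  P <- c(8, 3)
  T <- matrix(c(0, 1.5, 2, 0), 2, 2)  # A<->B cycle
  S <- provenance_shares(P, T)
  S_it <- provenance_shares_iterative(P, T)
  expect_lt(max(abs(S - S_it)), 1e-12)
  expect_equal(rowSums(S), c(1, 1), tolerance = 1e-12)
})

test_that("random networks conserve mass and match the iteration oracle", {
  for (seed in 1:100) {
    net <- random_trade_network(sample(2:20, 1), seed)
    S <- provenance_shares(net$production, net$trade, use = net$use)
    ok <- !is.na(S[, 1])
    expect_true(all(abs(rowSums(S[ok, , drop = FALSE]) - 1) < 1e-9))
    expect_true(all(S[ok, ] > -1e-12 & S[ok, ] < 1 + 1e-12))
    # sum_i use_i S[i,o] recovers production at every origin
    recovered <- as.numeric(net$use[ok] %*% S[ok, , drop = FALSE])
    scale <- max(net$production, 1)
    expect_lt(max(abs(recovered - net$production)) / scale, 1e-6)
    S_it <- provenance_shares_iterative(net$production, net$trade)
    expect_lt(max(abs(S[ok, ] - S_it[ok, ])), 1e-10)
  }
})

test_that("pathological networks are handled explicitly", {
  # zero-supply country with recorded use is dropped with a warning
  P <- c(10, 0)
  T <- matrix(0, 2, 2)
  expect_warning(S <- provenance_shares(P, T, use = c(10, 1)), "zero supply")
  expect_true(all(is.na(S[2, ])))
  # pure re-export cycle with no production anywhere has no valid solution
  expect_error(
    provenance_shares_iterative(c(0, 0), matrix(c(0, 2, 2, 0), 2, 2)),
    "no production")
  expect_error(
    provenance_shares(c(0, 0), matrix(c(0, 2, 2, 0), 2, 2)),
    "no production")
  # exports above supply are scaled down, with a warning
  expect_warning(provenance_shares(c(1, 5), matrix(c(0, 0, 4, 0), 2, 2)),
                 "scaled down")
  expect_error(provenance_shares(c(1, 1), matrix(c(1, 0, 0, 0), 2, 2)),
               "self-flows")
})

test_that("consumption impacts are provenance-weighted convex combinations", {
  S <- matrix(c(0.5, 0, 0.5, 1), 2, 2)
  v <- c(2e-11, 4e-11)
  ci <- consumption_perkg_impact(S, v)
  expect_equal(ci$value, c(3e-11, 4e-11))
  expect_equal(rowSums(ci$by_origin), ci$value)
  # convexity on random shares
  set.seed(8)
  for (k in 1:25) {
    n <- sample(2:8, 1)
    raw <- matrix(stats::rgamma(n * n, 1), n, n)
    S_r <- raw / rowSums(raw)
    v_r <- stats::runif(n, 1e-11, 1e-9)
    w <- consumption_perkg_impact(S_r, v_r)$value
    expect_true(all(w >= min(v_r) - 1e-24 & w <= max(v_r) + 1e-24))
  }
  # all weight on the max-impact origin is the maximal combination
  S_max <- matrix(c(0, 1), 1, 2)
  expect_equal(consumption_perkg_impact(S_max, v)$value, max(v))
  expect_error(consumption_perkg_impact(S, c(2e-11, NA)), "no production impact")
})
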