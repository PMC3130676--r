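# Hitting-time solvers against closed forms, enumeration and simulation.

test_that("mean hitting times match closed forms on small graphs", {
  fx <- gallery()
  # path a-b-c, symmetric walk, target c: E_a = 4, E_b = 3
  mh <- mean_hitting_time(fx$path3$P, "c")
  expect_equal(unname(mh$raw[c("a", "b", "c")]), c(4, 3, 0),
               tolerance = 1e-10)
  expect_equal(unname(mh$scaled[c("a", "b")]), c(1, 0.75))
  # complete graph K4, target d: all others 3 (x = 1 + 2/3 x)
  mh4 <- mean_hitting_time(fx$k4$P, "d")
  expect_equal(unname(mh4$raw[c("a", "b", "c", "d")]), c(3, 3, 3, 0),
               tolerance = 1e-10)
  # weighted star, from center to the weight-3 leaf: 1 + 1/4 E_a, E_a = 1 + E_x
  mhs <- mean_hitting_time(fx$star4$P, "b")
  expect_equal(unname(mhs$raw["x"]), 5 / 3, tolerance = 1e-10)
})

test_that("scaling maps the maximum to exactly 1 and keeps zeros", {
  sc <- scale_hitting(c(a = 0, b = 3, c = 4))
  expect_identical(unname(sc$scaled), c(0, 0.75, 1))
  expect_equal(sc$denominator, 4)
  # single non-target node is its own maximum
  sc1 <- scale_hitting(c(a = 0, b = 7))
  expect_identical(unname(sc1$scaled["b"]), 1)
  expect_warning(scale_hitting(c(a = 0, b = 0)), "zero")
})

test_that("harmonic potential solves the gambler's ruin and is harmonic", {
  fx <- gallery()
  h <- harmonic_potential(fx$ruin4$P, "3", "0")
  expect_equal(unname(h$values[c("0", "1", "2", "3")]),
               c(0, 1 / 3, 2 / 3, 1), tolerance = 1e-10)
  # mean-value property at every interior node of a bigger graph
  P <- fx$oracle8$P
  hp <- harmonic_potential(P, "n8", "n1")
  interior <- setdiff(rownames(P), c("n8", "n1"))
  resid <- as.numeric(P[interior, ] %*% hp$values) - hp$values[interior]
  expect_lt(max(abs(resid)), 1e-10)
  expect_error(harmonic_potential(P, "n8", "n8"), "overlap")
})

test_that("conditional MHT matches path-space enumeration", {
  fx <- gallery()
  cm <- conditional_mht(fx$ruin4$P, "3", "0")
  expect_equal(unname(cm$raw["1"]), 8 / 3, tolerance = 1e-10)
  expect_true(is.na(cm$raw["0"]))   # start inside the avoid set
  expect_equal(unname(cm$raw["3"]), 0)
  en <- enumerate_hitting_oracle(fx$ruin4$P, "3", "0", start = "1")
  expect_equal(en$estimate, 8 / 3, tolerance = 1e-8)
  expect_equal(en$mass, 1 / 3, tolerance = 1e-8)
  # 8-node irregular graph: every defined start agrees with enumeration
  P <- fx$oracle8$P
  cm8 <- conditional_mht(P, "n8", "n1")
  for (s in paste0("n", 2:7)) {
    e <- enumerate_hitting_oracle(P, "n8", "n1", start = s)
    expect_equal(unname(cm8$raw[s]), e$estimate, tolerance = 1e-6)
  }
})

test_that("conditioning is vacuous when every route to the avoid set crosses the target", {
  # path a-b-c-d: from a or b, d can only be reached through c
  P <- gallery()$ruin4$P  # nodes 0-1-2-3
  cm <- conditional_mht(P, "2", "3")
  mh <- mean_hitting_time(P, "2")
  for (s in c("0", "1"))
    expect_equal(unname(cm$raw[s]), unname(mh$raw[s]), tolerance = 1e-10)
})

test_that("Monte-Carlo oracle agrees with the solvers within 3 standard errors", {
  fx <- gallery()
  cases <- list(list(g = "path3", B = "c", s = "a", truth = 4),
                list(g = "cycle4", B = "c", s = "a", truth = 4),
                list(g = "star4", B = "b", s = "x", truth = 5 / 3))
  for (cs in cases) {
    mc <- mc_hitting_oracle(fx[[cs$g]]$P, cs$B, start = cs$s,
                            n_walks = 20000, seed = 7)
    expect_lt(abs(mc$estimate - cs$truth), 3 * mc$stderr + 1e-9)
  }
  # conditional, gambler's ruin: rejection sampling vs h-transform
  mcc <- mc_hitting_oracle(fx$ruin4$P, "3", avoid = "0", start = "1",
                           n_walks = 30000, seed = 11)
  expect_lt(abs(mcc$estimate - 8 / 3), 3 * mcc$stderr)
  # heterogeneous toy
  net <- fx$fig2a
  mh <- mean_hitting_time(net$P, "p:P1")
  mcf <- mc_hitting_oracle(net$P, "p:P1", start = "g:G4",
                           n_walks = 10000, seed = 3)
  expect_lt(abs(mcf$estimate - mh$raw["g:G4"]), 3 * mcf$stderr)
  # degenerate start
  mc0 <- mc_hitting_oracle(fx$path3$P, "c", start = "c", n_walks = 10,
                           seed = 1)
  expect_identical(mc0$estimate, 0)
  expect_identical(mc0$stderr, 0)
})

test_that("enlarging the target set never increases a hitting time", {
  P <- gallery()$oracle8$P
  small <- mean_hitting_time(P, "n8")$raw
  large <- mean_hitting_time(P, c("n8", "n4"))$raw
  expect_true(all(large <= small + 1e-12))
})

test_that("solver output is deterministic and scaled into [0,1]", {
  fx <- gallery()
  for (nm in names(fx)) {
    P <- fx[[nm]]$P
    tgt <- rownames(P)[1]
    a <- mean_hitting_time(P, tgt)
    b <- mean_hitting_time(P, tgt)
    expect_identical(a$raw, b$raw)
    sc <- a$scaled[!is.na(a$scaled)]
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(max(sc), 1)
  }
  expect_error(mean_hitting_time(fx$path3$P, character(0)), "empty")
  expect_error(mean_hitting_time(fx$path3$P, "zz"), "unknown")
})
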