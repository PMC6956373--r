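test_that("packet bands have the dyadic widths at every level", {
  set.seed(1)
  tree <- wpt_decompose(rnorm(1024), 128)
  expect_equal(diff(wpt_node(tree, 5, 0)$band), 2)
  expect_equal(diff(wpt_node(tree, 4, 3)$band), 4)
  expect_equal(diff(wpt_node(tree, 2, 1)$band), 16)
  expect_error(wpt_decompose(rnorm(16), 128), "too short")
  expect_error(wpt_decompose(rnorm(1000), 128), "divisible")
  expect_error(wpt_decompose(rnorm(1024), 128, wavelet = "sym5"), "unknown wavelet")
})

test_that("a 6 Hz tone concentrates in the frequency-ordered [4,8) node", {
  t <- (0:1023) / 128
  tree <- wpt_decompose(sin(2 * pi * 6 * t), 128)
  en <- vapply(0:15, function(f) {
    sum(wpt_node(tree, 4, f)$coefficients^2)
  }, numeric(1))
  expect_equal(which.max(en) - 1, 1)  # freq index 1 = [4,8) Hz
})

test_that("the transform preserves energy at every level (Parseval)", {
  set.seed(2)
  x <- rnorm(768)
  tree <- wpt_decompose(x, 128)
  ex <- sum(x^2)
  for (l in 0:5) {
    el <- sum(vapply(tree$levels[[l + 1]], function(v) sum(v^2), numeric(1)))
    expect_lt(abs(el - ex) / ex, 1e-8)
  }
})

test_that("band selector returns the five published packets and no delta", {
  set.seed(3)
  tree <- wpt_decompose(rnorm(1024), 128)
  sel <- select_band_nodes(tree)
  expect_length(sel, 5)
  expect_equal(vapply(sel, `[[`, numeric(1), "level"),
               c(theta = 4, alpha = 4, beta_low = 5, beta_high = 2,
                 gamma = 3))
  bands <- lapply(sel, `[[`, "band")
  expect_equal(unname(bands),
               list(c(4, 8), c(8, 12), c(14, 16), c(16, 32), c(32, 40)))
  expect_true(all(vapply(bands, `[`, numeric(1), 1) >= 4))  # no delta overlap
  tree100 <- wpt_decompose(rnorm(1024), 100)
  expect_error(select_band_nodes(tree100), "not representable")
})

test_that("wavelet features vanish on silence and one-hot packets have zero entropy", {
  tree <- wpt_decompose(numeric(512), 128)
  f <- wavelet_features(tree, select_band_nodes(tree))
  expect_equal(unname(f), rep(0, 8))

  # single nonzero coefficient: point-mass energy distribution, entropy 0
  tree2 <- wpt_decompose(rnorm(512), 128)
  sel2 <- select_band_nodes(tree2)
  for (b in seq_along(sel2)) {
    cc <- sel2[[b]]$coefficients
    sel2[[b]]$coefficients <- c(3, rep(0, length(cc) - 1))
  }
  f2 <- wavelet_features(tree2, sel2)
  expect_equal(unname(f2["F14"]), 0)
})

test_that("entropy is ln(n) summed for flat packets and F12 sums node energies", {
  set.seed(4)
  tree <- wpt_decompose(rnorm(512), 128)
  sel <- select_band_nodes(tree)
  flat <- sel
  for (b in seq_along(flat)) {
    n <- length(flat[[b]]$coefficients)
    flat[[b]]$coefficients <- rep(1, n)   # equal |c|: maximal entropy
  }
  f <- wavelet_features(tree, flat)
  max_ent <- sum(vapply(flat, function(nd) log(length(nd$coefficients)),
                        numeric(1)))
  expect_equal(unname(f["F14"]), max_ent, tolerance = 1e-12)

  f0 <- wavelet_features(tree, sel)
  node_energies <- vapply(sel, function(nd) sum(nd$coefficients^2),
                          numeric(1))
  expect_equal(unname(f0["F12"]), sum(node_energies), tolerance = 1e-12)
})

test_that("a 6 + 20 Hz mixture puts its power in theta and high beta", {
  t <- (0:(8 * 128 - 1)) / 128
  x <- sin(2 * pi * 6 * t) + sin(2 * pi * 20 * t)
  tree <- wpt_decompose(x, 128)
  f <- wavelet_features(tree, select_band_nodes(tree))
  # db4 packet roll-off keeps ~70% of a mid-band tone inside its nominal
  # band after single-node reconstruction; bounds calibrated on that
  for (feat in c("F15", "F18")) {
    expect_gt(unname(f[feat]), 0.55 * 0.5)
    expect_lt(unname(f[feat]), 1.15 * 0.5)
  }
  others <- f[c("F16", "F17", "F19")]
  expect_gt(min(f[c("F15", "F18")]) / max(others), 5)
})

test_that("removing a band's oscillator collapses that band power only", {
  t <- (0:1023) / 128
  full <- sin(2 * pi * 5 * t) + sin(2 * pi * 24 * t) + sin(2 * pi * 38 * t)
  no_beta <- sin(2 * pi * 5 * t) + sin(2 * pi * 38 * t)
  f_full <- wavelet_features(wpt_decompose(full, 128),
                             select_band_nodes(wpt_decompose(full, 128)))
  f_drop <- wavelet_features(wpt_decompose(no_beta, 128),
                             select_band_nodes(wpt_decompose(no_beta, 128)))
  expect_gt(f_full["F18"] / f_drop["F18"], 5)       # high beta collapses
  for (b in c("F15", "F16", "F19")) {
    expect_lt(abs(f_drop[b] - f_full[b]) / f_full[b], 0.2)
  }
})

test_that("total-pool energy and spread are stable under time reversal", {
  set.seed(6)
  x <- rnorm(768)
  t1 <- wpt_decompose(x, 128)
  t2 <- wpt_decompose(rev(x), 128)
  f1 <- wavelet_features(t1, select_band_nodes(t1))
  f2 <- wavelet_features(t2, select_band_nodes(t2))
  expect_lt(abs(f1["F12"] - f2["F12"]) / f1["F12"], 0.05)
  expect_lt(abs(f1["F13"] - f2["F13"]) / f1["F13"], 0.05)
})

test_that("single-node reconstructions sum back to the signal", {
  set.seed(7)
  x <- rnorm(512)
  tree <- wpt_decompose(x, 128)
  rec <- Reduce(`+`, lapply(0:31, function(f) {
    wpt_reconstruct_node(tree, wpt_node(tree, 5, f))
  }))
  expect_lt(max(abs(rec - x)), 1e-9)
})
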