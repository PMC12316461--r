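test_that("two-state encoding maps labels through the category map", {
  seq <- behavior_sequence(c("face_sniff", "rear", "still", "approach"),
                           category_map = default_category_map())
  enc <- encode_two_state(seq)
  expect_identical(enc$labels, c("social", "nonsocial", "nonsocial", "social"))
  expect_identical(enc$alphabet, c("social", "nonsocial"))

  all_soc <- behavior_sequence(c("approach", "attack", "flank_sniff"),
                               category_map = default_category_map())
  expect_true(all(encode_two_state(all_soc)$labels == "social"))

  bad <- behavior_sequence(c("approach", "warble"),
                           alphabet = c("approach", "warble"))
  expect_error(encode_two_state(bad, default_category_map()), "warble")
})

test_that("transition counts, probabilities and expected counts are correct", {
  m <- fit_transitions(chars("ABABABA"))
  expect_equal(unname(m$O), matrix(c(0, 3, 3, 0), 2), ignore_attr = TRUE)
  expect_equal(unname(m$P), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  # E oracle: product of margins / N, each margin 3, N = 6
  expect_equal(unname(m$E), matrix(1.5, 2, 2), ignore_attr = TRUE)
  expect_equal(m$N, 6)

  m1 <- fit_transitions(chars("AAAA"))
  expect_equal(dim(m1$O), c(1L, 1L))
  expect_equal(unname(m1$O[1, 1]), 3)
  expect_equal(unname(m1$P[1, 1]), 1)

  expect_error(behavior_sequence("A"), "at least 2")
})

test_that("occupied rows of P are stochastic and tidy() is faithful", {
  set.seed(11)
  for (rep in 1:20) {
    labs <- sample(LETTERS[1:4], 50, replace = TRUE)
    m <- fit_transitions(labs)
    occ <- rowSums(m$O) > 0
    expect_equal(unname(rowSums(m$P)[occ]), rep(1, sum(occ)), tolerance = 1e-12)
    expect_equal(sum(m$E), m$N, tolerance = 1e-9)
    td <- tidy(m)
    expect_equal(sum(td$n_obs), m$N)
    expect_equal(td$n_obs[td$from == labs[1] & td$to == labs[2]],
                 unname(m$O[labs[1], labs[2]]))
  }
})

test_that("G statistic matches term-by-term evaluation and is nonnegative", {
  g <- g_order_test(fit_transitions(chars("ABABABA")))
  expect_equal(g$statistic, 2 * (3 * log(2) + 3 * log(2)), tolerance = 1e-9)
  expect_equal(g$statistic, g_by_hand(chars("ABABABA")), tolerance = 1e-12)
  expect_equal(g$df, 1L)

  # Gibbs inequality: G >= 0 for every input, matching the oracle throughout
  set.seed(42)
  for (rep in 1:30) {
    labs <- sample(c("A", "B", "C"), 40, replace = TRUE)
    g <- g_order_test(fit_transitions(labs))
    expect_gte(g$statistic, 0)
    expect_equal(g$statistic, g_by_hand(labs), tolerance = 1e-9)
    expect_true(g$p_value >= 0 && g$p_value <= 1)
  }
})

test_that("G grows roughly linearly with sequence length for a structured chain", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  g1 <- g_order_test(fit_transitions(gen_markov_sequence(
    markov_spec(P, 2000, seed = 5))))
  g2 <- g_order_test(fit_transitions(gen_markov_sequence(
    markov_spec(P, 4000, seed = 6))))
  expect_gt(g2$statistic / g1$statistic, 1.5)
  expect_lt(g2$statistic / g1$statistic, 2.7)
})

test_that("LRX is zero for identical halves and matches brute force", {
  expect_equal(lrx_stationarity_test(chars("ABABABABABAB"))$statistic, 0,
               tolerance = 1e-12)
  expect_equal(lrx_stationarity_test(chars("AABBAABBAABBAABB"))$statistic, 0,
               tolerance = 1e-12)

  # brute-force oracle over the 2x2x2 terms for ABABAB | AAAAAA
  labs <- chars("ABABABAAAAAA")
  lrx <- lrx_stationarity_test(labs)
  seg1 <- chars("ABABAB")
  seg2 <- chars("AAAAAA")
  count_seg <- function(s) {
    table(factor(s[-length(s)], levels = c("A", "B")),
          factor(s[-1], levels = c("A", "B")))
  }
  fA <- count_seg(seg1)
  fB <- count_seg(seg2)
  pooled <- fA + fB
  p <- pooled / rowSums(pooled)
  brute <- 0
  for (f in list(fA, fB)) {
    pbar <- f / pmax(rowSums(f), 1)
    for (i in 1:2) for (j in 1:2) {
      if (f[i, j] > 0) brute <- brute + f[i, j] * log(pbar[i, j] / p[i, j])
    }
  }
  expect_equal(lrx$statistic, 2 * brute, tolerance = 1e-12)
  expect_equal(lrx$df, 2L)

  # nonnegativity across random sequences
  set.seed(7)
  for (rep in 1:30) {
    labs <- sample(c("A", "B"), 60, replace = TRUE)
    expect_gte(lrx_stationarity_test(labs)$statistic, -1e-12)
  }
})

test_that("odd-length sequences give the first segment the extra bin", {
  lrx <- lrx_stationarity_test(chars("ABABABA"))
  segs <- attr(lrx, "segments")
  expect_equal(segs[[1]]$N, 3)  # 4 bins -> 3 transitions
  expect_equal(segs[[2]]$N, 2)  # 3 bins -> 2 transitions
})

test_that("transition deltas subtract elementwise and flag unoccupied rows", {
  on <- fit_transitions(behavior_sequence(chars("ABABAB"),
                                          alphabet = c("A", "B")))
  off <- fit_transitions(behavior_sequence(chars("AABBAA"),
                                           alphabet = c("A", "B")))
  d <- transition_delta(on, off)
  expect_equal(dim(d), c(2L, 2L))
  expect_equal(d, on$P - off$P)
  # identical sessions -> zero
  expect_true(all(transition_delta(on, on) == 0, na.rm = TRUE))
  # more across-state transitions ON -> positive off-diagonal delta
  expect_gt(d["A", "B"], 0)

  # unoccupied row in one session -> NA row
  off2 <- fit_transitions(behavior_sequence(chars("AAAA"),
                                            alphabet = c("A", "B")))
  d2 <- transition_delta(on, off2)
  expect_true(all(is.na(d2["B", ])))

  off3 <- fit_transitions(behavior_sequence(chars("ABAB"),
                                            alphabet = c("B", "A")))
  expect_error(transition_delta(on, off3), "state order")
})

test_that("mean of per-subject deltas equals delta of mean matrices", {
  set.seed(3)
  deltas <- list()
  ons <- list()
  offs <- list()
  for (i in 1:6) {
    on <- fit_transitions(behavior_sequence(
      sample(c("A", "B"), 80, replace = TRUE), alphabet = c("A", "B")))
    off <- fit_transitions(behavior_sequence(
      sample(c("A", "B"), 80, replace = TRUE), alphabet = c("A", "B")))
    ons[[i]] <- on$P
    offs[[i]] <- off$P
    deltas[[i]] <- transition_delta(on, off)
  }
  mean_of_deltas <- Reduce(`+`, deltas) / 6
  delta_of_means <- Reduce(`+`, ons) / 6 - Reduce(`+`, offs) / 6
  expect_equal(mean_of_deltas, delta_of_means, tolerance = 1e-12)
})

test_that("two-state within/across summary partitions each row", {
  m <- fit_transitions(behavior_sequence(
    c("social", "social", "nonsocial", "social", "nonsocial", "nonsocial"),
    alphabet = c("social", "nonsocial")))
  s <- state_transition_summary(m)
  expect_equal(s$within + s$across, c(1, 1))
  expect_equal(s$within, unname(diag(m$P)))

  alt <- fit_transitions(behavior_sequence(chars("ABABAB"),
                                           alphabet = c("A", "B")))
  expect_equal(state_transition_summary(alt)$across, c(1, 1))

  set.seed(8)
  for (rep in 1:20) {
    labs <- sample(c("A", "B"), 30, replace = TRUE)
    m <- fit_transitions(behavior_sequence(labs, alphabet = c("A", "B")))
    s <- state_transition_summary(m)
    occ <- rowSums(m$O) > 0
    expect_equal((s$within + s$across)[occ], rep(1, sum(occ)),
                 tolerance = 1e-12)
  }

  m3 <- fit_transitions(chars("ABCABC"))
  expect_error(state_transition_summary(m3), "two-state")
})

test_that("multi-label bins resolve by category priority", {
  bins <- list("rear", c("groom", "approach"), c("still", "dig"))
  out <- resolve_multilabel(bins, default_category_map())
  expect_identical(out, c("rear", "approach", "still"))
  out2 <- resolve_multilabel(bins, default_category_map(),
                             priority = c("nonsocial", "social"))
  expect_identical(out2[2], "groom")
})

test_that("long-table import splits by subject and session in bin order", {
  df <- tibble::tibble(
    subject = rep(c("m1", "m2"), each = 4),
    session = "ON",
    bin_index = c(4:1, 1:4),
    state_label = c("rear", "still", "rear", "approach",
                    "groom", "dig", "groom", "dig")
  )
  seqs <- as_behavior_sequences(df, default_category_map())
  expect_length(seqs, 2)
  expect_identical(seqs[["m1.ON"]]$labels,
                   c("approach", "rear", "still", "rear"))
  expect_identical(seqs[["m2.ON"]]$labels, c("groom", "dig", "groom", "dig"))
})
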