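test_that("composition-moment features sum 1-based state positions over L(L-1)", {
  expect_equal(unname(cmv_state_features("HHH")), c(1, 0, 0))   # (1+2+3)/(3*2)
  expect_equal(unname(cmv_state_features("HHHEEC")), c(0.2, 0.3, 0.2))
  expect_error(cmv_state_features("H"), "length >= 2")

  # sum identity: D_H + D_E + D_C = (L+1) / (2(L-1))
  set.seed(8)
  for (L in c(2, 5, 31)) {
    s <- paste(sample(c("H", "E", "C"), L, replace = TRUE), collapse = "")
    expect_equal(sum(cmv_state_features(s)), (L + 1) / (2 * (L - 1)))
  }
})

test_that("max-run features are normalized longest runs", {
  expect_equal(unname(max_run_features("HHHEEC")), c(2 / 6, 3 / 6))
  expect_equal(unname(max_run_features("CCCC")), c(0, 0))
  expect_equal(unname(max_run_features("H")), c(0, 1))
  set.seed(2)
  for (i in 1:5) {
    s <- paste(sample(c("H", "E", "C"), 20, replace = TRUE), collapse = "")
    v <- max_run_features(s)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("motif density counts strand-helix-strand fragments over L-2", {
  expect_equal(motif_feature("EEHHEE"), 1 / 4)      # fragments b a b
  expect_equal(motif_feature("HHHEEC"), 0)          # fragments a b
  expect_equal(motif_feature("CCCCC"), 0)           # empty fragment sequence
  expect_equal(motif_feature("EEHHEEHHEE"), 2 / 8)  # b a b a b: two overlapping bab
  # runs separated by coil do not merge
  expect_equal(motif_feature("EECHHCEE"), 1 / 6)
  # the aba convention counts the complementary motif
  expect_equal(motif_feature("HHEEHH", motif = "aba"), 1 / 4)
  expect_equal(motif_feature("HHEEHH", motif = "bab"), 0)
  expect_error(motif_feature("HE"), "length >= 3")
})

test_that("global probability features are the column means in (C,H,E) order", {
  const <- matrix(rep(c(0.2, 0.5, 0.3), each = 6), 6, 3)
  expect_equal(unname(global_probability_features(const)), c(0.2, 0.5, 0.3))
  one <- matrix(c(0.1, 0.6, 0.3), 1, 3)
  expect_equal(unname(global_probability_features(one)), c(0.1, 0.6, 0.3))
  two <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(unname(global_probability_features(two)), c(0.5, 0.5, 0))
})

test_that("local features partition rows into 8 near-equal blocks, extras first", {
  # L = 8: one-row blocks, output is the matrix flattened row-wise
  m8 <- matrix(runif(24), 8, 3); m8 <- m8 / rowSums(m8)
  expect_equal(unname(local_probability_features(m8)), as.vector(t(m8)))

  const <- matrix(rep(c(0.3, 0.4, 0.3), each = 11), 11, 3)
  expect_equal(unname(local_probability_features(const)),
               rep(c(0.3, 0.4, 0.3), 8))

  # L = 10 -> sizes (2,2,1,1,1,1,1,1); brute-force partition oracle
  set.seed(6)
  m10 <- matrix(runif(30), 10, 3); m10 <- m10 / rowSums(m10)
  sizes <- c(2, 2, 1, 1, 1, 1, 1, 1)
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  oracle <- unlist(lapply(1:8, function(b)
    colMeans(m10[starts[b]:ends[b], , drop = FALSE])))
  expect_equal(unname(local_probability_features(m10)), unname(oracle))

  expect_error(local_probability_features(m10[1:7, ]), "at least 8")
})

test_that("size-weighted local block means reproduce the global means", {
  set.seed(12)
  for (L in c(8, 13, 50)) {
    m <- matrix(rgamma(L * 3, 2), L, 3); m <- m / rowSums(m)
    local <- matrix(local_probability_features(m), nrow = 8, byrow = TRUE)
    sizes <- c(base <- L %/% 8)[1] + as.integer(1:8 <= L %% 8)
    expect_equal(colSums(local * sizes) / L,
                 unname(global_probability_features(m)))
  }
})

test_that("ss_feature_block is the 33-value concatenation, id-invariant", {
  trk <- random_track(20, seed = 3)
  blk <- ss_feature_block(trk)
  expect_length(blk, 33L)
  expect_equal(unname(blk[1:3]), unname(cmv_state_features(trk$states)))
  expect_equal(unname(blk[4:5]), unname(max_run_features(trk$states)))
  expect_equal(unname(blk[6]), motif_feature(trk$states))
  expect_equal(unname(blk[7:9]), unname(global_probability_features(trk$probs)))
  expect_equal(unname(blk[10:33]), unname(local_probability_features(trk$probs)))

  renamed <- ss_track("other_id", trk$states, trk$probs)
  expect_equal(ss_feature_block(renamed), blk)

  # all-coil track with uniform probabilities
  L <- 10
  allc <- make_track(strrep("C", L))
  cblk <- ss_feature_block(allc)
  expect_equal(unname(cblk[1:6]),
               c(0, 0, sum(1:L) / (L * (L - 1)), 0, 0, 0))
  expect_equal(unname(cblk[7:9]), rep(1 / 3, 3))
})
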