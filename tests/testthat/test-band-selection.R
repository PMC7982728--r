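test_that("the screening grid tiles the requested range", {
  g <- subband_grid()
  expect_equal(nrow(g), 19)
  expect_equal(c(g$f_lo[1], g$f_hi[1]), c(2, 4))
  expect_equal(c(g$f_lo[19], g$f_hi[19]), c(38, 40))
  expect_equal(subband_grid(4, 8, 2),
               tibble::tibble(f_lo = c(4, 6), f_hi = c(6, 8)))
  expect_error(subband_grid(2, 40, 3), "divide")
})

test_that("pairwise distance matrices match the scalar primitives", {
  # identical matrices give the zero matrix
  P <- rspd(3)
  D0 <- pairwise_distance_matrix(list(P, P, P))
  expect_equal(max(abs(D0)), 0, tolerance = 1e-8)
  # worked Riemannian pair
  D <- pairwise_distance_matrix(list(diag(2), exp(2) * diag(2)))
  expect_equal(D[1, 2], 2 * sqrt(2), tolerance = 1e-10)
  # random set vs the element-by-element loop, both metrics
  set.seed(51)
  covs <- replicate(5, rspd(4), simplify = FALSE)
  for (metric in c("riemannian", "euclidean")) {
    Dm <- pairwise_distance_matrix(covs, metric)
    fun <- if (metric == "riemannian") riemannian_distance else euclidean_distance
    for (i in 1:5) for (j in 1:5) {
      want <- if (i == j) 0 else fun(covs[[i]], covs[[j]])
      expect_equal(Dm[i, j], want, tolerance = 1e-10)
    }
    expect_equal(Dm, t(Dm))
    expect_equal(diag(Dm), rep(0, 5))
  }
  expect_error(pairwise_distance_matrix(list(P)), "at least 2")
})

test_that("pseudo-F reduces to the classical one-way ANOVA F on scalars", {
  # worked instance: g1 = {0, 1}, g2 = {2, 3}
  D <- as.matrix(dist(c(0, 1, 2, 3)))
  res <- pseudo_f(D, c(1, 1, 2, 2))
  expect_equal(res$F_stat, 8)
  expect_equal(res$SS_A, res$SS_T - res$SS_W)
  # equivalence with aov on random balanced scalar designs
  set.seed(52)
  for (rep in 1:25) {
    a <- sample(2:4, 1); n <- sample(3:8, 1)
    y <- rnorm(a * n); g <- rep(seq_len(a), each = n)
    res <- pseudo_f(as.matrix(dist(y)), g)
    F_aov <- anova(lm(y ~ factor(g)))[["F value"]][1]
    expect_equal(res$F_stat, F_aov, tolerance = 1e-9)
  }
})

test_that("pseudo-F agrees with an independent distance-based MANOVA", {
  skip_if_not_installed("vegan")
  set.seed(53)
  for (rep in 1:5) {
    y <- matrix(rnorm(24 * 3), 24)
    g <- rep(1:3, each = 8)
    d <- dist(y)
    ours <- pseudo_f(as.matrix(d), g)
    ref <- vegan::adonis2(d ~ factor(g), permutations = 2)
    expect_equal(ours$F_stat, ref$F[1], tolerance = 1e-9)
  }
})

test_that("pseudo-F is permutation- and scale-consistent", {
  set.seed(54)
  covs <- replicate(12, rspd(3), simplify = FALSE)
  D <- pairwise_distance_matrix(covs)
  labels <- rep(1:3, each = 4)
  base <- pseudo_f(D, labels)
  # simultaneous permutation of rows/columns and labels leaves F unchanged
  perm <- sample(12)
  expect_equal(pseudo_f(D[perm, perm], labels[perm])$F_stat, base$F_stat,
               tolerance = 1e-12)
  # F is invariant to a global rescaling of the distances
  expect_equal(pseudo_f(3.2 * D, labels)$F_stat, base$F_stat,
               tolerance = 1e-12)
  # SS identity holds against independently accumulated sums
  D2 <- D^2
  ss_t <- sum(D2[upper.tri(D2)]) / 12
  same <- outer(labels, labels, `==`) & upper.tri(D2)
  ss_w <- sum(D2[same]) / 4
  expect_equal(base$SS_A, ss_t - ss_w, tolerance = 1e-9 * max(1, ss_t))
})

test_that("pseudo-F null distribution is centered near 1 under label permutation", {
  set.seed(55)
  y <- rnorm(40)                          # no group effect
  D <- as.matrix(dist(y))
  labels <- rep(1:4, each = 10)
  f <- replicate(1000, pseudo_f(D, sample(labels))$F_stat)
  expect_gt(mean(f), 0.8)
  expect_lt(mean(f), 1.25)
})

test_that("pseudo-F rejects invalid designs", {
  D <- as.matrix(dist(rnorm(5)))
  expect_error(pseudo_f(D, c(1, 1, 1, 2, 2)), "nbalanced design|balanced")
  expect_error(pseudo_f(as.matrix(dist(rnorm(4))), rep(1, 4)), "2 classes")
  # duplicate points across classes: SS_W = 0 gives an infinite F with warning
  Dz <- matrix(0, 4, 4)
  expect_warning(res <- pseudo_f(Dz, c(1, 1, 2, 2)), "infinite")
  expect_true(is.infinite(res$F_stat) || is.nan(res$F_stat))
})

test_that("sub-band scoring recovers a planted discriminative band", {
  set.seed(56)
  cfg <- sim_config(n_classes = 2, trials_per_class = 10, n_channels = 5,
                    duration = 2, class_bands = list(c(8, 12), c(8, 12)),
                    class_gain = c(2.5, 0), seed = 56)
  ep <- simulate_mi_epochs(cfg)
  sc <- score_subbands(ep)
  expect_s3_class(sc, "band_score_table")
  expect_equal(sort(sc$rank), 1:19)
  expect_true(all(sc$SS_T >= sc$SS_W - 1e-9))
  top2 <- sc[sc$rank <= 2, ]
  expect_setequal(top2$f_lo, c(8, 10))
  # identical data with different labels: no separation, F near zero
  dup <- ep
  half <- seq_len(dim(ep)[1] / 2)
  dup$data[half + length(half), , ] <- dup$data[half, , ]
  dup$labels <- rep(1:2, each = length(half))
  sc_dup <- score_subbands(dup)
  expect_lt(max(sc_dup$F_stat), 1e-6)
})

test_that("scoring is covariant under label shuffling (covariances unchanged)", {
  set.seed(57)
  ep <- simulate_mi_epochs(small_sim(57, trials_per_class = 4, n_channels = 4))
  sc1 <- score_subbands(ep, subband_grid(8, 16, 2))
  shuffled <- ep
  shuffled$labels <- with_seed_local(101, sample(ep$labels))
  sc2 <- score_subbands(shuffled, subband_grid(8, 16, 2))
  # same bands, different F values, same SS_T (distances don't see labels)
  expect_equal(sc1$SS_T, sc2$SS_T, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(sc1$F_stat, sc2$F_stat)))
})

test_that("top-G selection and merging behave deterministically", {
  tbl <- tibble::tibble(
    f_lo = seq(2, 38, 2), f_hi = seq(4, 40, 2),
    SS_T = 2, SS_W = 1, SS_A = 1,
    F_stat = c(5, 5, rep(1, 17)))
  ord <- order(-tbl$F_stat, tbl$f_lo)
  tbl$rank <- integer(19); tbl$rank[ord] <- 1:19
  class(tbl) <- c("band_score_table", class(tbl))
  # tie at the top: lower frequency ranked first
  expect_equal(select_top_g(tbl, 1)$f_lo, 2)
  expect_equal(nrow(select_top_g(tbl, 19)), 19)
  expect_error(select_top_g(tbl, 0), "G must")
  expect_error(select_top_g(tbl, 20), "G must")
  # merging fuses shared boundaries only
  m <- merge_adjacent(tibble::tibble(f_lo = c(8, 10, 20), f_hi = c(10, 12, 22)))
  expect_equal(m, tibble::tibble(f_lo = c(8, 20), f_hi = c(12, 22)))
  m2 <- merge_adjacent(tibble::tibble(f_lo = c(8, 14), f_hi = c(10, 16)))
  expect_equal(m2, tibble::tibble(f_lo = c(8, 14), f_hi = c(10, 16)))
  expect_equal(merge_adjacent(subband_grid()), tibble::tibble(f_lo = 2, f_hi = 40))
  # idempotence
  expect_equal(merge_adjacent(m), m)
  expect_error(merge_adjacent(tibble::tibble(f_lo = numeric(),
                                             f_hi = numeric())), "no bands")
})

test_that("multi-scale filter-bank generation enumerates fitting windows", {
  fb <- generate_dmfb(band_window(8, 16))
  expect_equal(nrow(fb$bands), 8)
  expect_equal(fb$bands$f_lo[fb$bands$f_hi - fb$bands$f_lo == 2], c(8, 10, 12, 14))
  expect_equal(fb$bands$f_lo[fb$bands$f_hi - fb$bands$f_lo == 4], c(8, 10, 12))
  expect_equal(fb$bands$f_lo[fb$bands$f_hi - fb$bands$f_lo == 8], 8)
  # a band equal to the smallest width is kept as itself
  expect_equal(nrow(generate_dmfb(band_window(8, 10))$bands), 1)
  # a band narrower than every width degrades to a single window, with a note
  expect_message(fb1 <- generate_dmfb(band_window(8, 9)), "single window")
  expect_equal(nrow(fb1$bands), 1)
  # full default parent range
  expect_equal(nrow(generate_dmfb(band_window(4, 40))$bands), 43)
})
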