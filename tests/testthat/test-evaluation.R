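make_gold <- function(edges, genes = NULL) gold_standard(edges, genes)

test_that("subnetwork sampling produces valid, seeded, edge-bearing sets", {
  edges <- data.frame(source = paste0("g", 1:10),
                      target = paste0("g", c(2:10, 1)))
  gold <- make_gold(edges, paste0("g", 1:20))
  subs <- sample_subnetworks(gold, size = 5, count = 500, seed = 42)
  expect_length(subs, 500)
  expect_true(all(lengths(subs) == 5))
  for (s in subs[1:50]) {
    sub <- subset_gold(gold, s)
    expect_gte(nrow(sub$edges), 1)
  }
  expect_identical(subs, sample_subnetworks(gold, 5, 500, seed = 42))
  expect_false(identical(subs, sample_subnetworks(gold, 5, 500, seed = 43)))
})

test_that("a five-gene universe yields identical subnetworks", {
  gold <- make_gold(data.frame(source = "g1", target = "g2"),
                    paste0("g", 1:5))
  subs <- sample_subnetworks(gold, size = 5, count = 10, seed = 1)
  expect_true(all(vapply(subs, function(s)
    setequal(s, paste0("g", 1:5)), logical(1))))
})

test_that("direction collapse keeps the strongest direction per pair", {
  sc <- score_matrix(matrix(c(0, 5, 1,
                              2, 0, 3,
                              4, 3, 0), 3, byrow = TRUE),
                     c("a", "b", "c"))
  ranked <- collapse_directions(sc)
  expect_equal(nrow(ranked), 3)
  # brute-force: every kept entry is the pairwise maximum
  for (r in seq_len(nrow(ranked))) {
    i <- ranked$source[r]; j <- ranked$target[r]
    expect_equal(ranked$score[r], max(sc[i, j], sc[j, i]))
  }
  # tie keeps the lexicographically smaller source (b-c pair ties at 3)
  bc <- ranked[ranked$score == 3, ]
  expect_equal(bc$source, "b")
  # p = 5 gives C(5,2) = 10 candidates
  sc5 <- score_matrix(matrix(stats::runif(25), 5))
  expect_equal(nrow(collapse_directions(sc5)), 10)
})

test_that("AUPRC reproduces hand-worked and boundary cases", {
  gold <- data.frame(source = c("a", "c"), target = c("b", "d"))
  # positives at ranks 1 and 3 of 4: (1/2) * (1 + 2/3)
  ranking <- data.frame(source = c("a", "b", "c", "d"),
                        target = c("b", "c", "d", "a"),
                        score = c(4, 3, 2, 1))
  expect_equal(auprc(ranking, gold), (1 + 2 / 3) / 2)
  # perfect ranking
  ranking2 <- data.frame(source = c("a", "c", "b", "d"),
                         target = c("b", "d", "c", "a"),
                         score = c(4, 3, 2, 1))
  expect_equal(auprc(ranking2, gold), 1)
  # no positives is undefined
  expect_error(auprc(ranking, data.frame(source = "x", target = "y")),
               "no positives")
})

test_that("AUPRC equals exhaustive prefix enumeration for N <= 6", {
  for (N in 2:6) {
    for (P in 1:(N - 1)) {
      placements <- utils::combn(N, P, simplify = FALSE)
      for (pos in placements) {
        labels <- rep(0, N)
        labels[pos] <- 1
        src <- paste0("s", seq_len(N))
        tgt <- paste0("t", seq_len(N))
        gold <- data.frame(source = src[labels == 1],
                           target = tgt[labels == 1])
        ranking <- data.frame(source = src, target = tgt,
                              score = seq(N, 1))
        expect_equal(auprc(ranking, gold, n_positives = P),
                     oracle_auprc(labels, P))
      }
    }
  }
})

test_that("tied scores average out to the random expectation", {
  # all four candidates tie: expectation equals the exact random baseline
  gold <- data.frame(source = c("a", "c"), target = c("b", "d"))
  ranking <- data.frame(source = c("a", "b", "c", "d"),
                        target = c("b", "c", "d", "a"),
                        score = rep(1, 4))
  got <- auprc(ranking, gold, tie_reps = 2000, seed = 11)
  expect_equal(got, random_baseline_exact(4, 2), tolerance = 0.02)
})

test_that("the exact random baseline matches brute-force enumeration", {
  for (N in 2:8) {
    for (P in c(1, 2, N - 1, N)) {
      if (P < 1 || P > N) next
      expect_equal(random_baseline_exact(N, P),
                   oracle_random_baseline_enum(N, P), tolerance = 1e-12)
    }
  }
  expect_equal(random_baseline_exact(3, 1), (1 + 1 / 2 + 1 / 3) / 3)
  expect_equal(random_baseline_exact(5, 5), 1)
})

test_that("Monte-Carlo baseline agrees with the exact value within 3 SE", {
  for (case in list(c(6, 2), c(8, 3), c(7, 5))) {
    mc <- random_baseline(case[1], case[2], reps = 2000, seed = 5)
    exact <- random_baseline_exact(case[1], case[2])
    expect_lt(abs(as.numeric(mc) - exact), 3 * attr(mc, "se"))
  }
  expect_equal(as.numeric(random_baseline(4, 4, reps = 10, seed = 1)), 1)
  expect_error(random_baseline(3, 4), "exceed")
})

test_that("the random baseline increases with the number of positives", {
  vals <- vapply(1:8, function(P) random_baseline_exact(8, P), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("protocol baseline matches a Monte-Carlo of random score matrices", {
  # independent route: random score matrices, collapsed and ranked
  gold <- make_gold(data.frame(source = c("g1", "g2", "g3"),
                               target = c("g2", "g3", "g4")),
                    paste0("g", 1:5))
  vals <- vapply(1:400, function(r) {
    sc <- lagnet:::with_seed(r, score_matrix(matrix(stats::runif(25), 5),
                                             paste0("g", 1:5)))
    auprc(collapse_directions(sc), gold, seed = r)
  }, numeric(1))
  expect_equal(mean(vals), protocol_baseline(10, 3),
               tolerance = 3 * stats::sd(vals) / sqrt(400))
})

test_that("method comparison flags separations and handles degenerate input", {
  x <- lagnet:::with_seed(1, stats::runif(50))
  expect_warning(compare_methods(list(a = x, b = x)), "zero-variance")
  expect_equal(suppressWarnings(
    compare_methods(list(a = x, b = x))$p_values["a", "b"]), 1)
  y <- x + 0.2 + lagnet:::with_seed(2, rnorm(50, sd = 0.01))
  cm <- compare_methods(list(a = x, b = y))
  expect_true(cm$significant["a", "b"])
  expect_equal(cm$p_values, t(cm$p_values))
  expect_error(compare_methods(list(a = x[1:5], b = x[1:5])), "at least 10")
})

test_that("the paired test matches the textbook t formula", {
  x <- c(0.61, 0.52, 0.45, 0.70, 0.58)
  y <- c(0.55, 0.49, 0.46, 0.61, 0.50)
  d <- x - y
  tstat <- mean(d) / (stats::sd(d) / sqrt(5))
  p_ref <- 2 * stats::pt(-abs(tstat), df = 4)
  cm <- suppressWarnings(compare_methods(list(a = rep(x, 2), b = rep(y, 2))))
  # recompute on the 5-point example directly through t.test
  expect_equal(stats::t.test(x, y, paired = TRUE)$p.value, p_ref)
})

test_that("shuffle control is deterministic and spares static methods", {
  d <- fly_dataset(91, p = 5, n_edges = 5)
  gold <- d$gold
  # identity permutation reproduces the unshuffled run
  a_id <- shuffle_control(d$series, gold, ggm_direct_scores, seed = 3,
                          permutation = seq_len(45))
  a_plain <- auprc(collapse_directions(ggm_direct_scores(d$series)), gold,
                   seed = lagnet:::child_seed(3, "tie"))
  expect_equal(a_id, a_plain)
  # static scores are invariant under any permutation of time points
  perm <- lagnet:::with_seed(5, sample(45))
  shuffled <- d$series
  shuffled$values <- d$series$values[, perm]
  expect_equal(ggm_direct_scores(shuffled), ggm_direct_scores(d$series),
               tolerance = 1e-9)
  expect_identical(shuffle_control(d$series, gold, tl_clr_wrap <- function(s)
    tl_clr_scores(s, 4), seed = 9),
    shuffle_control(d$series, gold, function(s) tl_clr_scores(s, 4),
                    seed = 9))
})

test_that("lag histograms localize planted lags and co-regulation at zero", {
  # planted lag-4 edges: histogram mode at +4
  counts <- NULL
  for (seed in 1:20) {
    d <- simulate_dataset(sim_config(p = 4, n_edges = 3, hub_fraction = 0,
                                     lag_support = 4, lag_probs = 1,
                                     coef_range = c(0.85, 0.95), n = 45,
                                     seed = seed))
    lm <- lagged_mi_matrix(d$series, 6)
    h <- lag_distribution(lm, d$gold, step = 30)
    counts <- if (is.null(counts)) h$count else counts + h$count
  }
  support <- seq(-6, 6)
  expect_equal(support[which.max(counts)], 4)
  # hidden co-regulation: assumed interactions between co-targets pile at 0
  counts0 <- NULL
  for (seed in 1:20) {
    cfg <- sim_config(p = 4, n_edges = 0, hub_fraction = 0,
                      n_confounders = 2, n = 45, seed = seed)
    sim <- simulate_expression(simulate_network(cfg), cfg)
    pairs <- unique(do.call(rbind, lapply(sim$confounder_pairs, function(pr)
      data.frame(source = pr[1], target = pr[2]))))
    pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
    if (nrow(pairs) == 0) next
    gold <- gold_standard(pairs, sim$series$gene_ids)
    lm <- lagged_mi_matrix(sim$series, 6)
    h <- lag_distribution(lm, gold)
    counts0 <- if (is.null(counts0)) h$count else counts0 + h$count
  }
  expect_equal(support[which.max(counts0)], 0)
  # empty gold: all-zero histogram
  d <- fly_dataset(7, p = 4, n_edges = 2)
  lm <- lagged_mi_matrix(d$series, 3)
  h0 <- lag_distribution(lm, gold_standard(
    data.frame(source = character(0), target = character(0)),
    d$series$gene_ids))
  expect_true(all(h0$count == 0))
})

test_that("the benchmark gives an oracle 1.0 and an anti-oracle <= random", {
  d <- fly_dataset(13, p = 8, n_edges = 8)
  adj <- matrix(0, 8, 8, dimnames = list(d$series$gene_ids,
                                         d$series$gene_ids))
  for (e in seq_len(nrow(d$gold$edges)))
    adj[d$gold$edges$source[e], d$gold$edges$target[e]] <- 1
  oracle <- function(series) {
    ids <- series$gene_ids
    score_matrix(adj[ids, ids] + 1e-6 * seq_along(ids), ids)
  }
  anti <- function(series) {
    ids <- series$gene_ids
    score_matrix(1 - adj[ids, ids], ids)
  }
  bm <- suppressWarnings(run_benchmark(d$series, d$gold,
                                       list(oracle = oracle, anti = anti),
                                       size = 5, count = 30, seed = 2))
  expect_equal(unname(bm$mean_auprc["oracle"]), 1)
  expect_lte(unname(bm$mean_auprc["anti"]), bm$random_baseline + 0.05)
  # bit-for-bit reproducibility
  bm2 <- suppressWarnings(run_benchmark(d$series, d$gold,
                                        list(oracle = oracle, anti = anti),
                                        size = 5, count = 30, seed = 2))
  expect_identical(bm$auprc, bm2$auprc)
  expect_identical(bm$random_baseline, bm2$random_baseline)
})

test_that("gold standards reject self-edges and unknown genes", {
  expect_error(gold_standard(data.frame(source = "a", target = "a")),
               "self-edges")
  expect_error(gold_standard(data.frame(source = "a", target = "b"),
                             gene_ids = "a"), "gene_ids")
  g <- gold_standard(data.frame(source = "a", target = "b"))
  expect_equal(nrow(g$edges), 1)
  path <- tempfile(fileext = ".tsv")
  write_gold_tsv(g, path)
  expect_equal(read_gold_tsv(path)$edges$source, "a")
})
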