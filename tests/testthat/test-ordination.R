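test_that("pcoa reconstructs Euclidean configurations exactly", {
  set.seed(3)
  pts <- matrix(rnorm(24), ncol = 2)
  dm <- as.matrix(dist(pts))
  p <- pcoa(dm)
  rec <- as.matrix(dist(p$points))
  expect_equal(rec, dm, tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalue sum identity for Euclidean input
  n <- nrow(dm)
  expect_equal(sum(p$eig), sum(dm^2) / (2 * n), tolerance = 1e-8)
  # agrees with classical MDS
  cmd <- cmdscale(dm, k = 2, eig = TRUE)
  expect_equal(abs(p$points[, 1:2]), abs(cmd$points), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("pcoa handles collinear points and rejects asymmetry", {
  dm <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  p <- pcoa(dm)
  expect_equal(length(p$eig), 1)   # a line: one positive axis
  expect_equal(sort(abs(diff(sort(p$points[, 1])))), c(1, 1), tolerance = 1e-8)
  bad <- dm
  bad[1, 2] <- 5
  expect_error(pcoa(bad), "symmetric")
})

test_that("permanova matches exhaustive enumeration on small instances", {
  set.seed(14)
  for (rep in 1:3) {
    m <- matrix(rexp(6 * 4), nrow = 6)
    dm <- pairwise_distance(m, "bray_curtis")
    g <- factor(rep(c("a", "b"), each = 3))
    res <- permanova(dm, g, complete = TRUE)
    # oracle: enumerate all 20 splits with first-principles pseudo-F
    combos <- combn(6, 3)
    f_all <- apply(combos, 2, function(idx)
      permanova_f_oracle(dm, ifelse(seq_len(6) %in% idx, "a", "b")))
    f_obs <- permanova_f_oracle(dm, g)
    expect_equal(res$pseudo_F, f_obs, tolerance = 1e-10)
    expect_equal(res$p, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
    expect_equal(res$n_permutations, 20)
  }
})

test_that("permanova agrees with vegan::adonis2 on pseudo-F and R2", {
  set.seed(7)
  m <- matrix(rexp(20 * 6), nrow = 20)
  g <- factor(rep(c("a", "b"), each = 10))
  dm <- pairwise_distance(m, "bray_curtis")
  mine <- permanova(dm, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(dm) ~ g, permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-8)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-8)
})

test_that("permanova p-values are uniform under exchangeability", {
  set.seed(17)
  ps <- replicate(150, {
    m <- matrix(rexp(16 * 5), nrow = 16)
    dm <- pairwise_distance(m, "bray_curtis")
    g <- factor(sample(rep(c("a", "b"), each = 8)))
    permanova(dm, g, n_perm = 199, seed = sample.int(1e6, 1))$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permanova floors at 1/(n_perm+1) for disjoint communities", {
  set.seed(23)
  a <- cbind(matrix(rpois(20 * 5, 40), nrow = 20), matrix(0L, 20, 5))
  b <- cbind(matrix(0L, 20, 5), matrix(rpois(20 * 5, 40), nrow = 20))
  dm <- pairwise_distance(rbind(a, b), "bray_curtis")
  g <- factor(rep(c("a", "b"), each = 20))
  res <- permanova(dm, g, n_perm = 999, seed = 1)
  expect_equal(res$p, 0.001)
  expect_error(permanova(dm, factor(c("a", rep("b", 39)))), "at least 2")
})

test_that("cap recovers a saturated constraint and ignores orthogonal columns", {
  set.seed(9)
  xy <- matrix(rnorm(40), ncol = 2)
  dm <- as.matrix(dist(xy))
  res <- cap(dm, data.frame(x = xy[, 1], y = xy[, 2]), n_perm = 49, seed = 1)
  expect_gte(res$constrained_proportion, 0.99)
  expect_true(res$constrained_proportion <= 1 + 1e-12)
  # an added variable can only increase the constrained inertia
  set.seed(10)
  z <- rnorm(20)
  res2 <- cap(dm, data.frame(x = xy[, 1], y = xy[, 2], z = z),
              n_perm = 49, seed = 1)
  expect_gte(res2$constrained_proportion, res$constrained_proportion - 1e-12)
})

test_that("cap agrees with vegan::capscale on the constrained proportion", {
  set.seed(12)
  comm <- matrix(rexp(30 * 8), nrow = 30)
  env <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  dm <- pairwise_distance(comm, "bray_curtis")
  mine <- cap(dm, env, n_perm = 49, seed = 1)
  ref <- vegan::capscale(as.dist(dm) ~ a + b + c, data = env)
  ref_prop <- ref$CCA$tot.chi / (ref$CCA$tot.chi + ref$CA$tot.chi)
  expect_equal(mine$constrained_proportion, ref_prop, tolerance = 1e-6)
})

test_that("cap adjusted R2 is centred near zero for pure-noise constraints", {
  set.seed(19)
  adj <- replicate(30, {
    comm <- matrix(rexp(60 * 10), nrow = 60)
    dm <- pairwise_distance(comm, "bray_curtis")
    env <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
    cap(dm, env, n_perm = 99, seed = sample.int(1e6, 1))$adjusted_R2
  })
  expect_lt(abs(mean(adj)), 0.05)
})

test_that("cap drops collinear columns with a warning", {
  set.seed(25)
  comm <- matrix(rexp(20 * 6), nrow = 20)
  dm <- pairwise_distance(comm, "bray_curtis")
  env <- data.frame(a = rnorm(20))
  env$b <- 2 * env$a
  expect_warning(res <- cap(dm, env, n_perm = 19, seed = 1), "collinear")
  expect_identical(res$dropped_vars, "b")
})

test_that("hierarchical clustering separates synthetic seasons", {
  set.seed(33)
  n <- 30
  dates <- c(as.Date("2016-07-01") + sample(0:60, 15),
             as.Date("2016-01-05") + sample(0:60, 15))
  profile <- rbind(matrix(rep(c(10, 1), each = 15), ncol = 2),
                   matrix(rep(c(1, 10), each = 15), ncol = 2))
  counts <- profile + matrix(rexp(n * 2, 2), ncol = 2)
  dm <- pairwise_distance(counts, "bray_curtis")
  cl <- hierarchical_clusters(dm, dates, k = 2)
  truth <- rep(c("warm", "cold"), each = 15)
  agree <- max(mean(cl$season == truth), mean(cl$season != truth))
  expect_gte(agree, 0.9)
  # k = n gives singletons; labels invariant to input order
  cln <- hierarchical_clusters(dm, dates, k = n)
  expect_equal(length(unique(cln$cluster)), n)
  perm <- sample(n)
  clp <- hierarchical_clusters(dm[perm, perm], dates[perm], k = 2)
  expect_equal(unname(clp$season[order(perm)]), unname(cl$season))
  expect_match(cl$newick, "^\\(")
})
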