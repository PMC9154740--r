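## Four well-separated Gaussian blobs in feature space, used as the
## clustering fixture.
blob_features <- function(n_per = 100, sep = 8, seed = 2) {
  set.seed(seed)
  centers <- matrix(rnorm(4 * 38), 4) * sep
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(n_per * 38), n_per), 2, centers[k, ], "+")))
  colnames(X) <- feature_names()
  list(X = X, truth = rep(1:4, each = n_per))
}

test_that("embedding is deterministic and keeps duplicates together", {
  b <- blob_features(60)
  Y1 <- embed_features(b$X, seed = 3, perplexity = 30, max_iter = 300)
  Y2 <- embed_features(b$X, seed = 3, perplexity = 30, max_iter = 300)
  expect_identical(Y1[, 1:2], Y2[, 1:2])
  ## duplicated rows land near-coincident
  Xd <- rbind(b$X, b$X[1, , drop = FALSE])
  Yd <- embed_features(Xd, seed = 3, perplexity = 30, max_iter = 400)
  d_dup <- sqrt(sum((Yd[1, ] - Yd[241, ])^2))
  med_d <- median(dist(Yd[sample(241, 60), ]))
  expect_lt(d_dup, med_d / 5)
})

test_that("well-separated blobs stay separated in the embedding", {
  skip_if_not_installed("cluster")
  b <- blob_features(75)
  Y <- embed_features(b$X, seed = 1, perplexity = 30, max_iter = 400)
  sil <- cluster::silhouette(b$truth, dist(Y[, 1:2]))
  expect_gt(mean(sil[, 3]), 0.5)
})

test_that("small or degenerate feature tables are rejected", {
  expect_error(embed_features(matrix(rnorm(100 * 38), 100)), "at least 200")
  X <- matrix(1, 300, 38)
  expect_error(embed_features(X), "constant")
  Xz <- blob_features(60)$X
  Xz[, 5] <- 2.5
  expect_warning(embed_features(Xz, seed = 1, max_iter = 50),
                 "zero-variance")
})

## 2-D coordinate blobs: the direct input contract of cluster_states()
blob_coords <- function(n_per = 250, seed = 9) {
  set.seed(seed)
  ctr <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  Y <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(n_per, ctr[k, 1]), rnorm(n_per, ctr[k, 2]))))
  colnames(Y) <- c("tsne1", "tsne2")
  list(Y = Y, truth = rep(1:4, each = n_per))
}

test_that("density peaks recover four blobs; kmeans and polygons agree", {
  b <- blob_coords(250)
  Y <- b$Y
  m <- cluster_states(Y, unassigned_quantile = 0)
  expect_equal(length(unique(m$cluster)), 4L)
  expect_gt(mclust::adjustedRandIndex(m$cluster, b$truth), 0.9)
  mk <- cluster_states(Y, method = "kmeans", n_clusters = 4)
  expect_gt(mclust::adjustedRandIndex(mk$cluster, b$truth), 0.9)
  ## a polygon covering one blob labels exactly that blob
  blob1 <- Y[b$truth == 1, , drop = FALSE]
  pad <- 1
  poly <- cbind(c(min(blob1[, 1]) - pad, max(blob1[, 1]) + pad,
                  max(blob1[, 1]) + pad, min(blob1[, 1]) - pad),
                c(min(blob1[, 2]) - pad, min(blob1[, 2]) - pad,
                  max(blob1[, 2]) + pad, max(blob1[, 2]) + pad))
  mp <- cluster_states(Y, method = "manual_polygons",
                       polygons = list(one = poly))
  inside <- !is.na(mp$cluster)
  expect_gt(mean(inside[b$truth == 1]), 0.95)
})

test_that("a single blob yields a single cluster", {
  set.seed(6)
  Y <- cbind(tsne1 = rnorm(300), tsne2 = rnorm(300))
  m <- cluster_states(Y, unassigned_quantile = 0)
  expect_equal(length(unique(m$cluster)), 1L)
})

test_that("state occupancy is a probability vector over window labels", {
  map <- data.frame(animal_id = "a1", start_s = seq(0, 110, by = 10),
                    tsne1 = 0, tsne2 = 0, cluster = 1L,
                    label = rep(c("rest", "local_search"), 6))
  occ <- state_occupancy(map, "a1", c(0, 140))
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ["rest"]), 0.5)
  map$label <- "rest"
  expect_equal(unname(state_occupancy(map, "a1", c(0, 140))["rest"]), 1)
  set.seed(7)
  map$label <- sample(c("rest", "engorge", "unassigned"), 12, TRUE)
  occ2 <- state_occupancy(map, "a1", c(5, 75))
  keep <- map$start_s < 75 & map$start_s + 30 > 5
  expect_equal(unname(occ2[names(table(map$label[keep]))]),
               as.numeric(table(map$label[keep]) / sum(keep)))
  expect_error(state_occupancy(map, "a1", c(500, 600)), "overlap")
})

test_that("state ethograms report compositions and transition rates", {
  feats <- as.data.frame(matrix(0, 12, 38,
                                dimnames = list(NULL, feature_names())))
  feats$prop_groom <- rep(c(0.8, 0.1), 6)
  map <- data.frame(animal_id = "a1", start_s = seq(0, 110, by = 10),
                    cluster = rep(1:2, 6),
                    label = rep(c("rest", "local_search"), 6))
  se <- state_ethograms(map, feats, step_s = 10)
  expect_equal(unname(se$composition["rest", "prop_groom"]), 0.8)
  ## alternation at every step: rate = 1/step_s
  expect_equal(unname(se$transition_rates["rest", "local_search"]),
               1 / 10 * (6 / 6))
  one <- map; one$label <- "rest"; one$cluster <- 1L
  se1 <- state_ethograms(one, feats, step_s = 10)
  expect_true(all(se1$transition_rates == 0))
})

test_that("cluster naming identifies the four canonical states", {
  ## synthetic profiles with the defining signatures
  n_per <- 50
  mk <- function(vel, fly, probe, walk, groom, none) {
    f <- matrix(0, n_per, 38, dimnames = list(NULL, feature_names()))
    f[, "vel_mean"] <- vel + rnorm(n_per, 0, 0.1)
    f[, "prop_fly"] <- fly; f[, "prop_probe"] <- probe
    f[, "prop_walk"] <- walk; f[, "prop_groom"] <- groom
    f[, "prop_none"] <- none
    f
  }
  feats <- as.data.frame(rbind(
    mk(30, 0.4, 0.08, 0.3, 0.01, 0.2),   # global search: fast, flying
    mk(3, 0.01, 0.5, 0.3, 0.01, 0.18),   # local search: probing while moving
    mk(1, 0.0, 0.01, 0.02, 0.15, 0.8),   # rest: still, grooming
    mk(0.3, 0.0, 0.8, 0.02, 0.01, 0.15)))  # engorge: probing, stationary
  map <- data.frame(animal_id = "x", start_s = seq_len(4 * n_per),
                    cluster = rep(1:4, each = n_per), label = "")
  named <- name_states(map, feats)
  lab <- unique(cbind(map$cluster, named$label))
  expect_equal(named$label[1], "global_search")
  expect_equal(named$label[n_per + 1], "local_search")
  expect_equal(named$label[2 * n_per + 1], "rest")
  expect_equal(named$label[3 * n_per + 1], "engorge")
  ## explicit override wins
  over <- name_states(map, feats, labels = c(`1` = "rest", `2` = "rest",
                                             `3` = "rest", `4` = "engorge"))
  expect_equal(unique(over$label[1:(3 * n_per)]), "rest")
})
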