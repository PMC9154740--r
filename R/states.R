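#' Embed window features in two dimensions
#'
#' Standardizes the feature table (z-score per feature; zero-variance
#' features dropped with a warning) and embeds it with exact t-SNE.
#' The neighborhood bandwidth follows the n/100 perplexity rule: the
#' perplexity is the number of windows divided by 100 unless overridden.
#' Deterministic given the seed.
#'
#' @param features Data frame from [window_features()] (feature columns
#'   are auto-detected) or a plain numeric matrix.
#' @param perplexity Override for the n/100 rule.
#' @param seed Integer RNG seed.
#' @param max_iter Gradient-descent iterations (default 1000).
#' @param eta Learning rate (default 200).
#' @param standardize Z-score features before embedding (default TRUE).
#' @return Numeric matrix `n x 2` of embedding coordinates; the input
#'   `animal_id`/`start_s` columns, when present, are carried in
#'   `attr(, "windows")`.
#' @export
embed_features <- function(features, perplexity = NULL, seed = 0L,
                           max_iter = 1000L, eta = 200,
                           standardize = TRUE) {
  meta <- NULL
  if (is.data.frame(features)) {
    fcols <- intersect(feature_names(), names(features))
    if (!length(fcols)) fcols <- names(features)[vapply(features, is.numeric,
                                                        TRUE)]
    meta <- features[setdiff(names(features), fcols)]
    X <- as.matrix(features[fcols])
  } else X <- as.matrix(features)
  n <- nrow(X)
  if (n < 200) stop("need at least 200 windows to embed (got ", n, ")")
  if (anyNA(X)) stop("features contain missing values")
  if (standardize) {
    sds <- apply(X, 2, sd)
    drop <- sds == 0
    if (all(drop)) stop("all features are constant")
    if (any(drop))
      warning("dropping zero-variance feature(s): ",
              paste(colnames(X)[drop], collapse = ", "))
    X <- scale(X[, !drop, drop = FALSE])
  }
  if (is.null(perplexity)) perplexity <- n / 100
  perplexity <- max(2, min(perplexity, (n - 1) / 3))
  set.seed(seed)
  Y <- .tsne_exact(X, perplexity, as.integer(max_iter), eta)
  colnames(Y) <- c("tsne1", "tsne2")
  attr(Y, "windows") <- meta
  attr(Y, "perplexity") <- perplexity
  Y
}

## Density-peak clustering (local density rho via Gaussian kernel, delta =
## distance to the nearest higher-density point).  Centers are points that
## are simultaneously dense and far from any denser point; automatically,
## those with delta > delta_ratio * dc and rho above the 10th percentile
## (well-separated blobs give centers with delta many times the kernel
## width dc, interior points a fraction of it).
density_peaks <- function(Y, n_clusters = NULL, dc_quantile = 0.02,
                          max_clusters = 12L, delta_ratio = 3) {
  n <- nrow(Y)
  d <- as.matrix(dist(Y))
  dc <- quantile(d[upper.tri(d)], dc_quantile)
  if (dc <= 0) dc <- mean(d) * 1e-3 + 1e-12
  rho <- rowSums(exp(-(d / dc)^2)) - 1
  ord <- order(rho, decreasing = TRUE)
  delta <- numeric(n)
  nn_higher <- integer(n)
  delta[ord[1]] <- max(d[ord[1], ])
  nn_higher[ord[1]] <- ord[1]
  for (k in 2:n) {
    i <- ord[k]
    prev <- ord[1:(k - 1)]
    j <- prev[which.min(d[i, prev])]
    delta[i] <- d[i, j]
    nn_higher[i] <- j
  }
  gamma <- rho * delta
  gord <- order(gamma, decreasing = TRUE)
  auto <- is.null(n_clusters)
  if (auto) {
    cand <- delta > delta_ratio * dc & rho > quantile(rho, 0.1)
    n_clusters <- max(1L, min(sum(cand), max_clusters))
  }
  centers <- gord[seq_len(n_clusters)]
  cl <- integer(n)
  cl[centers] <- seq_len(n_clusters)
  for (k in seq_len(n)) {      # descending density: inherit from parent
    i <- ord[k]
    if (cl[i] == 0L) cl[i] <- cl[nn_higher[i]]
  }
  if (auto && n_clusters > 1) {
    ## genuine modes are separated by a low-density valley; merge center
    ## pairs whose connecting corridor never drops below half their
    ## density (spurious splits of one cloud)
    repeat {
      merged <- FALSE
      cs <- sort(unique(cl))
      for (a in cs) for (b in cs) {
        if (b <= a) next
        ia <- centers[a]; ib <- centers[b]
        seg <- Y[ib, ] - Y[ia, ]
        len <- sqrt(sum(seg^2))
        if (len < 1e-12) next
        rel <- sweep(Y, 2, Y[ia, ])
        t <- (rel[, 1] * seg[1] + rel[, 2] * seg[2]) / len^2
        perp <- abs(rel[, 1] * seg[2] - rel[, 2] * seg[1]) / len
        corridor <- t > 0.1 & t < 0.9 & perp < max(2 * dc, 0.05 * len) &
          (cl == a | cl == b)    # a bridge via a third mode is not a valley
        ## density profile along the path: an empty or sparse slice is a
        ## genuine gap between modes
        slices <- cut(t[corridor], seq(0.1, 0.9, length.out = 9))
        prof <- tapply(rho[corridor], slices, max)
        prof[is.na(prof)] <- 0
        valley <- if (length(prof)) min(prof) else 0
        if (valley > 0.5 * min(rho[ia], rho[ib])) {
          cl[cl == b] <- a
          merged <- TRUE
          break
        }
      }
      if (merged) {
        keep <- sort(unique(cl))
        centers <- centers[keep]
        cl <- match(cl, keep)
      } else break
    }
    n_clusters <- length(unique(cl))
  }
  list(cluster = cl, rho = rho, delta = delta, centers = centers, dc = dc)
}

point_in_polygon <- function(px, py, poly) {
  ## even-odd ray casting
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Cluster embedded windows into behavioral states
#'
#' Segments the 2-D embedding into clusters.  The default is automatic
#' density-peak clustering (reproducible, no manual step); `kmeans` with a
#' given `n_clusters` and a manual-polygon override (the workflow of
#' circling dense groups by hand) are also available.  Windows of low
#' local density are left `unassigned`.
#'
#' @param coords `n x 2` matrix from [embed_features()].
#' @param method `"density_peaks"`, `"kmeans"` or `"manual_polygons"`.
#' @param n_clusters Number of clusters; `NULL` selects automatically at
#'   the largest gap in the density-peak decision statistic.
#' @param polygons For `manual_polygons`: named list of two-column vertex
#'   matrices in embedding coordinates; points in no polygon are
#'   unassigned.
#' @param unassigned_quantile Windows whose local density falls below this
#'   quantile are labeled `unassigned` (default 0.05; density-peaks only).
#' @param seed RNG seed (kmeans restarts).
#' @return A data frame of class `"state_map"` with columns `tsne1`,
#'   `tsne2`, `cluster` (integer, `NA` = unassigned), `label` (cluster as
#'   character, `"unassigned"` for NA), plus any window metadata carried
#'   by the embedding; clustering provenance in `attr(, "provenance")`.
#' @export
cluster_states <- function(coords, method = c("density_peaks", "kmeans",
                                              "manual_polygons"),
                           n_clusters = NULL, polygons = NULL,
                           unassigned_quantile = 0.05, seed = 0L) {
  method <- match.arg(method)
  Y <- coords[, 1:2, drop = FALSE]
  cl <- rep(NA_integer_, nrow(Y))
  if (method == "density_peaks") {
    dp <- density_peaks(Y, n_clusters)
    cl <- dp$cluster
    if (unassigned_quantile > 0) {
      thr <- quantile(dp$rho, unassigned_quantile)
      cl[dp$rho < thr] <- NA_integer_
    }
  } else if (method == "kmeans") {
    if (is.null(n_clusters)) stop("kmeans needs n_clusters")
    set.seed(seed)
    cl <- kmeans(Y, centers = n_clusters, nstart = 10, iter.max = 100)$cluster
  } else {
    if (is.null(polygons) || !length(polygons))
      stop("manual_polygons needs a polygon list")
    for (k in seq_along(polygons)) {
      inside <- point_in_polygon(Y[, 1], Y[, 2], as.matrix(polygons[[k]]))
      cl[inside & is.na(cl)] <- k
    }
    if (all(is.na(cl))) warning("polygons cover no embedded point")
  }
  out <- data.frame(tsne1 = Y[, 1], tsne2 = Y[, 2], cluster = cl,
                    label = ifelse(is.na(cl), "unassigned",
                                   as.character(cl)))
  w <- attr(coords, "windows")
  if (!is.null(w) && nrow(w) == nrow(out)) out <- cbind(w, out)
  attr(out, "provenance") <- list(method = method, n_clusters = n_clusters,
                                  unassigned_quantile = unassigned_quantile,
                                  seed = seed)
  class(out) <- c("state_map", "data.frame")
  out
}

#' Name clusters as behavioral states
#'
#' Assigns the four canonical state names (`global_search`,
#' `local_search`, `rest`, `engorge`) to clusters from their mean feature
#' profiles: global search moves fastest and flies most; local search
#' probes while moving; rest grooms; engorge probes while stationary.
#' When several clusters score as engorge they are merged under one
#' label.  Heuristic name scores can be overridden by passing an explicit
#' `labels` mapping.
#'
#' @param map A `state_map` from [cluster_states()].
#' @param features The [window_features()] table the embedding was built
#'   from (row order must match).
#' @param labels Optional named character vector mapping cluster number
#'   (as character) to state name, bypassing the heuristic.
#' @return The map with its `label` column set to state names.
#' @export
name_states <- function(map, features, labels = NULL) {
  ks <- sort(unique(map$cluster[!is.na(map$cluster)]))
  if (!is.null(labels)) {
    map$label <- ifelse(is.na(map$cluster), "unassigned",
                        unname(labels[as.character(map$cluster)]))
    return(map)
  }
  prof <- t(vapply(ks, function(k) {
    rows <- which(!is.na(map$cluster) & map$cluster == k)
    colMeans(features[rows, feature_names(), drop = FALSE])
  }, numeric(38)))
  ## absolute composition archetypes: rest is still and grooms; global
  ## search flies and moves fast; local search probes while walking;
  ## engorge probes continuously while motionless
  vn <- prof[, "vel_mean"] / max(prof[, "vel_mean"], 1e-9)
  score <- cbind(
    rest = prof[, "prop_none"] + prof[, "prop_groom"] -
      prof[, "prop_probe"] - prof[, "prop_fly"] - prof[, "prop_walk"],
    global_search = 2 * prof[, "prop_fly"] + prof[, "prop_walk"] + vn -
      prof[, "prop_probe"],
    local_search = prof[, "prop_probe"] + prof[, "prop_walk"] -
      prof[, "prop_fly"] - prof[, "prop_none"],
    engorge = prof[, "prop_probe"] - 2 * prof[, "prop_walk"] -
      prof[, "prop_fly"] - vn)
  ## each cluster independently takes its best-matching archetype; several
  ## clusters of the same state (e.g. an engorge state split in two, or a
  ## cutoff-bifurcated rest) merge under one label
  nm <- colnames(score)[apply(score, 1, which.max)]
  lab <- setNames(nm, as.character(ks))
  map$label <- ifelse(is.na(map$cluster), "unassigned",
                      unname(lab[as.character(map$cluster)]))
  map
}

#' Per-state occupancy of a time period
#'
#' Fraction of an animal's windows overlapping the period that carry each
#' state label (unassigned counted separately); fractions sum to 1.
#'
#' @param map A `state_map` whose window metadata includes `animal_id`
#'   and `start_s`.
#' @param animal Animal id.
#' @param period `c(t0, t1)` in seconds.
#' @param length_s Window length used when the features were extracted
#'   (default 30).
#' @return Named numeric vector of occupancy fractions.
#' @export
state_occupancy <- function(map, animal, period, length_s = 30) {
  rows <- map$animal_id == animal &
    map$start_s < period[2] & (map$start_s + length_s) > period[1]
  if (!any(rows)) stop("no windows overlap the period for ", animal)
  tab <- table(map$label[rows])
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' State composition and transition ethograms
#'
#' For each state: the mean behavior proportions of its windows, the mean
#' distance traveled per window, and the inter-state transition rates
#' (consecutive-window label changes per second of time spent in the
#' source state).
#'
#' @param map A `state_map` with `animal_id`/`start_s` metadata.
#' @param features The matching [window_features()] table.
#' @param step_s Window step in seconds (default 10).
#' @param cohort Optional cohort; when given, per-window travel distance
#'   is computed from the tracks.
#' @return List with `composition` (state x behavior proportions),
#'   `transition_rates` (state x state, per second), `travel` (mean
#'   pixels per window, `NA` without tracks), `n_windows`.
#' @export
state_ethograms <- function(map, features, step_s = 10, cohort = NULL) {
  states <- setdiff(unique(map$label), "unassigned")
  if (!length(states)) stop("no assigned windows")
  comp_cols <- paste0("prop_", c(BEHAVIORS, "none"))
  comp <- t(vapply(states, function(s)
    colMeans(features[map$label == s, comp_cols, drop = FALSE]),
    numeric(5)))
  nwin <- vapply(states, function(s) sum(map$label == s), 0)
  ## consecutive-window transitions within each animal
  counts <- matrix(0, length(states), length(states),
                   dimnames = list(states, states))
  for (id in unique(map$animal_id)) {
    rows <- which(map$animal_id == id)
    rows <- rows[order(map$start_s[rows])]
    lab <- map$label[rows]
    ok <- which(lab[-length(lab)] != lab[-1] &
                  lab[-length(lab)] %in% states & lab[-1] %in% states)
    for (i in ok) counts[lab[i], lab[i + 1]] <- counts[lab[i], lab[i + 1]] + 1
  }
  rates <- counts / (nwin * step_s)
  travel <- rep(NA_real_, length(states))
  names(travel) <- states
  if (!is.null(cohort)) {
    dist_w <- vapply(seq_len(nrow(map)), function(i) {
      eth <- cohort$ethograms[[map$animal_id[i]]]
      if (is.null(eth$track)) return(NA_real_)
      a <- as.integer(map$start_s[i] * eth$fps) + 1L
      b <- min(a + as.integer(30 * eth$fps) - 1L, n_frames(eth))
      seg <- eth$track[a:b, , drop = FALSE]
      sum(sqrt(diff(seg[, 1])^2 + diff(seg[, 2])^2), na.rm = TRUE)
    }, 0)
    travel <- vapply(states, function(s)
      mean(dist_w[map$label == s], na.rm = TRUE), 0)
  }
  list(composition = comp, transition_rates = rates, travel = travel,
       n_windows = nwin)
}

#' Window-size robustness of state inference
#'
#' Re-runs feature extraction, embedding and clustering at several window
#' lengths and reports the adjusted Rand agreement of the cluster labels
#' with the reference window length, matched on shared window start
#' times per animal.
#'
#' @param x A `cohort`.
#' @param lengths_s Window lengths to compare (default 10-60 s).
#' @param reference_s Reference length (default 30).
#' @param step_s Step size shared by all runs (default 10).
#' @param seed RNG seed for every embedding.
#' @param ... Passed to [embed_features()].
#' @return Data frame with `length_s` and `ari` against the reference.
#' @export
state_robustness <- function(x, lengths_s = c(10, 20, 30, 45, 60),
                             reference_s = 30, step_s = 10, seed = 0L, ...) {
  run <- function(L) {
    f <- window_features(x, length_s = L, step_s = step_s)
    co <- embed_features(f, seed = seed, ...)
    m <- cluster_states(co)
    data.frame(animal_id = f$animal_id, start_s = f$start_s,
               cluster = m$cluster)
  }
  ref <- run(reference_s)
  out <- lapply(lengths_s, function(L) {
    m <- run(L)
    key <- function(d) paste(d$animal_id, d$start_s)
    common <- intersect(key(ref), key(m))
    a <- ref$cluster[match(common, key(ref))]
    b <- m$cluster[match(common, key(m))]
    ok <- !is.na(a) & !is.na(b)
    data.frame(length_s = L,
               ari = mclust::adjustedRandIndex(a[ok], b[ok]))
  })
  do.call(rbind, out)
}
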