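# Independent oracles used by the tests. Each is a deliberately plain,
# brute-force implementation kept separate from the package's code paths.

# Generalized ESD outlier test, textbook recursion written independently:
# computes all k statistics and critical values up front, then takes the
# largest i with R_i > lambda_i.
oracle_gesd <- function(x, alpha = 0.05, max_k) {
  n <- length(x)
  idx <- seq_len(n)
  removed <- integer(0)
  R <- lambda <- numeric(max_k)
  pool <- x
  pool_idx <- idx
  for (i in seq_len(max_k)) {
    mu <- mean(pool)
    s <- sd(pool)
    if (!is.finite(s) || s == 0) {
      R <- R[seq_len(i - 1)]
      lambda <- lambda[seq_len(i - 1)]
      break
    }
    ad <- abs(pool - mu)
    j <- which.max(ad)
    R[i] <- ad[j] / s
    removed[i] <- pool_idx[j]
    pool <- pool[-j]
    pool_idx <- pool_idx[-j]
    p <- 1 - alpha / (2 * (n - i + 1))
    tq <- qt(p, df = n - i - 1)
    lambda[i] <- (n - i) * tq / sqrt((n - i - 1 + tq^2) * (n - i + 1))
  }
  k_sig <- which(R > lambda)
  n_out <- if (length(k_sig) > 0) max(k_sig) else 0
  sort(removed[seq_len(n_out)])
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(X, y) {
  X <- cbind(1, X)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# All-pairs brute-force semivariogram with haversine distances.
oracle_semivariogram <- function(lon, lat, z, edges) {
  n <- length(z)
  nb <- length(edges) - 1
  ssum <- numeric(nb)
  cnt <- integer(nb)
  hav <- function(i, j) {
    r <- 6378137
    phi1 <- lat[i] * pi / 180; phi2 <- lat[j] * pi / 180
    dphi <- phi2 - phi1; dlam <- (lon[j] - lon[i]) * pi / 180
    a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
    2 * r * asin(pmin(1, sqrt(a))) / 1000
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- hav(i, j)
    b <- findInterval(d, edges, rightmost.closed = TRUE)
    if (b >= 1 && b <= nb) {
      ssum[b] <- ssum[b] + (z[i] - z[j])^2
      cnt[b] <- cnt[b] + 1L
    }
  }
  gamma <- ifelse(cnt > 0, ssum / (2 * cnt), NA_real_)
  list(gamma = gamma, n_pairs = cnt)
}

# Tie-corrected Kruskal-Wallis H from the rank-sum formula.
oracle_kruskal_h <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) -
    3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}

# Tree-walk reconstruction of a forest's node-purity importance: pushes each
# tree's inbag sample down the tree and accumulates the weighted RSS
# decrease of every split, then divides by the number of trees (the
# convention of the reported IncNodePurity).
oracle_node_purity <- function(rf, X, y) {
  purity <- setNames(numeric(ncol(X)), names(X))
  for (t in seq_len(rf$ntree)) {
    tr <- randomForest::getTree(rf, t, labelVar = TRUE)
    w <- rf$inbag[, t]
    node_rows <- vector("list", nrow(tr))
    node_rows[[1]] <- which(w > 0)
    wss <- function(r) {
      ww <- w[r]; yy <- y[r]
      mu <- sum(ww * yy) / sum(ww)
      sum(ww * (yy - mu)^2)
    }
    for (k in seq_len(nrow(tr))) {
      if (tr$status[k] == -1) next
      rows <- node_rows[[k]]
      v <- as.character(tr[["split var"]][k])
      sp <- tr[["split point"]][k]
      left <- rows[X[rows, v] <= sp]
      right <- setdiff(rows, left)
      node_rows[[tr[["left daughter"]][k]]] <- left
      node_rows[[tr[["right daughter"]][k]]] <- right
      purity[v] <- purity[v] + wss(rows) - wss(left) - wss(right)
    }
  }
  purity / rf$ntree
}

# Small valid record table used across tests.
make_records <- function(n = 6, measure = "diversity", biome = "TBMF",
                         value = 10, area = 0.01, upper = 0, lower = 5,
                         month = 1, season = NA_character_, lat = 45,
                         lon = 5) {
  df <- data.frame(
    record_id = sprintf("r%03d", seq_len(n)),
    latitude = rep_len(lat, n), longitude = rep_len(lon, n),
    biome = rep_len(biome, n), measure = rep_len(measure, n),
    value = rep_len(value, n), sample_area_m2 = rep_len(area, n),
    depth_upper_cm = rep_len(upper, n), depth_lower_cm = rep_len(lower, n),
    sampling_month = rep_len(month, n), season = rep_len(season, n),
    stringsAsFactors = FALSE)
  globeseed:::as_seedbank_records(df)
}
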