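test_that("semivariogram equals the all-pairs brute-force definition", {
  # small fixed instance
  lon <- c(0, 1, 2, 0.5, 1.5)
  lat <- c(0, 0.5, 1, 1.5, 0.2)
  z <- c(1, 3, 2, 5, 4)
  edges <- c(0, 60, 120, 200)
  sv <- empirical_semivariogram(data.frame(longitude = lon, latitude = lat),
                                z, bin_edges_km = edges)
  want <- oracle_semivariogram(lon, lat, z, edges)
  expect_equal(sv$gamma, want$gamma)
  expect_equal(sv$n_pairs, want$n_pairs)
  expect_equal(attr(sv, "total_pairs"), sum(want$n_pairs))

  # randomized instances up to n = 50
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    lon <- runif(n, -10, 10); lat <- runif(n, -10, 10); z <- rnorm(n)
    edges <- seq(0, 2000, length.out = 8)
    sv <- empirical_semivariogram(data.frame(longitude = lon,
                                             latitude = lat), z,
                                  bin_edges_km = edges)
    want <- oracle_semivariogram(lon, lat, z, edges)
    expect_equal(sv$gamma, want$gamma, info = paste("draw", rep))
    expect_equal(sv$n_pairs, want$n_pairs, info = paste("draw", rep))
  }
})

test_that("a constant field has zero semivariance in every nonempty bin", {
  set.seed(3)
  sv <- empirical_semivariogram(
    data.frame(longitude = runif(30, 0, 5), latitude = runif(30, 0, 5)),
    rep(2, 30))
  expect_true(all(sv$gamma[sv$n_pairs > 0] == 0))
  expect_error(empirical_semivariogram(data.frame(longitude = 1,
                                                  latitude = 1), 5),
               "at least 2")
  expect_error(empirical_semivariogram(
    data.frame(longitude = c(1, 2), latitude = c(1, 2)), c(1, Inf)),
    "finite")
})

test_that("Kruskal-Wallis matches the tie-corrected rank formula", {
  # {1,2,3} vs {4,5,6} vs {7,8,9}: H = 7.2 with df = 2
  df <- make_records(9, biome = rep(c("TBMF", "TUN", "TGSS"), each = 3),
                     value = 1:9)
  kw <- kruskal_wallis_by_biome(df, "diversity")
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)

  # two groups with identical value multisets: H = 0
  df0 <- make_records(8, biome = rep(c("TBMF", "TUN"), each = 4),
                      value = c(1, 2, 3, 4, 1, 2, 3, 4))
  expect_equal(kruskal_wallis_by_biome(df0, "diversity")$H, 0)

  # seeded small instances (with ties) against the oracle
  set.seed(81)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    sizes <- sample(3:8, k, replace = TRUE)
    vals <- round(rnorm(sum(sizes), 0, 2), 1)  # rounding induces ties
    g <- rep(biome_codes()[seq_len(k)], sizes)
    df <- make_records(sum(sizes), biome = g, value = vals)
    kw <- kruskal_wallis_by_biome(df, "diversity")
    expect_equal(kw$H, oracle_kruskal_h(vals, g), tolerance = 1e-9,
                 info = paste("draw", rep))
  }

  expect_error(kruskal_wallis_by_biome(make_records(5), "diversity"),
               "at least 2 biomes")
})

test_that("hemisphere comparison covers exactly the both-hemisphere
           biomes", {
  north <- make_records(6, biome = rep(c("TBMF", "TUN"), each = 3),
                        value = 1:6, lat = 50)
  # all-northern data: every biome skipped
  hc_n <- hemisphere_comparison(north, "diversity")
  expect_equal(nrow(hc_n$table), 0)
  expect_setequal(hc_n$skipped, c("TBMF", "TUN"))

  south <- make_records(6, biome = rep(c("TBMF", "MGS"), each = 3),
                        value = 2:7, lat = -40)
  south$record_id <- sprintf("s%03d", 1:6)
  both <- rbind(north, south)
  hc <- hemisphere_comparison(both, "diversity")
  expect_equal(hc$table$biome, "TBMF")           # one row per shared biome
  expect_equal(hc$table$n_north, 3)
  expect_equal(hc$table$n_south, 3)
  expect_setequal(hc$skipped, c("TUN", "MGS"))
})

test_that("equal hemispheric distributions are rarely declared different", {
  rejections <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    set.seed(400 + s)
    vals <- rlnorm(40, 2, 0.5)
    df <- make_records(40, biome = "TBMF", value = vals,
                       lat = rep(c(45, -45), 20))
    hc <- hemisphere_comparison(df, "diversity")
    if (hc$table$p_value < 0.05) rejections <- rejections + 1L
  }
  # non-significant in at least 90% of seeds under the null
  expect_lte(rejections, 2L)
})
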