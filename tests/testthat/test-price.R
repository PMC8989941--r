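# Five-component Price partition of pairwise FD differences.

test_that("identical assemblages yield all-zero components", {
  z <- c(a = 0.1, b = 0.2, c = 0.15)
  p <- price_components(z, z)
  expect_equal(unlist(p[c("rich_l", "comp_l", "rich_g", "comp_g", "abun",
                          "delta_fd")]),
               setNames(rep(0, 6), c("rich_l", "comp_l", "rich_g",
                                     "comp_g", "abun", "delta_fd")))
  expect_equal(p$s_c, 3)
})

test_that("an equal-contribution loss is purely random", {
  # drop one species whose z equals the site mean: comp_l must vanish
  zbar <- 0.2
  base <- c(a = zbar, b = zbar, c = zbar)
  comp <- base[c("a", "b")]
  p <- price_components(base, comp)
  expect_equal(p$rich_l, -zbar)
  expect_equal(p$comp_l, 0)
  expect_equal(p$rich_g, 0)
  expect_equal(p$comp_g, 0)
  expect_equal(p$abun, 0)
})

test_that("the 3-vs-3 worked pair reproduces every component", {
  base <- c(A = 0.1, B = 0.2, C = 0.3)
  comp <- c(B = 0.25, C = 0.35, D = 0.4)
  p <- price_components(base, comp)
  expect_equal(p$rich_l, -0.2)
  expect_equal(p$comp_l, 0.1)
  expect_equal(p$rich_g, 1 / 3)
  expect_equal(p$comp_g, 1 / 15)  # ~0.0667
  expect_equal(p$abun, 0.1)
  # the five terms sum to the independent total-difference oracle
  expect_equal(p$delta_fd, sum(comp) - sum(base), tolerance = 1e-14)
  expect_equal(p$delta_fd, 0.4)
  expect_equal(p$rich_l_comp_l, p$rich_l + p$comp_l)
  expect_equal(p$rich_g_comp_g, p$rich_g + p$comp_g)
})

test_that("disjoint assemblages have zero shared-species terms", {
  p <- price_components(c(a = 0.2, b = 0.1), c(x = 0.3, y = 0.4))
  expect_equal(p$s_c, 0)
  expect_equal(p$comp_l, 0)
  expect_equal(p$comp_g, 0)
  expect_equal(p$abun, 0)
  expect_equal(p$delta_fd, 0.4)
})

test_that("fully shared assemblages reduce to the abundance term", {
  zb <- c(a = 0.1, b = 0.2, c = 0.3)
  zc <- c(a = 0.15, b = 0.1, c = 0.45)
  p <- price_components(zb, zc)
  expect_equal(p$rich_l, 0)
  expect_equal(p$comp_l, 0, tolerance = 1e-15)
  expect_equal(p$rich_g, 0)
  expect_equal(p$comp_g, 0, tolerance = 1e-15)
  expect_equal(p$abun, sum(zc) - sum(zb))
})

test_that("all_ordered visits every ordered pair within year and set", {
  counts <- fixture_counts() |> dplyr::filter(site %in% c("s1", "s2", "s3"))
  fd <- suppressWarnings(fd_table(counts, fixture_traits()))
  z <- species_contributions(counts, fd)
  pairs <- price_all_pairs(z)
  expect_equal(nrow(pairs), 6 * 3)  # 3 sites -> 6 ordered pairs x 3 sets
  expect_true(all(pairs$baseline != pairs$comparison))
})

test_that("pair records agree with the scalar partition (dual route)", {
  sim <- simulate_community(sim_config(n_sites = 10, n_species = 12,
                                       seed = 21))
  fd <- suppressWarnings(fd_table(sim$counts, sim$traits,
                                  trait_sets = "diet"))
  z <- species_contributions(sim$counts, fd)
  pairs <- price_all_pairs(z)
  take <- pairs[sample(nrow(pairs), 40), ]
  for (k in seq_len(nrow(take))) {
    rec <- take[k, ]
    zb <- z |>
      dplyr::filter(site == rec$baseline, year == rec$year,
                    trait_set == rec$trait_set)
    zc <- z |>
      dplyr::filter(site == rec$comparison, year == rec$year,
                    trait_set == rec$trait_set)
    # presence in the pipeline is count > 0; use counts as names support
    scalar <- price_components(setNames(pmax(zb$z, 1e-300), zb$species),
                               setNames(pmax(zc$z, 1e-300), zc$species))
    expect_equal(rec$rich_l, scalar$rich_l, tolerance = 1e-12)
    expect_equal(rec$comp_l, scalar$comp_l, tolerance = 1e-12)
    expect_equal(rec$rich_g, scalar$rich_g, tolerance = 1e-12)
    expect_equal(rec$comp_g, scalar$comp_g, tolerance = 1e-12)
    expect_equal(rec$abun, scalar$abun, tolerance = 1e-12)
  }
})

test_that("swapping baseline and comparison negates and mirrors the terms", {
  sim <- simulate_community(sim_config(n_sites = 8, n_species = 10,
                                       seed = 33))
  fd <- suppressWarnings(fd_table(sim$counts, sim$traits,
                                  trait_sets = "comb"))
  z <- species_contributions(sim$counts, fd)
  pairs <- price_all_pairs(z)
  swapped <- pairs |>
    dplyr::rename(baseline = comparison, comparison = baseline)
  merged <- dplyr::inner_join(
    pairs, swapped,
    by = c("year", "trait_set", "baseline", "comparison"),
    suffix = c("", ".sw"))
  expect_equal(merged$delta_fd, -merged$delta_fd.sw)
  expect_equal(merged$rich_l, -merged$rich_g.sw)
  expect_equal(merged$comp_l, -merged$comp_g.sw)
  expect_equal(merged$abun, -merged$abun.sw)
})

test_that("every pair satisfies five-term additivity against the z-sum oracle", {
  sim <- simulate_community(sim_config(n_sites = 10, n_species = 15,
                                       seed = 44))
  fd <- suppressWarnings(fd_table(sim$counts, sim$traits))
  z <- species_contributions(sim$counts, fd)
  pairs <- price_all_pairs(z)
  z_tot <- z |>
    dplyr::group_by(site, year, trait_set) |>
    dplyr::summarise(tot = sum(z), .groups = "drop")
  key_b <- paste(pairs$baseline, pairs$year, pairs$trait_set)
  key_c <- paste(pairs$comparison, pairs$year, pairs$trait_set)
  keys <- paste(z_tot$site, z_tot$year, z_tot$trait_set)
  oracle <- z_tot$tot[match(key_c, keys)] - z_tot$tot[match(key_b, keys)]
  five_sum <- pairs$rich_l + pairs$comp_l + pairs$rich_g + pairs$comp_g +
    pairs$abun
  expect_lt(max(abs(five_sum - oracle)), 1e-10)
  expect_equal(pairs$delta_fd, five_sum)
})

test_that("random_pairs draws a seeded subset and guards its size", {
  sim <- simulate_community(sim_config(n_sites = 6, n_species = 8,
                                       seed = 3, n_years = 1))
  fd <- suppressWarnings(fd_table(sim$counts, sim$traits,
                                  trait_sets = "comb"))
  z <- species_contributions(sim$counts, fd)
  p1 <- price_all_pairs(z, scheme = "random_pairs", n_pairs = 10, seed = 5)
  p2 <- price_all_pairs(z, scheme = "random_pairs", n_pairs = 10, seed = 5)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 10)
  expect_error(
    price_all_pairs(z, scheme = "random_pairs", n_pairs = 10000, seed = 1),
    "exceeds")
})

test_that("aggregates equal brute-force group-bys", {
  sim <- simulate_community(sim_config(n_sites = 7, n_species = 9,
                                       seed = 55))
  fd <- suppressWarnings(fd_table(sim$counts, sim$traits,
                                  trait_sets = "strata"))
  z <- species_contributions(sim$counts, fd)
  pairs <- price_all_pairs(z)
  # single pair aggregates to itself
  one <- pairs[1, ]
  s1 <- price_summary(one)
  expect_equal(s1$mean[s1$component == "rich_l"], one$rich_l)
  expect_equal(s1$n, rep(1, nrow(s1)))
  # duplicating the record list leaves means unchanged
  s2 <- price_summary(dplyr::bind_rows(pairs, pairs))
  s0 <- price_summary(pairs)
  expect_equal(s2$mean, s0$mean)
  # per-site means equal a naive loop
  sm <- price_site_means(pairs)
  for (k in sample(nrow(sm), 10)) {
    row <- sm[k, ]
    sub <- pairs[pairs$comparison == row$site & pairs$year == row$year &
                   pairs$trait_set == row$trait_set, ]
    expect_equal(row$rich_g, mean(sub$rich_g), tolerance = 1e-12)
    expect_equal(row$abun, mean(sub$abun), tolerance = 1e-12)
  }
})
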